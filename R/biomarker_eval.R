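# QMSP quantitation and diagnostic-evaluation statistics.
#
# A QMSP run reports cycle thresholds (Ct) for a methylation-specific
# target and for a methylation-independent beta-actin loading control; the
# standard-curve method interpolates template quantity from Ct, the
# relative methylation level is 100 * target / actin, and detection is
# dichotomized at zero (any signal = methylated). Panels combine markers
# by OR. Diagnostic summaries report sensitivity/specificity with exact
# binomial (Clopper-Pearson) intervals and two-sided Fisher exact tests;
# paired tissue/saliva concordance uses Cohen's kappa and percent
# agreement.

#' Fit a qPCR standard curve
#'
#' Least-squares line `Ct = slope * log10(quantity) + intercept`. A valid
#' amplification curve has negative slope (about -3.3 at 100% efficiency);
#' a nonnegative fitted slope triggers a warning, not an error.
#'
#' @param log10_quantity log10 input quantities of the standards.
#' @param ct measured cycle thresholds.
#' @return list `slope`, `intercept`, `r_squared`, class `standard_curve`.
#' @export
fit_standard_curve <- function(log10_quantity, ct) {
  if (length(unique(log10_quantity)) < 2L) {
    stop("need >= 2 distinct standard quantities")
  }
  fit <- lm(ct ~ log10_quantity)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope >= 0) warning("standard curve slope is nonnegative; curve is not a valid amplification line")
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = slope, intercept = intercept, r_squared = r2),
            class = "standard_curve")
}

#' Interpolate template quantity from Ct
#'
#' `quantity = 10^((ct - intercept) / slope)`; an undetermined Ct (`NA`) or
#' a Ct beyond `max_cycles` is censored to quantity 0 — late amplification
#' is treated as a false-positive signal, not a tiny quantity.
#'
#' @param ct Ct value(s); `NA` = undetermined.
#' @param curve a [fit_standard_curve()] result.
#' @param max_cycles detection limit in cycles (default 38).
#' @return nonnegative quantity (vectorized).
#' @export
quantify <- function(ct, curve, max_cycles = 38) {
  q <- 10^((ct - curve$intercept) / curve$slope)
  q[is.na(ct) | ct > max_cycles] <- 0
  q
}

#' Relative methylation level (ratio to beta-actin x 100)
#'
#' @param q_target target quantity.
#' @param q_actin beta-actin quantity; 0 means the loading control failed
#'   (insufficient / degraded DNA) and the sample is invalid, which is an
#'   error here — it must not be scored as level 0.
#' @return `100 * q_target / q_actin`.
#' @export
relative_level <- function(q_target, q_actin) {
  if (any(q_actin == 0, na.rm = TRUE)) {
    stop("beta-actin did not amplify: invalid sample (not level 0)")
  }
  100 * q_target / q_actin
}

#' Dichotomize a relative methylation level at zero
#'
#' Methylated iff any signal was detected (`level > 0`, strict).
#'
#' @param level nonnegative relative level (vectorized; NA propagates).
#' @return logical: `TRUE` = methylated.
#' @export
dichotomize <- function(level) {
  if (any(level < 0, na.rm = TRUE)) stop("negative relative level")
  level > 0
}

#' Combine per-gene calls into a panel call
#'
#' Any-marker rule: the panel is positive if any member call is positive.
#'
#' @param calls logical vector of per-gene calls for one patient.
#' @return single logical.
#' @export
panel_combine <- function(calls) {
  if (!length(calls)) stop("empty call set")
  any(calls, na.rm = FALSE)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Inverse incomplete-beta bounds: `L = qbeta(alpha/2, x, n-x+1)` (0 when
#' x = 0) and `U = qbeta(1-alpha/2, x+1, n-x)` (1 when x = n).
#'
#' @param x successes, `0 <= x <= n`.
#' @param n trials, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n, x == round(x), n == round(n))
  alpha <- 1 - level
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Minimum-likelihood rule: p is the sum of hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table (with a relative tolerance of 1e-7).
#'
#' Table layout: rows are condition A / condition B, columns positive /
#' negative, i.e. `matrix(c(a, c, b, d), 2)`.
#'
#' @param a,b,c,d nonnegative integer cell counts (a+b = row 1, c+d = row 2).
#' @return two-sided p-value; 1 for the all-zero table.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n == 0) return(1)
  m1 <- a + b          # row 1 total
  k <- a + c           # column 1 total
  support <- max(0, k - (c + d)):min(m1, k)
  probs <- dhyper(support, m1, n - m1, k)
  obs <- dhyper(a, m1, n - m1, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Sensitivity and specificity with exact intervals
#'
#' Sensitivity is the proportion test-positive among diseased, specificity
#' the proportion test-negative among non-diseased; both carry
#' Clopper-Pearson intervals, and a two-sided Fisher exact p for the
#' 2x2 (call x disease) table is attached.
#'
#' @param calls logical test calls, one per patient (`NA` = invalid sample,
#'   excluded from the denominators).
#' @param diseased logical disease labels, same length.
#' @param level confidence level for the intervals.
#' @return list of class `diagnostic_summary`: `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `se_ci`, `sp_ci`, `fisher_p`.
#' @export
sensitivity_specificity <- function(calls, diseased, level = 0.95) {
  stopifnot(length(calls) == length(diseased))
  ok <- !is.na(calls)
  calls <- calls[ok]; diseased <- diseased[ok]
  if (!any(diseased) || !any(!diseased)) {
    stop("need at least one diseased and one control patient")
  }
  tp <- sum(calls & diseased);  fn <- sum(!calls & diseased)
  fp <- sum(calls & !diseased); tn <- sum(!calls & !diseased)
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    se_ci = clopper_pearson(tp, tp + fn, level),
    sp_ci = clopper_pearson(tn, tn + fp, level),
    fisher_p = fisher_exact_2x2(tp, fn, fp, tn)),
    class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("sensitivity %.2f%% (95%% CI %.2f-%.2f), specificity %.2f%% (95%% CI %.2f-%.2f), Fisher p = %.4g\n",
              100 * x$sensitivity, 100 * x$se_ci[1], 100 * x$se_ci[2],
              100 * x$specificity, 100 * x$sp_ci[1], 100 * x$sp_ci[2],
              x$fisher_p))
  invisible(x)
}

#' Cohen's kappa for a paired 2x2 table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o = (a+d)/N` and
#' `p_e = ((a+b)(a+c) + (c+d)(b+d)) / N^2`. The confidence interval uses
#' the large-sample (Fleiss-Cohen-Everitt) asymptotic standard error with
#' normal quantiles. kappa is undefined when `p_e = 1` (both raters
#' constant); that degenerate case errors rather than returning 0.
#'
#' Cell convention: `a` both positive, `b` rater-1 positive only, `c`
#' rater-2 positive only, `d` both negative.
#'
#' @param a,b,c,d paired counts.
#' @param level confidence level.
#' @return list `kappa`, `ci`, `se`, `p_o`, `p_e`.
#' @export
cohen_kappa <- function(a, b, c, d, level = 0.95) {
  n <- a + b + c + d
  if (n < 1) stop("empty table")
  p <- matrix(c(a, b, c, d), 2, byrow = TRUE) / n
  p_o <- p[1, 1] + p[2, 2]
  pr <- rowSums(p); pc <- colSums(p)
  p_e <- sum(pr * pc)
  if (p_e >= 1) stop("kappa undefined: expected agreement is 1 (constant raters)")
  k <- (p_o - p_e) / (1 - p_e)
  t1 <- p[1, 1] * (1 - (pr[1] + pc[1]) * (1 - k))^2 +
        p[2, 2] * (1 - (pr[2] + pc[2]) * (1 - k))^2
  t2 <- (1 - k)^2 * (p[1, 2] * (pc[1] + pr[2])^2 + p[2, 1] * (pc[2] + pr[1])^2)
  t3 <- (k - p_e * (1 - k))^2
  se <- sqrt(max(t1 + t2 - t3, 0)) / ((1 - p_e) * sqrt(n))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(kappa = k, ci = c(lower = k - z * se, upper = k + z * se),
       se = se, p_o = p_o, p_e = p_e)
}

#' Percent agreement of a paired 2x2 table
#'
#' @param a,b,c,d paired counts (see [cohen_kappa()]).
#' @return `100 * (a + d) / N`.
#' @export
percent_agreement <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n < 1) stop("empty table")
  100 * (a + d) / n
}

#' Reconstruct a paired 2x2 table from marginals and agreement
#'
#' Given the number of pairs `n`, the positive counts of each rater and the
#' percent agreement, solves for the unique nonnegative integer table
#' `(a, b, c, d)` with `a+b = pos_a`, `a+c = pos_b` and
#' `a+d = round(n * agreement/100)`. Used to recover published concordance
#' tables from their printed summaries.
#'
#' @param n number of pairs.
#' @param pos_a positives of rater 1 (e.g. saliva).
#' @param pos_b positives of rater 2 (e.g. tissue).
#' @param agreement_percent printed percent agreement.
#' @return integer vector `c(a, b, c, d)`.
#' @export
reconstruct_paired_table <- function(n, pos_a, pos_b, agreement_percent) {
  stopifnot(pos_a >= 0, pos_a <= n, pos_b >= 0, pos_b <= n)
  agree <- round(n * agreement_percent / 100)
  a2 <- pos_a + pos_b + agree - n
  if (a2 %% 2 != 0) stop("no integer solution: parity mismatch")
  a <- a2 / 2
  b <- pos_a - a; c <- pos_b - a; d <- agree - a
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("no nonnegative solution for the given marginals")
  if (abs(percent_agreement(a, b, c, d) - agreement_percent) > 100 / n) {
    stop("reconstructed table does not reproduce the stated agreement")
  }
  as.integer(cells) |> setNames(c("a", "b", "c", "d"))
}

#' Paired Spearman correlation of continuous levels
#'
#' Same estimator as [spearman_meth_expr()] applied to paired relative
#' levels (tissue vs saliva per patient).
#'
#' @param levels_a,levels_b paired nonnegative levels.
#' @param exact exact permutation p for n <= 9.
#' @return list `rho`, `p`, `n`.
#' @export
paired_spearman <- function(levels_a, levels_b, exact = FALSE) {
  spearman_meth_expr(levels_a, levels_b, exact = exact)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((Ct_gene,sample - Ct_ref,sample) - (Ct_gene,cal - Ct_ref,cal))`.
#' With two reference genes the reference Ct is their arithmetic mean.
#'
#' @param ct_gene_sample,ct_gene_calibrator target-gene Ct values.
#' @param ct_ref_sample,ct_ref_calibrator reference Ct values: scalars, or
#'   vectors over multiple reference genes which are averaged.
#' @return fold change relative to the calibrator.
#' @export
ddct_expression <- function(ct_gene_sample, ct_ref_sample,
                            ct_gene_calibrator, ct_ref_calibrator) {
  stopifnot(is.finite(ct_gene_sample), is.finite(ct_ref_sample),
            is.finite(ct_gene_calibrator), is.finite(ct_ref_calibrator))
  d_sample <- ct_gene_sample - mean(ct_ref_sample)
  d_cal <- ct_gene_calibrator - mean(ct_ref_calibrator)
  2^(-(d_sample - d_cal))
}

# ---------------------------------------------------------------------------
# Panel-level evaluation on QMSP tables
# ---------------------------------------------------------------------------

#' Per-sample binary calls from a QMSP table
#'
#' Quantities are taken from the table when present, otherwise interpolated
#' from Ct through `curve`; calls follow [relative_level()] +
#' [dichotomize()]. Samples whose beta-actin failed are returned with `NA`
#' calls (invalid).
#'
#' @param qmsp a `qmsp_table`.
#' @param curve a [fit_standard_curve()] result (needed when quantities are
#'   absent).
#' @param max_cycles Ct detection limit.
#' @return data.frame `sample_id`, `gene`, `relative_level`, `call`.
#' @export
qmsp_calls <- function(qmsp, curve = NULL, max_cycles = 38) {
  qt <- qmsp$quantity_target
  qa <- qmsp$quantity_actin
  if (is.null(qt) || is.null(qa) || anyNA(qa)) {
    if (is.null(curve)) stop("quantities absent: a standard curve is required")
    qt <- quantify(qmsp$ct_target, curve, max_cycles)
    qa <- quantify(qmsp$ct_actin, curve, max_cycles)
  }
  level <- rep(NA_real_, nrow(qmsp))
  valid <- qa > 0
  level[valid] <- 100 * qt[valid] / qa[valid]
  data.frame(sample_id = qmsp$sample_id, gene = qmsp$gene,
             relative_level = level,
             call = ifelse(is.na(level), NA, level > 0),
             stringsAsFactors = FALSE)
}

#' Full diagnostic evaluation of a marker panel
#'
#' Computes, from per-sample QMSP calls and the sample annotation, the
#' per-gene and any-marker panel diagnostic summaries (for the requested
#' specimen), and — when both specimens are present — the per-patient
#' tissue/saliva concordance (kappa, percent agreement, paired Spearman).
#'
#' @param calls output of [qmsp_calls()].
#' @param annotation a `sample_annotation`; disease status is
#'   `group == "tumor"`, pairing across specimens is by `patient_id`.
#' @param genes marker genes of the panel (default: all in `calls`).
#' @param specimen specimen type evaluated for sensitivity/specificity
#'   (default `"saliva"`).
#' @return list with `per_gene` (named list of `diagnostic_summary`),
#'   `panel` (`diagnostic_summary`), `detection_rates` (per-gene and panel
#'   positivity among diseased, as percentages), and `concordance` (named
#'   list per gene plus `"panel"`, each with `table`, `kappa`, `kappa_ci`,
#'   `percent_agreement`, `spearman`), or `NULL` concordance if only one
#'   specimen is present.
#' @export
evaluate_panel <- function(calls, annotation, genes = NULL,
                           specimen = c("saliva", "tissue")) {
  specimen <- match.arg(specimen)
  if (is.null(genes)) genes <- sort(unique(calls$gene))
  ann <- annotation
  calls <- merge(calls, ann[, c("sample_id", "patient_id", "group", "specimen")],
                 by = "sample_id")
  eval_calls <- calls[calls$specimen == specimen & calls$gene %in% genes, ]
  wide <- .calls_wide(eval_calls, genes)
  diseased <- wide$group == "tumor"
  per_gene <- lapply(genes, function(g)
    sensitivity_specificity(wide[[g]], diseased))
  names(per_gene) <- genes
  panel_call <- apply(wide[, genes, drop = FALSE], 1, function(v) {
    if (all(is.na(v))) NA else any(v, na.rm = TRUE)
  })
  panel <- sensitivity_specificity(panel_call, diseased)
  rates <- c(vapply(genes, function(g)
    100 * mean(wide[[g]][diseased], na.rm = TRUE), numeric(1)),
    panel = 100 * mean(panel_call[diseased], na.rm = TRUE))
  conc <- NULL
  if (all(c("tissue", "saliva") %in% calls$specimen)) {
    conc <- .concordance_by_patient(calls, genes)
  }
  list(per_gene = per_gene, panel = panel, detection_rates = rates,
       concordance = conc)
}

.calls_wide <- function(calls, genes) {
  patients <- unique(calls[, c("sample_id", "patient_id", "group")])
  for (g in genes) {
    sub <- calls[calls$gene == g, ]
    patients[[g]] <- sub$call[match(patients$sample_id, sub$sample_id)]
  }
  patients
}

# degenerate tables (constant raters) report NA kappa instead of failing
# the whole evaluation
.kappa_or_na <- function(a, b, c, d) {
  tryCatch(cohen_kappa(a, b, c, d),
           error = function(e) list(kappa = NA_real_,
                                    ci = c(lower = NA_real_, upper = NA_real_)))
}

.concordance_by_patient <- function(calls, genes) {
  tum <- calls[calls$group == "tumor", ]
  out <- list()
  patients <- unique(tum$patient_id)
  panel_sal <- rep(FALSE, length(patients)); panel_tis <- rep(FALSE, length(patients))
  for (g in genes) {
    sal <- tum[tum$gene == g & tum$specimen == "saliva", ]
    tis <- tum[tum$gene == g & tum$specimen == "tissue", ]
    sal <- sal[match(patients, sal$patient_id), ]
    tis <- tis[match(patients, tis$patient_id), ]
    ok <- !is.na(sal$call) & !is.na(tis$call)
    a <- sum(sal$call[ok] & tis$call[ok])
    b <- sum(sal$call[ok] & !tis$call[ok])
    c_ <- sum(!sal$call[ok] & tis$call[ok])
    d <- sum(!sal$call[ok] & !tis$call[ok])
    kap <- .kappa_or_na(a, b, c_, d)
    sp <- tryCatch(paired_spearman(sal$relative_level[ok], tis$relative_level[ok]),
                   error = function(e) list(rho = NA_real_, p = NA_real_))
    out[[g]] <- list(table = c(a = a, b = b, c = c_, d = d),
                     kappa = kap$kappa, kappa_ci = kap$ci,
                     percent_agreement = percent_agreement(a, b, c_, d),
                     spearman = sp)
    panel_sal <- panel_sal | ifelse(is.na(sal$call), FALSE, sal$call)
    panel_tis <- panel_tis | ifelse(is.na(tis$call), FALSE, tis$call)
  }
  a <- sum(panel_sal & panel_tis); b <- sum(panel_sal & !panel_tis)
  c_ <- sum(!panel_sal & panel_tis); d <- sum(!panel_sal & !panel_tis)
  kap <- .kappa_or_na(a, b, c_, d)
  out[["panel"]] <- list(table = c(a = a, b = b, c = c_, d = d),
                         kappa = kap$kappa, kappa_ci = kap$ci,
                         percent_agreement = percent_agreement(a, b, c_, d),
                         spearman = list(rho = NA_real_, p = NA_real_))
  out
}
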