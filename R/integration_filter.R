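# Methylation-expression integration filtering.
#
# Outlier candidates are kept only when promoter methylation is negatively
# correlated with expression across samples (Spearman), the biologically
# expected direction for silencing by promoter hypermethylation. Group
# t-tests and an outlier-presence Fisher test supplement the filter, and
# comparisons can be stratified by HPV status.

#' Spearman rank correlation between methylation and expression
#'
#' rho is the Pearson correlation of midranks; the p-value uses the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 df, two-sided.
#' For n <= 9 an exact permutation p-value is available.
#'
#' @param meth per-sample beta-values.
#' @param expr per-sample expression, same sample order.
#' @param exact if `TRUE` (n <= 9 only), enumerate all permutations for an
#'   exact two-sided p-value on |rho|.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_meth_expr <- function(meth, expr, exact = FALSE) {
  ok <- !is.na(meth) & !is.na(expr)
  x <- meth[ok]; y <- expr[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 paired non-missing samples, got ", n)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("constant vector: Spearman correlation undefined")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 9) stop("exact permutation p only supported for n <= 9")
    p <- .spearman_exact_p(rx, ry)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

# exhaustive permutation distribution of |rho| (Heap's algorithm)
.spearman_exact_p <- function(rx, ry, obs = abs(stats::cor(rx, ry))) {
  n <- length(ry)
  count <- 0L; total <- 0L
  a <- ry
  c_ <- integer(n)
  repeat_rho <- function(perm) abs(stats::cor(rx, perm))
  total <- total + 1L
  if (repeat_rho(a) >= obs - 1e-12) count <- count + 1L
  i <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      if (i %% 2L == 1L) { tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp }
      else { tmp <- a[c_[i] + 1L]; a[c_[i] + 1L] <- a[i]; a[i] <- tmp }
      total <- total + 1L
      if (repeat_rho(a) >= obs - 1e-12) count <- count + 1L
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 0L
      i <- i + 1L
    }
  }
  count / total
}

#' Retain candidates with negative methylation-expression correlation
#'
#' The filter is on the sign of rho only (`rho < 0`, strict); an optional
#' `max_p` additionally requires the correlation p-value to be at most that
#' value. Every record receives a `passed_correlation_filter` flag.
#'
#' @param candidates data.frame with columns `spearman_rho`, `spearman_p`.
#' @param max_p optional p-value ceiling (default none).
#' @return the input with the pass flag set; attribute `"retained"` holds
#'   the filtered subset.
#' @export
correlation_filter <- function(candidates, max_p = NULL) {
  pass <- !is.na(candidates$spearman_rho) & candidates$spearman_rho < 0
  if (!is.null(max_p)) pass <- pass & candidates$spearman_p <= max_p
  candidates$passed_correlation_filter <- pass
  attr(candidates, "retained") <- candidates[pass, , drop = FALSE]
  candidates
}

#' Welch two-sample t-test with direction
#'
#' Two-sided Welch (unequal variance) test; if both groups are constant and
#' equal the degenerate case is reported as statistic 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups two-level factor/character of the same length.
#' @return list `statistic`, `p`, `direction` (sign of mean(a) - mean(b)),
#'   `group_a`, `group_b`.
#' @export
group_ttest <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  lev <- unique(groups)
  if (length(lev) != 2L) stop("need exactly two groups, got ", length(lev))
  a <- values[groups == lev[1]]; b <- values[groups == lev[2]]
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 observations per group")
  dir <- sign(mean(a) - mean(b))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p = 1, direction = 0,
                  group_a = lev[1], group_b = lev[2]))
    }
    return(list(statistic = Inf * dir, p = 0, direction = dir,
                group_a = lev[1], group_b = lev[2]))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value, direction = dir,
       group_a = lev[1], group_b = lev[2])
}

#' Fisher exact test on outlier presence
#'
#' Two-sided Fisher exact p for the 2x2 table (outlier / non-outlier) x
#' (tumor / normal), used when a heterogeneous outlier subset carries the
#' group difference that a t-test misses.
#'
#' @param n_tumor_outliers,n_tumor,n_normal_outliers,n_normal counts.
#' @return two-sided p-value.
#' @export
fisher_outlier_presence <- function(n_tumor_outliers, n_tumor,
                                    n_normal_outliers, n_normal) {
  stopifnot(n_tumor_outliers >= 0, n_normal_outliers >= 0,
            n_tumor_outliers <= n_tumor, n_normal_outliers <= n_normal)
  fisher_exact_2x2(n_tumor_outliers, n_tumor - n_tumor_outliers,
                   n_normal_outliers, n_normal - n_normal_outliers)
}

#' HPV positivity call from viral copy number
#'
#' Positive at >= 1 copy per genome per cell (inclusive boundary).
#'
#' @param copy_number nonnegative copies/genome/cell (vectorized).
#' @return `"positive"` / `"negative"` character vector.
#' @export
hpv_call <- function(copy_number) {
  if (any(copy_number < 0, na.rm = TRUE)) stop("negative copy number")
  ifelse(copy_number >= 1, "positive", "negative")
}

#' Per-gene group comparisons stratified by HPV status
#'
#' Runs Welch t-tests per gene for the contrasts tumor vs normal,
#' HPV- tumor vs normal, HPV+ tumor vs normal, and HPV- vs HPV+ tumor.
#' Contrasts with an empty (or singleton) stratum are skipped with a
#' message.
#'
#' @param x a `feature_matrix` (methylation or expression).
#' @param annotation a `sample_annotation` with `hpv_status` filled for the
#'   tumors.
#' @return long `data.frame`: `gene`, `contrast`, `statistic`, `p`,
#'   `direction`.
#' @export
stratified_comparisons <- function(x, annotation) {
  x <- align_samples(x, annotation)
  ann <- annotation[match(colnames(x), annotation$sample_id), ]
  strata <- list(
    tumor_vs_normal    = list(a = ann$group == "tumor", b = ann$group == "normal"),
    hpvneg_vs_normal   = list(a = ann$group == "tumor" & ann$hpv_status == "negative",
                              b = ann$group == "normal"),
    hpvpos_vs_normal   = list(a = ann$group == "tumor" & ann$hpv_status == "positive",
                              b = ann$group == "normal"),
    hpvneg_vs_hpvpos   = list(a = ann$group == "tumor" & ann$hpv_status == "negative",
                              b = ann$group == "tumor" & ann$hpv_status == "positive"))
  rows <- list()
  for (cn in names(strata)) {
    s <- strata[[cn]]
    if (sum(s$a) < 2L || sum(s$b) < 2L) {
      message("skipping contrast ", cn, ": stratum with < 2 samples")
      next
    }
    grp <- ifelse(s$a, "a", ifelse(s$b, "b", NA_character_))
    for (g in rownames(x)) {
      tt <- group_ttest(unclass(x)[g, ], grp)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, contrast = cn, statistic = tt$statistic, p = tt$p,
        direction = tt$direction, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(gene = character(), contrast = character(),
                                       statistic = numeric(), p = numeric(),
                                       direction = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the candidate table (screen scores + integration statistics)
#'
#' For each screened candidate gene present in the expression matrix,
#' computes the methylation-expression Spearman correlation over tumor
#' samples plus normals, the tumor-vs-normal and HPV[-]-vs-normal Welch
#' t-tests on methylation, and (when the gene has outlier calls) the
#' outlier-presence Fisher p. Genes whose correlation is undefined
#' (constant vectors) are flagged with `NA` rho rather than dropped
#' silently.
#'
#' @param screen result of [screen_genes()] (or a selected subset).
#' @param meth gene-level [meth_matrix()].
#' @param expr [expr_matrix()] (one row per gene).
#' @param annotation a `sample_annotation`.
#' @param max_p optional correlation p ceiling passed to
#'   [correlation_filter()].
#' @param bh_adjust if `TRUE`, append a Benjamini-Hochberg adjusted
#'   correlation p column (`spearman_p_bh`) as auxiliary output.
#' @return `data.frame` of candidate records with
#'   `passed_correlation_filter` flags, ranked by descending score.
#' @export
integrate_candidates <- function(screen, meth, expr, annotation,
                                 max_p = NULL, bh_adjust = FALSE) {
  genes <- intersect(screen$gene, rownames(expr))
  dropped <- setdiff(screen$gene, genes)
  if (length(dropped)) {
    message(length(dropped), " candidate gene(s) missing from expression matrix")
  }
  m <- align_samples(meth, annotation)
  e <- align_samples(expr, annotation)
  shared <- intersect(colnames(m), colnames(e))
  ann <- annotation[match(shared, annotation$sample_id), ]
  is_tumor <- ann$group == "tumor"
  is_hpvneg <- is_tumor & ann$hpv_status == "negative"
  n_tumor <- sum(is_tumor); n_normal <- sum(!is_tumor)
  rows <- lapply(genes, function(g) {
    mv <- unclass(m)[g, shared]; ev <- unclass(e)[g, shared]
    sp <- tryCatch(spearman_meth_expr(mv, ev),
                   error = function(err) list(rho = NA_real_, p = NA_real_, n = NA_integer_))
    tt_all <- tryCatch(group_ttest(mv, ann$group), error = function(err) list(p = NA_real_))
    tt_neg <- if (sum(is_hpvneg) >= 2L && n_normal >= 2L) {
      grp <- ifelse(is_hpvneg, "hpvneg", ifelse(!is_tumor, "normal", NA))
      tryCatch(group_ttest(mv, grp), error = function(err) list(p = NA_real_))
    } else list(p = NA_real_)
    srow <- screen[match(g, screen$gene), ]
    fp <- if (!is.na(srow$n_outliers)) {
      fisher_outlier_presence(srow$n_outliers, n_tumor, 0L, n_normal)
    } else NA_real_
    data.frame(gene = g, outlier_score = srow$score, tail = srow$tail,
               spearman_rho = sp$rho, spearman_p = sp$p,
               ttest_p_all = tt_all$p, ttest_p_hpvneg = tt_neg$p,
               fisher_outlier_p = fp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$outlier_score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out <- correlation_filter(out, max_p = max_p)
  if (bh_adjust) out$spearman_p_bh <- stats::p.adjust(out$spearman_p, "BH")
  out
}
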