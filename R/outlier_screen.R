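# Rank-sum outlier screening of methylation beta-values.
#
# The statistic targets genes altered in only a *subset* of tumors (the
# COPA regime): a per-gene baseline cutoff is derived from the normal
# samples (Tukey fence with a minimum-change floor), tumor samples beyond
# the cutoff are flagged as outliers, and the gene score sums the joint
# ranks of the flagged tumors normalized by the number of usable samples.

#' Outlier screening configuration
#'
#' @param delta_min minimum beta change (in \[0,1\]) for an outlier call;
#'   the cutoff is floored at `median(normals) +/- delta_min`. Default 0.10:
#'   methylation changes under 10% are not considered biologically
#'   meaningful.
#' @param fence_k Tukey fence multiplier on the normal IQR. Default 1.5.
#' @param tail `"right"` (hypermethylated outliers), `"left"`
#'   (hypomethylated) or `"both"`.
#' @param score_cutoff optional score threshold for candidate selection.
#' @param top_k optional number of top-scoring genes to select (ties with
#'   the k-th score are included). At most one of `score_cutoff` / `top_k`.
#' @param n_permutations permutations for the empirical null; 0 disables.
#' @param seed integer seed for the permutation generator.
#' @return an `outlier_config` list.
#' @export
outlier_config <- function(delta_min = 0.10, fence_k = 1.5,
                           tail = c("both", "right", "left"),
                           score_cutoff = NULL, top_k = NULL,
                           n_permutations = 0L, seed = 1L) {
  tail <- match.arg(tail)
  stopifnot(delta_min >= 0, delta_min <= 1, fence_k >= 0, n_permutations >= 0)
  if (!is.null(score_cutoff) && !is.null(top_k)) {
    stop("use exactly one of score_cutoff / top_k for selection")
  }
  structure(list(delta_min = delta_min, fence_k = fence_k, tail = tail,
                 score_cutoff = score_cutoff, top_k = top_k,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "outlier_config")
}

#' Beta-value from unmethylated/methylated intensities
#'
#' beta = M / (U + M), the proportion of methylated signal. Undefined
#' (returned as `NA`) when both intensities are zero.
#'
#' @param unmeth nonnegative unmethylated intensity U (vectorized).
#' @param meth nonnegative methylated intensity M.
#' @return beta in \[0,1\], `NA` where U + M = 0.
#' @export
compute_beta <- function(unmeth, meth) {
  if (any(unmeth < 0, na.rm = TRUE) || any(meth < 0, na.rm = TRUE)) {
    stop("negative intensity")
  }
  total <- unmeth + meth
  ifelse(total == 0, NA_real_, meth / total)
}

#' Collapse probe-level beta-values to gene level
#'
#' Per gene and sample the gene-level beta is the maximum over that gene's
#' probes, ignoring missing probes; the result is missing only when every
#' probe is missing. The max convention keeps the strongest promoter signal
#' and matches how sparse-probe platforms are usually summarized for
#' hypermethylation screens.
#'
#' @param probe_matrix [meth_matrix()] with `level = "probe"`.
#' @param map data.frame with columns `probe_id`, `gene_id` (many probes to
#'   one gene; every probe row must be mapped).
#' @return a gene-level [meth_matrix()].
#' @export
aggregate_probes <- function(probe_matrix, map) {
  stopifnot(inherits(probe_matrix, "meth_matrix"))
  if (attr(probe_matrix, "level") != "probe") stop("matrix is not probe-level")
  if (anyDuplicated(map$probe_id)) stop("a probe maps to more than one gene")
  idx <- match(rownames(probe_matrix), map$probe_id)
  if (anyNA(idx)) {
    stop("unmapped probe id(s): ",
         paste(head(rownames(probe_matrix)[is.na(idx)], 3), collapse = ", "))
  }
  gene <- map$gene_id[idx]
  dt <- data.table::as.data.table(unclass(probe_matrix))
  data.table::set(dt, j = ".gene_id", value = gene)
  maxna <- function(v) { v <- v[!is.na(v)]; if (length(v)) max(v) else NA_real_ }
  agg <- dt[, lapply(.SD, maxna), by = ".gene_id"]
  m <- as.matrix(agg[, setdiff(names(agg), ".gene_id"), with = FALSE])
  rownames(m) <- agg$.gene_id
  meth_matrix(m, level = "gene")
}

#' Normal-derived baseline cutoff for outlier calls
#'
#' Right tail: `max(q75 + fence_k * IQR, median + delta_min)`; left tail is
#' the mirror `min(q25 - fence_k * IQR, median - delta_min)`. Quartiles use
#' the type-7 (linear interpolation) convention. The `delta_min` floor
#' guarantees any called outlier differs from a typical normal sample by at
#' least that much beta.
#'
#' @param normal_values beta-values of the normal group (NA allowed).
#' @param config an [outlier_config()].
#' @param tail `"right"` or `"left"`.
#' @return the cutoff beta (may fall outside \[0,1\], in which case no
#'   sample can be flagged on that tail).
#' @export
baseline_cutoff <- function(normal_values, config = outlier_config(),
                            tail = c("right", "left")) {
  tail <- match.arg(tail)
  v <- normal_values[!is.na(normal_values)]
  if (length(v) < 3) stop("need >= 3 non-missing normal values, got ", length(v))
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  if (tail == "right") {
    max(q[3] + config$fence_k * iqr, q[2] + config$delta_min)
  } else {
    min(q[1] - config$fence_k * iqr, q[2] - config$delta_min)
  }
}

#' Flag tumor samples beyond the baseline cutoff
#'
#' Strict inequality: a value exactly at the cutoff is not an outlier.
#' Missing values are never flagged.
#'
#' @param tumor_values named vector of tumor beta-values.
#' @param cutoff from [baseline_cutoff()].
#' @param tail `"right"` or `"left"`.
#' @return logical vector (same names), `FALSE` where missing.
#' @export
call_outliers <- function(tumor_values, cutoff, tail = c("right", "left")) {
  tail <- match.arg(tail)
  flag <- if (tail == "right") tumor_values > cutoff else tumor_values < cutoff
  flag[is.na(flag)] <- FALSE
  flag
}

#' Normalized rank-sum outlier score
#'
#' Ranks are computed jointly over all non-missing samples (tumor and
#' normal) with midranks for ties; the score is the sum of ranks of the
#' flagged tumor samples divided by the number of ranked samples. Zero iff
#' no sample is flagged.
#'
#' @param values beta-values for all samples of one gene.
#' @param is_tumor logical, same length.
#' @param flagged logical over the tumor samples (i.e. over
#'   `values[is_tumor]`), as returned by [call_outliers()].
#' @return nonnegative score.
#' @export
rank_sum_score <- function(values, is_tumor, flagged) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0L) return(0)
  r <- rank(values[ok], ties.method = "average")
  # position of each tumor sample within the non-missing subset
  tumor_ok <- is_tumor & ok
  fl <- logical(length(values))
  fl[is_tumor] <- flagged
  sum(r[match(which(tumor_ok & fl), which(ok))]) / n
}

.score_one_tail <- function(values, is_tumor, config, tail) {
  normals <- values[!is_tumor]
  cutoff <- baseline_cutoff(normals, config, tail)
  flagged <- call_outliers(values[is_tumor], cutoff, tail)
  score <- rank_sum_score(values, is_tumor, flagged)
  list(cutoff = cutoff, flagged = flagged, score = score)
}

#' Permutation p-value for a gene's outlier score
#'
#' Class labels are permuted; per permutation the baseline cutoff is
#' recomputed from the permuted "normal" group and the score recomputed.
#' Add-one estimator: `p = (1 + #\{S_perm >= S_obs\}) / (1 + B)`.
#'
#' @param values beta-values for all samples of one gene.
#' @param is_tumor logical group labels.
#' @param config an [outlier_config()] with `n_permutations >= 1`.
#' @param tail `"right"` or `"left"`.
#' @return p-value in (0, 1\].
#' @export
permutation_null <- function(values, is_tumor, config, tail = c("right", "left")) {
  tail <- match.arg(tail)
  b <- config$n_permutations
  if (b < 1L) stop("n_permutations must be >= 1")
  obs <- .score_one_tail(values, is_tumor, config, tail)$score
  n <- length(values)
  perm_scores <- vapply(seq_len(b), function(i) {
    lab <- sample(is_tumor)
    .score_one_tail(values, lab, config, tail)$score
  }, numeric(1))
  (1 + sum(perm_scores >= obs)) / (1 + b)
}

#' Screen all genes for methylation outliers
#'
#' Scores every gene on the requested tail(s) against the normal-derived
#' baseline and returns one row per gene, ranked by descending score (for
#' `tail = "both"`, the better-scoring tail is reported, with both tail
#' scores kept as columns).
#'
#' @param meth gene-level [meth_matrix()].
#' @param annotation [as_sample_annotation()] table covering the matrix
#'   columns; both tumor and normal groups must be present.
#' @param config an [outlier_config()].
#' @return `data.frame` with columns `gene`, `tail`, `score`, `cutoff`,
#'   `n_outliers`, `outlier_samples` (comma-separated ids),
#'   `score_right`, `score_left`, and `permutation_p` when permutations are
#'   requested; ordered by descending score.
#' @export
screen_genes <- function(meth, annotation, config = outlier_config()) {
  x <- align_samples(meth, annotation)
  ann <- annotation[match(colnames(x), annotation$sample_id), ]
  is_tumor <- ann$group == "tumor"
  if (!any(is_tumor) || !any(!is_tumor)) {
    stop("annotation must contain both tumor and normal samples")
  }
  tails <- if (config$tail == "both") c("right", "left") else config$tail
  if (config$n_permutations > 0L) set.seed(config$seed)
  res <- lapply(rownames(x), function(g) {
    v <- unclass(x)[g, ]
    per_tail <- lapply(tails, function(tl) .score_one_tail(v, is_tumor, config, tl))
    scores <- vapply(per_tail, `[[`, numeric(1), "score")
    best <- which.max(scores)
    bt <- per_tail[[best]]
    out_ids <- colnames(x)[is_tumor][bt$flagged]
    row <- data.frame(
      gene = g, tail = tails[best], score = scores[best],
      cutoff = bt$cutoff, n_outliers = length(out_ids),
      outlier_samples = paste(out_ids, collapse = ","),
      score_right = if ("right" %in% tails) scores[match("right", tails)] else NA_real_,
      score_left = if ("left" %in% tails) scores[match("left", tails)] else NA_real_,
      stringsAsFactors = FALSE)
    if (config$n_permutations > 0L) {
      row$permutation_p <- permutation_null(v, is_tumor, config, tails[best])
    }
    row
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("outlier_screen", "data.frame")
  out
}

#' Select top candidates from a screen
#'
#' Either all genes with `score >= score_cutoff`, or the `top_k` genes with
#' every gene tied at the k-th score included. Genes with score 0 (no
#' outlier samples at all) are never selected: they carry no evidence, and
#' under `top_k` the zero-score tie block would otherwise swallow the whole
#' gene list.
#'
#' @param screen result of [screen_genes()].
#' @param config an [outlier_config()] carrying `score_cutoff` or `top_k`.
#' @return the selected subset, still ranked.
#' @export
select_candidates <- function(screen, config) {
  nonzero <- screen[screen$score > 0, , drop = FALSE]
  if (!is.null(config$score_cutoff)) {
    nonzero[nonzero$score >= config$score_cutoff, , drop = FALSE]
  } else if (!is.null(config$top_k)) {
    k <- min(config$top_k, nrow(nonzero))
    if (k == 0L) return(nonzero[0, , drop = FALSE])
    thr <- sort(nonzero$score, decreasing = TRUE)[k]
    nonzero[nonzero$score >= thr, , drop = FALSE]
  } else {
    stop("config must set score_cutoff or top_k to select candidates")
  }
}
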