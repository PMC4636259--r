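# Fixture builders and independent oracles shared across test files.

make_matrix <- function(values, genes = sprintf("g%d", seq_len(nrow(values))),
                        samples = sprintf("s%d", seq_len(ncol(values)))) {
  m <- matrix(values, nrow = length(genes),
              dimnames = list(genes, samples))
  m
}

tiny_annotation <- function(n_tumor = 3, n_normal = 3) {
  ids <- c(sprintf("T%d", seq_len(n_tumor)), sprintf("N%d", seq_len(n_normal)))
  as_sample_annotation(data.frame(
    sample_id = ids, patient_id = ids,
    group = rep(c("tumor", "normal"), c(n_tumor, n_normal)),
    specimen = "tissue", stringsAsFactors = FALSE))
}

# Independent brute-force oracle for the rank-sum outlier score:
# sort all non-missing values, assign midranks by explicit tie-group
# averaging, sum ranks of flagged tumors, divide by count.
oracle_rank_sum <- function(values, is_tumor, flagged) {
  ok <- !is.na(values)
  v <- values[ok]
  n <- length(v)
  if (n == 0) return(0)
  ord <- order(v)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && v[ord[j + 1]] == v[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  fl_all <- logical(length(values))
  fl_all[which(is_tumor)] <- flagged
  sum(r[fl_all[ok]]) / n
}

# Clopper-Pearson oracle: bisection on the binomial tail equations.
oracle_cp_bisect <- function(x, n, level = 0.95, tol = 1e-9) {
  alpha <- 1 - level
  lower <- if (x == 0) 0 else {
    f <- function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2
    stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = tol)$root
  }
  upper <- if (x == n) 1 else {
    f <- function(p) stats::pbinom(x, n, p) - alpha / 2
    stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = tol)$root
  }
  c(lower, upper)
}

# QMSP fixture encoding chosen per-patient tissue call patterns for three
# markers; counts is a named vector over the 8 patterns "+++", "++-", ...
qmsp_from_patterns <- function(counts, genes = c("ZNF14", "ZNF160", "ZNF420"),
                               n_controls = 31) {
  rows <- list(); ann <- list()
  add <- function(sid, pid, grp, pattern) {
    for (k in seq_along(genes)) {
      pos <- substr(pattern, k, k) == "+"
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sid, gene = genes[k],
        ct_target = if (pos) 30 else NA_real_, ct_actin = 29.9,
        quantity_target = if (pos) 5 else 0, quantity_actin = 100,
        stringsAsFactors = FALSE)
    }
    ann[[length(ann) + 1L]] <<- data.frame(
      sample_id = sid, patient_id = pid, group = grp, specimen = "tissue",
      stringsAsFactors = FALSE)
  }
  i <- 0
  for (pattern in names(counts)) {
    for (rep in seq_len(counts[[pattern]])) {
      i <- i + 1
      add(sprintf("P%03d_T", i), sprintf("P%03d", i), "tumor", pattern)
    }
  }
  for (j in seq_len(n_controls)) {
    add(sprintf("C%03d_T", j), sprintf("C%03d", j), "normal", "---")
  }
  list(qmsp = as_qmsp_table(do.call(rbind, rows)),
       annotation = as_sample_annotation(do.call(rbind, ann)))
}

# Table 2/3 tissue pattern counts: marginals 26/23/19, any = 34, all three
# positive in 10 patients.
table3_tissue_patterns <- c("+++" = 10, "++-" = 6, "+-+" = 5, "-++" = 3,
                            "+--" = 5, "-+-" = 4, "--+" = 1, "---" = 25)
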