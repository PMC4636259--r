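test_that("compute_beta follows M/(U+M) with degenerate denominator", {
  expect_equal(compute_beta(25, 75), 0.75)
  expect_equal(compute_beta(1000, 0), 0)
  expect_true(is.na(compute_beta(0, 0)))
  expect_equal(compute_beta(c(25, 0), c(75, 0)), c(0.75, NA))
  expect_error(compute_beta(-1, 5), "negative")
})

test_that("aggregate_probes takes the per-gene max over non-missing probes", {
  probes <- meth_matrix(make_matrix(
    matrix(c(0.10, 0.40, 0.20, NA,
             NA,   0.15, 0.30, 0.05), ncol = 2),
    genes = c("p1", "p2", "p3", "p4"), samples = c("s1", "s2")), "probe")
  map <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    gene_id = c("A", "A", "A", "B"))
  g <- aggregate_probes(probes, map)
  expect_equal(nrow(g), 2L)
  expect_equal(unclass(g)["A", "s1"], 0.40)
  expect_equal(unclass(g)["A", "s2"], 0.30)  # max over non-missing
  expect_true(is.na(unclass(g)["B", "s1"]))
  expect_equal(unclass(g)["B", "s2"], 0.05)

  map_bad <- map[-1, ]
  expect_error(aggregate_probes(probes, map_bad), "unmapped")

  # structural check on a scaled platform-like fixture: row count equals
  # the distinct-gene count of the map (many-to-one collapse)
  set.seed(9)
  n_probes <- 300; n_genes_map <- 157
  big <- meth_matrix(make_matrix(matrix(runif(n_probes * 3), n_probes),
                                 genes = sprintf("cg%03d", 1:n_probes)), "probe")
  bigmap <- data.frame(probe_id = sprintf("cg%03d", 1:n_probes),
                       gene_id = sprintf("G%03d",
                                         sample.int(n_genes_map, n_probes, TRUE)))
  agg <- aggregate_probes(big, bigmap)
  expect_equal(nrow(agg), length(unique(bigmap$gene_id)))
})

test_that("baseline_cutoff applies the Tukey fence with a delta floor", {
  cfg <- outlier_config(delta_min = 0.1, fence_k = 1.5)
  # IQR = 0: the floor binds
  expect_equal(baseline_cutoff(rep(0.03, 5), cfg, "right"), 0.13)
  # hand-computed type-7 quartiles: q75=0.3, IQR=0.2, median=0.2
  expect_equal(baseline_cutoff(c(0.0, 0.1, 0.2, 0.3, 0.4), cfg, "right"), 0.6)
  # left-tail mirror of the floor case
  expect_equal(baseline_cutoff(rep(0.9, 5), cfg, "left"), 0.8)
  expect_error(baseline_cutoff(c(0.1, NA, NA, 0.2), cfg, "right"), ">= 3")
})

test_that("call_outliers uses strict inequality and never flags missing", {
  flags <- call_outliers(c(0.05, 0.08, 0.30), 0.13, "right")
  expect_equal(flags, c(FALSE, FALSE, TRUE))
  expect_false(any(call_outliers(c(0.01, 0.1), 0.13, "right")))
  expect_false(call_outliers(0.13, 0.13, "right"))  # boundary: not flagged
  expect_false(call_outliers(NA_real_, 0.13, "right"))
  expect_true(call_outliers(0.01, 0.13, "left"))
})

test_that("rank_sum_score matches hand-computed examples", {
  # tumors hold ranks 5 and 6 of N = 6
  v <- c(0.5, 0.6, 0.1, 0.2, 0.3, 0.4)
  is_t <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(rank_sum_score(v, is_t, c(TRUE, TRUE)), 11 / 6)
  expect_equal(rank_sum_score(v, is_t, c(FALSE, FALSE)), 0)
  # tied top pair shares midrank 5.5
  v2 <- c(0.6, 0.6, 0.1, 0.2, 0.3, 0.4)
  expect_equal(rank_sum_score(v2, is_t, c(TRUE, TRUE)), 11 / 6)
})

test_that("rank_sum_score equals the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(2:8, 1)
    v <- round(runif(n), 2)           # rounding forces frequent ties
    v[runif(n) < 0.15] <- NA
    is_t <- runif(n) < 0.5
    if (!any(is_t)) is_t[1] <- TRUE
    flagged <- runif(sum(is_t)) < 0.5
    expect_equal(rank_sum_score(v, is_t, flagged),
                 oracle_rank_sum(v, is_t, flagged))
  }
})

test_that("score properties: flag monotonicity, delta_min monotonicity, permutation invariance", {
  set.seed(7)
  for (i in 1:25) {
    n <- 12
    v <- runif(n)
    is_t <- rep(c(TRUE, FALSE), each = 6)
    # adding flags at top ranks never decreases S
    tumor_order <- order(v[is_t], decreasing = TRUE)
    s_prev <- 0
    for (k in 0:6) {
      fl <- logical(6); fl[tumor_order[seq_len(k)]] <- TRUE
      s <- rank_sum_score(v, is_t, fl)
      expect_gte(s, s_prev)
      s_prev <- s
    }
    # raising delta_min never increases the score
    ann <- tiny_annotation(6, 6)
    m <- meth_matrix(make_matrix(matrix(v / 2 + 0.2, 1),
                                 samples = ann$sample_id), "gene")
    s_small <- screen_genes(m, ann, outlier_config(delta_min = 0.05))$score
    s_big <- screen_genes(m, ann, outlier_config(delta_min = 0.30))$score
    expect_lte(s_big, s_small)
    # within-group sample permutation leaves the score unchanged
    perm <- c(sample(1:6), sample(7:12))
    m2 <- meth_matrix(make_matrix(matrix((v / 2 + 0.2)[perm], 1),
                                  samples = ann$sample_id[perm]), "gene")
    expect_equal(screen_genes(m2, ann, outlier_config())$score,
                 screen_genes(m, ann, outlier_config())$score)
  }
})

test_that("permutation_null is deterministic under a seed and near 1 for S = 0", {
  set.seed(33)
  v <- c(runif(10, 0, 0.06), runif(8, 0, 0.06))
  is_t <- rep(c(TRUE, FALSE), c(10, 8))
  cfg <- outlier_config(n_permutations = 99, seed = 5)
  set.seed(cfg$seed); p1 <- permutation_null(v, is_t, cfg, "right")
  set.seed(cfg$seed); p2 <- permutation_null(v, is_t, cfg, "right")
  expect_identical(p1, p2)
  # a gene with no outliers has observed S = 0 <= every permuted S
  expect_equal(p1, 1, tolerance = 0.02)
  expect_error(permutation_null(v, is_t, outlier_config(), "right"), "n_permutations")
})

test_that("screen_genes ranks planted outlier genes first and handles edge cases", {
  co <- generate_discovery_cohort(cohort_spec(n_genes = 120, n_signal_genes = 8,
                                              seed = 11))
  sc <- screen_genes(co$meth, co$annotation, outlier_config())
  expect_s3_class(sc, "outlier_screen")
  expect_equal(sort(sc$score, decreasing = TRUE), sc$score)
  expect_true(all(co$truth$gene %in% head(sc$gene, 8)))
  # outlier samples are tumors, and score = 0 iff no outliers
  expect_true(all(sc$n_outliers[sc$score > 0] > 0))
  expect_true(all(sc$score[sc$n_outliers == 0] == 0))
  flagged <- unlist(strsplit(sc$outlier_samples[sc$score > 0], ","))
  tumors <- co$annotation$sample_id[co$annotation$group == "tumor"]
  expect_true(all(flagged %in% tumors))

  # constant gene scores 0 and ranks last
  vals <- unclass(co$meth)
  vals["G0120", ] <- 0.05
  m2 <- meth_matrix(vals, "gene")
  sc2 <- screen_genes(m2, co$annotation, outlier_config())
  expect_equal(sc2$score[sc2$gene == "G0120"], 0)

  ann_all_tumor <- co$annotation
  ann_all_tumor$group <- "tumor"
  expect_error(screen_genes(co$meth, as_sample_annotation(ann_all_tumor),
                            outlier_config()), "both tumor and normal")
})

test_that("select_candidates honors cutoff, top_k with ties, and drops score-0 genes", {
  sc <- data.frame(gene = letters[1:6], tail = "right",
                   score = c(5, 4, 4, 3, 0, 0), cutoff = 0.1,
                   n_outliers = c(3, 2, 2, 1, 0, 0),
                   outlier_samples = "", stringsAsFactors = FALSE)
  expect_equal(select_candidates(sc, outlier_config(score_cutoff = 4))$gene,
               c("a", "b", "c"))
  # k = 2 but the 2nd score (4) is tied -> 3 genes
  expect_equal(select_candidates(sc, outlier_config(top_k = 2))$gene,
               c("a", "b", "c"))
  # zero scores never selected even with huge k
  expect_equal(nrow(select_candidates(sc, outlier_config(top_k = 100))), 4L)
  expect_error(select_candidates(sc, outlier_config()), "score_cutoff or top_k")
  expect_error(outlier_config(score_cutoff = 1, top_k = 5), "exactly one")
})
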