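# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: normals with low, tight beta distributions; tumors in which a
# heterogeneous subset is hypermethylated; expression negatively coupled
# to methylation; and paired tissue/saliva QMSP assays in which saliva
# positivity is conditional on tissue positivity and controls carry no
# signal at all (the 100%-specificity regime).

#' Specification for a synthetic discovery cohort
#'
#' Defaults emulate the discovery design: 44 tumors vs 25 normals, normal
#' betas tight around 0.03 so per-gene normal means stay at or below ~0.06,
#' a 30% heterogeneous tumor subset hypermethylated by 0.3 beta at signal
#' genes, expression coupled to methylation with slope -5 (log-scale units
#' per unit beta) and unit noise, ~30% HPV-positive tumors with the signal
#' attenuated by half in HPV+ (hypermethylation concentrates in HPV-
#' disease).
#'
#' @param n_tumor,n_normal group sizes.
#' @param n_genes total genes simulated.
#' @param n_signal_genes number of planted hypermethylated-outlier genes.
#' @param outlier_fraction fraction `f` of tumors shifted at a signal gene.
#' @param effect_delta beta shift of the affected tumors.
#' @param normal_beta_mean,normal_beta_sd baseline beta distribution
#'   (clipped Gaussian; switchable to Beta with `beta_noise = "beta"`,
#'   moment-matched).
#' @param expr_coupling_slope negative slope of expression on beta.
#' @param expr_noise_sd expression noise SD (log-scale units).
#' @param expr_intercept baseline expression level.
#' @param hpv_pos_fraction fraction of tumors HPV-positive.
#' @param hpv_effect_ratio multiplicative attenuation of `effect_delta` in
#'   HPV+ tumors (0 = no signal in HPV+, 1 = no attenuation).
#' @param beta_noise `"gaussian"` (clipped) or `"beta"`.
#' @param seed integer seed; same seed gives bit-identical cohorts.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_tumor = 44L, n_normal = 25L, n_genes = 500L,
                        n_signal_genes = 25L, outlier_fraction = 0.3,
                        effect_delta = 0.3, normal_beta_mean = 0.03,
                        normal_beta_sd = 0.02, expr_coupling_slope = -5,
                        expr_noise_sd = 1, expr_intercept = 8,
                        hpv_pos_fraction = 0.3, hpv_effect_ratio = 0.5,
                        beta_noise = c("gaussian", "beta"), seed = 1L) {
  stopifnot(n_signal_genes <= n_genes,
            outlier_fraction >= 0, outlier_fraction <= 1,
            effect_delta >= 0, effect_delta <= 1,
            hpv_pos_fraction >= 0, hpv_pos_fraction <= 1,
            hpv_effect_ratio >= 0, hpv_effect_ratio <= 1,
            expr_coupling_slope <= 0, expr_noise_sd > 0)
  structure(list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
                 n_genes = as.integer(n_genes),
                 n_signal_genes = as.integer(n_signal_genes),
                 outlier_fraction = outlier_fraction, effect_delta = effect_delta,
                 normal_beta_mean = normal_beta_mean, normal_beta_sd = normal_beta_sd,
                 expr_coupling_slope = expr_coupling_slope,
                 expr_noise_sd = expr_noise_sd, expr_intercept = expr_intercept,
                 hpv_pos_fraction = hpv_pos_fraction,
                 hpv_effect_ratio = hpv_effect_ratio,
                 beta_noise = match.arg(beta_noise), seed = as.integer(seed)),
            class = "cohort_spec")
}

.rbeta_noise <- function(n, mean, sd, kind) {
  if (kind == "gaussian") {
    pmin(pmax(rnorm(n, mean, sd), 0), 1)
  } else {
    # moment-matched Beta(alpha, beta)
    v <- sd^2
    nu <- mean * (1 - mean) / v - 1
    stats::rbeta(n, mean * nu, (1 - mean) * nu)
  }
}

#' Generate a synthetic discovery cohort
#'
#' @param spec a [cohort_spec()].
#' @return list: `meth` ([meth_matrix()]), `expr` ([expr_matrix()]),
#'   `annotation` (`sample_annotation`), `truth` (data.frame of signal
#'   genes with their comma-separated outlier tumor sample ids).
#' @export
generate_discovery_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  nt <- spec$n_tumor; nn <- spec$n_normal; ng <- spec$n_genes
  samples <- c(sprintf("T%03d", seq_len(nt)), sprintf("N%03d", seq_len(nn)))
  genes <- sprintf("G%04d", seq_len(ng))
  hpv_pos <- runif(nt) < spec$hpv_pos_fraction
  beta <- matrix(.rbeta_noise(ng * (nt + nn), spec$normal_beta_mean,
                              spec$normal_beta_sd, spec$beta_noise),
                 nrow = ng, dimnames = list(genes, samples))
  signal_genes <- genes[seq_len(spec$n_signal_genes)]
  truth_outliers <- character(length(signal_genes))
  for (i in seq_along(signal_genes)) {
    affected <- runif(nt) < spec$outlier_fraction
    shift <- spec$effect_delta * ifelse(hpv_pos, spec$hpv_effect_ratio, 1)
    beta[signal_genes[i], seq_len(nt)][affected] <-
      pmin(beta[signal_genes[i], seq_len(nt)][affected] + shift[affected], 1)
    truth_outliers[i] <- paste(samples[seq_len(nt)][affected], collapse = ",")
  }
  expr <- spec$expr_intercept + spec$expr_coupling_slope * beta +
    matrix(rnorm(ng * (nt + nn), 0, spec$expr_noise_sd), nrow = ng)
  dimnames(expr) <- dimnames(beta)
  ann <- as_sample_annotation(data.frame(
    sample_id = samples,
    patient_id = samples,
    group = rep(c("tumor", "normal"), c(nt, nn)),
    specimen = "tissue",
    hpv_copy_number = c(ifelse(hpv_pos, 10, 0), rep(0, nn)),
    stringsAsFactors = FALSE))
  list(meth = meth_matrix(beta, level = "gene"),
       expr = expr_matrix(expr),
       annotation = ann,
       truth = data.frame(gene = signal_genes, outlier_samples = truth_outliers,
                          stringsAsFactors = FALSE))
}

#' Specification for a synthetic paired QMSP validation assay
#'
#' Defaults emulate the validation design: 59 cases with paired tissue and
#' saliva, 35 saliva controls and 31 tissue controls; per-gene tissue
#' positivity rates around 32-44%; saliva positivity only via a conditional
#' sensitivity given tissue positivity; controls never positive (forcing
#' 100% specificity on every seed).
#'
#' @param n_cases,n_controls cohort sizes (controls are simulated for both
#'   specimens: `n_controls` saliva and `n_controls_tissue` tissue).
#' @param n_controls_tissue tissue controls (default 31).
#' @param tissue_positive_rate named per-gene tissue positivity rates.
#' @param saliva_sensitivity_given_tissue named per-gene conditional saliva
#'   positivity given tissue positivity.
#' @param patient_correlation Gaussian-copula correlation of tissue
#'   positivity across genes within a patient (default 0.7, calibrated so
#'   the any-marker tissue rate implied by the per-gene rates matches the
#'   observed regime where markers co-occur in the same patients).
#' @param saliva_correlation copula correlation of the conditional saliva
#'   events across genes (default 0.9: whether a tumor sheds DNA into
#'   saliva is largely a patient property, so saliva positives overlap
#'   heavily across markers).
#' @param level_scale log-normal scale (median) of positive relative levels.
#' @param level_sdlog log-normal sdlog of positive levels.
#' @param curve_slope,curve_intercept standard curve used to back-compute
#'   Ct values so `quantify()` round-trips the planted quantities.
#' @param actin_quantity loading-control quantity for valid samples.
#' @param seed integer seed.
#' @return a `paired_assay_spec` list.
#' @export
paired_assay_spec <- function(n_cases = 59L, n_controls = 35L,
                              n_controls_tissue = 31L,
                              tissue_positive_rate = c(ZNF14 = 0.441,
                                                       ZNF160 = 0.390,
                                                       ZNF420 = 0.322),
                              saliva_sensitivity_given_tissue = c(ZNF14 = 0.19,
                                                                  ZNF160 = 0.43,
                                                                  ZNF420 = 0.42),
                              patient_correlation = 0.7,
                              saliva_correlation = 0.9,
                              level_scale = 5, level_sdlog = 0.8,
                              curve_slope = -3.3, curve_intercept = 36.5,
                              actin_quantity = 100, seed = 1L) {
  stopifnot(all(tissue_positive_rate >= 0 & tissue_positive_rate <= 1),
            all(saliva_sensitivity_given_tissue >= 0 &
                  saliva_sensitivity_given_tissue <= 1),
            identical(names(tissue_positive_rate),
                      names(saliva_sensitivity_given_tissue)),
            patient_correlation >= 0, patient_correlation <= 1,
            saliva_correlation >= 0, saliva_correlation <= 1,
            level_scale > 0, curve_slope < 0)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_controls_tissue = as.integer(n_controls_tissue),
                 tissue_positive_rate = tissue_positive_rate,
                 saliva_sensitivity_given_tissue = saliva_sensitivity_given_tissue,
                 patient_correlation = patient_correlation,
                 saliva_correlation = saliva_correlation,
                 saliva_false_rate_controls = 0,  # controls carry no signal, by design
                 level_scale = level_scale, level_sdlog = level_sdlog,
                 curve_slope = curve_slope, curve_intercept = curve_intercept,
                 actin_quantity = actin_quantity, seed = as.integer(seed)),
            class = "paired_assay_spec")
}

#' Generate a synthetic paired QMSP validation assay
#'
#' Positive relative levels are drawn log-normal (truncated below at 0.5 so
#' every planted positive stays within the 38-cycle detection window) and
#' Ct values are back-computed through the spec's standard curve, so that
#' `quantify()` with `fit_standard_curve()` reproduces the planted
#' quantities.
#'
#' @param spec a [paired_assay_spec()].
#' @return list: `qmsp` (a `qmsp_table` covering both specimens), `annotation`
#'   (`sample_annotation`), `truth` (per patient/gene planted tissue and
#'   saliva positivity).
#' @export
generate_validation_assay <- function(spec) {
  stopifnot(inherits(spec, "paired_assay_spec"))
  set.seed(spec$seed)
  genes <- names(spec$tissue_positive_rate)
  curve <- structure(list(slope = spec$curve_slope,
                          intercept = spec$curve_intercept, r_squared = 1),
                     class = "standard_curve")
  ct_of <- function(q) ifelse(q > 0, curve$intercept + curve$slope * log10(q), NA_real_)
  rows <- list(); truth <- list()
  add_row <- function(sid, gene, q_target) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sid, gene = gene,
      ct_target = ct_of(q_target), ct_actin = ct_of(spec$actin_quantity),
      quantity_target = q_target, quantity_actin = spec$actin_quantity,
      stringsAsFactors = FALSE)
  }
  rlevel <- function() max(rlnorm(1, log(spec$level_scale), spec$level_sdlog), 0.5)
  rt <- spec$patient_correlation; rs <- spec$saliva_correlation
  for (i in seq_len(spec$n_cases)) {
    pid <- sprintf("P%03d", i)
    # patient-level latent factors couple positivity across genes
    z_tis <- rnorm(1); z_sal <- rnorm(1)
    for (g in genes) {
      x <- sqrt(rt) * z_tis + sqrt(1 - rt) * rnorm(1)
      tis_pos <- x < stats::qnorm(spec$tissue_positive_rate[[g]])
      v <- sqrt(rs) * z_sal + sqrt(1 - rs) * rnorm(1)
      sal_pos <- tis_pos &&
        v < stats::qnorm(spec$saliva_sensitivity_given_tissue[[g]])
      q_tis <- if (tis_pos) rlevel() * spec$actin_quantity / 100 else 0
      q_sal <- if (sal_pos) rlevel() * spec$actin_quantity / 100 else 0
      add_row(paste0(pid, "_T"), g, q_tis)
      add_row(paste0(pid, "_S"), g, q_sal)
      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = pid, gene = g, tissue_positive = tis_pos,
        saliva_positive = sal_pos, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(spec$n_controls)) {
    for (g in genes) add_row(sprintf("C%03d_S", i), g, 0)
  }
  for (i in seq_len(spec$n_controls_tissue)) {
    for (g in genes) add_row(sprintf("C%03d_T", i + spec$n_controls), g, 0)
  }
  qmsp <- as_qmsp_table(do.call(rbind, rows))
  sid <- unique(qmsp$sample_id)
  ann <- as_sample_annotation(data.frame(
    sample_id = sid,
    patient_id = sub("_[TS]$", "", sid),
    group = ifelse(grepl("^P", sid), "tumor", "normal"),
    specimen = ifelse(grepl("_T$", sid), "tissue", "saliva"),
    stringsAsFactors = FALSE))
  list(qmsp = qmsp, annotation = ann, truth = do.call(rbind, truth),
       curve = curve)
}

#' Write a complete fixture bundle to disk
#'
#' Emits the discovery matrices and annotation, the validation QMSP table
#' and annotation, the truth tables, the generating specs (JSON) and a
#' MANIFEST listing every file with its md5 checksum. Stable across runs
#' for a fixed seed.
#'
#' @param outdir output directory (created if absent).
#' @param discovery_spec a [cohort_spec()].
#' @param assay_spec a [paired_assay_spec()].
#' @return character vector of written paths (invisibly); the MANIFEST is
#'   `MANIFEST.tsv` in `outdir`.
#' @export
write_fixture_bundle <- function(outdir, discovery_spec = cohort_spec(),
                                 assay_spec = paired_assay_spec(
                                   seed = discovery_spec$seed)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  disc <- generate_discovery_cohort(discovery_spec)
  val <- generate_validation_assay(assay_spec)
  paths <- c(
    meth = file.path(outdir, "discovery_meth.tsv"),
    expr = file.path(outdir, "discovery_expr.tsv"),
    disc_annot = file.path(outdir, "discovery_annotation.tsv"),
    disc_truth = file.path(outdir, "discovery_truth.tsv"),
    qmsp = file.path(outdir, "validation_qmsp.tsv"),
    val_annot = file.path(outdir, "validation_annotation.tsv"),
    val_truth = file.path(outdir, "validation_truth.tsv"),
    config = file.path(outdir, "generator_config.json"))
  write_matrix(disc$meth, paths[["meth"]])
  write_matrix(disc$expr, paths[["expr"]])
  write_annotation(disc$annotation, paths[["disc_annot"]])
  .write_tsv(disc$truth, paths[["disc_truth"]])
  write_qmsp(val$qmsp, paths[["qmsp"]])
  write_annotation(val$annotation, paths[["val_annot"]])
  .write_tsv(val$truth, paths[["val_truth"]])
  jsonlite::write_json(list(discovery = unclass(discovery_spec),
                            validation = unclass(assay_spec)),
                       paths[["config"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  sums <- tools::md5sum(unname(paths))
  manifest <- data.frame(file = basename(names(sums)), md5 = unname(sums),
                         stringsAsFactors = FALSE)
  .write_tsv(manifest, file.path(outdir, "MANIFEST.tsv"))
  invisible(c(paths, manifest = file.path(outdir, "MANIFEST.tsv")))
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
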