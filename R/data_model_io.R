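#' @importFrom stats median quantile rnorm rbinom rlnorm runif pt qbeta
#'   dhyper lm coef complete.cases setNames t.test
#' @importFrom utils read.delim write.table head
NULL

# ---------------------------------------------------------------------------
# Typed matrix containers
#
# Feature x sample matrices are plain numeric matrices carrying an S3 class
# and a `level` attribute, in the spirit of limma's lightweight containers.
# ---------------------------------------------------------------------------

#' Construct a methylation beta-value matrix
#'
#' A methylation matrix holds beta-values (proportion of methylated signal,
#' in \[0,1\]) for genes or probes (rows) by samples (columns). Missing
#' values are allowed and must be `NA`, never 0: a beta of 0 is a meaningful
#' "fully unmethylated" measurement.
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param level `"probe"` or `"gene"`.
#' @return a `meth_matrix` object.
#' @export
meth_matrix <- function(values, level = c("gene", "probe")) {
  level <- match.arg(level)
  values <- .validate_feature_matrix(values)
  bad <- values[!is.na(values)]
  if (any(bad < 0 | bad > 1)) {
    stop("beta-values must lie in [0,1]; offending value(s): ",
         paste(utils::head(bad[bad < 0 | bad > 1], 3), collapse = ", "))
  }
  structure(values, class = c("meth_matrix", "feature_matrix", "matrix", "array"),
            level = level)
}

#' Construct a normalized expression matrix
#'
#' Holds normalized, log-scale expression values, genes by samples. All
#' non-missing values must be finite.
#'
#' @param values numeric matrix with rownames and colnames.
#' @return an `expr_matrix` object.
#' @export
expr_matrix <- function(values) {
  values <- .validate_feature_matrix(values)
  if (any(!is.finite(values) & !is.na(values))) {
    stop("expression values must be finite or NA")
  }
  structure(values, class = c("expr_matrix", "feature_matrix", "matrix", "array"),
            level = "gene")
}

.validate_feature_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("matrix must carry feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  values
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d features x %d samples (level=%s)\n",
              class(x)[1], nrow(x), ncol(x), attr(x, "level")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Tab-delimited IO
# ---------------------------------------------------------------------------

#' Read a feature-by-sample matrix from a tab-delimited file
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' Empty cells and `NA` are read as missing; a methylation matrix is
#' range-checked to \[0,1\].
#'
#' @param path file path.
#' @param kind `"methylation"` or `"expression"`.
#' @param level for methylation, `"gene"` (default) or `"probe"`.
#' @return [meth_matrix()] or [expr_matrix()].
#' @export
read_matrix <- function(path, kind = c("methylation", "expression"),
                        level = c("gene", "probe")) {
  kind <- match.arg(kind)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed header: expected feature id column plus samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate feature ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("malformed matrix: non-numeric cells in ", path)
  rownames(m) <- ids
  if (kind == "methylation") meth_matrix(m, level = match.arg(level)) else expr_matrix(m)
}

#' Write a feature matrix to a tab-delimited file
#'
#' Missing values are written as `NA` (never 0), '.' decimal separator,
#' UTF-8, Unix newlines, so that a read/write round trip is exact to printed
#' precision.
#'
#' @param x a `feature_matrix`.
#' @param path output path.
#' @param digits printed precision (default 15 significant digits makes the
#'   round trip bit-exact for doubles generated at typical scales).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, digits = 15) {
  df <- data.frame(feature_id = rownames(x),
                   signif(unclass(x), digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample annotation table
#'
#' Requires columns `sample_id`, `patient_id`, `group` (tumor/normal) and
#' `specimen` (tissue/saliva); `hpv_copy_number` and `hpv_status` are
#' optional. Where a copy number is present, `hpv_status` is derived by the
#' one-copy-per-genome rule: >= 1 copy/genome/cell is positive.
#'
#' @param path tab-delimited file path.
#' @return a `data.frame` of class `sample_annotation`.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("NA", ""), stringsAsFactors = FALSE)
  as_sample_annotation(df)
}

#' Validate a sample annotation data.frame
#'
#' @param df data.frame with the columns documented in [read_annotation()].
#' @return validated `sample_annotation` data.frame.
#' @export
as_sample_annotation <- function(df) {
  required <- c("sample_id", "patient_id", "group", "specimen")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("annotation is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in annotation")
  if (!all(df$group %in% c("tumor", "normal"))) {
    stop("unknown group label(s): ",
         paste(setdiff(unique(df$group), c("tumor", "normal")), collapse = ", "))
  }
  if (!all(df$specimen %in% c("tissue", "saliva"))) {
    stop("unknown specimen label(s): ",
         paste(setdiff(unique(df$specimen), c("tissue", "saliva")), collapse = ", "))
  }
  if (is.null(df$hpv_copy_number)) df$hpv_copy_number <- NA_real_
  if (any(df$hpv_copy_number < 0, na.rm = TRUE)) stop("negative hpv_copy_number")
  if (is.null(df$hpv_status)) df$hpv_status <- NA_character_
  derivable <- !is.na(df$hpv_copy_number)
  derived <- ifelse(df$hpv_copy_number >= 1, "positive", "negative")
  conflict <- derivable & !is.na(df$hpv_status) & df$hpv_status != derived
  if (any(conflict)) {
    stop("hpv_status inconsistent with hpv_copy_number for: ",
         paste(df$sample_id[conflict], collapse = ", "))
  }
  df$hpv_status[derivable] <- derived[derivable]
  df$hpv_status[is.na(df$hpv_status)] <- "unknown"
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' Write a sample annotation table
#' @param annotation a `sample_annotation` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(annotation, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict and order a matrix to annotated samples
#'
#' Columns are restricted to samples present in the annotation (optionally a
#' single group) and reordered to the annotation order. Idempotent.
#'
#' @param x a `feature_matrix`.
#' @param annotation a `sample_annotation`.
#' @param group_filter optional `"tumor"` or `"normal"`.
#' @return the restricted matrix, with the sample mapping in attribute
#'   `"sample_map"`.
#' @export
align_samples <- function(x, annotation, group_filter = NULL) {
  ann <- annotation
  if (!is.null(group_filter)) {
    group_filter <- match.arg(group_filter, c("tumor", "normal"))
    ann <- ann[ann$group == group_filter, , drop = FALSE]
  }
  keep <- intersect(ann$sample_id, colnames(x))
  if (!length(keep)) stop("no overlap between matrix columns and annotation sample ids")
  out <- x[, keep, drop = FALSE]
  attrs <- attributes(x)
  attr(out, "level") <- attrs$level
  class(out) <- attrs$class
  attr(out, "sample_map") <- data.frame(
    sample_id = keep,
    matrix_col = match(keep, colnames(x)),
    stringsAsFactors = FALSE)
  out
}

# ---------------------------------------------------------------------------
# QMSP measurement tables
# ---------------------------------------------------------------------------

#' Validate a QMSP measurement table
#'
#' Long-format table with one row per (sample, gene): columns `sample_id`,
#' `gene`, `ct_target`, `ct_actin` (NA = undetermined / no amplification)
#' and optionally precomputed `quantity_target`, `quantity_actin`.
#'
#' @param df data.frame.
#' @return validated `qmsp_table` data.frame.
#' @export
as_qmsp_table <- function(df) {
  required <- c("sample_id", "gene", "ct_target", "ct_actin")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("QMSP table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  key <- paste(df$sample_id, df$gene, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (sample_id, gene) rows in QMSP table")
  for (qc in c("quantity_target", "quantity_actin")) {
    if (!is.null(df[[qc]]) && any(df[[qc]] < 0, na.rm = TRUE)) {
      stop(qc, " must be nonnegative")
    }
  }
  class(df) <- c("qmsp_table", "data.frame")
  df
}

#' Read a QMSP table from a tab-delimited file
#' @param path file path.
#' @return a `qmsp_table`.
#' @export
read_qmsp <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("NA", "", "Undetermined"), stringsAsFactors = FALSE)
  as_qmsp_table(df)
}

#' Write a QMSP table
#' @param qmsp a `qmsp_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qmsp <- function(qmsp, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(qmsp, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

.datatable.aware <- TRUE
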