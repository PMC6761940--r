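# Readers and writers for the package's plain-text interchange formats:
# expression matrices as TSV (first row = gene ids, first column = sample
# ids), pair manifests and sensitivity tables as CSV, ground-truth archives
# as JSON.

#' Read / write an expression matrix
#'
#' Tab-separated text: first row gene identifiers, first column sample
#' identifiers, real-valued entries.
#'
#' @param path File path.
#' @return `read_expression` returns a numeric matrix with sample row names
#'   and gene column names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' @rdname read_expression
#' @param x Samples-by-genes numeric matrix with dimnames.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a perturbation-pair manifest
#'
#' CSV with columns `drug_id`, `cell_line_id`, `control_sample`,
#' `treated_sample`, `batch_id`, `bead_id`, `concentration`, `duration_h`.
#'
#' @param path File path.
#' @export
read_pair_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "cell_line_id", "control_sample", "treated_sample",
            "batch_id", "bead_id", "concentration", "duration_h")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("pair manifest is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_pair_manifest
#' @param manifest Pair manifest data frame.
#' @export
write_pair_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a drug-sensitivity table
#'
#' CSV with columns `drug_id`, `cell_line_id`, `aac` (area above the
#' dose-response curve, in `[0, 1]`).
#'
#' @param path File path.
#' @export
read_sensitivity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "cell_line_id", "aac")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("sensitivity table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_sensitivity
#' @param sensitivity Sensitivity data frame.
#' @export
write_sensitivity <- function(sensitivity, path) {
  utils::write.csv(sensitivity, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `expression.tsv`, `pair_manifest.csv`, `sensitivity.csv`,
#' `samples.csv` and a JSON ground-truth archive `truth.json` (latent
#' states, effect map, decoder, labels) for recovery tests.  Byte-identical
#' output for identical datasets.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  write_pair_manifest(dataset$pair_manifest,
                      file.path(dir, "pair_manifest.csv"))
  write_sensitivity(dataset$sensitivity, file.path(dir, "sensitivity.csv"))
  utils::write.csv(dataset$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  tr <- dataset$truth
  truth <- list(z1 = tr$z1, z2 = tr$z2, W_star = tr$W_star,
                b_star = tr$b_star,
                decoder_D = tr$decoder$D, decoder_gain = tr$decoder$gain,
                label_rule = tr$label_rule,
                labels = as.list(tr$labels),
                labeled_pairs = tr$labeled_pairs,
                realized_ervr = tr$realized_ervr,
                seed = dataset$config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}
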