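# Pharmacogenomic data preparation: case-control pair matching, correlation
# filtering, per-gene standardization, first-principal-component removal,
# waterfall binarization of AAC drug sensitivity, and drug selection.

#' Match treatment profiles to vehicle controls
#'
#' Pairs each drug-treatment experiment with a DMSO vehicle control sharing
#' the same `(batch_id, bead_id)` key, the matching that minimizes batch
#' effects between cases and controls.  One control may serve several
#' treatments; when several controls share a key the one with the
#' lexicographically smallest sample id is used.  Treatments with no matching
#' control are reported unmatched.
#'
#' @param controls Data frame with columns `sample_id`, `batch_id`,
#'   `bead_id`.
#' @param treatments Data frame with columns `sample_id`, `batch_id`,
#'   `bead_id` and any pair metadata (e.g. `drug_id`, `cell_line_id`,
#'   `concentration`, `duration_h`).
#' @return A list with `pairs` (data frame: `treated_sample`,
#'   `control_sample`, the key columns and the treatment metadata) and
#'   `unmatched` (the treatment rows without a control).
#' @export
match_case_control <- function(controls, treatments) {
  need <- c("sample_id", "batch_id", "bead_id")
  chk <- function(df, nm) {
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop(nm, " is missing metadata column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    bad <- which(is.na(df$batch_id) | is.na(df$bead_id))
    if (length(bad)) {
      stop(nm, " has missing batch/bead metadata in row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
  }
  chk(controls, "controls"); chk(treatments, "treatments")
  key <- function(df) paste(df$batch_id, df$bead_id, sep = "\r")
  ctl <- controls[order(controls$sample_id), ]
  ctl <- ctl[!duplicated(key(ctl)), ]
  idx <- match(key(treatments), key(ctl))
  matched <- !is.na(idx)
  pairs <- treatments[matched, , drop = FALSE]
  names(pairs)[names(pairs) == "sample_id"] <- "treated_sample"
  pairs$control_sample <- ctl$sample_id[idx[matched]]
  rownames(pairs) <- NULL
  unmatched <- treatments[!matched, , drop = FALSE]
  rownames(unmatched) <- NULL
  list(pairs = pairs, unmatched = unmatched)
}

#' Filter perturbation pairs by pre/post correlation
#'
#' Retains pairs whose pre- and post-treatment profiles have Pearson
#' correlation strictly greater than `threshold`, removing likely mislabeled
#' experiments and outliers.  Degenerate profiles (zero variance) are
#' rejected with reason `"degenerate"` rather than raising an error.
#'
#' @param x1,x2 Matrices (pairs x genes) of control and treated expression.
#' @param threshold Correlation cutoff, default 0.75.
#' @return A list with `keep` (logical per pair), `correlation` (numeric per
#'   pair, `NA` for degenerate profiles) and `reason` (`"retained"`,
#'   `"low_correlation"` or `"degenerate"`).
#' @export
filter_pairs_by_correlation <- function(x1, x2, threshold = 0.75) {
  stopifnot(is.matrix(x1), is.matrix(x2), all(dim(x1) == dim(x2)),
            ncol(x1) >= 3L)
  n <- nrow(x1)
  rho <- rep(NA_real_, n)
  reason <- character(n)
  for (i in seq_len(n)) {
    a <- x1[i, ]; b <- x2[i, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      reason[i] <- "degenerate"
    } else {
      rho[i] <- stats::cor(a, b)
      reason[i] <- if (rho[i] > threshold) "retained" else "low_correlation"
    }
  }
  list(keep = reason == "retained", correlation = rho, reason = reason)
}

#' Standardize expression per gene
#'
#' Centers and scales every gene to zero mean and unit variance, with the
#' location and scale estimated on the `fit_on` rows only (the training
#' split) and applied to all rows, so held-out rows never influence the
#' transform.  The population variance convention (divide by n) is used and
#' recorded in the output.  Constant genes are flagged and their scale
#' clamped to 1 (centering only).
#'
#' @param x Samples-by-genes matrix with column names identifying genes.
#' @param fit_on Row indices to estimate the transform on (default: all).
#' @return A list with `matrix` (standardized, all rows), and `transform`
#'   (class `gene_standardizer`): `center`, `scale`, `flagged`, `genes`,
#'   `variance` (`"population"`), `fit_n`.
#' @export
standardize_genes <- function(x, fit_on = seq_len(nrow(x))) {
  stopifnot(is.matrix(x))
  if (length(fit_on) == 0L) stop("`fit_on` must be nonempty", call. = FALSE)
  xf <- x[fit_on, , drop = FALSE]
  n <- nrow(xf)
  center <- colMeans(xf)
  scale <- sqrt(colMeans(sweep(xf, 2L, center)^2))
  flagged <- scale <= 0
  scale[flagged] <- 1
  tr <- structure(list(center = center, scale = scale, flagged = flagged,
                       genes = colnames(x), variance = "population",
                       fit_n = n),
                  class = "gene_standardizer")
  list(matrix = apply_gene_transform(tr, x), transform = tr)
}

#' @rdname standardize_genes
#' @param transform A `gene_standardizer` returned by [standardize_genes()].
#' @export
apply_gene_transform <- function(transform, x) {
  stopifnot(inherits(transform, "gene_standardizer"), is.matrix(x))
  if (!identical(colnames(x), transform$genes)) {
    stop("gene set mismatch: the transform was fit on different genes",
         call. = FALSE)
  }
  sweep(sweep(x, 2L, transform$center), 2L, transform$scale, "/")
}

#' Remove the first principal component
#'
#' Estimates the leading principal axis `v` on the `fit_on` rows of an
#' already standardized matrix and deflates all rows as `X - (X v) v'`,
#' a coarse homogenization step that absorbs the dominant pooled-dataset
#' (batch/source) variation.  The component is stored for reuse on held-out
#' data.
#'
#' @param x Standardized samples-by-genes matrix with gene column names.
#' @param fit_on Row indices used to estimate the component (>= 2 rows).
#' @return A list with `matrix` (deflated, all rows) and `transform` (class
#'   `pc_remover`): `component`, `var_explained` (share of total variance on
#'   the fit rows), `genes`.
#' @export
remove_first_pc <- function(x, fit_on = seq_len(nrow(x))) {
  stopifnot(is.matrix(x))
  if (length(fit_on) < 2L) stop("`fit_on` needs >= 2 rows", call. = FALSE)
  xf <- x[fit_on, , drop = FALSE]
  total <- sum(xf^2)
  if (total <= 0) stop("rank-0 input: all fit rows are zero", call. = FALSE)
  sv <- svd(xf, nu = 0L, nv = 1L)
  v <- sv$v[, 1L]
  tr <- structure(list(component = v,
                       var_explained = sv$d[1L]^2 / total,
                       genes = colnames(x)),
                  class = "pc_remover")
  list(matrix = apply_pc_removal(tr, x), transform = tr)
}

#' @rdname remove_first_pc
#' @param transform A `pc_remover` returned by [remove_first_pc()].
#' @export
apply_pc_removal <- function(transform, x) {
  stopifnot(inherits(transform, "pc_remover"), is.matrix(x))
  if (!identical(colnames(x), transform$genes)) {
    stop("gene set mismatch: the component was fit on different genes",
         call. = FALSE)
  }
  v <- transform$component
  x - (x %*% v) %*% t(v)
}

#' Waterfall binarization of drug sensitivity
#'
#' Binarizes continuous AAC (area above the dose-response curve) values for
#' one drug.  The AAC values are sorted in decreasing order; if the sorted
#' curve is nearly linear in rank (Pearson correlation with its linear fit at
#' least `linearity_threshold`) the cutoff is the median AAC, otherwise the
#' cutoff is the AAC at the elbow: the point of maximum perpendicular
#' distance from the chord joining the first and last sorted points.  Cell
#' lines with AAC strictly above the cutoff are labeled sensitive (1); ties
#' at the cutoff go to non-sensitive.
#'
#' @param aac Numeric vector of AAC values in `[0, 1]`, optionally named by
#'   cell line.
#' @param cell_line_id Optional cell line identifiers (defaults to names of
#'   `aac` or an index).
#' @param linearity_threshold Correlation threshold for the median branch,
#'   default 0.95.
#' @return A list with `labels` (named 0/1 vector), `cutoff`, `linearity`
#'   (the rank correlation of the sorted curve) and `branch` (`"median"` or
#'   `"elbow"`).
#' @export
waterfall_binarize <- function(aac, cell_line_id = NULL,
                               linearity_threshold = 0.95) {
  aac <- as.numeric(aac)
  if (is.null(cell_line_id)) {
    cell_line_id <- if (!is.null(names(aac))) names(aac)
                    else as.character(seq_along(aac))
  }
  if (length(aac) < 3L) {
    stop("waterfall binarization needs at least 3 cell lines", call. = FALSE)
  }
  if (any(!is.finite(aac)) || any(aac < 0 | aac > 1)) {
    stop("AAC values must be finite and within [0, 1]", call. = FALSE)
  }
  if (length(unique(aac)) < 3L) {
    stop("waterfall binarization needs at least 3 distinct AAC values",
         call. = FALSE)
  }
  ord <- order(aac, decreasing = TRUE)
  s <- aac[ord]
  n <- length(s)
  linearity <- abs(stats::cor(s, seq_len(n)))
  if (linearity >= linearity_threshold) {
    cutoff <- stats::median(aac)
    branch <- "median"
  } else {
    # Perpendicular distance of (i, s_i) from the chord (1, s_1)-(n, s_n).
    dx <- n - 1; dy <- s[n] - s[1L]
    i <- seq_len(n)
    dist <- abs(dy * (i - 1) - dx * (s - s[1L])) / sqrt(dx^2 + dy^2)
    cutoff <- s[which.max(dist)]
    branch <- "elbow"
  }
  labels <- as.integer(aac > cutoff)
  names(labels) <- cell_line_id
  list(labels = labels, cutoff = cutoff, linearity = linearity,
       branch = branch)
}

#' Select drugs by perturbation coverage and response prevalence
#'
#' Retains drugs with (i) at least `min_cell_lines` distinct cell lines in
#' the perturbation-pair data and (ii) at least `min_sensitive_frac` of
#' screened cell lines labeled sensitive.
#'
#' @param pair_manifest Data frame with columns `drug_id`, `cell_line_id`
#'   (one row per perturbation pair).
#' @param labels Data frame with columns `drug_id`, `cell_line_id`, `label`
#'   (0/1).
#' @param min_cell_lines Minimum distinct cell lines with pairs, default 8.
#' @param min_sensitive_frac Minimum sensitive fraction, default 0.20.
#' @return Data frame with one row per drug: `drug_id`, `n_pair_cell_lines`,
#'   `sensitive_frac`, `retained`.
#' @export
select_drugs <- function(pair_manifest, labels, min_cell_lines = 8L,
                         min_sensitive_frac = 0.20) {
  stopifnot(all(c("drug_id", "cell_line_id") %in% names(pair_manifest)),
            all(c("drug_id", "cell_line_id", "label") %in% names(labels)))
  drugs <- sort(unique(c(pair_manifest$drug_id, labels$drug_id)))
  n_cl <- vapply(drugs, function(d) {
    length(unique(pair_manifest$cell_line_id[pair_manifest$drug_id == d]))
  }, integer(1))
  frac <- vapply(drugs, function(d) {
    y <- labels$label[labels$drug_id == d]
    if (length(y) == 0L) NA_real_ else mean(y)
  }, numeric(1))
  data.frame(drug_id = drugs,
             n_pair_cell_lines = n_cl,
             sensitive_frac = frac,
             retained = n_cl >= min_cell_lines &
               !is.na(frac) & frac >= min_sensitive_frac,
             row.names = NULL)
}

#' Pick the modal concentration for a drug
#'
#' Selects the concentration level at which the most cell lines were tested
#' (ties broken toward the lower concentration).  For cell lines not tested
#' at the chosen level, `closest_concentration()` gives the nearest tested
#' level by absolute log10 distance.
#'
#' @param concentration Numeric vector of tested concentrations (molar).
#' @return The modal concentration.
#' @export
most_common_concentration <- function(concentration) {
  stopifnot(length(concentration) > 0L, all(concentration > 0))
  tab <- table(concentration)
  best <- names(tab)[tab == max(tab)]
  min(as.numeric(best))
}

#' @rdname most_common_concentration
#' @param target The chosen concentration.
#' @param available Concentrations tested for a particular cell line.
#' @return The available concentration closest to `target` in log10 space.
#' @export
closest_concentration <- function(target, available) {
  stopifnot(target > 0, length(available) > 0L, all(available > 0))
  available[which.min(abs(log10(available) - log10(target)))]
}
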