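# Evaluation protocol: grouped/stratified repeated cross-validation splits,
# AUROC/AUPR, paired one-sided Wilcoxon comparisons, post-treatment
# prediction RMSE, and the effect-to-replicate variance ratio (ERVR).

#' Grouped, stratified repeated cross-validation splits
#'
#' Generates `n_folds * n_repeats` train/validation/test splits.  Cell lines
#' with perturbation pairs are folded as groups and pooled into training and
#' validation splits only (their singleton samples follow them); the
#' remaining singleton-only cell lines are folded with responder/
#' non-responder stratification.  For each repeat, fold f is the test fold
#' and fold f+1 (mod `n_folds`) the validation fold.  Test sets therefore
#' consist exclusively of singleton samples from cell lines without
#' perturbation data.
#'
#' @param singletons Data frame with columns `sample_id`, `cell_line_id`,
#'   `label` (0/1).
#' @param pair_cell_lines Character vector of cell line ids that have
#'   perturbation pairs.
#' @param n_folds,n_repeats Cross-validation geometry (defaults 5 and 20,
#'   giving 100 splits).
#' @param seed Integer seed; the plan is deterministic given it.
#' @return An object of class `split_plan`: a list with `splits` (each a
#'   list with `train`, `val`, `test` sample-id vectors and
#'   `train_pair_cell_lines`, `val_pair_cell_lines`), `n_folds`,
#'   `n_repeats`, `seed`.
#' @export
make_splits <- function(singletons, pair_cell_lines = character(),
                        n_folds = 5L, n_repeats = 20L, seed = 1L) {
  stopifnot(all(c("sample_id", "cell_line_id", "label") %in%
                  names(singletons)))
  if (!all(singletons$label %in% c(0, 1))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  if (length(unique(singletons$label)) < 2L) {
    stop("both response classes must be present", call. = FALSE)
  }
  pair_cell_lines <- unique(as.character(pair_cell_lines))
  cl <- as.character(singletons$cell_line_id)
  solo_cls <- setdiff(unique(cl), pair_cell_lines)
  if (length(solo_cls) < n_folds) {
    stop("need at least `n_folds` singleton-only cell lines (have ",
         length(solo_cls), ")", call. = FALSE)
  }
  # Cell-line level label for stratification (majority over its samples).
  cl_label <- vapply(solo_cls, function(g) {
    as.integer(mean(singletons$label[cl == g]) > 0.5)
  }, integer(1))

  splits <- list()
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      # Stratified round-robin assignment of singleton-only cell lines.
      pos <- sample(solo_cls[cl_label == 1L])
      neg <- sample(solo_cls[cl_label == 0L])
      ordered <- c(pos, neg)
      solo_fold <- stats::setNames(
        (seq_along(ordered) - 1L) %% n_folds + 1L, ordered)
      pair_fold <- if (length(pair_cell_lines)) {
        stats::setNames((seq_along(pair_cell_lines) - 1L) %% n_folds + 1L,
                        sample(pair_cell_lines))
      } else {
        integer()
      }
      for (f in seq_len(n_folds)) {
        fv <- f %% n_folds + 1L
        sample_fold <- ifelse(cl %in% pair_cell_lines,
                              NA_integer_, solo_fold[cl])
        in_pair_val <- cl %in% names(pair_fold)[pair_fold == fv]
        in_pair_train <- cl %in% pair_cell_lines & !in_pair_val
        test <- singletons$sample_id[!is.na(sample_fold) & sample_fold == f]
        val <- singletons$sample_id[
          (!is.na(sample_fold) & sample_fold == fv) | in_pair_val]
        train <- singletons$sample_id[
          (!is.na(sample_fold) & !(sample_fold %in% c(f, fv))) |
            in_pair_train]
        splits[[length(splits) + 1L]] <- list(
          train = train, val = val, test = test,
          train_pair_cell_lines =
            names(pair_fold)[!(pair_fold == fv)],
          val_pair_cell_lines = names(pair_fold)[pair_fold == fv])
      }
    }
  })
  structure(list(splits = splits, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan: ", length(x$splits), " splits (", x$n_folds,
      " folds x ", x$n_repeats, " repeats), seed ", x$seed, ">\n", sep = "")
  invisible(x)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney probability that a random positive is scored above a
#' random negative, ties counted one half (computed from midranks).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels, same length.
#' @return AUROC in `[0, 1]`, or `NA` (with a warning) when only one class
#'   is present.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("AUROC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) average precision: the sum over score
#' thresholds of the recall increment times the precision at that threshold.
#' Tied scores enter as one block.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels, same length.
#' @return AUPR in `(0, 1]`, or `NA` (with a warning) when no positives are
#'   present.
#' @export
aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels == 1)
  if (P == 0L) {
    warning("AUPR undefined: no positive labels", call. = FALSE)
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # Collapse tied scores into blocks.
  blocks <- cumsum(!duplicated(s))
  tp <- tapply(y, blocks, sum)
  n <- tapply(y, blocks, length)
  ctp <- cumsum(tp); cn <- cumsum(n)
  precision <- ctp / cn
  recall_inc <- tp / P
  sum(recall_inc * precision)
}

#' Paired one-sided Wilcoxon comparison of two methods
#'
#' Runs the one-sided Wilcoxon signed-rank test in both directions on the
#' paired per-split score differences (zero differences dropped, the classic
#' convention; exact distribution when n <= 25 and no tied magnitudes,
#' normal approximation with continuity correction otherwise) and reports
#' the significant direction, or a tie.
#'
#' @param a,b Numeric vectors of paired per-split scores (e.g. AUROC over
#'   100 splits).
#' @param alpha Significance level, default 0.05.
#' @return A list with `verdict` (`"a_better"`, `"b_better"` or `"tie"`),
#'   `p_a_better`, `p_b_better`, and `n_effective` (pairs after dropping
#'   zeros).
#' @export
wilcoxon_compare <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b), alpha > 0, alpha < 1)
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(list(verdict = "tie", p_a_better = 1, p_b_better = 1,
                n_effective = 0L))
  }
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  pa <- suppressWarnings(stats::wilcox.test(
    d, alternative = "greater", exact = exact, correct = TRUE))$p.value
  pb <- suppressWarnings(stats::wilcox.test(
    d, alternative = "less", exact = exact, correct = TRUE))$p.value
  verdict <- if (pa < alpha) "a_better" else if (pb < alpha) "b_better"
             else "tie"
  list(verdict = verdict, p_a_better = pa, p_b_better = pb,
       n_effective = length(d))
}

#' Root mean square prediction error
#'
#' Per-sample RMSE across coordinates, averaged over samples.
#'
#' @param predicted,reference Matrices of identical shape (rows = samples),
#'   or vectors.
#' @return A single nonnegative number.
#' @export
rmse_pred <- function(predicted, reference) {
  if (!is.matrix(predicted)) predicted <- matrix(predicted, nrow = 1L)
  if (!is.matrix(reference)) reference <- matrix(reference, nrow = 1L)
  if (!all(dim(predicted) == dim(reference))) {
    stop("shape mismatch between predicted and reference", call. = FALSE)
  }
  mean(sqrt(rowMeans((predicted - reference)^2)))
}

#' Effect-to-replicate variance ratio
#'
#' Signal-to-noise summary of perturbation experiments for one drug: the
#' mean over genes of the across-pair variance of the perturbation effect
#' `x2 - x1`, divided by the mean over genes of the pooled within-group
#' variance of replicate control profiles.
#'
#' @param x1,x2 Matrices (pairs x genes) of control and treated expression.
#' @param replicate_controls List of matrices, one per control group, each
#'   (replicates x genes) with >= 2 rows in at least one group.
#' @return A nonnegative number; `Inf` (with a warning) when the replicate
#'   variance is zero.
#' @export
ervr <- function(x1, x2, replicate_controls) {
  stopifnot(is.matrix(x1), is.matrix(x2), all(dim(x1) == dim(x2)))
  if (nrow(x1) < 2L) stop("need >= 2 perturbation pairs", call. = FALSE)
  stopifnot(is.list(replicate_controls), length(replicate_controls) >= 1L)
  eff <- x2 - x1
  num <- mean(apply(eff, 2L, stats::var))
  ss <- 0; df <- 0
  for (g in replicate_controls) {
    stopifnot(is.matrix(g), ncol(g) == ncol(x1))
    if (nrow(g) < 2L) next
    ss <- ss + sum(sweep(g, 2L, colMeans(g))^2)
    df <- df + (nrow(g) - 1L) * ncol(g)
  }
  if (df == 0L) {
    stop("no control group has >= 2 replicates", call. = FALSE)
  }
  den <- ss / df
  if (den == 0) {
    warning("replicate variance is zero; ERVR unbounded", call. = FALSE)
    return(Inf)
  }
  num / den
}

#' Correlate prediction improvement with a dataset covariate
#'
#' Pearson correlation (with two-sided p-value) between per-drug RMSE
#' improvements and a per-drug covariate such as ERVR, the number of
#' perturbation cell lines, or their product.
#'
#' @param delta_rmse Numeric vector of per-drug improvements.
#' @param covariate Numeric vector, same length.
#' @return A list with `rho` and `p_value`.
#' @export
improvement_correlation <- function(delta_rmse, covariate) {
  stopifnot(length(delta_rmse) == length(covariate))
  if (length(delta_rmse) < 3L) {
    stop("need at least 3 drugs", call. = FALSE)
  }
  if (!all(is.finite(delta_rmse)) || !all(is.finite(covariate))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(delta_rmse) == 0 || stats::sd(covariate) == 0) {
    warning("correlation undefined: zero variance", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(delta_rmse, covariate, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
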