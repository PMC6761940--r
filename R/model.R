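#' Model configuration for the Dr.VAE family
#'
#' Collects architecture and optimization settings shared by Dr.VAE and its
#' SSVAE / PertVAE ablations.  All networks have at most one hidden layer of
#' ELU units; the perturbation mean is the linear map `z1 + W z1 + b` and the
#' response classifier is linear with a two-unit softmax.
#'
#' @param n_genes Number of genes G in the expression vectors.
#' @param latent_dim Dimension d of the latent embedding z1/z2 (default 100).
#' @param z3_dim Dimension of the class-independent latent z3 (default
#'   `latent_dim`).
#' @param hidden_codec Hidden-layer width of the shared data encoder/decoder;
#'   0 gives purely affine maps.
#' @param hidden_aux Hidden width of the z3 encoder and the z1 prior network.
#' @param learning_rate,batch_size,max_epochs,patience Adam step size,
#'   minibatch size, epoch cap, and early-stopping patience (epochs without
#'   validation improvement).
#' @param class_loss_weights Candidate weights for the explicit classifier
#'   cross-entropy term; `drvae_fit()` picks one on the validation fold by
#'   AUROC.
#' @param perturb_init_sd Standard deviation of the near-zero initialization
#'   of the perturbation `W` and `b`, so the perturbation starts as an
#'   identity map.
#' @param clamp_eps Probability clamping epsilon for cross-entropy.
#' @return A list of class `drvae_config`.
#' @export
drvae_config <- function(n_genes,
                         latent_dim = 100L,
                         z3_dim = latent_dim,
                         hidden_codec = 512L,
                         hidden_aux = 256L,
                         learning_rate = 1e-3,
                         batch_size = 64L,
                         max_epochs = 100L,
                         patience = 20L,
                         class_loss_weights = c(0.1, 1, 10, 100),
                         perturb_init_sd = 1e-4,
                         clamp_eps = 1e-7) {
  stopifnot(n_genes >= 1, latent_dim >= 1, z3_dim >= 1,
            hidden_codec >= 0, hidden_aux >= 0,
            learning_rate > 0, batch_size >= 1, max_epochs >= 0,
            patience >= 1, all(class_loss_weights >= 0))
  structure(list(n_genes = as.integer(n_genes),
                 latent_dim = as.integer(latent_dim),
                 z3_dim = as.integer(z3_dim),
                 hidden_codec = as.integer(hidden_codec),
                 hidden_aux = as.integer(hidden_aux),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 class_loss_weights = class_loss_weights,
                 perturb_init_sd = perturb_init_sd,
                 clamp_eps = clamp_eps),
            class = "drvae_config")
}

#' Assemble a training batch of pairs and singletons
#'
#' A batch holds the four data regimes the semi-supervised objective sums
#' over: perturbation pairs (pre/post-treatment expression, label optional)
#' and pre-treatment singletons (label optional).  Use `NA` in the label
#' vectors for unlabeled items.
#'
#' @param x1_pairs,x2_pairs Matrices (pairs x genes) of pre- and
#'   post-treatment expression, or `NULL`.
#' @param y_pairs Numeric vector of labels in `{0, 1, NA}`, one per pair.
#' @param x1_singletons Matrix (singletons x genes) of pre-treatment
#'   expression, or `NULL`.
#' @param y_singletons Labels for the singletons (`NA` = unlabeled).
#' @return An object of class `drvae_batch`.
#' @export
drvae_batch <- function(x1_pairs = NULL, x2_pairs = NULL, y_pairs = NULL,
                        x1_singletons = NULL, y_singletons = NULL) {
  to_mat <- function(x) {
    if (is.null(x)) return(NULL)
    if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
    storage.mode(x) <- "double"
    x
  }
  x1_pairs <- to_mat(x1_pairs); x2_pairs <- to_mat(x2_pairs)
  x1_singletons <- to_mat(x1_singletons)
  np <- if (is.null(x1_pairs)) 0L else nrow(x1_pairs)
  ns <- if (is.null(x1_singletons)) 0L else nrow(x1_singletons)
  if (np > 0L) {
    if (is.null(x2_pairs) || nrow(x2_pairs) != np ||
        ncol(x2_pairs) != ncol(x1_pairs)) {
      stop("x1_pairs and x2_pairs must be matrices of identical shape",
           call. = FALSE)
    }
  }
  if (is.null(y_pairs)) y_pairs <- rep(NA_real_, np)
  if (is.null(y_singletons)) y_singletons <- rep(NA_real_, ns)
  y_pairs <- as.numeric(y_pairs); y_singletons <- as.numeric(y_singletons)
  if (length(y_pairs) != np || length(y_singletons) != ns) {
    stop("label vectors must match the number of pairs/singletons",
         call. = FALSE)
  }
  ok <- function(y) all(is.na(y) | y %in% c(0, 1))
  if (!ok(y_pairs) || !ok(y_singletons)) {
    stop("labels must be 0, 1 or NA", call. = FALSE)
  }
  if (np > 0L && ns > 0L && ncol(x1_pairs) != ncol(x1_singletons)) {
    stop("pairs and singletons must share the same gene dimension",
         call. = FALSE)
  }
  structure(list(x1_pairs = x1_pairs, x2_pairs = x2_pairs, y_pairs = y_pairs,
                 x1_singletons = x1_singletons, y_singletons = y_singletons),
            class = "drvae_batch")
}

batch_n_pairs <- function(b) length(b$y_pairs)
batch_n_singletons <- function(b) length(b$y_singletons)
batch_n_items <- function(b) batch_n_pairs(b) + batch_n_singletons(b)

batch_genes <- function(b) {
  if (batch_n_pairs(b) > 0L) return(ncol(b$x1_pairs))
  if (batch_n_singletons(b) > 0L) return(ncol(b$x1_singletons))
  0L
}

batch_subset <- function(b, pair_idx = integer(), single_idx = integer()) {
  drvae_batch(
    x1_pairs = if (length(pair_idx)) b$x1_pairs[pair_idx, , drop = FALSE],
    x2_pairs = if (length(pair_idx)) b$x2_pairs[pair_idx, , drop = FALSE],
    y_pairs = if (length(pair_idx)) b$y_pairs[pair_idx],
    x1_singletons = if (length(single_idx))
      b$x1_singletons[single_idx, , drop = FALSE],
    y_singletons = if (length(single_idx)) b$y_singletons[single_idx])
}

# Collapse pairs onto their pre-treatment member (used by the SSVAE ablation).
batch_flatten_pairs <- function(b) {
  if (batch_n_pairs(b) == 0L) return(b)
  drvae_batch(
    x1_singletons = rbind(b$x1_pairs, b$x1_singletons),
    y_singletons = c(b$y_pairs, b$y_singletons))
}

#' @export
print.drvae_batch <- function(x, ...) {
  yl <- sum(!is.na(x$y_pairs)); sl <- sum(!is.na(x$y_singletons))
  cat("<drvae_batch: ", batch_n_pairs(x), " pairs (", yl, " labeled), ",
      batch_n_singletons(x), " singletons (", sl, " labeled), ",
      batch_genes(x), " genes>\n", sep = "")
  invisible(x)
}

#' Initialize a model of the Dr.VAE family
#'
#' Draws fresh parameters for the requested model.  The shared data
#' encoder/decoder serve both the pre- and post-treatment profiles; the
#' perturbation map `W`, `b` is initialized close to zero so that
#' `p(z2 | z1)` starts as an identity function.
#'
#' @param config A [drvae_config()].
#' @param model_type `"drvae"` (full model), `"ssvae"` (no perturbation
#'   branch; classifier on z1 alone) or `"pertvae"` (unsupervised pairs
#'   model with a standard-normal prior on z1).
#' @param seed Optional seed used only for this initialization.
#' @return An object of class `drvae_model` with elements `params`, `config`,
#'   `model_type`, `class_loss_weight` and (after fitting) `log`.
#' @export
drvae_init <- function(config, model_type = c("drvae", "ssvae", "pertvae"),
                       seed = NULL) {
  model_type <- match.arg(model_type)
  stopifnot(inherits(config, "drvae_config"))
  G <- config$n_genes; d <- config$latent_dim; d3 <- config$z3_dim
  params <- with_seed(seed, {
    p <- list(enc = nn_gauss_init(G, d, config$hidden_codec),
              dec = nn_mean_init(d, G, config$hidden_codec),
              dec_log_var = matrix(0, 1L, G))
    if (model_type %in% c("drvae", "pertvae")) {
      p$pert <- list(
        W = matrix(stats::rnorm(d * d, sd = config$perturb_init_sd), d, d),
        b = matrix(stats::rnorm(d, sd = config$perturb_init_sd), 1L, d),
        log_var = matrix(0, 1L, d))
    }
    if (model_type %in% c("drvae", "ssvae")) {
      p$z3enc <- nn_gauss_init(d + 1L, d3, config$hidden_aux)
      p$z1prior <- nn_gauss_init(d3 + 1L, d, config$hidden_aux)
      cls_in <- if (model_type == "drvae") 2L * d else d
      p$cls <- list(W = matrix(stats::rnorm(cls_in * 2L, sd = 0.01),
                               cls_in, 2L),
                    b = matrix(0, 1L, 2L))
    }
    p
  })
  structure(list(params = params, config = config, model_type = model_type,
                 class_loss_weight = 1, log = NULL),
            class = "drvae_model")
}

#' @export
print.drvae_model <- function(x, ...) {
  cat("<", x$model_type, " model: ", x$config$n_genes, " genes, d = ",
      x$config$latent_dim, ", z3 dim = ", x$config$z3_dim, ">\n", sep = "")
  if (!is.null(x$log)) {
    cat("  trained ", nrow(x$log), " epochs; class loss weight ",
        x$class_loss_weight, "\n", sep = "")
  }
  invisible(x)
}

check_expr_dim <- function(x, model, what = "x") {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1L)
  if (ncol(x) != model$config$n_genes) {
    stop("dimension mismatch: ", what, " has ", ncol(x), " genes, model has ",
         model$config$n_genes, call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

as_latent_mat <- function(z, d, what = "z") {
  if (!is.matrix(z)) z <- matrix(as.numeric(z), nrow = 1L)
  if (ncol(z) != d) {
    stop("dimension mismatch: ", what, " has length ", ncol(z),
         ", expected ", d, call. = FALSE)
  }
  z
}

maybe_gp <- function(m, was_vector) {
  if (was_vector) gaussian_params(m$mean[1L, ], m$log_var[1L, ]) else m
}

#' Amortized encoder q(z | x)
#'
#' Maps expression to the approximate posterior over its latent embedding.
#' The same encoder serves both pre-treatment (z1) and post-treatment (z2)
#' profiles.
#'
#' @param x Expression vector of length G, or a samples-by-genes matrix.
#' @param model A `drvae_model`.
#' @return For a vector input a [gaussian_params()]; for a matrix input a
#'   list with `mean` and `log_var` matrices (rows = samples).
#' @export
drvae_encode <- function(x, model) {
  vec <- !is.matrix(x)
  X <- check_expr_dim(x, model)
  maybe_gp(nn_gauss_fwd(model$params$enc, X), vec)
}

#' Decoder p(x | z)
#'
#' Diagonal Gaussian over gene expression given a latent state; the
#' log-variance is a free per-gene parameter shared across samples.
#'
#' @param z Latent vector of length d, or a samples-by-d matrix.
#' @param model A `drvae_model`.
#' @return A [gaussian_params()] over genes (or matrices for matrix input).
#' @export
drvae_decode <- function(z, model) {
  vec <- !is.matrix(z)
  Z <- as_latent_mat(z, model$config$latent_dim)
  m <- nn_mean_fwd(model$params$dec, Z)
  lv <- matrix(model$params$dec_log_var, nrow(Z), ncol(m), byrow = TRUE)
  maybe_gp(list(mean = m, log_var = lv), vec)
}

perturb_mean_mat <- function(Z, model) {
  p <- model$params$pert
  Z + Z %*% t(p$W) + matrix(p$b, nrow(Z), ncol(Z), byrow = TRUE)
}

#' Latent perturbation p(z2 | z1)
#'
#' The drug effect in latent space: a Gaussian whose mean is the linear map
#' `z1 + W z1 + b` and whose per-dimension variance is state-independent.
#'
#' @param z1 Latent vector (length d) or matrix of row vectors.
#' @param model A `drvae_model` with a perturbation branch.
#' @return [gaussian_params()] over z2 (or matrices for matrix input).
#' @export
drvae_perturb <- function(z1, model) {
  if (is.null(model$params$pert)) {
    stop("model has no perturbation branch", call. = FALSE)
  }
  vec <- !is.matrix(z1)
  Z <- as_latent_mat(z1, model$config$latent_dim, "z1")
  m <- perturb_mean_mat(Z, model)
  lv <- matrix(model$params$pert$log_var, nrow(Z), ncol(Z), byrow = TRUE)
  maybe_gp(list(mean = m, log_var = lv), vec)
}

classifier_score <- function(Z1, Z2, model) {
  p <- model$params$cls
  H <- if (model$model_type == "drvae") cbind(Z1, Z2 - Z1) else Z1
  logits <- sweep(H %*% p$W, 2L, p$b, "+")
  logits[, 2L] - logits[, 1L]
}

#' Response classifier q(y | z1, z2)
#'
#' Linear two-unit softmax over the concatenation `[z1, z2 - z1]` (for the
#' full model) or over z1 alone (SSVAE).  Returns the probability of a
#' positive (sensitive) response.
#'
#' @param z1,z2 Latent vectors (length d) or matrices of row vectors.
#' @param model A `drvae_model` with a classifier.
#' @return Probability (or vector of probabilities) in `[0, 1]`.
#' @export
drvae_classify <- function(z1, z2, model) {
  if (is.null(model$params$cls)) {
    stop("model has no classifier", call. = FALSE)
  }
  d <- model$config$latent_dim
  Z1 <- as_latent_mat(z1, d, "z1"); Z2 <- as_latent_mat(z2, d, "z2")
  stopifnot(nrow(Z1) == nrow(Z2))
  as.numeric(stats::plogis(classifier_score(Z1, Z2, model)))
}

#' Approximate posterior q(z3 | z1, y)
#'
#' @param z1 Latent vector/matrix.
#' @param y Response label(s) in `{0, 1}`.
#' @param model A `drvae_model` with the class branch.
#' @return [gaussian_params()] over z3 (or matrices for matrix input).
#' @export
drvae_infer_z3 <- function(z1, y, model) {
  if (is.null(model$params$z3enc)) {
    stop("model has no z3 branch", call. = FALSE)
  }
  vec <- !is.matrix(z1)
  Z <- as_latent_mat(z1, model$config$latent_dim, "z1")
  stopifnot(all(y %in% c(0, 1)))
  y <- rep_len(as.numeric(y), nrow(Z))
  maybe_gp(nn_gauss_fwd(model$params$z3enc, cbind(Z, y)), vec)
}

#' Conditional prior p(z1 | z3, y)
#'
#' The label-conditioned prior over the latent embedding; `p(z3)` itself is a
#' fixed standard normal and `p(y)` a uniform categorical.
#'
#' @param z3 Latent vector/matrix of z3 dimension.
#' @param y Response label(s) in `{0, 1}`.
#' @param model A `drvae_model` with the class branch.
#' @return [gaussian_params()] over z1 (or matrices for matrix input).
#' @export
drvae_prior_z1 <- function(z3, y, model) {
  if (is.null(model$params$z1prior)) {
    stop("model has no z3 branch", call. = FALSE)
  }
  vec <- !is.matrix(z3)
  Z <- as_latent_mat(z3, model$config$z3_dim, "z3")
  stopifnot(all(y %in% c(0, 1)))
  y <- rep_len(as.numeric(y), nrow(Z))
  maybe_gp(nn_gauss_fwd(model$params$z1prior, cbind(Z, y)), vec)
}

#' Replace the learned perturbation with the identity map
#'
#' Produces the "w/I" ablation of a trained model: `W` and `b` are zeroed
#' without retraining anything else, so the predicted post-treatment latent
#' state equals the pre-treatment one.
#'
#' @param model A trained `drvae_model` with a perturbation branch.
#' @return A modified copy of the model.
#' @export
set_identity_perturbation <- function(model) {
  if (is.null(model$params$pert)) {
    stop("model has no perturbation branch", call. = FALSE)
  }
  model$params$pert$W[] <- 0
  model$params$pert$b[] <- 0
  model
}
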