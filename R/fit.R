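# Minibatch Adam training with early stopping and classification-loss-weight
# selection on a validation fold.

adam_state <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(theta, grad, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mhat <- st$m / (1 - b1^st$t)
  vhat <- st$v / (1 - b2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

# Validation AUROC of the response classifier over all labeled items (both
# singleton and pair pre-treatment profiles); NA when undefined.
val_auroc <- function(model, val) {
  if (is.null(val) || is.null(model$params$cls)) return(NA_real_)
  xs <- NULL; ys <- NULL
  if (batch_n_pairs(val) > 0L) {
    keep <- !is.na(val$y_pairs)
    if (any(keep)) {
      xs <- rbind(xs, val$x1_pairs[keep, , drop = FALSE])
      ys <- c(ys, val$y_pairs[keep])
    }
  }
  if (batch_n_singletons(val) > 0L) {
    keep <- !is.na(val$y_singletons)
    if (any(keep)) {
      xs <- rbind(xs, val$x1_singletons[keep, , drop = FALSE])
      ys <- c(ys, val$y_singletons[keep])
    }
  }
  if (is.null(xs) || length(unique(ys)) < 2L) return(NA_real_)
  auroc(predict_response(xs, model)$prob_sensitive, ys)
}

fit_one_candidate <- function(train, val, config, seed, model_type, clw,
                              verbose) {
  set.seed(seed)
  model <- drvae_init(config, model_type)
  model$class_loss_weight <- clw
  skeleton <- model$params
  theta <- param_flatten(model$params)
  st <- adam_state(length(theta))
  np <- batch_n_pairs(train); ns <- batch_n_singletons(train)
  n_items <- np + ns
  has_val <- !is.null(val) && batch_n_items(val) > 0L
  eval_seed <- (seed %% 1000000L) + 104729L
  best_val <- Inf
  best_theta <- theta
  patience_left <- config$patience
  log <- data.frame(epoch = integer(), train_objective = numeric(),
                    val_objective = numeric())
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_items)
    chunks <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_obj <- 0
    for (ch in chunks) {
      sub <- batch_subset(train, pair_idx = ch[ch <= np],
                          single_idx = ch[ch > np] - np)
      g <- objective_grad(sub, model)
      if (!is.finite(g$value)) {
        stop("non-finite training objective at epoch ", epoch,
             "; reduce the learning rate or check the inputs", call. = FALSE)
      }
      epoch_obj <- epoch_obj + g$value
      upd <- adam_step(theta, param_flatten(g$grads), st,
                       config$learning_rate)
      theta <- upd$theta; st <- upd$state
      model$params <- param_unflatten(theta, skeleton)
    }
    vobj <- if (has_val) {
      total_objective(val, model, seed = eval_seed)
    } else {
      NA_real_
    }
    val_n <- if (has_val) batch_n_items(val) else 1L
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_objective = epoch_obj / n_items,
                                 val_objective = vobj / val_n))
    if (verbose) {
      message(sprintf("[%s w=%g] epoch %d train %.4f val %.4f",
                      model_type, clw, epoch, epoch_obj / n_items,
                      vobj / val_n))
    }
    if (has_val) {
      if (vobj < best_val - 1e-10) {
        best_val <- vobj
        best_theta <- theta
        patience_left <- config$patience
      } else {
        patience_left <- patience_left - 1L
        if (patience_left <= 0L) break
      }
    } else {
      best_theta <- theta
    }
  }
  model$params <- param_unflatten(best_theta, skeleton)
  model$log <- log
  model$best_val_objective <- if (has_val) best_val else NA_real_
  model
}

#' Fit a model of the Dr.VAE family
#'
#' Minibatch Adam optimization of the semi-supervised objective.  For each
#' candidate classification loss weight the model is trained with early
#' stopping on the validation objective; the candidate with the best
#' validation AUROC (falling back to the validation objective when AUROC is
#' undefined) is returned.  Fully reproducible given `seed`.
#'
#' @param train A [drvae_batch()] of training data (must be nonempty).
#' @param val Optional validation [drvae_batch()]; when absent the model
#'   trains for the full `max_epochs` with a warning.
#' @param config A [drvae_config()].
#' @param seed Integer seed controlling initialization, shuffling and noise.
#' @param model_type `"drvae"`, `"ssvae"` or `"pertvae"`.
#' @param verbose Print per-epoch progress.
#' @return A trained `drvae_model`; its `log` field holds the per-epoch
#'   training/validation objective of the selected candidate, and
#'   `weight_selection` the per-candidate summary.
#' @export
drvae_fit <- function(train, val = NULL, config, seed = 1L,
                      model_type = c("drvae", "ssvae", "pertvae"),
                      verbose = FALSE) {
  model_type <- match.arg(model_type)
  stopifnot(inherits(train, "drvae_batch"), inherits(config, "drvae_config"))
  if (batch_n_items(train) == 0L) stop("empty training batch", call. = FALSE)
  if (model_type == "ssvae") {
    train <- batch_flatten_pairs(train)
    if (!is.null(val)) val <- batch_flatten_pairs(val)
  }
  has_val <- !is.null(val) && batch_n_items(val) > 0L
  if (!has_val && config$max_epochs > 0L) {
    warning("no validation data: training for the full epoch budget ",
            "without early stopping", call. = FALSE)
  }
  has_labels <- any(!is.na(train$y_pairs)) || any(!is.na(train$y_singletons))
  weights <- if (model_type == "pertvae" || !has_labels) {
    0
  } else {
    config$class_loss_weights
  }
  if (length(weights) > 1L && !has_val) {
    weights <- weights[1L]
    warning("no validation data to select the class loss weight; using ",
            weights, call. = FALSE)
  }
  candidates <- lapply(weights, function(w) {
    fit_one_candidate(train, val, config, seed, model_type, w, verbose)
  })
  aurocs <- vapply(candidates, val_auroc, numeric(1), val = val)
  pick <- if (any(!is.na(aurocs))) {
    which.max(ifelse(is.na(aurocs), -Inf, aurocs))
  } else {
    vals <- vapply(candidates, function(m) m$best_val_objective, numeric(1))
    if (all(is.na(vals))) 1L else which.min(ifelse(is.na(vals), Inf, vals))
  }
  model <- candidates[[pick]]
  model$weight_selection <- data.frame(class_loss_weight = weights,
                                       val_auroc = aurocs,
                                       selected = seq_along(weights) == pick)
  model
}

#' Predict drug response from pre-treatment expression
#'
#' Deterministic mean-propagation prediction: embed x1 to the posterior mean
#' z1, push it through the mean of the latent perturbation to get z2, and
#' apply the linear classifier.  No sampling and no post-treatment profile is
#' involved, so the prediction is defined for every singleton.
#'
#' @param x1 Pre-treatment expression vector (length G) or matrix.
#' @param model A trained `drvae_model` of type `"drvae"` or `"ssvae"`.
#' @return A list of class `response_prediction` with `prob_sensitive`
#'   (vector), `z1_mean` and `z2_mean` (matrices, rows = samples).
#' @export
predict_response <- function(x1, model) {
  if (is.null(model$params$cls)) {
    stop("model has no response classifier (PertVAE is unsupervised)",
         call. = FALSE)
  }
  X <- check_expr_dim(x1, model, "x1")
  z1 <- nn_gauss_fwd(model$params$enc, X)$mean
  z2 <- if (model$model_type == "drvae") perturb_mean_mat(z1, model) else z1
  prob <- as.numeric(stats::plogis(classifier_score(z1, z2, model)))
  structure(list(prob_sensitive = prob, z1_mean = z1, z2_mean = z2),
            class = "response_prediction")
}

#' Predict the post-treatment expression profile
#'
#' Decodes the predicted post-treatment latent state (as in
#' [predict_response()]) back to gene space.  With the identity-perturbation
#' ablation this reduces to the plain autoencoding reconstruction of x1.
#'
#' @param x1 Pre-treatment expression vector or matrix.
#' @param model A trained `drvae_model` with a perturbation branch (or an
#'   SSVAE, for which the prediction is the reconstruction of x1).
#' @return Matrix (samples x genes) of predicted post-treatment means; a
#'   vector input gives a vector.
#' @export
predict_posttreatment <- function(x1, model) {
  vec <- !is.matrix(x1)
  X <- check_expr_dim(x1, model, "x1")
  z1 <- nn_gauss_fwd(model$params$enc, X)$mean
  z2 <- if (!is.null(model$params$pert)) perturb_mean_mat(z1, model) else z1
  out <- nn_mean_fwd(model$params$dec, z2)
  if (vec) as.numeric(out) else out
}

#' Latent embedding from the shared encoder
#'
#' Returns the posterior mean of `q(z1 | x)`, the reduced representation used
#' when a PertVAE serves as an unsupervised dimensionality reduction ahead of
#' a standard classifier.
#'
#' @param x Expression vector or matrix.
#' @param model Any `drvae_model`.
#' @return Matrix (samples x latent_dim); a vector input gives a vector.
#' @export
pertvae_embed <- function(x, model) {
  vec <- !is.matrix(x)
  X <- check_expr_dim(x, model)
  out <- nn_gauss_fwd(model$params$enc, X)$mean
  if (vec) as.numeric(out) else out
}

#' Train the SSVAE ablation
#'
#' SSVAE drops the perturbation branch entirely: pairs are flattened to their
#' pre-treatment member, the generative model is
#' `p(x1|z1) p(z1|z3,y) p(z3) p(y)` and the classifier sees z1 alone.  All
#' shared hyperparameters follow the full model's configuration.
#'
#' @inheritParams drvae_fit
#' @return A list with `model` (the trained SSVAE) and `predictions`
#'   (response probabilities for every pre-treatment profile in `train`).
#' @export
ssvae_variant <- function(train, val = NULL, config, seed = 1L,
                          verbose = FALSE) {
  model <- drvae_fit(train, val, config, seed, model_type = "ssvae",
                     verbose = verbose)
  flat <- batch_flatten_pairs(train)
  list(model = model,
       predictions = predict_response(flat$x1_singletons,
                                      model)$prob_sensitive)
}

#' Train the PertVAE ablation
#'
#' The unsupervised perturbation sub-model: `p(x1|z1) p(x2|z2) p(z2|z1) p(z1)`
#' with a standard-normal prior on z1 and posterior `q(z1|x1) q(z2|x2)`.
#' Labels, if present, are ignored.
#'
#' @inheritParams drvae_fit
#' @return A list with `model` and `embed`, a function mapping expression to
#'   the latent posterior mean for downstream classifiers.
#' @export
pertvae_variant <- function(train, val = NULL, config, seed = 1L,
                            verbose = FALSE) {
  model <- drvae_fit(train, val, config, seed, model_type = "pertvae",
                     verbose = verbose)
  list(model = model, embed = function(x) pertvae_embed(x, model))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single portable archive holding a format-version field,
#' the configuration, every parameter tensor by name, and the training log.
#'
#' @param model A `drvae_model`.
#' @param path File path for the checkpoint.
#' @return `drvae_save` returns `path` invisibly; `drvae_load` returns the
#'   restored `drvae_model`.
#' @export
drvae_save <- function(model, path) {
  stopifnot(inherits(model, "drvae_model"))
  saveRDS(list(format_version = 1L,
               model_type = model$model_type,
               config = model$config,
               class_loss_weight = model$class_loss_weight,
               params = model$params,
               log = model$log), path)
  invisible(path)
}

#' @rdname drvae_save
#' @param expect_genes Optional gene count the checkpoint must match; a
#'   mismatch is an error.
#' @export
drvae_load <- function(path, expect_genes = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) {
    stop("unsupported checkpoint format version: ", obj$format_version,
         call. = FALSE)
  }
  if (!is.null(expect_genes) && obj$config$n_genes != expect_genes) {
    stop("checkpoint gene count (", obj$config$n_genes,
         ") does not match the expected gene count (", expect_genes, ")",
         call. = FALSE)
  }
  structure(list(params = obj$params, config = obj$config,
                 model_type = obj$model_type,
                 class_loss_weight = obj$class_loss_weight,
                 log = obj$log),
            class = "drvae_model")
}
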