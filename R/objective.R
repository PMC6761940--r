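# The semi-supervised variational objective.
#
# Single-sample reparameterized estimators of the four evidence lower bounds
# (labeled/unlabeled perturbation pairs, labeled/unlabeled singletons).
# Gaussian-Gaussian KL sub-terms whose two factors do not share a sampled
# conditioning variable on the q side are computed in closed form
# (KL(q(z2|x2) || p(z2|z1)) given the z1 sample, and KL(q(z3|z1,y) || p(z3))
# given the z1 sample); the z1 cross/entropy terms are kept in sampled form
# because q(z3 | z1, y) conditions on the same z1 sample.

LOG_HALF <- log(0.5)

# Classifier score node: logit(y = 1) - logit(y = 0); n x 1.
ad_cls_score <- function(tp, pn, model_type, z1, delta) {
  H <- if (model_type == "drvae") ad_cbind(tp, z1, delta) else z1
  n <- nrow(H$value)
  logits <- ad_add(tp, ad_mm(tp, H, pn$cls$W), ad_tile_rows(tp, pn$cls$b, n))
  ad_mm(tp, logits, ad_const(tp, matrix(c(-1, 1), 2L, 1L)))
}

# z3 branch of the bound for a fixed label column: E_q(z3|z1,y)[log p(z1|z3,y)]
# - KL(q(z3|z1,y) || N(0, I)), per sample (n x 1).
ad_z3_branch <- function(tp, pn, z1, yvec, eps3) {
  ycol <- ad_const(tp, matrix(yvec, ncol = 1L))
  q3 <- ad_gauss_fwd(tp, pn$z3enc, ad_cbind(tp, z1, ycol))
  z3 <- ad_gauss_sample(tp, q3$mean, q3$log_var, eps3)
  kl3 <- ad_gauss_row_kl_std(tp, q3$mean, q3$log_var)
  p1 <- ad_gauss_fwd(tp, pn$z1prior, ad_cbind(tp, z3, ycol))
  cross <- ad_gauss_row_logdens(tp, z1, p1$mean, p1$log_var)
  ad_sub(tp, cross, kl3)
}

# Marginalize the discrete label: q0 * branch0 + q1 * branch1 + entropy(q(y)).
ad_marginalize_y <- function(tp, score, branch0, branch1) {
  p1 <- ad_sigmoid(tp, score)
  p0 <- ad_shift(tp, ad_scale(tp, p1, -1), 1)
  sp_pos <- ad_softplus(tp, score)                       # -log(1 - p)
  sp_neg <- ad_softplus(tp, ad_scale(tp, score, -1))     # -log(p)
  entropy <- ad_add(tp, ad_mul(tp, p1, sp_neg), ad_mul(tp, p0, sp_pos))
  ad_add(tp, ad_add(tp, ad_mul(tp, p0, branch0), ad_mul(tp, p1, branch1)),
         entropy)
}

# Cross-entropy of the classifier at the observed labels: softplus(s) - y * s.
ad_cls_ce <- function(tp, score, yvec) {
  ad_sub(tp, ad_softplus(tp, score),
         ad_mul(tp, ad_const(tp, matrix(yvec, ncol = 1L)), score))
}

# Per-sample ELBO nodes for a block of perturbation pairs.
# Returns list(elbo = n x 1 node, ce = n x 1 node or NULL).
ad_elbo_pairs <- function(tp, pn, model_type, X1, X2, yvec, eps, clamp_eps) {
  n <- nrow(X1); G <- ncol(X1); d <- ncol(eps$e1)
  X1n <- ad_const(tp, X1); X2n <- ad_const(tp, X2)
  q1 <- ad_gauss_fwd(tp, pn$enc, X1n)
  q2 <- ad_gauss_fwd(tp, pn$enc, X2n)
  z1 <- ad_gauss_sample(tp, q1$mean, q1$log_var, eps$e1)
  z2 <- ad_gauss_sample(tp, q2$mean, q2$log_var, eps$e2)
  dlv <- ad_tile_rows(tp, pn$dec_log_var, n)
  recon1 <- ad_gauss_row_logdens(tp, X1n, ad_mean_fwd(tp, pn$dec, z1), dlv)
  recon2 <- ad_gauss_row_logdens(tp, X2n, ad_mean_fwd(tp, pn$dec, z2), dlv)
  pmean <- ad_add(tp, z1, ad_add(tp, ad_mm_nt(tp, z1, pn$pert$W),
                                 ad_tile_rows(tp, pn$pert$b, n)))
  plv <- ad_tile_rows(tp, pn$pert$log_var, n)
  kl_z2 <- ad_gauss_row_kl(tp, q2$mean, q2$log_var, pmean, plv)
  recon <- ad_sub(tp, ad_add(tp, recon1, recon2), kl_z2)

  if (model_type == "pertvae") {
    kl_z1 <- ad_gauss_row_kl_std(tp, q1$mean, q1$log_var)
    return(list(elbo = ad_sub(tp, recon, kl_z1), ce = NULL))
  }

  ent1 <- ad_scale(tp, ad_gauss_row_logdens(tp, z1, q1$mean, q1$log_var), -1)
  base <- ad_shift(tp, ad_add(tp, recon, ent1), LOG_HALF)
  score <- ad_cls_score(tp, pn, model_type, z1, ad_sub(tp, z2, z1))
  labeled <- !is.na(yvec[1L])
  if (labeled) {
    elbo <- ad_add(tp, base, ad_z3_branch(tp, pn, z1, yvec, eps$e3))
    ce <- ad_cls_ce(tp, score, yvec)
  } else {
    b0 <- ad_z3_branch(tp, pn, z1, rep(0, n), eps$e3)
    b1 <- ad_z3_branch(tp, pn, z1, rep(1, n), eps$e3)
    elbo <- ad_add(tp, base, ad_marginalize_y(tp, score, b0, b1))
    ce <- NULL
  }
  list(elbo = elbo, ce = ce)
}

# Per-sample ELBO nodes for a block of pre-treatment singletons.
ad_elbo_singletons <- function(tp, pn, model_type, X1, yvec, eps, clamp_eps) {
  n <- nrow(X1)
  X1n <- ad_const(tp, X1)
  q1 <- ad_gauss_fwd(tp, pn$enc, X1n)
  z1 <- ad_gauss_sample(tp, q1$mean, q1$log_var, eps$e1)
  dlv <- ad_tile_rows(tp, pn$dec_log_var, n)
  recon1 <- ad_gauss_row_logdens(tp, X1n, ad_mean_fwd(tp, pn$dec, z1), dlv)

  if (model_type == "pertvae") {
    kl_z1 <- ad_gauss_row_kl_std(tp, q1$mean, q1$log_var)
    return(list(elbo = ad_sub(tp, recon1, kl_z1), ce = NULL))
  }

  ent1 <- ad_scale(tp, ad_gauss_row_logdens(tp, z1, q1$mean, q1$log_var), -1)
  base <- ad_shift(tp, ad_add(tp, recon1, ent1), LOG_HALF)
  # With x2 unobserved the classifier sees the mean of p(z2 | z1) for z2,
  # i.e. the delta block is z1 W' + b (identically zero at W = b = 0).
  delta <- if (model_type == "drvae") {
    ad_add(tp, ad_mm_nt(tp, z1, pn$pert$W), ad_tile_rows(tp, pn$pert$b, n))
  } else {
    NULL
  }
  score <- ad_cls_score(tp, pn, model_type, z1, delta)
  labeled <- !is.na(yvec[1L])
  if (labeled) {
    elbo <- ad_add(tp, base, ad_z3_branch(tp, pn, z1, yvec, eps$e3))
    ce <- ad_cls_ce(tp, score, yvec)
  } else {
    b0 <- ad_z3_branch(tp, pn, z1, rep(0, n), eps$e3)
    b1 <- ad_z3_branch(tp, pn, z1, rep(1, n), eps$e3)
    elbo <- ad_add(tp, base, ad_marginalize_y(tp, score, b0, b1))
    ce <- NULL
  }
  list(elbo = elbo, ce = ce)
}

# Canonical regime split of a batch under a model type.
split_regimes <- function(batch, model_type) {
  if (model_type == "ssvae") batch <- batch_flatten_pairs(batch)
  lp <- which(!is.na(batch$y_pairs)); up <- which(is.na(batch$y_pairs))
  ls <- which(!is.na(batch$y_singletons))
  us <- which(is.na(batch$y_singletons))
  if (model_type == "pertvae") {
    # Unsupervised: labels are ignored, all pairs/singletons pool together.
    list(batch = batch, lp = integer(), up = seq_along(batch$y_pairs),
         ls = integer(), us = seq_along(batch$y_singletons))
  } else {
    list(batch = batch, lp = lp, up = up, ls = ls, us = us)
  }
}

# Draw reparameterization noise for every regime, in a fixed canonical order
# (labeled pairs, unlabeled pairs, labeled singletons, unlabeled singletons)
# so that runs are reproducible under a seed.
draw_objective_noise <- function(model, regimes) {
  d <- model$config$latent_dim; d3 <- model$config$z3_dim
  rn <- function(n, k) {
    if (n == 0L) NULL else matrix(stats::rnorm(n * k), n, k)
  }
  with_z3 <- model$model_type != "pertvae"
  pair_eps <- function(n) {
    list(e1 = rn(n, d), e2 = rn(n, d),
         e3 = if (with_z3) rn(n, d3) else NULL)
  }
  single_eps <- function(n) {
    list(e1 = rn(n, d), e3 = if (with_z3) rn(n, d3) else NULL)
  }
  list(lp = pair_eps(length(regimes$lp)), up = pair_eps(length(regimes$up)),
       ls = single_eps(length(regimes$ls)),
       us = single_eps(length(regimes$us)))
}

# Build the full objective graph; returns scalar loss node plus bookkeeping.
objective_graph <- function(tp, pn, model, batch, noise) {
  mt <- model$model_type
  reg <- split_regimes(batch, mt)
  b <- reg$batch
  if (is.null(noise)) noise <- draw_objective_noise(model, reg)
  ce_eps <- model$config$clamp_eps
  pieces <- list()
  if (length(reg$lp)) {
    pieces$lp <- ad_elbo_pairs(tp, pn, mt,
                               b$x1_pairs[reg$lp, , drop = FALSE],
                               b$x2_pairs[reg$lp, , drop = FALSE],
                               b$y_pairs[reg$lp], noise$lp, ce_eps)
  }
  if (length(reg$up)) {
    pieces$up <- ad_elbo_pairs(tp, pn, mt,
                               b$x1_pairs[reg$up, , drop = FALSE],
                               b$x2_pairs[reg$up, , drop = FALSE],
                               b$y_pairs[reg$up], noise$up, ce_eps)
  }
  if (length(reg$ls)) {
    pieces$ls <- ad_elbo_singletons(tp, pn, mt,
                                    b$x1_singletons[reg$ls, , drop = FALSE],
                                    b$y_singletons[reg$ls], noise$ls, ce_eps)
  }
  if (length(reg$us)) {
    pieces$us <- ad_elbo_singletons(tp, pn, mt,
                                    b$x1_singletons[reg$us, , drop = FALSE],
                                    b$y_singletons[reg$us], noise$us, ce_eps)
  }
  if (!length(pieces)) stop("empty batch", call. = FALSE)
  loss <- NULL
  add_piece <- function(loss, node) {
    if (is.null(loss)) node else ad_add(tp, loss, node)
  }
  for (pc in pieces) {
    loss <- add_piece(loss, ad_scale(tp, ad_sum(tp, pc$elbo), -1))
    if (!is.null(pc$ce) && model$class_loss_weight > 0) {
      loss <- add_piece(loss, ad_scale(tp, ad_sum(tp, pc$ce),
                                       model$class_loss_weight))
    }
  }
  list(loss = loss, pieces = pieces, regimes = reg)
}

#' Semi-supervised training objective
#'
#' Single-sample estimate of the negative sum of the four evidence lower
#' bounds (labeled/unlabeled pairs and singletons) plus
#' `class_loss_weight` times the classifier cross-entropy on labeled items.
#' This is the quantity minimized during training.
#'
#' @param batch A [drvae_batch()].
#' @param model A `drvae_model` (its `class_loss_weight` field weights the
#'   cross-entropy term).
#' @param noise Optional explicit reparameterization noise (advanced use;
#'   the list structure produced internally).  When `NULL`, noise is drawn
#'   from the current RNG (or under `seed` if given).
#' @param seed Optional seed for the noise draw; the caller's RNG state is
#'   restored afterwards.
#' @return A single numeric value.
#' @export
total_objective <- function(batch, model, noise = NULL, seed = NULL) {
  stopifnot(inherits(batch, "drvae_batch"), inherits(model, "drvae_model"))
  if (batch_n_items(batch) == 0L) stop("empty batch", call. = FALSE)
  with_seed(seed, {
    tp <- ad_tape()
    pn <- params_to_nodes(tp, model$params)
    g <- objective_graph(tp, pn, model, batch, noise)
    v <- g$loss$value[1L]
    if (!is.finite(v)) {
      stop("non-finite objective value (", v, "); ",
           "check inputs and learning rate", call. = FALSE)
    }
    v
  })
}

# Objective value and nested gradient list, via backprop.
objective_grad <- function(batch, model, noise = NULL, seed = NULL) {
  with_seed(seed, {
    tp <- ad_tape()
    pn <- params_to_nodes(tp, model$params)
    g <- objective_graph(tp, pn, model, batch, noise)
    ad_backward(tp, g$loss)
    list(value = g$loss$value[1L], grads = nodes_to_grads(pn))
  })
}

elbo_noise_pairs <- function(model, n, noise, seed) {
  d <- model$config$latent_dim; d3 <- model$config$z3_dim
  if (!is.null(noise)) return(noise)
  with_seed(seed, list(e1 = matrix(stats::rnorm(n * d), n, d),
                       e2 = matrix(stats::rnorm(n * d), n, d),
                       e3 = matrix(stats::rnorm(n * d3), n, d3)))
}

#' Evidence lower bound for perturbation pairs
#'
#' Single-sample estimate of the pair ELBO, labeled (`y` given) or unlabeled
#' (`y = NULL`; the label is marginalized under the classifier posterior,
#' adding its entropy).  Vectorized: matrix inputs give one value per row.
#'
#' @param x1,x2 Pre-/post-treatment expression (vector or matrix).
#' @param y Label in `{0, 1}`, a vector of labels, or `NULL` for unlabeled.
#' @param model A `drvae_model` of type `"drvae"`.
#' @param noise Optional list with noise matrices `e1`, `e2`, `e3`.
#' @param seed Optional seed for the noise draw.
#' @return Numeric scalar (or vector for matrix input).
#' @export
elbo_pair <- function(x1, x2, y = NULL, model, noise = NULL, seed = NULL) {
  X1 <- check_expr_dim(x1, model, "x1"); X2 <- check_expr_dim(x2, model, "x2")
  stopifnot(nrow(X1) == nrow(X2))
  n <- nrow(X1)
  if (!is.null(y)) {
    stopifnot(all(y %in% c(0, 1)))
    y <- rep_len(as.numeric(y), n)
  } else {
    y <- rep(NA_real_, n)
  }
  eps <- elbo_noise_pairs(model, n, noise, seed)
  tp <- ad_tape()
  pn <- params_to_nodes(tp, model$params)
  out <- ad_elbo_pairs(tp, pn, model$model_type, X1, X2, y, eps,
                       model$config$clamp_eps)
  v <- as.numeric(out$elbo$value)
  if (n == 1L) v[1L] else v
}

#' Evidence lower bound for pre-treatment singletons
#'
#' As [elbo_pair()] but without the post-treatment reconstruction and
#' perturbation terms.  When the classifier posterior needs z2 it uses the
#' mean of `p(z2 | z1)`.
#'
#' @param x1 Pre-treatment expression (vector or matrix).
#' @param y Label in `{0, 1}`, a vector, or `NULL` for unlabeled.
#' @param model A `drvae_model`.
#' @param noise Optional list with noise matrices `e1`, `e3`.
#' @param seed Optional seed for the noise draw.
#' @return Numeric scalar (or vector for matrix input).
#' @export
elbo_singleton <- function(x1, y = NULL, model, noise = NULL, seed = NULL) {
  X1 <- check_expr_dim(x1, model, "x1")
  n <- nrow(X1)
  if (!is.null(y)) {
    stopifnot(all(y %in% c(0, 1)))
    y <- rep_len(as.numeric(y), n)
  } else {
    y <- rep(NA_real_, n)
  }
  d <- model$config$latent_dim; d3 <- model$config$z3_dim
  if (is.null(noise)) {
    noise <- with_seed(seed, list(e1 = matrix(stats::rnorm(n * d), n, d),
                                  e3 = matrix(stats::rnorm(n * d3), n, d3)))
  }
  tp <- ad_tape()
  pn <- params_to_nodes(tp, model$params)
  out <- ad_elbo_singletons(tp, pn, model$model_type, X1, y, noise,
                            model$config$clamp_eps)
  v <- as.numeric(out$elbo$value)
  if (n == 1L) v[1L] else v
}
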