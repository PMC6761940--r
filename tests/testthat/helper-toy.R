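# Hand-set linear toy models (1 gene, 1 latent dim, no hidden layers) and an
# independent quadrature oracle for their log evidence.  The oracle uses only
# explicit scalar density formulas (dnorm + trapezoidal integration), never
# the package's forward passes.

toy_par_names <- c("enc_a", "enc_b", "enc_lv", "g", "h", "sx",
                   "pW", "pb", "sp", "q3_a", "q3_by", "q3_c", "q3_lv",
                   "pr_a", "pr_by", "pr_c", "pr_lv")

make_toy_model <- function(pars, cls_w = c(0.3, -0.2, 0.1, 0.4)) {
  cfg <- drvae_config(n_genes = 1, latent_dim = 1, z3_dim = 1,
                      hidden_codec = 0, hidden_aux = 0,
                      class_loss_weights = 1)
  m <- drvae_init(cfg, "drvae", seed = 1)
  m$params$enc$Wm[] <- pars$enc_a
  m$params$enc$bm[] <- pars$enc_b
  m$params$enc$Wv[] <- 0
  m$params$enc$bv[] <- pars$enc_lv
  m$params$dec$Wm[] <- pars$g
  m$params$dec$bm[] <- pars$h
  m$params$dec_log_var[] <- log(pars$sx)
  m$params$pert$W[] <- pars$pW
  m$params$pert$b[] <- pars$pb
  m$params$pert$log_var[] <- log(pars$sp)
  m$params$z3enc$Wm[] <- c(pars$q3_a, pars$q3_by)
  m$params$z3enc$bm[] <- pars$q3_c
  m$params$z3enc$Wv[] <- 0
  m$params$z3enc$bv[] <- pars$q3_lv
  m$params$z1prior$Wm[] <- c(pars$pr_a, pars$pr_by)
  m$params$z1prior$bm[] <- pars$pr_c
  m$params$z1prior$Wv[] <- 0
  m$params$z1prior$bv[] <- pars$pr_lv
  m$params$cls$W[] <- cls_w
  m$params$cls$b[] <- 0
  m
}

# Log evidence of the toy model by nested 1-d quadrature: outer integral over
# z1, inner integrals over z3 (the z1 prior marginal) and over z2 (the
# post-treatment likelihood).  y = NULL marginalizes the uniform binary label.
toy_log_evidence <- function(pars, x1, x2 = NULL, y = NULL,
                             lim = 10, n = 2501) {
  zg <- seq(-lim, lim, length.out = n)
  dz <- zg[2] - zg[1]
  pz1y <- function(yv) {
    vapply(zg, function(z1v) {
      mu <- pars$pr_a * zg + pars$pr_by * yv + pars$pr_c
      sum(dnorm(z1v, mu, sqrt(exp(pars$pr_lv))) * dnorm(zg)) * dz
    }, numeric(1))
  }
  lik1 <- dnorm(x1, pars$g * zg + pars$h, sqrt(pars$sx))
  evid_y <- function(yv) {
    f <- lik1 * pz1y(yv)
    if (!is.null(x2)) {
      lik2 <- dnorm(x2, pars$g * zg + pars$h, sqrt(pars$sx))
      ix2 <- vapply(zg, function(z1v) {
        m2 <- z1v + pars$pW * z1v + pars$pb
        sum(lik2 * dnorm(zg, m2, sqrt(pars$sp))) * dz
      }, numeric(1))
      f <- f * ix2
    }
    sum(f) * dz
  }
  if (!is.null(y)) {
    log(evid_y(y)) + log(0.5)
  } else {
    log(0.5 * evid_y(0) + 0.5 * evid_y(1))
  }
}

toy_pars_random <- function() {
  list(enc_a = 0.4, enc_b = 0.1, enc_lv = log(0.5), g = 0.9, h = -0.2,
       sx = 0.4, pW = 0.3, pb = 0.25, sp = 0.6,
       q3_a = 0.5, q3_by = -0.3, q3_c = 0.05, q3_lv = log(0.7),
       pr_a = 0.7, pr_by = 0.5, pr_c = -0.1, pr_lv = log(0.5))
}

# Conjugate linear-Gaussian construction whose variational family contains
# the true posterior for the tested label y* = 1: the perturbation weight is
# -1 (z2 independent of z1) and every q is set to the exact conditional
# computed by standard Gaussian conjugacy.
toy_pars_conjugate <- function() {
  a <- 0.6; s1 <- 0.5; c0 <- 0.3; cy <- 0.4
  g <- 0.8; h <- 0.1; sx <- 0.3
  ystar <- 1
  cys <- c0 + cy * ystar
  v0 <- a^2 + s1                        # marginal var of z1 | y*
  prec <- 1 / v0 + g^2 / sx             # posterior precision of z1 | x1, y*
  prec3 <- 1 + a^2 / s1                 # posterior precision of z3 | z1, y
  al <- (a / s1) / prec3
  list(enc_a = (g / sx) / prec,
       enc_b = (cys / v0 - g * h / sx) / prec,
       enc_lv = log(1 / prec),
       g = g, h = h, sx = sx,
       pW = -1, pb = cys, sp = v0,
       q3_a = al, q3_by = -al * cy, q3_c = -al * c0, q3_lv = log(1 / prec3),
       pr_a = a, pr_by = cy, pr_c = c0, pr_lv = log(s1))
}

# Small random training fixture drawn from the generator.
small_fixture <- function(seed = 1, n_pairs = 40, n_singletons = 200,
                          n_genes = 12, d = 4) {
  cf <- synthetic_config(n_genes = n_genes, latent_dim_true = 2,
                         n_cell_lines_pairs = n_pairs,
                         n_singletons = n_singletons,
                         effect_scale = 1, noise_sd_gene = 0.1,
                         decoder_gain = 0.2, seed = seed)
  as_drvae_batch(synthetic_generate(cf))
}

small_config <- function(n_genes = 12, d = 4, max_epochs = 10,
                         learning_rate = 1e-3) {
  drvae_config(n_genes = n_genes, latent_dim = d, z3_dim = d,
               hidden_codec = 8, hidden_aux = 4, class_loss_weights = 1,
               batch_size = 64, max_epochs = max_epochs,
               patience = max(10, max_epochs),
               learning_rate = learning_rate)
}

flat_params <- function(model) drvae:::param_flatten(model$params)
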