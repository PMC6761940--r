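test_that("shared encoder/decoder contracts: shapes, determinism, degeneracy", {
  cfg <- small_config()
  m <- drvae_init(cfg, "drvae", seed = 2)
  x <- rnorm(12)
  g1 <- drvae_encode(x, m)
  g2 <- drvae_encode(x, m)
  expect_identical(g1, g2)           # same encoder for pre/post profiles
  expect_length(g1$mean, 4)
  expect_length(g1$log_var, 4)
  # default latent dimensionality is 100
  m100 <- drvae_init(drvae_config(n_genes = 8, hidden_codec = 4,
                                  hidden_aux = 4), "drvae", seed = 1)
  expect_length(drvae_encode(rnorm(8), m100)$mean, 100)
  # degenerate zero-weight encoder emits a constant distribution
  mz <- m
  for (nm in names(mz$params$enc)) mz$params$enc[[nm]][] <- 0
  expect_identical(drvae_encode(rnorm(12), mz), drvae_encode(rnorm(12), mz))
  # decode round trip has gene dimension and is shared across the k roles
  z <- drvae_encode(x, m)$mean
  dec <- drvae_decode(z, m)
  expect_length(dec$mean, 12)
  expect_identical(drvae_decode(z, m), dec)
  expect_error(drvae_encode(rnorm(5), m), "dimension")
  expect_error(drvae_decode(rnorm(3), m), "dimension")
})

test_that("latent perturbation is the linear map z1 + W z1 + b", {
  cfg <- small_config(d = 2)
  m <- drvae_init(cfg, "drvae", seed = 3)
  m$params$pert$W[] <- 0
  m$params$pert$b[] <- 0
  z <- c(0.7, -1.1)
  expect_equal(drvae_perturb(z, m)$mean, z)
  m$params$pert$b[] <- 1
  expect_equal(drvae_perturb(z, m)$mean, z + 1)
  # direct matrix arithmetic oracle
  m$params$pert$W <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  m$params$pert$b <- matrix(c(0.5, 0), 1)
  expect_equal(drvae_perturb(c(1, 0), m)$mean, c(1.5, 0))
  # variance is state-independent
  expect_equal(drvae_perturb(c(1, 0), m)$log_var,
               drvae_perturb(c(-3, 2), m)$log_var)
})

test_that("classifier is a two-unit softmax on [z1, z2 - z1]", {
  cfg <- small_config(d = 2)
  m <- drvae_init(cfg, "drvae", seed = 4)
  m$params$cls$W[] <- 0
  m$params$cls$b[] <- 0
  expect_equal(drvae_classify(rnorm(2), rnorm(2), m), 0.5)
  # with z2 = z1 the difference block is zero: only z1 weights matter
  m$params$cls$W[] <- rnorm(8)
  z <- rnorm(2)
  p0 <- drvae_classify(z, z, m)
  m2 <- m
  m2$params$cls$W[3:4, ] <- 99   # perturb only the difference-block weights
  expect_equal(drvae_classify(z, z, m2), p0)
  # scalar logistic oracle at d = 1
  cfg1 <- small_config(n_genes = 3, d = 1)
  m1 <- drvae_init(cfg1, "drvae", seed = 5)
  # columns are the (y0, y1) logit weights over input (z1, z2 - z1)
  m1$params$cls$W <- matrix(c(0, 0, 0.8, -0.3), 2, 2)
  m1$params$cls$b <- matrix(c(0, 0.2), 1)
  z1 <- 0.9; z2 <- -0.4
  score <- (0.8 * z1 - 0.3 * (z2 - z1) + 0.2) - 0
  expect_equal(drvae_classify(z1, z2, m1), plogis(score), tolerance = 1e-12)
})

test_that("z3 posterior and conditional prior have the declared contracts", {
  cfg <- small_config(d = 3)
  cfg$z3_dim <- 2L
  m <- drvae_init(cfg, "drvae", seed = 6)
  q3 <- drvae_infer_z3(rnorm(3), 1, m)
  expect_length(q3$mean, 2)
  expect_identical(drvae_infer_z3(c(1, 2, 3), 0, m),
                   drvae_infer_z3(c(1, 2, 3), 0, m))
  p1 <- drvae_prior_z1(rnorm(2), 0, m)
  expect_length(p1$mean, 3)
  # degenerate prior net ignores its inputs
  mz <- m
  for (nm in names(mz$params$z1prior)) mz$params$z1prior[[nm]][] <- 0
  expect_equal(drvae_prior_z1(rnorm(2), 0, mz), drvae_prior_z1(rnorm(2), 1, mz))
  # full ancestral sampling yields finite expression of length G
  set.seed(7)
  z3 <- rnorm(2)
  y <- rbinom(1, 1, 0.5)
  z1 <- reparameterize(drvae_prior_z1(z3, y, m), rnorm(3))
  x <- reparameterize(drvae_decode(z1, m), rnorm(12))
  expect_length(x, 12)
  expect_true(all(is.finite(x)))
})

test_that("ELBO estimators obey the label-marginalization identities", {
  pars <- toy_pars_random()
  m <- make_toy_model(pars, cls_w = rep(0, 4))   # classifier fixed at 0.5
  x1 <- 0.3; x2 <- -0.5
  noise <- list(e1 = matrix(0.4), e2 = matrix(-1.2), e3 = matrix(0.8))
  l0 <- elbo_pair(x1, x2, y = 0, m, noise = noise)
  l1 <- elbo_pair(x1, x2, y = 1, m, noise = noise)
  lu <- elbo_pair(x1, x2, y = NULL, m, noise = noise)
  expect_equal(lu, (l0 + l1) / 2 + log(2), tolerance = 1e-10)
  sn <- list(e1 = matrix(0.4), e3 = matrix(0.8))
  s0 <- elbo_singleton(x1, y = 0, m, noise = sn)
  s1 <- elbo_singleton(x1, y = 1, m, noise = sn)
  su <- elbo_singleton(x1, y = NULL, m, noise = sn)
  expect_equal(su, (s0 + s1) / 2 + log(2), tolerance = 1e-10)
  # with the label edge weights zeroed, the labeled bounds coincide across y
  pars0 <- pars; pars0$q3_by <- 0; pars0$pr_by <- 0
  my <- make_toy_model(pars0)
  expect_equal(elbo_singleton(x1, y = 0, my, noise = sn),
               elbo_singleton(x1, y = 1, my, noise = sn), tolerance = 1e-12)
})

test_that("ELBO is invariant to a consistent gene permutation", {
  cfg <- small_config()
  m <- drvae_init(cfg, "drvae", seed = 8)
  set.seed(9)
  x1 <- rnorm(12); x2 <- rnorm(12)
  noise <- list(e1 = matrix(rnorm(4), 1), e2 = matrix(rnorm(4), 1),
                e3 = matrix(rnorm(4), 1))
  v0 <- elbo_pair(x1, x2, y = 1, m, noise = noise)
  perm <- sample(12)
  mp <- m
  mp$params$enc$W1 <- m$params$enc$W1[perm, , drop = FALSE]
  mp$params$dec$Wm <- m$params$dec$Wm[, perm, drop = FALSE]
  mp$params$dec$bm <- m$params$dec$bm[, perm, drop = FALSE]
  mp$params$dec_log_var <- m$params$dec_log_var[, perm, drop = FALSE]
  expect_equal(elbo_pair(x1[perm], x2[perm], y = 1, mp, noise = noise), v0,
               tolerance = 1e-10)
})

test_that("total objective: regime structure, additivity, validation errors", {
  cfg <- small_config()
  m <- drvae_init(cfg, "drvae", seed = 10)
  set.seed(11)
  Xs <- matrix(rnorm(3 * 12), 3, 12)
  ns <- list(e1 = matrix(rnorm(12), 3, 4), e3 = matrix(rnorm(12), 3, 4))
  # unlabeled singletons only: objective is the negative ELBO sum,
  # whatever the class loss weight
  b_us <- drvae_batch(x1_singletons = Xs)
  m$class_loss_weight <- 37
  expect_equal(total_objective(b_us, m, noise = list(us = ns)),
               -sum(elbo_singleton(Xs, NULL, m, noise = ns)),
               tolerance = 1e-10)
  # labeled data with weight zero: pure negative ELBO
  ys <- c(1, 0, 1)
  b_ls <- drvae_batch(x1_singletons = Xs, y_singletons = ys)
  m$class_loss_weight <- 0
  expect_equal(total_objective(b_ls, m, noise = list(ls = ns)),
               -sum(elbo_singleton(Xs, ys, m, noise = ns)),
               tolerance = 1e-10)
  # duplicating every item (and its noise) doubles the objective
  m$class_loss_weight <- 2.5
  b2 <- drvae_batch(x1_singletons = rbind(Xs, Xs),
                    y_singletons = c(ys, ys))
  ns2 <- list(e1 = rbind(ns$e1, ns$e1), e3 = rbind(ns$e3, ns$e3))
  expect_equal(total_objective(b2, m, noise = list(ls = ns2)),
               2 * total_objective(b_ls, m, noise = list(ls = ns)),
               tolerance = 1e-10)
  expect_error(drvae_batch(), NA)
  expect_error(total_objective(drvae_batch(), m), "empty")
})

test_that("objective gradients match central finite differences", {
  cfg <- drvae_config(n_genes = 5, latent_dim = 2, z3_dim = 2,
                      hidden_codec = 3, hidden_aux = 2,
                      class_loss_weights = 1)
  m <- drvae_init(cfg, "drvae", seed = 12)
  m$class_loss_weight <- 1.7
  set.seed(13)
  b <- drvae_batch(x1_pairs = matrix(rnorm(10), 2, 5),
                   x2_pairs = matrix(rnorm(10), 2, 5),
                   y_pairs = c(1, NA),
                   x1_singletons = matrix(rnorm(15), 3, 5),
                   y_singletons = c(0, NA, 1))
  reg <- drvae:::split_regimes(b, "drvae")
  noise <- drvae:::with_seed(14, drvae:::draw_objective_noise(m, reg))
  g <- drvae:::objective_grad(b, m, noise = noise)
  flat_g <- drvae:::param_flatten(g$grads)
  theta <- drvae:::param_flatten(m$params)
  skel <- m$params
  idx <- sort(sample(length(theta), 60))
  h <- 1e-5
  for (i in idx) {
    tp <- theta; tp[i] <- theta[i] + h
    m$params <- drvae:::param_unflatten(tp, skel)
    up <- total_objective(b, m, noise = noise)
    tp[i] <- theta[i] - h
    m$params <- drvae:::param_unflatten(tp, skel)
    dn <- total_objective(b, m, noise = noise)
    fd <- (up - dn) / (2 * h)
    denom <- max(abs(fd), abs(flat_g[i]), 1e-4)
    expect_lt(abs(unname(flat_g[i]) - fd) / denom, 1e-3)
  }
})

test_that("training descends, is reproducible, and respects a zero epoch budget", {
  batch <- small_fixture(seed = 15, n_pairs = 40, n_singletons = 200)
  cfg <- small_config(max_epochs = 50, learning_rate = 3e-3)
  m0 <- drvae_init(cfg, "drvae", seed = 16)
  obj0 <- total_objective(batch, m0, seed = 17)
  m <- suppressWarnings(drvae_fit(batch, NULL, cfg, seed = 16))
  objT <- total_objective(batch, m, seed = 17)
  expect_lt(objT, obj0)
  # bitwise reproducibility of the training log under a fixed seed
  cfg3 <- small_config(max_epochs = 3)
  l1 <- suppressWarnings(drvae_fit(batch, NULL, cfg3, seed = 18))$log
  l2 <- suppressWarnings(drvae_fit(batch, NULL, cfg3, seed = 18))$log
  expect_identical(l1, l2)
  # zero epochs returns the near-identity initialization
  cfg0 <- small_config(max_epochs = 0)
  mz <- suppressWarnings(drvae_fit(batch, NULL, cfg0, seed = 19))
  expect_lt(max(abs(mz$params$pert$W)), 1e-3)
  expect_lt(max(abs(mz$params$pert$b)), 1e-3)
  expect_identical(mz$params, drvae_init(cfg0, "drvae", seed = 19)$params)
})

test_that("response prediction is deterministic mean propagation from x1 only", {
  cfg <- small_config(d = 2)
  m <- drvae_init(cfg, "drvae", seed = 20)
  m$params$pert$W[] <- 0; m$params$pert$b[] <- 0
  m$params$cls$W[] <- 0; m$params$cls$b[] <- 0
  x <- rnorm(12)
  pr <- predict_response(x, m)
  expect_equal(pr$prob_sensitive, 0.5)
  expect_equal(pr$z2_mean, pr$z1_mean)
  out <- predict_posttreatment(x, m)
  expect_length(out, 12)
  expect_true(all(is.finite(out)))
  # trained on a strong latent label effect, responders score higher
  cf <- synthetic_config(n_genes = 20, latent_dim_true = 2,
                         n_cell_lines_pairs = 80, n_singletons = 120,
                         effect_scale = 1.5, noise_sd_gene = 0.05,
                         decoder_gain = 0, label_gain = 6,
                         frac_pairs_labeled = 1, seed = 21)
  ds <- synthetic_generate(cf)
  batch <- as_drvae_batch(ds)
  cfg2 <- drvae_config(n_genes = 20, latent_dim = 2, z3_dim = 2,
                       hidden_codec = 8, hidden_aux = 4,
                       class_loss_weights = 10, batch_size = 64,
                       max_epochs = 30, patience = 30,
                       learning_rate = 3e-3)
  mt <- suppressWarnings(drvae_fit(batch, NULL, cfg2, seed = 22))
  p <- predict_response(batch$x1_singletons, mt)$prob_sensitive
  y <- batch$y_singletons
  expect_gt(mean(p[y == 1]), mean(p[y == 0]))
})

test_that("checkpoints round-trip and refuse mismatched gene counts", {
  cfg <- small_config()
  m <- drvae_init(cfg, "drvae", seed = 23)
  path <- tempfile(fileext = ".rds")
  drvae_save(m, path)
  m2 <- drvae_load(path, expect_genes = 12)
  x <- matrix(rnorm(24), 2, 12)
  expect_equal(predict_response(x, m2)$prob_sensitive,
               predict_response(x, m)$prob_sensitive)
  expect_error(drvae_load(path, expect_genes = 973), "gene count")
  unlink(path)
})
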