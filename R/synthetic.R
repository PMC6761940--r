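# Seeded generator of pharmacogenomic fixtures with known ground truth:
# latent cell-line states, a linear latent drug effect z2 = z1 + W z1 + b,
# a fixed decoder to gene space, replicate vehicle controls with shared
# batch/bead structure, logistic response labels on (z1, z2 - z1), and AAC
# sensitivity values that waterfall-binarize back to the labels at high
# signal.

#' Configuration of the synthetic pharmacogenomic generator
#'
#' Defaults describe a compact cohort that exercises every modeling regime:
#' matched perturbation pairs with replicate controls and batch structure,
#' labeled pre-treatment singletons, a low-dimensional linear latent drug
#' effect, and labels driven by a logistic rule on `(z1, z2 - z1)`.
#'
#' @param n_genes Number of genes (default 100; scalable to the ~973
#'   landmark-gene regime).
#' @param latent_dim_true Dimension of the ground-truth latent space.
#' @param n_cell_lines_pairs Number of cell lines with perturbation pairs
#'   (one pair each).
#' @param n_singletons Number of singleton-only cell lines.
#' @param replicates_per_control Vehicle-control replicates per pair.
#' @param effect_scale Scale of the random ground-truth `W*`, `b*`.
#' @param effect_W,effect_b Optional explicit ground-truth effect map
#'   (overrides `effect_scale` draws).
#' @param label_rule Optional logistic weight vector on `(z1, z2 - z1)`
#'   (length `2 * latent_dim_true`); drawn at random when `NULL`.
#' @param label_gain Steepness of the logistic label rule.
#' @param noise_sd_gene Gene-level observation noise standard deviation.
#' @param replicate_sd Replicate-control noise standard deviation.
#' @param aac_noise_sd Noise added to the AAC sensitivity values.
#' @param decoder Optional fixed decoder (list with `D`, orthonormal-column
#'   gene loading matrix, and `gain`), shared across datasets of a sweep.
#' @param decoder_gain Gain of the mild tanh nonlinearity applied after the
#'   linear decoding map; 0 gives a purely linear decoder.
#' @param frac_pairs_labeled Fraction of pairs carrying a response label.
#' @param batch_count Number of experimental batches for the pairs.
#' @param seed Integer seed; generation is fully reproducible under it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 100L,
                             latent_dim_true = 5L,
                             n_cell_lines_pairs = 20L,
                             n_singletons = 200L,
                             replicates_per_control = 3L,
                             effect_scale = 1,
                             effect_W = NULL,
                             effect_b = NULL,
                             label_rule = NULL,
                             label_gain = 4,
                             noise_sd_gene = 0.1,
                             replicate_sd = 0.1,
                             aac_noise_sd = 0.02,
                             decoder = NULL,
                             decoder_gain = 0.3,
                             frac_pairs_labeled = 0.5,
                             batch_count = 4L,
                             seed = 1L) {
  stopifnot(n_genes >= 1, latent_dim_true >= 1, latent_dim_true <= n_genes,
            n_cell_lines_pairs >= 1, n_singletons >= 0,
            replicates_per_control >= 1, noise_sd_gene >= 0,
            replicate_sd >= 0, aac_noise_sd >= 0, decoder_gain >= 0,
            frac_pairs_labeled >= 0, frac_pairs_labeled <= 1,
            batch_count >= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

synthetic_decoder <- function(n_genes, latent_dim_true, gain, seed = NULL) {
  with_seed(seed, {
    D <- qr.Q(qr(matrix(stats::rnorm(n_genes * latent_dim_true),
                        n_genes, latent_dim_true)))
    list(D = D, gain = gain)
  })
}

decode_truth <- function(decoder, z) {
  u <- z %*% t(decoder$D)
  if (decoder$gain > 0) tanh(decoder$gain * u) / decoder$gain else u
}

#' Generate a synthetic pharmacogenomic dataset
#'
#' Samples ground-truth latent states `z1 ~ N(0, I)` per cell line, applies
#' the linear latent effect `z2 = z1 + W* z1 + b*`, decodes both through a
#' fixed random map to gene space with additive noise, emits replicate
#' vehicle controls sharing batch/bead ids, and produces response labels and
#' AAC sensitivity values from a logistic rule on `(z1, z2 - z1)`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset` with elements
#'   `expression` (samples x genes matrix, all profiles incl. replicates),
#'   `pair_manifest` (data frame in the preprocessing pair format),
#'   `sensitivity` (data frame `drug_id`, `cell_line_id`, `aac`),
#'   `samples` (per-sample metadata), and `truth` (latents, `W_star`,
#'   `b_star`, decoder, labels, scores, `realized_ervr`, config).
#' @export
synthetic_generate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  G <- cf$n_genes; d <- cf$latent_dim_true
  set.seed(cf$seed)
  W <- if (!is.null(cf$effect_W)) cf$effect_W else
    matrix(stats::rnorm(d * d, sd = cf$effect_scale / sqrt(d)), d, d)
  b <- if (!is.null(cf$effect_b)) as.numeric(cf$effect_b) else
    stats::rnorm(d, sd = cf$effect_scale / 2)
  stopifnot(all(dim(W) == c(d, d)), length(b) == d)
  decoder <- if (!is.null(cf$decoder)) cf$decoder else
    synthetic_decoder(G, d, cf$decoder_gain)
  stopifnot(nrow(decoder$D) == G, ncol(decoder$D) == d)
  w_lab <- if (!is.null(cf$label_rule)) as.numeric(cf$label_rule) else
    stats::rnorm(2L * d) / sqrt(2L * d)
  stopifnot(length(w_lab) == 2L * d)

  np <- cf$n_cell_lines_pairs; ns <- cf$n_singletons
  ncl <- np + ns
  cl_ids <- sprintf("CL%04d", seq_len(ncl))
  pair_cls <- cl_ids[seq_len(np)]
  solo_cls <- if (ns > 0L) cl_ids[np + seq_len(ns)] else character()

  z1 <- matrix(stats::rnorm(ncl * d), ncl, d)
  z2 <- z1 + z1 %*% t(W) + matrix(b, ncl, d, byrow = TRUE)
  score <- as.numeric(cbind(z1, z2 - z1) %*% w_lab)
  p_lab <- stats::plogis(cf$label_gain * score)
  y <- stats::rbinom(ncl, 1L, p_lab)
  aac <- pmin(pmax(p_lab + stats::rnorm(ncl, sd = cf$aac_noise_sd), 0), 1)

  noise <- function(n) matrix(stats::rnorm(n * G, sd = cf$noise_sd_gene),
                              n, G)
  x1 <- decode_truth(decoder, z1) + noise(ncl)
  x2 <- decode_truth(decoder, z2) + noise(ncl)

  gene_ids <- sprintf("g%04d", seq_len(G))
  rows <- list(); meta <- list()
  add <- function(id, x, role, cl) {
    rows[[length(rows) + 1L]] <<- x
    meta[[length(meta) + 1L]] <<- data.frame(
      sample_id = id, cell_line_id = cl, role = role,
      stringsAsFactors = FALSE)
  }
  manifest <- NULL
  for (i in seq_len(np)) {
    ctl_id <- paste0(pair_cls[i], "_ctrl")
    trt_id <- paste0(pair_cls[i], "_trt")
    add(ctl_id, x1[i, ], "control", pair_cls[i])
    add(trt_id, x2[i, ], "treated", pair_cls[i])
    batch <- sprintf("B%02d", (i - 1L) %% cf$batch_count + 1L)
    bead <- sprintf("bead%03d", i)
    for (r in seq_len(cf$replicates_per_control)) {
      rep_id <- sprintf("%s_rep%d", pair_cls[i], r)
      add(rep_id, x1[i, ] + stats::rnorm(G, sd = cf$replicate_sd),
          "control_replicate", pair_cls[i])
    }
    manifest <- rbind(manifest, data.frame(
      drug_id = "DRUG1", cell_line_id = pair_cls[i],
      control_sample = ctl_id, treated_sample = trt_id,
      batch_id = batch, bead_id = bead,
      concentration = 1e-6, duration_h = 6,
      stringsAsFactors = FALSE))
  }
  for (j in seq_along(solo_cls)) {
    add(paste0(solo_cls[j], "_pre"), x1[np + j, ], "singleton", solo_cls[j])
  }
  expression <- do.call(rbind, rows)
  samples <- do.call(rbind, meta)
  rownames(expression) <- samples$sample_id
  colnames(expression) <- gene_ids

  labeled_pairs <- stats::runif(np) < cf$frac_pairs_labeled

  realized_ervr <- if (np >= 2L && cf$replicates_per_control >= 2L) {
    groups <- lapply(seq_len(np), function(i) {
      ids <- sprintf("%s_rep%d", pair_cls[i],
                     seq_len(cf$replicates_per_control))
      expression[ids, , drop = FALSE]
    })
    ervr(x1[seq_len(np), , drop = FALSE], x2[seq_len(np), , drop = FALSE],
         groups)
  } else {
    NA_real_
  }

  truth <- list(z1 = z1, z2 = z2, W_star = W, b_star = b,
                decoder = decoder, label_rule = w_lab,
                labels = stats::setNames(y, cl_ids),
                scores = stats::setNames(score, cl_ids),
                labeled_pairs = labeled_pairs,
                realized_ervr = realized_ervr)
  structure(list(expression = expression,
                 pair_manifest = manifest,
                 sensitivity = data.frame(drug_id = "DRUG1",
                                          cell_line_id = cl_ids,
                                          aac = aac,
                                          stringsAsFactors = FALSE),
                 samples = samples,
                 pair_cell_lines = pair_cls,
                 singleton_cell_lines = solo_cls,
                 truth = truth,
                 config = cf),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset: ", length(x$pair_cell_lines), " pair cell lines, ",
      length(x$singleton_cell_lines), " singletons, ",
      ncol(x$expression), " genes, seed ", x$config$seed, ">\n", sep = "")
  invisible(x)
}

#' Fresh evaluation pairs from a generated dataset's ground truth
#'
#' Samples additional perturbation pairs from the same ground-truth effect
#' map, decoder and noise level as an existing dataset, for held-out
#' evaluation of post-treatment prediction.
#'
#' @param dataset A `synthetic_dataset`.
#' @param n Number of evaluation pairs.
#' @param seed Seed for the fresh draws.
#' @return A list with matrices `x1`, `x2` and latents `z1`, `z2`.
#' @export
synthetic_eval_pairs <- function(dataset, n, seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"), n >= 1)
  tr <- dataset$truth; cf <- dataset$config
  d <- cf$latent_dim_true; G <- cf$n_genes
  with_seed(seed, {
    z1 <- matrix(stats::rnorm(n * d), n, d)
    z2 <- z1 + z1 %*% t(tr$W_star) + matrix(tr$b_star, n, d, byrow = TRUE)
    x1 <- decode_truth(tr$decoder, z1) +
      matrix(stats::rnorm(n * G, sd = cf$noise_sd_gene), n, G)
    x2 <- decode_truth(tr$decoder, z2) +
      matrix(stats::rnorm(n * G, sd = cf$noise_sd_gene), n, G)
    list(x1 = x1, x2 = x2, z1 = z1, z2 = z2)
  })
}

#' Assemble a training batch from a synthetic dataset
#'
#' Pairs carry labels only where the generator marked them labeled;
#' singleton cell lines are fully labeled (the sensitivity-screen regime).
#'
#' @param dataset A `synthetic_dataset`.
#' @return A [drvae_batch()].
#' @export
as_drvae_batch <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  cf <- dataset$config
  np <- length(dataset$pair_cell_lines)
  expr <- dataset$expression
  man <- dataset$pair_manifest
  x1p <- expr[man$control_sample, , drop = FALSE]
  x2p <- expr[man$treated_sample, , drop = FALSE]
  yp <- dataset$truth$labels[man$cell_line_id]
  yp[!dataset$truth$labeled_pairs] <- NA_real_
  solo <- dataset$singleton_cell_lines
  if (length(solo)) {
    xs <- expr[paste0(solo, "_pre"), , drop = FALSE]
    ys <- dataset$truth$labels[solo]
  } else {
    xs <- NULL; ys <- NULL
  }
  drvae_batch(x1_pairs = x1p, x2_pairs = x2p, y_pairs = as.numeric(yp),
              x1_singletons = xs, y_singletons = as.numeric(ys))
}

#' Grid of synthetic datasets for the signal/size sweep
#'
#' One dataset per combination of effect scale and pair-cell-line count,
#' with per-dataset seeds derived deterministically from the base seed.  The
#' decoder can be shared across all grid points to isolate the swept
#' factors.
#'
#' @param effect_scales Numeric vector of effect scales.
#' @param n_cell_lines Integer vector of pair cell-line counts.
#' @param base A [synthetic_config()] providing all other settings.
#' @param share_decoder Use one decoder (drawn from the base seed) for every
#'   dataset (default `TRUE`).
#' @return A list of `synthetic_dataset` objects with attributes
#'   `effect_scale` and `n_cell_lines` per element.
#' @export
make_sweep <- function(effect_scales, n_cell_lines, base,
                       share_decoder = TRUE) {
  stopifnot(inherits(base, "synthetic_config"),
            length(effect_scales) >= 1, length(n_cell_lines) >= 1)
  decoder <- if (share_decoder) {
    synthetic_decoder(base$n_genes, base$latent_dim_true, base$decoder_gain,
                      seed = base$seed)
  } else {
    NULL
  }
  grid <- expand.grid(effect_scale = effect_scales,
                      n_cl = n_cell_lines)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cf <- base
    cf$effect_scale <- grid$effect_scale[i]
    cf$n_cell_lines_pairs <- as.integer(grid$n_cl[i])
    cf$decoder <- decoder
    cf$seed <- (base$seed + 7919L * i) %% .Machine$integer.max
    ds <- synthetic_generate(cf)
    attr(ds, "effect_scale") <- grid$effect_scale[i]
    attr(ds, "n_cell_lines") <- as.integer(grid$n_cl[i])
    out[[i]] <- ds
  }
  out
}
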