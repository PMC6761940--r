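# Small fully-connected networks with ELU activations, in both plain-numeric
# and tape (autodiff) form.  A "gaussian net" maps an input matrix (rows =
# samples) to the mean and log-variance of a diagonal Gaussian; a "mean net"
# emits only a mean.  n_hidden = 0 gives a purely affine map, which is what
# makes exact linear-Gaussian toy models representable in tests.

nn_gauss_init <- function(n_in, n_out, n_hidden, head_sd = 0.05) {
  p <- list()
  fan <- n_in
  if (n_hidden > 0L) {
    p$W1 <- matrix(stats::rnorm(n_in * n_hidden, sd = sqrt(1 / n_in)),
                   n_in, n_hidden)
    p$b1 <- matrix(0, 1L, n_hidden)
    fan <- n_hidden
  }
  p$Wm <- matrix(stats::rnorm(fan * n_out, sd = head_sd / sqrt(fan)),
                 fan, n_out)
  p$bm <- matrix(0, 1L, n_out)
  p$Wv <- matrix(stats::rnorm(fan * n_out, sd = head_sd / sqrt(fan)),
                 fan, n_out)
  p$bv <- matrix(0, 1L, n_out)
  p
}

nn_mean_init <- function(n_in, n_out, n_hidden, head_sd = 0.05) {
  p <- nn_gauss_init(n_in, n_out, n_hidden, head_sd)
  p$Wv <- NULL
  p$bv <- NULL
  p
}

# Numeric forward passes ------------------------------------------------------

elu <- function(x) ifelse(x > 0, x, expm1(x))

nn_hidden_fwd <- function(p, x) {
  if (is.null(p$W1)) return(x)
  elu(sweep(x %*% p$W1, 2L, p$b1, "+"))
}

nn_gauss_fwd <- function(p, x) {
  h <- nn_hidden_fwd(p, x)
  list(mean = sweep(h %*% p$Wm, 2L, p$bm, "+"),
       log_var = sweep(h %*% p$Wv, 2L, p$bv, "+"))
}

nn_mean_fwd <- function(p, x) {
  h <- nn_hidden_fwd(p, x)
  sweep(h %*% p$Wm, 2L, p$bm, "+")
}

# Tape forward passes (pn: list of ad_param nodes mirroring the numeric list) -

ad_hidden_fwd <- function(tp, pn, x) {
  if (is.null(pn$W1)) return(x)
  n <- nrow(x$value)
  ad_elu(tp, ad_add(tp, ad_mm(tp, x, pn$W1), ad_tile_rows(tp, pn$b1, n)))
}

ad_gauss_fwd <- function(tp, pn, x) {
  h <- ad_hidden_fwd(tp, pn, x)
  n <- nrow(h$value)
  list(mean = ad_add(tp, ad_mm(tp, h, pn$Wm), ad_tile_rows(tp, pn$bm, n)),
       log_var = ad_add(tp, ad_mm(tp, h, pn$Wv), ad_tile_rows(tp, pn$bv, n)))
}

ad_mean_fwd <- function(tp, pn, x) {
  h <- ad_hidden_fwd(tp, pn, x)
  n <- nrow(h$value)
  ad_add(tp, ad_mm(tp, h, pn$Wm), ad_tile_rows(tp, pn$bm, n))
}

# Parameter pytree helpers ----------------------------------------------------

# Recursively wrap a nested list of matrices into parameter nodes.
params_to_nodes <- function(tp, params) {
  lapply(params, function(p) {
    if (is.list(p)) params_to_nodes(tp, p) else ad_param(tp, p)
  })
}

# Recursively extract accumulated gradients (zero where a node was unused).
nodes_to_grads <- function(nodes) {
  lapply(nodes, function(nd) {
    if (is.list(nd)) {
      nodes_to_grads(nd)
    } else if (is.null(nd$grad)) {
      array(0, dim = dim(nd$value))
    } else {
      nd$grad
    }
  })
}

param_flatten <- function(params) {
  unlist(params, use.names = TRUE)
}

param_unflatten <- function(flat, skeleton) {
  pos <- 0L
  fill <- function(tmpl) {
    if (is.list(tmpl)) return(lapply(tmpl, fill))
    k <- length(tmpl)
    v <- flat[pos + seq_len(k)]
    pos <<- pos + k
    matrix(v, nrow(tmpl), ncol(tmpl))
  }
  fill(skeleton)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
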