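# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every value on the tape is a numeric matrix.  Nodes are environments holding
# the forward value, an accumulated gradient, parent references and a local
# backward closure.  The tape records creation order; ad_backward() walks it in
# reverse.  Only the operations needed by the variational objectives are
# implemented; all binary ops require identical shapes (use ad_tile_rows() to
# broadcast a 1 x k parameter over a minibatch).

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_register <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node$idx <- n
  node
}

ad_new_node <- function(tape, value, parents = list(), bwd = NULL,
                        req = NULL) {
  if (is.null(req)) {
    req <- any(vapply(parents, function(p) p$req, logical(1)))
  }
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$bwd <- bwd
  nd$req <- req
  ad_register(tape, nd)
}

as_ad_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

# Leaf carrying a trainable parameter (gradient is tracked).
ad_param <- function(tape, value) {
  ad_new_node(tape, as_ad_matrix(value), req = TRUE)
}

# Leaf carrying data or noise (no gradient tracked).
ad_const <- function(tape, value) {
  ad_new_node(tape, as_ad_matrix(value), req = FALSE)
}

ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  for (i in seq_len(loss$idx)) tape$nodes[[i]]$grad <- NULL
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq(loss$idx, 1L)) {
    nd <- tape$nodes[[i]]
    if (!nd$req || is.null(nd$bwd) || is.null(nd$grad)) next
    gs <- nd$bwd(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!p$req || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(loss)
}

# Binary/unary op constructors ------------------------------------------------

ad_op <- function(tape, value, parents, bwd) {
  nd <- ad_new_node(tape, value, parents, bwd)
  nd
}

ad_mm <- function(tape, a, b) {
  ad_op(tape, a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

# a %*% t(b); avoids materializing transposed parameter nodes.
ad_mm_nt <- function(tape, a, b) {
  ad_op(tape, a$value %*% t(b$value), list(a, b), function(g) {
    list(g %*% b$value, t(g) %*% a$value)
  })
}

ad_add <- function(tape, a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ad_op(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ad_op(tape, a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ad_op(tape, a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

ad_scale <- function(tape, a, k) {
  ad_op(tape, a$value * k, list(a), function(g) list(g * k))
}

ad_shift <- function(tape, a, k) {
  ad_op(tape, a$value + k, list(a), function(g) list(g))
}

ad_exp <- function(tape, a) {
  v <- exp(a$value)
  ad_op(tape, v, list(a), function(g) list(g * v))
}

ad_square <- function(tape, a) {
  ad_op(tape, a$value^2, list(a), function(g) list(2 * g * a$value))
}

ad_elu <- function(tape, a) {
  v <- ifelse(a$value > 0, a$value, expm1(a$value))
  ad_op(tape, v, list(a), function(g) {
    list(g * ifelse(a$value > 0, 1, v + 1))
  })
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$value)
  ad_op(tape, v, list(a), function(g) list(g * (1 - v^2)))
}

ad_softplus <- function(tape, a) {
  v <- pmax(a$value, 0) + log1p(exp(-abs(a$value)))
  s <- stats::plogis(a$value)
  ad_op(tape, v, list(a), function(g) list(g * s))
}

ad_sigmoid <- function(tape, a) {
  v <- stats::plogis(a$value)
  ad_op(tape, v, list(a), function(g) list(g * v * (1 - v)))
}

# 1 x k row vector tiled to n x k.
ad_tile_rows <- function(tape, a, n) {
  stopifnot(nrow(a$value) == 1L)
  v <- matrix(a$value, n, ncol(a$value), byrow = TRUE)
  ad_op(tape, v, list(a), function(g) {
    list(matrix(colSums(g), 1L))
  })
}

ad_rowsum <- function(tape, a) {
  k <- ncol(a$value)
  ad_op(tape, matrix(rowSums(a$value), ncol = 1L), list(a), function(g) {
    list(matrix(g, nrow(a$value), k))
  })
}

ad_sum <- function(tape, a) {
  ad_op(tape, matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    list(matrix(g[1L], nrow(a$value), ncol(a$value)))
  })
}

ad_cbind <- function(tape, a, b) {
  ka <- ncol(a$value)
  ad_op(tape, cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(ka), drop = FALSE],
         g[, -seq_len(ka), drop = FALSE])
  })
}

# Composite helpers -----------------------------------------------------------

# Row-wise log density of V under diagonal Gaussians (M, LV); returns n x 1.
ad_gauss_row_logdens <- function(tape, v, m, lv) {
  k <- ncol(m$value)
  d2 <- ad_square(tape, ad_sub(tape, v, m))
  prec <- ad_exp(tape, ad_scale(tape, lv, -1))
  quad <- ad_mul(tape, d2, prec)
  inner <- ad_add(tape, ad_scale(tape, lv, 0.5), ad_scale(tape, quad, 0.5))
  ad_shift(tape, ad_scale(tape, ad_rowsum(tape, inner), -1),
           -0.5 * k * log(2 * pi))
}

# Row-wise KL( N(mq, e^lq) || N(mp, e^lp) ); returns n x 1.
ad_gauss_row_kl <- function(tape, mq, lq, mp, lp) {
  dl <- ad_sub(tape, lq, lp)
  r <- ad_exp(tape, dl)
  d2 <- ad_square(tape, ad_sub(tape, mq, mp))
  quad <- ad_mul(tape, d2, ad_exp(tape, ad_scale(tape, lp, -1)))
  inner <- ad_shift(tape, ad_sub(tape, ad_add(tape, r, quad), dl), -1)
  ad_scale(tape, ad_rowsum(tape, inner), 0.5)
}

# Row-wise KL( N(mq, e^lq) || N(0, I) ).
ad_gauss_row_kl_std <- function(tape, mq, lq) {
  inner <- ad_sub(tape,
                  ad_shift(tape,
                           ad_add(tape, ad_exp(tape, lq), ad_square(tape, mq)),
                           -1),
                  lq)
  ad_scale(tape, ad_rowsum(tape, inner), 0.5)
}

# Reparameterized sample: M + exp(LV / 2) * eps (eps a constant matrix).
ad_gauss_sample <- function(tape, m, lv, eps) {
  sd <- ad_exp(tape, ad_scale(tape, lv, 0.5))
  ad_add(tape, m, ad_mul(tape, sd, ad_const(tape, eps)))
}
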