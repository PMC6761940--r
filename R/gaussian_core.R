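#' Diagonal Gaussian parameters
#'
#' Container for the mean and log-variance of a factorized (diagonal
#' covariance) multivariate Gaussian.  Variances are carried in log-space
#' throughout the package for numerical stability.
#'
#' @param mean Numeric vector of means.
#' @param log_var Numeric vector of log-variances, same length as `mean`.
#' @return An object of class `gaussian_params` with fields `mean` and
#'   `log_var`.
#' @examples
#' g <- gaussian_params(c(0, 1), c(0, log(4)))
#' diag_gaussian_log_density(c(0, 1), g)
#' @export
gaussian_params <- function(mean, log_var) {
  mean <- as.numeric(mean)
  log_var <- as.numeric(log_var)
  if (length(mean) != length(log_var)) {
    stop("`mean` and `log_var` must have equal length", call. = FALSE)
  }
  if (!all(is.finite(mean)) || !all(is.finite(log_var))) {
    stop("gaussian_params entries must be finite", call. = FALSE)
  }
  structure(list(mean = mean, log_var = log_var), class = "gaussian_params")
}

#' @export
print.gaussian_params <- function(x, ...) {
  cat("<diagonal Gaussian, dim ", length(x$mean), ">\n", sep = "")
  cat("  mean:    ", paste(signif(utils::head(x$mean, 6), 4), collapse = " "),
      if (length(x$mean) > 6) " ...", "\n", sep = "")
  cat("  log_var: ",
      paste(signif(utils::head(x$log_var, 6), 4), collapse = " "),
      if (length(x$mean) > 6) " ...", "\n", sep = "")
  invisible(x)
}

#' Log density of a diagonal Gaussian
#'
#' Evaluates `sum_i [ -log(2*pi)/2 - log_var_i/2 -
#' (x_i - mean_i)^2 / (2 * exp(log_var_i)) ]`, the log density of `x` under a
#' factorized Gaussian.
#'
#' @param x Numeric vector, same length as the distribution.
#' @param g A [gaussian_params()] object.
#' @return A single numeric value.
#' @export
diag_gaussian_log_density <- function(x, g) {
  stopifnot(inherits(g, "gaussian_params"))
  x <- as.numeric(x)
  if (length(x) != length(g$mean)) {
    stop("dimension mismatch: x has length ", length(x),
         ", distribution has length ", length(g$mean), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  sum(-0.5 * log(2 * pi) - 0.5 * g$log_var -
        (x - g$mean)^2 / (2 * exp(g$log_var)))
}

#' Closed-form KL divergence between diagonal Gaussians
#'
#' Computes `KL(q || p)` exactly:
#' `0.5 * sum_i [ exp(lq_i - lp_i) + (mq_i - mp_i)^2 / exp(lp_i) - 1
#'   + lp_i - lq_i ]`.  Nonnegative, and zero iff `q` equals `p`.
#'
#' @param q,p [gaussian_params()] objects of equal dimension.
#' @return A single nonnegative numeric value.
#' @export
diag_gaussian_kl <- function(q, p) {
  stopifnot(inherits(q, "gaussian_params"), inherits(p, "gaussian_params"))
  if (length(q$mean) != length(p$mean)) {
    stop("dimension mismatch between q and p", call. = FALSE)
  }
  dl <- q$log_var - p$log_var
  0.5 * sum(exp(dl) + (q$mean - p$mean)^2 / exp(p$log_var) - 1 - dl)
}

#' Reparameterized sample from a diagonal Gaussian
#'
#' Maps an externally supplied noise vector through the location-scale
#' transform `mean + exp(log_var / 2) * noise`.  With standard-normal noise
#' the result is a draw from the distribution; keeping the noise explicit is
#' what makes the draw differentiable in the distribution's parameters (the
#' reparameterization trick).
#'
#' @param g A [gaussian_params()] object.
#' @param noise Numeric vector of the same length.
#' @return Numeric vector: the transformed sample.
#' @export
reparameterize <- function(g, noise) {
  stopifnot(inherits(g, "gaussian_params"))
  noise <- as.numeric(noise)
  if (length(noise) != length(g$mean)) {
    stop("dimension mismatch: noise has length ", length(noise),
         ", distribution has length ", length(g$mean), call. = FALSE)
  }
  g$mean + exp(0.5 * g$log_var) * noise
}

#' Binary cross-entropy
#'
#' `-(label * log(p) + (1 - label) * log(1 - p))` with `p` clamped to
#' `[eps, 1 - eps]` before taking logs.  Vectorized over both arguments.
#'
#' @param prob_positive Predicted probability (or vector) of the positive
#'   class.
#' @param label Observed label(s) in `{0, 1}`.
#' @param eps Clamping epsilon, default `1e-7`.
#' @return Nonnegative numeric vector of losses.
#' @export
binary_cross_entropy <- function(prob_positive, label, eps = 1e-7) {
  if (!all(label %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  p <- pmin(pmax(prob_positive, eps), 1 - eps)
  -(label * log(p) + (1 - label) * log1p(-p))
}
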