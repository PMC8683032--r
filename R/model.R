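#' BPR kernel shape parameters
#'
#' The blink-locked pupillary response (BPR) kernel is a shifted, scaled
#' gamma probability density,
#' \eqn{h(x) = \gamma \, f(x - t; \alpha, \beta)}, with \eqn{f} the
#' gamma density in shape--scale form (mode at \eqn{(\alpha-1)\beta}).
#' `gamma_amp` carries the sign of the response: a negative value
#' encodes the transient constriction that follows a blink, and because
#' \eqn{f} integrates to one, the kernel integrates to `gamma_amp`.
#'
#' @param alpha Gamma shape, > 0.
#' @param beta Gamma scale, seconds, > 0.
#' @param gamma_amp Amplitude scale, mm (negative = constriction).
#' @param t_shift Temporal shift of kernel onset relative to blink
#'   offset, seconds (|t_shift| <= 1.5).
#' @return A list of class `bpr_shape`.
#' @export
bpr_shape <- function(alpha, beta, gamma_amp, t_shift = 0) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0",
                                             call. = FALSE)
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (abs(t_shift) > 1.5) stop("|t_shift| must be <= 1.5 s", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma_amp = gamma_amp,
                 t_shift = t_shift), class = "bpr_shape")
}

#' Background noise model
#'
#' The spontaneous pupil background is modelled in a Box-Cox-transformed
#' space as a stationary Gaussian process with AR(1) covariance. The
#' two-parameter (shifted) Box-Cox transform is used because band-passed
#' pupil segments are near zero-mean while the classic transform
#' requires positivity: `shift_bc` is added before the power transform.
#'
#' @param lambda_bc Box-Cox power.
#' @param shift_bc Positivity offset, mm (>= 0 in typical use).
#' @param sigma Marginal SD in transformed units, > 0.
#' @param rho Lag-1 autocorrelation on the 5-Hz model grid, |rho| < 1.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(lambda_bc = 1, shift_bc = 0, sigma = 0.05,
                        rho = 0.8) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0",
                                             call. = FALSE)
  if (!is.numeric(rho) || abs(rho) >= 1) stop("|rho| must be < 1",
                                              call. = FALSE)
  structure(list(lambda_bc = lambda_bc, shift_bc = shift_bc, sigma = sigma,
                 rho = rho), class = "noise_model")
}

#' Evaluate the BPR kernel
#'
#' @param shape A [bpr_shape()].
#' @param times Numeric vector of times (seconds, relative to blink
#'   offset).
#' @return Kernel values in mm; zero for `times <= t_shift`.
#' @export
#' @examples
#' sh <- bpr_shape(alpha = 2, beta = 0.5, gamma_amp = -0.2)
#' gamma_kernel(sh, seq(0, 3, by = 0.2))
gamma_kernel <- function(shape, times) {
  stopifnot(inherits(shape, "bpr_shape"))
  if (any(!is.finite(times))) stop("times must be finite", call. = FALSE)
  shape$gamma_amp * stats::dgamma(times - shape$t_shift,
                                  shape = shape$alpha, scale = shape$beta)
}

#' Box-Cox power transform (forward and inverse)
#'
#' Forward: \eqn{y \mapsto ((y + s)^\lambda - 1)/\lambda} for
#' \eqn{\lambda \neq 0} and \eqn{\ln(y + s)} for \eqn{\lambda = 0},
#' with \eqn{s} = `noise$shift_bc`. The inverse is the exact algebraic
#' inverse.
#'
#' @param values Numeric vector (mm for forward, transformed units for
#'   inverse).
#' @param noise A [noise_model()] supplying `lambda_bc` and `shift_bc`.
#' @param direction `"forward"` or `"inverse"`.
#' @return Transformed numeric vector.
#' @export
boxcox_transform <- function(values, noise,
                             direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  lam <- noise$lambda_bc
  s <- noise$shift_bc
  if (direction == "forward") {
    z <- values + s
    if (any(z[!is.na(z)] <= 0)) {
      stop("nonpositive shifted value in Box-Cox forward transform; ",
           "shift_bc too small", call. = FALSE)
    }
    if (abs(lam) < 1e-12) log(z) else (z^lam - 1) / lam
  } else {
    if (abs(lam) < 1e-12) exp(values) - s else {
      z <- lam * values + 1
      if (any(z[!is.na(z)] <= 0)) {
        stop("value outside the range of the Box-Cox transform",
             call. = FALSE)
      }
      z^(1 / lam) - s
    }
  }
}

#' Stationary AR(1) covariance matrix
#'
#' Entry \eqn{(k, l)} is \eqn{\sigma^2 \rho^{|k-l|}}: the covariance of
#' a stationary first-order autoregressive process with marginal
#' variance \eqn{\sigma^2} and lag-1 autocorrelation \eqn{\rho}.
#'
#' @param sigma Marginal SD, > 0.
#' @param rho Lag-1 autocorrelation, |rho| < 1.
#' @param n Dimension (default 16, the 3-s model grid at 5 Hz).
#' @return An `n x n` symmetric positive-definite matrix.
#' @export
ar1_covariance <- function(sigma, rho, n = 16) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0",
                                             call. = FALSE)
  if (!is.numeric(rho) || abs(rho) >= 1) stop("|rho| must be < 1",
                                              call. = FALSE)
  k <- seq_len(n)
  sigma^2 * rho^abs(outer(k, k, "-"))
}

#' Multivariate normal log-density
#'
#' Exact log-density of `x` under \eqn{\mathrm{MVN}(\mu, \Sigma)},
#' evaluated via the Cholesky factor of the covariance.
#'
#' @param x Numeric vector (or matrix with one observation per row).
#' @param mu Mean vector.
#' @param cov Positive-definite covariance matrix.
#' @return Scalar log-density (or vector, one per row of `x`).
#' @export
mvn_loglik <- function(x, mu, cov) {
  if (is.matrix(x)) return(mvn_loglik_rows(x, mu, cov))
  if (length(x) != length(mu) || length(mu) != nrow(cov)) {
    stop("dimension mismatch between x, mu and cov", call. = FALSE)
  }
  mvn_loglik_rows(matrix(x, nrow = 1L), mu, cov)[1L]
}

mvn_loglik_rows <- function(X, mu, cov) {
  L <- tryCatch(chol(cov), error = function(e) {
    stop("covariance matrix is not positive-definite", call. = FALSE)
  })
  d <- ncol(X)
  z <- backsolve(L, t(X) - mu, transpose = TRUE)
  quad <- colSums(z^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(L))) + quad)
}
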