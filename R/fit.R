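#' Fitting configuration
#'
#' Controls the staged maximum-likelihood fit of the BPR model.
#'
#' @param tol Optimizer tolerance (default 1e-8).
#' @param max_iter Maximum optimizer iterations per stage (default
#'   2000).
#' @param n_starts Multi-start count for the kernel-shape fit (default
#'   8); starts beyond the first are jittered from the data-driven
#'   initial values using `seed`.
#' @param alpha_bounds,beta_bounds,t_bounds,gamma_bounds,sigma_bounds,rho_bounds
#'   Parameter bounds (length-2 numeric vectors).
#' @param min_affected Minimum number of blink-affected segments
#'   required to fit the kernel shape (default 10). Below this floor the
#'   fit falls back to `fallback_shape` if supplied, otherwise errors.
#' @param fallback_shape Optional [bpr_shape()] used when too few
#'   affected segments are available.
#' @param background How the non-BPR background profile of the
#'   blink-affected windows (`mu_affected`) is anchored at the window
#'   start. `"preblink"` (default) anchors it on genuine pre-blink
#'   samples (the 0.3 s before each blink's artifact window), since
#'   the first samples after the blink offset are artifact
#'   interpolation output whose level tracks the interpolation chord
#'   rather than the true background; `"window_ends"` uses the
#'   transformed affected mean's own end values via
#'   [compute_mean_profiles()].
#' @param exclude_artifact_points Drop the model-grid points that fall
#'   inside the maximal peri-blink artifact span (the first 0.5 s
#'   after blink offset) from the kernel-shape and amplitude
#'   likelihoods, by marginalizing the multivariate normal onto the
#'   remaining coordinates (default TRUE). Those samples are linear
#'   interpolation output, not measurements.
#' @param evoked_passes Number of evoked-response adjustment passes
#'   used when `fit_bpr_model()` is given a trial table (default 1):
#'   after an initial fit, the per-condition trial-averaged response of
#'   the corrected trace is subtracted from the input and the model is
#'   refit on the residual, so event-locked cognitive responses inside
#'   blink-locked windows do not masquerade as part of the kernel.
#' @param theta_refine Number of amplitude-refinement passes (default
#'   2). After the first per-blink amplitude pass, each pass
#'   re-estimates every amplitude on the segment with the current
#'   estimates of neighbouring blinks' responses subtracted
#'   (coordinate-wise ascent on the joint likelihood), which resolves
#'   overlapping footprints far better than the padded reference
#'   alone. Set to 0 for the single-pass behaviour.
#' @param shape_segments Which blink-affected segments feed the
#'   kernel-shape stage: `"isolated"` (default) uses only blinks whose
#'   nearest neighbour is more than 3 s away, falling back to all
#'   segments when fewer than `min_affected` are isolated; `"all"` uses
#'   every affected segment. Isolated windows are free of neighbouring
#'   blinks' responses, which the end-anchored background spline cannot
#'   absorb, so they give a less biased kernel estimate.
#' @param seed Integer seed for the multi-start jitter.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(tol = 1e-8, max_iter = 2000, n_starts = 8,
                       alpha_bounds = c(1.01, 50),
                       beta_bounds = c(0.01, 2),
                       t_bounds = c(-1.5, 1.5),
                       gamma_bounds = c(-5, 5),
                       sigma_bounds = c(1e-6, 5),
                       rho_bounds = c(-0.99, 0.99),
                       min_affected = 10, fallback_shape = NULL,
                       background = c("preblink", "window_ends"),
                       exclude_artifact_points = TRUE,
                       evoked_passes = 1,
                       theta_refine = 2,
                       shape_segments = c("isolated", "all"),
                       seed = 1L) {
  shape_segments <- match.arg(shape_segments)
  background <- match.arg(background)
  bounds_ok <- function(b) length(b) == 2L && b[1] < b[2]
  if (!all(vapply(list(alpha_bounds, beta_bounds, t_bounds, gamma_bounds,
                       sigma_bounds, rho_bounds), bounds_ok, logical(1)))) {
    stop("all bounds must be length-2 with lower < upper", call. = FALSE)
  }
  structure(list(tol = tol, max_iter = max_iter, n_starts = n_starts,
                 alpha_bounds = alpha_bounds, beta_bounds = beta_bounds,
                 t_bounds = t_bounds, gamma_bounds = gamma_bounds,
                 sigma_bounds = sigma_bounds, rho_bounds = rho_bounds,
                 min_affected = min_affected,
                 fallback_shape = fallback_shape,
                 background = background,
                 exclude_artifact_points = exclude_artifact_points,
                 evoked_passes = evoked_passes,
                 theta_refine = theta_refine,
                 shape_segments = shape_segments,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Convert segments to a numeric matrix
#'
#' Accepts segments as a matrix (one row per segment), a list of
#' equal-length vectors, or a tibble with a `values` list-column (as
#' returned by [extract_segments()]), and returns the matrix form used
#' by the estimation routines.
#'
#' @param segments Segments in any of the accepted forms.
#' @return A numeric matrix with one row per segment.
#' @export
segment_matrix <- function(segments) {
  if (is.matrix(segments)) return(segments)
  if (is.data.frame(segments)) {
    if (!"values" %in% names(segments)) {
      stop("segment tibble must have a `values` list-column", call. = FALSE)
    }
    segments <- segments$values
  }
  if (!length(segments)) return(matrix(numeric(0), nrow = 0, ncol = 16))
  do.call(rbind, lapply(segments, as.numeric))
}

#' Estimate the Box-Cox power from blink-free segments
#'
#' Pools all values of the blink-free segments, shifts them into
#' positive territory (`shift = max(0, 0.01 - min)` mm), and maximizes
#' the profile Box-Cox log-likelihood over the power in `[-2, 3]`.
#'
#' @param free_segments Blink-free segments (matrix, list of vectors,
#'   or tibble with a `values` column).
#' @param eps Positivity margin for the shift, mm (default 0.01).
#' @param min_value Smallest value the transform must accommodate;
#'   defaults to the minimum of the free segments themselves. Pass the
#'   pooled minimum over free and blink-affected segments when the
#'   transform will also be applied to the latter.
#' @return A list with `lambda_bc` and `shift_bc`.
#' @export
estimate_lambda <- function(free_segments, eps = 0.01, min_value = NULL) {
  y <- as.numeric(t(segment_matrix(free_segments)))
  if (length(y) < 32) stop("need at least 2 blink-free segments",
                           call. = FALSE)
  if (stats::sd(y) < 1e-12) {
    stop("degenerate input: segments are constant", call. = FALSE)
  }
  shift <- max(0, eps - min(y, min_value))
  z <- y + shift
  n <- length(z)
  lz <- sum(log(z))
  prof <- function(lam) {
    w <- if (abs(lam) < 1e-12) log(z) else (z^lam - 1) / lam
    v <- stats::var(w) * (n - 1) / n
    -n / 2 * log(v) + (lam - 1) * lz
  }
  opt <- stats::optimize(prof, c(-2, 3), maximum = TRUE, tol = 1e-6)
  list(lambda_bc = opt$maximum, shift_bc = shift)
}

#' Estimate AR(1) noise parameters from blink-free segments
#'
#' Maximizes the multivariate-normal log-likelihood of the transformed
#' blink-free segments around `mu_free` over the AR(1) covariance
#' parameters (sigma, rho), with bounded optimization initialized at
#' the sample SD and lag-1 autocorrelation of the residuals.
#'
#' @param free_segments Blink-free segments.
#' @param noise A [noise_model()] with `lambda_bc` and `shift_bc`
#'   already fixed.
#' @param mu_free Mean profile of the transformed free segments
#'   (length 16).
#' @param config A [fit_config()].
#' @return A [noise_model()] with fitted `sigma`, `rho` and attributes
#'   `loglik` and `convergence`.
#' @export
estimate_ar1_noise <- function(free_segments, noise, mu_free,
                               config = fit_config()) {
  X <- segment_matrix(free_segments)
  if (nrow(X) < 1L) stop("no blink-free segments", call. = FALSE)
  G <- boxcox_transform(X, noise, "forward")
  E <- sweep(G, 2, mu_free)
  s0 <- stats::sd(as.numeric(E))
  r0 <- lag1_autocor(E)
  nll <- function(par) {
    -sum(mvn_loglik_rows(G, mu_free, ar1_covariance(par[1], par[2],
                                                    ncol(G))))
  }
  opt <- stats::optim(c(max(s0, 1e-4), r0), nll, method = "L-BFGS-B",
                      lower = c(config$sigma_bounds[1],
                                config$rho_bounds[1]),
                      upper = c(config$sigma_bounds[2],
                                config$rho_bounds[2]),
                      control = list(maxit = config$max_iter,
                                     factr = config$tol * 1e9))
  out <- noise_model(lambda_bc = noise$lambda_bc,
                     shift_bc = noise$shift_bc,
                     sigma = opt$par[1], rho = opt$par[2])
  attr(out, "loglik") <- -opt$value
  attr(out, "convergence") <- opt$convergence == 0 && nrow(X) > 1
  out
}

lag1_autocor <- function(E) {
  num <- sum(E[, -1, drop = FALSE] * E[, -ncol(E), drop = FALSE])
  den <- sum(E^2)
  if (den < 1e-300) return(0)
  max(min(num / den, 0.95), -0.95)
}

#' Mean profiles of the transformed segments
#'
#' `mu_free` is the pointwise mean of the transformed blink-free
#' segments. `mu_affected` approximates the non-BPR background of the
#' blink-affected windows: a natural cubic spline through the first
#' `n_anchor` and last `n_anchor` grid points of the transformed
#' affected mean (the interior of the window is dominated by the BPR
#' itself, so only the ends are trusted). With the default
#' `n_anchor = 1` the spline degenerates to the chord between the
#' window endpoints; larger anchor counts let the spline pick up local
#' slope at the ends, but the first grid points always lie inside the
#' peri-blink artifact-interpolation zone, and propagating their local
#' slope into the window interior biases the background (and hence the
#' fitted kernel amplitude) downward.
#'
#' @param free_segments,affected_segments Segments (matrix, list, or
#'   tibble with a `values` column).
#' @param noise A [noise_model()] fixing the transform.
#' @param n_anchor Anchor points per end for the spline (default 1).
#' @return A list with `mu_free` and `mu_affected` (length-16 vectors
#'   in transformed units).
#' @export
compute_mean_profiles <- function(free_segments, affected_segments, noise,
                                  n_anchor = 1) {
  Xf <- segment_matrix(free_segments)
  Xa <- segment_matrix(affected_segments)
  if (nrow(Xf) < 1L || nrow(Xa) < 1L) {
    stop("need at least one free and one affected segment", call. = FALSE)
  }
  mu_free <- colMeans(boxcox_transform(Xf, noise, "forward"))
  m_aff <- colMeans(boxcox_transform(Xa, noise, "forward"))
  k <- length(m_aff)
  grid <- model_grid()[seq_len(k)]
  idx <- c(seq_len(n_anchor), (k - n_anchor + 1):k)
  sp <- stats::spline(grid[idx], m_aff[idx], xout = grid, method = "natural")
  list(mu_free = mu_free, mu_affected = sp$y)
}

#' Estimate the BPR kernel shape
#'
#' Fits (alpha, beta, gamma_amp, t_shift) by maximizing the
#' multivariate-normal log-likelihood of the transformed
#' (mean affected segment - kernel) around `mu_affected` with
#' covariance `Sigma / n_affected` (the covariance of a mean of
#' `n_affected` AR(1) draws). A multi-start bounded quasi-Newton search
#' is used; starts are jittered around data-driven initial values
#' (kernel onset at the blink offset, time-to-trough and trough depth
#' read from the affected mean).
#'
#' @param affected_segments Blink-affected segments.
#' @param noise Fitted [noise_model()].
#' @param means Mean profiles from [compute_mean_profiles()].
#' @param config A [fit_config()].
#' @param drop_points Integer indices of model-grid points excluded
#'   from the likelihood (marginalized out); used to ignore grid
#'   points inside the peri-blink artifact-interpolation zone.
#' @return A [bpr_shape()] with attributes `loglik`, `convergence` and
#'   `n_starts_converged`.
#' @export
estimate_bpr_shape <- function(affected_segments, noise, means,
                               config = fit_config(),
                               drop_points = integer(0)) {
  Xa <- segment_matrix(affected_segments)
  n_aff <- nrow(Xa)
  if (n_aff < config$min_affected) {
    stop("insufficient data: ", n_aff, " affected segments (< ",
         config$min_affected, ")", call. = FALSE)
  }
  ybar <- colMeans(Xa)
  grid <- model_grid()[seq_len(length(ybar))]
  keep <- setdiff(seq_along(ybar), drop_points)
  cov <- ar1_covariance(noise$sigma, noise$rho,
                        length(ybar))[keep, keep, drop = FALSE] / n_aff
  Lc <- chol(cov)
  ldet <- 2 * sum(log(diag(Lc)))
  d <- length(keep)
  nll <- function(par) {
    h <- par[3] * stats::dgamma(grid - par[4], shape = par[1],
                                scale = par[2])
    v <- ybar - h + noise$shift_bc
    if (any(v <= 0) || any(!is.finite(h))) return(1e10)
    g <- if (abs(noise$lambda_bc) < 1e-12) log(v) else
      (v^noise$lambda_bc - 1) / noise$lambda_bc
    z <- backsolve(Lc, (g - means$mu_affected)[keep], transpose = TRUE)
    0.5 * (d * log(2 * pi) + ldet + sum(z^2))
  }
  # data-driven initialization: trough of the affected mean
  i_tr <- which.min(ybar)
  tt <- max(grid[i_tr], 0.2)
  depth <- min(ybar[i_tr] - stats::median(ybar[c(1, length(ybar))]), -0.01)
  a0 <- 4
  b0 <- min(max(tt / (a0 - 1), config$beta_bounds[1]), config$beta_bounds[2])
  g0 <- depth / stats::dgamma(tt, shape = a0, scale = b0)
  start0 <- c(a0, b0, g0, 0)
  lower <- c(config$alpha_bounds[1], config$beta_bounds[1],
             config$gamma_bounds[1], config$t_bounds[1])
  upper <- c(config$alpha_bounds[2], config$beta_bounds[2],
             config$gamma_bounds[2], config$t_bounds[2])
  rng <- rng_stream(config$seed)
  best <- NULL
  n_conv <- 0L
  for (s in seq_len(config$n_starts)) {
    start <- if (s == 1L) start0 else {
      jit <- c(start0[1] * exp(rng(1) * 0.5),
               start0[2] * exp(rng(1) * 0.5),
               start0[3] * exp(rng(1) * 0.4),
               start0[4] + rng(1) * 0.3)
      pmin(pmax(jit, lower + 1e-6), upper - 1e-6)
    }
    opt <- tryCatch(
      stats::optim(start, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = config$max_iter,
                                  factr = config$tol * 1e9)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || n_conv == 0L) {
    stop("kernel-shape fit failed to converge from any start",
         call. = FALSE)
  }
  # simplex polish: L-BFGS-B stops on gradient size, which leaves
  # sloppy directions of the (alpha, beta, gamma) trade-off resolved
  # only coarsely
  nll_pen <- function(par) {
    if (any(par < lower) || any(par > upper)) return(1e10)
    nll(par)
  }
  pol <- tryCatch(
    stats::optim(best$par, nll_pen, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) best <- pol
  out <- bpr_shape(alpha = best$par[1], beta = best$par[2],
                   gamma_amp = best$par[3], t_shift = best$par[4])
  attr(out, "loglik") <- -best$value
  attr(out, "convergence") <- TRUE
  attr(out, "n_starts_converged") <- n_conv
  out
}

# mean pupil level just before the blinks' artifact windows: the last
# genuine samples before each blink, averaged across blinks
preblink_anchor <- function(trace, blinks, anchors, pre_span = 0.3) {
  tt <- trace$time
  x <- trace$pupil
  lv <- vapply(anchors, function(o) {
    j <- which.min(abs(blinks$offset - o))
    ps <- if ("pre_start" %in% names(blinks)) blinks$pre_start[j] else
      blinks$onset[j] - 0.15
    sel <- tt >= ps - pre_span & tt <= ps
    if (any(sel)) mean(x[sel]) else NA_real_
  }, numeric(1))
  mean(lv, na.rm = TRUE)
}

# deterministic jitter stream that does not disturb the global RNG
rng_stream <- function(seed) {
  env <- new.env()
  env$state <- seed
  function(n) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)  # initialize the RNG state
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(env$state)
    env$state <- env$state + 1L
    stats::rnorm(n)
  }
}

#' Estimate blink-by-blink BPR amplitudes
#'
#' For each blink-affected segment, finds the amplitude multiplier
#' theta maximizing the multivariate-normal log-likelihood of the
#' transformed (segment - theta * kernel) around its reference profile,
#' by bounded 1-D search on `[-2, 10]`.
#'
#' @param affected_segments Blink-affected segments.
#' @param shape Fitted [bpr_shape()].
#' @param noise Fitted [noise_model()].
#' @param means Mean profiles; `means$mu_affected` is the default
#'   reference.
#' @param mu_refs Optional list of per-segment reference profiles
#'   (overlap-padded references for blinks with close neighbours).
#' @param bounds Search interval for theta.
#' @param drop_points Integer indices of model-grid points excluded
#'   from the likelihood.
#' @return Numeric vector of amplitude estimates, one per segment.
#' @export
estimate_blink_amplitudes <- function(affected_segments, shape, noise,
                                      means, mu_refs = NULL,
                                      bounds = c(-2, 10),
                                      drop_points = integer(0)) {
  Xa <- segment_matrix(affected_segments)
  n <- nrow(Xa)
  if (n == 0L) return(numeric(0))
  grid <- model_grid()[seq_len(ncol(Xa))]
  h <- gamma_kernel(shape, grid)
  keep <- setdiff(seq_len(ncol(Xa)), drop_points)
  cov <- ar1_covariance(noise$sigma, noise$rho,
                        ncol(Xa))[keep, keep, drop = FALSE]
  Lc <- chol(cov)
  ldet <- 2 * sum(log(diag(Lc)))
  d <- length(keep)
  theta <- numeric(n)
  for (j in seq_len(n)) {
    mu_ref <- if (is.null(mu_refs)) means$mu_affected else mu_refs[[j]]
    y <- Xa[j, ]
    nll <- function(th) {
      v <- y - th * h + noise$shift_bc
      if (any(v <= 0)) return(1e10)
      g <- if (abs(noise$lambda_bc) < 1e-12) log(v) else
        (v^noise$lambda_bc - 1) / noise$lambda_bc
      z <- backsolve(Lc, (g - mu_ref)[keep], transpose = TRUE)
      0.5 * (d * log(2 * pi) + ldet + sum(z^2))
    }
    opt <- stats::optimize(nll, bounds, tol = 1e-8)
    theta[j] <- opt$minimum
  }
  theta
}

# Overlap-padded reference profile for blink j: within j's 3-s window,
# mask grid points covered by each neighbouring blink's 3-s footprint,
# pad the masked run with the nearest unmasked value of mu_affected,
# and average the padded references across neighbours.
padded_reference <- function(mu_affected, offset_j, neighbour_offsets,
                             grid = model_grid()) {
  if (!length(neighbour_offsets)) return(mu_affected)
  refs <- lapply(neighbour_offsets, function(ob) {
    tt <- offset_j + grid
    masked <- tt >= ob & tt <= ob + grid[length(grid)]
    if (all(masked) || !any(masked)) return(mu_affected)
    r <- mu_affected
    keep <- which(!masked)
    bad <- which(masked)
    # pad each masked point with the nearest unmasked value
    near <- vapply(bad, function(i) keep[which.min(abs(keep - i))],
                   integer(1))
    r[bad] <- mu_affected[near]
    r
  })
  Reduce(`+`, refs) / length(refs)
}

#' Fit the full BPR generative model to one run
#'
#' Runs the staged maximum-likelihood fit on a preprocessed
#' (artifact-interpolated, band-passed) trace: (1) Box-Cox power from
#' the pooled blink-free segments; (2) mean profiles; (3) AR(1) noise
#' parameters; (4) kernel shape from the mean affected segment;
#' (5) blink-by-blink amplitudes. Blinks with another blink within 3 s
#' are flagged `overlapping` and their amplitude is estimated against
#' an overlap-padded reference profile.
#'
#' When a trial table is supplied via `events`, the fit additionally
#' runs `config$evoked_passes` evoked-adjustment rounds: the
#' per-condition trial-averaged response of the BPR-corrected trace is
#' subtracted from the input and the model refit on the residual.
#' Without this, event-locked cognitive responses that fall inside
#' blink-locked windows (blinks cluster at task breakpoints) bias the
#' kernel and amplitude estimates.
#'
#' @param trace A preprocessed [pupil_trace()] (see
#'   [remove_periblink_artifacts()] and [bandpass_filter()]).
#' @param blinks Blink table for this trace.
#' @param config A [fit_config()].
#' @param events Optional trial table (`onset`, `duration`,
#'   `condition`) enabling evoked-response adjustment.
#' @return An object of class `bpr_fit`: a list with elements `shape`,
#'   `noise`, `means`, `amplitudes` (tibble with `onset`, `offset`,
#'   `theta`, `overlapping`), and `diagnostics`.
#' @export
fit_bpr_model <- function(trace, blinks, config = fit_config(),
                          events = NULL) {
  fit <- fit_bpr_core(trace, blinks, config)
  if (!is.null(events) && !is.null(fit$shape) &&
        config$evoked_passes > 0) {
    for (p in seq_len(config$evoked_passes)) {
      mb <- subtract_bpr(trace, blinks, fit)
      ev <- evoked_by_condition(mb$corrected, events)
      fit <- fit_bpr_core(remove_evoked(trace, events, ev), blinks,
                          config)
    }
    fit$flags <- c(fit$flags, "evoked_adjusted")
  }
  fit
}

# per-condition trial-averaged time course over the trial grid
evoked_by_condition <- function(trace, events) {
  rate <- trace_rate(trace)
  L <- round(events$duration[1L] * rate)
  x <- trace$pupil
  t1 <- trace$time[1L]
  out <- list()
  for (cc in unique(events$condition)) {
    idx <- which(events$condition == cc)
    M <- vapply(idx, function(i) {
      i0 <- round((events$onset[i] - t1) * rate) + 1L
      x[i0:(i0 + L - 1L)]
    }, numeric(L))
    out[[cc]] <- rowMeans(M)
  }
  out
}

remove_evoked <- function(trace, events, evoked) {
  rate <- trace_rate(trace)
  L <- round(events$duration[1L] * rate)
  t1 <- trace$time[1L]
  out <- trace
  for (i in seq_len(nrow(events))) {
    i0 <- round((events$onset[i] - t1) * rate) + 1L
    idx <- i0:(i0 + L - 1L)
    out$pupil[idx] <- out$pupil[idx] - evoked[[events$condition[i]]]
  }
  out
}

fit_bpr_core <- function(trace, blinks, config = fit_config()) {
  segs <- extract_segments(trace, blinks)
  free <- dplyr::filter(segs, .data$kind == "blink_free")
  aff <- dplyr::filter(segs, .data$kind == "blink_affected")
  if (nrow(free) == 0L) {
    stop("insufficient data: no blink-free segments", call. = FALSE)
  }
  min_aff <- if (nrow(aff)) min(segment_matrix(aff)) else NULL
  lam <- estimate_lambda(free, min_value = min_aff)
  noise0 <- noise_model(lambda_bc = lam$lambda_bc, shift_bc = lam$shift_bc,
                        sigma = 1, rho = 0)
  mu_free <- colMeans(boxcox_transform(segment_matrix(free), noise0,
                                       "forward"))
  noise <- estimate_ar1_noise(free, noise0, mu_free, config)
  diagnostics <- tibble::tibble(
    stage = c("lambda", "noise"),
    loglik = c(NA_real_, attr(noise, "loglik")),
    converged = c(TRUE, isTRUE(attr(noise, "convergence"))))

  if (nrow(aff) == 0L) {
    fit <- structure(
      list(shape = NULL, noise = noise,
           means = list(mu_free = mu_free, mu_affected = NULL),
           amplitudes = tibble::tibble(onset = numeric(0),
                                       offset = numeric(0),
                                       theta = numeric(0),
                                       overlapping = logical(0)),
           diagnostics = dplyr::bind_rows(
             diagnostics,
             tibble::tibble(stage = "shape", loglik = NA_real_,
                            converged = FALSE)),
           n_free = nrow(free), n_affected = 0L,
           flags = "no_blinks"),
      class = "bpr_fit")
    warning("run contains no usable blink-affected segments; ",
            "kernel shape left undefined", call. = FALSE)
    return(fit)
  }

  aff_shape <- if (config$shape_segments == "isolated" &&
                     sum(aff$isolated) >= config$min_affected) {
    dplyr::filter(aff, .data$isolated)
  } else {
    aff
  }
  means <- compute_mean_profiles(free, aff_shape, noise)
  if (config$background == "preblink") {
    pre <- preblink_anchor(trace, blinks, aff_shape$anchor)
    if (is.finite(pre)) {
      grid <- model_grid()
      start_anchor <- boxcox_transform(pre, noise, "forward")
      means$mu_affected <- stats::approx(
        grid[c(1, length(grid))],
        c(start_anchor, means$mu_affected[length(grid)]),
        xout = grid)$y
    }
  }
  drop_pts <- if (config$exclude_artifact_points) {
    which(model_grid() <= 0.5 + 1e-9)
  } else integer(0)
  shape <- if (nrow(aff_shape) >= config$min_affected) {
    estimate_bpr_shape(aff_shape, noise, means, config,
                       drop_points = drop_pts)
  } else if (!is.null(config$fallback_shape)) {
    sh <- config$fallback_shape
    attr(sh, "loglik") <- NA_real_
    attr(sh, "convergence") <- NA
    sh
  } else {
    stop("insufficient data: ", nrow(aff), " affected segments (< ",
         config$min_affected, ") and no fallback kernel supplied",
         call. = FALSE)
  }

  # overlap handling: neighbours whose 3-s footprint intersects window j
  span <- model_grid()[length(model_grid())]
  offs <- aff$anchor
  mu_refs <- vector("list", nrow(aff))
  overlapping <- logical(nrow(aff))
  all_off <- blinks$offset
  for (j in seq_len(nrow(aff))) {
    nb <- all_off[abs(all_off - offs[j]) > 1e-9 &
                    all_off + span > offs[j] & all_off < offs[j] + span]
    overlapping[j] <- length(nb) > 0L
    mu_refs[[j]] <- padded_reference(means$mu_affected, offs[j], nb)
  }
  theta <- estimate_blink_amplitudes(aff, shape, noise, means,
                                     mu_refs = mu_refs,
                                     drop_points = drop_pts)
  if (config$theta_refine > 0 && any(overlapping)) {
    Xa <- segment_matrix(aff)
    grid <- model_grid()
    ker <- function(x) ifelse(x > span, 0, gamma_kernel(shape, x))
    seg_of_blink <- vapply(offs, function(o) which.min(abs(all_off - o)),
                           integer(1))
    th_all <- rep(stats::median(theta), length(all_off))
    th_all[seg_of_blink] <- theta
    for (p in seq_len(config$theta_refine)) {
      for (j in seq_len(nrow(aff))) {
        o <- offs[j]
        nbi <- which(abs(all_off - o) > 1e-9 & all_off + span > o &
                       all_off < o + span)
        y <- Xa[j, ]
        for (b in nbi) y <- y - th_all[b] * ker(o + grid - all_off[b])
        th_all[seg_of_blink[j]] <-
          estimate_blink_amplitudes(matrix(y, 1), shape, noise, means,
                                    drop_points = drop_pts)[1]
      }
    }
    theta <- th_all[seg_of_blink]
  }
  amp <- tibble::tibble(
    onset = vapply(offs, function(o) {
      i <- which.min(abs(blinks$offset - o)); blinks$onset[i]
    }, numeric(1)),
    offset = offs, theta = theta, overlapping = overlapping)
  diagnostics <- dplyr::bind_rows(
    diagnostics,
    tibble::tibble(stage = "shape", loglik = attr(shape, "loglik"),
                   converged = isTRUE(attr(shape, "convergence"))))
  structure(list(shape = shape, noise = noise, means = means,
                 amplitudes = amp, diagnostics = diagnostics,
                 n_free = nrow(free), n_affected = nrow(aff),
                 flags = character(0)),
            class = "bpr_fit")
}

#' @export
print.bpr_fit <- function(x, ...) {
  cat("BPR generative-model fit\n")
  cat(sprintf("  segments: %d blink-free, %d blink-affected\n",
              x$n_free, x$n_affected))
  if (!is.null(x$shape)) {
    cat(sprintf("  kernel: alpha=%.3f beta=%.3f s gamma=%.3f mm t=%.3f s\n",
                x$shape$alpha, x$shape$beta, x$shape$gamma_amp,
                x$shape$t_shift))
    tt <- (x$shape$alpha - 1) * x$shape$beta + x$shape$t_shift
    h <- gamma_kernel(x$shape, tt)
    cat(sprintf("  kernel trough: %.3f mm at %.2f s after blink offset\n",
                h, tt))
  } else {
    cat("  kernel: undefined (", paste(x$flags, collapse = ", "), ")\n")
  }
  cat(sprintf("  noise: lambda=%.3f shift=%.3f sigma=%.4f rho=%.3f\n",
              x$noise$lambda_bc, x$noise$shift_bc, x$noise$sigma,
              x$noise$rho))
  if (nrow(x$amplitudes)) {
    cat(sprintf("  amplitudes: n=%d, mean theta=%.3f (SD %.3f)\n",
                nrow(x$amplitudes), mean(x$amplitudes$theta),
                stats::sd(x$amplitudes$theta)))
  }
  invisible(x)
}

#' Tidy a fitted BPR model
#'
#' @param x A `bpr_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter (`term`,
#'   `estimate`).
#' @export
tidy.bpr_fit <- function(x, ...) {
  sh <- x$shape
  tibble::tibble(
    term = c("alpha", "beta", "gamma_amp", "t_shift", "lambda_bc",
             "shift_bc", "sigma", "rho"),
    estimate = c(if (is.null(sh)) rep(NA_real_, 4) else
      c(sh$alpha, sh$beta, sh$gamma_amp, sh$t_shift),
      x$noise$lambda_bc, x$noise$shift_bc, x$noise$sigma, x$noise$rho))
}

#' Glance at a fitted BPR model
#'
#' @param x A `bpr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with segment counts, stage log-likelihoods
#'   and convergence.
#' @export
glance.bpr_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    n_free = x$n_free, n_affected = x$n_affected,
    loglik_noise = d$loglik[d$stage == "noise"][1],
    loglik_shape = if (any(d$stage == "shape"))
      d$loglik[d$stage == "shape"][1] else NA_real_,
    converged = all(d$converged[d$stage != "lambda"], na.rm = FALSE),
    mean_theta = if (nrow(x$amplitudes)) mean(x$amplitudes$theta) else
      NA_real_)
}

#' Serialize or restore a fitted BPR model as JSON
#'
#' @param fit A `bpr_fit`.
#' @param path Output path.
#' @return `path` invisibly; `read_bpr_model()` returns a `bpr_fit`.
#' @export
write_bpr_model <- function(fit, path) {
  sh <- fit$shape
  obj <- list(
    alpha = if (is.null(sh)) NA else sh$alpha,
    beta = if (is.null(sh)) NA else sh$beta,
    gamma_amp = if (is.null(sh)) NA else sh$gamma_amp,
    t_shift = if (is.null(sh)) NA else sh$t_shift,
    lambda_bc = fit$noise$lambda_bc, shift_bc = fit$noise$shift_bc,
    sigma = fit$noise$sigma, rho = fit$noise$rho,
    mu_free = fit$means$mu_free, mu_affected = fit$means$mu_affected,
    theta = fit$amplitudes$theta,
    blink_onset = fit$amplitudes$onset,
    blink_offset = fit$amplitudes$offset,
    overlapping = fit$amplitudes$overlapping,
    convention_tags = list(gamma_parameterization = "shape-scale",
                           kernel_origin = "blink_offset",
                           boxcox = "two-parameter-shifted"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_bpr_model
#' @export
read_bpr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  shape <- if (is.null(obj$alpha) || is.na(obj$alpha)) NULL else
    bpr_shape(obj$alpha, obj$beta, obj$gamma_amp, obj$t_shift)
  structure(list(
    shape = shape,
    noise = noise_model(obj$lambda_bc, obj$shift_bc, obj$sigma, obj$rho),
    means = list(mu_free = obj$mu_free, mu_affected = obj$mu_affected),
    amplitudes = tibble::tibble(
      onset = as.numeric(obj$blink_onset),
      offset = as.numeric(obj$blink_offset),
      theta = as.numeric(obj$theta),
      overlapping = as.logical(obj$overlapping)),
    diagnostics = tibble::tibble(stage = character(0), loglik = numeric(0),
                                 converged = logical(0)),
    n_free = NA_integer_, n_affected = length(obj$theta),
    flags = character(0)), class = "bpr_fit")
}
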