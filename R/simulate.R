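#' Simulation configuration for confounded pupillometry experiments
#'
#' Describes a synthetic recording: a sequence of fixed-length trials,
#' each assigned a condition that determines both the event-locked
#' cognitive pupil response and the within-trial blink-rate profile
#' (blinks concentrate at task "breakpoints", which couples the
#' blink-locked response to the task and creates the confound this
#' package exists to remove). On top sit AR(1)-correlated spontaneous
#' fluctuations (generated in the Box-Cox-transformed space of the
#' noise model) and a gamma-kernel BPR per blink with blink-to-blink
#' amplitude variability.
#'
#' @param n_trials Number of trials.
#' @param trial_length Trial length, seconds.
#' @param rate Sampling rate, Hz.
#' @param conditions List of condition specs from [sim_condition()].
#' @param refractory Minimum gap between a blink offset and the next
#'   onset, seconds (default 0.2).
#' @param theta_dist Blink-amplitude distribution:
#'   `list(family = "gamma"|"lognormal"|"constant", mean, cv)`.
#'   Default gamma with mean 1 and CV 0.6, giving the severalfold
#'   blink-to-blink amplitude spread seen in real recordings.
#' @param true_shape True BPR kernel, a [bpr_shape()]. The default has
#'   its trough at -0.2 mm, 0.9 s after blink offset (the canonical
#'   BPR this method targets).
#' @param true_noise True background [noise_model()].
#' @param baseline_mm Constant baseline pupil diameter, mm.
#' @param pad Task-free padding before and after the trial block,
#'   seconds (default 6; keeps trials clear of filter edge transients).
#' @param pad_rate Blink rate during the padding, Hz.
#' @param blink_duration Range of blink durations, seconds.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trials = 100, trial_length = 2, rate = 100,
                       conditions = list(sim_condition("a")),
                       refractory = 0.2,
                       theta_dist = list(family = "gamma", mean = 1,
                                         cv = 0.6),
                       true_shape = default_true_shape(),
                       true_noise = noise_model(lambda_bc = 1,
                                                shift_bc = 0,
                                                sigma = 0.05, rho = 0.8),
                       baseline_mm = 4, pad = 6, pad_rate = 0.3,
                       blink_duration = c(0.1, 0.4), seed = 1L) {
  stopifnot(n_trials >= 1, trial_length > 0, rate > 0, refractory >= 0,
            theta_dist$cv >= 0, length(conditions) >= 1)
  cfg <- list(n_trials = n_trials, trial_length = trial_length,
              rate = rate, conditions = conditions,
              refractory = refractory, theta_dist = theta_dist,
              true_shape = true_shape, true_noise = true_noise,
              baseline_mm = baseline_mm, pad = pad, pad_rate = pad_rate,
              blink_duration = blink_duration, seed = as.integer(seed))
  cfg$duration <- 2 * pad + n_trials * trial_length
  # materialize per-condition profiles on the native trial grid
  L <- round(trial_length * rate)
  phase <- (seq_len(L) - 1L) / rate
  cfg$conditions <- lapply(conditions, function(cd) {
    cd$cognitive_vec <- profile_vector(cd$cognitive, phase)
    cd$blink_rate_vec <- profile_vector(cd$blink_rate, phase)
    if (any(cd$blink_rate_vec < 0)) {
      stop("blink-rate profiles must be nonnegative", call. = FALSE)
    }
    cd
  })
  probs <- vapply(cfg$conditions, `[[`, numeric(1), "prob")
  cfg$probs <- probs / sum(probs)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param label Condition label.
#' @param prob Relative frequency of the condition across trials.
#' @param cognitive Event-locked cognitive pupil response (mm): a
#'   function of trial phase (seconds), a numeric vector on the native
#'   trial grid, or a single number (constant).
#' @param blink_rate Within-trial blink-rate profile (Hz), same forms.
#' @export
sim_condition <- function(label, prob = 1, cognitive = 0,
                          blink_rate = 0.3) {
  list(label = label, prob = prob, cognitive = cognitive,
       blink_rate = blink_rate)
}

profile_vector <- function(p, phase) {
  if (is.function(p)) return(vapply(phase, p, numeric(1)))
  if (length(p) == 1L) return(rep(as.numeric(p), length(phase)))
  if (length(p) != length(phase)) {
    stop("profile vector must match the trial grid (", length(phase),
         " samples)", call. = FALSE)
  }
  as.numeric(p)
}

#' @rdname sim_config
#' @export
default_true_shape <- function() {
  # alpha = 4, mode (alpha-1)*beta = 0.9 s; gamma chosen so the trough
  # depth is -0.2 mm
  alpha <- 4
  beta <- 0.9 / (alpha - 1)
  g <- -0.2 / stats::dgamma(0.9, shape = alpha, scale = beta)
  bpr_shape(alpha = alpha, beta = beta, gamma_amp = g, t_shift = 0)
}

# run-level blink rate at arbitrary times, given trial table
run_blink_rate <- function(times, cfg, cond_idx) {
  L <- round(cfg$trial_length * cfg$rate)
  r <- rep(cfg$pad_rate, length(times))
  rel <- times - cfg$pad
  tr <- floor(rel / cfg$trial_length)
  ok <- tr >= 0 & tr < cfg$n_trials
  ph <- rel[ok] - tr[ok] * cfg$trial_length
  pidx <- pmin(floor(ph * cfg$rate) + 1L, L)
  rate_mat <- vapply(cfg$conditions, `[[`, numeric(L), "blink_rate_vec")
  r[ok] <- rate_mat[cbind(pidx, cond_idx[tr[ok] + 1L])]
  r
}

#' Sample blink event trains
#'
#' Draws blink onsets from an inhomogeneous Poisson process (thinning
#' against the per-trial, per-condition blink-rate profile) with an
#' absolute refractory period, then assigns each blink a duration drawn
#' uniformly from `config$blink_duration`.
#'
#' @param config A [sim_config()].
#' @param cond_idx Optional integer vector of per-trial condition
#'   indices; drawn from `config$probs` if missing.
#' @return A tibble with columns `onset`, `offset` (seconds).
#' @export
sample_blink_trains <- function(config, cond_idx = NULL) {
  set.seed(config$seed)
  if (is.null(cond_idx)) {
    cond_idx <- sample.int(length(config$conditions), config$n_trials,
                           replace = TRUE, prob = config$probs)
  }
  sample_blinks_impl(config, cond_idx)
}

sample_blinks_impl <- function(cfg, cond_idx) {
  rate_max <- max(cfg$pad_rate,
                  max(vapply(cfg$conditions,
                             function(cd) max(cd$blink_rate_vec),
                             numeric(1))))
  onsets <- numeric(0)
  offsets <- numeric(0)
  if (rate_max <= 0) {
    return(tibble::tibble(onset = onsets, offset = offsets))
  }
  t <- 0
  last_off <- -Inf
  repeat {
    t <- t + stats::rexp(1, rate_max)
    if (t >= cfg$duration) break
    if (stats::runif(1) < run_blink_rate(t, cfg, cond_idx) / rate_max &&
        t >= last_off + cfg$refractory) {
      dur <- stats::runif(1, cfg$blink_duration[1], cfg$blink_duration[2])
      if (t + dur < cfg$duration) {
        onsets <- c(onsets, t)
        offsets <- c(offsets, t + dur)
        last_off <- t + dur
      }
    }
  }
  tibble::tibble(onset = onsets, offset = offsets)
}

sample_theta <- function(n, dist) {
  if (n == 0L) return(numeric(0))
  m <- dist$mean
  cv <- dist$cv
  switch(dist$family,
         constant = rep(m, n),
         gamma = {
           if (cv == 0) return(rep(m, n))
           shp <- 1 / cv^2
           stats::rgamma(n, shape = shp, scale = m / shp)
         },
         lognormal = {
           if (cv == 0) return(rep(m, n))
           s2 <- log(1 + cv^2)
           stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
         },
         stop("unknown theta_dist family: ", dist$family, call. = FALSE))
}

#' Synthesize a confounded pupillometry run
#'
#' Composes a full synthetic recording: spontaneous fluctuation (the
#' inverse Box-Cox of an AR(1) Gaussian process on the 5-Hz model grid,
#' cubic-interpolated to the native rate and centred), the per-trial
#' cognitive response, and the per-blink BPR
#' (`theta_j * h(t - offset_j)`, truncated at the 3-s model window),
#' on top of a constant baseline. Blink spans are also stamped as
#' invalid samples so the full preprocessing path is exercised; the
#' stored pupil values at those samples remain the latent composition.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_run` with elements `trace`
#'   ([pupil_trace()]), `events` (trial tibble: `onset`, `duration`,
#'   `condition`), `blinks` (tibble: `onset`, `offset`, `theta`),
#'   `truth` (tibble: `time`, `sf`, `pr`, `bpr`) and `config`.
#' @export
synthesize_trace <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  cond_idx <- sample.int(length(cfg$conditions), cfg$n_trials,
                         replace = TRUE, prob = cfg$probs)
  blinks <- sample_blinks_impl(cfg, cond_idx)
  theta <- sample_theta(nrow(blinks), cfg$theta_dist)

  n <- round(cfg$duration * cfg$rate) + 1L
  tt <- (seq_len(n) - 1L) / cfg$rate

  # spontaneous fluctuation: AR(1) on the 5-Hz grid in transformed space
  n5 <- ceiling(cfg$duration * 5) + 8L
  t5 <- (seq_len(n5) - 1L) / 5 - 0.4
  ns <- cfg$true_noise
  e <- numeric(n5)
  e[1] <- stats::rnorm(1, 0, ns$sigma)
  innov <- stats::rnorm(n5 - 1, 0, ns$sigma * sqrt(1 - ns$rho^2))
  for (k in 2:n5) e[k] <- ns$rho * e[k - 1] + innov[k - 1]
  if (ns$lambda_bc > 1e-12) {
    # clip into the invertible domain of the transform (no-op for the
    # default lambda = 1, sigma = 0.05 regime)
    e <- pmax(e, -1 / ns$lambda_bc + 1e-6)
  } else if (ns$lambda_bc < -1e-12) {
    e <- pmin(e, -1 / ns$lambda_bc - 1e-6)
  }
  sf5 <- boxcox_transform(e, ns, "inverse")
  sf <- stats::spline(t5, sf5, xout = tt)$y
  sf <- sf - mean(sf)

  # cognitive response tiled per trial
  pr <- numeric(n)
  L <- round(cfg$trial_length * cfg$rate)
  onsets <- cfg$pad + (seq_len(cfg$n_trials) - 1L) * cfg$trial_length
  for (i in seq_len(cfg$n_trials)) {
    i0 <- round(onsets[i] * cfg$rate) + 1L
    idx <- i0:(i0 + L - 1L)
    pr[idx] <- pr[idx] + cfg$conditions[[cond_idx[i]]]$cognitive_vec
  }

  # BPR component, truncated at the 3-s model window
  span <- model_grid()[length(model_grid())]
  bpr <- numeric(n)
  for (j in seq_len(nrow(blinks))) {
    off <- blinks$offset[j]
    i <- window_indices(tt, off, off + span)
    if (length(i)) {
      bpr[i] <- bpr[i] + theta[j] * gamma_kernel(cfg$true_shape, tt[i] - off)
    }
  }

  pupil <- cfg$baseline_mm + sf + pr + bpr
  valid <- rep(TRUE, n)
  for (j in seq_len(nrow(blinks))) {
    valid[window_indices(tt, blinks$onset[j], blinks$offset[j])] <- FALSE
  }
  trace <- pupil_trace(tt, pupil, rate = cfg$rate, unit = "mm",
                       valid = valid,
                       run_id = sprintf("sim-seed%d", cfg$seed))
  events <- tibble::tibble(
    onset = onsets, duration = cfg$trial_length,
    condition = vapply(cfg$conditions, `[[`, character(1),
                       "label")[cond_idx])
  blinks$theta <- theta
  truth <- tibble::tibble(time = tt, sf = sf, pr = pr, bpr = bpr)
  structure(list(trace = trace, events = events, blinks = blinks,
                 truth = truth, config = cfg),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf(
    "# synthetic run: %d trials x %g s @ %g Hz, %d blinks (seed %d)\n",
    x$config$n_trials, x$config$trial_length, x$config$rate,
    nrow(x$blinks), x$config$seed))
  invisible(x)
}

#' Closed-form prediction of the blink-rate confound
#'
#' Predicts the mean trial-locked pupil trace implied by a blink-rate
#' profile: the cognitive profile is tiled across `n_trials_span`
#' trials, the tiled blink-rate time course is linearly convolved with
#' the (amplitude-scaled) BPR kernel across trial boundaries, the two
#' are summed, and each trial is re-baselined to zero at its onset.
#'
#' @param blink_rate Blink-rate profile over one trial grid, Hz.
#' @param kernel BPR kernel sampled at the same rate (typically
#'   `mean(theta) * h`), mm.
#' @param cognitive Cognitive response profile over one trial grid, mm.
#' @param n_trials_span Number of trials to tile.
#' @param rate Sampling rate shared by all three grids, Hz.
#' @param baseline Re-baseline each trial at its onset (default TRUE).
#' @return A tibble with columns `trial`, `phase`, `time`, `predicted`,
#'   `cognitive` and `bpr` (the convolution term).
#' @export
predict_confound <- function(blink_rate, kernel, cognitive, n_trials_span,
                             rate, baseline = TRUE) {
  if (length(blink_rate) != length(cognitive)) {
    stop("blink_rate and cognitive must share the trial grid",
         call. = FALSE)
  }
  L <- length(blink_rate)
  n <- n_trials_span * L
  r <- rep(blink_rate, n_trials_span)
  cg <- rep(cognitive, n_trials_span)
  conv <- stats::convolve(r, rev(kernel), type = "open")[seq_len(n)] / rate
  pred <- cg + conv
  trial <- rep(seq_len(n_trials_span), each = L)
  if (baseline) {
    base <- pred[(seq_len(n_trials_span) - 1L) * L + 1L]
    pred <- pred - base[trial]
  }
  tibble::tibble(trial = trial,
                 phase = rep((seq_len(L) - 1L) / rate, n_trials_span),
                 time = (seq_len(n) - 1L) / rate,
                 predicted = pred, cognitive = cg, bpr = conv)
}

#' Select trials by their blink-history pattern
#'
#' Returns the indices of trials whose blink history over the trailing
#' window of trials matches `pattern` exactly. `pattern` is a binary
#' vector ordered oldest to current; e.g. `c(0, 0, 0, 1)` selects
#' blink-in-current-trial sequences with no blink in the three
#' preceding trials, and `c(0, 0, 1, 0)` blink-in-previous-trial
#' sequences. Trials with fewer preceding trials than the pattern
#' requires are skipped.
#'
#' @param blinks Blink table (`onset`, `offset`).
#' @param trials Trial table (`onset`, `duration`).
#' @param pattern Binary vector over `[t - k + 1, ..., t]`.
#' @return Integer vector of matching current-trial indices.
#' @export
select_trial_sequences <- function(blinks, trials, pattern) {
  pattern <- as.integer(pattern != 0)
  m <- length(pattern)
  nt <- nrow(trials)
  has_blink <- vapply(seq_len(nt), function(i) {
    any(blinks$onset >= trials$onset[i] &
          blinks$onset < trials$onset[i] + trials$duration[i])
  }, logical(1))
  out <- integer(0)
  if (nt < m) return(out)
  for (t in m:nt) {
    if (all(as.integer(has_blink[(t - m + 1L):t]) == pattern)) {
      out <- c(out, t)
    }
  }
  out
}
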