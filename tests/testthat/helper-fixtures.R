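# Shared fixtures and independent oracles.

# identity-transform noise model: lambda = 1, shift = 1 makes the
# Box-Cox transform exactly the identity, ((y + 1)^1 - 1)/1 = y
identity_noise <- function(sigma = 0.1, rho = 0.8) {
  noise_model(lambda_bc = 1, shift_bc = 1, sigma = sigma, rho = rho)
}

# draws from MVN with AR(1) covariance, one segment per row
rmvn_ar1 <- function(n, sigma, rho, mu = rep(0, 16)) {
  L <- chol(ar1_covariance(sigma, rho, length(mu)))
  sweep(matrix(stats::rnorm(n * length(mu)), n) %*% L, 2, mu, "+")
}

# constant-pupil trace with planted invalid gaps (and optional square
# jump artifacts); gaps given as list of c(onset_idx, offset_idx)
make_gap_trace <- function(n = 6000, rate = 100, level = 3.5,
                           gaps = list(), jumps = list()) {
  pupil <- rep(level, n)
  valid <- rep(TRUE, n)
  for (g in gaps) valid[g[1]:g[2]] <- FALSE
  for (j in jumps) pupil[j[1]:j[2]] <- pupil[j[1]:j[2]] + j[3]
  pupil_trace((seq_len(n) - 1) / rate, pupil, rate = rate, valid = valid)
}

# brute-force sequential clustering of candidate sample indices with
# the "< merge_gap" rule (independent of detect_blinks internals)
oracle_cluster <- function(times, merge_gap = 0.2) {
  if (!length(times)) {
    return(tibble::tibble(onset = numeric(0), offset = numeric(0)))
  }
  times <- sort(times)
  onset <- times[1]
  offset <- times[1]
  out <- NULL
  for (t in times[-1]) {
    if (t - offset < merge_gap) {
      offset <- t
    } else {
      out <- rbind(out, c(onset, offset))
      onset <- t
      offset <- t
    }
  }
  out <- rbind(out, c(onset, offset))
  tibble::tibble(onset = out[, 1], offset = out[, 2])
}

# brute-force MVN log-density via explicit inverse and determinant
oracle_mvn <- function(x, mu, cov) {
  d <- length(x)
  -0.5 * (d * log(2 * pi) + log(det(cov)) +
            t(x - mu) %*% solve(cov) %*% (x - mu))[1, 1]
}

# brute-force AUC by pairwise comparison, ties counted one half
oracle_auc <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(b))
}

# brute-force trial classification by scanning the 3-trial history
oracle_classify <- function(trials, blinks) {
  nt <- nrow(trials)
  hit <- sapply(seq_len(nt), function(i) {
    any(blinks$onset >= trials$onset[i] &
          blinks$onset < trials$onset[i] + trials$duration[i])
  })
  out <- rep(NA_character_, nt)
  for (i in seq_len(nt)) {
    if (i >= 3) {
      out[i] <- if (hit[i] || hit[i - 1] || hit[i - 2]) "blink_affected"
      else "blink_free"
    }
  }
  out
}

# a short fixation-style simulated run shared by several tests
cached_fix_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      run <- synthesize_trace(sim_config_fixation(n_trials = 120,
                                                  seed = 77))
      pp <- suppressWarnings(preprocess_trace(run$trace))
      cache <<- list(run = run, pp = pp)
    }
    cache
  }
})
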