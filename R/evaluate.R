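#' Extract blink-affected and blink-free segments
#'
#' Blink-affected segments are 3-s windows starting at each blink
#' offset, resampled onto the 16-point model grid; a blink is `isolated`
#' when its nearest neighbouring blink is more than `min_isolation`
#' seconds away, and `overlapping` when another blink's 3-s footprint
#' intersects its window. Blink-free segments come from inter-blink
#' intervals longer than `free_gap` seconds: the initial 3-s portion
#' (still recovering from the preceding blink) is dropped and the
#' remainder divided into as many 3-s chunks as fit, the leftover
#' discarded. The first and last `edge_sec` seconds of the trace
#' (filter edge transients) are excluded throughout.
#'
#' @param trace A preprocessed (interpolated, band-passed)
#'   [pupil_trace()].
#' @param blinks Blink table for this trace.
#' @param min_isolation Isolation criterion, seconds (default 3).
#' @param free_gap Minimum inter-blink interval for blink-free
#'   segments, seconds (default 6).
#' @param edge_sec Edge exclusion; defaults to the trace's `edge_sec`
#'   attribute (set by [bandpass_filter()]) or 0.
#' @return A tibble with columns `kind` (`"blink_affected"` /
#'   `"blink_free"`), `anchor` (blink offset or segment start, s),
#'   `isolated`, `overlapping`, and a `values` list-column of length-16
#'   vectors.
#' @export
extract_segments <- function(trace, blinks, min_isolation = 3,
                             free_gap = 6, edge_sec = NULL) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (is.null(edge_sec)) edge_sec <- attr(trace, "edge_sec") %||% 0
  span <- model_grid()[length(model_grid())]
  t0 <- trace$time[1L] + edge_sec
  t1 <- trace$time[nrow(trace)] - edge_sec
  kind <- character(0)
  anchor <- numeric(0)
  isolated <- logical(0)
  overlapping <- logical(0)
  values <- list()

  bl <- dplyr::arrange(blinks, .data$onset)
  nb <- nrow(bl)
  for (j in seq_len(nb)) {
    off <- bl$offset[j]
    if (off < t0 || off + span > t1) next
    gap_prev <- if (j > 1L) bl$onset[j] - bl$offset[j - 1L] else Inf
    gap_next <- if (j < nb) bl$onset[j + 1L] - bl$offset[j] else Inf
    overl <- any(abs(bl$offset - off) > 1e-9 &
                   bl$offset + span > off & bl$offset < off + span)
    kind <- c(kind, "blink_affected")
    anchor <- c(anchor, off)
    isolated <- c(isolated, min(gap_prev, gap_next) > min_isolation)
    overlapping <- c(overlapping, overl)
    values[[length(values) + 1L]] <- resample_window(trace, off, span)
  }

  # inter-blink intervals (run start and end count as boundaries)
  starts <- c(trace$time[1L], bl$offset)
  ends <- c(bl$onset, trace$time[nrow(trace)])
  for (k in seq_along(starts)) {
    lo <- max(starts[k], t0)
    hi <- min(ends[k], t1)
    if (hi - lo <= free_gap) next
    lo <- lo + span  # drop the initial 3 s, not blink-free yet
    nseg <- floor((hi - lo) / span)
    for (s in seq_len(nseg)) {
      a <- lo + (s - 1L) * span
      kind <- c(kind, "blink_free")
      anchor <- c(anchor, a)
      isolated <- c(isolated, TRUE)
      overlapping <- c(overlapping, FALSE)
      values[[length(values) + 1L]] <- resample_window(trace, a, span)
    }
  }
  tibble::tibble(kind = kind, anchor = anchor, isolated = isolated,
                 overlapping = overlapping, values = values)
}

#' Classify trials by blink history
#'
#' A trial is `blink_free` when no blink onset falls within the
#' current, 1-back, or 2-back trial's span, and `blink_affected`
#' otherwise. The first two trials of a run have incomplete history and
#' are left unlabelled (`NA`).
#'
#' @param trials Trial table (`onset`, `duration`, `condition`).
#' @param blinks Blink table (`onset`, `offset`).
#' @return The trial table with added columns `blink_in_trial`
#'   (logical) and `label` (`"blink_free"`, `"blink_affected"`, or
#'   `NA`).
#' @export
classify_trials <- function(trials, blinks) {
  nt <- nrow(trials)
  hit <- vapply(seq_len(nt), function(i) {
    any(blinks$onset >= trials$onset[i] &
          blinks$onset < trials$onset[i] + trials$duration[i])
  }, logical(1))
  label <- rep(NA_character_, nt)
  for (i in seq_len(nt)) {
    if (i < 3L) next
    label[i] <- if (any(hit[(i - 2L):i])) "blink_affected" else "blink_free"
  }
  dplyr::mutate(trials, blink_in_trial = hit, label = label)
}

#' Within-trial blink-rate time course
#'
#' Builds a binary blink-offset pulse raster per trial at the native
#' rate, averages it across trials, smooths with a centred boxcar, and
#' scales to blinks per second.
#'
#' @param blinks Blink table.
#' @param trials Trial table with uniform durations.
#' @param rate Sampling rate of the raster, Hz.
#' @param boxcar Boxcar width, seconds (default 0.1).
#' @return A tibble with columns `phase` (s) and `rate_hz`.
#' @export
blink_rate_timecourse <- function(blinks, trials, rate, boxcar = 0.1) {
  L <- round(trials$duration[1L] * rate)
  nt <- nrow(trials)
  pulse <- numeric(L)
  for (i in seq_len(nt)) {
    rel <- blinks$offset - trials$onset[i]
    rel <- rel[rel >= 0 & rel < trials$duration[i]]
    if (length(rel)) {
      idx <- pmin(floor(rel * rate) + 1L, L)
      for (k in idx) pulse[k] <- pulse[k] + 1
    }
  }
  p <- pulse / nt
  w <- max(1L, round(boxcar * rate))
  sm <- boxcar_mean(p, w)
  tibble::tibble(phase = (seq_len(L) - 1L) / rate, rate_hz = sm * rate)
}

# centred moving average with shrinking windows at the edges
boxcar_mean <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Trial-locked response magnitudes
#'
#' Normalizes the trace run-wise (demean or z-score), baselines each
#' trial at its onset sample, and averages the baselined values inside
#' an integration window: either a fixed `[start, end]` window relative
#' to trial onset, or the span where the grand-average response (across
#' all trials) exceeds `auto_frac` of its maximum.
#'
#' @param trials Trial table (`onset`, `duration`, `condition`).
#' @param trace A [pupil_trace()].
#' @param window Either `list(fixed = c(start, end))` in seconds after
#'   trial onset, or `list(auto_frac = 0.75)`.
#' @param normalization `"demean"` or `"zscore"` (run-wise).
#' @return A tibble of trial records: `trial`, `condition`,
#'   `magnitude`, `run_id`.
#' @export
response_magnitudes <- function(trials, trace,
                                window = list(fixed = c(0.5, 2)),
                                normalization = c("demean", "zscore")) {
  normalization <- match.arg(normalization)
  rate <- trace_rate(trace)
  x <- trace$pupil
  x <- x - mean(x)
  if (normalization == "zscore") x <- x / stats::sd(x)
  L <- round(trials$duration[1L] * rate)
  nt <- nrow(trials)
  M <- matrix(NA_real_, nt, L)
  for (i in seq_len(nt)) {
    i0 <- round((trials$onset[i] - trace$time[1L]) * rate) + 1L
    if (i0 < 1L || i0 + L - 1L > length(x)) {
      stop("trial ", i, " extends beyond the trace", call. = FALSE)
    }
    M[i, ] <- x[i0:(i0 + L - 1L)] - x[i0]
  }
  phase <- (seq_len(L) - 1L) / rate
  if (!is.null(window$fixed)) {
    sel <- phase >= window$fixed[1] & phase <= window$fixed[2]
  } else {
    grand <- colMeans(M)
    mx <- max(grand)
    if (mx <= 0 || stats::sd(grand) < 1e-12) {
      stop("flat grand-average response; cannot select an auto window",
           call. = FALSE)
    }
    above <- which(grand >= window$auto_frac * mx)
    sel <- seq(min(above), max(above))
  }
  tibble::tibble(trial = seq_len(nt), condition = trials$condition,
                 magnitude = rowMeans(M[, sel, drop = FALSE]),
                 run_id = trace_run_id(trace))
}

#' Quantile profiles of BPR amplitude
#'
#' Quantifies blink-to-blink amplitude variability. Each blink-affected
#' segment's amplitude is the lowest value within 0.5--1.2 s after
#' blink offset; within each stratum (e.g. background-luminance group)
#' segments are sorted into `n_quantiles` amplitude bins, and the
#' per-quantile mean profiles are averaged across strata with equal
#' weight. A cubic smoothing spline (GCV-selected smoothness) is fitted
#' to each quantile profile before the peak amplitude and time-to-peak
#' are read off.
#'
#' @param segments Tibble of blink-affected segments (a `values`
#'   list-column, as from [extract_segments()]).
#' @param stratum Optional factor of the same length grouping segments;
#'   a single stratum is assumed when omitted.
#' @param n_quantiles Number of amplitude bins (default 5).
#' @param trough_window Search window for the per-segment amplitude,
#'   seconds after blink offset (default `c(0.5, 1.2)`).
#' @return A tibble with one row per quantile: `quantile`, `n`,
#'   `profile` and `smoothed` (list-columns over the model grid),
#'   `peak_amplitude`, `time_to_peak`.
#' @export
quantile_bpr_profiles <- function(segments, stratum = NULL,
                                  n_quantiles = 5,
                                  trough_window = c(0.5, 1.2)) {
  X <- segment_matrix(segments)
  n <- nrow(X)
  if (is.null(stratum)) stratum <- rep("all", n)
  grid <- model_grid()[seq_len(ncol(X))]
  tw <- grid >= trough_window[1] & grid <= trough_window[2]
  amp <- apply(X[, tw, drop = FALSE], 1L, min)
  df <- tibble::tibble(idx = seq_len(n), stratum = as.character(stratum),
                       amp = amp)
  per_stratum <- df |>
    dplyr::group_by(.data$stratum) |>
    dplyr::group_split()
  prof <- array(NA_real_, dim = c(length(per_stratum), n_quantiles,
                                  ncol(X)))
  counts <- matrix(0L, length(per_stratum), n_quantiles)
  for (s in seq_along(per_stratum)) {
    d <- per_stratum[[s]]
    if (nrow(d) < n_quantiles) {
      warning("stratum '", d$stratum[1], "' has fewer segments than ",
              "quantiles; skipped", call. = FALSE)
      next
    }
    # quantile 1 = shallowest, n_quantiles = deepest trough
    q <- dplyr::ntile(-d$amp, n_quantiles)
    for (b in seq_len(n_quantiles)) {
      rows <- d$idx[q == b]
      counts[s, b] <- length(rows)
      prof[s, b, ] <- colMeans(X[rows, , drop = FALSE])
    }
  }
  out <- vector("list", n_quantiles)
  for (b in seq_len(n_quantiles)) {
    keep <- which(counts[, b] > 0L)
    if (!length(keep)) next
    p <- colMeans(prof[keep, b, , drop = FALSE], dims = 1)
    dim(p) <- NULL
    sp <- tryCatch(stats::smooth.spline(grid, p, cv = FALSE),
                   error = function(e) NULL)
    fine <- seq(grid[1], grid[length(grid)], by = 0.01)
    sm <- if (is.null(sp)) stats::spline(grid, p, xout = fine)$y else
      stats::predict(sp, fine)$y
    i_min <- which.min(sm)
    out[[b]] <- tibble::tibble(
      quantile = b, n = sum(counts[, b]), profile = list(p),
      smoothed = list(if (is.null(sp)) p else
        stats::predict(sp, grid)$y),
      peak_amplitude = sm[i_min], time_to_peak = fine[i_min])
  }
  dplyr::bind_rows(out)
}

#' Euclidean distance between mean time courses
#'
#' The L2 norm of the difference between a blink-locked mean profile
#' and the blink-free mean profile; a scalar summary of how much the
#' BPR (or its residue after correction) displaces the blink-locked
#' average.
#'
#' @param mean_affected,mean_free Equal-length numeric vectors.
#' @return Scalar distance.
#' @export
compare_to_blink_free <- function(mean_affected, mean_free) {
  if (length(mean_affected) != length(mean_free)) {
    stop("profiles must have equal length", call. = FALSE)
  }
  sqrt(sum((mean_affected - mean_free)^2))
}

#' Condition discriminability
#'
#' Mean difference, pooled SEM, and the area under the ROC curve
#' (equivalently the Mann-Whitney probability, ties counted one half)
#' between two sets of trial response magnitudes.
#'
#' @param magnitudes_a,magnitudes_b Numeric vectors (>= 2 values each).
#' @return A one-row tibble: `mean_diff`, `pooled_sem`, `auc`, `n_a`,
#'   `n_b`.
#' @export
discriminability <- function(magnitudes_a, magnitudes_b) {
  na <- length(magnitudes_a)
  nb <- length(magnitudes_b)
  if (na < 2L || nb < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  r <- rank(c(magnitudes_a, magnitudes_b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  tibble::tibble(
    mean_diff = mean(magnitudes_a) - mean(magnitudes_b),
    pooled_sem = sqrt(stats::var(magnitudes_a) / na +
                        stats::var(magnitudes_b) / nb),
    auc = u / (na * nb), n_a = na, n_b = nb)
}

#' Bootstrap power analysis
#'
#' Estimates, for each candidate trial count `n`, the probability that
#' a linear regression of trial response magnitudes on a coded
#' condition regressor is significant at level `alpha`, by drawing
#' bootstrap samples of size `n` with replacement from the pooled trial
#' records. Reports the smallest `n` whose rejection fraction reaches
#' `target_frac`.
#'
#' @param records Tibble of trial records with columns `condition` and
#'   `magnitude` (e.g. from [response_magnitudes()], pooled across
#'   runs).
#' @param coding Named numeric vector mapping condition labels to
#'   regressor values (e.g. `c(freq = -0.5, mid = 0, rare = 0.5)`).
#' @param n_grid Integer vector of sample sizes to evaluate.
#' @param reps Bootstrap replicates per sample size (default 10000).
#' @param alpha Significance level of the two-sided slope test
#'   (default 0.01).
#' @param target_frac Target rejection fraction (default 0.95).
#' @param seed Integer seed.
#' @return A list of class `bpr_power`: `results` (tibble `n`,
#'   `rejection_frac`), `min_n` (smallest `n` reaching `target_frac`,
#'   or `Inf` when not reached), plus the call parameters.
#' @export
power_bootstrap <- function(records, coding, n_grid, reps = 10000,
                            alpha = 0.01, target_frac = 0.95,
                            seed = 1L) {
  x_all <- unname(coding[records$condition])
  if (anyNA(x_all)) stop("`coding` must cover every condition label",
                         call. = FALSE)
  if (length(unique(x_all)) < 2L) {
    stop("need at least 2 distinct regressor values", call. = FALSE)
  }
  y_all <- records$magnitude
  N <- length(y_all)
  set.seed(seed)
  frac <- vapply(n_grid, function(n) {
    idx <- matrix(sample.int(N, n * reps, replace = TRUE), nrow = n)
    X <- matrix(x_all[idx], nrow = n)
    Y <- matrix(y_all[idx], nrow = n)
    sx <- colSums(X); sy <- colSums(Y)
    sxx <- colSums(X^2) - sx^2 / n
    sxy <- colSums(X * Y) - sx * sy / n
    syy <- colSums(Y^2) - sy^2 / n
    ok <- sxx > 1e-12
    beta <- ifelse(ok, sxy / sxx, 0)
    sse <- pmax(syy - beta^2 * sxx, 0)
    se <- sqrt(sse / (n - 2) / ifelse(ok, sxx, 1))
    tval <- ifelse(ok & se > 0, beta / se, 0)
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    mean(ok & p < alpha)  # degenerate resamples count as non-significant
  }, numeric(1))
  reached <- which(frac >= target_frac)
  structure(list(
    results = tibble::tibble(n = n_grid, rejection_frac = frac),
    min_n = if (length(reached)) n_grid[min(reached)] else Inf,
    reps = reps, alpha = alpha, target_frac = target_frac),
    class = "bpr_power")
}

#' @export
print.bpr_power <- function(x, ...) {
  cat(sprintf(
    "# bootstrap power (reps = %d, alpha = %g): min n for %.0f%% = %s\n",
    x$reps, x$alpha, 100 * x$target_frac,
    if (is.finite(x$min_n)) x$min_n else "not reached"))
  print(x$results)
  invisible(x)
}
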