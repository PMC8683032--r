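#' Preprocessing parameters
#'
#' Bundles the thresholds used for blink detection, peri-blink artifact
#' removal and band-pass filtering. Defaults follow common pupillometry
#' practice for video eye trackers: samples are flagged as blink
#' candidates when they are missing, implausibly small (< `min_pupil`
#' mm), or when the zero-phase high-passed signal exceeds `jump_thresh`
#' mm; candidates closer than `merge_gap` form one blink event.
#'
#' @param min_pupil Minimum plausible pupil diameter, mm (default 1).
#' @param hp_cutoff,hp_order High-pass cutoff (Hz) and Butterworth order
#'   of the jump detector (defaults 10 Hz, 3).
#' @param jump_thresh Absolute threshold on the high-passed signal, mm
#'   (default 0.25).
#' @param merge_gap Candidate samples closer than this are one blink,
#'   seconds (default 0.2).
#' @param pre_artifact Pre-blink artifact span, seconds (default 0.15).
#' @param deriv_smooth Boxcar width for the post-blink derivative,
#'   seconds (default 0.25).
#' @param deriv_thresh Derivative threshold ending the post-blink
#'   artifact, mm/s (default 0.1).
#' @param post_min,post_max Bounds on the post-blink artifact length,
#'   seconds (defaults 0.2 and 0.5).
#' @param bp_low,bp_high,bp_order Band-pass corner frequencies (Hz) and
#'   Butterworth order (defaults 0.02, 4, 3).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(min_pupil = 1, hp_cutoff = 10, hp_order = 3,
                              jump_thresh = 0.25, merge_gap = 0.2,
                              pre_artifact = 0.15, deriv_smooth = 0.25,
                              deriv_thresh = 0.1, post_min = 0.2,
                              post_max = 0.5, bp_low = 0.02, bp_high = 4,
                              bp_order = 3) {
  p <- list(min_pupil = min_pupil, hp_cutoff = hp_cutoff,
            hp_order = hp_order, jump_thresh = jump_thresh,
            merge_gap = merge_gap, pre_artifact = pre_artifact,
            deriv_smooth = deriv_smooth, deriv_thresh = deriv_thresh,
            post_min = post_min, post_max = post_max, bp_low = bp_low,
            bp_high = bp_high, bp_order = bp_order)
  if (any(vapply(p, function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    stop("all preprocessing parameters must be positive numbers",
         call. = FALSE)
  }
  if (p$post_min >= p$post_max) stop("post_min must be < post_max",
                                     call. = FALSE)
  if (p$bp_low >= p$bp_high) stop("bp_low must be < bp_high", call. = FALSE)
  structure(p, class = "preprocess_params")
}

# Butterworth design in second-order sections (bilinear transform of
# the analog prototype). Direct transfer-function filtering is badly
# conditioned at the very low normalized corner frequencies this
# pipeline needs (0.02 Hz at hundreds of Hz sampling); cascaded
# biquads keep each recursion well conditioned. `w` is in fractions
# of the Nyquist frequency, as in signal::butter.
butter_sos <- function(order, w, type = c("pass", "high", "low")) {
  type <- match.arg(type)
  warp <- function(wn) tan(pi * wn / 2)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  if (type == "pass") {
    wl <- warp(w[1])
    wh <- warp(w[2])
    w0 <- sqrt(wl * wh)
    bw <- wh - wl
    p <- unlist(lapply(proto, function(pk) {
      disc <- sqrt((bw * pk)^2 / 4 - w0^2 + 0i)
      c(bw * pk / 2 + disc, bw * pk / 2 - disc)
    }))
    zero_sec <- c(1, 0, -1)   # one zero at z = 1, one at z = -1
    w_cal <- 2 * atan(w0)
  } else if (type == "high") {
    p <- warp(w[1]) / proto
    zero_sec <- c(1, -2, 1)   # double zero at z = 1
    w_cal <- pi
  } else {
    p <- warp(w[1]) * proto
    zero_sec <- c(1, 2, 1)    # double zero at z = -1
    w_cal <- 0
  }
  zp <- (1 + p) / (1 - p)     # bilinear transform of the poles
  # pair each pole with its conjugate into biquads
  used <- rep(FALSE, length(zp))
  sections <- list()
  for (i in seq_along(zp)) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(zp[i])) > 1e-10) {
      j <- which(!used & abs(zp - Conj(zp[i])) < 1e-8)[1]
      used[j] <- TRUE
      a <- c(1, -2 * Re(zp[i]), abs(zp[i])^2)
    } else {
      j <- which(!used & abs(Im(zp)) <= 1e-10)
      if (length(j)) {
        j <- j[1]
        used[j] <- TRUE
        a <- c(1, -Re(zp[i]) - Re(zp[j]), Re(zp[i]) * Re(zp[j]))
      } else {
        a <- c(1, -Re(zp[i]), 0)
      }
    }
    b <- zero_sec
    if ((type == "high" || type == "low") && abs(a[3]) < 1e-14) {
      # odd-order designs put a first-order zero in the real section
      b <- if (type == "high") c(1, -1, 0) else c(1, 1, 0)
    }
    sections[[length(sections) + 1L]] <- list(b = b, a = a)
  }
  # calibrate unit gain at the reference frequency
  z <- exp(1i * w_cal)
  h <- prod(vapply(sections, function(s) {
    (s$b[1] * z^2 + s$b[2] * z + s$b[3]) /
      (s$a[1] * z^2 + s$a[2] * z + s$a[3])
  }, complex(1)))
  list(sections = sections, gain = 1 / abs(h))
}

sos_filter <- function(sos, x) {
  y <- sos$gain * x
  for (s in sos$sections) {
    y <- as.numeric(signal::filter(signal::Arma(b = s$b, a = s$a), y))
  }
  y
}

# Zero-phase (forward-backward) second-order-section filtering with
# odd-reflection padding to suppress edge transients. `pad` in samples.
filtfilt_padded <- function(sos, x, pad) {
  n <- length(x)
  p <- min(pad, n - 1L)
  xp <- if (p >= 1L) {
    c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  } else x
  y <- sos_filter(sos, xp)
  y <- rev(sos_filter(sos, rev(y)))
  if (p >= 1L) y[(p + 1):(p + n)] else y
}

# Linear fill of invalid samples (nearest valid neighbours; ends held).
fill_invalid <- function(time, pupil, valid) {
  if (all(valid)) return(pupil)
  if (!any(valid)) stop("trace has no valid samples", call. = FALSE)
  stats::approx(time[valid], pupil[valid], xout = time, rule = 2)$y
}

#' Detect blink events
#'
#' Flags candidate samples that are missing, smaller than
#' `params$min_pupil`, or whose zero-phase high-passed value exceeds
#' `params$jump_thresh` in absolute value, then merges candidates closer
#' than `params$merge_gap` (consecutive blinks are physiologically
#' implausible within that gap) into single blink events. The event
#' onset/offset are the first/last candidate sample of each cluster.
#'
#' @param trace A [pupil_trace()] in mm.
#' @param params A [preprocess_params()].
#' @return A tibble with columns `onset`, `offset` (seconds).
#' @export
detect_blinks <- function(trace, params = preprocess_params()) {
  stopifnot(inherits(trace, "pupil_trace"))
  rate <- trace_rate(trace)
  if (nrow(trace) < rate) stop("trace shorter than 1 s", call. = FALSE)
  cand <- !trace$valid | (!is.na(trace$pupil) & trace$pupil < params$min_pupil)
  if (params$hp_cutoff < rate / 2) {
    filled <- fill_invalid(trace$time, trace$pupil, trace$valid)
    hp <- butter_sos(params$hp_order, params$hp_cutoff / (rate / 2),
                     type = "high")
    hx <- filtfilt_padded(hp, filled - mean(filled), pad = round(rate))
    cand <- cand | (abs(hx) > params$jump_thresh)
  }
  idx <- which(cand)
  if (length(idx) == 0L) {
    return(tibble::tibble(onset = numeric(0), offset = numeric(0)))
  }
  # new cluster where the gap to the previous candidate is >= merge_gap
  gap_samp <- diff(trace$time[idx])
  brk <- c(TRUE, gap_samp >= params$merge_gap)
  cl <- cumsum(brk)
  onset <- tapply(trace$time[idx], cl, min)
  offset <- tapply(trace$time[idx], cl, max)
  tibble::tibble(onset = as.numeric(onset), offset = as.numeric(offset))
}

#' Remove peri-blink artifacts
#'
#' Video eye trackers produce distorted samples immediately before and
#' after each blink. For every blink the window
#' `[onset - pre_artifact, onset]` is removed; after the blink, samples
#' are removed up to the first time where the boxcar-smoothed absolute
#' first derivative of the trace drops below `deriv_thresh` mm/s,
#' clamped to `[offset + post_min, offset + post_max]`. All removed
#' samples (and the blink itself) are then linearly interpolated from
#' the nearest valid neighbours. The smoothed derivative is used only to
#' locate the artifact endpoint; the output trace is not smoothed.
#'
#' @param trace A [pupil_trace()] in mm.
#' @param blinks Blink table from [detect_blinks()] run on this trace.
#' @param params A [preprocess_params()].
#' @return A list with elements `trace` (the interpolated
#'   [pupil_trace()], with an added logical column `interpolated`) and
#'   `blinks` (the blink table with added `pre_start`, `post_end`
#'   columns).
#' @export
remove_periblink_artifacts <- function(trace, blinks,
                                       params = preprocess_params()) {
  stopifnot(inherits(trace, "pupil_trace"))
  rate <- trace_rate(trace)
  n <- nrow(trace)
  if (nrow(blinks) == 0L) {
    out <- trace
    out$interpolated <- !out$valid
    out$pupil <- fill_invalid(out$time, out$pupil, out$valid)
    out$valid <- TRUE
    return(list(trace = out,
                blinks = dplyr::mutate(blinks, pre_start = numeric(0),
                                       post_end = numeric(0))))
  }
  # smoothed |derivative| for endpoint detection, on a gap-filled copy
  filled <- fill_invalid(trace$time, trace$pupil, trace$valid)
  dv <- abs(c(diff(filled), 0) * rate)
  w <- max(1L, round(params$deriv_smooth * rate))
  sm <- as.numeric(stats::filter(dv, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- dv[is.na(sm)]

  pre_start <- blinks$onset - params$pre_artifact
  post_end <- numeric(nrow(blinks))
  for (j in seq_len(nrow(blinks))) {
    off <- blinks$offset[j]
    i0 <- findInterval(off, trace$time) + 1L
    below <- which(sm[seq(min(i0, n), n)] < params$deriv_thresh)
    cand <- if (length(below)) trace$time[min(i0, n) + below[1L] - 1L] else
      off + params$post_max
    post_end[j] <- min(max(cand, off + params$post_min), off + params$post_max)
  }
  kill <- rep(FALSE, n)
  for (j in seq_len(nrow(blinks))) {
    kill[window_indices(trace$time, pre_start[j], post_end[j])] <- TRUE
  }
  keep_valid <- trace$valid & !kill
  if (!keep_valid[1L] || !keep_valid[n]) {
    warning("artifact window reaches trace edge; holding nearest valid value",
            call. = FALSE)
  }
  out <- trace
  out$interpolated <- !keep_valid
  out$pupil <- fill_invalid(out$time, out$pupil, keep_valid)
  out$valid <- TRUE
  blinks$pre_start <- pre_start
  blinks$post_end <- post_end
  list(trace = out, blinks = blinks)
}

#' Band-pass filter a pupil trace
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass to an
#' artifact-interpolated trace, removing slow drift and high-frequency
#' noise. The trace is demeaned first and padded by odd reflection so
#' the very low high-pass corner does not leave start-up transients; the
#' first and last `edge_sec` seconds are still flagged as edge
#' transients (attribute `edge_sec`) and excluded from segment
#' extraction.
#'
#' @param trace A fully interpolated [pupil_trace()] (no invalid
#'   samples).
#' @param params A [preprocess_params()].
#' @param edge_sec Edge-transient span flagged on the output, seconds.
#' @return The filtered [pupil_trace()] (approximately zero-mean).
#' @export
bandpass_filter <- function(trace, params = preprocess_params(),
                            edge_sec = 5) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (!all(trace$valid) || anyNA(trace$pupil)) {
    stop("trace still has invalid samples; interpolate artifacts first",
         call. = FALSE)
  }
  rate <- trace_rate(trace)
  bf <- butter_sos(params$bp_order,
                   c(params$bp_low, params$bp_high) / (rate / 2),
                   type = "pass")
  x <- trace$pupil - mean(trace$pupil)
  y <- filtfilt_padded(bf, x, pad = round(10 * rate))
  out <- trace
  out$pupil <- y
  attr(out, "edge_sec") <- edge_sec
  out
}

#' Resample a 3-s window onto the model grid
#'
#' Down-samples a window of the trace onto the fixed grid
#' `t0 + {0, 0.2, ..., duration}` (16 points for the default 3-s window
#' at 5 Hz). Each grid value is the mean of the native samples in the
#' block centred on the grid point (block width `1/out_rate`; the first
#' and last blocks are half-width so they stay inside the window).
#'
#' @param trace A [pupil_trace()].
#' @param t0 Window start, seconds.
#' @param duration Window length, seconds (default 3).
#' @param out_rate Output rate, Hz (default 5).
#' @return Numeric vector of length `duration * out_rate + 1`.
#' @export
resample_window <- function(trace, t0, duration = 3, out_rate = 5) {
  tt <- trace$time
  n <- length(tt)
  eps <- 1e-9
  if (t0 < tt[1L] - eps || t0 + duration > tt[n] + eps) {
    stop("window [", t0, ", ", t0 + duration, "] exceeds trace span",
         call. = FALSE)
  }
  half <- 1 / (2 * out_rate)
  grid <- t0 + seq(0, duration, by = 1 / out_rate)
  k <- length(grid)
  out <- numeric(k)
  x <- trace$pupil
  dt <- tt[2L] - tt[1L]
  tol <- 1e-4  # in index units; the grid is uniform by construction
  for (i in seq_len(k)) {
    lo <- max(grid[i] - half, t0)
    hi <- min(grid[i] + half, t0 + duration)
    # blocks are half-open [lo, hi) except the last, which is closed
    i0 <- ceiling((lo - tt[1L]) / dt - tol) + 1L
    i1 <- if (i == k) floor((hi - tt[1L]) / dt + tol) + 1L else
      ceiling((hi - tt[1L]) / dt - tol)
    i0 <- max(i0, 1L)
    i1 <- min(i1, n)
    out[i] <- if (i1 >= i0) mean(x[i0:i1]) else NA_real_
  }
  out
}

# index range of samples with time in [from, to] (closed); assumes the
# uniform grid every pupil_trace guarantees
window_indices <- function(tt, from, to) {
  dt <- tt[2L] - tt[1L]
  tol <- 1e-4
  i0 <- max(ceiling((from - tt[1L]) / dt - tol) + 1L, 1L)
  i1 <- min(floor((to - tt[1L]) / dt + tol) + 1L, length(tt))
  if (i1 < i0) integer(0) else i0:i1
}

#' The blink-locked model grid
#'
#' Time points (seconds after the window anchor) of the down-sampled
#' grid on which all segments and mean profiles live: 16 points at
#' 5 Hz over a 3-s window by default.
#'
#' @param duration Window length, seconds.
#' @param out_rate Grid rate, Hz.
#' @return Numeric vector of grid times.
#' @export
model_grid <- function(duration = 3, out_rate = 5) {
  seq(0, duration, by = 1 / out_rate)
}
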