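#' Model-based BPR subtraction
#'
#' Removes the estimated blink-locked pupillary response from a trace:
#' for every blink the fitted kernel, scaled by that blink's amplitude
#' estimate, is evaluated at the native sampling times over the 3-s
#' model window after the blink offset and subtracted. Overlapping
#' footprints subtract additively, and samples outside every footprint
#' are untouched. Blinks without an amplitude estimate (e.g. windows
#' truncated by the trace end) use the median estimated amplitude.
#'
#' When the blink table carries peri-blink artifact windows
#' (`pre_start`, `post_end` columns from
#' [remove_periblink_artifacts()]) and `reinterpolate_artifacts` is
#' `TRUE` (default), samples inside those windows — which are linear
#' interpolation output, not measurements, and therefore already free
#' of most of the blink response — are re-interpolated from the
#' corrected samples at the window boundaries instead of having the
#' kernel subtracted from them a second time. The re-interpolation
#' delta is returned in `adjustment` so the decomposition stays exact:
#' `input = corrected + kernel components + adjustment`.
#'
#' @param trace A [pupil_trace()] (typically preprocessed).
#' @param blinks Blink table for this trace.
#' @param model A `bpr_fit` from [fit_bpr_model()].
#' @param span Kernel support after blink offset, seconds (default 3;
#'   the kernel is truncated there to match the fitted window).
#' @param reinterpolate_artifacts Re-interpolate peri-blink artifact
#'   windows after subtraction (default TRUE; only possible when the
#'   blink table has `pre_start` / `post_end` columns).
#' @return A list of class `bpr_correction` with elements `corrected`
#'   (the trace), `removed` (tibble: `blink`, `onset`, `offset`,
#'   `theta`, and a `component` list-column of the subtracted kernel
#'   values), `adjustment` (numeric vector, zero outside artifact
#'   windows), and `method = "model_based"`.
#' @export
subtract_bpr <- function(trace, blinks, model, span = 3,
                         reinterpolate_artifacts = TRUE) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (is.null(model$shape)) {
    warning("model has no fitted kernel; returning trace unchanged",
            call. = FALSE)
    return(structure(list(corrected = trace,
                          removed = tibble::tibble(
                            blink = integer(0), onset = numeric(0),
                            offset = numeric(0), theta = numeric(0),
                            component = list()),
                          adjustment = numeric(nrow(trace)),
                          method = "model_based"),
                     class = "bpr_correction"))
  }
  out <- trace
  removed <- vector("list", nrow(blinks))
  theta_default <- if (nrow(model$amplitudes)) {
    stats::median(model$amplitudes$theta)
  } else 1
  tt <- trace$time
  for (j in seq_len(nrow(blinks))) {
    off <- blinks$offset[j]
    i <- window_indices(tt, off, off + span)
    i <- i[i <= nrow(out)]
    if (!length(i)) next
    k <- which.min(abs(model$amplitudes$offset - off))
    th <- if (length(k) && nrow(model$amplitudes) &&
              abs(model$amplitudes$offset[k] - off) < 1e-6) {
      model$amplitudes$theta[k]
    } else theta_default
    comp <- th * gamma_kernel(model$shape, tt[i] - off)
    out$pupil[i] <- out$pupil[i] - comp
    removed[[j]] <- tibble::tibble(blink = j, onset = blinks$onset[j],
                                   offset = off, theta = th,
                                   component = list(comp))
  }
  adjustment <- numeric(nrow(out))
  if (reinterpolate_artifacts &&
      all(c("pre_start", "post_end") %in% names(blinks))) {
    n <- nrow(out)
    for (j in seq_len(nrow(blinks))) {
      inside <- which(tt >= blinks$pre_start[j] & tt <= blinks$post_end[j])
      if (!length(inside)) next
      i0 <- inside[1L] - 1L
      i1 <- inside[length(inside)] + 1L
      new_vals <- if (i0 < 1L && i1 > n) {
        next
      } else if (i0 < 1L) {
        rep(out$pupil[i1], length(inside))
      } else if (i1 > n) {
        rep(out$pupil[i0], length(inside))
      } else {
        stats::approx(tt[c(i0, i1)], out$pupil[c(i0, i1)],
                      xout = tt[inside])$y
      }
      adjustment[inside] <- adjustment[inside] +
        (out$pupil[inside] - new_vals)
      out$pupil[inside] <- new_vals
    }
  }
  structure(list(corrected = out,
                 removed = dplyr::bind_rows(removed),
                 adjustment = adjustment,
                 method = "model_based"),
            class = "bpr_correction")
}

#' Linear-interpolation blink correction (comparator)
#'
#' The widely used alternative to model-based correction: for every
#' blink, all samples from the pre-artifact start to `span` seconds
#' after the blink offset are replaced by the straight line joining the
#' trace values at the window's boundary samples. Overlapping windows
#' are merged before interpolation. This removes the BPR but also every
#' genuine signal inside the window.
#'
#' @param trace A [pupil_trace()].
#' @param blinks Blink table; `pre_start` column is used when present,
#'   otherwise `onset - pre_artifact`.
#' @param span Interpolation span after blink offset, seconds
#'   (default 3).
#' @param pre_artifact Pre-blink margin when `pre_start` is absent,
#'   seconds (default 0.15).
#' @return A list of class `bpr_correction` with elements `corrected`,
#'   `removed` (merged windows actually replaced), and
#'   `method = "interpolation"`.
#' @export
interpolate_blinks <- function(trace, blinks, span = 3,
                               pre_artifact = 0.15) {
  stopifnot(inherits(trace, "pupil_trace"))
  out <- trace
  if (nrow(blinks) == 0L) {
    return(structure(list(corrected = out,
                          removed = tibble::tibble(start = numeric(0),
                                                   end = numeric(0)),
                          method = "interpolation"),
                     class = "bpr_correction"))
  }
  starts <- if ("pre_start" %in% names(blinks)) blinks$pre_start else
    blinks$onset - pre_artifact
  ends <- blinks$offset + span
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  # merge overlapping windows
  ms <- starts[1]
  me <- ends[1]
  merged <- list()
  for (j in seq_along(starts)[-1]) {
    if (starts[j] <= me) {
      me <- max(me, ends[j])
    } else {
      merged[[length(merged) + 1L]] <- c(ms, me)
      ms <- starts[j]
      me <- ends[j]
    }
  }
  merged[[length(merged) + 1L]] <- c(ms, me)
  tt <- out$time
  n <- nrow(out)
  for (w in merged) {
    inside <- which(tt >= w[1] & tt <= w[2])
    if (!length(inside)) next
    i0 <- inside[1] - 1L
    i1 <- inside[length(inside)] + 1L
    if (i0 < 1L && i1 > n) next
    if (i0 < 1L) {
      warning("interpolation window reaches trace start; holding value",
              call. = FALSE)
      out$pupil[inside] <- out$pupil[i1]
    } else if (i1 > n) {
      warning("interpolation window reaches trace end; holding value",
              call. = FALSE)
      out$pupil[inside] <- out$pupil[i0]
    } else {
      out$pupil[inside] <- stats::approx(
        x = tt[c(i0, i1)], y = out$pupil[c(i0, i1)], xout = tt[inside])$y
    }
  }
  structure(list(corrected = out,
                 removed = tibble::tibble(
                   start = vapply(merged, `[`, numeric(1), 1L),
                   end = vapply(merged, `[`, numeric(1), 2L)),
                 method = "interpolation"),
            class = "bpr_correction")
}
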