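#' Plot a pupil trace
#'
#' @param object A [pupil_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pupil_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$pupil)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = dplyr::filter(df, !.data$valid),
                        colour = "red", size = 0.4) +
    ggplot2::labs(x = "time (s)",
                  y = paste0("pupil (", trace_unit(object), ")"),
                  title = trace_run_id(object)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted BPR kernel and mean profiles
#'
#' Shows the fitted blink-locked kernel over the 3-s model window,
#' together with the mean blink-free and blink-affected profiles
#' (back-transformed to mm).
#'
#' @param object A `bpr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bpr_fit <- function(object, ...) {
  grid <- model_grid()
  layers <- list()
  df <- NULL
  if (!is.null(object$shape)) {
    fine <- seq(0, grid[length(grid)], by = 0.01)
    df <- tibble::tibble(time = fine,
                         value = gamma_kernel(object$shape, fine),
                         what = "fitted kernel")
  }
  inv <- function(v) boxcox_transform(v, object$noise, "inverse")
  prof <- dplyr::bind_rows(
    tibble::tibble(time = grid, value = inv(object$means$mu_free),
                   what = "blink-free mean"),
    if (!is.null(object$means$mu_affected))
      tibble::tibble(time = grid, value = inv(object$means$mu_affected),
                     what = "affected background"))
  ggplot2::ggplot(dplyr::bind_rows(df, prof),
                  ggplot2::aes(x = .data$time, y = .data$value,
                               colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after blink offset (s)", y = "pupil (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a correction result
#'
#' Overlays the input and corrected traces.
#'
#' @param object A `bpr_correction`.
#' @param input Optional original [pupil_trace()] to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bpr_correction <- function(object, input = NULL, ...) {
  df <- tibble::tibble(time = object$corrected$time,
                       pupil = object$corrected$pupil,
                       what = paste0("corrected (", object$method, ")"))
  if (!is.null(input)) {
    df <- dplyr::bind_rows(
      tibble::tibble(time = input$time, pupil = input$pupil,
                     what = "input"), df)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$pupil,
                                   colour = .data$what)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "pupil", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap power curve
#'
#' @param object A `bpr_power` (or a named list of them, via
#'   [plot_power_curves()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bpr_power <- function(object, ...) {
  plot_power_curves(list(power = object))
}

#' @rdname autoplot.bpr_power
#' @param curves Named list of `bpr_power` objects (one per correction
#'   method).
#' @export
plot_power_curves <- function(curves) {
  df <- purrr::imap(curves, function(p, nm) {
    dplyr::mutate(p$results, method = nm)
  }) |> dplyr::bind_rows()
  target <- curves[[1]]$target_frac
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$rejection_frac,
                                   colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = target, linetype = 2) +
    ggplot2::labs(x = "trials per bootstrap sample",
                  y = "fraction of significant regressions",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
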