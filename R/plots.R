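#' Plot deformation curves with phase-boundary markers
#'
#' Draws all segment curves of a trace with a fixed qualitative palette
#' and, when event times are supplied, dashed vertical markers labelled
#' MVC, AVO, AVC, MVO at the valve events.
#'
#' @param x A [strain_trace()].
#' @param events Optional [event_timing()] for the valve-event markers.
#' @param main Plot title.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @export
plot.strain_trace <- function(x, events = NULL, main = NULL, ...) {
  ylab <- if (x$quantity == "strain") "strain (%)" else "strain rate (1/s)"
  cols <- grDevices::hcl.colors(ncol(x$segments), "Dark 3")
  graphics::matplot(x$time, x$segments, type = "l", lty = 1, col = cols,
                    xlab = "time (ms)", ylab = ylab,
                    main = main %||% sprintf("%s %s", x$chamber,
                                             x$quantity), ...)
  if (!is.null(events)) add_event_markers(events)
  invisible(x)
}

add_event_markers <- function(events) {
  ev <- c(MVC = events$mvc, AVO = events$avo, AVC = events$avc,
          MVO = events$mvo)
  graphics::abline(v = ev, lty = 2, col = "grey40")
  graphics::mtext(names(ev), side = 3, at = ev, cex = 0.7, line = 0.2)
}

#' @export
plot.ecg_trace <- function(x, events = NULL, ...) {
  graphics::plot(x$time, x$amplitude, type = "l", xlab = "time (ms)",
                 ylab = "ECG (a.u.)", ...)
  if (!is.null(events)) add_event_markers(events)
  invisible(x)
}

#' @export
plot.qq_data <- function(x, main = "Normal Q-Q", ...) {
  graphics::plot(x$theoretical, x$sample,
                 xlab = "theoretical quantiles",
                 ylab = "ordered sample", main = main, ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  invisible(x)
}

#' Paired measurements against the line of equality
#'
#' @param pairs A [paired_measurements()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_equality <- function(pairs, ...) {
  stopifnot(inherits(pairs, "paired_measurements"))
  graphics::plot(pairs$a, pairs$b, xlab = "method A", ylab = "method B",
                 main = "Line of equality", ...)
  graphics::abline(0, 1, col = "red")
  invisible(pairs)
}

#' Bland-Altman plot
#'
#' Differences against means with the bias line (solid) and the 1.96-SD
#' limits of agreement (dashed).
#'
#' @param report An `agreement_report` from [compare_methods()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_bland_altman <- function(report, ...) {
  stopifnot(inherits(report, "agreement_report"))
  pts <- bland_altman_points(report$pairs)
  ba <- report$bland_altman
  graphics::plot(pts$mean, pts$diff, xlab = "mean of methods",
                 ylab = "difference (A - B)", main = "Bland-Altman", ...)
  graphics::abline(h = ba$bias, col = "blue")
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2, col = "blue")
  invisible(report)
}

# open a png device if the build supports it; returns FALSE when figure
# output is unavailable (headless build without png support)
open_png <- function(path, width = 1200, height = 800) {
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height, res = 110)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) warning("png device unavailable; skipping figure ", path,
                   call. = FALSE)
  ok
}
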