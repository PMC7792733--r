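#' Time-sampled myocardial deformation curves for one chamber
#'
#' A `strain_trace` holds the deformation curves of the segments of one
#' cardiac chamber over (at least) one cardiac cycle: a strictly increasing
#' time axis in milliseconds, with `t = 0` at the onset of the first QRS
#' complex of the selected cycle, and one sample sequence per myocardial
#' segment. Strain is expressed in percent (negative during systolic
#' shortening for longitudinal strain); strain rate in 1/s.
#'
#' @param time Numeric vector of sample times in ms, strictly increasing.
#' @param segments Numeric matrix (samples x segments) with segment labels
#'   as column names, or a named list of equal-length numeric vectors.
#' @param chamber One of `"LV"`, `"RV"`, `"LA"`, `"RA"`.
#' @param view Apical view the curves come from: `"A4C"`, `"A3C"`, `"A2C"`,
#'   or `"NONE"` for multi-view merged or simulated traces.
#' @param quantity `"strain"` (%) or `"strain_rate"` (1/s).
#' @param segment_model `"SIX"` for a single-view 6-segment trace, `"AHA18"`
#'   for the merged 18-segment left-ventricular model.
#' @return An object of class `strain_trace`.
#' @seealso [read_trace_export()], [align_views()], [compute_gls()]
#' @export
strain_trace <- function(time, segments,
                         chamber = c("LV", "RV", "LA", "RA"),
                         view = c("A4C", "A3C", "A2C", "NONE"),
                         quantity = c("strain", "strain_rate"),
                         segment_model = c("SIX", "AHA18")) {
  chamber <- match.arg(chamber)
  view <- match.arg(view)
  quantity <- match.arg(quantity)
  segment_model <- match.arg(segment_model)

  if (is.list(segments)) {
    if (is.null(names(segments)) || any(!nzchar(names(segments)))) {
      stop("segments supplied as a list must be named", call. = FALSE)
    }
    segments <- do.call(cbind, lapply(segments, as.numeric))
  }
  segments <- as.matrix(segments)
  storage.mode(segments) <- "double"
  time <- as.numeric(time)

  if (nrow(segments) != length(time)) {
    stop("all segment sequences must have the same length as 'time'",
         call. = FALSE)
  }
  if (length(time) < 2 || any(diff(time) <= 0)) {
    stop("'time' must be strictly increasing with at least 2 samples",
         call. = FALSE)
  }
  labs <- colnames(segments)
  if (is.null(labs) || anyDuplicated(labs) || any(!nzchar(labs))) {
    stop("segment columns must carry unique non-empty labels", call. = FALSE)
  }
  n_expect <- if (segment_model == "AHA18") 18L else 6L
  if (ncol(segments) != n_expect) {
    stop(sprintf("segment_model %s requires exactly %d segments, got %d",
                 segment_model, n_expect, ncol(segments)), call. = FALSE)
  }
  structure(
    list(time = time, segments = segments, chamber = chamber, view = view,
         quantity = quantity, segment_model = segment_model),
    class = "strain_trace"
  )
}

#' @export
print.strain_trace <- function(x, ...) {
  cat(sprintf("<strain_trace> %s %s (%s, %s)\n", x$chamber, x$quantity,
              x$view, x$segment_model))
  cat(sprintf("  %d samples over %.0f-%.0f ms, %d segments: %s\n",
              length(x$time), min(x$time), max(x$time), ncol(x$segments),
              paste(utils::head(colnames(x$segments), 6L), collapse = ", ")))
  invisible(x)
}

#' Single-lead ECG record accompanying a trace export
#'
#' @param time Sample times in ms, strictly increasing.
#' @param amplitude Amplitude samples (arbitrary units), same length as
#'   `time`.
#' @param source_view Apical view whose export carried the ECG; the
#'   4-chamber record is the conventional time reference.
#' @return An object of class `ecg_trace`.
#' @export
ecg_trace <- function(time, amplitude, source_view = c("A4C", "A3C", "A2C")) {
  source_view <- match.arg(source_view)
  time <- as.numeric(time)
  amplitude <- as.numeric(amplitude)
  if (length(time) != length(amplitude)) {
    stop("'time' and 'amplitude' must have the same length", call. = FALSE)
  }
  if (length(time) < 2 || any(diff(time) <= 0)) {
    stop("'time' must be strictly increasing", call. = FALSE)
  }
  structure(list(time = time, amplitude = amplitude,
                 source_view = source_view),
            class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> %d samples over %.0f-%.0f ms (from %s)\n",
              length(x$time), min(x$time), max(x$time), x$source_view))
  invisible(x)
}

#' Canonical segment labels of the AHA 18-segment model
#'
#' Returns the six segment labels imaged by one apical view, in
#' base-to-apex, then apex-to-base wall order; across the three views they
#' enumerate the 18 left-ventricular segments of the AHA model.
#'
#' @param view `"A4C"`, `"A3C"` or `"A2C"`; `NULL` returns all 18 labels
#'   in view order A4C, A3C, A2C.
#' @return Character vector of segment labels.
#' @export
aha18_segments <- function(view = NULL) {
  labs <- list(
    A4C = c("BasSept", "MidSept", "ApSept", "ApLat", "MidLat", "BasLat"),
    A3C = c("BasAntSept", "MidAntSept", "ApAntSept",
            "ApInfLat", "MidInfLat", "BasInfLat"),
    A2C = c("BasInf", "MidInf", "ApInf", "ApAnt", "MidAnt", "BasAnt")
  )
  if (is.null(view)) return(unlist(labs, use.names = FALSE))
  if (!view %in% names(labs)) stop("unknown view: ", view, call. = FALSE)
  labs[[view]]
}

# generic six-segment labels for non-LV chambers (free wall + septal wall)
six_segments <- function(chamber) {
  paste0(chamber, c("BasFree", "MidFree", "ApFree",
                    "ApSept", "MidSept", "BasSept"))
}

#' Paired measurements of one quantity by two methods
#'
#' Container for a method-comparison series: one value per subject by
#' method A and by method B (here typically GLS in %, signed negative).
#'
#' @param labels Subject identifiers.
#' @param a,b Numeric measurement series, equal length >= 3, no missing
#'   values.
#' @return An object of class `paired_measurements`.
#' @seealso [compare_methods()], [bland_altman_points()]
#' @export
paired_measurements <- function(labels, a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) != length(labels)) {
    stop("'labels', 'a' and 'b' must have equal length", call. = FALSE)
  }
  if (length(a) < 3) stop("at least 3 pairs are required", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed",
                                 call. = FALSE)
  structure(list(labels = labels, a = a, b = b),
            class = "paired_measurements")
}

#' @export
print.paired_measurements <- function(x, ...) {
  cat(sprintf("<paired_measurements> n = %d\n", length(x$a)))
  cat(sprintf("  a: mean %.2f  b: mean %.2f  mean diff (a - b): %.3f\n",
              mean(x$a), mean(x$b), mean(x$a - x$b)))
  invisible(x)
}

#' @export
length.paired_measurements <- function(x) length(x$a)

#' @export
as.data.frame.paired_measurements <- function(x, ...) {
  data.frame(label = x$labels, a = x$a, b = x$b)
}
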