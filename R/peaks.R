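#' Peak systolic strain of one segment
#'
#' Locates the peak systolic strain of a single segment curve inside the
#' systolic search window, the interval from the first QRS onset to aortic
#' valve closure (AVC); the samples nearest each window boundary are
#' included. Two selection rules are implemented:
#'
#' * `"min"` — the most negative sample in the window, regardless of any
#'   positive peak (and the least positive sample when the curve is
#'   exclusively positive); ties broken by earliest time.
#' * `"pos75"` — the rule used by the EchoPAC package: with `N` the most
#'   negative and `P` the most positive value in the window, the positive
#'   peak `P` is selected when it exceeds 75% of `|N|`, otherwise `N`; a
#'   curve with no negative values in the window yields `P`.
#'
#' The two rules diverge on dyssynchronous (left-bundle-branch-block-like)
#' curves, where early systolic stretching of basal segments produces
#' positive peaks comparable in magnitude to the negative systolic peak.
#'
#' @param value Numeric vector of strain samples (%).
#' @param time Sample times (ms), strictly increasing, same length.
#' @param events An [event_timing()] providing `qrs1` and `avc`; `NULL`
#'   searches the whole curve (unphased mode, used when no ECG is
#'   available).
#' @param rule `"min"` or `"pos75"`.
#' @return A list of class `segment_peak`: `value` (%), `time` (ms),
#'   `rule`.
#' @export
peak_systolic <- function(value, time, events, rule = c("min", "pos75")) {
  rule <- match.arg(rule)
  stopifnot(length(value) == length(time))
  if (is.null(events)) {
    idx <- seq_along(time)
  } else {
    stopifnot(inherits(events, "event_timing"))
    i1 <- which.min(abs(time - events$qrs1))
    i2 <- which.min(abs(time - events$avc))
    idx <- i1:i2
  }
  if (length(idx) < 2) {
    stop("data error: systolic window contains fewer than 2 samples",
         call. = FALSE)
  }
  v <- value[idx]; tt <- time[idx]
  nmin <- min(v)
  if (rule == "min") {
    pick <- nmin
  } else {
    pmax_ <- max(v)
    pick <- if (nmin >= 0) pmax_
            else if (pmax_ > 0.75 * abs(nmin)) pmax_
            else nmin
  }
  at <- tt[which(v == pick)[1L]]  # earliest occurrence
  structure(list(value = pick, time = at, rule = rule),
            class = "segment_peak")
}

#' Global Longitudinal Strain over the 18-segment model
#'
#' Computes GLS as the arithmetic mean of the per-segment peak systolic
#' strain values of the 18 left-ventricular segments, under the chosen
#' peak-selection rule. Individual segments judged inadequate may be
#' excluded by passing the subset to keep in `segments`; excluding more
#' than two raises a quality-control flag (the exclusion threshold used
#' when validating the pipeline).
#'
#' @param trace An 18-segment [strain_trace()] (`segment_model = "AHA18"`,
#'   quantity strain).
#' @param events [event_timing()] bounding the systolic window, or `NULL`
#'   for unphased peak search over the whole trace.
#' @param rule Peak-selection rule, see [peak_systolic()].
#' @param segments Optional character vector of segment labels to use;
#'   default all 18.
#' @return A list of class `gls_result`: `peaks` (data frame with
#'   `segment`, `value`, `time`), `gls` (%), `rule`, `n_segments`,
#'   `excluded`, `qc_flag` (`TRUE` when more than two segments were
#'   excluded), `unphased`.
#' @export
compute_gls <- function(trace, events, rule = c("min", "pos75"),
                        segments = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(trace, "strain_trace"))
  if (trace$segment_model != "AHA18") {
    stop("GLS requires an 18-segment (AHA18) trace; run align_views() first",
         call. = FALSE)
  }
  if (trace$quantity != "strain") {
    stop("GLS is defined on strain curves, not ", trace$quantity,
         call. = FALSE)
  }
  all_labs <- colnames(trace$segments)
  use <- segments %||% all_labs
  miss <- setdiff(use, all_labs)
  if (length(miss)) {
    stop("missing segment(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  excluded <- setdiff(all_labs, use)
  pk <- lapply(use, function(s) {
    peak_systolic(trace$segments[, s], trace$time, events, rule)
  })
  peaks <- data.frame(
    segment = use,
    value = vapply(pk, `[[`, 0, "value"),
    time = vapply(pk, `[[`, 0, "time"),
    stringsAsFactors = FALSE
  )
  structure(
    list(peaks = peaks, gls = mean(peaks$value), rule = rule,
         n_segments = length(use), excluded = excluded,
         qc_flag = length(excluded) > 2L, unphased = is.null(events)),
    class = "gls_result"
  )
}

#' @export
print.gls_result <- function(x, ...) {
  cat(sprintf("GLS (%s rule%s): %.2f %% over %d segments\n",
              x$rule, if (x$unphased) ", unphased" else "", x$gls,
              x$n_segments))
  for (i in seq_len(nrow(x$peaks))) {
    cat(sprintf("  peak %-12s %8.2f %%  at %6.1f ms\n",
                x$peaks$segment[i], x$peaks$value[i], x$peaks$time[i]))
  }
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  if (x$qc_flag) cat("  QC flag: more than two segments excluded\n")
  invisible(x)
}

#' Derive strain rate from strain curves
#'
#' Differentiates fractional strain (strain % / 100) with respect to time
#' in seconds by central finite differences (one-sided at the endpoints),
#' yielding strain rate in 1/s. Non-uniform grids are handled by divided
#' differences. An optional moving-average smoother may be applied to the
#' strain before differentiation; it defaults to off, since exported
#' curves are already temporally filtered.
#'
#' @param trace A [strain_trace()] with `quantity = "strain"` and at
#'   least 3 samples.
#' @param smooth_ms Moving-average window in ms (0 = no smoothing).
#' @return A [strain_trace()] with `quantity = "strain_rate"` (1/s).
#' @export
strain_rate_from_strain <- function(trace, smooth_ms = 0) {
  stopifnot(inherits(trace, "strain_trace"))
  if (trace$quantity != "strain") {
    stop("input must be a strain trace", call. = FALSE)
  }
  if (length(trace$time) < 3) {
    stop("data error: at least 3 samples are required", call. = FALSE)
  }
  t_s <- trace$time / 1000
  seg <- trace$segments / 100
  if (smooth_ms > 0) {
    k <- max(1L, round(smooth_ms / stats::median(diff(trace$time))))
    if (k > 1) {
      w <- rep(1 / k, k)
      seg <- apply(seg, 2L, function(v) {
        sm <- stats::filter(v, w, sides = 2)
        ifelse(is.na(sm), v, as.numeric(sm))
      })
    }
  }
  sr <- apply(seg, 2L, function(v) pracma::gradient(v, t_s))
  strain_trace(trace$time, sr, chamber = trace$chamber, view = trace$view,
               quantity = "strain_rate",
               segment_model = trace$segment_model)
}
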