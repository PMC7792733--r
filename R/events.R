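#' Valve event and ECG landmark times of one cardiac cycle
#'
#' Collects the seven time marks that bound the mechanical phases of one
#' cycle: the ECG landmarks (onset of the first QRS complex, which defines
#' the cycle start and the time origin; onset of the P wave; onset of the
#' second QRS complex, the cycle end) and the four valve events (mitral
#' valve closure MVC, aortic valve opening AVO, aortic valve closure AVC,
#' mitral valve opening MVO). Physiological ordering is enforced:
#' `qrs1 <= mvc < avo < avc < mvo < p_onset < qrs2`; `qrs1 == mvc` is
#' permitted as a degenerate electromechanical-coupling phase.
#'
#' @param qrs1 First QRS onset (ms), conventionally 0.
#' @param mvc Mitral valve closure (ms).
#' @param avo Aortic valve opening (ms).
#' @param avc Aortic valve closure (ms); end of the systolic search window
#'   for peak systolic strain.
#' @param mvo Mitral valve opening (ms).
#' @param p_onset P-wave onset (ms).
#' @param qrs2 Second QRS onset (ms), the cycle end.
#' @return An object of class `event_timing`.
#' @seealso [segment_phases()], [read_event_config()]
#' @export
event_timing <- function(qrs1 = 0, mvc, avo, avc, mvo, p_onset, qrs2) {
  ev <- list(qrs1 = qrs1, mvc = mvc, avo = avo, avc = avc, mvo = mvo,
             p_onset = p_onset, qrs2 = qrs2)
  ev <- lapply(ev, function(v) {
    v <- as.numeric(v)
    if (length(v) != 1 || !is.finite(v)) {
      stop("each event must be a single finite time in ms", call. = FALSE)
    }
    v
  })
  nm <- names(ev)
  strict <- c(FALSE, rep(TRUE, 5L))  # qrs1 <= mvc, all later pairs strict
  for (i in seq_len(6L)) {
    lo <- ev[[i]]; hi <- ev[[i + 1L]]
    bad <- if (strict[i]) lo >= hi else lo > hi
    if (bad) {
      stop(sprintf("event ordering violated: %s %s %s (%g vs %g)",
                   nm[i], if (strict[i]) "<" else "<=", nm[i + 1L],
                   lo, hi), call. = FALSE)
    }
  }
  structure(ev, class = "event_timing")
}

#' @export
print.event_timing <- function(x, ...) {
  cat("<event_timing> (ms)\n")
  for (nm in names(x)) cat(sprintf("  %-8s %8.1f\n", nm, x[[nm]]))
  invisible(x)
}

#' Read event and landmark times from a key-value config file
#'
#' The file holds one `key: value` (or `key = value`) pair per line, keys
#' being the field names of [event_timing()]; blank lines and lines
#' starting with `#` are ignored. `qrs1` defaults to 0 when absent.
#'
#' @param path Path to the config file.
#' @return An [event_timing()] object.
#' @export
read_event_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- regmatches(ln, regexec("^([A-Za-z_0-9]+)\\s*[:=]\\s*(\\S+)", ln))
  keys <- vapply(kv, function(m) if (length(m)) m[2] else NA_character_, "")
  vals <- suppressWarnings(
    as.numeric(vapply(kv, function(m) if (length(m)) m[3] else NA, ""))
  )
  ok <- !is.na(keys) & !is.na(vals)
  ev <- as.list(vals[ok]); names(ev) <- tolower(keys[ok])
  need <- c("mvc", "avo", "avc", "mvo", "p_onset", "qrs2")
  miss <- setdiff(need, names(ev))
  if (length(miss)) {
    stop("config is missing event(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(ev$qrs1)) ev$qrs1 <- 0
  do.call(event_timing, ev[c("qrs1", need)])
}

#' Partition a cardiac cycle into its six mechanical phases
#'
#' Splits the interval from first to second QRS onset into the six phases
#' in their order of occurrence: EMC (electromechanical coupling, QRS
#' onset to MVC), IVC (isovolumic contraction, MVC to AVO), Ejec (ejection,
#' AVO to AVC), IVR (isovolumic relaxation, AVC to MVO), E (early filling,
#' MVO to P-wave onset; diastasis is merged into E), and A (atrial
#' contraction, P onset to the second QRS onset). Intervals are half-open
#' `[start, end)` so every sample time belongs to exactly one phase and the
#' six durations sum exactly to the cycle length.
#'
#' @param events An [event_timing()] object.
#' @return An object of class `cycle_phases`: a data frame with columns
#'   `phase`, `start`, `end`, `duration` (ms), one row per phase in order.
#' @examples
#' ev <- event_timing(qrs1 = 0, mvc = 30, avo = 80, avc = 380,
#'                    mvo = 460, p_onset = 700, qrs2 = 850)
#' segment_phases(ev)
#' @export
segment_phases <- function(events) {
  stopifnot(inherits(events, "event_timing"))
  bounds <- c(events$qrs1, events$mvc, events$avo, events$avc,
              events$mvo, events$p_onset, events$qrs2)
  ph <- data.frame(
    phase = c("EMC", "IVC", "Ejec", "IVR", "E", "A"),
    start = bounds[1:6],
    end = bounds[2:7],
    stringsAsFactors = FALSE
  )
  ph$duration <- ph$end - ph$start
  structure(ph, class = c("cycle_phases", "data.frame"), events = events)
}

#' @export
print.cycle_phases <- function(x, ...) {
  cat("Cardiac cycle phases (half-open intervals, ms):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-4s start %7.1f  duration %7.1f\n",
                x$phase[i], x$start[i], x$duration[i]))
  }
  cat(sprintf("  cycle length %.1f ms\n", sum(x$duration)))
  invisible(x)
}

#' Validate ECG landmark marks against an ECG trace
#'
#' Checks that the three operator-supplied ECG landmarks (first QRS onset,
#' P-wave onset, second QRS onset) are ordered and lie within the span of
#' the ECG record, and returns them as the ECG-landmark fragment of an
#' [event_timing()].
#'
#' @param ecg An [ecg_trace()].
#' @param qrs1,p_onset,qrs2 Landmark times in ms.
#' @return Named list with elements `qrs1`, `p_onset`, `qrs2`.
#' @export
validate_landmarks <- function(ecg, qrs1, p_onset, qrs2) {
  stopifnot(inherits(ecg, "ecg_trace"))
  marks <- c(qrs1 = qrs1, p_onset = p_onset, qrs2 = qrs2)
  span <- range(ecg$time)
  out <- marks < span[1] | marks > span[2]
  if (any(out)) {
    stop(sprintf("landmark(s) outside the ECG span [%g, %g] ms: %s",
                 span[1], span[2],
                 paste(names(marks)[out], collapse = ", ")), call. = FALSE)
  }
  if (!(qrs1 < p_onset && p_onset < qrs2)) {
    stop("landmarks misordered: require qrs1 < p_onset < qrs2",
         call. = FALSE)
  }
  as.list(marks)
}

#' Consistency check of repeated event-time registrations
#'
#' Some exams carry more than one registration of the valve event and
#' landmark times. An event is flagged inconsistent when the maximum
#' pairwise absolute difference between registrations exceeds `tol`
#' (default 10 ms, the exclusion rule applied during validation of the
#' pipeline); the exam fails overall if any event fails.
#'
#' @param registrations List of two or more [event_timing()] objects for
#'   the same exam.
#' @param tol Tolerance in ms (default 10).
#' @return Data frame with columns `event`, `max_diff`, `pass`; attribute
#'   `overall` is `TRUE` only if every event passes.
#' @export
check_event_timing_consistency <- function(registrations, tol = 10) {
  if (!is.list(registrations) || length(registrations) < 2) {
    stop("at least two registrations are required", call. = FALSE)
  }
  stopifnot(all(vapply(registrations, inherits, TRUE, "event_timing")))
  nm <- names(registrations[[1]])
  res <- data.frame(
    event = nm,
    max_diff = vapply(nm, function(e) {
      v <- vapply(registrations, `[[`, 0, e)
      diff(range(v))
    }, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$pass <- res$max_diff <= tol
  structure(res, overall = all(res$pass), tol = tol)
}
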