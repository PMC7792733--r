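#' Display/processing options of the pipeline
#'
#' The six view options: which chamber/quantity panels are shown and
#' whether an ECG (and hence phase separation) is involved. Option 6 is
#' the test mode for simulated input (for example curves produced by the
#' CircAdapt cardiovascular model), which carries no ECG: phase-dependent
#' quantities are not computed and peaks are searched over the whole
#' trace.
#'
#' @param code Integer 1 to 6.
#' @return A list with `code`, `panels` (data frame with columns
#'   `chamber`, `quantity`, `source`) and `ecg` (logical).
#' @export
view_option <- function(code) {
  opts <- list(
    list(panels = data.frame(chamber = c("LV", "LV"),
                             quantity = c("strain", "strain_rate"),
                             source = c("files", "files")), ecg = TRUE),
    list(panels = data.frame(chamber = c("LV", "LA"),
                             quantity = c("strain", "strain"),
                             source = c("files", "files")), ecg = TRUE),
    list(panels = data.frame(chamber = c("LV", "LA"),
                             quantity = c("strain", "strain_rate"),
                             source = c("files", "files")), ecg = TRUE),
    list(panels = data.frame(chamber = c("LV", "RV"),
                             quantity = c("strain", "strain"),
                             source = c("files", "files")), ecg = TRUE),
    list(panels = data.frame(chamber = c("LV", "LV"),
                             quantity = c("strain", "strain_rate"),
                             source = c("files", "derived")), ecg = TRUE),
    list(panels = data.frame(chamber = c("LV", "LV"),
                             quantity = c("strain", "strain_rate"),
                             source = c("files", "files")), ecg = FALSE)
  )
  if (!code %in% 1:6) stop("view option must be 1..6", call. = FALSE)
  c(list(code = as.integer(code)), opts[[code]])
}

trace_file <- function(dir, chamber, view, quantity) {
  q <- if (quantity == "strain") "strain" else "sr"
  file.path(dir, sprintf("%s_%s_%s.txt", chamber, view, q))
}

# read + align the three LV views for one quantity; A4C ECG returned too
read_lv_18 <- function(dir, quantity) {
  views <- c("A4C", "A3C", "A2C")
  paths <- vapply(views, function(v) trace_file(dir, "LV", v, quantity), "")
  miss <- !file.exists(paths)
  if (any(miss)) {
    stop("configuration error: missing LV trace file(s): ",
         paste(basename(paths[miss]), collapse = ", "), call. = FALSE)
  }
  reads <- lapply(paths, read_trace_export)
  traces <- lapply(reads, `[[`, "trace")
  ecg <- reads[[1]]$ecg
  list(trace18 = align_views(traces, reference = "A4C"), ecg = ecg)
}

#' Run the post-processing pipeline on a directory of trace exports
#'
#' Executes the full program flow: read the per-view LV exports (plus the
#' second chamber the chosen option asks for), merge the three apical
#' views onto the 4-chamber time base, validate the ECG landmarks,
#' segment the cycle into its six phases, detect per-segment peak
#' systolic strain and GLS under the chosen rule, print a stable
#' `key: value` report to the terminal, and (optionally) write the report,
#' a cached aligned 18-segment trace, and a multi-panel figure with
#' MVC/AVO/AVC/MVO markers to `out_dir`.
#'
#' Expected file names are `<CHAMBER>_<VIEW>_<strain|sr>.txt` in the
#' canonical dialect of [write_trace_export()], the `LV_A4C_strain.txt`
#' file carrying the ECG column. Under option 6 (simulated input, no ECG)
#' phases are not computed and peaks are searched over the whole trace,
#' flagged "unphased" in the report.
#'
#' @param traces_dir Directory holding the trace export files.
#' @param events An [event_timing()] or path to a key-value config file;
#'   must be `NULL` under option 6 (phase separation is disregarded for
#'   simulated input).
#' @param option View option 1-6, see [view_option()].
#' @param rule Peak-selection rule, see [peak_systolic()].
#' @param exam_id Exam identifier used in report lines and file names.
#' @param out_dir Output directory for report, cache and figure (`NULL`
#'   for terminal output only).
#' @param landmarks Optional named list (`qrs1`, `p_onset`, `qrs2`) of ECG
#'   landmark times, validated against the ECG and overriding the config
#'   values.
#' @param use_cache Reuse `<exam_id>_aligned18.txt` from `out_dir` when
#'   present instead of re-reading and re-aligning the view files.
#' @param make_figure Render the curves figure (PNG) into `out_dir`.
#' @param quiet Suppress terminal output.
#' @return Invisibly, a list with `trace18`, `ecg`, `phases`, `gls`,
#'   `secondary`, `report` (character lines) and `paths`.
#' @export
run_pipeline <- function(traces_dir, events = NULL, option = 1,
                         rule = c("min", "pos75"), exam_id = "exam",
                         out_dir = NULL, landmarks = NULL,
                         use_cache = TRUE, make_figure = !is.null(out_dir),
                         quiet = FALSE) {
  rule <- match.arg(rule)
  opt <- view_option(option)

  if (opt$ecg) {
    if (is.null(events)) {
      stop("configuration error: event times are required for option ",
           opt$code, call. = FALSE)
    }
    if (is.character(events)) events <- read_event_config(events)
    stopifnot(inherits(events, "event_timing"))
  } else if (!is.null(events) || !is.null(landmarks)) {
    stop("option 6 ingests simulated curves without ECG; phase ",
         "separation must be disregarded (do not pass events/landmarks)",
         call. = FALSE)
  }

  # primary LV 18-segment strain (with cache)
  cache_path <- if (!is.null(out_dir)) {
    file.path(out_dir, paste0(exam_id, "_aligned18.txt"))
  }
  if (use_cache && !is.null(cache_path) && file.exists(cache_path)) {
    cached <- read_trace_export(cache_path)
    lv <- list(trace18 = cached$trace, ecg = cached$ecg)
  } else {
    lv <- read_lv_18(traces_dir, "strain")
  }

  if (opt$ecg && is.null(lv$ecg)) {
    stop("configuration error: option ", opt$code,
         " requires an ECG but LV_A4C_strain.txt has no ecg column",
         call. = FALSE)
  }

  if (!is.null(landmarks)) {
    lm <- validate_landmarks(lv$ecg, landmarks$qrs1, landmarks$p_onset,
                             landmarks$qrs2)
    events <- do.call(event_timing,
                      utils::modifyList(unclass(events), lm))
  }

  phases <- if (opt$ecg) segment_phases(events)
  gls <- compute_gls(lv$trace18, if (opt$ecg) events, rule = rule)

  # secondary panel
  second <- opt$panels[2, ]
  secondary <- if (second$source == "derived") {
    strain_rate_from_strain(lv$trace18)
  } else if (second$chamber == "LV") {
    read_lv_18(traces_dir, second$quantity)$trace18
  } else {
    p <- trace_file(traces_dir, second$chamber, "A4C", second$quantity)
    if (!file.exists(p)) {
      stop("configuration error: missing trace file ", basename(p),
           call. = FALSE)
    }
    read_trace_export(p)$trace
  }

  report <- c(
    sprintf("exam: %s", exam_id),
    sprintf("option: %d", opt$code),
    sprintf("rule: %s", rule),
    if (!is.null(phases)) {
      vapply(seq_len(nrow(phases)), function(i) {
        sprintf("phase %s: start %.1f ms, duration %.1f ms",
                phases$phase[i], phases$start[i], phases$duration[i])
      }, "")
    } else "phases: unphased (option 6)",
    vapply(seq_len(nrow(gls$peaks)), function(i) {
      sprintf("peak %s: %.4f %% at %.1f ms", gls$peaks$segment[i],
              gls$peaks$value[i], gls$peaks$time[i])
    }, ""),
    sprintf("GLS: %.4f %%", gls$gls),
    sprintf("n_segments: %d", gls$n_segments),
    sprintf("qc_flag: %s", gls$qc_flag)
  )
  if (!quiet) cat(report, sep = "\n")

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$report <- file.path(out_dir, paste0(exam_id, "_report.txt"))
    writeLines(report, paths$report)
    if (!is.null(cache_path) && !file.exists(cache_path)) {
      write_trace_export(lv$trace18, cache_path, ecg = lv$ecg)
      paths$cache <- cache_path
    }
    if (make_figure) {
      fig <- file.path(out_dir, paste0(exam_id, "_curves.png"))
      if (open_png(fig, height = if (opt$ecg) 1100 else 800)) {
        on.exit(grDevices::dev.off(), add = TRUE)
        n_panel <- 2L + opt$ecg
        graphics::par(mfrow = c(n_panel, 1), mar = c(4, 4, 2, 1))
        plot(lv$trace18, events = if (opt$ecg) events)
        plot(secondary, events = if (opt$ecg) events)
        if (opt$ecg) plot(lv$ecg, events = events)
        paths$figure <- fig
      }
    }
  }

  invisible(list(trace18 = lv$trace18, ecg = lv$ecg, phases = phases,
                 gls = gls, secondary = secondary, report = report,
                 paths = paths))
}

#' Run the packaged GLS method-agreement validation
#'
#' Applies [compare_methods()] to the packaged 48-subject paired-GLS
#' series ([gls_validation_pairs()]), prints the report, and optionally
#' renders the Q-Q panels, the line-of-equality plot and the Bland-Altman
#' plot to `out_dir`.
#'
#' @param subject19 Transcription variant, see [gls_validation_pairs()].
#' @param out_dir Optional output directory for report and figures.
#' @param quiet Suppress terminal output.
#' @return The `agreement_report`, invisibly.
#' @export
validate_gls_pairs <- function(subject19 = c("printed", "corrected"),
                               out_dir = NULL, quiet = FALSE) {
  pairs <- gls_validation_pairs(match.arg(subject19))
  report <- compare_methods(pairs)
  if (!quiet) print(report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(format_agreement_report(report),
               file.path(out_dir, "agreement_report.txt"))
    if (open_png(file.path(out_dir, "qq.png"), width = 1500)) {
      graphics::par(mfrow = c(1, 3))
      plot(report$normal_a$qq, main = "Q-Q: method A")
      plot(report$normal_b$qq, main = "Q-Q: method B")
      plot(report$normal_diff$qq, main = "Q-Q: differences")
      grDevices::dev.off()
    }
    if (open_png(file.path(out_dir, "equality.png"), width = 800)) {
      plot_equality(pairs)
      grDevices::dev.off()
    }
    if (open_png(file.path(out_dir, "bland_altman.png"), width = 800)) {
      plot_bland_altman(report)
      grDevices::dev.off()
    }
  }
  invisible(report)
}
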