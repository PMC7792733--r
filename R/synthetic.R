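# run code with a locally-set RNG seed, restoring global state afterwards
local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic strain study
#'
#' Bundles the ground truth of a simulated single-cycle 18-segment strain
#' study: the event times, one target peak systolic strain per segment,
#' the amplitude of an optional positive early-systolic bulge (emulating
#' the basal stretching seen in left-bundle-branch-block dyssynchrony),
#' a post-systolic offset, the measurement-noise level and the sampling
#' interval. Defaults describe a normal subject at roughly 70 bpm: an
#' 850 ms cycle with MVC 30 ms, AVO 80 ms, AVC 380 ms, MVO 460 ms and
#' P-wave onset 700 ms after the QRS onset, 5 ms sampling, and peaks of
#' -18% (a normal GLS).
#'
#' @param events An [event_timing()].
#' @param peaks Numeric vector of 18 target peak strains (%), optionally
#'   named with segment labels (default [aha18_segments()] and -18 each).
#' @param early_stretch Positive early-systolic bulge amplitude (%),
#'   reached at MVC (default 0). Only representable when all target peaks
#'   are negative.
#' @param post_systolic_offset Offset (%) added to the early-diastolic
#'   plateau (default 0).
#' @param noise_sd Marginal SD (%) of the additive measurement noise,
#'   modelled as a smooth correlated Gaussian process (default 0).
#' @param sample_interval Sampling interval in ms (default 5).
#' @param seed Integer RNG seed (default 1).
#' @return A list of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(events = event_timing(0, 30, 80, 380,
                                                       460, 700, 850),
                                 peaks = rep(-18, 18),
                                 early_stretch = 0,
                                 post_systolic_offset = 0,
                                 noise_sd = 0,
                                 sample_interval = 5,
                                 seed = 1L) {
  stopifnot(inherits(events, "event_timing"))
  if (length(peaks) != 18) stop("'peaks' must have length 18",
                                call. = FALSE)
  if (any(!is.finite(peaks))) stop("'peaks' must be finite", call. = FALSE)
  if (is.null(names(peaks))) names(peaks) <- aha18_segments()
  if (sample_interval <= 0) stop("'sample_interval' must be positive",
                                 call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  if (early_stretch < 0) stop("'early_stretch' must be non-negative",
                              call. = FALSE)
  if (early_stretch > 0 && any(peaks >= 0)) {
    stop("spec error: early stretch with non-negative target peaks is ",
         "not representable (the window minimum would not be the target)",
         call. = FALSE)
  }
  structure(
    list(events = events, peaks = peaks, early_stretch = early_stretch,
         post_systolic_offset = post_systolic_offset, noise_sd = noise_sd,
         sample_interval = sample_interval, seed = as.integer(seed)),
    class = "synthetic_study_spec"
  )
}

# time grid: regular sampling plus the exact event times, so target peaks
# fall on grid samples
cycle_grid <- function(events, interval) {
  sort(unique(c(seq(events$qrs1, events$qrs2, by = interval),
                unlist(events))))
}

# half-cosine easing through a set of (time, value) control points
cosine_through <- function(t, ct, cv) {
  out <- numeric(length(t))
  for (i in seq_len(length(ct) - 1L)) {
    sel <- t >= ct[i] & t <= ct[i + 1L]
    s <- (t[sel] - ct[i]) / (ct[i + 1L] - ct[i])
    out[sel] <- cv[i] + (cv[i + 1L] - cv[i]) * (1 - cos(pi * s)) / 2
  }
  out
}

# one segment's noiseless cycle: 0 at QRS onset, optional positive bulge
# peaking at MVC, monotone half-cosine descent to the target peak at AVC,
# recovery through IVR/E, small atrial deflection, back to ~0 at QRS2
segment_cycle <- function(t, ev, peak, stretch, pso) {
  a_mid <- ev$p_onset + 0.55 * (ev$qrs2 - ev$p_onset)
  ct <- c(ev$qrs1, ev$mvc, ev$avc, ev$mvo, ev$p_onset, a_mid, ev$qrs2)
  cv <- c(0, stretch, peak, 0.35 * peak + pso, 0.08 * peak, 0.15 * peak, 0)
  if (any(diff(ct) <= 0)) {  # degenerate EMC: drop the duplicated point
    keep <- c(TRUE, diff(ct) > 0)
    ct <- ct[keep]; cv <- cv[keep]
  }
  cosine_through(t, ct, cv)
}

# smooth correlated gaussian noise: gaussian-kernel-smoothed white noise,
# renormalized to marginal sd; tau is the correlation time in ms
smooth_noise <- function(t, sd, tau = 30) {
  if (sd == 0) return(numeric(length(t)))
  w <- stats::rnorm(length(t))
  K <- exp(-outer(t, t, "-")^2 / (2 * tau^2))
  z <- as.vector(K %*% w)
  z / stats::sd(z) * sd
}

# impulse-like QRS complexes at the cycle bounds plus a P-wave bump
synth_ecg <- function(t, ev) {
  tri <- function(center, width, amp) {
    amp * pmax(0, 1 - abs(t - center) / (width / 2))
  }
  bump <- function(onset, width, amp) {
    s <- (t - onset) / width
    ifelse(s >= 0 & s <= 1, amp * (1 - cos(2 * pi * s)) / 2, 0)
  }
  tri(ev$qrs1, 30, 1) + tri(ev$qrs2, 30, 1) +
    bump(ev$p_onset, 0.8 * (ev$qrs2 - ev$p_onset), 0.15) +
    bump(ev$avc - 80, 120, 0.25)  # T wave ending near AVC
}

#' Generate one synthetic phase-structured strain cycle
#'
#' Builds an 18-segment single-cycle strain trace whose per-segment
#' systolic minima equal the spec's target peaks exactly (the event times
#' are inserted into the sampling grid), together with a matching ECG
#' trace. Curves are piecewise half-cosine: zero at the first QRS onset,
#' an optional positive bulge during EMC/IVC, monotone descent to the
#' target peak at aortic valve closure, recovery through IVR and early
#' filling, a small atrial deflection, and return to zero at the second
#' QRS onset. Noise, when requested, is smooth correlated Gaussian noise
#' with marginal SD `noise_sd`, reproducible under the spec's seed.
#'
#' @param spec A [synthetic_study_spec()].
#' @return List with components `trace` (18-segment [strain_trace()]),
#'   `ecg` ([ecg_trace()]) and `events`.
#' @export
generate_strain_cycle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  ev <- spec$events
  t <- cycle_grid(ev, spec$sample_interval)
  clean <- vapply(spec$peaks, function(p) {
    segment_cycle(t, ev, p, spec$early_stretch, spec$post_systolic_offset)
  }, numeric(length(t)))
  seg <- local_seed(spec$seed, {
    clean + vapply(seq_len(ncol(clean)),
                   function(i) smooth_noise(t, spec$noise_sd),
                   numeric(length(t)))
  })
  colnames(seg) <- names(spec$peaks)
  list(
    trace = strain_trace(t, seg, chamber = "LV", view = "NONE",
                         quantity = "strain", segment_model = "AHA18"),
    ecg = ecg_trace(t, synth_ecg(t, ev), source_view = "A4C"),
    events = ev
  )
}

#' Write a synthetic study as canonical per-view trace files
#'
#' Splits the spec's 18 segments into the three apical views and writes
#' one canonical export file per view (`LV_A4C_strain.txt`,
#' `LV_A3C_strain.txt`, `LV_A2C_strain.txt`), the 4-chamber file carrying
#' the ECG column, so the full file-based pipeline can be exercised
#' end-to-end. Optionally adds a 6-segment second chamber (RV or LA) and
#' strain-rate exports derived from the strain curves.
#'
#' @param spec A [synthetic_study_spec()].
#' @param dir Output directory (created if needed).
#' @param rv_peaks,la_peaks Optional length-6 target peaks for an RV / LA
#'   A4C strain file.
#' @param sr_files Also write LV strain-rate exports per view.
#' @param with_ecg Include the ECG column in the A4C files (set `FALSE`
#'   to emulate simulated input that carries no ECG).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_synthetic_study <- function(spec, dir, rv_peaks = NULL,
                                  la_peaks = NULL, sr_files = FALSE,
                                  with_ecg = TRUE) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  full <- generate_strain_cycle(spec)
  t <- full$trace$time
  paths <- character(0)

  for (vw in c("A4C", "A3C", "A2C")) {
    labs <- aha18_segments(vw)
    tr <- strain_trace(t, full$trace$segments[, labs, drop = FALSE],
                       chamber = "LV", view = vw, quantity = "strain",
                       segment_model = "SIX")
    p <- file.path(dir, sprintf("LV_%s_strain.txt", vw))
    write_trace_export(tr, p,
                       ecg = if (vw == "A4C" && with_ecg) full$ecg)
    paths <- c(paths, p)
    if (sr_files) {
      ps <- file.path(dir, sprintf("LV_%s_sr.txt", vw))
      write_trace_export(strain_rate_from_strain(tr), ps)
      paths <- c(paths, ps)
    }
  }

  extra <- list(RV = rv_peaks, LA = la_peaks)
  for (ch in names(extra)) {
    pk <- extra[[ch]]
    if (is.null(pk)) next
    stopifnot(length(pk) == 6)
    seg <- vapply(pk, function(p) {
      segment_cycle(t, spec$events, p, 0, 0)
    }, numeric(length(t)))
    colnames(seg) <- six_segments(ch)
    tr <- strain_trace(t, seg, chamber = ch, view = "A4C",
                       quantity = "strain", segment_model = "SIX")
    p <- file.path(dir, sprintf("%s_A4C_strain.txt", ch))
    write_trace_export(tr, p)
    paths <- c(paths, p)
    if (sr_files && ch == "LA") {
      ps <- file.path(dir, "LA_A4C_sr.txt")
      write_trace_export(strain_rate_from_strain(tr), ps)
      paths <- c(paths, ps)
    }
  }
  invisible(paths)
}

#' Generate paired GLS measurements with known bias and spread
#'
#' Simulates a method-comparison series: reference values
#' `a_i ~ Normal(mu, spread)` and candidate values
#' `b_i = a_i - bias + Normal(0, sd_diff)`, so the differences
#' `a - b` have mean `bias` and SD `sd_diff`.
#'
#' @param n Number of pairs (>= 3).
#' @param mu Mean GLS (%), default -16.
#' @param spread Between-subject SD (%), default 5.
#' @param bias Systematic offset (%) of method b below method a.
#' @param sd_diff Within-pair SD (%).
#' @param seed Integer RNG seed.
#' @return A [paired_measurements()] object.
#' @export
generate_paired_gls <- function(n, mu = -16, spread = 5, bias = 0,
                                sd_diff = 0.5, seed = 1L) {
  stopifnot(n >= 3, spread >= 0, sd_diff >= 0)
  local_seed(seed, {
    a <- stats::rnorm(n, mu, spread)
    b <- a - bias + stats::rnorm(n, 0, sd_diff)
    paired_measurements(seq_len(n), a, b)
  })
}
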