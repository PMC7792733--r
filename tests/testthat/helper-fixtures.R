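# shared fixtures: event sets, random curves, and independent brute-force
# peak evaluators (kept deliberately naive so they stay independent of the
# package's own implementation)

default_events <- function() {
  event_timing(qrs1 = 0, mvc = 30, avo = 80, avc = 380, mvo = 460,
               p_onset = 700, qrs2 = 850)
}

# random valid event ordering (possibly degenerate EMC), arbitrary origin
random_events <- function(allow_degenerate_emc = TRUE) {
  t0 <- stats::runif(1, -500, 500)
  g1 <- if (allow_degenerate_emc && stats::runif(1) < 0.2) 0
        else stats::runif(1, 1, 80)
  gaps <- c(g1, stats::runif(5, 1, 300))
  v <- t0 + cumsum(c(0, gaps))
  event_timing(v[1], v[2], v[3], v[4], v[5], v[6], v[7])
}

# wiggly random curve on a grid, mixing trends, bumps and sign changes
random_curve <- function(t) {
  s <- (t - min(t)) / diff(range(t))
  a <- stats::rnorm(3, 0, 8)
  a[1] * sin(pi * s) + a[2] * sin(2 * pi * s) + a[3] * s +
    stats::rnorm(length(t), 0, 2)
}

# naive enumeration of the window [qrs1, avc] (nearest-sample boundaries)
brute_window <- function(t, ev) {
  i1 <- which.min(abs(t - ev$qrs1))
  i2 <- which.min(abs(t - ev$avc))
  seq(i1, i2)
}

brute_peak_min <- function(v, t, ev) {
  w <- brute_window(t, ev)
  best <- Inf; at <- NA_real_
  for (i in w) if (v[i] < best) { best <- v[i]; at <- t[i] }
  list(value = best, time = at)
}

brute_peak_75 <- function(v, t, ev) {
  w <- brute_window(t, ev)
  N <- Inf; P <- -Inf
  for (i in w) { N <- min(N, v[i]); P <- max(P, v[i]) }
  if (N >= 0) P else if (P > 0.75 * abs(N)) P else N
}

# small noiseless six-segment trace used across io tests
toy_trace <- function(n = 100, k = 6, view = "A4C", chamber = "LV") {
  t <- seq(0, by = 8, length.out = n)
  seg <- vapply(seq_len(k), function(i) {
    -10 - i + 5 * sin(2 * pi * t / max(t) + i)
  }, numeric(n))
  labs <- if (chamber == "LV" && k == 6) aha18_segments(view)
          else paste0("S", seq_len(k))
  colnames(seg) <- labs
  strain_trace(t, seg, chamber = chamber, view = view,
               quantity = "strain",
               segment_model = if (k == 18) "AHA18" else "SIX")
}
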