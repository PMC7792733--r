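test_that("the window-minimum rule returns the most negative sample", {
  ev <- default_events()
  t <- seq(0, 850, by = 10)
  v <- -18.4 * sin(pi * pmin(t, 400) / 400)  # reaches -18.4 at 200 ms
  pk <- peak_systolic(v, t, ev, rule = "min")
  expect_equal(pk$value, min(v[t <= 380]))

  # exclusively positive curve: the least positive value is still taken
  vp <- 2.1 + 3 * (t / 850)
  expect_equal(peak_systolic(vp, t, ev, rule = "min")$value, 2.1)

  # tie broken by earliest time
  vt <- rep(0, length(t)); vt[t == 300] <- -5; vt[t == 350] <- -5
  pk <- peak_systolic(vt, t, ev, rule = "min")
  expect_equal(pk$value, -5)
  expect_equal(pk$time, 300)
})

test_that("the 75% rule switches to the positive peak exactly at threshold", {
  ev <- default_events()
  t <- seq(0, 850, by = 10)
  curve_np <- function(N, P) {
    v <- numeric(length(t)); v[t == 100] <- P; v[t == 300] <- N; v
  }
  expect_equal(peak_systolic(curve_np(-10, 8), t, ev, "pos75")$value, 8)
  expect_equal(peak_systolic(curve_np(-10, 7), t, ev, "pos75")$value, -10)
  # exactly 75% does not "exceed"
  expect_equal(peak_systolic(curve_np(-10, 7.5), t, ev, "pos75")$value, -10)
  # monotone negative curve: P is negative, never selected
  vneg <- -1 - 14 * pmin(t, 380) / 380
  expect_equal(peak_systolic(vneg, t, ev, "pos75")$value, min(vneg[t <= 380]))
  # no negative values in window: the positive maximum is returned
  vpos <- 1 + 2 * sin(pi * t / 850)
  expect_equal(peak_systolic(vpos, t, ev, "pos75")$value,
               max(vpos[t <= 380]))
})

test_that("both rules agree with naive brute-force evaluation", {
  set.seed(21)
  t <- seq(0, 850, by = 5)
  for (i in 1:60) {
    ev <- random_events()
    tt <- seq(ev$qrs1, ev$qrs2, length.out = 150)
    v <- random_curve(tt)
    bm <- brute_peak_min(v, tt, ev)
    pk <- peak_systolic(v, tt, ev, "min")
    expect_identical(pk$value, bm$value)
    expect_identical(pk$time, bm$time)
    expect_identical(peak_systolic(v, tt, ev, "pos75")$value,
                     brute_peak_75(v, tt, ev))
    # minimality: no window sample lies below the detected peak
    expect_true(all(v[brute_window(tt, ev)] >= pk$value))
  }
})

test_that("rules coincide whenever the positive peak is within 75% of |N|", {
  set.seed(22)
  ev <- default_events()
  tt <- seq(0, 850, by = 5)
  agree <- 0
  for (i in 1:100) {
    v <- random_curve(tt)
    w <- brute_window(tt, ev)
    N <- min(v[w]); P <- max(v[w])
    a <- peak_systolic(v, tt, ev, "min")$value
    b <- peak_systolic(v, tt, ev, "pos75")$value
    if (N < 0 && P <= 0.75 * abs(N)) {
      expect_identical(a, b)
      agree <- agree + 1
    }
  }
  expect_gt(agree, 0)  # the agreement region was actually exercised
})

test_that("GLS is the arithmetic mean of the 18 segment peaks", {
  ev <- default_events()
  spec <- synthetic_study_spec(events = ev, peaks = rep(-20, 18))
  g <- generate_strain_cycle(spec)
  expect_equal(compute_gls(g$trace, ev)$gls, -20)

  spec <- synthetic_study_spec(events = ev,
                               peaks = c(rep(-10, 9), rep(-20, 9)))
  g <- generate_strain_cycle(spec)
  expect_equal(compute_gls(g$trace, ev)$gls, -15)
})

test_that("GLS is permutation-invariant and linear under uniform scaling", {
  set.seed(23)
  ev <- default_events()
  spec <- synthetic_study_spec(events = ev, peaks = runif(18, -25, -5))
  g <- generate_strain_cycle(spec)
  r1 <- compute_gls(g$trace, ev)

  perm <- sample(18)
  tr2 <- strain_trace(g$trace$time, g$trace$segments[, perm],
                      chamber = "LV", view = "NONE", quantity = "strain",
                      segment_model = "AHA18")
  expect_equal(compute_gls(tr2, ev)$gls, r1$gls)

  tr3 <- g$trace; tr3$segments <- tr3$segments * 0.5
  expect_equal(compute_gls(tr3, ev)$gls, r1$gls * 0.5)
})

test_that("segment exclusion reports and flags quality control", {
  ev <- default_events()
  g <- generate_strain_cycle(synthetic_study_spec(events = ev))
  labs <- colnames(g$trace$segments)

  r <- compute_gls(g$trace, ev, segments = labs[-(1:2)])
  expect_equal(r$n_segments, 16L)
  expect_false(r$qc_flag)

  r <- compute_gls(g$trace, ev, segments = labs[-(1:3)])
  expect_true(r$qc_flag)  # more than two segments excluded

  expect_error(compute_gls(g$trace, ev, segments = c(labs[1], "NoSuch")),
               "NoSuch")
})

test_that("strain rate is the time derivative of fractional strain", {
  t <- seq(0, 800, by = 5)
  mk <- function(v) {
    seg <- matrix(rep(v, 6), ncol = 6,
                  dimnames = list(NULL, aha18_segments("A4C")))
    strain_trace(t, seg, chamber = "LV", view = "A4C",
                 quantity = "strain", segment_model = "SIX")
  }
  # constant strain -> SR identically 0
  expect_true(all(strain_rate_from_strain(mk(rep(-10, length(t))))$segments
                  == 0))

  # -20% ramp over 400 ms -> -0.5 1/s on the ramp interior
  ramp <- ifelse(t <= 400, -20 * t / 400, -20)
  sr <- strain_rate_from_strain(mk(ramp))$segments[, 1]
  interior <- t > 10 & t < 390
  expect_equal(sr[interior], rep(-0.5, sum(interior)), tolerance = 1e-9)

  # sinusoid matches the analytic derivative to O(h^2)
  f <- -15 * sin(2 * pi * t / 800)
  sr <- strain_rate_from_strain(mk(f))$segments[, 1]
  truth <- -0.15 * (2 * pi / 0.8) * cos(2 * pi * t / 800)
  expect_lt(max(abs(sr - truth)[-c(1, length(t))]), 5e-3)

  expect_error(strain_rate_from_strain(
    strain_trace(c(0, 10), matrix(0, 2, 6,
                                  dimnames = list(NULL, paste0("S", 1:6))),
                 quantity = "strain")), "3 samples")
})

test_that("integrating strain rate recovers the strain curve", {
  t <- seq(0, 800, by = 5)
  f <- -18 * sin(pi * t / 800)^2
  seg <- matrix(rep(f, 6), ncol = 6,
                dimnames = list(NULL, aha18_segments("A4C")))
  tr <- strain_trace(t, seg, chamber = "LV", view = "A4C",
                     quantity = "strain", segment_model = "SIX")
  sr <- strain_rate_from_strain(tr)
  rebuilt <- 100 * pracma::cumtrapz(t / 1000, sr$segments[, 1]) + f[1]
  expect_lt(max(abs(rebuilt - f)), 0.05)
})
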