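test_that("canonical export round-trips every value exactly", {
  tr <- toy_trace()
  ecg <- ecg_trace(tr$time, sin(tr$time / 50), source_view = "A4C")
  p <- withr::local_tempfile(fileext = ".txt")
  write_trace_export(tr, p, ecg = ecg)

  got <- read_trace_export(p)
  expect_identical(got$trace$segments, tr$segments)
  expect_identical(got$trace$time, tr$time)
  expect_identical(got$trace$chamber, "LV")
  expect_identical(got$trace$view, "A4C")
  expect_identical(got$trace$segment_model, "SIX")
  expect_equal(got$ecg$amplitude, ecg$amplitude)
})

test_that("an 18-segment export lists all 18 labels in its header", {
  ev <- default_events()
  full <- generate_strain_cycle(synthetic_study_spec(events = ev))
  p <- withr::local_tempfile(fileext = ".txt")
  write_trace_export(full$trace, p)
  header <- grep("^time_ms", readLines(p), value = TRUE)
  expect_length(strsplit(header, "\t")[[1]], 19L)  # time + 18 segments
  expect_setequal(strsplit(header, "\t")[[1]][-1], aha18_segments())
})

test_that("tolerant dialect accepts decimal commas and reordered columns", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "SegA;ecg;time_ms;SegB;SegC;SegD;SegE;SegF",
    "-17,88;0,1;0;1,5;2;3;4;5",
    "-18,02;0,2;10;1,6;2;3;4;5",
    "-18,40;0,0;20;1,7;2;3;4;5"
  ), p)
  got <- read_trace_export(p, dialect = "tolerant")
  expect_equal(got$trace$segments[, "SegA"], c(-17.88, -18.02, -18.40))
  expect_equal(got$trace$time, c(0, 10, 20))
  expect_equal(got$ecg$amplitude, c(0.1, 0.2, 0.0))
})

test_that("malformed exports are rejected with clear errors", {
  # ragged row
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("time_ms\tA\tB", "0\t1\t2", "10\t1", "20\t1\t2"), p)
  expect_error(read_trace_export(p), "row 2")

  # no time column
  writeLines(c("A\tB", "0\t1", "10\t1"), p)
  expect_error(read_trace_export(p), "time column")

  # non-monotone time
  writeLines(c("time_ms\tA", "0\t1", "10\t2", "5\t3"), p)
  expect_error(read_trace_export(p), "strictly increasing")

  # unwritable path
  expect_error(write_trace_export(toy_trace(), "/nonexistent/dir/x.txt"),
               "I/O error")
})

test_that("align_views is the identity when cycle lengths match", {
  t <- seq(0, 800, by = 10)
  mk <- function(view) {
    seg <- matrix(rnorm(length(t) * 6), ncol = 6,
                  dimnames = list(NULL, aha18_segments(view)))
    strain_trace(t, seg, chamber = "LV", view = view,
                 quantity = "strain", segment_model = "SIX")
  }
  set.seed(7)
  trs <- lapply(c("A4C", "A3C", "A2C"), mk)
  out <- align_views(trs)
  expect_identical(out$segment_model, "AHA18")
  expect_equal(ncol(out$segments), 18L)
  for (tr in trs) {
    expect_equal(out$segments[, colnames(tr$segments)], tr$segments,
                 tolerance = 1e-12)
  }
})

test_that("align_views rescales time linearly and interpolates on lines", {
  # reference 800 ms; A2C cycle 1000 ms sampled coarsely, values linear in
  # its own time: after scaling by 0.8 the value at reference time t is
  # the closed-form line evaluated at t / 0.8
  t_ref <- seq(0, 800, by = 10)
  mk <- function(view, t, vals) {
    seg <- matrix(rep(vals, 6), ncol = 6,
                  dimnames = list(NULL, aha18_segments(view)))
    strain_trace(t, seg, chamber = "LV", view = view,
                 quantity = "strain", segment_model = "SIX")
  }
  a4c <- mk("A4C", t_ref, rnorm(length(t_ref)))
  a3c <- mk("A3C", t_ref, rnorm(length(t_ref)))
  t2 <- seq(0, 1000, by = 50)
  a2c <- mk("A2C", t2, 2 - 0.03 * t2)

  out <- align_views(list(a4c, a3c, a2c))
  expect_equal(out$segments[, "BasInf"], 2 - 0.03 * (t_ref / 0.8),
               tolerance = 1e-10)

  # ratio guard: 300 ms cycle against an 800 ms reference is rejected
  t3 <- seq(0, 300, by = 10)
  bad <- mk("A2C", t3, rnorm(length(t3)))
  expect_error(align_views(list(a4c, a3c, bad)), "ratio")

  rv <- mk("A2C", t2, rnorm(length(t2)))
  rv$chamber <- "RV"
  expect_error(align_views(list(a4c, a3c, rv)), "chamber")
})

test_that("packaged GLS validation series matches its source listing", {
  pairs <- gls_validation_pairs()
  expect_length(pairs, 48L)
  expect_equal(pairs$a[pairs$labels == 1], -17.90)
  expect_equal(pairs$b[pairs$labels == 1], -17.88)
  expect_equal(pairs$a[pairs$labels == 36], -2.70)
  expect_equal(pairs$b[pairs$labels == 36], -3.37)
  expect_true(all(abs(pairs$a) > 0 & abs(pairs$a) < 30))
  expect_true(all(abs(pairs$b) > 0 & abs(pairs$b) < 30))

  fixed <- gls_validation_pairs("corrected")
  expect_equal(fixed$b[fixed$labels == 19], -19.68)
  expect_identical(fixed$b[fixed$labels != 19],
                   pairs$b[pairs$labels != 19])
})

test_that("paired_measurements enforces its invariants", {
  expect_error(paired_measurements(1:2, c(1, 2), c(1, 2)), "at least 3")
  expect_error(paired_measurements(1:3, c(1, 2, NA), c(1, 2, 3)),
               "missing")
  expect_error(paired_measurements(1:3, c(1, 2), c(1, 2, 3)),
               "equal length")
})
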