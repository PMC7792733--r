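#' Shapiro-Wilk normality assessment
#'
#' Runs the Shapiro-Wilk test and packages it together with the Q-Q data
#' used for the accompanying graphical check. The sample is judged normal
#' when `p > alpha`.
#'
#' @param x Numeric sample, 3 to 5000 values.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `normality_result`: `statistic` (W),
#'   `p_value`, `normal`, `alpha`, `qq` (see [qq_data()]).
#' @export
shapiro_normality <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("degenerate sample: all values identical", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  structure(
    list(statistic = unname(sw$statistic), p_value = sw$p.value,
         normal = sw$p.value > alpha, alpha = alpha, qq = qq_data(x)),
    class = "normality_result"
  )
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk: W = %.4f, p = %.4g -> %s at alpha = %g\n",
              x$statistic, x$p_value,
              if (x$normal) "normal" else "non-normal", x$alpha))
  invisible(x)
}

#' Normal Q-Q data with a quartile reference line
#'
#' Pairs the ordered sample with standard-normal quantiles at plotting
#' positions `(i - 0.5)/n` and computes the reference line through the
#' first- and third-quartile points, the convention behind the usual red
#' reference line of a Q-Q plot.
#'
#' @param x Numeric sample, n >= 3.
#' @return A list of class `qq_data`: `theoretical`, `sample` (ordered),
#'   `slope`, `intercept`.
#' @export
qq_data <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("usage error: n >= 3 required", call. = FALSE)
  s <- sort(x)
  theo <- stats::qnorm((seq_len(n) - 0.5) / n)
  qy <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  qx <- stats::qnorm(c(0.25, 0.75))
  slope <- (qy[2] - qy[1]) / (qx[2] - qx[1])
  structure(
    list(theoretical = theo, sample = s, slope = slope,
         intercept = qy[1] - slope * qx[1]),
    class = "qq_data"
  )
}

#' Normality-gated method-agreement analysis
#'
#' Runs the full paired method-comparison battery on two measurement
#' series `a` (reference method) and `b` (candidate method), with
#' differences oriented `d = a - b`:
#'
#' 1. Shapiro-Wilk normality of `a`, `b`, and `d` (with Q-Q data).
#' 2. Correlation: Pearson when both `a` and `b` are normal, Spearman
#'    otherwise.
#' 3. Paired hypothesis test of H0 "mean difference = 0": Student's
#'    paired t when `d` is normal, Wilcoxon signed rank otherwise
#'    (normal approximation with continuity correction when more than 25
#'    non-zero differences, exact distribution otherwise; zero
#'    differences dropped).
#' 4. Bland-Altman: bias = mean of `d`, limits of agreement
#'    `bias +/- 1.96 * SD(d)`; "dispersion" is the half-width
#'    `1.96 * SD(d)` (the raw SD is also reported).
#'
#' The equivalence verdict applies four criteria: correlation coefficient
#' (rounded to 2 decimals) at least `min_r`, test p-value above `alpha`,
#' `|bias|` at most `max_bias`, and dispersion at most `max_dispersion`
#' (thresholds in the measurement's own units, here % GLS, i.e. absolute
#' variation). The two methods are declared equivalent when all four hold.
#'
#' @param pairs A [paired_measurements()] object.
#' @param alpha Significance level for the normality gates and the paired
#'   test (default 0.05).
#' @param min_r Correlation criterion (default 0.95).
#' @param max_bias Bias criterion in measurement units (default 1).
#' @param max_dispersion Dispersion criterion, half-width of the limits of
#'   agreement (default 2).
#' @return A list of class `agreement_report`; see Details.
#' @examples
#' rep <- compare_methods(gls_validation_pairs())
#' rep$verdict$equivalent
#' @export
compare_methods <- function(pairs, alpha = 0.05, min_r = 0.95,
                            max_bias = 1, max_dispersion = 2) {
  stopifnot(inherits(pairs, "paired_measurements"))
  a <- pairs$a; b <- pairs$b
  d <- a - b
  n <- length(a)

  normal_a <- shapiro_normality(a, alpha)
  normal_b <- shapiro_normality(b, alpha)

  degenerate <- diff(range(d)) == 0
  normal_diff <- if (degenerate) NULL else shapiro_normality(d, alpha)

  cor_method <- if (normal_a$normal && normal_b$normal) "pearson"
                else "spearman"
  r <- stats::cor(a, b, method = cor_method)

  if (degenerate) {
    if (all(d == 0)) {
      warning("all differences are zero; paired test is degenerate (p = 1)",
              call. = FALSE)
      test <- list(method = "t_paired", statistic = NA_real_, p_value = 1)
    } else {
      warning("differences are constant and non-zero; paired test is ",
              "degenerate (p = 0)", call. = FALSE)
      test <- list(method = "t_paired", statistic = Inf, p_value = 0)
    }
  } else if (normal_diff$normal) {
    tt <- stats::t.test(a, b, paired = TRUE)
    test <- list(method = "t_paired", statistic = unname(tt$statistic),
                 p_value = tt$p.value)
  } else {
    n_nonzero <- sum(d != 0)
    wt <- stats::wilcox.test(a, b, paired = TRUE,
                             exact = n_nonzero <= 25, correct = TRUE)
    test <- list(method = "wilcoxon", statistic = unname(wt$statistic),
                 p_value = wt$p.value)
  }

  bias <- mean(d)
  sd_diff <- stats::sd(d)
  dispersion <- 1.96 * sd_diff
  ba <- list(bias = bias, sd_diff = sd_diff,
             loa_low = bias - dispersion, loa_high = bias + dispersion,
             dispersion = dispersion)

  verdict <- list(
    correlation_ok = round(r, 2) >= min_r,
    test_ok = test$p_value > alpha,
    bias_ok = abs(bias) <= max_bias,
    dispersion_ok = dispersion <= max_dispersion
  )
  verdict$equivalent <- all(unlist(verdict))

  structure(
    list(n = n, normal_a = normal_a, normal_b = normal_b,
         normal_diff = normal_diff,
         correlation = list(method = cor_method, r = r),
         paired_test = test, bland_altman = ba, verdict = verdict,
         criteria = list(alpha = alpha, min_r = min_r, max_bias = max_bias,
                         max_dispersion = max_dispersion),
         pairs = pairs),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  for (ln in format_agreement_report(x)) cat(ln, "\n", sep = "")
  invisible(x)
}

# stable key: value rendering shared by print and report export
format_agreement_report <- function(x) {
  v <- x$verdict
  nd <- if (is.null(x$normal_diff)) "degenerate"
        else sprintf("W = %.4f, p = %.4f (%s)", x$normal_diff$statistic,
                     x$normal_diff$p_value,
                     if (x$normal_diff$normal) "normal" else "non-normal")
  c(sprintf("n: %d", x$n),
    sprintf("normality a: W = %.4f, p = %.4f (%s)", x$normal_a$statistic,
            x$normal_a$p_value,
            if (x$normal_a$normal) "normal" else "non-normal"),
    sprintf("normality b: W = %.4f, p = %.4f (%s)", x$normal_b$statistic,
            x$normal_b$p_value,
            if (x$normal_b$normal) "normal" else "non-normal"),
    sprintf("normality diff: %s", nd),
    sprintf("correlation: %s r = %.4f (%.2f)", x$correlation$method,
            x$correlation$r, round(x$correlation$r, 2)),
    sprintf("paired test: %s p = %.4f", x$paired_test$method,
            x$paired_test$p_value),
    sprintf("bias: %.4f", x$bland_altman$bias),
    sprintf("sd diff: %.4f", x$bland_altman$sd_diff),
    sprintf("loa: [%.4f, %.4f]", x$bland_altman$loa_low,
            x$bland_altman$loa_high),
    sprintf("dispersion: %.4f", x$bland_altman$dispersion),
    sprintf("correlation_ok: %s", v$correlation_ok),
    sprintf("test_ok: %s", v$test_ok),
    sprintf("bias_ok: %s", v$bias_ok),
    sprintf("dispersion_ok: %s", v$dispersion_ok),
    sprintf("equivalent: %s", v$equivalent))
}

#' Bland-Altman point coordinates
#'
#' Per-subject `(mean, difference)` pairs of the Bland-Altman plot:
#' `mean_i = (a_i + b_i)/2`, `diff_i = a_i - b_i`, in input order. Useful
#' for probing whether differences grow at small measurement magnitudes
#' (as observed for |GLS| below 10%).
#'
#' @param pairs A [paired_measurements()] object (n >= 2).
#' @return Data frame with columns `label`, `mean`, `diff`.
#' @export
bland_altman_points <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  data.frame(label = pairs$labels,
             mean = (pairs$a + pairs$b) / 2,
             diff = pairs$a - pairs$b,
             stringsAsFactors = FALSE)
}
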