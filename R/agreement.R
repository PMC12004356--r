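# Method-comparison statistics between a test method (SERS + PLSR) and a
# reference method (HPLC): Bland-Altman agreement, minimal detectable
# change, unit conversion and scatter regression.

#' Bland-Altman agreement analysis
#'
#' Computes paired differences d = test - reference, their mean (bias), SD
#' (n-1 denominator), the limits of agreement `bias +/- z * sd`, and the
#' minimal detectable change `MDC = z * sd` -- the half-width of the
#' agreement interval, i.e. the smallest concentration difference that
#' exceeds the paired measurement variability. The scatter regression of
#' test on reference (see [method_scatter()]) is included in the report.
#'
#' @param data Data frame of paired measurements.
#' @param reference,test Columns (unquoted) holding the reference and test
#'   concentrations (uM).
#' @param z Limit multiplier; the default 1.96 gives 95% limits under
#'   normal differences.
#' @return An `agreement_report`; `tidy()` returns the per-pair
#'   differences, `glance()` the one-row summary, `autoplot()` the
#'   Bland-Altman plot.
#' @export
#' @examples
#' cohort <- generate_paired_cohort(27, seed = 9)
#' ba <- bland_altman(cohort, reference, test)
#' glance(ba)
bland_altman <- function(data, reference, test, z = 1.96) {
  ref <- dplyr::pull(data, {{ reference }})
  tst <- dplyr::pull(data, {{ test }})
  if (length(ref) != length(tst)) abort("paired series must have equal length")
  n <- length(ref)
  if (n < 3) abort("Bland-Altman analysis needs >= 3 pairs")
  d <- tst - ref
  bias <- mean(d)
  sd_diff <- sd(d)
  ula <- bias + z * sd_diff
  lla <- bias - z * sd_diff
  pairs <- tibble::tibble(reference = ref, test = tst,
                          mean_pair = (ref + tst) / 2, difference = d,
                          outside_loa = d > ula | d < lla)
  structure(
    list(n_pairs = n, bias = bias, sd_diff = sd_diff,
         ula = ula, lla = lla, z = z,
         mdc = z * sd_diff,
         mdc_mg_per_l = micromolar_to_mg_per_l(z * sd_diff),
         n_outside_loa = sum(pairs$outside_loa),
         pairs = pairs,
         regression = method_scatter(data, {{ reference }}, {{ test }})),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> Bland-Altman, test - reference\n")
  cat(sprintf("  n = %d pairs, bias = %.2f uM, SD of differences = %.2f uM\n",
              x$n_pairs, x$bias, x$sd_diff))
  cat(sprintf("  LoA [%.2f, %.2f] uM (z = %g), %d pair(s) outside\n",
              x$lla, x$ula, x$z, x$n_outside_loa))
  cat(sprintf("  MDC = %.2f uM (%.2f mg/L)\n", x$mdc, x$mdc_mg_per_l))
  cat(sprintf("  scatter: slope = %.3f, R^2 = %.3f\n",
              x$regression$slope, x$regression$r_squared))
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) x$pairs

#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, bias = x$bias, sd_diff = x$sd_diff,
                 lla = x$lla, ula = x$ula, mdc = x$mdc,
                 mdc_mg_per_l = x$mdc_mg_per_l,
                 n_outside_loa = x$n_outside_loa,
                 slope = x$regression$slope,
                 r_squared = x$regression$r_squared)
}

#' Minimal detectable change from limits of agreement
#'
#' The MDC is the half-width of the agreement interval,
#' `(ULA - LLA) / 2 = z * sd_diff`.
#'
#' @param ula,lla Upper and lower limits of agreement (uM), `ula >= lla`.
#' @return The MDC (uM).
#' @export
#' @examples
#' mdc_from_loa(45.8, -74.9)
mdc_from_loa <- function(ula, lla) {
  if (ula < lla) abort("`ula` must be >= `lla`")
  (ula - lla) / 2
}

#' Convert a micromolar concentration to mg/L
#'
#' @param c Concentration (uM), >= 0.
#' @param molar_mass Molar mass (g/mol); default 383.46, meropenem free
#'   acid.
#' @return Concentration in mg/L.
#' @export
#' @examples
#' micromolar_to_mg_per_l(60.38)
micromolar_to_mg_per_l <- function(c, molar_mass = 383.46) {
  if (any(c < 0)) abort("concentration must be >= 0")
  if (molar_mass <= 0) abort("`molar_mass` must be > 0")
  c * molar_mass / 1000
}

#' Scatter regression between two measurement methods
#'
#' Ordinary least squares of the test method on the reference method, with
#' the pointwise 95% confidence band for the mean response and the
#' two-sided t-test of the slope.
#'
#' @inheritParams bland_altman
#' @param conf_level Confidence level of the band.
#' @return A `method_scatter` object with `slope`, `intercept`,
#'   `r_squared`, `slope_p_value` and a `band` tibble (reference grid,
#'   fit, lwr, upr).
#' @export
method_scatter <- function(data, reference, test, conf_level = 0.95) {
  ref <- dplyr::pull(data, {{ reference }})
  tst <- dplyr::pull(data, {{ test }})
  if (length(ref) < 3) abort("scatter regression needs >= 3 pairs")
  if (sd(ref) == 0) abort("reference series has zero variance")
  df <- data.frame(reference = ref, test = tst)
  fit <- lm(test ~ reference, data = df)
  sm <- summary(fit)
  grid <- data.frame(reference = seq(min(ref), max(ref), length.out = 100))
  band <- cbind(grid, predict(fit, grid, interval = "confidence",
                              level = conf_level))
  structure(
    list(fit = fit,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         slope_p_value = sm$coefficients["reference", "Pr(>|t|)"],
         conf_level = conf_level,
         band = tibble::as_tibble(band),
         pairs = tibble::tibble(reference = ref, test = tst)),
    class = "method_scatter"
  )
}

#' @export
print.method_scatter <- function(x, ...) {
  cat(sprintf("<method_scatter> test = %.3f + %.3f x reference, R^2 = %.3f, slope p = %.3g\n",
              x$intercept, x$slope, x$r_squared, x$slope_p_value))
  invisible(x)
}

#' @export
glance.method_scatter <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, slope_p_value = x$slope_p_value,
                 n = nrow(x$pairs))
}
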