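# Spectral preprocessing: cropping, asymmetric-least-squares background
# correction, top-fraction map reduction and signal-to-noise estimation.

#' Configure map reduction
#'
#' @param target_band Quantification band center (cm^-1); default 1559, the
#'   dominant meropenem band.
#' @param window_halfwidth Half-width (cm^-1) of the window in which the
#'   band maximum is sought; "~1559" is read as 1559 +/- this.
#' @param fraction Fraction of brightest pixels averaged, in (0, 1].
#' @param crop_range Wavenumber range retained before any correction.
#' @param baseline_lambda,baseline_p Smoothness penalty and asymmetry of the
#'   baseline estimator (see [baseline_correct()]).
#' @return A `reduction_config` list.
#' @export
reduction_config <- function(target_band = 1559, window_halfwidth = 10,
                             fraction = 0.20, crop_range = c(600, 1800),
                             baseline_lambda = 1e5, baseline_p = 0.01) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  if (window_halfwidth <= 0) abort("`window_halfwidth` must be > 0")
  if (target_band - window_halfwidth < crop_range[1] ||
      target_band + window_halfwidth > crop_range[2]) {
    abort("target window must lie inside the crop range")
  }
  structure(list(target_band = target_band,
                 window_halfwidth = window_halfwidth,
                 fraction = fraction,
                 crop_range = as.numeric(crop_range),
                 baseline_lambda = baseline_lambda,
                 baseline_p = baseline_p),
            class = "reduction_config")
}

#' Crop a spectrum to a wavenumber range
#'
#' Retains only the channels whose wavenumber lies inside the closed range;
#' works on any tibble with `wavenumber` and `intensity` columns (single
#' spectra and long-format maps alike).
#'
#' @param data A `sers_spectrum` / `sers_map` tibble.
#' @param range Length-2 numeric, `[min, max]` cm^-1.
#' @return The cropped tibble (same class as the input).
#' @export
#' @examples
#' sp <- generate_spectrum(100, seed = 1)
#' crop_spectrum(sp, c(1500, 1650))
crop_spectrum <- function(data, range) {
  if (!is_spectrum_like(data)) {
    abort("`data` must have `wavenumber` and `intensity` columns")
  }
  keep <- data$wavenumber >= range[1] & data$wavenumber <= range[2]
  if (!any(keep)) abort("crop range does not overlap the wavenumber axis")
  dplyr::filter(data, .data$wavenumber >= range[1],
                .data$wavenumber <= range[2])
}

# Baseline for a matrix of spectra (rows = spectra), via the compiled
# asymmetric-least-squares Whittaker smoother.
als_baseline_matrix <- function(Y, lambda = 1e5, p = 0.01, maxit = 20) {
  if (any(!is.finite(Y))) abort("intensities must be finite")
  als_baseline_cpp(Y, lambda, p, as.integer(maxit))
}

#' Estimate and subtract a smooth background
#'
#' Asymmetric least squares (AsLS): a Whittaker smoother with a
#' second-difference roughness penalty `lambda` and asymmetric weights that
#' downweight points above the running baseline (peaks get weight
#' `asymmetry`, valley points `1 - asymmetry`). Larger `lambda` gives a
#' stiffer baseline.
#'
#' @param data A spectrum or long map tibble (`wavenumber`, `intensity`,
#'   optionally `pixel`).
#' @param lambda Smoothness penalty (dimensionless, typical 1e4-1e7).
#' @param asymmetry Peak weight in (0, 0.5); default 0.01.
#' @param maxit Maximum reweighting iterations.
#' @return The input with `intensity` replaced by the corrected signal and
#'   the estimated background in a new `baseline` column.
#' @export
#' @examples
#' sp <- generate_spectrum(250, seed = 2)
#' corr <- baseline_correct(sp)
baseline_correct <- function(data, lambda = 1e5, asymmetry = 0.01,
                             maxit = 20) {
  if (!is_spectrum_like(data)) {
    abort("`data` must have `wavenumber` and `intensity` columns")
  }
  if (asymmetry <= 0 || asymmetry >= 0.5) {
    abort("`asymmetry` must be in (0, 0.5)")
  }
  if ("pixel" %in% names(data)) {
    mm <- map_to_matrix(data)
    if (ncol(mm$X) < 10) abort("need >= 10 channels for baseline estimation")
    B <- als_baseline_matrix(mm$X, lambda, asymmetry, maxit)
    idx <- cbind(match(data$pixel, mm$pixels),
                 match(data$wavenumber, mm$wavenumbers))
    base <- B[idx]
  } else {
    if (nrow(data) < 10) abort("need >= 10 channels for baseline estimation")
    base <- drop(als_baseline_matrix(matrix(data$intensity, nrow = 1),
                                     lambda, asymmetry, maxit))
  }
  out <- data
  out$baseline <- base
  out$intensity <- data$intensity - base
  out
}

# Shared matrix-form reduction: crop, per-pixel baseline correction, rank by
# corrected peak height in the target window, average top fraction.
reduce_matrix_top_fraction <- function(X, wavenumbers, config) {
  keep <- wavenumbers >= config$crop_range[1] &
    wavenumbers <= config$crop_range[2]
  if (!any(keep)) abort("crop range does not overlap the wavenumber axis")
  X <- X[, keep, drop = FALSE]
  wn <- wavenumbers[keep]
  win <- window_idx(wn, config$target_band, config$window_halfwidth)
  if (!length(win)) abort("target window contains no channels")
  B <- als_baseline_matrix(X, config$baseline_lambda, config$baseline_p)
  C <- X - B
  heights <- apply(C[, win, drop = FALSE], 1, max)
  n_top <- max(1L, ceiling(config$fraction * nrow(X)))
  top <- order(heights, decreasing = TRUE)[seq_len(n_top)]
  list(spectrum = colMeans(C[top, , drop = FALSE]),
       peak_height = mean(heights[top]),
       pixel_heights = heights,
       top_pixels = sort(top),
       wavenumbers = wn)
}

#' Reduce a SERS map to one representative spectrum
#'
#' Crops each pixel spectrum, removes its background with
#' [baseline_correct()]'s AsLS estimator, ranks pixels by their maximum
#' corrected intensity inside the target-band window (default 1559 +/- 10
#' cm^-1), and averages the top fraction (default 20%, at least one pixel)
#' channelwise. This keeps the hotspot pixels that carry analytical signal
#' and discards weakly enhancing regions of the chip.
#'
#' @param map A `sers_map` tibble (long format, `pixel` column).
#' @param config A [reduction_config()].
#' @return A `sers_spectrum` tibble of the representative (baseline-
#'   corrected) spectrum, with attributes `peak_height` (mean corrected
#'   band height of the retained pixels), `n_pixels_used` and `top_pixels`.
#' @export
#' @examples
#' m <- generate_map(500, n_pixels = 25, seed = 4)
#' r <- reduce_map_top_fraction(m)
#' attr(r, "peak_height")
reduce_map_top_fraction <- function(map, config = reduction_config()) {
  if (!is_spectrum_like(map) || !"pixel" %in% names(map)) {
    abort("`map` must be a long map tibble with a `pixel` column")
  }
  mm <- map_to_matrix(map)
  red <- reduce_matrix_top_fraction(mm$X, mm$wavenumbers, config)
  out <- new_spectrum(red$wavenumbers, red$spectrum)
  attr(out, "peak_height") <- red$peak_height
  attr(out, "n_pixels_used") <- length(red$top_pixels)
  attr(out, "top_pixels") <- mm$pixels[red$top_pixels]
  out
}

#' Signal-to-noise ratio of a band
#'
#' Net band height (maximum baseline-corrected intensity in the signal
#' window) divided by the SD of the baseline-corrected intensities in a
#' signal-free noise region.
#'
#' @param spectrum A `sers_spectrum` tibble.
#' @param signal_band Band center (cm^-1), default 1559.
#' @param window_halfwidth Signal window half-width (cm^-1).
#' @param noise_region Length-2 range (cm^-1) free of configured bands;
#'   must contain >= 5 channels.
#' @param correct_baseline If `TRUE` (default) the spectrum is AsLS
#'   baseline-corrected first; set `FALSE` for already-corrected input.
#' @return The SNR (dimensionless scalar).
#' @export
snr <- function(spectrum, signal_band = 1559, window_halfwidth = 10,
                noise_region = c(1700, 1790), correct_baseline = TRUE) {
  if (correct_baseline) spectrum <- baseline_correct(spectrum)
  wn <- spectrum$wavenumber
  win <- window_idx(wn, signal_band, window_halfwidth)
  if (!length(win)) abort("signal window contains no channels")
  noise_idx <- which(wn >= noise_region[1] & wn <= noise_region[2])
  if (length(noise_idx) < 5) abort("noise region must contain >= 5 channels")
  noise_sd <- sd(spectrum$intensity[noise_idx])
  if (noise_sd == 0) {
    abort("noise SD is zero in the noise region; SNR is undefined")
  }
  max(spectrum$intensity[win]) / noise_sd
}
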