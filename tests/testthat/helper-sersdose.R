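# Shared fixtures: small, fast generator configurations built in code.

# Short axis (150 channels over the default crop range) for speed.
tiny_config <- function(noise_sd = 5, pixel_heterogeneity = 0.25,
                        baseline_coefs = c(120, -60, 25), ...) {
  generator_config(wavenumbers = seq(600, 1800, length.out = 150),
                   noise_sd = noise_sd,
                   pixel_heterogeneity = pixel_heterogeneity,
                   baseline_coefs = baseline_coefs, ...)
}

# Deterministic config: no noise, no heterogeneity, flat-zero baseline.
clean_config <- function(...) {
  tiny_config(noise_sd = 0, pixel_heterogeneity = 0,
              baseline_coefs = 0, ...)
}

# Calibration tibble built directly from a spectra matrix (bypasses the
# map simulation; used to feed controlled inputs to the modelling code).
caldata_from_matrix <- function(X, y, wavenumbers = NULL) {
  if (is.null(colnames(X))) {
    if (is.null(wavenumbers)) {
      wavenumbers <- seq(600, 1800, length.out = ncol(X))
    }
    colnames(X) <- sersdose:::format_wn(wavenumbers)
  }
  out <- tibble::tibble(concentration = y)
  out$spectra <- X
  out
}

# Single-peak spectra matrix: one Lorentzian analyte band whose height is
# `heights[i]` in row i, on the tiny axis. The center is snapped to the
# nearest grid channel so the row maximum equals the height exactly.
peak_matrix <- function(heights, center = 1559, width = 14, n_chan = 150) {
  wn <- seq(600, 1800, length.out = n_chan)
  center <- wn[which.min(abs(wn - center))]
  prof <- 1 / (1 + (2 * (wn - center) / width)^2)
  X <- outer(heights, prof)
  colnames(X) <- sersdose:::format_wn(wn)
  X
}
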