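# Synthetic SERS data generation: single spectra, chip maps, calibration
# designs and paired method-comparison cohorts with known ground truth.

#' Define a Raman band
#'
#' A band is parameterised by its center, full width at half maximum and a
#' response. For analyte bands the response is the peak amplitude per unit
#' concentration (intensity / uM); for interferent bands it is a fixed peak
#' amplitude (intensity units).
#'
#' @param center Band center (cm^-1).
#' @param width Full width at half maximum (cm^-1), > 0.
#' @param response Peak amplitude per uM (analyte) or fixed amplitude
#'   (interferent). Must be >= 0.
#' @param shape `"lorentzian"` (default, the usual Raman line shape) or
#'   `"gaussian"`.
#' @return A one-row tibble with columns `center`, `width`, `response`,
#'   `shape`.
#' @export
#' @examples
#' band_spec(1559, 14, 1)
band_spec <- function(center, width, response,
                      shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (width <= 0) abort("band `width` must be > 0")
  if (response < 0) abort("band `response` must be >= 0")
  tibble::tibble(center = center, width = width, response = response,
                 shape = shape)
}

#' Default meropenem SERS band set
#'
#' The characteristic meropenem bands at 1559 (dominant, the quantification
#' band), 1387, 1052, 890, 771, 709 and 670 cm^-1, with relative responses
#' chosen so the 1559 cm^-1 band dominates.
#'
#' @param shape Line shape passed to [band_spec()].
#' @return A tibble of band specifications.
#' @export
meropenem_bands <- function(shape = "lorentzian") {
  dplyr::bind_rows(
    band_spec(1559, 14, 1.00, shape),
    band_spec(1387, 14, 0.55, shape),
    band_spec(1052, 12, 0.35, shape),
    band_spec(890, 12, 0.45, shape),
    band_spec(771, 12, 0.30, shape),
    band_spec(709, 12, 0.20, shape),
    band_spec(670, 12, 0.18, shape)
  )
}

#' Default serum interferent band set
#'
#' Residual serum-matrix bands surviving cleanup, dominated by the uric acid
#' band at 640 cm^-1; responses are fixed amplitudes (intensity units) before
#' the cleanup-method scale factor is applied.
#'
#' @inheritParams meropenem_bands
#' @return A tibble of band specifications.
#' @export
serum_interferent_bands <- function(shape = "lorentzian") {
  dplyr::bind_rows(
    band_spec(640, 16, 120, shape),
    band_spec(1003, 12, 60, shape),
    band_spec(1450, 18, 40, shape)
  )
}

#' Serum cleanup method profiles
#'
#' Relative effect of each serum cleanup method on the simulated spectra:
#' `interferent_scale` multiplies interferent band amplitudes and
#' `noise_scale` multiplies the additive noise SD. Protein precipitation (PP)
#' leaves the most matrix behind; mono-spin solid-phase extraction (msSPE)
#' the least, with ultrafiltration (3 kDa and 10 kDa cutoffs) in between.
#'
#' @return A tibble with columns `method`, `interferent_scale`,
#'   `noise_scale`.
#' @export
cleanup_profiles <- function() {
  tibble::tibble(
    method = c("PP", "UF3k", "UF10k", "msSPE"),
    interferent_scale = c(1.00, 0.80, 0.50, 0.12),
    noise_scale = c(2.0, 1.6, 1.3, 1.0)
  )
}

#' Configure the synthetic SERS generator
#'
#' Holds every assumption of the simulation: the wavenumber grid, the
#' analyte and interferent band sets, the serum cleanup method, a smooth
#' polynomial substrate baseline, the additive noise level and the
#' pixel-to-pixel enhancement heterogeneity of a SERS map.
#'
#' @param wavenumbers Strictly increasing wavenumber grid (cm^-1). Default:
#'   696 channels spanning 600-1800 cm^-1.
#' @param analyte_bands Tibble of [band_spec()] rows with per-uM responses.
#' @param interferent_bands Tibble of [band_spec()] rows with fixed
#'   amplitudes.
#' @param cleanup Serum cleanup method, one of
#'   `"msSPE"`, `"UF10k"`, `"UF3k"`, `"PP"` (see [cleanup_profiles()]).
#' @param baseline_coefs Polynomial coefficients (intercept first) of the
#'   substrate background, evaluated on the axis rescaled to `[0, 1]`.
#' @param noise_sd Additive homoscedastic Gaussian noise SD (intensity
#'   units), before the cleanup noise scale. Must be >= 0.
#' @param pixel_heterogeneity Log-SD of the per-pixel log-normal
#'   multiplicative enhancement factor (mean 1). 0 gives identical pixels.
#' @return A `generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(noise_sd = 2)
#' sp <- generate_spectrum(100, cfg, seed = 1)
generator_config <- function(wavenumbers = seq(600, 1800, length.out = 696),
                             analyte_bands = meropenem_bands(),
                             interferent_bands = serum_interferent_bands(),
                             cleanup = "msSPE",
                             baseline_coefs = c(120, -60, 25),
                             noise_sd = 5,
                             pixel_heterogeneity = 0.25) {
  check_axis(wavenumbers)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (pixel_heterogeneity < 0) abort("`pixel_heterogeneity` must be >= 0")
  prof <- cleanup_profiles()
  if (!cleanup %in% prof$method) {
    abort(paste0("unknown cleanup method '", cleanup, "'"))
  }
  rng <- range(wavenumbers)
  for (b in list(analyte_bands, interferent_bands)) {
    if (nrow(b) && any(b$center < rng[1] | b$center > rng[2])) {
      warn("some band centers fall outside the wavenumber axis")
    }
  }
  structure(
    list(wavenumbers = as.numeric(wavenumbers),
         analyte_bands = analyte_bands,
         interferent_bands = interferent_bands,
         cleanup = cleanup,
         baseline_coefs = as.numeric(baseline_coefs),
         noise_sd = noise_sd,
         pixel_heterogeneity = pixel_heterogeneity),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  axis: %d channels, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  cat(sprintf("  analyte bands: %d (dominant %g cm^-1)\n",
              nrow(x$analyte_bands),
              x$analyte_bands$center[which.max(x$analyte_bands$response)]))
  cat(sprintf("  interferent bands: %d, cleanup: %s\n",
              nrow(x$interferent_bands), x$cleanup))
  cat(sprintf("  noise_sd: %g, pixel_heterogeneity: %g\n",
              x$noise_sd, x$pixel_heterogeneity))
  invisible(x)
}

# Peak-normalised line profiles for a band table: channels x bands matrix.
band_profiles <- function(bands, wavenumbers) {
  if (!nrow(bands)) {
    return(matrix(0, length(wavenumbers), 0))
  }
  vapply(seq_len(nrow(bands)), function(i) {
    d <- wavenumbers - bands$center[i]
    w <- bands$width[i]
    if (bands$shape[i] == "lorentzian") {
      1 / (1 + (2 * d / w)^2)
    } else {
      exp(-4 * log(2) * (d / w)^2)
    }
  }, numeric(length(wavenumbers)))
}

# Deterministic spectral components of a config.
config_components <- function(config) {
  wn <- config$wavenumbers
  u <- (wn - min(wn)) / diff(range(wn))
  baseline <- drop(outer(u, seq_along(config$baseline_coefs) - 1, `^`) %*%
                     config$baseline_coefs)
  prof <- cleanup_profiles()
  cl <- prof[prof$method == config$cleanup, ]
  analyte <- drop(band_profiles(config$analyte_bands, wn) %*%
                    config$analyte_bands$response)
  interferent <- cl$interferent_scale *
    drop(band_profiles(config$interferent_bands, wn) %*%
           config$interferent_bands$response)
  list(baseline = baseline, analyte_per_um = analyte,
       interferent = interferent, noise_sd = config$noise_sd * cl$noise_scale)
}

# Evaluate a block with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one SERS spectrum
#'
#' Intensity model: polynomial substrate baseline + enhancement x (analyte
#' band profiles x response x concentration + interferent band profiles) +
#' additive Gaussian noise.
#'
#' @param concentration Analyte concentration (uM), >= 0.
#' @param config A [generator_config()].
#' @param enhancement Positive multiplicative SERS enhancement factor for
#'   this spectrum (hotspot strength).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A `sers_spectrum` tibble with columns `wavenumber`, `intensity`.
#' @export
generate_spectrum <- function(concentration, config = generator_config(),
                              enhancement = 1, seed = NULL) {
  if (concentration < 0) abort("`concentration` must be >= 0")
  if (enhancement <= 0) abort("`enhancement` must be > 0")
  comp <- config_components(config)
  with_seed(seed, {
    intensity <- comp$baseline +
      enhancement * (comp$analyte_per_um * concentration + comp$interferent) +
      rnorm(length(config$wavenumbers), 0, comp$noise_sd)
    new_spectrum(config$wavenumbers, intensity)
  })
}

# Matrix-form map generator: rows = pixels. Fast path shared by the tibble
# interface and the calibration-design generator.
generate_map_matrix <- function(concentration, n_pixels, config,
                                seed = NULL) {
  if (n_pixels < 1) abort("`n_pixels` must be >= 1")
  if (concentration < 0) abort("`concentration` must be >= 0")
  comp <- config_components(config)
  with_seed(seed, {
    s <- config$pixel_heterogeneity
    enh <- if (s > 0) rlnorm(n_pixels, meanlog = -s^2 / 2, sdlog = s)
           else rep(1, n_pixels)
    signal <- comp$analyte_per_um * concentration + comp$interferent
    Y <- outer(enh, signal) +
      matrix(comp$baseline, n_pixels, length(signal), byrow = TRUE)
    if (comp$noise_sd > 0) {
      Y <- Y + matrix(rnorm(length(Y), 0, comp$noise_sd), n_pixels)
    }
    colnames(Y) <- format_wn(config$wavenumbers)
    list(X = Y, enhancement = enh, wavenumbers = config$wavenumbers)
  })
}

#' Simulate a SERS chip map
#'
#' Draws a log-normal enhancement factor per pixel (hotspot heterogeneity)
#' and generates each pixel spectrum with [generate_spectrum()]'s intensity
#' model. Pixels are laid out row-major on a near-square grid.
#'
#' @inheritParams generate_spectrum
#' @param n_pixels Number of map pixels, >= 1.
#' @return A `sers_map` tibble with columns `pixel`, `row`, `col`,
#'   `wavenumber`, `intensity`; the true concentration is kept as the
#'   `"concentration"` attribute.
#' @export
#' @examples
#' m <- generate_map(250, n_pixels = 16, seed = 7)
generate_map <- function(concentration, n_pixels = 100,
                         config = generator_config(), seed = NULL) {
  gm <- generate_map_matrix(concentration, n_pixels, config, seed)
  ncol_grid <- ceiling(sqrt(n_pixels))
  p <- length(gm$wavenumbers)
  out <- tibble::new_tibble(
    list(
      pixel = rep(seq_len(n_pixels), each = p),
      row = rep((seq_len(n_pixels) - 1L) %/% ncol_grid + 1L, each = p),
      col = rep((seq_len(n_pixels) - 1L) %% ncol_grid + 1L, each = p),
      wavenumber = rep(gm$wavenumbers, n_pixels),
      intensity = as.numeric(t(gm$X))
    ),
    class = "sers_map"
  )
  attr(out, "concentration") <- concentration
  out
}

#' Simulate a concentration-graded calibration dataset
#'
#' For each concentration level and replicate, simulates one SERS chip map
#' and reduces it to a representative spectrum by baseline-corrected
#' top-fraction pixel averaging (see [reduce_map_top_fraction()]). The
#' default design is 6 levels x 5 replicate maps on a 696-channel axis,
#' yielding a 30 x 696 spectra matrix.
#'
#' @param levels Concentration levels (uM), non-empty, >= 0.
#' @param replicates Replicate maps per level, >= 1.
#' @param n_pixels Pixels per map.
#' @param config A [generator_config()].
#' @param reduction A [reduction_config()] controlling crop, baseline
#'   correction and top-fraction averaging.
#' @param seed Optional integer seed.
#' @return A tibble with one row per map: `sample_id`, `concentration`,
#'   `replicate`, `peak_height`, and a matrix column `spectra` whose columns
#'   are named by wavenumber.
#' @export
#' @examples
#' cal <- generate_calibration_dataset(c(100, 500), replicates = 2,
#'                                     n_pixels = 9, seed = 1)
#' dim(cal$spectra)
generate_calibration_dataset <- function(levels = c(25, 50, 100, 250, 500, 750),
                                         replicates = 5,
                                         n_pixels = 100,
                                         config = generator_config(),
                                         reduction = reduction_config(),
                                         seed = NULL) {
  if (!length(levels)) abort("`levels` must be non-empty")
  if (any(levels < 0)) abort("`levels` must be >= 0")
  if (replicates < 1) abort("`replicates` must be >= 1")
  with_seed(seed, {
    design <- tidyr::expand_grid(concentration = as.numeric(levels),
                                 replicate = seq_len(replicates))
    red <- purrr::pmap(design, function(concentration, replicate) {
      gm <- generate_map_matrix(concentration, n_pixels, config)
      reduce_matrix_top_fraction(gm$X, gm$wavenumbers, reduction)
    })
    spectra <- do.call(rbind, purrr::map(red, "spectrum"))
    colnames(spectra) <- format_wn(red[[1]]$wavenumbers)
    out <- tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(nrow(design))),
      concentration = design$concentration,
      replicate = design$replicate,
      peak_height = purrr::map_dbl(red, "peak_height")
    )
    out$spectra <- spectra
    out
  })
}

#' Simulate a paired reference/test cohort
#'
#' Draws true concentrations uniformly over the therapeutic window and adds
#' independent measurement error to the reference method (e.g. HPLC) and the
#' test method (e.g. SERS + PLSR), plus a constant test-method bias. Used to
#' exercise the agreement module with known ground truth. Defaults emulate a
#' 27-patient ICU cohort whose paired differences have SD ~30.8 uM and mean
#' ~-14.6 uM (test - reference).
#'
#' @param n_patients Number of paired samples, >= 3.
#' @param concentration_range Range (uM) of the uniform true concentrations.
#' @param reference_error_sd,test_error_sd Measurement error SDs (uM), >= 0.
#' @param test_bias Constant additive bias of the test method (uM),
#'   test - reference convention.
#' @param seed Optional integer seed.
#' @return A tibble with columns `patient`, `truth`, `reference`, `test`
#'   (all concentrations in uM).
#' @export
#' @examples
#' cohort <- generate_paired_cohort(27, seed = 3)
#' bland_altman(cohort, reference, test)
generate_paired_cohort <- function(n_patients = 27,
                                   concentration_range = c(20, 450),
                                   reference_error_sd = 5,
                                   test_error_sd = 30.4,
                                   test_bias = -14.55,
                                   seed = NULL) {
  if (n_patients < 3) abort("`n_patients` must be >= 3 for agreement statistics")
  if (reference_error_sd < 0 || test_error_sd < 0) {
    abort("error SDs must be >= 0")
  }
  with_seed(seed, {
    truth <- runif(n_patients, concentration_range[1], concentration_range[2])
    tibble::tibble(
      patient = sprintf("P%03d", seq_len(n_patients)),
      truth = truth,
      reference = truth + rnorm(n_patients, 0, reference_error_sd),
      test = truth + test_bias + rnorm(n_patients, 0, test_error_sd)
    )
  })
}

#' Write or read a generator configuration as a key-value text file
#'
#' @param config A [generator_config()].
#' @param path File path (YAML key-value text).
#' @return `read_generator_config()` returns a `generator_config`;
#'   `write_generator_config()` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  x$analyte_bands <- as.list(as.data.frame(config$analyte_bands))
  x$interferent_bands <- as.list(as.data.frame(config$interferent_bands))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  generator_config(
    wavenumbers = as.numeric(x$wavenumbers),
    analyte_bands = tibble::as_tibble(x$analyte_bands),
    interferent_bands = tibble::as_tibble(x$interferent_bands),
    cleanup = x$cleanup,
    baseline_coefs = as.numeric(x$baseline_coefs),
    noise_sd = x$noise_sd,
    pixel_heterogeneity = x$pixel_heterogeneity
  )
}
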