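test_that("noise-free spectrum follows the additive band model exactly", {
  cfg <- tiny_config(noise_sd = 0)
  # independent reconstruction of the deterministic model
  wn <- cfg$wavenumbers
  u <- (wn - min(wn)) / diff(range(wn))
  baseline <- 120 - 60 * u + 25 * u^2
  lorentz <- function(center, width) 1 / (1 + (2 * (wn - center) / width)^2)
  interf <- rowSums(mapply(
    function(c, w, a) a * lorentz(c, w),
    cfg$interferent_bands$center, cfg$interferent_bands$width,
    cfg$interferent_bands$response)) * 0.12  # msSPE interferent scale

  blank <- generate_spectrum(0, cfg)
  expect_equal(blank$intensity, baseline + interf, tolerance = 1e-12)

  # analyte contribution is linear through the origin per band
  sp <- generate_spectrum(100, cfg, enhancement = 2)
  analyte <- rowSums(mapply(
    function(c, w, r) r * lorentz(c, w),
    cfg$analyte_bands$center, cfg$analyte_bands$width,
    cfg$analyte_bands$response))
  expect_equal(sp$intensity, baseline + 2 * (100 * analyte + interf),
               tolerance = 1e-12)
})

test_that("the 1559 band dominates any noise-free analyte spectrum", {
  cfg <- tiny_config(noise_sd = 0, baseline_coefs = 0)
  for (conc in c(5, 100, 750)) {
    sp <- generate_spectrum(conc, cfg)
    blank <- generate_spectrum(0, cfg)
    net <- sp$intensity - blank$intensity
    expect_equal(sp$wavenumber[which.max(net)],
                 sp$wavenumber[which.min(abs(sp$wavenumber - 1559))])
  }
})

test_that("replicate mean of the net 1559 height matches its expectation", {
  cfg <- tiny_config(noise_sd = 6, baseline_coefs = 0,
                     interferent_bands = band_spec(640, 16, 0))
  i1559 <- which.min(abs(cfg$wavenumbers - 1559))
  resp <- cfg$analyte_bands$response[cfg$analyte_bands$center == 1559]
  # channel value at the 1559 grid point, not exactly at the band center
  prof <- 1 / (1 + (2 * (cfg$wavenumbers[i1559] - 1559) / 14)^2)
  conc <- 200; enh <- 1.5
  other <- sum(mapply(function(c, w, r) r / (1 + (2 * (cfg$wavenumbers[i1559] - c) / w)^2),
                      cfg$analyte_bands$center, cfg$analyte_bands$width,
                      cfg$analyte_bands$response)) - resp * prof
  expected <- enh * conc * (resp * prof + other)
  set.seed(42)
  heights <- vapply(seq_len(1000), function(i) {
    generate_spectrum(conc, cfg, enhancement = enh)$intensity[i1559]
  }, numeric(1))
  se <- 6 / sqrt(1000)
  expect_lt(abs(mean(heights) - expected), 3 * se)
})

test_that("spectrum generation rejects invalid inputs", {
  expect_error(generate_spectrum(-1, tiny_config()), ">= 0")
  expect_error(generator_config(noise_sd = -1), ">= 0")
  expect_error(generator_config(wavenumbers = c(2, 1, 3)), "increasing")
  expect_error(generate_map(100, n_pixels = 0, tiny_config()), ">= 1")
})

test_that("maps honour shape, degenerate-dispersion and determinism contracts", {
  cfg0 <- clean_config()
  m <- generate_map(100, n_pixels = 9, config = cfg0, seed = 1)
  byp <- split(m$intensity, m$pixel)
  for (p in byp[-1]) expect_identical(p, byp[[1]])

  m100 <- generate_map(50, n_pixels = 100, config = tiny_config(), seed = 2)
  expect_equal(length(unique(m100$pixel)), 100)
  expect_equal(max(m100$row), 10)
  expect_equal(max(m100$col), 10)

  a <- generate_map(50, n_pixels = 20, config = tiny_config(), seed = 7)
  b <- generate_map(50, n_pixels = 20, config = tiny_config(), seed = 7)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("calibration dataset has the designed shape", {
  cal <- generate_calibration_dataset(n_pixels = 4, config = tiny_config(),
                                      seed = 3)
  expect_equal(nrow(cal), 30)  # 6 levels x 5 replicates
  expect_equal(ncol(cal$spectra), 150)
  full <- generate_calibration_dataset(
    levels = c(100, 500), replicates = 1, n_pixels = 4,
    config = generator_config(), seed = 3)
  expect_equal(dim(full$spectra), c(2L, 696L))
  one <- generate_calibration_dataset(100, replicates = 1, n_pixels = 4,
                                      config = tiny_config(), seed = 4)
  expect_equal(nrow(one), 1)
  expect_error(generate_calibration_dataset(numeric(0)), "non-empty")
  expect_error(generate_calibration_dataset(100, replicates = 0), ">= 1")
})

test_that("noise-free, homogeneous maps give exactly proportional heights", {
  cal <- generate_calibration_dataset(
    levels = c(50, 100, 400), replicates = 2, n_pixels = 4,
    config = clean_config(interferent_bands = band_spec(640, 16, 0)),
    seed = 5)
  ratio <- cal$peak_height / cal$concentration
  expect_equal(ratio, rep(ratio[1], nrow(cal)), tolerance = 1e-8)
  # with a real substrate baseline the AsLS estimate leaves a small residual
  cal2 <- generate_calibration_dataset(
    levels = c(50, 100, 400), replicates = 1, n_pixels = 4,
    config = tiny_config(noise_sd = 0, pixel_heterogeneity = 0), seed = 5)
  ratio2 <- cal2$peak_height / cal2$concentration
  expect_equal(ratio2, rep(ratio2[1], nrow(cal2)), tolerance = 0.05)
})

test_that("paired cohorts recover their injected parameters", {
  z <- generate_paired_cohort(10, reference_error_sd = 0, test_error_sd = 0,
                              test_bias = 0, seed = 1)
  expect_equal(z$reference, z$test)

  d <- generate_paired_cohort(27, seed = 2)
  expect_equal(nrow(d), 27)
  expect_true(all(d$truth >= 20 & d$truth <= 450))

  big <- generate_paired_cohort(10000, test_bias = -14.55, seed = 3)
  diffs <- big$test - big$reference
  se <- sd(diffs) / sqrt(nrow(big))
  expect_lt(abs(mean(diffs) + 14.55), 3 * se)
  expect_error(generate_paired_cohort(2), ">= 3")
})

test_that("cleanup methods order interferent height and SNR as expected", {
  mk <- function(method, noise_sd = 0) {
    tiny_config(noise_sd = noise_sd, baseline_coefs = 0, cleanup = method)
  }
  h640 <- vapply(c("PP", "UF3k", "UF10k", "msSPE"), function(m) {
    sp <- generate_spectrum(0, mk(m))
    max(sp$intensity[abs(sp$wavenumber - 640) <= 10])
  }, numeric(1))
  expect_true(all(diff(h640) < 0))  # PP > UF3k > UF10k > msSPE

  snrs <- vapply(c("PP", "UF10k", "msSPE"), function(m) {
    sp <- generate_spectrum(500, tiny_config(cleanup = m), seed = 11)
    snr(sp)
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))  # msSPE > UF10k > PP
})

test_that("generator config round-trips through the key-value file", {
  cfg <- tiny_config(noise_sd = 3.5, cleanup = "UF10k")
  path <- withr::local_tempfile(fileext = ".yml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back$wavenumbers, cfg$wavenumbers)
  expect_equal(back$noise_sd, cfg$noise_sd)
  expect_equal(back$cleanup, cfg$cleanup)
  expect_equal(as.data.frame(back$analyte_bands),
               as.data.frame(cfg$analyte_bands))
  sp1 <- generate_spectrum(100, cfg, seed = 1)
  sp2 <- generate_spectrum(100, back, seed = 1)
  expect_equal(sp1$intensity, sp2$intensity, tolerance = 1e-9)
})
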