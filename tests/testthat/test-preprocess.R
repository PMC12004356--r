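test_that("crop retains exactly the channels a counting oracle predicts", {
  sp <- generate_spectrum(100, tiny_config(), seed = 1)
  expect_equal(crop_spectrum(sp, range(sp$wavenumber)), sp)

  set.seed(7)
  for (i in 1:20) {
    lo <- runif(1, 600, 1500); hi <- lo + runif(1, 50, 300)
    cr <- crop_spectrum(sp, c(lo, hi))
    expect_true(all(cr$wavenumber >= lo & cr$wavenumber <= hi))
    expect_equal(nrow(cr), sum(sp$wavenumber >= lo & sp$wavenumber <= hi))
  }
  expect_error(crop_spectrum(sp, c(3000, 4000)), "overlap")
})

test_that("nested crops compose to the inner crop", {
  sp <- generate_spectrum(100, tiny_config(), seed = 2)
  inner <- c(900, 1200)
  expect_equal(crop_spectrum(crop_spectrum(sp, c(700, 1500)), inner),
               crop_spectrum(sp, inner))
})

test_that("baseline correction flattens a pure smooth background", {
  wn <- seq(600, 1800, length.out = 300)
  u <- (wn - 600) / 1200
  base <- 200 + 80 * u - 120 * u^2
  sp <- tibble::tibble(wavenumber = wn, intensity = base)
  # moderate smoothness: nothing peak-like to preserve in this input
  corr <- baseline_correct(sp, lambda = 1e3)
  expect_lt(max(abs(corr$intensity)), 0.01 * diff(range(base)))
})

test_that("baseline correction recovers injected peak heights within 5%", {
  wn <- seq(600, 1800, length.out = 400)
  peaks <- 300 / (1 + (2 * (wn - 1559) / 14)^2) +
    150 / (1 + (2 * (wn - 890) / 12)^2)
  base <- 100 + 0.15 * (wn - 600)  # known linear baseline
  sp <- tibble::tibble(wavenumber = wn, intensity = base + peaks)
  corr <- baseline_correct(sp, lambda = 1e6)
  h1559 <- max(corr$intensity[abs(wn - 1559) <= 10])
  h890 <- max(corr$intensity[abs(wn - 890) <= 10])
  expect_lt(abs(h1559 - max(peaks[abs(wn - 1559) <= 10])) /
              max(peaks[abs(wn - 1559) <= 10]), 0.05)
  expect_lt(abs(h890 - max(peaks[abs(wn - 890) <= 10])) /
              max(peaks[abs(wn - 890) <= 10]), 0.05)
})

test_that("correction barely moves an already baseline-free spectrum", {
  set.seed(3)
  wn <- seq(600, 1800, length.out = 400)
  noise_sd <- 4
  peak <- 400 / (1 + (2 * (wn - 1559) / 14)^2)
  sp <- tibble::tibble(wavenumber = wn,
                       intensity = peak + rnorm(length(wn), 0, noise_sd))
  corr <- baseline_correct(sp, lambda = 1e6)
  h_before <- max(sp$intensity[abs(wn - 1559) <= 10])
  h_after <- max(corr$intensity[abs(wn - 1559) <= 10])
  expect_lt(abs(h_after - h_before), noise_sd)
})

test_that("top-fraction reduction matches a full-sort oracle", {
  # controlled pixel heights 1..10 with no baseline or noise
  X <- peak_matrix(1:10 * 50)
  wn <- as.numeric(colnames(X))
  map <- tibble::tibble(
    pixel = rep(1:10, each = length(wn)),
    row = rep(1:10, each = length(wn)), col = 1L,
    wavenumber = rep(wn, 10), intensity = as.numeric(t(X)))
  red <- reduce_map_top_fraction(map, reduction_config(fraction = 0.2))
  # top 2 pixels are those with heights 9*50 and 10*50
  expect_equal(attr(red, "n_pixels_used"), 2)
  expect_setequal(attr(red, "top_pixels"), c(9, 10))
  cfg <- reduction_config(fraction = 0.2)
  corrected <- X - sersdose:::als_baseline_matrix(X, cfg$baseline_lambda,
                                                 cfg$baseline_p)
  expect_equal(red$intensity, unname(colMeans(corrected[9:10, ])),
               tolerance = 1e-10)
  expect_equal(attr(red, "peak_height"),
               mean(apply(corrected[9:10, abs(wn - 1559) <= 10], 1, max)),
               tolerance = 1e-10)
})

test_that("reduction degenerates correctly and ignores pixel order", {
  m <- generate_map(200, n_pixels = 9, config = clean_config(), seed = 1)
  red <- reduce_map_top_fraction(m)
  onepix <- dplyr::filter(m, pixel == 1)
  corr <- baseline_correct(
    crop_spectrum(onepix[c("wavenumber", "intensity")], c(600, 1800)))
  expect_equal(red$intensity, corr$intensity, tolerance = 1e-8)

  m2 <- generate_map(200, n_pixels = 20, config = tiny_config(), seed = 2)
  full <- reduce_map_top_fraction(m2, reduction_config(fraction = 1))
  mm <- sersdose:::map_to_matrix(m2)
  corr_all <- mm$X - sersdose:::als_baseline_matrix(mm$X, 1e5, 0.01)
  expect_equal(full$intensity, unname(colMeans(corr_all)), tolerance = 1e-10)

  shuffled <- dplyr::arrange(m2, dplyr::desc(pixel), wavenumber)
  red_a <- reduce_map_top_fraction(m2)
  red_b <- reduce_map_top_fraction(shuffled)
  expect_equal(red_a$intensity, red_b$intensity)
  expect_equal(attr(red_a, "peak_height"), attr(red_b, "peak_height"))
})

test_that("top-fraction mean height dominates the all-pixel mean height", {
  for (s in 1:5) {
    m <- generate_map(300, n_pixels = 30, config = tiny_config(), seed = s)
    top <- attr(reduce_map_top_fraction(m), "peak_height")
    all_mean <- attr(reduce_map_top_fraction(m, reduction_config(fraction = 1)),
                     "peak_height")
    expect_gte(top, all_mean)
  }
})

test_that("SNR scales exactly with signal and recovers injected h/sigma", {
  wn <- seq(600, 1800, length.out = 400)
  # Gaussian line shape: negligible tail inside the 1700-1790 noise region
  peak <- exp(-4 * log(2) * ((wn - 1559) / 14)^2)
  set.seed(9)
  noise <- ifelse(wn >= 1700 & wn <= 1790, rnorm(length(wn), 0, 3), 0)
  s1 <- tibble::tibble(wavenumber = wn, intensity = 100 * peak + noise)
  s2 <- tibble::tibble(wavenumber = wn, intensity = 200 * peak + noise)
  expect_equal(snr(s2, correct_baseline = FALSE),
               2 * snr(s1, correct_baseline = FALSE))

  # Monte Carlo: injected height h and noise sd sigma everywhere
  h <- 300; sigma <- 5
  set.seed(10)
  vals <- vapply(1:500, function(i) {
    sp <- tibble::tibble(wavenumber = wn,
                         intensity = h * peak + rnorm(length(wn), 0, sigma))
    snr(sp, correct_baseline = FALSE)
  }, numeric(1))
  expect_lt(abs(mean(vals) - h / sigma) / (h / sigma), 0.10)

  flat <- tibble::tibble(wavenumber = wn, intensity = rep(5, length(wn)))
  expect_error(snr(flat, noise_region = c(1700, 1790),
                   correct_baseline = FALSE), "undefined")
})

test_that("min-max scaling maps training columns onto [0, 1]", {
  expect_equal(as.numeric(scale_dataset(matrix(c(0, 5, 10)), "minmax")),
               c(0, 0.5, 1))
  set.seed(4)
  X <- matrix(rnorm(200, 50, 20), 20, 10)
  Z <- scale_dataset(X, "minmax")
  expect_equal(unname(apply(Z, 2, min)), rep(0, 10))
  expect_equal(unname(apply(Z, 2, max)), rep(1, 10))
  # idempotent on its own output
  expect_equal(unname(scale_dataset(Z, "minmax")), unname(Z),
               ignore_attr = TRUE)
  # constant column policy
  Xc <- cbind(X, 7)
  expect_true(all(scale_dataset(Xc, "minmax")[, 11] == 0))
  expect_error(fit_scaling(Xc, "autoscale"), "constant")
})

test_that("stored scaling parameters transfer unchanged to new rows", {
  set.seed(5)
  X <- matrix(rnorm(100), 10, 10)
  sc <- fit_scaling(X, "minmax")
  Xnew <- matrix(rnorm(30, 2), 3, 10)
  Znew <- apply_scaling(sc, Xnew)
  mins <- apply(X, 2, min); rng <- apply(X, 2, max) - mins
  expect_equal(Znew, sweep(sweep(Xnew, 2, mins), 2, rng, `/`))
})

test_that("autoscale output has exactly zero mean and unit SD", {
  set.seed(6)
  X <- matrix(rnorm(150, 10, 3), 15, 10)
  Z <- scale_dataset(X, "autoscale")
  expect_equal(unname(colMeans(Z)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 10), tolerance = 1e-12)
})

test_that("row-wise transforms behave as documented", {
  set.seed(8)
  X <- matrix(rnorm(60, 5, 2), 4, 15)
  V <- apply_scaling(fit_scaling(X, "vector_norm"), X)
  expect_equal(unname(sqrt(rowSums(V^2))), rep(1, 4))

  ramp <- matrix(rep(seq(0, 14), 2), 2, 15, byrow = TRUE) * c(2, 5)
  D <- apply_scaling(fit_scaling(ramp, "savgol_derivative"), ramp)
  # first derivative of a linear ramp is its slope, away from the edges
  expect_equal(unname(D[1, 5:11]), rep(2, 7), tolerance = 1e-8)
  expect_equal(unname(D[2, 5:11]), rep(5, 7), tolerance = 1e-8)

  neg <- matrix(c(-3, 0, 1, exp(1) - 1), 2, 2)
  L <- apply_scaling(fit_scaling(neg, "log"), neg)
  expect_equal(as.numeric(L), c(0, 0, log(2), 1))
})
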