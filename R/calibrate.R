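# Univariate calibration, PCA exploration and multivariate figures of merit.

#' Univariate band-intensity calibration
#'
#' Ordinary least-squares line of net band height (maximum intensity inside
#' the band window of each sample's reduced, baseline-corrected spectrum)
#' versus concentration, with the per-level replicate spread used for error
#' bars.
#'
#' @param data Calibration tibble (`concentration` + `spectra` matrix
#'   column).
#' @param band Band center (cm^-1), default 1559.
#' @param window_halfwidth Window half-width (cm^-1).
#' @return A `univariate_cal` object; `tidy()` gives the per-level mean +/-
#'   SD table, `glance()` the slope/intercept/R^2, `autoplot()` the
#'   calibration curve.
#' @export
#' @examples
#' cal <- generate_calibration_dataset(c(50, 250, 750), replicates = 3,
#'                                     n_pixels = 16, seed = 5)
#' uc <- univariate_calibration(cal)
#' glance(uc)
univariate_calibration <- function(data, band = 1559, window_halfwidth = 10) {
  X <- get_spectra_matrix(data)
  wn <- spectra_wavenumbers(data)
  y <- data$concentration
  if (length(unique(y)) < 2) {
    abort("need >= 2 distinct concentration levels for a calibration line")
  }
  win <- window_idx(wn, band, window_halfwidth)
  if (!length(win)) abort("band window contains no channels")
  height <- apply(X[, win, drop = FALSE], 1, max)
  fit <- lm(height ~ y)
  levels_tbl <- tibble::tibble(concentration = y, height = height) |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(n = dplyr::n(), mean_height = mean(.data$height),
                     sd_height = ifelse(dplyr::n() > 1, sd(.data$height), NA_real_),
                     .groups = "drop")
  structure(
    list(fit = fit, band = band,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         heights = tibble::tibble(concentration = y, height = height),
         levels = levels_tbl),
    class = "univariate_cal"
  )
}

#' @export
print.univariate_cal <- function(x, ...) {
  cat(sprintf("<univariate_cal> band %g cm^-1: height = %.4g + %.4g x conc, R^2 = %.4f\n",
              x$band, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
tidy.univariate_cal <- function(x, ...) x$levels

#' @export
glance.univariate_cal <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = nrow(x$heights))
}

#' Principal component analysis of a spectral dataset
#'
#' Mean-centered PCA of the spectra matrix. The suggested component count is
#' chosen from the cross-validated reconstruction RMSE curve: held-out rows
#' are projected onto loadings fitted without them, and the elbow is the
#' component count farthest (perpendicularly) below the chord joining the
#' first and last points of the CV-RMSE curve.
#'
#' @param data Calibration tibble or matrix.
#' @param max_components Maximum number of components to evaluate.
#' @param cv_folds Folds for the reconstruction cross-validation.
#' @return A `sers_pca` object with `scores`, `loadings`,
#'   `explained_variance` (proportions), `cv_rmse` and
#'   `suggested_components`.
#' @export
spectral_pca <- function(data, max_components = 10, cv_folds = 5) {
  X <- get_spectra_matrix(data)
  n <- nrow(X)
  if (n < 2) abort("PCA needs >= 2 rows")
  kmax_allowed <- min(n - 1L, ncol(X))
  if (max_components > kmax_allowed) {
    abort(sprintf("`max_components` must be <= min(rows - 1, columns) = %d",
                  kmax_allowed))
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  K <- min(max_components, ncol(pc$rotation))
  ev <- pc$sdev^2 / sum(pc$sdev^2)

  fold <- integer(n)
  fold[sample.int(n)] <- rep_len(seq_len(min(cv_folds, n)), n)
  cv_sse <- numeric(K)
  for (k in unique(fold)) {
    te <- which(fold == k); tr <- which(fold != k)
    if (length(tr) < 2) next
    pk <- prcomp(X[tr, , drop = FALSE], center = TRUE, scale. = FALSE)
    Xe <- sweep(X[te, , drop = FALSE], 2, pk$center)
    for (a in seq_len(K)) {
      V <- pk$rotation[, seq_len(min(a, ncol(pk$rotation))), drop = FALSE]
      R <- Xe - Xe %*% V %*% t(V)
      cv_sse[a] <- cv_sse[a] + sum(R^2)
    }
  }
  cv_rmse <- sqrt(cv_sse / length(X))
  suggested <- if (K >= 3) {
    # farthest point below the chord from (1, rmse_1) to (K, rmse_K)
    x1 <- 1; y1 <- cv_rmse[1]; x2 <- K; y2 <- cv_rmse[K]
    d <- abs((y2 - y1) * seq_len(K) - (x2 - x1) * cv_rmse + x2 * y1 - y2 * x1)
    which.max(d)
  } else K

  structure(
    list(scores = pc$x[, seq_len(K), drop = FALSE],
         loadings = pc$rotation[, seq_len(K), drop = FALSE],
         explained_variance = ev[seq_len(K)],
         cv_rmse = cv_rmse,
         suggested_components = suggested,
         center = pc$center),
    class = "sers_pca"
  )
}

#' @export
print.sers_pca <- function(x, ...) {
  cat(sprintf("<sers_pca> %d components, PC1 %.1f%%, suggested %d\n",
              ncol(x$scores), 100 * x$explained_variance[1],
              x$suggested_components))
  invisible(x)
}

#' Multivariate figures of merit for a PLSR calibration
#'
#' Computes the standard prediction and sensitivity metrics of a
#' multivariate calibration, in the pseudounivariate convention:
#' \itemize{
#'   \item RMSEP, bias and SEP from test-set residuals
#'     (e = predicted - reference): `RMSEP = sqrt(mean(e^2))`,
#'     `bias = mean(e)`, `SEP = sd(e - bias)` with the n-1 denominator.
#'   \item SEN = 1 / ||b||, the model sensitivity (scaled intensity per uM).
#'   \item Blank noise: blank spectra are pushed through the full
#'     prediction pipeline; the SD of the resulting pseudo-concentrations
#'     is gamma^-1, the inverse analytical sensitivity (uM). gamma is its
#'     reciprocal; the equivalent instrumental noise is
#'     sigma_x = gamma^-1 x SEN.
#'   \item LoD = 3.3 x gamma^-1, LoQ = 10 x gamma^-1.
#' }
#'
#' @param model A fitted `sers_plsr`.
#' @param test_data Test tibble/matrix (>= 3 samples).
#' @param test_y Reference concentrations (uM) when not carried by
#'   `test_data`.
#' @param blank_data Blank (0 uM) replicate spectra, >= 5 rows.
#' @return A `figures_of_merit` object (also a one-row tibble via
#'   `tidy()`).
#' @export
figures_of_merit <- function(model, test_data, test_y = NULL, blank_data) {
  if (is.null(test_y)) {
    if (!is.data.frame(test_data) || !"concentration" %in% names(test_data)) {
      abort("supply `test_y` or test data with a `concentration` column")
    }
    test_y <- test_data$concentration
  }
  n <- length(test_y)
  if (n < 3) abort("figures of merit need >= 3 test samples")
  nb <- nrow(get_spectra_matrix(blank_data))
  if (nb < 5) abort("need >= 5 blank replicate spectra for noise estimation")

  pred <- predict(model, test_data)$.pred
  e <- pred - test_y
  rmsep <- rmse(e)
  bias <- mean(e)
  sep <- sd(e)  # sd() uses the n-1 denominator on (e - mean(e))

  b <- model$coefficients[, model$lv]
  sen <- 1 / sqrt(sum(b^2))
  blank_pred <- suppressWarnings(predict(model, blank_data)$.pred)
  gamma_inv <- sd(blank_pred)
  if (gamma_inv == 0) abort("blank replicates have zero noise; LoD undefined")
  gamma <- 1 / gamma_inv
  sigma_x <- gamma_inv * sen

  sst <- sum((test_y - mean(test_y))^2)
  r2_pred <- 1 - sum(e^2) / sst

  structure(
    list(rmsep = rmsep, bias = bias, sep = sep, sen = sen,
         gamma = gamma, gamma_inverse = gamma_inv, sigma_x = sigma_x,
         lod = 3.3 * gamma_inv, loq = 10 * gamma_inv,
         r2_cal = model$r2_cal[model$lv], r2_cv = model$r2_cv[model$lv],
         r2_pred = r2_pred, n_test = n, n_blanks = nb,
         predictions = tibble::tibble(reference = test_y, predicted = pred)),
    class = "figures_of_merit"
  )
}

#' @export
print.figures_of_merit <- function(x, ...) {
  cat("<figures_of_merit>\n")
  print(as.data.frame(tidy(x)), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.figures_of_merit <- function(x, ...) {
  tibble::tibble(
    rmsep = x$rmsep, bias = x$bias, sep = x$sep, sen = x$sen,
    gamma = x$gamma, gamma_inverse = x$gamma_inverse,
    lod = x$lod, loq = x$loq,
    r2_cal = x$r2_cal, r2_cv = x$r2_cv, r2_pred = x$r2_pred
  )
}
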