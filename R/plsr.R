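# Partial least squares regression (PLS1, NIPALS) with venetian-blinds
# cross-validation and parsimonious latent-variable selection.

# NIPALS for a single response on a pre-scaled matrix. Centering of X and y
# happens here; returns per-component weights/loadings and the regression
# vector for every component count up to ncomp.
plsr_nipals <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pvec <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - t * qa
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa; Tm[, a] <- t
    a_used <- a
  }
  if (a_used == 0L) abort("no PLS component could be extracted (degenerate y?)")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  # regression vectors for 1..a_used components
  coefs <- matrix(0, p, a_used)
  for (a in seq_len(a_used)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    R <- Wa %*% solve(crossprod(Pa, Wa))
    coefs[, a] <- R %*% q[seq_len(a)]
  }
  list(W = W, P = P, q = q, scores = Tm, coefs = coefs,
       x_mean = x_mean, y_mean = y_mean, ncomp = a_used)
}

# Venetian-blinds fold assignment. With a replicate column, fold r holds
# replicate r of every level (each fold spans the concentration range);
# otherwise samples are interleaved along increasing response.
venetian_folds <- function(data, y, n_folds) {
  n <- length(y)
  if (is.data.frame(data) && all(c("replicate") %in% names(data)) &&
      length(unique(data$replicate)) >= n_folds) {
    fold <- ((data$replicate - 1L) %% n_folds) + 1L
  } else {
    fold <- integer(n)
    fold[order(y)] <- rep_len(seq_len(n_folds), n)
  }
  fold
}

#' Fit a PLSR calibration model
#'
#' Single-response partial least squares regression (NIPALS) of
#' concentration on the scaled spectra matrix. The spectra are transformed
#' with [fit_scaling()] (default: min-max, the best-performing dataset
#' scaling in the preprocessing comparison), then mean-centered inside the
#' PLS decomposition. Cross-validation uses venetian blinds; the latent
#' variable (LV) count is the smallest whose RMSECV is within one standard
#' error of the global minimum (parsimony rule), unless `lv` is forced.
#'
#' @param data Calibration tibble with a `concentration` column and a
#'   `spectra` matrix column (see [generate_calibration_dataset()]), or a
#'   plain matrix plus `y`.
#' @param y Concentrations (uM) when `data` is a matrix.
#' @param scaling Scaling method name, see [fit_scaling()].
#' @param max_lv Maximum LV count to consider.
#' @param cv_folds Number of venetian-blinds folds (default 5).
#' @param lv Optional forced LV count (skips the selection rule, CV still
#'   runs for diagnostics).
#' @return A `sers_plsr` object with the fitted regression vector,
#'   per-LV RMSEC/RMSECV diagnostics and the stored scaler. Methods:
#'   [predict.sers_plsr()], [tidy.sers_plsr()], [glance.sers_plsr()],
#'   [autoplot.sers_plsr()].
#' @export
#' @examples
#' cal <- generate_calibration_dataset(c(50, 250, 750), replicates = 5,
#'                                     n_pixels = 16, seed = 11)
#' fit <- plsr_fit(cal, max_lv = 5)
#' glance(fit)
plsr_fit <- function(data, y = NULL, scaling = "minmax", max_lv = 10,
                     cv_folds = 5, lv = NULL) {
  X <- get_spectra_matrix(data)
  if (is.null(y)) {
    if (!is.data.frame(data) || !"concentration" %in% names(data)) {
      abort("supply `y` or a data frame with a `concentration` column")
    }
    y <- data$concentration
  }
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 4) abort("PLSR needs at least 4 samples")
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  if (max_lv < 1) abort("`max_lv` must be >= 1")
  if (sd(y) == 0) abort("`y` is constant; calibration is undefined")
  max_lv <- min(max_lv, n - 1L, ncol(X))

  scaler <- fit_scaling(X, scaling)
  Xs <- apply_scaling(scaler, X)
  fit <- plsr_nipals(Xs, y, max_lv)
  A <- fit$ncomp

  sst <- sum((y - mean(y))^2)
  rmsec <- r2_cal <- numeric(A)
  Xc <- sweep(Xs, 2, fit$x_mean)
  for (a in seq_len(A)) {
    res <- y - (fit$y_mean + drop(Xc %*% fit$coefs[, a]))
    rmsec[a] <- rmse(res)
    r2_cal[a] <- 1 - sum(res^2) / sst
  }

  # cross-validation: scaler refit inside each training fold
  fold <- venetian_folds(data, y, min(cv_folds, n))
  n_folds <- length(unique(fold))
  cv_pred <- matrix(NA_real_, n, A)
  fold_rmse <- matrix(NA_real_, n_folds, A)
  for (k in seq_len(n_folds)) {
    te <- which(fold == k); tr <- which(fold != k)
    sck <- fit_scaling(X[tr, , drop = FALSE], scaling)
    Xtr <- apply_scaling(sck, X[tr, , drop = FALSE])
    Xte <- apply_scaling(sck, X[te, , drop = FALSE])
    fk <- plsr_nipals(Xtr, y[tr], max_lv)
    Xte_c <- sweep(Xte, 2, fk$x_mean)
    for (a in seq_len(A)) {
      aa <- min(a, fk$ncomp)
      cv_pred[te, a] <- fk$y_mean + drop(Xte_c %*% fk$coefs[, aa])
      fold_rmse[k, a] <- rmse(y[te] - cv_pred[te, a])
    }
  }
  rmsecv <- sqrt(colMeans((cv_pred - y)^2))
  r2_cv <- 1 - colSums((cv_pred - y)^2) / sst
  se_cv <- apply(fold_rmse, 2, sd) / sqrt(n_folds)

  if (is.null(lv)) {
    k_min <- which.min(rmsecv)
    lv <- which(rmsecv <= rmsecv[k_min] + se_cv[k_min])[1]
  } else {
    if (lv < 1 || lv > A) abort(sprintf("`lv` must be in 1..%d", A))
  }

  structure(
    list(scaler = scaler, x_mean = fit$x_mean, y_mean = fit$y_mean,
         weights = fit$W, loadings = fit$P, q = fit$q, scores = fit$scores,
         coefficients = fit$coefs, lv = lv, max_lv = A,
         rmsec = rmsec, rmsecv = rmsecv, rmsecv_se = se_cv,
         r2_cal = r2_cal, r2_cv = r2_cv,
         cv_predictions = cv_pred, folds = fold,
         y = y, fitted = fit$y_mean + drop(Xc %*% fit$coefs[, lv]),
         wavenumbers = suppressWarnings(as.numeric(colnames(X))),
         scaling = scaling, n = n),
    class = "sers_plsr"
  )
}

#' Predict concentrations from a PLSR model
#'
#' Applies the stored training scaler unchanged, centers with the training
#' means and projects through the regression vector. Negative predictions
#' are reported as-is and flagged, never truncated.
#'
#' @param object A `sers_plsr` model.
#' @param new_data Matrix or tibble with a `spectra` matrix column; columns
#'   must match the training channels (a consistent permutation of named
#'   columns is accepted and reordered).
#' @param lv LV count to use (default: the model's selected count).
#' @param ... Unused.
#' @return A tibble with columns `.pred` (uM) and `negative` (logical
#'   flag).
#' @export
predict.sers_plsr <- function(object, new_data, lv = object$lv, ...) {
  X <- get_spectra_matrix(new_data)
  train_names <- names(object$x_mean)
  if (!is.null(colnames(X)) && !is.null(train_names)) {
    if (!setequal(colnames(X), train_names)) {
      abort("new data channels do not match the training axis")
    }
    X <- X[, train_names, drop = FALSE]
  } else if (ncol(X) != length(object$x_mean)) {
    abort("new data channel count does not match the training axis")
  }
  if (lv < 1 || lv > object$max_lv) {
    abort(sprintf("`lv` must be in 1..%d", object$max_lv))
  }
  Xs <- apply_scaling(object$scaler, X)
  pred <- object$y_mean +
    drop(sweep(Xs, 2, object$x_mean) %*% object$coefficients[, lv])
  if (any(pred < 0)) {
    warn(sprintf("%d prediction(s) below 0 uM (reported as-is)",
                 sum(pred < 0)))
  }
  tibble::tibble(.pred = pred, negative = pred < 0)
}

#' @export
print.sers_plsr <- function(x, ...) {
  cat("<sers_plsr> PLSR calibration\n")
  cat(sprintf("  n = %d samples, %d channels, scaling = %s\n",
              x$n, length(x$x_mean), x$scaling))
  cat(sprintf("  selected LV = %d (of %d), RMSEC = %.3g, RMSECV = %.3g uM\n",
              x$lv, x$max_lv, x$rmsec[x$lv], x$rmsecv[x$lv]))
  invisible(x)
}

#' Tidy a PLSR model
#'
#' @param x A `sers_plsr` model.
#' @param ... Unused.
#' @return One row per channel: `wavenumber`, `coefficient` (regression
#'   vector at the selected LV count, concentration per scaled intensity
#'   unit).
#' @export
tidy.sers_plsr <- function(x, ...) {
  tibble::tibble(wavenumber = x$wavenumbers,
                 coefficient = x$coefficients[, x$lv])
}

#' One-row summary of a PLSR model
#'
#' @inheritParams tidy.sers_plsr
#' @return A tibble with `lv`, `rmsec`, `rmsecv`, `r2_cal`, `r2_cv`, `n`.
#' @export
glance.sers_plsr <- function(x, ...) {
  tibble::tibble(lv = x$lv, rmsec = x$rmsec[x$lv], rmsecv = x$rmsecv[x$lv],
                 r2_cal = x$r2_cal[x$lv], r2_cv = x$r2_cv[x$lv], n = x$n)
}
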