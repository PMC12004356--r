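# Model-robustness procedures: leave-group-out resampling with fold plans of
# 2-3 samples, permutation testing of the cross-validated statistic, and
# overfitting diagnostics across latent-variable counts.

#' Random fold plan with group sizes of 2 or 3
#'
#' Partitions `n_samples` indices into `n_folds` disjoint held-out groups of
#' size 2 or 3 covering every sample exactly once (the 27-sample / 12-model
#' leave-group-out design gives nine pairs and three triples). The split of
#' sizes is forced by arithmetic: with g3 = n - 2k triples and g2 = 3k - n
#' pairs, both must be non-negative.
#'
#' @param n_samples Total sample count.
#' @param n_folds Number of held-out groups.
#' @param seed Optional integer seed.
#' @return A `fold_plan` tibble with columns `sample` (index) and `fold`.
#' @export
#' @examples
#' plan <- make_fold_plan(27, 12, seed = 1)
#' table(table(plan$fold))
make_fold_plan <- function(n_samples, n_folds, seed = NULL) {
  g3 <- n_samples - 2L * n_folds
  g2 <- 3L * n_folds - n_samples
  if (g3 < 0 || g2 < 0) {
    abort(sprintf(
      "infeasible plan: %d samples cannot split into %d groups of size 2-3",
      n_samples, n_folds))
  }
  with_seed(seed, {
    sizes <- sample(c(rep(2L, g2), rep(3L, g3)))
    idx <- sample.int(n_samples)
    fold <- rep.int(seq_len(n_folds), times = sizes)
    out <- tibble::tibble(sample = idx, fold = fold)
    out <- dplyr::arrange(out, .data$sample)
    class(out) <- c("fold_plan", class(out))
    out
  })
}

check_fold_plan <- function(plan, n) {
  if (!all(c("sample", "fold") %in% names(plan))) {
    abort("fold plan needs `sample` and `fold` columns")
  }
  if (!setequal(plan$sample, seq_len(n)) || anyDuplicated(plan$sample)) {
    abort("fold plan must cover every sample index exactly once")
  }
  invisible(plan)
}

#' Iterative leave-group-out PLSR
#'
#' For each fold of the plan, fits a PLSR model on all remaining samples
#' (the latent-variable count is re-selected inside every fold by the inner
#' cross-validation) and predicts the held-out group, so every sample is
#' predicted exactly once by a model that never saw it. Pooled metrics are
#' computed on the aggregated out-of-fold predictions.
#'
#' @param data Calibration tibble or matrix (with `y`).
#' @param fold_plan A [make_fold_plan()] result (or any tibble with
#'   `sample` and `fold` columns covering the data).
#' @param y Concentrations when `data` is a matrix.
#' @param scaling,max_lv,cv_folds Passed to [plsr_fit()] for every fold.
#' @return A `lgo_result` with `predictions` (sample, fold, reference,
#'   predicted, lv), pooled `rmsep` and `r2_pred`, and per-fold LV counts.
#' @export
leave_group_out_plsr <- function(data, fold_plan, y = NULL,
                                 scaling = "minmax", max_lv = 10,
                                 cv_folds = 5) {
  X <- get_spectra_matrix(data)
  if (is.null(y)) y <- data$concentration
  n <- nrow(X)
  if (any(fold_plan$sample < 1 | fold_plan$sample > n)) {
    abort("fold plan index out of range")
  }
  check_fold_plan(fold_plan, n)
  folds <- split(fold_plan$sample, fold_plan$fold)
  rows <- purrr::imap(folds, function(te, fid) {
    tr <- setdiff(seq_len(n), te)
    dtr <- if (is.data.frame(data)) data[tr, , drop = FALSE] else X[tr, , drop = FALSE]
    fit <- plsr_fit(dtr, y = y[tr], scaling = scaling, max_lv = max_lv,
                    cv_folds = cv_folds)
    pred <- predict(fit, X[te, , drop = FALSE])$.pred
    tibble::tibble(sample = te, fold = as.integer(fid),
                   reference = y[te], predicted = pred, lv = fit$lv)
  })
  preds <- dplyr::arrange(dplyr::bind_rows(rows), .data$sample)
  e <- preds$predicted - preds$reference
  structure(
    list(predictions = preds,
         rmsep = rmse(e),
         bias = mean(e),
         r2_pred = 1 - sum(e^2) / sum((y - mean(y))^2),
         lv_per_fold = purrr::map_int(rows, ~ .x$lv[1]),
         n_folds = length(folds)),
    class = "lgo_result"
  )
}

#' @export
print.lgo_result <- function(x, ...) {
  cat(sprintf("<lgo_result> %d folds: pooled RMSEP = %.3g uM, R^2_pred = %.3f\n",
              x$n_folds, x$rmsep, x$r2_pred))
  invisible(x)
}

#' @export
glance.lgo_result <- function(x, ...) {
  tibble::tibble(n_folds = x$n_folds, rmsep = x$rmsep, bias = x$bias,
                 r2_pred = x$r2_pred)
}

#' Permutation test of a PLSR calibration
#'
#' Shuffles the concentrations `B` times and re-runs the full modelling
#' pipeline (scaling, LV selection, venetian-blinds cross-validation) on
#' each shuffle, building the null distribution of the cross-validated
#' statistic. The empirical p-value counts the observed statistic in its
#' own null: `p = (1 + #{null >= observed}) / (B + 1)` for R^2_cv
#' (reversed for RMSECV), so `p >= 1/(B+1)` always.
#'
#' @param data Calibration tibble or matrix (with `y`).
#' @param y Concentrations when `data` is a matrix.
#' @param B Number of permutations, >= 99.
#' @param statistic `"r2_cv"` (default) or `"rmsecv"`.
#' @param seed Optional integer seed.
#' @param scaling,max_lv,cv_folds Passed to [plsr_fit()].
#' @return A `permutation_result` with `observed`, `null` (length B) and
#'   `p_value`.
#' @export
permutation_test <- function(data, y = NULL, B = 999,
                             statistic = c("r2_cv", "rmsecv"), seed = NULL,
                             scaling = "minmax", max_lv = 10, cv_folds = 5) {
  statistic <- match.arg(statistic)
  if (B < 99) abort("`B` must be >= 99 for a meaningful null distribution")
  X <- get_spectra_matrix(data)
  if (is.null(y)) y <- data$concentration

  stat_of <- function(yy) {
    fit <- plsr_fit(X, y = yy, scaling = scaling, max_lv = max_lv,
                    cv_folds = cv_folds)
    if (statistic == "r2_cv") fit$r2_cv[fit$lv] else fit$rmsecv[fit$lv]
  }
  observed <- stat_of(y)
  null <- with_seed(seed, {
    vapply(seq_len(B), function(b) stat_of(sample(y)), numeric(1))
  })
  extreme <- if (statistic == "r2_cv") sum(null >= observed)
             else sum(null <= observed)
  structure(
    list(observed = observed, null = null,
         p_value = (1 + extreme) / (B + 1),
         statistic = statistic, B = B),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s = %.4f, B = %d, p = %.4g\n",
              x$statistic, x$observed, x$B, x$p_value))
  invisible(x)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, observed = x$observed, B = x$B,
                 p_value = x$p_value)
}

#' Overfitting diagnostics across LV counts
#'
#' Tabulates RMSEC, RMSECV (and RMSEP / R^2_pred when a test set is given)
#' for every latent-variable count of a fitted model, and flags counts
#' where the cross-validated error rises while the calibration error keeps
#' falling -- the signature of overfitting.
#'
#' @param model A fitted `sers_plsr`.
#' @param test_data,test_y Optional held-out set for per-LV RMSEP.
#' @return A tibble with one row per LV count and a logical
#'   `overfit_flag`.
#' @export
overfitting_report <- function(model, test_data = NULL, test_y = NULL) {
  A <- model$max_lv
  out <- tibble::tibble(
    lv = seq_len(A),
    rmsec = model$rmsec,
    rmsecv = model$rmsecv,
    r2_cal = model$r2_cal,
    r2_cv = model$r2_cv
  )
  if (!is.null(test_data)) {
    if (is.null(test_y)) test_y <- test_data$concentration
    sst <- sum((test_y - mean(test_y))^2)
    per_lv <- purrr::map(seq_len(A), function(a) {
      e <- suppressWarnings(predict(model, test_data, lv = a)$.pred) - test_y
      c(rmsep = rmse(e), r2_pred = 1 - sum(e^2) / sst)
    })
    out$rmsep <- purrr::map_dbl(per_lv, "rmsep")
    out$r2_pred <- purrr::map_dbl(per_lv, "r2_pred")
  }
  out$selected <- out$lv == model$lv
  d_rmsec <- c(NA, diff(out$rmsec))
  d_rmsecv <- c(NA, diff(out$rmsecv))
  out$overfit_flag <- !is.na(d_rmsec) & d_rmsec <= 0 & d_rmsecv > 0
  out
}
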