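# Dataset-level scaling / transformation methods compared for PLSR
# preprocessing. Column-wise methods store their training parameters so new
# rows are transformed with the *training* statistics; row-wise methods are
# parameter-free.

scaling_methods <- c("minmax", "autoscale", "meancenter", "vector_norm",
                     "savgol_derivative", "log", "none")

#' Fit a dataset scaling transform
#'
#' @param X Numeric matrix (rows = samples, columns = channels), non-empty.
#' @param method One of `"minmax"` (each column to `[0,1]` on the training
#'   set; the min-max winner of the preprocessing comparison),
#'   `"autoscale"` (column z-score), `"meancenter"`, `"vector_norm"`
#'   (row-wise unit L2 norm), `"savgol_derivative"` (row-wise
#'   Savitzky-Golay first derivative), `"log"` (`log(1 + x)` after clipping
#'   negatives to 0), or `"none"`.
#' @param sg_order,sg_window Savitzky-Golay polynomial order and window
#'   length (channels), used by `"savgol_derivative"`.
#' @param deriv Derivative order for `"savgol_derivative"`.
#' @return A `sers_scaler` object; apply it with [apply_scaling()].
#' @details A constant column is mapped to 0 by `"minmax"`; `"autoscale"`
#'   raises an error on constant columns rather than silently patching a
#'   zero SD.
#' @export
#' @examples
#' X <- matrix(c(0, 5, 10, 1, 2, 3), ncol = 2)
#' sc <- fit_scaling(X, "minmax")
#' apply_scaling(sc, X)
fit_scaling <- function(X, method = scaling_methods, sg_order = 2,
                        sg_window = 9, deriv = 1) {
  method <- match.arg(method)
  if (!is.matrix(X) || !nrow(X) || !ncol(X)) {
    abort("`X` must be a non-empty numeric matrix")
  }
  params <- list()
  if (method == "minmax") {
    params$min <- apply(X, 2, min)
    params$max <- apply(X, 2, max)
  } else if (method == "autoscale") {
    params$mean <- colMeans(X)
    params$sd <- apply(X, 2, sd)
    if (any(params$sd == 0)) {
      abort("autoscale is undefined for constant columns (zero SD)")
    }
  } else if (method == "meancenter") {
    params$mean <- colMeans(X)
  } else if (method == "savgol_derivative") {
    if (sg_window > ncol(X)) abort("Savitzky-Golay window exceeds channel count")
    params$sg_order <- sg_order
    params$sg_window <- sg_window
    params$deriv <- deriv
  }
  structure(list(method = method, params = params, n_channels = ncol(X)),
            class = "sers_scaler")
}

#' Apply a fitted scaling transform
#'
#' @param scaler A [fit_scaling()] result.
#' @param X Matrix with the same channel count as the training set.
#' @return The transformed matrix.
#' @export
apply_scaling <- function(scaler, X) {
  if (!inherits(scaler, "sers_scaler")) abort("`scaler` must be a sers_scaler")
  if (ncol(X) != scaler$n_channels) {
    abort(sprintf("channel count mismatch: scaler expects %d, got %d",
                  scaler$n_channels, ncol(X)))
  }
  p <- scaler$params
  out <- switch(
    scaler$method,
    none = X,
    minmax = {
      rng <- p$max - p$min
      Z <- sweep(X, 2, p$min)
      Z <- sweep(Z, 2, ifelse(rng == 0, 1, rng), `/`)
      Z[, rng == 0] <- 0  # constant training column -> 0 by policy
      Z
    },
    autoscale = sweep(sweep(X, 2, p$mean), 2, p$sd, `/`),
    meancenter = sweep(X, 2, p$mean),
    vector_norm = {
      nrm <- sqrt(rowSums(X^2))
      if (any(nrm == 0)) abort("vector_norm undefined for an all-zero row")
      X / nrm
    },
    savgol_derivative = t(apply(X, 1, function(r) {
      signal::sgolayfilt(r, p = p$sg_order, n = p$sg_window, m = p$deriv)
    })),
    log = log1p(pmax(X, 0))
  )
  dimnames(out) <- dimnames(X)
  out
}

#' Scale a dataset in one step
#'
#' Convenience wrapper: fits the transform on `X` and returns the scaled
#' matrix with the fitted `sers_scaler` attached as attribute `"scaler"`
#' (use it with [apply_scaling()] on prediction rows).
#'
#' @inheritParams fit_scaling
#' @return The scaled matrix with a `"scaler"` attribute.
#' @export
scale_dataset <- function(X, method = scaling_methods, ...) {
  sc <- fit_scaling(X, method, ...)
  out <- apply_scaling(sc, X)
  attr(out, "scaler") <- sc
  out
}
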