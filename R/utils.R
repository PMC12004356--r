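# Internal helpers shared across modules.

# Matrix of spectra (rows = pixels/samples) from a long map tibble.
map_to_matrix <- function(map) {
  wn <- sort(unique(map$wavenumber))
  pix <- unique(map$pixel)
  X <- matrix(NA_real_, nrow = length(pix), ncol = length(wn),
              dimnames = list(NULL, format_wn(wn)))
  m <- match(map$pixel, pix)
  j <- match(map$wavenumber, wn)
  X[cbind(m, j)] <- map$intensity
  list(X = X, wavenumbers = wn, pixels = pix)
}

format_wn <- function(wn) trimws(formatC(wn, format = "fg", digits = 10))

new_spectrum <- function(wavenumber, intensity) {
  tibble::new_tibble(
    list(wavenumber = as.numeric(wavenumber), intensity = as.numeric(intensity)),
    class = "sers_spectrum"
  )
}

is_spectrum_like <- function(x) {
  is.data.frame(x) && all(c("wavenumber", "intensity") %in% names(x))
}

check_axis <- function(wavenumber) {
  if (any(!is.finite(wavenumber))) abort("wavenumber axis must be finite")
  if (is.unsorted(wavenumber, strictly = TRUE)) {
    abort("wavenumber axis must be strictly increasing")
  }
  invisible(wavenumber)
}

# Channel indices falling inside a closed wavenumber window.
window_idx <- function(wavenumber, center, halfwidth) {
  which(wavenumber >= center - halfwidth & wavenumber <= center + halfwidth)
}

rmse <- function(e) sqrt(mean(e^2))

# Spectra matrix from a calibration tibble (matrix column `spectra`)
# or a plain matrix.
get_spectra_matrix <- function(data) {
  if (is.matrix(data)) return(data)
  if (is.data.frame(data) && "spectra" %in% names(data)) {
    X <- data$spectra
    if (!is.matrix(X)) abort("`spectra` column must be a matrix column")
    return(X)
  }
  abort("expected a matrix or a data frame with a `spectra` matrix column")
}

spectra_wavenumbers <- function(data) {
  X <- get_spectra_matrix(data)
  wn <- suppressWarnings(as.numeric(colnames(X)))
  if (anyNA(wn)) abort("spectra matrix must carry numeric wavenumber colnames")
  wn
}
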