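#' Hyperspectral cube container
#'
#' A light S3 wrapper around an `H x W x B` numeric array with its wavelength
#' grid and a domain flag distinguishing raw digital numbers (`"dn"`) from
#' percent reflectance (`"reflectance"`). Array axis order is (row, col,
#' band) regardless of the on-disk interleave; indices are 1-based as usual
#' in R.
#'
#' @param data numeric `H x W x B` array.
#' @param wavelengths a [make_wavelength_grid()] result or numeric vector of
#'   ascending band centers; length must equal `dim(data)[3]`.
#' @param domain `"dn"` or `"reflectance"`.
#' @return An object of class `hsi_cube` with fields `data`, `wavelengths`,
#'   `domain`.
#' @export
hsi_cube <- function(data, wavelengths, domain = c("dn", "reflectance")) {
  domain <- match.arg(domain)
  if (length(dim(data)) != 3L) stop_invalid("data must be an H x W x B array")
  wavelengths <- as_wavelength_grid(wavelengths)
  if (dim(data)[3] != length(wavelengths$values))
    stop_invalid("band count ", dim(data)[3], " != wavelength count ",
                 length(wavelengths$values))
  if (domain == "reflectance" && !all(is.finite(data)))
    stop_invalid("reflectance cube contains non-finite values")
  structure(list(data = data, wavelengths = wavelengths, domain = domain),
            class = "hsi_cube")
}

#' @export
dim.hsi_cube <- function(x) dim(x$data)

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hsi_cube [%s]: %d x %d x %d, %.0f-%.0f nm\n", x$domain,
              d[1], d[2], d[3], x$wavelengths$values[1],
              x$wavelengths$values[d[3]]))
  invisible(x)
}

#' Integer label mask
#'
#' `H x W` integer raster: 0 = unlabeled/background, 1..K = target classes.
#'
#' @param values integer matrix.
#' @param n_classes number of target classes K (default 13).
#' @param class_names optional character vector of length K.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(values, n_classes = 13L, class_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (any(values < 0L) || any(values > n_classes))
    stop_format("mask labels must lie in 0..", n_classes)
  if (!is.null(class_names) && length(class_names) != n_classes)
    stop_invalid("class_names must have length n_classes")
  structure(list(values = values, n_classes = as.integer(n_classes),
                 class_names = class_names),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask: %d x %d, %d classes, %d labeled pixels\n",
              nrow(x$values), ncol(x$values), x$n_classes,
              sum(x$values > 0L)))
  invisible(x)
}

#' Convert raw digital numbers to percent reflectance
#'
#' Applies the standard white/dark reference calibration per element:
#' `reflectance = (raw - dark) / (white - dark) * 100`. Elements whose
#' `white - dark` denominator falls below `eps` are guarded to 0 %
#' reflectance and counted, so the output is always finite; reflectance is
#' deliberately not clipped to \[0, 100\] (specular pixels may exceed 100 %).
#'
#' @param raw an `hsi_cube` in the `"dn"` domain.
#' @param white,dark DN reference arrays with the same dimensions as `raw`
#'   (element-wise `white >= dark` after validation).
#' @param eps denominator guard threshold.
#' @return A list with `cube` (the reflectance-domain `hsi_cube`) and
#'   `n_guarded` (count of guarded elements).
#' @export
calibrate_reflectance <- function(raw, white, dark, eps = 1e-6) {
  stopifnot(inherits(raw, "hsi_cube"))
  if (raw$domain != "dn") stop_invalid("raw cube must be in the DN domain")
  if (!identical(dim(raw$data), dim(white)) ||
      !identical(dim(raw$data), dim(dark)))
    stop_invalid("reference frame shapes must match the raw cube")
  denom <- white - dark
  guarded <- denom < eps
  n_guarded <- sum(guarded)
  denom[guarded] <- 1
  refl <- (raw$data - dark) / denom * 100
  refl[guarded] <- 0
  list(cube = hsi_cube(refl, raw$wavelengths, domain = "reflectance"),
       n_guarded = n_guarded)
}

#' Subset a cube to a closed wavelength interval
#'
#' Keeps bands with `lo_nm <= lambda <= hi_nm` inclusive; applying the same
#' range twice is a no-op. The package's working range is 1000-1700 nm.
#'
#' @param cube an `hsi_cube`.
#' @param lo_nm,hi_nm interval bounds in nanometres.
#' @return The subset `hsi_cube`.
#' @export
subset_bands <- function(cube, lo_nm, hi_nm) {
  stopifnot(inherits(cube, "hsi_cube"))
  lam <- cube$wavelengths$values
  keep <- which(lam >= lo_nm & lam <= hi_nm)
  if (length(keep) == 0L)
    stop_invalid("no bands fall inside [", lo_nm, ", ", hi_nm, "] nm")
  if (length(keep) < 2L)
    stop_invalid("band subset must retain >= 2 bands")
  hsi_cube(cube$data[, , keep, drop = FALSE], lam[keep], domain = cube$domain)
}
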