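#' Construct a uniform wavelength grid
#'
#' Band centers are spaced uniformly between `lo_nm` and `hi_nm` inclusive,
#' mirroring the sampling of a line-scan NIR spectrograph after band
#' subsetting. The default working grid of the package is 171 bands over
#' 1000--1700 nm, whose mean adjacent spacing is 700/170 = 4.1176 nm
#' (reported as 4.1 nm at instrument precision).
#'
#' @param n_bands number of band centers (>= 2).
#' @param lo_nm first band center in nanometres.
#' @param hi_nm last band center in nanometres; must exceed `lo_nm`.
#' @return An object of class `wavelength_grid`: a list with `values`
#'   (ascending band centers, nm) and `spacing` (mean adjacent spacing, nm).
#' @examples
#' g <- make_wavelength_grid(171, 1000, 1700)
#' round(g$spacing, 1)  # 4.1
#' @export
make_wavelength_grid <- function(n_bands, lo_nm, hi_nm) {
  if (!is.numeric(n_bands) || length(n_bands) != 1L || n_bands < 2)
    stop_invalid("n_bands must be a single integer >= 2")
  if (lo_nm >= hi_nm) stop_invalid("lo_nm must be < hi_nm")
  n_bands <- as.integer(n_bands)
  values <- seq(lo_nm, hi_nm, length.out = n_bands)
  structure(list(values = values,
                 spacing = (hi_nm - lo_nm) / (n_bands - 1)),
            class = "wavelength_grid")
}

#' @export
length.wavelength_grid <- function(x) length(x$values)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("wavelength_grid: %d bands, %.1f-%.1f nm, mean spacing %.4f nm\n",
              length(x$values), x$values[1], x$values[length(x$values)], x$spacing))
  invisible(x)
}

# Validate a numeric vector as an ascending, uniform wavelength grid.
as_wavelength_grid <- function(values) {
  if (inherits(values, "wavelength_grid")) return(values)
  values <- as.numeric(values)
  if (length(values) < 2L) stop_invalid("a wavelength grid needs >= 2 bands")
  d <- diff(values)
  if (any(d <= 0)) stop_invalid("wavelengths must be strictly increasing")
  structure(list(values = values, spacing = mean(d)), class = "wavelength_grid")
}
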