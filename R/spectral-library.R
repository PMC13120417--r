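#' Spectral library for the synthetic scene simulator
#'
#' Each entry describes one material as a linear reflectance continuum plus a
#' set of Gaussian absorption dips, with a within-class variability scale used
#' to perturb individual pixels. Entry 0 is the unlabeled conveyor background;
#' entries 1..K are the target classes (1 = fillet, 2..13 = polymer types).
#' The parameterisation is a qualitative stand-in for NIR polymer/meat
#' reflectance: distinct continuum levels and C-H / O-H overtone-like dips
#' make the classes spectrally separable while remaining smooth.
#'
#' @param classes a named list; each element a list with fields `level`
#'   (continuum, % reflectance at the mid wavelength), `slope` (%/nm),
#'   `features` (data.frame with columns `center_nm`, `width_nm`, `depth_pct`,
#'   possibly empty) and `variability` (scale of smooth per-pixel
#'   perturbations, % reflectance units).
#' @param background one entry of the same shape for the unlabeled background.
#' @return An object of class `spectral_library`.
#' @seealso [default_spectral_library()], [sample_class_spectrum()]
#' @export
spectral_library <- function(classes, background) {
  check_entry <- function(e, who) {
    need <- c("level", "slope", "features", "variability")
    if (!all(need %in% names(e)))
      stop_invalid("library entry '", who, "' must have fields: ",
                   paste(need, collapse = ", "))
    if (e$level < 0 || e$level > 100)
      stop_invalid("library entry '", who, "': level must be in [0, 100]")
    if (e$variability < 0)
      stop_invalid("library entry '", who, "': variability must be >= 0")
    e$features <- as.data.frame(e$features)
    e
  }
  classes <- lapply(seq_along(classes), function(i)
    check_entry(classes[[i]], names(classes)[i]))
  names(classes) <- NULL
  structure(list(classes = classes,
                 class_names = if (is.null(names(background))) NULL else NULL,
                 background = check_entry(background, "background")),
            class = "spectral_library")
}

feat <- function(center_nm = numeric(), width_nm = numeric(),
                 depth_pct = numeric()) {
  data.frame(center_nm = center_nm, width_nm = width_nm, depth_pct = depth_pct)
}

#' Default 13-class spectral library
#'
#' Thirteen target materials (fillet plus 12 polymer classes commonly found in
#' poultry processing: ABS, fabric, HDPE, LDPE, nylon, PET, PP, PS, PUR, PVC,
#' rubber, Teflon) and a flat conveyor-belt background. The entries are
#' synthetic: continuum levels are spread over 30-90 % reflectance and dip
#' centers are placed at plausible NIR overtone positions, giving a minimum
#' pairwise mean-spectrum separation well above the package's default floor.
#'
#' @return A `spectral_library` with 13 target classes.
#' @export
default_spectral_library <- function() {
  cl <- list(
    fillet = list(level = 45, slope = -0.010,
                  features = feat(c(1450, 1200), c(60, 40), c(18, 6)),
                  variability = 2.0),
    ABS  = list(level = 70, slope =  0.004,
                features = feat(c(1680, 1140), c(30, 25), c(14, 7)),
                variability = 1.0),
    FAB  = list(level = 62, slope = -0.004,
                features = feat(c(1490, 1320), c(45, 30), c(12, 5)),
                variability = 1.5),
    HDPE = list(level = 80, slope =  0.002,
                features = feat(c(1212, 1395, 1540), c(22, 30, 35), c(16, 9, 5)),
                variability = 1.0),
    LDPE = list(level = 76, slope =  0.000,
                features = feat(c(1215, 1400, 1620), c(24, 32, 40), c(13, 8, 5)),
                variability = 1.2),
    NYL  = list(level = 58, slope =  0.006,
                features = feat(c(1500, 1190), c(40, 28), c(15, 6)),
                variability = 1.0),
    PET  = list(level = 66, slope = -0.006,
                features = feat(c(1660, 1130, 1415), c(28, 22, 30), c(13, 8, 6)),
                variability = 1.0),
    PP   = list(level = 72, slope =  0.005,
                features = feat(c(1195, 1360, 1690), c(20, 25, 30), c(12, 9, 6)),
                variability = 1.2),
    PS   = list(level = 55, slope =  0.003,
                features = feat(c(1144, 1680), c(20, 32), c(14, 9)),
                variability = 1.0),
    PUR  = list(level = 38, slope =  0.008,
                features = feat(c(1540, 1240), c(40, 30), c(10, 5)),
                variability = 1.2),
    PVC  = list(level = 85, slope = -0.003,
                features = feat(c(1190, 1420), c(24, 30), c(9, 12)),
                variability = 1.0),
    RUB  = list(level = 30, slope =  0.004,
                features = feat(c(1210, 1440), c(30, 40), c(8, 6)),
                variability = 1.5),
    TEF  = list(level = 90, slope = -0.002,
                features = feat(c(1150, 1620), c(35, 45), c(5, 7)),
                variability = 0.8))
  bg <- list(level = 22, slope = 0.002, features = feat(), variability = 0.5)
  lib <- spectral_library(cl, bg)
  lib$class_names <- names(cl)
  lib
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("spectral_library: %d target classes + background\n",
              length(x$classes)))
  invisible(x)
}

n_classes <- function(library) length(library$classes)

library_entry <- function(library, class_id) {
  if (class_id == 0) return(library$background)
  if (class_id < 0 || class_id > length(library$classes))
    stop_key("unknown class_id: ", class_id)
  library$classes[[class_id]]
}

# Noise-free mean spectrum of one class on a grid (% reflectance, clipped).
mean_class_spectrum <- function(library, class_id, grid) {
  grid <- as_wavelength_grid(grid)
  e <- library_entry(library, class_id)
  lam <- grid$values
  mid <- (lam[1] + lam[length(lam)]) / 2
  s <- e$level + e$slope * (lam - mid)
  if (nrow(e$features) > 0) {
    for (i in seq_len(nrow(e$features))) {
      f <- e$features[i, ]
      s <- s - f$depth_pct * exp(-0.5 * ((lam - f$center_nm) / f$width_nm)^2)
    }
  }
  pmin(pmax(s, 0), 100)
}

# Legendre basis (P0..P2) on the normalised wavelength axis u in [-1, 1];
# used for smooth low-order within-class perturbations.
smooth_basis <- function(grid) {
  lam <- as_wavelength_grid(grid)$values
  u <- 2 * (lam - lam[1]) / (lam[length(lam)] - lam[1]) - 1
  rbind(rep(1, length(u)), u, (3 * u^2 - 1) / 2)
}

#' Draw one within-class reflectance spectrum
#'
#' The spectrum is the class continuum minus its Gaussian absorption dips,
#' perturbed by a smooth low-order polynomial whose coefficients are drawn
#' from the RNG and scaled by the class variability, then clipped to
#' \[0, 100\] %.
#'
#' @param library a `spectral_library`.
#' @param class_id integer class id (0 = background, 1..K = target classes).
#' @param grid a `wavelength_grid` (or numeric vector of band centers).
#' @param seed optional integer; when given, the draw is made under this seed
#'   and the caller's RNG state is untouched, so identical seeds give
#'   identical spectra.
#' @return Numeric vector of length `length(grid)`, percent reflectance.
#' @export
sample_class_spectrum <- function(library, class_id, grid, seed = NULL) {
  grid <- as_wavelength_grid(grid)
  e <- library_entry(library, class_id)
  base <- mean_class_spectrum(library, class_id, grid)
  coef <- with_seed(seed, stats::rnorm(3L)) * e$variability * c(1, 0.6, 0.4)
  pmin(pmax(base + drop(coef %*% smooth_basis(grid)), 0), 100)
}

#' Minimum pairwise separation of the target-class mean spectra
#'
#' Euclidean distance between mean spectra over all band pairs; the scene
#' simulator requires this to stay above a floor so that the target classes
#' remain distinguishable.
#'
#' @inheritParams sample_class_spectrum
#' @return Smallest pairwise Euclidean distance between the mean spectra of
#'   the target classes (% reflectance units, aggregated over bands).
#' @export
library_separability <- function(library, grid) {
  grid <- as_wavelength_grid(grid)
  S <- t(vapply(seq_len(n_classes(library)),
                function(k) mean_class_spectrum(library, k, grid),
                numeric(length(grid$values))))
  min(stats::dist(S))
}
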