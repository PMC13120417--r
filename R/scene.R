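#' Specify a synthetic NIR hyperspectral scene
#'
#' A scene is a conveyor background, a rectangular fillet region, and square
#' regions of interest placed on the fillet: `n_regions_per_class` regions of
#' `region_size` x `region_size` pixels for each of the 13 target classes
#' (class 1 regions are pure-fillet ROIs; classes 2..13 are plastic pieces
#' resting on the fillet, nominally 5x5 mm at the instrument's resolution).
#' Labeling excludes a `margin`-pixel ring at every class boundary, emulating
#' the annotation rule that boundary pixels with mixed spectra are dropped.
#'
#' @param height,width scene size in pixels.
#' @param n_bands,lo_nm,hi_nm spectral axis (default 171 bands, 1000-1700 nm).
#' @param n_regions_per_class number of square ROIs per target class.
#' @param region_size side of each ROI in pixels.
#' @param fillet integer vector `c(row0, col0, row1, col1)` (1-based,
#'   inclusive) delimiting the fillet; all ROIs must fit inside it.
#' @param margin boundary-exclusion margin in pixels (>= 0).
#' @param illum_amplitude relative amplitude of the smooth multiplicative
#'   illumination field baked into the reference frames.
#' @param noise_sd additive sensor noise standard deviation, % reflectance.
#' @param seed integer seed; the whole render is a pure function of the spec.
#' @param n_classes number of target classes (13: fillet + 12 polymers).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height = 256L, width = 256L,
                       n_bands = 171L, lo_nm = 1000, hi_nm = 1700,
                       n_regions_per_class = 16L, region_size = 7L,
                       fillet = c(17L, 17L, 240L, 240L),
                       margin = 1L, illum_amplitude = 0.05,
                       noise_sd = 1.0, seed = 42L, n_classes = 13L) {
  if (margin < 0) stop_invalid("margin must be >= 0")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (length(fillet) != 4L) stop_invalid("fillet must be c(row0, col0, row1, col1)")
  if (fillet[1] < 1 || fillet[2] < 1 || fillet[3] > height || fillet[4] > width ||
      fillet[1] > fillet[3] || fillet[2] > fillet[4])
    stop_invalid("fillet rectangle must lie inside the scene")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_bands = as.integer(n_bands), lo_nm = lo_nm, hi_nm = hi_nm,
                 n_regions_per_class = as.integer(n_regions_per_class),
                 region_size = as.integer(region_size),
                 fillet = as.integer(fillet), margin = as.integer(margin),
                 illum_amplitude = illum_amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed), n_classes = as.integer(n_classes)),
            class = "scene_spec")
}

#' Scene presets
#'
#' `"desk"` is the package's working scale: 256x256x171 with 16 ROIs of 7x7
#' per class, i.e. 400 labeled pixels per class at margin 1 — enough for a
#' 200 train / 100 val / 100 test per-class protocol while keeping render and
#' training times small. `"paper"` scales the ROIs up (16 regions of 17x17,
#' 3600 labeled pixels per class on a 320x320 scene) so that the full
#' 2400/1200 per-class split protocol can be exercised.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed integer seed stored in the spec.
#' @return A `scene_spec`.
#' @export
scene_preset <- function(preset = c("desk", "paper"), seed = 42L) {
  preset <- match.arg(preset)
  switch(preset,
    desk  = scene_spec(seed = seed),
    paper = scene_spec(height = 320L, width = 320L,
                       n_regions_per_class = 16L, region_size = 17L,
                       fillet = c(11L, 11L, 310L, 310L), seed = seed))
}

# Labeled pixels per class implied by a spec (interior after margin erosion).
labeled_per_class <- function(spec) {
  side <- spec$region_size - 2L * spec$margin
  if (side <= 0) 0L else spec$n_regions_per_class * side^2
}

# Place ROIs on a jittered grid inside the fillet. Returns a data.frame
# (class_id, row0, col0) of region top-left corners; cells are spaced so that
# two regions of different classes are always > margin apart.
place_regions <- function(spec) {
  rs <- spec$region_size
  gap <- spec$margin + 2L          # inter-region clearance
  cell <- rs + gap
  f <- spec$fillet
  fh <- f[3] - f[1] + 1L; fw <- f[4] - f[2] + 1L
  ncr <- fh %/% cell; ncc <- fw %/% cell
  need <- spec$n_classes * spec$n_regions_per_class
  if (ncr * ncc < need)
    stop_config("cannot place ", need, " regions of ", rs, "x", rs,
                " inside the fillet (capacity ", ncr * ncc, ")")
  cells <- sample.int(ncr * ncc, need)   # seeded by caller
  jmax <- gap - spec$margin - 1L         # jitter keeping clearance > margin
  jr <- if (jmax > 0) sample.int(jmax + 1L, need, replace = TRUE) - 1L else integer(need)
  jc <- if (jmax > 0) sample.int(jmax + 1L, need, replace = TRUE) - 1L else integer(need)
  data.frame(class_id = rep(seq_len(spec$n_classes), each = spec$n_regions_per_class),
             row0 = f[1] + ((cells - 1L) %/% ncc) * cell + jr,
             col0 = f[2] + ((cells - 1L) %% ncc) * cell + jc)
}

# Smooth periodic 2D field in [-1, 1] used for illumination / dark structure.
smooth_field <- function(height, width, phase = c(0, 0)) {
  r <- sin(2 * pi * (seq_len(height) / height) + phase[1])
  c <- cos(2 * pi * (seq_len(width) / width) + phase[2])
  outer(r, c)
}

#' Render a synthetic hyperspectral scene
#'
#' Produces a raw digital-number (DN) cube together with the white/dark
#' reference frames that invert it, a label mask with boundary-pixel
#' exclusion, and the noise-free reflectance cube the render intends.
#' The DN model is `raw = dark + R/100 * (white - dark)` with a smoothly
#' structured illumination term shared between raw and white frames, so the
#' standard reflectance calibration recovers `R` exactly up to the additive
#' sensor noise drawn in reflectance units.
#'
#' @param spec a [scene_spec()].
#' @param library a [spectral_library()]; default [default_spectral_library()].
#' @param min_separation floor on the pairwise mean-spectrum distance of the
#'   target classes; rendering refuses a library below it.
#' @return A list with elements `raw`, `white`, `dark` (H x W x B arrays, DN),
#'   `truth` (H x W x B intended noise-free reflectance, %), `mask`
#'   (`label_mask`), `grid` (`wavelength_grid`), `class_map` (H x W material
#'   map incl. unlabeled boundary pixels), and the `spec`/`library` used.
#' @export
render_scene <- function(spec, library = default_spectral_library(),
                         min_separation = 25) {
  stopifnot(inherits(spec, "scene_spec"))
  grid <- make_wavelength_grid(spec$n_bands, spec$lo_nm, spec$hi_nm)
  if (length(library$classes) < spec$n_classes)
    stop_config("library has fewer classes than the scene spec requests")
  sep <- library_separability(library, grid)
  if (sep < min_separation)
    stop_config("library separability ", round(sep, 2),
                " below floor ", min_separation)

  H <- spec$height; W <- spec$width; B <- spec$n_bands
  npx <- H * W
  f <- spec$fillet

  with_seed(spec$seed, {
    regions <- place_regions(spec)

    # material map: 0 background, 1 fillet everywhere on the fillet,
    # 2..K on plastic regions; label mask: interiors only.
    class_map <- matrix(0L, H, W)
    class_map[f[1]:f[3], f[2]:f[4]] <- 1L
    mask <- matrix(0L, H, W)
    rs <- spec$region_size; m <- spec$margin
    for (i in seq_len(nrow(regions))) {
      r0 <- regions$row0[i]; c0 <- regions$col0[i]; k <- regions$class_id[i]
      class_map[r0:(r0 + rs - 1L), c0:(c0 + rs - 1L)] <- k
      if (rs - 2L * m > 0)
        mask[(r0 + m):(r0 + rs - 1L - m), (c0 + m):(c0 + rs - 1L - m)] <- k
    }
    # class-1 labels additionally require pure fillet: regions of class 1 are
    # fillet ROIs so their interiors are already class 1 in class_map.

    # mean spectra (rows: material id 0..K)
    S <- rbind(mean_class_spectrum(library, 0L, grid),
               t(vapply(seq_len(spec$n_classes),
                        function(k) mean_class_spectrum(library, k, grid),
                        numeric(B))))
    vari <- c(library$background$variability,
              vapply(seq_len(spec$n_classes),
                     function(k) library_entry(library, k)$variability, numeric(1)))

    cm <- as.vector(class_map)                  # pixel-major (row fastest)
    R0 <- S[cm + 1L, , drop = FALSE]            # npx x B continuum+dips
    basis <- smooth_basis(grid)                 # 3 x B
    coef <- matrix(stats::rnorm(npx * 3L), npx, 3L) *
      (vari[cm + 1L] %o% c(1, 0.6, 0.4))
    R0 <- R0 + coef %*% basis
    R0 <- pmin(pmax(R0, 0), 100)                # intended reflectance (truth)

    Rn <- R0
    if (spec$noise_sd > 0)
      Rn <- pmin(pmax(Rn + matrix(stats::rnorm(npx * B, sd = spec$noise_sd),
                                  npx, B), 0), 100)

    # illumination-times-response term (white - dark), strictly positive
    lam <- grid$values
    L <- 2500 + 900 * sin(pi * (lam - lam[1]) / (lam[B] - lam[1]))
    illum <- 1 + spec$illum_amplitude *
      as.vector(smooth_field(H, W, phase = c(0.7, 1.3)))
    I <- illum %o% L                            # npx x B
    dark <- 96 + 4 * as.vector(smooth_field(H, W, phase = c(2.1, 0.4))) +
      rep(2 * (lam - mean(lam)) / (lam[B] - lam[1]), each = npx)
    dim(dark) <- c(npx, B)

    raw <- dark + Rn / 100 * I
    white <- dark + I

    shape <- function(mat) { dim(mat) <- c(H, W, B); mat }
    list(raw   = hsi_cube(shape(raw), grid, domain = "dn"),
         white = shape(white),
         dark  = shape(dark),
         truth = hsi_cube(shape(R0), grid, domain = "reflectance"),
         mask  = label_mask(mask, n_classes = spec$n_classes,
                            class_names = library$class_names),
         grid = grid, class_map = class_map,
         spec = spec, library = library)
  })
}
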