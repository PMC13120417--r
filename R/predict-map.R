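#' Pixel-level classification map
#'
#' Classifies every labeled target pixel of a scene (patch extraction,
#' forward pass, argmax) and writes the prediction into an `H x W` integer
#' map; non-target pixels stay 0.
#'
#' @param cube a reflectance-domain [hsi_cube()].
#' @param mask a [label_mask()] marking the target pixels.
#' @param model a trained model.
#' @param batch_size inference batch size.
#' @return An object of class `classification_map`: list with `values`
#'   (`H x W` integer predictions), `n_classes`, `class_names`.
#' @export
predict_map <- function(cube, mask, model, batch_size = 512L) {
  ds <- patch_dataset(cube, mask, patch_size = model$cfg$patch_size)
  pred <- predict_classes(ds, model, batch_size)
  vals <- matrix(0L, nrow(mask$values), ncol(mask$values))
  vals[cbind(ds$targets$row, ds$targets$col)] <- pred
  structure(list(values = vals, n_classes = mask$n_classes,
                 class_names = mask$class_names),
            class = "classification_map")
}

#' @export
print.classification_map <- function(x, ...) {
  cat(sprintf("classification_map: %d x %d, %d predicted pixels\n",
              nrow(x$values), ncol(x$values), sum(x$values > 0L)))
  invisible(x)
}

# Qualitative palette for up to 13 classes + background (black).
map_palette <- function(n_classes) {
  base <- c("#e6194b", "#3cb44b", "#ffe119", "#4363d8", "#f58231",
            "#911eb4", "#46f0f0", "#f032e6", "#bcf60c", "#fabebe",
            "#008080", "#e6beff", "#9a6324", "#fffac8", "#800000")
  c("#000000", base[seq_len(n_classes)])
}

#' Render a classification map (or label mask) to PNG
#'
#' @param map a `classification_map` or `label_mask`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(map, path) {
  vals <- map$values
  pal <- map_palette(map$n_classes)
  rgb <- grDevices::col2rgb(pal[vals + 1L]) / 255
  img <- array(0, c(nrow(vals), ncol(vals), 3L))
  img[, , 1] <- matrix(rgb[1, ], nrow(vals)); img[, , 2] <- matrix(rgb[2, ], nrow(vals))
  img[, , 3] <- matrix(rgb[3, ], nrow(vals))
  png::writePNG(img, path)
  invisible(path)
}
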