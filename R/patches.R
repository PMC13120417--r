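#' Enumerate labeled target pixels
#'
#' Every pixel with label >= 1 is one classification target; patches are
#' extracted one per target, so the patch count always equals the target
#' count. Order is deterministic row-major (by row, then column).
#'
#' @param mask a [label_mask()].
#' @return A data.frame with columns `row`, `col` (1-based) and `label`.
#' @export
enumerate_target_pixels <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  idx <- which(mask$values > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(row = integer(), col = integer(), label = integer()))
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  data.frame(row = unname(idx[, 1L]), col = unname(idx[, 2L]),
             label = mask$values[idx])
}

# Mirror reflection of out-of-range indices (no edge repetition): index 0
# maps to 2, index -1 to 3, index n+1 to n-1, ...
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  m <- (i - 1L) %% p
  m <- ifelse(m >= n, p - m, m)
  m + 1L
}

patch_offsets <- function(patch_size) {
  h <- (patch_size - 1L) %/% 2L
  # row-major token order: row offset outer, column offset inner
  list(dr = rep(-h:h, each = patch_size), dc = rep(-h:h, times = patch_size))
}

#' Extract one patch cube centered on a target pixel
#'
#' Returns the `P x P x B` window around `center`. Windows overlapping the
#' cube edge are handled per `border`: `"reflect"` mirrors indices without
#' repeating the edge row/column, `"zero"` fills with zeros, `"error"`
#' refuses.
#'
#' @param cube an [hsi_cube()].
#' @param center integer `c(row, col)`, 1-based, inside the cube.
#' @param patch_size odd patch side P (default 7).
#' @param border `"reflect"`, `"zero"` or `"error"`.
#' @param label optional class label attached to the patch.
#' @return An object of class `patch_cube`: list with `data` (P x P x B),
#'   `center`, `label`.
#' @export
extract_patch <- function(cube, center, patch_size = 7L,
                          border = c("reflect", "zero", "error"),
                          label = NA_integer_) {
  stopifnot(inherits(cube, "hsi_cube"))
  border <- match.arg(border)
  if (patch_size %% 2L == 0L) stop_invalid("patch_size must be odd")
  d <- dim(cube$data)
  if (center[1] < 1L || center[1] > d[1] || center[2] < 1L || center[2] > d[2])
    stop_invalid("center must lie inside the cube")
  h <- (patch_size - 1L) %/% 2L
  rows <- center[1] + (-h:h); cols <- center[2] + (-h:h)
  out_of_bounds <- any(rows < 1L | rows > d[1] | cols < 1L | cols > d[2])
  if (out_of_bounds && border == "error")
    stop_invalid("patch window exceeds cube bounds at center (",
                 center[1], ", ", center[2], ")")
  if (border == "zero") {
    dat <- array(0, dim = c(patch_size, patch_size, d[3]))
    rok <- which(rows >= 1L & rows <= d[1]); cok <- which(cols >= 1L & cols <= d[2])
    dat[rok, cok, ] <- cube$data[rows[rok], cols[cok], , drop = FALSE]
  } else {
    dat <- cube$data[reflect_index(rows, d[1]), reflect_index(cols, d[2]), ,
                     drop = FALSE]
  }
  structure(list(data = dat, center = as.integer(center),
                 label = as.integer(label)),
            class = "patch_cube")
}

#' Index-based patch dataset over a cube and mask
#'
#' Builds a lazy dataset: patches are never materialised up front; instead a
#' precomputed index matrix maps each target pixel to the `P^2` pixel
#' positions of its (reflect-padded) window, and batches are gathered from
#' the cube on demand. This bounds memory at the cost of one integer matrix.
#'
#' @param cube a reflectance-domain [hsi_cube()].
#' @param mask a [label_mask()] with the same spatial dimensions.
#' @param patch_size odd patch side (default 7).
#' @param border border policy passed to the window indexing (`"reflect"` or
#'   `"zero"`).
#' @return An object of class `patch_dataset` with fields `pixels`
#'   (`(H*W[+1]) x B` matrix view of the cube; the final row is the zero fill
#'   row under the `"zero"` policy), `index` (`N x P^2` gather matrix),
#'   `targets` (data.frame from [enumerate_target_pixels()]), `labels`,
#'   `patch_size`, `n_bands`.
#' @export
patch_dataset <- function(cube, mask, patch_size = 7L,
                          border = c("reflect", "zero")) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(mask, "label_mask"))
  border <- match.arg(border)
  if (patch_size %% 2L == 0L) stop_invalid("patch_size must be odd")
  d <- dim(cube$data)
  if (!identical(d[1:2], dim(mask$values)))
    stop_invalid("mask dimensions must match the cube")
  targets <- enumerate_target_pixels(mask)
  off <- patch_offsets(patch_size)
  H <- d[1]; W <- d[2]
  pixmat <- cube$data
  dim(pixmat) <- c(H * W, d[3])
  if (border == "zero") pixmat <- rbind(pixmat, 0)
  zero_row <- H * W + 1L
  n <- nrow(targets)
  Rm <- outer(targets$row, off$dr, "+")
  Cm <- outer(targets$col, off$dc, "+")
  if (border == "reflect") {
    Rm[] <- reflect_index(Rm, H); Cm[] <- reflect_index(Cm, W)
    index <- Rm + (Cm - 1L) * H
  } else {
    inside <- Rm >= 1L & Rm <= H & Cm >= 1L & Cm <= W
    index <- ifelse(inside, Rm + (Cm - 1L) * H, zero_row)
  }
  storage.mode(index) <- "integer"
  structure(list(pixels = pixmat, index = index, targets = targets,
                 labels = targets$label, patch_size = as.integer(patch_size),
                 n_bands = d[3], n_classes = mask$n_classes,
                 class_names = mask$class_names),
            class = "patch_dataset")
}

#' @export
length.patch_dataset <- function(x) nrow(x$index)

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("patch_dataset: %d patches of %dx%dx%d, %d classes\n",
              nrow(x$index), x$patch_size, x$patch_size, x$n_bands,
              x$n_classes))
  invisible(x)
}

# Gather the spectral matrix for a batch of dataset items. Rows are ordered
# batch-fastest within token blocks: row (b + (t-1)*Nb) holds token t of
# batch item b — the layout the model core expects.
gather_batch <- function(ds, items) {
  ds$pixels[as.vector(ds$index[items, , drop = FALSE]), , drop = FALSE]
}

#' Class-balanced train/validation/test split
#'
#' Per class, exactly `n_train` target pixels are sampled for training and
#' `n_val` for validation, without replacement; every remaining labeled
#' target pixel goes to the test set. With the study-scale protocol
#' (13 classes, 2400/1200 per class) this yields 31,200 training, 15,600
#' validation and `N - 46,800` test patches.
#'
#' @param targets data.frame from [enumerate_target_pixels()] (or a
#'   `patch_dataset`, whose targets are used).
#' @param n_train_per_class,n_val_per_class per-class sample sizes.
#' @param seed integer seed; identical inputs and seed give the identical
#'   assignment.
#' @return An object of class `split_assignment`: list of integer index
#'   vectors `train`, `val`, `test` (row indices into `targets`), pairwise
#'   disjoint with union covering all targets.
#' @export
make_splits <- function(targets, n_train_per_class = 2400L,
                        n_val_per_class = 1200L, seed = 1L) {
  if (inherits(targets, "patch_dataset")) targets <- targets$targets
  if (n_train_per_class < 0L || n_val_per_class < 0L)
    stop_invalid("per-class sizes must be >= 0")
  labels <- targets$label
  classes <- sort(unique(labels))
  need <- n_train_per_class + n_val_per_class
  with_seed(seed, {
    train <- integer(); val <- integer()
    for (k in classes) {
      idx <- which(labels == k)
      if (length(idx) < need)
        stop_config("class ", k, " has ", length(idx),
                    " target pixels; need ", need)
      pick <- sample(idx, need)
      train <- c(train, pick[seq_len(n_train_per_class)])
      val <- c(val, pick[n_train_per_class + seq_len(n_val_per_class)])
    }
    test <- setdiff(seq_along(labels), c(train, val))
    out <- structure(list(train = sort(train), val = sort(val), test = test),
                     class = "split_assignment")
    stopifnot(length(intersect(out$train, out$val)) == 0L,
              length(intersect(out$train, out$test)) == 0L,
              length(intersect(out$val, out$test)) == 0L,
              length(c(out$train, out$val, out$test)) == length(labels))
    out
  })
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment: %d train / %d val / %d test\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}
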