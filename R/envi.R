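#' Read and write ENVI-style rasters
#'
#' Minimal ENVI dialect used by the package: a text header (`<path>.hdr`)
#' with keys `samples`, `lines`, `bands`, `data type` (4 = float32,
#' 2 = int16), `interleave` (`bsq` or `bil`), `byte order` (0, little
#' endian) and a `wavelength` list, next to a flat binary file at `<path>`.
#' The in-memory axis order is always (row, col, band); interleave only
#' affects the byte layout on disk, so a cube written as BIL reads back
#' identical to the same cube written as BSQ.
#'
#' @param cube an [hsi_cube()].
#' @param path path of the binary file; the header is written at
#'   `paste0(path, ".hdr")`.
#' @param interleave `"bsq"` (band-sequential) or `"bil"`
#'   (band-interleaved-by-line).
#' @param data_type ENVI data type code: 4 (float32) or 2 (int16).
#' @return `write_envi()` returns `path` invisibly; `read_envi()` returns an
#'   `hsi_cube`.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil"),
                       data_type = 4L) {
  stopifnot(inherits(cube, "hsi_cube"))
  interleave <- match.arg(interleave)
  if (!data_type %in% c(2L, 4L)) stop_format("unsupported data type: ", data_type)
  d <- dim(cube$data)
  write_envi_raw(cube$data, path, interleave, data_type,
                 wavelength = cube$wavelengths$values,
                 extra = c(domain = cube$domain))
  invisible(path)
}

# Core writer shared by cube and mask writers. `arr` is (rows, cols, bands).
write_envi_raw <- function(arr, path, interleave, data_type,
                           wavelength = NULL, extra = character()) {
  d <- dim(arr)
  v <- switch(interleave,
              bsq = as.vector(aperm(arr, c(2L, 1L, 3L))),
              bil = as.vector(aperm(arr, c(2L, 3L, 1L))))
  con <- file(path, "wb")
  on.exit(close(con))
  if (data_type == 4L) {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  } else {
    iv <- as.integer(round(v))
    if (any(iv < -32768L | iv > 32767L))
      stop_format("values out of int16 range for data type 2")
    writeBin(iv, con, size = 2L, endian = "little")
  }
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", data_type),
           paste0("interleave = ", interleave),
           "byte order = 0")
  if (length(extra))
    hdr <- c(hdr, paste0(names(extra), " = ", unname(extra)))
  if (!is.null(wavelength))
    hdr <- c(hdr, "wavelength units = Nanometers",
             paste0("wavelength = { ",
                    paste(format(wavelength, trim = TRUE, digits = 10),
                          collapse = ", "), " }"))
  writeLines(hdr, paste0(path, ".hdr"))
}

# Parse a minimal ENVI header into a named list.
read_envi_header <- function(hdr_path) {
  if (!file.exists(hdr_path)) stop_format("missing ENVI header: ", hdr_path)
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  out <- list()
  # brace-delimited values may span lines
  m <- gregexpr("([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n{]*)", txt)[[1]]
  starts <- m; lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- trimws(sub("=.*", "", piece))
    val <- trimws(sub("^[^=]*=", "", piece))
    out[[tolower(key)]] <- val
  }
  out
}

envi_type_bytes <- c(`2` = 2L, `4` = 4L)

read_envi_raw <- function(path) {
  hdr <- read_envi_header(paste0(path, ".hdr"))
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop_format("ENVI header missing keys: ",
                                paste(miss, collapse = ", "))
  samples <- as.integer(hdr$samples); lines <- as.integer(hdr$lines)
  bands <- as.integer(hdr$bands)
  dtype <- as.integer(hdr[["data type"]])
  interleave <- tolower(hdr$interleave)
  if (!interleave %in% c("bsq", "bil"))
    stop_format("unsupported interleave: ", interleave)
  if (!as.character(dtype) %in% names(envi_type_bytes))
    stop_format("unsupported data type: ", dtype)
  nbytes <- envi_type_bytes[[as.character(dtype)]]
  n <- samples * lines * bands
  sz <- file.info(path)$size
  if (is.na(sz) || sz != n * nbytes)
    stop_format("binary size ", sz, " does not match header (", n * nbytes,
                " bytes expected)")
  con <- file(path, "rb")
  on.exit(close(con))
  v <- if (dtype == 4L)
    readBin(con, "numeric", n = n, size = 4L, endian = "little")
  else
    readBin(con, "integer", n = n, size = 2L, signed = TRUE, endian = "little")
  arr <- switch(interleave,
                bsq = aperm(array(v, dim = c(samples, lines, bands)), c(2L, 1L, 3L)),
                bil = aperm(array(v, dim = c(samples, bands, lines)), c(3L, 1L, 2L)))
  wl <- NULL
  if (!is.null(hdr$wavelength)) {
    wl <- as.numeric(strsplit(gsub("[{}]", "", hdr$wavelength), ",")[[1]])
    if (length(wl) != bands)
      stop_format("header wavelength count ", length(wl), " != bands ", bands)
  }
  list(arr = arr, wavelength = wl, header = hdr)
}

#' @rdname write_envi
#' @export
read_envi <- function(path) {
  r <- read_envi_raw(path)
  wl <- if (is.null(r$wavelength)) seq_len(dim(r$arr)[3]) else r$wavelength
  domain <- if (!is.null(r$header$domain) &&
                r$header$domain == "reflectance") "reflectance" else "dn"
  hsi_cube(r$arr, wl, domain = domain)
}

#' Read and write integer label masks as single-band ENVI rasters
#'
#' Masks are stored as int16 rasters; labels are validated against
#' `0..n_classes` on read (out-of-range values are a format error).
#'
#' @param mask a [label_mask()].
#' @param path binary path (header written at `<path>.hdr`).
#' @param n_classes number of target classes used for validation.
#' @return `write_label_mask()` returns `path` invisibly; `read_label_mask()`
#'   returns a `label_mask`.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  arr <- array(mask$values, dim = c(dim(mask$values), 1L))
  extra <- c(`mask classes` = as.character(mask$n_classes))
  write_envi_raw(arr, path, "bsq", 2L, extra = extra)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path, n_classes = NULL) {
  r <- read_envi_raw(path)
  if (dim(r$arr)[3] != 1L) stop_format("label mask must be single-band")
  if (is.null(n_classes)) {
    n_classes <- if (!is.null(r$header[["mask classes"]]))
      as.integer(r$header[["mask classes"]]) else 13L
  }
  vals <- r$arr[, , 1L]
  if (any(vals < 0L) || any(vals > n_classes))
    stop_format("mask labels outside 0..", n_classes)
  label_mask(vals, n_classes = n_classes)
}
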