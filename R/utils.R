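#' @keywords internal
#' @useDynLib sstfpo, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(...) {
  stop(structure(class = c("sstfpo_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("sstfpo_configuration_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("sstfpo_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_key <- function(...) {
  stop(structure(class = c("sstfpo_key_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

relu <- function(x) x * (x > 0)

# Row-wise softmax of a matrix (numerically stabilised).
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}
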