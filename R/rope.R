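#' Patch-local mixed-axis 2D rotary position embedding
#'
#' Consecutive dimension pairs `(2j-1, 2j)` of each attention head are
#' treated as complex numbers and rotated by the position-dependent angle
#' `phi = theta_x[j] * x + theta_y[j] * y`, where `(x, y)` is the token's
#' grid coordinate and the frequencies are learnable per head and pair.
#' Because a rotation is an isometry, per-pair norms are preserved; and
#' because the inner product of two rotated vectors depends only on the
#' angle difference, the attention score between the center token and any
#' other token depends only on the coordinate offset
#' `(theta_x * dx + theta_y * dy)` — a relative-position encoding on the 2D
#' grid that mixes the two axes into a single rotation.
#'
#' @param X numeric matrix (rows = tokens, columns = `d` model dims grouped
#'   head-major; `d` must be even).
#' @param coords integer matrix `nrow(X) x 2` of `(x, y)` grid coordinates,
#'   or a single `c(x, y)` applied to every row (e.g. the center reference
#'   coordinates for the query).
#' @param theta_x,theta_y frequency vectors of length `d/2` (head-major pair
#'   order).
#' @return The rotated matrix, same shape as `X`.
#' @export
apply_rope_mixed <- function(X, coords, theta_x, theta_y) {
  X <- rbind(X)  # promote vectors to 1-row matrices
  d <- ncol(X)
  if (d %% 2L != 0L) stop_config("rotary embedding needs an even dimension")
  np <- d %/% 2L
  if (length(theta_x) != np || length(theta_y) != np)
    stop_invalid("theta_x/theta_y must have length ncol(X)/2")
  if (is.null(dim(coords))) coords <- matrix(coords, nrow(X), 2L, byrow = TRUE)
  phi <- outer(coords[, 1L], theta_x) + outer(coords[, 2L], theta_y)
  rope_rotate(X, cos(phi), sin(phi))
}

# Rotate consecutive column pairs of M by angles with cosines C, sines S
# (matrices nrow(M) x ncol(M)/2). Inverse rotation: pass -S.
rope_rotate <- function(M, C, S) {
  d <- ncol(M)
  odd <- seq.int(1L, d, by = 2L); even <- odd + 1L
  a <- M[, odd, drop = FALSE]; b <- M[, even, drop = FALSE]
  out <- M
  out[, odd] <- a * C - b * S
  out[, even] <- a * S + b * C
  out
}

# Phase matrix (n_tokens x d/2) for a layer's frequencies on a coordinate
# grid.
rope_phases <- function(coords, theta_x, theta_y) {
  outer(coords[, 1L], theta_x) + outer(coords[, 2L], theta_y)
}
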