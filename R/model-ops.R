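# Spec-level operations on a single token sequence. These wrap the batched
# core with a batch of one, so unit tests of the operation surface also
# exercise the training path.

# Flatten a patch cube (P x P x B) into an n x B matrix in row-major token
# order (token t = (row-1)*P + col).
patch_matrix <- function(patch) {
  dat <- if (inherits(patch, "patch_cube")) patch$data else patch
  d <- dim(dat)
  matrix(aperm(dat, c(2L, 1L, 3L)), d[1] * d[2], d[3])
}

#' Embed a patch into a token sequence
#'
#' Projects each pixel's spectrum to `d_emb` dimensions with a shared 1x1
#' convolution (a per-pixel linear map over bands), batch-normalises over
#' channels and applies the rectifier, then flattens the `P x P` grid
#' row-major into `n = P^2` tokens with their grid coordinates attached.
#' The center token sits at 0-based index `floor(n/2)` (R index
#' `floor(n/2) + 1`, the 25th of 49 tokens for P = 7).
#'
#' @param patch a [extract_patch()] result or bare `P x P x B` array.
#' @param model a model as returned by [init_params()].
#' @param mode `"eval"` (running batch-norm statistics) or `"train"`.
#' @return An object of class `token_sequence`: list with `X` (`n x d_emb`),
#'   `coords` (`n x 2`, 0-based `(x, y)` grid coordinates), `center_index`
#'   (1-based), `patch_size`.
#' @export
embed_patch <- function(patch, model, mode = "eval") {
  cfg <- model$cfg
  Pm <- patch_matrix(patch)
  if (ncol(Pm) != cfg$n_bands)
    stop_invalid("patch has ", ncol(Pm), " bands; model expects ",
                 cfg$n_bands)
  p <- model$params; st <- model$state
  pre <- addrow(Pm %*% p[["emb.W"]], p[["emb.b"]])
  bn <- bn_fwd(pre, p[["emb.gamma"]], p[["emb.beta"]],
               st$emb_mean, st$emb_var, mode)
  X <- bn$out * (bn$out > 0)
  if (cfg$pos_encoding == "ape") X <- X + p[["ape"]]
  structure(list(X = X, coords = token_coords(cfg$patch_size),
                 center_index = center_token(cfg),
                 patch_size = cfg$patch_size),
            class = "token_sequence")
}

#' Center-focused linear attention over one token sequence
#'
#' Computes the attention update of the center token: the query is formed
#' from the center token only, keys and values from all `n` tokens; rotary
#' position embedding is applied to query and keys; per head, scaled
#' dot-product scores over the `n` tokens are softmax-normalised and applied
#' to the values; head outputs are concatenated and output-projected. Cost
#' is linear in `n` (one query row), against the quadratic cost of full
#' self-attention.
#'
#' @param X a `token_sequence` (or bare `n x d_emb` matrix).
#' @param model a model from [init_params()].
#' @param layer encoder layer index whose weights to use.
#' @param return_weights also return the `k x n` per-head attention weights
#'   (each row sums to 1; reshape a row to `P x P` for a spatial map).
#' @return A list with `output` (length-`d_emb` attention result for the
#'   center token, after output projection) and, if requested, `weights`.
#' @export
cfla_attention <- function(X, model, layer = 1L, return_weights = FALSE) {
  r <- attention_single(X, model, layer, mode = "cfla",
                        return_weights = return_weights)
  list(output = r$center_out, weights = r$weights)
}

#' Full self-attention over one token sequence (ablation baseline)
#'
#' Standard multi-head self-attention: every token forms a query, giving an
#' `n x n` score matrix per head (each row softmax-normalised). With shared
#' weights, its center row reproduces the CFLA head outputs exactly.
#'
#' @inheritParams cfla_attention
#' @return A list with `output` (`n x d_emb` updated sequence after output
#'   projection) and, if requested, `weights` (`k x n` center-row weights).
#' @export
full_attention <- function(X, model, layer = 1L, return_weights = FALSE) {
  r <- attention_single(X, model, layer, mode = "full",
                        return_weights = return_weights)
  list(output = r$all_out, weights = r$weights)
}

# Shared single-sequence attention; X may be a token_sequence or matrix.
attention_single <- function(X, model, layer, mode, return_weights) {
  cfg <- model$cfg; p <- model$params
  Xm <- if (inherits(X, "token_sequence")) X$X else X
  n <- nrow(Xm); d <- ncol(Xm)
  k <- cfg$n_heads; dh <- cfg$d_head
  if (d != cfg$d_emb) stop_invalid("sequence width != d_emb")
  ps <- as.integer(round(sqrt(n)))
  coords <- if (inherits(X, "token_sequence")) X$coords
            else token_coords(ps)
  cidx <- (n %/% 2L) + 1L
  pwq <- layer_proj(p, layer, "q"); pwk <- layer_proj(p, layer, "k")
  pwv <- layer_proj(p, layer, "v"); pwo <- layer_proj(p, layer, "out")
  use_rope <- cfg$pos_encoding == "rope2d_mixed"
  K <- proj_fwd(Xm, pwk)$out
  V <- proj_fwd(Xm, pwv)$out
  tx <- p[[paste0("l", layer, ".theta_x")]]
  ty <- p[[paste0("l", layer, ".theta_y")]]
  if (use_rope) K <- apply_rope_mixed(K, coords, tx, ty)
  if (mode == "cfla") {
    q <- proj_fwd(Xm[cidx, , drop = FALSE], pwq)$out
    if (use_rope) q <- apply_rope_mixed(q, coords[cidx, ], tx, ty)
    W <- matrix(0, k, n)
    o <- numeric(d)
    for (h in seq_len(k)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      s <- drop(K[, cols, drop = FALSE] %*% q[1, cols]) / sqrt(dh)
      a <- drop(softmax_rows(rbind(s)))
      W[h, ] <- a
      o[cols] <- drop(a %*% V[, cols, drop = FALSE])
    }
    out <- drop(proj_fwd(rbind(o), pwo)$out)
    list(center_out = out, weights = if (return_weights) W else NULL)
  } else {
    Q <- proj_fwd(Xm, pwq)$out
    if (use_rope) Q <- apply_rope_mixed(Q, coords, tx, ty)
    O <- matrix(0, n, d)
    W <- matrix(0, k, n)
    for (h in seq_len(k)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) /
        sqrt(dh)
      A <- softmax_rows(S)
      W[h, ] <- A[cidx, ]
      O[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    out <- proj_fwd(O, pwo)$out
    list(all_out = out, weights = if (return_weights) W else NULL)
  }
}

#' Run the encoder stack over an embedded sequence
#'
#' Applies the `L` encoder layers. Each layer pre-normalises, attends,
#' adds the residual, pre-normalises again and applies the feed-forward
#' block; in CFLA mode the residual/FFN update touches the center token
#' only and the updated center embedding replaces the center entry of the
#' sequence passed to the next layer (all other tokens are left exactly as
#' they were). The context-aware center representation of every layer is
#' returned for aggregation.
#'
#' @param X a `token_sequence` from [embed_patch()].
#' @param model a model from [init_params()].
#' @return A list of `n_layers` center representations (each length
#'   `d_emb`), with the final sequence matrix as attribute `"sequence"`.
#' @export
encoder_forward <- function(X, model) {
  cfg <- model$cfg; p <- model$params
  Xm <- if (inherits(X, "token_sequence")) X$X else X
  n <- nrow(Xm)
  cidx <- (n %/% 2L) + 1L
  z_list <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pre_l <- paste0("l", l, ".")
    ln1 <- ln_fwd(Xm, p[[paste0(pre_l, "ln1.gamma")]],
                  p[[paste0(pre_l, "ln1.beta")]])
    seqX <- if (inherits(X, "token_sequence")) {
      tmp <- X; tmp$X <- ln1$out; tmp
    } else ln1$out
    if (cfg$attention_mode == "cfla") {
      att <- cfla_attention(seqX, model, layer = l)$output
      xc1 <- Xm[cidx, ] + att
      ln2 <- ln_fwd(rbind(xc1), p[[paste0(pre_l, "ln2.gamma")]],
                    p[[paste0(pre_l, "ln2.beta")]])
      h1 <- drop(ln2$out %*% p[[paste0(pre_l, "ffn.W1")]]) +
        p[[paste0(pre_l, "ffn.b1")]]
      z <- xc1 + drop(relu(h1) %*% p[[paste0(pre_l, "ffn.W2")]]) +
        p[[paste0(pre_l, "ffn.b2")]]
      Xm[cidx, ] <- z
    } else {
      att <- full_attention(seqX, model, layer = l)$output
      X1 <- Xm + att
      ln2 <- ln_fwd(X1, p[[paste0(pre_l, "ln2.gamma")]],
                    p[[paste0(pre_l, "ln2.beta")]])
      h1 <- addrow(ln2$out %*% p[[paste0(pre_l, "ffn.W1")]],
                   p[[paste0(pre_l, "ffn.b1")]])
      Xm <- X1 + addrow(relu(h1) %*% p[[paste0(pre_l, "ffn.W2")]],
                        p[[paste0(pre_l, "ffn.b2")]])
      z <- Xm[cidx, ]
    }
    z_list[[l]] <- z
  }
  attr(z_list, "sequence") <- Xm
  z_list
}

#' Aggregate per-layer center representations
#'
#' Learnable weighted sum `zF = sum_l w[l] * z[l]` over the encoder layers'
#' center-token outputs; the weights are unconstrained scalars.
#'
#' @param z_list list of equal-length numeric vectors.
#' @param w numeric weights, one per layer.
#' @return The aggregated vector.
#' @export
aggregate_layers <- function(z_list, w) {
  if (length(z_list) != length(w))
    stop_invalid("need one aggregation weight per layer")
  out <- z_list[[1]] * w[1]
  for (l in seq_along(z_list)[-1]) out <- out + w[l] * z_list[[l]]
  out
}

#' Classify an aggregated center representation
#'
#' Two-layer MLP head: Linear -> Dropout -> BatchNorm -> ReLU -> Linear.
#' Dropout is active only in `"train"` mode, so eval-mode calls are
#' deterministic.
#'
#' @param z numeric vector of length `d_emb` (or matrix of rows).
#' @param model a model from [init_params()].
#' @param mode `"eval"` or `"train"`.
#' @return Logits: a length-`n_classes` vector (or matrix of rows).
#' @export
classify <- function(z, model, mode = "eval") {
  cfg <- model$cfg; p <- model$params; st <- model$state
  Z <- rbind(z)
  c1 <- addrow(Z %*% p[["cls.W1"]], p[["cls.b1"]])
  if (mode == "train" && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    c1 <- c1 * matrix((stats::runif(length(c1)) < keep) / keep,
                      nrow(c1), ncol(c1))
  }
  bn <- bn_fwd(c1, p[["cls.gamma"]], p[["cls.beta"]],
               st$cls_mean, st$cls_var, mode)
  cr <- bn$out * (bn$out > 0)
  out <- addrow(cr %*% p[["cls.W2"]], p[["cls.b2"]])
  if (is.null(dim(z))) drop(out) else out
}

#' Forward pass: patch to class logits
#'
#' Composition of [embed_patch()], [encoder_forward()],
#' [aggregate_layers()] and [classify()]; deterministic in eval mode.
#'
#' @param patch a `patch_cube` or `P x P x B` array.
#' @param model a model from [init_params()].
#' @param mode `"eval"` or `"train"`.
#' @return Length-`n_classes` logit vector.
#' @export
sst_forward <- function(patch, model, mode = "eval") {
  Pm <- patch_matrix(patch)
  r <- sst_forward_batch(Pm, model, mode = mode)
  drop(r$logits)
}

#' Attention maps for one patch
#'
#' Per-head center-query attention weights of a given encoder layer,
#' reshaped to the patch grid — the map visualised when inspecting what
#' spatial context the model aggregates into the center pixel.
#'
#' @param patch a `patch_cube` or array.
#' @param model a model from [init_params()].
#' @param layer encoder layer to inspect (default 2).
#' @return A `P x P x n_heads` array of attention weights (each head slice
#'   sums to 1).
#' @export
sst_attention_maps <- function(patch, model, layer = 2L) {
  cfg <- model$cfg
  Pm <- patch_matrix(patch)
  r <- sst_forward_batch(Pm, model, mode = "eval", return_attention = TRUE)
  A <- r$attention[[layer]]           # 1 x k x n
  P <- cfg$patch_size
  out <- array(0, c(P, P, cfg$n_heads))
  for (h in seq_len(cfg$n_heads))
    out[, , h] <- matrix(A[1, h, ], P, P, byrow = TRUE)
  out
}
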