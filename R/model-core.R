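# Batched forward pass of the spatial-spectral transformer.
#
# Throughout, a batch of Nb token sequences of length n lives in a
# (Nb*n) x d matrix whose row (b + (t-1)*Nb) holds token t of batch item b
# ("batch-fastest" layout); this lets every linear map run as one BLAS
# matrix product. The center-token rows of such a matrix are the contiguous
# index block ((c-1)*Nb + 1) : (c*Nb). Element-wise work (normalisation,
# rotations, attention mixing) is fused in the C++ kernels of
# src/kernels.cpp; everything else is plain BLAS.

addrow <- function(M, v) add_bias_cpp(M, v)
mulrow <- function(M, v) M * rep(v, each = nrow(M))

# token-wise normalisation (layer norm over the embedding dimension)
ln_fwd <- function(X, g, b, eps = 1e-5) ln_fwd_cpp(X, g, b, eps)

ln_bwd <- function(dout, cache, g) ln_bwd_cpp(dout, cache$xhat, cache$inv, g)

# feature-wise batch normalisation over the rows of a matrix
bn_fwd <- function(X, g, b, run_mean, run_var, mode, momentum = 0.1,
                   eps = 1e-5) {
  if (mode == "train") {
    r <- bn_fwd_train_cpp(X, g, b, eps)
    nr <- nrow(X)
    unbias <- if (nr > 1L) nr / (nr - 1L) else 1
    list(out = r$out, xhat = r$xhat, inv = r$inv,
         run_mean = (1 - momentum) * run_mean + momentum * r$mu,
         run_var = (1 - momentum) * run_var + momentum * r$var * unbias)
  } else {
    r <- bn_fwd_eval_cpp(X, g, b, run_mean, run_var, eps)
    list(out = r$out, xhat = r$xhat, inv = r$inv,
         run_mean = run_mean, run_var = run_var)
  }
}

bn_bwd <- function(dout, cache, g) bn_bwd_cpp(dout, cache$xhat, cache$inv, g)

#' Apply a (possibly factorized) projection
#'
#' Full-rank path: `x %*% W + b`. Factorized (LRP) path:
#' `x %*% W1 %*% W2 + b`, identical to multiplying by the composed rank-
#' limited matrix `W1 %*% W2`; at the reference dimensions (128 x 128 at
#' rank 32) the factors hold half the weight entries of the full matrix.
#'
#' @param x numeric vector or matrix (rows = tokens) with `d_emb` columns.
#' @param pw projection weights: either `list(W, b)` or `list(W1, W2, b)`
#'   in right-multiplication orientation (see [init_params()]).
#' @return Matrix of the same row count in `d_emb` columns (a vector input
#'   returns a 1-row matrix).
#' @export
project <- function(x, pw) {
  x <- rbind(x)
  proj_fwd(x, pw)$out
}

proj_fwd <- function(X, pw) {
  if (!is.null(pw$W)) {
    if (ncol(X) != nrow(pw$W)) stop_invalid("projection input width mismatch")
    list(out = addrow(X %*% pw$W, pw$b), H1 = NULL)
  } else {
    if (ncol(X) != nrow(pw$W1)) stop_invalid("projection input width mismatch")
    H1 <- X %*% pw$W1
    list(out = addrow(H1 %*% pw$W2, pw$b), H1 = H1)
  }
}

# Returns list(dX, grads = named list relative to the role prefix)
proj_bwd <- function(dY, X, fwd, pw) {
  if (!is.null(pw$W)) {
    list(dX = tcrossprod(dY, pw$W),
         grads = list(W = crossprod(X, dY), b = colSums(dY)))
  } else {
    dH1 <- tcrossprod(dY, pw$W2)
    list(dX = tcrossprod(dH1, pw$W1),
         grads = list(W1 = crossprod(X, dH1),
                      W2 = crossprod(fwd$H1, dY), b = colSums(dY)))
  }
}

# head indicator matrix (d x k): column h selects the dims of head h
head_indicator <- function(d, k) {
  dh <- d %/% k
  m <- matrix(0, d, k)
  for (h in seq_len(k)) m[(h - 1L) * dh + seq_len(dh), h] <- 1
  m
}

# --- full forward pass -------------------------------------------------------

# Pmat: (Nb*n) x B spectral matrix in batch-fastest layout.
# model: list(params, state, cfg). mode: "train" or "eval".
# Returns logits, per-layer center representations, updated BN state, and
# (optionally) caches for backward and per-layer attention weights.
sst_forward_batch <- function(Pmat, model, mode = c("eval", "train"),
                              keep_cache = FALSE, return_attention = FALSE,
                              dropout_mask = NULL) {
  mode <- match.arg(mode)
  cfg <- model$cfg; p <- model$params; st <- model$state
  n <- cfg$n_tokens; d <- cfg$d_emb
  if (ncol(Pmat) != cfg$n_bands)
    stop_invalid("patch band count ", ncol(Pmat), " != configured ",
                 cfg$n_bands)
  Nb <- nrow(Pmat) %/% n
  stopifnot(Nb * n == nrow(Pmat))
  cidx <- center_token(cfg)
  idx_c <- (cidx - 1L) * Nb + seq_len(Nb)
  tok_of_row <- rep(seq_len(n), each = Nb)
  coords <- token_coords(cfg$patch_size)
  cache <- if (keep_cache) list() else NULL

  # (1) spectral embedding: 1x1 conv + batch norm + ReLU
  pre <- addrow(Pmat %*% p[["emb.W"]], p[["emb.b"]])
  bn <- bn_fwd(pre, p[["emb.gamma"]], p[["emb.beta"]],
               st$emb_mean, st$emb_var, mode)
  st$emb_mean <- bn$run_mean; st$emb_var <- bn$run_var
  act <- relu_cpp(bn$out)
  X <- if (cfg$pos_encoding == "ape")
    act + p[["ape"]][tok_of_row, , drop = FALSE] else act
  if (keep_cache)
    cache$emb <- list(Pmat = Pmat, bn = bn[c("xhat", "inv")], act = act)

  # (2) encoder layers
  use_rope <- cfg$pos_encoding == "rope2d_mixed"
  k <- cfg$n_heads; dh <- cfg$d_head
  z_list <- vector("list", cfg$n_layers)
  att_maps <- if (return_attention) vector("list", cfg$n_layers) else NULL

  for (l in seq_len(cfg$n_layers)) {
    pre_l <- paste0("l", l, ".")
    ln1 <- ln_fwd(X, p[[paste0(pre_l, "ln1.gamma")]],
                  p[[paste0(pre_l, "ln1.beta")]])
    pwq <- layer_proj(p, l, "q"); pwk <- layer_proj(p, l, "k")
    pwv <- layer_proj(p, l, "v"); pwo <- layer_proj(p, l, "out")

    Kp <- proj_fwd(ln1$out, pwk)
    Vp <- proj_fwd(ln1$out, pwv)
    if (use_rope) {
      tx <- p[[paste0(pre_l, "theta_x")]]; ty <- p[[paste0(pre_l, "theta_y")]]
      Phi <- rope_phases(coords, tx, ty)             # n x d/2
      Ck <- cos(Phi)[tok_of_row, , drop = FALSE]
      Sk <- sin(Phi)[tok_of_row, , drop = FALSE]
      Krot <- rope_rot_cpp(Kp$out, Ck, Sk, FALSE)
    } else Krot <- Kp$out

    if (cfg$attention_mode == "cfla") {
      Xc <- ln1$out[idx_c, , drop = FALSE]
      qp <- proj_fwd(Xc, pwq)
      if (use_rope) {
        phic <- Phi[cidx, ]
        Cq <- matrix(cos(phic), Nb, d %/% 2L, byrow = TRUE)
        Sq <- matrix(sin(phic), Nb, d %/% 2L, byrow = TRUE)
        qrot <- rope_rot_cpp(qp$out, Cq, Sq, FALSE)
      } else qrot <- qp$out
      scores <- head_scores_cpp(Krot, qrot, Nb, k) / sqrt(dh)  # (Nb*n) x k
      Aflat <- token_softmax_cpp(scores, Nb)
      o <- value_mix_cpp(Aflat, Vp$out, Nb)                    # Nb x d
      op <- proj_fwd(o, pwo)
      xc1 <- X[idx_c, , drop = FALSE] + op$out
      ln2 <- ln_fwd(xc1, p[[paste0(pre_l, "ln2.gamma")]],
                    p[[paste0(pre_l, "ln2.beta")]])
      h1 <- addrow(ln2$out %*% p[[paste0(pre_l, "ffn.W1")]],
                   p[[paste0(pre_l, "ffn.b1")]])
      hr <- relu_cpp(h1)
      z <- xc1 + addrow(hr %*% p[[paste0(pre_l, "ffn.W2")]],
                        p[[paste0(pre_l, "ffn.b2")]])
      X[idx_c, ] <- z
      if (return_attention)
        att_maps[[l]] <- aperm(array(Aflat, c(Nb, n, k)), c(1L, 3L, 2L))
      if (keep_cache) {
        lc <- list(ln1 = ln1[c("xhat", "inv")], Xn = ln1$out, Xc = Xc,
                   Kp = Kp["H1"], Vp = Vp["H1"], qp = qp["H1"],
                   Krot = Krot, Vout = Vp$out, qrot = qrot,
                   Aflat = Aflat, o = o, op = op["H1"],
                   ln2 = ln2[c("xhat", "inv")], ln2out = ln2$out, hr = hr)
        if (use_rope) lc$rope <- list(Ck = Ck, Sk = Sk, Phi = Phi)
        cache[[paste0("layer", l)]] <- lc
      }
    } else {  # full self-attention baseline
      Qp <- proj_fwd(ln1$out, pwq)
      Qrot <- if (use_rope) rope_rot_cpp(Qp$out, Ck, Sk, FALSE) else Qp$out
      O <- matrix(0, Nb * n, d)
      Aall <- array(0, c(n, n, Nb, k))
      for (h in seq_len(k)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        for (b in seq_len(Nb)) {
          rows <- b + (seq_len(n) - 1L) * Nb
          S <- tcrossprod(Qrot[rows, cols, drop = FALSE],
                          Krot[rows, cols, drop = FALSE]) / sqrt(dh)
          Ab <- softmax_rows(S)
          Aall[, , b, h] <- Ab
          O[rows, cols] <- Ab %*% Vp$out[rows, cols, drop = FALSE]
        }
      }
      op <- proj_fwd(O, pwo)
      X1 <- X + op$out
      ln2 <- ln_fwd(X1, p[[paste0(pre_l, "ln2.gamma")]],
                    p[[paste0(pre_l, "ln2.beta")]])
      h1 <- addrow(ln2$out %*% p[[paste0(pre_l, "ffn.W1")]],
                   p[[paste0(pre_l, "ffn.b1")]])
      hr <- relu_cpp(h1)
      X <- X1 + addrow(hr %*% p[[paste0(pre_l, "ffn.W2")]],
                       p[[paste0(pre_l, "ffn.b2")]])
      z <- X[idx_c, , drop = FALSE]
      if (return_attention)
        att_maps[[l]] <- aperm(Aall[cidx, , , , drop = TRUE], c(2L, 3L, 1L))
      if (keep_cache) {
        lc <- list(ln1 = ln1[c("xhat", "inv")], Xn = ln1$out,
                   Kp = Kp["H1"], Vp = Vp["H1"], Qp = Qp["H1"],
                   Krot = Krot, Vout = Vp$out, Qrot = Qrot,
                   Aall = Aall, O = O, op = op["H1"], X1 = X1,
                   ln2 = ln2[c("xhat", "inv")], ln2out = ln2$out, hr = hr)
        if (use_rope) lc$rope <- list(Ck = Ck, Sk = Sk, Phi = Phi)
        cache[[paste0("layer", l)]] <- lc
      }
    }
    z_list[[l]] <- z
  }

  # (3) layer aggregation
  w <- p[["agg.w"]]
  zF <- w[1] * z_list[[1]]
  for (l in seq_len(cfg$n_layers)[-1]) zF <- zF + w[l] * z_list[[l]]

  # (4) classifier: Linear -> Dropout -> BN -> ReLU -> Linear
  c1 <- addrow(zF %*% p[["cls.W1"]], p[["cls.b1"]])
  if (mode == "train" && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    if (is.null(dropout_mask))
      dropout_mask <- matrix((stats::runif(length(c1)) < keep) / keep,
                             nrow(c1), ncol(c1))
    cd <- c1 * dropout_mask
  } else {
    dropout_mask <- NULL
    cd <- c1
  }
  bn2 <- bn_fwd(cd, p[["cls.gamma"]], p[["cls.beta"]],
                st$cls_mean, st$cls_var, mode)
  st$cls_mean <- bn2$run_mean; st$cls_var <- bn2$run_var
  cr <- relu_cpp(bn2$out)
  logits <- addrow(cr %*% p[["cls.W2"]], p[["cls.b2"]])

  if (keep_cache)
    cache$head <- list(z_list = z_list, zF = zF, c1 = c1,
                       dropout_mask = dropout_mask,
                       bn = bn2[c("xhat", "inv")], cr = cr, Nb = Nb)
  list(logits = logits, z_list = z_list, state = st, cache = cache,
       attention = att_maps)
}
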