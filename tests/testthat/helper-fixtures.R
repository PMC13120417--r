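# Shared fixtures and independent oracles, built in code at test time.

# A small model configuration that keeps forward/backward tests fast.
tiny_cfg <- function(...) {
  defaults <- list(patch_size = 3L, n_bands = 6L, d_emb = 8L, n_heads = 2L,
                   d_bottleneck = 3L, n_layers = 2L, ffn_hidden = 10L,
                   classifier_hidden = 7L, n_classes = 4L, dropout = 0.1)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# A small scene: 13 classes, one 5x5 region each, 25 bands.
small_scene_spec <- function(seed = 7L, margin = 1L, noise_sd = 1.0,
                             n_regions = 1L, region_size = 5L) {
  scene_spec(height = 96L, width = 96L, n_bands = 25L,
             n_regions_per_class = n_regions, region_size = region_size,
             fillet = c(9L, 9L, 88L, 88L), margin = margin,
             noise_sd = noise_sd, seed = seed)
}

# Render a small scene with a separation floor scaled to its band count
# (the default floor is calibrated for the 171-band working grid).
render_small <- function(spec, ...) render_scene(spec, min_separation = 15, ...)

# Independent multi-head self-attention oracle: plain loops over heads and
# tokens, softmax over keys, optional rotary rotation via apply_rope_mixed.
naive_full_attention <- function(X, coords, model, layer) {
  cfg <- model$cfg; p <- model$params
  n <- nrow(X); d <- cfg$d_emb; k <- cfg$n_heads; dh <- cfg$d_head
  getw <- function(nm) {
    pre <- paste0("l", layer, ".", nm, ".")
    if (!is.null(p[[paste0(pre, "W")]]))
      list(M = p[[paste0(pre, "W")]], b = p[[paste0(pre, "b")]])
    else
      list(M = p[[paste0(pre, "W1")]] %*% p[[paste0(pre, "W2")]],
           b = p[[paste0(pre, "b")]])
  }
  wq <- getw("q"); wk <- getw("k"); wv <- getw("v"); wo <- getw("out")
  Q <- sweep(X %*% wq$M, 2, wq$b, "+")
  K <- sweep(X %*% wk$M, 2, wk$b, "+")
  V <- sweep(X %*% wv$M, 2, wv$b, "+")
  if (cfg$pos_encoding == "rope2d_mixed") {
    tx <- p[[paste0("l", layer, ".theta_x")]]
    ty <- p[[paste0("l", layer, ".theta_y")]]
    Q <- apply_rope_mixed(Q, coords, tx, ty)
    K <- apply_rope_mixed(K, coords, tx, ty)
  }
  O <- matrix(0, n, d)
  for (h in seq_len(k)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    for (i in seq_len(n)) {
      s <- numeric(n)
      for (j in seq_len(n)) s[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dh)
      a <- exp(s - max(s)); a <- a / sum(a)
      O[i, cols] <- colSums(a * V[, cols, drop = FALSE])
    }
  }
  sweep(O %*% wo$M, 2, wo$b, "+")
}

# Loop-based per-pixel embedding oracle: linear map over bands, batch norm
# with the given statistics, rectifier.
naive_embed <- function(patch_arr, model) {
  p <- model$params; st <- model$state; cfg <- model$cfg
  P <- dim(patch_arr)[1]; B <- dim(patch_arr)[3]; d <- cfg$d_emb
  out <- matrix(0, P * P, d)
  for (r in seq_len(P)) for (cc in seq_len(P)) {
    x <- drop(patch_arr[r, cc, ]) %*% p[["emb.W"]] + p[["emb.b"]]
    xhat <- (x - st$emb_mean) / sqrt(st$emb_var + 1e-5)
    y <- xhat * p[["emb.gamma"]] + p[["emb.beta"]]
    out[(r - 1L) * P + cc, ] <- pmax(y, 0)
  }
  out
}

# A separable two-material cube for learnability smoke tests: left half
# spectrum A, right half spectrum B, plus noise; boundary column unlabeled.
two_class_cube <- function(h = 20L, w = 20L, bands = 6L, seed = 5L) {
  set.seed(seed)
  lamA <- seq(20, 70, length.out = bands)
  lamB <- seq(80, 30, length.out = bands)
  arr <- array(0, c(h, w, bands))
  mask <- matrix(0L, h, w)
  half <- w %/% 2L
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    base <- if (cc <= half) lamA else lamB
    arr[r, cc, ] <- base + rnorm(bands)
    if (abs(cc - half) > 1L) mask[r, cc] <- if (cc <= half) 1L else 2L
  }
  list(cube = hsi_cube(arr, seq(1000, 1100, length.out = bands),
                       "reflectance"),
       mask = label_mask(mask, n_classes = 2L))
}
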