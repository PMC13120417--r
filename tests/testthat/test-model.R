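test_that("model configuration validates its invariants", {
  expect_s3_class(model_config(), "model_config")
  expect_error(model_config(d_emb = 100, n_heads = 8),
               class = "sstfpo_configuration_error")
  expect_error(model_config(patch_size = 4),
               class = "sstfpo_configuration_error")
  expect_error(model_config(d_bottleneck = 256, d_emb = 128),
               class = "sstfpo_configuration_error")
  cfg <- model_config()
  expect_equal(cfg$n_tokens, 49L)
  expect_equal(sstfpo:::center_token(cfg), 25L)   # 0-based floor(49/2) = 24
  expect_equal(cfg$d_head, 16L)
})

test_that("patch embedding matches a per-pixel linear-map oracle", {
  cfg <- tiny_cfg()
  model <- init_params(cfg, seed = 2)
  patch <- array(runif(3 * 3 * 6, 0, 100), c(3, 3, 6))
  ts <- embed_patch(patch, model, mode = "eval")
  expect_equal(dim(ts$X), c(9L, 8L))
  expect_equal(ts$center_index, 5L)
  expect_equal(ts$coords[5L, ], c(x = 1L, y = 1L))
  expect_equal(ts$X, naive_embed(patch, model), tolerance = 1e-6)

  # reference dimensions give the documented sequence shape
  big <- init_params(model_config(), seed = 1)
  tb <- embed_patch(array(0, c(7, 7, 171)), big)
  expect_equal(dim(tb$X), c(49L, 128L))
  # zero patch, unit statistics: rectifier of beta-shifted zeros
  expect_true(all(tb$X >= 0))

  expect_error(embed_patch(array(0, c(3, 3, 5)), model),
               class = "sstfpo_invalid_argument")
})

test_that("factorized projections equal their composed full-rank map", {
  set.seed(3)
  d <- 128L; r <- 32L
  W1 <- matrix(rnorm(d * r), d, r); W2 <- matrix(rnorm(r * d), r, d)
  b <- rnorm(d)
  X <- matrix(rnorm(5 * d), 5, d)
  got <- project(X, list(W1 = W1, W2 = W2, b = b))
  want <- sweep(X %*% (W1 %*% W2), 2, b, "+")
  expect_equal(got, want, tolerance = 1e-6)
  expect_lte(qr(W1 %*% W2)$rank, r)

  # orthogonal selector factors: identity on the retained subspace
  S <- cbind(diag(r), matrix(0, r, d - r))    # selects first r coords
  x <- c(1, rep(0, d - 1))
  out <- project(x, list(W1 = t(S), W2 = S, b = rep(0, d)))
  expect_equal(drop(out), x)

  expect_error(project(matrix(0, 2, 64), list(W1 = W1, W2 = W2, b = b)),
               class = "sstfpo_invalid_argument")
})

test_that("rotary embedding is an isometry with relative-position scores", {
  set.seed(4)
  d <- 16L; np <- d / 2L
  coords <- sstfpo:::token_coords(3L)
  X <- matrix(rnorm(9 * d), 9, d)
  tx <- runif(np, 0, pi); ty <- runif(np, 0, pi)

  # zero frequencies: identity
  expect_equal(apply_rope_mixed(X, coords, rep(0, np), rep(0, np)), X)

  # per-pair norms preserved
  R <- apply_rope_mixed(X, coords, tx, ty)
  odd <- seq(1, d, 2)
  expect_equal(X[, odd]^2 + X[, odd + 1]^2, R[, odd]^2 + R[, odd + 1]^2,
               tolerance = 1e-9)

  # center-vs-token scores depend only on the coordinate offset: rigid
  # translation of the grid leaves every q.k score unchanged
  q <- matrix(rnorm(d), 1, d)
  score <- function(shift) {
    co <- sweep(coords, 2, -shift)
    qr_ <- apply_rope_mixed(q, co[5L, ], tx, ty)
    Kr <- apply_rope_mixed(X, co, tx, ty)
    drop(Kr %*% t(qr_))
  }
  expect_equal(score(c(0, 0)), score(c(5, 3)), tolerance = 1e-9)

  expect_error(apply_rope_mixed(matrix(0, 2, 7), coords[1:2, ],
                                rep(0, 3), rep(0, 3)),
               class = "sstfpo_configuration_error")
})

test_that("CFLA equals the center row of a naive full-attention oracle", {
  for (P in c(3L, 5L)) {
    cfg <- model_config(patch_size = P, n_bands = 6L, d_emb = 8L,
                        n_heads = 2L, d_bottleneck = 3L, n_layers = 1L,
                        ffn_hidden = 8L, classifier_hidden = 6L,
                        n_classes = 3L, use_lrp = (P == 3L))
    model <- init_params(cfg, seed = P)
    n <- P^2
    X <- matrix(rnorm(n * 8), n, 8)
    coords <- sstfpo:::token_coords(P)
    want <- naive_full_attention(X, coords, model, layer = 1L)
    got_c <- cfla_attention(X, model, layer = 1L, return_weights = TRUE)
    got_f <- full_attention(X, model, layer = 1L)
    cidx <- n %/% 2L + 1L
    expect_equal(got_c$output, want[cidx, ], tolerance = 1e-6)
    expect_equal(got_f$output, want, tolerance = 1e-6)
    # per-head attention weights normalise over the patch
    expect_equal(rowSums(got_c$weights), rep(1, 2), tolerance = 1e-6)
  }
})

test_that("identical tokens attract uniform attention", {
  cfg <- tiny_cfg(n_layers = 1L, dropout = 0)
  model <- init_params(cfg, seed = 6)
  model$params[["l1.theta_x"]][] <- 0
  model$params[["l1.theta_y"]][] <- 0
  X <- matrix(rep(rnorm(8), each = 9), 9, 8)
  w <- cfla_attention(X, model, return_weights = TRUE)$weights
  expect_equal(w, matrix(1 / 9, 2, 9), tolerance = 1e-9)
})

test_that("a single-token sequence reduces to its projected value", {
  cfg <- model_config(patch_size = 1L, n_bands = 6L, d_emb = 8L,
                      n_heads = 2L, d_bottleneck = 3L, n_layers = 1L,
                      ffn_hidden = 8L, classifier_hidden = 6L,
                      n_classes = 3L, attention_mode = "full",
                      pos_encoding = "none")
  model <- init_params(cfg, seed = 8)
  x <- matrix(rnorm(8), 1, 8)
  out <- full_attention(x, model)$output
  v <- project(x, sstfpo:::layer_proj(model$params, 1, "v"))
  want <- project(v, sstfpo:::layer_proj(model$params, 1, "out"))
  expect_equal(out, want, tolerance = 1e-9)
})

test_that("encoder updates only the center token and returns L outputs", {
  cfg <- tiny_cfg(n_layers = 2L)
  model <- init_params(cfg, seed = 9)
  patch <- array(runif(3 * 3 * 6, 0, 100), c(3, 3, 6))
  ts <- embed_patch(patch, model)
  zl <- encoder_forward(ts, model)
  expect_length(zl, 2L)
  expect_length(zl[[1]], 8L)
  final_seq <- attr(zl, "sequence")
  expect_identical(final_seq[-5L, ], ts$X[-5L, ])   # update locality
  expect_identical(final_seq[5L, ], zl[[2]])

  # zero attention output + zero FFN second layer: residual passthrough
  m0 <- model
  for (l in 1:2) {
    m0$params[[paste0("l", l, ".out.W1")]][] <- 0
    m0$params[[paste0("l", l, ".out.b")]][] <- 0
    m0$params[[paste0("l", l, ".ffn.W2")]][] <- 0
    m0$params[[paste0("l", l, ".ffn.b2")]][] <- 0
  }
  z0 <- encoder_forward(ts, m0)
  expect_equal(z0[[1]], ts$X[5L, ])
  expect_equal(z0[[2]], ts$X[5L, ])
})

test_that("layer aggregation is the expected weighted sum", {
  z <- list(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(aggregate_layers(z, c(1, 0, 0)), c(1, 2))
  v <- c(7, 8)
  expect_equal(aggregate_layers(list(v, v, v), rep(1 / 3, 3)), v)
  set.seed(10)
  zr <- lapply(1:3, function(i) rnorm(4)); w <- rnorm(3)
  want <- w[1] * zr[[1]] + w[2] * zr[[2]] + w[3] * zr[[3]]
  expect_equal(aggregate_layers(zr, w), want, tolerance = 1e-7)
  expect_error(aggregate_layers(zr, c(1, 2)), class = "sstfpo_invalid_argument")
})

test_that("the classifier head has the documented shape and determinism", {
  model <- init_params(model_config(), seed = 11)
  z <- rnorm(128)
  lg <- classify(z, model)
  expect_length(lg, 13L)
  expect_identical(classify(z, model), lg)    # eval mode: no dropout noise

  m0 <- model
  m0$params[["cls.W1"]][] <- 0; m0$params[["cls.b1"]][] <- 0
  m0$params[["cls.W2"]][] <- 0
  expect_equal(classify(z, m0), m0$params[["cls.b2"]])
})

test_that("full forward is deterministic and position-sensitive", {
  cfg <- tiny_cfg(n_layers = 1L)
  model <- init_params(cfg, seed = 12)
  patch <- array(runif(3 * 3 * 6, 0, 100), c(3, 3, 6))
  l1 <- sst_forward(patch, model)
  expect_length(l1, 4L)
  expect_identical(sst_forward(patch, model), l1)

  # permute the 8 non-center pixels of the patch
  perm <- c(2, 3, 6, 1, 8, 4, 7, 5)
  idx <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 1), c(2, 3),
               c(3, 1), c(3, 2), c(3, 3))
  patch2 <- patch
  for (i in seq_len(8)) patch2[idx[i, 1], idx[i, 2], ] <-
    patch[idx[perm[i], 1], idx[perm[i], 2], ]

  # with zero frequencies attention is permutation-invariant ...
  m0 <- model
  m0$params[["l1.theta_x"]][] <- 0; m0$params[["l1.theta_y"]][] <- 0
  expect_equal(sst_forward(patch2, m0), sst_forward(patch, m0),
               tolerance = 1e-9)
  # ... with rotary frequencies the logits move
  expect_gt(max(abs(sst_forward(patch2, model) - l1)), 1e-6)
})

test_that("attention maps reshape to the patch grid and normalise", {
  cfg <- tiny_cfg(n_layers = 2L, dropout = 0)
  model <- init_params(cfg, seed = 13)
  patch <- array(runif(3 * 3 * 6, 0, 100), c(3, 3, 6))
  maps <- sst_attention_maps(patch, model, layer = 2L)
  expect_equal(dim(maps), c(3L, 3L, 2L))
  expect_equal(apply(maps, 3, sum), rep(1, 2), tolerance = 1e-6)
})
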