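#' Initialise model parameters
#'
#' Returns the trainable weights as a flat named list of numeric arrays
#' (names like `"l2.q.W1"`), plus the non-trainable batch-norm running
#' statistics as a separate `state` list. Linear and convolution weights and
#' biases use uniform fan-in scaling `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`;
#' normalisation scales start at 1 and shifts at 0; layer aggregation weights
#' start at `1/L`; rotary frequencies start at a geometric ladder
#' `theta[j] = (pi/2) * 0.5^j` per head (identical for both axes), spanning
#' one full rotation across the +/-3-pixel offset range of a 7x7 patch
#' before training adapts them.
#'
#' Projection factor orientation: matrices are stored for right-multiplication
#' of row-token matrices, i.e. `W1` is `d_emb x d_bottleneck`, `W2` is
#' `d_bottleneck x d_emb`, and a token `x` maps to `x %*% W1 %*% W2 + b`
#' (mathematically the composed map `W2 W1 x` on column vectors).
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the draws.
#' @return A list with `params` (flat named list of trainable arrays),
#'   `state` (running batch-norm statistics), and `cfg`.
#' @export
init_params <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  d <- cfg$d_emb
  with_seed(seed, {
    p <- list()
    lin <- function(fan_in, nr, nc = NULL) {
      s <- 1 / sqrt(fan_in)
      if (is.null(nc)) stats::runif(nr, -s, s)
      else matrix(stats::runif(nr * nc, -s, s), nr, nc)
    }
    # spectral embedding: 1x1 conv over bands + batch norm scale/shift
    p[["emb.W"]] <- lin(cfg$n_bands, cfg$n_bands, d)
    p[["emb.b"]] <- lin(cfg$n_bands, d)
    p[["emb.gamma"]] <- rep(1, d)
    p[["emb.beta"]] <- rep(0, d)
    if (cfg$pos_encoding == "ape")
      p[["ape"]] <- matrix(stats::rnorm(cfg$n_tokens * d, sd = 0.02),
                           cfg$n_tokens, d)
    theta0 <- rep((pi / 2) * 0.5^(seq_len(cfg$d_head %/% 2L) - 1L),
                  times = cfg$n_heads)
    for (l in seq_len(cfg$n_layers)) {
      pre <- paste0("l", l, ".")
      for (nm in c("q", "k", "v", "out")) {
        if (cfg$use_lrp) {
          p[[paste0(pre, nm, ".W1")]] <- lin(d, d, cfg$d_bottleneck)
          p[[paste0(pre, nm, ".W2")]] <- lin(cfg$d_bottleneck,
                                             cfg$d_bottleneck, d)
        } else {
          p[[paste0(pre, nm, ".W")]] <- lin(d, d, d)
        }
        p[[paste0(pre, nm, ".b")]] <- lin(d, d)
      }
      if (cfg$pos_encoding == "rope2d_mixed") {
        p[[paste0(pre, "theta_x")]] <- theta0
        p[[paste0(pre, "theta_y")]] <- theta0
      }
      p[[paste0(pre, "ln1.gamma")]] <- rep(1, d)
      p[[paste0(pre, "ln1.beta")]] <- rep(0, d)
      p[[paste0(pre, "ln2.gamma")]] <- rep(1, d)
      p[[paste0(pre, "ln2.beta")]] <- rep(0, d)
      p[[paste0(pre, "ffn.W1")]] <- lin(d, d, cfg$ffn_hidden)
      p[[paste0(pre, "ffn.b1")]] <- lin(d, cfg$ffn_hidden)
      p[[paste0(pre, "ffn.W2")]] <- lin(cfg$ffn_hidden, cfg$ffn_hidden, d)
      p[[paste0(pre, "ffn.b2")]] <- lin(cfg$ffn_hidden, d)
    }
    p[["agg.w"]] <- rep(1 / cfg$n_layers, cfg$n_layers)
    p[["cls.W1"]] <- lin(d, d, cfg$classifier_hidden)
    p[["cls.b1"]] <- lin(d, cfg$classifier_hidden)
    p[["cls.gamma"]] <- rep(1, cfg$classifier_hidden)
    p[["cls.beta"]] <- rep(0, cfg$classifier_hidden)
    p[["cls.W2"]] <- lin(cfg$classifier_hidden, cfg$classifier_hidden,
                         cfg$n_classes)
    p[["cls.b2"]] <- lin(cfg$classifier_hidden, cfg$n_classes)
    list(params = p, state = init_bn_state(cfg), cfg = cfg)
  })
}

init_bn_state <- function(cfg) {
  list(emb_mean = rep(0, cfg$d_emb), emb_var = rep(1, cfg$d_emb),
       cls_mean = rep(0, cfg$classifier_hidden),
       cls_var = rep(1, cfg$classifier_hidden))
}

#' Count the weights held in an instantiated parameter set
#'
#' Exhaustive enumeration over the flat parameter list; the closed-form
#' [count_params()] must agree exactly for every configuration.
#'
#' @param model output of [init_params()] (or its `params` element).
#' @return Integer total of trainable scalar weights.
#' @export
enumerate_params <- function(model) {
  p <- if (!is.null(model$params)) model$params else model
  sum(vapply(p, length, integer(1)))
}

# Projection weights for layer l and role nm, as a list the projection
# forward/backward understands.
layer_proj <- function(params, l, nm) {
  pre <- paste0("l", l, ".", nm, ".")
  if (!is.null(params[[paste0(pre, "W")]]))
    list(W = params[[paste0(pre, "W")]], b = params[[paste0(pre, "b")]])
  else
    list(W1 = params[[paste0(pre, "W1")]], W2 = params[[paste0(pre, "W2")]],
         b = params[[paste0(pre, "b")]])
}
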