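#' Closed-form trainable parameter count
#'
#' Sums learnable weights across the embedding layer (1x1 conv + batch
#' norm), each encoder layer (four q/k/v/out projections — full `d^2 + d`
#' or factorized `2*d*r + d` each, rotary frequencies `2 * k * d_head/2`
#' when RoPE is on, two token-wise norms, FFN), the `L` aggregation
#' scalars, the classifier (linear + batch norm + linear), and the
#' absolute-position table when APE is on. At the reference dimensions this
#' gives 451,216 for the full-rank baseline and 352,912 with LRP — a
#' per-projection saving of `d^2 - 2*d*r = 8,192` weights, 50% of the
#' 16,384 entries of each 128 x 128 projection matrix.
#'
#' @param cfg a [model_config()].
#' @return Integer parameter count; equals [enumerate_params()] on an
#'   instantiated model exactly.
#' @export
count_params <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  d <- cfg$d_emb; r <- cfg$d_bottleneck; f <- cfg$ffn_hidden
  h <- cfg$classifier_hidden; K <- cfg$n_classes; L <- cfg$n_layers
  proj <- if (cfg$use_lrp) 2 * d * r + d else d * d + d
  per_layer <- 4 * proj +
    (if (cfg$pos_encoding == "rope2d_mixed") 2 * cfg$n_heads * cfg$d_head / 2 else 0) +
    2 * (2 * d) +
    (d * f + f) + (f * d + d)
  total <- (cfg$n_bands * d + d) + 2 * d +      # embedding conv + norm
    (if (cfg$pos_encoding == "ape") cfg$n_tokens * d else 0) +
    L * per_layer +
    L +                                          # aggregation scalars
    (d * h + h) + 2 * h + (h * K + K)            # classifier
  as.integer(total)
}

#' Closed-form multiply-accumulate count for one forward pass
#'
#' Counts weight multiplications of one patch forward: the embedding
#' convolution (`n * B * d`), every projection and linear map, the
#' attention score and attention-value products, layer aggregation and the
#' classifier. Biases, normalisations, rectifiers, softmax, rotary
#' rotations and residual additions are excluded — the convention under
#' which the final configuration counts 3,795,192 MACs (3.80 M) and the
#' baseline 22,214,904, an 83% reduction. In CFLA mode the query, output
#' projection and FFN touch the center token only while keys/values cover
#' all `n` tokens, making the attention cost linear in `n`; in full mode
#' every map covers all tokens and scores are quadratic in `n`.
#'
#' @param cfg a [model_config()].
#' @param breakdown return per-component counts instead of the total.
#' @return Total MAC count, or (with `breakdown = TRUE`) a list with
#'   `embedding`, `per_layer` (itemised), `attention_per_layer`,
#'   `aggregation`, `classifier`, `total`.
#' @export
count_macs <- function(cfg, breakdown = FALSE) {
  stopifnot(inherits(cfg, "model_config"))
  d <- cfg$d_emb; r <- cfg$d_bottleneck; f <- cfg$ffn_hidden
  h <- cfg$classifier_hidden; K <- cfg$n_classes; L <- cfg$n_layers
  n <- cfg$n_tokens
  proj1 <- if (cfg$use_lrp) 2 * d * r else d * d      # one token, one proj
  cfla <- cfg$attention_mode == "cfla"
  kv <- 2 * n * proj1
  q_out <- if (cfla) 2 * proj1 else 2 * n * proj1
  attn <- if (cfla) 2 * n * d else 2 * n^2 * d        # scores + A*V
  ffn <- (if (cfla) 1 else n) * 2 * d * f
  per_layer <- kv + q_out + attn + ffn
  emb <- n * cfg$n_bands * d
  cls <- d * h + h * K
  agg <- L * d
  total <- emb + L * per_layer + agg + cls
  if (!breakdown) return(total)
  list(embedding = emb,
       per_layer = list(kv_projections = kv, q_and_out_projections = q_out,
                        attention = attn, ffn = ffn, total = per_layer),
       attention_per_layer = attn, aggregation = agg, classifier = cls,
       total = total)
}

#' Serialized model size under float32 storage
#'
#' `size_bytes = 4 * count_params(cfg)`; `size_mib` divides by 2^20 (the
#' "MB" printed in model-size tables). Optionally verifies against an
#' actual float32 dump of an instantiated model.
#'
#' @param cfg a [model_config()].
#' @param verify also serialize an instantiated model to a temporary
#'   float32 file and check agreement within 64 KiB.
#' @return List with `size_bytes` and `size_mib`.
#' @export
model_size <- function(cfg, verify = FALSE) {
  bytes <- 4 * count_params(cfg)
  if (verify) {
    tmp <- tempfile(fileext = ".f32")
    on.exit(unlink(tmp))
    serialize_params_f32(init_params(cfg, seed = 1L), tmp)
    actual <- file.info(tmp)$size
    if (abs(actual - bytes) > 65536)
      stop_config("serialized size ", actual, " deviates from analytic ",
                  bytes, " by more than 64 KiB")
  }
  list(size_bytes = bytes, size_mib = bytes / 2^20)
}

#' Dump trainable parameters as raw float32
#'
#' Concatenates every trainable array in parameter order as little-endian
#' float32, the storage convention under which model sizes are reported.
#'
#' @param model model from [init_params()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
serialize_params_f32 <- function(model, path) {
  p <- if (!is.null(model$params)) model$params else model
  con <- file(path, "wb")
  on.exit(close(con))
  for (nm in names(p))
    writeBin(as.numeric(p[[nm]]), con, size = 4L, endian = "little")
  invisible(path)
}

#' Architecture-level efficiency report
#'
#' @param cfg a [model_config()].
#' @return An object of class `efficiency_report`: `params`, `macs`,
#'   `flops` (`= 2 * macs`), `size_bytes`, `size_mib`.
#' @export
efficiency_report <- function(cfg) {
  params <- count_params(cfg)
  macs <- count_macs(cfg)
  sz <- model_size(cfg)
  structure(list(params = params, macs = macs, flops = 2 * macs,
                 size_bytes = sz$size_bytes, size_mib = sz$size_mib),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("params %.1f K | MACs %.2f M | FLOPs %.2f M | size %.2f MB\n",
              x$params / 1e3, x$macs / 1e6, x$flops / 1e6, x$size_mib))
  invisible(x)
}

#' Ablation-grid efficiency table
#'
#' One row per configuration of the LRP x CFLA grid (the three published
#' rows: baseline, CFLA-only, LRP+CFLA; optionally the LRP-only fourth),
#' with MACs/FLOPs in millions, parameters in thousands and size in MB —
#' the layout of an architecture-ablation table.
#'
#' @param variants character vector of [reference_config()] variants.
#' @param ... passed to [reference_config()].
#' @return A data.frame.
#' @export
profile_table <- function(variants = c("baseline", "cfla_only", "final"),
                          ...) {
  rows <- lapply(seq_along(variants), function(i) {
    cfg <- reference_config(variants[i], ...)
    r <- efficiency_report(cfg)
    data.frame(index = i, variant = variants[i],
               lrp = cfg$use_lrp, cfla = cfg$attention_mode == "cfla",
               macs_m = round(r$macs / 1e6, 2),
               flops_m = round(r$flops / 1e6, 2),
               params_k = round(r$params / 1e3, 1),
               size_mb = round(r$size_mib, 2))
  })
  do.call(rbind, rows)
}

#' Timing harness configuration
#'
#' The published protocol measures at batch size 1024 over 1000 timed runs
#' after 50 warmup iterations; scale these down for quick checks.
#'
#' @param batch_size patches per forward.
#' @param warmup untimed warmup iterations.
#' @param runs timed iterations.
#' @param device informational device tag.
#' @return An object of class `timing_config`.
#' @export
timing_config <- function(batch_size = 1024L, warmup = 50L, runs = 1000L,
                          device = "cpu") {
  if (batch_size < 1L || warmup < 1L || runs < 1L)
    stop_invalid("timing settings must all be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 warmup = as.integer(warmup), runs = as.integer(runs),
                 device = device),
            class = "timing_config")
}

#' Empirical inference latency and throughput
#'
#' Runs warmup then timed batched eval-mode forward passes on random input
#' and reports mean and standard deviation of the per-patch latency (ms),
#' throughput (patches/s) and, when a baseline report is supplied, the
#' speedup of mean latency. Hardware-dependent numbers are informational.
#'
#' @param model a model from [init_params()] or [train_model()].
#' @param timing a [timing_config()].
#' @param baseline optional `timing_report` to compute speedup against.
#' @param seed seed for the random benchmark batch.
#' @return An object of class `timing_report`: `latency_ms_mean`,
#'   `latency_ms_sd`, `throughput_pps`, `speedup`, `timing`.
#' @export
benchmark_inference <- function(model, timing = timing_config(),
                                baseline = NULL, seed = 1L) {
  cfg <- model$cfg
  n <- cfg$n_tokens
  Pmat <- with_seed(seed,
    matrix(stats::runif(timing$batch_size * n * cfg$n_bands, 0, 100),
           timing$batch_size * n, cfg$n_bands))
  for (i in seq_len(timing$warmup))
    invisible(sst_forward_batch(Pmat, model, mode = "eval"))
  times <- numeric(timing$runs)
  for (i in seq_len(timing$runs)) {
    t0 <- proc.time()[["elapsed"]]
    invisible(sst_forward_batch(Pmat, model, mode = "eval"))
    times[i] <- proc.time()[["elapsed"]] - t0
  }
  per_patch_ms <- times * 1000 / timing$batch_size
  lat <- mean(per_patch_ms)
  structure(list(latency_ms_mean = lat,
                 latency_ms_sd = stats::sd(per_patch_ms),
                 throughput_pps = 1000 / lat,
                 speedup = if (is.null(baseline)) NA_real_
                           else baseline$latency_ms_mean / lat,
                 timing = timing),
            class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf("latency %.4f +/- %.4f ms/patch | throughput %.1f patches/s",
              x$latency_ms_mean, x$latency_ms_sd, x$throughput_pps))
  if (!is.na(x$speedup)) cat(sprintf(" | speedup %.2fx", x$speedup))
  cat("\n")
  invisible(x)
}
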