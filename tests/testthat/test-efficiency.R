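test_that("closed-form parameter counts equal enumeration on the full grid", {
  for (lrp in c(TRUE, FALSE)) for (att in c("cfla", "full"))
    for (pe in c("rope2d_mixed", "ape")) {
      cfg <- model_config(use_lrp = lrp, attention_mode = att,
                          pos_encoding = pe)
      expect_identical(count_params(cfg),
                       enumerate_params(init_params(cfg, seed = 1)),
                       label = paste(lrp, att, pe))
    }
})

test_that("reference configurations reproduce the published accounting", {
  fin <- reference_config("final"); bas <- reference_config("baseline")
  expect_identical(count_params(bas), 451216L)
  expect_identical(count_params(fin), 352912L)
  expect_equal(count_macs(fin), 3795192)
  expect_equal(count_macs(bas), 22214904)
  # per-component reconstruction of the final-config MAC total
  br <- count_macs(fin, breakdown = TRUE)
  expect_equal(br$embedding, 1072512)
  expect_equal(br$per_layer$total, 897280)
  expect_equal(br$classifier, 30456)
  expect_equal(br$aggregation, 384)
})

test_that("LRP saves the analytic weight count", {
  fin <- reference_config("final"); bas <- reference_config("baseline")
  expect_equal(count_params(bas) - count_params(fin), 3 * 4 * 8192)
  d <- 128; r <- 32
  expect_equal(count_params(bas) - count_params(fin),
               3 * 4 * (d^2 - 2 * d * r))
})

test_that("MAC counts scale linearly (CFLA) and quadratically (full) in n", {
  ns <- c(3, 5, 7, 9)^2
  att_cfla <- sapply(c(3, 5, 7, 9), function(P)
    count_macs(reference_config("final", patch_size = P),
               breakdown = TRUE)$attention_per_layer)
  att_full <- sapply(c(3, 5, 7, 9), function(P)
    count_macs(reference_config("baseline", patch_size = P),
               breakdown = TRUE)$attention_per_layer)
  expect_equal(unname(coef(lm(log(att_cfla) ~ log(ns)))[2]), 1,
               tolerance = 1e-8)
  expect_equal(unname(coef(lm(log(att_full) ~ log(ns)))[2]), 2,
               tolerance = 1e-8)
  # total CFLA MACs are affine in n: a degree-1 fit is exact
  tot <- sapply(c(3, 5, 7, 9), function(P)
    count_macs(reference_config("final", patch_size = P)))
  fit1 <- lm(tot ~ ns)
  expect_lt(max(abs(residuals(fit1))), 1e-6)
  # total full-attention MACs need the quadratic term
  totf <- sapply(c(3, 5, 7, 9), function(P)
    count_macs(reference_config("baseline", patch_size = P)))
  expect_gt(max(abs(residuals(lm(totf ~ ns)))), 1e3)
  expect_lt(max(abs(residuals(lm(totf ~ ns + I(ns^2))))), 1e-6)
})

test_that("FLOPs double MACs and sizes follow float32 storage", {
  for (v in c("final", "baseline", "cfla_only", "lrp_only")) {
    r <- efficiency_report(reference_config(v))
    expect_identical(r$flops, 2 * r$macs)
    expect_identical(r$size_bytes, 4 * r$params)
    expect_equal(r$size_mib, r$size_bytes / 2^20)
  }
  expect_equal(model_size(reference_config("final"))$size_bytes, 1411648)
  expect_equal(model_size(reference_config("baseline"))$size_bytes, 1804864)
})

test_that("serialized float32 dumps match the analytic size", {
  cfg <- tiny_cfg()
  model <- init_params(cfg, seed = 1)
  tmp <- tempfile()
  serialize_params_f32(model, tmp)
  expect_identical(file.info(tmp)$size, 4 * as.numeric(count_params(cfg)))
  unlink(tmp)
  expect_silent(model_size(tiny_cfg(), verify = TRUE))
})

test_that("the timing harness is self-consistent and orders the variants", {
  tiny_t <- timing_config(batch_size = 16L, warmup = 2L, runs = 5L)
  fin <- init_params(reference_config("final"), seed = 1)
  bas <- init_params(reference_config("baseline"), seed = 1)
  rb <- benchmark_inference(bas, tiny_t)
  rf <- benchmark_inference(fin, tiny_t, baseline = rb)
  # definitional identity between throughput and latency
  expect_equal(rf$throughput_pps * rf$latency_ms_mean, 1000,
               tolerance = 1e-6)
  # the linear-attention low-rank model must outpace the quadratic baseline
  expect_gt(rf$speedup, 1)
  expect_error(timing_config(batch_size = 0), class = "sstfpo_invalid_argument")
})

test_that("the ablation table carries the published rows", {
  tab <- profile_table(c("baseline", "cfla_only", "final"))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$params_k, c(451.2, 451.2, 352.9))
  expect_equal(tab$size_mb, c(1.72, 1.72, 1.35))
  expect_equal(tab$macs_m[3], 3.80)
  # exact FLOPs = 2 * 3,795,192 = 7,590,384, printing as 7.59 M
  expect_equal(tab$flops_m[3], 7.59)
})
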