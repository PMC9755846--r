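test_that("replicate aggregation excludes failed wells and needs two usable values", {
  expect_equal(aggregate_replicates(c(30, 30, 30)),
               list(mean = 30, sd = 0, n_used = 3L, n_total = 3L))
  agg <- aggregate_replicates(c(30, 31))
  expect_equal(agg$mean, 30.5)
  expect_equal(agg$sd, sd(c(30, 31)))  # sample SD, ~0.707
  expect_equal(round(agg$sd, 3), 0.707)
  agg_na <- aggregate_replicates(c(30, 31, NA))
  expect_equal(agg_na$n_used, 2L)
  expect_equal(agg_na$n_total, 3L)
  expect_error(aggregate_replicates(c(30, NA)), "insufficient replicates")
  expect_error(aggregate_replicates(c(30, -1)), "positive")
})

test_that("informativeness gate is inclusive at the 34-cycle boundary", {
  expect_true(is_informative(34.0))
  expect_false(is_informative(34.01))
  expect_true(is_informative(20))
  expect_false(is_informative(NA_real_))
  expect_true(is_informative(35, cutoff = 36))
})

test_that("delta-delta-Ct relative copy number follows the efficiency power law", {
  expect_equal(relative_copy_number(5, 5), 1.0)
  expect_equal(relative_copy_number(6, 5), 0.5)
  # a 20% deletion shifts delta-Ct by log2(1/0.8)
  expect_equal(relative_copy_number(log2(1 / 0.8), 0), 0.8)
  expect_equal(1 - relative_copy_number(log2(1 / 0.8), 0), 0.2)
  # identity and log-linearity
  for (x in c(-3, 0, 2.5)) expect_equal(relative_copy_number(x, x), 1)
  ddct <- seq(-2, 2, by = 0.5)
  expect_equal(log2(relative_copy_number(ddct, 0)), -ddct)
  # efficiency override
  expect_equal(relative_copy_number(1, 0, efficiency = 1.9), 1 / 1.9)
  expect_error(relative_copy_number(1, 0, efficiency = 2.5), "efficiency")
  expect_error(relative_copy_number(1, 0, efficiency = 1), "efficiency")
})

test_that("call_scnv calls direction at the t-test and handles degenerate input", {
  # identical triplicates: zero difference, degenerate variance -> p = 1
  expect_warning(res <- call_scnv(c(1, 1, 1), c(1, 1, 1), test_space = "rcn"),
                 "zero-variance")
  expect_equal(res$call, "neutral")
  expect_equal(res$p_value, 1)

  # clear deletion, oracle = standard two-sample t-test
  s <- c(0.60, 0.62, 0.58); r <- c(1.00, 0.98, 1.02)
  res_d <- call_scnv(s, r, test_space = "rcn")
  expect_equal(res_d$call, "deletion")
  expect_equal(res_d$p_value, t.test(s, r, var.equal = TRUE)$p.value)
  expect_lt(res_d$p_value, 0.001)

  # amplification: direction flips
  res_a <- call_scnv(c(1.50, 1.48, 1.52), r, test_space = "rcn")
  expect_equal(res_a$call, "amplification")

  # dct space: higher delta-Ct means fewer copies
  res_dct <- call_scnv(c(1.0, 1.02, 0.98), c(0, 0.02, -0.02))
  expect_equal(res_dct$call, "deletion")

  expect_error(call_scnv(1, c(1, 2)), "insufficient replicates")
})

test_that("quantify_samples runs the full paired chain on a simulated plate", {
  samples <- data.frame(
    sample_id = c("T1", "N1", "T2", "N2", "T3", "N3"),
    true_copies = c(2, 2, 2, 2, 4, 2),
    null_fraction = c(0.5, 0, 0, 0, 0, 0))
  plate <- gen_qpcr_plate(samples, ct_noise_sd = 0.05, seed = 7)
  pairs <- data.frame(tumor_id = c("T1", "T2", "T3"),
                      normal_id = c("N1", "N2", "N3"))
  q <- quantify_samples(plate, pairs)
  expect_equal(q$call, c("deletion", "neutral", "amplification"))
  expect_equal(q$rel_copy_number, c(0.5, 1, 2), tolerance = 0.15)
  expect_true(all(q$informative))
})

test_that("non-informative and dropout samples are flagged, not tested", {
  # reference too weak (Ct > 34): non-informative
  plate <- data.frame(
    sample_id = rep(c("T", "N"), each = 6),
    assay = rep(rep(c("target", "reference"), each = 3), 2),
    replicate = rep(1:3, 4),
    ct = c(30, 30.1, 29.9, 35, 35.1, 34.9,   # tumor: reference over cutoff
           30, 30.1, 29.9, 30, 30.1, 29.9))
  q <- quantify_samples(plate, data.frame(tumor_id = "T", normal_id = "N"))
  expect_equal(q$call, "non_informative")
  expect_false(q$informative)
  expect_true(is.na(q$rel_copy_number))

  # complete target dropout with informative reference: total deletion
  plate2 <- data.frame(
    sample_id = rep(c("T", "N"), each = 6),
    assay = rep(rep(c("target", "reference"), each = 3), 2),
    replicate = rep(1:3, 4),
    ct = c(NA, NA, NA, 30, 30.1, 29.9,
           30, 30.1, 29.9, 30, 30.1, 29.9))
  q2 <- quantify_samples(plate2, data.frame(tumor_id = "T", normal_id = "N"))
  expect_equal(q2$call, "deletion")
  expect_true(q2$dropout)
  expect_equal(q2$p_value, 0)
  expect_equal(q2$deletion_proportion, 1)
})

test_that("titration efficiency recovers the slope by least squares", {
  # exact one cycle per doubling
  amounts <- c(10, 5, 2.5)
  series <- data.frame(
    amount_ng = rep(amounts, each = 2),
    assay = rep(c("target", "reference"), 3),
    replicate = 1,
    ct = rep(28 - log2(amounts / 10), each = 2))
  fit <- titration_efficiency(series)
  expect_equal(fit$target$slope, -1)
  expect_equal(fit$target$efficiency, 2.0)
  expect_equal(fit$delta_ct_by_amount$delta_ct, rep(0, 3))

  # hand-set Ct values: oracle slope from the normal equations
  cts <- c(30, 31.1, 32.0)
  x <- log2(c(10, 5, 2.5))
  oracle_slope <- sum((x - mean(x)) * (cts - mean(cts))) / sum((x - mean(x))^2)
  series2 <- data.frame(amount_ng = rep(c(10, 5, 2.5), each = 2),
                        assay = rep(c("target", "reference"), 3),
                        replicate = 1,
                        ct = rep(cts, each = 2))
  fit2 <- titration_efficiency(series2)
  expect_equal(fit2$target$slope, oracle_slope)
  expect_equal(oracle_slope, -1, tolerance = 0.01)

  # flat response is degenerate
  flat <- series
  flat$ct <- 30
  expect_error(titration_efficiency(flat), "no amplification response")
  expect_error(titration_efficiency(series[series$amount_ng > 4, ]),
               "distinct template amounts")
})

test_that("titration efficiency is recovered within 0.05 under cycle noise", {
  series <- gen_titration_series(ct_noise_sd = 0.1, seed = 11)
  fit <- titration_efficiency(series)
  expect_equal(fit$target$efficiency, 2.0, tolerance = 0.05 / 2)
  expect_equal(fit$reference$efficiency, 2.0, tolerance = 0.05 / 2)
})

test_that("mixture linearity is exact without noise and near-identity with noise", {
  s0 <- gen_mixture_series(ct_noise_sd = 0, seed = 5)
  fit0 <- mixture_linearity(s0)
  expect_equal(fit0$slope, 1.0)
  expect_equal(fit0$intercept, 0.0, tolerance = 1e-12)
  expect_equal(fit0$r, 1.0)
  expect_equal(fit0$measured$deletion_proportion, fit0$measured$null_fraction)

  s1 <- gen_mixture_series(null_fractions = c(0, 0.05, 0.1, 0.15, 0.2, 0.3),
                           ct_noise_sd = 0.1, seed = 9)
  fit1 <- mixture_linearity(s1)
  expect_gte(fit1$slope, 0.9)
  expect_lte(fit1$slope, 1.1)
  expect_gt(fit1$r, 0.9)

  expect_error(mixture_linearity(s0[s0$null_fraction == 0, ]), "fractions")
})

test_that("detection limit follows the monotone lowest-significant-dilution rule", {
  # noise-free: every nonzero fraction differs from the control exactly
  s0 <- gen_mixture_series(ct_noise_sd = 0, seed = 5)
  suppressWarnings(lod0 <- detection_limit(s0))
  expect_equal(lod0$detection_limit, 0.10)

  # forced p-value pattern via direct series construction: make the
  # 10% fraction noisy/insignificant but 20% and 30% clear
  mk <- function(f, cts_t) data.frame(null_fraction = f,
                                      assay = rep(c("target", "reference"), each = 3),
                                      replicate = rep(1:3, 2),
                                      ct = c(cts_t, 28, 28.01, 27.99))
  series <- rbind(
    mk(0,    c(28.00, 28.02, 27.98)),
    mk(0.10, c(28.30, 27.90, 28.20)),   # wide spread: not significant
    mk(0.20, c(28.32, 28.33, 28.31)),
    mk(0.30, c(28.51, 28.52, 28.50)))
  lod <- detection_limit(series)
  expect_false(lod$per_fraction$significant[lod$per_fraction$null_fraction == 0.10])
  expect_true(all(lod$per_fraction$significant[lod$per_fraction$null_fraction >= 0.20]))
  expect_equal(lod$detection_limit, 0.20)

  # nothing significant: not detected
  flat <- rbind(mk(0, c(28.3, 27.8, 28.1)), mk(0.1, c(28.4, 27.7, 28.0)),
                mk(0.2, c(28.2, 27.9, 28.3)), mk(0.3, c(28.1, 28.4, 27.7)))
  expect_true(is.na(detection_limit(flat)$detection_limit))
})

test_that("deletion proportion of simulated mixtures is recovered with small bias", {
  for (f in c(0.1, 0.2, 0.3)) {
    series <- gen_mixture_series(null_fractions = c(0, f), replicates = 100,
                                 ct_noise_sd = 0.1, seed = 20220917 + round(100 * f))
    meas <- mixture_linearity(
      gen_mixture_series(null_fractions = c(0, f, 0.5), replicates = 100,
                         ct_noise_sd = 0.1, seed = 20220917 + round(100 * f)))
    dp <- meas$measured$deletion_proportion[meas$measured$null_fraction == f]
    expect_lt(abs(dp - f), 0.02)
  }
})

test_that("controls policy downgrades rather than errors", {
  plate <- gen_qpcr_plate(data.frame(sample_id = c("RKO_100", "A549_100", "MIX_20"),
                                     true_copies = c(2, 0, 2),
                                     null_fraction = c(0, 0, 0.2)), seed = 2)
  expect_equal(check_controls(plate)$status, "controlled")
  bad <- plate[plate$sample_id != "MIX_20", ]
  cc <- check_controls(bad)
  expect_equal(cc$status, "uncontrolled")
  expect_equal(cc$missing, "mix20")
})
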