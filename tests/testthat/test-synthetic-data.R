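test_that("generator plants exactly the configured peak structure", {
  ds <- generate_dataset(tiny_config(seed = 4))
  pt <- ds$peaks
  expect_equal(ncol(pt$intensities), 60 + 3 + 4)
  expect_equal(nrow(pt$intensities), 12 * 3)
  zero_cols <- colnames(pt$intensities)[apply(pt$intensities, 2, max) == 0]
  expect_setequal(zero_cols, ds$truth$planted$zero_max)
  expect_length(zero_cols, 3)

  cv <- replicate_cv(remove_zero_max_peaks(pt))
  worst <- apply(cv, 2, max)
  expect_true(all(worst[ds$truth$planted$informative] < 10))
  expect_true(all(worst[ds$truth$planted$high_cv] >= 10))
})

test_that("same seed and config give bit-identical datasets", {
  a <- generate_dataset(tiny_config(seed = 11))
  b <- generate_dataset(tiny_config(seed = 11))
  expect_identical(a, b)
  c <- generate_dataset(tiny_config(seed = 12))
  expect_false(identical(a$peaks$intensities, c$peaks$intensities))
})

test_that("expected scores are a clipped affine map of driver intensities", {
  ds <- generate_dataset(tiny_config(seed = 2))
  tr <- ds$truth
  at <- ds$config$attributes[1, ]
  exp_sc <- tr$expected_scores[, at$name]
  expect_true(all(exp_sc >= at$scale_min & exp_sc <= at$scale_max))
  # reconstruct the affine map from the driver weights and intensities
  sm <- sample_mean_intensities(ds$peaks)[rownames(tr$expected_scores), ]
  dm <- tr$driver_map[[at$name]]
  z <- scale(sm[, dm$peak_id])
  sig <- as.vector(z %*% dm$weight)
  sig <- sig / sd(sig)
  mid <- (at$scale_min + at$scale_max) / 2
  pred <- mid + at$effect_size * (at$scale_max - at$scale_min) / 6 * sig
  unclipped <- exp_sc > min(exp_sc) & exp_sc < max(exp_sc)
  expect_gt(cor(pred[unclipped], exp_sc[unclipped]), 0.999)
})

test_that("panelist scores follow expectation plus bias and bounded noise", {
  ds <- generate_dataset(tiny_config(seed = 5, outlier_rate = 0))
  rec <- ds$panel$records
  at <- ds$config$attributes[1, ]
  rec <- rec[rec$attribute == at$name, ]
  exp_sc <- ds$truth$expected_scores[rec$sample_id, at$name]
  dev <- rec$score - exp_sc
  bound <- (ds$config$panelist_bias_sd + at$noise_sd) * sqrt(3) + 1e-9
  expect_true(all(abs(dev) <= bound))
  # per-panelist mean deviation reflects the panelist's bias
  bias_hat <- tapply(dev, rec$panelist_id, mean)
  expect_gt(sd(bias_hat), 0)
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config(outlier_rate = 0.6), "outlier_rate")
  expect_error(generator_config(n_rounds = 2), "n_rounds")
  expect_error(generator_config(replicate_cv_target = 12), "replicate_cv_target")
  expect_error(generator_config(
    attributes = default_attributes(n_driver_peaks = 500L)), "drivers")
  # drivers exceeding the independent pool are caught at generation
  cfg <- tiny_config(independent_fraction = 0.05)
  expect_error(generate_dataset(cfg), "independent peak pool")
})

test_that("split_years partitions samples and shares ground truth", {
  cfg <- tiny_config(seed = 9, n_samples = 20L)
  ds <- generate_dataset(cfg)
  yrs <- split_years(ds, 0.5, seed = 3)
  sa <- unique(yrs$a$peaks$injections$sample_id)
  sb <- unique(yrs$b$peaks$injections$sample_id)
  expect_length(sa, 10)
  expect_length(sb, 10)
  expect_length(intersect(sa, sb), 0)
  expect_identical(yrs$a$truth$driver_map, yrs$b$truth$driver_map)
  expect_identical(yrs$a$truth$driver_map, ds$truth$driver_map)
  # sensory noise re-drawn: scores differ from the parent panel for the
  # same (panelist, sample, attribute, round)
  pa <- yrs$a$panel$records
  key <- paste(pa$panelist_id, pa$sample_id, pa$attribute, pa$round)
  parent <- ds$panel$records
  pkey <- paste(parent$panelist_id, parent$sample_id, parent$attribute, parent$round)
  shared <- intersect(key, pkey)
  expect_false(all(pa$score[match(shared, key)] ==
                     parent$score[match(shared, pkey)]))
  expect_error(split_years(ds, 0.05, seed = 1), "at least 8")
  expect_error(split_years(ds, 1.2, seed = 1), "fraction")
})

test_that("sample-level signal strength is monotone in effect size", {
  effects <- c(0.25, 0.5, 1, 2)
  snr <- sapply(effects, function(e) {
    mean(sapply(1:5, function(s) {
      cfg <- tiny_config(seed = s,
                         attributes = default_attributes(effect_size = e,
                                                         n_driver_peaks = 5L)[c(1, 3), ])
      ds <- generate_dataset(cfg)
      mm <- sample_means(remove_outliers(ds$panel)$panel)
      sd(mm$means[, "sweetness"])
    }))
  })
  expect_identical(order(snr), seq_along(effects))
})

test_that("an effect-free attribute carries no predictable signal", {
  attrs <- default_attributes(n_driver_peaks = 5L)[c(1, 3), ]
  attrs$effect_size[2] <- 0
  q2 <- sapply(1:5, function(s) {
    ds <- generate_dataset(tiny_config(seed = 100 + s, attributes = attrs))
    t2 <- filter_by_replicate_cv(remove_zero_max_peaks(ds$peaks))
    mm <- sample_means(remove_outliers(ds$panel)$panel)
    sid <- t2$injections$sample_id
    y <- unname(mm$means[sid, "body"])
    folds <- make_grouped_folds(sid, k = 4, seed = s)
    grouped_q2(t2$intensities, y, 0, folds)$q2
  })
  expect_lte(median(q2), 0.2)
})
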