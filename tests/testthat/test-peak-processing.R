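test_that("zero-max filter removes exactly the all-zero peaks", {
  m <- cbind(a = c(1, 2, 3), b = 0, c = c(0.5, 0, 0.2), d = 0)
  pt <- toy_peak_table(m)
  out <- remove_zero_max_peaks(pt)
  expect_equal(colnames(out$intensities), c("a", "c"))
  # strictly positive table passes through unchanged
  pos <- toy_peak_table(matrix(runif(12, 1, 2), 3, 4))
  expect_identical(remove_zero_max_peaks(pos), pos)
  # idempotent
  expect_identical(remove_zero_max_peaks(out), out)
})

test_that("replicate CV uses the n-1 standard deviation over replicate means", {
  # one sample with replicates (8, 10, 12): sd = 2, mean = 10 -> CV = 20%
  inj <- matrix(c(8, 10, 12, 5, 5, 5), ncol = 2,
                dimnames = list(NULL, c("p1", "p2")))
  pt <- peak_table(inj, rep("S01", 3), 1:3,
                   data.frame(peak_id = c("p1", "p2"), rt = 1:2, mz = 101:102))
  cv <- replicate_cv(pt)
  expect_equal(cv["S01", "p1"], 20)
  expect_equal(cv["S01", "p2"], 0)
  out <- filter_by_replicate_cv(pt)
  expect_equal(colnames(out$intensities), "p2")
})

test_that("the CV threshold is inclusive and zero means force removal", {
  # CV exactly 10%: values 10*(1 +/- 0.1) with centred deviations
  inj <- rbind(c(9, 1), c(10, 1), c(11, 1),       # S1: sd 1, mean 10 -> 10%
               c(5, 0), c(5, 0), c(5, 0))         # S2: p2 zero mean -> Inf
  colnames(inj) <- c("p1", "p2")
  pt <- peak_table(inj, rep(c("S1", "S2"), each = 3), rep(1:3, 2),
                   data.frame(peak_id = c("p1", "p2"), rt = 1:2, mz = 101:102))
  cv <- replicate_cv(pt)
  expect_equal(cv["S1", "p1"], 10)
  expect_equal(cv["S2", "p2"], Inf)
  out <- filter_by_replicate_cv(pt, 10)
  expect_equal(ncol(out$intensities), 0)
  # identical replicates everywhere -> CV 0 -> retained
  same <- toy_peak_table(matrix(runif(8, 1, 2), 2, 4), n_rep = 3)
  expect_equal(ncol(filter_by_replicate_cv(same)$intensities), 4)
  # single-replicate samples are an error
  one <- peak_table(matrix(1:2, 2, 1,
                           dimnames = list(NULL, "p")), c("A", "B"), c(1, 1),
                    data.frame(peak_id = "p", rt = 1, mz = 100))
  expect_error(replicate_cv(one), "single injection")
})

test_that("filters recover exactly the planted informative set", {
  for (s in c(3, 17)) {
    ds <- generate_dataset(tiny_config(seed = s))
    t1 <- remove_zero_max_peaks(ds$peaks)
    t2 <- filter_by_replicate_cv(t1)
    expect_setequal(colnames(t2$intensities), ds$truth$planted$informative)
    # order fixed: zero-max then CV; both idempotent
    expect_identical(filter_by_replicate_cv(t2), t2)
  }
})

test_that("annotation matches within tolerances and picks the nearest candidate", {
  pt <- toy_peak_table(matrix(1, 2, 3), rt = c(5.00, 10.0, 20.0),
                       mz = c(200.000, 300.000, 400.000))
  lib <- data.frame(
    compound_name = c("near", "far_rt", "second"),
    rt = c(5.05, 10.20, 5.04),
    mz = c(200.003, 300.000, 200.0061),
    compound_group = "ester", stringsAsFactors = FALSE)
  ann <- annotate_peaks(pt, lib)
  # inside both tolerances
  expect_equal(ann$annotation$compound_name[1], "near")
  expect_equal(ann$annotation$delta_rt[1], 0.05)
  expect_equal(ann$annotation$delta_mz[1], 0.003, tolerance = 1e-9)
  # delta rt 0.20 > 0.1 -> unmatched regardless of mz
  expect_true(is.na(ann$annotation$compound_name[2]))
  expect_true(is.na(ann$annotation$compound_name[3]))
  # two candidates for peak 1: normalized distances
  # near: 0.05/0.1 + 0.003/0.007 = 0.929; second: 0.04/0.1 + 0.0061/0.007 = 1.271
  cands <- ann$candidates[ann$candidates$peak_id == ann$annotation$peak_id[1], ]
  expect_equal(nrow(cands), 2)
  expect_equal(cands$compound_name[1], "near")
  expect_error(annotate_peaks(pt, lib, rt_tol = -1), "positive")
})

test_that("annotation assignments are invariant to a common RT shift", {
  ds <- generate_dataset(tiny_config(seed = 8))
  base <- annotate_peaks(remove_zero_max_peaks(ds$peaks), ds$library)
  shifted_pt <- ds$peaks
  shifted_pt$peaks$rt <- shifted_pt$peaks$rt + 0.37
  shifted_lib <- ds$library
  shifted_lib$rt <- shifted_lib$rt + 0.37
  shifted <- annotate_peaks(remove_zero_max_peaks(shifted_pt), shifted_lib)
  expect_equal(base$annotation$compound_name, shifted$annotation$compound_name)
})

test_that("library hits annotate their true peaks on synthetic data", {
  ds <- generate_dataset(tiny_config(seed = 6))
  ann <- annotate_peaks(ds$peaks, ds$library)
  truth <- attr(ds$library, "true_peak")
  hits <- !is.na(truth)
  assigned <- ann$annotation$compound_name[match(truth[hits], ann$annotation$peak_id)]
  expect_gt(mean(assigned == ds$library$compound_name[hits], na.rm = TRUE), 0.95)
})

test_that("extra variables broadcast per sample as pseudo-peaks", {
  pt <- toy_peak_table(matrix(runif(20, 1, 2), 4, 5))
  extras <- matrix(c(1.4, 2.0, 3.1, 0.7, 10, 20, 30, 40), ncol = 2,
                   dimnames = list(sprintf("S%02d", 1:4), c("acidity", "ethanol")))
  out <- merge_extra_variables(pt, extras)
  expect_equal(ncol(out$intensities), 7)
  expect_true(all(out$intensities[out$injections$sample_id == "S01", "acidity"] == 1.4))
  expect_equal(sum(out$peaks$is_extra), 2)
  # empty extras -> identity
  expect_identical(merge_extra_variables(pt, NULL), pt)
  bad <- extras; rownames(bad) <- paste0("X", 1:4)
  expect_error(merge_extra_variables(pt, bad), "indexed")
})
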