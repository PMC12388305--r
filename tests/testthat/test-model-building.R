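make_signal_instance <- function(seed = 1, n_s = 30, p = 10, rep = 2,
                                 orth = 0, noise = 0.3) {
  set.seed(seed)
  sid <- rep(sprintf("S%02d", seq_len(n_s)), each = rep)
  base <- matrix(rnorm(n_s * p), n_s, p, dimnames = list(NULL, paste0("V", 1:p)))
  x <- base[rep(seq_len(n_s), each = rep), ] +
    matrix(rnorm(n_s * rep * p, sd = 0.02), n_s * rep, p)
  y_s <- base[, 1] + 0.8 * base[, 2] + rnorm(n_s, sd = noise)
  if (orth > 0) {
    t_o <- scale(residuals(lm(rnorm(n_s) ~ y_s)))[, 1]
    x <- x + orth * outer(t_o[rep(seq_len(n_s), each = rep)], rnorm(p))
  }
  list(x = x, y = y_s[rep(seq_len(n_s), each = rep)], sid = sid)
}

test_that("the forward search accepts orthogonal components only while Q2 increases", {
  d <- make_signal_instance(seed = 3)
  folds <- make_grouped_folds(d$sid, k = 5, seed = 1)
  tr <- select_orthogonal_components(d$x, d$y, folds, max_a_o = 4)
  q2 <- tr$trace$q2
  # chosen is the last index of the strictly increasing prefix
  expected <- 0L
  for (i in seq_along(q2)[-1]) {
    if (q2[i] > q2[i - 1]) expected <- i - 1L else break
  }
  expect_equal(tr$chosen, expected)
  expect_true(all(diff(tr$trace$q2[seq_len(tr$chosen + 1)]) > 0))
})

test_that("a planted strong orthogonal factor leads to at least one component", {
  hits <- sapply(1:10, function(s) {
    d <- make_signal_instance(seed = s, orth = 4)
    folds <- make_grouped_folds(d$sid, k = 5, seed = s)
    select_orthogonal_components(d$x, d$y, folds, max_a_o = 3)$chosen
  })
  expect_gte(mean(hits >= 1), 0.9)
})

test_that("the permutation anchor reproduces the model R2 at correlation 1", {
  d <- make_signal_instance(seed = 5)
  folds <- make_grouped_folds(d$sid, k = 5, seed = 2)
  rep <- permutation_test(d$x, d$y, 0, folds, n_perm = 15, seed = 2)
  sx <- uv_scale(d$x); sy <- uv_scale(d$y)
  expect_equal(rep$model_r2, fit_opls(sx$x, sy$x, 0)$r2, tolerance = 1e-10)
  expect_equal(nrow(rep$permutations), 15)
  expect_true(all(rep$permutations$correlation >= 0 &
                    rep$permutations$correlation <= 1))
  # deterministic given seed
  rep2 <- permutation_test(d$x, d$y, 0, folds, n_perm = 15, seed = 2)
  expect_identical(rep$permutations, rep2$permutations)
})

test_that("permutation validation separates signal from null", {
  d <- make_signal_instance(seed = 8, noise = 0.2)
  folds <- make_grouped_folds(d$sid, k = 5, seed = 3)
  rep_sig <- permutation_test(d$x, d$y, 0, folds, n_perm = 40, seed = 1)
  expect_true(rep_sig$valid_flag)
  expect_lt(rep_sig$p_q2, 0.05)
  # same X, shuffled y: the model no longer beats its null distribution
  y_null <- with_seed(99, sample(unique(d$y)))[match(d$sid, unique(d$sid))]
  rep_null <- permutation_test(d$x, y_null, 0, folds, n_perm = 40, seed = 1)
  expect_false(rep_null$valid_flag)
})

test_that("reduction walks down until the permutation test passes", {
  d <- make_signal_instance(seed = 13, orth = 4)
  folds <- make_grouped_folds(d$sid, k = 5, seed = 1)
  tr <- select_orthogonal_components(d$x, d$y, folds, max_a_o = 3)
  red <- reduce_until_valid(d$x, d$y, tr, folds, n_perm = 30, seed = 1)
  expect_lte(red$a_o, tr$chosen)
  expect_equal(red$model$n_components[["x_orthogonal"]], red$a_o)
  if (red$report$valid_flag) {
    # every a_o above the final one must have failed
    for (a in seq_len(tr$chosen - red$a_o)) {
      above <- permutation_test(d$x, d$y, red$a_o + a, folds, n_perm = 30, seed = 1)
      expect_false(above$valid_flag)
    }
  } else {
    expect_equal(red$a_o, 0L)
  }
})

test_that("CV-ANOVA matches direct F arithmetic and takes correct limits", {
  # hand-built example: ss_tot 10, press 2, n 20, a 2
  res <- cv_anova(press = 2, ss_tot = 10, n = 20, a = 2)
  f <- ((10 - 2) / 2) / (2 / 17)
  expect_equal(res$f_value, f, tolerance = 1e-12)
  expect_equal(res$p_value, pf(f, 2, 17, lower.tail = FALSE), tolerance = 1e-9)
  # near-perfect CV prediction: p near 0
  expect_lt(cv_anova(1e-8, 10, 30, 1)$p_value, 1e-10)
  # press equal to total variation: F clamps at 0, p = 1
  null_case <- cv_anova(10, 10, 30, 1)
  expect_equal(null_case$f_value, 0)
  expect_equal(null_case$p_value, 1)
  expect_error(cv_anova(1, 10, 3, 4), "degrees of freedom")
})

test_that("VIPpred follows the closed form and its normalization identity", {
  # all-equal weights -> every VIP is 1
  x <- uv_scale(matrix(rnorm(40), 10, 4))$x
  w <- rep(0.5, 4)
  m <- structure(list(w = setNames(w, colnames(x))), class = "opls_model")
  expect_equal(vip_pred(m)$vip_pred, rep(1, 4))
  # p = 4 with one nonzero weight -> that VIP is 2, the rest 0
  m2 <- structure(list(w = setNames(c(1, 0, 0, 0), colnames(x))), class = "opls_model")
  expect_equal(vip_pred(m2)$vip_pred, c(2, 0, 0, 0))
  # sum of squared VIPs equals the number of variables on fitted models
  d <- make_signal_instance(seed = 2)
  sx <- uv_scale(d$x); sy <- uv_scale(d$y)
  for (a_o in 0:2) {
    fit <- fit_opls(sx$x, sy$x, a_o)
    v <- vip_pred(fit)$vip_pred
    expect_equal(sum(v^2), length(v), tolerance = 1e-8)
    expect_equal(mean(v^2), 1, tolerance = 1e-8)
  }
})

test_that("signing and selection use strict thresholds and sample-level correlation", {
  xm <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(2, 2, 2, 2))
  y <- c(1.1, 1.9, 3.2, 3.8)
  vips <- structure(data.frame(variable = c("a", "b", "c"),
                               vip_pred = c(1.6, 1.5, 0.2)),
                    class = c("vip_report", "data.frame"))
  out <- sign_and_select(vips, xm, y, threshold = 1.5)
  expect_equal(sign(out$pearson_r), c(1, -1, 0))
  expect_equal(out$signed_vip[2], -1.5)
  # strict >: only the 1.6 variable is selected
  expect_equal(out$variable[out$selected], "a")
  # zero-variance variable never selected even with a huge VIP
  vips$vip_pred <- c(0.1, 0.1, 99)
  out2 <- sign_and_select(vips, xm, y, threshold = 1.5)
  expect_false(any(out2$selected))
})
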