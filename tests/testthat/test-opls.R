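scaled_instance <- function(n = 30, p = 20, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", seq_len(p))))
  y <- rnorm(n)
  list(x = uv_scale(x)$x, y = uv_scale(y)$x)
}

test_that("a response proportional to one column is fit perfectly", {
  d <- scaled_instance(seed = 2)
  y <- d$x[, 3]
  m <- fit_opls(d$x[, 3, drop = FALSE], y, 0)
  expect_equal(m$r2, 1, tolerance = 1e-10)
  expect_equal(unname(abs(m$w)), 1)
})

test_that("with no orthogonal components the fit equals one-component PLS1", {
  skip_if_not_installed("mixOmics")
  for (seed in 1:3) {
    d <- scaled_instance(n = 25, p = 40, seed = seed)
    m <- fit_opls(d$x, d$y, 0)
    ref <- suppressMessages(
      mixOmics::pls(d$x, d$y, ncomp = 1, scale = FALSE, mode = "regression"))
    yhat_ref <- predict(ref, d$x)$predict[, 1, 1]
    expect_equal(unname(m$t * m$c), unname(yhat_ref), tolerance = 1e-8)
  }
})

test_that("orthogonal scores are orthogonal to the predictive score", {
  d <- scaled_instance(n = 40, p = 30, seed = 7)
  for (a_o in 1:3) {
    m <- fit_opls(d$x, d$y, a_o)
    expect_equal(m$n_components[["x_orthogonal"]], a_o)
    expect_lt(max(abs(crossprod(m$t, m$T_o))), 1e-8)
    expect_equal(sum(m$w^2), 1, tolerance = 1e-12)
    # coefficient vector reproduces the fitted values
    expect_equal(unname(c(d$x %*% m$coefficients)), unname(m$t * m$c),
                 tolerance = 1e-10)
  }
})

test_that("an added y-orthogonal structured factor is removed by one component", {
  set.seed(11)
  n <- 40; p <- 25
  y <- scale(rnorm(n))[, 1]
  p1 <- rnorm(p); po <- rnorm(p)
  t_o <- scale(residuals(lm(rnorm(n) ~ y)))[, 1]   # orthogonal to y
  x0 <- outer(y, p1)
  colnames(x0) <- paste0("V", 1:p)
  x1 <- x0 + 3 * outer(t_o, po)
  clean <- fit_opls(x0, y, 0)
  aug <- fit_opls(x1, y, 1)
  expect_equal(unname(aug$t), unname(clean$t), tolerance = 1e-6)
  expect_equal(aug$r2, clean$r2, tolerance = 1e-6)
})

test_that("predictions are invariant to variable order and affine rescaling", {
  set.seed(3)
  n <- 24; p <- 15
  x <- matrix(rexp(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
  y <- rnorm(n)
  fit_raw <- function(xr) {
    sx <- uv_scale(xr); sy <- uv_scale(y)
    m <- fit_opls(sx$x, sy$x, 1, x_scaling = sx$params, y_scaling = sy$params)
    predict(m, xr)
  }
  base <- fit_raw(x)
  perm <- sample(p)
  expect_equal(fit_raw(x[, perm]), base, tolerance = 1e-8)
  resc <- sweep(sweep(x, 2, runif(p, 0.5, 4), "*"), 2, runif(p, -2, 2), "+")
  expect_equal(fit_raw(resc), base, tolerance = 1e-8)
})

test_that("degenerate OPLS inputs are rejected", {
  d <- scaled_instance(n = 10, p = 4, seed = 1)
  expect_error(fit_opls(d$x, rep(1, 10), 0), "constant")
  expect_error(fit_opls(d$x, d$y, 20), "rank")
  expect_error(fit_opls(d$x, d$y[-1], 0), "align")
})

test_that("grouped folds keep replicates together with balanced sizes", {
  sid <- rep(sprintf("S%02d", 1:26), each = 3)
  folds <- make_grouped_folds(sid, k = 7, seed = 4)
  # every injection of a sample shares its fold
  per_sample <- tapply(folds$fold, sid, function(f) length(unique(f)))
  expect_true(all(per_sample == 1))
  # 26 samples over 7 folds: five folds of 4, two of 3
  sizes <- sort(as.vector(table(folds$sample_fold)))
  expect_equal(sizes, c(3, 3, 4, 4, 4, 4, 4))
  # deterministic given seed
  expect_identical(folds, make_grouped_folds(sid, k = 7, seed = 4))
  expect_false(identical(folds$sample_fold,
                         make_grouped_folds(sid, k = 7, seed = 5)$sample_fold))
  expect_error(make_grouped_folds(sid, k = 1), "k")
  expect_error(make_grouped_folds(sid, k = 30), "distinct samples")
})

test_that("grouped Q2 approaches 1 for noiseless signal and is fold-label invariant", {
  set.seed(9)
  n_s <- 150
  sid <- sprintf("S%03d", 1:n_s)
  x <- matrix(rnorm(n_s * 6), n_s, 6, dimnames = list(NULL, paste0("V", 1:6)))
  y <- 2 * x[, 1]
  folds <- make_grouped_folds(sid, k = 5, seed = 1)
  res <- grouped_q2(x, y, 0, folds)
  expect_gt(res$q2, 0.9)
  # relabeling folds leaves Q2 unchanged
  relab <- folds
  map <- sample(5)
  relab$fold <- map[folds$fold]
  relab$sample_fold <- stats::setNames(map[folds$sample_fold], names(folds$sample_fold))
  expect_equal(grouped_q2(x, y, 0, relab)$q2, res$q2, tolerance = 1e-12)
})

test_that("Q2 does not exceed R2 on typical draws and permuted y scores near zero", {
  set.seed(15)
  worse <- 0
  for (i in 1:10) {
    ds <- NULL
    n_s <- 20
    sid <- rep(sprintf("S%02d", 1:n_s), each = 2)
    x <- matrix(rnorm(40 * 15), 40, 15, dimnames = list(NULL, paste0("V", 1:15)))
    y <- x[, 1] + rnorm(40, sd = 0.5)
    folds <- make_grouped_folds(sid, k = 5, seed = i)
    q2 <- grouped_q2(x, y, 0, folds)$q2
    sx <- uv_scale(x); sy <- uv_scale(y)
    r2 <- fit_opls(sx$x, sy$x, 0)$r2
    if (q2 > r2) worse <- worse + 1
    q2_perm <- grouped_q2(x, sample(y), 0, folds)$q2
    expect_lt(q2_perm, 0.3)
  }
  expect_lte(worse, 1)
})

test_that("model serialization round-trips predictions", {
  set.seed(21)
  x <- matrix(rexp(30 * 8), 30, 8, dimnames = list(NULL, paste0("V", 1:8)))
  y <- rnorm(30)
  sx <- uv_scale(x); sy <- uv_scale(y)
  m <- fit_opls(sx$x, sy$x, 2, x_scaling = sx$params, y_scaling = sy$params)
  path <- withr::local_tempfile(fileext = ".json")
  write_opls_model(m, path)
  m2 <- read_opls_model(path)
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-10)
})
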