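# Orthogonal-component selection, permutation validation, CV-ANOVA and
# signed VIPpred variable importance.

fit_scaled <- function(x, y, a_o, rmse_denominator = "n") {
  sx <- suppressWarnings(uv_scale(x))
  sy <- uv_scale(y)
  fit_opls(sx$x, sy$x, a_o, x_scaling = sx$params, y_scaling = sy$params,
           rmse_denominator = rmse_denominator)
}

#' Forward search for the number of orthogonal components
#'
#' Starting from zero orthogonal components, a_o + 1 is accepted whenever it
#' strictly increases the grouped cross-validated Q2; the search stops at the
#' first non-increase (or at `max_a_o`) and the last accepted a_o is chosen,
#' so Q2 increases strictly along the accepted path.
#'
#' @param x raw injection-by-variable matrix.
#' @param y raw response per injection.
#' @param folds a [make_grouped_folds()] object.
#' @param max_a_o largest number of orthogonal components to try.
#' @param scale_in_fold see [grouped_q2()].
#' @return object of class `component_search_trace`: `trace` data.frame
#'   (a_o, r2, q2), `chosen`, `reason`.
#' @export
select_orthogonal_components <- function(x, y, folds, max_a_o = 8L,
                                         scale_in_fold = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  prep <- prepare_cv_folds(x, folds, scale_in_fold = scale_in_fold)
  rows <- list()
  chosen <- 0L
  reason <- "reached max_a_o"
  best_q2 <- -Inf
  for (a_o in 0:max_a_o) {
    q2 <- cv_q2(prep, y, a_o)$q2
    r2 <- fit_scaled(x, y, a_o)$r2
    rows[[a_o + 1L]] <- data.frame(a_o = a_o, r2 = r2, q2 = q2)
    if (q2 > best_q2) {
      best_q2 <- q2
      chosen <- a_o
    } else {
      reason <- "Q2 stopped increasing"
      break
    }
  }
  structure(list(trace = do.call(rbind, rows), chosen = chosen, reason = reason),
            class = "component_search_trace")
}

#' Permutation test of an OPLS model
#'
#' The response is permuted over samples (each injection keeps the permuted
#' value of its sample) `n_perm` times; for each permutation the model is
#' refit with the same number of orthogonal components and the same folds,
#' recording R2, grouped Q2 and the absolute Pearson correlation between the
#' permuted and original sample-level responses. Least-squares lines through
#' the permuted points plus the unpermuted model at correlation 1 give the
#' R2 and Q2 intercepts. The model is flagged valid when the R2 intercept is
#' below 0.3, the Q2 intercept below -0.05 (no overfitting), and the
#' empirical permutation p-value of Q2 — the fraction of permutations
#' reaching the model's Q2, with the +1 correction — is below `p_limit`
#' (the model beats its own null distribution).
#'
#' @param x raw injection-by-variable matrix.
#' @param y raw response per injection.
#' @param a_o number of orthogonal components of the model under test.
#' @param folds a [make_grouped_folds()] object.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed for the permutations.
#' @param r2_limit,q2_limit intercept validity thresholds.
#' @param p_limit threshold on the permutation p-value of Q2.
#' @param scale_in_fold see [grouped_q2()].
#' @return object of class `permutation_report`: `permutations` data.frame
#'   (correlation, r2, q2), `r2_intercept`, `q2_intercept`, `p_r2`, `p_q2`,
#'   `model_r2`, `model_q2`, `valid_flag`.
#' @export
permutation_test <- function(x, y, a_o, folds, n_perm = 100L, seed = 1L,
                             r2_limit = 0.3, q2_limit = -0.05, p_limit = 0.05,
                             scale_in_fold = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  sid <- as.character(folds$sample_ids)
  samples <- unique(sid)
  y_sample <- c(tapply(y, sid, mean))[samples]
  prep <- prepare_cv_folds(x, folds, scale_in_fold = scale_in_fold)
  xs_full <- suppressWarnings(uv_scale(x))$x
  r2_full <- function(yv) {
    ys <- (yv - mean(yv)) / stats::sd(yv)
    core <- opls_core(xs_full, ys, a_o)
    1 - sum((ys - core$t * core$c)^2) / sum(ys^2)
  }
  perms <- with_seed(substream_seed(seed, "perm"),
                     replicate(n_perm, sample(length(samples)), simplify = FALSE))
  res <- vapply(perms, function(pr) {
    y_perm_sample <- stats::setNames(y_sample[pr], samples)
    y_perm <- unname(y_perm_sample[sid])
    c(abs(stats::cor(y_perm_sample, y_sample)), r2_full(y_perm),
      cv_q2(prep, y_perm, a_o)$q2)
  }, numeric(3L))
  model_r2 <- r2_full(y)
  model_q2 <- cv_q2(prep, y, a_o)$q2
  corr <- c(res[1L, ], 1)
  r2s <- c(res[2L, ], model_r2)
  q2s <- c(res[3L, ], model_q2)
  r2_int <- unname(stats::coef(stats::lm(r2s ~ corr))[1L])
  q2_int <- unname(stats::coef(stats::lm(q2s ~ corr))[1L])
  p_q2 <- (1 + sum(res[3L, ] >= model_q2)) / (n_perm + 1)
  p_r2 <- (1 + sum(res[2L, ] >= model_r2)) / (n_perm + 1)
  structure(list(
    permutations = data.frame(correlation = res[1L, ], r2 = res[2L, ], q2 = res[3L, ]),
    n_perm = n_perm, a_o = a_o,
    r2_intercept = r2_int, q2_intercept = q2_int,
    p_r2 = p_r2, p_q2 = p_q2,
    model_r2 = model_r2, model_q2 = model_q2,
    valid_flag = r2_int < r2_limit && q2_int < q2_limit && p_q2 < p_limit),
    class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf(
    "permutation test (n = %d, a_o = %d): R2 intercept %.3f, Q2 intercept %.3f, p(Q2) %.3f -> %s\n",
    x$n_perm, x$a_o, x$r2_intercept, x$q2_intercept, x$p_q2,
    if (x$valid_flag) "valid" else "NOT valid"))
  invisible(x)
}

#' Reduce orthogonal components until the permutation test passes
#'
#' Starting from the a_o chosen by [select_orthogonal_components()], the
#' permutation test is run; while it fails and a_o > 0, a_o is decremented
#' and the test repeated. The final model is returned together with its
#' permutation report (flagged invalid if no a_o passed).
#'
#' @inheritParams permutation_test
#' @param trace a [select_orthogonal_components()] result.
#' @return list with `model` (an [fit_opls()] model with `q2`/`press` filled
#'   in), `report` (the [permutation_test()] at the final a_o) and `a_o`.
#' @export
reduce_until_valid <- function(x, y, trace, folds, n_perm = 100L, seed = 1L,
                               scale_in_fold = TRUE) {
  a_o <- trace$chosen
  repeat {
    report <- permutation_test(x, y, a_o, folds, n_perm = n_perm, seed = seed,
                               scale_in_fold = scale_in_fold)
    if (report$valid_flag || a_o == 0L) break
    a_o <- a_o - 1L
  }
  model <- finalize_model(x, y, a_o, folds, scale_in_fold = scale_in_fold)
  list(model = model, report = report, a_o = a_o)
}

# Full-data fit at a_o with cross-validation metrics attached.
finalize_model <- function(x, y, a_o, folds, scale_in_fold = TRUE,
                           rmse_denominator = "n") {
  model <- fit_scaled(x, y, a_o, rmse_denominator = rmse_denominator)
  cv <- grouped_q2(x, y, a_o, folds, scale_in_fold = scale_in_fold)
  model$q2 <- cv$q2
  model$press <- cv$press
  model$ss_tot_cv <- cv$ss_tot
  model$folds <- folds
  model
}

#' CV-ANOVA significance test
#'
#' F-test of the cross-validated predictive residuals against the total
#' response variation: F = ((ss_tot - press)/a) / (press/(n - a - 1)) with a
#' the total number of latent variables, referred to the F(a, n - a - 1)
#' distribution. Small p-values indicate that cross-validated predictions
#' explain real variation.
#'
#' @param press cross-validated predictive residual sum of squares.
#' @param ss_tot total sum of squares of the (scaled) response over the same
#'   held-out predictions.
#' @param n number of injections.
#' @param a total number of latent variables (predictive + orthogonal).
#' @return list with `f_value` and `p_value`.
#' @export
cv_anova <- function(press, ss_tot, n, a) {
  if (press < 0 || ss_tot <= 0) stop("press and ss_tot must be positive")
  df1 <- a
  df2 <- n - a - 1
  if (df1 < 1 || df2 < 1) stop("non-positive degrees of freedom")
  f <- max((ss_tot - press) / df1 / (press / df2), 0)
  list(f_value = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Predictive-component VIP (VIPpred)
#'
#' Variable importance in projection over the single predictive component:
#' vip_j = sqrt(p) * |w_j| / ||w||, so the mean squared VIP over the
#' variables retained in the model is exactly 1. Orthogonal components do not
#' enter by definition of the predictive VIP.
#'
#' @param model a fitted [fit_opls()] model.
#' @return object of class `vip_report`: data.frame with `variable` and
#'   `vip_pred`.
#' @export
vip_pred <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  w <- model$w
  vip <- sqrt(length(w)) * abs(w) / sqrt(sum(w^2))
  structure(data.frame(variable = names(w), vip_pred = unname(vip),
                       stringsAsFactors = FALSE),
            class = c("vip_report", "data.frame"))
}

#' Sign VIPs by correlation with the response and select variables
#'
#' The Pearson correlation between each variable's sample-mean values and the
#' attribute's sample-mean scores gives the sign of the VIP; a variable is
#' selected when its (unsigned) VIPpred strictly exceeds the threshold.
#' Zero-variance variables get sign 0 and are never selected.
#'
#' @param vips a [vip_pred()] report.
#' @param x_sample_means sample-by-variable matrix of mean intensities.
#' @param y_means sample-level mean scores, aligned to the rows of
#'   `x_sample_means`.
#' @param threshold selection threshold on unsigned VIPpred (strict >).
#' @param annotation optional data.frame keyed by `peak_id` to carry through
#'   (e.g. the `annotation` element of [annotate_peaks()]).
#' @return the report with `pearson_r`, `signed_vip`, `selected` columns (and
#'   annotation columns when given).
#' @export
sign_and_select <- function(vips, x_sample_means, y_means, threshold = 1.5,
                            annotation = NULL) {
  stopifnot(inherits(vips, "vip_report"))
  x_sample_means <- as.matrix(x_sample_means)
  missing <- setdiff(vips$variable, colnames(x_sample_means))
  if (length(missing)) stop("sample means missing for some model variables")
  xm <- x_sample_means[, vips$variable, drop = FALSE]
  y <- as.numeric(y_means)
  if (length(y) != nrow(xm)) stop("y_means must align with the rows of x_sample_means")
  sds <- col_sds(xm)
  r <- rep(0, ncol(xm))
  ok <- sds > 0 & stats::sd(y) > 0
  if (any(ok)) r[ok] <- suppressWarnings(as.vector(stats::cor(xm[, ok, drop = FALSE], y)))
  vips$pearson_r <- r
  vips$signed_vip <- sign(r) * vips$vip_pred
  vips$selected <- vips$vip_pred > threshold & sds > 0
  if (!is.null(annotation)) {
    idx <- match(vips$variable, annotation$peak_id)
    for (nm in setdiff(names(annotation), "peak_id"))
      vips[[nm]] <- annotation[[nm]][idx]
  }
  vips
}

#' Fit, tune and validate an OPLS model for one attribute
#'
#' The full single-attribute modeling recipe: replicate-grouped folds, the
#' forward search over orthogonal components, optional permutation-based
#' reduction, a final full-data fit with cross-validation metrics, and
#' CV-ANOVA.
#'
#' @param x raw injection-by-variable matrix.
#' @param y raw response per injection (sample mean score, replicated over a
#'   sample's injections).
#' @param sample_ids sample id per injection.
#' @param k folds (default 7).
#' @param seed integer seed (folds and permutations).
#' @param max_a_o forward-search limit.
#' @param n_perm permutations (default 100).
#' @param validate run the permutation reduction (default TRUE).
#' @param scale_in_fold see [grouped_q2()].
#' @return list of class `opls_build`: `model`, `trace`, `report` (NULL when
#'   `validate = FALSE`), `folds`, `cv_anova`.
#' @export
build_opls_model <- function(x, y, sample_ids, k = 7L, seed = 1L, max_a_o = 8L,
                             n_perm = 100L, validate = TRUE,
                             scale_in_fold = TRUE) {
  x <- as.matrix(x)
  folds <- make_grouped_folds(sample_ids, k = k, seed = seed)
  trace <- select_orthogonal_components(x, y, folds, max_a_o = max_a_o,
                                        scale_in_fold = scale_in_fold)
  if (validate) {
    red <- reduce_until_valid(x, y, trace, folds, n_perm = n_perm, seed = seed,
                              scale_in_fold = scale_in_fold)
    model <- red$model
    report <- red$report
  } else {
    model <- finalize_model(x, y, trace$chosen, folds, scale_in_fold = scale_in_fold)
    report <- NULL
  }
  a_tot <- 1L + model$n_components[["x_orthogonal"]]
  ca <- cv_anova(model$press, model$ss_tot_cv, length(y), a_tot)
  structure(list(model = model, trace = trace, report = report, folds = folds,
                 cv_anova = ca), class = "opls_build")
}
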