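# Single-response OPLS (orthogonal projections to latent structures) by
# NIPALS, with replicate-grouped cross-validation. Models are written
# "1 + k + 0": one predictive component, k X-orthogonal components, no
# y-orthogonal components (single response).

opls_core <- function(X, y, a_o) {
  p <- ncol(X)
  W_o <- P_o <- matrix(0, p, 0)
  T_o <- matrix(0, nrow(X), 0)
  Xd <- X
  for (i in seq_len(a_o)) {
    w <- crossprod(Xd, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) stop("y is orthogonal to X; cannot extract a predictive weight")
    w <- w / nw
    t <- Xd %*% w
    pl <- crossprod(Xd, t) / sum(t^2)
    wo <- pl - c(crossprod(w, pl)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break                 # no orthogonal variation left
    wo <- wo / nwo
    to <- Xd %*% wo
    po <- crossprod(Xd, to) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    W_o <- cbind(W_o, wo); P_o <- cbind(P_o, po); T_o <- cbind(T_o, to)
  }
  w <- crossprod(Xd, y)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-14) stop("y is orthogonal to X; cannot extract a predictive weight")
  w <- w / nw
  t <- Xd %*% w
  p_load <- crossprod(Xd, t) / sum(t^2)
  cc <- sum(t * y) / sum(t^2)
  rownames(w) <- rownames(p_load) <- colnames(X)
  if (ncol(W_o)) rownames(W_o) <- rownames(P_o) <- colnames(X)
  # net coefficient vector on the scaled X: yhat = X %*% coef
  coef <- w * cc
  for (i in rev(seq_len(ncol(W_o))))
    coef <- coef - W_o[, i] * c(crossprod(P_o[, i], coef))
  list(w = w[, 1L], t = t[, 1L], p_load = p_load[, 1L], c = cc,
       W_o = W_o, P_o = P_o, T_o = T_o, a_o = ncol(W_o),
       coefficients = coef[, 1L])
}

# Remove the model's orthogonal components from (scaled) new data.
opls_filter <- function(model, Xs) {
  for (i in seq_len(NCOL(model$W_o))) {
    to <- Xs %*% model$W_o[, i]
    Xs <- Xs - tcrossprod(to, model$P_o[, i, drop = FALSE])
  }
  Xs
}

#' Fit a single-response OPLS model
#'
#' NIPALS O-PLS for one response: the predictive weight is proportional to
#' X'y; each of `a_o` rounds extracts an X-orthogonal component from the
#' predictive loading and deflates X, so that the final single predictive
#' component is computed on the orthogonality-filtered matrix. Inputs are
#' expected UV-scaled (see [uv_scale()]); pass the scaling parameter objects
#' so the model can predict on, and report errors in, the original score
#' scale.
#'
#' @param X scaled injection-by-variable matrix.
#' @param y scaled response, one value per injection.
#' @param a_o number of X-orthogonal components (>= 0).
#' @param x_scaling,y_scaling optional `params` from [uv_scale()]; stored for
#'   prediction and original-scale RMSE.
#' @param rmse_denominator `"n"` (default) or `"df"` (n - a - 1) for the
#'   training RMSE.
#' @return object of class `opls_model`: predictive weight `w` (unit norm),
#'   scores `t`, loading `p_load`, y-loading `c`, orthogonal `W_o`/`P_o`/`T_o`,
#'   `n_components` (1, a_o, 0), net `coefficients` on scaled X, `r2`, `rmse`
#'   (original y scale when `y_scaling` given), plus `q2`/`press`/`folds`
#'   filled in by the cross-validation helpers.
#' @export
fit_opls <- function(X, y, a_o, x_scaling = NULL, y_scaling = NULL,
                     rmse_denominator = c("n", "df")) {
  rmse_denominator <- match.arg(rmse_denominator)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  stopifnot_scalar_count(a_o, "a_o", min = 0L)
  if (stats::sd(y) == 0) stop("y is constant")
  if (a_o >= min(nrow(X) - 1L, ncol(X)))
    stop("a_o must be smaller than the rank of X")
  core <- opls_core(X, y, a_o)
  yhat_s <- core$t * core$c
  ss_res <- sum((y - yhat_s)^2)
  ss_tot <- sum((y - mean(y))^2)
  n <- length(y)
  denom <- if (rmse_denominator == "n") n else max(n - (1L + core$a_o) - 1L, 1L)
  if (!is.null(y_scaling)) {
    sdy <- unname(y_scaling$sd[y_scaling$kept[1L]])
    rmse <- sqrt(ss_res / denom) * sdy
  } else {
    rmse <- sqrt(ss_res / denom)
  }
  structure(c(core, list(
    n_components = c(predictive = 1L, x_orthogonal = core$a_o, y_orthogonal = 0L),
    x_scaling = x_scaling, y_scaling = y_scaling,
    fitted_scaled = yhat_s,
    r2 = 1 - ss_res / ss_tot, rmse = rmse,
    q2 = NA_real_, press = NA_real_, folds = NULL)),
    class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("OPLS model (%s): R2 = %.3f, RMSE = %.3g",
              format_components(x), x$r2, x$rmse))
  if (is.finite(x$q2)) cat(sprintf(", Q2 = %.3f", x$q2))
  cat("\n")
  invisible(x)
}

format_components <- function(model) {
  nc <- model$n_components
  sprintf("%d + %d + %d", nc[[1L]], nc[[2L]], nc[[3L]])
}

#' Predict from an OPLS model
#'
#' New data are scaled with the model's training scaling parameters, the
#' model's orthogonal components are filtered out, and the predictive score
#' times the y-loading gives the prediction, back-transformed to the original
#' response scale when the model stores y-scaling.
#'
#' @param object fitted [fit_opls()] model holding `x_scaling`.
#' @param newdata raw injection-by-variable matrix with named columns.
#' @param scaled set `TRUE` if `newdata` is already scaled to the model's
#'   training scale.
#' @param ... unused.
#' @export
predict.opls_model <- function(object, newdata, scaled = FALSE, ...) {
  newdata <- as.matrix(newdata)
  if (scaled || is.null(object$x_scaling)) {
    Xs <- newdata[, names(object$w), drop = FALSE]
  } else {
    Xs <- uv_scale(newdata, object$x_scaling)$x
    Xs <- Xs[, names(object$w), drop = FALSE]
  }
  yhat_s <- c(opls_filter(object, Xs) %*% object$w) * object$c
  if (!is.null(object$y_scaling) && !scaled) {
    v <- object$y_scaling$kept[1L]
    yhat_s * object$y_scaling$sd[v] + object$y_scaling$mean[v]
  } else yhat_s
}

#' Replicate-grouped cross-validation folds
#'
#' Assigns whole samples (with all their replicate injections) to folds, so
#' that no sample contributes injections to more than one fold. Samples are
#' shuffled deterministically by `seed` and dealt round-robin; fold sizes
#' differ by at most one sample.
#'
#' @param sample_ids sample identifier per injection.
#' @param k number of folds (default 7).
#' @param seed integer seed for the shuffle.
#' @return object of class `grouped_folds`: `fold` (per injection),
#'   `sample_fold` (named, per sample), `sample_ids`, `k`, `seed`.
#' @export
make_grouped_folds <- function(sample_ids, k = 7L, seed = 1L) {
  samples <- unique(sample_ids)
  stopifnot_scalar_count(k, "k", min = 2L)
  if (k > length(samples)) stop("k exceeds the number of distinct samples")
  shuffled <- with_seed(substream_seed(seed, "folds"), sample(samples))
  sample_fold <- stats::setNames(rep_len(seq_len(k), length(samples)), shuffled)
  structure(list(fold = unname(sample_fold[as.character(sample_ids)]),
                 sample_fold = sample_fold,
                 sample_ids = sample_ids, k = as.integer(k), seed = seed),
            class = "grouped_folds")
}

#' Grouped cross-validated Q2
#'
#' For each fold, scaling parameters and the OPLS fit are computed on the
#' training injections only (variables that become constant within a training
#' fold are dropped for that fold); held-out injections are scaled with the
#' training parameters and predicted. PRESS accumulates squared residuals on
#' the scaled response; Q2 = 1 - PRESS/SS, with SS the total sum of squares of
#' the held-out responses scaled by their fold's training parameters.
#'
#' @param x raw injection-by-variable matrix.
#' @param y raw response per injection.
#' @param a_o number of orthogonal components.
#' @param folds a [make_grouped_folds()] object.
#' @param scale_in_fold re-estimate scaling inside each training fold
#'   (default). `FALSE` reproduces the global-scaling convention of common
#'   commercial chemometrics software.
#' @return list with `q2`, `press`, `ss_tot`.
#' @export
grouped_q2 <- function(x, y, a_o, folds, scale_in_fold = TRUE) {
  prep <- prepare_cv_folds(as.matrix(x), folds, scale_in_fold = scale_in_fold)
  cv_q2(prep, as.numeric(y), a_o)
}

# Per-fold scaled training/test X blocks; the X-side scaling does not depend
# on y, so cross-validation over many responses (permutations, component
# search) reuses one preparation.
prepare_cv_folds <- function(x, folds, scale_in_fold = TRUE) {
  if (!inherits(folds, "grouped_folds")) stop("`folds` must come from make_grouped_folds()")
  if (length(folds$fold) != nrow(x)) stop("x and folds must align")
  if (!scale_in_fold) gx <- uv_scale(x)
  out <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    test <- folds$fold == f
    if (!any(test)) next
    if (scale_in_fold) {
      sx <- suppressWarnings(uv_scale(x[!test, , drop = FALSE]))
      xs_te <- uv_scale(x[test, , drop = FALSE], sx$params)$x
    } else {
      sx <- list(x = gx$x[!test, , drop = FALSE], params = gx$params)
      xs_te <- gx$x[test, , drop = FALSE]
    }
    out[[f]] <- list(xs_tr = sx$x, xs_te = xs_te, test = which(test),
                     train = which(!test))
  }
  structure(list(folds = out, n = nrow(x), scale_in_fold = scale_in_fold),
            class = "cv_prep")
}

cv_q2 <- function(prep, y, a_o) {
  press <- 0; ss_tot <- 0
  for (fd in prep$folds) {
    if (is.null(fd)) next
    y_tr <- y[fd$train]
    mu <- mean(y_tr); sdy <- stats::sd(y_tr)
    if (sdy == 0) stop("y constant within a training fold")
    if (!prep$scale_in_fold) { mu <- mean(y); sdy <- stats::sd(y) }
    core <- opls_core(fd$xs_tr, (y_tr - mu) / sdy, a_o)
    ys_te <- (y[fd$test] - mu) / sdy
    yhat <- c(opls_filter(core, fd$xs_te) %*% core$w) * core$c
    press <- press + sum((ys_te - yhat)^2)
    ss_tot <- ss_tot + sum(ys_te^2)
  }
  list(q2 = 1 - press / ss_tot, press = press, ss_tot = ss_tot)
}
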