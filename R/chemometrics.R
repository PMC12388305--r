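#' Unit-variance (UV) scaling
#'
#' Centres each variable to mean 0 and scales to unit variance (n-1
#' denominator), the standard "autoscaling" used before PCA and OPLS on
#' metabolome peak tables. Variables with zero standard deviation on the
#' training data carry no information after scaling and are dropped (with a
#' warning); their names are recorded in the returned parameters.
#'
#' @param x numeric matrix (observations x variables) or numeric vector.
#' @param params optional scaling parameters from a previous call, to apply a
#'   training-set scaling to new (e.g. validation) data.
#' @return list with `x` (scaled matrix) and `params` (list with `mean`, `sd`,
#'   `kept`, `dropped`).
#' @export
uv_scale <- function(x, params = NULL) {
  vec <- length(dim(x)) < 2L
  if (vec) x <- matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, "y"))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (!is.null(params)) {
    missing <- setdiff(params$kept, colnames(x))
    if (length(missing))
      stop("variables in scaling params absent from `x`: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    xs <- x[, params$kept, drop = FALSE]
    xs <- sweep(xs, 2L, params$mean[params$kept], "-")
    xs <- sweep(xs, 2L, params$sd[params$kept], "/")
    return(list(x = if (vec) xs[, 1L] else xs, params = params))
  }
  mu <- colMeans(x)
  sd <- col_sds(x)
  keep <- is.finite(sd) & sd > 0
  if (!any(keep)) stop("all variables have zero standard deviation")
  if (any(!keep))
    warning(sprintf("dropping %d zero-variance variable(s) during UV scaling",
                    sum(!keep)))
  params <- list(mean = mu, sd = sd,
                 kept = colnames(x)[keep], dropped = colnames(x)[!keep])
  xs <- sweep(x[, keep, drop = FALSE], 2L, mu[keep], "-")
  xs <- sweep(xs, 2L, sd[keep], "/")
  list(x = if (vec) xs[, 1L] else xs, params = params)
}

#' PCA overview of a (scaled) data matrix
#'
#' SVD-based principal component analysis, intended for UV-scaled sample-mean
#' matrices (sensory attribute means, or analytical data). Explained variance
#' ratio of component k is sigma_k^2 / sum(sigma^2).
#'
#' @param x numeric matrix, already centred/scaled (see [uv_scale()]).
#' @param n_components number of components to retain (default: all).
#' @return object of class `pca_result` with `scores`, `loadings`,
#'   `explained_variance_ratio`.
#' @export
pca_overview <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least 2 samples and 2 variables")
  sv <- svd(x)
  ev <- sv$d^2
  if (sum(ev) <= 0) stop("input matrix has rank 0")
  k <- min(if (is.null(n_components)) length(sv$d) else n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = (ev / sum(ev))[seq_len(k)]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", nrow(x$loadings), "variables\n")
  evr <- round(100 * x$explained_variance_ratio[seq_len(min(5L, length(x$explained_variance_ratio)))], 1)
  cat("explained variance (%):", paste(evr, collapse = ", "), "\n")
  invisible(x)
}
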