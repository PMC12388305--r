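# QDA sensory-panel containers, box-whisker outlier QC, ANOVA gating and
# sample means.

#' Construct a sensory panel
#'
#' Long-format QDA records: one row per (panelist, sample, attribute, round)
#' score, plus the attribute scale bounds. Raw panels may contain scores
#' outside the scale (e.g. aberrant entries destined for QC); set
#' `check_bounds = TRUE` to enforce the scale instead.
#'
#' @param records data.frame with columns `panelist_id`, `sample_id`,
#'   `attribute`, `round`, `score`.
#' @param scales data.frame with columns `attribute`, `min`, `max`.
#' @param check_bounds error on scores outside the attribute scale.
#' @return object of class `sensory_panel`.
#' @export
sensory_panel <- function(records, scales, check_bounds = FALSE) {
  req <- c("panelist_id", "sample_id", "attribute", "round", "score")
  if (!all(req %in% names(records))) stop("records need columns: ", paste(req, collapse = ", "))
  if (!all(c("attribute", "min", "max") %in% names(scales)))
    stop("scales need columns attribute, min, max")
  if (any(scales$min >= scales$max)) stop("scale min must be below max")
  miss <- setdiff(unique(records$attribute), scales$attribute)
  if (length(miss)) stop("no scale for attribute(s): ", paste(miss, collapse = ", "))
  if (check_bounds) {
    lo <- scales$min[match(records$attribute, scales$attribute)]
    hi <- scales$max[match(records$attribute, scales$attribute)]
    if (any(records$score < lo | records$score > hi))
      stop("scores outside the attribute scale")
  }
  structure(list(records = as.data.frame(records, stringsAsFactors = FALSE),
                 scales = as.data.frame(scales, stringsAsFactors = FALSE)),
            class = "sensory_panel")
}

#' @export
print.sensory_panel <- function(x, ...) {
  cat(sprintf("sensory_panel: %d records, %d panelists, %d samples, %d attributes\n",
              nrow(x$records), length(unique(x$records$panelist_id)),
              length(unique(x$records$sample_id)),
              length(unique(x$records$attribute))))
  invisible(x)
}

#' Box-whisker outlier removal
#'
#' For each (sample, attribute) group (pooling panelists and rounds), Tukey
#' fences are computed from linear-interpolation quartiles: records strictly
#' below Q1 - 1.5*IQR or strictly above Q3 + 1.5*IQR (i.e. beyond the
#' whiskers, which are anchored at the extreme observations inside the
#' fences) are removed, in a single pass. Groups with fewer than 4 scores
#' pass through untouched.
#'
#' @param panel a [sensory_panel()].
#' @param k whisker multiplier (1.5, the boxplot convention).
#' @param quantile_type quantile algorithm (7 = linear interpolation).
#' @return list with `panel` (cleaned) and `removed` (the dropped records).
#' @export
remove_outliers <- function(panel, k = 1.5, quantile_type = 7L) {
  stopifnot(inherits(panel, "sensory_panel"))
  rec <- panel$records
  grp <- interaction(rec$sample_id, rec$attribute, drop = TRUE)
  drop <- logical(nrow(rec))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 4L) next
    q <- stats::quantile(rec$score[idx], c(0.25, 0.75), type = quantile_type,
                         names = FALSE)
    iqr <- q[2L] - q[1L]
    drop[idx] <- rec$score[idx] < q[1L] - k * iqr | rec$score[idx] > q[2L] + k * iqr
  }
  panel$records <- rec[!drop, , drop = FALSE]
  rownames(panel$records) <- NULL
  list(panel = panel, removed = rec[drop, , drop = FALSE])
}

#' One-way ANOVA gate for a sensory attribute
#'
#' Fixed-effects one-way ANOVA of the post-QC individual scores with sample
#' as the factor. Attributes whose samples do not differ (p >= alpha) are
#' excluded from downstream modeling. Degenerate within-group variation
#' (all residuals zero with non-zero between-group variation) yields an
#' infinite F and p = 0.
#'
#' @param panel a [sensory_panel()] (post-QC).
#' @param attribute attribute name to test.
#' @param alpha significance level (0.05).
#' @return one-row data.frame: `attribute`, `f_value`, `p_value`, `pass_flag`.
#' @export
anova_gate <- function(panel, attribute, alpha = 0.05) {
  stopifnot(inherits(panel, "sensory_panel"))
  rec <- panel$records[panel$records$attribute == attribute, , drop = FALSE]
  if (!nrow(rec)) stop("no records for attribute ", attribute)
  counts <- table(rec$sample_id)
  if (length(counts) < 2L || min(counts) < 2L)
    stop("ANOVA needs >= 2 samples with >= 2 scores each")
  fit <- stats::aov(score ~ factor(sample_id), data = rec)
  tab <- summary(fit)[[1L]]
  ms_b <- tab[1L, "Mean Sq"]; ms_w <- tab[2L, "Mean Sq"]
  if (ms_w <= .Machine$double.eps * max(ms_b, 1)) {
    f <- if (ms_b > 0) Inf else 0
    p <- if (ms_b > 0) 0 else 1
  } else {
    f <- tab[1L, "F value"]
    p <- tab[1L, "Pr(>F)"]
  }
  data.frame(attribute = attribute, f_value = f, p_value = p,
             pass_flag = p < alpha, stringsAsFactors = FALSE)
}

#' ANOVA gate over all attributes of a panel
#'
#' @param panel a [sensory_panel()].
#' @param alpha significance level.
#' @return data.frame with one row per attribute (see [anova_gate()]).
#' @export
anova_gate_all <- function(panel, alpha = 0.05) {
  res <- lapply(unique(panel$records$attribute), function(a)
    anova_gate(panel, a, alpha))
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Sample-mean sensory scores
#'
#' Arithmetic mean over the remaining records per (sample, attribute) cell,
#' the response used by PCA and OPLS.
#'
#' @param panel a [sensory_panel()] after QC.
#' @return object of class `sensory_means`: `means` (sample x attribute
#'   matrix, NA where a cell is empty) and `n_used` (records per cell).
#' @export
sample_means <- function(panel) {
  stopifnot(inherits(panel, "sensory_panel"))
  rec <- panel$records
  samples <- unique(rec$sample_id)
  attrs <- unique(rec$attribute)
  means <- n_used <- matrix(NA_real_, length(samples), length(attrs),
                            dimnames = list(samples, attrs))
  agg <- stats::aggregate(score ~ sample_id + attribute, data = rec,
                          FUN = mean)
  cnt <- stats::aggregate(score ~ sample_id + attribute, data = rec,
                          FUN = length)
  means[cbind(agg$sample_id, agg$attribute)] <- agg$score
  n_used[cbind(cnt$sample_id, cnt$attribute)] <- cnt$score
  n_used[is.na(n_used)] <- 0
  structure(list(means = means, n_used = n_used), class = "sensory_means")
}
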