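# Peak-table containers and the two quality filters applied to exported
# LC-MS peak tables before modeling, plus library annotation.

#' Construct a peak table
#'
#' An injection-by-peak intensity matrix with per-injection sample/replicate
#' metadata and per-peak retention time (minutes) and mass-to-charge (Da)
#' metadata. Every sample must carry the same number of replicate injections.
#'
#' @param intensities non-negative numeric matrix, injections x peaks.
#' @param sample_ids sample identifier per injection (row).
#' @param replicate replicate index per injection.
#' @param peak_meta data.frame with columns `peak_id`, `rt`, `mz` (one row per
#'   column of `intensities`); extra columns (e.g. `is_extra`) are carried
#'   along.
#' @return object of class `peak_table` with elements `intensities`,
#'   `injections`, `peaks`.
#' @export
peak_table <- function(intensities, sample_ids, replicate, peak_meta) {
  intensities <- as.matrix(intensities)
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  if (nrow(intensities) != length(sample_ids) || length(sample_ids) != length(replicate))
    stop("sample_ids and replicate must have one entry per injection")
  if (!all(c("peak_id", "rt", "mz") %in% names(peak_meta)))
    stop("peak_meta needs columns peak_id, rt, mz")
  peak_meta <- as.data.frame(peak_meta, stringsAsFactors = FALSE)
  if (nrow(peak_meta) != ncol(intensities))
    stop("peak_meta must have one row per peak column")
  if (anyDuplicated(peak_meta$peak_id)) stop("peak_ids must be unique")
  real <- if ("is_extra" %in% names(peak_meta)) !peak_meta$is_extra else rep(TRUE, nrow(peak_meta))
  if (any(!is.na(peak_meta$rt[real]) & peak_meta$rt[real] <= 0) ||
      any(!is.na(peak_meta$mz[real]) & peak_meta$mz[real] <= 0))
    stop("rt and mz must be positive")
  if (length(unique(table(sample_ids))) > 1L)
    stop("every sample must have the same replicate count")
  colnames(intensities) <- peak_meta$peak_id
  rownames(intensities) <- paste(sample_ids, replicate, sep = "_r")
  structure(list(intensities = intensities,
                 injections = data.frame(sample_id = as.character(sample_ids),
                                         replicate = as.integer(replicate),
                                         stringsAsFactors = FALSE),
                 peaks = peak_meta),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table: %d injections (%d samples), %d peaks\n",
              nrow(x$intensities), length(unique(x$injections$sample_id)),
              ncol(x$intensities)))
  invisible(x)
}

subset_peaks <- function(table, keep) {
  table$intensities <- table$intensities[, keep, drop = FALSE]
  table$peaks <- table$peaks[keep, , drop = FALSE]
  rownames(table$peaks) <- NULL
  table
}

#' Remove peaks whose maximum intensity is zero
#'
#' Drops every peak column whose maximum over all injections is zero (i.e.
#' never detected); column order is otherwise preserved.
#'
#' @param table a [peak_table()].
#' @export
remove_zero_max_peaks <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  keep <- apply(table$intensities, 2L, max) > 0
  subset_peaks(table, keep)
}

#' Per-sample replicate coefficients of variation
#'
#' CV (percent) of the replicate injections of each sample for each peak:
#' 100 * sd / mean with the n-1 standard deviation. A zero replicate mean
#' yields `Inf` (undetected in that sample), which forces removal by
#' [filter_by_replicate_cv()].
#'
#' @param table a [peak_table()].
#' @return samples x peaks matrix of percent CVs.
#' @export
replicate_cv <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  sid <- table$injections$sample_id
  if (min(table(sid)) < 2L) stop("replicate CV undefined: a sample has a single injection")
  samples <- unique(sid)
  out <- matrix(NA_real_, length(samples), ncol(table$intensities),
                dimnames = list(samples, colnames(table$intensities)))
  for (s in samples) {
    block <- table$intensities[sid == s, , drop = FALSE]
    m <- colMeans(block)
    cv <- 100 * col_sds(block) / m
    cv[m == 0] <- Inf
    out[s, ] <- cv
  }
  out
}

#' Filter peaks by maximum replicate CV
#'
#' Removes every peak whose replicate CV reaches or exceeds the threshold
#' (default 10%, inclusive) for any sample. Zero-maximum peaks should be
#' removed first; a peak with a zero replicate mean in some sample is always
#' removed.
#'
#' @param table a [peak_table()] with zero-max peaks already removed.
#' @param threshold_percent inclusive removal threshold in percent.
#' @export
filter_by_replicate_cv <- function(table, threshold_percent = 10) {
  if (threshold_percent <= 0) stop("threshold must be positive")
  cv <- replicate_cv(table)
  worst <- apply(cv, 2L, max)
  subset_peaks(table, worst < threshold_percent)
}

#' Annotate peaks against a compound library
#'
#' A library entry is a candidate for a peak when both the retention-time and
#' mass-to-charge differences fall within the tolerances (inclusive by
#' default). The assigned annotation minimises the normalised combined
#' distance |dRT|/rt_tol + |dmz|/mz_tol, with ties broken by compound name;
#' all candidates are retained.
#'
#' @param table a [peak_table()].
#' @param library data.frame with `compound_name`, `rt`, `mz`,
#'   `compound_group`.
#' @param rt_tol,mz_tol matching tolerances in minutes and daltons.
#' @param inclusive use `<=` (default) rather than `<` at the tolerance.
#' @return the table with `annotation` (one row per peak; NA where unmatched)
#'   and `candidates` data.frames attached; class `annotated_peak_table`.
#' @export
annotate_peaks <- function(table, library, rt_tol = 0.1, mz_tol = 0.007,
                           inclusive = TRUE) {
  stopifnot(inherits(table, "peak_table"))
  if (rt_tol <= 0 || mz_tol <= 0) stop("tolerances must be positive")
  if (!all(c("compound_name", "rt", "mz") %in% names(library)))
    stop("library needs columns compound_name, rt, mz")
  if (is.null(library$compound_group)) library$compound_group <- NA_character_
  cmp <- if (inclusive) `<=` else `<`
  pk <- table$peaks
  cand <- vector("list", nrow(pk))
  ann <- data.frame(peak_id = pk$peak_id, compound_name = NA_character_,
                    compound_group = NA_character_, delta_rt = NA_real_,
                    delta_mz = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pk))) {
    if (!is.na(pk$rt[i])) {
      drt <- library$rt - pk$rt[i]
      dmz <- library$mz - pk$mz[i]
      hit <- cmp(abs(drt), rt_tol) & cmp(abs(dmz), mz_tol)
    } else hit <- logical(nrow(library))
    if (any(hit)) {
      ci <- data.frame(peak_id = pk$peak_id[i],
                       compound_name = library$compound_name[hit],
                       compound_group = library$compound_group[hit],
                       delta_rt = drt[hit], delta_mz = dmz[hit],
                       distance = abs(drt[hit]) / rt_tol + abs(dmz[hit]) / mz_tol,
                       stringsAsFactors = FALSE)
      ci <- ci[order(ci$distance, ci$compound_name), , drop = FALSE]
      cand[[i]] <- ci
      ann$compound_name[i] <- ci$compound_name[1L]
      ann$compound_group[i] <- ci$compound_group[1L]
      ann$delta_rt[i] <- ci$delta_rt[1L]
      ann$delta_mz[i] <- ci$delta_mz[1L]
    }
  }
  table$annotation <- ann
  table$candidates <- do.call(rbind, c(cand, list(make.row.names = FALSE)))
  class(table) <- c("annotated_peak_table", class(table))
  table
}

#' Merge per-sample explanatory variables into a peak table
#'
#' Appends general-property or aroma columns (acidity, ethyl hexanoate, ...)
#' as pseudo-peak columns. Values measured once per sample are broadcast to
#' all of that sample's injections; a matrix with one row per injection is
#' used as-is.
#'
#' @param table a [peak_table()].
#' @param extras data.frame/matrix of extra variables with rownames either
#'   the table's sample ids (per-sample) or one row per injection.
#' @export
merge_extra_variables <- function(table, extras) {
  stopifnot(inherits(table, "peak_table"))
  if (is.null(extras) || ncol(as.matrix(extras)) == 0L) return(table)
  extras <- as.matrix(extras)
  sids <- table$injections$sample_id
  if (nrow(extras) == nrow(table$intensities) && is.null(rownames(extras))) {
    vals <- extras
  } else if (!is.null(rownames(extras)) && all(unique(sids) %in% rownames(extras))) {
    vals <- extras[sids, , drop = FALSE]
  } else if (nrow(extras) == nrow(table$intensities)) {
    vals <- extras
  } else {
    stop("extras must be indexed by the table's sample ids or have one row per injection")
  }
  if (is.null(colnames(vals))) colnames(vals) <- paste0("extra", seq_len(ncol(vals)))
  if (any(colnames(vals) %in% table$peaks$peak_id)) stop("extra variable names clash with peak ids")
  meta <- table$peaks
  if (is.null(meta$is_extra)) meta$is_extra <- FALSE
  extra_meta <- data.frame(peak_id = colnames(vals), rt = NA_real_, mz = NA_real_,
                           stringsAsFactors = FALSE)
  for (nm in setdiff(names(meta), names(extra_meta))) extra_meta[[nm]] <- NA
  extra_meta$is_extra <- TRUE
  table$intensities <- cbind(table$intensities, vals)
  table$peaks <- rbind(meta, extra_meta[names(meta)])
  rownames(table$peaks) <- NULL
  table
}

#' Sample-mean intensity matrix
#'
#' Averages replicate injections, giving the sample-by-peak matrix used for
#' correlation signing and for aligning with sensory sample means.
#'
#' @param table a [peak_table()].
#' @export
sample_mean_intensities <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  sid <- table$injections$sample_id
  samples <- unique(sid)
  out <- matrix(NA_real_, length(samples), ncol(table$intensities),
                dimnames = list(samples, colnames(table$intensities)))
  for (s in samples) out[s, ] <- colMeans(table$intensities[sid == s, , drop = FALSE])
  out
}
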