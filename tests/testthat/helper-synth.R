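# Small generator configuration for fast module tests: 12 samples, 60
# informative peaks, 2 attributes with 5 drivers each.
tiny_config <- function(seed = 1L, ...) {
  args <- list(
    n_samples = 12L, n_replicates = 3L,
    n_informative_peaks = 60L, n_zero_max_peaks = 3L, n_high_cv_peaks = 4L,
    n_panelists = 8L, n_rounds = 3L,
    attributes = default_attributes(n_driver_peaks = 5L)[c(1L, 3L), ],
    independent_fraction = 0.3, n_neighbor_peaks = 12L,
    n_decoy_library = 5L, seed = seed)
  do.call(generator_config, utils::modifyList(args, list(...)))
}

# Hand-built peak table: `mat` is samples x peaks of sample-level values;
# each sample gets `n_rep` identical replicate injections unless `jitter`
# supplies per-replicate values directly (injections x peaks).
toy_peak_table <- function(mat, n_rep = 3L, rt = NULL, mz = NULL) {
  n <- nrow(mat)
  p <- ncol(mat)
  inj <- mat[rep(seq_len(n), each = n_rep), , drop = FALSE]
  peak_table(inj,
             sample_ids = rep(sprintf("S%02d", seq_len(n)), each = n_rep),
             replicate = rep(seq_len(n_rep), times = n),
             peak_meta = data.frame(
               peak_id = if (is.null(colnames(mat))) sprintf("P%03d", seq_len(p))
                         else colnames(mat),
               rt = if (is.null(rt)) seq_len(p) else rt,
               mz = if (is.null(mz)) 100 + seq_len(p) else mz))
}

# Long-format panel from a score vector for one (sample, attribute) group
# plus filler groups so ANOVA preconditions hold.
toy_panel <- function(scores, attribute = "sweetness", sample = "S01") {
  rec <- data.frame(panelist_id = sprintf("J%02d", seq_along(scores)),
                    sample_id = sample, attribute = attribute,
                    round = 1L, score = scores, stringsAsFactors = FALSE)
  sensory_panel(rec, data.frame(attribute = attribute, min = 0, max = 10))
}

# Type-7 quantile computed from first principles (independent of
# stats::quantile): position 1 + (n-1)p interpolated on the sorted values.
manual_quantile <- function(x, p) {
  xs <- sort(x)
  pos <- 1 + (length(x) - 1) * p
  lo <- floor(pos)
  xs[lo] + (pos - lo) * (xs[min(lo + 1, length(x))] - xs[lo])
}
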