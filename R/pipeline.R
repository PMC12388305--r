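# End-to-end orchestration: preprocessing, sensory QC, per-attribute OPLS
# models with validation and VIP selection, and a simulation dashboard
# against the generator's ground truth.

#' Run the full metabolome-to-sensory analysis
#'
#' Executes the pipeline on in-memory objects: zero-max filter, replicate-CV
#' filter and annotation on the peak table; box-whisker outlier removal and
#' one-way ANOVA gating on the panel; then, per passing attribute, an OPLS
#' model with grouped cross-validation, permutation validation, CV-ANOVA and
#' signed VIPpred selection. Attributes failing the ANOVA gate appear in the
#' report without a model. A fixed seed makes the report reproducible.
#'
#' @param peaks a [peak_table()].
#' @param library annotation library data.frame (or NULL to skip annotation).
#' @param panel a [sensory_panel()].
#' @param extras optional per-sample explanatory variables (see
#'   [merge_extra_variables()]).
#' @param cv_threshold replicate-CV removal threshold (percent).
#' @param rt_tol,mz_tol annotation tolerances.
#' @param alpha ANOVA gate level.
#' @param k,n_perm,max_a_o,vip_threshold modeling settings.
#' @param validate run permutation validation (default TRUE).
#' @param seed master seed; per-attribute substreams derive from it.
#' @param attributes restrict modeling to these attributes (default: all).
#' @return object of class `run_report`: `filter_summary`, `anova`, `table`
#'   (one row per attribute with the latent-variable notation "1 + k + 0",
#'   R2, RMSE, Q2, number of selected variables and CV-ANOVA p), `models`,
#'   `vip`, `removed_outliers`, `sensory_means`, `peaks` (processed table).
#' @export
run_full <- function(peaks, library = NULL, panel, extras = NULL,
                     cv_threshold = 10, rt_tol = 0.1, mz_tol = 0.007,
                     alpha = 0.05, k = 7L, n_perm = 100L, max_a_o = 8L,
                     vip_threshold = 1.5, validate = TRUE, seed = 1L,
                     attributes = NULL) {
  stopifnot(inherits(peaks, "peak_table"), inherits(panel, "sensory_panel"))
  n0 <- ncol(peaks$intensities)
  t1 <- remove_zero_max_peaks(peaks)
  t2 <- filter_by_replicate_cv(t1, cv_threshold)
  filter_summary <- data.frame(
    stage = c("input", "zero_max_filter", "replicate_cv_filter"),
    peaks = c(n0, ncol(t1$intensities), ncol(t2$intensities)))
  if (!is.null(library)) t2 <- annotate_peaks(t2, library, rt_tol, mz_tol)
  if (!is.null(extras)) t2 <- merge_extra_variables(t2, extras)

  qc <- remove_outliers(panel)
  anova <- anova_gate_all(qc$panel, alpha = alpha)
  means <- sample_means(qc$panel)

  model_attrs <- if (is.null(attributes)) anova$attribute else attributes
  x <- t2$intensities
  sid <- t2$injections$sample_id
  xm <- sample_mean_intensities(t2)
  models <- list(); vips <- list(); rows <- list()
  for (a in model_attrs) {
    pass <- anova$pass_flag[anova$attribute == a]
    if (!length(pass) || !pass) {
      rows[[a]] <- data.frame(attribute = a, latent_variables = NA_character_,
                              r2 = NA_real_, rmse = NA_real_, q2 = NA_real_,
                              n_selected = NA_integer_, cv_anova_p = NA_real_,
                              valid = NA, stringsAsFactors = FALSE)
      next
    }
    y_means <- means$means[, a]
    if (anyNA(y_means[unique(sid)])) stop("attribute ", a, " has empty sensory cells")
    y <- unname(y_means[sid])
    build <- build_opls_model(x, y, sid, k = k,
                              seed = substream_seed(seed, paste0("attr_", a)),
                              max_a_o = max_a_o, n_perm = n_perm,
                              validate = validate)
    vr <- vip_pred(build$model)
    vr <- sign_and_select(vr, xm, y_means[rownames(xm)], threshold = vip_threshold,
                          annotation = if (!is.null(t2$annotation)) t2$annotation)
    models[[a]] <- build
    vips[[a]] <- vr
    rows[[a]] <- data.frame(
      attribute = a, latent_variables = format_components(build$model),
      r2 = build$model$r2, rmse = build$model$rmse, q2 = build$model$q2,
      n_selected = sum(vr$selected), cv_anova_p = build$cv_anova$p_value,
      valid = if (validate) build$report$valid_flag else NA,
      stringsAsFactors = FALSE)
  }
  structure(list(filter_summary = filter_summary, anova = anova,
                 table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 models = models, vip = vips,
                 removed_outliers = qc$removed, sensory_means = means,
                 peaks = t2, seed = seed),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Peak filters:", paste(sprintf("%s=%d", x$filter_summary$stage,
                                     x$filter_summary$peaks), collapse = " -> "), "\n")
  tab <- x$table
  tab$r2 <- round(tab$r2, 3); tab$q2 <- round(tab$q2, 3)
  tab$rmse <- round(tab$rmse, 2)
  tab$cv_anova_p <- signif(tab$cv_anova_p, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Simulate a study and evaluate recovery against ground truth
#'
#' Generates a synthetic dataset, optionally splits it into two "years", runs
#' the full pipeline on each part, and scores how well the analysis recovers
#' the planted structure: exactness of the peak filters, exactness of the
#' outlier QC, driver-peak recovery and sign agreement among selected
#' variables, and (with a split) cross-year validation R2 with a
#' common-variable reduced refit.
#'
#' @param config a [generator_config()].
#' @param transfer split into two years and run transfer validation.
#' @param split_fraction fraction of samples in year A.
#' @param attributes restrict to these attributes (default: all configured).
#' @param n_perm,validate,k,max_a_o,vip_threshold modeling settings (see
#'   [run_full()]); `validate = FALSE` skips permutation testing for speed.
#' @return list of class `sim_dashboard`: `reports`, `recovery` (named
#'   numeric metrics), `checks` (named logical pass/fail), `truth`.
#' @export
simulate_and_run <- function(config, transfer = FALSE, split_fraction = 0.5,
                             attributes = NULL, n_perm = 100L, validate = TRUE,
                             k = 7L, max_a_o = 8L, vip_threshold = 1.5) {
  ds <- generate_dataset(config)
  recovery <- c()
  checks <- c()

  eval_part <- function(part, seed_key) {
    run_full(part$peaks, part$library, part$panel,
             k = k, n_perm = n_perm, max_a_o = max_a_o,
             vip_threshold = vip_threshold, validate = validate,
             seed = substream_seed(config$seed, seed_key),
             attributes = attributes)
  }
  outlier_exact <- function(report, truth) {
    rem <- report$removed_outliers[, c("panelist_id", "sample_id", "attribute", "round")]
    inj <- truth$injected_outliers[, c("panelist_id", "sample_id", "attribute", "round")]
    key <- function(d) sort(do.call(paste, c(d, sep = "|")))
    identical(key(rem), key(inj))
  }
  driver_recovery <- function(report, truth) {
    hits <- signs <- c()
    for (a in names(report$vip)) {
      dm <- truth$driver_map[[a]]
      if (is.null(dm)) next
      vr <- report$vip[[a]]
      sel <- vr$variable[vr$selected]
      hits <- c(hits, dm$peak_id %in% sel)
      rec <- intersect(dm$peak_id, sel)
      if (length(rec)) {
        planted <- sign(dm$weight[match(rec, dm$peak_id)])
        observed <- sign(vr$signed_vip[match(rec, vr$variable)])
        signs <- c(signs, planted == observed)
      }
    }
    c(driver_recovery = mean(hits), sign_agreement = if (length(signs)) mean(signs) else NA_real_)
  }

  if (transfer) {
    yrs <- split_years(ds, split_fraction, seed = substream_seed(config$seed, "years"))
    rep_a <- eval_part(yrs$a, "run_a")
    rep_b <- eval_part(yrs$b, "run_b")
    reports <- list(a = rep_a, b = rep_b)
    part_ok <- function(rep_part) {
      kept <- colnames(rep_part$peaks$intensities)
      kept <- kept[!grepl("^extra", kept)]
      all(ds$truth$planted$informative %in% kept) &&
        all(kept %in% c(ds$truth$planted$informative, ds$truth$planted$high_cv))
    }
    checks["filters_exact"] <- part_ok(rep_a) && part_ok(rep_b)
    checks["outliers_exact"] <- outlier_exact(rep_a, yrs$a$truth) &&
      outlier_exact(rep_b, yrs$b$truth)
    dr <- (driver_recovery(rep_a, yrs$a$truth) + driver_recovery(rep_b, yrs$b$truth)) / 2
    recovery <- c(recovery, dr)
    # transfer per attribute modeled in both years, on the peaks retained in
    # both (models built on one year can only be applied to peaks the other
    # year's table also carries)
    common_attrs <- intersect(names(rep_a$models), names(rep_b$models))
    pairing <- align_variables(rep_a$peaks, rep_b$peaks)$pairs
    sid_a <- rep_a$peaks$injections$sample_id
    sid_b <- rep_b$peaks$injections$sample_id
    xa <- rep_a$peaks$intensities[, pairing$peak_a, drop = FALSE]
    xb <- rep_b$peaks$intensities[, pairing$peak_b, drop = FALSE]
    colnames(xb) <- pairing$peak_a
    r2s <- red_r2s <- frac <- c()
    for (a in common_attrs) {
      ya <- unname(rep_a$sensory_means$means[sid_a, a])
      yb <- unname(rep_b$sensory_means$means[sid_b, a])
      ba <- build_opls_model(xa, ya, sid_a, k = k,
                             seed = substream_seed(config$seed, paste0("tr_", a)),
                             max_a_o = max_a_o, n_perm = n_perm, validate = validate)
      pe <- predict_external(ba$model, xb, yb)
      r2s <- c(r2s, pe$r2_validation)
      id_pairs <- data.frame(peak_a = pairing$peak_a, peak_b = pairing$peak_a,
                             stringsAsFactors = FALSE)
      vip_a <- rep_a$vip[[a]]
      vip_b <- rep_b$vip[[a]]
      vip_b$variable <- pairing$peak_a[match(vip_b$variable, pairing$peak_b)]
      sel <- common_important(vip_a, vip_b, id_pairs, vip_threshold)
      rr <- refit_reduced(xa, ya, sid_a, xb, yb, sid_b, sel,
                          k = k, seed = substream_seed(config$seed, paste0("red_", a)),
                          max_a_o = max_a_o, n_perm = n_perm, validate = validate)
      if (!rr$skipped) {
        red_r2s <- c(red_r2s, rr$validation_a_on_b$r2_validation)
        frac <- c(frac, nrow(sel) / ncol(xa))
      }
    }
    recovery["transfer_r2"] <- stats::median(r2s)
    recovery["reduced_transfer_r2"] <- if (length(red_r2s)) stats::median(red_r2s) else NA_real_
    recovery["reduced_variable_fraction"] <- if (length(frac)) stats::median(frac) else NA_real_
  } else {
    rep1 <- eval_part(ds, "run")
    reports <- list(full = rep1)
    checks["filters_exact"] <-
      setequal(colnames(rep1$peaks$intensities), ds$truth$planted$informative)
    checks["outliers_exact"] <- outlier_exact(rep1, ds$truth)
    recovery <- c(recovery, driver_recovery(rep1, ds$truth))
    recovery["median_q2"] <- stats::median(rep1$table$q2, na.rm = TRUE)
  }
  checks["driver_recovery_ok"] <- is.finite(recovery[["driver_recovery"]]) &&
    recovery[["driver_recovery"]] >= 0.8
  structure(list(reports = reports, recovery = recovery, checks = checks,
                 truth = ds$truth, dataset = ds),
            class = "sim_dashboard")
}
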