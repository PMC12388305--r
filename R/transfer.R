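# Cross-dataset ("cross-year") transfer validation: variable alignment,
# external prediction, common-importance selection and reduced refits.

#' Align peak variables across two datasets
#'
#' Peaks are paired across two preprocessed tables by mutual nearest match
#' within the retention-time and mass-to-charge tolerances, using the
#' normalised combined distance |dRT|/rt_tol + |dmz|/mz_tol. Peaks without a
#' mutual match remain unpaired; exact distance ties are reported.
#'
#' @param table_a,table_b [peak_table()] objects.
#' @param rt_tol,mz_tol matching tolerances (minutes, daltons).
#' @return list with `pairs` (data.frame peak_a, peak_b, delta_rt, delta_mz,
#'   distance), `unpaired_a`, `unpaired_b`, `ties`.
#' @export
align_variables <- function(table_a, table_b, rt_tol = 0.1, mz_tol = 0.007) {
  stopifnot(inherits(table_a, "peak_table"), inherits(table_b, "peak_table"))
  if (rt_tol <= 0 || mz_tol <= 0) stop("tolerances must be positive")
  pa <- table_a$peaks; pb <- table_b$peaks
  real_a <- which(!is.na(pa$rt)); real_b <- which(!is.na(pb$rt))
  # candidate distances (normalised); Inf outside the tolerance box
  cand <- list()
  for (i in real_a) {
    drt <- pb$rt[real_b] - pa$rt[i]
    dmz <- pb$mz[real_b] - pa$mz[i]
    hit <- abs(drt) <= rt_tol & abs(dmz) <= mz_tol
    if (any(hit))
      cand[[length(cand) + 1L]] <- data.frame(
        a = i, b = real_b[hit], delta_rt = drt[hit], delta_mz = dmz[hit],
        distance = abs(drt[hit]) / rt_tol + abs(dmz[hit]) / mz_tol)
  }
  pairs <- data.frame(peak_a = character(), peak_b = character(),
                      delta_rt = numeric(), delta_mz = numeric(),
                      distance = numeric(), stringsAsFactors = FALSE)
  ties <- pairs
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    # mutual nearest: keep (a, b) iff b is a's closest candidate and vice versa
    best_for_a <- tapply(seq_len(nrow(cand)), cand$a,
                         function(ix) ix[which.min(cand$distance[ix])])
    best_for_b <- tapply(seq_len(nrow(cand)), cand$b,
                         function(ix) ix[which.min(cand$distance[ix])])
    mutual <- intersect(unlist(best_for_a), unlist(best_for_b))
    tie_rows <- unlist(tapply(seq_len(nrow(cand)), cand$a, function(ix) {
      d <- cand$distance[ix]
      if (sum(d == min(d)) > 1L) ix[d == min(d)] else integer()
    }))
    m <- cand[mutual, , drop = FALSE]
    pairs <- data.frame(peak_a = pa$peak_id[m$a], peak_b = pb$peak_id[m$b],
                        delta_rt = m$delta_rt, delta_mz = m$delta_mz,
                        distance = m$distance, stringsAsFactors = FALSE)
    if (length(tie_rows))
      ties <- data.frame(peak_a = pa$peak_id[cand$a[tie_rows]],
                         peak_b = pb$peak_id[cand$b[tie_rows]],
                         delta_rt = cand$delta_rt[tie_rows],
                         delta_mz = cand$delta_mz[tie_rows],
                         distance = cand$distance[tie_rows],
                         stringsAsFactors = FALSE)
  }
  list(pairs = pairs,
       unpaired_a = setdiff(pa$peak_id, pairs$peak_a),
       unpaired_b = setdiff(pb$peak_id, pairs$peak_b),
       ties = ties)
}

#' Predict an external dataset with a fitted model
#'
#' The target matrix is scaled with the model's training scaling parameters
#' (the target is treated as unknown: no re-centering on it), the model's
#' orthogonal components are filtered out, and predictions are compared with
#' the target responses. The validation R2 is the coefficient of
#' determination 1 - SS_res/SS_tot on the target response scaled by the
#' model's y-parameters (it can be negative); the squared Pearson correlation
#' is also reported, and RMSE is on the original score scale.
#'
#' @param model a fitted [fit_opls()] model with scaling attached.
#' @param x_target raw target injection-by-variable matrix; columns must
#'   cover the model's variables (align first, see [align_variables()]).
#' @param y_target raw target response per injection.
#' @return list of class `transfer_metrics`: `r2_validation`,
#'   `rmse_validation`, `r2_pearson`, `predictions`, `n`.
#' @export
predict_external <- function(model, x_target, y_target) {
  stopifnot(inherits(model, "opls_model"))
  x_target <- as.matrix(x_target)
  y_target <- as.numeric(y_target)
  missing <- setdiff(names(model$w), colnames(x_target))
  if (length(missing))
    stop("target is missing model variables: ", paste(utils::head(missing, 5), collapse = ", "))
  if (length(unique(rownames(x_target))) < 5L && nrow(x_target) < 5L)
    stop("fewer than 5 target samples")
  yhat <- predict(model, x_target)
  v <- model$y_scaling$kept[1L]
  ys <- (y_target - model$y_scaling$mean[v]) / model$y_scaling$sd[v]
  yhat_s <- (yhat - model$y_scaling$mean[v]) / model$y_scaling$sd[v]
  r2 <- 1 - sum((ys - yhat_s)^2) / sum(ys^2)
  structure(list(r2_validation = unname(r2),
                 rmse_validation = sqrt(mean((y_target - yhat)^2)),
                 r2_pearson = unname(suppressWarnings(stats::cor(y_target, yhat))^2),
                 predictions = yhat, n = length(y_target)),
            class = "transfer_metrics")
}

#' Variables important in both datasets
#'
#' Paired variables whose absolute signed VIPpred strictly exceeds the
#' threshold in both reports. An empty selection is allowed (the reduced
#' refit is then skipped).
#'
#' @param vip_a,vip_b [sign_and_select()] reports for the two datasets.
#' @param pairing the `pairs` data.frame from [align_variables()].
#' @param threshold strict threshold on |signed VIPpred| (default 1.5).
#' @return data.frame of selected pairs: `peak_a`, `peak_b`, `vip_a`, `vip_b`.
#' @export
common_important <- function(vip_a, vip_b, pairing, threshold = 1.5) {
  ia <- match(pairing$peak_a, vip_a$variable)
  ib <- match(pairing$peak_b, vip_b$variable)
  ok <- !is.na(ia) & !is.na(ib)
  va <- abs(vip_a$signed_vip[ia])
  vb <- abs(vip_b$signed_vip[ib])
  sel <- ok & !is.na(va) & !is.na(vb) & va > threshold & vb > threshold
  data.frame(peak_a = pairing$peak_a[sel], peak_b = pairing$peak_b[sel],
             vip_a = va[sel], vip_b = vb[sel], stringsAsFactors = FALSE)
}

#' Refit reduced models on commonly important variables
#'
#' Reruns the full modeling pipeline (component selection and, optionally,
#' permutation validation) on the selected variable subset for each dataset,
#' and recomputes the cross-dataset validation metrics, comparing the
#' reduced models with the full-variable models.
#'
#' @param x_a,y_a,sid_a dataset A: injection matrix, response, sample ids.
#' @param x_b,y_b,sid_b dataset B likewise.
#' @param selected data.frame from [common_important()] (columns `peak_a`,
#'   `peak_b`).
#' @param k,seed,max_a_o,n_perm,validate passed to [build_opls_model()].
#' @return list of class `transfer_result`: per-direction reduced builds and
#'   validation metrics, or a skip record when `selected` is empty.
#' @export
refit_reduced <- function(x_a, y_a, sid_a, x_b, y_b, sid_b, selected,
                          k = 7L, seed = 1L, max_a_o = 8L, n_perm = 100L,
                          validate = TRUE) {
  if (!nrow(selected))
    return(structure(list(skipped = TRUE, reason = "no common variables",
                          n_common_variables = 0L), class = "transfer_result"))
  xa <- as.matrix(x_a)[, selected$peak_a, drop = FALSE]
  xb <- as.matrix(x_b)[, selected$peak_b, drop = FALSE]
  # express B's columns in A's naming so either model can score either table
  colnames(xb) <- selected$peak_a
  build_a <- build_opls_model(xa, y_a, sid_a, k = k, seed = seed,
                              max_a_o = max_a_o, n_perm = n_perm, validate = validate)
  build_b <- build_opls_model(xb, y_b, sid_b, k = k, seed = seed,
                              max_a_o = max_a_o, n_perm = n_perm, validate = validate)
  structure(list(
    skipped = FALSE,
    n_common_variables = nrow(selected),
    selected = selected,
    model_a = build_a, model_b = build_b,
    validation_a_on_b = predict_external(build_a$model, xb, y_b),
    validation_b_on_a = predict_external(build_b$model, xa, y_a)),
    class = "transfer_result")
}
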