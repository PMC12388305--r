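# Plain-text readers and writers for the pipeline's tabular formats.

#' Write / read a peak table as CSV
#'
#' The CSV has `sample_id` and `replicate` as the first columns and one
#' column per peak, the header encoding peak id, retention time and
#' mass-to-charge as `id@rt/mz` (e.g. `P0123@5.02/200.0032`). Extra
#' (pseudo-peak) variables are written with their plain names.
#'
#' @param table a [peak_table()].
#' @param path file path.
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  pm <- table$peaks
  hdr <- ifelse(is.na(pm$rt), pm$peak_id,
                sprintf("%s@%.4f/%.4f", pm$peak_id, pm$rt, pm$mz))
  df <- data.frame(sample_id = table$injections$sample_id,
                   replicate = table$injections$replicate,
                   table$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-(1:2)] <- hdr
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- names(df)[-(1:2)]
  enc <- grepl("@", hdr, fixed = TRUE)
  peak_id <- ifelse(enc, sub("@.*$", "", hdr), hdr)
  rt <- mz <- rep(NA_real_, length(hdr))
  rt[enc] <- as.numeric(sub("^.*@([^/]+)/.*$", "\\1", hdr[enc]))
  mz[enc] <- as.numeric(sub("^.*/", "", hdr[enc]))
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  m[is.na(m)] <- 0   # undetected peaks export as zero
  meta <- data.frame(peak_id = peak_id, rt = rt, mz = mz, stringsAsFactors = FALSE)
  if (any(!enc)) meta$is_extra <- !enc
  peak_table(m, df$sample_id, df$replicate, meta)
}

#' Write / read a sensory panel as CSV (+ scales as YAML)
#'
#' @param panel a [sensory_panel()].
#' @param path records CSV path.
#' @param scales_path optional YAML path for the attribute scales.
#' @export
write_sensory_panel <- function(panel, path, scales_path = NULL) {
  stopifnot(inherits(panel, "sensory_panel"))
  utils::write.csv(panel$records, path, row.names = FALSE)
  if (!is.null(scales_path)) {
    sc <- lapply(seq_len(nrow(panel$scales)), function(i)
      list(min = panel$scales$min[i], max = panel$scales$max[i]))
    names(sc) <- panel$scales$attribute
    yaml::write_yaml(sc, scales_path)
  }
  invisible(path)
}

#' @rdname write_sensory_panel
#' @param scales data.frame of scales, or path to the YAML written by
#'   [write_sensory_panel()].
#' @export
read_sensory_panel <- function(path, scales) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(scales) && length(scales) == 1L && file.exists(scales)) {
    sc <- yaml::read_yaml(scales)
    scales <- data.frame(attribute = names(sc),
                         min = vapply(sc, function(s) s$min, numeric(1)),
                         max = vapply(sc, function(s) s$max, numeric(1)),
                         stringsAsFactors = FALSE)
  }
  sensory_panel(rec, scales)
}

#' Read an annotation library CSV
#'
#' Expects columns `compound_name`, `rt` (minutes), `mz` (daltons) and
#' optionally `compound_group` (aliases `rt_min` and `group` are accepted).
#'
#' @param path CSV path.
#' @export
read_annotation_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"rt" %in% names(df) && "rt_min" %in% names(df)) df$rt <- df$rt_min
  if (!"compound_group" %in% names(df) && "group" %in% names(df))
    df$compound_group <- df$group
  if (!all(c("compound_name", "rt", "mz") %in% names(df)))
    stop("library CSV needs compound_name, rt, mz")
  if (any(df$rt <= 0) || any(df$mz <= 0)) stop("rt and mz must be positive")
  df
}

#' Serialize a fitted OPLS model to JSON
#'
#' Stores weights, loadings, scaling parameters, metrics and the fold
#' specification; [read_opls_model()] restores a model usable for
#' prediction.
#'
#' @param model a [fit_opls()] model.
#' @param path JSON path.
#' @export
write_opls_model <- function(model, path) {
  stopifnot(inherits(model, "opls_model"))
  obj <- list(
    w = as.list(model$w), c = model$c,
    p_load = as.list(model$p_load),
    W_o = apply(model$W_o, 2L, identity, simplify = FALSE),
    P_o = apply(model$P_o, 2L, identity, simplify = FALSE),
    n_components = as.list(model$n_components),
    coefficients = as.list(model$coefficients),
    x_scaling = list(mean = as.list(model$x_scaling$mean),
                     sd = as.list(model$x_scaling$sd),
                     kept = model$x_scaling$kept,
                     dropped = model$x_scaling$dropped),
    y_scaling = list(mean = as.list(model$y_scaling$mean),
                     sd = as.list(model$y_scaling$sd),
                     kept = model$y_scaling$kept,
                     dropped = model$y_scaling$dropped),
    metrics = list(r2 = model$r2, rmse = model$rmse, q2 = model$q2,
                   press = model$press),
    folds = if (!is.null(model$folds)) list(k = model$folds$k,
                                            sample_fold = as.list(model$folds$sample_fold)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_opls_model
#' @export
read_opls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$w)
  unwrap <- function(x) stats::setNames(as.numeric(unlist(x)), names(x))
  mk <- function(cols) {
    if (is.null(cols) || !length(cols)) return(matrix(0, p, 0))
    m <- if (is.matrix(cols)) t(cols) else do.call(cbind, lapply(cols, as.numeric))
    rownames(m) <- names(obj$w); m
  }
  scal <- function(s) if (is.null(s)) NULL else
    list(mean = unwrap(s$mean), sd = unwrap(s$sd), kept = unlist(s$kept),
         dropped = if (length(s$dropped)) unlist(s$dropped) else character())
  structure(list(
    w = unwrap(obj$w), c = obj$c, p_load = unwrap(obj$p_load),
    W_o = mk(obj$W_o), P_o = mk(obj$P_o), T_o = NULL,
    a_o = ncol(mk(obj$W_o)),
    n_components = unlist(obj$n_components),
    coefficients = unwrap(obj$coefficients),
    x_scaling = scal(obj$x_scaling), y_scaling = scal(obj$y_scaling),
    r2 = obj$metrics$r2, rmse = obj$metrics$rmse,
    q2 = obj$metrics$q2, press = obj$metrics$press,
    folds = obj$folds), class = "opls_model")
}

#' Write ground truth / generator config as JSON or YAML
#'
#' @param truth a `ground_truth` object from [generate_dataset()].
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(driver_map = truth$driver_map,
              injected_outliers = truth$injected_outliers,
              planted = truth$planted,
              expected_scores = as.data.frame(truth$expected_scores))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @param config a [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  obj <- unclass(config)
  obj$attributes <- as.data.frame(obj$attributes)
  yaml::write_yaml(obj, path)
  invisible(path)
}
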