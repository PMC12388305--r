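# Synthetic sake-metabolome study generator: peak tables with planted
# filter targets, an annotation library, QDA-style sensory panels driven by
# known peak subsets, and the ground truth needed to verify the analysis
# end-to-end.

#' Default sensory attribute definitions for the generator
#'
#' Five taste/quality attributes on the usual QDA line scales (0-5, overall
#' quality 1-5), each driven by 10 peaks with unit effect size and bounded
#' round-to-round noise of standard deviation 0.3 score units.
#'
#' @param effect_size signal strength shared by all attributes.
#' @param noise_sd round noise standard deviation shared by all attributes.
#' @param n_driver_peaks drivers per attribute.
#' @return data.frame with one row per attribute.
#' @export
default_attributes <- function(effect_size = 1, noise_sd = 0.3, n_driver_peaks = 10L) {
  data.frame(
    name = c("sweetness", "sourness", "body", "bitterness", "overall_quality"),
    scale_min = c(0, 0, 0, 0, 1),
    scale_max = 5,
    n_driver_peaks = as.integer(n_driver_peaks),
    effect_size = effect_size,
    noise_sd = noise_sd,
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic study generator
#'
#' Defaults mirror a one-year sake study: 26 samples injected in triplicate,
#' 430 informative peaks plus 5 all-zero and 20 high-replicate-CV peaks
#' destined for the quality filters, and a 19-panelist QDA panel scoring at
#' least 3 rounds. Peak intensities are log-normal with a low-rank
#' latent-factor correlation structure across peaks (communality and factor
#' shares chosen so a PCA of the peak data explains roughly 30%/20% on the
#' first two components, as typical for such data).
#'
#' @param n_samples,n_replicates sample and replicate-injection counts.
#' @param n_informative_peaks,n_zero_max_peaks,n_high_cv_peaks planted peak
#'   counts: retained, all-zero, and high replicate-CV peaks.
#' @param n_panelists,n_rounds panel size and scoring rounds (>= 3).
#' @param attributes data.frame as [default_attributes()].
#' @param replicate_cv_target upper percent CV for retained peaks (< 10).
#' @param outlier_rate per-record probability of an injected outlier (< 0.5).
#' @param panelist_bias_sd standard deviation of the per-panelist bias (score
#'   units; the bias distribution is bounded uniform).
#' @param library_fraction fraction of informative peaks with a library entry
#'   inside the annotation tolerances.
#' @param n_decoy_library library entries placed away from every peak.
#' @param n_factors,factor_shares,communality latent-factor model of the
#'   log-intensity correlation across peaks.
#' @param independent_fraction fraction of informative peaks whose variation
#'   is mostly independent of the shared factors (compounds on dedicated
#'   pathways, e.g. specific esters); attribute drivers are drawn from this
#'   pool.
#' @param communality_independent communality of the independent pool.
#' @param driver_communality share of a driver peak's variance explained by
#'   its attribute's driver factor.
#' @param n_neighbor_peaks,neighbor_communality number of non-driver
#'   "pathway neighbour" peaks per attribute that co-vary moderately with the
#'   driver factor, and the variance share they draw from it.
#' @param seed master integer seed; all module substreams derive from it.
#' @export
generator_config <- function(n_samples = 26L,
                             n_replicates = 3L,
                             n_informative_peaks = 430L,
                             n_zero_max_peaks = 5L,
                             n_high_cv_peaks = 20L,
                             n_panelists = 19L,
                             n_rounds = 3L,
                             attributes = default_attributes(),
                             replicate_cv_target = 5,
                             outlier_rate = 0.05,
                             panelist_bias_sd = 0.2,
                             library_fraction = 0.28,
                             n_decoy_library = 30L,
                             n_factors = 6L,
                             factor_shares = c(0.50, 0.33, 0.08, 0.05, 0.02, 0.02),
                             communality = 0.8,
                             independent_fraction = 0.15,
                             communality_independent = 0.25,
                             driver_communality = 0.7,
                             n_neighbor_peaks = 60L,
                             neighbor_communality = 0.4,
                             seed = 1L) {
  for (nm in c("n_samples", "n_informative_peaks", "n_panelists"))
    stopifnot_scalar_count(get(nm), nm, 1L)
  stopifnot_scalar_count(n_replicates, "n_replicates", 2L)
  stopifnot_scalar_count(n_rounds, "n_rounds", 3L)
  for (nm in c("n_zero_max_peaks", "n_high_cv_peaks", "n_decoy_library"))
    stopifnot_scalar_count(get(nm), nm, 0L)
  if (!(outlier_rate >= 0 && outlier_rate < 0.5)) stop("outlier_rate must be in [0, 0.5)")
  if (!(replicate_cv_target > 0 && replicate_cv_target < 10))
    stop("replicate_cv_target must be in (0, 10) percent")
  if (!(communality > 0 && communality < 1)) stop("communality must be in (0, 1)")
  if (!(communality_independent > 0 && communality_independent < 1))
    stop("communality_independent must be in (0, 1)")
  if (!(independent_fraction > 0 && independent_fraction <= 1))
    stop("independent_fraction must be in (0, 1]")
  req <- c("name", "scale_min", "scale_max", "n_driver_peaks", "effect_size", "noise_sd")
  if (!all(req %in% names(attributes))) stop("attributes must have columns: ",
                                             paste(req, collapse = ", "))
  if (any(attributes$scale_min >= attributes$scale_max))
    stop("attribute scale_min must be below scale_max")
  if (any(attributes$n_driver_peaks > n_informative_peaks))
    stop("attribute drivers exceed the available informative peaks")
  if (length(factor_shares) != n_factors) stop("factor_shares must have n_factors entries")
  structure(as.list(environment()), class = "generator_config")
}

# Replicate multipliers with an exact empirical CV: n_rep standard-normal
# draws are centred (so the replicate mean equals the sample-level value
# exactly) and rescaled so the n-1 standard deviation equals `cv` times the
# mean. Operates column-wise on a matrix of groups.
replicate_noise <- function(n_rep, cv) {
  e <- matrix(stats::rnorm(n_rep * length(cv)), nrow = n_rep)
  e <- sweep(e, 2L, colMeans(e), "-")
  s <- sqrt(colSums(e^2) / (n_rep - 1))
  s[s == 0] <- 1
  sweep(e, 2L, cv / s, "*")
}

# Sample-level log-intensity z-scores: shared low-rank factor structure
# across peaks; `h` is the per-peak communality. Driver peaks are overridden
# afterwards with their attribute's driver factor.
synth_log_z <- function(cfg, peak_ids, h, seed) {
  with_seed(seed, {
    p <- length(peak_ids)
    n <- cfg$n_samples
    shares <- cfg$factor_shares / sum(cfg$factor_shares)
    lambda <- matrix(stats::rnorm(p * cfg$n_factors), p, cfg$n_factors)
    lambda <- sweep(lambda, 2L, sqrt(shares), "*")
    lambda <- lambda / sqrt(rowSums(lambda^2))        # unit-variance factor part
    f <- matrix(stats::rnorm(cfg$n_factors * n), cfg$n_factors, n)
    z <- sqrt(h) * (lambda %*% f) +
      sqrt(1 - h) * matrix(stats::rnorm(p * n), p, n)
    dimnames(z) <- list(peak_ids, paste0("S", formatC(seq_len(n), width = 2, flag = "0")))
    z                                                  # peaks x samples
  })
}

# QDA panel scores for given per-sample expected scores, with bounded
# panelist bias and round noise, clipping to the attribute scale, and
# outlier injection displaced beyond the Tukey whiskers of the clean group.
# The round noise of a (sample, attribute) group is redrawn in the rare case
# that the clean scores would themselves cross the group's Tukey fences, so
# the only whisker-outliers in the panel are the injected ones (the exact
# QC-recovery contract of the generator).
tukey_flagged <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  x < q[1L] - 1.5 * iqr | x > q[2L] + 1.5 * iqr
}

synth_panel <- function(expected, attributes, n_panelists, n_rounds,
                        bias_sd, outlier_rate, seed) {
  panelists <- paste0("J", formatC(seq_len(n_panelists), width = 2, flag = "0"))
  samples <- rownames(expected)
  recs <- list()
  injected <- list()
  for (a in seq_len(nrow(attributes))) {
    at <- attributes[a, ]
    with_seed(substream_seed(seed, paste0("panel_", at$name)), {
      grid <- expand.grid(panelist_id = panelists, round = seq_len(n_rounds),
                          sample_id = samples, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      bias <- stats::setNames(
        stats::runif(n_panelists, -bias_sd * sqrt(3), bias_sd * sqrt(3)), panelists)
      half <- at$noise_sd * sqrt(3)
      out <- stats::runif(nrow(grid)) < outlier_rate
      side <- sample(c(-1, 1), nrow(grid), replace = TRUE)
      score <- numeric(nrow(grid))
      for (s in samples) {
        idx <- which(grid$sample_id == s)
        base <- expected[s, at$name] + bias[grid$panelist_id[idx]]
        o <- out[idx]
        for (try in 1:200) {
          g <- pmin(pmax(base + stats::runif(length(idx), -half, half),
                         at$scale_min), at$scale_max)
          if (any(o)) {
            iqr <- stats::IQR(g[!o], type = 7)
            g[o] <- ifelse(side[idx][o] > 0, max(g[!o]) + 3 * iqr + 1,
                           min(g[!o]) - 3 * iqr - 1)
          }
          if (identical(unname(tukey_flagged(g)), unname(o))) break
        }
        score[idx] <- g
      }
      if (any(out))
        injected[[at$name]] <- data.frame(
          panelist_id = grid$panelist_id[out], sample_id = grid$sample_id[out],
          attribute = at$name, round = grid$round[out], stringsAsFactors = FALSE)
      recs[[at$name]] <- data.frame(
        panelist_id = grid$panelist_id, sample_id = grid$sample_id,
        attribute = at$name, round = grid$round, score = score,
        stringsAsFactors = FALSE)
    })
  }
  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  scales <- data.frame(attribute = attributes$name, min = attributes$scale_min,
                       max = attributes$scale_max, stringsAsFactors = FALSE)
  list(panel = sensory_panel(records, scales, check_bounds = FALSE),
       injected = if (length(injected))
         do.call(rbind, c(injected, list(make.row.names = FALSE)))
       else data.frame(panelist_id = character(), sample_id = character(),
                       attribute = character(), round = integer(),
                       stringsAsFactors = FALSE))
}

#' Generate a synthetic sake-metabolome study with known ground truth
#'
#' Produces a replicate-injection peak table (informative peaks with
#' replicate CV strictly below 10%, planted all-zero peaks, and planted peaks
#' whose replicate CV reaches at least 10% for some sample), a compound
#' annotation library (a configurable fraction of informative peaks carry an
#' entry within the matching tolerances, plus decoys), a QDA sensory panel
#' whose sample-level expected scores are scale-clipped affine functions of
#' each attribute's driver-peak intensities, and a [ground truth] record of
#' everything planted.
#'
#' @param config a [generator_config()].
#' @return list of class `sake_dataset` with `peaks` ([peak_table()]),
#'   `library` (data.frame), `panel` ([sensory_panel()]), `truth`, `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "generator_config")) stop("config must be a generator_config()")
  cfg <- config
  n_total <- cfg$n_informative_peaks + cfg$n_zero_max_peaks + cfg$n_high_cv_peaks
  peak_ids <- sprintf("P%04d", seq_len(n_total))
  roles <- with_seed(substream_seed(cfg$seed, "roles"), {
    r <- rep("informative", n_total)
    idx <- sample(n_total)
    r[idx[seq_len(cfg$n_zero_max_peaks)]] <- "zero_max"
    r[idx[cfg$n_zero_max_peaks + seq_len(cfg$n_high_cv_peaks)]] <- "high_cv"
    r
  })
  peak_meta <- with_seed(substream_seed(cfg$seed, "peak_meta"), data.frame(
    peak_id = peak_ids,
    rt = stats::runif(n_total, 0.5, 25),
    mz = stats::runif(n_total, 60, 1000),
    stringsAsFactors = FALSE))

  nonzero <- peak_ids[roles != "zero_max"]
  # the "independent" pool: informative peaks whose log-intensities couple
  # only weakly to the shared factors; attribute drivers live here
  inf_ids <- peak_ids[roles == "informative"]
  independent <- with_seed(substream_seed(cfg$seed, "independent"),
                           sample(inf_ids, round(cfg$independent_fraction * length(inf_ids))))
  if (sum(cfg$attributes$n_driver_peaks) > length(independent))
    stop("attribute drivers exceed the independent peak pool")

  # drivers: disjoint subsets of the independent pool; each attribute's
  # drivers share one latent "driver factor" (a common biosynthetic
  # activity), with the planted weight sign equal to the loading sign so the
  # attribute tracks the factor
  driver_map <- with_seed(substream_seed(cfg$seed, "drivers"), {
    pool <- sample(independent)
    out <- list()
    used <- 0L
    for (a in seq_len(nrow(cfg$attributes))) {
      at <- cfg$attributes[a, ]
      ids <- pool[used + seq_len(at$n_driver_peaks)]
      used <- used + at$n_driver_peaks
      out[[at$name]] <- data.frame(
        peak_id = ids,
        weight = sample(c(-1, 1), at$n_driver_peaks, replace = TRUE) *
          stats::runif(at$n_driver_peaks, 0.5, 1.5),
        stringsAsFactors = FALSE)
    }
    out
  })

  h <- ifelse(nonzero %in% independent, cfg$communality_independent, cfg$communality)
  z <- synth_log_z(cfg, nonzero, h, substream_seed(cfg$seed, "intensities"))
  z <- with_seed(substream_seed(cfg$seed, "driver_factors"), {
    neighbor_pool <- setdiff(inf_ids, independent)
    for (a in names(driver_map)) {
      dm <- driver_map[[a]]
      g <- stats::rnorm(cfg$n_samples)
      u <- matrix(stats::rnorm(nrow(dm) * cfg$n_samples), nrow(dm))
      z[dm$peak_id, ] <- sqrt(cfg$driver_communality) * outer(sign(dm$weight), g) +
        sqrt(1 - cfg$driver_communality) * u
      # pathway neighbours: peaks co-varying moderately with the driver
      # factor (precursors/byproducts of the same biosynthetic activity)
      n_nb <- min(cfg$n_neighbor_peaks, length(neighbor_pool))
      if (n_nb > 0L) {
        nb <- sample(neighbor_pool, n_nb)
        neighbor_pool <- setdiff(neighbor_pool, nb)
        s_nb <- sample(c(-1, 1), n_nb, replace = TRUE)
        z[nb, ] <- sqrt(cfg$neighbor_communality) * outer(s_nb, g) +
          sqrt(1 - cfg$neighbor_communality) * z[nb, ]
      }
    }
    z
  })
  sample_vals <- with_seed(substream_seed(cfg$seed, "peak_scale"), {
    mu <- stats::runif(length(nonzero), log(1e3), log(1e5))
    sigma <- stats::runif(length(nonzero), 0.2, 0.6)
    t(exp(mu + sigma * z))                            # samples x peaks
  })
  samples <- rownames(sample_vals)

  # replicate CVs: informative strictly below the target, high-CV peaks get
  # at least one sample at >= 12%
  n_grp <- length(nonzero) * cfg$n_samples
  intens <- with_seed(substream_seed(cfg$seed, "replicates"), {
    cv <- matrix(stats::runif(n_grp, 0.2, 1) * cfg$replicate_cv_target / 100,
                 nrow = cfg$n_samples)
    hi <- which(nonzero %in% peak_ids[roles == "high_cv"])
    for (j in hi) {
      n_hi <- sample(1:2, 1L)
      rows <- sample(cfg$n_samples, n_hi)
      cv[rows, j] <- stats::runif(n_hi, 0.12, 0.25)
    }
    e <- replicate_noise(cfg$n_replicates, as.vector(cv))
    m <- rep(as.vector(sample_vals), each = cfg$n_replicates)
    vals <- m * (1 + as.vector(e))
    # reshape: groups are (sample within peak); build injections x peaks
    arr <- array(vals, dim = c(cfg$n_replicates, cfg$n_samples, length(nonzero)))
    mat <- matrix(aperm(arr, c(1, 2, 3)), nrow = cfg$n_replicates * cfg$n_samples)
    colnames(mat) <- nonzero
    mat
  })
  inj_samples <- rep(samples, each = cfg$n_replicates)
  replicate <- rep(seq_len(cfg$n_replicates), times = cfg$n_samples)
  full <- matrix(0, nrow(intens), n_total, dimnames = list(NULL, peak_ids))
  full[, nonzero] <- intens
  peaks <- peak_table(full, inj_samples, replicate, peak_meta)

  lib <- with_seed(substream_seed(cfg$seed, "library"), {
    inf_ids <- peak_ids[roles == "informative"]
    n_lib <- round(cfg$library_fraction * length(inf_ids))
    hits <- sample(inf_ids, n_lib)
    groups <- c("monosaccharide", "disaccharide", "trisaccharide", "amino acid",
                "dipeptide", "organic acid", "sugar alcohol", "amine", "alcohol", "ester")
    meta <- peak_meta[match(hits, peak_meta$peak_id), ]
    entries <- data.frame(
      compound_name = sprintf("compound_%03d", seq_len(n_lib + cfg$n_decoy_library)),
      rt = c(meta$rt + stats::runif(n_lib, -0.05, 0.05),
             stats::runif(cfg$n_decoy_library, 27, 35)),
      mz = c(meta$mz + stats::runif(n_lib, -0.0035, 0.0035),
             stats::runif(cfg$n_decoy_library, 60, 1000)),
      compound_group = sample(groups, n_lib + cfg$n_decoy_library, replace = TRUE),
      stringsAsFactors = FALSE)
    attr(entries, "true_peak") <- c(hits, rep(NA_character_, cfg$n_decoy_library))
    entries
  })

  expected <- matrix(NA_real_, cfg$n_samples, nrow(cfg$attributes),
                     dimnames = list(samples, cfg$attributes$name))
  for (a in seq_len(nrow(cfg$attributes))) {
    at <- cfg$attributes[a, ]
    dm <- driver_map[[at$name]]
    zz <- scale(sample_vals[, dm$peak_id, drop = FALSE])
    signal <- as.vector(zz %*% dm$weight)
    signal <- signal / stats::sd(signal)
    mid <- (at$scale_min + at$scale_max) / 2
    slope <- at$effect_size * (at$scale_max - at$scale_min) / 6
    # clip the expected score to the interior of the scale, leaving headroom
    # for the bounded panel noise: trained QDA panels anchor their standards
    # away from the line-scale endpoints, so individual scores do not
    # saturate at the bounds
    margin <- min((cfg$panelist_bias_sd + at$noise_sd) * sqrt(3),
                  0.45 * (at$scale_max - at$scale_min))
    expected[, at$name] <- pmin(pmax(mid + slope * signal, at$scale_min + margin),
                                at$scale_max - margin)
  }

  pan <- synth_panel(expected, cfg$attributes, cfg$n_panelists, cfg$n_rounds,
                     cfg$panelist_bias_sd, cfg$outlier_rate,
                     substream_seed(cfg$seed, "panel"))

  truth <- structure(list(
    driver_map = driver_map,
    injected_outliers = pan$injected,
    planted = list(informative = peak_ids[roles == "informative"],
                   zero_max = peak_ids[roles == "zero_max"],
                   high_cv = peak_ids[roles == "high_cv"],
                   independent = independent),
    expected_scores = expected), class = "ground_truth")

  structure(list(peaks = peaks, library = lib, panel = pan$panel,
                 truth = truth, config = cfg),
            class = "sake_dataset")
}

#' Split a synthetic dataset into two "years" sharing generative truth
#'
#' Samples are partitioned at random into two disjoint sets; sample-level
#' expected sensory scores (and hence the driver weights) are shared, while
#' panel noise, biases and injected outliers are re-drawn independently for
#' each part, emulating sensory panels run in different years on sake that
#' follows the same composition-to-flavour relationships.
#'
#' @param dataset a [generate_dataset()] result.
#' @param fraction fraction of samples assigned to the first part, in (0, 1).
#' @param seed integer seed for the partition and the fresh panel noise.
#' @return list with elements `a` and `b`, each a `sake_dataset`.
#' @export
split_years <- function(dataset, fraction = 0.5, seed = 1L) {
  if (!inherits(dataset, "sake_dataset")) stop("dataset must be a sake_dataset")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  cfg <- dataset$config
  samples <- rownames(dataset$truth$expected_scores)
  n_a <- round(fraction * length(samples))
  if (n_a < 8L || length(samples) - n_a < 8L)
    stop("both parts must receive at least 8 samples")
  ids_a <- with_seed(substream_seed(seed, "split"), sort(sample(samples, n_a)))
  ids_b <- setdiff(samples, ids_a)
  make_part <- function(ids, key) {
    keep <- dataset$peaks$injections$sample_id %in% ids
    pt <- peak_table(dataset$peaks$intensities[keep, , drop = FALSE],
                     dataset$peaks$injections$sample_id[keep],
                     dataset$peaks$injections$replicate[keep],
                     dataset$peaks$peaks)
    expected <- dataset$truth$expected_scores[ids, , drop = FALSE]
    pan <- synth_panel(expected, cfg$attributes, cfg$n_panelists, cfg$n_rounds,
                       cfg$panelist_bias_sd, cfg$outlier_rate,
                       substream_seed(seed, paste0("panel_", key)))
    truth <- dataset$truth
    truth$injected_outliers <- pan$injected
    truth$expected_scores <- expected
    structure(list(peaks = pt, library = dataset$library, panel = pan$panel,
                   truth = truth, config = cfg), class = "sake_dataset")
  }
  list(a = make_part(ids_a, "a"), b = make_part(ids_b, "b"))
}
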