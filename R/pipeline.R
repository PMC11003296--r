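# End-to-end analysis: manifest + masks -> per-drawing descriptors ->
# normalized data points with neuroanatomical covariates -> the regression
# tables (single-electrode shape, paired-electrode shape, summation,
# phosphene count, along- vs between-axon model comparison).

#' Extract per-drawing shape descriptors for a whole manifest
#'
#' For each trial: load the mask, optionally clean it against its sibling
#' trials (same participant, electrode set, amplitude and frequency), and
#' aggregate per-phosphene descriptors into one per-drawing row. Drawings
#' that come out empty after cleaning are excluded and logged.
#'
#' @param manifest tibble from [read_manifest()] (or
#'   [generate_cohort()]`$manifest`).
#' @param masks named list of logical matrices keyed by `mask_path`; if
#'   NULL, masks are read from `file.path(base_dir, mask_path)`.
#' @param base_dir directory that `mask_path` entries are relative to.
#' @param clean apply [clean_drawing()] (default TRUE).
#' @param single_agg aggregation of multi-phosphene single-electrode
#'   drawings (`"mean"` default; see [aggregate_drawing()]).
#' @param match_radius_px centroid matching radius for spec recurrence.
#' @return per-drawing tibble: manifest key columns plus `electrodes`
#'   (order-free set key), the four descriptors and `n_phosphenes`;
#'   attribute `excluded` lists dropped drawings.
#' @export
extract_drawing_descriptors <- function(manifest, masks = NULL,
                                        base_dir = ".", clean = TRUE,
                                        single_agg = c("mean", "sum"),
                                        match_radius_px = 20) {
  single_agg <- match.arg(single_agg)
  get_mask <- function(path) {
    if (!is.null(masks)) {
      m <- masks[[path]]
      if (is.null(m)) stop("mask not found in list: ", path, call. = FALSE)
      m
    } else {
      read_mask(file.path(base_dir, path))
    }
  }
  manifest$electrodes <- electrode_key(manifest$electrode1,
                                       manifest$electrode2)
  group_id <- paste(manifest$participant, manifest$electrodes,
                    manifest$amplitude_x_th, manifest$frequency_hz,
                    sep = "|")
  rows <- vector("list", nrow(manifest))
  excluded <- character()
  for (g in unique(group_id)) {
    idx <- which(group_id == g)
    group_masks <- lapply(manifest$mask_path[idx], get_mask)
    for (k in seq_along(idx)) {
      i <- idx[k]
      m <- group_masks[[k]]
      if (clean) {
        m <- clean_drawing(m, sibling_trials = group_masks,
                           match_radius_px = match_radius_px)
      }
      if (isTRUE(attr(m, "excluded")) || !any(m)) {
        excluded <- c(excluded, manifest$mask_path[i])
        next
      }
      desc <- describe_drawing(m)
      mode <- if (is_paired_key(manifest$electrodes[i])) "paired" else "single"
      agg <- aggregate_drawing(desc, mode = mode, single_agg = single_agg)
      rows[[i]] <- dplyr::bind_cols(
        manifest[i, c("participant", "electrode1", "electrode2",
                      "electrodes", "amplitude_x_th", "frequency_hz",
                      "trial", "viewing_distance_cm")],
        agg
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- excluded
  out
}

#' Attach neuroanatomical covariates to data points
#'
#' Adds electrode-fovea distance (mean over the set for pairs),
#' electrode-retina distance (0 unless provided per electrode), and for
#' paired points the between-axon and along-axon distances.
#'
#' @param points data-point tibble with `participant` and `electrodes`.
#' @param positions named list (by participant) of [electrode_positions()]
#'   tibbles.
#' @param map [build_axon_map()] object.
#' @param erd named list (by participant) of tibbles
#'   `electrode, electrode_retina_distance_um`; absent = 0.
#' @return `points` with `efd_um`, `erd_um`, `between_axon_um`,
#'   `along_axon_um` (NA for single-electrode points).
#' @export
attach_covariates <- function(points, positions, map, erd = NULL) {
  n <- nrow(points)
  efd <- numeric(n)
  erd_v <- numeric(n)
  btw <- rep(NA_real_, n)
  alo <- rep(NA_real_, n)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    part <- points$participant[i]
    pos_all <- positions[[part]]
    if (is.null(pos_all)) {
      stop("no electrode positions for participant ", part, call. = FALSE)
    }
    els <- strsplit(points$electrodes[i], "+", fixed = TRUE)[[1]]
    ps <- lapply(els, function(e) {
      p <- pos_all[pos_all$electrode == e, ]
      if (nrow(p) != 1) stop("unknown electrode ", e, call. = FALSE)
      c(p$x_um, p$y_um)
    })
    efd[i] <- mean(vapply(ps, electrode_fovea_distance, numeric(1)))
    if (!is.null(erd) && !is.null(erd[[part]])) {
      tab <- erd[[part]]
      vals <- tab$electrode_retina_distance_um[match(els, tab$electrode)]
      erd_v[i] <- mean(ifelse(is.na(vals), 0, vals))
    }
    if (length(els) == 2) {
      key <- paste(part, points$electrodes[i])
      pd <- if (!is.null(cache[[key]])) {
        cache[[key]]
      } else {
        cache[[key]] <- pair_distances(map, ps[[1]], ps[[2]], labels = els)
      }
      btw[i] <- pd$between_axon_um
      alo[i] <- pd$along_axon_um
    }
  }
  points$efd_um <- efd
  points$erd_um <- erd_v
  points$between_axon_um <- btw
  points$along_axon_um <- alo
  points
}

#' Shape-descriptor regression tables
#'
#' Per-participant standardized multiple regressions with partial
#' correlations, plus an all-participant mixed-effects model with a random
#' participant intercept, for each of the four descriptors: the
#' single-electrode analysis uses amplitude, frequency, electrode-fovea
#' distance (and electrode-retina distance where it varies); the paired
#' analysis uses amplitude and electrode-fovea distance. Bonferroni family
#' size defaults to predictors x descriptors per participant block.
#'
#' @param points analysis-ready data points (transformed descriptors,
#'   standardized covariates) for one analysis set.
#' @param predictors character vector of predictor columns.
#' @param group participant column name.
#' @param m_family Bonferroni family size (default
#'   `length(predictors) * 4`).
#' @return tibble of tidy rows (`model` = participant or `"all"`,
#'   `response`, `term`, `beta`, `r`, `p`, `p_adj`, `stars`, `vif`, `n`).
#' @export
shape_regression_tables <- function(points, predictors,
                                    group = "participant",
                                    m_family = length(predictors) *
                                      length(DESCRIPTOR_COLS)) {
  out <- list()
  for (part in unique(points[[group]])) {
    sub <- points[points[[group]] == part, ]
    for (d in DESCRIPTOR_COLS) {
      preds <- drop_constant(sub, predictors)
      fit <- ols_standardized(sub, d, preds, standardize = FALSE,
                              label = part)
      out[[length(out) + 1L]] <- tidy_fit(fit, m = m_family)
    }
  }
  for (d in DESCRIPTOR_COLS) {
    preds <- drop_constant(points, predictors)
    fit <- mixed_effects(points, d, preds, group = group,
                         standardize = FALSE, label = "all")
    out[[length(out) + 1L]] <- tidy_fit(fit, m = m_family)
  }
  dplyr::bind_rows(out)
}

#' Phosphene-count regression table
#'
#' Mean phosphene count per data point regressed on amplitude,
#' electrode-fovea distance (and electrode-retina distance where present),
#' between-axon and along-axon distance: per participant by OLS, across
#' participants by a mixed-effects model.
#'
#' @param points paired-electrode data points with standardized covariates
#'   and `n_phosphenes_mean`.
#' @param predictors covariate columns.
#' @param group participant column.
#' @param m_family Bonferroni family size (default `length(predictors)`).
#' @return tidy tibble as in [shape_regression_tables()].
#' @export
count_regression_tables <- function(points, predictors,
                                    group = "participant",
                                    m_family = length(predictors)) {
  out <- list()
  for (part in unique(points[[group]])) {
    sub <- points[points[[group]] == part, ]
    preds <- drop_constant(sub, predictors)
    fit <- ols_standardized(sub, "n_phosphenes_mean", preds,
                            standardize = FALSE, label = part)
    out[[length(out) + 1L]] <- tidy_fit(fit, m = m_family)
  }
  preds <- drop_constant(points, predictors)
  fit <- mixed_effects(points, "n_phosphenes_mean", preds, group = group,
                       standardize = FALSE, label = "all")
  out[[length(out) + 1L]] <- tidy_fit(fit, m = m_family)
  dplyr::bind_rows(out)
}

#' Along- vs between-axon model comparison for phosphene counts
#'
#' Model A predicts the mean phosphene count from the along-axon distance
#' plus additional factors; Model B swaps in the between-axon distance.
#' Fitted per participant (OLS) and across participants (random-intercept
#' mixed model, ML likelihoods), compared by AIC/BIC.
#'
#' @param points paired-electrode data points with standardized covariates.
#' @param extra_factors additional predictor columns (e.g. amplitude,
#'   electrode-fovea distance).
#' @param group participant column.
#' @return list: `per_participant` (named list of
#'   [compare_models()] results), `all` (pooled mixed-model comparison),
#'   `table` (summary tibble with AIC/BIC/deltas/verdicts).
#' @export
count_model_comparison <- function(points,
                                   extra_factors = c("amplitude_x_th",
                                                     "efd_um"),
                                   group = "participant") {
  per <- list()
  rows <- list()
  for (part in unique(points[[group]])) {
    sub <- points[points[[group]] == part, ]
    extras <- drop_constant(sub, extra_factors)
    cmp <- compare_models(
      sub, "n_phosphenes_mean",
      predictors_a = c(extras, "along_axon_um"),
      predictors_b = c(extras, "between_axon_um"),
      standardize = FALSE
    )
    per[[part]] <- cmp
    rows[[length(rows) + 1L]] <- comparison_row(part, cmp)
  }
  extras <- drop_constant(points, extra_factors)
  all_cmp <- compare_models(
    points, "n_phosphenes_mean",
    predictors_a = c(extras, "along_axon_um"),
    predictors_b = c(extras, "between_axon_um"),
    group = group, standardize = FALSE
  )
  rows[[length(rows) + 1L]] <- comparison_row("all", all_cmp)
  list(
    per_participant = per, all = all_cmp,
    table = dplyr::bind_rows(rows)
  )
}

comparison_row <- function(label, cmp) {
  tibble::tibble(
    model = label,
    aic_along = cmp$fit_a$aic, aic_between = cmp$fit_b$aic,
    bic_along = cmp$fit_a$bic, bic_between = cmp$fit_b$bic,
    delta_aic = cmp$delta_aic, delta_bic = cmp$delta_bic,
    preferred = cmp$preferred,
    verdict_aic = cmp$verdict[["aic"]],
    verdict_bic = cmp$verdict[["bic"]]
  )
}

#' Run the complete analysis on a cohort
#'
#' Convenience wrapper: descriptor extraction, covariate attachment, the
#' normalization pipeline (single- and paired-electrode sets), and all
#' analysis tables.
#'
#' @param manifest trial manifest.
#' @param masks named mask list (or NULL to read from `base_dir`).
#' @param positions named list of electrode-position tibbles by participant.
#' @param map axon map.
#' @param base_dir mask directory when `masks` is NULL.
#' @param erd optional per-participant electrode-retina distance tables.
#' @param clean apply drawing cleaning.
#' @return list: `drawings`, `single` / `paired` (pipeline results),
#'   `single_tables`, `paired_tables`, `summation`, `count_tables`,
#'   `model_comparison`, `counts` (paired count data points).
#' @export
run_cohort_analysis <- function(manifest, masks = NULL, positions, map,
                                base_dir = ".", erd = NULL, clean = TRUE) {
  drawings <- extract_drawing_descriptors(manifest, masks = masks,
                                          base_dir = base_dir, clean = clean)
  reference <- standard_pulse_reference(drawings)
  single <- build_datapoints(drawings[is_single(drawings), ],
                             reference = reference)
  paired_rows <- drawings[!is_single(drawings), ]
  has_pairs <- nrow(paired_rows) > 0
  paired <- if (has_pairs) {
    build_datapoints(paired_rows, reference = reference)
  }

  cov_single <- attach_covariates(single$points, positions, map, erd)
  covs_s <- drop_constant(
    cov_single, c("amplitude_x_th", "frequency_hz", "efd_um", "erd_um")
  )
  std_s <- standardize_covariates(cov_single, covs_s)
  single_tables <- shape_regression_tables(std_s$points, covs_s)

  paired_tables <- NULL
  summation <- NULL
  count_tables <- NULL
  model_comparison <- NULL
  counts <- NULL
  if (has_pairs) {
    cov_paired <- attach_covariates(paired$points, positions, map, erd)
    covs_p <- drop_constant(cov_paired,
                            c("amplitude_x_th", "efd_um", "erd_um"))
    std_p <- standardize_covariates(cov_paired, covs_p)
    paired_tables <- shape_regression_tables(std_p$points, covs_p)
    summation <- summation_regression(paired$points_untransformed,
                                      single$points_untransformed)
    counts <- attach_covariates(paired$points, positions, map, erd)
    covs_c <- drop_constant(
      counts, c("amplitude_x_th", "efd_um", "erd_um", "between_axon_um",
                "along_axon_um")
    )
    counts <- standardize_covariates(counts, covs_c)$points
    count_tables <- count_regression_tables(counts, covs_c)
    model_comparison <- count_model_comparison(
      counts,
      extra_factors = drop_constant(
        counts, intersect(c("amplitude_x_th", "efd_um", "erd_um"), covs_c)
      )
    )
  }
  list(
    drawings = drawings,
    single = single, paired = paired,
    single_tables = single_tables,
    paired_tables = paired_tables,
    summation = summation,
    count_tables = count_tables,
    model_comparison = model_comparison,
    counts = counts
  )
}

#' Count data points from paired drawings (no descriptor normalization)
#'
#' Phosphene counts need no standard-pulse normalization, so pairs-only
#' cohorts (e.g. [count_study_config()]) can go straight from per-drawing
#' rows to trial-averaged count data points with standardized covariates.
#'
#' @param drawings per-drawing table from [extract_drawing_descriptors()]
#'   (paired rows are selected automatically).
#' @param positions named list of electrode-position tibbles by participant.
#' @param map axon map.
#' @param erd optional per-participant electrode-retina distance tables.
#' @return tibble of count data points with standardized covariates;
#'   attribute `covariates` names the retained covariate columns.
#' @export
count_datapoints <- function(drawings, positions, map, erd = NULL) {
  paired <- drawings[!is_single(drawings), ]
  if (!nrow(paired)) stop("no paired-electrode drawings", call. = FALSE)
  points <- average_over_trials(paired)
  points <- attach_covariates(points, positions, map, erd)
  covs <- drop_constant(
    points, c("amplitude_x_th", "efd_um", "erd_um", "between_axon_um",
              "along_axon_um")
  )
  out <- standardize_covariates(points, covs)$points
  attr(out, "covariates") <- covs
  out
}

# drop columns with (near-)zero variance from a predictor set
drop_constant <- function(data, predictors) {
  keep <- vapply(predictors, function(p) {
    v <- data[[p]]
    v <- v[is.finite(v)]
    length(v) > 1 && sd(v) > 1e-12
  }, logical(1))
  predictors[keep]
}
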