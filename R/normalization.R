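# Normalization pipeline: per-drawing descriptor tables -> analysis-ready
# data points. Order is locked:
#   aggregate (per drawing) -> standard-pulse normalize -> trial-average ->
#   outlier removal -> power transform -> covariate standardization;
# every stage appends to the `pipeline_log` attribute so the order is
# auditable.

#' Aggregate per-phosphene descriptors into one per-drawing vector
#'
#' Paired-electrode drawings sum each descriptor over the phosphenes of the
#' drawing (accounting for the variable number of perceived phosphenes);
#' single-electrode drawings average by default (configurable to `"sum"`).
#'
#' @param descriptors tibble from [describe_drawing()].
#' @param mode `"single"` or `"paired"`.
#' @param single_agg `"mean"` (default) or `"sum"`: how single-electrode
#'   multi-phosphene drawings are reduced.
#' @return one-row tibble: `area`, `perimeter`, `major`, `minor`,
#'   `n_phosphenes`.
#' @export
aggregate_drawing <- function(descriptors, mode = c("single", "paired"),
                              single_agg = c("mean", "sum")) {
  mode <- match.arg(mode)
  single_agg <- match.arg(single_agg)
  stopifnot(nrow(descriptors) >= 1)
  f <- if (mode == "paired" || single_agg == "sum") sum else mean
  tibble::tibble(
    area = f(descriptors$area),
    perimeter = f(descriptors$perimeter),
    major = f(descriptors$major),
    minor = f(descriptors$minor),
    n_phosphenes = nrow(descriptors)
  )
}

#' Per-participant standard-pulse reference
#'
#' The reference stimulus is amplitude 2 x threshold at 20 Hz. For each
#' participant, the reference value of each descriptor is its mean over all
#' single-electrode drawings of that participant at the standard pulse,
#' pooling all recorded electrodes (this absorbs per-participant drawing
#' bias and scale).
#'
#' @param drawings per-drawing descriptor table (one row per trial) with
#'   columns `participant`, `electrode2` (NA for single), `amplitude_x_th`,
#'   `frequency_hz` and the four descriptors.
#' @param amplitude,frequency the standard pulse (defaults 2 x Th, 20 Hz).
#' @param tol relative tolerance for matching the standard stimulus levels.
#' @return tibble: `participant`, `area`, `perimeter`, `major`, `minor`
#'   (reference means), class `standard_pulse_reference`.
#' @export
standard_pulse_reference <- function(drawings, amplitude = 2, frequency = 20,
                                     tol = 1e-6) {
  single <- is_single(drawings)
  std <- single &
    abs(drawings$amplitude_x_th - amplitude) <= tol * amplitude &
    abs(drawings$frequency_hz - frequency) <= tol * frequency
  participants <- unique(drawings$participant)
  lacking <- setdiff(participants, unique(drawings$participant[std]))
  if (length(lacking)) {
    stop(
      "configuration error: no standard-pulse drawings for participant(s): ",
      paste(lacking, collapse = ", "),
      call. = FALSE
    )
  }
  ref <- drawings[std, ] |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(DESCRIPTOR_COLS), mean),
      .groups = "drop"
    )
  if (any(as.matrix(ref[, DESCRIPTOR_COLS]) <= 0)) {
    stop("standard-pulse reference means must be positive", call. = FALSE)
  }
  class(ref) <- c("standard_pulse_reference", class(ref))
  ref
}

#' Express descriptors as multiples of the standard-pulse reference
#'
#' @param drawings per-drawing descriptor table.
#' @param reference [standard_pulse_reference()] table.
#' @return `drawings` with descriptor columns divided by the participant's
#'   reference means.
#' @export
normalize_to_reference <- function(drawings, reference) {
  i <- match(drawings$participant, reference$participant)
  if (anyNA(i)) {
    stop("reference lacks participant(s): ",
         paste(unique(drawings$participant[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  for (d in DESCRIPTOR_COLS) {
    drawings[[d]] <- drawings[[d]] / reference[[d]][i]
  }
  log_stage(drawings, "normalize_to_reference")
}

#' Average drawings over trials of the same electrode/stimulus combination
#'
#' Arithmetic mean of each descriptor and of the phosphene count within each
#' (participant, electrode set, amplitude, frequency) group; one data point
#' per group, eliminating repeated measures.
#'
#' @param drawings per-drawing descriptor table with an `electrodes` key
#'   column (order-free electrode-set label).
#' @return tibble of data points with `n_trials` and `n_phosphenes_mean`.
#' @export
average_over_trials <- function(drawings) {
  out <- drawings |>
    dplyr::group_by(
      .data$participant, .data$electrodes,
      .data$amplitude_x_th, .data$frequency_hz
    ) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(DESCRIPTOR_COLS), mean),
      n_phosphenes_mean = mean(.data$n_phosphenes),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  log_stage(out, "average_over_trials", from = drawings)
}

#' Remove outlying data points
#'
#' A data point is an outlier if any descriptor deviates more than
#' `threshold_sd` standard deviations from that descriptor's mean within its
#' analysis set. Single- and paired-electrode sets are filtered separately;
#' means/SDs are pooled across participants by default (`scope =
#' "per_participant"` restricts them within participant). SD uses the n-1
#' estimator; a zero-SD descriptor removes nothing.
#'
#' @param points data-point tibble (normalized, untransformed descriptors)
#'   with an `electrodes` key column.
#' @param threshold_sd removal threshold, standard deviations.
#' @param scope `"pooled"` (default) or `"per_participant"`.
#' @return list with `kept`, `removed` (tibbles) and `log` (per-removal
#'   records: key columns plus the offending descriptor and z-score).
#' @export
remove_outliers <- function(points, threshold_sd = 2.5,
                            scope = c("pooled", "per_participant")) {
  scope <- match.arg(scope)
  stopifnot(threshold_sd > 0)
  set_id <- ifelse(is_paired_key(points$electrodes), "paired", "single")
  grp <- if (scope == "pooled") set_id else paste(set_id, points$participant)
  out <- rep(FALSE, nrow(points))
  worst_desc <- rep(NA_character_, nrow(points))
  worst_z <- rep(NA_real_, nrow(points))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    if (length(rows) < 3) next
    for (d in DESCRIPTOR_COLS) {
      v <- points[[d]][rows]
      s <- sd(v)
      if (!is.finite(s) || s == 0) next
      z <- (v - mean(v)) / s
      bad <- abs(z) > threshold_sd
      upd <- bad & (is.na(worst_z[rows]) | abs(z) > abs(worst_z[rows]))
      worst_z[rows][upd] <- z[upd]
      worst_desc[rows][upd] <- d
      out[rows] <- out[rows] | bad
    }
  }
  removed <- points[out, ]
  if (nrow(removed)) {
    removed$outlier_descriptor <- worst_desc[out]
    removed$outlier_z <- worst_z[out]
  }
  kept <- log_stage(points[!out, ], "remove_outliers", from = points)
  list(kept = kept, removed = removed, log = removed)
}

# default power exponents: cube root for area, square root for the
# linear-extent descriptors (keeps regression residuals near-normal)
DEFAULT_POWER <- c(area = 1 / 3, perimeter = 1 / 2, major = 1 / 2, minor = 1 / 2)

#' Power-transform descriptors
#'
#' area -> area^(1/3); perimeter, major and minor axis length -> sqrt.
#' Monotone and order-preserving; negative descriptor values are a domain
#' error.
#'
#' @param points data-point tibble.
#' @param exponents named numeric vector of exponents per descriptor.
#' @export
power_transform <- function(points, exponents = DEFAULT_POWER) {
  stopifnot(all(DESCRIPTOR_COLS %in% names(exponents)))
  for (d in DESCRIPTOR_COLS) {
    v <- points[[d]]
    if (any(v < 0, na.rm = TRUE)) {
      stop("domain error: negative ", d, " cannot be power-transformed",
           call. = FALSE)
    }
    points[[d]] <- v^exponents[[d]]
  }
  log_stage(points, "power_transform")
}

#' Standardize covariates across the pooled data set
#'
#' Each covariate column is z-scored (mean 0, SD 1, n-1 estimator) across
#' all rows. Zero-variance covariates cannot be standardized: they are
#' dropped from the returned design with a warning and recorded in the
#' context.
#'
#' @param points data-point tibble.
#' @param covariates character vector of covariate column names.
#' @return list: `points` (with standardized columns), `context` (tibble of
#'   per-covariate means/SDs and a `dropped` flag).
#' @export
standardize_covariates <- function(points, covariates) {
  missing <- setdiff(covariates, names(points))
  if (length(missing)) {
    stop("covariate(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ctx <- tibble::tibble(
    covariate = covariates,
    mean = vapply(covariates, function(v) mean(points[[v]]), numeric(1)),
    sd = vapply(covariates, function(v) sd(points[[v]]), numeric(1))
  )
  ctx$dropped <- !is.finite(ctx$sd) | ctx$sd == 0
  for (k in seq_len(nrow(ctx))) {
    v <- ctx$covariate[k]
    if (ctx$dropped[k]) {
      warning("zero-variance covariate dropped from design: ", v,
              call. = FALSE)
      points[[v]] <- NULL
    } else {
      points[[v]] <- (points[[v]] - ctx$mean[k]) / ctx$sd[k]
    }
  }
  list(points = log_stage(points, "standardize_covariates"), context = ctx)
}

#' Run the full normalization pipeline
#'
#' Locked stage order: standard-pulse normalization of per-drawing
#' descriptors, trial averaging, outlier removal, power transform, covariate
#' standardization (covariates, if present, are standardized on the combined
#' single + paired table).
#'
#' @param drawings per-drawing descriptor table (already aggregated per
#'   drawing; see [aggregate_drawing()]).
#' @param covariates character vector of covariate columns to standardize
#'   (may be empty).
#' @param threshold_sd outlier threshold.
#' @param reference optional precomputed [standard_pulse_reference()].
#' @return list: `points` (analysis-ready tibble), `reference`, `outliers`
#'   (removed rows), `covariate_context`, `log` (pipeline stage audit).
#' @export
build_datapoints <- function(drawings, covariates = character(),
                             threshold_sd = 2.5, reference = NULL) {
  if (is.null(reference)) reference <- standard_pulse_reference(drawings)
  normed <- normalize_to_reference(drawings, reference)
  points <- average_over_trials(normed)
  ol <- remove_outliers(points, threshold_sd = threshold_sd)
  transformed <- power_transform(ol$kept)
  ctx <- NULL
  if (length(covariates)) {
    std <- standardize_covariates(transformed, covariates)
    transformed <- std$points
    ctx <- std$context
  }
  list(
    points = transformed,
    points_untransformed = ol$kept,
    reference = reference,
    outliers = ol$removed,
    covariate_context = ctx,
    log = attr(transformed, "pipeline_log")
  )
}

#' Write an analysis-ready table with its normalization sidecar
#'
#' Emits the data points as CSV and a JSON sidecar recording the
#' standard-pulse reference, covariate z-scoring constants, outlier removals
#' and the pipeline stage log, for full reproducibility.
#'
#' @param result list from [build_datapoints()].
#' @param path output CSV path; the sidecar is `<path>.json`.
#' @export
write_datapoints <- function(result, path) {
  readr::write_csv(result$points, path, progress = FALSE)
  sidecar <- list(
    standard_pulse_reference = as.data.frame(result$reference),
    covariate_context = if (!is.null(result$covariate_context)) {
      as.data.frame(result$covariate_context)
    },
    outliers_removed = if (nrow(result$outliers)) {
      as.data.frame(result$outliers)
    } else {
      list()
    },
    pipeline_log = result$log
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Quantile-quantile normality summary of transformed descriptors
#'
#' Reports, per descriptor, the correlation between sample quantiles and
#' normal theoretical quantiles (a numeric stand-in for a visual Q-Q check)
#' and the Shapiro-Wilk p-value.
#'
#' @param points transformed data-point tibble.
#' @return tibble: `descriptor`, `qq_correlation`, `shapiro_p`, `n`.
#' @export
qq_normality_summary <- function(points) {
  rows <- lapply(DESCRIPTOR_COLS, function(d) {
    v <- points[[d]]
    v <- v[is.finite(v)]
    n <- length(v)
    qq <- if (n >= 4) {
      cor(sort(v), stats::qnorm(stats::ppoints(n)))
    } else {
      NA_real_
    }
    sw <- if (n >= 4 && n <= 5000 && sd(v) > 0) {
      stats::shapiro.test(v)$p.value
    } else {
      NA_real_
    }
    tibble::tibble(descriptor = d, qq_correlation = qq, shapiro_p = sw, n = n)
  })
  dplyr::bind_rows(rows)
}

# ---- helpers ----

is_single <- function(drawings) {
  if ("electrode2" %in% names(drawings)) {
    e2 <- drawings$electrode2
    is.na(e2) | !nzchar(ifelse(is.na(e2), "", e2))
  } else {
    !is_paired_key(drawings$electrodes)
  }
}

is_paired_key <- function(key) grepl("+", key, fixed = TRUE)

log_stage <- function(x, stage, from = NULL) {
  prev <- attr(if (is.null(from)) x else from, "pipeline_log")
  attr(x, "pipeline_log") <- c(prev, stage)
  x
}
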