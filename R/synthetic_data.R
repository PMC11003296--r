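# Synthetic phosphene cohorts with planted effects.
#
# The generative percept model is a deliberately simplified axon-map model:
# a percept is a ribbon of intensity decaying radially from a window of the
# stimulating electrode's closest nerve-fiber bundle. Radial half-width
# grows with amplitude, axial extent with frequency and eccentricity; paired
# percepts either sum (two regions, linear extents scaled by the planted
# summation gain) or merge along the shared bundle (one region), with the
# merge probability a logistic function of between-axon distance. It is a
# test harness that encodes the qualitative structure of the analysis
# assumptions, not a perceptual model.

#' Ground-truth parameters of the synthetic cohort generator
#'
#' @param radius_um radial half-width of a percept at the standard pulse
#'   (2 x threshold), microns.
#' @param length_um axial extent of a percept at 20 Hz and 2000 um
#'   eccentricity, microns.
#' @param gamma_amp exponent of radial growth with amplitude
#'   (`R = radius_um * (amp / 2)^gamma_amp`).
#' @param gamma_freq exponent of axial growth with frequency
#'   (`L = length_um * (freq / 20)^gamma_freq * ...`).
#' @param gamma_ecc exponent of axial growth with electrode-fovea distance.
#' @param gamma_ecc_radial exponent of radial growth with eccentricity
#'   (mild; eccentric phosphenes are larger overall).
#' @param summation_gain g in (0, 1]: linear-extent gain applied to each
#'   constituent percept under paired stimulation, so linear-extent
#'   descriptor sums are ~ g x (sum of singles) and area sums ~ g^2 x.
#' @param split_midpoint_um d0: between-axon distance at which the
#'   probability of perceiving two phosphenes is 50% (default near the
#'   median between-axon distance of a 6 x 10 epiretinal grid, so that
#'   roughly half of paired trials merge, as observed clinically).
#' @param split_slope_um s: logistic slope of the split rule,
#'   `P(two) = plogis((d - d0) / s)`.
#' @param jitter_sd relative SD of the boundary-radius jitter (AR(1) along
#'   the ribbon).
#' @param scale_bias_sd SD of the per-participant log-normal scale bias
#'   (cancelled by standard-pulse normalization downstream).
#' @param mechanism which axonal distance drives the phosphene split:
#'   `"between"` (axon-map prediction, default) or `"along"` (the
#'   alternative generative mechanism used for model-selection falsification).
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(radius_um = 150, length_um = 1000,
                         gamma_amp = 0.5, gamma_freq = 0.35,
                         gamma_ecc = 0.5, gamma_ecc_radial = 0.2,
                         summation_gain = 0.65,
                         split_midpoint_um = 1100, split_slope_um = 350,
                         jitter_sd = 0.08, scale_bias_sd = 0.1,
                         mechanism = c("between", "along")) {
  stopifnot(
    summation_gain > 0, summation_gain <= 1,
    split_midpoint_um > 0, split_slope_um > 0,
    jitter_sd >= 0, scale_bias_sd >= 0
  )
  structure(
    list(
      radius_um = radius_um, length_um = length_um,
      gamma_amp = gamma_amp, gamma_freq = gamma_freq,
      gamma_ecc = gamma_ecc, gamma_ecc_radial = gamma_ecc_radial,
      summation_gain = summation_gain,
      split_midpoint_um = split_midpoint_um,
      split_slope_um = split_slope_um,
      jitter_sd = jitter_sd, scale_bias_sd = scale_bias_sd,
      mechanism = match.arg(mechanism)
    ),
    class = "ground_truth"
  )
}

#' Drawing-canvas geometry for the synthetic touchscreen
#'
#' @param width_px,height_px canvas size in pixels.
#' @param pixel_pitch_mm physical pixel size of the simulated touchscreen.
#' @param viewing_distance_cm eye-to-screen distance.
#' @param center_dva visual-field position at the canvas center, degrees.
#' @return list with the derived degrees-per-pixel scale.
#' @export
drawing_canvas <- function(width_px = 288, height_px = 288,
                           pixel_pitch_mm = 1.0, viewing_distance_cm = 83.8,
                           center_dva = c(0, 0)) {
  list(
    width_px = width_px, height_px = height_px,
    pixel_pitch_mm = pixel_pitch_mm,
    viewing_distance_cm = viewing_distance_cm,
    deg_per_px = pixels_to_degrees(pixel_pitch_mm, viewing_distance_cm),
    center_dva = c(x = center_dva[[1]], y = center_dva[[2]])
  )
}

# square canvas centered on a retinal position, sized to a half-extent in
# degrees (descriptors are position-invariant, so each trial may use its own
# canvas center)
canvas_around <- function(center_um, half_deg, pixel_pitch_mm = 1.0,
                          viewing_distance_cm = 83.8,
                          um_per_deg = UM_PER_DEG) {
  deg_px <- pixels_to_degrees(pixel_pitch_mm, viewing_distance_cm)
  side <- 2L * as.integer(ceiling(half_deg / deg_px)) + 1L
  drawing_canvas(
    width_px = side, height_px = side,
    pixel_pitch_mm = pixel_pitch_mm,
    viewing_distance_cm = viewing_distance_cm,
    center_dva = c(center_um[[1]], center_um[[2]]) / um_per_deg
  )
}

# percept size laws
percept_radius_um <- function(truth, amplitude, efd_um, scale = 1) {
  truth$radius_um * (amplitude / 2)^truth$gamma_amp *
    (max(efd_um, 300) / 2000)^truth$gamma_ecc_radial * scale
}

percept_length_um <- function(truth, frequency, efd_um, scale = 1) {
  truth$length_um * (frequency / 20)^truth$gamma_freq *
    (max(efd_um, 300) / 2000)^truth$gamma_ecc * scale
}

# ribbon centers: points along a bundle arc window, with jittered radii.
# Consumes RNG (jitter); callers manage seeding.
ribbon_centers <- function(map, bundle, arc_center, length_um, radius_um,
                           jitter_sd) {
  b <- map$bundles[[bundle]]
  arc <- map$arc[[bundle]]
  step <- max(radius_um / 2, 1)
  s <- seq(arc_center - length_um / 2, arc_center + length_um / 2, by = step)
  s <- pmin(pmax(s, 0), max(arc))
  s <- unique(s)
  x <- approx(arc, b[, 1], xout = s)$y
  y <- approx(arc, b[, 2], xout = s)$y
  n <- length(s)
  e <- numeric(n)
  if (jitter_sd > 0 && n > 0) {
    phi <- 0.7
    z <- rnorm(n)
    e[1] <- z[1] * jitter_sd
    if (n > 1) {
      for (i in 2:n) {
        e[i] <- phi * e[i - 1] + sqrt(1 - phi^2) * jitter_sd * z[i]
      }
    }
  }
  cbind(x_um = x, y_um = y, radius_um = radius_um * pmax(0.2, 1 + e))
}

# rasterize disc stamps (centers in retinal microns) onto a canvas
rasterize_centers <- function(centers, canvas, um_per_deg = UM_PER_DEG) {
  w <- canvas$width_px
  h <- canvas$height_px
  mask <- matrix(FALSE, h, w)
  deg_px <- canvas$deg_per_px
  # retinal microns -> canvas degrees -> pixel indices (1-based)
  px_of <- function(um_x) (um_x / um_per_deg - canvas$center_dva[["x"]]) /
    deg_px + (w + 1) / 2
  py_of <- function(um_y) -(um_y / um_per_deg - canvas$center_dva[["y"]]) /
    deg_px + (h + 1) / 2
  um_per_px <- deg_px * um_per_deg
  for (i in seq_len(nrow(centers))) {
    cx <- px_of(centers[i, "x_um"])
    cy <- py_of(centers[i, "y_um"])
    r_px <- centers[i, "radius_um"] / um_per_px
    x0 <- max(1L, floor(cx - r_px))
    x1 <- min(w, ceiling(cx + r_px))
    y0 <- max(1L, floor(cy - r_px))
    y1 <- min(h, ceiling(cy + r_px))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1
    ys <- y0:y1
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    mask[ys, xs] <- mask[ys, xs] | d2 <= r_px^2
  }
  mask
}

#' Render a single-electrode percept
#'
#' The percept is a ribbon along the electrode's closest nerve-fiber bundle:
#' axial window of planted length centered on the electrode's foot point,
#' radial half-width of planted radius, with seeded AR(1) boundary jitter.
#' Deterministic given `rng_seed`.
#'
#' @param pos numeric `c(x_um, y_um)`: electrode center, retinal microns.
#' @param amplitude stimulus amplitude, multiples of threshold.
#' @param frequency stimulus frequency, Hz.
#' @param map [build_axon_map()] object.
#' @param truth [ground_truth()] parameters.
#' @param canvas [drawing_canvas()] geometry.
#' @param scale participant scale bias (and/or summation gain) applied to
#'   radius and length.
#' @param rng_seed integer seed for the jitter draw (NULL = current RNG).
#' @param anchor optional precomputed [closest_axon()] result for `pos`.
#' @return logical drawing mask.
#' @export
render_single_percept <- function(pos, amplitude, frequency, map, truth,
                                  canvas = drawing_canvas(), scale = 1,
                                  rng_seed = NULL, anchor = NULL) {
  if (is.null(anchor)) anchor <- closest_axon(map, pos)
  efd <- electrode_fovea_distance(pos)
  r_um <- percept_radius_um(truth, amplitude, efd, scale)
  l_um <- percept_length_um(truth, frequency, efd, scale)
  draw <- function() {
    centers <- ribbon_centers(map, anchor$bundle, anchor$arc_um, l_um, r_um,
                              truth$jitter_sd)
    rasterize_centers(centers, canvas)
  }
  mask <- if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
  if (!any(mask)) {
    stop("empty percept: electrode outside the drawing canvas", call. = FALSE)
  }
  mask
}

#' Render a paired-electrode percept
#'
#' Draws whether the pair is perceived as one or two phosphenes from the
#' planted logistic split rule (in between-axon distance by default), then
#' renders either the union of the two gain-scaled single percepts (two
#' phosphenes) or a merged ribbon along the more temporal electrode's
#' closest bundle with the two gain-scaled axial windows pulled together
#' until they touch (one phosphene).
#'
#' @inheritParams render_single_percept
#' @param pos1,pos2 electrode centers, retinal microns.
#' @return logical drawing mask with attributes `two_drawn` (logical),
#'   `p_two`, `between_axon_um`, `along_axon_um`.
#' @export
render_paired_percept <- function(pos1, pos2, amplitude, frequency = 20,
                                  map, truth, canvas = drawing_canvas(),
                                  scale = 1, rng_seed = NULL) {
  pd <- pair_distances(map, pos1, pos2)
  drive <- if (truth$mechanism == "between") {
    pd$between_axon_um
  } else {
    pd$along_axon_um
  }
  p_two <- plogis((drive - truth$split_midpoint_um) / truth$split_slope_um)
  g <- truth$summation_gain
  draw <- function() {
    two <- runif(1) < p_two
    if (two) {
      m1 <- render_single_percept(pos1, amplitude, frequency, map, truth,
                                  canvas, scale = scale * g)
      m2 <- render_single_percept(pos2, amplitude, frequency, map, truth,
                                  canvas, scale = scale * g)
      list(mask = m1 | m2, two = TRUE)
    } else {
      # merged percept: both windows live on the temporal electrode's
      # closest bundle, pulled together until they touch
      a_nasal <- pd$electrode_nasal == "A"
      temporal <- if (a_nasal) pos2 else pos1
      nasal <- if (a_nasal) pos1 else pos2
      ca_t <- closest_axon(map, temporal)
      pr_n <- project_on_bundle(map, ca_t$bundle, map_point(map, nasal))
      efd_t <- electrode_fovea_distance(temporal)
      efd_n <- electrode_fovea_distance(nasal)
      r_t <- percept_radius_um(truth, amplitude, efd_t, scale * g)
      r_n <- percept_radius_um(truth, amplitude, efd_n, scale * g)
      l_t <- percept_length_um(truth, frequency, efd_t, scale * g)
      l_n <- percept_length_um(truth, frequency, efd_n, scale * g)
      s_t <- ca_t$arc_um
      s_n <- pr_n$arc_um
      # place the two axial windows exactly end-to-end (slight overlap to
      # guarantee 8-connectivity): the merged region's extent is then
      # g * (L1 + L2), conserving summed linear-extent descriptors
      gap <- abs(s_t - s_n) - (l_t + l_n) / 2
      touch <- min(r_t, r_n) / 2
      shift <- (gap + touch) / 2
      dir <- if (s_n == s_t) 1 else sign(s_n - s_t)
      s_t <- s_t + dir * shift
      s_n <- s_n - dir * shift
      c1 <- ribbon_centers(map, ca_t$bundle, s_t, l_t, r_t, truth$jitter_sd)
      c2 <- ribbon_centers(map, ca_t$bundle, s_n, l_n, r_n, truth$jitter_sd)
      list(mask = rasterize_centers(rbind(c1, c2), canvas), two = FALSE)
    }
  }
  res <- if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
  if (!any(res$mask)) {
    stop("empty percept: electrodes outside the drawing canvas", call. = FALSE)
  }
  structure(
    res$mask,
    two_drawn = res$two, p_two = p_two,
    between_axon_um = pd$between_axon_um,
    along_axon_um = pd$along_axon_um
  )
}

#' Default synthetic cohort configuration
#'
#' Three participants with distinct implant poses; per participant a set of
#' electrodes tested on an amplitude grid at 20 Hz and a frequency grid at a
#' fixed near-threshold amplitude (the standard 2 x threshold / 20 Hz pulse
#' is always present), plus electrode pairs tested at 20 Hz only, mirroring
#' the stratification of the source experiments. Five trials per condition.
#'
#' @param n_trials trials per condition.
#' @param truth [ground_truth()] parameters.
#' @export
cohort_config <- function(n_trials = 5, truth = ground_truth()) {
  electrodes <- c("A2", "B4", "C7", "D3", "E6", "F9", "B8", "E2")
  pairs <- rbind(
    c("C7", "C8"), c("C7", "D7"), c("B4", "B6"), c("E2", "E6"),
    c("A2", "F9"), c("D3", "E6"), c("B8", "C7"), c("A2", "B4"),
    c("E6", "F9"), c("D3", "D7"), c("B4", "E2"), c("C7", "F9")
  )
  participants <- list(
    list(
      id = "S1",
      implant = implant_spec(rotation_deg = -38,
                             center_offset_um = c(-1300, 450)),
      viewing_distance_cm = 83.8,
      electrodes = electrodes, pairs = pairs,
      amp_levels = c(1.25, 1.5, 2, 4), freq_levels = c(6, 20, 60),
      freq_sweep_amp = 1.5, pair_amp_levels = c(1.5, 2)
    ),
    list(
      id = "S2",
      implant = implant_spec(rotation_deg = -28,
                             center_offset_um = c(-1100, 300)),
      viewing_distance_cm = 76.2,
      electrodes = electrodes, pairs = pairs,
      amp_levels = c(1.25, 1.5, 2, 4), freq_levels = c(6, 20, 60),
      freq_sweep_amp = 1.5, pair_amp_levels = c(1.5, 2)
    ),
    list(
      id = "S3",
      implant = implant_spec(rotation_deg = -44,
                             center_offset_um = c(-1200, 500)),
      viewing_distance_cm = 77.5,
      electrodes = electrodes, pairs = pairs,
      amp_levels = c(1.25, 1.5, 2, 4), freq_levels = c(6, 20, 60),
      freq_sweep_amp = 1.5, pair_amp_levels = c(1.5, 2)
    )
  )
  list(
    participants = participants,
    truth = truth,
    n_trials = n_trials,
    pixel_pitch_mm = 1.0,
    percept_margin_deg = 7,
    n_bundles = 300
  )
}

# counter-based per-trial seed: any single trial is regenerable in isolation
trial_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) * 1000003 + counter) %% 2147483647)
}

# deterministic electrode pairs stratified by grid distance, so axonal
# distances cover the whole logistic range (fixed internal seed: the pair
# list is part of the study design, not of the stochastic draw)
grid_pairs <- function(n_pairs) {
  labels <- electrode_labels()
  all_pairs <- t(utils::combn(labels, 2))
  row_i <- match(substr(all_pairs, 1, 1), LETTERS[1:6])
  col_i <- as.integer(substring(all_pairs, 2))
  dim(row_i) <- dim(col_i) <- dim(all_pairs)
  gd <- sqrt((row_i[, 1] - row_i[, 2])^2 + (col_i[, 1] - col_i[, 2])^2)
  bins <- cut(gd, breaks = stats::quantile(gd, probs = seq(0, 1, 0.25)),
              include.lowest = TRUE)
  withr::with_seed(101, {
    take <- unlist(lapply(split(seq_along(gd), bins), function(idx) {
      sample(idx, min(length(idx), ceiling(n_pairs / 4)))
    }))
    take <- sample(take)[seq_len(min(n_pairs, length(take)))]
  })
  all_pairs[take, , drop = FALSE]
}

#' Study configurations for paired-electrode experiments
#'
#' `summation_study_config()` is sized for summation-gain recovery: many
#' electrode pairs at the standard amplitude, each with matched
#' single-electrode trials of its constituent electrodes.
#' `count_study_config()` is a lean pairs-only design for the phosphene
#' count analyses (no single-electrode trials, so descriptor normalization
#' is not applicable; see [count_datapoints()]).
#'
#' @param n_pairs_per_participant electrode pairs sampled per participant
#'   (deterministic, stratified by grid distance).
#' @param n_participants 1-3 participants from the default cohort.
#' @param n_trials trials per condition.
#' @param truth [ground_truth()] parameters.
#' @export
summation_study_config <- function(n_pairs_per_participant = 34,
                                   n_participants = 3, n_trials = 3,
                                   truth = ground_truth()) {
  base <- cohort_config(n_trials = n_trials, truth = truth)
  base$participants <- base$participants[seq_len(n_participants)]
  pairs <- grid_pairs(n_pairs_per_participant)
  for (i in seq_along(base$participants)) {
    base$participants[[i]]$pairs <- pairs
    base$participants[[i]]$pair_amp_levels <- 2
    base$participants[[i]]$electrodes <- sort(unique(as.vector(pairs)))
    base$participants[[i]]$amp_levels <- 2
    base$participants[[i]]$freq_levels <- 20
    base$participants[[i]]$freq_sweep_amp <- 2
  }
  base
}

#' @rdname summation_study_config
#' @export
count_study_config <- function(n_pairs_per_participant = 16,
                               n_participants = 2, n_trials = 2,
                               truth = ground_truth()) {
  base <- cohort_config(n_trials = n_trials, truth = truth)
  base$participants <- base$participants[seq_len(n_participants)]
  pairs <- grid_pairs(n_pairs_per_participant)
  for (i in seq_along(base$participants)) {
    base$participants[[i]]$pairs <- pairs
    base$participants[[i]]$pair_amp_levels <- 2
    base$participants[[i]]$electrodes <- character() # pairs only
    base$participants[[i]]$amp_levels <- numeric()
    base$participants[[i]]$freq_levels <- numeric()
  }
  base
}

#' Generate a complete synthetic cohort
#'
#' Produces a trial manifest, one binary drawing mask per trial, and the
#' ground truth that generated them. With `out_dir` set, the cohort is
#' written to disk (manifest CSV, PNG masks, per-participant implant YAML,
#' `ground_truth.json`) in the exact format [read_manifest()] ingests.
#' Byte-identical for a fixed seed.
#'
#' @param config list from [cohort_config()].
#' @param seed master seed; per-trial seeds derive from it by a counter
#'   scheme.
#' @param out_dir optional output directory.
#' @param map optional prebuilt [build_axon_map()] (built once otherwise).
#' @return list: `manifest` (tibble), `masks` (named list of logical
#'   matrices keyed by `mask_path`), `truth`, `pair_truth` (per paired trial:
#'   planted split draw and axonal distances), `positions` (per participant),
#'   `scale_bias` (per participant), `map`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            out_dir = NULL, map = NULL) {
  truth <- config$truth
  pitch <- config$pixel_pitch_mm %||% 1.0
  margin <- config$percept_margin_deg %||% 7
  if (is.null(map)) {
    map <- build_axon_map(n_bundles = config$n_bundles %||% 300)
  }
  n_p <- length(config$participants)
  scale_bias <- withr::with_seed(
    trial_seed(seed, 0),
    exp(rnorm(n_p, 0, truth$scale_bias_sd))
  )
  names(scale_bias) <- vapply(config$participants, `[[`, "", "id")

  manifest <- list()
  masks <- list()
  pair_truth <- list()
  positions <- list()
  counter <- 0L
  for (pi in seq_len(n_p)) {
    part <- config$participants[[pi]]
    pos_all <- electrode_positions(part$implant)
    positions[[part$id]] <- pos_all
    pos_of <- function(e) {
      p <- pos_all[pos_all$electrode == e, ]
      if (nrow(p) != 1) {
        stop("electrode outside array: ", e, call. = FALSE)
      }
      c(p$x_um, p$y_um)
    }
    anchors <- lapply(
      setNames(nm = unique(c(part$electrodes, as.vector(part$pairs)))),
      function(e) closest_axon(map, pos_of(e))
    )
    # single-electrode condition grid (amplitude sweep at 20 Hz plus
    # frequency sweep at a fixed amplitude, duplicates removed)
    cond <- unique(rbind(
      expand.grid(
        electrode = part$electrodes, amp = part$amp_levels, freq = 20,
        stringsAsFactors = FALSE
      ),
      expand.grid(
        electrode = part$electrodes, amp = part$freq_sweep_amp,
        freq = part$freq_levels, stringsAsFactors = FALSE
      )
    ))
    for (ci in seq_len(nrow(cond))) {
      e <- cond$electrode[ci]
      canvas <- canvas_around(pos_of(e), margin, pitch,
                              part$viewing_distance_cm)
      for (tr in seq_len(config$n_trials)) {
        counter <- counter + 1L
        key <- sprintf("masks/%s_%s_a%g_f%g_t%d.png",
                       part$id, e, cond$amp[ci], cond$freq[ci], tr)
        masks[[key]] <- render_single_percept(
          pos_of(e), cond$amp[ci], cond$freq[ci], map, truth, canvas,
          scale = scale_bias[[part$id]],
          rng_seed = trial_seed(seed, counter),
          anchor = anchors[[e]]
        )
        manifest[[length(manifest) + 1L]] <- tibble::tibble(
          participant = part$id, electrode1 = e, electrode2 = NA_character_,
          amplitude_x_th = cond$amp[ci], frequency_hz = cond$freq[ci],
          trial = tr, mask_path = key,
          viewing_distance_cm = part$viewing_distance_cm
        )
      }
    }
    # paired conditions (20 Hz only)
    if (!is.null(part$pairs) && nrow(part$pairs)) {
      for (qi in seq_len(nrow(part$pairs))) {
        e1 <- part$pairs[qi, 1]
        e2 <- part$pairs[qi, 2]
        mid <- (pos_of(e1) + pos_of(e2)) / 2
        sep_deg <- sqrt(sum((pos_of(e1) - pos_of(e2))^2)) / UM_PER_DEG
        canvas <- canvas_around(mid, sep_deg / 2 + margin, pitch,
                                part$viewing_distance_cm)
        for (amp in part$pair_amp_levels) {
          for (tr in seq_len(config$n_trials)) {
            counter <- counter + 1L
            key <- sprintf("masks/%s_%s-%s_a%g_t%d.png",
                           part$id, e1, e2, amp, tr)
            m <- render_paired_percept(
              pos_of(e1), pos_of(e2), amp, 20, map, truth, canvas,
              scale = scale_bias[[part$id]],
              rng_seed = trial_seed(seed, counter)
            )
            pair_truth[[length(pair_truth) + 1L]] <- tibble::tibble(
              participant = part$id, electrode1 = e1, electrode2 = e2,
              amplitude_x_th = amp, trial = tr,
              two_drawn = attr(m, "two_drawn"),
              p_two = attr(m, "p_two"),
              between_axon_um = attr(m, "between_axon_um"),
              along_axon_um = attr(m, "along_axon_um")
            )
            attributes(m) <- attributes(m)["dim"]
            masks[[key]] <- m
            manifest[[length(manifest) + 1L]] <- tibble::tibble(
              participant = part$id, electrode1 = e1, electrode2 = e2,
              amplitude_x_th = amp, frequency_hz = 20, trial = tr,
              mask_path = key,
              viewing_distance_cm = part$viewing_distance_cm
            )
          }
        }
      }
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  pair_truth <- dplyr::bind_rows(pair_truth)
  out <- list(
    manifest = manifest, masks = masks, truth = truth,
    pair_truth = pair_truth, positions = positions,
    scale_bias = scale_bias, map = map, seed = seed
  )
  if (!is.null(out_dir)) write_cohort(out, config, out_dir)
  out
}

# write a cohort to disk in the manifest/PNG/YAML/JSON exchange format
write_cohort <- function(cohort, config, out_dir) {
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  for (key in names(cohort$masks)) {
    write_mask(cohort$masks[[key]], file.path(out_dir, key))
  }
  write_manifest(cohort$manifest, file.path(out_dir, "manifest.csv"))
  for (part in config$participants) {
    write_implant_spec(
      part$implant,
      file.path(out_dir, sprintf("implant_%s.yaml", part$id))
    )
  }
  truth_out <- c(
    unclass(cohort$truth),
    list(
      seed = cohort$seed,
      scale_bias = as.list(cohort$scale_bias),
      pair_truth = as.data.frame(cohort$pair_truth)
    )
  )
  jsonlite::write_json(
    truth_out, file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
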