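# Trial manifests, drawing masks and implant geometry.
#
# Retinal coordinate convention: canonical right-eye frame, fovea at the
# origin, +x toward the optic disc (nasal retina), +y superior, units microns.
# Left-eye implants are mirrored into this frame on load.

MANIFEST_COLS <- c(
  "participant", "electrode1", "electrode2", "amplitude_x_th",
  "frequency_hz", "trial", "mask_path", "viewing_distance_cm"
)

ELECTRODE_RE <- "^[A-F](10|[1-9])$"

#' Read a trial manifest
#'
#' One row per drawing trial. Rows whose stimulus fields violate the trial
#' invariants (amplitude <= 1x threshold, non-positive frequency, unparseable
#' or duplicated electrode labels) are rejected with a per-row reason, kept in
#' the `rejected` attribute of the result.
#'
#' @param path CSV file with header
#'   `participant,electrode1,electrode2,amplitude_x_th,frequency_hz,trial,mask_path,viewing_distance_cm`
#'   (`electrode2` empty for single-electrode trials).
#' @return tibble of valid trial records; attribute `rejected` is a tibble
#'   with columns `row` and `reason`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_character(),
    electrode1 = readr::col_character(),
    electrode2 = readr::col_character(),
    amplitude_x_th = readr::col_double(),
    frequency_hz = readr::col_double(),
    trial = readr::col_integer(),
    mask_path = readr::col_character(),
    viewing_distance_cm = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(MANIFEST_COLS, names(raw))
  if (length(missing)) {
    stop(
      "manifest schema error: missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  reason <- validate_trial_rows(raw)
  ok <- is.na(reason)
  rejected <- tibble::tibble(row = which(!ok), reason = reason[!ok])
  records <- raw[ok, MANIFEST_COLS]
  key <- with(records, paste(
    participant, electrode_key(electrode1, electrode2),
    amplitude_x_th, frequency_hz, trial,
    sep = "|"
  ))
  if (anyDuplicated(key)) {
    stop(
      "manifest integrity error: duplicate trial key(s): ",
      paste(unique(key[duplicated(key)]), collapse = "; "),
      call. = FALSE
    )
  }
  attr(records, "rejected") <- rejected
  records
}

# per-row validation; NA = valid, otherwise a reason string
validate_trial_rows <- function(df) {
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  set <- function(cond, msg) {
    reason[is.na(reason) & cond] <<- msg
  }
  e1 <- df$electrode1
  e2 <- df$electrode2
  has2 <- !is.na(e2) & nzchar(trimws(ifelse(is.na(e2), "", e2)))
  set(is.na(e1) | !grepl(ELECTRODE_RE, e1), "unparseable electrode1 label")
  set(has2 & !grepl(ELECTRODE_RE, ifelse(is.na(e2), "", e2)),
      "unparseable electrode2 label")
  set(has2 & !is.na(e1) & e1 == e2, "paired electrodes must be distinct")
  set(is.na(df$amplitude_x_th) | df$amplitude_x_th <= 1,
      "amplitude must exceed 1x threshold")
  set(is.na(df$frequency_hz) | df$frequency_hz <= 0,
      "frequency must be positive")
  set(is.na(df$trial) | df$trial < 1, "trial index must be >= 1")
  set(is.na(df$viewing_distance_cm) | df$viewing_distance_cm <= 0,
      "viewing distance must be positive")
  set(is.na(df$mask_path) | !nzchar(df$mask_path), "missing mask path")
  reason
}

# canonical order-free key for an electrode set
electrode_key <- function(e1, e2) {
  e2 <- ifelse(is.na(e2) | !nzchar(ifelse(is.na(e2), "", e2)), "", e2)
  ifelse(
    e2 == "", e1,
    paste(pmin(e1, e2), pmax(e1, e2), sep = "+")
  )
}

#' Write a trial manifest
#'
#' Inverse of [read_manifest()]; the round trip is lossless.
#'
#' @param records tibble of trial records.
#' @param path output CSV path.
#' @export
write_manifest <- function(records, path) {
  out <- records[, MANIFEST_COLS]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a binary drawing mask from PNG
#'
#' @param path single-channel (or RGB/RGBA) PNG; any nonzero value in the
#'   first channel counts as drawn.
#' @return logical matrix (rows = image rows, top-left origin).
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask not found: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

#' Write a binary drawing mask to PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Degrees of visual angle subtended by one screen pixel
#'
#' Per-pixel arctangent (not a global linear factor): the angle subtended by
#' one pixel of physical size `pixel_pitch_mm` viewed at
#' `viewing_distance_cm`. Strictly decreasing in viewing distance.
#'
#' @param pixel_pitch_mm physical size of one pixel, mm.
#' @param viewing_distance_cm eye-to-screen distance, cm.
#' @return degrees per pixel.
#' @export
pixels_to_degrees <- function(pixel_pitch_mm, viewing_distance_cm) {
  if (!is.finite(pixel_pitch_mm) || pixel_pitch_mm <= 0) {
    stop("pixel_pitch_mm must be positive", call. = FALSE)
  }
  if (!is.finite(viewing_distance_cm) || viewing_distance_cm <= 0) {
    stop("viewing_distance_cm must be positive", call. = FALSE)
  }
  atan(pixel_pitch_mm / (viewing_distance_cm * 10)) * 180 / pi
}

#' Implant geometry specification
#'
#' Describes a 6 x 10 epiretinal electrode array (rows A-F, columns 1-10):
#' 575 um electrode pitch, 200 um electrode diameter, rotated about its
#' center and translated relative to the fovea.
#'
#' @param rotation_deg array rotation about its center, degrees
#'   (counter-clockwise in the canonical +x nasal / +y superior frame).
#' @param center_offset_um numeric `c(x, y)`: array-center position relative
#'   to the fovea, microns.
#' @param eye `"RE"` or `"LE"`; left eyes are mirrored into the canonical
#'   right-eye frame by [electrode_positions()].
#' @param pitch_um inter-electrode spacing, microns.
#' @param electrode_diameter_um electrode disc diameter, microns.
#' @param per_electrode optional tibble with columns `electrode` and any of
#'   `electrode_retina_distance_um`, `threshold_current`.
#' @return object of class `implant_spec`.
#' @export
implant_spec <- function(rotation_deg = 0, center_offset_um = c(0, 0),
                         eye = "RE", pitch_um = 575,
                         electrode_diameter_um = 200,
                         per_electrode = NULL) {
  stopifnot(pitch_um > electrode_diameter_um, electrode_diameter_um > 0)
  eye <- match.arg(eye, c("RE", "LE"))
  if (!is.null(per_electrode)) {
    per_electrode <- tibble::as_tibble(per_electrode)
    stopifnot("electrode" %in% names(per_electrode))
    bad <- !grepl(ELECTRODE_RE, per_electrode$electrode)
    if (any(bad)) {
      stop("unknown electrode label(s): ",
           paste(per_electrode$electrode[bad], collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(per_electrode$electrode)) {
      stop("duplicate electrode labels in per_electrode", call. = FALSE)
    }
  }
  structure(
    list(
      grid_shape = c(rows = 6L, cols = 10L),
      pitch_um = pitch_um,
      electrode_diameter_um = electrode_diameter_um,
      rotation_deg = rotation_deg,
      center_offset_um = c(x = center_offset_um[[1]], y = center_offset_um[[2]]),
      eye = eye,
      per_electrode = per_electrode
    ),
    class = "implant_spec"
  )
}

#' @export
print.implant_spec <- function(x, ...) {
  cat(sprintf(
    "<implant_spec> 6x10 grid, pitch %g um, diameter %g um, eye %s\n",
    x$pitch_um, x$electrode_diameter_um, x$eye
  ))
  cat(sprintf(
    "  rotation %g deg, center offset (%g, %g) um\n",
    x$rotation_deg, x$center_offset_um[["x"]], x$center_offset_um[["y"]]
  ))
  invisible(x)
}

#' Read / write implant geometry configs (YAML or JSON)
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return [implant_spec()] object.
#' @export
read_implant_spec <- function(path) {
  if (!file.exists(path)) stop("implant config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  per <- cfg$per_electrode
  if (!is.null(per)) per <- tibble::as_tibble(per)
  implant_spec(
    rotation_deg = cfg$rotation_deg %||% 0,
    center_offset_um = unlist(cfg$center_offset_um %||% c(0, 0)),
    eye = cfg$eye %||% "RE",
    pitch_um = cfg$pitch_um %||% 575,
    electrode_diameter_um = cfg$electrode_diameter_um %||% 200,
    per_electrode = per
  )
}

#' @rdname read_implant_spec
#' @param spec [implant_spec()] object.
#' @export
write_implant_spec <- function(spec, path) {
  stopifnot(inherits(spec, "implant_spec"))
  cfg <- list(
    rotation_deg = spec$rotation_deg,
    center_offset_um = as.list(spec$center_offset_um),
    eye = spec$eye,
    pitch_um = spec$pitch_um,
    electrode_diameter_um = spec$electrode_diameter_um
  )
  if (!is.null(spec$per_electrode)) {
    cfg$per_electrode <- as.list(spec$per_electrode)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Retinal positions of all electrodes of an implant
#'
#' Positions form a rotated, translated regular grid in the canonical
#' right-eye retinal frame (fovea origin, +x nasal, +y superior, microns).
#' Rows A-F run superior to inferior before rotation; columns 1-10 run
#' temporal to nasal. Left-eye implants are mirrored about the vertical axis
#' so that +x remains nasal.
#'
#' @param spec [implant_spec()] object.
#' @param electrodes optional character vector of labels (default: all 60).
#' @return tibble with columns `electrode`, `x_um`, `y_um`.
#' @export
electrode_positions <- function(spec, electrodes = NULL) {
  stopifnot(inherits(spec, "implant_spec"))
  all_labels <- electrode_labels()
  if (is.null(electrodes)) {
    electrodes <- all_labels
  } else {
    bad <- !electrodes %in% all_labels
    if (any(bad)) {
      stop("unknown electrode label(s): ",
           paste(electrodes[bad], collapse = ", "), call. = FALSE)
    }
  }
  row_i <- match(substr(electrodes, 1, 1), LETTERS[1:6])
  col_i <- as.integer(substring(electrodes, 2))
  # array-local frame: x along columns, y along rows; row A is superior
  x0 <- (col_i - 5.5) * spec$pitch_um
  y0 <- (3.5 - row_i) * spec$pitch_um
  th <- spec$rotation_deg * pi / 180
  x <- x0 * cos(th) - y0 * sin(th) + spec$center_offset_um[["x"]]
  y <- x0 * sin(th) + y0 * cos(th) + spec$center_offset_um[["y"]]
  if (spec$eye == "LE") x <- -x
  tibble::tibble(electrode = electrodes, x_um = x, y_um = y)
}

electrode_labels <- function() {
  as.vector(t(outer(LETTERS[1:6], 1:10, paste0)))
}

#' Remove small non-recurring specs from a drawing
#'
#' Connected regions smaller than `min_area_px` pixels are treated as specs
#' and removed unless a region with a comparable centroid location recurs in
#' at least `recurrence` of the sibling trials (all trials of the same
#' electrode/stimulus combination, including the trial itself). "Comparable
#' location" means centroids within `match_radius_px` pixels (a deterministic
#' surrogate for a manual judgement; default two electrode radii expressed in
#' pixels via the caller's geometry).
#'
#' @param mask logical matrix (one trial's drawing).
#' @param sibling_trials list of logical matrices: all trials of the same
#'   electrode and stimulus combination (should include `mask` itself).
#' @param min_area_px regions at least this large are always kept.
#' @param recurrence minimum fraction of sibling trials in which a comparable
#'   region must appear for a spec to be kept.
#' @param match_radius_px centroid matching radius, pixels.
#' @return cleaned logical mask. If nothing survives, the mask is returned
#'   empty with attribute `excluded = TRUE` so callers can drop it.
#' @export
clean_drawing <- function(mask, sibling_trials = list(mask),
                          min_area_px = 10, recurrence = 0.5,
                          match_radius_px = 20) {
  mask <- as_mask(mask)
  if (!any(mask)) {
    attr(mask, "excluded") <- TRUE
    return(mask)
  }
  lab <- label_regions(mask)
  k <- max(lab)
  areas <- tabulate(lab[lab > 0], nbins = k)
  keep <- rep(TRUE, k)
  small <- which(areas < min_area_px)
  if (length(small)) {
    sib_cent <- lapply(sibling_trials, function(s) {
      s <- as_mask(s)
      if (!any(s)) return(NULL)
      ls <- label_regions(s)
      t(vapply(seq_len(max(ls)), function(l) {
        shape_centroid(ls == l)
      }, numeric(2)))
    })
    n_sib <- length(sibling_trials)
    for (l in small) {
      ce <- shape_centroid(lab == l)
      hits <- vapply(sib_cent, function(cc) {
        if (is.null(cc)) return(FALSE)
        any(sqrt((cc[, 1] - ce[["x"]])^2 + (cc[, 2] - ce[["y"]])^2) <=
              match_radius_px)
      }, logical(1))
      keep[l] <- n_sib > 0 && mean(hits) >= recurrence
    }
  }
  out <- lab > 0 & matrix(keep[pmax(lab, 1L)], nrow(lab), ncol(lab)) & lab > 0
  out <- matrix(out, nrow(mask), ncol(mask))
  if (!any(out)) attr(out, "excluded") <- TRUE
  out
}

#' Flood-fill the interior of closed contours (optional utility)
#'
#' Input drawings are assumed to have closed, already-filled contours; this
#' helper fills enclosed background holes for masks that are outlines only.
#' Off by default in the pipeline.
#'
#' @param mask logical matrix.
#' @return logical matrix with enclosed background regions filled.
#' @export
fill_contours <- function(mask) {
  mask <- as_mask(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  bg <- !mask
  # background regions 4-connected to the image border stay background
  lab <- label_regions(bg, connectivity = 4)
  border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border_labels <- border_labels[border_labels > 0]
  mask | (lab > 0 & !matrix(lab %in% border_labels, nr, nc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
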