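# Simulated retinal nerve-fiber-bundle geometry.
#
# Bundles follow the fundus-derived trajectory model of Jansonius et al.
# (2009): in polar coordinates (r, phi) about the optic-disc center,
#   phi(r) = phi0 + b * (r - r0)^c,   r >= r0 = 4 deg,
# with region-dependent coefficients
#   superior (phi0 > 0): b =  exp(beta_sup + 3.9 * tanh(-(phi0 - 121) / 14)),
#                        c = 1.9 + 1.4 * tanh((phi0 - 121) / 14)
#   inferior (phi0 <= 0): b = -exp(beta_inf + 1.5 * tanh(-(-phi0 - 90) / 25)),
#                        c = 1.0 + 0.5 * tanh((-phi0 - 90) / 25)
# (beta_sup = -1.9, beta_inf = 0.5 by default). Trajectories are traced from
# the optic-disc radius outward, converted to the canonical fovea-origin
# retinal frame (+x nasal, +y superior, microns; 280 um/deg), trimmed at the
# temporal raphe (y = 0, x < 0), and resampled at uniform arc length.

#' Default trajectory-model coefficients
#'
#' @param beta_sup,beta_inf superior / inferior slope parameters.
#' @param loc_od_deg optic-disc center, degrees, canonical right-eye frame.
#' @param r0_deg starting radius of trajectories (optic-disc radius), degrees.
#' @param r_max_deg maximum traced radius, degrees.
#' @param um_per_deg retinal magnification, microns per degree.
#' @return named list of model parameters.
#' @export
axon_model_params <- function(beta_sup = -1.9, beta_inf = 0.5,
                              loc_od_deg = c(15, 2), r0_deg = 4,
                              r_max_deg = 45, um_per_deg = UM_PER_DEG) {
  list(
    beta_sup = beta_sup, beta_inf = beta_inf,
    loc_od_deg = c(x = loc_od_deg[[1]], y = loc_od_deg[[2]]),
    r0_deg = r0_deg, r_max_deg = r_max_deg, um_per_deg = um_per_deg
  )
}

# single trajectory in fovea-origin microns, trimmed at the raphe
trace_bundle <- function(phi0, params, n_rho = 1200) {
  r <- seq(params$r0_deg, params$r_max_deg, length.out = n_rho)
  if (phi0 > 0) {
    b <- exp(params$beta_sup + 3.9 * tanh(-(phi0 - 121) / 14))
    cc <- 1.9 + 1.4 * tanh((phi0 - 121) / 14)
  } else {
    b <- -exp(params$beta_inf + 1.5 * tanh(-(-phi0 - 90) / 25))
    cc <- 1.0 + 0.5 * tanh((-phi0 - 90) / 25)
  }
  phi <- phi0 + b * (r - params$r0_deg)^cc
  # stop before the trajectory wraps past the horizontal
  ok <- abs(phi - phi0) < 180
  r <- r[ok]
  phi <- phi[ok]
  x <- (r * cos(phi * pi / 180) + params$loc_od_deg[["x"]]) * params$um_per_deg
  y <- (r * sin(phi * pi / 180) + params$loc_od_deg[["y"]]) * params$um_per_deg
  # trim at the temporal raphe: cut at the first crossing of y = 0 with x < 0
  if (length(x) > 1) {
    cross <- which(y[-length(y)] * y[-1] < 0 & x[-1] < 0)
    if (length(cross)) {
      i <- cross[1]
      t <- y[i] / (y[i] - y[i + 1])
      xc <- x[i] + t * (x[i + 1] - x[i])
      x <- c(x[seq_len(i)], xc)
      y <- c(y[seq_len(i)], 0)
    }
  }
  cbind(x_um = x, y_um = y)
}

# resample a polyline at uniform arc-length step (microns)
resample_polyline <- function(p, step_um) {
  d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total < step_um) {
    return(p)
  }
  si <- seq(0, total, by = step_um)
  if (si[length(si)] < total) si <- c(si, total)
  cbind(
    x_um = approx(s, p[, 1], xout = si)$y,
    y_um = approx(s, p[, 2], xout = si)$y
  )
}

#' Build a simulated axon map
#'
#' Traces `n_bundles` nerve-fiber-bundle trajectories from the optic-disc
#' radius toward the periphery, trims them at the temporal raphe, and
#' resamples each at a uniform `step_um` arc-length resolution.
#' Deterministic for fixed parameters.
#'
#' @param params coefficient set from [axon_model_params()].
#' @param n_bundles number of trajectories (seed angles uniformly spaced in
#'   (-180, 180) degrees around the optic disc).
#' @param step_um arc-length sampling resolution, microns.
#' @param eye `"RE"` or `"LE"`; left-eye maps are mirrored about the vertical
#'   axis (disc on the nasal side in both cases since +x is nasal).
#' @return object of class `axon_map`.
#' @export
build_axon_map <- function(params = axon_model_params(), n_bundles = 500,
                           step_um = 10, eye = "RE") {
  stopifnot(n_bundles >= 100)
  eye <- match.arg(eye, c("RE", "LE"))
  phi0 <- seq(-180, 180, length.out = n_bundles + 2L)
  phi0 <- phi0[-c(1L, n_bundles + 2L)] # exclude the raphe itself
  bundles <- lapply(phi0, function(p) {
    resample_polyline(trace_bundle(p, params), step_um)
  })
  bundles <- bundles[vapply(bundles, nrow, integer(1)) >= 2L]
  if (any(vapply(bundles, function(b) any(b[-1, 2] == 0 & b[-1, 1] < 0 &
                                            b[-nrow(b), 2] * b[-1, 2] < 0),
                 logical(1)))) {
    stop("model-validation error: a trajectory crosses the raphe",
         call. = FALSE)
  }
  # flat segment tables for fast nearest-bundle queries
  seg <- do.call(rbind, lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    n <- nrow(b)
    cbind(
      bundle = i,
      x1 = b[-n, 1], y1 = b[-n, 2], x2 = b[-1, 1], y2 = b[-1, 2],
      s1 = c(0, cumsum(sqrt(diff(b[, 1])^2 + diff(b[, 2])^2)))[-n]
    )
  }))
  arc <- lapply(bundles, function(b) {
    c(0, cumsum(sqrt(diff(b[, 1])^2 + diff(b[, 2])^2)))
  })
  structure(
    list(
      bundles = bundles, arc = arc, seg = seg,
      params = params, n_bundles = length(bundles),
      step_um = step_um, phi0 = phi0, eye = eye
    ),
    class = "axon_map"
  )
}

#' @export
print.axon_map <- function(x, ...) {
  cat(sprintf(
    "<axon_map> %d bundles, %g um arc sampling, eye %s\n",
    x$n_bundles, x$step_um, x$eye
  ))
  invisible(x)
}

# all positions entering the geometry API are already in the canonical frame
# (left-eye data are mirrored by electrode_positions() on load); bundles are
# identical for both eyes in that frame, so `eye` is metadata only.
map_point <- function(map, point) {
  c(point[[1]], point[[2]])
}

# nearest point on one bundle's polyline: returns foot, distance, arc position
project_on_bundle <- function(map, bundle_idx, point) {
  b <- map$bundles[[bundle_idx]]
  n <- nrow(b)
  ax <- b[-n, 1]; ay <- b[-n, 2]
  bx <- b[-1, 1]; by <- b[-1, 2]
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- ((point[1] - ax) * vx + (point[2] - ay) * vy) / pmax(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  fx <- ax + t * vx
  fy <- ay + t * vy
  d2 <- (point[1] - fx)^2 + (point[2] - fy)^2
  i <- which.min(d2)
  s <- map$arc[[bundle_idx]][i] + t[i] * sqrt(len2[i])
  list(
    foot = c(x_um = fx[i], y_um = fy[i]),
    distance_um = sqrt(d2[i]),
    arc_um = s
  )
}

#' Closest nerve-fiber bundle to a retinal point
#'
#' Finds the bundle minimizing point-to-polyline distance (exact segment
#' projection), the foot point of that projection, and its arc-length
#' position along the bundle.
#'
#' @param map [build_axon_map()] object.
#' @param point numeric `c(x_um, y_um)`, fovea-origin retinal microns.
#' @return list with `bundle` (index), `foot` (x, y microns), `distance_um`,
#'   `arc_um` (arc length from the bundle's disc-side start).
#' @export
closest_axon <- function(map, point) {
  stopifnot(inherits(map, "axon_map"))
  p <- map_point(map, point)
  lim <- map$params$r_max_deg * map$params$um_per_deg
  if (!all(is.finite(p)) || sqrt(sum(p^2)) > lim) {
    stop("point outside modeled region", call. = FALSE)
  }
  seg <- map$seg
  vx <- seg[, "x2"] - seg[, "x1"]
  vy <- seg[, "y2"] - seg[, "y1"]
  len2 <- vx^2 + vy^2
  t <- ((p[1] - seg[, "x1"]) * vx + (p[2] - seg[, "y1"]) * vy) /
    pmax(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  fx <- seg[, "x1"] + t * vx
  fy <- seg[, "y1"] + t * vy
  d2 <- (p[1] - fx)^2 + (p[2] - fy)^2
  i <- which.min(d2)
  bundle <- seg[i, "bundle"]
  list(
    bundle = as.integer(bundle),
    foot = c(x_um = unname(fx[i]), y_um = unname(fy[i])),
    distance_um = unname(sqrt(d2[i])),
    arc_um = unname(seg[i, "s1"] + t[i] * sqrt(len2[i]))
  )
}

#' Electrode-fovea distance
#'
#' Euclidean distance from a retinal position to the fovea (the coordinate
#' origin); a retinal-eccentricity proxy.
#'
#' @param point numeric `c(x_um, y_um)` or a two-column matrix.
#' @return microns.
#' @export
electrode_fovea_distance <- function(point) {
  if (is.matrix(point)) {
    return(sqrt(point[, 1]^2 + point[, 2]^2))
  }
  sqrt(point[[1]]^2 + point[[2]]^2)
}

#' Between-axon and along-axon distance for an electrode pair
#'
#' Splits the retinal separation of two electrodes into two nearly orthogonal
#' components measured on a simulated axon map:
#' \itemize{
#'   \item between-axon: shortest distance from the center of the more nasal
#'     electrode to the nerve-fiber bundle closest to the more temporal
#'     electrode;
#'   \item along-axon: arc length along that bundle between the temporal
#'     electrode's foot point and the nasal electrode's foot point.
#' }
#' Roles are assigned by the nasal-axis (+x) coordinate; for equal x the
#' electrode with larger |y| is treated as temporal. The decomposition is
#' defined for pairs straddling the raphe. Coincident electrodes return zero
#' distances with `degenerate = TRUE`.
#'
#' @param map [build_axon_map()] object.
#' @param pos_a,pos_b numeric `c(x_um, y_um)` electrode centers.
#' @param labels optional character(2) electrode labels for the output.
#' @param axis_bundle which electrode's closest bundle carries the
#'   decomposition: `"temporal"` (default, matching the reference method) or
#'   `"nasal"` (alternative formulation; results are similar).
#' @return one-row tibble: `electrode_nasal`, `electrode_temporal`,
#'   `between_axon_um`, `along_axon_um`, `euclidean_um`, `efd_nasal_um`,
#'   `efd_temporal_um`, `degenerate`.
#' @export
pair_distances <- function(map, pos_a, pos_b, labels = c("A", "B"),
                           axis_bundle = c("temporal", "nasal")) {
  stopifnot(inherits(map, "axon_map"))
  axis_bundle <- match.arg(axis_bundle)
  pa <- c(pos_a[[1]], pos_a[[2]])
  pb <- c(pos_b[[1]], pos_b[[2]])
  euclid <- sqrt(sum((pa - pb)^2))
  # nasal = larger +x coordinate; tie-break: larger |y| is temporal
  a_nasal <- if (pa[1] != pb[1]) pa[1] > pb[1] else abs(pa[2]) < abs(pb[2])
  nasal <- if (a_nasal) pa else pb
  temporal <- if (a_nasal) pb else pa
  lab_nasal <- if (a_nasal) labels[[1]] else labels[[2]]
  lab_temporal <- if (a_nasal) labels[[2]] else labels[[1]]
  if (euclid == 0) {
    return(tibble::tibble(
      electrode_nasal = lab_nasal, electrode_temporal = lab_temporal,
      between_axon_um = 0, along_axon_um = 0, euclidean_um = 0,
      efd_nasal_um = electrode_fovea_distance(nasal),
      efd_temporal_um = electrode_fovea_distance(temporal),
      degenerate = TRUE
    ))
  }
  anchor <- if (axis_bundle == "temporal") temporal else nasal
  other <- if (axis_bundle == "temporal") nasal else temporal
  ca <- closest_axon(map, anchor)
  pr <- project_on_bundle(map, ca$bundle, map_point(map, other))
  tibble::tibble(
    electrode_nasal = lab_nasal, electrode_temporal = lab_temporal,
    between_axon_um = pr$distance_um,
    along_axon_um = abs(pr$arc_um - ca$arc_um),
    euclidean_um = euclid,
    efd_nasal_um = electrode_fovea_distance(nasal),
    efd_temporal_um = electrode_fovea_distance(temporal),
    degenerate = FALSE
  )
}

#' Pairwise axonal distances for a set of electrodes
#'
#' @param map [build_axon_map()] object.
#' @param positions tibble with columns `electrode`, `x_um`, `y_um`
#'   (e.g. from [electrode_positions()]).
#' @param pairs two-column matrix or data frame of electrode labels.
#' @return tibble, one row per pair (see [pair_distances()]).
#' @export
pair_distance_table <- function(map, positions, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(ncol(pairs) >= 2)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    e1 <- pairs[i, 1]
    e2 <- pairs[i, 2]
    p1 <- positions[positions$electrode == e1, ]
    p2 <- positions[positions$electrode == e2, ]
    if (nrow(p1) != 1 || nrow(p2) != 1) {
      stop("electrode position lookup failed for pair ", e1, "-", e2,
           call. = FALSE)
    }
    pair_distances(map, c(p1$x_um, p1$y_um), c(p2$x_um, p2$y_um),
                   labels = c(e1, e2))
  })
  dplyr::bind_rows(rows)
}

#' Render an axon map to a PNG for visual QC
#'
#' @param map [build_axon_map()] object.
#' @param path output PNG path.
#' @param positions optional electrode position tibble to overlay.
#' @param width,height image size in pixels.
#' @export
render_axon_map <- function(map, path, positions = NULL,
                            width = 800, height = 600) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  lim <- 6000
  plot(NA, xlim = c(-lim, lim), ylim = c(-lim * height / width,
                                         lim * height / width),
       xlab = "x (um, nasal →)", ylab = "y (um, superior →)",
       asp = 1, main = "Simulated nerve-fiber bundles")
  for (b in map$bundles) {
    graphics::lines(b[, 1], b[, 2], col = grDevices::grey(0.7))
  }
  graphics::points(0, 0, pch = 3, col = "red", cex = 1.5)
  if (!is.null(positions)) {
    graphics::points(positions$x_um, positions$y_um, pch = 21,
                     bg = "steelblue")
  }
  invisible(path)
}

#' Write electrode coordinates / pair distances to CSV
#'
#' @param positions tibble from [electrode_positions()].
#' @param path output CSV.
#' @export
write_electrode_coordinates <- function(positions, path) {
  readr::write_csv(
    positions[, c("electrode", "x_um", "y_um")], path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_electrode_coordinates
#' @param distances tibble from [pair_distance_table()].
#' @export
write_pair_distances <- function(distances, path) {
  out <- tibble::tibble(
    e1 = distances$electrode_nasal,
    e2 = distances$electrode_temporal,
    between_um = distances$between_axon_um,
    along_um = distances$along_axon_um,
    euclidean_um = distances$euclidean_um
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
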