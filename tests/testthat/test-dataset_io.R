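# Manifest I/O, geometry conversions, implant grids and drawing cleaning.

make_manifest_df <- function() {
  tibble::tibble(
    participant = c("P1", "P1", "P2"),
    electrode1 = c("C7", "C7", "A1"),
    electrode2 = c(NA, "D7", NA),
    amplitude_x_th = c(2, 2, 1.5),
    frequency_hz = c(20, 20, 6),
    trial = c(1L, 1L, 2L),
    mask_path = c("m1.png", "m2.png", "m3.png"),
    viewing_distance_cm = c(83.8, 83.8, 76.2)
  )
}

test_that("manifest round-trips losslessly and keeps all valid rows", {
  df <- make_manifest_df()
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(df, path)
  back <- read_manifest(path)
  expect_identical(nrow(back), 3L)
  expect_equal(as.data.frame(back), as.data.frame(df), ignore_attr = TRUE)
  expect_identical(nrow(attr(back, "rejected")), 0L)
})

test_that("invalid rows are rejected with reasons; schema/duplicates error", {
  df <- make_manifest_df()
  bad <- dplyr::bind_rows(
    df,
    tibble::tibble(
      participant = "P3", electrode1 = "C7;C8;D1", electrode2 = NA,
      amplitude_x_th = 2, frequency_hz = 20, trial = 1L,
      mask_path = "x.png", viewing_distance_cm = 80
    ),
    tibble::tibble(
      participant = "P3", electrode1 = "B2", electrode2 = "B2",
      amplitude_x_th = 2, frequency_hz = 20, trial = 1L,
      mask_path = "y.png", viewing_distance_cm = 80
    ),
    tibble::tibble(
      participant = "P3", electrode1 = "B3", electrode2 = NA,
      amplitude_x_th = 0.8, frequency_hz = 20, trial = 1L,
      mask_path = "z.png", viewing_distance_cm = 80
    )
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(bad, path)
  got <- read_manifest(path)
  expect_identical(nrow(got), 3L)
  rej <- attr(got, "rejected")
  expect_identical(nrow(rej), 3L)
  expect_match(rej$reason[1], "unparseable electrode1")
  expect_match(rej$reason[2], "distinct")
  expect_match(rej$reason[3], "amplitude")

  # missing column -> schema error
  df2 <- df[, setdiff(names(df), "frequency_hz")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df2, path2)
  expect_error(read_manifest(path2), "schema")

  # duplicate trial key -> integrity error
  dup <- dplyr::bind_rows(df, df[1, ])
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_manifest(dup, path3)
  expect_error(read_manifest(path3), "integrity")
})

test_that("mask PNG round-trip preserves the binary raster", {
  withr::local_seed(5)
  m <- random_mask(24, 31, 0.3)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(m, path)
  expect_identical(read_mask(path), m)
})

test_that("pixel-to-degree scale matches the arctangent and halves with distance", {
  expect_error(pixels_to_degrees(0, 80), "pixel_pitch")
  expect_error(pixels_to_degrees(0.25, -1), "viewing_distance")
  got <- pixels_to_degrees(0.25, 83.8)
  expect_equal(got, atan2(0.25, 838) * 180 / pi, tolerance = 1e-12)
  expect_equal(pixels_to_degrees(0.25, 2 * 83.8), got / 2, tolerance = 1e-6)
  expect_gt(pixels_to_degrees(0.25, 50), pixels_to_degrees(0.25, 100))
})

test_that("electrode grid has 575 um pitch and is isometric under pose changes", {
  base <- implant_spec()
  pos <- electrode_positions(base)
  d <- function(p, a, b) {
    pa <- p[p$electrode == a, ]
    pb <- p[p$electrode == b, ]
    sqrt((pa$x_um - pb$x_um)^2 + (pa$y_um - pb$y_um)^2)
  }
  expect_equal(d(pos, "A1", "A2"), 575, tolerance = 1e-9)
  expect_equal(d(pos, "A1", "B1"), d(pos, "A1", "A2"), tolerance = 1e-9)

  posed <- electrode_positions(
    implant_spec(rotation_deg = 37, center_offset_um = c(-1200, 350))
  )
  pd_base <- dist(cbind(pos$x_um, pos$y_um))
  pd_posed <- dist(cbind(posed$x_um, posed$y_um))
  expect_equal(sort(as.vector(pd_posed)), sort(as.vector(pd_base)),
               tolerance = 1e-6)

  # left eyes mirror about the vertical axis
  le <- electrode_positions(implant_spec(eye = "LE"))
  expect_equal(le$x_um, -pos$x_um, tolerance = 1e-12)
  expect_equal(le$y_um, pos$y_um, tolerance = 1e-12)
  expect_error(electrode_positions(base, "Z9"), "unknown electrode")
})

test_that("implant spec YAML/JSON round-trips", {
  spec <- implant_spec(
    rotation_deg = -31, center_offset_um = c(-900, 240), eye = "LE",
    per_electrode = tibble::tibble(
      electrode = c("A1", "C7"),
      electrode_retina_distance_um = c(120, 0)
    )
  )
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_implant_spec(spec, path)
    back <- read_implant_spec(path)
    expect_equal(back$rotation_deg, spec$rotation_deg)
    expect_equal(back$center_offset_um, spec$center_offset_um)
    expect_identical(back$eye, "LE")
    expect_equal(back$per_electrode$electrode_retina_distance_um,
                 c(120, 0))
  }
})

test_that("spec cleaning follows the (size, recurrence) rule table", {
  blob_at <- function(r, c, size = 1) {
    m <- matrix(FALSE, 40, 40)
    m[r:(r + size - 1), c:(c + size - 1)] <- TRUE
    m
  }
  big <- matrix(FALSE, 40, 40)
  big[5:18, 5:18] <- TRUE # 196 px region, always kept
  # cases: (spec pixels, sibling recurrence count out of 5, expected kept)
  cases <- list(
    list(size = 2, recur = 1, kept = FALSE), # 4 px, 1/5 trials
    list(size = 2, recur = 3, kept = TRUE), # 4 px, 3/5 trials
    list(size = 3, recur = 3, kept = TRUE), # 9 px, 3/5 trials
    list(size = 3, recur = 1, kept = FALSE), # 9 px, 1/5 trials
    list(size = 4, recur = 1, kept = TRUE) # 16 px >= 10: always kept
  )
  for (cs in cases) {
    spec_mask <- big | blob_at(30, 30, cs$size)
    siblings <- c(
      replicate(cs$recur - 1, big | blob_at(30, 31, cs$size),
                simplify = FALSE),
      replicate(5 - cs$recur, big, simplify = FALSE),
      list(spec_mask)
    )
    cleaned <- clean_drawing(spec_mask, siblings)
    expect_identical(
      max(label_regions(cleaned)), if (cs$kept) 2L else 1L
    )
    expect_identical(sum(cleaned & big), sum(big)) # big region untouched
  }
})

test_that("cleaning is idempotent and flags empty results", {
  m <- matrix(FALSE, 30, 30)
  m[4:15, 4:15] <- TRUE
  m[25, 25] <- TRUE # 1-px spec, never recurring
  sibs <- replicate(4, {
    s <- matrix(FALSE, 30, 30)
    s[4:15, 4:15] <- TRUE
    s
  }, simplify = FALSE)
  c1 <- clean_drawing(m, c(sibs, list(m)))
  c2 <- clean_drawing(c1, c(sibs, list(m)))
  expect_identical(unname(c1), unname(c2))
  expect_identical(max(label_regions(c1)), 1L)
  # mask with no specs is untouched
  no_spec <- sibs[[1]]
  expect_identical(unname(clean_drawing(no_spec, sibs)), unname(no_spec))
  # everything removed -> excluded flag (spec far from any sibling region)
  tiny <- matrix(FALSE, 30, 30)
  tiny[29, 29] <- TRUE
  out <- clean_drawing(tiny, c(sibs, list(tiny)))
  expect_true(isTRUE(attr(out, "excluded")))
})

test_that("fill_contours fills enclosed holes only", {
  ring <- matrix(FALSE, 15, 15)
  ring[4:12, 4:12] <- TRUE
  ring[6:10, 6:10] <- FALSE
  filled <- fill_contours(ring)
  expect_true(all(filled[4:12, 4:12]))
  expect_false(any(filled[1:3, ]))
})
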