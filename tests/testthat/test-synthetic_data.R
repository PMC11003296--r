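# Synthetic cohort generator: determinism, planted monotonicities, and the
# paired-percept construction.

test_that("single-percept rendering is deterministic and grows with amplitude", {
  map <- shared_map()
  truth <- ground_truth()
  pos <- c(-1800, 700)
  cv <- canvas_around(pos, 6)
  m1 <- render_single_percept(pos, 2, 20, map, truth, cv, rng_seed = 42)
  m2 <- render_single_percept(pos, 2, 20, map, truth, cv, rng_seed = 42)
  expect_identical(m1, m2)
  m3 <- render_single_percept(pos, 2, 20, map, truth, cv, rng_seed = 43)
  expect_false(identical(m1, m3)) # different jitter draw

  nojit <- ground_truth(jitter_sd = 0)
  low <- render_single_percept(pos, 1.25, 20, map, nojit, cv)
  high <- render_single_percept(pos, 2, 20, map, nojit, cv)
  expect_gt(sum(high), sum(low))
  # frequency stretches the percept axially (major axis)
  f_low <- describe_drawing(render_single_percept(pos, 1.5, 6, map, nojit, cv))
  f_high <- describe_drawing(render_single_percept(pos, 1.5, 60, map, nojit, cv))
  expect_gt(f_high$major[1], f_low$major[1])
})

test_that("planted descriptor growth laws are recovered from rendered sweeps", {
  map <- shared_map()
  truth <- ground_truth(jitter_sd = 0)
  pos <- c(-1500, 900)
  cv <- canvas_around(pos, 8)
  amps <- c(1.25, 1.5, 2, 3, 4)
  minors <- vapply(amps, function(a) {
    describe_drawing(
      render_single_percept(pos, a, 20, map, truth, cv)
    )$minor[1]
  }, numeric(1))
  # minor axis ~ 2R ~ amp^gamma_amp: log-log slope close to the exponent
  slope <- coef(lm(log(minors) ~ log(amps)))[[2]]
  expect_lt(abs(slope - truth$gamma_amp) / truth$gamma_amp, 0.10)
})

test_that("far-apart paired percepts are the union of two gain-scaled singles", {
  map <- shared_map()
  truth <- ground_truth(jitter_sd = 0)
  p1 <- c(-2600, 1500)
  p2 <- c(1500, -1200)
  mid <- (p1 + p2) / 2
  sep_deg <- sqrt(sum((p1 - p2)^2)) / 280
  cv <- canvas_around(mid, sep_deg / 2 + 6)
  mp <- render_paired_percept(p1, p2, 2, 20, map, truth, cv, rng_seed = 3)
  expect_true(attr(mp, "two_drawn"))
  expect_gt(attr(mp, "p_two"), 0.99)
  d <- describe_drawing(mp)
  expect_identical(nrow(d), 2L)
  g <- truth$summation_gain
  s1 <- describe_drawing(
    render_single_percept(p1, 2, 20, map, truth, cv, scale = g)
  )
  s2 <- describe_drawing(
    render_single_percept(p2, 2, 20, map, truth, cv, scale = g)
  )
  singles <- dplyr::bind_rows(s1, s2)
  singles <- singles[order(-singles$area), ]
  for (col in c("area", "perimeter", "major", "minor")) {
    expect_equal(d[[col]], singles[[col]], tolerance = 1e-9)
  }
})

test_that("merged percepts form one region whose extent tracks the gain-scaled sum", {
  map <- shared_map()
  truth <- ground_truth(jitter_sd = 0)
  # same-bundle pair: between-axon ~ 0 -> always merged
  b <- map$bundles[[70]]
  arc <- map$arc[[70]]
  p1 <- b[which.min(abs(arc - 2000)), ]
  p2 <- b[which.min(abs(arc - 3300)), ]
  cv <- canvas_around((p1 + p2) / 2, 10)
  mp <- render_paired_percept(p1, p2, 2, 20, map, truth, cv, rng_seed = 5)
  expect_false(attr(mp, "two_drawn"))
  d <- describe_drawing(mp)
  expect_identical(nrow(d), 1L)
  g <- truth$summation_gain
  s1 <- describe_drawing(render_single_percept(p1, 2, 20, map, truth, cv))
  s2 <- describe_drawing(render_single_percept(p2, 2, 20, map, truth, cv))
  ratio <- d$major / (s1$major + s2$major)
  expect_lt(abs(ratio - g), 0.12)
})

test_that("the probability of seeing two phosphenes rises with between-axon distance", {
  map <- shared_map()
  truth <- ground_truth()
  pos <- electrode_positions(implant_spec(center_offset_um = c(-1200, 400)))
  pairs <- rbind(
    c("C5", "C6"), c("C5", "D6"), c("C5", "E7"), c("C5", "F8"),
    c("B3", "F8"), c("A2", "F9")
  )
  pd <- pair_distance_table(map, pos, pairs)
  p_two <- plogis((pd$between_axon_um - truth$split_midpoint_um) /
                    truth$split_slope_um)
  # Monte-Carlo: empirical split frequency follows the planted logistic
  emp <- vapply(seq_len(nrow(pairs)), function(i) {
    p1 <- unlist(pos[pos$electrode == pairs[i, 1], c("x_um", "y_um")])
    p2 <- unlist(pos[pos$electrode == pairs[i, 2], c("x_um", "y_um")])
    cvp <- canvas_around((p1 + p2) / 2,
                         sqrt(sum((p1 - p2)^2)) / 280 / 2 + 6)
    draws <- vapply(1:25, function(s) {
      attr(render_paired_percept(p1, p2, 2, 20, map, truth, cvp,
                                 rng_seed = 1000 + 37 * i + s),
           "two_drawn")
    }, logical(1))
    mean(draws)
  }, numeric(1))
  expect_gt(stats::cor(emp, p_two, method = "spearman"), 0.7)
  expect_true(all(abs(emp - p_two) < 0.3))
})

test_that("generate_cohort is reproducible and matches the design counting oracle", {
  map <- shared_map()
  cfg <- cohort_config(n_trials = 2)
  cfg$participants <- cfg$participants[1]
  cfg$participants[[1]]$electrodes <- c("C4", "D6")
  cfg$participants[[1]]$pairs <- rbind(c("C4", "D6"), c("B3", "E7"))
  c1 <- generate_cohort(cfg, seed = 9, map = map)
  c2 <- generate_cohort(cfg, seed = 9, map = map)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$masks, c2$masks)
  expect_identical(c1$pair_truth$two_drawn, c2$pair_truth$two_drawn)

  # counting oracle: conditions x trials
  p <- cfg$participants[[1]]
  n_single_cond <- nrow(unique(rbind(
    expand.grid(e = p$electrodes, a = p$amp_levels, f = 20),
    expand.grid(e = p$electrodes, a = p$freq_sweep_amp, f = p$freq_levels)
  )))
  n_pair_cond <- nrow(p$pairs) * length(p$pair_amp_levels)
  expect_identical(nrow(c1$manifest),
                   as.integer((n_single_cond + n_pair_cond) * cfg$n_trials))
  counts <- table(paste(c1$manifest$electrode1, c1$manifest$electrode2,
                        c1$manifest$amplitude_x_th,
                        c1$manifest$frequency_hz))
  expect_true(all(counts == cfg$n_trials))

  c3 <- generate_cohort(cfg, seed = 10, map = map)
  expect_false(identical(c1$masks, c3$masks))
})

test_that("a cohort written to disk is byte-stable and ingestible", {
  map <- shared_map()
  cfg <- cohort_config(n_trials = 2)
  cfg$participants <- cfg$participants[1]
  cfg$participants[[1]]$electrodes <- "C4"
  cfg$participants[[1]]$pairs <- rbind(c("C4", "E7"))
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cfg, seed = 4, out_dir = dir, map = map)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), nrow(coh$manifest))
  m_disk <- read_mask(file.path(dir, man$mask_path[1]))
  expect_identical(m_disk, unname(coh$masks[[man$mask_path[1]]]))
  # round trip through the full descriptor extraction
  dd <- extract_drawing_descriptors(man, base_dir = dir, clean = FALSE)
  expect_identical(nrow(dd), nrow(man))

  # an electrode pair outside the array errors
  bad <- cfg
  bad$participants[[1]]$pairs <- rbind(c("C4", "Z9"))
  expect_error(generate_cohort(bad, seed = 4, map = map), "Z9|unknown")
})
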