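# Synthetic scene generator: determinism, calibration, noise channels.

test_that("parameter validation rejects infeasible settings", {
  expect_error(scene_params(mixture = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(scene_params(mixture = c(-0.1, 0.9, 0.2)), "summing to 1")
  expect_error(scene_params(polarity_flip_prob = 1.5), "probabilities")
  expect_error(scene_params(n_filaments = 0), "positive")
})

test_that("scenes are bit-reproducible under a fixed seed", {
  p <- scene_params(n_filaments = 80, seed = 5)
  s1 <- simulate_scene(p)
  s2 <- simulate_scene(p)
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$membrane, s2$membrane)
  expect_identical(s1$branches, s2$branches)
  expect_identical(s1$ground_truth, s2$ground_truth)

  d1 <- file.path(tempdir(), "scn1")
  d2 <- file.path(tempdir(), "scn2")
  f1 <- scene_to_tables(s1, d1)
  f2 <- scene_to_tables(s2, d2)
  for (nm in setdiff(names(f1), "provenance")) {
    expect_identical(
      unname(tools::md5sum(f1[[nm]])), unname(tools::md5sum(f2[[nm]])),
      label = nm
    )
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("written tables round-trip through the readers", {
  sc <- simulate_scene(scene_params(n_filaments = 60, seed = 6))
  d <- file.path(tempdir(), "rt")
  f <- scene_to_tables(sc, d)
  seg <- read_segments(f[["segments"]])
  expect_equal(nrow(seg), nrow(sc$segments))
  expect_equal(seg$x_nm, sc$segments$x_nm, tolerance = 1e-5)
  expect_equal(seg$px, sc$segments$px, tolerance = 1e-4)
  mem <- read_membrane_points(f[["membrane"]])
  expect_equal(nrow(mem), nrow(sc$membrane))
  br <- read_branches(f[["branches"]])
  expect_equal(nrow(br), nrow(sc$branches))
  unlink(d, recursive = TRUE)
})

test_that("the noiseless perpendicular limit gives 100% forward at ~0 degrees", {
  sc <- simulate_scene(scene_params(
    n_filaments = 120, mixture = c(1, 0, 0),
    forward_mode = 0, forward_sd = 0,
    polarity_flip_prob = 0, segment_dropout_prob = 0,
    coordinate_jitter_sd = 0, polarity_jitter_sd = 0, dust_filament_rate = 0,
    seed = 17
  ))
  an <- analyze_quiet(sc$segments, sc$membrane)
  expect_equal(as.character(unique(an$orientation$category)), "forward")
  expect_lt(max(an$orientation$mean_angle), 5)
})

test_that("ground-truth proximal mixture matches the request within 3 points", {
  for (mix in list(c(0.85, 0.10, 0.05), c(0.40, 0.40, 0.20))) {
    sc <- simulate_scene(acceptance_scene_params(
      n_filaments = 500, mixture = mix, seed = 23
    ))
    got <- gt_proximal_fractions(sc)
    expect_true(all(abs(got - mix) <= 0.03), label = paste(mix, collapse = "/"))
  }
})

test_that("branch counts are Poisson-consistent with rate x length", {
  sc <- simulate_scene(scene_params(n_filaments = 250, seed = 29))
  lam <- (1 / 0.6) * sc$total_filament_length_um
  nb <- nrow(sc$branches)
  expect_lt(abs(nb - lam), 3 * sqrt(lam))
  expect_equal(sc$realized_branch_ratio, nb / nrow(sc$ground_truth))
  # branch table references existing filaments and in-range angles
  expect_true(all(sc$branches$mother_filament_id %in% sc$ground_truth$filament_id))
  expect_true(all(sc$branches$daughter_filament_id %in% sc$ground_truth$filament_id))
  expect_false(any(sc$branches$mother_filament_id == sc$branches$daughter_filament_id))
  expect_true(all(sc$branches$branch_angle > 0 & sc$branches$branch_angle < 180))
})

test_that("polarity flips and dropout hit their nominal rates", {
  sc <- simulate_scene(scene_params(
    n_filaments = 200, polarity_flip_prob = 0.2, segment_dropout_prob = 0,
    coordinate_jitter_sd = 0, polarity_jitter_sd = 0, dust_filament_rate = 0,
    seed = 37
  ))
  gts <- sc$ground_truth_segments
  q <- mean(gts$flipped)
  expect_lt(abs(q - 0.2), 4 * sqrt(0.2 * 0.8 / nrow(gts)))
  # flipped observed polarity is the exact negation of the truth
  m <- merge(sc$segments, gts, by = c("tomogram_id", "filament_id", "segment_index"))
  flip_sign <- ifelse(m$flipped, -1, 1)
  expect_equal(m$px, flip_sign * m$px_true, tolerance = 1e-9)

  sc2 <- simulate_scene(scene_params(
    n_filaments = 200, polarity_flip_prob = 0, segment_dropout_prob = 0.5,
    coordinate_jitter_sd = 0, polarity_jitter_sd = 0, dust_filament_rate = 0,
    seed = 41
  ))
  total <- nrow(sc2$ground_truth_segments)
  kept <- nrow(sc2$segments)
  # dropout ~ 0.5, biased slightly low by the keep->=2 guard
  expect_lt(abs(kept / total - 0.5), 0.06)
})

test_that("segment spacing is 11 nm and polarity vectors are unit before noise", {
  sc <- simulate_scene(scene_params(
    n_filaments = 50, polarity_flip_prob = 0, segment_dropout_prob = 0,
    coordinate_jitter_sd = 0, polarity_jitter_sd = 0, dust_filament_rate = 0,
    seed = 43
  ))
  seg <- sc$segments
  for (f in unique(seg$filament_id)[1:10]) {
    s <- seg[seg$filament_id == f, ]
    d <- sqrt(rowSums(diff(as.matrix(s[, c("x_nm", "y_nm", "z_nm")]))^2))
    expect_true(all(abs(d - 11) < 1e-6), label = f)
  }
  nrm <- sqrt(seg$px^2 + seg$py^2 + seg$pz^2)
  expect_true(all(abs(nrm - 1) < 1e-6))
})
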