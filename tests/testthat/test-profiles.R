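# Distance-resolved profiles, histograms, densities, Arp2/3 statistics.

make_records <- function(distances, categories, tomo = "t1") {
  data.frame(
    tomogram_id = tomo,
    filament_id = sprintf("f%03d", seq_along(distances)),
    mean_angle = ifelse(categories == "forward", 40,
      ifelse(categories == "parallel", 90, 130)
    ),
    category = factor(categories, levels = c("forward", "parallel", "backward")),
    membrane_distance = distances,
    n_segments_used = 5L,
    stringsAsFactors = FALSE
  )
}

test_that("distance binning is half-open and bounded by the analysis depth", {
  rec <- make_records(c(20, 40, 399.9, 400, 1000), rep("forward", 5))
  prof <- distance_profile(rec)
  expect_equal(prof$n[1], 1L) # 20 -> [0, 40)
  expect_equal(prof$n[2], 1L) # exactly 40 -> [40, 80)
  expect_equal(prof$n[10], 1L) # 399.9 -> [360, 400)
  expect_equal(sum(prof$n), 3L) # 400 and 1000 excluded
  expect_true(all(is.na(prof$f_forward[prof$n == 0])))
})

test_that("per-bin category fractions match a manual tally and sum to one", {
  set.seed(33)
  distances <- c(runif(10, 0, 40), runif(12, 40, 80), runif(8, 80, 120))
  cats <- c(
    rep(c("forward", "parallel"), c(7, 3)),
    rep(c("forward", "backward"), c(6, 6)),
    rep(c("parallel"), 8)
  )
  prof <- distance_profile(make_records(distances, cats))
  expect_equal(prof$f_forward[1:3], c(0.7, 0.5, 0))
  expect_equal(prof$f_parallel[1:3], c(0.3, 0, 1))
  expect_equal(prof$f_backward[1:3], c(0, 0.5, 0))
  sums <- rowSums(prof[prof$n > 0, c("f_forward", "f_parallel", "f_backward")])
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("orientation histogram is the count/total probability function", {
  h <- orientation_histogram(rep(45.2, 100))
  expect_equal(sum(h$p), 1)
  expect_equal(h$p[h$bin_lo == 40], 1)

  set.seed(8)
  a <- runif(9000, 0, 180)
  h <- orientation_histogram(a)
  expect_equal(sum(h$p), 1)
  expect_true(all(abs(h$p - 1 / 18) < 4 * sqrt((1 / 18) * (17 / 18) / 9000)))

  # 180 is counted in the last bin
  h <- orientation_histogram(c(0, 180))
  expect_equal(sum(h$count), 2L)
  expect_error(orientation_histogram(numeric(0)), "empty")
  expect_error(orientation_histogram(c(10, 190)), "0, 180")
})

test_that("densities divide counts by supplied slab volumes", {
  mem <- flat_membrane(31, 11, spacing = 10)
  m <- membrane_model(mem, interior_ref = c(150, 300, 50))
  # 5 filaments with barbed ends in the first slab
  segs <- do.call(rbind, lapply(1:5, function(i) {
    straight_segments(c(50 + 40 * i, 120, 50), c(0, -1, 0), 10, fid = paste0("f", i))
  }))
  fil <- suppressMessages(filament_polarity(segs))
  vols <- rep(0.002, 10)
  dp <- density_profiles(segs, fil, m, vols)
  expect_equal(dp$barbed_density_um3[1], 5 / 0.002) # 2500 per um^3
  expect_equal(dp$n_barbed[1], 5L)
  # empty slab has zero density; doubling volumes halves densities
  expect_equal(dp$barbed_density_um3[5], 0)
  dp2 <- density_profiles(segs, fil, m, vols * 2)
  expect_equal(dp2$barbed_density_um3, dp$barbed_density_um3 / 2)
  expect_equal(dp2$segment_density_um3, dp$segment_density_um3 / 2)
  # zero volume -> undefined density
  vols[1] <- 0
  dp3 <- density_profiles(segs, fil, m, vols)
  expect_true(is.na(dp3$barbed_density_um3[1]))
})

test_that("Arp2/3 statistics: ratio, density and length per branch", {
  fil <- data.frame(
    tomogram_id = "t1", filament_id = sprintf("f%02d", 1:30),
    passed_confidence = TRUE, contour_length_nm = 200,
    stringsAsFactors = FALSE
  )
  br <- data.frame(tomogram_id = "t1", mother_filament_id = sprintf("f%02d", 1:10),
    daughter_filament_id = sprintf("f%02d", 11:20), stringsAsFactors = FALSE)
  st <- arp_statistics(br, fil, analysis_volume_um3 = 0.004)
  expect_equal(st$branch_to_filament_ratio, 1 / 3)
  expect_equal(st$arp_density_um3, 2500)
  expect_equal(st$total_filament_length_um, 6)
  expect_equal(st$mean_filament_length_per_branch_um, 0.6)

  st0 <- arp_statistics(br[0, ], fil, 0.004)
  expect_equal(st0$branch_to_filament_ratio, 0)
  expect_true(is.na(st0$mean_filament_length_per_branch_um))
})

test_that("Arp2/3 statistics are invariant to relabeling and rigid motion", {
  set.seed(55)
  segs <- do.call(rbind, lapply(1:8, function(i) {
    v <- rnorm(3); v <- v / sqrt(sum(v * v))
    straight_segments(runif(3, 0, 300), v, sample(5:12, 1), fid = paste0("f", i))
  }))
  fil <- suppressMessages(filament_polarity(segs))
  br <- data.frame(tomogram_id = "t1",
    mother_filament_id = c("f1", "f2"), daughter_filament_id = c("f3", "f4"),
    stringsAsFactors = FALSE)
  st <- arp_statistics(br, fil, 0.01)

  # relabel filaments
  perm <- sample(8)
  segs2 <- segs
  segs2$filament_id <- paste0("g", perm[as.integer(sub("f", "", segs$filament_id))])
  fil2 <- suppressMessages(filament_polarity(segs2))
  st2 <- arp_statistics(br, fil2, 0.01)
  expect_equal(st2$total_filament_length_um, st$total_filament_length_um)
  expect_equal(st2$branch_to_filament_ratio, st$branch_to_filament_ratio)

  # rigid-body transform of the scene
  R <- random_rotation()
  xyz <- as.matrix(segs[, c("x_nm", "y_nm", "z_nm")]) %*% t(R)
  segs3 <- segs
  segs3[, c("x_nm", "y_nm", "z_nm")] <- sweep(xyz, 2, c(100, -50, 20), "+")
  pol <- as.matrix(segs[, c("px", "py", "pz")]) %*% t(R)
  segs3[, c("px", "py", "pz")] <- pol
  fil3 <- suppressMessages(filament_polarity(segs3))
  st3 <- arp_statistics(br, fil3, 0.01)
  expect_equal(st3$total_filament_length_um, st$total_filament_length_um)
  expect_equal(st3$mean_filament_length_per_branch_um,
    st$mean_filament_length_per_branch_um)
})
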