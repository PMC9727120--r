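# Sliding-frame proportion profiles, robust first-frame fits, k-means
# sub-domain classification and the per-label report.

records_at <- function(distances, categories) {
  data.frame(
    tomogram_id = "t1", filament_id = sprintf("f%03d", seq_along(distances)),
    mean_angle = 40, category = factor(categories,
      levels = c("forward", "parallel", "backward")
    ),
    membrane_distance = distances, n_segments_used = 5L,
    stringsAsFactors = FALSE
  )
}

profile_from <- function(centers, f, p, b) {
  out <- data.frame(
    frame = seq_along(centers), start = centers - 20, center = centers,
    n = 50L, f_forward = f, f_parallel = p, f_backward = b
  )
  class(out) <- c("proportion_profile", "data.frame")
  out
}

test_that("sliding frames cover [0, span-width] and match an interval oracle", {
  set.seed(71)
  d <- runif(200, 0, 400)
  cats <- sample(c("forward", "parallel", "backward"), 200, replace = TRUE)
  rec <- records_at(d, cats)
  prof <- sliding_frame_profile(rec)
  expect_equal(nrow(prof), 100L)
  expect_equal(prof$start[1], 0)
  expect_equal(prof$start[100], 360)
  expect_equal(diff(prof$start)[1], 360 / 99, tolerance = 1e-12)
  for (k in c(1L, 37L, 100L)) {
    mem <- oracle_frame_members(d, prof$start[k], 40)
    expect_equal(prof$n[k], length(mem))
    expect_equal(prof$f_forward[k], mean(cats[mem] == "forward"))
  }
  # all-forward records give (1, 0, 0) in every non-empty frame
  prof1 <- sliding_frame_profile(records_at(d, rep("forward", 200)))
  expect_true(all(prof1$f_forward[prof1$n > 0] == 1))

  # two frames reduce to the proximal and distal slabs
  prof2 <- sliding_frame_profile(rec, n_frames = 2)
  expect_equal(prof2$start, c(0, 360))
  expect_equal(prof2$n[1], sum(d >= 0 & d < 40))
  expect_equal(prof2$n[2], sum(d >= 360 & d < 400))
})

test_that("robust fit recovers a noiseless linear profile exactly", {
  centers <- seq(20, 380, length.out = 100)
  f <- 0.8 - 0.0005 * centers
  b <- 0.05 + 0.0005 * centers
  prof <- profile_from(centers, f, 0.15, b)
  fit <- robust_profile_fit(prof)
  expect_equal(unname(fit$first_frame["forward"]), 0.79, tolerance = 1e-9)
  expect_equal(unname(fit$first_frame["parallel"]), 0.15, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["forward", "slope"]), -0.0005,
    tolerance = 1e-9)
  expect_equal(sum(fit$first_frame), 1)
})

test_that("robust fit shrugs off outlier frames and handles constants", {
  centers <- seq(20, 380, length.out = 100)
  f <- rep(0.5, 100)
  f[seq(5, 95, by = 10)] <- 0 # 10% dropout-style outliers
  prof <- profile_from(centers, f, rep(0.3, 100), rep(0.2, 100))
  fit <- robust_profile_fit(prof)
  expect_lt(abs(fit$coefficients["forward", "intercept"] +
    20 * fit$coefficients["forward", "slope"] - 0.5), 0.02)

  # all frames identical: exact value, zero slope
  prof2 <- profile_from(centers, rep(0.6, 100), rep(0.25, 100), rep(0.15, 100))
  fit2 <- robust_profile_fit(prof2)
  expect_equal(unname(fit2$first_frame), c(0.6, 0.25, 0.15))
  expect_equal(unname(fit2$coefficients[, "slope"]), c(0, 0, 0))

  # too few frames: mean of the first five non-empty frames, with warning
  prof3 <- profile_from(centers[1:6], c(0.5, 0.6, 0.5, 0.6, 0.5, 0.9),
    rep(0.2, 6), rep(0.2, 6))
  prof3$n[6] <- 0L
  expect_warning(fit3 <- robust_profile_fit(prof3), "non-empty frames")
  expect_equal(unname(fit3$first_frame["forward"]), 0.54 / 0.94, tolerance = 1e-9)
})

test_that("k-means recovers separated sub-domain clusters and orders labels", {
  set.seed(13)
  ctr <- rbind(c(0.85, 0.07, 0.08), c(0.60, 0.25, 0.15), c(0.40, 0.40, 0.20))
  truth <- rep(1:3, each = 10)
  x <- ctr[truth, ] + matrix(rnorm(90, 0, 0.02), 30, 3)
  colnames(x) <- c("f_forward", "f_parallel", "f_backward")
  cl <- classify_subdomains(x, seed = 2)
  lab <- cl$assignments$label
  expect_equal(as.character(lab), c("protruding", "transition", "resting")[truth])
  # label order follows decreasing mean forward proportion
  mf <- tapply(cl$assignments$f_forward, lab, mean)
  expect_true(mf["protruding"] > mf["transition"])
  expect_true(mf["transition"] > mf["resting"])

  # row order must not matter for the recovered partition
  perm <- sample(30)
  cl2 <- classify_subdomains(x[perm, , drop = FALSE], seed = 2)
  expect_equal(as.character(cl2$assignments$label), as.character(lab[perm]))
})

test_that("k-means degenerate cases behave", {
  x <- rbind(c(0.8, 0.1, 0.1), c(0.5, 0.3, 0.2), c(0.2, 0.5, 0.3))
  colnames(x) <- c("f_forward", "f_parallel", "f_backward")
  cl <- classify_subdomains(x, seed = 1)
  expect_equal(sort(as.character(cl$assignments$label)),
    sort(c("protruding", "transition", "resting")))
  expect_error(classify_subdomains(x[1:2, , drop = FALSE]), "at least k")
})

test_that("sub-domain report averages member profiles", {
  centers <- seq(20, 380, length.out = 100)
  p1 <- profile_from(centers, rep(0.8, 100), rep(0.1, 100), rep(0.1, 100))
  p2 <- profile_from(centers, rep(0.6, 100), rep(0.3, 100), rep(0.1, 100))
  pc <- profile_from(centers, rep(0.55, 100), rep(0.3, 100), rep(0.15, 100))
  p3 <- profile_from(centers, rep(0.4, 100), rep(0.4, 100), rep(0.2, 100))
  x <- rbind(
    c(0.90, 0.05, 0.05), c(0.86, 0.09, 0.05),
    c(0.60, 0.25, 0.15), c(0.30, 0.50, 0.20)
  )
  colnames(x) <- c("f_forward", "f_parallel", "f_backward")
  rownames(x) <- c("a", "b", "c", "d")
  cl <- classify_subdomains(x, seed = 1)
  rep3 <- suppressWarnings(
    subdomain_report(cl, list(a = p1, b = p2, c = pc, d = p3))
  )
  # two-member protruding cluster: mean of the member profiles
  expect_equal(unname(rep3$protruding$mean[1, "forward"]), 0.7)
  expect_equal(unname(rep3$protruding$sd[1, "forward"]), stats::sd(c(0.8, 0.6)))
  # single-member cluster: mean equals the profile, sd 0
  expect_equal(unname(rep3$resting$mean[, "forward"]), rep(0.4, 100))
  expect_true(all(rep3$resting$sd == 0))
})
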