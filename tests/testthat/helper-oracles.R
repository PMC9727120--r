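# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written from scratch against the definitions, not
# by calling package internals.

oracle_angle <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  acos(max(-1, min(1, ct))) * 180 / pi
}

# Exhaustive fragmentation scan: segment i extends the current fragment
# unless the turn formed by the fragment's last two coordinates and i
# reaches the limit; then i starts a new fragment.
oracle_fragment <- function(pos, limit = 90) {
  n <- nrow(pos)
  frag <- integer(n)
  frag[1] <- 1L
  cur <- 1L
  members <- 1L
  for (i in 2:n) {
    cut <- FALSE
    if (length(members) >= 2L) {
      m <- length(members)
      a <- pos[members[m - 1L], ]
      b <- pos[members[m], ]
      if (oracle_angle(pos[i, ] - b, b - a) >= limit - 1e-9) cut <- TRUE
    }
    if (cut) {
      cur <- cur + 1L
      members <- i
    } else {
      members <- c(members, i)
    }
    frag[i] <- cur
  }
  frag
}

oracle_nn <- function(q, pts) {
  best <- 1L
  bd <- Inf
  for (j in seq_len(nrow(pts))) {
    d <- sqrt(sum((q - pts[j, ])^2))
    if (d < bd - 1e-12) {
      bd <- d
      best <- j
    }
  }
  c(index = best, distance = bd)
}

oracle_epsilon <- function(pol, s, cone = 30) {
  vapply(seq_len(nrow(pol)), function(j) {
    as.integer(oracle_angle(pol[j, ], s) <= cone + 1e-9)
  }, integer(1))
}

oracle_frame_members <- function(d, start, width) {
  which(d >= start & d < start + width)
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# straight test filament: n segments every 11 nm from `from` along unit `v`
straight_segments <- function(from, v, n, fid = "f1", tomo = "t1",
                              pol = NULL, spacing = 11) {
  v <- v / sqrt(sum(v * v))
  pos <- t(vapply(seq_len(n) - 1L, function(k) from + k * spacing * v, numeric(3)))
  if (is.null(pol)) pol <- matrix(v, n, 3, byrow = TRUE)
  data.frame(
    tomogram_id = tomo, filament_id = fid, segment_index = seq_len(n),
    x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3],
    px = pol[, 1], py = pol[, 2], pz = pol[, 3],
    stringsAsFactors = FALSE
  )
}

# unit vector at a given angle (deg) from unit vector v
vector_at_angle <- function(v, ang_deg, phi = 0) {
  v <- v / sqrt(sum(v * v))
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * v) * v
  e1 <- e1 / sqrt(sum(e1 * e1))
  e2 <- c(
    v[2] * e1[3] - v[3] * e1[2], v[3] * e1[1] - v[1] * e1[3],
    v[1] * e1[2] - v[2] * e1[1]
  )
  th <- ang_deg * pi / 180
  cos(th) * v + sin(th) * (cos(phi) * e1 + sin(phi) * e2)
}

# flat membrane grid on the y = 0 plane
flat_membrane <- function(nx = 21, nz = 11, spacing = 10, tomo = "t1") {
  g <- expand.grid(
    x = seq(0, by = spacing, length.out = nx),
    z = seq(0, by = spacing, length.out = nz)
  )
  data.frame(
    tomogram_id = tomo, x_nm = g$x, y_nm = 0, z_nm = g$z,
    stringsAsFactors = FALSE
  )
}

# Fibonacci sphere sample of approximately even spacing
fib_sphere <- function(r, spacing) {
  n <- max(64L, ceiling(4 * pi * r^2 / spacing^2))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(
    x_nm = r * sin(phi) * cos(theta),
    y_nm = r * sin(phi) * sin(theta),
    z_nm = r * cos(phi)
  )
}

cylinder_points <- function(r, height, spacing) {
  n_az <- ceiling(2 * pi * r / spacing)
  az <- seq(0, 2 * pi, length.out = n_az + 1L)[-(n_az + 1L)]
  zs <- seq(0, height, by = spacing)
  g <- expand.grid(az = az, z = zs)
  cbind(x_nm = r * cos(g$az), y_nm = r * sin(g$az), z_nm = g$z)
}

# criterion-condition scene parameters: only the stated noise channels on
acceptance_scene_params <- function(..., polarity_flip_prob = 0.1,
                                    segment_dropout_prob = 0.1) {
  scene_params(...,
    polarity_flip_prob = polarity_flip_prob,
    segment_dropout_prob = segment_dropout_prob,
    coordinate_jitter_sd = 0, polarity_jitter_sd = 0,
    dust_filament_rate = 0
  )
}

analyze_quiet <- function(segments, membrane, ...) {
  suppressWarnings(suppressMessages(analyze_tomogram(segments, membrane, ...)))
}

gt_proximal_fractions <- function(scene) {
  g <- scene$ground_truth
  g <- g[g$membrane_distance < 40, ]
  as.numeric(table(factor(g$category,
    levels = c("forward", "parallel", "backward")
  ))) / nrow(g)
}
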