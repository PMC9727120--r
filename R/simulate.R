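# Synthetic lamellipodium scenes: ground-truthed branched actin networks
# in a thin slab, with a membrane face, controllable orientation mixtures,
# Poisson branching, and realistic observation noise. Everything is driven
# by a single RNG seed so scenes are bit-reproducible.

#' Scene generator parameters
#'
#' Defaults emulate the statistical structure of lamellipodial actin
#' networks at a cell edge: a ~100 nm thin slab, segments every 11 nm,
#' forward filaments peaking around 40 degrees to the membrane normal, a
#' branch every 0.6 um of filament length, and a branch:filament ratio
#' near 1:3 (300 filaments of ~185 nm realized mean length in a
#' 1000 x 600 x 100 nm box give ~90-100 expected branches, i.e. about
#' 2500 branches per um^3 in the 0-400 nm analysis belt).
#'
#' @param box numeric length-3, box extents (x, y, z) in nm; the membrane
#'   lies at the y = 0 face and y is depth into the cell.
#' @param membrane_shape "flat" or "arc" (outward-bulging cylindrical
#'   membrane, to exercise normal estimation on a curved surface).
#' @param membrane_spacing membrane point spacing in nm (default 10).
#' @param arc_radius curvature radius for the arc membrane, nm.
#' @param n_filaments number of (non-dust) filaments.
#' @param mixture named or plain length-3 vector of target forward /
#'   parallel / backward fractions (sums to 1). The target is enforced
#'   exactly (up to rounding) within the proximal 0-40 nm slab and across
#'   the rest of the belt.
#' @param mixture_distal optional length-3 mixture at the distal (360-400
#'   nm) end; when given, the per-slab target is interpolated linearly
#'   between \code{mixture} and \code{mixture_distal}, emulating
#'   sub-domains whose forward fraction declines away from the membrane.
#'   Default NULL (constant mixture).
#' @param forward_mode,forward_sd mode and spread (degrees) of the
#'   truncated-normal angle draw for forward filaments (default 40 and 15;
#'   forward angles lie in [0, 80]).
#' @param parallel_sd spread around 90 degrees for parallel filaments
#'   (angles in (80, 100)).
#' @param backward_mode,backward_sd mode and spread for backward filaments
#'   (angles in [100, 180]; default mode 115 keeps proximal backward
#'   filaments geometrically placeable in the thin slab).
#' @param mean_filament_length nominal mean contour length, nm
#'   (exponential draw, minimum 3 segments). Clipping at the membrane and
#'   box walls shortens the realized mean; the default 420 yields a
#'   realized mean near 185 nm in the default box, which together with the
#'   default branch rate reproduces the ~1:3 branch:filament ratio and
#'   ~2500 per um^3 branch density of lamellipodial networks.
#' @param out_of_plane_sd spread of the growth direction's out-of-plane
#'   (slab thickness) component, as a fraction of the in-plane component
#'   (default 0.25; the lamellipodial network is quasi-two-dimensional).
#' @param branch_rate_per_um expected Arp2/3 branches per um of filament
#'   length (default 1/0.6).
#' @param branch_angle preferred mother-daughter angle in degrees
#'   (default 70, the canonical Arp2/3 branch angle; used to select
#'   mothers, realized angles are recorded).
#' @param segment_spacing inter-segment spacing, nm (11).
#' @param polarity_flip_prob per-segment probability of recording the
#'   polarity vector with inverted sign (default 0.1).
#' @param segment_dropout_prob per-segment probability of a missing
#'   segment (default 0.1).
#' @param coordinate_jitter_sd isotropic Gaussian coordinate noise, nm
#'   (default 2).
#' @param polarity_jitter_sd angular noise (degrees) on each observed
#'   polarity vector before any sign flip (default 5).
#' @param dust_filament_rate expected number of false-positive "dust"
#'   fragments (2-4 random segments) per real filament (default 0.05).
#' @param seed RNG seed.
#' @return list of class \code{scene_params}.
#' @export
scene_params <- function(box = c(1000, 600, 100),
                         membrane_shape = c("flat", "arc"),
                         membrane_spacing = 10,
                         arc_radius = 2000,
                         n_filaments = 300,
                         mixture = c(forward = 0.60, parallel = 0.25, backward = 0.15),
                         mixture_distal = NULL,
                         forward_mode = 40, forward_sd = 15,
                         parallel_sd = 4,
                         backward_mode = 115, backward_sd = 10,
                         mean_filament_length = 420,
                         out_of_plane_sd = 0.25,
                         branch_rate_per_um = 1 / 0.6,
                         branch_angle = 70,
                         segment_spacing = 11,
                         polarity_flip_prob = 0.1,
                         segment_dropout_prob = 0.1,
                         coordinate_jitter_sd = 2,
                         polarity_jitter_sd = 5,
                         dust_filament_rate = 0.05,
                         seed = 1) {
  membrane_shape <- match.arg(membrane_shape)
  mixture <- as.numeric(mixture)
  if (length(mixture) != 3L || any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture must be 3 non-negative fractions summing to 1")
  }
  if (!is.null(mixture_distal)) {
    mixture_distal <- as.numeric(mixture_distal)
    if (length(mixture_distal) != 3L || any(mixture_distal < 0) ||
      abs(sum(mixture_distal) - 1) > 1e-8) {
      stop("mixture_distal must be 3 non-negative fractions summing to 1")
    }
  }
  probs <- c(polarity_flip_prob, segment_dropout_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_filaments < 1L) stop("n_filaments must be positive")
  structure(as.list(environment()), class = "scene_params")
}

#' Sub-domain generator presets
#'
#' Proximal-slab orientation mixtures characteristic of the three
#' lamellipodial sub-domains: protruding (85/10/5), transition (60/25/15)
#' and resting (40/40/20) forward/parallel/backward fractions. With
#' \code{graded = TRUE} a distal mixture is returned as well, emulating
#' the decline of the forward fraction (and rise of the backward fraction)
#' toward the cell interior that distinguishes protruding sub-domains.
#'
#' @param name one of "protruding", "transition", "resting".
#' @param graded logical; return a list with \code{proximal} and
#'   \code{distal} mixtures instead of a single vector.
#' @return length-3 named mixture vector, or a list of two such vectors.
#' @export
subdomain_preset <- function(name = c("protruding", "transition", "resting"),
                             graded = FALSE) {
  name <- match.arg(name)
  prox <- switch(name,
    protruding = c(forward = 0.85, parallel = 0.10, backward = 0.05),
    transition = c(forward = 0.60, parallel = 0.25, backward = 0.15),
    resting = c(forward = 0.40, parallel = 0.40, backward = 0.20)
  )
  if (!graded) return(prox)
  distal <- switch(name,
    protruding = c(forward = 0.60, parallel = 0.10, backward = 0.30),
    transition = c(forward = 0.50, parallel = 0.30, backward = 0.20),
    resting = c(forward = 0.35, parallel = 0.40, backward = 0.25)
  )
  list(proximal = prox, distal = distal)
}

# truncated normal by rejection (bounds inclusive-ish; narrow use)
.rtruncnorm1 <- function(mode, sd, lo, hi) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mode, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stats::runif(1, lo, hi)
}

.category_theta <- function(category, p) {
  switch(category,
    forward = .rtruncnorm1(p$forward_mode, p$forward_sd, 0, 80),
    parallel = .rtruncnorm1(90, p$parallel_sd, 80 + 1e-6, 100 - 1e-6),
    backward = .rtruncnorm1(p$backward_mode, p$backward_sd, 100, 180)
  )
}

# membrane surface: returns points, analytic outward normal function and
# anchor sampler. Outward = toward negative y (away from the cytoplasm).
.make_membrane <- function(p) {
  s <- p$membrane_spacing
  xs <- seq(0, p$box[1], by = s)
  zs <- seq(0, p$box[3], by = s)
  g <- expand.grid(x = xs, z = zs)
  if (p$membrane_shape == "flat") {
    pts <- cbind(x_nm = g$x, y_nm = 0, z_nm = g$z)
    normal_at <- function(xz) {
      matrix(rep(c(0, -1, 0), nrow(xz)), ncol = 3L, byrow = TRUE)
    }
  } else {
    R <- p$arc_radius
    cx <- p$box[1] / 2
    sag <- function(x) R - sqrt(pmax(R^2 - (x - cx)^2, 0))
    pts <- cbind(x_nm = g$x, y_nm = sag(g$x), z_nm = g$z)
    normal_at <- function(xz) {
      dx <- (xz[, 1L] - cx)
      dy <- -sqrt(pmax(R^2 - dx^2, 0))
      m <- cbind(dx, dy, 0) / R
      m
    }
  }
  list(points = pts, normal_at = normal_at)
}

.inside_box <- function(pos, box) {
  pos[, 1] >= 0 & pos[, 1] <= box[1] &
    pos[, 2] >= 0 & pos[, 2] <= box[2] &
    pos[, 3] >= 0 & pos[, 3] <= box[3]
}

# small random rotation of unit vector v: angle ~ |N(0, sd_deg)|, random azimuth
.jitter_direction <- function(v, sd_deg) {
  a <- abs(stats::rnorm(1, 0, sd_deg)) / .DEG
  b <- .perp_basis(v)
  phi <- stats::runif(1, 0, 2 * pi)
  u <- cos(phi) * b$e1 + sin(phi) * b$e2
  cos(a) * v + sin(a) * u
}

#' Simulate a ground-truthed lamellipodium scene
#'
#' Generates a thin-slab branched actin scene: membrane points on one box
#' face, filaments with barbed ends placed throughout the 0-400 nm belt,
#' orientation categories allocated to match the requested mixture exactly
#' (largest-remainder allocation, stratified so the proximal 0-40 nm slab
#' hits the target on its own), straight growth from the barbed end toward
#' the pointed end at 11 nm spacing clipped at the membrane and box walls,
#' Poisson branch events attached to spatially adjacent filament pairs
#' with realized branch angles recorded, and observation noise applied
#' afterwards: per-segment polarity angular jitter and sign flips, segment
#' dropout, coordinate jitter, and short random "dust" fragments.
#'
#' @param params a \code{\link{scene_params}} list.
#' @return object of class \code{actin_scene}: list with \code{segments}
#'   (observed segment table), \code{membrane} (membrane point table),
#'   \code{branches} (branch table), \code{ground_truth} (per-filament
#'   truth: direction, theta, category, barbed-end membrane distance,
#'   dust flag), \code{ground_truth_segments} (per-segment true polarity,
#'   flip and dropout flags), \code{params}.
#' @export
simulate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(p$seed)

  mem <- .make_membrane(p)
  span <- 400
  n <- p$n_filaments

  # barbed-end anchors: membrane-parallel position + distance into the cell
  ax <- stats::runif(n, min(40, p$box[1] / 4), p$box[1] - min(40, p$box[1] / 4))
  az <- stats::runif(n, 5, p$box[3] - 5)
  dist <- stats::runif(n, 2, span - 2)

  # category allocation: exact (largest remainder) within the proximal slab
  # so the proximal ground-truth mixture is the target. With a distal
  # mixture, the target is interpolated linearly across the belt and
  # enforced per 40 nm slab; otherwise one constant mixture covers the rest.
  cats <- character(n)
  if (is.null(p$mixture_distal)) {
    groups <- list(which(dist < 40), which(dist >= 40))
    mixes <- list(p$mixture, p$mixture)
  } else {
    bin <- pmin(floor(dist / 40), 9)
    groups <- lapply(0:9, function(b) which(bin == b))
    w <- (40 * (0:9) + 20 - 20) / 360 # slab centers mapped to [0, 1]
    mixes <- lapply(w, function(wi) (1 - wi) * p$mixture + wi * p$mixture_distal)
  }
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    if (length(grp) == 0L) next
    cnt <- .allocate_counts(length(grp), mixes[[gi]])
    lab <- rep(c("forward", "parallel", "backward"), cnt)
    cats[grp] <- sample(lab)
  }

  seg_rows <- vector("list", n)
  gt_rows <- vector("list", n)
  for (i in seq_len(n)) {
    anchor_xz <- cbind(ax[i], az[i])
    n_out <- mem$normal_at(anchor_xz)[1L, ]
    base <- if (p$membrane_shape == "flat") c(ax[i], 0, az[i]) else {
      m <- mem$points[which.min((mem$points[, 1] - ax[i])^2 + (mem$points[, 3] - az[i])^2), ]
      as.numeric(m)
    }
    barbed <- base - dist[i] * n_out   # inward = -outward

    # sample an orientation within the category that fits >= 2 segments;
    # the lamellipodium is quasi-2D, so the out-of-plane (slab thickness)
    # component of the growth direction is damped
    for (try in 1:60) {
      theta <- .category_theta(cats[i], p)
      b <- .perp_basis(n_out)
      zeta <- .clamp(stats::rnorm(1, 0, p$out_of_plane_sd), -1, 1)
      sgn <- if (stats::runif(1) < 0.5) 1 else -1
      dvec <- cos(theta / .DEG) * n_out +
        sin(theta / .DEG) * (sgn * sqrt(1 - zeta^2) * b$e1 + zeta * b$e2)
      len <- stats::rexp(1, 1 / p$mean_filament_length)
      n_seg <- max(3L, as.integer(round(len / p$segment_spacing)) + 1L)
      ks <- seq_len(n_seg)
      pos <- t(vapply(ks, function(k) barbed - (n_seg - k) * p$segment_spacing * dvec,
        numeric(3)))
      inb <- .inside_box(pos, p$box)
      # keep the contiguous run ending at the barbed end; prefer
      # placements holding >= 3 segments (a stable polarity consensus),
      # fall back to 2 when the geometry forbids more near the membrane
      first_ok <- if (all(inb)) 1L else max(which(!inb)) + 1L
      min_fit <- if (try <= 40L) n_seg - 2L else n_seg - 1L
      if (first_ok <= min_fit) {
        pos <- pos[first_ok:n_seg, , drop = FALSE]
        break
      }
      pos <- NULL
    }
    if (is.null(pos)) next  # could not place (extremely rare); drop filament
    n_seg <- nrow(pos)
    fid <- sprintf("f%04d", i)
    seg_rows[[i]] <- data.frame(
      filament_id = fid, segment_index = seq_len(n_seg),
      x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3],
      tp_x = dvec[1], tp_y = dvec[2], tp_z = dvec[3],
      stringsAsFactors = FALSE
    )
    gt_rows[[i]] <- data.frame(
      filament_id = fid,
      dir_x = dvec[1], dir_y = dvec[2], dir_z = dvec[3],
      theta = theta, category = cats[i], membrane_distance = dist[i],
      n_segments = n_seg,
      contour_length_nm = (n_seg - 1L) * p$segment_spacing,
      is_dust = FALSE, stringsAsFactors = FALSE
    )
  }
  seg_true <- do.call(rbind, seg_rows[!vapply(seg_rows, is.null, logical(1))])
  gt <- do.call(rbind, gt_rows[!vapply(gt_rows, is.null, logical(1))])

  # Poisson branch events attached to adjacent filament pairs. Each event
  # selects a daughter filament and, among the spatially nearest candidate
  # mothers at its pointed end, the one whose realized inter-axis angle is
  # closest to the preferred branch angle.
  total_um <- sum(gt$contour_length_nm) / 1000
  n_branch <- stats::rpois(1, p$branch_rate_per_um * total_um)
  n_branch <- min(n_branch, nrow(gt) - 1L)
  branches <- NULL
  if (n_branch > 0L) {
    daughters <- sample(gt$filament_id, n_branch)
    pointed <- t(vapply(daughters, function(f) {
      s <- seg_true[seg_true$filament_id == f, ]
      as.numeric(s[1L, c("x_nm", "y_nm", "z_nm")])
    }, numeric(3)))
    segm <- as.matrix(seg_true[, c("x_nm", "y_nm", "z_nm")])
    br <- vector("list", n_branch)
    for (bidx in seq_len(n_branch)) {
      f <- daughters[bidx]
      cand <- seg_true$filament_id != f
      # candidate mothers: filaments owning the 25 nearest foreign segments
      ord <- order(.row_norms(sweep(segm[cand, , drop = FALSE], 2L, pointed[bidx, ])))
      near_f <- unique(seg_true$filament_id[cand][ord[seq_len(min(25L, sum(cand)))]])
      ddir <- as.numeric(gt[gt$filament_id == f, c("dir_x", "dir_y", "dir_z")])
      angs <- vapply(near_f, function(mf) {
        mdir <- as.numeric(gt[gt$filament_id == mf, c("dir_x", "dir_y", "dir_z")])
        .angle_deg(ddir, mdir)
      }, numeric(1))
      mother <- near_f[which.min(abs(angs - p$branch_angle))]
      midx <- which(cand)[ord[seg_true$filament_id[cand][ord] == mother][1L]]
      br[[bidx]] <- data.frame(
        mother_filament_id = mother, daughter_filament_id = f,
        branch_x = segm[midx, 1], branch_y = segm[midx, 2],
        branch_z = segm[midx, 3],
        branch_angle = min(max(angs[near_f == mother], 1e-6), 180 - 1e-6),
        stringsAsFactors = FALSE
      )
    }
    branches <- do.call(rbind, br)
  }

  # ---- observation noise -------------------------------------------------
  ns <- nrow(seg_true)
  obs <- seg_true
  # polarity: true direction + angular jitter, then sign flips
  pol <- t(vapply(seq_len(ns), function(r) {
    .jitter_direction(
      as.numeric(seg_true[r, c("tp_x", "tp_y", "tp_z")]), p$polarity_jitter_sd
    )
  }, numeric(3)))
  flipped <- stats::runif(ns) < p$polarity_flip_prob
  pol[flipped, ] <- -pol[flipped, , drop = FALSE]
  obs$px <- pol[, 1]
  obs$py <- pol[, 2]
  obs$pz <- pol[, 3]
  obs$flipped <- flipped
  # coordinate jitter
  jit <- matrix(stats::rnorm(3 * ns, 0, p$coordinate_jitter_sd), ns, 3L)
  obs$x_nm <- obs$x_nm + jit[, 1]
  obs$y_nm <- obs$y_nm + jit[, 2]
  obs$z_nm <- obs$z_nm + jit[, 3]
  # dropout (never below 2 surviving segments per filament)
  drop <- stats::runif(ns) < p$segment_dropout_prob
  for (f in unique(obs$filament_id)) {
    sel <- which(obs$filament_id == f)
    if (sum(!drop[sel]) < 2L) drop[sel] <- FALSE
  }
  obs$dropped <- drop

  gt_segments <- data.frame(
    filament_id = seg_true$filament_id, segment_index = seg_true$segment_index,
    px_true = seg_true$tp_x, py_true = seg_true$tp_y, pz_true = seg_true$tp_z,
    flipped = obs$flipped, dropped = obs$dropped, stringsAsFactors = FALSE
  )

  observed <- obs[!obs$dropped, c(
    "filament_id", "segment_index", "x_nm", "y_nm", "z_nm", "px", "py", "pz"
  )]

  # dust: short random false-positive fragments
  n_dust <- stats::rpois(1, p$dust_filament_rate * n)
  if (n_dust > 0L) {
    dust <- vector("list", n_dust)
    for (d in seq_len(n_dust)) {
      nsd <- sample(2:4, 1)
      origin <- stats::runif(3) * p$box
      v <- stats::rnorm(3)
      v <- v / sqrt(sum(v * v))
      posd <- t(vapply(seq_len(nsd), function(k) origin + (k - 1) * p$segment_spacing * v,
        numeric(3)))
      poldir <- if (stats::runif(1) < 0.5) v else -v
      dust[[d]] <- data.frame(
        filament_id = sprintf("dust%03d", d), segment_index = seq_len(nsd),
        x_nm = posd[, 1], y_nm = posd[, 2], z_nm = posd[, 3],
        px = poldir[1], py = poldir[2], pz = poldir[3],
        stringsAsFactors = FALSE
      )
    }
    observed <- rbind(observed, do.call(rbind, dust))
  }

  tomo <- sprintf("sim_seed%d", p$seed)
  observed <- cbind(tomogram_id = tomo, observed, stringsAsFactors = FALSE)
  gt <- cbind(tomogram_id = tomo, gt, stringsAsFactors = FALSE)
  gt_segments <- cbind(tomogram_id = tomo, gt_segments, stringsAsFactors = FALSE)
  membrane_tab <- data.frame(
    tomogram_id = tomo,
    x_nm = mem$points[, 1], y_nm = mem$points[, 2], z_nm = mem$points[, 3],
    stringsAsFactors = FALSE
  )
  if (!is.null(branches)) branches <- cbind(tomogram_id = tomo, branches,
    stringsAsFactors = FALSE)
  rownames(observed) <- rownames(gt) <- rownames(gt_segments) <- NULL

  structure(
    list(
      segments = observed, membrane = membrane_tab,
      branches = branches, ground_truth = gt,
      ground_truth_segments = gt_segments, params = p,
      realized_branch_ratio = if (nrow(gt) > 0) n_branch / nrow(gt) else NA_real_,
      total_filament_length_um = total_um
    ),
    class = "actin_scene"
  )
}

#' @export
print.actin_scene <- function(x, ...) {
  cat("Synthetic lamellipodium scene (seed", x$params$seed, ")\n")
  cat("  filaments:", nrow(x$ground_truth),
    " segments observed:", nrow(x$segments), "\n")
  cat("  membrane points:", nrow(x$membrane), "\n")
  nb <- if (is.null(x$branches)) 0L else nrow(x$branches)
  cat(sprintf(
    "  branches: %d (ratio %.3f, %.1f um filament length)\n",
    nb, x$realized_branch_ratio, x$total_filament_length_um
  ))
  cat("  ground-truth mixture:",
    paste(sprintf("%.2f", .category_fractions(x$ground_truth$category)), collapse = "/"),
    "(forward/parallel/backward)\n")
  invisible(x)
}

#' Write a scene to pipeline input files
#'
#' Writes the observed segment, membrane and branch tables plus the
#' ground-truth tables and a provenance JSON (parameters, seed, file
#' checksums) into a directory, in the TSV dialect the pipeline readers
#' accept. Output is byte-identical across runs with the same scene.
#'
#' @param scene an \code{\link{simulate_scene}} result.
#' @param dir output directory (created if missing).
#' @return invisibly, a named vector of file paths.
#' @export
scene_to_tables <- function(scene, dir) {
  stopifnot(inherits(scene, "actin_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    segments = file.path(dir, "segments.tsv"),
    membrane = file.path(dir, "membrane.tsv"),
    branches = file.path(dir, "branches.tsv"),
    ground_truth = file.path(dir, "ground_truth_filaments.tsv"),
    ground_truth_segments = file.path(dir, "ground_truth_segments.tsv"),
    provenance = file.path(dir, "provenance.json")
  )
  .write_tsv(scene$segments, paths[["segments"]])
  .write_tsv(scene$membrane, paths[["membrane"]])
  if (!is.null(scene$branches)) {
    .write_tsv(scene$branches, paths[["branches"]])
  } else {
    .write_tsv(
      data.frame(
        tomogram_id = character(), mother_filament_id = character(),
        daughter_filament_id = character(), branch_x = numeric(),
        branch_y = numeric(), branch_z = numeric(), branch_angle = numeric()
      ),
      paths[["branches"]]
    )
  }
  .write_tsv(scene$ground_truth, paths[["ground_truth"]])
  .write_tsv(scene$ground_truth_segments, paths[["ground_truth_segments"]])
  prov <- list(
    params = scene$params[setdiff(names(scene$params), "membrane_shape")],
    membrane_shape = scene$params$membrane_shape,
    seed = scene$params$seed,
    checksums = as.list(tools::md5sum(paths[-length(paths)]))
  )
  names(prov$checksums) <- names(paths)[-length(paths)]
  jsonlite::write_json(prov, paths[["provenance"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Simulate a multi-tomogram cohort
#'
#' One scene per tomogram, cycling through sub-domain presets (or a list
#' of mixtures), each with its own derived seed.
#'
#' @param n_per_preset tomograms per preset (default 4).
#' @param presets character vector of preset names or list of mixtures.
#' @param seed base seed; scene i uses \code{seed * 1000 + i}.
#' @param graded use graded presets (distal mixtures differing from
#'   proximal; see \code{\link{subdomain_preset}}). Default FALSE.
#' @param ... further arguments passed to \code{\link{scene_params}}.
#' @return list with \code{scenes} (named list of \code{actin_scene}) and
#'   \code{labels} (generating preset per tomogram).
#' @export
simulate_cohort <- function(n_per_preset = 4,
                            presets = c("protruding", "transition", "resting"),
                            seed = 1, graded = FALSE, ...) {
  scenes <- list()
  labels <- character(0)
  i <- 0L
  for (pr in presets) {
    mix <- if (is.character(pr)) subdomain_preset(pr, graded = graded) else pr
    nm <- if (is.character(pr)) pr else "custom"
    if (!is.list(mix)) mix <- list(proximal = mix, distal = NULL)
    for (r in seq_len(n_per_preset)) {
      i <- i + 1L
      sp <- scene_params(
        mixture = mix$proximal, mixture_distal = mix$distal,
        seed = seed * 1000 + i, ...
      )
      sc <- simulate_scene(sp)
      id <- sprintf("%s_%02d", nm, r)
      sc$segments$tomogram_id <- id
      sc$membrane$tomogram_id <- id
      sc$ground_truth$tomogram_id <- id
      sc$ground_truth_segments$tomogram_id <- id
      if (!is.null(sc$branches)) sc$branches$tomogram_id <- id
      scenes[[id]] <- sc
      labels <- c(labels, nm)
    }
  }
  names(labels) <- names(scenes)
  list(scenes = scenes, labels = labels)
}
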