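#' Orientation category from a mean filament-membrane angle
#'
#' Three intervals partition [0, 180]: forward (barbed end toward the
#' membrane) for mean angles <= 80, parallel for angles strictly between
#' 80 and 100, and backward (barbed end toward the cell interior) for
#' angles >= 100.
#'
#' @param mean_angle numeric vector of mean angles in degrees, in [0, 180].
#' @return factor with levels \code{forward}, \code{parallel},
#'   \code{backward}.
#' @examples
#' categorize_orientation(c(0, 75, 80, 90, 100, 180))
#' @export
categorize_orientation <- function(mean_angle) {
  if (any(!is.finite(mean_angle)) || any(mean_angle < 0 | mean_angle > 180)) {
    stop("mean_angle must lie in [0, 180]")
  }
  out <- ifelse(mean_angle <= 80, "forward",
    ifelse(mean_angle < 100, "parallel", "backward")
  )
  factor(out, levels = c("forward", "parallel", "backward"))
}

#' Per-filament membrane orientation records
#'
#' For every filament that passed the polarity confidence test, each
#' segment is matched to its nearest membrane point and the angle between
#' the filament's resolved direction and that point's smoothed outward
#' normal is computed. The per-segment angles use the consensus direction
#' (not the raw, possibly flipped, per-segment vectors), so a noisy
#' segment cannot invert its own angle. The per-filament mean angle is
#' categorized as forward / parallel / backward, and the filament's
#' membrane distance is that of its barbed-end representative coordinate.
#'
#' @param filaments filament table from \code{\link{filament_polarity}}.
#' @param segments the segment table the filaments were derived from.
#' @param membrane a \code{\link{membrane_model}} with oriented normals.
#' @return data frame (one row per passed filament) with columns
#'   \code{tomogram_id}, \code{filament_id}, \code{mean_angle},
#'   \code{category}, \code{membrane_distance}, \code{n_segments_used}.
#'   Filaments whose segments all map to undefined-normal membrane points
#'   are excluded with a warning.
#' @export
filament_orientation <- function(filaments, segments, membrane) {
  stopifnot(inherits(membrane, "membrane_model"))
  fl <- filaments[filaments$passed_confidence & !filaments$undefined_polarity, ,
    drop = FALSE
  ]
  if (nrow(fl) == 0L) stop("no filament passed the confidence test")
  keep <- .filament_key(segments) %in% .filament_key(fl)
  seg <- segments[keep, , drop = FALSE]
  nn <- nearest_membrane_point(seg[, c("x_nm", "y_nm", "z_nm")], membrane)
  seg_ok <- membrane$ok[nn$index]
  normal <- membrane$normals[nn$index, , drop = FALSE]

  key <- .filament_key(seg)
  fkey <- .filament_key(fl)
  groups <- split(seq_len(nrow(seg)), factor(key, levels = fkey))

  bnn <- nearest_membrane_point(
    as.matrix(fl[, c("barbed_x", "barbed_y", "barbed_z")]), membrane
  )

  mean_angle <- rep(NA_real_, nrow(fl))
  n_used <- integer(nrow(fl))
  for (i in seq_len(nrow(fl))) {
    g <- groups[[i]]
    g <- g[seg_ok[g]]
    n_used[i] <- length(g)
    if (length(g) == 0L) next
    dir <- as.numeric(fl[i, c("dir_x", "dir_y", "dir_z")])
    ang <- segment_membrane_angle(
      matrix(dir, length(g), 3L, byrow = TRUE),
      normal[g, , drop = FALSE]
    )
    mean_angle[i] <- mean(ang)
  }
  drop <- is.na(mean_angle)
  if (any(drop)) {
    warning(sum(drop), " filament(s) excluded: all segments map to undefined membrane normals")
  }
  out <- data.frame(
    tomogram_id = fl$tomogram_id,
    filament_id = fl$filament_id,
    mean_angle = mean_angle,
    membrane_distance = bnn$distance,
    n_segments_used = n_used,
    stringsAsFactors = FALSE
  )[!drop, , drop = FALSE]
  out$category <- categorize_orientation(out$mean_angle)
  rownames(out) <- NULL
  out[, c(
    "tomogram_id", "filament_id", "mean_angle", "category",
    "membrane_distance", "n_segments_used"
  )]
}

.category_fractions <- function(category) {
  n <- length(category)
  if (n == 0L) {
    return(c(forward = NA_real_, parallel = NA_real_, backward = NA_real_))
  }
  tab <- table(factor(category, levels = c("forward", "parallel", "backward")))
  as.numeric(tab) / n
}

#' Distance-resolved orientation profile
#'
#' Bins filaments by the membrane distance of their barbed-end
#' representative coordinate into half-open slabs \code{[k*w, (k+1)*w)} of
#' width \code{bin_width} up to \code{max_distance} (filaments at or beyond
#' it are excluded), and reports per-slab filament counts and category
#' fractions.
#'
#' @param records orientation records from
#'   \code{\link{filament_orientation}}.
#' @param bin_width slab width in nm (default 40).
#' @param max_distance analysis depth in nm (default 400).
#' @return data frame with \code{bin_lo}, \code{bin_hi}, \code{n},
#'   \code{f_forward}, \code{f_parallel}, \code{f_backward} (fractions NA
#'   in empty slabs).
#' @export
distance_profile <- function(records, bin_width = 40, max_distance = 400) {
  if (nrow(records) == 0L) stop("no orientation records")
  edges <- seq(0, max_distance, by = bin_width)
  nb <- length(edges) - 1L
  bin <- findInterval(records$membrane_distance, edges,
    rightmost.closed = FALSE, left.open = FALSE
  )
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L])
  out$n <- 0L
  out$f_forward <- NA_real_
  out$f_parallel <- NA_real_
  out$f_backward <- NA_real_
  for (k in seq_len(nb)) {
    sel <- bin == k
    out$n[k] <- sum(sel)
    if (out$n[k] > 0L) {
      f <- .category_fractions(records$category[sel])
      out$f_forward[k] <- f[1L]
      out$f_parallel[k] <- f[2L]
      out$f_backward[k] <- f[3L]
    }
  }
  out
}

#' Normalised orientation histogram
#'
#' Probability histogram of filament-membrane angles,
#' \code{p(bin) = count_bin / total}, over [0, 180] with the last bin
#' closed so that 180 degrees is counted.
#'
#' @param angles numeric vector of angles in degrees, in [0, 180].
#' @param bin_width_deg histogram bin width (default 10).
#' @return data frame with \code{bin_lo}, \code{bin_hi}, \code{count},
#'   \code{p}; \code{sum(p) == 1}.
#' @export
orientation_histogram <- function(angles, bin_width_deg = 10) {
  if (length(angles) == 0L) stop("empty angle vector")
  if (any(!is.finite(angles)) || any(angles < 0 | angles > 180)) {
    stop("angles must lie in [0, 180]")
  }
  edges <- seq(0, 180, by = bin_width_deg)
  if (edges[length(edges)] < 180) edges <- c(edges, 180)
  bin <- findInterval(angles, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  data.frame(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
    count = counts, p = counts / length(angles)
  )
}

#' Distance-resolved density profiles
#'
#' Densities of barbed ends and of filament segments per membrane-distance
#' slab, using externally supplied slab volumes, plus a filament length
#' density from the 11 nm inter-segment spacing. Segment slab membership
#' uses each segment's own nearest-membrane distance; barbed ends use the
#' filament's representative coordinate.
#'
#' @param segments segment table (only passed-confidence filaments are
#'   counted).
#' @param filaments filament table from \code{\link{filament_polarity}}.
#' @param membrane a \code{\link{membrane_model}}.
#' @param slab_volumes_um3 numeric vector of per-slab analysis volumes in
#'   cubic micrometres (length = number of slabs); NA or zero volumes give
#'   NA densities.
#' @param bin_width,max_distance slab geometry, as in
#'   \code{\link{distance_profile}}.
#' @param segment_spacing_nm nominal inter-segment spacing used for the
#'   length density (default 11).
#' @return data frame with per-slab counts and densities
#'   (\code{barbed_density_um3}, \code{segment_density_um3},
#'   \code{length_density_um_per_um3}).
#' @export
density_profiles <- function(segments, filaments, membrane, slab_volumes_um3,
                             bin_width = 40, max_distance = 400,
                             segment_spacing_nm = 11) {
  edges <- seq(0, max_distance, by = bin_width)
  nb <- length(edges) - 1L
  if (length(slab_volumes_um3) != nb) {
    stop("slab_volumes_um3 must have one entry per slab (", nb, ")")
  }
  fl <- filaments[filaments$passed_confidence, , drop = FALSE]
  keep <- .filament_key(segments) %in% .filament_key(fl)
  seg <- segments[keep, , drop = FALSE]
  snn <- nearest_membrane_point(seg[, c("x_nm", "y_nm", "z_nm")], membrane)
  bnn <- nearest_membrane_point(
    as.matrix(fl[, c("barbed_x", "barbed_y", "barbed_z")]), membrane
  )
  sbin <- findInterval(snn$distance, edges)
  bbin <- findInterval(bnn$distance, edges)
  seg_n <- tabulate(sbin[sbin >= 1 & sbin <= nb], nbins = nb)
  bar_n <- tabulate(bbin[bbin >= 1 & bbin <= nb], nbins = nb)
  vol <- as.numeric(slab_volumes_um3)
  vol[!is.na(vol) & vol <= 0] <- NA_real_
  data.frame(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
    n_segments = seg_n, n_barbed = bar_n,
    volume_um3 = vol,
    barbed_density_um3 = bar_n / vol,
    segment_density_um3 = seg_n / vol,
    length_density_um_per_um3 = seg_n * (segment_spacing_nm / 1000) / vol
  )
}

#' Arp2/3 branch statistics
#'
#' Branch counts relative to the passed-confidence filament population:
#' the branch-to-filament ratio, the branch density in the analysis
#' volume, and the mean filament contour length per branch (the branch
#' spacing along the network).
#'
#' @param branches branch table (one row per branch; may have zero rows).
#' @param filaments filament table from \code{\link{filament_polarity}}
#'   (only \code{passed_confidence} rows are counted).
#' @param analysis_volume_um3 analysed volume in cubic micrometres.
#' @return list of class \code{arp_stats}: \code{n_branches},
#'   \code{n_filaments}, \code{branch_to_filament_ratio},
#'   \code{arp_density_um3}, \code{total_filament_length_um},
#'   \code{mean_filament_length_per_branch_um} (NA when there are no
#'   branches).
#' @export
arp_statistics <- function(branches, filaments, analysis_volume_um3) {
  fl <- filaments[filaments$passed_confidence, , drop = FALSE]
  nb <- if (is.null(branches)) 0L else nrow(branches)
  nf <- nrow(fl)
  total_um <- sum(fl$contour_length_nm) / 1000
  structure(
    list(
      n_branches = nb,
      n_filaments = nf,
      branch_to_filament_ratio = if (nf > 0) nb / nf else NA_real_,
      arp_density_um3 = nb / analysis_volume_um3,
      total_filament_length_um = total_um,
      mean_filament_length_per_branch_um =
        if (nb > 0) total_um / nb else NA_real_
    ),
    class = "arp_stats"
  )
}

#' @export
print.arp_stats <- function(x, ...) {
  cat("Arp2/3 branch statistics\n")
  cat("  branches:", x$n_branches, " filaments:", x$n_filaments, "\n")
  cat(sprintf("  branch:filament ratio  %.3f (1:%.1f)\n",
    x$branch_to_filament_ratio,
    ifelse(x$branch_to_filament_ratio > 0, 1 / x$branch_to_filament_ratio, NA)
  ))
  cat(sprintf("  branch density         %.0f per um^3\n", x$arp_density_um3))
  if (!is.na(x$mean_filament_length_per_branch_um)) {
    cat(sprintf(
      "  filament length/branch %.2f um (total %.1f um)\n",
      x$mean_filament_length_per_branch_um, x$total_filament_length_um
    ))
  }
  invisible(x)
}
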