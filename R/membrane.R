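#' Estimate raw membrane normals by local plane fitting
#'
#' For each point of the membrane segmentation cloud, a total-least-squares
#' plane is fitted to all points within \code{fit_radius} (a 40 nm sphere
#' by default, boundary inclusive, including the query point) and the
#' normal is the direction of least variance (smallest eigenvector of the
#' neighbourhood covariance). The sign is arbitrary at this stage.
#'
#' @param points membrane point cloud: n x 3 matrix or data frame with
#'   \code{x_nm, y_nm, z_nm} columns.
#' @param fit_radius neighbourhood radius in nm (default 40).
#' @return list with \code{normals} (n x 3, unit rows; NA rows where
#'   undefined) and \code{ok} (logical; FALSE where fewer than 3 neighbours
#'   or a collinear neighbourhood made the fit degenerate).
#' @export
estimate_normals <- function(points, fit_radius = 40) {
  pts <- .as_xyz_matrix(points, "membrane points")
  n <- nrow(pts)
  nb <- .radius_neighbors(pts, fit_radius)
  normals <- matrix(NA_real_, n, 3L)
  ok <- logical(n)
  for (i in seq_len(n)) {
    j <- nb[[i]]
    if (length(j) < 3L) next
    x <- pts[j, , drop = FALSE]
    x <- sweep(x, 2L, colMeans(x))
    ev <- eigen(crossprod(x), symmetric = TRUE)
    # eigenvalues descending; collinear neighbourhood <=> 2nd ~ 0
    if (ev$values[2L] <= ev$values[1L] * 1e-9 + 1e-12) next
    normals[i, ] <- ev$vectors[, 3L]
    ok[i] <- TRUE
  }
  if (any(!ok)) {
    message("estimate_normals: ", sum(!ok), "/", n, " points with undefined normal")
  }
  list(normals = normals, ok = ok)
}

#' Smooth membrane normals over their neighbourhood
#'
#' Replaces each defined normal by the renormalised mean of the
#' sign-aligned normals of all points within \code{fit_radius} (itself
#' included). Neighbour normals are flipped to agree with the query normal
#' before averaging, so the raw field need not be globally sign-consistent.
#'
#' @param points n x 3 membrane point cloud (nm).
#' @param normals n x 3 raw normals (NA rows allowed, left untouched).
#' @param fit_radius smoothing radius in nm (default 40, the same sphere as
#'   the plane fit; one pass).
#' @return n x 3 matrix of smoothed unit normals.
#' @export
smooth_normals <- function(points, normals, fit_radius = 40) {
  pts <- .as_xyz_matrix(points, "membrane points")
  if (is.null(dim(normals))) normals <- matrix(normals, ncol = 3L)
  nb <- .radius_neighbors(pts, fit_radius)
  out <- normals
  defined <- !is.na(normals[, 1L])
  for (i in which(defined)) {
    j <- nb[[i]]
    j <- j[defined[j]]
    v <- normals[j, , drop = FALSE]
    sgn <- sign(v %*% normals[i, ])[, 1L]
    sgn[sgn == 0] <- 1
    m <- colSums(v * sgn)
    len <- sqrt(sum(m * m))
    if (len < 1e-6) {
      warning("smooth_normals: degenerate neighbourhood mean at point ", i,
        "; raw normal kept")
      next
    }
    out[i, ] <- m / len
  }
  out
}

#' Orient membrane normals away from the cell interior
#'
#' The orientation analysis defines 0 degrees as "barbed end straight
#' toward the plasma membrane", which requires outward normals. Each
#' normal's sign is chosen so that it points away from a cytoplasmic
#' reference point: \code{dot(normal, interior_ref - point) <= 0}.
#'
#' @param points n x 3 membrane point cloud (nm).
#' @param normals n x 3 unit normals (NA rows passed through).
#' @param interior_ref 3-vector on the cytoplasmic side of the membrane
#'   (typically the centroid of the filament segments).
#' @return n x 3 matrix of outward unit normals.
#' @export
orient_normals_outward <- function(points, normals, interior_ref) {
  pts <- .as_xyz_matrix(points, "membrane points")
  if (is.null(dim(normals))) normals <- matrix(normals, ncol = 3L)
  to_in <- sweep(-pts, 2L, -as.numeric(interior_ref))  # interior_ref - point
  d <- .row_norms(to_in)
  if (any(d < 1e-9, na.rm = TRUE)) {
    warning("orient_normals_outward: interior_ref coincides with a membrane point; sign kept there")
  }
  dt <- rowSums(normals * to_in)
  flip <- !is.na(dt) & dt > 0 & d >= 1e-9
  normals[flip, ] <- -normals[flip, , drop = FALSE]
  normals
}

#' Build a membrane model (points + smoothed outward normals)
#'
#' Convenience constructor running \code{\link{estimate_normals}},
#' \code{\link{smooth_normals}} and \code{\link{orient_normals_outward}} in
#' order. If the input data frame already carries \code{nx, ny, nz} normal
#' columns they are taken as the raw normals and only smoothed and
#' re-oriented.
#'
#' @param points membrane point cloud (matrix or data frame; see
#'   \code{\link{estimate_normals}}).
#' @param interior_ref 3-vector on the cytoplasmic side. Required here;
#'   \code{\link{analyze_tomogram}} defaults it to the centroid of the
#'   passed-confidence filament segments.
#' @param fit_radius plane-fit and smoothing radius, nm (default 40).
#' @param tomogram_id optional identifier carried in the object.
#' @return object of class \code{membrane_model}: list with \code{points},
#'   \code{normals}, \code{ok}, \code{interior_ref}, \code{fit_radius},
#'   \code{tomogram_id}.
#' @export
membrane_model <- function(points, interior_ref, fit_radius = 40,
                           tomogram_id = NA_character_) {
  pts <- .as_xyz_matrix(points, "membrane points")
  if (is.data.frame(points) && all(c("nx", "ny", "nz") %in% names(points))) {
    raw <- .unit_rows(as.matrix(points[, c("nx", "ny", "nz")]))
    ok <- !is.na(raw[, 1L])
  } else {
    est <- estimate_normals(pts, fit_radius)
    raw <- est$normals
    ok <- est$ok
  }
  sm <- smooth_normals(pts, raw, fit_radius)
  sm <- orient_normals_outward(pts, sm, interior_ref)
  structure(
    list(
      points = pts, normals = sm, ok = ok,
      interior_ref = as.numeric(interior_ref),
      fit_radius = fit_radius, tomogram_id = tomogram_id
    ),
    class = "membrane_model"
  )
}

#' @export
print.membrane_model <- function(x, ...) {
  cat("Membrane model", if (!is.na(x$tomogram_id)) paste0("(", x$tomogram_id, ")"), "\n")
  cat("  points:", nrow(x$points), " (", sum(!x$ok), "with undefined normal )\n")
  cat("  fit radius:", x$fit_radius, "nm\n")
  cat(
    "  interior reference:",
    paste(sprintf("%.1f", x$interior_ref), collapse = ", "), "nm\n"
  )
  invisible(x)
}

#' Nearest membrane point to a query coordinate
#'
#' Exact Euclidean nearest-neighbour query against the membrane cloud;
#' ties are broken by the lowest point index. Results are identical to an
#' exhaustive scan (the search is an exhaustive scan, chunked).
#'
#' @param query 3-vector or m x 3 matrix of query coordinates (nm).
#' @param membrane a \code{\link{membrane_model}} or an n x 3 point matrix.
#' @return list with \code{index} and \code{distance} (vectors of length m).
#' @export
nearest_membrane_point <- function(query, membrane) {
  pts <- if (inherits(membrane, "membrane_model")) membrane$points else
    .as_xyz_matrix(membrane, "membrane")
  if (nrow(pts) == 0L) stop("membrane is empty")
  .nn_bruteforce(query, pts)
}

#' Angle between a polarity vector and a membrane normal
#'
#' The filament-membrane orientation angle: 0 degrees means the barbed end
#' points straight toward the membrane (polarity parallel to the outward
#' normal), 90 parallel to the membrane, 180 straight into the cell.
#'
#' @param polarity 3-vector or m x 3 matrix (unit polarity vectors).
#' @param normal 3-vector or m x 3 matrix (unit outward normals).
#' @return angle(s) in degrees, in [0, 180]. Inputs with norms in
#'   (0.5, 2) are normalised silently; norms outside that range are
#'   rejected.
#' @export
segment_membrane_angle <- function(polarity, normal) {
  p <- .as_xyz_matrix(polarity, "polarity")
  n <- .as_xyz_matrix(normal, "normal")
  if (nrow(n) == 1L && nrow(p) > 1L) n <- n[rep(1L, nrow(p)), , drop = FALSE]
  np <- .row_norms(p)
  nn <- .row_norms(n)
  bad <- np <= 0.5 | np >= 2 | nn <= 0.5 | nn >= 2
  if (any(bad)) stop("vector norm outside (0.5, 2); refusing to normalise")
  acos(.clamp(rowSums(p * n) / (np * nn), -1, 1)) * .DEG
}
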