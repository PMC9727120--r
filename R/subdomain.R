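#' Sliding-frame orientation proportion profile
#'
#' The proportion of forward / parallel / backward filaments is computed
#' continuously along the membrane distance axis with overlapping frames:
#' \code{n_frames} window start positions evenly spaced over
#' \code{[0, span - frame_width]} (default 100 frames of 40 nm over a
#' 400 nm belt, i.e. a ~3.64 nm step), each frame covering the half-open
#' interval \code{[start, start + frame_width)}. With \code{n_frames = 2}
#' the frames reduce to the proximal (0-40 nm) and distal (360-400 nm)
#' slabs.
#'
#' @param records orientation records of one tomogram
#'   (\code{\link{filament_orientation}}).
#' @param n_frames number of frames (default 100).
#' @param frame_width frame width in nm (default 40).
#' @param span analysis depth in nm (default 400).
#' @return data frame of class \code{proportion_profile} with columns
#'   \code{frame}, \code{start}, \code{center}, \code{n},
#'   \code{f_forward}, \code{f_parallel}, \code{f_backward} (fractions NA
#'   for empty frames).
#' @export
sliding_frame_profile <- function(records, n_frames = 100, frame_width = 40,
                                  span = 400) {
  if (nrow(records) == 0L) stop("no orientation records")
  if (n_frames < 2L) stop("need at least 2 frames")
  starts <- seq(0, span - frame_width, length.out = n_frames)
  d <- records$membrane_distance
  out <- data.frame(
    frame = seq_len(n_frames), start = starts,
    center = starts + frame_width / 2
  )
  out$n <- 0L
  out$f_forward <- NA_real_
  out$f_parallel <- NA_real_
  out$f_backward <- NA_real_
  for (k in seq_len(n_frames)) {
    sel <- d >= starts[k] & d < starts[k] + frame_width
    out$n[k] <- sum(sel)
    if (out$n[k] > 0L) {
      f <- .category_fractions(records$category[sel])
      out$f_forward[k] <- f[1L]
      out$f_parallel[k] <- f[2L]
      out$f_backward[k] <- f[3L]
    }
  }
  class(out) <- c("proportion_profile", "data.frame")
  attr(out, "frame_width") <- frame_width
  attr(out, "span") <- span
  out
}

# Robust straight-line fit fraction ~ center; returns c(intercept, slope).
# IRLS with bisquare weights (MASS::rlm); ordinary least squares is used
# when the line fits exactly (zero residual scale breaks IRLS) or as a
# fallback if the IRLS fit fails to converge.
.robust_line <- function(x, y) {
  ls <- stats::lm.fit(cbind(1, x), y)
  if (sqrt(mean(ls$residuals^2)) < 1e-10) {
    return(as.numeric(ls$coefficients))
  }
  fit <- tryCatch(
    MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 100),
    error = function(e) NULL
  )
  if (is.null(fit)) as.numeric(ls$coefficients) else as.numeric(stats::coef(fit))
}

#' Robust first-frame proportion estimate
#'
#' Fits, for each orientation category, a robust straight line (iteratively
#' reweighted least squares with bisquare weights) to the fraction-versus-
#' frame-center profile, reducing the influence of outlier frames, and
#' evaluates it at the first frame center. The three estimates are clamped
#' to [0, 1] and renormalised to sum to 1; they are the tomogram's
#' coordinates for sub-domain clustering.
#'
#' @param profile a \code{\link{sliding_frame_profile}} result.
#' @param min_frames minimum number of non-empty frames for the regression
#'   (default 10); below it the estimate falls back to the mean of the
#'   first 5 non-empty frames, with a warning.
#' @return list with \code{first_frame} (named numeric, forward / parallel
#'   / backward, summing to 1), \code{coefficients} (3 x 2 matrix of
#'   intercept and slope per category, NA under the fallback) and
#'   \code{n_frames_used}.
#' @export
robust_profile_fit <- function(profile, min_frames = 10) {
  keep <- profile$n > 0L
  nf <- sum(keep)
  cats <- c("f_forward", "f_parallel", "f_backward")
  first_center <- profile$center[1L]
  co <- matrix(NA_real_, 3L, 2L,
    dimnames = list(c("forward", "parallel", "backward"), c("intercept", "slope"))
  )
  if (nf < min_frames) {
    warning("robust_profile_fit: only ", nf,
      " non-empty frames; using the mean of the first 5 non-empty frames")
    idx <- which(keep)[seq_len(min(5L, nf))]
    est <- vapply(cats, function(cn) mean(profile[[cn]][idx]), numeric(1))
  } else {
    x <- profile$center[keep]
    est <- vapply(cats, function(cn) {
      b <- .robust_line(x, profile[[cn]][keep])
      co[sub("f_", "", cn), ] <<- b
      b[1L] + b[2L] * first_center
    }, numeric(1))
  }
  est <- .clamp(est, 0, 1)
  if (sum(est) <= 0) {
    warning("robust_profile_fit: degenerate estimates; returning uniform proportions")
    est <- rep(1 / 3, 3L)
  } else {
    est <- est / sum(est)
  }
  names(est) <- c("forward", "parallel", "backward")
  list(first_frame = est, coefficients = co, n_frames_used = nf)
}

#' Classify tomograms into lamellipodial sub-domains
#'
#' k-means clustering (Euclidean, best of \code{n_restarts} random starts
#' under a fixed seed) of the per-tomogram first-frame orientation
#' proportions, into \code{k = 3} classes labelled by decreasing mean
#' forward proportion: protruding, transition, resting.
#'
#' @param coords data frame with columns \code{tomogram_id},
#'   \code{f_forward}, \code{f_parallel}, \code{f_backward} (one row per
#'   tomogram), or a plain numeric matrix with 3 columns.
#' @param k number of classes (default 3).
#' @param seed RNG seed for the k-means restarts (default 1).
#' @param n_restarts number of random starts (default 50).
#' @return object of class \code{subdomain_classification}: list with
#'   \code{assignments} (data frame: tomogram_id, proportions,
#'   \code{cluster_id} in 0..k-1 ordered by label, \code{label}),
#'   \code{centers}, \code{withinss} and the call parameters.
#' @export
classify_subdomains <- function(coords, k = 3, seed = 1, n_restarts = 50) {
  if (is.matrix(coords)) {
    coords <- data.frame(
      tomogram_id = if (is.null(rownames(coords))) {
        paste0("tomo", seq_len(nrow(coords)))
      } else {
        rownames(coords)
      },
      f_forward = coords[, 1L], f_parallel = coords[, 2L],
      f_backward = coords[, 3L], stringsAsFactors = FALSE
    )
  }
  x <- as.matrix(coords[, c("f_forward", "f_parallel", "f_backward")])
  if (nrow(x) < k) stop("need at least k = ", k, " tomograms, got ", nrow(x))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (nrow(x) == k) {
    # trivial optimum: every tomogram its own cluster (zero within-SS)
    km <- list(cluster = seq_len(k), centers = x, tot.withinss = 0)
    colnames(km$centers) <- colnames(x)
  } else {
    km <- stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 200)
  }
  # labels ordered by decreasing mean forward proportion of cluster members
  ord <- order(km$centers[, "f_forward"], decreasing = TRUE)
  labels <- c("protruding", "transition", "resting")
  if (k != 3L) labels <- paste0("class", seq_len(k))
  lab_of_cluster <- character(k)
  lab_of_cluster[ord] <- labels[seq_len(k)]
  id_of_cluster <- integer(k)
  id_of_cluster[ord] <- seq_len(k) - 1L
  assignments <- data.frame(
    tomogram_id = coords$tomogram_id,
    f_forward = x[, 1L], f_parallel = x[, 2L], f_backward = x[, 3L],
    cluster_id = id_of_cluster[km$cluster],
    label = factor(lab_of_cluster[km$cluster], levels = labels),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      assignments = assignments,
      centers = km$centers[ord, , drop = FALSE],
      withinss = km$tot.withinss,
      k = k, seed = seed, n_restarts = n_restarts
    ),
    class = "subdomain_classification"
  )
}

#' @export
print.subdomain_classification <- function(x, ...) {
  cat("Lamellipodial sub-domain classification (k-means, k =", x$k, ")\n")
  print(table(x$assignments$label))
  cat("cluster centers (first-frame proportions):\n")
  ctr <- x$centers
  rownames(ctr) <- levels(x$assignments$label)[seq_len(nrow(ctr))]
  print(round(ctr, 3))
  invisible(x)
}

#' @export
summary.subdomain_classification <- function(object, ...) {
  cat("Tomograms:", nrow(object$assignments), "\n")
  print(object)
  cat(sprintf("total within-cluster SS: %.4g\n", object$withinss))
  invisible(object)
}

#' Per-sub-domain profile summary
#'
#' The data behind per-sub-domain mean +/- SD proportion-versus-distance
#' plots: for each sub-domain label, the across-member mean and standard
#' deviation of the sliding-frame fractions, and (when orientation records
#' are supplied) pooled proximal (0-40 nm) and distal (360-400 nm)
#' orientation histograms.
#'
#' @param classification a \code{\link{classify_subdomains}} result.
#' @param profiles named list of \code{\link{sliding_frame_profile}}
#'   results, names = tomogram ids.
#' @param records optional named list of orientation-record data frames
#'   (same names) for the histograms.
#' @param hist_bin_width_deg histogram bin width (default 10).
#' @return list keyed by label; each element has \code{n_tomograms},
#'   \code{frame_centers}, \code{mean} and \code{sd} (frames x 3
#'   matrices), and optionally \code{proximal_hist}, \code{distal_hist}.
#'   Labels with no members are omitted with a warning.
#' @export
subdomain_report <- function(classification, profiles, records = NULL,
                             hist_bin_width_deg = 10) {
  asg <- classification$assignments
  out <- list()
  for (lab in levels(asg$label)) {
    ids <- asg$tomogram_id[asg$label == lab]
    if (length(ids) == 0L) {
      warning("sub-domain '", lab, "' has no members; omitted")
      next
    }
    pr <- profiles[ids]
    if (any(vapply(pr, is.null, logical(1)))) {
      stop("missing profile for tomogram(s): ",
        paste(ids[vapply(pr, is.null, logical(1))], collapse = ", "))
    }
    arr <- vapply(
      pr, function(p) as.matrix(p[, c("f_forward", "f_parallel", "f_backward")]),
      matrix(0, nrow(pr[[1L]]), 3L)
    )
    m <- apply(arr, c(1, 2), mean, na.rm = TRUE)
    s <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
    s[is.na(s)] <- 0
    colnames(m) <- colnames(s) <- c("forward", "parallel", "backward")
    el <- list(
      n_tomograms = length(ids),
      frame_centers = pr[[1L]]$center,
      mean = m, sd = s
    )
    if (!is.null(records)) {
      rec <- do.call(rbind, records[ids])
      prox <- rec$mean_angle[rec$membrane_distance >= 0 & rec$membrane_distance < 40]
      dist <- rec$mean_angle[rec$membrane_distance >= 360 & rec$membrane_distance < 400]
      if (length(prox)) el$proximal_hist <- orientation_histogram(prox, hist_bin_width_deg)
      if (length(dist)) el$distal_hist <- orientation_histogram(dist, hist_bin_width_deg)
    }
    out[[lab]] <- el
  }
  out
}
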