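#' End-to-end vector of a filament
#'
#' Traced actin filaments are short and nearly straight at the tomogram
#' scale, so the chord from the first to the last segment defines the
#' filament's overall axis, against which per-segment polarity vectors are
#' compared.
#'
#' @param positions numeric matrix (n x 3) of ordered segment coordinates, nm.
#' @return the 3-vector \code{last - first}; if the endpoints coincide
#'   (norm < 1e-9 nm) the vector is returned with attribute
#'   \code{undefined = TRUE} (polarity cannot be resolved).
#' @export
end_to_end_vector <- function(positions) {
  positions <- .as_xyz_matrix(positions, "positions")
  if (nrow(positions) < 2L) stop("need at least 2 segments")
  s <- positions[nrow(positions), ] - positions[1L, ]
  if (sqrt(sum(s * s)) < 1e-9) attr(s, "undefined") <- TRUE
  s
}

#' Per-segment polarity agreement labels
#'
#' Each segment carries a unit polarity vector pointing toward the barbed
#' end. A segment agrees with the filament's overall axis when the angle
#' between its polarity vector and the end-to-end vector is within
#' \code{cone_deg} (boundary inclusive: exactly 30 degrees counts as
#' agreement).
#'
#' @param polarity numeric matrix (n x 3) of per-segment polarity vectors.
#' @param s 3-vector, the filament end-to-end vector.
#' @param cone_deg agreement cone half-angle in degrees (default 30).
#' @return integer vector of 0/1 agreement labels.
#' @export
segment_agreement <- function(polarity, s, cone_deg = 30) {
  polarity <- .as_xyz_matrix(polarity, "polarity")
  nrm <- .row_norms(polarity)
  if (any(nrm < 1e-9)) stop("zero-length polarity vector")
  ns <- sqrt(sum(s * s))
  if (ns < 1e-9) stop("end-to-end vector undefined")
  ct <- (polarity %*% s)[, 1L] / (nrm * ns)
  # compare on the cosine side with a tiny slack so that acos round-off
  # cannot flip the inclusive boundary at exactly cone_deg
  as.integer(ct >= cos(cone_deg * pi / 180) - 1e-9)
}

#' Resolve the polarity of one filament by segment consensus
#'
#' The filament's polarity score is the mean of the per-segment agreement
#' labels; the combined confidence score is the majority fraction
#' \code{ccs = max(score, 1 - score)}, optionally multiplied by the mean
#' per-segment classification confidence when supplied. Filaments pass the
#' confidence test only when \code{ccs > ccs_threshold} (strictly). The
#' resolved direction is the end-to-end vector when the majority of
#' segments agree with it (score >= 0.5) and its negation otherwise; the
#' barbed end is the endpoint the resolved direction points toward.
#'
#' @param positions n x 3 matrix of ordered segment coordinates (nm).
#' @param polarity n x 3 matrix of per-segment polarity vectors.
#' @param cone_deg agreement cone passed to \code{\link{segment_agreement}}.
#' @param ccs_threshold confidence cut-off (default 0.6, strict).
#' @param confidence optional numeric vector of per-segment confidences in
#'   [0,1]; when given and \code{use_confidence = TRUE} the ccs is
#'   multiplied by its mean.
#' @param use_confidence logical, default FALSE.
#' @return list with elements \code{polarity_score}, \code{ccs},
#'   \code{passed_confidence}, \code{direction} (unit 3-vector, NA if
#'   undefined), \code{barbed_end} (3-vector), \code{epsilon} (labels) and
#'   \code{undefined} (logical).
#' @export
resolve_polarity <- function(positions, polarity, cone_deg = 30,
                             ccs_threshold = 0.6, confidence = NULL,
                             use_confidence = FALSE) {
  positions <- .as_xyz_matrix(positions, "positions")
  s <- end_to_end_vector(positions)
  if (isTRUE(attr(s, "undefined"))) {
    return(list(
      polarity_score = NA_real_, ccs = NA_real_, passed_confidence = FALSE,
      direction = c(NA_real_, NA_real_, NA_real_),
      barbed_end = positions[nrow(positions), ],
      epsilon = rep(NA_integer_, nrow(positions)), undefined = TRUE
    ))
  }
  eps <- segment_agreement(polarity, s, cone_deg)
  score <- mean(eps)
  ccs <- max(score, 1 - score)
  if (use_confidence && !is.null(confidence)) ccs <- ccs * mean(confidence)
  dir <- if (score >= 0.5) s else -s
  dir <- dir / sqrt(sum(dir * dir))
  barbed <- if (score >= 0.5) positions[nrow(positions), ] else positions[1L, ]
  list(
    polarity_score = score, ccs = ccs,
    passed_confidence = ccs > ccs_threshold,
    direction = dir, barbed_end = barbed, epsilon = eps, undefined = FALSE
  )
}

#' Per-filament polarity table
#'
#' Applies \code{\link{resolve_polarity}} to every filament of a (typically
#' fragmented) segment table and returns one row per filament with its
#' end-to-end vector, polarity score, combined confidence score,
#' confidence-test outcome, resolved unit direction, barbed-end coordinate
#' and contour length. Filaments flagged \code{too_short} (or with fewer
#' than 2 segments) are skipped with a warning; filaments with coincident
#' endpoints are retained with \code{undefined_polarity = TRUE} and
#' \code{passed_confidence = FALSE}.
#'
#' @param segments segment table (see \code{\link{fragment_filaments}})
#'   with polarity columns \code{px}, \code{py}, \code{pz} and optionally
#'   \code{confidence}.
#' @inheritParams resolve_polarity
#' @return data frame with columns \code{tomogram_id}, \code{filament_id},
#'   \code{n_segments}, \code{s_x,s_y,s_z}, \code{polarity_score},
#'   \code{ccs}, \code{passed_confidence}, \code{dir_x,dir_y,dir_z},
#'   \code{barbed_x,barbed_y,barbed_z}, \code{contour_length_nm},
#'   \code{undefined_polarity}.
#' @export
filament_polarity <- function(segments, cone_deg = 30, ccs_threshold = 0.6,
                              use_confidence = FALSE) {
  req <- c(
    "tomogram_id", "filament_id", "segment_index",
    "x_nm", "y_nm", "z_nm", "px", "py", "pz"
  )
  miss <- setdiff(req, names(segments))
  if (length(miss)) stop("segment table missing columns: ", paste(miss, collapse = ", "))
  o <- order(segments$tomogram_id, segments$filament_id, segments$segment_index)
  segments <- segments[o, , drop = FALSE]
  key <- .filament_key(segments)
  groups <- split(seq_len(nrow(segments)), factor(key, levels = unique(key)))

  n_short <- 0L
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (length(g) < 2L ||
      ("too_short" %in% names(segments) && isTRUE(segments$too_short[g[1L]]))) {
      n_short <- n_short + 1L
      next
    }
    pos <- as.matrix(segments[g, c("x_nm", "y_nm", "z_nm")])
    pol <- as.matrix(segments[g, c("px", "py", "pz")])
    conf <- if ("confidence" %in% names(segments)) segments$confidence[g] else NULL
    r <- resolve_polarity(pos, pol, cone_deg, ccs_threshold, conf, use_confidence)
    steps <- diff(pos)
    rows[[i]] <- data.frame(
      tomogram_id = segments$tomogram_id[g[1L]],
      filament_id = segments$filament_id[g[1L]],
      n_segments = length(g),
      s_x = pos[length(g), 1] - pos[1, 1],
      s_y = pos[length(g), 2] - pos[1, 2],
      s_z = pos[length(g), 3] - pos[1, 3],
      polarity_score = r$polarity_score,
      ccs = r$ccs,
      passed_confidence = r$passed_confidence,
      dir_x = r$direction[1], dir_y = r$direction[2], dir_z = r$direction[3],
      barbed_x = r$barbed_end[1], barbed_y = r$barbed_end[2],
      barbed_z = r$barbed_end[3],
      contour_length_nm = sum(.row_norms(steps)),
      undefined_polarity = r$undefined,
      stringsAsFactors = FALSE
    )
  }
  if (n_short > 0L) {
    warning(n_short, " filament(s) with < 2 segments skipped from polarity analysis")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    stop("no filament with >= 2 segments in input")
  }
  rownames(out) <- NULL
  out
}
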