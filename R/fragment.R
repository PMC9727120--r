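#' Fragment traced filaments at sharp direction changes
#'
#' Dendritic actin filaments are branched and capped, so a single traced
#' polyline can run through a branch joint and mix two physical filaments.
#' This walks each polyline's consecutive step vectors and truncates it
#' wherever the direction change between successive steps reaches
#' \code{angle_limit_deg}: the segment before the offending step ends the
#' current fragment and the next segment starts a new one, so the output
#' fragments partition the input segments. No direction test is possible
#' until a fragment has three coordinates, so scanning (re)starts at each
#' fragment's third segment.
#'
#' @param segments data frame of filament segments with columns
#'   \code{tomogram_id}, \code{filament_id}, \code{segment_index},
#'   \code{x_nm}, \code{y_nm}, \code{z_nm} (and any others, carried through).
#' @param angle_limit_deg truncation threshold in degrees (default 90); the
#'   fragment is cut when the step-to-step angle is \code{>=} this value.
#'   At 180 no cut is ever made.
#' @return the segment table with \code{filament_id} replaced by fragment
#'   ids (\code{"<original>.<k>"}) and the original id kept in
#'   \code{source_filament_id}. Fragments left with fewer than 2 segments
#'   are flagged in the logical column \code{too_short}; they are retained
#'   in the table but must be excluded from polarity analysis (as
#'   \code{\link{filament_polarity}} does). The number of cuts and short
#'   fragments is reported via \code{message()}.
#' @examples
#' seg <- data.frame(
#'   tomogram_id = "t1", filament_id = "f1", segment_index = 1:4,
#'   x_nm = c(0, 11, 22, 11), y_nm = 0, z_nm = c(0, 0, 0, 1),
#'   px = 1, py = 0, pz = 0
#' )
#' frag <- fragment_filaments(seg)
#' table(frag$filament_id)
#' @export
fragment_filaments <- function(segments, angle_limit_deg = 90) {
  stopifnot(is.data.frame(segments))
  req <- c("tomogram_id", "filament_id", "segment_index", "x_nm", "y_nm", "z_nm")
  miss <- setdiff(req, names(segments))
  if (length(miss)) stop("segment table missing columns: ", paste(miss, collapse = ", "))
  pos <- as.matrix(segments[, c("x_nm", "y_nm", "z_nm")])
  if (anyNA(pos) || any(!is.finite(pos))) {
    stop("segment table contains NA/non-finite coordinates")
  }

  o <- order(segments$tomogram_id, segments$filament_id, segments$segment_index)
  segments <- segments[o, , drop = FALSE]
  key <- .filament_key(segments)
  groups <- split(seq_len(nrow(segments)), factor(key, levels = unique(key)))

  frag_id <- character(nrow(segments))
  n_cuts <- 0L
  n_single_in <- 0L
  for (g in groups) {
    fid <- segments$filament_id[g[1L]]
    n <- length(g)
    if (n < 2L) {
      n_single_in <- n_single_in + 1L
      frag_id[g] <- paste0(fid, ".1")
      next
    }
    p <- as.matrix(segments[g, c("x_nm", "y_nm", "z_nm")])
    steps <- diff(p)                     # step k = C[k+1] - C[k]
    frag <- integer(n)
    cur <- 1L
    frag[1L] <- cur
    frag_start <- 1L
    for (k in seq_len(n - 1L)) {
      # step k extends the fragment with segment k+1; testable only if the
      # previous step lies fully inside the current fragment
      if (k - 1L >= frag_start) {
        ang <- .angle_deg(steps[k, ], steps[k - 1L, ])
        if (ang >= angle_limit_deg - 1e-9) {
          cur <- cur + 1L
          frag_start <- k + 1L
          n_cuts <- n_cuts + 1L
        }
      }
      frag[k + 1L] <- cur
    }
    frag_id[g] <- paste0(fid, ".", frag)
  }

  out <- segments
  out$source_filament_id <- out$filament_id
  out$filament_id <- frag_id
  sizes <- table(.filament_key(out))
  out$too_short <- sizes[.filament_key(out)] < 2L
  n_short <- sum(sizes < 2L)
  if (n_single_in > 0L) {
    warning(n_single_in, " input filament(s) with < 2 segments; skipped from polarity analysis")
  }
  message(
    "fragment_filaments: ", length(groups), " polylines in, ",
    length(sizes), " fragments out (", n_cuts, " cuts, ",
    n_short, " fragments < 2 segments flagged)"
  )
  out
}
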