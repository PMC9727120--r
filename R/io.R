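# Readers for the pipeline's canonical plain-text tables. TSV with a
# header row is the canonical dialect; comma-separated files are accepted
# (the delimiter is sniffed from the header line). Coordinates are
# nanometres throughout; conversions belong at this boundary.

.read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  utils::read.table(path,
    header = TRUE, sep = sep, quote = "\"",
    stringsAsFactors = FALSE, check.names = TRUE
  )
}

#' Read a filament segment table
#'
#' Expects header columns \code{tomogram_id, filament_id, segment_index,
#' x_nm, y_nm, z_nm, px, py, pz} and optionally \code{confidence}.
#'
#' @param path TSV or CSV file path.
#' @return data frame of segment records.
#' @export
read_segments <- function(path) {
  df <- .read_table_auto(path)
  req <- c(
    "tomogram_id", "filament_id", "segment_index",
    "x_nm", "y_nm", "z_nm", "px", "py", "pz"
  )
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(path, ": missing columns ", paste(miss, collapse = ", "))
  df
}

#' Read a membrane point cloud table
#'
#' Expects \code{tomogram_id, x_nm, y_nm, z_nm}; optional precomputed
#' normals \code{nx, ny, nz} are carried through (they are re-smoothed and
#' re-oriented by \code{\link{membrane_model}}).
#'
#' @param path TSV or CSV file path.
#' @return data frame of membrane points.
#' @export
read_membrane_points <- function(path) {
  df <- .read_table_auto(path)
  req <- c("tomogram_id", "x_nm", "y_nm", "z_nm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(path, ": missing columns ", paste(miss, collapse = ", "))
  df
}

#' Read an Arp2/3 branch table
#'
#' Expects \code{tomogram_id, mother_filament_id, daughter_filament_id,
#' branch_x, branch_y, branch_z} and optionally \code{branch_angle}.
#'
#' @param path TSV or CSV file path.
#' @return data frame of branch records.
#' @export
read_branches <- function(path) {
  df <- .read_table_auto(path)
  req <- c("tomogram_id", "mother_filament_id", "daughter_filament_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(path, ": missing columns ", paste(miss, collapse = ", "))
  df
}

#' Validate pipeline input tables
#'
#' Schema and plausibility checks on in-memory tables: required columns,
#' finite coordinates, polarity vector norms, duplicate segment indices
#' within a filament, and a unit heuristic (coordinates whose overall
#' magnitude looks like micrometres rather than nanometres). Violations
#' are returned, not raised.
#'
#' @param segments optional segment table.
#' @param membrane optional membrane point table.
#' @param branches optional branch table.
#' @return data frame report with columns \code{table}, \code{row},
#'   \code{column}, \code{message}; zero rows when everything passes.
#' @export
validate_inputs <- function(segments = NULL, membrane = NULL, branches = NULL) {
  rep <- list()
  add <- function(tab, row, col, msg) {
    rep[[length(rep) + 1L]] <<- data.frame(
      table = tab, row = row, column = col, message = msg,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(segments)) {
    req <- c(
      "tomogram_id", "filament_id", "segment_index",
      "x_nm", "y_nm", "z_nm", "px", "py", "pz"
    )
    for (cn in setdiff(req, names(segments))) {
      add("segments", NA_integer_, cn, "missing required column")
    }
    if (all(req %in% names(segments)) && nrow(segments) > 0L) {
      xyz <- as.matrix(segments[, c("x_nm", "y_nm", "z_nm")])
      bad <- which(!is.finite(rowSums(xyz)))
      for (r in bad) add("segments", r, "x_nm/y_nm/z_nm", "non-finite coordinate")
      nrm <- .row_norms(as.matrix(segments[, c("px", "py", "pz")]))
      bad <- which(!is.finite(nrm) | nrm <= 0.5 | nrm >= 2)
      for (r in bad) {
        add("segments", r, "px/py/pz",
          sprintf("polarity vector norm %.3g outside (0.5, 2)", nrm[r]))
      }
      key <- paste(segments$tomogram_id, segments$filament_id, segments$segment_index)
      dup <- which(duplicated(key))
      for (r in dup) add("segments", r, "segment_index", "duplicate segment index within filament")
      if (max(abs(xyz), na.rm = TRUE) < 10) {
        add("segments", NA_integer_, "x_nm/y_nm/z_nm",
          "coordinates all below 10: micrometre units suspected (expected nanometres)")
      }
    }
  }
  if (!is.null(membrane)) {
    req <- c("tomogram_id", "x_nm", "y_nm", "z_nm")
    for (cn in setdiff(req, names(membrane))) {
      add("membrane", NA_integer_, cn, "missing required column")
    }
    if (all(req %in% names(membrane)) && nrow(membrane) > 0L) {
      xyz <- as.matrix(membrane[, c("x_nm", "y_nm", "z_nm")])
      bad <- which(!is.finite(rowSums(xyz)))
      for (r in bad) add("membrane", r, "x_nm/y_nm/z_nm", "non-finite coordinate")
    }
  }
  if (!is.null(branches)) {
    req <- c("tomogram_id", "mother_filament_id", "daughter_filament_id")
    for (cn in setdiff(req, names(branches))) {
      add("branches", NA_integer_, cn, "missing required column")
    }
    if ("branch_angle" %in% names(branches) && nrow(branches) > 0L) {
      bad <- which(!(branches$branch_angle > 0 & branches$branch_angle < 180))
      for (r in bad) add("branches", r, "branch_angle", "branch angle outside (0, 180)")
    }
  }
  if (length(rep) == 0L) {
    return(data.frame(
      table = character(), row = integer(), column = character(),
      message = character(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rep)
}
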