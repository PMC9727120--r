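#' Pipeline parameters
#'
#' One place for every stage constant; the defaults are the analysis
#' constants of the method: 90 degree fragmentation limit, 30 degree
#' polarity agreement cone, 0.6 ccs cut-off, 40 nm membrane plane-fit
#' radius, 80/100 degree category bounds, 40 nm distance slabs over a
#' 400 nm belt, 100 sliding frames, and k = 3 sub-domain classes.
#'
#' @param angle_limit_deg fragmentation threshold (degrees).
#' @param cone_deg polarity agreement cone (degrees).
#' @param ccs_threshold combined confidence score cut-off (strict).
#' @param fit_radius membrane plane-fit / smoothing radius (nm).
#' @param bin_width distance slab width (nm).
#' @param max_distance analysis depth (nm).
#' @param n_frames sliding frames for the proportion profile.
#' @param k sub-domain classes.
#' @param seed k-means seed.
#' @param n_restarts k-means restarts.
#' @param use_confidence multiply ccs by mean per-segment confidence when
#'   a confidence column is present.
#' @return list of class \code{pipeline_params}.
#' @export
pipeline_params <- function(angle_limit_deg = 90, cone_deg = 30,
                            ccs_threshold = 0.6, fit_radius = 40,
                            bin_width = 40, max_distance = 400,
                            n_frames = 100, k = 3, seed = 1,
                            n_restarts = 50, use_confidence = FALSE) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Analyse one tomogram
#'
#' The single-tomogram pipeline: fragment the traced polylines at sharp
#' joints, resolve per-filament polarity by segment consensus and apply
#' the confidence filter, build the membrane model (smoothed outward
#' normals), measure filament-membrane orientation, and assemble the
#' distance-resolved orientation profile and the sliding-frame proportion
#' profile with its robust first-frame estimate.
#'
#' @param segments segment table (see \code{\link{read_segments}}).
#' @param membrane_points membrane point table or n x 3 matrix.
#' @param interior_ref optional 3-vector on the cytoplasmic side; default
#'   is the centroid of the passed-confidence filament segments.
#' @param params a \code{\link{pipeline_params}} list.
#' @return object of class \code{tomogram_analysis}: list with
#'   \code{segments} (fragmented), \code{filaments}, \code{membrane},
#'   \code{orientation}, \code{profile} (\code{\link{distance_profile}}),
#'   \code{frame_profile} (\code{\link{sliding_frame_profile}}),
#'   \code{first_frame} (robust estimate), \code{counts} (stage log),
#'   \code{params}.
#' @export
analyze_tomogram <- function(segments, membrane_points, interior_ref = NULL,
                             params = pipeline_params()) {
  if (is.null(segments) || nrow(segments) == 0L) stop("empty segment table")
  tomo <- segments$tomogram_id[1L]
  frag <- fragment_filaments(segments, params$angle_limit_deg)
  fil <- filament_polarity(frag,
    cone_deg = params$cone_deg,
    ccs_threshold = params$ccs_threshold,
    use_confidence = params$use_confidence
  )
  passed <- fil[fil$passed_confidence, , drop = FALSE]
  if (is.null(interior_ref)) {
    keep <- .filament_key(frag) %in% .filament_key(passed)
    interior_ref <- colMeans(frag[keep, c("x_nm", "y_nm", "z_nm")])
  }
  mem <- membrane_model(membrane_points, interior_ref,
    fit_radius = params$fit_radius, tomogram_id = tomo
  )
  orient <- filament_orientation(fil, frag, mem)
  prof <- distance_profile(orient, params$bin_width, params$max_distance)
  fprof <- sliding_frame_profile(orient,
    n_frames = params$n_frames,
    frame_width = params$bin_width, span = params$max_distance
  )
  ffit <- robust_profile_fit(fprof)
  structure(
    list(
      tomogram_id = tomo,
      segments = frag, filaments = fil, membrane = mem,
      orientation = orient, profile = prof,
      frame_profile = fprof, first_frame = ffit,
      counts = c(
        segments_in = nrow(segments),
        filaments_traced = length(unique(segments$filament_id)),
        fragments = nrow(fil),
        passed_confidence = nrow(passed),
        oriented = nrow(orient),
        within_belt = sum(orient$membrane_distance < params$max_distance)
      ),
      params = params
    ),
    class = "tomogram_analysis"
  )
}

#' @export
print.tomogram_analysis <- function(x, ...) {
  cat("Tomogram analysis:", x$tomogram_id, "\n")
  cat(sprintf(
    "  %d segments -> %d fragments, %d passed the polarity confidence test (ccs > %.2g)\n",
    x$counts[["segments_in"]], x$counts[["fragments"]],
    x$counts[["passed_confidence"]], x$params$ccs_threshold
  ))
  f <- .category_fractions(x$orientation$category)
  cat(sprintf(
    "  orientation mixture (all %d filaments): %.1f%% forward / %.1f%% parallel / %.1f%% backward\n",
    nrow(x$orientation), 100 * f[1], 100 * f[2], 100 * f[3]
  ))
  ff <- x$first_frame$first_frame
  cat(sprintf(
    "  robust first-frame estimate: %.1f%% / %.1f%% / %.1f%%\n",
    100 * ff[1], 100 * ff[2], 100 * ff[3]
  ))
  invisible(x)
}

#' @export
summary.tomogram_analysis <- function(object, ...) {
  print(object)
  cat("\ndistance profile (40 nm slabs):\n")
  print(transform(object$profile,
    f_forward = round(f_forward, 3),
    f_parallel = round(f_parallel, 3),
    f_backward = round(f_backward, 3)
  ))
  invisible(object)
}

#' @export
plot.tomogram_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  h <- orientation_histogram(x$orientation$mean_angle)
  graphics::barplot(h$p,
    names.arg = paste0(h$bin_lo, "-", h$bin_hi), las = 2,
    xlab = "filament-membrane angle (deg)", ylab = "probability",
    main = x$tomogram_id, col = "grey70", border = NA
  )
  pf <- x$frame_profile
  graphics::matplot(pf$center, pf[, c("f_forward", "f_parallel", "f_backward")],
    type = "l", lty = 1, lwd = 2,
    col = c("steelblue3", "goldenrod2", "firebrick3"),
    xlab = "distance from membrane (nm)", ylab = "fraction",
    ylim = c(0, 1), main = "orientation proportions"
  )
  graphics::legend("topright",
    legend = c("forward", "parallel", "backward"),
    col = c("steelblue3", "goldenrod2", "firebrick3"), lty = 1, lwd = 2, bty = "n"
  )
  invisible(x)
}

#' Run the full multi-tomogram pipeline
#'
#' Reads (or accepts in-memory) segment / membrane / branch tables,
#' validates them, analyses every tomogram, classifies sub-domains when at
#' least \code{k} tomograms are present, and optionally writes the stage
#' outputs (filament, orientation, profile and assignment tables plus a
#' JSON summary) to a directory. Reruns with the same inputs and
#' parameters produce byte-identical outputs.
#'
#' @param segments segment table or file path.
#' @param membrane membrane point table or file path.
#' @param branches optional branch table or file path.
#' @param params a \code{\link{pipeline_params}} list.
#' @param interior_ref optional named list of per-tomogram interior
#'   reference points.
#' @param output_dir optional directory for the result files.
#' @param analysis_volume_um3 optional analysed volume per tomogram for
#'   Arp2/3 statistics.
#' @return list of class \code{pipeline_result}: \code{analyses} (named
#'   list of \code{\link{analyze_tomogram}} results), \code{assignments}
#'   (\code{\link{classify_subdomains}} result or NULL), \code{arp}
#'   (named list of \code{\link{arp_statistics}} or NULL), \code{report}
#'   (validation report).
#' @export
run_pipeline <- function(segments, membrane, branches = NULL,
                         params = pipeline_params(), interior_ref = NULL,
                         output_dir = NULL, analysis_volume_um3 = NULL) {
  if (is.character(segments)) segments <- read_segments(segments)
  if (is.character(membrane)) membrane <- read_membrane_points(membrane)
  if (is.character(branches)) branches <- read_branches(branches)
  if (is.null(segments) || nrow(segments) == 0L) stop("empty segment table")
  report <- validate_inputs(segments, membrane, branches)
  fatal <- report[grepl("missing required column|non-finite", report$message), ]
  if (nrow(fatal) > 0L) {
    stop(
      "input validation failed:\n",
      paste(sprintf(
        "  [%s row %s col %s] %s",
        fatal$table, fatal$row, fatal$column, fatal$message
      ), collapse = "\n")
    )
  }
  tomos <- unique(segments$tomogram_id)
  analyses <- list()
  for (t in tomos) {
    seg_t <- segments[segments$tomogram_id == t, , drop = FALSE]
    mem_t <- membrane[membrane$tomogram_id == t, , drop = FALSE]
    if (nrow(mem_t) == 0L) stop("no membrane points for tomogram ", t)
    ir <- if (!is.null(interior_ref)) interior_ref[[t]] else NULL
    analyses[[t]] <- analyze_tomogram(seg_t, mem_t, ir, params)
    message(
      "run_pipeline [", t, "]: ",
      paste(names(analyses[[t]]$counts), analyses[[t]]$counts,
        sep = "=", collapse = " "
      )
    )
  }
  assignments <- NULL
  if (length(tomos) >= params$k) {
    coords <- do.call(rbind, lapply(tomos, function(t) {
      ff <- analyses[[t]]$first_frame$first_frame
      data.frame(
        tomogram_id = t, f_forward = ff[1], f_parallel = ff[2],
        f_backward = ff[3], stringsAsFactors = FALSE
      )
    }))
    assignments <- classify_subdomains(coords,
      k = params$k,
      seed = params$seed, n_restarts = params$n_restarts
    )
  }
  arp <- NULL
  if (!is.null(branches) && !is.null(analysis_volume_um3)) {
    arp <- lapply(tomos, function(t) {
      arp_statistics(
        branches[branches$tomogram_id == t, , drop = FALSE],
        analyses[[t]]$filaments, analysis_volume_um3
      )
    })
    names(arp) <- tomos
  }
  res <- structure(
    list(
      analyses = analyses, assignments = assignments,
      arp = arp, report = report, params = params
    ),
    class = "pipeline_result"
  )
  if (!is.null(output_dir)) .write_pipeline_outputs(res, output_dir)
  res
}

.write_pipeline_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fil <- do.call(rbind, lapply(res$analyses, `[[`, "filaments"))
  ori <- do.call(rbind, lapply(res$analyses, function(a) {
    d <- a$orientation
    d$category <- as.character(d$category)
    d
  }))
  rownames(fil) <- rownames(ori) <- NULL
  .write_tsv(fil, file.path(dir, "filaments.tsv"))
  .write_tsv(ori, file.path(dir, "orientation.tsv"))
  prof <- do.call(rbind, lapply(names(res$analyses), function(t) {
    cbind(tomogram_id = t, res$analyses[[t]]$profile, stringsAsFactors = FALSE)
  }))
  .write_tsv(prof, file.path(dir, "distance_profiles.tsv"))
  if (!is.null(res$assignments)) {
    asg <- res$assignments$assignments
    asg$label <- as.character(asg$label)
    .write_tsv(asg, file.path(dir, "subdomain_assignments.tsv"))
  }
  summ <- list(
    n_tomograms = length(res$analyses),
    counts = lapply(res$analyses, function(a) as.list(a$counts)),
    first_frame = lapply(res$analyses, function(a) as.list(a$first_frame$first_frame)),
    subdomains = if (!is.null(res$assignments)) {
      as.list(table(res$assignments$assignments$label))
    },
    arp = if (!is.null(res$arp)) lapply(res$arp, unclass),
    params = unclass(res$params)
  )
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", length(x$analyses), "tomogram(s)\n")
  for (a in x$analyses) {
    cat(sprintf(
      "  %s: %d filaments passed, %s\n", a$tomogram_id,
      a$counts[["passed_confidence"]],
      paste(sprintf("%.0f%%", 100 * .category_fractions(a$orientation$category)),
        collapse = "/"
      )
    ))
  }
  if (!is.null(x$assignments)) print(x$assignments)
  invisible(x)
}
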