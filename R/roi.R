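# Region-of-interest association: distances from somata to anatomical
# contour polylines, proximal/distal labelling, and count tables.

#' Define a region of interest by proximity to contoured structures
#'
#' A neuron is proximal to the ROI when it lies within `radius` of the named
#' structures' contours — of any one of them (`mode = "any"`, the union
#' rule, used for vessel roots and hila) or of every one of them
#' (`mode = "all"`, the junction rule, used for sulci, which are junctions
#' between two structures and have no contour of their own).
#'
#' @param name ROI name (see [roi_names()]).
#' @param structures non-empty character vector of structure names.
#' @param radius proximity threshold, um, > 0.
#' @param mode `"any"` or `"all"`.
#' @return A list of class `icns_roi`.
#' @export
roi_definition <- function(name, structures, radius = 500,
                           mode = c("any", "all")) {
  if (!length(structures)) abort_arg("ROI '%s' needs >= 1 structure", name)
  check_scalar_number(radius, "radius", positive = TRUE)
  structure(list(name = name, structures = as.character(structures),
                 radius = radius, mode = match.arg(mode)),
            class = "icns_roi")
}

#' Default definitions of the five regions of interest
#'
#' The pulmonary-vein hilum is the union of the three pulmonary veins; the
#' SVC-RA root the union of superior vena cava and right atrium; the left
#' atrioventricular sulcus the junction of left atrium and ventricles; the
#' anterior interatrial sulcus the junction of the two atria; the posterior
#' left atrium the left-atrial contour itself. The default 500 um radius is
#' roughly one atrial-wall thickness at rat scale and is configurable.
#'
#' @param radius proximity threshold applied to every ROI, um.
#' @return Named list of [roi_definition()]s.
#' @export
default_rois <- function(radius = 500) {
  defs <- list(
    roi_definition("pv_hilum",
                   c("pulmonary_vein_left", "pulmonary_vein_middle",
                     "pulmonary_vein_right"), radius, "any"),
    roi_definition("svc_ra_root",
                   c("superior_vena_cava", "right_atrium"), radius, "any"),
    roi_definition("left_av_sulcus",
                   c("left_atrium", "ventricles"), radius, "all"),
    roi_definition("anterior_interatrial_sulcus",
                   c("left_atrium", "right_atrium"), radius, "all"),
    roi_definition("posterior_left_atrium", "left_atrium", radius, "any"))
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

#' Read ROI definitions from YAML
#' @param path YAML file: a list of entries with `name`, `structures`,
#'   optional `radius` and `mode`.
#' @return Named list of [roi_definition()]s.
#' @export
read_rois_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  defs <- lapply(y, function(e)
    roi_definition(e$name, unlist(e$structures),
                   radius = e$radius %||% 500, mode = e$mode %||% "any"))
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimum distance from each row of `points` to any segment of the given
# contours (closed contours wrap around). Segment blocks are chunked to
# bound memory at large marker counts.
min_dist_to_contours <- function(points, contours) {
  points <- check_points3(points)
  segs_a <- list(); segs_b <- list()
  for (ct in contours) {
    P <- ct$points
    if (ct$closed) P <- rbind(P, P[1, , drop = FALSE])
    if (nrow(P) < 2L) next
    segs_a[[length(segs_a) + 1L]] <- P[-nrow(P), , drop = FALSE]
    segs_b[[length(segs_b) + 1L]] <- P[-1L, , drop = FALSE]
  }
  if (!length(segs_a)) abort_arg("structure has no usable contour segments")
  A <- do.call(rbind, segs_a); B <- do.call(rbind, segs_b)
  n <- nrow(points)
  best <- rep(Inf, n)
  chunk <- max(1L, floor(4e6 / n))
  for (s in seq(1L, nrow(A), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(A))
    a <- A[idx, , drop = FALSE]
    ab <- B[idx, , drop = FALSE] - a
    len2 <- pmax(rowSums(ab^2), 1e-30)
    # t(i,j): projection parameter of point i on segment j, clamped to [0,1]
    tt <- (points %*% t(ab) - rep(1, n) %*% t(rowSums(a * ab))) /
      (rep(1, n) %*% t(len2))
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    d2 <- matrix(0, n, length(idx))
    for (c3 in 1:3) {
      foot <- rep(1, n) %*% t(a[, c3]) + tt * (rep(1, n) %*% t(ab[, c3]))
      d2 <- d2 + (foot - points[, c3])^2
    }
    best <- pmin(best, sqrt(apply(d2, 1L, min)))
  }
  best
}

#' Distance from a point (or points) to a contoured structure
#'
#' Minimum 3D Euclidean point-to-segment distance over all polyline
#' segments of all of the structure's contours in the subject.
#'
#' @param point a 3-vector or n x 3 matrix, um.
#' @param subject an `icns_subject`.
#' @param structure_name a structure name present in the subject's contours.
#' @return Numeric distances, um.
#' @export
distance_to_structure <- function(point, subject, structure_name) {
  if (is.null(dim(point))) point <- matrix(point, 1L)
  cts <- Filter(function(ct) ct$structure_name == structure_name,
                subject$contours)
  if (!length(cts))
    abort_arg("subject '%s' has no contours for structure '%s'",
              subject$subject_id, structure_name)
  min_dist_to_contours(point, cts)
}

#' Label markers proximal or distal to one ROI
#'
#' @param subject an `icns_subject` whose contours include every structure
#'   the ROI references.
#' @param roi an [roi_definition()].
#' @return Logical vector, `TRUE` = proximal, one entry per marker.
#' @export
assign_proximity <- function(subject, roi) {
  stopifnot(inherits(roi, "icns_roi"))
  present <- unique(vapply(subject$contours, `[[`, "", "structure_name"))
  missing <- setdiff(roi$structures, present)
  if (length(missing))
    abort_arg("subject '%s' lacks contours for structure(s): %s",
              subject$subject_id, paste(missing, collapse = ", "))
  pts <- marker_xyz(subject$markers)
  if (!nrow(pts)) return(logical(0))
  per <- vapply(roi$structures, function(sn)
    distance_to_structure(pts, subject, sn) <= roi$radius, logical(nrow(pts)))
  per <- matrix(per, nrow = nrow(pts))
  if (roi$mode == "any") rowSums(per) > 0 else rowSums(per) == length(roi$structures)
}

#' Assign all ROIs to a subject's markers
#'
#' Runs [assign_proximity()] for each ROI and stores the proximal ROI names
#' (`;`-separated) in the markers' `rois` column.
#'
#' @param subject an `icns_subject`.
#' @param rois named list of [roi_definition()]s.
#' @return The subject with `markers$rois` filled in.
#' @export
assign_all_rois <- function(subject, rois = default_rois()) {
  if (!nrow(subject$markers)) return(subject)
  mat <- vapply(rois, function(r) assign_proximity(subject, r),
                logical(nrow(subject$markers)))
  mat <- matrix(mat, nrow = nrow(subject$markers),
                dimnames = list(NULL, names(rois)))
  subject$markers$rois <- apply(mat, 1L, function(row)
    if (any(row)) paste(names(rois)[row], collapse = ";") else NA_character_)
  subject
}

#' Tabulate neuron counts per subject and ROI
#'
#' Counts proximal neurons per subject x ROI together with the fraction of
#' the subject total. Overlapping ROIs mean fractions need not sum to one;
#' the union count over all ROIs (`any_roi`) is also reported and is always
#' at most the subject total. If cluster labels are present, each cluster's
#' majority ROI (the ROI proximal to > 50% of its members, if any) is
#' tabulated as well.
#'
#' @param subjects list of `icns_subject`s.
#' @param rois named list of [roi_definition()]s.
#' @return List of class `icns_roi_table`: `counts` (data.frame subject x
#'   ROI with count and fraction columns), `cluster_roi` (data.frame of
#'   per-cluster majority ROIs, possibly empty).
#' @export
roi_counts <- function(subjects, rois = default_rois()) {
  rows <- list(); crows <- list()
  for (s in subjects) {
    n <- nrow(s$markers)
    if (n) {
      mat <- vapply(rois, function(r) assign_proximity(s, r), logical(n))
      mat <- matrix(mat, nrow = n, dimnames = list(NULL, names(rois)))
    } else {
      mat <- matrix(logical(0), 0, length(rois),
                    dimnames = list(NULL, names(rois)))
    }
    rec <- data.frame(subject = s$subject_id, sex = s$sex, total = n)
    for (rn in names(rois)) {
      rec[[paste0(rn, "_count")]] <- sum(mat[, rn])
      rec[[paste0(rn, "_fraction")]] <- if (n) sum(mat[, rn]) / n else 0
    }
    rec$any_roi <- if (n) sum(rowSums(mat) > 0) else 0L
    rows[[length(rows) + 1L]] <- rec
    labs <- s$markers$cluster
    if (n && any(!is.na(labs))) {
      for (cl in sort(unique(labs[!is.na(labs)]))) {
        sub <- mat[labs %in% cl, , drop = FALSE]
        fr <- colSums(sub) / nrow(sub)
        crows[[length(crows) + 1L]] <- data.frame(
          subject = s$subject_id, cluster = cl, size = nrow(sub),
          majority_roi = if (any(fr > 0.5)) names(rois)[which.max(fr)]
                         else NA_character_,
          majority_fraction = max(fr))
      }
    }
  }
  structure(list(counts = do.call(rbind, rows),
                 cluster_roi = if (length(crows)) do.call(rbind, crows)
                               else data.frame()),
            class = "icns_roi_table")
}

#' @export
print.icns_roi_table <- function(x, ...) {
  cat("ROI neuron counts per subject:\n")
  print(x$counts, row.names = FALSE)
  if (nrow(x$cluster_roi)) {
    cat("Per-cluster majority ROI:\n")
    print(x$cluster_roi, row.names = FALSE)
  }
  invisible(x)
}
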