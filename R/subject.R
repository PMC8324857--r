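# Domain containers: markers, contours, subject maps.
#
# Markers are held as a data.frame (one row per soma) because every
# downstream stage consumes them columnwise; contours are a list of small
# lists because polylines are ragged.

#' Controlled vocabulary of anatomical structure names
#'
#' Structure names accepted without a warning flag by [read_subject()] and
#' used by the synthetic generator and ROI definitions.
#'
#' @return Character vector of structure names.
#' @export
structure_vocabulary <- function() {
  c("left_atrium", "right_atrium", "left_auricle", "right_auricle",
    "ventricles", "aorta", "pulmonary_trunk", "pulmonary_artery_left",
    "pulmonary_artery_right", "pulmonary_vein_left", "pulmonary_vein_middle",
    "pulmonary_vein_right", "superior_vena_cava", "inferior_vena_cava",
    "coronary_sinus", "coronary_artery")
}

#' ROI names used throughout the pipeline
#' @return Character vector of the five region-of-interest names.
#' @export
roi_names <- function() {
  c("posterior_left_atrium", "pv_hilum", "svc_ra_root", "left_av_sulcus",
    "anterior_interatrial_sulcus")
}

#' Construct a neuron-marker table
#'
#' One row per mapped soma. Coordinates are in micrometres; `section` is the
#' 0-based serial-section index; soma axes may be `NA` for records whose size
#' criterion was applied at annotation time.
#'
#' @param id character ids, unique within a subject.
#' @param x,y,z numeric coordinates, um.
#' @param section integer section indices (0-based); `NA` allowed.
#' @param soma_short,soma_long soma axis lengths, um; `NA` allowed.
#' @param cluster optional integer cluster labels.
#' @param rois optional character, `;`-separated ROI names per marker.
#' @return A `data.frame` with class `icns_markers`.
#' @export
neuron_markers <- function(id, x, y, z, section = NA_integer_,
                           soma_short = NA_real_, soma_long = NA_real_,
                           cluster = NA_integer_, rois = NA_character_) {
  n <- length(x)
  df <- data.frame(
    id = as.character(id), x = as.numeric(x), y = as.numeric(y),
    z = as.numeric(z),
    section = rep_len(as.integer(section), n),
    soma_short = rep_len(as.numeric(soma_short), n),
    soma_long = rep_len(as.numeric(soma_long), n),
    cluster = rep_len(as.integer(cluster), n),
    rois = rep_len(as.character(rois), n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("icns_markers", "data.frame")
  df
}

marker_xyz <- function(markers) {
  as.matrix(markers[, c("x", "y", "z"), drop = FALSE])
}

#' Construct one anatomical contour trace
#'
#' @param structure_name structure name (see [structure_vocabulary()];
#'   unknown names are kept verbatim with `known = FALSE`).
#' @param points n x 3 numeric matrix, um; all points share one z.
#' @param section_index integer section index.
#' @param closed logical; closed traces need >= 3 points, open >= 2.
#' @return A list of class `icns_contour`.
#' @export
contour_trace <- function(structure_name, points, section_index, closed = TRUE) {
  points <- check_points3(points, "points")
  if (nrow(points) < (if (closed) 3L else 2L))
    abort_arg("contour '%s' needs >= %d points", structure_name, if (closed) 3L else 2L)
  zs <- points[, 3]
  if (diff(range(zs)) > 1e-6 * max(1, max(abs(zs))))
    abort_arg("contour '%s': points do not share one z value", structure_name)
  structure(list(
    structure_name = as.character(structure_name),
    points = points,
    section_index = as.integer(section_index),
    closed = isTRUE(closed),
    known = structure_name %in% structure_vocabulary()
  ), class = "icns_contour")
}

#' Construct a subject map
#'
#' The per-subject container holding all neuron markers and anatomical
#' contours of one heart.
#'
#' @param subject_id character id.
#' @param sex one of `"male"`, `"female"`, `"unknown"`.
#' @param markers an `icns_markers` data.frame (see [neuron_markers()]).
#' @param contours list of `icns_contour` objects.
#' @param section_thickness section thickness in um (default 5).
#' @param provenance free-text metadata.
#' @return A list of class `icns_subject`.
#' @export
subject_map <- function(subject_id, sex = c("unknown", "male", "female"),
                        markers = neuron_markers(character(), numeric(),
                                                 numeric(), numeric()),
                        contours = list(), section_thickness = 5,
                        provenance = "") {
  sex <- match.arg(sex)
  check_scalar_number(section_thickness, "section_thickness", positive = TRUE)
  s <- structure(list(
    subject_id = as.character(subject_id), sex = sex,
    section_thickness = as.numeric(section_thickness),
    markers = markers, contours = contours,
    provenance = as.character(provenance)
  ), class = "icns_subject")
  validate_subject(s)
  s
}

#' Validate a subject map's invariants
#'
#' Checks unique marker ids, finite positions, soma-axis ordering, and
#' section/z consistency (z within half a thickness of the section mid-plane
#' `section * thickness` when both are present).
#'
#' @param subject an `icns_subject`.
#' @return The subject, invisibly; errors describe the first violation.
#' @export
validate_subject <- function(subject) {
  m <- subject$markers
  if (anyDuplicated(m$id))
    abort_arg("duplicate marker id(s): %s",
              paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  if (nrow(m) && !all(is.finite(marker_xyz(m))))
    abort_arg("marker positions must be finite")
  both <- !is.na(m$soma_short) & !is.na(m$soma_long)
  if (any(both & m$soma_long < m$soma_short))
    abort_arg("soma_long < soma_short for marker(s): %s",
              paste(m$id[both & m$soma_long < m$soma_short], collapse = ", "))
  hs <- !is.na(m$section)
  if (any(hs)) {
    off <- abs(m$z[hs] - m$section[hs] * subject$section_thickness)
    if (any(off > subject$section_thickness / 2 + 1e-6))
      abort_arg("marker z inconsistent with section index for: %s",
                paste(m$id[hs][off > subject$section_thickness / 2 + 1e-6],
                      collapse = ", "))
  }
  for (ct in subject$contours) {
    if (!inherits(ct, "icns_contour")) abort_arg("contours must be icns_contour objects")
  }
  invisible(subject)
}

#' @export
print.icns_subject <- function(x, ...) {
  cat(sprintf("ICNS subject '%s' (%s)\n", x$subject_id, x$sex))
  cat(sprintf("  %d neuron markers, %d contours, section thickness %g um\n",
              nrow(x$markers), length(x$contours), x$section_thickness))
  labs <- x$markers$cluster
  if (any(!is.na(labs)))
    cat(sprintf("  cluster labels present: %d clusters\n",
                length(unique(labs[!is.na(labs)]))))
  invisible(x)
}

#' @export
summary.icns_subject <- function(object, ...) {
  structs <- vapply(object$contours, `[[`, "", "structure_name")
  out <- list(
    subject_id = object$subject_id, sex = object$sex,
    n_markers = nrow(object$markers),
    n_contours = length(object$contours),
    structures = sort(unique(structs)),
    z_range = if (nrow(object$markers)) range(object$markers$z) else c(NA, NA)
  )
  class(out) <- "summary.icns_subject"
  out
}

#' @export
print.summary.icns_subject <- function(x, ...) {
  cat(sprintf("Subject %s (%s): %d markers, %d contours\n",
              x$subject_id, x$sex, x$n_markers, x$n_contours))
  if (length(x$structures))
    cat("  structures:", paste(x$structures, collapse = ", "), "\n")
  invisible(x)
}

#' Filter markers by the soma-size inclusion criterion
#'
#' Retains markers whose soma short and long axes are at least the stated
#' thresholds (boundary inclusive: a 13 x 23 um soma passes at the default
#' 13 x 23 um criterion). Markers lacking one or both axis measurements are
#' retained and flagged in the `size_unchecked` column, because annotation
#' files may record only somata already accepted at mapping time.
#'
#' @param markers an `icns_markers` data.frame.
#' @param min_short minimum short-axis length, um (default 13).
#' @param min_long minimum long-axis length, um (default 23).
#' @return The retained rows, in input order, with a logical
#'   `size_unchecked` column marking axis-free records.
#' @export
apply_inclusion_filter <- function(markers, min_short = 13, min_long = 23) {
  check_scalar_number(min_short, "min_short", nonneg = TRUE)
  check_scalar_number(min_long, "min_long", nonneg = TRUE)
  if (min_short > min_long) abort_arg("min_short must be <= min_long")
  has <- !is.na(markers$soma_short) & !is.na(markers$soma_long)
  keep <- !has | (markers$soma_short >= min_short & markers$soma_long >= min_long)
  out <- markers[keep, , drop = FALSE]
  out$size_unchecked <- !has[keep]
  rownames(out) <- NULL
  out
}

#' Export markers to CSV
#'
#' Writes the columns `id, x, y, z, section, cluster, rois`.
#'
#' @param markers an `icns_markers` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_markers_csv <- function(markers, path) {
  cols <- c("id", "x", "y", "z", "section", "cluster", "rois")
  utils::write.csv(as.data.frame(markers)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Duplicate markers across the sections spanned by each soma
#'
#' Serial-section annotation sees one soma on several adjacent 5 um sections.
#' This helper emulates that: each marker is replicated on
#' `round(soma_short / thickness)` consecutive sections (clamped to 3..5)
#' centred on its own, shifting z accordingly. Used with
#' [dedup_four_section()] to exercise the double-counting rule.
#'
#' @param markers an `icns_markers` data.frame with soma axes and sections.
#' @param thickness section thickness, um.
#' @return An expanded `icns_markers` data.frame; duplicated rows carry ids
#'   suffixed `#<section>`.
#' @export
expand_marker_sections <- function(markers, thickness = 5) {
  check_scalar_number(thickness, "thickness", positive = TRUE)
  n <- nrow(markers)
  if (!n) return(markers)
  span <- pmin(5L, pmax(3L, as.integer(round(
    ifelse(is.na(markers$soma_short), 16, markers$soma_short) / thickness))))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- span[i]
    offs <- seq_len(k) - 1L - (k - 1L) %/% 2L
    secs <- pmax(0L, markers$section[i] + offs)
    r <- markers[rep(i, k), , drop = FALSE]
    r$section <- secs
    r$z <- secs * thickness
    r$id <- paste0(markers$id[i], "#", secs)
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- class(markers)
  out
}

#' Deduplicate section-replicated markers with the four-section counting rule
#'
#' Mapping counts neurons only on every fourth section to prevent double
#' counting; a soma missed on its counting section is picked up from the
#' nearest section above or below. This operation groups records that share
#' an (x, y) position within `xy_tol` and lie on adjacent sections, then
#' keeps exactly one record per group: the one on a counting section
#' (`section %% 4 == offset`) when present, otherwise the group's middle
#' section.
#'
#' @param markers an expanded `icns_markers` data.frame.
#' @param offset counting-grid offset in `0..3`.
#' @param xy_tol in-plane tolerance identifying one soma, um.
#' @return Deduplicated `icns_markers`, one row per physical soma, ids
#'   restored to the pre-expansion stem.
#' @export
dedup_four_section <- function(markers, offset = 0L, xy_tol = 1e-6) {
  stopifnot(offset %in% 0:3)
  if (!nrow(markers)) return(markers)
  key <- paste(round(markers$x / xy_tol), round(markers$y / xy_tol))
  keep <- integer(0)
  for (g in split(seq_len(nrow(markers)), key)) {
    g <- g[order(markers$section[g])]
    on_grid <- g[markers$section[g] %% 4L == offset]
    keep <- c(keep, if (length(on_grid)) on_grid[1L] else g[(length(g) + 1L) %/% 2L])
  }
  out <- markers[sort(keep), , drop = FALSE]
  out$id <- sub("#[0-9]+$", "", out$id)
  rownames(out) <- NULL
  out
}
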