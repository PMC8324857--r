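# Mapping-XML dialect, modelled on tissue-mapper style annotation exports.
#
# Schema (all coordinates um, z increasing with section index):
#
#   <subjectmap subject_id="S" sex="male|female|unknown"
#               section_thickness="5" units="um">
#     <provenance>free text</provenance>
#     <markers>
#       <marker id="m1" x="10.5" y="3" z="12.5" section="2"
#               soma_short="15.1" soma_long="27.9" cluster="3"
#               rois="pv_hilum;svc_ra_root"/>
#     </markers>
#     <contours>
#       <contour name="left_atrium" section="4" closed="true">
#         <point x="0" y="0" z="20"/>
#         ...
#       </contour>
#     </contours>
#   </subjectmap>
#
# Optional marker attributes (section, soma axes, cluster, rois) may be
# absent. Unknown elements and attributes are ignored rather than rejected,
# for forward compatibility with richer annotation exports.

num_attr <- function(node, name, default = NA_real_) {
  v <- xml2::xml_attr(node, name)
  ifelse(is.na(v), default, suppressWarnings(as.numeric(v)))
}

#' Read a subject annotation file (mapping-XML dialect)
#'
#' Parses neuron markers and anatomical contour traces from the documented
#' XML dialect (see the package vignette for the schema). Unknown structure
#' names are preserved verbatim with `known = FALSE` and a warning. Markers
#' without a `section` attribute get `floor(z / thickness)`; contours whose z
#' is recorded as a section index rather than um can be read with
#' `contour_z = "section"`.
#'
#' @param path path to an XML file.
#' @param section_thickness section thickness in um; overrides the file's
#'   attribute when given.
#' @param contour_z `"um"` (default) if contour point z values are in um,
#'   `"section"` if they are section indices to be scaled by the thickness.
#' @return An `icns_subject` (see [subject_map()]).
#' @export
read_subject <- function(path, section_thickness = NULL,
                         contour_z = c("um", "section")) {
  contour_z <- match.arg(contour_z)
  if (!file.exists(path)) abort_arg("file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("malformed markup in %s: %s", path, conditionMessage(e)),
         call. = FALSE))
  root <- xml2::xml_root(doc)
  thick <- if (!is.null(section_thickness)) section_thickness
           else num_attr(root, "section_thickness", 5)
  check_scalar_number(thick, "section_thickness", positive = TRUE)

  mnodes <- xml2::xml_find_all(doc, ".//marker")
  if (length(mnodes)) {
    x <- num_attr(mnodes, "x"); y <- num_attr(mnodes, "y")
    z <- num_attr(mnodes, "z")
    ids <- xml2::xml_attr(mnodes, "id")
    bad <- is.na(x) | is.na(y) | is.na(z)
    if (any(bad))
      abort_arg("marker(s) missing position: %s",
                paste(ifelse(is.na(ids[bad]), "<no id>", ids[bad]),
                      collapse = ", "))
    if (any(is.na(ids))) ids[is.na(ids)] <-
      paste0("marker_", which(is.na(ids)))
    sec <- num_attr(mnodes, "section")
    sec <- ifelse(is.na(sec), floor(z / thick), sec)
    markers <- neuron_markers(
      id = ids, x = x, y = y, z = z, section = as.integer(sec),
      soma_short = num_attr(mnodes, "soma_short"),
      soma_long = num_attr(mnodes, "soma_long"),
      cluster = as.integer(num_attr(mnodes, "cluster")),
      rois = xml2::xml_attr(mnodes, "rois"))
  } else {
    markers <- neuron_markers(character(), numeric(), numeric(), numeric())
  }

  contours <- lapply(xml2::xml_find_all(doc, ".//contour"), function(cn) {
    pts <- xml2::xml_find_all(cn, "./point")
    pm <- cbind(num_attr(pts, "x"), num_attr(pts, "y"), num_attr(pts, "z"))
    if (contour_z == "section") pm[, 3] <- pm[, 3] * thick
    sec <- num_attr(cn, "section")
    if (is.na(sec)) sec <- floor(pm[1, 3] / thick)
    contour_trace(xml2::xml_attr(cn, "name"), pm, as.integer(sec),
                  closed = !identical(xml2::xml_attr(cn, "closed"), "false"))
  })
  unknown <- vapply(contours, function(ct) !ct$known, logical(1))
  if (any(unknown))
    warning(sprintf("unknown structure name(s) preserved verbatim: %s",
                    paste(unique(vapply(contours[unknown], `[[`, "",
                                        "structure_name")), collapse = ", ")),
            call. = FALSE)

  prov <- xml2::xml_find_first(doc, ".//provenance")
  subject_map(
    subject_id = xml2::xml_attr(root, "subject_id"),
    sex = {
      s <- xml2::xml_attr(root, "sex")
      if (is.na(s) || !s %in% c("male", "female")) "unknown" else s
    },
    markers = markers, contours = contours, section_thickness = thick,
    provenance = if (inherits(prov, "xml_missing")) "" else xml2::xml_text(prov))
}

fmt_num <- function(x) formatC(x, digits = 9, format = "g")

#' Write a subject annotation file (mapping-XML dialect)
#'
#' The emitted file round-trips through [read_subject()] with exact equality
#' of ids and names and coordinate agreement to at least 6 significant
#' digits.
#'
#' @param subject an `icns_subject`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subject <- function(subject, path) {
  validate_subject(subject)
  doc <- xml2::xml_new_root("subjectmap",
    subject_id = subject$subject_id, sex = subject$sex,
    section_thickness = fmt_num(subject$section_thickness), units = "um")
  if (nzchar(subject$provenance))
    xml2::xml_add_child(doc, "provenance", subject$provenance)
  mk <- xml2::xml_add_child(doc, "markers")
  m <- subject$markers
  for (i in seq_len(nrow(m))) {
    attrs <- list(id = m$id[i], x = fmt_num(m$x[i]), y = fmt_num(m$y[i]),
                  z = fmt_num(m$z[i]))
    if (!is.na(m$section[i])) attrs$section <- as.character(m$section[i])
    if (!is.na(m$soma_short[i])) attrs$soma_short <- fmt_num(m$soma_short[i])
    if (!is.na(m$soma_long[i])) attrs$soma_long <- fmt_num(m$soma_long[i])
    if (!is.na(m$cluster[i])) attrs$cluster <- as.character(m$cluster[i])
    if (!is.na(m$rois[i])) attrs$rois <- m$rois[i]
    do.call(xml2::xml_add_child, c(list(mk, "marker"), attrs))
  }
  ck <- xml2::xml_add_child(doc, "contours")
  for (ct in subject$contours) {
    cn <- xml2::xml_add_child(ck, "contour", name = ct$structure_name,
                              section = as.character(ct$section_index),
                              closed = if (ct$closed) "true" else "false")
    for (j in seq_len(nrow(ct$points)))
      xml2::xml_add_child(cn, "point", x = fmt_num(ct$points[j, 1]),
                          y = fmt_num(ct$points[j, 2]),
                          z = fmt_num(ct$points[j, 3]))
  }
  tryCatch(xml2::write_xml(doc, path),
           error = function(e) stop(sprintf("cannot write %s: %s", path,
                                            conditionMessage(e)), call. = FALSE))
  invisible(path)
}
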