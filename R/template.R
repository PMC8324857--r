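# Synthetic heart-base geometry.
#
# The template is a single-sheet parametric surface over (u,v) in [0,1]^2:
# a smooth dome (the atrial mass seen from the base) carrying a ridge near
# v ~ 0.85 that stands in for the great-vessel hilum. All downstream
# analyses consume epicardial-surface point clouds, so a height-field sheet
# is sufficient; no chamber volumes are modelled.

heart_surface_xyz <- function(u, v, extent) {
  x <- extent * (u - 0.5)
  y <- 0.8 * extent * (v - 0.5)
  dome <- 0.30 * extent * exp(-(((u - 0.5) / 0.35)^2 + ((v - 0.5) / 0.35)^2))
  tube <- 0.12 * extent * exp(-(((u - 0.5) / 0.25)^2 + ((v - 0.85) / 0.10)^2))
  cbind(x = x, y = y, z = dome + tube)
}

template_anchors <- function() {
  rbind(
    pv_hilum                    = c(0.50, 0.78),
    svc_ra_root                 = c(0.22, 0.62),
    left_av_sulcus              = c(0.78, 0.235),  # left-atrium/ventricle junction
    anterior_interatrial_sulcus = c(0.38, 0.45),   # inside both atrial bands
    posterior_left_atrium       = c(0.60, 0.55))
}

# (umin, umax, vmin, vmax) rectangles of the structures traced as contours.
template_regions <- function() {
  list(
    left_atrium           = c(0.35, 0.95, 0.25, 0.75),
    right_atrium          = c(0.05, 0.40, 0.30, 0.75),
    pulmonary_vein_left   = c(0.40, 0.50, 0.70, 0.88),
    pulmonary_vein_middle = c(0.46, 0.56, 0.80, 0.95),
    pulmonary_vein_right  = c(0.52, 0.62, 0.70, 0.88),
    superior_vena_cava    = c(0.12, 0.30, 0.55, 0.75),
    inferior_vena_cava    = c(0.08, 0.25, 0.10, 0.28),
    left_auricle          = c(0.80, 0.95, 0.55, 0.75),
    right_auricle         = c(0.05, 0.18, 0.60, 0.80),
    aorta                 = c(0.30, 0.45, 0.75, 0.90),
    ventricles            = c(0.55, 0.95, 0.05, 0.22),
    coronary_sinus        = c(0.30, 0.60, 0.05, 0.18))
}

#' Build the template heart-base surface
#'
#' Deterministic parametric surface (dome plus hilum ridge) sampled on a
#' `(nu+1) x (nv+1)` node grid, with named (u,v) anchors for the five
#' regions of interest and (u,v) rectangles for the traced anatomical
#' structures.
#'
#' @param extent organ extent in um (default 8000, a rat atrial base).
#' @param grid integer `c(nu, nv)` element counts, both >= 2.
#' @return An object of class `icns_template`: fields `extent`, `grid`,
#'   `u`, `v` (node parameter values), `nodes` (matrix of 3D node
#'   coordinates, um), `surface` (vectorized `(u,v) -> n x 3` map),
#'   `roi_anchors`, `structure_regions`, and `warp` (`NULL` for the
#'   undeformed template).
#' @export
#' @examples
#' th <- make_template_heart(8000, c(8, 8))
#' nrow(th$nodes)  # 81 nodes
make_template_heart <- function(extent = 8000, grid = c(8, 8)) {
  check_scalar_number(extent, "extent", positive = TRUE)
  nu <- as.integer(grid[1]); nv <- as.integer(grid[2])
  if (nu < 2 || nv < 2) abort_arg("grid must be at least c(2, 2)")
  u <- seq(0, 1, length.out = nu + 1L)
  v <- seq(0, 1, length.out = nv + 1L)
  uv <- expand.grid(u = u, v = v)   # u fastest, matching node indexing
  surface <- function(u, v) heart_surface_xyz(u, v, extent)
  structure(list(
    extent = extent, grid = c(nu, nv), u = u, v = v,
    nodes = surface(uv$u, uv$v),
    surface = surface,
    roi_anchors = template_anchors(),
    structure_regions = template_regions(),
    warp = NULL
  ), class = "icns_template")
}

#' @export
print.icns_template <- function(x, ...) {
  cat(sprintf("Template heart surface: extent %g um, %d x %d elements%s\n",
              x$extent, x$grid[1], x$grid[2],
              if (is.null(x$warp)) "" else " (deformed)"))
  cat("  ROI anchors:", paste(rownames(x$roi_anchors), collapse = ", "), "\n")
  invisible(x)
}

# Orthonormal tangent frame + unit normal of the surface at (u,v), by
# central differences in parameter space.
surface_frame <- function(template, u, v, h = 1e-4) {
  tu <- (template$surface(u + h, v) - template$surface(u - h, v)) / (2 * h)
  tv <- (template$surface(u, v + h) - template$surface(u, v - h)) / (2 * h)
  e1 <- tu / sqrt(rowSums(tu^2))
  tv <- tv - rowSums(tv * e1) * e1
  e2 <- tv / sqrt(rowSums(tv^2))
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  list(e1 = e1, e2 = e2, normal = nrm)
}

# Bilinear interpolation of a grid-sampled field at query (u,v).
interp_grid <- function(u_grid, v_grid, Z, uq, vq) {
  iu <- pmin(pmax(findInterval(uq, u_grid), 1L), length(u_grid) - 1L)
  iv <- pmin(pmax(findInterval(vq, v_grid), 1L), length(v_grid) - 1L)
  fu <- (uq - u_grid[iu]) / (u_grid[iu + 1L] - u_grid[iu])
  fv <- (vq - v_grid[iv]) / (v_grid[iv + 1L] - v_grid[iv])
  Z[cbind(iu, iv)] * (1 - fu) * (1 - fv) +
    Z[cbind(iu + 1L, iv)] * fu * (1 - fv) +
    Z[cbind(iu, iv + 1L)] * (1 - fu) * fv +
    Z[cbind(iu + 1L, iv + 1L)] * fu * fv
}

#' Section a template surface into anatomical contour traces
#'
#' Emulates serial sectioning: intersects each structure's surface patch
#' with the planes `z = k * thickness` and emits the resulting iso-z
#' polylines as [contour_trace()] objects. Every emitted contour's points
#' share the plane's exact z value.
#'
#' @param template an `icns_template` (possibly deformed).
#' @param thickness section thickness, um.
#' @param step trace every `step`-th section (annotators do not trace every
#'   5 um section; default 1 traces all).
#' @param resolution parameter-grid resolution per structure patch.
#' @param min_points drop degenerate intersections shorter than this.
#' @return List of `icns_contour` objects.
#' @export
slice_contours <- function(template, thickness = 5, step = 1L,
                           resolution = 48L, min_points = 3L) {
  check_scalar_number(thickness, "thickness", positive = TRUE)
  step <- max(1L, as.integer(step))
  out <- list()
  for (nm in names(template$structure_regions)) {
    r <- template$structure_regions[[nm]]
    ug <- seq(r[1], r[2], length.out = resolution)
    vg <- seq(r[3], r[4], length.out = resolution)
    uv <- expand.grid(u = ug, v = vg)
    P <- template$surface(uv$u, uv$v)
    X <- matrix(P[, 1], resolution); Y <- matrix(P[, 2], resolution)
    Z <- matrix(P[, 3], resolution)
    zr <- range(Z)
    ks <- seq(ceiling(zr[1] / thickness), floor(zr[2] / thickness))
    ks <- ks[ks %% step == 0L & ks >= 0L]
    if (!length(ks)) next
    cls <- grDevices::contourLines(ug, vg, Z, levels = ks * thickness)
    for (cl in cls) {
      if (length(cl$x) < min_points) next
      px <- interp_grid(ug, vg, X, cl$x, cl$y)
      py <- interp_grid(ug, vg, Y, cl$x, cl$y)
      closed <- abs(cl$x[1] - cl$x[length(cl$x)]) < 1e-9 &&
        abs(cl$y[1] - cl$y[length(cl$y)]) < 1e-9
      if (closed) { px <- px[-length(px)]; py <- py[-length(py)] }
      if (length(px) < (if (closed) 3L else 2L)) next
      pts <- cbind(px, py, cl$level)
      out[[length(out) + 1L]] <- contour_trace(
        nm, pts, as.integer(round(cl$level / thickness)), closed = closed)
    }
  }
  out
}
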