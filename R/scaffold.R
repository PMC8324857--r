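# Material-coordinate scaffold: a structured grid of bilinear quad
# elements. Node (i, j), i = 0..nu along u, j = 0..nv along v, is row
# i + j*(nu+1) + 1 of `nodes`. Element (ei, ej), ei = 1..nu, ej = 1..nv, is
# id (ej-1)*nu + ei; its corners, counterclockwise from local (0,0), are
# nodes (ei-1, ej-1), (ei, ej-1), (ei, ej), (ei-1, ej). Local coordinates
# xi = (xi1, xi2) live in [0,1]^2, xi1 along u.

bilinear_phi <- function(xi) {
  cbind((1 - xi[, 1]) * (1 - xi[, 2]), xi[, 1] * (1 - xi[, 2]),
        xi[, 1] * xi[, 2], (1 - xi[, 1]) * xi[, 2])
}

element_corner_ids <- function(nu, nv) {
  ei <- rep(seq_len(nu), nv)
  ej <- rep(seq_len(nv), each = nu)
  node <- function(i, j) i + j * (nu + 1L) + 1L
  cbind(node(ei - 1L, ej - 1L), node(ei, ej - 1L),
        node(ei, ej), node(ei - 1L, ej))
}

#' Build the generic atrial-base scaffold
#'
#' A deterministic structured surface mesh of `nu x nv` bilinear quad
#' elements whose node geometry is the template heart-base surface (see
#' [make_template_heart()]), so that synthetic subjects are within the
#' scaffold's shape family. Element ids are stable under deformation of the
#' node coordinates.
#'
#' @param extent organ extent, um.
#' @param grid integer `c(nu, nv)`, both >= 2.
#' @return Object of class `icns_scaffold`: `nodes` (`(nu+1)(nv+1) x 3`,
#'   um), `grid`, `elements` (`nu*nv x 4` corner node ids, counterclockwise
#'   from local (0,0)), `extent`.
#' @export
#' @examples
#' sc <- make_generic_scaffold(8000, c(8, 8))
#' nrow(sc$elements)  # 64
make_generic_scaffold <- function(extent = 8000, grid = c(10, 10)) {
  th <- make_template_heart(extent, grid)
  nu <- th$grid[1]; nv <- th$grid[2]
  structure(list(nodes = th$nodes, grid = c(nu, nv),
                 elements = element_corner_ids(nu, nv), extent = extent),
            class = "icns_scaffold")
}

#' @export
print.icns_scaffold <- function(x, ...) {
  cat(sprintf("Scaffold: %d x %d bilinear quad elements, %d nodes\n",
              x$grid[1], x$grid[2], nrow(x$nodes)))
  invisible(x)
}

check_scaffold <- function(x) {
  if (!inherits(x, "icns_scaffold")) abort_arg("expected an icns_scaffold")
  invisible(x)
}

#' Evaluate material coordinates on a scaffold
#'
#' Bilinear interpolation of each element's four corner nodes at the local
#' coordinates.
#'
#' @param scaffold an `icns_scaffold`.
#' @param element_id integer element id(s).
#' @param xi n x 2 matrix (or length-2 vector) of local coordinates in
#'   `[0,1]^2`.
#' @return n x 3 matrix of surface positions, um.
#' @export
scaffold_evaluate <- function(scaffold, element_id, xi) {
  check_scaffold(scaffold)
  if (is.null(dim(xi))) xi <- matrix(xi, 1L)
  xi <- pmin(pmax(as.matrix(xi), 0), 1)
  element_id <- rep_len(as.integer(element_id), nrow(xi))
  if (any(element_id < 1L | element_id > nrow(scaffold$elements)))
    abort_arg("invalid element id")
  phi <- bilinear_phi(xi)
  corners <- scaffold$elements[element_id, , drop = FALSE]
  out <- matrix(0, nrow(xi), 3L)
  for (c4 in 1:4)
    out <- out + phi[, c4] * scaffold$nodes[corners[, c4], , drop = FALSE]
  out
}

# Vectorized clamped Gauss-Newton projection of all `pts` onto one element
# given its corner coordinates (4 x 3). Returns list(xi, d2).
project_onto_element <- function(P, pts, n_iter = 20L) {
  A <- P[2, ] - P[1, ]; B <- P[4, ] - P[1, ]; C <- P[3, ] - P[2, ] - P[4, ] + P[1, ]
  n <- nrow(pts)
  starts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  best_d2 <- rep(Inf, n); best_xi <- matrix(0.5, n, 2L)
  for (s in seq_len(nrow(starts))) {
    xi1 <- rep(starts[s, 1], n); xi2 <- rep(starts[s, 2], n)
    f0 <- rep(1, n) %o% P[1, ] + xi1 %o% A + xi2 %o% B + (xi1 * xi2) %o% C
    d0 <- rowSums((f0 - pts)^2)        # start itself is a candidate: a
    upd0 <- d0 < best_d2 - 1e-12       # Gauss-Newton step never backtracks
    best_d2[upd0] <- d0[upd0]
    best_xi[upd0, ] <- cbind(xi1, xi2)[upd0, , drop = FALSE]
    for (it in seq_len(n_iter)) {
      f <- rep(1, n) %o% P[1, ] + xi1 %o% A + xi2 %o% B + (xi1 * xi2) %o% C
      r <- f - pts
      J1 <- rep(1, n) %o% A + xi2 %o% C
      J2 <- rep(1, n) %o% B + xi1 %o% C
      g1 <- rowSums(J1 * r); g2 <- rowSums(J2 * r)
      h11 <- rowSums(J1 * J1); h22 <- rowSums(J2 * J2); h12 <- rowSums(J1 * J2)
      det <- pmax(h11 * h22 - h12^2, 1e-12)
      d1 <- -(h22 * g1 - h12 * g2) / det
      d2 <- -(h11 * g2 - h12 * g1) / det
      xi1 <- pmin(pmax(xi1 + d1, 0), 1)
      xi2 <- pmin(pmax(xi2 + d2, 0), 1)
      if (max(abs(d1), abs(d2)) < 1e-10) break
    }
    f <- rep(1, n) %o% P[1, ] + xi1 %o% A + xi2 %o% B + (xi1 * xi2) %o% C
    d2v <- rowSums((f - pts)^2)
    upd <- d2v < best_d2 - 1e-12
    best_d2[upd] <- d2v[upd]
    best_xi[upd, ] <- cbind(xi1, xi2)[upd, , drop = FALSE]
  }
  list(xi = best_xi, d2 = best_d2)
}

#' Project points onto the nearest scaffold element
#'
#' Finds, for each point, the globally nearest point on the scaffold
#' surface: every element is searched with a clamped Gauss-Newton descent
#' on the local coordinates, multi-started at the four corners and the
#' centre; distance ties resolve to the lower element id.
#'
#' @param scaffold an `icns_scaffold`.
#' @param points n x 3 matrix (or 3-vector), um.
#' @return Object of class `icns_projection` (a data.frame): `element_id`,
#'   `xi1`, `xi2`, `distance` (um), plus the foot points in an attribute
#'   `"foot"`.
#' @export
project_points <- function(scaffold, points) {
  check_scaffold(scaffold)
  if (is.null(dim(points))) points <- matrix(points, 1L)
  points <- check_points3(points)
  n <- nrow(points)
  # A bilinear patch is a convex combination of its corners, so it lies in
  # the corners' bounding sphere: elements whose sphere is farther than the
  # current best distance cannot contain the nearest point and are skipped.
  # The search stays globally exact; the upper bound is seeded from the
  # nearest node.
  nel <- nrow(scaffold$elements)
  centres <- matrix(0, nel, 3L)
  for (c4 in 1:4)
    centres <- centres + scaffold$nodes[scaffold$elements[, c4], , drop = FALSE] / 4
  radius <- rep(0, nel)
  for (c4 in 1:4)
    radius <- pmax(radius, sqrt(rowSums(
      (scaffold$nodes[scaffold$elements[, c4], , drop = FALSE] - centres)^2)))
  seed_xi <- as.matrix(expand.grid(c(0.17, 0.5, 0.83), c(0.17, 0.5, 0.83)))
  seed_pts <- do.call(rbind, lapply(seq_len(nel), function(e)
    scaffold_evaluate(scaffold, e, seed_xi)))
  best_d <- pmin(apply(cross_dist(points, scaffold$nodes), 1L, min),
                 apply(cross_dist(points, seed_pts), 1L, min))
  d_centre <- cross_dist(points, centres)
  best_d2 <- best_d^2
  best_el <- rep(1L, n); best_xi <- matrix(0.5, n, 2L)
  found <- rep(FALSE, n)
  for (e in seq_len(nel)) {
    active <- which(d_centre[, e] - radius[e] < best_d + 1e-9 |
                      (!found & d_centre[, e] - radius[e] <= best_d + 1e-9))
    if (!length(active)) next
    P <- scaffold$nodes[scaffold$elements[e, ], , drop = FALSE]
    pr <- project_onto_element(P, points[active, , drop = FALSE])
    upd <- pr$d2 < best_d2[active] - 1e-12 |
      (!found[active] & pr$d2 <= best_d2[active] + 1e-12)
    ia <- active[upd]
    best_d2[ia] <- pr$d2[upd]
    best_d[ia] <- sqrt(pmax(pr$d2[upd], 0))
    best_el[ia] <- e
    best_xi[ia, ] <- pr$xi[upd, , drop = FALSE]
    found[ia] <- TRUE
  }
  out <- data.frame(element_id = best_el, xi1 = best_xi[, 1],
                    xi2 = best_xi[, 2], distance = sqrt(pmax(best_d2, 0)))
  attr(out, "foot") <- scaffold_evaluate(scaffold, best_el, best_xi)
  class(out) <- c("icns_projection", "data.frame")
  out
}

#' @rdname project_points
#' @param point a single 3-vector.
#' @export
project_point <- function(scaffold, point) {
  project_points(scaffold, matrix(point, 1L))
}

# Edge list (pairs of adjacent node ids) of the structured grid.
grid_edges <- function(nu, nv) {
  node <- function(i, j) i + j * (nu + 1L) + 1L
  h <- cbind(node(rep(0:(nu - 1L), nv + 1L), rep(0:nv, each = nu)),
             node(rep(1:nu, nv + 1L), rep(0:nv, each = nu)))
  v <- cbind(node(rep(0:nu, nv), rep(0:(nv - 1L), each = nu + 1L)),
             node(rep(0:nu, nv), rep(1:nv, each = nu + 1L)))
  rbind(h, v)
}

#' Fit a scaffold to contour data by alternating least squares
#'
#' Deforms the scaffold's nodes so its surface matches a cloud of
#' segmentation (contour) points. Each round (1) projects every data point
#' onto the current surface to fix its element and local coordinates, then
#' (2) solves the linear least-squares problem
#' `sum_i w_i ||x_i - sum_j phi_j(xi_i) p_j||^2 +
#'  lambda * sum_edges ||(p_a - p_b) - (g_a - g_b)||^2`
#' for the node coordinates `p`, where `g` are the generic nodes: the
#' membrane penalty is anchored to the generic edge vectors, so it is zero
#' for any translation of the generic configuration and does not shrink the
#' mesh. Iterates until the RMS data distance changes by less than `tol`.
#'
#' @param generic an `icns_scaffold` (the starting configuration).
#' @param data n x 3 matrix of contour points, um.
#' @param weights per-point weights (recycled; default 1).
#' @param lambda_smooth membrane penalty weight (>= 0). With 0 the normal
#'   equations must be full rank (every node constrained by data).
#' @param max_iters maximum correspondence rounds.
#' @param tol RMS-change stopping tolerance, um.
#' @param xi0 optional fixed correspondences for the first round: a list or
#'   data.frame with `element_id`, `xi1`, `xi2` per data point (used e.g.
#'   when correspondences are known a priori).
#' @param affine_init number of coarse alignment rounds run before the
#'   free-node fit, each restricted to a single affine map of all nodes
#'   (12 parameters). This absorbs global rotation/scale/translation without
#'   letting the element parameterization slide across sharp features;
#'   0 disables it.
#' @return Object of class `icns_scaffold_fit`: `scaffold` (fitted),
#'   `generic`, `rms` (final RMS data distance, um), `rms_history`,
#'   `lambda`, `n_data`.
#' @export
fit_scaffold <- function(generic, data, weights = 1, lambda_smooth = 0.05,
                         max_iters = 8L, tol = 0.5, xi0 = NULL,
                         affine_init = 3L) {
  check_scaffold(generic)
  data <- check_points3(data, "data")
  check_scalar_number(lambda_smooth, "lambda_smooth", nonneg = TRUE)
  w <- rep_len(as.numeric(weights), nrow(data))
  nu <- generic$grid[1]; nv <- generic$grid[2]
  nn <- nrow(generic$nodes)
  E <- grid_edges(nu, nv)
  L <- matrix(0, nrow(E), nn)
  L[cbind(seq_len(nrow(E)), E[, 1])] <- 1
  L[cbind(seq_len(nrow(E)), E[, 2])] <- -1
  LtL <- crossprod(L)

  fitted <- generic
  # coarse stage: alternate projection with a 12-parameter affine update of
  # all nodes, so global pose and scale are absorbed before nodes move freely
  if (is.null(xi0) && affine_init > 0L) {
    for (it in seq_len(affine_init)) {
      pr <- project_points(fitted, data)
      S <- cbind(attr(pr, "foot"), 1)
      AB <- tryCatch(qr.solve(S * sqrt(w), data * sqrt(w)),
                     error = function(e) NULL)
      if (is.null(AB)) break
      fitted$nodes <- cbind(fitted$nodes, 1) %*% AB
    }
  }
  # the membrane penalty is anchored at the (possibly affine-aligned)
  # reference edge vectors, so it vanishes for the reference shape and any
  # translation of it instead of shrinking the mesh
  LtLG <- LtL %*% fitted$nodes
  rms_hist <- numeric(0)
  for (iter in seq_len(max_iters)) {
    if (iter == 1L && !is.null(xi0)) {
      el <- rep_len(as.integer(xi0$element_id), nrow(data))
      xi <- cbind(rep_len(xi0$xi1, nrow(data)), rep_len(xi0$xi2, nrow(data)))
      dists <- sqrt(rowSums((scaffold_evaluate(fitted, el, xi) - data)^2))
    } else {
      pr <- project_points(fitted, data)
      el <- pr$element_id; xi <- cbind(pr$xi1, pr$xi2); dists <- pr$distance
    }
    A <- matrix(0, nrow(data), nn)
    phi <- bilinear_phi(xi)
    corners <- generic$elements[el, , drop = FALSE]
    for (c4 in 1:4)
      A[cbind(seq_len(nrow(data)), corners[, c4])] <-
        A[cbind(seq_len(nrow(data)), corners[, c4])] + phi[, c4]
    AtWA <- crossprod(A * sqrt(w))
    M <- AtWA + lambda_smooth * LtL
    rhs <- crossprod(A, w * data) + lambda_smooth * LtLG
    sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      if (lambda_smooth == 0)
        abort_arg(paste("singular normal equations: some nodes are not",
                        "constrained by data; set lambda_smooth > 0"))
      abort_arg("normal equations could not be solved")
    }
    fitted$nodes <- sol
    # RMS against the new surface at the fixed correspondences
    new_d <- sqrt(rowSums((scaffold_evaluate(fitted, el, xi) - data)^2))
    rms <- sqrt(mean(w * new_d^2) / mean(w))
    rms_hist <- c(rms_hist, rms)
    if (iter > 1L && abs(rms_hist[iter - 1L] - rms) < tol) break
  }
  pr <- project_points(fitted, data)
  structure(list(scaffold = fitted, generic = generic,
                 rms = sqrt(mean(w * pr$distance^2) / mean(w)),
                 rms_history = rms_hist, lambda = lambda_smooth,
                 n_data = nrow(data)),
            class = "icns_scaffold_fit")
}

#' @export
print.icns_scaffold_fit <- function(x, ...) {
  cat(sprintf(
    "Scaffold fit: %d data points, lambda = %g, %d rounds, RMS %.2f um\n",
    x$n_data, x$lambda, length(x$rms_history), x$rms))
  invisible(x)
}

#' Pool a subject's contour points for scaffold fitting
#'
#' Stacks the points of all contour traces and, above `max_points`,
#' down-samples them evenly so fitting cost stays bounded.
#'
#' @param subject an `icns_subject` with contours.
#' @param max_points cap on returned points.
#' @return n x 3 matrix, um.
#' @export
contour_points <- function(subject, max_points = 4000L) {
  pts <- do.call(rbind, lapply(subject$contours, `[[`, "points"))
  if (is.null(pts)) abort_arg("subject has no contours")
  if (nrow(pts) > max_points)
    pts <- pts[round(seq(1L, nrow(pts), length.out = max_points)), , drop = FALSE]
  pts
}

#' Embed neuron markers into a fitted scaffold as material coordinates
#'
#' Projects each marker onto the fitted surface and stores its (element,
#' xi) address together with the projection distance. The mapping is
#' one-to-one: n markers give n embedded records, in order.
#'
#' @param fit an `icns_scaffold_fit` (or an `icns_scaffold`).
#' @param markers an `icns_markers` data.frame.
#' @return Data.frame of class `icns_embedding`: `marker_id`, `element_id`,
#'   `xi1`, `xi2`, `projection_distance` (um), with the scaffold grid in
#'   attribute `"grid"`.
#' @export
embed_markers <- function(fit, markers) {
  sc <- if (inherits(fit, "icns_scaffold_fit")) fit$scaffold else fit
  check_scaffold(sc)
  pr <- project_points(sc, marker_xyz(markers))
  out <- data.frame(marker_id = markers$id, element_id = pr$element_id,
                    xi1 = pr$xi1, xi2 = pr$xi2,
                    projection_distance = pr$distance)
  attr(out, "grid") <- sc$grid
  class(out) <- c("icns_embedding", "data.frame")
  out
}

#' Transfer embedded markers onto the generic scaffold
#'
#' Evaluates each stored material coordinate on the generic scaffold,
#' realizing the one-to-one transfer between individually fitted and
#' generic geometries. The material coordinates themselves are untouched.
#'
#' @param embedded an `icns_embedding`.
#' @param generic an `icns_scaffold` with the same element grid the
#'   embedding was made against.
#' @return n x 3 matrix of positions on the generic surface, um.
#' @export
transfer_to_generic <- function(embedded, generic) {
  check_scaffold(generic)
  g <- attr(embedded, "grid")
  if (!is.null(g) && !identical(as.integer(g), as.integer(generic$grid)))
    abort_arg("scaffold topology mismatch: embedding was made on a %dx%d grid",
              g[1], g[2])
  scaffold_evaluate(generic, embedded$element_id,
                    cbind(embedded$xi1, embedded$xi2))
}

bin_ids <- function(embedded, subgrid) {
  cx <- pmin(floor(embedded$xi1 * subgrid), subgrid - 1L)
  cy <- pmin(floor(embedded$xi2 * subgrid), subgrid - 1L)
  (embedded$element_id - 1L) * subgrid^2 + cy * subgrid + cx + 1L
}

#' Cross-subject overlap of embedded neuron distributions
#'
#' Bins two subjects' material coordinates on a per-element subgrid of the
#' generic scaffold, normalizes each subject's histogram to sum 1, and
#' reports the histogram intersection `sum_bins min(d_a, d_b)` as the
#' global proportion of neuronal overlap (in `[0, 1]`, symmetric), a
#' per-bin overlap ratio `min/max`, and the Jaccard index of occupied bins.
#'
#' @param embedded_a,embedded_b `icns_embedding`s on the same topology.
#' @param generic the generic `icns_scaffold`.
#' @param subgrid per-element subdivisions per axis (default 2).
#' @return Object of class `icns_overlap`: `global_overlap`,
#'   `jaccard_occupied`, `per_bin` (data.frame with bin id, densities and
#'   overlap ratio), `subgrid`.
#' @export
overlap_map <- function(embedded_a, embedded_b, generic, subgrid = 2L) {
  check_scaffold(generic)
  if (!nrow(embedded_a) || !nrow(embedded_b))
    abort_arg("both embeddings must be non-empty")
  subgrid <- max(1L, as.integer(subgrid))
  nbins <- nrow(generic$elements) * subgrid^2
  da <- tabulate(bin_ids(embedded_a, subgrid), nbins) / nrow(embedded_a)
  db <- tabulate(bin_ids(embedded_b, subgrid), nbins) / nrow(embedded_b)
  occ <- da > 0 | db > 0
  per_bin <- data.frame(bin = which(occ), density_a = da[occ],
                        density_b = db[occ],
                        overlap = pmin(da[occ], db[occ]) /
                          pmax(da[occ], db[occ]))
  structure(list(global_overlap = sum(pmin(da, db)),
                 jaccard_occupied = sum(da > 0 & db > 0) / sum(occ),
                 per_bin = per_bin, subgrid = subgrid),
            class = "icns_overlap")
}

#' @export
print.icns_overlap <- function(x, ...) {
  cat(sprintf(
    "Neuronal overlap on generic scaffold: global %.3f, occupied-bin Jaccard %.3f (%d occupied bins)\n",
    x$global_overlap, x$jaccard_occupied, nrow(x$per_bin)))
  invisible(x)
}
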