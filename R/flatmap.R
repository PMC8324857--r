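# PCA flatmaps and packing density.
#
# The flatmap is a linear projection of the 3D soma cloud onto its two
# leading principal axes; packing density is a Gaussian-kernel intensity
# (neurons per um^2) evaluated at every soma and on a raster.

#' Project a 3D neuron cloud onto its PCA flatmap
#'
#' Centres the points and projects them onto the two leading principal
#' axes. The reflection ambiguity of PCA is fixed by a deterministic sign
#' convention: each axis is flipped so its largest-magnitude loading is
#' positive, making the superior-inferior orientation reproducible across
#' runs and subjects.
#'
#' @param points n x 3 coordinates, um, `n >= 3`, not all collinear.
#' @return Object of class `icns_flatmap`: `coords2d` (n x 2 scores, um,
#'   column means 0), `axis_loadings` (2 x 3), `variance_explained` (two
#'   non-increasing fractions), `degenerate` (TRUE when the cloud is
#'   collinear and the second axis is meaningless).
#' @export
pca_flatmap <- function(points) {
  points <- check_points3(points)
  n <- nrow(points)
  if (n < 3L) abort_arg("need at least 3 points for a flatmap")
  pc <- stats::prcomp(points, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  if (ve[1] >= 1 - 1e-12)
    warning("points are collinear; second flatmap axis is degenerate",
            call. = FALSE)
  load2 <- t(pc$rotation[, 1:2])
  flip <- apply(load2, 1L, function(r) sign(r[which.max(abs(r))]))
  flip[flip == 0] <- 1
  load2 <- load2 * flip
  scores <- pc$x[, 1:2, drop = FALSE] %*% diag(flip, 2)
  colnames(scores) <- c("axis1", "axis2")
  structure(list(coords2d = scores, axis_loadings = load2,
                 variance_explained = ve[1:2],
                 degenerate = ve[1] >= 1 - 1e-12),
            class = "icns_flatmap")
}

#' @export
print.icns_flatmap <- function(x, ...) {
  cat(sprintf("PCA flatmap of %d neurons: %.1f%% + %.1f%% variance on the two axes\n",
              nrow(x$coords2d), 100 * x$variance_explained[1],
              100 * x$variance_explained[2]))
  invisible(x)
}

scott_bandwidth <- function(coords2d) {
  n <- nrow(coords2d)
  h <- apply(coords2d, 2L, stats::sd) * n^(-1 / 6)
  if (any(h <= 0)) h[h <= 0] <- max(h, 1e-6)
  h
}

#' Packing density of a flatmapped neuron cloud
#'
#' Gaussian-kernel intensity estimate: at a location p,
#' `density(p) = sum_j (2 pi h1 h2)^-1 exp(-dx^2/(2 h1^2) - dy^2/(2 h2^2))`,
#' in neurons per um^2, so the raster integrates to the neuron count.
#' The default bandwidth is Scott's rule per axis (`sd * n^(-1/6)`). A
#' counts-per-bin raster is returned alongside the smoothed one.
#'
#' @param coords2d n x 2 flatmap coordinates (um), `n >= 2`; an
#'   `icns_flatmap` is also accepted.
#' @param bandwidth `"auto"` (Scott) or one/two positive numbers, um.
#' @param raster_n raster resolution per axis.
#' @return Object of class `icns_density`: `point_density` (per neuron,
#'   neurons/um^2), `bandwidth`, `raster` (list `x`, `y`, `z`), `counts`
#'   (same grid, raw per-cell counts), `integral` (raster integral, ~n).
#' @export
packing_density <- function(coords2d, bandwidth = "auto", raster_n = 96L) {
  if (inherits(coords2d, "icns_flatmap")) coords2d <- coords2d$coords2d
  coords2d <- as.matrix(coords2d)
  n <- nrow(coords2d)
  if (n < 2L || ncol(coords2d) != 2L) abort_arg("coords2d must be n x 2, n >= 2")
  h <- if (identical(bandwidth, "auto")) scott_bandwidth(coords2d)
       else rep_len(as.numeric(bandwidth), 2L)
  if (any(!is.finite(h)) || any(h <= 0)) abort_arg("bandwidth must be positive")

  kern_at <- function(qx, qy) {
    # column-chunked so memory stays bounded for large n
    out <- numeric(length(qx))
    step <- max(1L, floor(4e6 / n))
    for (s in seq(1L, length(qx), by = step)) {
      idx <- s:min(s + step - 1L, length(qx))
      E <- exp(-0.5 * (outer(coords2d[, 1], qx[idx], "-") / h[1])^2
               - 0.5 * (outer(coords2d[, 2], qy[idx], "-") / h[2])^2)
      out[idx] <- colSums(E) / (2 * pi * h[1] * h[2])
    }
    out
  }
  pd <- kern_at(coords2d[, 1], coords2d[, 2])

  pad <- 4 * h
  gx <- seq(min(coords2d[, 1]) - pad[1], max(coords2d[, 1]) + pad[1],
            length.out = raster_n)
  gy <- seq(min(coords2d[, 2]) - pad[2], max(coords2d[, 2]) + pad[2],
            length.out = raster_n)
  gz <- matrix(kern_at(rep(gx, raster_n), rep(gy, each = raster_n)), raster_n)
  cell <- diff(gx[1:2]) * diff(gy[1:2])
  cx <- findInterval(coords2d[, 1], gx, all.inside = TRUE)
  cy <- findInterval(coords2d[, 2], gy, all.inside = TRUE)
  counts <- matrix(0L, raster_n, raster_n)
  for (i in seq_len(n)) counts[cx[i], cy[i]] <- counts[cx[i], cy[i]] + 1L
  structure(list(point_density = pd, bandwidth = h,
                 raster = list(x = gx, y = gy, z = gz),
                 counts = counts, integral = sum(gz) * cell),
            class = "icns_density")
}

#' @export
print.icns_density <- function(x, ...) {
  cat(sprintf(
    "Packing density: bandwidth (%.1f, %.1f) um, mean %.3g neurons/um^2, raster integral %.1f\n",
    x$bandwidth[1], x$bandwidth[2], mean(x$point_density), x$integral))
  invisible(x)
}

#' Plot a flatmap coloured by cluster or density
#'
#' @param x an `icns_flatmap`.
#' @param cluster optional integer labels used for colouring.
#' @param density optional `icns_density` whose raster is drawn underneath.
#' @param ... passed to [graphics::plot()].
#' @export
plot.icns_flatmap <- function(x, cluster = NULL, density = NULL, ...) {
  if (!is.null(density)) {
    graphics::image(density$raster$x, density$raster$y, density$raster$z,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "flatmap axis 1 (um)", ylab = "flatmap axis 2 (um)")
    graphics::points(x$coords2d, pch = 20, cex = 0.5,
                     col = if (is.null(cluster)) "grey30"
                           else cluster + 1L)
  } else {
    plot(x$coords2d, pch = 20, asp = 1,
         col = if (is.null(cluster)) "grey30" else cluster + 1L,
         xlab = "flatmap axis 1 (um)", ylab = "flatmap axis 2 (um)", ...)
  }
  invisible(x)
}
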