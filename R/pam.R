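# Partitioning around medoids, written from first principles
# (Kaufman-Rousseeuw BUILD + steepest-descent SWAP), with silhouette widths
# and the randomized-null criterion for choosing the number of clusters.
# Distances are plain 3D Euclidean in um; no scaling.

# labels = index into `medoids` of the nearest medoid; ties resolve to the
# lower medoid index because medoids are kept sorted and which.min takes
# the first minimum.
nearest_two <- function(D, medoids) {
  Dm <- D[, medoids, drop = FALSE]
  j1 <- max.col(-Dm, ties.method = "first")
  d1 <- Dm[cbind(seq_len(nrow(Dm)), j1)]
  if (length(medoids) > 1L) {
    Dm[cbind(seq_len(nrow(Dm)), j1)] <- Inf
    j2 <- max.col(-Dm, ties.method = "first")
    d2 <- Dm[cbind(seq_len(nrow(Dm)), j2)]
  } else d2 <- rep(Inf, nrow(Dm))
  list(j1 = j1, d1 = d1, d2 = d2)
}

#' PAM (k-medoids) clustering of a 3D point cloud
#'
#' Classic partitioning around medoids: the BUILD phase greedily seeds k
#' medoids (the first minimizes total distance to all points; each later one
#' maximizes the cost reduction), then the SWAP phase repeatedly evaluates
#' every (medoid, non-medoid) exchange and applies the single best strictly
#' cost-reducing swap until none remains. Deterministic for a given input
#' order; the total cost is the sum of point-to-assigned-medoid Euclidean
#' distances. Medoid indices are reported sorted increasing and nearest-
#' medoid ties resolve to the lower medoid index.
#'
#' @param points n x 3 numeric matrix of coordinates (um). Duplicated points
#'   are allowed.
#' @param k number of clusters, `1 <= k <= n`.
#' @return Object of class `icns_pam`: `k`, `labels` (integer in 1..k),
#'   `medoid_indices` (increasing), `total_cost` (um).
#' @export
#' @examples
#' pts <- cbind(c(0, 1, 10, 11), 0, 0)
#' pam_medoids(pts, 2)$total_cost  # 2
pam_medoids <- function(points, k) {
  points <- check_points3(points)
  D <- as.matrix(stats::dist(points))
  pam_core(D, k)
}

# PAM on a precomputed distance matrix; shared by pam_medoids() and
# select_k() so the O(n^2) distances are built once per dataset.
pam_core <- function(D, k) {
  n <- nrow(D)
  if (length(k) != 1L || k != round(k) || k < 1 || k > n)
    abort_arg("k must be an integer in 1..n (n = %d)", n)
  k <- as.integer(k)

  dimnames(D) <- NULL
  # BUILD
  medoids <- which.min(colSums(D))
  d1 <- D[, medoids]
  while (length(medoids) < k) {
    gain <- colSums(pmax(d1 - D, 0))
    gain[medoids] <- -Inf
    h <- which.max(gain)
    medoids <- c(medoids, h)
    d1 <- pmin(d1, D[, h])
  }
  medoids <- sort(medoids)

  # SWAP: steepest descent over all (medoid, candidate) exchanges. The
  # exact cost change of every swap is accumulated in O(n^2) per round:
  # for candidate h, removing medoid j,
  #   delta_j(h) = sum_i min(0, D(i,h) - d1_i)                  [i not in j]
  #              + sum_{i in cluster j} (min(D(i,h), d2_i) - d1_i)
  # which splits into a j-independent column sum plus a per-cluster
  # correction (rowsum over each medoid's cluster).
  cost <- sum(nearest_two(D, medoids)$d1)
  repeat {
    nt <- nearest_two(D, medoids)
    shrink <- pmin(D - nt$d1, 0)                 # n x n, recycles by row
    t1 <- colSums(shrink)
    corr <- rowsum(pmin(D, nt$d2) - nt$d1 - shrink, nt$j1)
    delta <- matrix(t1, k, n, byrow = TRUE) + corr
    delta[, medoids] <- Inf
    b <- which.min(delta)                        # deterministic first min
    if (delta[b] >= -1e-12) break
    j_out <- (b - 1L) %% k + 1L
    h_in <- (b - 1L) %/% k + 1L
    medoids[j_out] <- h_in
    medoids <- sort(medoids)
    cost <- cost + delta[b]
  }

  nt <- nearest_two(D, medoids)
  structure(list(k = k, labels = nt$j1, medoid_indices = medoids,
                 total_cost = sum(nt$d1), n = n),
            class = "icns_pam")
}

#' @export
print.icns_pam <- function(x, ...) {
  cat(sprintf("PAM clustering: k = %d, n = %d, total cost %.6g um\n",
              x$k, x$n, x$total_cost))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Silhouette widths of a clustering
#'
#' Kaufman-Rousseeuw silhouettes: `a(i)` is the mean distance of point i to
#' its own cluster (excluding itself), `b(i)` the smallest mean distance to
#' any other cluster, and `s(i) = (b - a) / max(a, b)`. Points in singleton
#' clusters get `s(i) = 0`.
#'
#' @param points n x 3 coordinate matrix (um).
#' @param labels integer cluster labels; at least two distinct clusters.
#' @return List with `widths` (per point, in `[-1, 1]`) and `mean`.
#' @export
silhouette_widths <- function(points, labels) {
  points <- check_points3(points)
  silhouette_core(as.matrix(stats::dist(points)), labels)
}

silhouette_core <- function(D, labels) {
  labels <- as.integer(as.factor(labels))
  n <- nrow(D)
  if (length(labels) != n) abort_arg("labels must match the number of points")
  sizes <- tabulate(labels)
  if (sum(sizes > 0) < 2L)
    abort_arg("silhouette is undefined for a single cluster")
  S <- rowsum(D, labels)                        # cluster x point distance sums
  own <- S[cbind(labels, seq_len(n))]
  a <- ifelse(sizes[labels] > 1L, own / (sizes[labels] - 1L), 0)
  Mean <- S / sizes                             # mean distance to each cluster
  Mean[cbind(labels, seq_len(n))] <- Inf
  b <- apply(Mean, 2L, min)
  s <- ifelse(sizes[labels] == 1L, 0, (b - a) / pmax(a, b))
  s[!is.finite(s)] <- 0                         # a = b = 0 (coincident points)
  list(widths = s, mean = mean(s))
}

#' Randomize a point cloud for the null clustering model
#'
#' Independently permutes each coordinate axis across points. This preserves
#' every marginal distribution (the spatial footprint of the organ) while
#' destroying the association between axes, i.e. the clusters. A uniform
#' resampling over the bounding box is available as a laxer alternative.
#'
#' @param points n x 3 coordinate matrix.
#' @param seed integer seed; reproducible.
#' @param method `"permute"` (default) or `"uniform"` (bounding box).
#' @return An n x 3 matrix of null coordinates.
#' @export
randomize_null <- function(points, seed, method = c("permute", "uniform")) {
  points <- check_points3(points)
  method <- match.arg(method)
  if (nrow(points) < 2L) abort_arg("need at least 2 points")
  with_seed(seed, {
    if (method == "permute")
      apply(points, 2L, sample)
    else
      apply(points, 2L, function(col)
        stats::runif(length(col), min(col), max(col)))
  })
}

#' Choose the number of clusters against a randomized null
#'
#' For every k on the grid, clusters the real data with [pam_medoids()] and
#' records the mean silhouette; clusters `n_null` randomized replicates of
#' the data (same replicates reused across k) the same way; and forms the
#' gap `real - mean(null)` per k. Candidates are the k whose real silhouette
#' is within `epsilon` of the best; among candidates the k with the widest
#' gap wins, ties going to the smaller k. `epsilon` replaces the visual
#' inspection a human would apply to near-equal silhouette curves.
#'
#' @param points n x 3 coordinate matrix (um).
#' @param k_min,k_max inclusive k grid bounds, `2 <= k_min <= k_max < n`.
#' @param n_null number of randomized replicates (default 10).
#' @param seed integer master seed.
#' @param epsilon absolute silhouette tolerance defining the candidate set.
#' @param null_method passed to [randomize_null()].
#' @return Object of class `icns_kselect`: `k_grid`, `real_silhouette`,
#'   `null_silhouettes` (`n_null` x length(k_grid) matrix), `gap`,
#'   `chosen_k`, `seed`, and the per-k `icns_pam` fits in `fits`.
#' @export
select_k <- function(points, k_min = 2L, k_max = 20L, n_null = 10L, seed = 1L,
                     epsilon = 0.01, null_method = "permute") {
  points <- check_points3(points)
  n <- nrow(points)
  if (!(2 <= k_min && k_min <= k_max && k_max < n))
    abort_arg("need 2 <= k_min <= k_max < n")
  seed <- check_seed(seed)
  ks <- seq(as.integer(k_min), as.integer(k_max))
  D_real <- as.matrix(stats::dist(points))
  D_null <- lapply(seq_len(n_null), function(r)
    as.matrix(stats::dist(
      randomize_null(points, derive_seed(seed, paste0("null_", r)),
                     method = null_method))))
  real <- numeric(length(ks))
  nullmat <- matrix(NA_real_, n_null, length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    fits[[i]] <- pam_core(D_real, ks[i])
    real[i] <- silhouette_core(D_real, fits[[i]]$labels)$mean
    for (r in seq_len(n_null)) {
      nf <- pam_core(D_null[[r]], ks[i])
      nullmat[r, i] <- silhouette_core(D_null[[r]], nf$labels)$mean
    }
  }
  gap <- real - colMeans(nullmat)
  cand <- which(real >= max(real) - epsilon)
  chosen <- cand[order(-gap[cand], ks[cand])][1L]
  structure(list(k_grid = ks, real_silhouette = real,
                 null_silhouettes = nullmat, gap = gap,
                 chosen_k = ks[chosen], seed = seed, epsilon = epsilon,
                 fits = fits),
            class = "icns_kselect")
}

#' Labels of the chosen clustering
#' @param x an `icns_kselect`.
#' @return Integer labels from the PAM fit at the chosen k.
#' @export
chosen_labels <- function(x) {
  stopifnot(inherits(x, "icns_kselect"))
  x$fits[[match(x$chosen_k, x$k_grid)]]$labels
}

#' @export
print.icns_kselect <- function(x, ...) {
  cat(sprintf("Cluster-number selection over k = %d..%d (%d null replicates)\n",
              min(x$k_grid), max(x$k_grid), nrow(x$null_silhouettes)))
  cat(sprintf("  chosen k = %d (silhouette %.3f, gap over null %.3f)\n",
              x$chosen_k, x$real_silhouette[match(x$chosen_k, x$k_grid)],
              x$gap[match(x$chosen_k, x$k_grid)]))
  invisible(x)
}

#' @export
plot.icns_kselect <- function(x, ...) {
  nl <- x$null_silhouettes
  ylim <- range(c(x$real_silhouette, nl))
  plot(x$k_grid, x$real_silhouette, type = "b", pch = 19, ylim = ylim,
       xlab = "number of clusters k", ylab = "mean silhouette width", ...)
  graphics::matpoints(x$k_grid, t(nl), pch = 1, col = "grey60")
  graphics::lines(x$k_grid, colMeans(nl), lty = 2, col = "grey40")
  graphics::abline(v = x$chosen_k, lty = 3)
  graphics::legend("topright", c("data", "randomized null"), pch = c(19, 1),
                   col = c("black", "grey60"), bty = "n")
  invisible(x)
}
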