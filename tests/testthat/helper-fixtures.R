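# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

tiny_subject <- function() {
  m <- neuron_markers(
    id = c("a", "b", "c"),
    x = c(0, 100, 200), y = c(0, 50, 100), z = c(10, 10, 15),
    section = c(2L, 2L, 3L),
    soma_short = c(15, 14, NA), soma_long = c(28, 25, NA))
  ct1 <- contour_trace("left_atrium",
                       cbind(c(0, 100, 100, 0), c(0, 0, 100, 100), 10), 2L)
  ct2 <- contour_trace("superior_vena_cava",
                       cbind(c(-50, -20), c(0, 30), 15), 3L, closed = FALSE)
  subject_map("t1", "male", markers = m, contours = list(ct1, ct2))
}

# exhaustive k-medoids optimum over all C(n, k) medoid sets
brute_force_pam_cost <- function(points, k) {
  D <- as.matrix(dist(points))
  n <- nrow(points)
  min(apply(combn(n, k), 2, function(m)
    sum(apply(D[, m, drop = FALSE], 1, min))))
}

# instance with k well-separated gaussian clusters in 3D
clustered_instance <- function(n, k, sep = 100, sd = 1) {
  ctr <- matrix(runif(3 * k, 0, sep), k, 3)
  idx <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
  list(points = ctr[idx, , drop = FALSE] + matrix(rnorm(3 * n, 0, sd), n, 3),
       k = k)
}

# dense xi-grid nearest-distance oracle for scaffold projection
grid_projection_oracle <- function(scaffold, points, res = 200L) {
  xg <- seq(0, 1, length.out = res + 1L)
  uv <- as.matrix(expand.grid(xg, xg))
  best <- rep(Inf, nrow(points))
  max_step <- 0
  for (e in seq_len(nrow(scaffold$elements))) {
    S <- scaffold_evaluate(scaffold, e, uv)
    best <- pmin(best, apply(icnsmap:::cross_dist(points, S), 1, min))
    P <- scaffold$nodes[scaffold$elements[e, ], ]
    diam <- max(dist(P))
    max_step <- max(max_step, diam / res)
  }
  list(distance = best, resolution = max_step)
}

test_template <- function() make_template_heart(8000, c(8, 8))

four_cluster_profile <- function(total = 400)
  sex_profile("male", total_neurons_mean = total, n_clusters_range = c(4L, 4L))
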