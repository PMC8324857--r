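test_that("pam solves the two-pair line instance exactly", {
  pts <- cbind(c(0, 1, 10, 11), 0, 0)
  f <- pam_medoids(pts, 2)
  expect_equal(f$total_cost, 2)
  expect_true(any(f$medoid_indices %in% 1:2) && any(f$medoid_indices %in% 3:4))
  expect_equal(f$labels[1], f$labels[2])
  expect_equal(f$labels[3], f$labels[4])
  expect_equal(f$total_cost, brute_force_pam_cost(pts, 2))
})

test_that("pam with k = n puts every point on its own medoid at zero cost", {
  set.seed(1)
  pts <- matrix(rnorm(15), 5, 3)
  f <- pam_medoids(pts, 5)
  expect_equal(f$total_cost, 0)
  expect_equal(sort(f$medoid_indices), 1:5)
  expect_error(pam_medoids(pts, 6), "k must be")
  expect_error(pam_medoids(pts, 0), "k must be")
})

test_that("pam result invariants hold and cost is independently recomputable", {
  set.seed(2)
  for (i in 1:10) {
    inst <- clustered_instance(sample(10:40, 1), sample(2:4, 1))
    f <- pam_medoids(inst$points, inst$k)
    D <- as.matrix(dist(inst$points))
    # medoids sorted, each medoid labelled as its own cluster
    expect_identical(f$medoid_indices, sort(f$medoid_indices))
    expect_equal(f$labels[f$medoid_indices], seq_len(inst$k))
    # labels are the nearest medoid and cost is the sum of those distances
    dm <- D[, f$medoid_indices, drop = FALSE]
    expect_equal(f$total_cost, sum(dm[cbind(seq_len(nrow(D)), f$labels)]))
    expect_equal(f$total_cost, sum(apply(dm, 1, min)))
  }
})

test_that("pam matches the exhaustive optimum on clustered small instances", {
  set.seed(31)
  for (i in 1:30) {
    inst <- clustered_instance(sample(5:8, 1), sample(2:3, 1))
    f <- pam_medoids(inst$points, inst$k)
    expect_equal(f$total_cost, brute_force_pam_cost(inst$points, inst$k),
                 tolerance = 1e-12)
  }
})

test_that("pam cost agrees exactly with the reference implementation", {
  skip_if_not_installed("cluster")
  set.seed(32)
  for (i in 1:30) {
    n <- sample(4:8, 1); k <- min(sample(1:3, 1), n)
    pts <- cbind(runif(n), runif(n), runif(n)) * 10
    f <- pam_medoids(pts, k)
    ref <- cluster::pam(pts, k)
    ref_cost <- sum(as.matrix(dist(pts))[cbind(seq_len(n), ref$id.med[
      as.integer(ref$clustering)])])
    expect_equal(f$total_cost, ref_cost, tolerance = 1e-9)
  }
})

test_that("silhouettes match the closed form on the four-point instance", {
  pts <- cbind(c(0, 0.1, 10, 10.1), 0, 0)
  s <- silhouette_widths(pts, c(1, 1, 2, 2))
  expected <- c((10.05 - 0.1) / 10.05, (9.95 - 0.1) / 9.95,
                (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05)
  expect_equal(s$widths, expected, tolerance = 1e-9)
  expect_equal(s$mean, mean(expected), tolerance = 1e-9)
})

test_that("silhouette edge cases: coincident clusters, singletons, renaming", {
  two <- rbind(matrix(0, 3, 3), matrix(5, 3, 3))
  s <- silhouette_widths(two, rep(1:2, each = 3))
  expect_equal(s$widths, rep(1, 6))

  with_singleton <- silhouette_widths(cbind(c(0, 1, 50), 0, 0), c(1, 1, 2))
  expect_equal(with_singleton$widths[3], 0)

  set.seed(3)
  pts <- matrix(rnorm(30), 10, 3)
  lab <- rep(1:2, 5)
  expect_equal(silhouette_widths(pts, lab)$widths,
               silhouette_widths(pts, 3 - lab)$widths)
  expect_equal(silhouette_widths(pts, lab)$widths,
               silhouette_widths(pts, c(7, 9)[lab])$widths)
  expect_error(silhouette_widths(pts, rep(1, 10)), "single cluster")
})

test_that("silhouettes agree with the cluster package on random data", {
  skip_if_not_installed("cluster")
  set.seed(4)
  pts <- matrix(rnorm(90), 30, 3)
  lab <- pam_medoids(pts, 3)$labels
  mine <- silhouette_widths(pts, lab)
  ref <- cluster::silhouette(lab, dist(pts))
  expect_equal(mine$widths, as.numeric(ref[, 3]), tolerance = 1e-9)
})

test_that("coordinate randomization permutes each axis independently", {
  set.seed(5)
  pts <- matrix(rnorm(60), 20, 3)
  nul <- randomize_null(pts, 99)
  for (c3 in 1:3) expect_setequal(nul[, c3], pts[, c3])
  expect_false(isTRUE(all.equal(nul, pts)))
  expect_identical(nul, randomize_null(pts, 99))
  two <- randomize_null(pts[1:2, ], 1)
  for (c3 in 1:3) expect_setequal(two[, c3], pts[1:2, c3])
  u <- randomize_null(pts, 7, method = "uniform")
  for (c3 in 1:3) {
    expect_gte(min(u[, c3]), min(pts[, c3]))
    expect_lte(max(u[, c3]), max(pts[, c3]))
  }
})

test_that("randomization destroys cluster structure as seen by silhouettes", {
  set.seed(6)
  worse <- 0L
  inst <- clustered_instance(45, 3, sep = 60, sd = 1)
  real_sil <- silhouette_widths(inst$points,
                                pam_medoids(inst$points, 3)$labels)$mean
  for (s in 1:100) {
    nul <- randomize_null(inst$points, s)
    nul_sil <- silhouette_widths(nul, pam_medoids(nul, 3)$labels)$mean
    if (nul_sil <= real_sil) worse <- worse + 1L
  }
  expect_gte(worse, 95L)
})

test_that("select_k identifies a perfect two-cluster instance and keeps its contract", {
  set.seed(7)
  tight <- rbind(matrix(rnorm(60, sd = 0.1), 20, 3),
                 matrix(rnorm(60, sd = 0.1), 20, 3) + 500)
  rep <- select_k(tight, 2, 6, n_null = 5, seed = 10)
  expect_equal(rep$chosen_k, 2L)
  expect_equal(dim(rep$null_silhouettes), c(5L, 5L))
  expect_true(rep$chosen_k %in% rep$k_grid)
  # chosen k maximizes the gap within the near-max silhouette candidate set
  cand <- which(rep$real_silhouette >= max(rep$real_silhouette) - rep$epsilon)
  expect_equal(rep$gap[match(rep$chosen_k, rep$k_grid)], max(rep$gap[cand]))
  expect_error(select_k(tight, 1, 6), "k_min")
  # labels of the chosen fit are exposed
  expect_length(chosen_labels(rep), 40L)
})
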