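flat_unit_scaffold <- function() {
  # a 2 x 2 flat scaffold over [0, 2]^2 in the z = 0 plane, built by hand
  sc <- make_generic_scaffold(8000, c(2, 2))
  g <- expand.grid(x = 0:2, y = 0:2)
  sc$nodes <- cbind(g$x, g$y, 0)
  sc
}

test_that("generic scaffold has the documented structured topology", {
  sc <- make_generic_scaffold(8000, c(8, 8))
  expect_equal(nrow(sc$elements), 64L)
  expect_equal(nrow(sc$nodes), 81L)
  expect_identical(sc$nodes, make_generic_scaffold(8000, c(8, 8))$nodes)
  # evaluating element corners returns the corner nodes themselves
  for (e in c(1L, 30L, 64L)) {
    corners <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
    got <- scaffold_evaluate(sc, e, corners)
    expect_equal(got, sc$nodes[sc$elements[e, ], ], tolerance = 1e-12)
  }
})

test_that("bilinear evaluation matches the shape-function oracle", {
  sc <- flat_unit_scaffold()
  expect_equal(as.numeric(scaffold_evaluate(sc, 1L, c(0, 0))),
               c(0, 0, 0))
  expect_equal(as.numeric(scaffold_evaluate(sc, 1L, c(0.5, 0.5))),
               c(0.5, 0.5, 0))
  set.seed(1)
  sc2 <- make_generic_scaffold(8000, c(4, 4))
  for (i in 1:20) {
    e <- sample(nrow(sc2$elements), 1)
    xi <- runif(2)
    P <- sc2$nodes[sc2$elements[e, ], ]
    phi <- c((1 - xi[1]) * (1 - xi[2]), xi[1] * (1 - xi[2]),
             xi[1] * xi[2], (1 - xi[1]) * xi[2])
    expect_equal(as.numeric(scaffold_evaluate(sc2, e, xi)),
                 as.numeric(phi %*% P), tolerance = 1e-12)
  }
  expect_error(scaffold_evaluate(sc2, 999L, c(0.5, 0.5)), "invalid element")
})

test_that("projection finds exact feet for on-surface and overhead points", {
  sc <- flat_unit_scaffold()
  on <- project_point(sc, c(0.3, 0.4, 0))
  expect_equal(on$distance, 0, tolerance = 1e-9)
  over <- project_point(sc, c(0.5, 0.5, 1))
  expect_equal(over$element_id, 1L)
  expect_equal(c(over$xi1, over$xi2), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(over$distance, 1, tolerance = 1e-12)
  # surface points on the curved scaffold project to themselves
  sc2 <- make_generic_scaffold(8000, c(6, 6))
  set.seed(2)
  xi <- cbind(runif(25), runif(25))
  el <- sample(nrow(sc2$elements), 25, replace = TRUE)
  pts <- scaffold_evaluate(sc2, el, xi)
  pr <- project_points(sc2, pts)
  expect_lt(max(pr$distance), 1e-6)
  feet <- scaffold_evaluate(sc2, pr$element_id, cbind(pr$xi1, pr$xi2))
  expect_equal(feet, pts, tolerance = 1e-6)
})

test_that("projection agrees with a dense local-coordinate grid search", {
  sc <- make_generic_scaffold(8000, c(4, 4))
  set.seed(3)
  q <- cbind(runif(25, -5000, 5000), runif(25, -4000, 4000),
             runif(25, -500, 4000))
  pr <- project_points(sc, q)
  oracle <- grid_projection_oracle(sc, q, res = 120L)
  expect_true(all(abs(pr$distance - oracle$distance) <= oracle$resolution))
})

test_that("fitting the generic surface to its own nodes is a fixed point", {
  sc <- make_generic_scaffold(8000, c(4, 4))
  fit <- fit_scaffold(sc, sc$nodes, lambda_smooth = 0, max_iters = 2)
  expect_lt(fit$rms, 1e-8)
  expect_equal(fit$scaffold$nodes, sc$nodes, tolerance = 1e-8)
})

test_that("a translated dataset is recovered exactly by one linear solve", {
  sc <- make_generic_scaffold(8000, c(4, 4))
  set.seed(4)
  n <- 5L * nrow(sc$elements)
  el <- rep(seq_len(nrow(sc$elements)), each = 5L)
  xi <- cbind(runif(n), runif(n))
  t_vec <- c(700, -300, 450)
  data <- scaffold_evaluate(sc, el, xi) +
    matrix(t_vec, n, 3, byrow = TRUE)
  fit <- fit_scaffold(sc, data, lambda_smooth = 0, max_iters = 1,
                      xi0 = list(element_id = el, xi1 = xi[, 1], xi2 = xi[, 2]))
  expect_equal(fit$scaffold$nodes,
               sc$nodes + matrix(t_vec, nrow(sc$nodes), 3, byrow = TRUE),
               tolerance = 1e-6)
  # and the translation leaves the anchored membrane penalty at zero,
  # so a smoothed fit recovers it too
  fit2 <- fit_scaffold(sc, data, lambda_smooth = 0.05, max_iters = 1,
                       xi0 = list(element_id = el, xi1 = xi[, 1], xi2 = xi[, 2]))
  expect_equal(fit2$scaffold$nodes, fit$scaffold$nodes, tolerance = 1e-6)
})

test_that("unconstrained nodes with no smoothing raise an instructive error", {
  sc <- make_generic_scaffold(8000, c(4, 4))
  few <- sc$nodes[1:4, , drop = FALSE]   # constrains one corner only
  expect_error(fit_scaffold(sc, few, lambda_smooth = 0),
               "lambda_smooth > 0")
})

test_that("embedding is one-to-one and round-trips through evaluation", {
  th <- test_template()
  gen <- synth_subject(th, four_cluster_profile(80), 15, warp_amplitude = 0,
                       contour_step = 80L)
  sc <- make_generic_scaffold(8000, c(6, 6))
  emb <- embed_markers(sc, gen$subject$markers)
  expect_equal(nrow(emb), nrow(gen$subject$markers))
  expect_equal(emb$marker_id, gen$subject$markers$id)
  expect_true(all(emb$projection_distance >= 0))
  feet <- scaffold_evaluate(sc, emb$element_id, cbind(emb$xi1, emb$xi2))
  d <- sqrt(rowSums((feet - as.matrix(
    gen$subject$markers[, c("x", "y", "z")]))^2))
  expect_equal(d, emb$projection_distance, tolerance = 1e-6)
  # transfer onto the same scaffold reproduces the feet, with xi untouched
  tg <- transfer_to_generic(emb, sc)
  expect_equal(tg, feet, tolerance = 1e-12)
  other <- make_generic_scaffold(8000, c(5, 5))
  expect_error(transfer_to_generic(emb, other), "topology mismatch")
})

test_that("overlap maps equal an independent histogram-intersection oracle", {
  sc <- make_generic_scaffold(8000, c(4, 4))
  set.seed(6)
  mk <- function(n) data.frame(
    element_id = sample(nrow(sc$elements), n, replace = TRUE),
    xi1 = runif(n), xi2 = runif(n))
  a <- mk(300); b <- mk(200)
  ov <- overlap_map(a, b, sc, subgrid = 2L)
  # oracle: factor-based histogram intersection
  key <- function(e, x1, x2)
    paste(e, pmin(floor(x1 * 2), 1), pmin(floor(x2 * 2), 1))
  ka <- table(key(a$element_id, a$xi1, a$xi2)) / nrow(a)
  kb <- table(key(b$element_id, b$xi1, b$xi2)) / nrow(b)
  common <- intersect(names(ka), names(kb))
  expect_equal(ov$global_overlap,
               sum(pmin(ka[common], kb[common])), tolerance = 1e-12)
  expect_equal(ov$jaccard_occupied,
               length(common) / length(union(names(ka), names(kb))),
               tolerance = 1e-12)
  # symmetry, identity, disjointness
  expect_equal(overlap_map(b, a, sc)$global_overlap, ov$global_overlap)
  expect_equal(overlap_map(a, a, sc)$global_overlap, 1)
  expect_equal(overlap_map(a, a, sc)$jaccard_occupied, 1)
  dis <- overlap_map(data.frame(element_id = 1L, xi1 = 0.1, xi2 = 0.1),
                     data.frame(element_id = 2L, xi1 = 0.1, xi2 = 0.1), sc)
  expect_equal(dis$global_overlap, 0)
  expect_error(overlap_map(a[0, ], b, sc), "non-empty")
})

test_that("fit RMS is non-increasing across correspondence rounds", {
  th <- test_template()
  gen <- synth_subject(th, four_cluster_profile(60), 17, warp_amplitude = 300,
                       contour_step = 60L)
  sc <- make_generic_scaffold(8000, c(6, 6))
  fit <- fit_scaffold(sc, contour_points(gen$subject, 800), max_iters = 5)
  expect_true(all(diff(fit$rms_history) <= 1e-6))
})
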