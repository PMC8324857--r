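square_contour <- function(z = 0, side = 1000, name = "left_atrium") {
  contour_trace(name, cbind(c(0, side, side, 0), c(0, 0, side, side), z), 0L)
}

test_that("point-to-structure distance handles vertices and perpendiculars", {
  s <- subject_map("d", markers = neuron_markers(character(), numeric(),
                                                 numeric(), numeric()),
                   contours = list(square_contour()))
  expect_equal(distance_to_structure(c(0, 0, 0), s, "left_atrium"), 0)
  # perpendicular offset from the bottom edge
  expect_equal(distance_to_structure(c(500, -120, 0), s, "left_atrium"), 120)
  # off-plane component counts in 3D
  expect_equal(distance_to_structure(c(500, 0, 50), s, "left_atrium"), 50)
  expect_error(distance_to_structure(c(0, 0, 0), s, "aorta"), "no contours")
})

test_that("distances agree with a densely resampled brute-force oracle", {
  set.seed(8)
  th <- test_template()
  cts <- slice_contours(th, thickness = 400)
  la <- Filter(function(ct) ct$structure_name == "left_atrium", cts)
  s <- subject_map("d", contours = la)
  q <- cbind(runif(20, -4000, 4000), runif(20, -3000, 3000), runif(20, 0, 3000))
  mine <- distance_to_structure(q, s, "left_atrium")
  # oracle: resample every segment at a fine step, take nearest sample
  step <- 5
  samples <- do.call(rbind, lapply(la, function(ct) {
    P <- if (ct$closed) rbind(ct$points, ct$points[1, ]) else ct$points
    do.call(rbind, lapply(seq_len(nrow(P) - 1), function(i) {
      t <- seq(0, 1, length.out = max(2, ceiling(
        sqrt(sum((P[i + 1, ] - P[i, ])^2)) / step)))
      cbind(P[i, 1] + t * (P[i + 1, 1] - P[i, 1]),
            P[i, 2] + t * (P[i + 1, 2] - P[i, 2]),
            P[i, 3] + t * (P[i + 1, 3] - P[i, 3]))
    }))
  }))
  oracle <- apply(icnsmap:::cross_dist(q, samples), 1, min)
  expect_true(all(abs(mine - oracle) <= step / 2 + 1e-9))
  expect_true(all(mine <= oracle + 1e-9))
})

test_that("proximity labels behave at radius extremes and are monotone", {
  th <- test_template()
  gen <- synth_subject(th, four_cluster_profile(150), 5, warp_amplitude = 0,
                       contour_step = 60L)
  sub <- gen$subject
  huge <- assign_proximity(sub, roi_definition("posterior_left_atrium",
                                               "left_atrium", radius = 1e9))
  expect_true(all(huge))
  tiny <- assign_proximity(sub, roi_definition("posterior_left_atrium",
                                               "left_atrium", radius = 1e-9))
  expect_false(any(tiny))
  r1 <- assign_proximity(sub, roi_definition("posterior_left_atrium",
                                             "left_atrium", radius = 300))
  r2 <- assign_proximity(sub, roi_definition("posterior_left_atrium",
                                             "left_atrium", radius = 900))
  expect_true(all(r2[r1]))  # proximal at 300 um stays proximal at 900 um
  expect_error(
    assign_proximity(sub, roi_definition("pv_hilum", "coronary_artery", 500)),
    "coronary_artery")
})

test_that("planted hilum clusters are proximal to the pulmonary-vein ROI", {
  th <- test_template()
  gen <- synth_subject(th, four_cluster_profile(300), 9, warp_amplitude = 0,
                       contour_step = 20L)
  sub <- gen$subject
  prox <- assign_proximity(sub, default_rois()$pv_hilum)
  hilum <- gen$truth$true_cluster == 1L  # cluster 1 is planted at pv_hilum
  expect_gte(mean(prox[hilum]), 0.95)
})

test_that("ROI tables count every neuron once per region", {
  th <- test_template()
  gen <- synth_subject(th, four_cluster_profile(120), 6, warp_amplitude = 0,
                       contour_step = 60L)
  sub <- gen$subject
  all_roi <- list(everything = roi_definition("posterior_left_atrium",
                                              "left_atrium", radius = 1e9))
  tab <- roi_counts(list(sub), all_roi)
  expect_equal(tab$counts$everything_count, nrow(sub$markers))
  expect_equal(tab$counts$everything_fraction, 1)

  empty <- subject_map("empty", contours = sub$contours)
  tab0 <- roi_counts(list(empty), default_rois())
  expect_true(all(tab0$counts[, grep("_count$", names(tab0$counts))] == 0))

  full <- roi_counts(list(sub), default_rois())
  expect_lte(full$counts$any_roi, nrow(sub$markers))
  for (rn in roi_names())
    expect_lte(full$counts[[paste0(rn, "_count")]], nrow(sub$markers))
})

test_that("each planted cluster is associated with its planting ROI", {
  # association = more than half the cluster's members proximal to the ROI;
  # overlapping ROIs mean one cluster may associate with several regions
  th <- test_template()
  gen <- synth_subject(th, four_cluster_profile(400), 13, warp_amplitude = 0,
                       contour_step = 20L)
  sub <- gen$subject
  rois <- default_rois()
  planted <- c("pv_hilum", "svc_ra_root", "left_av_sulcus",
               "anterior_interatrial_sulcus")
  for (k in 1:4) {
    prox <- assign_proximity(sub, rois[[planted[k]]])
    expect_gt(mean(prox[gen$truth$true_cluster == k]), 0.5)
  }
  # the tabulated majority ROI is a genuinely associated one
  sub$markers$cluster <- gen$truth$true_cluster
  sub$markers <- sub$markers[sub$markers$cluster > 0, ]
  tab <- roi_counts(list(sub), rois)
  expect_true(all(tab$cluster_roi$majority_fraction > 0.5))
})

test_that("ROI definitions round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    list(name = "pv_hilum", structures = list("pulmonary_vein_left"),
         radius = 350, mode = "any"),
    list(name = "anterior_interatrial_sulcus",
         structures = list("left_atrium", "right_atrium"), mode = "all")), f)
  defs <- read_rois_yaml(f)
  expect_equal(defs$pv_hilum$radius, 350)
  expect_equal(defs$anterior_interatrial_sulcus$mode, "all")
  expect_equal(defs$anterior_interatrial_sulcus$radius, 500)
})
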