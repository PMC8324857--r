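# Synthetic ICNS generation: sex profiles, ROI-anchored neuron clusters,
# per-subject deformation, and assembly into complete subject maps.

#' Sex-specific generation profile
#'
#' Encodes the study conditions the generator emulates: mean mapped-neuron
#' totals of 2845 (male, consistent across hearts, range 2676-2973) and 1581
#' (female), a smaller number of large distinct clusters with lower packing
#' density in females, and cluster counts bracketing the 12 groups observed
#' in a male heart. The female `density_scale < 1` widens the effective
#' cluster spread (`cluster_spread / sqrt(density_scale)`), lowering local
#' packing density.
#'
#' @param sex `"male"` or `"female"`.
#' @param ... overrides for any profile field (`total_neurons_mean`,
#'   `total_neurons_cv`, `n_clusters_range`, `cluster_spread` (um),
#'   `background_fraction`, `density_scale`).
#' @return A list of class `icns_profile`.
#' @export
#' @examples
#' sex_profile("female")
#' sex_profile("male", total_neurons_mean = 200, n_clusters_range = c(4, 4))
sex_profile <- function(sex = c("male", "female"), ...) {
  sex <- match.arg(sex)
  p <- if (sex == "male") {
    list(label = "male", total_neurons_mean = 2845, total_neurons_cv = 0.05,
         n_clusters_range = c(8L, 12L), cluster_spread = 250,
         background_fraction = 0.05, density_scale = 1.0)
  } else {
    list(label = "female", total_neurons_mean = 1581, total_neurons_cv = 0.08,
         n_clusters_range = c(4L, 8L), cluster_spread = 250,
         background_fraction = 0.05, density_scale = 0.5)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) abort_arg("unknown profile field(s): %s", paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (p$total_neurons_mean <= 0) abort_arg("total_neurons_mean must be > 0")
  if (p$background_fraction < 0 || p$background_fraction >= 1)
    abort_arg("background_fraction must be in [0, 1)")
  class(p) <- "icns_profile"
  p
}

#' Read / write a generation profile as YAML
#' @param path YAML file path.
#' @return [read_profile()] returns an `icns_profile`;
#'   [write_profile()] returns `path` invisibly.
#' @export
read_profile <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(sex_profile, c(list(sex = y$label), y[setdiff(names(y), "label")]))
}

#' @rdname read_profile
#' @param profile an `icns_profile`.
#' @export
write_profile <- function(profile, path) {
  yaml::write_yaml(unclass(profile), path)
  invisible(path)
}

effective_spread <- function(profile) {
  profile$cluster_spread / sqrt(profile$density_scale)
}

# Choose cluster centres in (u,v): the four paper ROIs always receive one
# cluster each, the fifth goes to the posterior left atrium, and any
# additional centres are rejection-sampled to keep >= 4x effective spread
# 3D separation from all earlier centres (so the planted k is recoverable).
place_cluster_centres <- function(template, n_clusters, min_sep) {
  anchors <- template$roi_anchors
  ord <- c("pv_hilum", "svc_ra_root", "left_av_sulcus",
           "anterior_interatrial_sulcus", "posterior_left_atrium")
  uv <- anchors[ord[seq_len(min(n_clusters, 5L))], , drop = FALSE]
  names_out <- rownames(uv)
  while (nrow(uv) < n_clusters) {
    for (try in seq_len(400L)) {
      cand <- c(stats::runif(1, 0.08, 0.92), stats::runif(1, 0.08, 0.92))
      d <- cross_dist(template$surface(cand[1], cand[2]),
                      template$surface(uv[, 1], uv[, 2]))
      if (min(d) >= min_sep) break
      cand <- NULL
    }
    if (is.null(cand)) break   # surface saturated; accept fewer clusters
    uv <- rbind(uv, cand)
    names_out <- c(names_out, sprintf("free_%d", nrow(uv)))
  }
  rownames(uv) <- names_out
  uv
}

#' Sample a synthetic ICNS neuron cloud on a template heart
#'
#' Draws a cluster count from the profile's range, anchors clusters at the
#' region-of-interest anchors (the four ROIs always receive a cluster),
#' distributes the subject total multinomially across clusters, places each
#' neuron at its cluster centre plus a tangent-plane Gaussian offset of sd
#' `cluster_spread / sqrt(density_scale)` and a small (15 um sd) normal
#' offset, scatters `background_fraction` of neurons uniformly over the
#' surface, and draws soma axes from lognormals (medians 16 and 28 um) that
#' straddle the 13 x 23 um inclusion criterion so roughly 97% pass.
#'
#' @param template an `icns_template`.
#' @param profile an `icns_profile`.
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @param section_thickness um, for marker section indices.
#' @return List with `markers` (an `icns_markers` data.frame) and `truth`
#'   (per-marker `true_cluster` — 0 denotes background — and `roi`, plus the
#'   cluster centre table).
#' @export
sample_icns <- function(template, profile, seed, section_thickness = 5) {
  seed <- check_seed(seed)
  if (!inherits(profile, "icns_profile")) abort_arg("profile must be an icns_profile")
  with_seed(seed, {
    kr <- as.integer(profile$n_clusters_range)
    k <- if (kr[1] == kr[2]) kr[1] else sample(seq(kr[1], kr[2]), 1L)
    sd_eff <- effective_spread(profile)
    centres <- place_cluster_centres(template, k, 4 * sd_eff)
    k <- nrow(centres)
    total <- max(k, round(stats::rnorm(
      1, profile$total_neurons_mean,
      profile$total_neurons_cv * profile$total_neurons_mean)))
    n_bg <- round(profile$background_fraction * total)
    n_cl <- total - n_bg
    w <- stats::rgamma(k, shape = 4)
    sizes <- as.vector(stats::rmultinom(1, n_cl, w / sum(w)))

    frame <- surface_frame(template, centres[, 1], centres[, 2])
    cpts <- template$surface(centres[, 1], centres[, 2])
    pos <- matrix(0, 0, 3); lab <- integer(0)
    for (i in seq_len(k)) {
      ni <- sizes[i]
      if (!ni) next
      off <- stats::rnorm(ni, 0, sd_eff) %o% frame$e1[i, ] +
        stats::rnorm(ni, 0, sd_eff) %o% frame$e2[i, ] +
        stats::rnorm(ni, 0, 15) %o% frame$normal[i, ]
      pos <- rbind(pos, sweep(off, 2, cpts[i, ], "+"))
      lab <- c(lab, rep(i, ni))
    }
    if (n_bg) {
      ub <- stats::runif(n_bg); vb <- stats::runif(n_bg)
      pos <- rbind(pos, template$surface(ub, vb) +
                     stats::rnorm(n_bg, 0, 15) %o% c(0, 0, 1))
      lab <- c(lab, rep(0L, n_bg))
    }
    short <- stats::rlnorm(nrow(pos), log(16), 0.095)
    long <- pmax(short, stats::rlnorm(nrow(pos), log(28), 0.09))
    sec <- pmax(0L, as.integer(round(pos[, 3] / section_thickness)))
    markers <- neuron_markers(
      id = sprintf("n%05d", seq_len(nrow(pos))),
      x = pos[, 1], y = pos[, 2], z = pos[, 3], section = sec,
      soma_short = short, soma_long = long)
    roi_of <- c(rownames(centres), "background")[ifelse(lab == 0L, k + 1L, lab)]
    roi_of[!roi_of %in% roi_names()] <- NA_character_
    list(markers = markers,
         truth = list(true_cluster = lab, roi = roi_of,
                      centres = cbind(centres, cpts),
                      n_clusters = k, sizes = sizes, seed = seed))
  })
}

#' Deform a template and its markers into one synthetic subject
#'
#' Applies a mild affine map (isotropic scale drawn from 0.9-1.1, rotation
#' about z of up to 5 degrees) followed by a low-frequency sinusoidal
#' displacement field with one spatial period across the organ and total
#' amplitude bounded by `warp_amplitude`, identically to the surface and the
#' markers. Amplitude 0 yields the identity map. The subject is finally
#' shifted so all z stay non-negative, and marker section indices are
#' recomputed.
#'
#' @param template an `icns_template`.
#' @param markers an `icns_markers` data.frame on that template.
#' @param warp_amplitude maximum sinusoidal displacement, um, >= 0.
#' @param seed integer seed.
#' @param subject_id,sex,section_thickness subject metadata.
#' @return List with `subject` (an `icns_subject`, contours not yet traced),
#'   `template` (the deformed `icns_template`), and `warp` (parameters).
#' @export
deform_subject <- function(template, markers, warp_amplitude = 300, seed = 1,
                           subject_id = "synthetic", sex = "unknown",
                           section_thickness = 5) {
  check_scalar_number(warp_amplitude, "warp_amplitude", nonneg = TRUE)
  seed <- check_seed(seed)
  ext <- template$extent
  warp <- with_seed(seed, {
    if (warp_amplitude == 0) {
      list(identity = TRUE, amplitude = 0)
    } else {
      th <- stats::runif(1, -5, 5) * pi / 180
      list(identity = FALSE, amplitude = warp_amplitude,
           scale = stats::runif(1, 0.9, 1.1), theta = th,
           dirs = matrix(stats::rnorm(9), 3, 3),
           phases = stats::runif(3, 0, 2 * pi))
    }
  })
  if (!warp$identity)
    warp$dirs <- warp$dirs / sqrt(rowSums(warp$dirs^2))
  warp_fun <- function(P) {
    if (warp$identity) return(P)
    R <- matrix(c(cos(warp$theta), sin(warp$theta), 0,
                  -sin(warp$theta), cos(warp$theta), 0, 0, 0, 1), 3, 3)
    Q <- warp$scale * (P %*% R)
    amp <- warp$amplitude / sqrt(3)
    for (c3 in 1:3)
      Q[, c3] <- Q[, c3] + amp * sin(2 * pi * (P %*% warp$dirs[c3, ]) / ext +
                                       warp$phases[c3])
    Q
  }
  base_surface <- template$surface
  warped <- template
  warped$surface <- function(u, v) warp_fun(base_surface(u, v))
  pos <- warp_fun(marker_xyz(markers))
  warped$nodes <- warp_fun(template$nodes)
  # keep the sheet in z >= 0 after rotation/displacement
  dz <- max(0, -min(warped$nodes[, 3], pos[, 3], 0))
  if (dz > 0) {
    prev <- warped$surface
    warped$surface <- function(u, v) {
      P <- prev(u, v); P[, 3] <- P[, 3] + dz; P
    }
    pos[, 3] <- pos[, 3] + dz
    warped$nodes[, 3] <- warped$nodes[, 3] + dz
  }
  warp$z_shift <- if (dz > 0) dz else 0
  warped$warp <- warp
  m <- markers
  m$x <- pos[, 1]; m$y <- pos[, 2]; m$z <- pos[, 3]
  m$section <- pmax(0L, as.integer(round(m$z / section_thickness)))
  subj <- subject_map(subject_id, sex = sex, markers = m,
                      section_thickness = section_thickness)
  list(subject = subj, template = warped, warp = warp)
}

#' Generate one complete synthetic subject
#'
#' Convenience wrapper: samples a neuron cloud on the template, deforms it
#' into an individual, slices the deformed surface into anatomical contours,
#' and assembles the `icns_subject`. All randomness derives from `seed`.
#'
#' @inheritParams sample_icns
#' @inheritParams deform_subject
#' @param contour_step trace every `contour_step`-th section (see
#'   [slice_contours()]).
#' @return List: `subject` (complete `icns_subject`), `truth` (ground truth
#'   incl. warp parameters), `template` (the deformed surface).
#' @export
synth_subject <- function(template, profile, seed, subject_id = NULL,
                          warp_amplitude = 300, section_thickness = 5,
                          contour_step = 40L) {
  seed <- check_seed(seed)
  if (is.null(subject_id))
    subject_id <- sprintf("%s_%d", profile$label, seed)
  smp <- sample_icns(template, profile, derive_seed(seed, "sample_icns"),
                     section_thickness = section_thickness)
  def <- deform_subject(template, smp$markers, warp_amplitude,
                        derive_seed(seed, "deform_subject"),
                        subject_id = subject_id, sex = profile$label,
                        section_thickness = section_thickness)
  subj <- def$subject
  subj$contours <- slice_contours(def$template, thickness = section_thickness,
                                  step = contour_step)
  truth <- smp$truth
  truth$warp <- def$warp
  list(subject = subj, truth = truth, template = def$template)
}

#' Write ground truth as a JSON sidecar
#' @param truth a ground-truth list from [synth_subject()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  truth$centres <- as.data.frame(truth$centres)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
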