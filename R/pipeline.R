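# End-to-end orchestration: synthesize or load subjects, filter, cluster,
# flatmap, ROI-associate, register on the scaffold, and report. All
# randomness flows from the config's master seed through derive_seed()
# (stage name hashed with the master seed), so a config + seed pair pins
# the whole report.

#' Build a pipeline run configuration
#'
#' Either `input_paths` (annotation XML files) or a synthetic recipe
#' (`profiles`, a list of [sex_profile()]s, one subject generated per
#' entry) must be given.
#'
#' @param input_paths character vector of subject XML files, or `NULL`.
#' @param profiles list of `icns_profile`s for synthetic subjects.
#' @param seed master integer seed.
#' @param k_min,k_max,n_null cluster-number search grid and null count.
#' @param cluster_subsample cluster-number selection runs on at most this
#'   many markers (seeded subsample) to keep the O(n^2) silhouette work
#'   bounded; labels for the full set come from the nearest chosen medoid.
#' @param roi_radius proximity threshold, um.
#' @param scaffold_grid integer `c(nu, nv)` for fitting.
#' @param lambda_smooth membrane penalty for [fit_scaffold()].
#' @param warp_amplitude synthetic per-subject deformation, um.
#' @param extent template extent, um.
#' @param out_dir optional directory for JSON/CSV artifacts.
#' @return A list of class `icns_config`.
#' @export
run_config <- function(input_paths = NULL,
                       profiles = list(sex_profile("male"), sex_profile("male")),
                       seed = 1L, k_min = 2L, k_max = 20L, n_null = 10L,
                       cluster_subsample = 600L, roi_radius = 500,
                       scaffold_grid = c(10L, 10L), lambda_smooth = 0.05,
                       warp_amplitude = 300, extent = 8000, out_dir = NULL) {
  if (!is.null(input_paths)) {
    missing <- input_paths[!file.exists(input_paths)]
    if (length(missing))
      abort_arg("input file(s) not found: %s", paste(missing, collapse = ", "))
  }
  seed <- check_seed(seed)
  structure(as.list(environment()), class = "icns_config")
}

cluster_subject <- function(subject, cfg, seed) {
  pts <- marker_xyz(subject$markers)
  n <- nrow(pts)
  idx <- if (n > cfg$cluster_subsample)
    with_seed(derive_seed(seed, "cluster_subsample"),
              sort(sample.int(n, cfg$cluster_subsample)))
  else seq_len(n)
  sel <- select_k(pts[idx, , drop = FALSE], cfg$k_min,
                  min(cfg$k_max, length(idx) - 1L), cfg$n_null,
                  derive_seed(seed, "select_k"))
  fit <- sel$fits[[match(sel$chosen_k, sel$k_grid)]]
  med <- pts[idx[fit$medoid_indices], , drop = FALSE]
  labels <- max.col(-cross_dist(pts, med), ties.method = "first")
  list(selection = sel, labels = labels)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or synthesize subjects; soma-size inclusion
#' filter; PAM cluster-number selection and labelling; PCA flatmap and
#' packing density; ROI association; scaffold fit, marker embedding and
#' transfer to the generic scaffold; cross-subject overlap between the
#' first two subjects. Identical config and seed reproduce the report
#' exactly. If a stage fails its error is recorded in the report and later
#' stages that depend on it are skipped; earlier results are kept.
#'
#' @param config an [run_config()] object.
#' @return Object of class `icns_report`: per-subject results
#'   (`subjects`), the overlap (`overlap`), a summary data.frame
#'   (`summary`), the echoed config, and `failed` (named stage errors).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "icns_config"))
  cfg <- config
  seed <- cfg$seed
  failed <- list()
  truths <- list()

  if (!is.null(cfg$input_paths)) {
    subjects <- lapply(cfg$input_paths, read_subject)
  } else {
    template <- make_template_heart(cfg$extent)
    gen <- lapply(seq_along(cfg$profiles), function(i) {
      synth_subject(template, cfg$profiles[[i]],
                    derive_seed(seed, paste0("subject_", i)),
                    warp_amplitude = cfg$warp_amplitude)
    })
    subjects <- lapply(gen, `[[`, "subject")
    truths <- lapply(gen, `[[`, "truth")
  }

  res <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    s$markers <- apply_inclusion_filter(s$markers)
    r <- list(subject_id = s$subject_id, sex = s$sex,
              n_markers = nrow(s$markers))
    r$clustering <- tryCatch(
      cluster_subject(s, cfg, derive_seed(seed, paste0("cluster_", i))),
      error = function(e) { failed[[paste0("cluster_", i)]] <<- conditionMessage(e); NULL })
    if (!is.null(r$clustering))
      s$markers$cluster <- r$clustering$labels
    r$flatmap <- tryCatch({
      fm <- pca_flatmap(marker_xyz(s$markers))
      list(flatmap = fm, density = packing_density(fm))
    }, error = function(e) { failed[[paste0("flatmap_", i)]] <<- conditionMessage(e); NULL })
    s <- tryCatch(assign_all_rois(s, default_rois(cfg$roi_radius)),
                  error = function(e) { failed[[paste0("roi_", i)]] <<- conditionMessage(e); s })
    r$subject <- s
    res[[i]] <- r
  }
  subjects <- lapply(res, `[[`, "subject")

  roi_table <- tryCatch(roi_counts(subjects, default_rois(cfg$roi_radius)),
                        error = function(e) { failed$roi_table <- conditionMessage(e); NULL })

  generic <- make_generic_scaffold(cfg$extent, cfg$scaffold_grid)
  for (i in seq_along(subjects)) {
    res[[i]]$registration <- tryCatch({
      fit <- fit_scaffold(generic, contour_points(subjects[[i]]),
                          lambda_smooth = cfg$lambda_smooth)
      emb <- embed_markers(fit, subjects[[i]]$markers)
      list(fit_rms = fit$rms, embedding = emb,
           on_generic = transfer_to_generic(emb, generic))
    }, error = function(e) { failed[[paste0("scaffold_", i)]] <<- conditionMessage(e); NULL })
  }
  overlap <- if (length(res) >= 2L && !is.null(res[[1]]$registration) &&
                 !is.null(res[[2]]$registration)) {
    tryCatch(overlap_map(res[[1]]$registration$embedding,
                         res[[2]]$registration$embedding, generic),
             error = function(e) { failed$overlap <- conditionMessage(e); NULL })
  } else NULL

  summary_df <- do.call(rbind, lapply(res, function(r) data.frame(
    subject = r$subject_id, sex = r$sex, n_neurons = r$n_markers,
    chosen_k = if (!is.null(r$clustering)) r$clustering$selection$chosen_k else NA,
    mean_silhouette = if (!is.null(r$clustering))
      r$clustering$selection$real_silhouette[
        match(r$clustering$selection$chosen_k,
              r$clustering$selection$k_grid)] else NA,
    mean_density = if (!is.null(r$flatmap))
      mean(r$flatmap$density$point_density) else NA,
    fit_rms = if (!is.null(r$registration)) r$registration$fit_rms else NA)))

  report <- structure(list(
    subjects = res, roi_table = roi_table, overlap = overlap,
    summary = summary_df, truths = truths, config = cfg, failed = failed),
    class = "icns_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.icns_report <- function(x, ...) {
  cat("ICNS pipeline report\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$overlap)) print(x$overlap)
  if (length(x$failed))
    cat("failed stages:", paste(names(x$failed), collapse = ", "), "\n")
  invisible(x)
}

#' Write report artifacts to a directory
#' @param report an `icns_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$roi_table))
    utils::write.csv(report$roi_table$counts, file.path(dir, "roi_counts.csv"),
                     row.names = FALSE)
  for (r in report$subjects)
    write_markers_csv(r$subject$markers,
                      file.path(dir, paste0(r$subject_id, "_markers.csv")))
  head_json <- list(
    seed = report$config$seed,
    summary = report$summary,
    global_overlap = if (!is.null(report$overlap))
      report$overlap$global_overlap else NULL,
    failed = report$failed)
  jsonlite::write_json(head_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Compare male and female pipeline runs
#'
#' Summarizes a set of reports by sex: mean and sd of per-subject neuron
#' counts, packing densities and chosen cluster numbers, and the fraction
#' of subjects showing neurons in each ROI.
#'
#' @param reports list of `icns_report`s (each may hold several subjects).
#' @return Data.frame of class `icns_sex_comparison`, one row per sex, with
#'   the female/male count ratio in attribute `"count_ratio"`.
#' @export
compare_sexes <- function(reports) {
  rows <- do.call(rbind, lapply(reports, `[[`, "summary"))
  rois <- do.call(rbind, lapply(reports, function(r)
    if (!is.null(r$roi_table)) r$roi_table$counts else NULL))
  if (is.null(rows) || !nrow(rows)) abort_arg("no subjects in reports")
  out <- do.call(rbind, lapply(split(rows, rows$sex), function(g) {
    rec <- data.frame(sex = g$sex[1], n_subjects = nrow(g),
                      mean_count = mean(g$n_neurons), sd_count = stats::sd(g$n_neurons),
                      mean_density = mean(g$mean_density, na.rm = TRUE),
                      mean_chosen_k = mean(g$chosen_k, na.rm = TRUE))
    if (!is.null(rois)) {
      gr <- rois[rois$sex == g$sex[1], , drop = FALSE]
      for (rn in roi_names()) {
        col <- paste0(rn, "_count")
        if (col %in% names(gr))
          rec[[paste0(rn, "_presence")]] <- mean(gr[[col]] > 0)
      }
    }
    rec
  }))
  rownames(out) <- NULL
  if (all(c("male", "female") %in% out$sex))
    attr(out, "count_ratio") <-
      out$mean_count[out$sex == "female"] / out$mean_count[out$sex == "male"]
  class(out) <- c("icns_sex_comparison", "data.frame")
  out
}
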