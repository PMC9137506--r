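#' Compute all subject maps and the smoothed group median map
#'
#' The subject-to-group half of the pipeline in its fixed order: subject
#' GLM contrast maps, isotropic Gaussian smoothing of each map, then the
#' voxelwise median (smoothing precedes the median; the two operations do
#' not commute).
#'
#' @param cohort A [generate_cohort()] cohort.
#' @param hrf HRF kernel; default [gamma_hrf()] at the cohort's TR.
#' @param smoothing_sd_mm Gaussian SD in mm (default 3).
#' @param mask_fraction Brain-mask threshold fraction.
#' @param contrast Contrast vector.
#' @return List: `group_map` ([median_map()] result), `subject_maps`
#'   (list of [subject_map()] results), `smoothed_maps` (list of 3D
#'   arrays), `group_mask` (intersection of subject masks).
#' @export
group_map_from_cohort <- function(cohort, hrf = NULL, smoothing_sd_mm = 3,
                                  mask_fraction = 0.5,
                                  contrast = nogo_vs_go_contrast()) {
  if (length(cohort) == 0L) stop_bad("`cohort` must be non-empty")
  if (is.null(hrf))
    hrf <- gamma_hrf(tr_seconds = cohort[[1L]]$tr_seconds)
  vox <- cohort[[1L]]$voxel_size_mm
  subject_maps <- lapply(cohort, subject_map, hrf = hrf,
                         mask_fraction = mask_fraction, contrast = contrast)
  grid <- dim(subject_maps[[1L]]$tmap)
  smoother <- make_smoother(grid, smoothing_sd_mm, vox)
  smoothed <- lapply(subject_maps, function(m) smoother(m$tmap))
  gmask <- Reduce(`&`, lapply(subject_maps, `[[`, "mask"))
  list(group_map = median_map(smoothed, smoothing_sd_mm = smoothing_sd_mm),
       subject_maps = subject_maps, smoothed_maps = smoothed,
       group_mask = gmask)
}

#' Full-study configuration
#'
#' Bundles every stage's parameters: task and cohort generation, HRF and
#' masking, smoothing, the permutation count and FWER levels, cluster
#' filtering, and the PCA/sparse-PCA settings.
#'
#' @param task A [task_config()].
#' @param cohort A [cohort_spec()].
#' @param hrf An [gamma_hrf()] kernel (default: at the task's TR).
#' @param mask_fraction Brain-mask threshold fraction.
#' @param smoothing_sd_mm Gaussian SD, mm.
#' @param B Permutation count.
#' @param alphas Per-tail FWER levels.
#' @param min_cluster_mm3 Strict minimum cluster volume, mm^3.
#' @param connectivity Cluster connectivity (6, 18, 26).
#' @param K Number of PCs to extract and test.
#' @param sparsity Target nonzero-loading fraction for sparse PCA, in
#'   (0, 1].
#' @param master_seed Integer seed for the permutation engine (cohort
#'   generation uses `cohort$seed`).
#' @param output_dir Output directory for [run_study()].
#' @return Object of class `study_config`.
#' @export
study_config <- function(task = task_config(),
                         cohort = cohort_spec(),
                         hrf = gamma_hrf(tr_seconds = task$tr_seconds),
                         mask_fraction = 0.5,
                         smoothing_sd_mm = 3,
                         B = 1000L,
                         alphas = c(0.001, 0.01, 0.05),
                         min_cluster_mm3 = 100,
                         connectivity = 18L,
                         K = 10L,
                         sparsity = 0.45,
                         master_seed = 1L,
                         output_dir = tempfile("permbold_study_")) {
  structure(list(task = task, cohort = cohort, hrf = hrf,
                 mask_fraction = mask_fraction,
                 smoothing_sd_mm = smoothing_sd_mm, B = as.integer(B),
                 alphas = alphas, min_cluster_mm3 = min_cluster_mm3,
                 connectivity = as.integer(connectivity), K = as.integer(K),
                 sparsity = sparsity, master_seed = master_seed,
                 output_dir = output_dir),
            class = "study_config")
}

#' Validate a study configuration
#'
#' @param cfg A [study_config()].
#' @return List with `errors` (blocking) and `warnings` (advisory)
#'   character vectors; an empty pair of vectors means no findings.
#' @export
validate_config <- function(cfg) {
  errors <- character()
  warnings <- character()
  if (!inherits(cfg, "study_config")) {
    return(list(errors = "not a study_config object", warnings = warnings))
  }
  if (!inherits(cfg$task, "task_config"))
    errors <- c(errors, "task must be a task_config")
  if (!inherits(cfg$cohort, "cohort_spec"))
    errors <- c(errors, "cohort must be a cohort_spec")
  else if (cfg$cohort$noise_sd < 0)
    errors <- c(errors, "cohort noise_sd must be non-negative")
  if (cfg$B < 1) errors <- c(errors, "B must be at least 1")
  if (any(cfg$alphas <= 0 | cfg$alphas >= 1))
    errors <- c(errors, "alphas must lie in (0, 1)")
  else if (cfg$B < 1 / min(cfg$alphas))
    warnings <- c(warnings, sprintf(
      paste0("B = %d cannot resolve the most stringent level alpha = %g: ",
             "the empirical exceedance probability has resolution 1/B, so ",
             "at least %d permutation runs are needed"),
      cfg$B, min(cfg$alphas), ceiling(1 / min(cfg$alphas))))
  if (!cfg$connectivity %in% c(6L, 18L, 26L))
    errors <- c(errors, "connectivity must be 6, 18 or 26")
  if (cfg$min_cluster_mm3 < 0)
    errors <- c(errors, "min_cluster_mm3 must be non-negative")
  if (cfg$K < 1) errors <- c(errors, "K must be at least 1")
  if (inherits(cfg$cohort, "cohort_spec") &&
      cfg$K > 2L * cfg$cohort$n_per_group - 1L)
    errors <- c(errors, "K exceeds the number of subjects minus 1")
  if (!is.null(cfg$sparsity) &&
      (cfg$sparsity <= 0 || cfg$sparsity > 1))
    errors <- c(errors, "sparsity must lie in (0, 1]")
  list(errors = errors, warnings = warnings)
}

#' Run the full study pipeline
#'
#' Executes every stage in fixed order: cohort simulation; subject GLM
#' maps; smoothing and group median; the permutation null (B runs) and
#' FWER thresholds; significance tiers and cluster extraction; the
#' response matrix, PC scores, per-component Mann-Whitney tests and
#' sparse PCA; and behavioral accuracy tests between groups. In total
#' `B + 1` group maps are computed: B permuted and 1 true. Results and a
#' manifest are written under `cfg$output_dir`.
#'
#' @param cfg A [study_config()]; validated first, aborting on blocking
#'   findings.
#' @param verbose Log per-stage progress to stderr.
#' @return Object of class `study_report` (also written as
#'   `report.json`): headline numbers (cluster table, threshold set, u1
#'   test, explained variance, sparse support size, file paths).
#' @export
run_study <- function(cfg, verbose = TRUE) {
  v <- validate_config(cfg)
  if (length(v$errors))
    stop_bad("invalid study configuration:\n  - ",
             paste(v$errors, collapse = "\n  - "))
  for (w in v$warnings) warning(w, call. = FALSE)
  say <- function(...) if (verbose)
    message(sprintf("[permbold %s] ", format(Sys.time(), "%H:%M:%S")), ...)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  vox <- cfg$cohort$voxel_size_mm

  say("simulating cohort (", 2L * cfg$cohort$n_per_group, " subjects)")
  cohort <- generate_cohort(cfg$cohort, cfg$task, hrf = cfg$hrf)
  groups <- vapply(cohort, `[[`, "", "group_name")

  say("computing subject maps and group median map")
  gm <- group_map_from_cohort(cohort, hrf = cfg$hrf,
                              smoothing_sd_mm = cfg$smoothing_sd_mm,
                              mask_fraction = cfg$mask_fraction)
  true_map <- gm$group_map$median_map
  write_nifti_map(true_map, vox, file.path(out, "group_median_map.nii.gz"))

  say("running ", cfg$B, " permutation analyses")
  null <- null_distribution(cohort, B = cfg$B,
                            master_seed = cfg$master_seed, hrf = cfg$hrf,
                            smoothing_sd_mm = cfg$smoothing_sd_mm,
                            mask_fraction = cfg$mask_fraction)
  thr <- compute_thresholds(null, cfg$alphas)

  say("thresholding and extracting clusters")
  sig <- threshold_map(true_map, thr)
  sig_masked <- sig
  sig_masked[!gm$group_mask] <- 0L
  clusters <- extract_clusters(sig_masked, voxel_size_mm = vox,
                               connectivity = cfg$connectivity,
                               min_size_mm3 = cfg$min_cluster_mm3,
                               values = true_map)
  write_nifti_map(array(as.integer(sig_masked), dim(sig_masked)), vox,
                  file.path(out, "significance_map.nii.gz"))
  utils::write.table(clusters, file.path(out, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("group-difference decomposition")
  n_sig <- sum(sig_masked != 0L)
  groupdiff <- NULL
  if (n_sig > 0L) {
    R <- build_response_matrix(gm$smoothed_maps, sig_masked,
                               group_labels = groups)
    Kuse <- min(cfg$K, length(cohort) - 1L, n_sig)
    pcs <- pca_scores(R, K = Kuse)
    comp_tests <- test_top_components(pcs, groups, K_test = Kuse)
    spc <- sparse_pc(R, target_nnz_fraction = cfg$sparsity)
    u1 <- mw_u_test(pcs$U[, 1L], groups)
    scores <- data.frame(subject = seq_along(cohort), group = groups,
                         pcs$U)
    names(scores)[-(1:2)] <- paste0("u", seq_len(Kuse))
    utils::write.table(scores, file.path(out, "pc_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(comp_tests, file.path(out, "component_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    eig <- eigenimage_to_volume(spc$v1_sparse, R$voxel_index, dim(sig))
    write_nifti_map(eig, vox, file.path(out, "sparse_eigenimage.nii.gz"))
    groupdiff <- list(n_significant_voxels = n_sig,
                      explained_variance_pc1 = pcs$explained[1L],
                      u1_U = u1$U, u1_p = u1$p,
                      n_components_tested = Kuse,
                      sparse_nnz = spc$nnz, sparse_c = spc$c)
  } else say("no significant voxels; skipping group-difference stage")

  say("behavioral accuracy tests")
  acc <- data.frame(
    group = groups,
    go = vapply(cohort, function(s) {
      go <- s$Z[, "correct_go"] + s$Z[, "omission"]
      sum(s$Z[, "correct_go"]) / max(sum(go), 1L)
    }, 0),
    nogo = vapply(cohort, function(s) {
      ng <- s$Z[, "correct_nogo"] + s$Z[, "commission"]
      sum(s$Z[, "correct_nogo"]) / max(sum(ng), 1L)
    }, 0))
  gsplit <- split(acc, acc$group)
  behav <- lapply(c(go = "go", nogo = "nogo"), function(vname) {
    r <- t_from_summary(gsplit[[1L]][[vname]], gsplit[[2L]][[vname]],
                        variant = "auto")
    list(t = r$t, df = r$df, p = r$p, variant = r$variant)
  })

  report <- list(
    config = list(n_per_group = cfg$cohort$n_per_group,
                  grid_shape = cfg$cohort$grid_shape,
                  voxel_size_mm = vox, B = cfg$B, alphas = cfg$alphas,
                  min_cluster_mm3 = cfg$min_cluster_mm3,
                  connectivity = cfg$connectivity, K = cfg$K,
                  sparsity = cfg$sparsity,
                  master_seed = cfg$master_seed,
                  cohort_seed = cfg$cohort$seed),
    n_group_maps = cfg$B + 1L,
    thresholds = list(upper = as.list(thr$upper),
                      lower = as.list(thr$lower)),
    n_clusters = nrow(clusters),
    clusters = clusters,
    groupdiff = groupdiff,
    behavioral = behav,
    files = list(group_map = "group_median_map.nii.gz",
                 significance_map = "significance_map.nii.gz",
                 clusters = "clusters.tsv",
                 pc_scores = if (n_sig > 0L) "pc_scores.tsv" else NULL,
                 component_tests = if (n_sig > 0L)
                   "component_tests.tsv" else NULL,
                 sparse_eigenimage = if (n_sig > 0L)
                   "sparse_eigenimage.nii.gz" else NULL))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  say("done; outputs in ", out)
  structure(c(report, list(output_dir = out)), class = "study_report")
}
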