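#' Define a rectangular active region for the synthetic cohort
#'
#' @param from,to Integer 3-vectors: inclusive voxel index corners.
#' @param nogo_amplitude Length-2 numeric: BOLD amplitude (signal units)
#'   added to the correct-NoGo regressor for group 1 and group 2 subjects.
#' @param go_amplitude Length-2 numeric: amplitude on the correct-Go
#'   regressor per group (default 0).
#' @return List with a `voxels` index matrix (k x 3) and the amplitudes.
#' @export
cuboid_region <- function(from, to, nogo_amplitude, go_amplitude = c(0, 0)) {
  stopifnot(length(from) == 3L, length(to) == 3L, all(to >= from),
            length(nogo_amplitude) == 2L, length(go_amplitude) == 2L)
  g <- as.matrix(expand.grid(x = from[1]:to[1], y = from[2]:to[2],
                             z = from[3]:to[3]))
  dimnames(g) <- NULL
  list(voxels = g, nogo_amplitude = as.numeric(nogo_amplitude),
       go_amplitude = as.numeric(go_amplitude))
}

#' Default ground-truth active regions
#'
#' Three compact cuboid blobs (18 voxels, about 390 mm^3 each at the
#' default 2.5 x 2.5 x 3.5 mm voxels) in which the correct-NoGo response
#' amplitude is 1.0 noise-SD units in group 1 ("control") and 0.5 in
#' group 2 ("case") -- a 0.5-noise-SD activation deficit in the case group.
#'
#' @param grid_shape Integer 3-vector of voxel counts; regions are placed
#'   for the default 16 x 16 x 12 grid and scale-checked against it.
#' @param nogo_amplitude Per-group correct-NoGo amplitudes shared by all
#'   regions.
#' @return List of regions as produced by [cuboid_region()].
#' @export
default_active_regions <- function(grid_shape = c(16L, 16L, 12L),
                                   nogo_amplitude = c(1, 0.5)) {
  regions <- list(
    cuboid_region(c(4L, 10L, 7L), c(6L, 12L, 8L), nogo_amplitude),
    cuboid_region(c(11L, 9L, 5L), c(13L, 11L, 6L), nogo_amplitude),
    cuboid_region(c(8L, 3L, 8L), c(10L, 5L, 9L), nogo_amplitude))
  for (r in regions)
    if (any(r$voxels > rep(grid_shape, each = nrow(r$voxels))))
      stop_bad("default regions do not fit inside `grid_shape`; ",
               "supply regions explicitly for small grids")
  regions
}

#' Synthetic two-group cohort specification
#'
#' Describes a cohort of synthetic Go/NoGo fMRI subjects generated in a
#' common space: grid geometry, ground-truth active regions with per-group
#' amplitudes, noise and nuisance levels, and per-group task accuracies.
#' Defaults emulate the study conditions the pipeline targets: 15 subjects
#' per group on a 16 x 16 x 12 grid of 2.5 x 2.5 x 3.5 mm voxels, unit
#' Gaussian noise, a baseline of 100 signal units, and a 0.5-noise-SD
#' correct-NoGo amplitude deficit in group 2.
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param grid_shape Integer 3-vector of voxel counts.
#' @param voxel_size_mm Numeric 3-vector of voxel edge lengths, mm.
#' @param active_regions List of regions ([cuboid_region()]); `NULL` for
#'   the defaults, `list()` for a null cohort with no activation.
#' @param noise_sd SD of i.i.d. Gaussian noise, signal units.
#' @param baseline Baseline signal level.
#' @param motion_sd Length-2 numeric: random-walk step SD for the three
#'   translation (mm) and three rotation (degrees) series.
#' @param nuisance_weight_sd SD of the random spatial weights coupling the
#'   motion series into the voxel signal (signal units per motion unit).
#' @param drift_amplitude Amplitude of the slow cosine drift, signal units.
#' @param go_accuracy,nogo_accuracy Length-2 numeric: per-group response
#'   accuracies used when simulating performance. Defaults are the group
#'   mean accuracies of the cohort the generator emulates (group 1
#'   "control": Go 0.89, NoGo 0.94; group 2 "case": Go 0.91, NoGo 0.85).
#' @param group_names Length-2 character group labels.
#' @param seed Master integer seed; per-subject seeds are derived as
#'   `seed + subject index` (mod 2^31 - 1).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 15L,
                        grid_shape = c(16L, 16L, 12L),
                        voxel_size_mm = c(2.5, 2.5, 3.5),
                        active_regions = NULL,
                        noise_sd = 1,
                        baseline = 100,
                        motion_sd = c(0.02, 0.01),
                        nuisance_weight_sd = 0.3,
                        drift_amplitude = 1,
                        go_accuracy = c(0.89, 0.91),
                        nogo_accuracy = c(0.94, 0.85),
                        group_names = c("control", "case"),
                        seed = 1L) {
  check_number(n_per_group, "n_per_group", min = 1)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            length(motion_sd) == 2L, all(motion_sd >= 0),
            length(go_accuracy) == 2L, length(nogo_accuracy) == 2L,
            length(group_names) == 2L)
  if (noise_sd < 0) stop_bad("`noise_sd` must be non-negative")
  if (drift_amplitude < 0) stop_bad("`drift_amplitude` must be non-negative")
  grid_shape <- as.integer(grid_shape)
  if (is.null(active_regions))
    active_regions <- default_active_regions(grid_shape)
  for (r in active_regions) {
    if (!all(c("voxels", "nogo_amplitude", "go_amplitude") %in% names(r)))
      stop_bad("each active region needs voxels, nogo_amplitude, go_amplitude")
    if (!all(is.finite(r$nogo_amplitude)) || !all(is.finite(r$go_amplitude)))
      stop_bad("region amplitudes must be finite")
    v <- r$voxels
    if (any(v < 1L) || any(v > rep(grid_shape, each = nrow(v))))
      stop_bad("active region voxels fall outside the grid")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 grid_shape = grid_shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 active_regions = active_regions,
                 noise_sd = noise_sd, baseline = baseline,
                 motion_sd = as.numeric(motion_sd),
                 nuisance_weight_sd = nuisance_weight_sd,
                 drift_amplitude = drift_amplitude,
                 go_accuracy = as.numeric(go_accuracy),
                 nogo_accuracy = as.numeric(nogo_accuracy),
                 group_names = as.character(group_names),
                 seed = seed),
            class = "cohort_spec")
}

# Random rigid-body motion: centered Gaussian random walks, one column per
# parameter (3 translations mm, 3 rotations degrees).
simulate_motion <- function(n, motion_sd) {
  steps <- matrix(stats::rnorm(n * 6L), n, 6L)
  steps <- steps * rep(rep(motion_sd, each = 3L), each = n)
  m <- apply(steps, 2L, cumsum)
  sweep(m, 2L, colMeans(m))
}

#' Simulate one subject's 4D BOLD dataset
#'
#' Forward model: at every voxel,
#' `bold = baseline + sum_j amplitude_j(group) * (h * z_j) + drift +
#' motion %*% w + noise`, where the amplitudes are nonzero only inside the
#' spec's active regions, `h * z_j` is the HRF-convolved event indicator,
#' drift is a single slow cosine (one cycle over the run), `w` are small
#' random per-voxel spatial weights coupling the motion series into the
#' signal, and noise is i.i.d. Gaussian. The per-voxel ground-truth
#' NoGo-minus-Go contrast amplitude is recorded in `truth`.
#'
#' @param cfg A [task_config()].
#' @param spec A [cohort_spec()].
#' @param Z Performance matrix from [simulate_performance()].
#' @param group Group index (1 or 2) selecting region amplitudes.
#' @param hrf HRF kernel; default [gamma_hrf()] at the task's TR.
#' @param seed Optional integer seed for noise, motion, and weights.
#' @return Object of class `subject_dataset`: list with `bold` (4D array
#'   x,y,z,t), `Z`, `motion` (n x 6), `group`, `group_name`, `truth`
#'   (3D array), `voxel_size_mm`, `tr_seconds`, `seed`.
#' @export
simulate_subject <- function(cfg, spec, Z, group, hrf = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "task_config"), inherits(spec, "cohort_spec"))
  Z <- as_performance_matrix(Z)
  n <- nrow(Z)
  if (n != cfg$n_trials)
    stop_bad("rows of Z (", n, ") must equal n_trials (", cfg$n_trials, ")")
  if (!group %in% c(1L, 2L)) stop_bad("`group` must be 1 or 2")
  if (is.null(hrf)) hrf <- gamma_hrf(tr_seconds = cfg$tr_seconds)
  grid <- spec$grid_shape
  V <- prod(grid)

  E <- convolve_events(Z, hrf)                       # n x 4 event responses
  tsec <- (seq_len(n) - 1) * cfg$tr_seconds
  drift <- spec$drift_amplitude * cos(2 * pi * tsec / (n * cfg$tr_seconds))

  with_seed(seed, {
    motion <- simulate_motion(n, spec$motion_sd)
    W <- matrix(stats::rnorm(6L * V, sd = spec$nuisance_weight_sd), 6L, V)
    noise <- if (spec$noise_sd > 0)
      matrix(stats::rnorm(n * V, sd = spec$noise_sd), n, V) else
      matrix(0, n, V)

    Y <- noise + spec$baseline + drift + motion %*% W  # n x V
    truth <- numeric(V)
    for (r in spec$active_regions) {
      idx <- r$voxels[, 1L] + grid[1L] * (r$voxels[, 2L] - 1L) +
        grid[1L] * grid[2L] * (r$voxels[, 3L] - 1L)
      sig <- E[, "correct_nogo"] * r$nogo_amplitude[group] +
        E[, "correct_go"] * r$go_amplitude[group]
      Y[, idx] <- Y[, idx] + sig
      truth[idx] <- truth[idx] +
        (r$nogo_amplitude[group] - r$go_amplitude[group])
    }

    structure(list(bold = array(t(Y), c(grid, n)),
                   Z = Z, motion = motion,
                   group = as.integer(group),
                   group_name = spec$group_names[group],
                   truth = array(truth, grid),
                   voxel_size_mm = spec$voxel_size_mm,
                   tr_seconds = cfg$tr_seconds,
                   seed = seed),
              class = "subject_dataset")
  })
}

#' Generate a two-group synthetic cohort
#'
#' Subjects are generated independently with seeds derived from the master
#' seed (`spec$seed + subject index`), so a fixed master seed reproduces
#' the cohort exactly. Group 1 subjects come first. Each subject gets an
#' independently drawn task sequence and performance matrix using the
#' per-group accuracies in `spec`.
#'
#' @param spec A [cohort_spec()].
#' @param cfg A [task_config()].
#' @param hrf Optional shared HRF kernel; default [gamma_hrf()] at the
#'   task's TR.
#' @return List of [simulate_subject()] datasets of class `cohort`, with
#'   attributes `spec`, `task`, `groups` (integer vector).
#' @export
generate_cohort <- function(spec, cfg = task_config(), hrf = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(hrf)) hrf <- gamma_hrf(tr_seconds = cfg$tr_seconds)
  n_sub <- 2L * spec$n_per_group
  groups <- rep(1:2, each = spec$n_per_group)
  subjects <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    g <- groups[i]
    s_i <- derive_seed(spec$seed, i)
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(s_i, 10000L)
    sq <- generate_task_sequence(cfg_i)
    Z <- simulate_performance(sq, go_accuracy = spec$go_accuracy[g],
                              nogo_accuracy = spec$nogo_accuracy[g],
                              seed = derive_seed(s_i, 20000L))
    subjects[[i]] <- simulate_subject(cfg, spec, Z, g, hrf = hrf, seed = s_i)
  }
  structure(subjects, class = "cohort", spec = spec, task = cfg,
            groups = groups)
}

#' Write a cohort to disk (NIfTI + TSV + manifest)
#'
#' Writes one 4D NIfTI per subject, an events TSV (`volume_index`,
#' `trial_type`, `outcome`) encoding Z, a motion TSV with the six
#' rigid-body series, and a JSON manifest tying files to groups and seeds.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest JSON, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- attr(cohort, "spec")
  entries <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    id <- sprintf("sub-%03d", i)
    bold_path <- file.path(dir, paste0(id, "_bold.nii.gz"))
    img <- RNifti::asNifti(s$bold)
    RNifti::pixdim(img) <- c(s$voxel_size_mm, s$tr_seconds)
    RNifti::writeNifti(img, bold_path)
    ev <- data.frame(volume_index = seq_len(nrow(s$Z)) - 1L,
                     trial_type = ifelse(s$Z[, "correct_go"] +
                                           s$Z[, "omission"] > 0,
                                         "go", "nogo"),
                     outcome = outcome_levels[max.col(s$Z)])
    ev_path <- file.path(dir, paste0(id, "_events.tsv"))
    utils::write.table(ev, ev_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mo <- as.data.frame(s$motion)
    names(mo) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                   "rot_x_deg", "rot_y_deg", "rot_z_deg")
    mo_path <- file.path(dir, paste0(id, "_motion.tsv"))
    utils::write.table(mo, mo_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    entries[[i]] <- list(id = id, group = s$group_name,
                         seed = s$seed, bold = basename(bold_path),
                         events = basename(ev_path),
                         motion = basename(mo_path))
  }
  manifest <- list(n_subjects = length(cohort),
                   group_names = spec$group_names,
                   master_seed = spec$seed,
                   grid_shape = spec$grid_shape,
                   voxel_size_mm = spec$voxel_size_mm,
                   n_true_active_voxels =
                     sum(vapply(spec$active_regions,
                                function(r) nrow(r$voxels), 0L)),
                   subjects = entries)
  path <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
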