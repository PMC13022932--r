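# Synthetic BIDS phantom datasets: small 3D "brains" (an outer sphere at
# intensity 1 containing an inner "ventricle" sphere at intensity 0.2) whose
# inner-sphere radius encodes a scalar target (age or SDMT), so the whole
# federation stack can be exercised without downloading imaging data.

#' Configuration of the synthetic phantom generator
#'
#' Phantoms are cubic volumes holding an outer "brain" sphere of fixed radius
#' and an inner "ventricle" sphere whose radius varies linearly with the
#' regression target around the target-range midpoint. Additive Gaussian
#' noise is applied inside the brain sphere only.
#'
#' @param n_subjects Number of subjects to generate.
#' @param volume_shape Integer triple of voxel dimensions (all >= 16 so both
#'   spheres fit).
#' @param voxel_spacing_mm Isotropic voxel spacing in millimetres.
#' @param target_name Name of the target column (`"age"` or `"sdmt"`).
#' @param target_range Closed interval targets are drawn from (uniformly).
#' @param signal_slope Voxels of inner-sphere radius per target unit.
#' @param noise_sd Standard deviation of the additive intensity noise.
#' @param images_per_subject Images per subject (sessions when > 1).
#' @param target_shift Constant added to every drawn target: a non-IID knob
#'   that shifts one client's target distribution without changing the
#'   radius-to-target mapping shared by all clients.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects = 20L,
                           volume_shape = c(32L, 32L, 32L),
                           voxel_spacing_mm = 1.0,
                           target_name = "age",
                           target_range = c(20, 80),
                           signal_slope = 0.12,
                           noise_sd = 0.1,
                           images_per_subject = 1L,
                           target_shift = 0,
                           seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 16L))
    stop_fedbids("volume_shape must be three integers >= 16",
                 "fedbids_input_error")
  if (!(target_range[1] < target_range[2]))
    stop_fedbids("target_range lower bound must be below upper bound",
                 "fedbids_input_error")
  stopifnot(n_subjects >= 1L, voxel_spacing_mm > 0, noise_sd >= 0,
            images_per_subject >= 1L)
  structure(list(
    n_subjects = as.integer(n_subjects), volume_shape = volume_shape,
    voxel_spacing_mm = voxel_spacing_mm, target_name = target_name,
    target_range = as.numeric(target_range), signal_slope = signal_slope,
    noise_sd = noise_sd, images_per_subject = as.integer(images_per_subject),
    target_shift = target_shift, seed = as.integer(seed)
  ), class = "phantom_config")
}

# Geometry shared by generator and test oracles: outer radius and the
# target-dependent inner radius (clipped so the ventricle stays inside).
phantom_radii <- function(target_value, config) {
  outer <- floor(min(config$volume_shape) / 2) - 2
  base <- outer / 2
  mid <- mean(config$target_range)
  inner <- base + config$signal_slope * (target_value - mid)
  inner <- min(max(inner, 1), outer - 2)
  list(outer = outer, inner = inner)
}

#' Generate one phantom volume
#'
#' @param target_value The regression target encoded in the geometry; must
#'   lie within the configuration's (shift-adjusted) target range.
#' @param config A [phantom_config()].
#' @param subject_seed Integer seed for this subject's noise.
#' @return List with `data` (3D intensity array) and `affine` (4x4 RAS
#'   voxel-to-world matrix using the configured spacing).
#' @export
phantom_volume <- function(target_value, config, subject_seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  lo <- config$target_range[1] + min(0, config$target_shift)
  hi <- config$target_range[2] + max(0, config$target_shift)
  if (!is_scalar_number(target_value) || target_value < lo ||
      target_value > hi)
    stop_fedbids(sprintf("target %g outside the valid range [%g, %g]",
                         target_value, lo, hi), "fedbids_input_error")
  shp <- config$volume_shape
  rad <- phantom_radii(target_value, config)
  ctr <- (shp + 1) / 2
  ax <- lapply(1:3, function(a) (seq_len(shp[a]) - ctr[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  vol <- array(0, dim = shp)
  brain <- d2 <= rad$outer^2
  vol[brain] <- 1.0
  vol[d2 <= rad$inner^2] <- 0.2
  if (config$noise_sd > 0) {
    noise <- with_seed(subject_seed,
                       rnorm(sum(brain), sd = config$noise_sd))
    vol[brain] <- vol[brain] + noise
  }
  affine <- diag(c(rep(config$voxel_spacing_mm, 3), 1))
  list(data = vol, affine = affine)
}

#' Write a synthetic BIDS phantom dataset
#'
#' Creates `participants.tsv` (columns `participant_id`, `sex`, and the
#' configured target) plus one gzipped NIfTI T1w image per subject and
#' session under `sub-<k>/[ses-<s>/]anat/`. Targets are drawn uniformly from
#' the target range (plus any non-IID shift) under the configuration seed;
#' generation is byte-reproducible. Refuses to write into a non-empty
#' directory.
#'
#' @param config A [phantom_config()].
#' @param output_root Directory to create the dataset in (created if absent;
#'   must be empty).
#' @return Invisibly, a list with `n_written`, `participants` (the table) and
#'   `participants_path`.
#' @export
generate_bids_dataset <- function(config, output_root) {
  stopifnot(inherits(config, "phantom_config"))
  if (dir.exists(output_root) && length(dir(output_root, all.files = TRUE,
                                            no.. = TRUE)) > 0)
    stop_fedbids(sprintf("output_root '%s' is not empty; refusing to overwrite",
                         output_root), "fedbids_io_error")
  dir.create(output_root, recursive = TRUE, showWarnings = FALSE)
  n <- config$n_subjects
  ids <- sprintf("sub-%03d", seq_len(n))
  targets <- with_seed(config$seed,
                       runif(n, config$target_range[1], config$target_range[2]))
  targets <- round(targets + config$target_shift, 1)
  tab <- data.frame(participant_id = ids,
                    sex = rep_len(c("m", "f"), n),
                    target = targets,
                    stringsAsFactors = FALSE)
  names(tab)[3] <- config$target_name
  tsv <- file.path(output_root, "participants.tsv")
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  n_img <- 0L
  for (i in seq_len(n)) {
    for (s in seq_len(config$images_per_subject)) {
      vol <- phantom_volume(targets[i], config,
                            subject_seed = derive_seed(config$seed, i, s))
      if (config$images_per_subject > 1L) {
        adir <- file.path(output_root, ids[i], sprintf("ses-%d", s), "anat")
        fname <- sprintf("%s_ses-%d_T1w.nii.gz", ids[i], s)
      } else {
        adir <- file.path(output_root, ids[i], "anat")
        fname <- sprintf("%s_T1w.nii.gz", ids[i])
      }
      dir.create(adir, recursive = TRUE, showWarnings = FALSE)
      write_volume(vol$data, vol$affine, file.path(adir, fname))
      n_img <- n_img + 1L
    }
  }
  invisible(list(n_written = n_img, participants = tab,
                 participants_path = tsv))
}
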