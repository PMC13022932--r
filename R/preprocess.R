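# Deterministic image standardisation: RAS reorientation, isotropic trilinear
# resampling, centre crop / zero-pad to a cubic window, intensity
# normalisation. Skull-stripping, bias-field correction and affine template
# registration are third-party tools and enter only as pluggable external
# command hooks.

#' Preprocessing configuration
#'
#' Defaults follow the standard brain-age preparation: isotropic resampling
#' at 1.4 mm and a 130x130x130 voxel window. Intensity normalisation is not
#' part of that published chain; the package default is per-volume min-max
#' scaling to \[0, 1\] (surfaced here rather than hidden).
#'
#' @param target_spacing Isotropic output voxel spacing in mm.
#' @param window Output edge length in voxels.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param normalize `"minmax"`, `"zscore"`, or `"none"`.
#' @param external_hooks Named list of external command templates (names
#'   among `skull_strip`, `bias_correct`, `affine_register`), each a string
#'   with `{in}`/`{out}` placeholders substituted with temporary NIfTI paths.
#'   Hooks run in that fixed order when present.
#' @param cache_dir Optional directory for the preprocessing cache; results
#'   are keyed by (input-file hash, configuration hash).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = 1.4, window = 130L,
                              interpolation = c("linear", "nearest"),
                              normalize = c("minmax", "zscore", "none"),
                              external_hooks = list(),
                              cache_dir = NULL) {
  interpolation <- match.arg(interpolation)
  normalize <- match.arg(normalize)
  stopifnot(target_spacing > 0, window >= 1)
  allowed <- c("skull_strip", "bias_correct", "affine_register")
  if (length(external_hooks)) {
    bad <- setdiff(names(external_hooks), allowed)
    if (length(bad))
      stop_fedbids(paste0("unknown external hooks: ",
                          paste(bad, collapse = ", ")),
                   "fedbids_input_error")
  }
  structure(list(target_spacing = target_spacing, window = as.integer(window),
                 interpolation = interpolation, normalize = normalize,
                 external_hooks = external_hooks, cache_dir = cache_dir),
            class = "preprocess_config")
}

#' Reorient a volume to RAS
#'
#' Pure axis permutation and flips (no resampling) so that increasing voxel
#' indices move Right, Anterior, Superior; the affine is updated so every
#' voxel keeps its world coordinate. Idempotent.
#'
#' @param volume 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @return List with reoriented `data` and `affine`.
#' @export
to_ras <- function(volume, affine) {
  M <- affine[1:3, 1:3]
  if (abs(det(M)) < 1e-12)
    stop_fedbids("affine is singular; cannot determine orientation",
                 "fedbids_input_error")
  # Greedy assignment: strongest |M[i,j]| pairs world axis i with voxel axis j
  A <- abs(M)
  perm <- integer(3); sgn <- numeric(3)
  for (step in 1:3) {
    w <- which(A == max(A), arr.ind = TRUE)[1, ]
    i <- w[1]; j <- w[2]
    perm[i] <- j
    sgn[i] <- sign(M[i, j])
    A[i, ] <- -1; A[, j] <- -1
  }
  dims_in <- dim(volume)
  out <- aperm(volume, perm)
  for (a in 1:3) {
    if (sgn[a] < 0) {
      idx <- list(TRUE, TRUE, TRUE)
      idx[[a]] <- rev(seq_len(dim(out)[a]))
      out <- do.call(`[`, c(list(out), idx, list(drop = FALSE)))
    }
  }
  Tm <- matrix(0, 4, 4); Tm[4, 4] <- 1
  for (a in 1:3) {
    d <- dims_in[perm[a]]
    if (sgn[a] >= 0) {
      Tm[perm[a], a] <- 1
    } else {
      Tm[perm[a], a] <- -1
      Tm[perm[a], 4] <- d - 1
    }
  }
  list(data = out, affine = affine %*% Tm)
}

#' Resample a volume to isotropic spacing
#'
#' Output shape per axis is `round(extent_mm / target_spacing)`; voxel
#' centres are mapped into the input grid and interpolated (trilinear by
#' default, with edge clamping).
#'
#' @inheritParams to_ras
#' @param target_spacing Desired isotropic spacing in mm.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return List with resampled `data` and updated `affine`.
#' @export
resample_isotropic <- function(volume, affine, target_spacing = 1.4,
                               interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop_fedbids("affine has non-positive voxel spacings",
                 "fedbids_input_error")
  d <- dim(volume)
  out_shape <- pmax(1L, as.integer(round(d * spacing / target_spacing)))
  f <- target_spacing / spacing
  coords <- lapply(1:3, function(a) {
    cc <- (seq_len(out_shape[a]) - 1 + 0.5) * f[a] - 0.5
    pmin(pmax(cc, 0), d[a] - 1)
  })
  o1 <- out_shape[1]; o2 <- out_shape[2]; o3 <- out_shape[3]
  rep3 <- function(v, axis) switch(axis,
    rep.int(v, o2 * o3),
    rep.int(rep(v, each = o1), o3),
    rep(v, each = o1 * o2))
  if (interpolation == "nearest") {
    ix <- lapply(1:3, function(a) round(coords[[a]]))
    lin <- 1 + rep3(ix[[1]], 1) + rep3(ix[[2]], 2) * d[1] +
      rep3(ix[[3]], 3) * (d[1] * d[2])
    out <- array(volume[lin], dim = out_shape)
  } else {
    lo <- lapply(coords, floor)
    wf <- mapply(function(cc, l) cc - l, coords, lo, SIMPLIFY = FALSE)
    hi <- mapply(function(l, a) pmin(l + 1, d[a] - 1), lo, 1:3,
                 SIMPLIFY = FALSE)
    out <- numeric(o1 * o2 * o3)
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      X <- if (cx == 0) lo[[1]] else hi[[1]]
      Y <- if (cy == 0) lo[[2]] else hi[[2]]
      Z <- if (cz == 0) lo[[3]] else hi[[3]]
      WX <- if (cx == 0) 1 - wf[[1]] else wf[[1]]
      WY <- if (cy == 0) 1 - wf[[2]] else wf[[2]]
      WZ <- if (cz == 0) 1 - wf[[3]] else wf[[3]]
      lin <- 1 + rep3(X, 1) + rep3(Y, 2) * d[1] + rep3(Z, 3) * (d[1] * d[2])
      w <- rep3(WX, 1) * rep3(WY, 2) * rep3(WZ, 3)
      out <- out + w * volume[lin]
    }
    out <- array(out, dim = out_shape)
  }
  newA <- affine
  newA[1:3, 1:3] <- sweep(affine[1:3, 1:3], 2, f, `*`)
  newA[1:3, 4] <- affine[1:3, 1:3] %*% ((f - 1) / 2) + affine[1:3, 4]
  list(data = out, affine = newA)
}

#' Centre crop or zero-pad to a cubic window
#'
#' Per axis: centre-crop when the input exceeds the window, symmetric
#' zero-pad when it is smaller; the extra voxel of an odd difference goes to
#' the trailing side in both cases.
#'
#' @param volume 3D numeric array.
#' @param window Output edge length in voxels.
#' @return 3D array of shape `window^3`.
#' @export
crop_or_pad <- function(volume, window = 130L) {
  w <- as.integer(window)
  d <- dim(volume)
  stopifnot(length(d) == 3L, w >= 1L)
  if (all(d == w)) return(volume)
  src <- vector("list", 3); dst <- vector("list", 3)
  for (a in 1:3) {
    if (d[a] >= w) {
      start <- (d[a] - w) %/% 2L
      src[[a]] <- seq.int(start + 1L, start + w)
      dst[[a]] <- seq_len(w)
    } else {
      lead <- (w - d[a]) %/% 2L
      src[[a]] <- seq_len(d[a])
      dst[[a]] <- seq.int(lead + 1L, lead + d[a])
    }
  }
  out <- array(vector(typeof(volume), 1L), dim = c(w, w, w))
  out[dst[[1]], dst[[2]], dst[[3]]] <- volume[src[[1]], src[[2]], src[[3]]]
  out
}

#' Normalise voxel intensities
#'
#' @param volume 3D numeric array.
#' @param mode `"minmax"` (rescale observed range to \[0, 1\]), `"zscore"`
#'   (mean 0, sd 1), or `"none"`.
#' @return The normalised array.
#' @export
normalize_intensity <- function(volume, mode = c("minmax", "zscore", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(volume)
  rng <- range(volume)
  if (rng[1] == rng[2])
    stop_fedbids("constant volume cannot be intensity-normalised",
                 "fedbids_input_error")
  if (mode == "minmax") (volume - rng[1]) / (rng[2] - rng[1])
  else (volume - mean(volume)) / sd(as.vector(volume))
}

run_hook <- function(name, template, vol, aff) {
  fin <- tempfile(fileext = ".nii.gz")
  fout <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(fin, fout)))
  write_volume(vol, aff, fin)
  cmd <- gsub("{out}", fout, gsub("{in}", fin, template, fixed = TRUE),
              fixed = TRUE)
  status <- suppressWarnings(
    system(cmd, ignore.stdout = TRUE, ignore.stderr = TRUE))
  if (status != 0 || !file.exists(fout))
    stop_fedbids(sprintf("external hook '%s' failed (exit status %d): %s",
                         name, status, cmd),
                 "fedbids_pipeline_error", hook = name, status = status)
  v <- load_volume(fout)
  list(data = v$data, affine = v$affine)
}

#' Run the full preprocessing pipeline on one image
#'
#' Order: RAS reorientation, then any configured external hooks
#' (skull-strip, bias-correct, affine-register, run as external commands on
#' temporary NIfTI files), RAS again, isotropic resampling, centre
#' crop/zero-pad, intensity normalisation. The result — a model-ready
#' 1-channel array of shape `c(1, window, window, window)` — is cached on
#' disk keyed by the input file hash and the configuration hash.
#'
#' @param path Path to a NIfTI image.
#' @param config A [preprocess_config()].
#' @return Numeric array of shape `c(1, window, window, window)`.
#' @export
preprocess_pipeline <- function(path, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  cache_file <- NULL
  if (!is.null(config$cache_dir)) {
    key_cfg <- config
    key_cfg$cache_dir <- NULL
    key <- object_md5(list(file = file_md5(path), config = key_cfg))
    dir.create(config$cache_dir, recursive = TRUE, showWarnings = FALSE)
    cache_file <- file.path(config$cache_dir, paste0(key, ".rds"))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  v <- load_volume(path)
  cur <- to_ras(v$data, v$affine)
  for (h in c("skull_strip", "bias_correct", "affine_register")) {
    tpl <- config$external_hooks[[h]]
    if (!is.null(tpl)) cur <- run_hook(h, tpl, cur$data, cur$affine)
  }
  cur <- to_ras(cur$data, cur$affine)
  cur <- resample_isotropic(cur$data, cur$affine, config$target_spacing,
                            config$interpolation)
  vol <- crop_or_pad(cur$data, config$window)
  vol <- normalize_intensity(vol, config$normalize)
  out <- array(vol, dim = c(1L, dim(vol)))
  if (!is.null(cache_file)) saveRDS(out, cache_file)
  out
}
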