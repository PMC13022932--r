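# BIDS dataset discovery, NIfTI volume I/O, and leak-free subject-level
# splitting (80/20 train/test, then per-round 75/25 bootstrap partitions of
# the training pool, giving the 60/20/20 accounting).

#' Read a NIfTI volume
#'
#' @param path Path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return List with `data` (3D double array; singleton trailing dimensions
#'   are squeezed), `affine` (4x4 voxel-to-world matrix, 0-based voxel
#'   indices) and `spacing` (voxel spacings in mm).
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    stop_fedbids(sprintf("cannot read NIfTI file '%s': no such file", path),
                 "fedbids_io_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_fedbids(
                    sprintf("cannot read NIfTI file '%s': %s", path,
                            conditionMessage(e)), "fedbids_io_error"))
  dat <- as.array(img)
  dd <- dim(dat)
  attributes(dat) <- list(dim = dd)
  while (length(dd) > 3L && dd[length(dd)] == 1L) {
    dd <- dd[-length(dd)]
    dim(dat) <- dd
  }
  if (length(dim(dat)) != 3L)
    stop_fedbids(sprintf("'%s' is not a 3D volume", path), "fedbids_io_error")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(data = dat, affine = aff,
       spacing = sqrt(colSums(aff[1:3, 1:3]^2)))
}

#' Write a NIfTI volume
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path Output path (`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, affine, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Discover subjects in a BIDS regression dataset
#'
#' Walks `participants.tsv`, keeping one record per row that has a
#' non-missing value in `target_column` and at least one T1-weighted image on
#' disk under `sub-<ID>/[ses-*/]anat/`. Rows failing either condition are
#' reported via a message (count and IDs) and skipped. Records are ordered
#' lexicographically by subject ID.
#'
#' @param dataset_root BIDS dataset directory.
#' @param target_column Name of the participants-table column holding the
#'   regression target.
#' @return A data.frame of class `subject_records` with columns
#'   `subject_id`, `target`, `sex` (NA if absent), `n_images` and a
#'   list-column `image_paths`. Skipped IDs are attached as
#'   `attr(, "skipped")`.
#' @export
discover_subjects <- function(dataset_root, target_column) {
  tsv <- file.path(dataset_root, "participants.tsv")
  if (!file.exists(tsv))
    stop_fedbids(sprintf("no participants.tsv under '%s'", dataset_root),
                 "fedbids_format_error")
  tab <- read.delim(tsv, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("", "NA", "n/a"))
  if (!"participant_id" %in% names(tab))
    stop_fedbids("participants.tsv lacks the mandatory participant_id column",
                 "fedbids_format_error")
  if (!target_column %in% names(tab))
    stop_fedbids(sprintf("target column '%s' absent from participants.tsv",
                         target_column), "fedbids_schema_error")
  tab <- tab[order(tab$participant_id), , drop = FALSE]
  imgs <- lapply(tab$participant_id, function(id) {
    sdir <- file.path(dataset_root, id)
    if (!dir.exists(sdir)) return(character(0))
    sort(list.files(sdir, pattern = "_T1w\\.nii(\\.gz)?$",
                    recursive = TRUE, full.names = TRUE))
  })
  target <- suppressWarnings(as.numeric(tab[[target_column]]))
  keep <- is.finite(target) & lengths(imgs) > 0
  skipped <- tab$participant_id[!keep]
  if (length(skipped))
    message(sprintf("discover_subjects: skipped %d of %d rows (%s)",
                    length(skipped), nrow(tab),
                    paste(skipped, collapse = ", ")))
  out <- data.frame(subject_id = tab$participant_id[keep],
                    target = target[keep],
                    sex = if ("sex" %in% names(tab)) tab$sex[keep]
                          else NA_character_,
                    n_images = lengths(imgs)[keep],
                    stringsAsFactors = FALSE)
  out$image_paths <- imgs[keep]
  covars <- setdiff(names(tab), c("participant_id", "sex", target_column))
  for (cv in covars) out[[cv]] <- tab[[cv]][keep]
  attr(out, "skipped") <- skipped
  class(out) <- c("subject_records", "data.frame")
  out
}

record_ids <- function(subjects) {
  if (is.character(subjects)) subjects else subjects$subject_id
}

#' Subject-level train/test split
#'
#' Splits subjects (never individual images) into train and test sets, so
#' multiple images of one subject always fall on the same side — the
#' leak-freedom rule. `|test| = round(test_fraction * n)`, at least 1.
#' Deterministic under `seed`.
#'
#' @param subjects A `subject_records` data.frame or character vector of IDs.
#' @param test_fraction Fraction of subjects held out for testing (0-1,
#'   exclusive).
#' @param seed Integer seed.
#' @return List of class `fl_split` with `train_subjects`, `test_subjects`
#'   (both sorted character vectors).
#' @export
subject_split <- function(subjects, test_fraction = 0.2, seed = 1L) {
  ids <- record_ids(subjects)
  n <- length(ids)
  if (n < 2L)
    stop_fedbids("need at least 2 subjects to split", "fedbids_input_error")
  if (!(test_fraction > 0 && test_fraction < 1))
    stop_fedbids("test_fraction must be in (0, 1)", "fedbids_input_error")
  n_test <- max(1L, min(n - 1L, as.integer(round(test_fraction * n))))
  test <- with_seed(seed, sample(ids, n_test))
  structure(list(train_subjects = sort(setdiff(ids, test)),
                 test_subjects = sort(test)),
            class = "fl_split")
}

#' Per-round bootstrap partitions of the training pool
#'
#' Each of `n_bootstraps` splits is a fresh random partition (without
#' replacement) of the training subjects into a training part and a
#' validation part of `round(val_fraction * n)` subjects (at least 1).
#' Seeds derive deterministically from `(base_seed, round_index,
#' bootstrap_index)`, so every federation round draws distinct partitions
#' reproducibly. With the defaults (80% upstream training pool, 25%
#' validation) this realises the 60/20/20 train/validation/test accounting.
#'
#' @param train_subjects Character vector of training-pool subject IDs.
#' @param n_bootstraps Number of partitions per round (study protocol: 5).
#' @param val_fraction Fraction of the pool held out for validation.
#' @param round_index Federation round (>= 1).
#' @param base_seed Integer base seed.
#' @return List of `fl_bootstrap_split` objects, each with `round_index`,
#'   `bootstrap_index` (0-based), `train_subjects`, `val_subjects`.
#' @export
bootstrap_splits <- function(train_subjects, n_bootstraps = 5L,
                             val_fraction = 0.25, round_index = 1L,
                             base_seed = 1L) {
  ids <- record_ids(train_subjects)
  if (length(ids) < 2L)
    stop_fedbids("training pool must hold at least 2 subjects to bootstrap",
                 "fedbids_input_error")
  if (!(val_fraction > 0 && val_fraction < 1))
    stop_fedbids("val_fraction must be in (0, 1)", "fedbids_input_error")
  stopifnot(n_bootstraps >= 1L)
  n <- length(ids)
  n_val <- max(1L, min(n - 1L, as.integer(round(val_fraction * n))))
  lapply(seq_len(n_bootstraps) - 1L, function(b) {
    s <- derive_seed(base_seed, round_index, b)
    val <- with_seed(s, sample(ids, n_val))
    structure(list(round_index = as.integer(round_index),
                   bootstrap_index = b,
                   train_subjects = sort(setdiff(ids, val)),
                   val_subjects = sort(val),
                   seed = s),
              class = "fl_bootstrap_split")
  })
}
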