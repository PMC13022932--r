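# Per-round local training: receive global weights, train one fresh model
# copy per bootstrap partition, report the validated weights and statistics.

#' Load and preprocess a client's images into model-ready tensors
#'
#' Runs every image of every record through [preprocess_pipeline()] (disk
#' cache honoured across rounds — the image set is fixed for the whole
#' federation) and stacks the flattened volumes into a matrix.
#'
#' @param records A `subject_records` data.frame from [discover_subjects()].
#' @param config A [preprocess_config()].
#' @return List of class `client_data`: `X` (n_images x voxels), `dims`,
#'   `index` (data.frame subject_id / image / target per row).
#' @export
prepare_client_data <- function(records, config = preprocess_config()) {
  rows <- list(); meta <- list()
  for (i in seq_len(nrow(records))) {
    paths <- records$image_paths[[i]]
    for (j in seq_along(paths)) {
      rows[[length(rows) + 1L]] <- as.vector(
        preprocess_pipeline(paths[j], config))
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = records$subject_id[i], image = j,
        target = records$target[i], stringsAsFactors = FALSE)
    }
  }
  X <- do.call(rbind, rows)
  w <- config$window
  structure(list(X = X, dims = c(w, w, w), index = do.call(rbind, meta)),
            class = "client_data")
}

data_rows <- function(client_data, subject_ids) {
  which(client_data$index$subject_id %in% subject_ids)
}

# 95% CI of the mean across bootstraps (t distribution).
boot_ci95 <- function(x) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(m, m))
  half <- stats::qt(0.975, df = n - 1L) * stats::sd(x) / sqrt(n)
  c(m - half, m + half)
}

#' Run one client round of bootstrapped local training
#'
#' For each of the plan's bootstrap partitions of the (fixed) training pool:
#' load the global weights into a fresh model copy, apply the plan's freeze
#' mode, train `epochs_per_round` epochs of minibatch Adam on the L1
#' objective, and record the validation MAE. The update carries the weights
#' of the bootstrap with the lowest validation MAE (or the elementwise
#' average of all bootstrap models when the plan's selector is
#' `"average"`), plus the per-bootstrap validation statistics and the
#' training-pool image count used as the aggregation weight.
#'
#' @param global_weights The broadcast `weight_set`.
#' @param plan An [fl_plan()].
#' @param client_data A `client_data` object from [prepare_client_data()].
#' @param split The client's fixed `fl_split` (computed once at federation
#'   start; the test side is never touched in training).
#' @param round_index Federation round (>= 1).
#' @param model Model skeleton matching the weights (from
#'   [build_densenet()]).
#' @param client_name Label reported with the update.
#' @return An `fl_client_update`: `client_name`, `round_index`, `weights`,
#'   `n_train_samples`, `val_mae_per_bootstrap`, `val_mae_mean`,
#'   `val_mae_ci95`.
#' @export
run_client_round <- function(global_weights, plan, client_data, split,
                             round_index, model, client_name = "client") {
  train_rows_all <- data_rows(client_data, split$train_subjects)
  if (length(train_rows_all) < 1L)
    stop_fedbids("client has an empty training pool", "fedbids_config_error")
  bsplits <- bootstrap_splits(split$train_subjects, plan$n_bootstraps,
                              plan$val_fraction, round_index, plan$seed)
  val_mae <- numeric(plan$n_bootstraps)
  boot_weights <- vector("list", plan$n_bootstraps)
  for (b in seq_len(plan$n_bootstraps)) {
    bs <- bsplits[[b]]
    mb <- load_weights(model, global_weights)
    mb <- apply_freeze_policy(mb, plan$freeze_mode)
    tr_rows <- data_rows(client_data, bs$train_subjects)
    va_rows <- data_rows(client_data, bs$val_subjects)
    mb <- train_model(mb, client_data$X[tr_rows, , drop = FALSE],
                      client_data$index$target[tr_rows], client_data$dims,
                      epochs = plan$epochs_per_round,
                      batch_size = plan$batch_size, lr = plan$learning_rate,
                      seed = derive_seed(plan$seed, round_index, b, 777))
    pv <- predict_model(mb, client_data$X[va_rows, , drop = FALSE],
                        client_data$dims, batch_size = plan$batch_size)
    val_mae[b] <- mae(client_data$index$target[va_rows], pv)
    boot_weights[[b]] <- weights_of(mb)
  }
  weights <- if (plan$selector == "best") {
    boot_weights[[which.min(val_mae)]]
  } else {
    acc <- boot_weights[[1]]
    for (b in seq_len(plan$n_bootstraps)[-1]) acc <- acc + boot_weights[[b]]
    acc / plan$n_bootstraps
  }
  structure(list(client_name = client_name,
                 round_index = as.integer(round_index),
                 weights = weights,
                 n_train_samples = length(train_rows_all),
                 val_mae_per_bootstrap = val_mae,
                 val_mae_mean = mean(val_mae),
                 val_mae_ci95 = boot_ci95(val_mae)),
            class = "fl_client_update")
}

#' Evaluate a weight set on a client's held-out test subjects
#'
#' Deterministic forward passes over all images of the split's test
#' subjects, ordered by (subject ID, image index).
#'
#' @inheritParams run_client_round
#' @param weights The `weight_set` to evaluate.
#' @return Data.frame with `subject_id`, `image`, `truth`, `predicted`.
#' @export
evaluate_on_test <- function(weights, model, client_data, split,
                             batch_size = 10) {
  rows <- data_rows(client_data, split$test_subjects)
  if (length(rows) < 1L)
    stop_fedbids("client has an empty test set", "fedbids_config_error")
  m <- load_weights(model, weights)
  preds <- predict_model(m, client_data$X[rows, , drop = FALSE],
                         client_data$dims, batch_size = batch_size)
  data.frame(subject_id = client_data$index$subject_id[rows],
             image = client_data$index$image[rows],
             truth = client_data$index$target[rows],
             predicted = preds, stringsAsFactors = FALSE)
}
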