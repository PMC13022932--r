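# Server orchestration: client sampling, sample-size-weighted federated
# averaging, the federation round loop with early stopping and best-round
# model selection, and the hyperparameter-synced centralised benchmark.

#' Sample clients into a round's aggregation
#'
#' Uniform random subset without replacement, deterministic under
#' (plan seed, round index); returned in sorted (canonical) order.
#'
#' @param client_names Character vector of client names.
#' @param k Number of clients to sample.
#' @param round_index Federation round.
#' @param seed The plan's base seed.
#' @return Sorted character vector of `k` names.
#' @export
sample_clients <- function(client_names, k, round_index, seed = 1L) {
  n <- length(client_names)
  if (k < 1L || k > n)
    stop_fedbids(sprintf("cannot sample %d of %d clients", k, n),
                 "fedbids_config_error")
  sort(with_seed(derive_seed(seed, round_index, 555),
                 sample(client_names, k)))
}

#' Sample-size-weighted federated averaging
#'
#' For every parameter `p`: `out[p] = sum_i (n_i / N) w_i[p]` with
#' `N = sum_i n_i`, computed in double precision as the first update plus
#' weighted deviations from it — algebraically identical, and bit-exact when
#' all updates coincide (a plain weighted sum is not, in floating point).
#'
#' @param updates List of updates, each a list with `weights` (a
#'   `weight_set`) and `n` (positive sample size); `fl_client_update`
#'   objects (which carry `n_train_samples`) are accepted directly.
#' @return The aggregated `weight_set`.
#' @export
fedavg <- function(updates) {
  if (length(updates) < 1L)
    stop_fedbids("fedavg needs at least one update", "fedbids_input_error")
  get_n <- function(u) as.numeric(u$n %||% u$n_train_samples)
  ns <- vapply(updates, get_n, numeric(1))
  if (any(!is.finite(ns)) || any(ns <= 0))
    stop_fedbids("all sample sizes must be positive", "fedbids_input_error")
  ref <- updates[[1]]$weights
  keys <- names(ref)
  for (u in updates[-1]) {
    if (!identical(names(u$weights), keys)) {
      bad <- c(setdiff(keys, names(u$weights)),
               setdiff(names(u$weights), keys))
      stop_fedbids(paste0("weight sets disagree on keys: ",
                          paste(unique(bad), collapse = ", ")),
                   "fedbids_aggregation_error")
    }
  }
  N <- sum(ns)
  out <- unclass(ref)
  for (i in seq_along(updates)[-1]) {
    ci <- ns[i] / N
    wi <- updates[[i]]$weights
    for (key in keys) {
      if (length(wi[[key]]) != length(out[[key]]))
        stop_fedbids(sprintf("shape mismatch for parameter '%s'", key),
                     "fedbids_aggregation_error")
      out[[key]] <- out[[key]] + ci * (wi[[key]] - ref[[key]])
    }
  }
  structure(out, class = "weight_set")
}

new_history <- function() {
  list(rounds = data.frame(round = integer(), avg_val_mae = numeric(),
                           sampled = character(), stringsAsFactors = FALSE),
       per_client = data.frame(round = integer(), client = character(),
                               val_mae_mean = numeric(),
                               val_mae_ci_lo = numeric(),
                               val_mae_ci_hi = numeric(),
                               n_train = integer(), in_sample = logical(),
                               stringsAsFactors = FALSE))
}

append_round <- function(history, round_index, updates, sampled, avg) {
  history$rounds <- rbind(history$rounds, data.frame(
    round = round_index, avg_val_mae = avg,
    sampled = paste(sampled, collapse = ","), stringsAsFactors = FALSE))
  for (u in updates) {
    history$per_client <- rbind(history$per_client, data.frame(
      round = round_index, client = u$client_name,
      val_mae_mean = u$val_mae_mean,
      val_mae_ci_lo = u$val_mae_ci95[1], val_mae_ci_hi = u$val_mae_ci95[2],
      n_train = u$n_train_samples, in_sample = u$client_name %in% sampled,
      stringsAsFactors = FALSE))
  }
  history
}

log_round <- function(ws, round_index, updates, sampled, avg) {
  rec <- list(round = round_index, sampled = sampled, avg_val_mae = avg,
              clients = lapply(updates, function(u)
                list(name = u$client_name, val_mae_mean = u$val_mae_mean,
                     n_train = u$n_train_samples)))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = file.path(ws$logs, "rounds.jsonl"), append = TRUE)
}

#' Drive a federation
#'
#' The server loop: broadcast the current global weights to every client,
#' collect every client's update, sample `clients_per_round` of them,
#' aggregate the sampled updates with [fedavg()], and record the average
#' validation MAE across the sampled clients. Training stops early once that
#' average has not improved its running minimum for `patience` consecutive
#' rounds; the final model is the aggregate of the round with the minimum
#' server-side average validation MAE (not the last round). The final model
#' and a stop message are then broadcast, and the full history is persisted
#' (JSON-lines round log plus tab-separated summary under the server
#' workspace).
#'
#' A client that fails to report within `timeout_s` aborts the federation
#' with an error naming it: silent client loss would corrupt the sample-size
#' weighting unnoticed.
#'
#' @param plan An [fl_plan()].
#' @param settings A [server_settings()].
#' @param transport An `fl_transport` reaching every client.
#' @param client_drivers Optional named list of functions
#'   `function(round_index)`; when supplied (simulation mode) they are
#'   invoked after each broadcast to make the in-process clients act.
#' @param model Optional model skeleton; defaults to sourcing the settings'
#'   model-definition file and calling its `build_model()`.
#' @param timeout_s,poll_s Receive timeout and poll interval (seconds).
#' @param verbose Print per-round progress.
#' @return List of class `fl_result`: `final_weights`, `final_round`,
#'   `stopped_round`, `history` (an `fl_history`).
#' @export
run_federation <- function(plan, settings, transport, client_drivers = NULL,
                           model = NULL, timeout_s = 86400, poll_s = 0.05,
                           verbose = FALSE) {
  stopifnot(inherits(plan, "fl_plan"), inherits(settings, "server_settings"))
  client_names <- vapply(settings$clients, `[[`, character(1), "name")
  if (plan$clients_per_round > length(client_names))
    stop_fedbids("clients_per_round exceeds the number of clients",
                 "fedbids_config_error")
  ws <- init_workspace(settings$workspace_root, "server")
  if (is.null(model)) {
    env <- new.env()
    sys.source(settings$model_definition, envir = env)
    if (!is.function(env$build_model))
      stop_fedbids("model definition file must define build_model()",
                   "fedbids_config_error")
    model <- env$build_model()
  }
  bundle <- tempfile(fileext = ".json")
  jsonlite::write_json(list(plan = unclass(plan),
                            model_spec = unclass(model$spec)),
                       bundle, auto_unbox = TRUE, digits = NA)
  for (nm in client_names)
    fl_send(fl_message("plan", 0L, bundle, "server"), transport, nm)
  unlink(bundle)
  global <- weights_of(model)
  history <- new_history()
  aggregates <- list()
  best <- Inf
  since_improve <- 0L
  stopped_round <- plan$n_rounds_max
  for (r in seq_len(plan$n_rounds_max)) {
    gpath <- file.path(ws$state, sprintf("global_round%d.rds", r))
    save_weights(global, gpath)
    for (nm in client_names)
      fl_send(fl_message("global_model", r, gpath, "server"), transport, nm)
    if (!is.null(client_drivers))
      for (nm in client_names) client_drivers[[nm]](r)
    updates <- list()
    for (nm in client_names) {
      msg <- tryCatch(
        fl_receive(ws, "client_update", r, nm, timeout_s, poll_s),
        fedbids_timeout_error = function(e) stop_fedbids(
          sprintf("federation aborted: client '%s' silent in round %d (%s)",
                  nm, r, conditionMessage(e)),
          "fedbids_federation_error", client = nm))
      updates[[nm]] <- readRDS(msg$payload_path)
    }
    sampled <- sample_clients(client_names, plan$clients_per_round, r,
                              plan$seed)
    agg <- fedavg(updates[sampled])
    avg <- mean(vapply(updates[sampled], `[[`, numeric(1), "val_mae_mean"))
    apath <- file.path(ws$state, sprintf("aggregate_round%d.rds", r))
    save_weights(agg, apath)
    aggregates[[r]] <- apath
    history <- append_round(history, r, updates, sampled, avg)
    log_round(ws, r, updates, sampled, avg)
    if (verbose)
      message(sprintf("round %d: avg val MAE %.3f (sample: %s)",
                      r, avg, paste(sampled, collapse = ",")))
    if (avg < best) {
      best <- avg
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
    }
    global <- agg
    if (since_improve >= plan$patience) {
      stopped_round <- r
      break
    }
    stopped_round <- r
  }
  final_round <- history$rounds$round[which.min(history$rounds$avg_val_mae)]
  final_weights <- read_weights(aggregates[[final_round]])
  fpath <- file.path(ws$state, "final_model.rds")
  save_weights(final_weights, fpath)
  # announced on the round the clients are about to wait for
  for (nm in client_names) {
    fl_send(fl_message("final_model", stopped_round + 1L, fpath, "server"),
            transport, nm)
    fl_send(fl_message("stop", stopped_round + 1L, tempfile(), "server"),
            transport, nm)
  }
  write.table(history$rounds, file.path(ws$logs, "round_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  class(history) <- "fl_history"
  structure(list(final_weights = final_weights, final_round = final_round,
                 stopped_round = stopped_round, history = history),
            class = "fl_result")
}

#' Centralised benchmark run with federation-synced hyperparameters
#'
#' One training process over the union of the clients' training pools,
#' mimicking federated training as closely as possible: the same per-round
#' bootstrap structure with each client's bootstrap-b partitions merged by
#' index, validation MAE over the merged validation set, the same
#' best-of-bootstraps selection, early stopping and best-round model choice.
#' (Test evaluation of a centralised model pools all test subjects, rather
#' than using the per-client weighting.)
#'
#' @param plan An [fl_plan()].
#' @param client_datasets Named list, one entry per client: a list with
#'   `data` (a `client_data`) and `split` (that client's `fl_split`).
#' @param model Model skeleton providing the initial weights.
#' @param verbose Print per-round progress.
#' @return List of class `fl_result` (per-round `history` has a single
#'   pseudo-client `"centralized"`).
#' @export
run_centralized <- function(plan, client_datasets, model, verbose = FALSE) {
  stopifnot(length(client_datasets) >= 1L)
  global <- weights_of(model)
  history <- new_history()
  aggregates <- list()
  best <- Inf
  since_improve <- 0L
  stopped_round <- plan$n_rounds_max
  for (r in seq_len(plan$n_rounds_max)) {
    # merged bootstrap b = union over clients of their bootstrap-b partition
    per_client_bs <- lapply(client_datasets, function(cd)
      bootstrap_splits(cd$split$train_subjects, plan$n_bootstraps,
                       plan$val_fraction, r, plan$seed))
    val_mae <- numeric(plan$n_bootstraps)
    boot_weights <- vector("list", plan$n_bootstraps)
    for (b in seq_len(plan$n_bootstraps)) {
      Xtr <- list(); ttr <- list(); Xva <- list(); tva <- list()
      for (nm in names(client_datasets)) {
        cd <- client_datasets[[nm]]
        bs <- per_client_bs[[nm]][[b]]
        tr <- data_rows(cd$data, bs$train_subjects)
        va <- data_rows(cd$data, bs$val_subjects)
        Xtr[[nm]] <- cd$data$X[tr, , drop = FALSE]
        ttr[[nm]] <- cd$data$index$target[tr]
        Xva[[nm]] <- cd$data$X[va, , drop = FALSE]
        tva[[nm]] <- cd$data$index$target[va]
      }
      mb <- load_weights(model, global)
      mb <- apply_freeze_policy(mb, plan$freeze_mode)
      mb <- train_model(mb, do.call(rbind, Xtr), unlist(ttr),
                        client_datasets[[1]]$data$dims,
                        epochs = plan$epochs_per_round,
                        batch_size = plan$batch_size,
                        lr = plan$learning_rate,
                        seed = derive_seed(plan$seed, r, b, 777))
      pv <- predict_model(mb, do.call(rbind, Xva),
                          client_datasets[[1]]$data$dims,
                          batch_size = plan$batch_size)
      val_mae[b] <- mae(unlist(tva), pv)
      boot_weights[[b]] <- weights_of(mb)
    }
    agg <- if (plan$selector == "best") {
      boot_weights[[which.min(val_mae)]]
    } else {
      acc <- boot_weights[[1]]
      for (b in seq_len(plan$n_bootstraps)[-1]) acc <- acc + boot_weights[[b]]
      acc / plan$n_bootstraps
    }
    avg <- mean(val_mae)
    update <- list(client_name = "centralized", val_mae_mean = avg,
                   val_mae_ci95 = boot_ci95(val_mae),
                   n_train_samples = sum(vapply(
                     client_datasets, function(cd)
                       length(data_rows(cd$data, cd$split$train_subjects)),
                     numeric(1))))
    history <- append_round(history, r, list(update), "centralized", avg)
    aggregates[[r]] <- agg
    if (verbose)
      message(sprintf("centralized round %d: val MAE %.3f", r, avg))
    if (avg < best) {
      best <- avg
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
    }
    global <- agg
    stopped_round <- r
    if (since_improve >= plan$patience) break
  }
  final_round <- history$rounds$round[which.min(history$rounds$avg_val_mae)]
  class(history) <- "fl_history"
  structure(list(final_weights = aggregates[[final_round]],
                 final_round = final_round, stopped_round = stopped_round,
                 history = history),
            class = "fl_result")
}
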