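# Desk-scale federation simulation: synthetic non-IID phantom clients, local
# transport, server and clients in one process tree — plus the standalone
# polling client loop used when server and clients are separate processes.

client_split_seed <- function(plan) derive_seed(plan$seed, 31)

build_client_state <- function(dataset_root, target_column, plan,
                               preprocess_cfg) {
  records <- discover_subjects(dataset_root, target_column)
  split <- subject_split(records, plan$test_fraction,
                         seed = client_split_seed(plan))
  data <- prepare_client_data(records, preprocess_cfg)
  list(records = records, split = split, data = data)
}

#' Simulate a federation on synthetic non-IID phantom clients
#'
#' Generates one BIDS phantom dataset per client (uniform targets; one
#' client's targets shifted by `target_shift` — the non-IID knob emulating
#' between-centre differences in the target distribution), spawns server and
#' client workspaces wired over the local transport, runs the full federated
#' protocol, evaluates the final model on every client's held-out test
#' subjects, and writes the evaluation report.
#'
#' @param plan An [fl_plan()].
#' @param n_subjects Integer vector: subjects per client.
#' @param shifted_client Index of the client whose target distribution is
#'   shifted (0 for none).
#' @param target_shift Shift in target units added to that client's targets.
#' @param work_dir Directory for datasets, workspaces and reports (defaults
#'   to a fresh temporary directory).
#' @param model_spec The [densenet_spec()] to train (desk-scale default:
#'   [densenet_small_spec()]).
#' @param phantom Base [phantom_config()]; per-client copies get the sizes,
#'   shift and derived seeds.
#' @param preprocess A [preprocess_config()]; the default matches the
#'   phantom geometry (32^3 window at native spacing) so simulations stay
#'   desk-scale.
#' @param verbose Print per-round progress.
#' @return List with `result` (an `fl_result`), `evaluation` (per-client
#'   metrics data.frame), `overall_mae`, `report_dir`, `client_states`.
#' @export
simulate_federation <- function(plan = fl_plan(),
                                n_subjects = c(40L, 60L, 80L),
                                shifted_client = 3L, target_shift = 25,
                                work_dir = tempfile("fedsim"),
                                model_spec = densenet_small_spec(),
                                phantom = phantom_config(),
                                preprocess = preprocess_config(
                                  target_spacing = phantom$voxel_spacing_mm,
                                  window = phantom$volume_shape[1]),
                                verbose = FALSE) {
  n_clients <- length(n_subjects)
  stopifnot(n_clients >= 1L, shifted_client <= n_clients)
  client_names <- sprintf("client%d", seq_len(n_clients))
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)

  states <- list()
  for (i in seq_len(n_clients)) {
    cfg <- phantom
    cfg$n_subjects <- as.integer(n_subjects[i])
    cfg$seed <- derive_seed(plan$seed, 1000 + i)
    cfg$target_shift <- if (i == shifted_client) target_shift else 0
    droot <- file.path(work_dir, "data", client_names[i])
    generate_bids_dataset(cfg, droot)
    states[[client_names[i]]] <-
      build_client_state(droot, cfg$target_name, plan, preprocess)
  }

  model <- build_densenet(model_spec, seed = derive_seed(plan$seed, 99))
  roots <- c(stats::setNames(
    file.path(work_dir, "ws", client_names), client_names),
    server = file.path(work_dir, "ws", "server"))
  transport <- local_transport(roots)
  client_ws <- lapply(client_names, function(nm)
    init_workspace(roots[[nm]], "client"))
  names(client_ws) <- client_names

  drivers <- lapply(client_names, function(nm) {
    force(nm)
    function(round_index) {
      msg <- fl_receive(client_ws[[nm]], "global_model", round_index,
                        "server", timeout_s = 60, poll_s = 0.01)
      gw <- read_weights(msg$payload_path)
      upd <- run_client_round(gw, plan, states[[nm]]$data,
                              states[[nm]]$split, round_index, model,
                              client_name = nm)
      upath <- file.path(client_ws[[nm]]$outbox,
                         sprintf("update_round%d.rds", round_index))
      saveRDS(upd, upath, version = 2)
      fl_send(fl_message("client_update", round_index, upath, nm),
              transport, "server")
    }
  })
  names(drivers) <- client_names

  settings <- server_settings(
    workspace_root = roots[["server"]],
    clients = lapply(client_names, function(nm)
      list(name = nm, address = nm, workspace_root = roots[[nm]])),
    model_definition = NA_character_, plan_path = NA_character_)

  result <- run_federation(plan, settings, transport,
                           client_drivers = drivers, model = model,
                           timeout_s = 600, poll_s = 0.01,
                           verbose = verbose)

  evals <- list(); scatter <- list()
  for (nm in client_names) {
    pairs <- evaluate_on_test(result$final_weights, model,
                              states[[nm]]$data, states[[nm]]$split,
                              batch_size = plan$batch_size)
    evals[[nm]] <- evaluate_predictions(pairs, client_name = nm, bad = TRUE)
    scatter[[nm]] <- data.frame(client_name = nm, truth = pairs$truth,
                                predicted = pairs$predicted,
                                stringsAsFactors = FALSE)
  }
  evaluation <- do.call(rbind, evals)
  report_dir <- file.path(work_dir, "report")
  emit_report(evaluation, result$history, report_dir,
              scatter = do.call(rbind, scatter))
  list(result = result, evaluation = evaluation,
       overall_mae = overall_mae(evaluation$mae, evaluation$n_test),
       report_dir = report_dir, client_states = states)
}

#' Run a standalone federation client (polling loop)
#'
#' Joins a federation as a separate process: waits for the plan, then for
#' each round's global model, trains locally via [run_client_round()] and
#' returns the update, until the final model and stop message arrive.
#'
#' @param settings A [client_settings()].
#' @param transport An `fl_transport` that reaches the server.
#' @param preprocess A [preprocess_config()].
#' @param model Optional model skeleton; by default rebuilt from the model
#'   spec carried in the plan message.
#' @param timeout_s,poll_s Receive timeout and poll interval (seconds).
#' @return Invisibly, the path of the received final model checkpoint.
#' @export
run_client <- function(settings, transport,
                       preprocess = preprocess_config(), model = NULL,
                       timeout_s = 86400, poll_s = 5) {
  stopifnot(inherits(settings, "client_settings"))
  ws <- init_workspace(settings$workspace_root, "client")
  pmsg <- fl_receive(ws, "plan", 0L, "server", timeout_s, poll_s)
  bundle <- jsonlite::read_json(pmsg$payload_path, simplifyVector = TRUE)
  plan <- do.call(fl_plan, bundle$plan)
  if (is.null(model)) {
    sp <- bundle$model_spec
    model <- build_densenet(
      densenet_spec(in_channels = sp$in_channels, out_units = sp$out_units,
                    init_features = sp$init_features,
                    growth_rate = sp$growth_rate,
                    block_layers = sp$block_layers,
                    bottleneck_factor = sp$bottleneck_factor,
                    compression = sp$compression),
      seed = derive_seed(plan$seed, 99))
  }
  state <- build_client_state(settings$dataset_root, settings$target_column,
                              plan, preprocess)
  r <- 1L
  repeat {
    msg <- fl_receive(ws, c("global_model", "final_model"), r, "server",
                      timeout_s, poll_s)
    if (msg$kind == "final_model") {
      final <- file.path(ws$state, "final_model.rds")
      file.copy(msg$payload_path, final, overwrite = TRUE)
      return(invisible(final))
    }
    gw <- read_weights(msg$payload_path)
    upd <- run_client_round(gw, plan, state$data, state$split, r, model,
                            client_name = settings$client_name)
    upath <- file.path(ws$outbox, sprintf("update_round%d.rds", r))
    saveRDS(upd, upath, version = 2)
    fl_send(fl_message("client_update", r, upath, settings$client_name),
            transport, settings$server)
    r <- r + 1L
  }
}
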