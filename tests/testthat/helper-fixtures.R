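# Shared fixtures: tiny network specs, phantom datasets and weight sets
# built in code at test time.

tiny_spec <- function() {
  densenet_spec(init_features = 4L, growth_rate = 2L,
                block_layers = c(1L, 1L, 1L, 1L), bottleneck_factor = 2L)
}

# A generated phantom dataset on disk plus discovered records.
make_phantom_dataset <- function(n = 10, seed = 1, dir = tempfile("bids"),
                                 images_per_subject = 1, noise_sd = 0.1,
                                 target_shift = 0) {
  cfg <- phantom_config(n_subjects = n, seed = seed,
                        images_per_subject = images_per_subject,
                        noise_sd = noise_sd, target_shift = target_shift)
  generate_bids_dataset(cfg, dir)
  list(config = cfg, root = dir,
       records = discover_subjects(dir, cfg$target_name))
}

phantom_preprocess <- function() {
  preprocess_config(target_spacing = 1.0, window = 32L)
}

# Preprocessed matrix + targets for a dataset on disk.
phantom_matrix <- function(records, config = phantom_preprocess()) {
  data <- prepare_client_data(records, config)
  list(X = data$X, targets = data$index$target, dims = data$dims,
       data = data)
}

# Small random weight sets for aggregation tests.
random_weight_set <- function(seed, shapes = list(a = c(3, 2), b = 5,
                                                  c = c(2, 2, 2))) {
  set.seed(seed)
  ws <- lapply(shapes, function(s) {
    if (length(s) == 1) rnorm(s) else array(rnorm(prod(s)), dim = s)
  })
  structure(ws, class = "weight_set")
}

# In-memory federation fixture: fake clients that report prescribed
# validation MAEs and constant weight sets, for orchestration logic tests.
run_scripted_federation <- function(val_mae_by_round, plan,
                                    work_dir = tempfile("fedfake")) {
  model <- build_densenet(tiny_spec(), seed = 1)
  roots <- c(client1 = file.path(work_dir, "c1"),
             server = file.path(work_dir, "s"))
  transport <- local_transport(roots)
  cws <- init_workspace(roots[["client1"]], "client")
  driver <- function(r) {
    msg <- fl_receive(cws, "global_model", r, "server",
                      timeout_s = 30, poll_s = 0.01)
    gw <- read_weights(msg$payload_path)
    upd <- structure(list(
      client_name = "client1", round_index = r,
      weights = gw * 0 + r,
      n_train_samples = 10L,
      val_mae_per_bootstrap = rep(val_mae_by_round[r], plan$n_bootstraps),
      val_mae_mean = val_mae_by_round[r],
      val_mae_ci95 = rep(val_mae_by_round[r], 2)), class = "fl_client_update")
    up <- file.path(cws$outbox, sprintf("u%d.rds", r))
    saveRDS(upd, up, version = 2)
    fl_send(fl_message("client_update", r, up, "client1"),
            transport, "server")
  }
  settings <- server_settings(
    workspace_root = roots[["server"]],
    clients = list(list(name = "client1", address = "client1",
                        workspace_root = roots[["client1"]])),
    model_definition = NA_character_, plan_path = NA_character_)
  run_federation(plan, settings, transport,
                 client_drivers = list(client1 = driver), model = model,
                 timeout_s = 30, poll_s = 0.01)
}
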