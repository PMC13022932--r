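# End-to-end federation behaviour on real (synthetic-phantom) clients.

test_that("a 1-client federation equals the standalone centralized loop", {
  plan <- fl_plan(n_rounds_max = 2, n_bootstraps = 2, clients_per_round = 1,
                  learning_rate = 0.05, seed = 11)
  sim <- simulate_federation(plan, n_subjects = 8, shifted_client = 0)
  st <- sim$client_states[[1]]
  model <- build_densenet(densenet_small_spec(),
                          seed = derive_seed(plan$seed, 99))
  cen <- run_centralized(plan,
                         list(client1 = list(data = st$data,
                                             split = st$split)), model)
  expect_identical(unclass(sim$result$final_weights),
                   unclass(cen$final_weights))
  expect_equal(sim$result$history$rounds$avg_val_mae,
               cen$history$rounds$avg_val_mae)
})

test_that("centralized validation merges the per-client bootstrap splits", {
  # with a zero learning rate the trained model equals the initial model, so
  # the reported validation MAE must equal the initial model's MAE over the
  # union of the clients' bootstrap-b validation sets
  plan <- fl_plan(n_rounds_max = 1, n_bootstraps = 2, learning_rate = 0,
                  seed = 13)
  d1 <- make_phantom_dataset(n = 6, seed = 31)
  d2 <- make_phantom_dataset(n = 8, seed = 32)
  cds <- lapply(list(d1, d2), function(d) {
    pm <- phantom_matrix(d$records)
    list(data = pm$data,
         split = subject_split(d$records, plan$test_fraction,
                               seed = fedbids:::client_split_seed(plan)))
  })
  names(cds) <- c("c1", "c2")
  model <- build_densenet(densenet_small_spec(), seed = 1)
  res <- run_centralized(plan, cds, model)
  # recompute by hand for bootstrap b = 1, 2 and average
  val_mae <- vapply(1:2, function(b) {
    truths <- list(); preds <- list()
    for (nm in names(cds)) {
      bs <- bootstrap_splits(cds[[nm]]$split$train_subjects, 2,
                             plan$val_fraction, 1, plan$seed)[[b]]
      rows <- fedbids:::data_rows(cds[[nm]]$data, bs$val_subjects)
      truths[[nm]] <- cds[[nm]]$data$index$target[rows]
      preds[[nm]] <- cds[[nm]]$data$X[rows, , drop = FALSE]
    }
    mae(unlist(truths),
        predict_model(model, do.call(rbind, preds), cds$c1$data$dims,
                      plan$batch_size))
  }, numeric(1))
  expect_equal(res$history$rounds$avg_val_mae, mean(val_mae))
})

test_that("federation aborts with a report naming a silent client", {
  model <- build_densenet(tiny_spec(), seed = 1)
  wd <- tempfile("fedsilent")
  roots <- c(mute = file.path(wd, "mute"), server = file.path(wd, "s"))
  init_workspace(roots[["mute"]], "client")
  transport <- local_transport(roots)
  settings <- server_settings(
    workspace_root = roots[["server"]],
    clients = list(list(name = "mute", address = "mute",
                        workspace_root = roots[["mute"]])),
    model_definition = NA_character_, plan_path = NA_character_)
  plan <- fl_plan(n_rounds_max = 2, clients_per_round = 1, seed = 1)
  err <- tryCatch(
    run_federation(plan, settings, transport,
                   client_drivers = list(mute = function(r) NULL),
                   model = model, timeout_s = 0.3, poll_s = 0.05),
    error = identity)
  expect_s3_class(err, "fedbids_federation_error")
  expect_match(conditionMessage(err), "mute")
})

test_that("the polling client loop interoperates with the server loop", {
  # run_client() in a background R process against run_federation()
  wd <- tempfile("fedproc")
  dir.create(wd, recursive = TRUE)
  droot <- file.path(wd, "bids")
  generate_bids_dataset(phantom_config(n_subjects = 6, seed = 41), droot)
  roots <- c(worker = file.path(wd, "worker"), server = file.path(wd, "s"))
  init_workspace(roots[["worker"]], "client")
  plan <- fl_plan(n_rounds_max = 2, n_bootstraps = 1, clients_per_round = 1,
                  learning_rate = 0.05, seed = 17)
  model <- build_densenet(tiny_spec(), seed = derive_seed(plan$seed, 99))
  cs <- client_settings(roots[["worker"]], droot, "age", "server", "worker")
  csf <- file.path(wd, "client_settings.json")
  write_fl_json(cs, csf)
  script <- file.path(wd, "client.R")
  writeLines(sprintf('
    .libPaths(%s)
    suppressMessages(library(fedbids))
    cs <- read_client_settings("%s")
    tr <- local_transport(c(server = "%s", worker = "%s"))
    run_client(cs, tr,
               preprocess = preprocess_config(target_spacing = 1, window = 32),
               timeout_s = 120, poll_s = 0.05)
  ', paste(deparse(.libPaths()), collapse = ""), csf,
    roots[["server"]], roots[["worker"]]), script)
  p <- system2("Rscript", script, wait = FALSE,
               stdout = file.path(wd, "client.log"),
               stderr = file.path(wd, "client.log"))
  settings <- server_settings(
    workspace_root = roots[["server"]],
    clients = list(list(name = "worker", address = "worker",
                        workspace_root = roots[["worker"]])),
    model_definition = NA_character_, plan_path = NA_character_)
  transport <- local_transport(roots)
  res <- run_federation(plan, settings, transport, model = model,
                        timeout_s = 120, poll_s = 0.05)
  expect_s3_class(res, "fl_result")
  expect_equal(nrow(res$history$rounds), 2)
  # the client stored the final model it was sent
  final <- file.path(roots[["worker"]], "state", "final_model.rds")
  for (i in 1:100) {
    if (file.exists(final)) break
    Sys.sleep(0.1)
  }
  expect_true(file.exists(final))
  expect_identical(unclass(read_weights(final)),
                   unclass(res$final_weights))
})
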