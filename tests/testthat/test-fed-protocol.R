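# Workspace, settings documents, and the two-file (payload + marker)
# transmission protocol.

make_pair <- function() {
  roots <- c(alice = tempfile("alice"), bob = tempfile("bob"))
  list(roots = roots,
       alice = init_workspace(roots[["alice"]], "client"),
       bob = init_workspace(roots[["bob"]], "server"),
       transport = local_transport(roots))
}

test_that("workspaces initialise idempotently and guard their role", {
  root <- tempfile("ws")
  ws <- init_workspace(root, "server")
  expect_true(all(dir.exists(file.path(
    root, c("inbox", "outbox", "state", "logs", "preproc_cache")))))
  ws2 <- init_workspace(root, "server")
  expect_identical(ws2$root, ws$root)
  expect_error(init_workspace(root, "client"),
               class = "fedbids_conflict_error")
})

test_that("send places payload before marker under deterministic names", {
  p <- make_pair()
  f <- tempfile(fileext = ".rds")
  saveRDS(list(x = 1), f)
  fl_send(fl_message("global_model", 3, f, "server"), p$transport, "alice")
  inbox <- p$alice$inbox
  expect_true(file.exists(file.path(inbox, "global_model_round3_server.rds")))
  marker <- file.path(inbox, "global_model_round3_server.done")
  expect_true(file.exists(marker))
  expect_equal(file.size(marker), 0)
  expect_gte(as.numeric(file.mtime(marker)),
             as.numeric(file.mtime(
               file.path(inbox, "global_model_round3_server.rds"))))
  # a re-send of the same message is one logical message
  fl_send(fl_message("global_model", 3, f, "server"), p$transport, "alice")
  expect_length(list.files(inbox, pattern = "^global_model_round3"), 2)
  # missing payloads are refused before anything is transmitted
  expect_error(
    fl_send(fl_message("client_update", 1, tempfile(), "alice"),
            p$transport, "bob"),
    class = "fedbids_protocol_error")
})

test_that("receive is gated on the marker, not the payload", {
  p <- make_pair()
  # payload present, marker absent: must time out, payload untouched
  writeLines("partial", file.path(p$alice$inbox, "plan_round0_server.json"))
  expect_error(
    fl_receive(p$alice, "plan", 0, "server", timeout_s = 0.3, poll_s = 0.05),
    class = "fedbids_timeout_error")
  # marker arrives: message is returned immediately
  file.create(file.path(p$alice$inbox, "plan_round0_server.done"))
  msg <- fl_receive(p$alice, "plan", 0, "server", timeout_s = 1,
                    poll_s = 0.05)
  expect_equal(msg$kind, "plan")
  expect_equal(readLines(msg$payload_path), "partial")
})

test_that("a slowly written payload is never consumed torn (chaos test)", {
  p <- make_pair()
  payload <- file.path(p$alice$inbox, "client_update_round1_bob.txt")
  marker <- file.path(p$alice$inbox, "client_update_round1_bob.done")
  # background writer: dribbles the payload out, then writes the marker
  script <- sprintf(
    "for i in $(seq 1 20); do printf 'line%%d\\n' $i >> %s; sleep 0.02; done; : > %s",
    shQuote(payload), shQuote(marker))
  system2("bash", c("-c", shQuote(script)), wait = FALSE)
  msg <- fl_receive(p$alice, "client_update", 1, "bob", timeout_s = 10,
                    poll_s = 0.01)
  got <- readLines(msg$payload_path)
  expect_length(got, 20)
  expect_identical(got, sprintf("line%d", 1:20))
})

test_that("the remote-copy transport reproduces the local exchange", {
  # loopback remote endpoint: plain `cp` as the authenticated-copy command
  roots <- c(hub = tempfile("hub"))
  hub_local <- init_workspace(roots[["hub"]], "server")
  hub_remote_root <- tempfile("hubR")
  hub_remote <- init_workspace(hub_remote_root, "server")
  tl <- local_transport(roots)
  tr <- remote_copy_transport("cp {src} {dest}",
                              list(hub = file.path(hub_remote_root, "inbox")))
  f <- tempfile(fileext = ".rds")
  saveRDS(random_weight_set(1), f)
  for (kind in c("plan", "global_model", "client_update", "final_model")) {
    fl_send(fl_message(kind, 2, f, "peer"), tl, "hub")
    fl_send(fl_message(kind, 2, f, "peer"), tr, "hub")
  }
  for (fn in list.files(hub_local$inbox)) {
    a <- file.path(hub_local$inbox, fn)
    b <- file.path(hub_remote$inbox, fn)
    expect_true(file.exists(b))
    if (file.size(a) > 0)
      expect_identical(readBin(a, "raw", file.size(a)),
                       readBin(b, "raw", file.size(b)))
  }
  # failing copy commands surface as retryable transport errors
  tbad <- remote_copy_transport("false # {src} {dest}", list(hub = "x"),
                                retries = 2)
  err <- tryCatch(fl_send(fl_message("plan", 1, f, "peer"), tbad, "hub"),
                  error = identity)
  expect_s3_class(err, "fedbids_transport_error")
  expect_equal(err$attempts, 2L)
})

test_that("settings and plan documents survive the JSON round trip", {
  plan <- fl_plan(n_rounds_max = 7, n_bootstraps = 5, batch_size = 10,
                  epochs_per_round = 2, learning_rate = 0.01,
                  clients_per_round = 2, patience = 4,
                  freeze_mode = "shallow", seed = 99)
  f <- tempfile(fileext = ".json")
  write_fl_json(plan, f)
  expect_equal(read_fl_plan(f), plan)

  ss <- server_settings(
    workspace_root = "/srv/fl",
    clients = list(list(name = "brussels", address = "10.0.0.2",
                        workspace_root = "/home/fl"),
                   list(name = "prague", address = "10.0.0.3",
                        workspace_root = "/data/fl")),
    model_definition = "model.R", plan_path = "plan.json")
  fs <- tempfile(fileext = ".json")
  write_fl_json(ss, fs)
  expect_equal(read_server_settings(fs), ss)
  expect_error(server_settings("/srv", list(
    list(name = "a", address = "x", workspace_root = "w"),
    list(name = "a", address = "y", workspace_root = "v")),
    "m.R", "p.json"), class = "fedbids_input_error")

  cs <- client_settings("/home/fl", "/data/bids", "sdmt", "server",
                        "greifswald")
  fc <- tempfile(fileext = ".json")
  write_fl_json(cs, fc)
  expect_equal(read_client_settings(fc), cs)

  expect_error(fl_plan(val_fraction = 1.2), class = "fedbids_input_error")
})
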