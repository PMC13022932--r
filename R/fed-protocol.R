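# The federation workspace and two-file transmission protocol: every message
# is a payload file copied into the receiver's inbox, followed by a zero-byte
# `.done` marker. A receiver only ever reads payloads whose marker exists, so
# partially transferred files are never consumed.

MESSAGE_KINDS <- c("plan", "global_model", "client_update", "final_model",
                   "stop")

#' Initialise a federation workspace
#'
#' Creates the standard sub-folders (`inbox/`, `outbox/`, `state/`, `logs/`,
#' `preproc_cache/`) and a role marker. Re-initialisation with the same role
#' is a no-op; with a different role it is refused.
#'
#' @param root Workspace directory (created if absent).
#' @param role `"server"` or `"client"`.
#' @return A workspace handle (list with `root`, `role`, folder paths).
#' @export
init_workspace <- function(root, role = c("server", "client")) {
  role <- match.arg(role)
  marker <- file.path(root, "fl_role")
  if (file.exists(marker)) {
    existing <- readLines(marker, warn = FALSE)[1]
    if (!identical(existing, role))
      stop_fedbids(sprintf(
        "workspace '%s' already initialised with role '%s'", root, existing),
        "fedbids_conflict_error")
  }
  sub <- c("inbox", "outbox", "state", "logs", "preproc_cache")
  for (s in sub)
    dir.create(file.path(root, s), recursive = TRUE, showWarnings = FALSE)
  writeLines(role, marker)
  h <- c(list(root = root, role = role),
         stats::setNames(as.list(file.path(root, sub)), sub))
  structure(h, class = "fl_workspace")
}

#' Construct a federation message
#'
#' @param kind One of `"plan"`, `"global_model"`, `"client_update"`,
#'   `"final_model"`, `"stop"`.
#' @param round_index Federation round the message belongs to.
#' @param payload_path Path of the payload file (must exist before sending;
#'   `"stop"` messages may have an empty payload).
#' @param sender Sender label.
#' @return An `fl_message`.
#' @export
fl_message <- function(kind, round_index, payload_path, sender) {
  kind <- match.arg(kind, MESSAGE_KINDS)
  structure(list(kind = kind, round_index = as.integer(round_index),
                 payload_path = payload_path, sender = sender),
            class = "fl_message")
}

message_stem <- function(kind, round_index, sender, ext) {
  sprintf("%s_round%d_%s%s", kind, round_index, sender, ext)
}

# ---- transports -------------------------------------------------------------

#' Local shared-filesystem transport
#'
#' Maps participant names to workspace roots on the same filesystem; powers
#' single-machine simulation and tests.
#'
#' @param roots Named character vector/list: participant name -> workspace
#'   root.
#' @return An `fl_transport`.
#' @export
local_transport <- function(roots) {
  structure(list(type = "local", roots = as.list(roots)),
            class = "fl_transport")
}

#' Remote file-copy transport
#'
#' An authenticated file-copy contract in the shape of `scp`: a command
#' template with `{src}` and `{dest}` placeholders (e.g.
#' `"scp -i {key} {src} {host}:{dest}"` after filling in host/key yourself),
#' plus the mapping from participant name to its remote inbox directory.
#' The template is executed via the shell; a non-zero exit is a retryable
#' transport error.
#'
#' @param command_template Copy command with `{src}`/`{dest}` placeholders.
#' @param inboxes Named list: participant name -> destination inbox
#'   directory (remote path as understood by the command).
#' @param retries Number of attempts per file.
#' @return An `fl_transport`.
#' @export
remote_copy_transport <- function(command_template, inboxes, retries = 3L) {
  structure(list(type = "remote", template = command_template,
                 inboxes = as.list(inboxes), retries = as.integer(retries)),
            class = "fl_transport")
}

transport_copy <- function(transport, src, destination, filename) {
  if (transport$type == "local") {
    root <- transport$roots[[destination]]
    if (is.null(root))
      stop_fedbids(sprintf("unknown destination '%s'", destination),
                   "fedbids_transport_error")
    dest <- file.path(root, "inbox", filename)
    ok <- file.copy(src, dest, overwrite = TRUE)
    if (!ok)
      stop_fedbids(sprintf("local copy to '%s' failed", dest),
                   "fedbids_transport_error", attempts = 1L)
    return(invisible(dest))
  }
  inbox <- transport$inboxes[[destination]]
  if (is.null(inbox))
    stop_fedbids(sprintf("unknown destination '%s'", destination),
                 "fedbids_transport_error")
  dest <- file.path(inbox, filename)
  cmd <- gsub("{dest}", shQuote(dest),
              gsub("{src}", shQuote(src), transport$template, fixed = TRUE),
              fixed = TRUE)
  for (attempt in seq_len(transport$retries)) {
    status <- system(cmd, ignore.stdout = TRUE, ignore.stderr = TRUE)
    if (status == 0) return(invisible(dest))
  }
  stop_fedbids(sprintf(
    "transport command failed after %d attempts (exit %d): %s",
    transport$retries, status, cmd),
    "fedbids_transport_error", attempts = transport$retries)
}

#' Send a federation message
#'
#' Copies the payload into the destination inbox under the deterministic name
#' `<kind>_round<r>_<sender>.<ext>`, then creates the zero-byte completion
#' marker `<same stem>.done`. The marker is strictly ordered after the
#' payload, which makes re-sends idempotent and partial transfers invisible
#' to receivers.
#'
#' @param message An [fl_message()].
#' @param transport An `fl_transport`.
#' @param destination Destination participant name.
#' @return Invisibly, the destination payload name.
#' @export
fl_send <- function(message, transport, destination) {
  stopifnot(inherits(message, "fl_message"), inherits(transport,
                                                      "fl_transport"))
  if (message$kind != "stop" && !file.exists(message$payload_path))
    stop_fedbids(sprintf("payload '%s' does not exist", message$payload_path),
                 "fedbids_protocol_error")
  ext <- if (message$kind == "stop") ".txt"
         else paste0(".", sub("^[^.]*\\.", "", basename(message$payload_path)))
  payload <- message$payload_path
  if (message$kind == "stop" && !file.exists(payload)) {
    payload <- tempfile()
    writeLines("stop", payload)
    on.exit(unlink(payload))
  }
  name <- message_stem(message$kind, message$round_index, message$sender, ext)
  transport_copy(transport, payload, destination, name)
  marker <- tempfile()
  file.create(marker)
  on.exit(unlink(marker), add = TRUE)
  stem <- tools::file_path_sans_ext(name)
  transport_copy(transport, marker, destination,
                 paste0(stem, ".done"))
  invisible(name)
}

#' Receive a federation message (marker-gated polling)
#'
#' Polls the workspace inbox for the completion marker of the expected
#' message and returns only once the marker is observed; the payload is never
#' touched before its marker exists. Also accepts an optional set of
#' alternative kinds (e.g. waiting for either the next global model or a stop
#' message).
#'
#' @param workspace An `fl_workspace` (the receiver's own).
#' @param kind Expected message kind (or vector of acceptable kinds).
#' @param round_index Expected round.
#' @param sender Expected sender label.
#' @param timeout_s Give up after this many seconds.
#' @param poll_s Poll interval in seconds.
#' @return An `fl_message` whose `payload_path` points into the inbox.
#' @export
fl_receive <- function(workspace, kind, round_index, sender,
                       timeout_s = 86400, poll_s = 5) {
  stopifnot(inherits(workspace, "fl_workspace"),
            timeout_s > poll_s, poll_s > 0)
  kinds <- match.arg(kind, MESSAGE_KINDS, several.ok = TRUE)
  deadline <- Sys.time() + timeout_s
  repeat {
    for (k in kinds) {
      pat <- sprintf("^%s_round%d_%s\\.", k, round_index, sender)
      markers <- list.files(workspace$inbox,
                            pattern = paste0(pat, ".*done$"))
      if (length(markers)) {
        stem <- sub("\\.done$", "", markers[1])
        payloads <- setdiff(
          list.files(workspace$inbox, pattern = paste0("^", stem, "\\.")),
          markers[1])
        if (length(payloads))
          return(fl_message(k, round_index,
                            file.path(workspace$inbox, payloads[1]), sender))
      }
    }
    if (Sys.time() >= deadline)
      stop_fedbids(sprintf(
        "timed out after %gs waiting for %s (round %d) from '%s'",
        timeout_s, paste(kinds, collapse = "/"), round_index, sender),
        "fedbids_timeout_error")
    Sys.sleep(poll_s)
  }
}

# ---- settings and plan documents -------------------------------------------

#' Server settings
#'
#' @param workspace_root The server's FL workspace directory.
#' @param clients List of client descriptors, each a list with `name`,
#'   `address` (endpoint understood by the transport) and `workspace_root`.
#' @param model_definition Path to the model-definition file (an R source
#'   file exporting `build_model(spec)`).
#' @param plan_path Path to the FL-plan JSON.
#' @return A `server_settings` object.
#' @export
server_settings <- function(workspace_root, clients, model_definition,
                            plan_path) {
  nms <- vapply(clients, `[[`, character(1), "name")
  if (length(nms) < 1L || anyDuplicated(nms))
    stop_fedbids("need at least one client and unique client names",
                 "fedbids_input_error")
  structure(list(workspace_root = workspace_root, clients = clients,
                 model_definition = model_definition, plan_path = plan_path),
            class = "server_settings")
}

#' Client settings
#'
#' @param workspace_root The client's FL workspace directory.
#' @param dataset_root BIDS dataset directory holding the local data.
#' @param target_column Participants-table column holding the target.
#' @param server Server endpoint label.
#' @param client_name This client's name.
#' @return A `client_settings` object.
#' @export
client_settings <- function(workspace_root, dataset_root, target_column,
                            server = "server", client_name) {
  structure(list(workspace_root = workspace_root, dataset_root = dataset_root,
                 target_column = target_column, server = server,
                 client_name = client_name),
            class = "client_settings")
}

#' The FL plan: training hyperparameters governing the federation
#'
#' @param n_rounds_max Maximum number of federation rounds.
#' @param n_bootstraps Bootstrap partitions per round (study protocol: 5).
#' @param val_fraction Validation share of each bootstrap partition.
#' @param test_fraction Held-out test share of each client's subjects.
#' @param batch_size Minibatch size (study protocol: 10).
#' @param epochs_per_round Local epochs per bootstrap per round.
#' @param learning_rate Adam learning rate.
#' @param clients_per_round Clients sampled into each aggregation.
#' @param patience Early stopping: consecutive rounds without improving the
#'   running-minimum server validation MAE before training stops.
#' @param freeze_mode `"none"` (train everything), `"shallow"` (head only)
#'   or `"deep"` (all layers; distinct from `"none"` only in intent).
#' @param selector Which bootstrap model a client transmits: the one with
#'   the `"best"` (lowest) validation MAE, or the `"average"` of all five.
#' @param seed Base seed for sampling, splits and shuffling.
#' @return An `fl_plan` object.
#' @export
fl_plan <- function(n_rounds_max = 10L, n_bootstraps = 5L,
                    val_fraction = 0.25, test_fraction = 0.2,
                    batch_size = 10L, epochs_per_round = 1L,
                    learning_rate = 1e-3, clients_per_round = 2L,
                    patience = 20L,
                    freeze_mode = c("none", "shallow", "deep"),
                    selector = c("best", "average"), seed = 1L) {
  freeze_mode <- match.arg(freeze_mode)
  selector <- match.arg(selector)
  stopifnot(n_rounds_max >= 1, n_bootstraps >= 1, batch_size >= 1,
            epochs_per_round >= 1, learning_rate >= 0,
            clients_per_round >= 1, patience >= 1)
  if (!(val_fraction > 0 && val_fraction < 1) ||
      !(test_fraction > 0 && test_fraction < 1))
    stop_fedbids("fractions must lie strictly between 0 and 1",
                 "fedbids_input_error")
  structure(list(n_rounds_max = as.integer(n_rounds_max),
                 n_bootstraps = as.integer(n_bootstraps),
                 val_fraction = val_fraction, test_fraction = test_fraction,
                 batch_size = as.integer(batch_size),
                 epochs_per_round = as.integer(epochs_per_round),
                 learning_rate = learning_rate,
                 clients_per_round = as.integer(clients_per_round),
                 patience = as.integer(patience),
                 freeze_mode = freeze_mode, selector = selector,
                 seed = as.integer(seed)),
            class = "fl_plan")
}

#' Read / write settings and plan JSON documents
#'
#' Settings and plans are exchanged as JSON files with exactly the field
#' names of the corresponding constructors.
#'
#' @param x A `server_settings`, `client_settings` or `fl_plan`.
#' @param path JSON file path.
#' @return `write_fl_json()` returns `path` invisibly; the readers return
#'   the reconstructed object.
#' @export
write_fl_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fl_json
#' @export
read_fl_plan <- function(path) {
  do.call(fl_plan, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname write_fl_json
#' @export
read_server_settings <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  server_settings(raw$workspace_root,
                  lapply(raw$clients, function(cl)
                    list(name = cl$name, address = cl$address,
                         workspace_root = cl$workspace_root)),
                  raw$model_definition, raw$plan_path)
}

#' @rdname write_fl_json
#' @export
read_client_settings <- function(path) {
  do.call(client_settings, jsonlite::read_json(path, simplifyVector = TRUE))
}
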