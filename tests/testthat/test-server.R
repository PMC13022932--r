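# Server orchestration: sampling, aggregation, stopping, model selection.

test_that("client sampling is uniform over subsets (exhaustive check)", {
  names3 <- c("A", "B", "C")
  draws <- vapply(1:10000, function(r)
    paste(sample_clients(names3, 2, r, seed = 17), collapse = ""),
    character(1))
  freq <- table(draws) / length(draws)
  expect_setequal(names(freq), c("AB", "AC", "BC"))
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("sampling edge cases: k = n, determinism, bad k", {
  nms <- c("x", "y", "z")
  expect_equal(sample_clients(nms, 3, 5, 1), sort(nms))
  expect_identical(sample_clients(nms, 2, 9, 3),
                   sample_clients(nms, 2, 9, 3))
  expect_false(identical(sample_clients(nms, 2, 9, 3),
                         sample_clients(nms, 2, 10, 3)) &&
               identical(sample_clients(nms, 2, 10, 3),
                         sample_clients(nms, 2, 11, 3)))
  expect_error(sample_clients(nms, 4, 1, 1), class = "fedbids_config_error")
})

test_that("fedavg reproduces hand-computed weighted means", {
  u <- function(w, n) list(weights = structure(list(p = w),
                                               class = "weight_set"), n = n)
  got <- fedavg(list(u(1.0, 100), u(2.0, 300)))
  expect_equal(got$p, 1.75)
  eq <- fedavg(list(u(1, 5), u(2, 5), u(6, 5)))
  expect_equal(eq$p, 3)
  single <- fedavg(list(u(c(1.1, 2.2), 7)))
  expect_identical(single$p, c(1.1, 2.2))
})

test_that("fedavg matches a brute-force per-entry mean to 1e-12", {
  set.seed(55)
  for (rep in 1:10) {
    ws <- lapply(1:3, function(i) random_weight_set(rep * 10 + i))
    ns <- sample(1:500, 3)
    got <- fedavg(mapply(function(w, n) list(weights = w, n = n),
                         ws, ns, SIMPLIFY = FALSE))
    for (key in names(ws[[1]])) {
      brute <- Reduce(`+`, mapply(function(w, n) w[[key]] * (n / sum(ns)),
                                  ws, ns, SIMPLIFY = FALSE))
      expect_lt(max(abs(got[[key]] - brute)), 1e-12)
    }
  }
})

test_that("identical updates aggregate to a bit-identical weight set", {
  w <- random_weight_set(3)
  for (ns in list(c(1, 1), c(100, 300), c(7, 13, 997))) {
    ups <- lapply(ns, function(n) list(weights = w, n = n))
    expect_identical(unclass(fedavg(ups)), unclass(w))
  }
})

test_that("fedavg validates keys and shapes by name", {
  a <- random_weight_set(1)
  b <- random_weight_set(2)
  names(b)[2] <- "rogue"
  err <- tryCatch(fedavg(list(list(weights = a, n = 1),
                              list(weights = b, n = 1))), error = identity)
  expect_s3_class(err, "fedbids_aggregation_error")
  expect_match(conditionMessage(err), "rogue")
  c2 <- random_weight_set(3)
  c2$a <- matrix(0, 4, 4)
  err2 <- tryCatch(fedavg(list(list(weights = a, n = 1),
                               list(weights = c2, n = 1))), error = identity)
  expect_s3_class(err2, "fedbids_aggregation_error")
  expect_match(conditionMessage(err2), "'a'")
})

test_that("early stopping follows the hand-traced patience rule", {
  # sequence 5, 4, 4.5, 4.6, 4.7 with patience 3: stop after round 5,
  # final model from round 2 (the minimum)
  plan <- fl_plan(n_rounds_max = 10, patience = 3, clients_per_round = 1,
                  n_bootstraps = 1, seed = 2)
  res <- run_scripted_federation(c(5, 4, 4.5, 4.6, 4.7, 99, 99, 99, 99, 99),
                                 plan)
  expect_equal(res$stopped_round, 5)
  expect_equal(res$final_round, 2)
  # the scripted client sent all-(round) weights; round 2 must come back
  expect_true(all(vapply(res$final_weights, function(a) all(a == 2),
                         logical(1))))
  expect_equal(res$history$rounds$avg_val_mae, c(5, 4, 4.5, 4.6, 4.7))
})

test_that("monotone improvement runs to the horizon, final = last round", {
  plan <- fl_plan(n_rounds_max = 6, patience = 3, clients_per_round = 1,
                  n_bootstraps = 1, seed = 2)
  res <- run_scripted_federation(c(9, 8, 7, 6, 5, 4), plan)
  expect_equal(res$stopped_round, 6)
  expect_equal(res$final_round, 6)
  expect_equal(res$history$rounds$avg_val_mae, c(9:4))
})

test_that("a single-client history equals that client's local MAEs", {
  plan <- fl_plan(n_rounds_max = 4, patience = 10, clients_per_round = 1,
                  n_bootstraps = 1, seed = 2)
  seqs <- c(3.2, 2.8, 2.9, 2.7)
  res <- run_scripted_federation(seqs, plan)
  expect_equal(res$history$rounds$avg_val_mae, seqs)
  expect_equal(res$history$per_client$val_mae_mean, seqs)
  expect_equal(res$final_round, 4)
})

test_that("the server persists round logs and summaries", {
  plan <- fl_plan(n_rounds_max = 3, patience = 5, clients_per_round = 1,
                  n_bootstraps = 1, seed = 2)
  wd <- tempfile("fedlog")
  res <- run_scripted_federation(c(3, 2, 1), plan, work_dir = wd)
  logf <- file.path(wd, "s", "logs", "rounds.jsonl")
  expect_true(file.exists(logf))
  lines <- readLines(logf)
  expect_length(lines, 3)
  rec <- jsonlite::fromJSON(lines[2])
  expect_equal(rec$round, 2)
  expect_equal(rec$avg_val_mae, 2)
  expect_true(file.exists(file.path(wd, "s", "logs", "round_summary.tsv")))
})
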