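# The 3D DenseNet: parameter accounting, freeze policies, weight-set I/O.

# Analytic per-segment parameter counts for the default configuration:
# stem 7^3 conv (343*64) + its norm (2*64); per dense layer
# 130*C_in + 110,848; transitions 2*C + C*C/2; final norm 2*1024; head
# 1024 + 1.
DEFAULT_LEDGER <- c(
  stem_conv = 21952, stem_norm = 128,
  denseblock1 = 777408, transition1 = 33280,
  denseblock2 = 1804416, transition2 = 132096,
  denseblock3 = 4607232, transition3 = 526336,
  denseblock4 = 3337728, final_norm = 2048, head = 1025)

test_that("the default network matches the analytic ledger layer-by-layer", {
  m <- build_densenet(densenet_spec())
  ledger <- parameter_ledger(m)
  expect_equal(ledger[names(DEFAULT_LEDGER)], DEFAULT_LEDGER)
  expect_equal(unname(ledger["total"]), 11243649)
  expect_equal(count_trainable(m), 11243649)
  expect_equal(m$feature_width, 1024L)
})

test_that("freeze policies expose exactly the head or everything", {
  m <- build_densenet(densenet_spec())
  ms <- apply_freeze_policy(m, "shallow")
  expect_equal(count_trainable(ms), 1025)
  expect_setequal(names(ms$trainable)[ms$trainable],
                  c("classifier.weight", "classifier.bias"))
  md <- apply_freeze_policy(ms, "deep")
  expect_equal(count_trainable(md), 11243649)
  # idempotent per mode, reversible across modes
  expect_identical(apply_freeze_policy(ms, "shallow")$trainable,
                   ms$trainable)
  mn <- apply_freeze_policy(ms, "none")
  expect_equal(count_trainable(mn), 11243649)
})

test_that("count_trainable sums element counts of trainable parameters", {
  toy <- list(params = list(w = matrix(0, 5, 1), b = 0),
              trainable = c(w = TRUE, b = TRUE))
  expect_equal(count_trainable(toy), 6)
  toy$trainable[] <- FALSE
  expect_equal(count_trainable(toy), 0)
})

test_that("parameter count is invariant to input volume size", {
  # adaptive pooling: same network runs on 32^3 and larger inputs alike
  m <- build_densenet(densenet_small_spec(), seed = 2)
  n_par <- count_trainable(m)
  for (d in list(c(32, 32, 32), c(40, 36, 44))) {
    x <- matrix(rnorm(prod(d)), 1)
    y <- fedbids:::net_forward(m, fedbids:::stack_batch(x, 1), d, 1L)$y
    expect_length(as.vector(y), 1)
    expect_true(is.finite(as.vector(y)))
  }
  expect_equal(count_trainable(m), n_par)
})

test_that("the default network forwards a 32^3 volume to one finite real", {
  m <- build_densenet(densenet_spec(), seed = 3)
  x <- matrix(rnorm(32768), 1)
  y <- fedbids:::net_forward(m, fedbids:::stack_batch(x, 1), c(32, 32, 32), 1L)$y
  expect_length(as.vector(y), 1)
  expect_true(is.finite(as.vector(y)))
})

test_that("weight sets round-trip bit-exactly and validate keys/shapes", {
  m <- build_densenet(tiny_spec(), seed = 4)
  ws <- weights_of(m)
  f1 <- tempfile(fileext = ".rds")
  f2 <- tempfile(fileext = ".rds")
  save_weights(ws, f1)
  ws2 <- read_weights(f1)
  save_weights(ws2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  m2 <- load_weights(m, ws2)
  expect_identical(m2$params, m$params)

  bad <- ws
  names(bad)[1] <- "features.bogus"
  err <- tryCatch(load_weights(m, bad), error = identity)
  expect_s3_class(err, "fedbids_checkpoint_error")
  expect_match(conditionMessage(err), "features.bogus")
  bad2 <- ws
  bad2[[2]] <- c(bad2[[2]], 0)
  err2 <- tryCatch(load_weights(m, bad2), error = identity)
  expect_s3_class(err2, "fedbids_checkpoint_error")
  expect_match(conditionMessage(err2), names(ws)[2], fixed = TRUE)

  zero <- ws - ws
  expect_true(all(vapply(zero, function(a) all(a == 0), logical(1))))
})

test_that("gradients agree with central finite differences", {
  set.seed(42)
  m <- build_densenet(tiny_spec(), seed = 7)
  dims <- c(32L, 32L, 32L)
  B <- 2L
  X <- matrix(rnorm(B * prod(dims)), B)
  tg <- c(1.5, -0.3)
  loss_of <- function(mm) {
    y <- fedbids:::net_forward(mm, fedbids:::stack_batch(X, 1:B), dims, B)$y
    mean(abs(as.vector(y) - tg))
  }
  fw <- fedbids:::net_forward(m, fedbids:::stack_batch(X, 1:B), dims, B,
                    want_tape = TRUE)
  pred <- as.vector(fw$y)
  gr <- fedbids:::net_backward(m, fw$tapes, matrix(sign(pred - tg) / B, ncol = 1))
  eps <- 1e-6
  for (nm in sample(names(gr), 8)) {
    i <- sample(length(m$params[[nm]]), 1)
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm_ <- m; mm_$params[[nm]][i] <- mm_$params[[nm]][i] - eps
    num <- (loss_of(mp) - loss_of(mm_)) / (2 * eps)
    ana <- gr[[nm]][i]
    expect_lt(abs(num - ana) / max(1e-4, abs(num) + abs(ana)), 1e-4)
  }
})

test_that("the desk-scale network learns phantoms past the mean baseline", {
  d <- make_phantom_dataset(n = 40, seed = 11)
  pm <- phantom_matrix(d$records)
  baseline <- mean(abs(pm$targets - mean(pm$targets)))
  m <- build_densenet(densenet_small_spec(), seed = 2)
  m <- train_model(m, pm$X, pm$targets, pm$dims, epochs = 30,
                   batch_size = 10, lr = 0.1, seed = 5)
  final_mae <- tail(attr(m, "train_mae"), 1)
  expect_lt(final_mae, baseline)
})
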