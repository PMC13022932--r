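# Neural-network engine: im2col 3D convolution via gather + GEMM, batch
# normalisation, pooling, a reverse-mode tape, Adam, and the L1 training loop.
# Activations are (batch*voxels) x channels matrices, voxels in column-major
# grid order, images stacked image-major.

BN_EPS <- 1e-5

# ---- gather plans -----------------------------------------------------------

# A plan maps output voxels x kernel offsets to input row indices (0 = outside
# the zero-padded volume). Cached per (input dims, kernel, stride, pad, batch).
nn_plan <- function(cache, dims, k, stride, pad, B, keep_matrix = FALSE) {
  key <- paste(c(dims, k, stride, pad, B, keep_matrix), collapse = "_")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  d1 <- dims[1]; d2 <- dims[2]; d3 <- dims[3]
  o <- (dims + 2L * pad - k) %/% stride + 1L
  if (any(o < 1L))
    stop_fedbids(sprintf("input of size %s too small for kernel %d",
                         paste(dims, collapse = "x"), k), "fedbids_shape_error")
  o1 <- o[1]; o2 <- o[2]; o3 <- o[3]
  Vout <- o1 * o2 * o3; Vin <- d1 * d2 * d3
  gx <- (seq_len(o1) - 1L) * stride - pad
  gy <- (seq_len(o2) - 1L) * stride - pad
  gz <- (seq_len(o3) - 1L) * stride - pad
  cx <- rep.int(gx, o2 * o3)
  cy <- rep.int(rep(gy, each = o1), o3)
  cz <- rep(gz, each = o1 * o2)
  k3 <- as.integer(k^3)
  idx1 <- matrix(0L, Vout, k3)
  col <- 0L
  for (dz in 0:(k - 1L)) for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
    col <- col + 1L
    ix <- cx + dx; iy <- cy + dy; iz <- cz + dz
    ok <- ix >= 0L & ix < d1 & iy >= 0L & iy < d2 & iz >= 0L & iz < d3
    lin <- 1L + ix + iy * d1 + iz * (d1 * d2)
    lin[!ok] <- 0L
    idx1[, col] <- lin
  }
  if (B > 1L) {
    idx <- idx1[rep(seq_len(Vout), B), , drop = FALSE]
    off <- rep.int((seq_len(B) - 1L) * Vin, rep.int(Vout, B))
    idx <- idx + as.integer(off * (idx > 0L))
  } else {
    idx <- idx1
  }
  plan <- list(out_dims = o, Vout = Vout, k3 = k3,
               ivec = as.integer(idx),
               idx = if (keep_matrix) idx else NULL)
  cache[[key]] <- plan
  plan
}

# ---- primitives -------------------------------------------------------------

fwd_conv <- function(x, dims, B, W, k, stride, pad, cache) {
  if (k == 1L && stride == 1L && pad == 0L) {
    # 1^3 convolution at stride 1 is a plain channel-mixing GEMM
    return(list(y = x %*% W, out_dims = dims,
                tape = list(x = x, k1 = TRUE)))
  }
  plan <- nn_plan(cache, dims, k, stride, pad, B)
  y <- cpp_conv_fwd(x, plan$ivec, B * plan$Vout, plan$k3, W)
  list(y = y, out_dims = plan$out_dims,
       tape = list(x = x, plan = plan, n_in = nrow(x)))
}

bwd_conv <- function(tape, dy, W, need_dx = TRUE, need_dw = TRUE) {
  if (isTRUE(tape$k1)) {
    return(list(
      dx = if (need_dx) tcrossprod(dy, W),
      dW = if (need_dw) crossprod(tape$x, dy)))
  }
  plan <- tape$plan
  nout <- nrow(dy)
  list(
    dx = if (need_dx)
      cpp_conv_dx(dy, plan$ivec, nout, plan$k3, W, tape$n_in),
    dW = if (need_dw)
      cpp_conv_dw(tape$x, plan$ivec, nout, plan$k3, dy))
}

fwd_bn <- function(x, gamma, beta) {
  r <- cpp_bn_fwd(x, gamma, beta, BN_EPS)
  list(y = r$y, tape = list(xhat = r$xhat, istd = r$istd))
}

bwd_bn <- function(tape, dy, gamma) {
  r <- cpp_bn_bwd(dy, tape$xhat, tape$istd, gamma)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

fwd_relu <- function(x) {
  y <- x * (x > 0)
  list(y = y, tape = list(y = y))
}

bwd_relu <- function(tape, dy) dy * (tape$y > 0)

fwd_maxpool <- function(x, dims, B, k, stride, pad, cache) {
  plan <- nn_plan(cache, dims, k, stride, pad, B)
  nout <- B * plan$Vout
  r <- cpp_maxpool_fwd(x, plan$ivec, nout, plan$k3)
  list(y = r$y, out_dims = plan$out_dims,
       tape = list(plan = plan, arg = r$arg, n_in = nrow(x), nout = nout))
}

bwd_maxpool <- function(tape, dy) {
  cpp_maxpool_bwd(dy, tape$arg, tape$plan$ivec, tape$nout,
                  tape$plan$k3, tape$n_in)
}

fwd_avgpool <- function(x, dims, B, k, stride, cache) {
  plan <- nn_plan(cache, dims, k, stride, 0L, B)
  C <- ncol(x)
  nout <- B * plan$Vout
  P <- cpp_gather_rows(x, plan$ivec, 0)
  dim(P) <- c(nout, plan$k3, C)
  y <- P[, 1L, ]
  for (kk in 2:plan$k3) y <- y + P[, kk, ]
  y <- y / plan$k3
  dim(y) <- c(nout, C)
  list(y = y, out_dims = plan$out_dims,
       tape = list(plan = plan, n_in = nrow(x), nout = nout))
}

bwd_avgpool <- function(tape, dy) {
  plan <- tape$plan
  dP <- dy[rep.int(seq_len(tape$nout), plan$k3), , drop = FALSE] / plan$k3
  cpp_scatter_add_rows(dP, plan$ivec, tape$n_in)
}

fwd_gap <- function(x, dims, B) {
  V <- prod(dims)
  grp <- rep(seq_len(B), each = V)
  y <- rowsum(x, grp, reorder = FALSE) / V
  list(y = y, tape = list(V = V, B = B))
}

bwd_gap <- function(tape, dy) {
  dy[rep(seq_len(tape$B), each = tape$V), , drop = FALSE] / tape$V
}

# ---- dense layer (the DenseNet unit: BN-ReLU-1x1 conv-BN-ReLU-3x3 conv,
# concatenated onto the incoming feature stack) --------------------------------

fwd_dense_layer <- function(x, dims, B, pars, cache) {
  b1 <- fwd_bn(x, pars$g1, pars$b1)
  r1 <- fwd_relu(b1$y)
  c1 <- fwd_conv(r1$y, dims, B, pars$W1, 1L, 1L, 0L, cache)
  b2 <- fwd_bn(c1$y, pars$g2, pars$b2)
  r2 <- fwd_relu(b2$y)
  c2 <- fwd_conv(r2$y, dims, B, pars$W2, 3L, 1L, 1L, cache)
  list(y = cbind(x, c2$y),
       tape = list(b1 = b1$tape, r1 = r1$tape, c1 = c1$tape,
                   b2 = b2$tape, r2 = r2$tape, c2 = c2$tape,
                   cin = ncol(x)))
}

bwd_dense_layer <- function(tape, dy, pars) {
  cin <- tape$cin
  dx_skip <- dy[, seq_len(cin), drop = FALSE]
  dnew <- dy[, -seq_len(cin), drop = FALSE]
  g2 <- bwd_conv(tape$c2, dnew, pars$W2)
  dr2 <- bwd_relu(tape$r2, g2$dx)
  gb2 <- bwd_bn(tape$b2, dr2, pars$g2)
  g1 <- bwd_conv(tape$c1, gb2$dx, pars$W1)
  dr1 <- bwd_relu(tape$r1, g1$dx)
  gb1 <- bwd_bn(tape$b1, dr1, pars$g1)
  list(dx = dx_skip + gb1$dx,
       dW1 = g1$dW, dW2 = g2$dW,
       dg1 = gb1$dgamma, db1 = gb1$dbeta,
       dg2 = gb2$dgamma, db2 = gb2$dbeta)
}

# ---- network forward / backward --------------------------------------------

# model: list(spec, ops, params, trainable, cache). Each op is a list with
# $type and parameter names; see build_densenet().
net_forward <- function(model, x, dims, B, want_tape = FALSE) {
  p <- model$params
  cache <- model$cache
  ops <- model$ops
  tapes <- if (want_tape) vector("list", length(ops)) else NULL
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    res <- switch(op$type,
      conv = fwd_conv(x, dims, B, p[[op$w]], op$k, op$stride, op$pad, cache),
      bn = fwd_bn(x, p[[op$w]], p[[op$b]]),
      relu = fwd_relu(x),
      maxpool = fwd_maxpool(x, dims, B, op$k, op$stride, op$pad, cache),
      avgpool = fwd_avgpool(x, dims, B, op$k, op$stride, cache),
      gap = fwd_gap(x, dims, B),
      fc = list(y = x %*% p[[op$w]] +
                  rep(p[[op$b]], each = nrow(x)),
                tape = list(x = x)),
      dense_layer = fwd_dense_layer(
        x, dims, B,
        list(g1 = p[[op$g1]], b1 = p[[op$b1]], W1 = p[[op$w1]],
             g2 = p[[op$g2]], b2 = p[[op$b2]], W2 = p[[op$w2]]),
        cache),
      stop("unknown op type: ", op$type)
    )
    x <- res$y
    if (!is.null(res$out_dims)) dims <- res$out_dims
    if (op$type == "gap") dims <- c(1L, 1L, 1L)
    if (want_tape) tapes[[i]] <- res$tape
  }
  list(y = x, tapes = tapes)
}

# Reverse pass: returns named list of gradients for trainable parameters only.
# Stops early once no trainable parameter lies upstream.
net_backward <- function(model, tapes, dy) {
  p <- model$params
  ops <- model$ops
  tr <- model$trainable
  grads <- list()
  op_par_names <- lapply(ops, function(op)
    unlist(op[c("w", "b", "w1", "w2", "g1", "b1", "g2", "b2")],
           use.names = FALSE))
  has_tr <- vapply(op_par_names, function(nm)
    length(nm) > 0 && any(tr[nm]), logical(1))
  last_needed <- if (any(has_tr)) min(which(has_tr)) else length(ops) + 1L
  for (i in rev(seq_along(ops))) {
    if (i < last_needed) break
    op <- ops[[i]]
    tape <- tapes[[i]]
    switch(op$type,
      conv = {
        g <- bwd_conv(tape, dy, p[[op$w]],
                      need_dx = i > last_needed, need_dw = tr[op$w])
        if (tr[op$w]) grads[[op$w]] <- g$dW
        dy <- g$dx
      },
      bn = {
        g <- bwd_bn(tape, dy, p[[op$w]])
        if (tr[op$w]) grads[[op$w]] <- g$dgamma
        if (tr[op$b]) grads[[op$b]] <- g$dbeta
        dy <- g$dx
      },
      relu = dy <- bwd_relu(tape, dy),
      maxpool = dy <- bwd_maxpool(tape, dy),
      avgpool = dy <- bwd_avgpool(tape, dy),
      gap = dy <- bwd_gap(tape, dy),
      fc = {
        if (tr[op$w]) grads[[op$w]] <- crossprod(tape$x, dy)
        if (tr[op$b]) grads[[op$b]] <- colSums(dy)
        dy <- tcrossprod(dy, p[[op$w]])
      },
      dense_layer = {
        g <- bwd_dense_layer(
          tape, dy,
          list(g1 = p[[op$g1]], W1 = p[[op$w1]], g2 = p[[op$g2]],
               W2 = p[[op$w2]]))
        if (tr[op$w1]) grads[[op$w1]] <- g$dW1
        if (tr[op$w2]) grads[[op$w2]] <- g$dW2
        if (tr[op$g1]) grads[[op$g1]] <- g$dg1
        if (tr[op$b1]) grads[[op$b1]] <- g$db1
        if (tr[op$g2]) grads[[op$g2]] <- g$dg2
        if (tr[op$b2]) grads[[op$b2]] <- g$db2
        dy <- g$dx
      }
    )
  }
  grads
}

# ---- optimiser --------------------------------------------------------------

adam_init <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- state$m[[nm]]
    if (is.null(m)) m <- g * 0
    v <- state$v[[nm]]
    if (is.null(v)) v <- g * 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  params
}

# ---- batching helpers -------------------------------------------------------

# Stack images (rows of X, each a flattened volume) into one image-major
# activation column.
stack_batch <- function(X, ids) {
  matrix(as.vector(t(X[ids, , drop = FALSE])), ncol = 1L)
}

# Near-equal-size consecutive chunks (sizes differ by at most one).
balanced_chunks <- function(n, max_size) {
  nb <- ceiling(n / max_size)
  bounds <- floor(seq(0, n, length.out = nb + 1))
  lapply(seq_len(nb), function(i) seq.int(bounds[i] + 1L, bounds[i + 1L]))
}

# ---- training and prediction ------------------------------------------------

#' Train a regression network with minibatch Adam and L1 loss
#'
#' Runs `epochs` passes over the rows of `X` (flattened single-channel
#' volumes) in shuffled minibatches, minimising the mean absolute error
#' between the network output and `targets`. Only parameters currently marked
#' trainable (see [apply_freeze_policy()]) are updated.
#'
#' @param model A model built by [build_densenet()].
#' @param X Numeric matrix, one flattened volume per row.
#' @param targets Numeric vector of regression targets, one per row of `X`.
#' @param dims Integer triple: the spatial dimensions of each volume.
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size (the study protocol uses 10).
#' @param lr Adam learning rate.
#' @param seed Integer seed controlling shuffling (training is fully
#'   deterministic given `seed` and the initial weights).
#' @return The model with updated parameters; per-epoch mean training MAE is
#'   attached as `attr(, "train_mae")`.
#' @export
train_model <- function(model, X, targets, dims, epochs, batch_size = 10,
                        lr = 1e-3, seed = 1L) {
  stopifnot(nrow(X) == length(targets), nrow(X) >= 1)
  dims <- as.integer(dims)
  n <- nrow(X)
  state <- adam_init()
  epoch_mae <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      abs_err <- 0
      for (ids in balanced_chunks(n, batch_size)) {
        bids <- perm[ids]
        xb <- stack_batch(X, bids)
        tb <- targets[bids]
        fw <- net_forward(model, xb, dims, length(bids), want_tape = TRUE)
        pred <- as.vector(fw$y)
        abs_err <- abs_err + sum(abs(pred - tb))
        dpred <- matrix(sign(pred - tb) / length(bids), ncol = 1L)
        grads <- net_backward(model, fw$tapes, dpred)
        model$params <- adam_step(model$params, grads, state, lr)
      }
      epoch_mae[ep] <- abs_err / n
    }
  })
  attr(model, "train_mae") <- epoch_mae
  model
}

#' Predict regression targets for a set of volumes
#'
#' Deterministic forward passes in near-equal consecutive batches of at most
#' `batch_size` images. Batch-normalisation statistics are computed over each
#' evaluation batch (the network carries no running statistics; see the
#' methods vignette).
#'
#' @inheritParams train_model
#' @param batch_size Maximum evaluation batch size.
#' @return Numeric vector of predictions, one per row of `X`.
#' @export
predict_model <- function(model, X, dims, batch_size = 10) {
  dims <- as.integer(dims)
  n <- nrow(X)
  preds <- numeric(n)
  for (ids in balanced_chunks(n, batch_size)) {
    xb <- stack_batch(X, ids)
    fw <- net_forward(model, xb, dims, length(ids))
    preds[ids] <- as.vector(fw$y)
  }
  preds
}
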