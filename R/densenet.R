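# The 3D DenseNet regression network. Architecture: 7^3 stem convolution
# (stride 2, no bias) + BN + ReLU + 3^3 max-pool (stride 2, pad 1); four dense
# blocks whose layers are BN-ReLU-1^3 bottleneck conv (to bottleneck_factor x
# growth_rate channels)-BN-ReLU-3^3 conv (to growth_rate channels), each
# concatenated onto its block's running feature stack; compression transitions
# (BN + 1^3 conv halving channels + 2^3 average-pool) between blocks; final BN
# + ReLU + adaptive average-pool + fully connected head emitting one real.
# With the default configuration the network has 11,243,649 trainable
# parameters, 1,025 of them in the head.

#' Specification of the 3D DenseNet regression network
#'
#' The default values give the DenseNet-121 configuration in three dimensions
#' with a single input channel and a scalar regression output: 11,243,649
#' trainable parameters, of which the fully connected head holds 1,025
#' (1,024 weights and one bias).
#'
#' @param spatial_dims Number of spatial dimensions (only 3 is supported).
#' @param in_channels Input image channels.
#' @param out_units Output units (1 for scalar regression).
#' @param init_features Channels produced by the stem convolution.
#' @param growth_rate Channels each dense layer adds to the feature stack.
#' @param block_layers Integer 4-tuple: dense layers per block.
#' @param bottleneck_factor Bottleneck width as a multiple of `growth_rate`.
#' @param compression Channel-compression factor of the transitions.
#' @param conv_bias Whether convolutions carry bias terms (the reference
#'   configuration uses none; only `FALSE` is supported).
#' @return An object of class `densenet_spec`.
#' @seealso [densenet_small_spec()] for a desk-scale preset,
#'   [build_densenet()] to construct the network.
#' @export
densenet_spec <- function(spatial_dims = 3L, in_channels = 1L, out_units = 1L,
                          init_features = 64L, growth_rate = 32L,
                          block_layers = c(6L, 12L, 24L, 16L),
                          bottleneck_factor = 4L, compression = 0.5,
                          conv_bias = FALSE) {
  if (spatial_dims != 3L)
    stop_fedbids("only 3-dimensional networks are supported",
                 "fedbids_input_error")
  if (isTRUE(conv_bias))
    stop_fedbids("biased convolutions are not part of this architecture",
                 "fedbids_input_error")
  stopifnot(length(block_layers) == 4L, all(block_layers >= 1L),
            in_channels >= 1L, out_units >= 1L, init_features >= 1L,
            growth_rate >= 1L, bottleneck_factor >= 1L,
            compression > 0, compression <= 1)
  structure(list(
    spatial_dims = 3L, in_channels = as.integer(in_channels),
    out_units = as.integer(out_units),
    init_features = as.integer(init_features),
    growth_rate = as.integer(growth_rate),
    block_layers = as.integer(block_layers),
    bottleneck_factor = as.integer(bottleneck_factor),
    compression = compression, conv_bias = FALSE
  ), class = "densenet_spec")
}

#' Desk-scale DenseNet preset
#'
#' A reduced configuration (blocks 2/2/2/2, growth 8, 16 stem features) that
#' trains in minutes on CPU against 32^3 synthetic phantoms. Intended for
#' tests and simulations; analyses of real images use [densenet_spec()].
#'
#' @inheritParams densenet_spec
#' @return A `densenet_spec`.
#' @export
densenet_small_spec <- function(in_channels = 1L, out_units = 1L) {
  densenet_spec(in_channels = in_channels, out_units = out_units,
                init_features = 16L, growth_rate = 8L,
                block_layers = c(2L, 2L, 2L, 2L))
}

#' Build the 3D DenseNet regression model
#'
#' Constructs the network described by `spec` with freshly initialised
#' weights (He-normal convolutions, unit-gain batch norm, uniform head).
#' The network accepts any input volume large enough for its pooling
#' cascade — parameter count is independent of input size thanks to the
#' adaptive final pooling.
#'
#' @param spec A [densenet_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return A model object (list with `spec`, `ops`, `params`, `trainable`).
#' @export
build_densenet <- function(spec = densenet_spec(), seed = 1L) {
  stopifnot(inherits(spec, "densenet_spec"))
  ops <- list()
  params <- list()
  add_conv <- function(name, k, stride, pad, cin, cout) {
    w <- paste0(name, ".weight")
    fan_in <- k^3 * cin
    params[[w]] <<- matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                           fan_in, cout)
    ops[[length(ops) + 1L]] <<- list(type = "conv", w = w, k = as.integer(k),
                                     stride = as.integer(stride),
                                     pad = as.integer(pad))
  }
  add_bn <- function(name, C) {
    w <- paste0(name, ".weight"); b <- paste0(name, ".bias")
    params[[w]] <<- rep(1, C)
    params[[b]] <<- rep(0, C)
    ops[[length(ops) + 1L]] <<- list(type = "bn", w = w, b = b)
  }
  add_simple <- function(type, ...) {
    ops[[length(ops) + 1L]] <<- c(list(type = type), list(...))
  }

  with_seed(seed, {
    ch <- spec$init_features
    add_conv("features.conv0", 7L, 2L, 3L, spec$in_channels, ch)
    add_bn("features.norm0", ch)
    add_simple("relu")
    add_simple("maxpool", k = 3L, stride = 2L, pad = 1L)
    bneck <- spec$bottleneck_factor * spec$growth_rate
    for (blk in 1:4) {
      for (lyr in seq_len(spec$block_layers[blk])) {
        base <- sprintf("features.denseblock%d.denselayer%d", blk, lyr)
        g1 <- paste0(base, ".norm1.weight"); b1 <- paste0(base, ".norm1.bias")
        params[[g1]] <- rep(1, ch); params[[b1]] <- rep(0, ch)
        w1 <- paste0(base, ".conv1.weight")
        params[[w1]] <- matrix(rnorm(ch * bneck, sd = sqrt(2 / ch)), ch, bneck)
        g2 <- paste0(base, ".norm2.weight"); b2 <- paste0(base, ".norm2.bias")
        params[[g2]] <- rep(1, bneck); params[[b2]] <- rep(0, bneck)
        w2 <- paste0(base, ".conv2.weight")
        fan2 <- 27L * bneck
        params[[w2]] <- matrix(
          rnorm(fan2 * spec$growth_rate, sd = sqrt(2 / fan2)),
          fan2, spec$growth_rate)
        ops[[length(ops) + 1L]] <- list(type = "dense_layer",
                                        g1 = g1, b1 = b1, w1 = w1,
                                        g2 = g2, b2 = b2, w2 = w2)
        ch <- ch + spec$growth_rate
      }
      if (blk < 4L) {
        tname <- sprintf("features.transition%d", blk)
        add_bn(paste0(tname, ".norm"), ch)
        add_simple("relu")
        out_ch <- as.integer(floor(ch * spec$compression))
        add_conv(paste0(tname, ".conv"), 1L, 1L, 0L, ch, out_ch)
        add_simple("avgpool", k = 2L, stride = 2L)
        ch <- out_ch
      }
    }
    add_bn("features.norm5", ch)
    add_simple("relu")
    add_simple("gap")
    wfc <- "classifier.weight"; bfc <- "classifier.bias"
    bound <- 1 / sqrt(ch)
    params[[wfc]] <- matrix(runif(ch * spec$out_units, -bound, bound),
                            ch, spec$out_units)
    params[[bfc]] <- rep(0, spec$out_units)
    ops[[length(ops) + 1L]] <- list(type = "fc", w = wfc, b = bfc)
  })

  trainable <- rep(TRUE, length(params))
  names(trainable) <- names(params)
  structure(list(spec = spec, ops = ops, params = params,
                 trainable = trainable, feature_width = ch,
                 cache = new.env(parent = emptyenv())),
            class = "fedbids_model")
}

#' Mark parameters trainable under a transfer-learning freeze policy
#'
#' `"shallow"` freezes the feature extractor so that only the fully connected
#' head (1,025 parameters in the default configuration) is updated;
#' `"deep"` (or `"none"`) marks every parameter trainable. Policies are
#' idempotent and mutually reversible.
#'
#' @param model A model from [build_densenet()].
#' @param mode One of `"shallow"`, `"deep"`, `"none"`.
#' @return The model with its `trainable` flags updated.
#' @export
apply_freeze_policy <- function(model, mode = c("deep", "shallow", "none")) {
  mode <- match.arg(mode)
  nm <- names(model$params)
  model$trainable <- if (mode == "shallow")
    stats::setNames(startsWith(nm, "classifier."), nm)
  else
    stats::setNames(rep(TRUE, length(nm)), nm)
  model
}

#' Count currently trainable parameters
#'
#' @param model A model from [build_densenet()].
#' @return Total number of parameter elements marked trainable.
#' @export
count_trainable <- function(model) {
  sum(vapply(names(model$params)[model$trainable[names(model$params)]],
             function(nm) length(model$params[[nm]]), numeric(1)))
}

#' Per-segment parameter ledger
#'
#' Groups the model's parameters into architectural segments (stem, dense
#' blocks, transitions, final norm, head) and counts elements in each, so the
#' construction can be audited layer-by-layer against the analytic counts.
#'
#' @param model A model from [build_densenet()].
#' @return Named numeric vector of per-segment parameter counts, with a
#'   `total` entry.
#' @export
parameter_ledger <- function(model) {
  nm <- names(model$params)
  seg <- function(prefix) {
    sum(vapply(nm[startsWith(nm, prefix)],
               function(x) length(model$params[[x]]), numeric(1)))
  }
  out <- c(
    stem_conv = seg("features.conv0"),
    stem_norm = seg("features.norm0"),
    denseblock1 = seg("features.denseblock1."),
    transition1 = seg("features.transition1."),
    denseblock2 = seg("features.denseblock2."),
    transition2 = seg("features.transition2."),
    denseblock3 = seg("features.denseblock3."),
    transition3 = seg("features.transition3."),
    denseblock4 = seg("features.denseblock4."),
    final_norm = seg("features.norm5"),
    head = seg("classifier.")
  )
  c(out, total = sum(out))
}

# ---- weight sets -------------------------------------------------------------

#' Extract the model's weights as an ordered weight set
#'
#' A weight set — the unit of federation exchange — is an ordered named list
#' of numeric arrays, one per model parameter.
#'
#' @param model A model from [build_densenet()].
#' @return An object of class `weight_set`.
#' @export
weights_of <- function(model) {
  structure(model$params, class = "weight_set")
}

#' Load a weight set into a model
#'
#' @param model A model from [build_densenet()].
#' @param weights A `weight_set` whose names and shapes match the model.
#' @return The model carrying `weights`.
#' @export
load_weights <- function(model, weights) {
  ref <- model$params
  missing_keys <- setdiff(names(ref), names(weights))
  extra_keys <- setdiff(names(weights), names(ref))
  if (length(missing_keys) || length(extra_keys))
    stop_fedbids(paste0(
      "weight set does not match model",
      if (length(missing_keys))
        paste0("; missing: ", paste(missing_keys, collapse = ", ")),
      if (length(extra_keys))
        paste0("; unexpected: ", paste(extra_keys, collapse = ", "))),
      "fedbids_checkpoint_error")
  for (nm in names(ref)) {
    a <- ref[[nm]]; b <- weights[[nm]]
    if (!identical(dim(a), dim(b)) || length(a) != length(b))
      stop_fedbids(sprintf("shape mismatch for parameter '%s'", nm),
                   "fedbids_checkpoint_error")
  }
  model$params <- stats::setNames(
    lapply(names(ref), function(nm) weights[[nm]]), names(ref))
  model
}

#' Save / read a weight set checkpoint
#'
#' Checkpoints are the package's native serialised form of a weight set
#' (version-2 RDS, fixed compression), so save-load-save round trips are
#' byte-identical.
#'
#' @param weights A `weight_set`.
#' @param path File path of the checkpoint.
#' @return `save_weights()` returns `path` invisibly; `read_weights()` the
#'   `weight_set`.
#' @export
save_weights <- function(weights, path) {
  stopifnot(inherits(weights, "weight_set"))
  saveRDS(weights, path, version = 2, compress = "gzip")
  invisible(path)
}

#' @rdname save_weights
#' @export
read_weights <- function(path) {
  ws <- readRDS(path)
  if (!inherits(ws, "weight_set"))
    stop_fedbids(sprintf("'%s' is not a weight-set checkpoint", path),
                 "fedbids_checkpoint_error")
  ws
}

#' Elementwise arithmetic on weight sets
#'
#' Weight sets support `+`, `-` and scalar `*` / `/`, aligned by parameter
#' name; used by aggregation and by tests (e.g. `w - w` is the all-zero set).
#'
#' @param e1,e2 Weight sets or scalars.
#' @export
Ops.weight_set <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*", "/"))
    stop_fedbids(sprintf("operation '%s' not defined for weight sets",
                         .Generic), "fedbids_input_error")
  if (inherits(e1, "weight_set") && inherits(e2, "weight_set")) {
    if (!identical(names(e1), names(e2)))
      stop_fedbids("weight sets have different keys",
                   "fedbids_checkpoint_error")
    out <- mapply(function(a, b) get(.Generic)(a, b),
                  unclass(e1), unclass(e2), SIMPLIFY = FALSE)
  } else if (inherits(e1, "weight_set")) {
    out <- lapply(unclass(e1), function(a) get(.Generic)(a, e2))
  } else {
    out <- lapply(unclass(e2), function(b) get(.Generic)(e1, b))
  }
  structure(out, class = "weight_set")
}

#' @export
print.fedbids_model <- function(x, ...) {
  cat(sprintf(
    "<fedbids 3D DenseNet: blocks %s, growth %d, init features %d>\n",
    paste(x$spec$block_layers, collapse = "/"),
    x$spec$growth_rate, x$spec$init_features))
  cat(sprintf("  parameters: %s (%s trainable)\n",
              format(sum(lengths(x$params)), big.mark = ","),
              format(count_trainable(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.densenet_spec <- function(x, ...) {
  cat(sprintf(
    "<densenet_spec: blocks %s, growth %d, init %d, bottleneck %dx, compression %g>\n",
    paste(x$block_layers, collapse = "/"), x$growth_rate, x$init_features,
    x$bottleneck_factor, x$compression))
  invisible(x)
}
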