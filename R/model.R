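#' Model architecture configuration
#'
#' Hyperparameters of the dilated residual network: a regression stage of
#' `reg_blocks` residual blocks (three dilated convolutions plus an identity
#' skip each, ReLU activations, no batch normalization) ending in a
#' single-filter regression head whose ReLU output is the denoised coverage;
#' that output feeds a classification stage of `cls_blocks` residual blocks
#' ending in a single-filter sigmoid head giving per-base peak
#' probabilities.
#'
#' @param in_channels Input channels C (1 for coverage only; 3 with
#'   strand-specific motif channels).
#' @param filters Convolution filters per layer (default 15).
#' @param kernel Odd kernel size (default 51).
#' @param dilation Dilation factor (default 8).
#' @param reg_blocks Residual blocks in the regression stage (default 5,
#'   which makes the regression receptive field 6001 bp, about 6 kb).
#' @param cls_blocks Residual blocks in the classification stage (default 2).
#' @param cls_init_gain Multiplier on the He initialization scale of the
#'   classification stage (default 0.02). Its input is the denoised
#'   coverage, whose magnitude is tens of read units, so unit-gain
#'   initialization would saturate the sigmoid head from the first step;
#'   a small gain keeps initial logits O(1).
#' @param seed Seed for parameter initialization.
#' @return A `model_config` object.
#' @export
model_config <- function(in_channels = 1L, filters = 15L, kernel = 51L,
                         dilation = 8L, reg_blocks = 5L, cls_blocks = 2L,
                         cls_init_gain = 0.02, seed = 1L) {
  stopifnot(in_channels >= 1L, filters >= 1L, kernel >= 1L,
            dilation >= 1L, reg_blocks >= 1L, cls_blocks >= 1L,
            cls_init_gain > 0)
  if (kernel %% 2L == 0L) stop("kernel size must be odd")
  structure(list(in_channels = as.integer(in_channels),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 dilation = as.integer(dilation),
                 reg_blocks = as.integer(reg_blocks),
                 cls_blocks = as.integer(cls_blocks),
                 cls_init_gain = cls_init_gain,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Receptive field of a model stage
#'
#' Span of input bases influencing one output base of the stacked dilated
#' convolutions of a stage: `1 + 3 * blocks * (kernel - 1) * dilation` bp
#' (three convolutions per residual block; skip connections do not extend
#' it). The default regression stage (5 blocks, kernel 51, dilation 8)
#' gives 6001 bp.
#'
#' @param config A [model_config()].
#' @param stage `"regression"` (default) or `"classification"`.
#' @return Receptive field in bp (odd integer).
#' @export
receptive_field <- function(config, stage = c("regression", "classification")) {
  stage <- match.arg(stage)
  blocks <- if (stage == "regression") config$reg_blocks else config$cls_blocks
  1L + 3L * blocks * (config$kernel - 1L) * config$dilation
}

# span influencing the probability output: both stages plus the two
# single-filter heads; used for padding-sufficiency checks
full_receptive_field <- function(config) {
  layers <- 3L * (config$reg_blocks + config$cls_blocks) + 2L
  1L + layers * (config$kernel - 1L) * config$dilation
}

#' Build an untrained model
#'
#' Initializes all convolution parameters deterministically from
#' `config$seed` (He-scaled normal weights, zero biases).
#'
#' @param config A [model_config()].
#' @return A `trained_model` object (config, parameters, empty manifest).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  params <- withr::with_seed(config$seed, init_params(config))
  structure(list(config = config, params = params,
                 manifest = list(epochs_run = 0L)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, function(p) length(p$W) + length(p$b),
                      numeric(1)))
  cat("<trained_model> ", cfg$reg_blocks, "+", cfg$cls_blocks,
      " residual blocks, ", cfg$filters, " filters, kernel ", cfg$kernel,
      ", dilation ", cfg$dilation, "; ", format(n_par, big.mark = ","),
      " parameters; epochs run: ", x$manifest$epochs_run, "\n", sep = "")
  invisible(x)
}

#' Forward pass on one padded window
#'
#' @param model A `trained_model`.
#' @param input Either a W x C numeric matrix (one column per input
#'   channel) or a length-W numeric vector (single channel).
#' @return List with `signal` (denoised coverage, length W, nonnegative)
#'   and `prob` (peak probabilities, length W, in (0, 1)).
#' @export
model_forward <- function(model, input) {
  stopifnot(inherits(model, "trained_model"))
  X <- if (is.matrix(input)) input else matrix(input, ncol = 1)
  if (ncol(X) != model$config$in_channels) {
    stop("input has ", ncol(X), " channels, model expects ",
         model$config$in_channels)
  }
  fwd <- nn_forward(model$params, model$config, X)
  list(signal = as.numeric(fwd$signal), prob = as.numeric(fwd$prob))
}

#' Loss weights for the composite training loss
#' @param w_mse,w_pearson,w_bce Nonnegative weights (defaults 1) of the MSE,
#'   `1 - Pearson r` and binary cross-entropy components.
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(w_mse = 1, w_pearson = 1, w_bce = 1) {
  stopifnot(w_mse >= 0, w_pearson >= 0, w_bce >= 0)
  if (w_mse + w_pearson + w_bce == 0) stop("loss weights must not all be zero")
  structure(list(w_mse = w_mse, w_pearson = w_pearson, w_bce = w_bce),
            class = "loss_weights")
}

#' Composite training loss for one window
#'
#' `total = w_mse * MSE(signal, target) + w_pearson * (1 - r(signal, target))
#' + w_bce * BCE(prob, labels)`. The Pearson term treats a constant vector
#' as `r = 0` (so all-zero padded windows contribute a finite loss of 1),
#' and probabilities are clamped to the interval (`eps`, `1 - eps`) inside
#' the BCE.
#'
#' @param pred_signal,target_signal Equal-length numeric vectors.
#' @param pred_prob Predicted probabilities in (0, 1).
#' @param target_labels 0/1 labels.
#' @param weights A [loss_weights()].
#' @param eps BCE clamp (default 1e-7).
#' @return List with `total`, `mse`, `pearson_loss`, `bce`.
#' @export
composite_loss <- function(pred_signal, pred_prob, target_signal,
                           target_labels, weights = loss_weights(),
                           eps = 1e-7) {
  n <- length(target_signal)
  if (length(pred_signal) != n || length(pred_prob) != length(target_labels)) {
    stop("length mismatch between predictions and targets")
  }
  mse <- mean((pred_signal - target_signal)^2)
  pc <- pred_signal - mean(pred_signal)
  yc <- target_signal - mean(target_signal)
  Sp <- sqrt(sum(pc^2)); Sy <- sqrt(sum(yc^2))
  r <- if (Sp > 0 && Sy > 0) sum(pc * yc) / (Sp * Sy + 1e-8) else 0
  pearson_loss <- 1 - r
  q <- pmin(pmax(pred_prob, eps), 1 - eps)
  bce <- -mean(target_labels * log(q) + (1 - target_labels) * log(1 - q))
  total <- weights$w_mse * mse + weights$w_pearson * pearson_loss +
    weights$w_bce * bce
  list(total = total, mse = mse, pearson_loss = pearson_loss, bce = bce)
}

checkpoint_magic <- "atacdenoise-checkpoint-v1"

#' Save / load a model checkpoint
#'
#' Single-file archive holding a versioned magic header, the config echo,
#' all parameter tensors and the training manifest; a reloaded model
#' reproduces forward outputs bit-identically.
#'
#' @param model A `trained_model`.
#' @param path Checkpoint file path.
#' @return `save_model`: the path, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(list(magic = checkpoint_magic, config = model$config,
               params = model$params, manifest = model$manifest), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$magic, checkpoint_magic)) {
    stop("not an atacdenoise checkpoint: ", path)
  }
  structure(list(config = x$config, params = x$params,
                 manifest = x$manifest), class = "trained_model")
}
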