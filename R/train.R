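#' Chromosome-based split specification
#'
#' Assigns every chromosome to exactly one of train / validation / holdout.
#' Defaults follow the convention of validating on chr20 (human) or chr11
#' (mouse) and holding out chr10; all other chromosomes train.
#'
#' @param validation_chroms Validation chromosomes.
#' @param holdout_chroms Holdout chromosomes (never seen during training or
#'   checkpoint selection).
#' @return A `split_spec` object.
#' @export
split_spec <- function(validation_chroms = c("chr20", "chr11"),
                       holdout_chroms = "chr10") {
  if (length(intersect(validation_chroms, holdout_chroms)) > 0L) {
    stop("validation and holdout chromosome sets must be disjoint")
  }
  structure(list(validation_chroms = validation_chroms,
                 holdout_chroms = holdout_chroms), class = "split_spec")
}

#' Partition training examples by chromosome
#'
#' @param examples List of examples from [extract_examples()].
#' @param split A [split_spec()].
#' @return List with `train`, `val`, `holdout` example lists (a partition of
#'   the input). Errors if the validation set is empty, since checkpoint
#'   selection requires it.
#' @export
split_examples <- function(examples, split = split_spec()) {
  chroms <- vapply(examples, function(e) e$chrom, character(1))
  val <- chroms %in% split$validation_chroms
  hold <- chroms %in% split$holdout_chroms
  out <- list(train = examples[!val & !hold], val = examples[val],
              holdout = examples[hold])
  if (length(out$val) == 0L) {
    stop("empty validation set: no examples on ",
         paste(split$validation_chroms, collapse = "/"))
  }
  out
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 2e-4).
#' @param epochs Number of epochs (default 25).
#' @param batch_size Examples per batch (default 64).
#' @param weights A [loss_weights()].
#' @param shuffle_seed Seed for per-epoch shuffling.
#' @param select_metric Checkpoint-selection criterion: `"loss"` (lowest
#'   total validation loss, default) or `"auprc"` (highest validation
#'   AUPRC).
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 2e-4, epochs = 25L, batch_size = 64L,
                         weights = loss_weights(), shuffle_seed = 1L,
                         select_metric = c("loss", "auprc")) {
  stopifnot(lr > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), weights = weights,
                 shuffle_seed = as.integer(shuffle_seed),
                 select_metric = match.arg(select_metric)),
            class = "train_config")
}

# loss value + gradients for one example; used by train()
example_loss_and_grads <- function(params, config, ex, weights, g) {
  fwd <- nn_forward(params, config, ex$input, keep_cache = TRUE)
  loss <- composite_loss(as.numeric(fwd$signal), as.numeric(fwd$prob),
                         ex$target, ex$labels, weights)
  gr <- loss_gradients(fwd$signal, fwd$prob, ex$target, ex$labels, weights)
  nn_backward(params, config, fwd, gr$dSignal, gr$dLogit, g)
  loss
}

#' Train a model
#'
#' Mini-batch Adam training with per-epoch shuffling (seeded) and per-epoch
#' validation; returns the parameters from the epoch with the best
#' validation performance, not the last. Gradients are averaged over each
#' batch; a non-finite loss aborts with a diagnostic.
#'
#' @param model An untrained or pre-trained `trained_model`.
#' @param train_examples,val_examples Nonempty example lists from
#'   [extract_examples()] / [split_examples()].
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best-validation checkpoint) and `run` (a
#'   `training_run`: per-epoch train loss components, validation records,
#'   best epoch index, wall time).
#' @export
train <- function(model, train_examples, val_examples,
                  config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "trained_model"), length(train_examples) > 0L,
            length(val_examples) > 0L)
  mcfg <- model$config
  params <- model$params
  state <- adam_state(params)
  history <- vector("list", config$epochs)
  best <- list(epoch = NA_integer_, score = Inf, params = NULL, val = NULL)
  t0 <- proc.time()[["elapsed"]]
  withr::with_seed(config$shuffle_seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(length(train_examples))
      comp_sum <- c(total = 0, mse = 0, pearson_loss = 0, bce = 0)
      n_seen <- 0L
      for (batch in split(perm, ceiling(seq_along(perm) / config$batch_size))) {
        g <- new_grad_env(params)
        for (i in batch) {
          loss <- example_loss_and_grads(params, mcfg, train_examples[[i]],
                                         config$weights, g)
          if (!is.finite(loss$total)) {
            stop("non-finite training loss at epoch ", epoch,
                 " (example on ", train_examples[[i]]$chrom, ":",
                 train_examples[[i]]$start, ")")
          }
          comp_sum <- comp_sum + unlist(loss)
          n_seen <- n_seen + 1L
        }
        # average over the batch
        for (nm in names(g$gW)) {
          g$gW[[nm]] <- g$gW[[nm]] / length(batch)
          g$gb[[nm]] <- g$gb[[nm]] / length(batch)
        }
        st <- adam_step(params, g, state, config$lr)
        params <- st$params; state <- st$state
      }
      train_loss <- as.list(comp_sum / n_seen)
      cur <- structure(list(config = mcfg, params = params,
                            manifest = model$manifest),
                       class = "trained_model")
      val <- validate(cur, val_examples, config)
      score <- if (config$select_metric == "auprc") -val$auprc else val$total
      if (is.finite(score) && score < best$score) {
        best <- list(epoch = epoch, score = score, params = params, val = val)
      }
      history[[epoch]] <- list(epoch = epoch, train = train_loss, val = val)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f | val %.4f (auprc %.3f)",
                        epoch, train_loss$total, val$total, val$auprc))
      }
    }
  })
  run <- structure(list(
    epochs = history, best_epoch = best$epoch, best_val = best$val,
    select_metric = config$select_metric,
    elapsed_sec = proc.time()[["elapsed"]] - t0
  ), class = "training_run")
  manifest <- list(
    epochs_run = config$epochs, best_epoch = best$epoch,
    lr = config$lr, batch_size = config$batch_size,
    weights = unclass(config$weights), shuffle_seed = config$shuffle_seed,
    select_metric = config$select_metric,
    adam = list(beta1 = 0.9, beta2 = 0.999, eps = 1e-8),
    loss_window = "full padded window"
  )
  best_model <- structure(list(config = mcfg, params = best$params,
                               manifest = manifest),
                          class = "trained_model")
  list(model = best_model, run = run)
}

#' Evaluate a model on a set of examples
#'
#' Deterministic given model and data: mean composite-loss components over
#' the examples, plus AUPRC of the pooled per-base probabilities against
#' the pooled labels (NA when the labels are single-class).
#'
#' @param model A `trained_model`.
#' @param examples Nonempty example list with targets and labels.
#' @param config A [train_config()] (for the loss weights).
#' @return List: `total`, `mse`, `pearson_loss`, `bce`, `auprc`, `n`.
#' @export
validate <- function(model, examples, config = train_config()) {
  stopifnot(length(examples) > 0L)
  comp_sum <- c(total = 0, mse = 0, pearson_loss = 0, bce = 0)
  probs <- vector("list", length(examples))
  labs <- vector("list", length(examples))
  for (i in seq_along(examples)) {
    ex <- examples[[i]]
    fwd <- nn_forward(model$params, model$config, ex$input)
    loss <- composite_loss(as.numeric(fwd$signal), as.numeric(fwd$prob),
                           ex$target, ex$labels, config$weights)
    comp_sum <- comp_sum + unlist(loss)
    probs[[i]] <- as.numeric(fwd$prob)
    labs[[i]] <- ex$labels
  }
  out <- as.list(comp_sum / length(examples))
  y <- unlist(labs)
  auprc <- if (length(unique(y)) == 2L) {
    classification_metrics(unlist(probs), y)$auprc
  } else NA_real_
  c(out, list(auprc = auprc, n = length(examples)))
}
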