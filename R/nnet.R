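# Internal network machinery: parameter initialization, forward/backward
# passes through the dilated residual stages, and the Adam optimizer.
# Feature maps are position-major (W x C, one column per channel) and
# convolutions run through the Rcpp im2col+GEMM kernels; weights live as
# (C*K) x F matrices (row index c + C*t).

conv_layer <- function(in_ch, out_ch, K, dilation, gain = 1) {
  sd <- gain * sqrt(2 / (in_ch * K))  # He initialization for ReLU stacks
  list(W = matrix(stats::rnorm(out_ch * in_ch * K, sd = sd), ncol = out_ch),
       b = numeric(out_ch),
       K = as.integer(K), dilation = as.integer(dilation),
       in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
}

conv_f <- function(X, ly) cpp_conv1d_forward(X, ly$W, ly$b, ly$K, ly$dilation)
conv_b <- function(X, ly, G) cpp_conv1d_backward(X, ly$W, G, ly$K, ly$dilation)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# layer names of one residual block; proj only when channel counts differ
block_layer_names <- function(prefix, has_proj) {
  c(paste0(prefix, "_", 1:3), if (has_proj) paste0(prefix, "_proj"))
}

# ordered layer plan for a config: list(name, in_ch, out_ch, K, dilation)
layer_plan <- function(config) {
  plan <- list()
  add <- function(name, i, o, K, d, g = 1) {
    plan[[name]] <<- list(in_ch = i, out_ch = o, K = K, dilation = d,
                          gain = g)
  }
  F <- config$filters; K <- config$kernel; d <- config$dilation
  stage <- function(tag, n_blocks, in_ch, g) {
    for (b in seq_len(n_blocks)) {
      p <- paste0(tag, b)
      add(paste0(p, "_1"), in_ch, F, K, d, g)
      add(paste0(p, "_2"), F, F, K, d, g)
      add(paste0(p, "_3"), F, F, K, d, g)
      if (in_ch != F) add(paste0(p, "_proj"), in_ch, F, 1L, 1L, g)
      in_ch <- F
    }
    in_ch
  }
  # the classification stage consumes raw-coverage-scale signal; a reduced
  # init gain keeps its initial logits O(1) so the sigmoid is unsaturated
  g_cls <- config$cls_init_gain
  last <- stage("reg", config$reg_blocks, config$in_channels, 1)
  add("reg_head", last, 1L, K, d, 1)
  last <- stage("cls", config$cls_blocks, 1L, g_cls)
  add("cls_head", last, 1L, K, d, g_cls)
  plan
}

init_params <- function(config) {
  plan <- layer_plan(config)
  lapply(plan, function(p) conv_layer(p$in_ch, p$out_ch, p$K, p$dilation,
                                      p$gain))
}

block_forward <- function(params, prefix, A0) {
  c1 <- params[[paste0(prefix, "_1")]]
  c2 <- params[[paste0(prefix, "_2")]]
  c3 <- params[[paste0(prefix, "_3")]]
  proj <- params[[paste0(prefix, "_proj")]]
  Z1 <- conv_f(A0, c1); A1 <- relu(Z1)
  Z2 <- conv_f(A1, c2); A2 <- relu(Z2)
  Z3 <- conv_f(A2, c3)
  S <- if (is.null(proj)) A0 else conv_f(A0, proj)
  Zb <- Z3 + S
  list(out = relu(Zb), cache = list(A0 = A0, Z1 = Z1, A1 = A1, Z2 = Z2,
                                    A2 = A2, Zb = Zb))
}

# dAb -> dA0, accumulating layer gradients into env `g` (named lists gW, gb)
block_backward <- function(params, prefix, cache, dAb, g) {
  c1 <- params[[paste0(prefix, "_1")]]
  c2 <- params[[paste0(prefix, "_2")]]
  c3 <- params[[paste0(prefix, "_3")]]
  proj <- params[[paste0(prefix, "_proj")]]
  dZb <- dAb * (cache$Zb > 0)
  bw3 <- conv_b(cache$A2, c3, dZb)
  acc_grad(g, paste0(prefix, "_3"), bw3)
  dZ2 <- bw3$dX * (cache$Z2 > 0)
  bw2 <- conv_b(cache$A1, c2, dZ2)
  acc_grad(g, paste0(prefix, "_2"), bw2)
  dZ1 <- bw2$dX * (cache$Z1 > 0)
  bw1 <- conv_b(cache$A0, c1, dZ1)
  acc_grad(g, paste0(prefix, "_1"), bw1)
  dA0 <- bw1$dX
  if (is.null(proj)) {
    dA0 + dZb
  } else {
    bwp <- conv_b(cache$A0, proj, dZb)
    acc_grad(g, paste0(prefix, "_proj"), bwp)
    dA0 + bwp$dX
  }
}

new_grad_env <- function(params) {
  g <- new.env(parent = emptyenv())
  g$gW <- lapply(params, function(p) p$W * 0)
  g$gb <- lapply(params, function(p) p$b * 0)
  g
}

acc_grad <- function(g, name, bw) {
  g$gW[[name]] <- g$gW[[name]] + bw$dW
  g$gb[[name]] <- g$gb[[name]] + bw$db
}

# full forward pass; X is a W x C matrix
nn_forward <- function(params, config, X, keep_cache = FALSE) {
  caches <- list()
  A <- X
  for (b in seq_len(config$reg_blocks)) {
    fb <- block_forward(params, paste0("reg", b), A)
    if (keep_cache) caches[[paste0("reg", b)]] <- fb$cache
    A <- fb$out
  }
  A_reg <- A
  Zr <- conv_f(A_reg, params$reg_head)
  signal <- relu(Zr)               # nonnegative predicted coverage, W x 1
  A <- signal
  for (b in seq_len(config$cls_blocks)) {
    fb <- block_forward(params, paste0("cls", b), A)
    if (keep_cache) caches[[paste0("cls", b)]] <- fb$cache
    A <- fb$out
  }
  A_cls <- A
  Zc <- conv_f(A_cls, params$cls_head)
  out <- list(signal = signal, logit = Zc, prob = sigmoid(Zc))
  if (keep_cache) {
    out$cache <- list(blocks = caches, A_reg = A_reg, Zr = Zr, A_cls = A_cls)
  }
  out
}

# backward pass from per-base gradients on the regression output (dSignal)
# and the classification logits (dLogit); both W x 1
nn_backward <- function(params, config, fwd, dSignal, dLogit, g) {
  cache <- fwd$cache
  bwh <- conv_b(cache$A_cls, params$cls_head, dLogit)
  acc_grad(g, "cls_head", bwh)
  dA <- bwh$dX
  for (b in rev(seq_len(config$cls_blocks))) {
    dA <- block_backward(params, paste0("cls", b), cache$blocks[[paste0("cls", b)]],
                         dA, g)
  }
  # classification stage consumes the (post-ReLU) regression output
  dZr <- (dSignal + dA) * (cache$Zr > 0)
  bwr <- conv_b(cache$A_reg, params$reg_head, dZr)
  acc_grad(g, "reg_head", bwr)
  dA <- bwr$dX
  for (b in rev(seq_len(config$reg_blocks))) {
    dA <- block_backward(params, paste0("reg", b), cache$blocks[[paste0("reg", b)]],
                         dA, g)
  }
  invisible(dA)
}

# gradients of the composite loss w.r.t. the regression output and the
# classification logits, for one window
loss_gradients <- function(signal, prob, target, labels, weights,
                           eps = 1e-8) {
  n <- length(target)
  s <- as.numeric(signal)
  dS <- weights$w_mse * 2 * (s - target) / n
  if (weights$w_pearson != 0) {
    pc <- s - mean(s); yc <- target - mean(target)
    Sp <- sqrt(sum(pc^2)); Sy <- sqrt(sum(yc^2))
    if (Sp > 0 && Sy > 0) {
      denom <- Sp * Sy + eps
      r <- sum(pc * yc) / denom
      dr <- (yc - r * (denom / Sp) * pc / Sp) / denom
      dS <- dS - weights$w_pearson * dr
    }
  }
  dL <- weights$w_bce * (as.numeric(prob) - labels) / n
  list(dSignal = matrix(dS, ncol = 1), dLogit = matrix(dL, ncol = 1))
}

adam_state <- function(params) {
  list(mW = lapply(params, function(p) p$W * 0),
       vW = lapply(params, function(p) p$W * 0),
       mb = lapply(params, function(p) p$b * 0),
       vb = lapply(params, function(p) p$b * 0),
       t = 0L)
}

adam_step <- function(params, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gW <- g$gW[[nm]]; gb <- g$gb[[nm]]
    state$mW[[nm]] <- beta1 * state$mW[[nm]] + (1 - beta1) * gW
    state$vW[[nm]] <- beta2 * state$vW[[nm]] + (1 - beta2) * gW^2
    state$mb[[nm]] <- beta1 * state$mb[[nm]] + (1 - beta1) * gb
    state$vb[[nm]] <- beta2 * state$vb[[nm]] + (1 - beta2) * gb^2
    params[[nm]]$W <- params[[nm]]$W -
      lr * (state$mW[[nm]] / c1) / (sqrt(state$vW[[nm]] / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b -
      lr * (state$mb[[nm]] / c1) / (sqrt(state$vb[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
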