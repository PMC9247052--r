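# Self-contained 1-D convolutional network engine for spectral
# classification. Activations flow as (batch, length, channels) arrays
# through the convolutional blocks and as (batch, features) matrices after
# flattening. Every block is linear-map -> batch normalization -> ELU,
# followed by average pooling (conv blocks) or dropout (fully connected
# blocks); a final linear layer produces class logits. Convolutions are
# "valid" (no padding). All randomness (initialization, dropout, batch
# sampling) is driven by R's RNG, so seeded runs are bit-reproducible.

#' Architecture of the spectral CNN
#'
#' Defaults reproduce the study architecture: three convolutional layers
#' with 64, 32 and 16 filters (kernel size 5, each followed by average
#' pooling with kernel size 2), two fully connected layers with 100 and 50
#' neurons (each with dropout), batch normalization and ELU on all five
#' hidden layers, and a final linear layer onto 20 class logits. On
#' 100-band input this totals 34,326 trainable parameters.
#'
#' @param conv_filters Integer vector of filters per convolutional layer.
#' @param conv_kernel Convolution kernel size (spectral bands).
#' @param pool_kernel Average-pooling kernel size.
#' @param fc_sizes Integer vector of fully connected layer widths.
#' @param n_classes Number of output classes.
#' @param dropout_p Dropout probability on the fully connected blocks.
#' @param input_bands Spectral length of the input.
#' @return A list of class `cnn_architecture`.
#' @export
cnn_architecture <- function(conv_filters = c(64L, 32L, 16L), conv_kernel = 5L,
                             pool_kernel = 2L, fc_sizes = c(100L, 50L),
                             n_classes = 20L, dropout_p = 0.2,
                             input_bands = 100L) {
  if (any(c(conv_filters, conv_kernel, pool_kernel, fc_sizes, n_classes,
            input_bands) < 1)) {
    abort("All architecture sizes must be positive.")
  }
  if (dropout_p < 0 || dropout_p >= 1) abort("`dropout_p` must be in [0, 1).")
  len <- input_bands
  for (i in seq_along(conv_filters)) {
    len <- len - conv_kernel + 1L
    len <- if (len >= pool_kernel) len %/% pool_kernel else 0L
    if (len < 1L) {
      min_len <- minimal_input_length(length(conv_filters), conv_kernel, pool_kernel)
      abort(sprintf("Input of %d bands too short for %d conv/pool stages; minimal admissible length is %d.",
                    input_bands, length(conv_filters), min_len))
    }
  }
  structure(
    list(conv_filters = as.integer(conv_filters),
         conv_kernel = as.integer(conv_kernel),
         pool_kernel = as.integer(pool_kernel),
         fc_sizes = as.integer(fc_sizes), n_classes = as.integer(n_classes),
         dropout_p = dropout_p, input_bands = as.integer(input_bands),
         flatten_dim = len * conv_filters[length(conv_filters)]),
    class = "cnn_architecture"
  )
}

minimal_input_length <- function(n_conv, k, pool) {
  for (len in seq_len(10000L)) {
    l <- len
    ok <- TRUE
    for (i in seq_len(n_conv)) {
      l <- l - k + 1L
      l <- if (l >= pool) l %/% pool else 0L
      if (l < 1L) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(len)
  }
  NA_integer_
}

new_bn_layer <- function(channels) {
  list(kind = "bn", gamma = rep(1, channels), beta = rep(0, channels),
       run_mean = rep(0, channels), run_var = rep(1, channels),
       momentum = 0.1, eps = 1e-5, n_batches = 0L)
}

#' Build a seeded spectral CNN
#'
#' Instantiates the architecture with He-scaled normal initial weights.
#' Identical `(arch, seed)` give identical models.
#'
#' @param arch A [cnn_architecture()].
#' @param seed Integer seed for the initialization.
#' @return An object of class `spectral_cnn`.
#' @export
build_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "cnn_architecture"))
  set.seed(seed)
  layers <- list()
  c_in <- 1L
  for (f in arch$conv_filters) {
    k <- arch$conv_kernel
    layers <- c(layers, list(
      list(kind = "conv", k = k,
           W = array(rnorm(c_in * f * k, sd = sqrt(2 / (c_in * k))),
                     dim = c(c_in, f, k)),
           b = rep(0, f)),
      new_bn_layer(f),
      list(kind = "elu"),
      list(kind = "pool", k = arch$pool_kernel)
    ))
    c_in <- f
  }
  layers <- c(layers, list(list(kind = "flatten")))
  f_in <- arch$flatten_dim
  for (f in arch$fc_sizes) {
    layers <- c(layers, list(
      list(kind = "dense",
           W = matrix(rnorm(f_in * f, sd = sqrt(2 / f_in)), f_in, f),
           b = rep(0, f)),
      new_bn_layer(f),
      list(kind = "elu"),
      list(kind = "dropout", p = arch$dropout_p)
    ))
    f_in <- f
  }
  layers <- c(layers, list(
    list(kind = "dense",
         W = matrix(rnorm(f_in * arch$n_classes, sd = sqrt(1 / f_in)),
                    f_in, arch$n_classes),
         b = rep(0, arch$n_classes))
  ))
  structure(list(layers = layers, arch = arch, seed = seed, classes = NULL),
            class = "spectral_cnn")
}

#' @export
print.spectral_cnn <- function(x, ...) {
  a <- x$arch
  cat(sprintf(
    "<spectral_cnn> conv(%s, k=%d) + fc(%s) -> %d classes; %d parameters%s\n",
    paste(a$conv_filters, collapse = "/"), a$conv_kernel,
    paste(a$fc_sizes, collapse = "/"), a$n_classes, n_parameters(x),
    if (is.null(x$classes)) " (untrained)" else ""
  ))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Counts convolution and dense weights and biases plus the batch
#' normalization scale/shift pairs (running statistics are not trainable).
#'
#' @param model A [build_model()] result.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    switch(l$kind,
      conv = length(l$W) + length(l$b),
      dense = length(l$W) + length(l$b),
      bn = length(l$gamma) + length(l$beta),
      0L
    )
  }, numeric(1)))
}

## ---- layer forward/backward --------------------------------------------

conv_forward <- function(A, layer) {
  d <- dim(A)
  n <- d[1]; len <- d[2]; c_in <- d[3]
  k <- layer$k
  c_out <- dim(layer$W)[2]
  lo <- len - k + 1L
  out <- matrix(rep(layer$b, each = n * lo), n * lo, c_out)
  wj <- layer$W
  dim(wj) <- c(c_in, c_out * k)
  for (j in seq_len(k)) {
    xj <- A[, j:(j + lo - 1L), , drop = FALSE]
    dim(xj) <- c(n * lo, c_in)
    out <- out + xj %*% wj[, ((j - 1L) * c_out + 1L):(j * c_out), drop = FALSE]
  }
  dim(out) <- c(n, lo, c_out)
  list(out = out, cache = list(A = A))
}

conv_backward <- function(dout, cache, layer) {
  A <- cache$A
  d <- dim(A)
  n <- d[1]; c_in <- d[3]
  k <- layer$k
  c_out <- dim(dout)[3]
  lo <- dim(dout)[2]
  dmat <- dout
  dim(dmat) <- c(n * lo, c_out)
  dW <- array(0, dim = dim(layer$W))
  dA <- array(0, dim = d)
  for (j in seq_len(k)) {
    xj <- A[, j:(j + lo - 1L), , drop = FALSE]
    dim(xj) <- c(n * lo, c_in)
    dW[, , j] <- crossprod(xj, dmat)
    wj <- layer$W[, , j]
    dim(wj) <- c(c_in, c_out)
    dxj <- tcrossprod(dmat, wj)
    dim(dxj) <- c(n, lo, c_in)
    dA[, j:(j + lo - 1L), ] <- dA[, j:(j + lo - 1L), , drop = FALSE] + dxj
  }
  list(dA = dA, grads = list(W = dW, b = colSums(dmat)))
}

bn_forward <- function(A, layer, training) {
  dims <- dim(A)
  ch <- dims[length(dims)]
  M <- A
  if (length(dims) == 3L) dim(M) <- c(dims[1] * dims[2], ch)
  if (training) {
    mu <- colMeans(M)
    v <- colMeans(M * M) - mu^2
    # exact cumulative average over the first 1/momentum batches, then an
    # exponential moving average: removes the arbitrary (0, 1) initialization
    # from the running statistics of short training runs
    layer$n_batches <- layer$n_batches + 1L
    mom <- max(layer$momentum, 1 / layer$n_batches)
    layer$run_mean <- (1 - mom) * layer$run_mean + mom * mu
    layer$run_var <- (1 - mom) * layer$run_var + mom * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  m <- nrow(M)
  xhat <- (M - rep(mu, each = m)) * rep(invstd, each = m)
  out <- xhat * rep(layer$gamma, each = m) + rep(layer$beta, each = m)
  dim(out) <- dims
  list(out = out, cache = list(xhat = xhat, invstd = invstd, dims = dims),
       layer = layer)
}

bn_backward <- function(dout, cache, layer) {
  dims <- cache$dims
  ch <- dims[length(dims)]
  dM <- dout
  if (length(dims) == 3L) dim(dM) <- c(dims[1] * dims[2], ch)
  m <- nrow(dM)
  xhat <- cache$xhat
  dgamma <- colSums(dM * xhat)
  dbeta <- colSums(dM)
  dxhat <- dM * rep(layer$gamma, each = m)
  s1 <- colSums(dxhat) / m
  s2 <- colSums(dxhat * xhat) / m
  dX <- (dxhat - rep(s1, each = m) - xhat * rep(s2, each = m)) *
    rep(cache$invstd, each = m)
  dim(dX) <- dims
  list(dA = dX, grads = list(gamma = dgamma, beta = dbeta))
}

elu_forward <- function(A) {
  # branch-free: pmax(A,0) + expm1(pmin(A,0)); derivative exp(pmin(A,0))
  deriv <- exp(pmin(A, 0))
  out <- pmax(A, 0) + (deriv - 1)
  list(out = out, cache = list(deriv = deriv))
}

elu_backward <- function(dout, cache) {
  list(dA = dout * cache$deriv, grads = NULL)
}

pool_forward <- function(A, layer) {
  d <- dim(A)
  k <- layer$k
  lo <- d[2] %/% k
  out <- array(0, dim = c(d[1], lo, d[3]))
  for (j in seq_len(k)) {
    out <- out + A[, seq(j, lo * k, by = k), , drop = FALSE]
  }
  list(out = out / k, cache = list(dims = d))
}

pool_backward <- function(dout, cache, layer) {
  k <- layer$k
  lo <- dim(dout)[2]
  dA <- array(0, dim = cache$dims)
  for (j in seq_len(k)) {
    dA[, seq(j, lo * k, by = k), ] <- dout / k
  }
  list(dA = dA, grads = NULL)
}

flatten_forward <- function(A) {
  d <- dim(A)
  out <- A
  dim(out) <- c(d[1], d[2] * d[3])
  list(out = out, cache = list(dims = d))
}

flatten_backward <- function(dout, cache) {
  dim(dout) <- cache$dims
  list(dA = dout, grads = NULL)
}

dense_forward <- function(A, layer) {
  out <- A %*% layer$W + rep(layer$b, each = nrow(A))
  list(out = out, cache = list(A = A))
}

dense_backward <- function(dout, cache, layer) {
  list(dA = dout %*% t(layer$W),
       grads = list(W = t(cache$A) %*% dout, b = colSums(dout)))
}

dropout_forward <- function(A, layer, training) {
  if (!training || layer$p == 0) {
    return(list(out = A, cache = NULL))
  }
  mask <- (matrix(runif(length(A)), nrow(A)) >= layer$p) / (1 - layer$p)
  list(out = A * mask, cache = list(mask = mask))
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache)) return(list(dA = dout, grads = NULL))
  list(dA = dout * cache$mask, grads = NULL)
}

nn_forward <- function(model, X, training = FALSE) {
  A <- array(X, dim = c(nrow(X), ncol(X), 1L))
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    res <- switch(layer$kind,
      conv = conv_forward(A, layer),
      bn = bn_forward(A, layer, training),
      elu = elu_forward(A),
      pool = pool_forward(A, layer),
      flatten = flatten_forward(A),
      dense = dense_forward(A, layer),
      dropout = dropout_forward(A, layer, training)
    )
    A <- res$out
    caches[[li]] <- res$cache
    if (!is.null(res$layer)) model$layers[[li]] <- res$layer
  }
  list(out = A, caches = caches, model = model)
}

nn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (li in rev(seq_along(model$layers))) {
    layer <- model$layers[[li]]
    res <- switch(layer$kind,
      conv = conv_backward(dout, caches[[li]], layer),
      bn = bn_backward(dout, caches[[li]], layer),
      elu = elu_backward(dout, caches[[li]]),
      pool = pool_backward(dout, caches[[li]], layer),
      flatten = flatten_backward(dout, caches[[li]]),
      dense = dense_backward(dout, caches[[li]], layer),
      dropout = dropout_backward(dout, caches[[li]])
    )
    dout <- res$dA
    grads[li] <- list(res$grads) # keep NULL placeholders for param-free layers
  }
  grads
}

# numerically stable softmax cross-entropy; optional per-class weights
# (torch convention: weighted mean with weight-sum denominator)
softmax_xent <- function(logits, y, weights = NULL) {
  n <- nrow(logits)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  p_true <- probs[cbind(seq_len(n), y)]
  nll <- -log(pmax(p_true, 1e-12))
  onehot <- matrix(0, n, ncol(logits))
  onehot[cbind(seq_len(n), y)] <- 1
  if (is.null(weights)) {
    list(loss = mean(nll), dlogits = (probs - onehot) / n)
  } else {
    wy <- weights[y]
    sw <- sum(wy)
    list(loss = sum(wy * nll) / sw, dlogits = (probs - onehot) * (wy / sw))
  }
}

adam_init <- function(model) {
  model$opt <- list(t = 0L, state = lapply(model$layers, function(l) {
    if (l$kind %in% c("conv", "dense")) {
      list(mW = array(0, dim = dim(l$W) %||% c(length(l$W))), vW = array(0, dim = dim(l$W) %||% c(length(l$W))),
           mb = rep(0, length(l$b)), vb = rep(0, length(l$b)))
    } else if (l$kind == "bn") {
      list(mg = rep(0, length(l$gamma)), vg = rep(0, length(l$gamma)),
           mb = rep(0, length(l$beta)), vb = rep(0, length(l$beta)))
    } else {
      NULL
    }
  }))
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(model, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  model$opt$t <- model$opt$t + 1L
  t <- model$opt$t
  upd <- function(param, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(param = param - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (li in seq_along(model$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    l <- model$layers[[li]]
    s <- model$opt$state[[li]]
    if (l$kind %in% c("conv", "dense")) {
      r <- upd(l$W, g$W, s$mW, s$vW)
      l$W <- r$param; s$mW <- r$m; s$vW <- r$v
      r <- upd(l$b, g$b, s$mb, s$vb)
      l$b <- r$param; s$mb <- r$m; s$vb <- r$v
    } else if (l$kind == "bn") {
      r <- upd(l$gamma, g$gamma, s$mg, s$vg)
      l$gamma <- r$param; s$mg <- r$m; s$vg <- r$v
      r <- upd(l$beta, g$beta, s$mb, s$vb)
      l$beta <- r$param; s$mb <- r$m; s$vb <- r$v
    }
    model$layers[[li]] <- l
    model$opt$state[[li]] <- s
  }
  model
}

#' Training configuration for the spectral CNN
#'
#' Adam (beta1 = 0.9, beta2 = 0.999) with an exponential learning-rate
#' decay: the rate is multiplied by `lr_decay` after each epoch. Each epoch
#' draws `samples_per_epoch` annotations with replacement, uniformly or
#' class-balanced (`oversampling`). The loss is multiclass cross-entropy,
#' optionally class-weighted inversely to per-class training counts
#' (weights normalized to mean one). The study-scale values are
#' 10^7 samples/epoch, 10 epochs, batch 20,000; the desk-scale defaults
#' here train a fold in seconds to minutes on one CPU.
#'
#' @param initial_lr Initial learning rate (> 0).
#' @param lr_decay Per-epoch decay factor in (0, 1].
#' @param batch_size Minibatch size.
#' @param samples_per_epoch Annotations drawn per epoch.
#' @param epochs Number of epochs.
#' @param class_weighting Weight the loss inversely to class counts.
#' @param oversampling Sample classes uniformly when drawing batches.
#' @param seed Integer seed for sampling, dropout and initialization.
#' @return A list of class `training_config`.
#' @export
training_config <- function(initial_lr = 0.001, lr_decay = 0.9,
                            batch_size = 128L, samples_per_epoch = 8192L,
                            epochs = 3L, class_weighting = TRUE,
                            oversampling = FALSE, seed = 1L) {
  if (initial_lr <= 0) abort("`initial_lr` must be > 0.")
  if (lr_decay <= 0 || lr_decay > 1) abort("`lr_decay` must be in (0, 1].")
  if (batch_size < 1) abort("`batch_size` must be >= 1.")
  structure(
    list(initial_lr = initial_lr, lr_decay = lr_decay,
         batch_size = as.integer(batch_size),
         samples_per_epoch = as.integer(samples_per_epoch),
         epochs = as.integer(epochs), class_weighting = class_weighting,
         oversampling = oversampling, seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Inverse-frequency class weights
#'
#' Weights proportional to `1 / n_c`, normalized to mean one over the
#' classes present.
#'
#' @param counts Named vector of per-class training counts (> 0).
#' @return Named numeric weights.
#' @export
class_weights <- function(counts) {
  stopifnot(all(counts > 0))
  w <- 1 / counts
  w / mean(w)
}

#' Train a spectral CNN
#'
#' @param model A [build_model()] result.
#' @param X Numeric matrix of spectra (rows = annotations, columns = bands).
#' @param y Factor of class labels (its levels define the logit order).
#' @param config A [training_config()].
#' @return The trained model, with `history` (per-batch loss) and `classes`
#'   attached. Seeded: identical inputs give identical loss trajectories.
#' @export
train_model <- function(model, X, y, config) {
  stopifnot(inherits(model, "spectral_cnn"), is.factor(y),
            nrow(X) == length(y))
  K <- model$arch$n_classes
  if (nlevels(y) != K) {
    abort(sprintf("`y` has %d levels but the model has %d classes.",
                  nlevels(y), K))
  }
  yi <- as.integer(y)
  counts <- tabulate(yi, nbins = K)
  present <- which(counts > 0)
  weights <- NULL
  if (config$class_weighting) {
    if (length(present) < K) {
      warn(sprintf("%d class(es) absent from the training fold; their weight terms are dropped.",
                   K - length(present)))
    }
    weights <- rep(0, K)
    weights[present] <- class_weights(counts[present])
  }
  by_class <- split(seq_along(yi), yi)
  set.seed(config$seed)
  model <- adam_init(model)
  lr <- config$initial_lr
  history <- numeric()
  for (epoch in seq_len(config$epochs)) {
    if (config$oversampling) {
      cls <- sample(present, config$samples_per_epoch, replace = TRUE)
      tab <- tabulate(cls, nbins = K)
      idx <- unlist(lapply(present, function(cc) {
        pool <- by_class[[as.character(cc)]]
        pool[sample.int(length(pool), tab[cc], replace = TRUE)]
      }))
      idx <- sample(idx)
    } else {
      idx <- sample.int(nrow(X), config$samples_per_epoch, replace = TRUE)
    }
    starts <- seq(1L, length(idx), by = config$batch_size)
    for (s in starts) {
      batch <- idx[s:min(s + config$batch_size - 1L, length(idx))]
      fwd <- nn_forward(model, X[batch, , drop = FALSE], training = TRUE)
      model <- fwd$model
      loss <- softmax_xent(fwd$out, yi[batch], weights)
      grads <- nn_backward(model, fwd$caches, loss$dlogits)
      model <- adam_step(model, grads, lr)
      history <- c(history, loss$loss)
    }
    lr <- lr * config$lr_decay
  }
  model$history <- history
  model$classes <- levels(y)
  model
}

#' Class logits of a trained model
#'
#' Forward pass in evaluation mode (batch normalization uses running
#' statistics, dropout disabled). Softmax is applied only when
#' probabilities are requested.
#'
#' @param model A trained `spectral_cnn`.
#' @param X Numeric matrix of spectra.
#' @return Numeric matrix (rows x classes) of logits.
#' @export
predict_logits <- function(model, X) {
  out <- nn_forward(model, as.matrix(X), training = FALSE)$out
  colnames(out) <- model$classes
  out
}

#' @export
predict.spectral_cnn <- function(object, newdata,
                                 type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  logits <- predict_logits(object, newdata)
  switch(type,
    logits = logits,
    prob = {
      ex <- exp(logits - apply(logits, 1L, max))
      ex / rowSums(ex)
    },
    class = {
      cls <- object$classes %||% as.character(seq_len(ncol(logits)))
      factor(cls[max.col(logits, ties.method = "first")], levels = cls)
    }
  )
}
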