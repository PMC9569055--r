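# Hierarchical neural network for pair scoring.
#
# Two three-layer ReLU towers project a circRNA's fused-similarity row and a
# disease's fused-similarity row into length-N high-order features CH and DH.
# Their element-wise product CD models multiplicative co-occurrence; the
# concatenation [CH; CD; DH] feeds a three-layer head
# (ReLU, ReLU, sigmoid) that outputs the association probability.
#
# Training minimizes binary cross-entropy plus an L2 penalty on all weight
# matrices by mini-batch Adam; every source of randomness (initialization,
# shuffling) derives from the config seed.

#' Model configuration
#'
#' @param highorder_dim length N of the high-order features; the supported
#'   sweep grid is 8/16/32/64/128 (other values work but warn).
#' @param tower_hidden widths of the first two tower layers.
#' @param head_hidden widths of the first two head layers.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param l2 L2 penalty coefficient on weight matrices (biases unpenalized).
#' @param seed integer seed controlling initialization and shuffling.
#' @return an object of class `model_config`.
#' @export
model_config <- function(highorder_dim = 64, tower_hidden = c(256, 128),
                         head_hidden = c(128, 64), learning_rate = 0.001,
                         batch_size = 128, epochs = 200, l2 = 1e-4, seed = 1) {
  stopifnot(highorder_dim >= 1, length(tower_hidden) == 2, length(head_hidden) == 2,
            all(tower_hidden >= 1), all(head_hidden >= 1),
            learning_rate > 0, batch_size >= 1, epochs >= 1, l2 >= 0)
  if (!(highorder_dim %in% c(8, 16, 32, 64, 128))) {
    warning(sprintf("highorder_dim %d is outside the usual sweep grid {8,16,32,64,128}",
                    highorder_dim))
  }
  structure(list(highorder_dim = as.integer(highorder_dim),
                 tower_hidden = as.integer(tower_hidden),
                 head_hidden = as.integer(head_hidden),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 l2 = l2, seed = as.integer(seed)),
            class = "model_config")
}

# Glorot (uniform) initialization; draws come from the current RNG stream.
.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

.init_stack <- function(dims, init) {
  W <- list()
  b <- list()
  for (i in seq_len(length(dims) - 1)) {
    W[[i]] <- if (init == "zero") matrix(0, dims[i], dims[i + 1]) else .glorot(dims[i], dims[i + 1])
    b[[i]] <- numeric(dims[i + 1])
  }
  list(W = W, b = b)
}

#' Initialize an untrained model
#'
#' Layer shapes chain `nc -> tower_hidden -> N` (circRNA tower),
#' `nd -> tower_hidden -> N` (disease tower) and
#' `3N -> head_hidden -> 1` (head).
#'
#' @param nc,nd input dimensions (number of circRNAs / diseases, i.e. the
#'   lengths of the fused-similarity rows).
#' @param config a [model_config()].
#' @param init `"glorot"` (seeded from `config$seed`) or `"zero"`.
#' @return an object of class `mspcd_model`.
#' @export
init_model <- function(nc, nd, config = model_config(), init = c("glorot", "zero")) {
  init <- match.arg(init)
  set.seed(config$seed)
  N <- config$highorder_dim
  model <- structure(list(
    tower_c = .init_stack(c(nc, config$tower_hidden, N), init),
    tower_d = .init_stack(c(nd, config$tower_hidden, N), init),
    head = .init_stack(c(3L * N, config$head_hidden, 1L), init),
    config = config,
    input_dims = c(nc = nc, nd = nd),
    loss_trace = numeric(0)
  ), class = "mspcd_model")
  model
}

.addbias <- function(Z, b) sweep(Z, 2, b, "+")
.relu <- function(Z) {
  Z[Z < 0] <- 0
  Z
}
.sigmoid <- function(z) 1 / (1 + exp(-z))

.as_batch <- function(x, width) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != width) stop(sprintf("input width %d does not match expected %d",
                                     ncol(x), width))
  x
}

# Forward through a ReLU stack; returns activations and pre-activations for
# backprop. The final layer is also ReLU (towers) unless linear = TRUE (head
# output layer, which is followed by the sigmoid).
.stack_forward <- function(X, stack, linear_last = FALSE) {
  L <- length(stack$W)
  H <- vector("list", L + 1)
  Z <- vector("list", L)
  H[[1]] <- X
  for (i in seq_len(L)) {
    Z[[i]] <- .addbias(H[[i]] %*% stack$W[[i]], stack$b[[i]])
    H[[i + 1]] <- if (i == L && linear_last) Z[[i]] else .relu(Z[[i]])
  }
  list(H = H, Z = Z)
}

#' Tower forward pass
#'
#' Applies the three ReLU layers of a feature tower to one or more input rows.
#'
#' @param x input vector, or matrix with one input per row.
#' @param tower a tower parameter stack (`$tower_c` or `$tower_d` of an
#'   `mspcd_model`).
#' @return matrix of high-order features (rows match inputs).
#' @export
tower_forward <- function(x, tower) {
  x <- .as_batch(x, nrow(tower$W[[1]]))
  .stack_forward(x, tower)$H[[length(tower$W) + 1]]
}

#' Element-wise interaction and concatenation
#'
#' Multiplies the two high-order features position-wise and concatenates
#' `[CH; CH*DH; DH]` into the pair representation.
#'
#' @param CH,DH equal-length vectors or matrices (rows = pairs).
#' @return matrix with `3 * N` columns.
#' @export
interact_and_concat <- function(CH, DH) {
  if (is.null(dim(CH))) CH <- matrix(CH, nrow = 1)
  if (is.null(dim(DH))) DH <- matrix(DH, nrow = 1)
  if (!all(dim(CH) == dim(DH))) stop("CH and DH must have identical shape")
  cbind(CH, CH * DH, DH)
}

#' Classifier head forward pass
#'
#' Two ReLU layers followed by a sigmoid output unit.
#'
#' @param vg pair vector of length `3 * N`, or matrix of pair rows.
#' @param head a head parameter stack (`$head` of an `mspcd_model`).
#' @return numeric vector of scores in (0, 1).
#' @export
head_forward <- function(vg, head) {
  vg <- .as_batch(vg, nrow(head$W[[1]]))
  out <- .stack_forward(vg, head, linear_last = TRUE)
  as.numeric(.sigmoid(out$H[[length(head$W) + 1]]))
}

# Full forward pass retaining intermediates for backprop.
.forward_full <- function(model, Xc, Xd) {
  fc <- .stack_forward(Xc, model$tower_c)
  fd <- .stack_forward(Xd, model$tower_d)
  CH <- fc$H[[4]]
  DH <- fd$H[[4]]
  VG <- cbind(CH, CH * DH, DH)
  fh <- .stack_forward(VG, model$head, linear_last = TRUE)
  p <- .sigmoid(fh$H[[4]])
  list(fc = fc, fd = fd, CH = CH, DH = DH, VG = VG, fh = fh, p = p)
}

# Gradient of (batch-mean BCE + l2 * sum of squared weights) w.r.t. every
# parameter; returns a flat named list aligned with .param_list().
.backward <- function(model, fw, y) {
  l2 <- model$config$l2
  B <- length(y)
  N <- model$config$highorder_dim
  g <- list()

  dz <- (fw$p - matrix(y, ncol = 1)) / B        # d loss / d z6
  head <- model$head
  dH <- dz
  for (i in 3:1) {
    Zi <- fw$fh$Z[[i]]
    dZ <- if (i == 3) dH else dH * (Zi > 0)
    g[[paste0("head_W", i)]] <- crossprod(fw$fh$H[[i]], dZ) + 2 * l2 * head$W[[i]]
    g[[paste0("head_b", i)]] <- colSums(dZ)
    dH <- dZ %*% t(head$W[[i]])
  }
  dVG <- dH
  dCH <- dVG[, 1:N, drop = FALSE] + dVG[, N + 1:N, drop = FALSE] * fw$DH
  dDH <- dVG[, 2 * N + 1:N, drop = FALSE] + dVG[, N + 1:N, drop = FALSE] * fw$CH

  for (side in c("c", "d")) {
    tower <- model[[paste0("tower_", side)]]
    ft <- if (side == "c") fw$fc else fw$fd
    dH <- if (side == "c") dCH else dDH
    for (i in 3:1) {
      dZ <- dH * (ft$Z[[i]] > 0)
      g[[paste0(side, "_W", i)]] <- crossprod(ft$H[[i]], dZ) + 2 * l2 * tower$W[[i]]
      g[[paste0(side, "_b", i)]] <- colSums(dZ)
      dH <- dZ %*% t(tower$W[[i]])
    }
  }
  g
}

.param_list <- function(model) {
  g <- list()
  for (i in 1:3) {
    g[[paste0("head_W", i)]] <- model$head$W[[i]]
    g[[paste0("head_b", i)]] <- model$head$b[[i]]
    g[[paste0("c_W", i)]] <- model$tower_c$W[[i]]
    g[[paste0("c_b", i)]] <- model$tower_c$b[[i]]
    g[[paste0("d_W", i)]] <- model$tower_d$W[[i]]
    g[[paste0("d_b", i)]] <- model$tower_d$b[[i]]
  }
  g
}

.set_params <- function(model, params) {
  for (i in 1:3) {
    model$head$W[[i]] <- params[[paste0("head_W", i)]]
    model$head$b[[i]] <- params[[paste0("head_b", i)]]
    model$tower_c$W[[i]] <- params[[paste0("c_W", i)]]
    model$tower_c$b[[i]] <- params[[paste0("c_b", i)]]
    model$tower_d$W[[i]] <- params[[paste0("d_W", i)]]
    model$tower_d$b[[i]] <- params[[paste0("d_b", i)]]
  }
  model
}

.bce <- function(p, y) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.l2_penalty <- function(model) {
  s <- 0
  for (i in 1:3) {
    s <- s + sum(model$head$W[[i]]^2) + sum(model$tower_c$W[[i]]^2) +
      sum(model$tower_d$W[[i]]^2)
  }
  model$config$l2 * s
}

#' Train the pair-scoring network
#'
#' Minimizes binary cross-entropy with an L2 weight penalty by mini-batch
#' Adam for `config$epochs` epochs. Feature vectors are the raw rows of the
#' fused circRNA and disease similarity matrices. Deterministic given
#' `config$seed`.
#'
#' @param cv fused circRNA `sim_matrix` (CV).
#' @param dv fused disease `sim_matrix` (DV).
#' @param samples a `pair_dataset` (see [sample_negatives()]).
#' @param config a [model_config()].
#' @return a trained `mspcd_model` carrying `loss_trace`, the per-epoch mean
#'   training objective.
#' @export
train_model <- function(cv, dv, samples, config = model_config()) {
  stopifnot(inherits(cv, "sim_matrix"), inherits(dv, "sim_matrix"),
            inherits(samples, "pair_dataset"))
  n <- length(samples$labels)
  if (n == 0) stop("cannot train on an empty dataset")
  if (length(unique(samples$labels)) < 2) {
    stop("training requires both positive and negative examples")
  }
  if (max(samples$pairs[, 1]) > nrow(cv$values) ||
      max(samples$pairs[, 2]) > nrow(dv$values)) {
    stop("sample indices exceed similarity matrix dimensions")
  }
  model <- init_model(nrow(cv$values), nrow(dv$values), config, init = "glorot")

  params <- .param_list(model)
  m1 <- lapply(params, function(p) p * 0)
  m2 <- m1
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L
  y <- samples$labels
  trace <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1, n)]
      Xc <- cv$values[samples$pairs[idx, 1], , drop = FALSE]
      Xd <- dv$values[samples$pairs[idx, 2], , drop = FALSE]
      fw <- .forward_full(model, Xc, Xd)
      grads <- .backward(model, fw, y[idx])
      step <- step + 1L
      for (k in names(params)) {
        m1[[k]] <- beta1 * m1[[k]] + (1 - beta1) * grads[[k]]
        m2[[k]] <- beta2 * m2[[k]] + (1 - beta2) * grads[[k]]^2
        mhat <- m1[[k]] / (1 - beta1^step)
        vhat <- m2[[k]] / (1 - beta2^step)
        params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
      }
      model <- .set_params(model, params)
      ep_loss <- ep_loss + (.bce(as.numeric(fw$p), y[idx]) + .l2_penalty(model)) *
        length(idx)
    }
    trace[ep] <- ep_loss / n
  }
  model$loss_trace <- trace
  model
}

#' Score circRNA-disease pairs
#'
#' Pure forward pass; scores depend only on the model parameters and the
#' similarity rows, so duplicated pairs get identical scores and batching
#' does not change results.
#'
#' @param model a trained `mspcd_model`.
#' @param cv,dv fused `sim_matrix` inputs used at training time.
#' @param pairs two-column matrix of (circRNA index, disease index), 1-based.
#' @param batch_size internal evaluation chunk size.
#' @return numeric vector of scores in (0, 1), one per pair, order preserved.
#' @export
predict_pairs <- function(model, cv, dv, pairs, batch_size = 4096L) {
  stopifnot(inherits(model, "mspcd_model"))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0) return(numeric(0))
  if (min(pairs) < 1 || max(pairs[, 1]) > nrow(cv$values) ||
      max(pairs[, 2]) > nrow(dv$values)) {
    stop("pair index out of range")
  }
  out <- numeric(nrow(pairs))
  starts <- seq(1, nrow(pairs), by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1, nrow(pairs))
    CH <- tower_forward(cv$values[pairs[idx, 1], , drop = FALSE], model$tower_c)
    DH <- tower_forward(dv$values[pairs[idx, 2], , drop = FALSE], model$tower_d)
    out[idx] <- head_forward(interact_and_concat(CH, DH), model$head)
  }
  out
}

#' @export
print.mspcd_model <- function(x, ...) {
  cat(sprintf("mspcd_model: inputs (%d, %d), N = %d, %s\n",
              x$input_dims[["nc"]], x$input_dims[["nd"]],
              x$config$highorder_dim,
              if (length(x$loss_trace) > 0) {
                sprintf("trained %d epochs (final loss %.4f)",
                        length(x$loss_trace), x$loss_trace[length(x$loss_trace)])
              } else "untrained"))
  invisible(x)
}

MODEL_FORMAT_VERSION <- 1L

#' Save a model checkpoint
#'
#' Writes all weight arrays, the full configuration and a format-version tag
#' into a single archive; a load/save round trip is bit-stable.
#'
#' @param model an `mspcd_model`.
#' @param path output file.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mspcd_model"))
  saveRDS(list(format_version = MODEL_FORMAT_VERSION, model = model), path,
          version = 2)
  invisible(NULL)
}

#' Load a model checkpoint
#'
#' @param path file written by [write_model()].
#' @return an `mspcd_model`.
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    stop(sprintf("unsupported model format version: %s", obj$format_version))
  }
  obj$model
}
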