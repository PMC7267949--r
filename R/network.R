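#' Shape arithmetic for the valid-convolution network
#'
#' Every 3x3x3 convolution is applied without padding and with unit stride,
#' shrinking the feature maps by two voxels per dimension, so a network with
#' `depth` such layers maps an input cube of side `s` to an output cube of
#' side `s - 2 * depth` (e.g., 25^3 -> 9^3 for the 8-layer baseline, and a
#' 16-layer variant needs a 41^3 input to produce the same 9^3 output).
#'
#' @param input_side,output_side patch sides in voxels.
#' @param depth number of 3x3x3 convolutional layers.
#' @return an integer side length.
#' @export
output_side <- function(input_side, depth) {
  out <- as.integer(input_side - 2L * depth)
  if (any(out <= 0L))
    stop("input side too small for this depth", call. = FALSE)
  out
}

#' @rdname output_side
#' @export
required_input_side <- function(output_side, depth) {
  if (any(output_side <= 0L)) stop("output side must be positive", call. = FALSE)
  as.integer(output_side + 2L * depth)
}

#' Declarative network specification
#'
#' The architecture is a stack of `depth` 3x3x3 valid convolutions (ELU,
#' `width` filters each), a dense connection that concatenates the centrally
#' cropped feature maps of *all* preceding convolutional layers
#' (`depth * width` channels), batch normalization, two 1x1x1 convolutions
#' of 128 and 64 filters (ELU, dropout p = 0.1 after each), and a final
#' 1x1x1 classifier with a voxelwise softmax over `classes` channels.
#'
#' @param depth number of 3x3x3 layers (8 baseline; 10-16 for deep variants).
#' @param width filters per 3x3x3 layer (default 32).
#' @param channels number of input channels N (e.g., 4 = appearance + three
#'   coordinate channels).
#' @param classes number of classes C including background (>= 2).
#' @param input_side training patch side; defaults to
#'   `required_input_side(9, depth)`.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(depth = 8L, width = 32L, channels = 4L, classes = 3L,
                         input_side = NULL) {
  if (depth < 1L || width < 1L || channels < 1L || classes < 2L)
    stop("invalid network hyperparameters", call. = FALSE)
  if (is.null(input_side)) input_side <- required_input_side(9L, depth)
  out <- output_side(input_side, depth)  # errors if input_side <= 2*depth
  dense_channels <- as.integer(depth * width)
  layers <- c(
    lapply(seq_len(depth), function(l) list(
      kind = "conv3", filters = as.integer(width),
      in_channels = if (l == 1L) as.integer(channels) else as.integer(width),
      nonlinearity = "ELU", dropout = 0)),
    list(list(kind = "dense_connection", filters = dense_channels,
              nonlinearity = "none", dropout = 0),
         list(kind = "batch_norm", filters = dense_channels,
              nonlinearity = "none", dropout = 0),
         list(kind = "conv1", filters = 128L, in_channels = dense_channels,
              nonlinearity = "ELU", dropout = 0.1),
         list(kind = "conv1", filters = 64L, in_channels = 128L,
              nonlinearity = "ELU", dropout = 0.1),
         list(kind = "classifier", filters = as.integer(classes),
              in_channels = 64L, nonlinearity = "spatial softmax", dropout = 0))
  )
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 channels = as.integer(channels), classes = as.integer(classes),
                 input_side = as.integer(input_side), output_side = out,
                 dense_channels = dense_channels, layers = layers),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "3D FCN: %d x conv3(%d) -> dense(%d) -> BN -> conv1(128) -> conv1(64) -> softmax(%d)\n",
    x$depth, x$width, x$dense_channels, x$classes))
  cat(sprintf("input %d^3 x %d channels -> output %d^3 x %d classes; %s parameters\n",
              x$input_side, x$channels, x$output_side, x$classes,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count learnable parameters
#'
#' Layer-by-layer sum of filter entries and biases, plus one scale/shift
#' pair per batch-normalized channel.
#'
#' @param spec a [network_spec()].
#' @return exact integer parameter count.
#' @export
count_parameters <- function(spec) {
  n <- 0
  for (ly in spec$layers) {
    n <- n + switch(ly$kind,
      conv3 = 27 * ly$in_channels * ly$filters + ly$filters,
      dense_connection = 0,
      batch_norm = 2 * ly$filters,
      conv1 = ,
      classifier = ly$in_channels * ly$filters + ly$filters)
  }
  as.integer(n)
}

#' Initialize network weights
#'
#' Glorot uniform initialization for all convolutional filters (limit
#' `sqrt(6 / (fan_in + fan_out))`), zero biases, unit batch-norm scales.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed.
#' @return weight list with components `conv` (per 3x3x3 layer), `bn`,
#'   `fc1`, `fc2`, `clf`.
#' @export
init_weights <- function(spec, seed = 1L) {
  with_seed(seed, {
    glorot <- function(fan_in, fan_out, dims) {
      lim <- sqrt(6 / (fan_in + fan_out))
      array(runif(prod(dims), -lim, lim), dim = dims)
    }
    conv <- lapply(seq_len(spec$depth), function(l) {
      ci <- if (l == 1L) spec$channels else spec$width
      list(W = glorot(27 * ci, 27 * spec$width, c(3, 3, 3, ci, spec$width)),
           b = numeric(spec$width))
    })
    dw <- spec$dense_channels
    list(
      conv = conv,
      bn = list(gamma = rep(1, dw), beta = numeric(dw),
                run_mean = numeric(dw), run_var = rep(1, dw)),
      fc1 = list(W = glorot(dw, 128, c(dw, 128)), b = numeric(128)),
      fc2 = list(W = glorot(128, 64, c(128, 64)), b = numeric(64)),
      clf = list(W = glorot(64, spec$classes, c(64, spec$classes)),
                 b = numeric(spec$classes))
    )
  })
}

# Central crop of a conv activation [s,s,s,w,B] to spatial side `side`,
# returned as a (voxel*batch) x channels matrix.
crop_to_matrix <- function(a, side) {
  d <- dim(a)
  m <- (d[1] - side) %/% 2L
  idx <- (m + 1L):(m + side)
  ac <- a[idx, idx, idx, , , drop = FALSE]
  ac <- aperm(ac, c(1, 2, 3, 5, 4))
  dim(ac) <- c(side^3 * d[5], d[4])
  ac
}

# Inverse of crop_to_matrix: scatter a gradient matrix back into a zero
# activation array of spatial side `full_side`.
matrix_to_uncrop <- function(m, side, full_side, nchan, batch) {
  g <- array(0, dim = c(full_side, full_side, full_side, nchan, batch))
  mm <- m
  dim(mm) <- c(side, side, side, batch, nchan)
  mm <- aperm(mm, c(1, 2, 3, 5, 4))
  off <- (full_side - side) %/% 2L
  idx <- (off + 1L):(off + side)
  g[idx, idx, idx, , ] <- mm
  g
}

#' Forward pass
#'
#' Runs a batch of multichannel patches through the network. In training
#' mode, batch statistics are used for batch normalization (and the running
#' statistics updated with momentum 0.9) and dropout (p = 0.1) is active
#' after the two 1x1x1 feature layers; in inference mode running statistics
#' are used and dropout is disabled, so the pass is deterministic.
#'
#' @param spec a [network_spec()].
#' @param weights from [init_weights()] or training.
#' @param x input batch, array (side, side, side, channels, batch).
#' @param training logical.
#' @param keep_cache keep intermediates for a backward pass (internal).
#' @return probabilities array (out_side, out_side, out_side, classes,
#'   batch); with `keep_cache = TRUE`, a list with `probs` and `cache`.
#' @export
net_forward <- function(spec, weights, x, training = FALSE, keep_cache = FALSE) {
  d <- dim(x)
  if (length(d) == 4L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[1] != spec$input_side || d[4] != spec$channels)
    stop(sprintf("input shape mismatch at layer 1: got %d^3 x %d, expected %d^3 x %d",
                 d[1], d[4], spec$input_side, spec$channels), call. = FALSE)
  B <- d[5]
  so <- spec$output_side
  ov <- so^3
  acts <- vector("list", spec$depth)
  a <- x
  for (l in seq_len(spec$depth)) {
    z <- cpp_conv3_fwd(a, weights$conv[[l]]$W, weights$conv[[l]]$b)
    a <- elu(z)
    dim(a) <- dim(z)
    acts[[l]] <- a
  }
  Fm <- do.call(cbind, lapply(acts, crop_to_matrix, side = so))
  bn <- weights$bn
  eps <- 1e-5
  if (training) {
    mu <- colMeans(Fm)
    xc <- sweep(Fm, 2, mu)
    va <- colMeans(xc^2)
    xhat <- sweep(xc, 2, sqrt(va + eps), "/")
    bn_used <- list(mean = mu, var = va)
  } else {
    xhat <- sweep(sweep(Fm, 2, bn$run_mean), 2, sqrt(bn$run_var + eps), "/")
    bn_used <- list(mean = bn$run_mean, var = bn$run_var)
  }
  Fbn <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  p_drop <- 0.1
  F1 <- sweep(Fbn %*% weights$fc1$W, 2, weights$fc1$b, "+")
  h1 <- elu(F1)
  if (training) {
    m1 <- matrix(runif(length(h1)) >= p_drop, nrow = nrow(h1)) / (1 - p_drop)
    h1d <- h1 * m1
  } else { m1 <- NULL; h1d <- h1 }
  F2 <- sweep(h1d %*% weights$fc2$W, 2, weights$fc2$b, "+")
  h2 <- elu(F2)
  if (training) {
    m2 <- matrix(runif(length(h2)) >= p_drop, nrow = nrow(h2)) / (1 - p_drop)
    h2d <- h2 * m2
  } else { m2 <- NULL; h2d <- h2 }
  logits <- sweep(h2d %*% weights$clf$W, 2, weights$clf$b, "+")
  mx <- apply(logits, 1, max)
  el <- exp(logits - mx)
  probs_m <- el / rowSums(el)
  probs <- probs_m
  dim(probs) <- c(so, so, so, B, spec$classes)
  probs <- aperm(probs, c(1, 2, 3, 5, 4))
  if (!keep_cache) return(probs)
  list(probs = probs, cache = list(
    x = x, acts = acts, Fm = Fm, xhat = xhat, bn_used = bn_used,
    F1 = F1, h1 = h1, m1 = m1, h1d = h1d, F2 = F2, h2 = h2, m2 = m2,
    h2d = h2d, probs_m = probs_m, B = B, so = so, ov = ov))
}

#' Training loss
#'
#' Categorical cross-entropy averaged over batch and output voxels, plus an
#' l2 penalty `alpha * sum(W^2)` over all convolutional filter entries
#' (biases and batch-norm parameters are excluded). Probabilities are
#' clipped to `[eps, 1 - eps]` before the log.
#'
#' @param probs probabilities (out^3, C, B) from [net_forward()].
#' @param targets soft targets of the same shape; per-voxel class sums must
#'   be 1.
#' @param weights network weights (for the penalty); may be NULL with
#'   `alpha = 0`.
#' @param alpha weight-decay coefficient (default 1e-4).
#' @param eps probability clip (default 1e-7).
#' @return scalar loss; the cross-entropy term alone is returned as
#'   attribute `"J"`.
#' @export
net_loss <- function(probs, targets, weights = NULL, alpha = 1e-4, eps = 1e-7) {
  if (!identical(dim(probs), dim(targets)))
    stop("probs and targets shapes differ", call. = FALSE)
  if (length(dim(probs)) == 4L) {
    dim(probs) <- c(dim(probs), 1L)
    dim(targets) <- dim(probs)
  }
  d <- dim(probs)
  nd <- length(d)
  csum <- apply(targets, setdiff(seq_len(nd), nd - 1L), sum)
  if (any(abs(csum - 1) > 1e-4))
    stop("target class sums differ from 1", call. = FALSE)
  B <- d[nd]
  V <- prod(d[1:3])
  p <- pmin(pmax(probs, eps), 1 - eps)
  J <- -sum(targets * log(p)) / (B * V)
  pen <- 0
  if (!is.null(weights) && alpha > 0) {
    for (l in seq_along(weights$conv)) pen <- pen + sum(weights$conv[[l]]$W^2)
    pen <- pen + sum(weights$fc1$W^2) + sum(weights$fc2$W^2) + sum(weights$clf$W^2)
  }
  out <- J + alpha * pen
  attr(out, "J") <- J
  out
}

# Backward pass: gradients of cross-entropy + weight decay wrt all
# parameters. `fw` is the output of net_forward(..., keep_cache = TRUE);
# targets is (so,so,so,C,B).
net_backward <- function(spec, weights, fw, targets, alpha = 1e-4) {
  cache <- fw$cache
  B <- cache$B; so <- cache$so; ov <- cache$ov
  tm <- aperm(targets, c(1, 2, 3, 5, 4))
  dim(tm) <- c(ov * B, spec$classes)
  dlogits <- (cache$probs_m - tm) / (B * ov)
  g <- list(conv = vector("list", spec$depth), bn = list(), fc1 = list(),
            fc2 = list(), clf = list())
  g$clf$W <- crossprod(cache$h2d, dlogits) + 2 * alpha * weights$clf$W
  g$clf$b <- colSums(dlogits)
  dh2d <- dlogits %*% t(weights$clf$W)
  dh2 <- if (is.null(cache$m2)) dh2d else dh2d * cache$m2
  dF2 <- dh2 * elu_grad_from_act(cache$h2)
  g$fc2$W <- crossprod(cache$h1d, dF2) + 2 * alpha * weights$fc2$W
  g$fc2$b <- colSums(dF2)
  dh1d <- dF2 %*% t(weights$fc2$W)
  dh1 <- if (is.null(cache$m1)) dh1d else dh1d * cache$m1
  dF1 <- dh1 * elu_grad_from_act(cache$h1)
  Fbn <- sweep(sweep(cache$xhat, 2, weights$bn$gamma, "*"), 2,
               weights$bn$beta, "+")
  g$fc1$W <- crossprod(Fbn, dF1) + 2 * alpha * weights$fc1$W
  g$fc1$b <- colSums(dF1)
  dFbn <- dF1 %*% t(weights$fc1$W)
  # batch-norm backward (batch statistics)
  M <- nrow(dFbn)
  g$bn$gamma <- colSums(dFbn * cache$xhat)
  g$bn$beta <- colSums(dFbn)
  dxhat <- sweep(dFbn, 2, weights$bn$gamma, "*")
  inv_sd <- 1 / sqrt(cache$bn_used$var + 1e-5)
  dF <- sweep(dxhat, 2, inv_sd, "*") -
    sweep(matrix(1, M, 1) %*% (colSums(dxhat) / M), 2, inv_sd, "*") -
    sweep(cache$xhat * (matrix(1, M, 1) %*%
      (colSums(dxhat * cache$xhat) / M)), 2, inv_sd, "*")
  # split the dense-connection gradient back to each conv layer
  w <- spec$width
  dA_crop <- lapply(seq_len(spec$depth), function(l)
    dF[, ((l - 1L) * w + 1L):(l * w), drop = FALSE])
  dA_next <- NULL
  for (l in rev(seq_len(spec$depth))) {
    side_l <- spec$input_side - 2L * l
    dA <- matrix_to_uncrop(dA_crop[[l]], so, side_l, w, B)
    if (!is.null(dA_next)) dA <- dA + dA_next
    a_l <- fw$cache$acts[[l]]
    dZ <- dA * elu_grad_from_act(a_l)
    dim(dZ) <- dim(a_l)
    a_prev <- if (l == 1L) cache$x else cache$acts[[l - 1L]]
    bw <- cpp_conv3_bwd(a_prev, weights$conv[[l]]$W, dZ)
    g$conv[[l]] <- list(W = bw$gw + 2 * alpha * weights$conv[[l]]$W, b = bw$gb)
    dA_next <- if (l > 1L) bw$gx else NULL
  }
  g
}

# Update batch-norm running statistics after a training-mode forward pass.
update_bn_running <- function(weights, fw, momentum = 0.9) {
  bu <- fw$cache$bn_used
  weights$bn$run_mean <- momentum * weights$bn$run_mean + (1 - momentum) * bu$mean
  weights$bn$run_var <- momentum * weights$bn$run_var + (1 - momentum) * bu$var
  weights
}

# One RMSProp + Nesterov-momentum update, in place on the weight list.
# state holds per-parameter accumulators r (squared-gradient EMA) and v
# (velocity); created on first call.
optimizer_step <- function(weights, grads, state, lr = 2.5e-4, momentum = 0.9,
                           rho = 0.9, eps = 1e-6) {
  walk <- function(w, g, r, v) {
    if (is.numeric(w)) {
      if (is.null(r)) { r <- w * 0; v <- w * 0 }
      r <- rho * r + (1 - rho) * g^2
      gs <- g / (sqrt(r) + eps)
      v <- momentum * v - lr * gs
      w <- w + momentum * v - lr * gs
      return(list(w = w, r = r, v = v))
    }
    for (nm in names(w)) {
      if (nm %in% c("run_mean", "run_var")) next
      res <- walk(w[[nm]], g[[nm]], r[[nm]], v[[nm]])
      w[[nm]] <- res$w
      if (is.null(r)) r <- list()
      if (is.null(v)) v <- list()
      r[[nm]] <- res$r
      v[[nm]] <- res$v
    }
    list(w = w, r = r, v = v)
  }
  # conv is an unnamed list; give names for the walker
  names(weights$conv) <- paste0("l", seq_along(weights$conv))
  names(grads$conv) <- names(weights$conv)
  if (!is.null(state$r)) {
    names(state$r$conv) <- names(weights$conv)
    names(state$v$conv) <- names(weights$conv)
  }
  res <- walk(weights, grads, state$r, state$v)
  list(weights = res$w, state = list(r = res$r, v = res$v))
}
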