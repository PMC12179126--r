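# Forward / backward machinery for the vd_cnn. Batches are lists of (D,H,W)
# arrays; convolution and pooling run per sample in C++, batch norm and the
# fully connected stack operate on the whole batch at once.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Full forward pass. training = TRUE uses batch statistics for batch norm,
# applies inverted dropout (masks drawn from the current RNG stream), and
# returns every cache needed by nn_backward. training = FALSE uses running
# statistics and no dropout.
#
# The conv bias is folded into the batch-norm mean bookkeeping: batch norm
# subtracts the batch mean, so a constant shift of the conv output leaves the
# normalized activations unchanged (and the bias gradient is exactly zero).
# Running means are stored on the biased scale (mu_conv + b) so inference is
# consistent.
nn_forward <- function(model, xs, training = FALSE) {
  n <- length(xs)
  caches <- list(conv = vector("list", length(model$conv)))
  cur <- xs
  for (i in seq_along(model$conv)) {
    ly <- model$conv[[i]]
    z <- lapply(cur, function(x) .conv3d_fwd(x, ly$K, ly$pad))
    if (training) {
      st <- .bn_stats(z)
      mu <- st[1]
      va <- st[2]
      model$conv[[i]]$run_mean <- (1 - BN_MOMENTUM) * ly$run_mean +
        BN_MOMENTUM * (mu + ly$b)
      model$conv[[i]]$run_var <- (1 - BN_MOMENTUM) * ly$run_var + BN_MOMENTUM * va
    } else {
      mu <- ly$run_mean - ly$b
      va <- ly$run_var
    }
    std <- sqrt(va + BN_EPS)
    fz <- .bn_relu_pool_fwd(z, mu, std, ly$gamma, ly$beta, training)
    if (training)
      caches$conv[[i]] <- list(x_in = cur, xhat = fz$xhat, std = std,
                               argmax = fz$argmax, in_dim = dim(z[[1]]))
    cur <- fz$pooled
  }
  flat <- matrix(unlist(lapply(cur, as.vector), use.names = FALSE),
                 nrow = n, byrow = TRUE)
  caches$flat_dim <- dim(cur[[1]])
  h <- flat
  nf <- length(model$fc)
  caches$fc <- vector("list", nf)
  for (j in seq_len(nf)) {
    ly <- model$fc[[j]]
    z <- h %*% ly$W + matrix(ly$b, n, length(ly$b), byrow = TRUE)
    if (j < nf) {
      a <- z; a[a < 0] <- 0
      if (training && model$spec$dropout_p > 0) {
        keep <- 1 - model$spec$dropout_p
        m <- matrix(stats::runif(length(a)) < keep, nrow(a), ncol(a)) / keep
        caches$fc[[j]] <- list(h_in = h, z = z, drop = m)
        a <- a * m
      } else if (training) {
        caches$fc[[j]] <- list(h_in = h, z = z, drop = NULL)
      }
      h <- a
    } else {
      if (training) caches$fc[[j]] <- list(h_in = h, z = z)
      h <- z  # raw logits, no activation on the output layer
    }
  }
  list(logits = h, caches = caches, model = model)
}

# Backward pass from dlogits; returns grads mirroring the parameter layout.
nn_backward <- function(model, caches, dlogits) {
  n <- nrow(dlogits)
  nf <- length(model$fc)
  g_fc <- vector("list", nf)
  dh <- dlogits
  for (j in rev(seq_len(nf))) {
    cc <- caches$fc[[j]]
    if (j < nf) {
      if (!is.null(cc$drop)) dh <- dh * cc$drop
      dh[cc$z <= 0] <- 0
    }
    g_fc[[j]] <- list(W = t(cc$h_in) %*% dh, b = colSums(dh))
    dh <- dh %*% t(model$fc[[j]]$W)
  }
  # unflatten into per-sample cubes
  fd <- caches$flat_dim
  dcur <- lapply(seq_len(n), function(s) array(dh[s, ], dim = fd))
  g_conv <- vector("list", length(model$conv))
  for (i in rev(seq_along(model$conv))) {
    ly <- model$conv[[i]]
    cc <- caches$conv[[i]]
    bw <- .bn_relu_pool_bwd(dcur, cc$argmax, cc$xhat, ly$gamma, ly$beta, cc$std)
    dz <- bw$dz
    dK <- array(0, dim = dim(ly$K))
    for (s in seq_len(n))
      dK <- dK + .conv3d_bwd_kernel(cc$x_in[[s]], dz[[s]], dim(ly$K), ly$pad)
    if (i > 1L) {
      xdim <- as.integer(dim(cc$x_in[[1]]))
      dcur <- lapply(seq_len(n), function(s)
        .conv3d_bwd_input(dz[[s]], ly$K, xdim, ly$pad))
    }
    # conv bias gradient is identically zero under batch norm (shift
    # invariance of the normalization); the parameter is kept for
    # architectural fidelity
    g_conv[[i]] <- list(K = dK, b = 0, gamma = bw$dgamma, beta = bw$dbeta)
  }
  list(conv = g_conv, fc = g_fc)
}

# Mean softmax cross-entropy over a batch of logits (rows) with 0-based
# integer labels; returns loss and dlogits.
softmax_ce <- function(logits, labels) {
  if (any(!is.finite(logits))) stop("non-finite logits")
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(probs[idx]))
  dl <- probs
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n, probs = probs)
}

# Adam state and update (bias-corrected first/second moment estimates).
adam_init <- function(model) {
  zeros <- function(x) if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
  list(t = 0L,
       conv = lapply(model$conv, function(l)
         list(K = list(m = zeros(l$K), v = zeros(l$K)),
              b = list(m = 0, v = 0),
              gamma = list(m = 0, v = 0),
              beta = list(m = 0, v = 0))),
       fc = lapply(model$fc, function(l)
         list(W = list(m = zeros(l$W), v = zeros(l$W)),
              b = list(m = zeros(l$b), v = zeros(l$b)))))
}

adam_step <- function(model, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(theta, g, st) {
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    theta <- theta - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    list(theta = theta, st = st)
  }
  for (i in seq_along(model$conv)) {
    for (p in c("K", "b", "gamma", "beta")) {
      u <- upd(model$conv[[i]][[p]], grads$conv[[i]][[p]], state$conv[[i]][[p]])
      model$conv[[i]][[p]] <- u$theta
      state$conv[[i]][[p]] <- u$st
    }
  }
  for (j in seq_along(model$fc)) {
    for (p in c("W", "b")) {
      u <- upd(model$fc[[j]][[p]], grads$fc[[j]][[p]], state$fc[[j]][[p]])
      model$fc[[j]][[p]] <- u$theta
      state$fc[[j]][[p]] <- u$st
    }
  }
  list(model = model, state = state)
}

#' Compute class logits for a batch of samples
#'
#' Runs the network in inference mode (running batch-norm statistics, no
#' dropout); deterministic given fixed weights.
#'
#' @param model a `vd_cnn`.
#' @param xs list of `(D, H, W)` arrays, or a single array.
#' @return numeric matrix, one row of logits per sample.
#' @export
predict_logits <- function(model, xs) {
  if (is.array(xs) && length(dim(xs)) == 3L) xs <- list(xs)
  nn_forward(model, xs, training = FALSE)$logits
}
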