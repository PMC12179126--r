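#' Variable-depth 3D kernel specification
#'
#' The convolutional kernels are 3 x 3 spatially; their extent along the
#' spectral axis (the depth `d`) is the searched hyperparameter, odd-valued
#' between 3 and `d_max`.
#'
#' @param depth odd integer kernel depth.
#' @param d_max largest admissible depth. Default 25.
#' @return a `vd_kernel_spec` list.
#' @export
vd_kernel_spec <- function(depth, d_max = 25L) {
  depth <- as.integer(depth)
  if (depth %% 2L == 0L || depth < 3L || depth > d_max)
    stop(sprintf("kernel depth must be odd and in [3, %d], got %d", d_max, depth))
  structure(list(width = 3L, height = 3L, depth = depth, d_max = as.integer(d_max)),
            class = "vd_kernel_spec")
}

#' Network family specification
#'
#' The classifier stacks `n_conv_modules` single-channel convolution modules
#' (variable-depth conv, batch norm, ReLU, 2x2x2 max-pool) followed by three
#' fully connected modules. The first `vd_layer_count` conv layers carry the
#' searched depth `d`; the remaining layers use depth 3. Every conv layer uses
#' "same" padding `(floor(d_i/2), 1, 1)` so convolution preserves dimensions
#' and only pooling shrinks them.
#'
#' @param n_classes number of output classes.
#' @param input_dims integer triple `(D, H, W)` of a standardized sample.
#' @param n_conv_modules conv modules to stack. Default 4.
#' @param vd_layer_count how many leading conv layers carry the searched
#'   depth (1-4). Default 2.
#' @param fc_hidden hidden widths of the fully connected stack.
#'   Default `c(512, 256)`.
#' @param dropout_p dropout probability in the hidden FC modules. Default 0.5.
#' @return a `model_spec` list.
#' @export
model_spec <- function(n_classes, input_dims = c(462L, 100L, 100L),
                       n_conv_modules = 4L, vd_layer_count = 2L,
                       fc_hidden = c(512L, 256L), dropout_p = 0.5) {
  stopifnot(n_classes >= 2L, length(input_dims) == 3L,
            n_conv_modules >= 1L, vd_layer_count >= 1L,
            vd_layer_count <= n_conv_modules,
            dropout_p >= 0, dropout_p < 1)
  structure(list(n_classes = as.integer(n_classes),
                 input_dims = as.integer(input_dims),
                 n_conv_modules = as.integer(n_conv_modules),
                 vd_layer_count = as.integer(vd_layer_count),
                 fc_hidden = as.integer(fc_hidden),
                 dropout_p = dropout_p),
            class = "model_spec")
}

# Per-layer kernel depths implied by a spec and a searched depth d.
layer_depths <- function(spec, kernel_depth) {
  ifelse(seq_len(spec$n_conv_modules) <= spec$vd_layer_count,
         as.integer(kernel_depth), 3L)
}

#' Plan per-stage tensor shapes
#'
#' Walks the convolutional front end symbolically: each conv stage preserves
#' dimensions (same padding), each pool maps every axis `n -> floor(n/2)`.
#' The flatten length is the product of the final stage's dimensions (one
#' channel throughout). The trace is identical for every kernel depth because
#' depth padding tracks the kernel.
#'
#' @param input_dims integer triple `(D, H, W)`.
#' @param spec a [model_spec].
#' @param kernel_depth searched depth (affects padding bookkeeping only).
#' @return a `shape_trace` list with `stages` (matrix of dims after each
#'   stage), `flatten_len`, and `paddings`.
#' @export
plan_shapes <- function(input_dims, spec, kernel_depth = 3L) {
  dims <- as.integer(input_dims)
  depths <- layer_depths(spec, kernel_depth)
  stages <- list(input = dims)
  paddings <- list()
  for (i in seq_len(spec$n_conv_modules)) {
    pad <- c(depths[i] %/% 2L, 1L, 1L)
    paddings[[i]] <- pad
    stages[[sprintf("conv%d", i)]] <- dims     # same padding preserves dims
    dims <- dims %/% 2L
    if (any(dims < 1L))
      stop(sprintf("axis collapsed to zero at pool stage %d (dims before pool: %s)",
                   i, paste(stages[[sprintf("conv%d", i)]], collapse = "x")))
    stages[[sprintf("pool%d", i)]] <- dims
  }
  structure(list(stages = do.call(rbind, stages),
                 flatten_len = as.integer(prod(dims)),
                 paddings = paddings,
                 kernel_depths = depths),
            class = "shape_trace")
}

#' @export
print.shape_trace <- function(x, ...) {
  cat("<shape_trace>\n")
  s <- x$stages
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-7s %s\n", rownames(s)[i], paste(s[i, ], collapse = " x ")))
  cat(sprintf("  flatten %d\n", x$flatten_len))
  invisible(x)
}

#' Build a variable-depth 3D CNN
#'
#' Instantiates the network for one kernel depth with seeded uniform
#' fan-in-scaled weight initialization (bound `1/sqrt(fan_in)` for conv and
#' linear weights and biases), batch-norm affine parameters at identity, and
#' running statistics at (0, 1). Two builds with the same seed are
#' bit-identical.
#'
#' @param spec a [model_spec].
#' @param kernel_depth odd searched depth in `[3, 25]`.
#' @param rng_seed integer seed for the initialization.
#' @return an object of class `vd_cnn`.
#' @export
build_model <- function(spec, kernel_depth, rng_seed = 1L) {
  kspec <- vd_kernel_spec(kernel_depth)       # validates depth
  trace <- plan_shapes(spec$input_dims, spec, kernel_depth)
  depths <- trace$kernel_depths
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(rng_seed)
  conv <- lapply(seq_len(spec$n_conv_modules), function(i) {
    kd <- depths[i]
    fan_in <- kd * 9L
    bound <- 1 / sqrt(fan_in)
    list(K = array(stats::runif(kd * 9L, -bound, bound), dim = c(kd, 3L, 3L)),
         b = stats::runif(1L, -bound, bound),
         gamma = 1, beta = 0, run_mean = 0, run_var = 1,
         pad = trace$paddings[[i]], depth = kd)
  })
  fc_dims <- c(trace$flatten_len, spec$fc_hidden, spec$n_classes)
  fc <- lapply(seq_len(length(fc_dims) - 1L), function(i) {
    fi <- fc_dims[i]
    bound <- 1 / sqrt(fi)
    list(W = matrix(stats::runif(fi * fc_dims[i + 1L], -bound, bound),
                    nrow = fi),
         b = stats::runif(fc_dims[i + 1L], -bound, bound))
  })
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(spec = spec, kernel_depth = as.integer(kernel_depth),
                 kernel = kspec, rng_seed = as.integer(rng_seed),
                 trace = trace, conv = conv, fc = fc),
            class = "vd_cnn")
}

#' @export
print.vd_cnn <- function(x, ...) {
  cat(sprintf("<vd_cnn M%d> %d conv modules (depths %s), fc %s, %d classes, %s parameters\n",
              x$kernel_depth, length(x$conv),
              paste(vapply(x$conv, `[[`, integer(1), "depth"), collapse = "/"),
              paste(c(x$trace$flatten_len, x$spec$fc_hidden), collapse = "-"),
              x$spec$n_classes, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars: conv weights and biases, batch-norm
#' affine pairs, and fully connected weights and biases. Also accepts a bare
#' list of numeric arrays (an empty list counts 0).
#'
#' @param model a `vd_cnn`, or a list of numeric arrays.
#' @return integer scalar.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "vd_cnn")) {
    nconv <- sum(vapply(model$conv, function(l)
      length(l$K) + length(l$b) + length(l$gamma) + length(l$beta), numeric(1)))
    nfc <- sum(vapply(model$fc, function(l) length(l$W) + length(l$b), numeric(1)))
    return(as.integer(nconv + nfc))
  }
  as.integer(sum(vapply(model, length, numeric(1))))
}

#' Reference 3D convolution (triple-sum oracle)
#'
#' Direct evaluation of single-channel 3D cross-correlation
#' \deqn{y(i,j,k) = \sum_m \sum_n \sum_p X(i+m, j+n, k+p)\, K(m,n,p)}
#' over a zero-padded input, written as explicit loops in R. This is the
#' semantic reference for the optimized C++ layer used inside the network;
#' the two must agree within 1e-5 and are tested against each other. Use only
#' on small inputs.
#'
#' @param X numeric 3-axis array `(D, H, W)`.
#' @param K numeric 3-axis kernel array `(kd, kh, kw)`.
#' @param padding integer triple of zero-padding widths `(p_d, p_h, p_w)`.
#' @return the output array.
#' @export
conv3d_direct <- function(X, K, padding = c(0L, 0L, 0L)) {
  stopifnot(length(dim(X)) == 3L, length(dim(K)) == 3L)
  d <- dim(X); kd <- dim(K); p <- as.integer(padding)
  pd <- d + 2L * p
  if (any(pd - kd + 1L < 1L)) stop("kernel larger than padded input")
  Xp <- array(0, dim = pd)
  Xp[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3])] <- X
  od <- pd - kd + 1L
  Y <- array(0, dim = od)
  for (k in seq_len(od[3])) for (j in seq_len(od[2])) for (i in seq_len(od[1])) {
    acc <- 0
    for (pp in seq_len(kd[3])) for (nn in seq_len(kd[2])) for (mm in seq_len(kd[1]))
      acc <- acc + Xp[i + mm - 1L, j + nn - 1L, k + pp - 1L] * K[mm, nn, pp]
    Y[i, j, k] <- acc
  }
  Y
}

#' Optimized 3D convolution
#'
#' The production C++ layer: identical semantics to [conv3d_direct] (zero
#' padding, stride 1, cross-correlation), implemented with contiguous
#' spectral-axis inner loops.
#'
#' @inheritParams conv3d_direct
#' @return the output array.
#' @export
conv3d <- function(X, K, padding = c(0L, 0L, 0L)) {
  .conv3d_fwd(X, K, as.integer(padding))
}
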