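#' 1D classifier hyperparameter specification
#'
#' One point of the architecture grid: `n_layers` repetitions of
#' \[1D convolution (channels, kernel_width, stride) - ReLU - max pool
#' (width 2, stride 2)\] over the 2 x W fused input, then a single fully
#' connected layer to the two class scores.  Convolutions use same-style
#' padding (output width `ceiling(w / stride)`); pooling floors halved
#' widths, so deep or strided specs can collapse below width 1 and become
#' infeasible.
#'
#' @param n_layers number of conv/pool stages (grid: 2-5).
#' @param channels conv channels per stage (grid: 8, 16, 32, 64, 80).
#' @param kernel_width conv kernel width (grid: 2-4).
#' @param stride conv stride (grid: 1-3).
#' @param input_channels input channels, 2 (DAF + distance).
#' @param input_width window width W, default 128.
#' @return a `model_spec`.
#' @export
#' @examples
#' model_spec(3, 80, 2)        # the grid-search winner
#' layer_widths(model_spec(3, 80, 2))
model_spec <- function(n_layers = 3L, channels = 80L, kernel_width = 2L,
                       stride = 1L, input_channels = 2L,
                       input_width = 128L) {
  s <- list(n_layers = as.integer(n_layers), channels = as.integer(channels),
            kernel_width = as.integer(kernel_width),
            stride = as.integer(stride),
            input_channels = as.integer(input_channels),
            input_width = as.integer(input_width))
  if (s$n_layers < 1L || s$channels < 1L || s$kernel_width < 1L ||
      s$stride < 1L || s$input_width < 1L)
    stop_fmt("model_spec fields must be positive")
  structure(s, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %d conv layers, %d channels, kernel %d, stride %d (input %d x %d)\n",
              x$n_layers, x$channels, x$kernel_width, x$stride,
              x$input_channels, x$input_width))
  invisible(x)
}

#' Per-stage width bookkeeping
#'
#' @param spec a [model_spec()].
#' @return data.frame with one row per conv/pool stage: widths entering the
#'   stage, after the convolution, and after the pool.
#' @export
layer_widths <- function(spec) {
  w <- spec$input_width
  out <- data.frame(layer = seq_len(spec$n_layers), width_in = NA_integer_,
                    after_conv = NA_integer_, after_pool = NA_integer_)
  for (i in seq_len(spec$n_layers)) {
    out$width_in[i] <- w
    wc <- conv_out_width(w, spec$stride)
    wp <- pool_out_width(wc)
    out$after_conv[i] <- wc
    out$after_pool[i] <- wp
    w <- wp
    if (w < 1L) break
  }
  out
}

#' Is a spec feasible for its input width?
#' @param spec a [model_spec()].
#' @return `TRUE` if every stage keeps width >= 1.
#' @export
spec_feasible <- function(spec) {
  lw <- layer_widths(spec)
  !anyNA(lw$after_pool) && all(lw$after_pool >= 1L)
}

#' Enumerate the architecture grid
#'
#' Cartesian product of the hyperparameter ranges in deterministic
#' lexicographic order (layers, then channels, kernel width, stride).  The
#' default ranges give the full 180-candidate grid.
#'
#' @param n_layers,channels,kernel_widths,strides value ranges.
#' @param input_width,input_channels fixed input geometry.
#' @return data.frame with one row per candidate and a `feasible` column.
#' @export
enumerate_grid <- function(n_layers = c(2L, 3L, 4L, 5L),
                           channels = c(8L, 16L, 32L, 64L, 80L),
                           kernel_widths = c(2L, 3L, 4L),
                           strides = c(1L, 2L, 3L),
                           input_width = 128L, input_channels = 2L) {
  if (!length(n_layers) || !length(channels) || !length(kernel_widths) ||
      !length(strides)) stop_fmt("empty hyperparameter range")
  g <- expand.grid(stride = strides, kernel_width = kernel_widths,
                   channels = channels, n_layers = n_layers,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("n_layers", "channels", "kernel_width", "stride")]
  g <- g[order(g$n_layers, g$channels, g$kernel_width, g$stride), ]
  rownames(g) <- NULL
  g$input_width <- as.integer(input_width)
  g$input_channels <- as.integer(input_channels)
  g$feasible <- vapply(seq_len(nrow(g)), function(i)
    spec_feasible(grid_spec(g, i)), TRUE)
  g
}

# row i of an enumerate_grid() frame as a model_spec
grid_spec <- function(grid, i) {
  model_spec(grid$n_layers[i], grid$channels[i], grid$kernel_width[i],
             grid$stride[i], input_channels = grid$input_channels[i],
             input_width = grid$input_width[i])
}

#' Build the 1D classifier for a spec
#'
#' @param spec a [model_spec()].
#' @return an `nn_seq` network (weights drawn from the current RNG stream).
#' @export
build_1d_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  lw <- layer_widths(spec)
  bad <- which(lw$after_pool < 1L | is.na(lw$after_pool))
  if (length(bad))
    stop_fmt("infeasible spec: width collapses to 0 at stage %d (pool)",
             bad[1L])
  layers <- list()
  w <- spec$input_width
  cin <- spec$input_channels
  for (i in seq_len(spec$n_layers)) {
    g <- geom1d(cin, w, spec$kernel_width, spec$stride)
    layers <- c(layers, list(layer_conv(g, spec$channels), layer_relu(),
                             layer_pool(1L)))
    w <- pool_out_width(g$Wout)
    cin <- spec$channels
  }
  layers <- c(layers, list(layer_flatten(),
                           layer_dense(spec$channels * w, 2L)))
  structure(list(layers = layers, spec = spec,
                 input_shape = c(spec$input_channels, spec$input_width)),
            class = c("nn_seq", "nn_net"))
}

#' Number of trainable parameters
#' @param net a built network (or a [model_spec()], which is built with
#'   throwaway weights just to count).
#' @return integer parameter count.
#' @export
n_params <- function(net) {
  if (inherits(net, "model_spec"))
    net <- with_seed(1L, build_1d_model(net))
  sum(vapply(nn_params(net), length, 0L))
}

#' 2D reference baseline specification
#'
#' The raw-genotype reference classifier: a compact 2D CNN over the N x W
#' allele image (three 3x3 conv / ReLU / 2x2 max-pool stages, a fully
#' connected layer, and the 2-class head), in three position-fusion
#' variants: `"none"` (image only), `"late_fc"` (the distance vector enters
#' through its own fully connected branch, concatenated before the final
#' layer), and `"early_conv"` (distances broadcast as a second input
#' channel).  All variants share the convolutional trunk, so accuracy
#' differences isolate the fusion strategy.
#'
#' @param fusion fusion variant.
#' @param N,W image height (haplotypes) and width (SNPs).
#' @param channels trunk conv channels.
#' @param n_layers trunk conv/pool stages.
#' @param fc_units trunk fully connected width (and the late branch width).
#' @return a `fusion2d_spec`.
#' @export
fusion2d_spec <- function(fusion = c("none", "late_fc", "early_conv"),
                          N = 128L, W = 128L, channels = 32L,
                          n_layers = 3L, fc_units = 32L) {
  fusion <- match.arg(fusion)
  if (N < 2L^n_layers || W < 2L^n_layers)
    stop_fmt("image %dx%d too small for %d pooling stages", N, W, n_layers)
  structure(list(fusion = fusion, N = as.integer(N), W = as.integer(W),
                 channels = as.integer(channels),
                 n_layers = as.integer(n_layers),
                 fc_units = as.integer(fc_units)),
            class = "fusion2d_spec")
}

#' Build a 2D reference baseline
#'
#' @param spec a [fusion2d_spec()].
#' @return an `nn_seq` network (`none`/`early_conv`) or an `nn_late`
#'   network (`late_fc`) whose forward input is `list(img, dist)`.
#' @export
build_reference_2d <- function(spec) {
  stopifnot(inherits(spec, "fusion2d_spec"))
  cin <- if (spec$fusion == "early_conv") 2L else 1L
  trunk <- list()
  h <- spec$N; w <- spec$W; c_in <- cin
  for (i in seq_len(spec$n_layers)) {
    g <- geom2d(c_in, h, w, 3L, 3L, 1L)
    trunk <- c(trunk, list(layer_conv(g, spec$channels), layer_relu(),
                           layer_pool(2L)))
    h <- pool_out_width(g$Hout); w <- pool_out_width(g$Wout)
    c_in <- spec$channels
  }
  trunk <- c(trunk, list(layer_flatten(),
                         layer_dense(spec$channels * h * w, spec$fc_units),
                         layer_relu()))
  if (spec$fusion == "late_fc") {
    aux <- list(layer_dense(spec$W, spec$fc_units), layer_relu())
    head <- list(layer_dense(2L * spec$fc_units, 2L))
    structure(list(trunk = trunk, aux = aux, head = head, spec = spec,
                   input_shape = c(1L, spec$N, spec$W)),
              class = c("nn_late", "nn_net"))
  } else {
    layers <- c(trunk, list(layer_dense(spec$fc_units, 2L)))
    structure(list(layers = layers, spec = spec,
                   input_shape = c(cin, spec$N, spec$W)),
              class = c("nn_seq", "nn_net"))
  }
}
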