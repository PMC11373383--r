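test_that("the default grid enumerates 180 candidates in stable order", {
  g <- enumerate_grid()
  expect_identical(nrow(g), 180L)
  expect_identical(g, enumerate_grid())
  # lexicographic in (layers, channels, kernel, stride)
  key <- with(g, order(n_layers, channels, kernel_width, stride))
  expect_identical(key, seq_len(180L))
  expect_identical(nrow(enumerate_grid(3L, 80L, 2L, 1L)), 1L)
  expect_error(enumerate_grid(channels = integer(0)), "empty")
})

test_that("width bookkeeping matches an independent oracle on all 180 specs", {
  oracle <- function(W, L, k, s) {
    # straight re-derivation: same-padded conv then floor-halving pool
    out <- integer(0)
    for (i in seq_len(L)) {
      W <- as.integer(ceiling(W / s))
      W <- W %/% 2L
      out <- c(out, W)
      if (W < 1L) break
    }
    out
  }
  g <- enumerate_grid()
  for (i in seq_len(nrow(g))) {
    widths <- oracle(128L, g$n_layers[i], g$kernel_width[i], g$stride[i])
    spec <- model_spec(g$n_layers[i], g$channels[i], g$kernel_width[i],
                       g$stride[i])
    lw <- layer_widths(spec)
    feasible <- length(widths) == g$n_layers[i] && all(widths >= 1L)
    expect_identical(g$feasible[i], feasible)
    expect_identical(lw$after_pool[seq_along(widths)], widths)
    if (feasible) {
      net <- with_seed_test(1L, build_1d_model(spec))
      # every conv stage's built geometry agrees with the oracle
      convs <- Filter(function(l) l$type == "conv", net$layers)
      built <- vapply(convs, function(l) l$geom$Wout %/% 2L, 0L)
      expect_identical(built, widths)
      out <- dafsweep:::nn_forward(net, array(runif(2 * 128), c(2, 128, 1)))
      expect_identical(dim(out$out), c(2L, 1L))
    } else {
      expect_error(build_1d_model(spec), "width collapses")
    }
  }
})

test_that("the winning architecture maps a fused window to two scores", {
  spec <- model_spec(3L, 80L, 2L, 1L)
  expect_identical(layer_widths(spec)$after_pool, c(64L, 32L, 16L))
  net <- with_seed_test(2L, build_1d_model(spec))
  x <- array(runif(2 * 128 * 5), c(2, 128, 5))
  expect_identical(dim(dafsweep:::nn_forward(net, x)$out), c(2L, 5L))
})

test_that("1D logits depend only on features: sample size and row order drop out", {
  model <- untrained_model(model_spec(2L, 8L, 3L, 1L, input_width = 16L),
                           seed = 5L)
  base <- random_window(16L, 16L, seed = 31L)
  # 4x the sample size with identical column frequencies
  big <- snp_matrix(base$alleles[rep(1:16, 4L), ], base$positions)
  shuf <- augment_row_shuffle(base, seed = 9L)
  p0 <- predict(model, list(base))
  expect_identical(predict(model, list(big)), p0)
  expect_identical(predict(model, list(shuf)), p0)
})

test_that("2D baselines share the trunk and differ only in fusion plumbing", {
  specs <- lapply(c("none", "late_fc", "early_conv"), fusion2d_spec,
                  N = 16L, W = 16L, channels = 4L, n_layers = 2L,
                  fc_units = 6L)
  nets <- lapply(seq_along(specs), function(i)
    with_seed_test(1L, build_reference_2d(specs[[i]])))
  names(nets) <- c("none", "late", "early")

  img1 <- array(runif(1 * 16 * 16 * 3), c(1, 16, 16, 3))
  img2 <- array(runif(2 * 16 * 16 * 3), c(2, 16, 16, 3))
  dist <- matrix(runif(16 * 3), 16, 3)
  expect_identical(dim(dafsweep:::nn_forward(nets$none, img1)$out),
                   c(2L, 3L))
  expect_identical(dim(dafsweep:::nn_forward(nets$early, img2)$out),
                   c(2L, 3L))
  expect_identical(
    dim(dafsweep:::nn_forward(nets$late, list(img = img1, dist = dist))$out),
    c(2L, 3L))

  shapes <- function(net) {
    layers <- if (inherits(net, "nn_late")) net$trunk else net$layers
    lapply(Filter(function(l) l$type == "conv", layers),
           function(l) dim(l$W))
  }
  sn <- shapes(nets$none); sl <- shapes(nets$late); se <- shapes(nets$early)
  expect_identical(sn, sl)
  # early fusion only widens the first conv's input patch (2 channels)
  expect_identical(sn[-1L], se[-1L])
  expect_identical(se[[1L]][1L], sn[[1L]][1L])
  expect_identical(se[[1L]][2L], 2L * sn[[1L]][2L])
})

test_that("builds are deterministic under a fixed seed", {
  spec <- model_spec(3L, 16L, 2L, 1L, input_width = 32L)
  n1 <- with_seed_test(7L, build_1d_model(spec))
  n2 <- with_seed_test(7L, build_1d_model(spec))
  expect_identical(dafsweep:::nn_params(n1), dafsweep:::nn_params(n2))
  expect_gt(n_params(n1), 0L)
  # first-batch loss identical too
  x <- array(runif(2 * 32 * 4), c(2, 32, 4)); y <- c(0L, 1L, 0L, 1L)
  l1 <- dafsweep:::softmax_xent(dafsweep:::nn_forward(n1, x)$out, y)$loss
  l2 <- dafsweep:::softmax_xent(dafsweep:::nn_forward(n2, x)$out, y)$loss
  expect_identical(l1, l2)
})

test_that("analytic gradients match numeric differentiation", {
  numgrad <- function(net, inp, y, eps = 1e-5) {
    p <- dafsweep:::nn_params(net)
    fw <- dafsweep:::nn_forward(net, inp)
    an <- dafsweep:::grads_flat(net, dafsweep:::nn_backward(
      net, fw$caches, dafsweep:::softmax_xent(fw$out, y)$dlogits))
    worst <- 0
    for (k in names(p)) {
      take <- seq_len(min(length(p[[k]]), 12L))  # spot-check entries
      for (j in take) {
        num <- 0
        for (s in c(1, -1)) {
          p2 <- p
          p2[[k]][j] <- p2[[k]][j] + s * eps
          n2 <- dafsweep:::nn_set_params(net, p2)
          l <- dafsweep:::softmax_xent(
            dafsweep:::nn_forward(n2, inp)$out, y)$loss
          num <- num + s * l / (2 * eps)
        }
        worst <- max(worst, abs(num - an[[k]][j]) / max(1e-6, abs(num)))
      }
    }
    worst
  }
  y <- c(0L, 1L, 1L)
  n1 <- with_seed_test(3L, build_1d_model(model_spec(2L, 5L, 3L, 2L,
                                                     input_width = 13L)))
  x1 <- with_seed_test(4L, array(rnorm(2 * 13 * 3), c(2, 13, 3)))
  expect_lt(numgrad(n1, x1, y), 1e-5)

  n2 <- with_seed_test(3L, build_reference_2d(
    fusion2d_spec("late_fc", N = 8L, W = 8L, channels = 3L, n_layers = 2L,
                  fc_units = 5L)))
  inp <- with_seed_test(5L, list(img = array(runif(64 * 3), c(1, 8, 8, 3)),
                                 dist = matrix(runif(24), 8, 3)))
  expect_lt(numgrad(n2, inp, y), 1e-5)
})
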