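# Small in-code fixtures shared across the test files.

# random ternary window; missing entries optional, never a fully missing locus
random_window <- function(N, W, p_missing = 0, seed = NULL) {
  gen <- function() {
    a <- matrix(rbinom(N * W, 1L, runif(1, 0.2, 0.8)), N, W)
    if (p_missing > 0) {
      drop <- matrix(runif(N * W) < p_missing, N, W)
      for (j in seq_len(W)) if (all(drop[, j])) drop[1L, j] <- FALSE
      a[drop] <- NA_integer_
    }
    snp_matrix(a, sort(runif(W)))
  }
  if (is.null(seed)) gen() else with_seed_test(seed, gen())
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# jittered copies of the toy sweep-like / neutral-like fixtures: a linearly
# separable two-class problem for training sanity checks
toy_labeled_windows <- function(kind, n, seed) {
  with_seed_test(seed, {
    base <- make_toy_fixture(kind)
    lab <- if (kind == "sweep_like") "sweep" else "neutral"
    lapply(seq_len(n), function(i) {
      a <- base$alleles
      ij <- cbind(sample(nrow(a), 2L, TRUE), sample(ncol(a), 2L, TRUE))
      a[ij] <- 1L - a[ij]
      snp_matrix(a, base$positions, label = lab)
    })
  })
}

toy_dataset <- function(n_per = 20L, seed = 1L) {
  list(train = c(toy_labeled_windows("sweep_like", n_per, seed),
                 toy_labeled_windows("neutral_like", n_per, seed + 1L)),
       val = c(toy_labeled_windows("sweep_like", max(4L, n_per %/% 4L),
                                   seed + 2L),
               toy_labeled_windows("neutral_like", max(4L, n_per %/% 4L),
                                   seed + 3L)),
       test = c(toy_labeled_windows("sweep_like", max(4L, n_per %/% 2L),
                                    seed + 4L),
                toy_labeled_windows("neutral_like", max(4L, n_per %/% 2L),
                                    seed + 5L)))
}

grid_spec_test <- function(g, i) {
  model_spec(g$n_layers[i], g$channels[i], g$kernel_width[i], g$stride[i],
             input_width = g$input_width[i])
}

# minimal untrained classifier around a built network, for scan/predict
# plumbing tests that do not need a meaningful decision rule
untrained_model <- function(spec, seed = 1L) {
  net <- with_seed_test(seed, build_1d_model(spec))
  structure(list(net = net, spec = spec,
                 control = train_control(epochs = 1L, seed = seed),
                 report = NULL, best_epoch = NA_integer_,
                 best_val_accuracy = NA_real_, input_kind = "daf",
                 scale = 1, classes = c("neutral", "sweep")),
            class = "sweep_nn")
}
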