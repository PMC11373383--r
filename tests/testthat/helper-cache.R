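# Shared heavyweight objects (simulated datasets, fitted models), built
# once per test session.  Sizes are the package's desk-scale defaults: 400
# training / 100 validation / 160 test windows per scenario and a 25-epoch
# budget for the scenario-accuracy checks; smaller slices feed the search
# and fusion comparisons.

.ds_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.ds_cache[[name]])) assign(name, force(expr), .ds_cache)
  .ds_cache[[name]]
}

desk_spec <- function(seed) dataset_spec(400L, 100L, 160L, seed = seed)
desk_control <- function(seed = 201L) train_control(epochs = 25L,
                                                    seed = seed)

desk_dataset <- function(id) {
  seed <- c(D1 = 101L, D2 = 102L, D4 = 104L)[[id]]
  cached(paste0("ds_", id),
         make_dataset(scenario_config(id), desk_spec(seed)))
}

desk_model <- function(id) {
  cached(paste0("fit_", id), {
    ds <- desk_dataset(id)
    fit_sweep_model(model_spec(3L, 80L, 2L, 1L), ds$train, ds$val,
                    desk_control())
  })
}

desk_accuracy <- function(id) {
  cached(paste0("acc_", id),
         evaluate(desk_model(id), desk_dataset(id)$test)$accuracy)
}

# balanced subset of a make_dataset() split (neutral block first, sweep
# block second, by construction)
balanced_subset <- function(windows, n_per_class) {
  h <- length(windows) %/% 2L
  c(windows[seq_len(n_per_class)], windows[h + seq_len(n_per_class)])
}

# reduced architecture search on the old-migration scenario: a subsampled
# grid trained with 3 master seeds
nas_reduced <- function() {
  cached("nas_reduced", {
    ds <- desk_dataset("D4")
    tr_w <- balanced_subset(ds$train, 80L)
    sc <- distance_scale(tr_w)
    data <- list(train = prepare_input(tr_w, "daf", scale = sc),
                 val = prepare_input(balanced_subset(ds$val, 30L), "daf",
                                     scale = sc))
    grid <- enumerate_grid(n_layers = c(2L, 3L), channels = c(16L, 80L),
                           kernel_widths = c(2L, 3L), strides = 1L)
    lapply(1:3, function(r)
      run_grid_search(grid, data,
                      train_control(epochs = 6L, seed = 300L + r),
                      keep_reports = TRUE))
  })
}

# reduced low-intensity-hotspot dataset (64 haplotypes, 64-SNP windows)
# for the 2D fusion comparison
d5_dataset <- function() {
  cached("ds_D5",
         make_dataset(scenario_config("D5"),
                      dataset_spec(240L, 60L, 100L, sample_size = 64L,
                                   window_width = 64L, seed = 105L)))
}

fusion_runs <- function() {
  cached("fusion_runs", {
    ds <- d5_dataset()
    lapply(c(none = "none", late_fc = "late_fc",
             early_conv = "early_conv"), function(fu) {
      spec <- fusion2d_spec(fu, N = 64L, W = 64L, channels = 16L,
                            n_layers = 3L, fc_units = 16L)
      repeat_runs(spec, ds,
                  train_control(epochs = 10L, seed = 500L,
                                shuffle_rows = TRUE),
                  n_runs = 3L)
    })
  })
}

# full-region D1 replicates for scan localization checks
scan_replicates <- function(cls, n) {
  cached(paste0("scanreps_", cls, "_", n), {
    seeds <- vapply(seq_len(n), function(i)
      dafsweep:::derive_seed(601L, i, match(cls, c("neutral", "sweep"))),
      0L)
    simulate_replicates(scenario_config("D1"), cls, seeds)
  })
}
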