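# Simulation harness: labeled training data from coalescent simulations.
# The heavy lifting is done by msprime, driven through the shipped python
# bridge (inst/python/coalsim.py), which emits ms-dialect text parsed by
# parse_ms().  All randomness flows from explicit per-replicate seeds.

find_python <- function() {
  p <- getOption("dafsweep.python", Sys.getenv("DAFSWEEP_PYTHON", ""))
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop_fmt("no python interpreter found; set options(dafsweep.python=...)")
  p
}

coalsim_script <- function() {
  f <- system.file("python", "coalsim.py", package = "dafsweep")
  if (!nzchar(f)) stop_fmt("coalsim.py not found in installed package")
  f
}

run_coalsim <- function(cfg, seeds) {
  cfg$seeds <- I(as.integer(seeds))  # I() keeps length-1 vectors as arrays
  conf <- tempfile(fileext = ".json")
  on.exit(unlink(conf))
  jsonlite::write_json(cfg, conf, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(system2(find_python(), c(coalsim_script(), conf),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    stop_fmt("coalescent bridge failed (exit %d):\n%s", status,
             paste(utils::tail(out, 15L), collapse = "\n"))
  parse_ms(out)
}

#' Simulate labeled coalescent replicates
#'
#' Runs one scenario/class combination for a vector of seeds, retrying (with
#' derived seeds, up to 10 times) any replicate that produces fewer
#' segregating sites than `min_snps`.  Output haplotypes are intrinsically
#' polarized (1 = derived) and sweep replicates place the fixed beneficial
#' allele at the region center.
#'
#' @param scenario a [scenario_config()].
#' @param cls `"neutral"` or `"sweep"`.
#' @param seeds integer vector, one seed per replicate.
#' @param min_snps minimum segregating sites per replicate.
#' @return list of [snp_matrix] replicates (full region, not windowed) with
#'   `label` and `scenario` set.
#' @export
simulate_replicates <- function(scenario, cls = c("neutral", "sweep"),
                                seeds, min_snps = 128L) {
  stopifnot(inherits(scenario, "scenario_config"))
  cls <- match.arg(cls)
  cfg <- engine_config(scenario, cls)
  cfg$min_snps <- as.integer(min_snps)
  cfg$max_retries <- 10L
  reps <- run_coalsim(cfg, seeds)
  lapply(reps, function(m) {
    m$label <- cls
    m$scenario <- scenario$id
    m
  })
}

#' @rdname simulate_replicates
#' @param seed single seed for a single replicate.
#' @export
simulate_replicate <- function(scenario, cls = c("neutral", "sweep"),
                               seed = 1L, min_snps = 128L) {
  simulate_replicates(scenario, cls, seeds = seed, min_snps = min_snps)[[1L]]
}

#' Replicate plan for a dataset specification
#'
#' The deterministic bookkeeping behind [make_dataset()]: every replicate
#' of every split, its class, and the seed derived for it from the master
#' seed.  Splits are exactly 50% neutral / 50% sweep by construction.
#'
#' @param spec a [dataset_spec()].
#' @return data.frame with columns `split`, `class`, `index` (within
#'   split/class) and `seed`.
#' @export
dataset_plan <- function(spec = dataset_spec()) {
  stopifnot(inherits(spec, "dataset_spec"))
  sizes <- c(train = spec$n_train, val = spec$n_val, test = spec$n_test)
  rows <- list()
  for (si in seq_along(sizes)) {
    for (ci in 1:2) {
      n <- sizes[[si]] %/% 2L
      rows[[length(rows) + 1L]] <- data.frame(
        split = names(sizes)[si],
        class = c("neutral", "sweep")[ci],
        index = seq_len(n),
        seed = vapply(seq_len(n), function(i)
          derive_seed(spec$seed, si, ci, i), 0L))
    }
  }
  do.call(rbind, rows)
}

#' Build a labeled train/validation/test dataset
#'
#' Simulates the full dataset for one scenario: each split is exactly 50%
#' neutral / 50% sweep, every replicate is cut to its central
#' `window_width`-SNP window, and every replicate's seed derives
#' deterministically from `spec$seed`, so any single replicate can be
#' regenerated in isolation.
#'
#' @param scenario a [scenario_config()].
#' @param spec a [dataset_spec()].
#' @param chunk_size replicates per bridge invocation (memory/latency
#'   trade-off; results do not depend on it).
#' @param progress print per-chunk progress.
#' @return a `sweep_dataset`: list with `train`, `val`, `test` window lists
#'   (labeled [snp_matrix] objects), plus `scenario` and `spec`.
#' @export
make_dataset <- function(scenario, spec = dataset_spec(), chunk_size = 100L,
                         progress = FALSE) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(spec, "dataset_spec"))
  scenario$sample_haplotypes <- spec$sample_size
  plan <- dataset_plan(spec)
  out <- list()
  for (sname in c("train", "val", "test")) {
    windows <- list()
    for (cls in c("neutral", "sweep")) {
      part <- plan[plan$split == sname & plan$class == cls, ]
      got <- list()
      for (lo in seq(1L, nrow(part), by = chunk_size)) {
        hi <- min(lo + chunk_size - 1L, nrow(part))
        reps <- simulate_replicates(scenario, cls, part$seed[lo:hi],
                                    min_snps = spec$window_width)
        got <- c(got, lapply(reps, extract_center_window,
                             width = spec$window_width))
        if (progress)
          message(sprintf("  %s/%s: %d/%d", sname, cls, hi, nrow(part)))
      }
      windows <- c(windows, got)
    }
    out[[sname]] <- windows
  }
  structure(c(out, list(scenario = scenario, spec = spec)),
            class = "sweep_dataset")
}

#' @export
print.sweep_dataset <- function(x, ...) {
  cat(sprintf("<sweep_dataset> scenario %s: train %d, val %d, test %d (%d x %d windows)\n",
              x$scenario$id, length(x$train), length(x$val), length(x$test),
              x$spec$sample_size, x$spec$window_width))
  invisible(x)
}

#' Labels of a window list
#' @param windows list of labeled [snp_matrix] or [feature_matrix] objects.
#' @return character vector of `"neutral"`/`"sweep"`.
#' @export
window_labels <- function(windows) {
  vapply(windows, function(w)
    (if (inherits(w, "feature_matrix")) attr(w, "label") else w$label) %||%
      NA_character_, "")
}

#' Tiny deterministic fixtures
#'
#' Hand-written matrices (at most 8 x 8) with known DAF and distance values,
#' used throughout the unit tests.  `"sweep_like"` mimics the post-sweep
#' signature (extreme frequencies, a central SNP desert); `"neutral_like"`
#' has intermediate frequencies and even spacing.
#'
#' @param kind fixture name.
#' @return an [snp_matrix].
#' @export
make_toy_fixture <- function(kind = c("all_derived", "checkerboard",
                                      "with_missing", "sweep_like",
                                      "neutral_like")) {
  kind <- match.arg(kind)
  switch(kind,
    all_derived = snp_matrix(matrix(1L, 4L, 4L),
                             c(0.2, 0.4, 0.6, 0.8)),
    checkerboard = snp_matrix(
      rbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L),
            c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L)),
      c(0.2, 0.4, 0.6, 0.8)),
    with_missing = snp_matrix(
      rbind(c(1L, 1L, 0L), c(1L, NA, 0L), c(NA, 1L, 1L), c(0L, 0L, NA)),
      c(0.25, 0.5, 0.75)),
    sweep_like = snp_matrix(
      {
        daf8 <- c(1, 7, 8, 0, 8, 1, 7, 0)  # derived counts of 8: extremes
        vapply(daf8, function(k) c(rep(1L, k), rep(0L, 8L - k)),
               integer(8L))
      },
      c(0.02, 0.05, 0.08, 0.11, 0.89, 0.92, 0.95, 0.98)),
    neutral_like = snp_matrix(
      {
        daf8 <- c(4, 3, 5, 4, 3, 5, 4, 4)  # intermediate frequencies
        vapply(daf8, function(k) c(rep(1L, k), rep(0L, 8L - k)),
               integer(8L))
      },
      seq(0.1, 0.9, length.out = 8L))
  )
}
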