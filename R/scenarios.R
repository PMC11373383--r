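# Evaluation scenarios: neutral vs. hard-sweep classification under three
# classes of confounding demography.  Times are in units of 4N generations
# (the ms convention), relative sizes are fractions of the present-day
# population of 50 000 diploids.  theta and rho are population-scaled over
# the whole simulated region.

SCENARIO_IDS <- c("D1", "D2", "D3", "D4", "D5", "D6", "constant")

#' Demographic/selection scenario configuration
#'
#' The six evaluation scenarios pair one confounding factor with a hard
#' selective sweep (selection coefficient 0.02) at the region center:
#' mild/severe bottleneck (`D1`/`D2`), recent/old two-deme structure
#' (`D3`/`D4`), and a low/high-intensity recombination hotspot (`D5`/`D6`).
#' `"constant"` is an equilibrium control used in sanity checks.
#'
#' Region length and, for D1-D4, theta/rho have package defaults (100 kb,
#' theta = rho = 500) chosen so that every replicate comfortably exceeds the
#' 128-SNP window; D5/D6 use theta = rho = 2000.
#'
#' @param id one of `"D1"`..`"D6"` or `"constant"`.
#' @param ... overrides for any configuration field (e.g. `theta`, `rho`,
#'   `region_bp`, `present_size`, `sample_haplotypes`).
#' @return a `scenario_config` list.
#' @export
#' @examples
#' scenario_config("D2")
scenario_config <- function(id = SCENARIO_IDS, ...) {
  id <- match.arg(id)
  base <- list(
    id = id,
    confounder = switch(id, D1 = , D2 = "bottleneck",
                        D3 = , D4 = "migration",
                        D5 = , D6 = "hotspot", constant = "none"),
    present_size = 50000,         # diploids
    sample_haplotypes = 128L,
    region_bp = 1e5,
    theta = if (id %in% c("D5", "D6")) 2000 else 500,
    rho = if (id %in% c("D5", "D6")) 2000 else 500,
    selection_coefficient = 0.02,
    # time (4N units) before sampling at which the beneficial allele fixed
    sweep_time = if (id %in% c("D1", "D2")) 0.016 else 0.005,
    bottleneck_severity = switch(id, D1 = 0.5, D2 = 0.005, NULL),
    bottleneck_duration = switch(id, D1 = 0.001, D2 = 0.002, NULL),
    bottleneck_onset = switch(id, D1 = 0.1, D2 = 0.01, NULL),
    join_time = switch(id, D3 = 0.003, D4 = 3, NULL),
    hotspot_intensity = switch(id, D5 = 2, D6 = 20, NULL),
    hotspot_span_bp = if (id %in% c("D5", "D6")) 5000 else NULL
  )
  if (id == "constant") base$sweep_time <- 0.005
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop_fmt("unknown scenario fields: %s",
                            paste(bad, collapse = ", "))
  base[names(over)] <- over
  structure(base, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario %s> confounder: %s; theta=%g rho=%g L=%g bp; s=%g\n",
              x$id, x$confounder, x$theta, x$rho, x$region_bp,
              x$selection_coefficient))
  invisible(x)
}

# Translate a scenario + class into the engine-level configuration consumed
# by the python/msprime bridge: absolute times in generations, per-bp rates.
engine_config <- function(scenario, cls = c("neutral", "sweep")) {
  cls <- match.arg(cls)
  s <- scenario
  N0 <- s$present_size
  L <- s$region_bp
  four_n <- 4 * N0
  cfg <- list(
    N0 = N0, L = L,
    samples = as.integer(s$sample_haplotypes / 2L),  # diploid individuals
    mut_rate = s$theta / (four_n * L),
    recomb_rate = s$rho / (four_n * L),
    class = cls
  )
  if (s$confounder == "bottleneck") {
    cfg$bottleneck <- list(
      start_gen = s$bottleneck_onset * four_n,
      end_gen = (s$bottleneck_onset + s$bottleneck_duration) * four_n,
      size = s$bottleneck_severity * N0)
  }
  if (s$confounder == "migration")
    cfg$structure <- list(join_gen = s$join_time * four_n)
  if (s$confounder == "hotspot")
    cfg$hotspot <- list(left = L / 2 - s$hotspot_span_bp / 2,
                        right = L / 2 + s$hotspot_span_bp / 2,
                        fold = s$hotspot_intensity)
  if (cls == "sweep")
    cfg$sweep <- list(s = s$selection_coefficient,
                      fix_gen = s$sweep_time * four_n,
                      position = L / 2)
  cfg
}

#' Dataset size specification
#'
#' Split sizes follow the evaluation protocol: 1700 training, 300 validation
#' and 2000 test replicates, each split evenly divided between the neutral
#' and sweep classes, 128 haplotypes and 128-SNP center windows.  All sizes
#' scale down proportionally for quick experiments.
#'
#' @param n_train,n_val,n_test total replicates per split (must be even).
#' @param sample_size haplotypes per replicate.
#' @param window_width SNPs per training window.
#' @param seed master seed from which all per-replicate seeds derive.
#' @return a `dataset_spec` list.
#' @export
dataset_spec <- function(n_train = 1700L, n_val = 300L, n_test = 2000L,
                         sample_size = 128L, window_width = 128L,
                         seed = 1L) {
  sizes <- c(train = n_train, val = n_val, test = n_test)
  if (any(sizes <= 0L)) stop_fmt("split sizes must be positive")
  if (any(sizes %% 2L != 0L))
    stop_fmt("split sizes must be even for a 50/50 class balance")
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test),
                 sample_size = as.integer(sample_size),
                 window_width = as.integer(window_width),
                 seed = as.integer(seed)),
            class = "dataset_spec")
}
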