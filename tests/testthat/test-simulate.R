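test_that("toy fixtures have their advertised frequencies", {
  expect_equal(compute_daf(make_toy_fixture("all_derived")), rep(1, 4))
  expect_equal(compute_daf(make_toy_fixture("checkerboard")), rep(0.5, 4))
  expect_equal(compute_daf(make_toy_fixture("with_missing")),
               c(2 / 3, 2 / 3, 1 / 3))
  sw <- compute_daf(make_toy_fixture("sweep_like"))
  nl <- compute_daf(make_toy_fixture("neutral_like"))
  expect_true(all(pmin(sw, 1 - sw) <= 1 / 8))
  expect_true(all(nl >= 3 / 8 & nl <= 5 / 8))
})

test_that("scenario parameters convert to engine units", {
  cfg <- dafsweep:::engine_config(scenario_config("D2"), "sweep")
  # 4N generations x ms-time; N = 50 000 diploids
  expect_equal(cfg$sweep$fix_gen, 0.016 * 4 * 50000)
  expect_equal(cfg$bottleneck$start_gen, 0.01 * 4 * 50000)
  expect_equal(cfg$bottleneck$end_gen, (0.01 + 0.002) * 4 * 50000)
  expect_equal(cfg$bottleneck$size, 0.005 * 50000)
  expect_equal(cfg$mut_rate * 4 * 50000 * cfg$L,
               scenario_config("D2")$theta)
  expect_equal(cfg$samples, 64L)

  h <- dafsweep:::engine_config(scenario_config("D6"), "neutral")
  expect_equal(h$hotspot$fold, 20)
  expect_equal(h$hotspot$right - h$hotspot$left, 5000)
  expect_null(h$sweep)
  expect_equal(dafsweep:::engine_config(scenario_config("D4"),
                                        "neutral")$structure$join_gen,
               3 * 4 * 50000)
  expect_error(scenario_config("D1", nonsense = 2), "unknown")
})

test_that("the replicate plan is balanced, exact and seed-deterministic", {
  plan <- dataset_plan(dataset_spec())
  counts <- table(plan$split, plan$class)
  expect_identical(as.vector(counts[c("train", "val", "test"), ]),
                   c(850L, 150L, 1000L, 850L, 150L, 1000L))
  expect_false(anyDuplicated(plan$seed) > 0L)
  expect_identical(plan, dataset_plan(dataset_spec()))
  small <- dataset_plan(dataset_spec(100L, 20L, 40L, seed = 2L))
  expect_identical(sum(small$split == "train"), 100L)
  expect_identical(sum(small$split == "train" & small$class == "sweep"),
                   50L)
  expect_error(dataset_spec(101L), "even")
})

test_that("replicates are reproducible from their seed, and distinct across seeds", {
  sc <- scenario_config("D1")
  a <- simulate_replicate(sc, "neutral", seed = 424242L)
  b <- simulate_replicate(sc, "neutral", seed = 424242L)
  expect_identical(a$alleles, b$alleles)
  expect_identical(a$positions, b$positions)
  expect_identical(a$label, "neutral")
  expect_identical(a$scenario, "D1")
  d <- simulate_replicate(sc, "neutral", seed = 424243L)
  expect_false(identical(a$alleles, d$alleles))
  expect_gte(ncol(a$alleles), 128L)
  expect_true(all(a$alleles %in% c(0L, 1L)))
  expect_false(is.unsorted(a$positions))
})

test_that("generated datasets honor split sizes, balance and windowing", {
  ds <- make_dataset(scenario_config("D1"),
                     dataset_spec(12L, 4L, 8L, seed = 77L),
                     chunk_size = 5L)
  expect_length(ds$train, 12L)
  expect_length(ds$val, 4L)
  expect_length(ds$test, 8L)
  for (split in list(ds$train, ds$val, ds$test)) {
    labs <- window_labels(split)
    expect_identical(sum(labs == "sweep"), length(split) %/% 2L)
    expect_true(all(vapply(split, function(w) ncol(w$alleles), 0L) == 128L))
  }
  # chunking is bookkeeping only: same seed, different chunking, same data
  ds2 <- make_dataset(scenario_config("D1"),
                      dataset_spec(12L, 4L, 8L, seed = 77L),
                      chunk_size = 100L)
  expect_identical(lapply(ds$train, `[[`, "alleles"),
                   lapply(ds2$train, `[[`, "alleles"))
})

test_that("sweep replicates carry the two sweep signatures", {
  # desk-scale mild-bottleneck training windows: 200 neutral, 200 sweep
  ds <- desk_dataset("D1")
  labs <- window_labels(ds$train)
  sweep_w <- ds$train[labs == "sweep"]
  neut_w <- ds$train[labs == "neutral"]

  # (a) SFS mass shifted toward extreme frequencies near the swept center
  extreme_mass <- function(w) {
    f <- compute_daf(w)
    mean(f < 0.1 | f > 0.9)
  }
  es <- vapply(sweep_w, extreme_mass, 0)
  en <- vapply(neut_w, extreme_mass, 0)
  tt <- stats::wilcox.test(es, en, alternative = "greater")
  expect_lt(tt$p.value, 0.01)

  # (b) reduced polymorphism: the 128-SNP center window spans more sequence
  span <- function(w) max(w$positions) - min(w$positions)
  ss <- vapply(sweep_w, span, 0)
  sn <- vapply(neut_w, span, 0)
  st <- stats::wilcox.test(ss, sn, alternative = "greater")
  expect_lt(st$p.value, 0.01)
})

test_that("a severe bottleneck depresses segregating-site counts", {
  n <- 250L
  seeds <- vapply(seq_len(n), function(i)
    dafsweep:::derive_seed(881L, i), 0L)
  d2 <- simulate_replicates(scenario_config("D2"), "neutral", seeds,
                            min_snps = 1L)
  ct <- simulate_replicates(scenario_config("constant"), "neutral", seeds,
                            min_snps = 1L)
  s2 <- vapply(d2, function(m) ncol(m$alleles), 0L)
  sc <- vapply(ct, function(m) ncol(m$alleles), 0L)
  expect_lt(mean(s2), mean(sc))
  expect_lt(stats::wilcox.test(s2, sc, alternative = "less")$p.value, 0.01)
})
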