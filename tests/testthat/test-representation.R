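test_that("DAF follows the reduced-denominator rule", {
  m <- snp_matrix(matrix(c(1L, 1L, 1L, 0L), 4L, 1L), 0.5)
  expect_equal(compute_daf(m), 0.75)
  mm <- snp_matrix(matrix(c(1L, 1L, NA, 0L), 4L, 1L), 0.5)
  expect_equal(compute_daf(mm), 2 / 3)
  fx <- make_toy_fixture("with_missing")
  expect_equal(compute_daf(fx), c(2 / 3, 2 / 3, 1 / 3))
  expect_equal(compute_daf(make_toy_fixture("all_derived")), rep(1, 4))
  expect_equal(compute_daf(make_toy_fixture("checkerboard")), rep(0.5, 4))

  all_na <- matrix(c(1L, 0L, NA, NA), 2L, 2L)
  expect_error(compute_daf(snp_matrix(all_na, c(0.1, 0.2))),
               "locus 2 is entirely missing")
})

test_that("DAF agrees with a brute-force per-locus counter", {
  brute <- function(x) {
    a <- x$alleles
    out <- numeric(ncol(a))
    for (j in seq_len(ncol(a))) {
      der <- 0L; obs <- 0L
      for (i in seq_len(nrow(a))) {
        if (!is.na(a[i, j])) {
          obs <- obs + 1L
          if (a[i, j] == 1L) der <- der + 1L
        }
      }
      out[j] <- der / obs
    }
    out
  }
  for (case in 1:25) {
    m <- random_window(sample(2:64, 1L), sample(2:64, 1L),
                       p_missing = (case %% 4L) / 10)
    expect_equal(compute_daf(m), brute(m))
  }
})

test_that("DAF and features are invariant to sample-row permutation", {
  for (case in 1:100) {
    m <- random_window(sample(3:24, 1L), sample(2:16, 1L),
                       p_missing = 0.1)
    perm <- sample(nrow(m$alleles))
    ms <- snp_matrix(m$alleles[perm, , drop = FALSE], m$positions)
    expect_identical(compute_daf(m), compute_daf(ms))
    expect_identical(unclass(featurize(m)), unclass(featurize(ms)))
  }
})

test_that("marking one derived allele missing shifts DAF from k/n to (k-1)/(n-1)", {
  for (case in 1:20) {
    m <- random_window(sample(4:32, 1L), sample(2:10, 1L), seed = 90L + case)
    j <- sample(ncol(m$alleles), 1L)
    der_rows <- which(m$alleles[, j] == 1L)
    if (length(der_rows) < 2L) next
    k <- length(der_rows); n <- nrow(m$alleles)
    m2 <- m
    m2$alleles[der_rows[1L], j] <- NA_integer_
    expect_equal(compute_daf(m2)[j], (k - 1) / (n - 1))
    expect_equal(compute_daf(m)[j], k / n)
  }
})

test_that("distances difference positions and zero-terminate", {
  expect_equal(compute_distances(c(10, 15, 22)), c(5, 7, 0))
  expect_equal(compute_distances(3.7), 0)
  p <- sort(runif(30))
  expect_equal(compute_distances(p), compute_distances(p + 1000))
  expect_error(compute_distances(c(2, 1)), "nondecreasing")
})

test_that("featurize is sample-size invariant and respects scale", {
  base <- random_window(8L, 16L, seed = 7L)
  big <- snp_matrix(base$alleles[rep(1:8, 8L), ], base$positions)
  f1 <- featurize(base); f2 <- featurize(big)
  expect_identical(dim(f1), c(2L, 16L))
  expect_identical(dim(f2), c(2L, 16L))
  expect_equal(f1["daf", ], f2["daf", ])  # same column frequencies

  eq <- snp_matrix(matrix(1L, 2L, 5L), seq(0.1, 0.5, by = 0.1))
  expect_equal(featurize(eq)["dist", ], c(rep(0.1, 4L), 0))
  expect_equal(featurize(eq, scale = 2)["dist", ], c(rep(0.05, 4L), 0))
})

test_that("center-window extraction matches a brute-force center rule", {
  # oracle: start whose window center is closest to S/2, ties to lower index
  oracle_start <- function(S, W) {
    starts <- 0:(S - W)
    centers <- starts + (W - 1) / 2
    starts[which.min(abs(centers - S / 2))]
  }
  m200 <- random_window(4L, 200L, seed = 11L)
  w <- extract_center_window(m200, 128L)
  expect_identical(w$alleles, m200$alleles[, 37:164])
  expect_equal(oracle_start(200L, 128L), 36)

  for (S in c(128L, 129L, 130L, 155L, 199L)) {
    m <- random_window(3L, S, seed = S)
    w <- extract_center_window(m, 128L)
    s0 <- oracle_start(S, 128L)
    expect_identical(w$alleles, m$alleles[, (s0 + 1L):(s0 + 128L)])
    expect_identical(w$positions, m$positions[(s0 + 1L):(s0 + 128L)])
  }
  expect_identical(extract_center_window(m200, 200L)$alleles, m200$alleles)
  expect_error(extract_center_window(random_window(3L, 100L), 128L),
               "fewer than window width")
  lab <- snp_matrix(m200$alleles, m200$positions, label = "sweep",
                    scenario = "D1")
  expect_identical(extract_center_window(lab, 128L)$label, "sweep")
})

test_that("windows cut from translated regions featurize identically", {
  m <- random_window(6L, 40L, seed = 21L)
  shifted <- snp_matrix(m$alleles, m$positions + 0.73)
  for (s0 in c(0L, 5L, 20L)) {
    idx <- (s0 + 1L):(s0 + 20L)
    w1 <- snp_matrix(m$alleles[, idx], m$positions[idx])
    w2 <- snp_matrix(shifted$alleles[, idx], shifted$positions[idx])
    expect_equal(unclass(featurize(w1)), unclass(featurize(w2)))
  }
})
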