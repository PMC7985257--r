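test_that("NODF endpoints: perfect staircase scores 100, checkerboards 0, ties 0", {
  expect_equal(nodf(nested_staircase(3))$NODF, 100)
  expect_equal(nodf(nested_staircase(5))$NODF, 100)
  expect_equal(nodf(diag(2))$NODF, 0)
  expect_equal(nodf(rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))$NODF, 0)

  # equal-marginal pairs contribute nothing even with overlap structure
  b <- rbind(c(1, 1, 0), c(0, 1, 1))
  ledger <- nodf(b)$pairs
  rowpair <- ledger[ledger$margin == "rows", ]
  expect_equal(rowpair$Npaired, 0)
  expect_equal(rowpair$DF_paired, 0)
})

test_that("NODF equals the brute-force pair-enumeration oracle on random matrices", {
  set.seed(31)
  for (k in 1:60) {
    b <- random_binary(5, 6, runif(1, 0.3, 0.8))
    expect_equal(nodf(b)$NODF, oracle_nodf(b))
  }
})

test_that("NODF agrees with vegan's independent implementation", {
  set.seed(36)
  for (k in 1:25) {
    b <- random_binary(sample(3:8, 1), sample(3:8, 1), 0.5)
    expect_equal(nodf(b)$NODF,
                 unname(vegan::nestednodf(b)$statistic["NODF"]))
  }
})

test_that("NODF is invariant under row and column permutations", {
  set.seed(32)
  b <- random_binary(6, 7, 0.5)
  v <- nodf(b)$NODF
  for (k in 1:10) {
    expect_equal(nodf(b[sample(6), sample(7)])$NODF, v)
  }
})

test_that("NODF validates its input", {
  expect_error(nodf(rbind(c(1, 1), c(0, 0))), "all-zero")
  expect_error(nodf(rbind(c(2, 1), c(1, 1))), "not binary")
  expect_error(nodf(matrix(1, 1, 3)), "at least 2")
})

test_that("max_nodf on small instances equals exhaustive enumeration", {
  # independent oracle on a sample of shapes
  for (case in list(c(3, 3, 6), c(3, 3, 7), c(2, 4, 5), c(3, 4, 8))) {
    got <- max_nodf(case[1], case[2], case[3])
    expect_equal(got$value, oracle_max_nodf(case[1], case[2], case[3]))
    expect_equal(sum(got$matrix), case[3])
  }
  # full matrix: every marginal ties, so max NODF is 0
  expect_equal(max_nodf(3, 4, 12)$value, 0)
  expect_error(max_nodf(3, 3, 4), "infeasible")
  expect_error(max_nodf(3, 3, 10), "infeasible")
})

test_that("stochastic max_nodf search matches enumeration on small instances", {
  for (case in list(c(3, 3, 6), c(2, 5, 7), c(3, 4, 7), c(4, 4, 9))) {
    exact <- max_nodf(case[1], case[2], case[3], method = "exhaustive")$value
    found <- max_nodf(case[1], case[2], case[3], method = "search",
                      restarts = 6, moves = 600, seed = 2)$value
    expect_equal(found, exact)
  }
})

test_that("max_nodf search dominates sampled matrices and is monotone in budget", {
  set.seed(33)
  m <- 6; n <- 9; fill <- 24
  best <- max_nodf(m, n, fill, method = "search", restarts = 4, moves = 800,
                   seed = 5)
  for (k in 1:20) {
    b <- matrix(0, m, n)
    repeat {
      b[] <- 0
      b[sample(m * n, fill)] <- 1
      if (all(rowSums(b) > 0) && all(colSums(b) > 0)) break
    }
    expect_gte(best$value + 1e-9, nodf(b)$NODF)
  }
  # same seed schedule, larger budget: never worse
  small <- max_nodf(m, n, fill, method = "search", restarts = 2, moves = 300, seed = 5)
  bigger <- max_nodf(m, n, fill, method = "search", restarts = 4, moves = 300, seed = 5)
  longer <- max_nodf(m, n, fill, method = "search", restarts = 2, moves = 900, seed = 5)
  expect_gte(bigger$value, small$value)
  expect_gte(longer$value, small$value)
})

test_that("NODFc satisfies its definitional identity and invariances", {
  set.seed(34)
  b <- random_binary(5, 7, 0.5)
  res <- nodfc(b, seed = 3)
  expect_equal(res$NODFc * res$max_NODF * res$C * log(res$S), res$NODF)
  expect_equal(res$C, sum(b) / 35)
  expect_equal(res$S, sqrt(35))

  # permutation invariance
  res2 <- nodfc(b[sample(5), sample(7)], seed = 3)
  expect_equal(res2$NODFc, res$NODFc)

  # 3x3 staircase fixture against the brute-force max-NODF normalization
  b3 <- nested_staircase(3)   # fill 6
  mx <- oracle_max_nodf(3, 3, 6)
  expect_equal(nodfc(b3)$NODFc, 100 / mx / ((6 / 9) * log(3)))

  # full matrix: max NODF is 0, NODFc undefined
  expect_warning(full <- nodfc(matrix(1, 3, 3)), "undefined")
  expect_true(is.na(full$NODFc))
})

test_that("mean NODF declines as the generator's ranking noise grows", {
  # reduced sweep of the monotone-response property (full grid in the
  # acceptance suite): rank correlation of NODF with the noise knob
  set.seed(35)
  levels <- seq(0, 1, length.out = 8)
  vals <- c(); xs <- c()
  for (eps in levels) for (s in 1:4) {
    im <- generate_interaction_matrix(synthetic_config(
      n_hosts = 6, n_fungi = 30, plots_per_host = 2, reads_per_sample = 1000,
      epsilon = eps, seed = 1000 * s + round(100 * eps)))
    vals <- c(vals, nodf(binary_view(im))$NODF)
    xs <- c(xs, eps)
  }
  ct <- suppressWarnings(cor.test(xs, vals, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
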