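test_that("degrees and the degree distribution follow the link structure", {
  full <- matrix(1, 3, 5)
  expect_true(all(species_degree(full, "hosts") == 5))
  expect_true(all(species_degree(full, "fungi") == 3))
  expect_true(all(species_degree(diag(4), "fungi") == 1))

  dd <- degree_distribution(diag(4), "fungi")
  expect_equal(dd$frequency, c(4, 0, 0, 0))
  expect_equal(sum(dd$frequency), 4)

  set.seed(51)
  b <- random_binary(5, 8, 0.5)
  dd2 <- degree_distribution(b, "fungi")
  expect_equal(sum(dd2$frequency), 8)
  expect_equal(dd2$degree, 1:5)

  # planted generalist fixture: all mass at the maximum degree
  gen <- matrix(1, 4, 6); gen[1, 1] <- 1
  expect_equal(degree_distribution(gen, "fungi")$frequency, c(0, 0, 0, 6))
})

test_that("connectance is the realized link fraction", {
  expect_equal(connectance(matrix(1, 4, 5)), 1)
  stair <- nested_staircase(4)
  expect_equal(connectance(stair), sum(stair) / 16)
  m <- 3; n <- 6
  spanning <- matrix(0, m, n)
  spanning[1, ] <- 1; spanning[, 1] <- 1
  expect_equal(connectance(spanning), (m + n - 1) / (m * n))
})

test_that("d' endpoints: proportional use gives 0, exclusive rare partner gives 1", {
  # every host uses partners exactly in proportion to availability
  w <- rbind(c(4, 2, 2), c(4, 2, 2), c(4, 2, 2))
  dimnames(w) <- list(paste0("h", 1:3), paste0("f", 1:3))
  dp <- d_prime(w, margin = "hosts")
  expect_equal(unname(dp), rep(0, 3))

  # a host exclusively on a partner nobody else touches, in a larger network
  w2 <- rbind(c(0, 0, 0, 6),
              c(10, 8, 6, 0),
              c(9, 9, 6, 0))
  dimnames(w2) <- list(paste0("h", 1:3), paste0("f", 1:4))
  expect_equal(unname(d_prime(w2, species = "h1", margin = "hosts")), 1)
})

test_that("d' equals the exhaustive-reallocation oracle on random integer matrices", {
  set.seed(52)
  for (k in 1:8) {
    w <- random_weights(4, 4, lambda = 1.2)
    for (i in 1:4) {
      got <- suppressWarnings(d_prime(w, species = i, margin = "hosts",
                                      method = "search"))
      want <- oracle_dprime(w, i, "hosts")
      if (is.na(want)) expect_true(is.na(got)) else expect_equal(unname(got), want)
    }
  }
})

test_that("d' search path agrees with its own exhaustive path on larger totals", {
  set.seed(53)
  for (k in 1:5) {
    w <- random_weights(3, 4, lambda = 2)
    for (i in 1:3) {
      a <- suppressWarnings(d_prime(w, i, "hosts", method = "search"))
      b <- suppressWarnings(d_prime(w, i, "hosts", method = "exact"))
      expect_equal(a, b)
    }
  }
})

test_that("H2' endpoints: independence gives 0, diagonal specialization gives 1", {
  expect_equal(h2_prime(matrix(4, 4, 4))$H2prime, 0)
  # any outer-product-of-marginals table
  r <- c(2, 4); cc <- c(3, 3)
  w <- outer(r, cc) / sum(r)
  expect_equal(h2_prime(w)$H2prime, 0)
  expect_equal(h2_prime(diag(c(3, 5, 2, 4)))$H2prime, 1)
})

test_that("H2' matches the exhaustive table-enumeration oracle on small matrices", {
  set.seed(54)
  for (k in 1:6) {
    w <- random_weights(3, 3, lambda = 1)
    if (sum(w) > 14) next  # keep the oracle enumeration small
    got <- h2_prime(w, method = "search", restarts = 30, proposals = 600,
                    seed = k)
    want <- oracle_h2prime(w)
    expect_equal(got$H2prime, want, tolerance = 1e-8)
  }
})

test_that("d' and H2' are (approximately) invariant to scaling all weights", {
  set.seed(55)
  w <- random_weights(4, 5, lambda = 3) + 1
  d1 <- suppressWarnings(d_prime(w, margin = "hosts"))
  d2 <- suppressWarnings(d_prime(3 * w, margin = "hosts"))
  expect_lt(max(abs(d1 - d2)), 0.02)   # up to integer-granularity effects
  h1 <- h2_prime(w, seed = 1)$H2prime
  h2 <- h2_prime(3 * w, seed = 1)$H2prime
  expect_lt(abs(h1 - h2), 0.02)
})

test_that("C-score endpoints and brute-force equality", {
  expect_equal(c_score(nested_staircase(4), "fungi"), 0)
  expect_equal(c_score(nested_staircase(4), "hosts"), 0)
  expect_equal(c_score(diag(2), "fungi"), 1)
  set.seed(56)
  for (k in 1:20) {
    b <- random_binary(5, 5, 0.5)
    expect_equal(c_score(b, "fungi"), oracle_cscore(b, "fungi"))
    expect_equal(c_score(b, "hosts"), oracle_cscore(b, "hosts"))
  }
  expect_error(c_score(rbind(c(1, 0), c(1, 0)), "fungi"), "zero presences")
})

test_that("fungal d' rises with the specialization knob while C-score opposes NODF on noise", {
  # reduced sweep (full grids in the acceptance suite)
  set.seed(57)
  gammas <- c(0, 0.3, 0.8, 1.5)
  means <- vapply(gammas, function(g) {
    vals <- vapply(1:4, function(s) {
      im <- generate_interaction_matrix(synthetic_config(
        n_hosts = 5, n_fungi = 20, plots_per_host = 2, reads_per_sample = 600,
        gamma = g, seed = 100 * s + round(10 * g)))
      mean(suppressWarnings(d_prime(im, margin = "fungi")), na.rm = TRUE)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > 0))

  # C-score increases with ranking noise (NODF decreases; tested in the
  # nestedness file): positive rank correlation over a reduced grid
  levels <- seq(0, 1, length.out = 6)
  cs <- c(); xs <- c()
  for (eps in levels) for (s in 1:4) {
    im <- generate_interaction_matrix(synthetic_config(
      n_hosts = 8, n_fungi = 60, plots_per_host = 3, reads_per_sample = 2000,
      epsilon = eps, seed = 300 * s + round(10 * eps)))
    cs <- c(cs, c_score(binary_view(im), "fungi"))
    xs <- c(xs, eps)
  }
  ct <- suppressWarnings(cor.test(xs, cs, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
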