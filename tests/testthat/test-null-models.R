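test_that("EE null preserves fill exactly and spreads presences uniformly", {
  set.seed(41)
  b <- random_binary(4, 6, 0.4)
  reps <- ee_null(b, reps = 200, seed = 2)
  expect_length(reps, 200)
  expect_true(all(vapply(reps, sum, numeric(1)) == sum(b)))

  # degenerate full matrix: every replicate is the matrix itself
  full <- matrix(1, 3, 3)
  expect_true(all(vapply(ee_null(full, 20, 1), identical, logical(1), full)))

  # per-cell occupancy frequency matches the binomial expectation F/(mn)
  b2 <- random_binary(3, 5, 0.5)
  p <- sum(b2) / 15
  nrep <- 3000
  occ <- Reduce(`+`, ee_null(b2, nrep, 7)) / nrep
  se <- sqrt(p * (1 - p) / nrep)
  expect_true(all(abs(occ - p) < 3.5 * se))
})

test_that("FF null follows its cell probabilities and fill expectation", {
  set.seed(42)
  b <- random_binary(4, 5, 0.5)
  p <- ff_cell_probabilities(b)
  # algebraic identity: expected fill equals observed fill
  expect_equal(sum(p), sum(b))
  expect_true(all(p >= 0 & p <= 1))

  # all-ones input is a fixed point
  ones <- matrix(1, 3, 4)
  expect_true(all(vapply(ff_null(ones, 10, 1), identical, logical(1), ones)))

  # Monte-Carlo per-cell frequency against the closed form
  nrep <- 3000
  freq <- Reduce(`+`, ff_null(b, nrep, 9)) / nrep
  se <- sqrt(p * (1 - p) / nrep)
  expect_true(all(abs(freq - p) < 3.5 * pmax(se, 1e-6)))
  # mean fill across replicates near F
  fills <- vapply(ff_null(b, 2000, 11), sum, numeric(1))
  expect_lt(abs(mean(fills) - sum(b)), 3.5 * sd(fills) / sqrt(2000))
})

test_that("swap-web null preserves marginals and fill on every replicate", {
  set.seed(43)
  for (k in 1:3) {
    w <- random_weights(4, 5, lambda = 3)
    reps <- swap_web_null(w, reps = 40, seed = k)
    expect_length(reps, 40)
    for (r in reps) {
      expect_equal(rowSums(r), rowSums(w), ignore_attr = TRUE)
      expect_equal(colSums(r), colSums(w), ignore_attr = TRUE)
      expect_equal(sum(r > 0), sum(w > 0))
      expect_true(all(r >= 0) && all(r == round(r)))
    }
  }
})

test_that("swap-web replicates are confined to the enumerable contract set", {
  # marginals (2,1)/(2,1) with fill 3: the only integer table satisfying the
  # contract is the observed one
  w <- rbind(c(1, 1), c(1, 0))
  reps <- swap_web_null(w, reps = 25, seed = 3)
  expect_true(all(vapply(reps, function(r) all(r == w), logical(1))))

  # 1x1 degenerate matrix: only itself
  one <- matrix(5, 1, 1)
  expect_true(all(vapply(swap_web_null(one, 5, 1), identical, logical(1), one)))
})

test_that("null ensembles are deterministic given seed and scheme", {
  set.seed(44)
  w <- random_weights(4, 5)
  for (scheme in c("EE", "FF", "SWAP_WEB")) {
    a <- null_test(w, "nodf", scheme, reps = 30, seed = 99)
    b <- null_test(w, "nodf", scheme, reps = 30, seed = 99)
    expect_identical(a$nulls, b$nulls)
    expect_identical(a$obs, b$obs)
  }
})

test_that("null_test reports add-one empirical P and undefined z when sd = 0", {
  set.seed(45)
  b <- random_binary(4, 5, 0.5)
  # constant statistic: obs equals every null
  expect_warning(
    ne <- null_test(b, function(w) 1, "EE", reps = 99, seed = 1),
    "sd is 0")
  expect_true(is.na(ne$z))
  expect_equal(ne$p_upper, 1)
  expect_equal(ne$p_lower, 1)

  # perfectly nested staircase beats every EE null: add-one rule
  stair <- nested_staircase(6)
  ne2 <- null_test(stair, "nodf", "EE", reps = 999, seed = 5)
  expect_equal(ne2$obs, 100)
  expect_equal(ne2$p_upper, 1 / 1000)
  expect_lt(ne2$p_upper, 0.05)
  expect_gt(ne2$z, 2)
})

test_that("link z-scores recover a planted over-weighted link", {
  w <- matrix(3, 4, 4, dimnames = list(paste0("h", 1:4), paste0("f", 1:4)))
  w[1, 1] <- 30
  lz <- link_zscores(interaction_matrix(w), reps = 400, seed = 6)
  expect_gt(lz$z[1, 1], 1.96)
  expect_true(lz$significant[1, 1])

  # significance uses strict inequality at the threshold
  fake <- lz
  expect_identical(unname(lz$significant), unname(!is.na(lz$z) & abs(lz$z) > 1.96))
})

test_that("uniform fixtures are almost never flagged (type-I control of link tests)", {
  flags <- vapply(1:10, function(s) {
    w <- matrix(4, 4, 4)
    lz <- link_zscores(w, reps = 199, seed = s)
    sum(lz$significant, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(flags == 0), 0.9)
})

test_that("per-species d' z-scores cover every species on the chosen margin", {
  set.seed(46)
  im <- generate_interaction_matrix(synthetic_config(
    n_hosts = 4, n_fungi = 10, plots_per_host = 2, reads_per_sample = 400,
    seed = 8))
  dz <- suppressWarnings(dprime_zscores(im, margin = "fungi", reps = 99, seed = 9))
  expect_equal(nrow(dz), ncol(im))
  # single-interaction species are undefined (NA); all others in [0, 1]
  ok <- !is.na(dz$dprime)
  expect_true(all(dz$dprime[ok] >= 0 & dz$dprime[ok] <= 1))
  expect_true(all(is.na(dz$dprime[!ok]) | dz$degree[!ok] == 1))
  expect_setequal(names(dz)[1:4], c("species", "degree", "dprime", "null_mean"))
  dzh <- suppressWarnings(dprime_zscores(im, margin = "hosts", reps = 99, seed = 9))
  expect_equal(nrow(dzh), nrow(im))
})
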