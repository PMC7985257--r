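test_that("reading a counts/metadata pair round-trips and validates", {
  ot <- tiny_otu_table()
  cdir <- withr::local_tempdir()
  cp <- file.path(cdir, "counts.tsv"); mp <- file.path(cdir, "meta.tsv")
  write_otu_table(ot, cp, mp)
  back <- read_otu_table(cp, mp)
  expect_identical(back$counts, ot$counts)
  expect_identical(back$metadata, ot$metadata)
  expect_equal(unname(sample_totals(back)), rowSums(ot$counts), ignore_attr = TRUE)

  # negative count names the offending cell
  counts <- ot$counts; counts["s2", "otu3"] <- -1
  expect_error(otu_table(counts, ot$metadata), "s2.*otu3")

  # missing metadata names the sample
  expect_error(otu_table(ot$counts, ot$metadata[-2, ]), "s2")

  # ragged counts file is a hard error
  writeLines(c("sample\to1\to2", "s1\t1\t2", "s2\t3"), cp)
  expect_error(read_otu_table(cp, mp), "ragged")
})

test_that("rare-OTU filter removes strictly below the grand-total fraction", {
  # grand total 10,000; threshold at fraction 1e-3 is 10 reads:
  # an OTU with 9 reads goes, one with exactly 10 stays
  counts <- matrix(c(9981, 9, 10), 1, 3,
                   dimnames = list("s1", c("big", "nine", "ten")))
  counts <- rbind(counts, 0)
  rownames(counts) <- c("s1", "s2")
  meta <- data.frame(sample = c("s1", "s2"), host = c("hA", "hB"),
                     site = "rural", plot = "p1")
  ot <- otu_table(counts, meta)
  f <- filter_rare_otus(ot, 1e-3)
  expect_setequal(colnames(f$counts), c("big", "ten"))
  expect_identical(attr(f, "removed_otus"), "nine")

  # fraction 0 is a no-op
  expect_identical(filter_rare_otus(ot, 0)$counts, ot$counts)

  # a single remaining OTU always holds 100% of reads: never removable
  one <- otu_table(matrix(5, 1, 1, dimnames = list("s1", "otu1")),
                   meta[1, ])
  expect_identical(filter_rare_otus(one, 0.5)$counts, one$counts)

  # idempotence: re-filtering the filtered table changes nothing
  expect_identical(filter_rare_otus(f, 1e-3)$counts, f$counts)
})

test_that("low-depth exclusion drops exactly the below-threshold samples", {
  counts <- diag(c(3, 7, 4227, 5000))
  dimnames(counts) <- list(paste0("s", 1:4), paste0("otu", 1:4))
  meta <- data.frame(sample = paste0("s", 1:4), host = paste0("h", 1:4),
                     site = "urban", plot = "p1")
  ot <- otu_table(counts, meta)
  kept <- exclude_low_depth_samples(ot, 4227)
  expect_identical(rownames(kept$counts), c("s3", "s4"))
  expect_identical(attr(kept, "dropped_samples"), c("s1", "s2"))
  expect_identical(exclude_low_depth_samples(ot, 1)$counts, ot$counts)
  expect_error(exclude_low_depth_samples(ot, 10000), "every sample")
})

test_that("rarefaction conserves depth, is seed-deterministic, and matches the urn draw", {
  ot <- tiny_otu_table()
  expect_error(rarefy_table(ot, 11), "s1")  # sample below depth is named

  # total = depth leaves every sample untouched (subsample of everything)
  expect_identical(rarefy_table(ot, 10, seed = 1)$counts, ot$counts)

  r1 <- rarefy_table(ot, 8, seed = 42)
  expect_true(all(sample_totals(r1) == 8))
  expect_true(all(r1$counts <= ot$counts))
  expect_identical(rarefy_table(ot, 8, seed = 42)$counts, r1$counts)
  expect_false(identical(rarefy_table(ot, 8, seed = 43)$counts, r1$counts))

  # per-OTU subsample frequencies match the hypergeometric expectation:
  # sample (6, 4, 10) rarefied to 5; E[count_i] = 5 * n_i / 20
  counts <- matrix(c(6, 4, 10), 1, 3, dimnames = list("s1", c("a", "b", "c")))
  ot1 <- otu_table(counts, data.frame(sample = "s1", host = "h", site = "rural",
                                      plot = "p"))
  draws <- t(vapply(1:4000, function(s) rarefy_table(ot1, 5, seed = s)$counts[1, ],
                    numeric(3)))
  expected <- 5 * c(6, 4, 10) / 20
  se <- sqrt(5 * (c(6, 4, 10) / 20) * (1 - c(6, 4, 10) / 20) * (20 - 5) / (20 - 1) / 4000)
  expect_true(all(abs(colMeans(draws) - expected) < 3 * se))
})

test_that("aggregation pools replicate samples per host at one site", {
  ot <- tiny_otu_table("rural")
  im <- aggregate_to_network(ot, "rural")
  expect_s3_class(im, "interaction_matrix")
  # additivity: host A's otu1 weight is the sum over its two samples
  expect_equal(unclass(im)["hostA", "otu1"], 5 + 4)
  # conservation of the total per (host, site) stratum
  expect_equal(sum(im), sum(ot$counts))

  # OTUs present only at the other site are absent; all-zero columns dropped
  counts <- ot$counts; counts[, "otu4"] <- 0
  ot0 <- otu_table(counts, ot$metadata)
  expect_false("otu4" %in% colnames(aggregate_to_network(ot0, "rural")))

  expect_error(aggregate_to_network(ot, "urban"), "no samples")
  one_host <- otu_table(ot$counts[1:2, ], ot$metadata[1:2, ])
  expect_error(aggregate_to_network(one_host, "rural"), "2 host")
})

test_that("interaction matrices round-trip through TSV", {
  set.seed(1)
  for (k in 1:3) {
    w <- random_weights(3 + k, 4)
    dimnames(w) <- list(paste0("h", seq_len(nrow(w))), paste0("f", 1:4))
    im <- interaction_matrix(w)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_interaction_matrix(im, path)
    back <- read_interaction_matrix(path)
    expect_equal(unclass(back), unclass(im), ignore_attr = TRUE)
    expect_identical(dimnames(back), dimnames(im))
  }
  expect_error(read_interaction_matrix(withr::local_tempfile()), "not found")
})

test_that("synthetic aggregation recovers the generator's host count", {
  st <- tiny_study(seed = 5)
  im <- aggregate_to_network(st$combined, "rural")
  expect_equal(nrow(im), 4)
  expect_true(all(marginal_totals(im, "hosts") == 2 * 300))
})
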