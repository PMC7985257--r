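# Shared fixture builders. All fixtures are generated in code.

# Random binary matrix with no all-zero row or column.
random_binary <- function(m, n, p = 0.5) {
  repeat {
    b <- matrix(rbinom(m * n, 1, p), m, n)
    if (all(rowSums(b) > 0) && all(colSums(b) > 0)) return(b)
  }
}

# Random small quantitative matrix with no empty row/column.
random_weights <- function(m, n, lambda = 2) {
  repeat {
    w <- matrix(rpois(m * n, lambda), m, n)
    if (all(rowSums(w) > 0) && all(colSums(w) > 0)) return(w)
  }
}

# Perfectly nested staircase with strictly decreasing marginals.
nested_staircase <- function(k) {
  b <- matrix(0, k, k)
  for (i in seq_len(k)) b[i, seq_len(k - i + 1)] <- 1
  b
}

# Small OTU table: 4 samples (2 hosts x 2 plots) at one site.
tiny_otu_table <- function(site = "rural") {
  counts <- matrix(c(5, 3, 0, 2,
                     4, 4, 1, 1,
                     0, 6, 3, 1,
                     1, 5, 4, 0), 4, 4, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4), paste0("otu", 1:4)))
  meta <- data.frame(sample = paste0("s", 1:4),
                     host = rep(c("hostA", "hostB"), each = 2),
                     site = site, plot = rep(c("p1", "p2"), 2),
                     stringsAsFactors = FALSE)
  otu_table(counts, meta)
}

# 4-tip caterpillar tree with fixed branch lengths.
caterpillar_tree <- function() {
  ape::read.tree(text = "(((a:1,b:2):0.5,c:1.5):0.25,d:3):0;")
}

# Tiny study whose scale keeps pipeline tests fast.
tiny_study <- function(seed = 1) {
  generate_two_site_study(
    rural_config(seed = seed, n_hosts = 4, n_fungi = 12, plots_per_host = 2,
                 reads_per_sample = 300),
    urban_config(seed = seed, n_hosts = 4, n_fungi = 12, plots_per_host = 2,
                 reads_per_sample = 300))
}

tiny_analysis_config <- function(seed = 1, ...) {
  analysis_config(min_reads = 300, rarefaction_depth = 300, nodf_reps = 49,
                  nodfc_reps = 19, swap_reps = 49, optimizer_restarts = 2,
                  optimizer_moves = 300, seed = seed, ...)
}
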