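# Independent brute-force oracles, written as plain loops so they share no
# code path with the package internals they check.

# NODF by explicit pair enumeration.
oracle_nodf <- function(b) {
  score_pairs <- function(mat) {
    n <- nrow(mat)
    mt <- apply(mat, 1, sum)
    total <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (mt[i] == mt[j]) next
      lo <- if (mt[i] < mt[j]) i else j
      hi <- if (mt[i] < mt[j]) j else i
      if (mt[lo] == 0) next
      shared <- sum(mat[lo, ] == 1 & mat[hi, ] == 1)
      total <- total + 100 * shared / mt[lo]
    }
    total
  }
  (score_pairs(b) + score_pairs(t(b))) /
    (choose(nrow(b), 2) + choose(ncol(b), 2))
}

# Normalized C-score by explicit pair enumeration over the chosen margin.
oracle_cscore <- function(b, margin = "fungi") {
  m <- if (margin == "fungi") t(b) else b
  k <- nrow(m)
  vals <- c()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ri <- sum(m[i, ]); rj <- sum(m[j, ])
    s <- sum(m[i, ] == 1 & m[j, ] == 1)
    vals <- c(vals, (ri - s) * (rj - s) / (ri * rj))
  }
  mean(vals)
}

# All compositions of total A into n non-negative parts (rows of a matrix).
oracle_compositions <- function(A, n) {
  if (n == 1) return(matrix(A, 1, 1))
  out <- NULL
  for (v in 0:A) {
    rest <- oracle_compositions(A - v, n - 1)
    out <- rbind(out, cbind(v, rest))
  }
  unname(out)
}

# d' by exhaustive search over all integer reallocations of the species
# total, with availability q fixed at the observed matrix's column shares.
oracle_dprime <- function(w, i, margin = "hosts") {
  if (margin == "fungi") w <- t(w)
  q <- apply(w, 2, sum) / sum(w)
  a <- w[i, ]
  A <- sum(a)
  kl <- function(v) {
    p <- v / A
    sum(ifelse(p > 0, p * log(p / q), 0))
  }
  d_i <- kl(a)
  allocs <- oracle_compositions(A, length(q))
  ds <- apply(allocs, 1, kl)
  d_min <- min(ds); d_max <- max(ds)
  if (d_max - d_min <= 0) return(NA_real_)
  (d_i - d_min) / (d_max - d_min)
}

# All integer tables with the given margins, via row-wise composition
# recursion (independent of the package's enumerator).
oracle_margin_tables <- function(r, cc) {
  out <- list()
  build <- function(rows_done, rem_c) {
    i <- length(rows_done) + 1
    if (i > length(r)) {
      out[[length(out) + 1]] <<- do.call(rbind, rows_done)
      return(invisible(NULL))
    }
    comps <- oracle_compositions(r[i], length(cc))
    ok <- apply(comps, 1, function(row) all(row <= rem_c))
    for (k in which(ok))
      build(c(rows_done, list(comps[k, ])), rem_c - comps[k, ])
  }
  build(list(), cc)
  out
}

oracle_entropy <- function(tab) {
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log(p))
}

# H2' with exact entropy extremes from exhaustive table enumeration.
oracle_h2prime <- function(w) {
  tabs <- oracle_margin_tables(apply(w, 1, sum), apply(w, 2, sum))
  ents <- vapply(tabs, oracle_entropy, numeric(1))
  (max(ents) - oracle_entropy(w)) / (max(ents) - min(ents))
}

# Faith's PD by explicit edge enumeration: an edge counts when any present
# tip lies below it (root-inclusive).
oracle_faith <- function(tree, present) {
  tips_below <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    below <- tips_below(tree$edge[e, 2])
    if (any(below %in% present)) total <- total + tree$edge.length[e]
  }
  total
}

# Exhaustive max-NODF: every placement of `fill` ones with no empty line.
oracle_max_nodf <- function(m, n, fill, value_fn = oracle_nodf) {
  best <- -1
  combos <- utils::combn(m * n, fill)
  for (k in seq_len(ncol(combos))) {
    b <- matrix(0, m, n)
    b[combos[, k]] <- 1
    if (any(apply(b, 1, sum) == 0) || any(apply(b, 2, sum) == 0)) next
    v <- value_fn(b)
    if (v > best) best <- v
  }
  best
}
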