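#' Species degree: number of distinct partners
#'
#' @param x [interaction_matrix] or matrix (binary or quantitative; any
#'   positive weight is a link).
#' @param margin `"hosts"` (rows) or `"fungi"` (columns).
#' @return named integer vector of per-species link counts, ranging 1
#'   (specialist) to the number of partners (generalist).
#' @export
species_degree <- function(x, margin = c("hosts", "fungi")) {
  margin <- match.arg(margin)
  b <- binary_view(x)
  if (margin == "hosts") rowSums(b) else colSums(b)
}

#' Frequency table of species degrees
#'
#' @inheritParams species_degree
#' @return data.frame with columns `degree` (1..number of partners) and
#'   `frequency`; frequencies sum to the species count on the margin.
#' @export
degree_distribution <- function(x, margin = c("hosts", "fungi")) {
  margin <- match.arg(margin)
  d <- species_degree(x, margin)
  b <- binary_view(x)
  max_deg <- if (margin == "hosts") ncol(b) else nrow(b)
  data.frame(degree = seq_len(max_deg),
             frequency = as.integer(tabulate(d, nbins = max_deg)))
}

#' Network connectance
#'
#' Realized fraction of possible links, `C = fill / (m * n)`.
#'
#' @param x [interaction_matrix] or matrix.
#' @export
connectance <- function(x) {
  w <- as_weight_matrix(x)
  sum(w > 0) / length(w)
}

# ---- Kullback-Leibler specialization (d', H2') ---------------------------

# KL objective of an integer allocation `a` of total A over partners with
# availabilities q (all > 0): sum over a>0 of (a/A) * log((a/A)/q).
kl_objective <- function(a, A, q) {
  pos <- a > 0
  sum((a[pos] / A) * log((a[pos] / A) / q[pos]))
}

# Exact minimizer of the KL objective over integer allocations summing to A.
# The objective is separable convex on the integer simplex, so largest-
# remainder rounding of the continuous optimum (a = A q) followed by
# single-unit exchange descent terminates at the global minimum.
kl_min_allocation <- function(A, q) {
  n <- length(q)
  target <- A * q
  a <- floor(target)
  rem <- as.integer(round(A - sum(a)))
  if (rem > 0) {
    frac <- target - a
    a[order(frac, decreasing = TRUE)[seq_len(rem)]] <- a[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  f <- function(v, j) if (v <= 0) 0 else (v / A) * log((v / A) / q[j])
  for (iter in seq_len(10 * n + as.integer(A))) {
    add <- vapply(seq_len(n), function(j) f(a[j] + 1, j) - f(a[j], j), numeric(1))
    rem_d <- vapply(seq_len(n), function(j)
      if (a[j] >= 1) f(a[j] - 1, j) - f(a[j], j) else Inf, numeric(1))
    k <- which.min(add); j <- which.min(rem_d)
    if (j == k) {  # best donor equals best receiver: pick next-best receiver
      add[k] <- Inf
      k <- which.min(add)
    }
    if (!is.finite(rem_d[j]) || add[k] + rem_d[j] >= -1e-12) break
    a[j] <- a[j] - 1
    a[k] <- a[k] + 1
  }
  a
}

# Enumerate all compositions of A into n non-negative parts (oracle-grade
# exhaustive search); `cap` bounds the enumeration size.
kl_min_exact <- function(A, q) {
  n <- length(q)
  best <- Inf
  recurse <- function(prefix, remaining, depth) {
    if (depth == n) {
      a <- c(prefix, remaining)
      v <- kl_objective(a, A, q)
      if (v < best) best <<- v
      return(invisible(NULL))
    }
    for (v in 0:remaining) recurse(c(prefix, v), remaining - v, depth + 1)
  }
  recurse(integer(0), A, 1)
  best
}

#' Species-level specialization d'
#'
#' Kullback-Leibler specialization of a species' partner use against partner
#' availability. For species i with interaction shares
#' `p'_ij = a_ij / A_i` and availabilities `q_j` (partner marginal totals over
#' the grand total), `d_i = sum_j p'_ij ln(p'_ij / q_j)`; it is rescaled as
#' `d' = (d_i - d_min) / (d_max - d_min)` to `[0, 1]` (0 = perfect
#' generalist using partners in proportion to availability, 1 = maximal
#' specialist). `d_max = ln(1 / min q)` is the analytic extreme (all
#' interactions on the least-available partner); `d_min` is the minimum of
#' `d_i` over integer reallocations of the species' total, found by exact
#' exchange descent (`method = "search"`, the default for all but tiny
#' totals) or exhaustive enumeration (`method = "exact"`).
#'
#' @param x [interaction_matrix] or quantitative matrix.
#' @param species species label or index on the margin, or `NULL` for every
#'   species.
#' @param margin `"hosts"` (rows) or `"fungi"` (columns).
#' @param method `"auto"`, `"search"` (exchange descent) or `"exact"`
#'   (exhaustive over all integer reallocations; only feasible for small
#'   totals).
#' @param detailed if `TRUE` (single species only) return a list with the
#'   intermediates `d_i`, `d_min`, `d_max`, `p`, `q`.
#' @return named numeric vector of d' values in `[0, 1]` (or a detailed
#'   list). Degenerate one-partner networks give the undefined marker `NA`
#'   with a warning.
#' @export
d_prime <- function(x, species = NULL, margin = c("hosts", "fungi"),
                    method = c("auto", "search", "exact"), detailed = FALSE) {
  margin <- match.arg(margin)
  method <- match.arg(method)
  w <- as_weight_matrix(x)
  if (margin == "fungi") w <- t(w)
  q <- colSums(w) / sum(w)
  if (any(q == 0)) stop("partner with zero marginal total; drop empty species",
                        call. = FALSE)
  labs <- rownames(w)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(w)))
  rows <- if (is.null(species)) seq_len(nrow(w)) else {
    i <- if (is.character(species)) match(species, labs) else as.integer(species)
    if (any(is.na(i)) || any(i < 1) || any(i > nrow(w)))
      stop("unknown species: ", species, call. = FALSE)
    i
  }
  d_max <- log(1 / min(q))
  one <- function(i) {
    a <- w[i, ]
    A <- sum(a)
    if (A == 0) stop("species '", labs[i], "' has no interactions", call. = FALSE)
    d_i <- kl_objective(a, A, q)
    if (d_max <= 0)
      return(list(dprime = undefined_value(
        "d' is undefined for a degenerate one-partner network"),
        d_i = d_i, d_min = 0, d_max = d_max))
    use_exact <- method == "exact" ||
      (method == "auto" && choose(A + length(q) - 1, length(q) - 1) <= 5000)
    d_min <- if (use_exact) kl_min_exact(as.integer(A), q)
             else kl_objective(kl_min_allocation(A, q), A, q)
    if (d_max - d_min <= 1e-12)
      return(list(dprime = undefined_value(
        "d' is undefined: allocation extremes coincide (single-interaction species)"),
        d_i = d_i, d_min = d_min, d_max = d_max, p = a / A, q = q))
    dp <- (d_i - d_min) / (d_max - d_min)
    list(dprime = min(1, max(0, dp)), d_i = d_i, d_min = d_min, d_max = d_max,
         p = a / A, q = q)
  }
  if (detailed) {
    if (length(rows) != 1) stop("detailed = TRUE needs a single species", call. = FALSE)
    return(one(rows))
  }
  out <- vapply(rows, function(i) one(i)$dprime, numeric(1))
  names(out) <- labs[rows]
  out
}

# ---- network-level H2' ----------------------------------------------------

# Shannon entropy of a quantitative table (natural log, in nats).
table_entropy <- function(tab) {
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log(p))
}

# Largest-remainder rounding of the independence expectation r c'/T to an
# integer table with exact margins (start for entropy maximization).
proportional_integer_table <- function(r, cc) {
  T <- sum(r)
  expd <- outer(r, cc) / T
  a <- floor(expd)
  dr <- r - rowSums(a)
  dc <- cc - colSums(a)
  frac <- expd - a
  while (sum(dr) > 0) {
    cand <- which(outer(dr > 0, dc > 0, "&"), arr.ind = TRUE)
    pick <- cand[which.max(frac[cand]), , drop = FALSE]
    a[pick] <- a[pick] + 1
    dr[pick[1]] <- dr[pick[1]] - 1
    dc[pick[2]] <- dc[pick[2]] - 1
  }
  a
}

# Greedy most-specialized filling: repeatedly allocate min(remaining row,
# remaining column) to the currently largest row/column — concentrates mass
# and minimizes entropy. Randomized tie-breaking for restarts.
specialized_integer_table <- function(r, cc, randomize = FALSE) {
  a <- matrix(0, length(r), length(cc))
  rem_r <- r; rem_c <- cc
  pick <- function(rem) {
    pos <- which(rem > 0)
    if (!randomize || length(pos) == 1 || stats::runif(1) < 0.5) {
      cand <- pos[rem[pos] == max(rem[pos])]
      if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
    } else {
      # weighted random pairing explores row/column matchings the strict
      # greedy never tries
      pos[sample.int(length(pos), 1, prob = rem[pos]^2)]
    }
  }
  while (sum(rem_r) > 0) {
    i <- if (randomize) pick(rem_r) else which.max(rem_r)
    j <- if (randomize) pick(rem_c) else which.max(rem_c)
    amt <- min(rem_r[i], rem_c[j])
    a[i, j] <- a[i, j] + amt
    rem_r[i] <- rem_r[i] - amt
    rem_c[j] <- rem_c[j] - amt
  }
  a
}

# Local search over the transportation polytope with 2x2 cycle moves, using
# O(1) local entropy deltas. direction = +1 maximizes entropy (unit steps
# suffice directionally: the objective is concave along any cycle),
# direction = -1 minimizes it (extreme transfers tried as well). Small
# matrices get exhaustive improving-move sweeps until a clean pass; larger
# ones use random proposals.
entropy_local_search <- function(a, direction, proposals = 4000) {
  m <- nrow(a); n <- ncol(a)
  if (m < 2 || n < 2) return(a)
  T <- sum(a)
  f <- function(v) { out <- numeric(length(v)); pos <- v > 0
    out[pos] <- -(v[pos] / T) * log(v[pos] / T); out }
  candidate_ts <- function(a11, a12, a21, a22) {
    c(if (min(a12, a21) >= 1) 1, if (min(a11, a22) >= 1) -1,
      if (direction < 0 && min(a12, a21) > 1) min(a12, a21),
      if (direction < 0 && min(a11, a22) > 1) -min(a11, a22))
  }
  delta <- function(a11, a12, a21, a22, t) {
    sum(f(c(a11 + t, a22 + t, a12 - t, a21 - t))) -
      sum(f(c(a11, a12, a21, a22)))
  }
  apply_move <- function(i1, i2, j1, j2, t) {
    a[i1, j1] <<- a[i1, j1] + t; a[i2, j2] <<- a[i2, j2] + t
    a[i1, j2] <<- a[i1, j2] - t; a[i2, j1] <<- a[i2, j1] - t
  }
  if (m * n <= 200) {
    for (sweep in 1:200) {
      improved <- FALSE
      for (i1 in 1:(m - 1)) for (i2 in (i1 + 1):m)
        for (j1 in 1:(n - 1)) for (j2 in (j1 + 1):n) {
          repeat {
            a11 <- a[i1, j1]; a12 <- a[i1, j2]
            a21 <- a[i2, j1]; a22 <- a[i2, j2]
            ts <- candidate_ts(a11, a12, a21, a22)
            if (is.null(ts)) break
            ds <- vapply(ts, function(t) delta(a11, a12, a21, a22, t), numeric(1))
            k <- which.max(direction * ds)
            if (direction * ds[k] <= 1e-12) break
            apply_move(i1, i2, j1, j2, ts[k])
            improved <- TRUE
          }
        }
      if (!improved) break
    }
  } else {
    for (it in seq_len(proposals)) {
      i <- sample.int(m, 2); j <- sample.int(n, 2)
      a11 <- a[i[1], j[1]]; a12 <- a[i[1], j[2]]
      a21 <- a[i[2], j[1]]; a22 <- a[i[2], j[2]]
      ts <- candidate_ts(a11, a12, a21, a22)
      if (is.null(ts)) next
      for (t in ts) {
        if (direction * delta(a11, a12, a21, a22, t) > 1e-12) {
          apply_move(i[1], i[2], j[1], j[2], t)
          break
        }
      }
    }
  }
  a
}

# Enumerate all non-negative integer tables with the given margins; returns
# NULL if more than `cap` tables exist.
enumerate_margin_tables <- function(r, cc, cap = 20000) {
  m <- length(r); n <- length(cc)
  out <- list()
  count <- 0
  aborted <- FALSE
  rec_row <- function(tab, i, rem_c) {
    if (aborted) return(invisible(NULL))
    if (i > m) {
      count <<- count + 1
      if (count > cap) { aborted <<- TRUE; return(invisible(NULL)) }
      out[[count]] <<- tab
      return(invisible(NULL))
    }
    # enumerate compositions of r[i] within remaining column capacities
    comp <- function(prefix, remaining, j) {
      if (aborted) return(invisible(NULL))
      if (j == n) {
        if (remaining <= rem_c[n]) {
          row <- c(prefix, remaining)
          tab2 <- tab; tab2[i, ] <- row
          rec_row(tab2, i + 1, rem_c - row)
        }
        return(invisible(NULL))
      }
      for (v in 0:min(remaining, rem_c[j])) comp(c(prefix, v), remaining - v, j + 1)
    }
    comp(integer(0), r[i], 1)
  }
  rec_row(matrix(0, m, n), 1, cc)
  if (aborted) NULL else out
}

#' Network-level specialization H2'
#'
#' Two-dimensional Shannon entropy of the interaction frequency distribution,
#' standardized against its extremes at fixed marginal totals:
#' `H2' = (H2_max - H2) / (H2_max - H2_min)` with
#' `H2 = -sum (a_ij / T) ln(a_ij / T)`. `H2_max` corresponds to the most
#' generalized integer table (marginal-proportional expectation, found by
#' largest-remainder rounding plus entropy-increasing 2x2 moves) and `H2_min`
#' to the most specialized one (greedy concentrated filling with randomized
#' restarts plus entropy-decreasing moves). 0 means interactions match the
#' random expectation given the marginals; 1 means maximal specialization.
#' Small instances are solved exactly by enumerating all tables with the
#' observed margins.
#'
#' @param x [interaction_matrix] or quantitative matrix with grand total
#'   >= 2.
#' @param method `"auto"` (exact when the margin-constrained table space is
#'   small), `"search"`, or `"exact"`.
#' @param restarts randomized greedy restarts for the `H2_min` heuristic.
#' @param proposals local-search proposals per start.
#' @param seed RNG seed for the stochastic search.
#' @return object of class `h2_result`: list with `H2prime`, `H2`, `H2_min`,
#'   `H2_max`, `method`. Values outside `[0, 1]` from heuristic overshoot are
#'   clamped with a warning. Single-cell matrices give the undefined marker.
#' @export
h2_prime <- function(x, method = c("auto", "search", "exact"), restarts = 100,
                     proposals = 4000, seed = 1L) {
  method <- match.arg(method)
  w <- as_weight_matrix(x)
  if (length(w) == 1 || sum(w) < 2 || nrow(w) < 2 || ncol(w) < 2) {
    val <- undefined_value("H2' is undefined for a single-cell or near-empty matrix")
    out <- list(H2prime = val, H2 = table_entropy(w), H2_min = NA_real_,
                H2_max = NA_real_, method = "degenerate")
    class(out) <- "h2_result"
    return(out)
  }
  r <- rowSums(w); cc <- colSums(w)
  H2 <- table_entropy(w)
  tables <- NULL
  if (method != "search") {
    # exact route only worth attempting for small totals/dimensions
    if (method == "exact" || (sum(w) <= 40 && length(w) <= 20))
      tables <- enumerate_margin_tables(r, cc)
    if (method == "exact" && is.null(tables))
      stop("exact H2' enumeration exceeds the enumeration cap", call. = FALSE)
  }
  if (!is.null(tables)) {
    ents <- vapply(tables, table_entropy, numeric(1))
    H2_max <- max(ents); H2_min <- min(ents)
    used <- "exact"
  } else {
    res <- with_seed(seed, {
      hi <- entropy_local_search(proportional_integer_table(r, cc), +1, proposals)
      best_lo <- Inf
      for (s in seq_len(restarts)) {
        lo <- specialized_integer_table(r, cc, randomize = s > 1)
        lo <- entropy_local_search(lo, -1, proposals %/% 4)
        best_lo <- min(best_lo, table_entropy(lo))
      }
      c(table_entropy(hi), best_lo)
    })
    H2_max <- res[1]; H2_min <- res[2]
    used <- "search"
  }
  if (H2_max - H2_min <= 1e-12) {
    val <- undefined_value("H2' is undefined: entropy extremes coincide for these marginals")
  } else {
    val <- (H2_max - H2) / (H2_max - H2_min)
    if (val < -1e-9 || val > 1 + 1e-9)
      warning(sprintf("H2' heuristic overshoot (raw %.6f); clamped to [0, 1]", val),
              call. = FALSE)
    val <- min(1, max(0, val))
  }
  out <- list(H2prime = val, H2 = H2, H2_min = H2_min, H2_max = H2_max,
              method = used)
  class(out) <- "h2_result"
  out
}

#' @export
print.h2_result <- function(x, ...) {
  cat(sprintf("H2' = %.4f  (H2 %.4f, min %.4f, max %.4f; %s)\n",
              x$H2prime, x$H2, x$H2_min, x$H2_max, x$method))
  invisible(x)
}

#' Checkerboard C-score
#'
#' For every unordered pair of species on the chosen margin with presence
#' counts `r_i`, `r_j` and co-occurrence count `S_ij`, the checkerboard unit
#' count is `CU = (r_i - S_ij)(r_j - S_ij)`, normalized per pair by
#' `r_i * r_j`; the C-score is the mean over all pairs. It ranges 0 (complete
#' aggregation — any nested matrix scores 0, since the smaller species' sites
#' are a subset of the larger's) to 1 (perfect checkerboard segregation,
#' e.g. the 2x2 identity).
#'
#' @param x binary matrix or [interaction_matrix] of 0/1 values (binarize
#'   quantitative data upstream).
#' @param margin `"fungi"` (columns, default: fungal pairs compared across
#'   hosts) or `"hosts"`.
#' @return mean normalized checkerboard score in `[0, 1]`.
#' @export
c_score <- function(x, margin = c("fungi", "hosts")) {
  margin <- match.arg(margin)
  b <- as_binary_matrix(x)
  if (margin == "fungi") b <- t(b)
  r <- rowSums(b)
  if (any(r == 0))
    stop("species with zero presences; drop empty species first", call. = FALSE)
  if (nrow(b) < 2) stop("need at least 2 species on the margin", call. = FALSE)
  S <- tcrossprod(b)
  CU <- (outer(r, rep(1, length(r))) - S) * (outer(rep(1, length(r)), r) - S) /
    outer(r, r)
  mean(CU[upper.tri(CU)])
}
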