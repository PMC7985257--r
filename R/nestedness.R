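#' NODF nestedness of a binary bipartite matrix
#'
#' NODF (nestedness metric based on overlap and decreasing fill) scores every
#' unordered pair of rows and every unordered pair of columns. A pair
#' contributes its paired overlap `PO` — the percentage of the
#' smaller-marginal member's presences that coincide with the larger-marginal
#' member's presences — only when the two marginal totals differ strictly
#' (decreasing fill); equal-marginal pairs contribute 0. NODF is the mean
#' contribution over all `m(m-1)/2 + n(n-1)/2` pairs, ranging 0 (checkerboard)
#' to 100 (perfect nesting with strictly decreasing marginals). The score is
#' invariant under row/column permutations.
#'
#' @param x binary matrix (or [interaction_matrix] of 0/1 values) with
#'   `m >= 2` rows, `n >= 2` columns, and no all-zero row or column.
#'   Quantitative matrices must be binarized explicitly upstream (see
#'   [binary_view]).
#' @return object of class `nodf_result`: list with `NODF`, the per-pair
#'   ledger `pairs` (margin, member labels, marginal totals, overlap,
#'   `Npaired`), and the dimensions `m`, `n`.
#' @examples
#' b <- matrix(c(1,1,1, 1,1,0, 1,0,0), 3, 3, byrow = TRUE)
#' nodf(b)$NODF  # perfectly nested: 100
#' @export
nodf <- function(x) {
  b <- as_binary_matrix(x)
  if (nrow(b) < 2 || ncol(b) < 2)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  if (any(rowSums(b) == 0) || any(colSums(b) == 0))
    stop("all-zero row or column; drop empty species first", call. = FALSE)
  ledger <- rbind(nodf_pair_ledger(b, "rows"), nodf_pair_ledger(t(b), "columns"))
  res <- list(NODF = sum(ledger$Npaired) /
                (choose(nrow(b), 2) + choose(ncol(b), 2)),
              pairs = ledger, m = nrow(b), n = ncol(b))
  class(res) <- "nodf_result"
  res
}

#' @export
print.nodf_result <- function(x, ...) {
  cat(sprintf("NODF = %.4f (%d x %d matrix, %d pairs)\n",
              x$NODF, x$m, x$n, nrow(x$pairs)))
  invisible(x)
}

# Fast NODF score. allow_empty = TRUE relaxes the no-empty-line validation for
# null-model replicates (FF nulls may produce empty rows/columns); pairs
# involving an empty line contribute 0.
nodf_value <- function(b, allow_empty = FALSE) {
  m <- nrow(b); n <- ncol(b)
  if (!allow_empty && (any(rowSums(b) == 0) || any(colSums(b) == 0)))
    stop("all-zero row or column", call. = FALSE)
  (nodf_margin_sum(tcrossprod(b), rowSums(b)) +
   nodf_margin_sum(crossprod(b), colSums(b))) /
    (choose(m, 2) + choose(n, 2))
}

# Sum of Npaired over the upper triangle for one margin, given the
# co-occurrence matrix S and the marginal totals mt.
nodf_margin_sum <- function(S, mt) {
  lo <- outer(mt, mt, pmin)
  contrib <- 100 * S / ifelse(lo == 0, 1, lo)
  contrib[outer(mt, mt, "==") | lo == 0] <- 0
  sum(contrib[upper.tri(contrib)])
}

# Per-pair ledger for one margin ("rows": pairs of rows of b).
nodf_pair_ledger <- function(b, margin) {
  mt <- rowSums(b)
  S <- tcrossprod(b)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  lower <- pmin(mt[i], mt[j])
  df_paired <- ifelse(mt[i] != mt[j], 100, 0)
  po <- ifelse(lower > 0, 100 * S[idx] / pmax(lower, 1), 0)
  labs <- rownames(b)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(b)))
  data.frame(margin = margin, a = labs[i], b = labs[j],
             mt_a = mt[i], mt_b = mt[j], overlap = S[idx],
             PO = po, DF_paired = df_paired,
             Npaired = ifelse(df_paired == 100, po, 0),
             stringsAsFactors = FALSE)
}

#' Maximum NODF achievable at fixed size and fill
#'
#' Finds (or approximates) the largest NODF over binary `m x n` matrices with
#' exactly `fill` ones and no empty row or column — the normalizing constant
#' of [nodfc]. Instances with `m * n <= 16` cells are solved by exhaustive
#' enumeration; larger instances use a greedy nested-template construction
#' followed by stochastic hill climbing (single-cell moves) with restarts.
#' With the same `seed`, enlarging `moves` or `restarts` never lowers the
#' returned value.
#'
#' @param m,n matrix dimensions (>= 2).
#' @param fill number of ones; must satisfy `m + n - 1 <= fill <= m * n`.
#' @param method `"auto"` (exhaustive when `m * n <= 16`), `"exhaustive"`, or
#'   `"search"`.
#' @param restarts,moves search budget: number of restarts and of candidate
#'   single-cell moves per restart.
#' @param seed RNG seed for the stochastic search.
#' @return list with `value` (max NODF), `matrix` (an argmax matrix),
#'   `method`, and for the search path a `trace` of the best value per
#'   restart.
#' @export
max_nodf <- function(m, n, fill, method = c("auto", "exhaustive", "search"),
                     restarts = 10, moves = 5000, seed = 1L) {
  method <- match.arg(method)
  if (m < 2 || n < 2) stop("need m >= 2 and n >= 2", call. = FALSE)
  if (fill < m + n - 1 || fill > m * n)
    stop(sprintf("infeasible fill %d for a %d x %d matrix with no empty row/column",
                 fill, m, n), call. = FALSE)
  if (fill == m * n) {
    full <- matrix(1, m, n)
    return(list(value = 0, matrix = full, method = "degenerate",
                trace = numeric(0)))
  }
  if (method == "auto")
    method <- if (m * n <= 16) "exhaustive" else "search"
  if (method == "exhaustive") max_nodf_exhaustive(m, n, fill)
  else max_nodf_search(m, n, fill, restarts, moves, seed)
}

max_nodf_exhaustive <- function(m, n, fill) {
  best <- -1; best_mat <- NULL
  combos <- utils::combn(m * n, fill)
  for (k in seq_len(ncol(combos))) {
    b <- matrix(0, m, n)
    b[combos[, k]] <- 1
    if (any(rowSums(b) == 0) || any(colSums(b) == 0)) next
    v <- nodf_value(b)
    if (v > best) { best <- v; best_mat <- b }
  }
  list(value = best, matrix = best_mat, method = "exhaustive", trace = numeric(0))
}

# Left-packed nested template: row i carries ones in columns 1..k_i with
# non-increasing k, k_1 = n so no column is empty. Extra ones beyond the
# minimal staircase are distributed greedily (or randomly for restarts > 1).
nested_template <- function(m, n, fill, randomize = FALSE) {
  k <- c(n, rep(1L, m - 1L))
  extra <- fill - sum(k)
  while (extra > 0) {
    open <- which(k < c(n, k[-m]))  # rows that can grow, keeping k non-increasing
    open <- open[open > 1]
    if (length(open) == 0) break
    i <- if (randomize) open[sample.int(length(open), 1)] else open[1]
    add <- if (randomize) sample.int(min(extra, c(n, k[-m])[i] - k[i]), 1)
           else min(extra, c(n, k[-m])[i] - k[i])
    k[i] <- k[i] + add
    extra <- extra - add
  }
  b <- matrix(0, m, n)
  for (i in seq_len(m)) b[i, seq_len(k[i])] <- 1
  b
}

max_nodf_search <- function(m, n, fill, restarts, moves, seed) {
  best <- -1; best_mat <- NULL; trace <- numeric(restarts)
  random_move <- function(b) {
    ones <- which(b == 1); zeros <- which(b == 0)
    for (try in 1:20) {
      from <- ones[sample.int(length(ones), 1)]
      to <- zeros[sample.int(length(zeros), 1)]
      i <- (from - 1) %% m + 1; j <- (from - 1) %/% m + 1
      if (sum(b[i, ]) == 1 || sum(b[, j]) == 1) next
      b[from] <- 0; b[to] <- 1
      break
    }
    b
  }
  for (r in seq_len(restarts)) {
    res <- with_seed(child_seed(seed, r), {
      b <- nested_template(m, n, fill, randomize = r > 1)
      # later restarts perturb away from the template so the search explores
      # structurally different basins (the template is unique at minimal fill)
      if (r > 1) for (p in seq_len(5 * r)) b <- random_move(b)
      best_b <- b; best_v <- cur <- nodf_value(b)
      for (step in seq_len(moves)) {
        ones <- which(b == 1)
        zeros <- which(b == 0)
        from <- ones[sample.int(length(ones), 1)]
        to <- zeros[sample.int(length(zeros), 1)]
        i <- (from - 1) %% m + 1; j <- (from - 1) %/% m + 1
        if (sum(b[i, ]) == 1 || sum(b[, j]) == 1) next  # would empty a line
        b[from] <- 0; b[to] <- 1
        v <- nodf_value(b)
        # plateau moves are accepted occasionally to escape tie regions
        if (v > cur || (v == cur && stats::runif(1) < 0.25)) {
          cur <- v
          if (v > best_v) { best_v <- v; best_b <- b }
        } else {
          b[from] <- 1; b[to] <- 0
        }
      }
      list(value = best_v, matrix = best_b)
    })
    trace[r] <- res$value
    if (res$value > best) { best <- res$value; best_mat <- res$matrix }
  }
  list(value = best, matrix = best_mat, method = "search", trace = trace)
}

#' Connectance- and size-corrected nestedness NODFc
#'
#' `NODFc = NODF / max(NODF) / (C * log S)` where `max(NODF)` is the maximum
#' nestedness achievable at the observed dimensions and fill (see
#' [max_nodf]), `C = fill / (m n)` is connectance and `S = sqrt(m n)` is the
#' geometric mean species richness. The correction makes nestedness
#' comparable across networks of different size and connectance. Natural
#' logarithm by default (`log_base` is exposed).
#'
#' @param x binary matrix or [interaction_matrix] (0/1 values).
#' @param log_base base of the logarithm applied to S.
#' @param method,restarts,moves,seed passed to [max_nodf].
#' @param max_nodf_value optional precomputed `max(NODF)` for the observed
#'   `(m, n, fill)`, to avoid re-optimizing (e.g. across fill-preserving null
#'   replicates).
#' @return object of class `nodfc_result`: list with `NODFc` and its
#'   components `NODF`, `max_NODF`, `C`, `S`, plus the optimizer trace.
#' @export
nodfc <- function(x, log_base = exp(1), method = c("auto", "exhaustive", "search"),
                  restarts = 10, moves = 5000, seed = 1L,
                  max_nodf_value = NULL) {
  b <- as_binary_matrix(x)
  obs <- nodf(b)
  m <- nrow(b); n <- ncol(b); fill <- sum(b)
  if (is.null(max_nodf_value)) {
    opt <- max_nodf(m, n, fill, method = method, restarts = restarts,
                    moves = moves, seed = seed)
    max_nodf_value <- opt$value
    trace <- opt$trace
  } else {
    trace <- numeric(0)
  }
  C <- fill / (m * n)
  S <- sqrt(m * n)
  value <- if (max_nodf_value <= 0)
    undefined_value("NODFc is undefined when max(NODF) = 0 (full matrix)")
  else
    obs$NODF / max_nodf_value / (C * log(S, base = log_base))
  res <- list(NODFc = value, NODF = obs$NODF, max_NODF = max_nodf_value,
              C = C, S = S, m = m, n = n, fill = fill,
              log_base = log_base, trace = trace)
  class(res) <- "nodfc_result"
  res
}

#' @export
print.nodfc_result <- function(x, ...) {
  cat(sprintf("NODFc = %.4f  (NODF %.2f / maxNODF %.2f / (C %.4f * log S %.4f))\n",
              x$NODFc, x$NODF, x$max_NODF, x$C, log(x$S, base = x$log_base)))
  invisible(x)
}
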