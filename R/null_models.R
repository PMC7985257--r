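#' Equiprobable (EE) binary null model
#'
#' Each replicate places exactly `fill` presences uniformly at random among
#' the `m * n` cells (without replacement). Fill is preserved exactly; empty
#' rows/columns are permitted, matching the behavior of the classic
#' equiprobable null used for nestedness testing.
#'
#' @param x binary matrix or [interaction_matrix] (binarized views are the
#'   caller's responsibility).
#' @param reps number of replicates (>= 1).
#' @param seed RNG seed; the ensemble is reproducible given the seed.
#' @return list of `reps` binary matrices.
#' @export
ee_null <- function(x, reps = 999, seed = 1L) {
  b <- as_binary_matrix(x)
  fill <- sum(b)
  mn <- length(b)
  with_seed(seed, lapply(seq_len(reps), function(r) {
    out <- matrix(0, nrow(b), ncol(b))
    out[sample.int(mn, fill)] <- 1
    out
  }))
}

#' Fixed-row fixed-column probabilistic (FF) null model
#'
#' Each cell is independently set to presence with probability
#' `p_ij = (P_i / C + P_j / R) / 2`, the mean of its row incidence proportion
#' (`P_i` presences over `C` columns) and its column incidence proportion
#' (`P_j` presences over `R` rows). Fill varies between replicates but its
#' expectation equals the observed fill, since `sum(p_ij) = fill`
#' analytically.
#'
#' @inheritParams ee_null
#' @return list of `reps` binary matrices.
#' @export
ff_null <- function(x, reps = 999, seed = 1L) {
  b <- as_binary_matrix(x)
  p <- ff_cell_probabilities(b)
  with_seed(seed, lapply(seq_len(reps), function(r) {
    (matrix(stats::runif(length(b)), nrow(b), ncol(b)) < p) + 0
  }))
}

#' Per-cell presence probabilities of the FF null
#' @param x binary matrix.
#' @return matrix of `p_ij = (P_i / C + P_j / R) / 2`.
#' @export
ff_cell_probabilities <- function(x) {
  b <- as_binary_matrix(x)
  (outer(rowSums(b) / ncol(b), rep(1, ncol(b))) +
   outer(rep(1, nrow(b)), colSums(b) / nrow(b))) / 2
}

#' Quantitative swap-web null model
#'
#' Marginal- and connectance-preserving randomization of a quantitative
#' interaction matrix: every replicate is a non-negative integer matrix whose
#' row sums, column sums and number of non-zero cells (fill) all equal the
#' observed values exactly. Replicates are independent draws generated by
#' marginal-conditioned random table allocation followed by
#' connectance-adjusting quantitative swaps (vegan's `quasiswap_count`
#' null model).
#'
#' @param x [interaction_matrix] or non-negative integer matrix.
#' @param reps number of replicates.
#' @param seed RNG seed.
#' @return list of `reps` integer matrices.
#' @export
swap_web_null <- function(x, reps = 999, seed = 1L) {
  w <- as_weight_matrix(x)
  if (nrow(w) == 1 && ncol(w) == 1)
    return(lapply(seq_len(reps), function(r) w))
  if (nrow(w) == 1 || ncol(w) == 1)  # marginals pin every cell
    return(lapply(seq_len(reps), function(r) w))
  # vegan's C implementation needs checkerboard units to thin fill; matrices
  # without any (perfectly nested or full binary views) fall back to the
  # in-package generator.
  if (vegan::nestedchecker(w)$statistic == 0)
    return(with_seed(seed, lapply(seq_len(reps), function(r)
      swap_web_one(w))))
  nm <- vegan::nullmodel(w, "quasiswap_count")
  sims <- stats::simulate(nm, nsim = reps, seed = as.integer(seed))
  lapply(seq_len(reps), function(r) {
    out <- sims[, , r]
    dimnames(out) <- dimnames(w)
    out
  })
}

# One swap-web replicate: marginal-conditioned random table (Patefield
# algorithm) followed by connectance-adjusting 2x2 transfers until the number
# of non-zero cells matches the observed fill. Hard error with diagnostics if
# the move budget is exhausted.
swap_web_one <- function(w, budget = 20000L) {
  target <- sum(w > 0)
  rs <- rowSums(w); cs <- colSums(w)
  x <- stats::r2dtable(1, rs, cs)[[1]]
  gap <- abs(sum(x > 0) - target)
  for (it in seq_len(budget)) {
    if (gap == 0) break
    i <- sample.int(nrow(x), 2); j <- sample.int(ncol(x), 2)
    a11 <- x[i[1], j[1]]; a12 <- x[i[1], j[2]]
    a21 <- x[i[2], j[1]]; a22 <- x[i[2], j[2]]
    lo <- -min(a11, a22); hi <- min(a12, a21)
    if (lo == hi) next
    t <- sample(setdiff(lo:hi, 0L), 1)
    y <- x
    y[i[1], j[1]] <- a11 + t; y[i[2], j[2]] <- a22 + t
    y[i[1], j[2]] <- a12 - t; y[i[2], j[1]] <- a21 - t
    new_gap <- abs(sum(y > 0) - target)
    if (new_gap < gap) { x <- y; gap <- new_gap }
  }
  if (gap != 0)
    stop(sprintf("swap-web fill adjustment failed: fill %d != target %d after %d proposals",
                 sum(x > 0), target, budget), call. = FALSE)
  dimnames(x) <- dimnames(w)
  x
}

# Named statistic registry for null_test. Binary statistics binarize the
# replicate; quantitative ones use the weights.
null_statistic <- function(statistic) {
  if (is.function(statistic)) return(statistic)
  switch(statistic,
    nodf = function(w) nodf_value((w > 0) + 0, allow_empty = TRUE),
    cscore = function(w) c_score((w > 0) + 0, margin = "fungi"),
    h2prime = function(w) h2_prime(w)$H2prime,
    connectance = function(w) sum(w > 0) / length(w),
    stop("unknown statistic '", statistic, "'", call. = FALSE))
}

#' Permutation test of a network statistic against a null ensemble
#'
#' Evaluates a statistic on the observed matrix and on every replicate of a
#' null scheme, and reports the null mean, null standard deviation, the
#' standardized effect size `z = (obs - mean) / sd`, and add-one empirical
#' P-values: `P_upper = (#{null >= obs} + 1) / (reps + 1)`, symmetrically for
#' the lower tail; the two-sided P doubles the smaller tail (capped at 1).
#'
#' For NODFc under fill-preserving schemes (EE, swap-web) the max-NODF
#' normalization is computed once and shared across replicates, since it
#' depends only on `(m, n, fill)`.
#'
#' @param x [interaction_matrix] or matrix. Binary statistics are evaluated on
#'   the binarized view; empty rows/columns in null replicates are tolerated
#'   (they contribute zero pairs to NODF).
#' @param statistic `"nodf"`, `"nodfc"`, `"cscore"`, `"h2prime"`,
#'   `"connectance"`, or a function of a weight matrix returning a scalar.
#' @param scheme `"EE"`, `"FF"` or `"SWAP_WEB"`.
#' @param reps number of null replicates (>= 1).
#' @param seed RNG seed.
#' @param ... passed to [nodfc] when `statistic = "nodfc"` (optimizer budget).
#' @return object of class `null_ensemble`: list with `statistic`, `scheme`,
#'   `obs`, `nulls` (vector of null statistic values), `mean`, `sd`, `z`
#'   (`NA` with a warning when `sd = 0`), `p_upper`, `p_lower`, `p_two_sided`,
#'   `reps`, `seed`.
#' @export
null_test <- function(x, statistic, scheme = c("EE", "FF", "SWAP_WEB"),
                      reps = 999, seed = 1L, ...) {
  scheme <- match.arg(scheme)
  stopifnot(reps >= 1)
  w <- as_weight_matrix(x)
  stat_name <- if (is.character(statistic)) statistic else "custom"

  if (stat_name == "nodfc") {
    # Shared normalization across fill-preserving replicates.
    b <- (w > 0) + 0
    mx <- max_nodf(nrow(b), ncol(b), sum(b), seed = seed, ...)$value
    denom <- (sum(b) / length(b)) * log(sqrt(length(b)))
    fn <- function(v) {
      val <- nodf_value((v > 0) + 0, allow_empty = TRUE) / mx / denom
      val
    }
    if (scheme == "FF")
      warning("NODFc null with FF does not preserve fill; the observed-fill ",
              "max(NODF) normalization is reused for all replicates", call. = FALSE)
  } else {
    fn <- null_statistic(statistic)
  }

  nulls_mats <- switch(scheme,
    EE = ee_null((w > 0) + 0, reps, seed),
    FF = ff_null((w > 0) + 0, reps, seed),
    SWAP_WEB = swap_web_null(w, reps, seed))
  obs <- fn(w)
  nulls <- vapply(nulls_mats, fn, numeric(1))
  null_summary(stat_name, scheme, obs, nulls, reps, seed)
}

null_summary <- function(stat_name, scheme, obs, nulls, reps, seed) {
  mu <- mean(nulls)
  sdev <- stats::sd(nulls)
  z <- if (isTRUE(sdev > 0)) (obs - mu) / sdev
       else undefined_value("null sd is 0; z-score undefined (P still reported)")
  p_up <- (sum(nulls >= obs) + 1) / (reps + 1)
  p_lo <- (sum(nulls <= obs) + 1) / (reps + 1)
  res <- list(statistic = stat_name, scheme = scheme, obs = obs, nulls = nulls,
              mean = mu, sd = sdev, z = z,
              p_upper = p_up, p_lower = p_lo,
              p_two_sided = min(1, 2 * min(p_up, p_lo)),
              reps = reps, seed = seed)
  class(res) <- "null_ensemble"
  res
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("%s vs %s null (%d reps): obs = %.4f, null %.4f +/- %.4f, z = %s, P(upper) = %.4g\n",
              x$statistic, x$scheme, x$reps, x$obs, x$mean, x$sd,
              if (is_undefined(x$z)) "NA" else sprintf("%.3f", x$z), x$p_upper))
  invisible(x)
}

# Shared machinery for per-component z-scores against a swap-web ensemble:
# `extract` maps a weight matrix to a numeric vector (per-cell weights,
# per-species d', ...).
ensemble_zscores <- function(w, extract, reps, seed, alpha_z, strong_z) {
  nulls <- swap_web_null(w, reps, seed)
  obs <- suppressWarnings(extract(w))
  mat <- vapply(nulls, function(v) suppressWarnings(extract(v)),
                numeric(length(obs)))
  if (length(obs) == 1) mat <- matrix(mat, nrow = 1)
  mu <- rowMeans(mat, na.rm = TRUE)
  sdev <- apply(mat, 1, stats::sd, na.rm = TRUE)
  ok <- !is.na(obs) & !is.na(sdev) & sdev > 0
  z <- ifelse(ok, (obs - mu) / sdev, NA_real_)
  if (!all(ok))
    warning("zero-variance or undefined component(s) in null ensemble; z set to NA",
            call. = FALSE)
  list(obs = obs, mean = mu, sd = sdev, z = z,
       significant = !is.na(z) & abs(z) > alpha_z,
       strongly_significant = !is.na(z) & abs(z) > strong_z)
}

#' Per-link z-scores against the swap-web null
#'
#' For every host-fungus cell, the observed weight is compared with its
#' distribution across a swap-web ensemble; `z = (obs - mean) / sd`. Links
#' with `|z| > z_alpha` (strict inequality, default 1.96) are flagged
#' significant at the 0.05 level, and `|z| > z_strong` (default 2.576) at the
#' 0.01 level. Zero-variance cells get the undefined marker `NA`.
#'
#' @param x [interaction_matrix] or integer matrix.
#' @param reps,seed swap-web ensemble size and seed.
#' @param z_alpha,z_strong significance thresholds on `|z|`.
#' @return object of class `link_zscores`: list with matrices `z`,
#'   `significant`, `strongly_significant`, and `mean`/`sd` of the null.
#' @export
link_zscores <- function(x, reps = 999, seed = 1L,
                         z_alpha = 1.96, z_strong = 2.576) {
  w <- as_weight_matrix(x)
  res <- ensemble_zscores(w, as.vector, reps, seed, z_alpha, z_strong)
  shape <- function(v) matrix(v, nrow(w), ncol(w), dimnames = dimnames(w))
  out <- list(z = shape(res$z), mean = shape(res$mean), sd = shape(res$sd),
              significant = shape(res$significant),
              strongly_significant = shape(res$strongly_significant),
              reps = reps, seed = seed, z_alpha = z_alpha, z_strong = z_strong)
  class(out) <- "link_zscores"
  out
}

#' @export
print.link_zscores <- function(x, ...) {
  cat(sprintf("link z-scores (%d reps): %d/%d links |z| > %.2f, %d |z| > %.2f\n",
              x$reps, sum(x$significant, na.rm = TRUE), length(x$z), x$z_alpha,
              sum(x$strongly_significant, na.rm = TRUE), x$z_strong))
  invisible(x)
}

#' Per-species d' z-scores against the swap-web null
#'
#' Species-level specialization d' of every species on one margin, compared
#' with its swap-web null distribution — the basis for counting significantly
#' specialized species per degree class.
#'
#' @param x [interaction_matrix] or integer matrix.
#' @param margin `"fungi"` (columns, default) or `"hosts"`.
#' @param reps,seed,z_alpha,z_strong as in [link_zscores].
#' @return data.frame with one row per species: `species`, `degree`, `dprime`
#'   (observed), `null_mean`, `null_sd`, `z`, `significant`,
#'   `strongly_significant`.
#' @export
dprime_zscores <- function(x, margin = c("fungi", "hosts"), reps = 999,
                           seed = 1L, z_alpha = 1.96, z_strong = 2.576) {
  margin <- match.arg(margin)
  w <- as_weight_matrix(x)
  extract <- function(v) d_prime(v, margin = margin)
  res <- ensemble_zscores(w, extract, reps, seed, z_alpha, z_strong)
  labs <- if (margin == "fungi") colnames(w) else rownames(w)
  data.frame(species = labs,
             degree = species_degree(w, margin),
             dprime = res$obs, null_mean = res$mean, null_sd = res$sd,
             z = res$z, significant = res$significant,
             strongly_significant = res$strongly_significant,
             row.names = NULL, stringsAsFactors = FALSE)
}
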