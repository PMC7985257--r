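#' Shannon diversity of an abundance vector
#'
#' \eqn{H = -\sum_i p_i \ln p_i} with natural logarithm, where \eqn{p_i} is
#' the relative abundance of OTU i within the sample; zero entries contribute
#' nothing.
#'
#' @param counts non-negative abundance vector with at least one positive
#'   entry.
#' @return Shannon index H (>= 0).
#' @export
shannon <- function(counts) {
  check_abundance(counts)
  as.numeric(vegan::diversity(rbind(counts), index = "shannon"))
}

#' Simpson diversity of an abundance vector
#'
#' \eqn{D = 1 - \sum_i p_i^2}, in `[0, 1]`.
#'
#' @inheritParams shannon
#' @return Simpson index D.
#' @export
simpson <- function(counts) {
  check_abundance(counts)
  as.numeric(vegan::diversity(rbind(counts), index = "simpson"))
}

#' Pielou evenness of an abundance vector
#'
#' \eqn{E = H / \ln S} with S the observed richness. Undefined for a
#' single-species sample (`\ln S = 0`): returns the explicit undefined marker
#' `NA` with a warning rather than a silent 0.
#'
#' @inheritParams shannon
#' @return evenness E in `[0, 1]`, or `NA` when S = 1.
#' @export
pielou <- function(counts) {
  check_abundance(counts)
  s <- sum(counts > 0)
  if (s < 2)
    return(undefined_value("Pielou evenness is undefined for a single-species sample"))
  shannon(counts) / log(s)
}

check_abundance <- function(counts) {
  if (!is.numeric(counts) || any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative numbers", call. = FALSE)
  if (sum(counts) == 0)
    stop("all-zero abundance vector", call. = FALSE)
  invisible(counts)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal rooted subtree connecting the present
#' tips to the root.
#'
#' @param tree a rooted `phylo` tree with non-negative branch lengths.
#' @param present character vector of tip labels present in the sample
#'   (non-empty subset of the tree's tips).
#' @return PD (>= 0).
#' @export
faith_pd <- function(tree, present) {
  stopifnot(inherits(tree, "phylo"))
  if (length(present) == 0) stop("no tips present", call. = FALSE)
  missing <- setdiff(present, tree$tip.label)
  if (length(missing) > 0)
    stop("tip(s) not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  comm <- matrix(as.numeric(tree$tip.label %in% present), nrow = 1,
                 dimnames = list("sample", tree$tip.label))
  picante::pd(comm, tree, include.root = TRUE)$PD
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{BC = \sum_k |x_k - y_k| / \sum_k (x_k + y_k)}, in `[0, 1]`.
#' Undefined when both vectors are all-zero (returns `NA` with a warning).
#'
#' @param x,y equal-length non-negative abundance vectors.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (sum(x) == 0 && sum(y) == 0)
    return(undefined_value("Bray-Curtis is undefined for two all-zero vectors"))
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Pairwise Bray-Curtis dissimilarity among host species
#'
#' Aggregates abundances per host (for an [otu_table], summing the site's
#' samples within host; an [interaction_matrix] is used as-is) and returns the
#' symmetric host-by-host Bray-Curtis matrix — the host community-convergence
#' surface: lower mean dissimilarity means more convergent host communities.
#'
#' @param x an [otu_table] or [interaction_matrix].
#' @param site site class, required when `x` is an [otu_table].
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
host_dissimilarity <- function(x, site = NULL) {
  w <- if (inherits(x, "otu_table")) {
    if (is.null(site)) stop("site is required for an otu_table", call. = FALSE)
    as_weight_matrix(aggregate_to_network(x, site))
  } else {
    as_weight_matrix(x)
  }
  if (nrow(w) < 2) stop("need at least 2 hosts", call. = FALSE)
  as.matrix(vegan::vegdist(w, method = "bray"))
}

# Upper-triangle values of a symmetric dissimilarity matrix, ordered by
# column-major unordered pairs.
pairwise_values <- function(d) d[upper.tri(d)]

#' Paired-sample t test
#'
#' Classical paired t on the differences with `df = n - 1`. Zero-variance
#' differences are mathematically degenerate: the statistic is returned as the
#' undefined marker `NA` with a warning (with `p = 1` when the differences are
#' all exactly zero).
#'
#' @param a,b equal-length paired measurement vectors (n >= 2).
#' @return list with elements `t`, `df`, `p`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("a and b must be paired vectors of equal length >= 2", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    t <- undefined_value("paired t is undefined for zero-variance differences")
    return(list(t = t, df = length(d) - 1L, p = if (all(d == 0)) 1 else NA_real_))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Per-sample alpha diversity table
#'
#' Computes richness S, Shannon H, Simpson D, Pielou E and (when a tree is
#' supplied) Faith's PD for every sample, on the counts as given — typically
#' after rarefaction so depths are comparable.
#'
#' @param x an [otu_table].
#' @param tree optional rooted `phylo` whose tips cover the OTU ids.
#' @return data.frame with one row per sample: `sample`, `host`, `site`,
#'   `plot`, `S`, `shannon`, `simpson`, `pielou` and optionally `pd`.
#' @export
sample_diversity <- function(x, tree = NULL) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts
  res <- data.frame(
    x$metadata,
    S = rowSums(counts > 0),
    shannon = as.numeric(vegan::diversity(counts, "shannon")),
    simpson = as.numeric(vegan::diversity(counts, "simpson")),
    stringsAsFactors = FALSE
  )
  res$pielou <- ifelse(res$S >= 2, res$shannon / log(res$S), NA_real_)
  if (any(res$S < 2))
    warning("Pielou evenness undefined for single-species sample(s)", call. = FALSE)
  if (!is.null(tree)) {
    comm <- counts[, intersect(colnames(counts), tree$tip.label), drop = FALSE]
    res$pd <- picante::pd((comm > 0) + 0, tree, include.root = TRUE)$PD
  }
  rownames(res) <- NULL
  res
}
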