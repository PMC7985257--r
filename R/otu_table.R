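#' Construct a sample-by-OTU count table with sample metadata
#'
#' The basic container for community sequencing data downstream of OTU
#' clustering: a non-negative integer matrix of read counts (samples in rows,
#' OTUs in columns) together with per-sample metadata giving the host plant
#' species, the site class (`"rural"` or `"urban"`) and the plot label.
#'
#' @param counts numeric matrix of non-negative integer read counts with
#'   sample ids as row names and OTU ids as column names.
#' @param metadata data.frame with columns `sample`, `host`, `site`, `plot`;
#'   every sample in `counts` must have exactly one metadata row.
#' @return an object of class `otu_table`: a list with elements `counts`
#'   (matrix) and `metadata` (data.frame aligned to the rows of `counts`).
#' @examples
#' counts <- matrix(c(3, 0, 1, 2), 2, 2, byrow = TRUE,
#'                  dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' meta <- data.frame(sample = c("s1", "s2"), host = "hostA",
#'                    site = "rural", plot = c("p1", "p2"))
#' ot <- otu_table(counts, meta)
#' sample_totals(ot)
#' @export
otu_table <- function(counts, metadata) {
  counts <- check_count_matrix(counts, "counts")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and OTU column names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicated sample ids in counts", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicated OTU ids in counts", call. = FALSE)
  need <- c("sample", "host", "site", "plot")
  if (!is.data.frame(metadata) || !all(need %in% names(metadata)))
    stop("metadata must be a data.frame with columns sample, host, site, plot",
         call. = FALSE)
  missing <- setdiff(rownames(counts), metadata$sample)
  if (length(missing) > 0)
    stop("missing metadata for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad_site <- setdiff(unique(as.character(metadata$site)), c("rural", "urban"))
  if (length(bad_site) > 0)
    stop("site class must be 'rural' or 'urban'; found: ",
         paste(bad_site, collapse = ", "), call. = FALSE)
  metadata <- metadata[match(rownames(counts), metadata$sample),
                       need, drop = FALSE]
  rownames(metadata) <- NULL
  metadata$sample <- as.character(metadata$sample)
  metadata$host <- as.character(metadata$host)
  metadata$site <- as.character(metadata$site)
  metadata$plot <- as.character(metadata$plot)
  structure(list(counts = counts, metadata = metadata), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  cat(sprintf("  hosts: %s\n", paste(sort(unique(x$metadata$host)), collapse = ", ")))
  cat(sprintf("  sites: %s\n",
              paste(sprintf("%s (%d)", names(table(x$metadata$site)),
                            table(x$metadata$site)), collapse = ", ")))
  invisible(x)
}

#' Per-sample read totals
#' @param x an `otu_table`.
#' @return named numeric vector of total reads per sample.
#' @export
sample_totals <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  rowSums(x$counts)
}

#' Read an OTU table and its sample metadata from TSV files
#'
#' The counts file is tab-separated with OTU ids in the header row and sample
#' ids in the first column; the metadata file has columns `sample`, `host`,
#' `site`, `plot`. Row and column order are preserved from file.
#'
#' @param counts_path path to the counts TSV.
#' @param metadata_path path to the metadata TSV.
#' @return an [otu_table].
#' @export
read_otu_table <- function(counts_path, metadata_path) {
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path, call. = FALSE)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path, call. = FALSE)
  counts <- read_tsv_matrix(counts_path)
  metadata <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                                colClasses = "character", check.names = FALSE)
  otu_table(counts, metadata)
}

#' Write an OTU table and its metadata to TSV files
#' @param x an [otu_table].
#' @param counts_path,metadata_path output paths.
#' @return `x`, invisibly.
#' @export
write_otu_table <- function(x, counts_path, metadata_path) {
  stopifnot(inherits(x, "otu_table"))
  write_tsv_matrix(x$counts, counts_path, id_col = "sample")
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

# Shared TSV matrix reader: first column = row labels, header = column labels.
# Ragged rows are a hard error.
read_tsv_matrix <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1)
    stop("ragged rows in ", path, ": differing field counts ",
         paste(unique(nf), collapse = ", "), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = c("character", rep(NA, nf[1] - 1L)))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    m2 <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                  dimnames = dimnames(m)))
    bad <- which(is.na(m2) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric value in %s at row '%s', column '%s'",
                   path, df[[1]][bad[1, 1]], colnames(m)[bad[1, 2]]),
           call. = FALSE)
    m <- m2
  }
  rownames(m) <- df[[1]]
  m
}

write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove rare OTUs below a proportion of the grand read total
#'
#' OTUs whose summed count across all samples is strictly below
#' `fraction * sum(counts)` are dropped (strict inequality, matching the usual
#' "< x % of total reads" rule used to guard against sequencing-error
#' clusters). The operation is idempotent: survivors can only gain relative
#' weight when the grand total shrinks.
#'
#' @param x an [otu_table].
#' @param fraction proportion of the grand total in `[0, 1)`; note a
#'   percentage threshold like 0.0001% corresponds to `fraction = 1e-6`.
#' @return filtered [otu_table]; removed OTU ids in attribute `removed_otus`.
#' @export
filter_rare_otus <- function(x, fraction) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction < 0 || fraction >= 1)
    stop("fraction must be a single proportion in [0, 1)", call. = FALSE)
  threshold <- fraction * sum(x$counts)
  totals <- colSums(x$counts)
  drop <- names(totals)[totals < threshold]
  if (length(drop) == ncol(x$counts))
    stop("filter_rare_otus would remove every OTU", call. = FALSE)
  if (length(drop) > 0)
    nw_log("filter_rare_otus",
           sprintf("removed %d/%d OTUs below %.6g reads (%s)",
                   length(drop), ncol(x$counts), threshold,
                   paste(utils::head(drop, 10), collapse = ", ")))
  keep <- setdiff(colnames(x$counts), drop)
  out <- otu_table(x$counts[, keep, drop = FALSE], x$metadata)
  attr(out, "removed_otus") <- drop
  out
}

#' Drop samples whose read total falls below a minimum depth
#'
#' Emulates the exclusion of low-yield samples before rarefaction (samples
#' that returned only a handful of target reads carry no usable community
#' signal).
#'
#' @param x an [otu_table].
#' @param min_reads minimum total reads a sample must have (>= 1).
#' @return filtered [otu_table]; dropped sample ids in attribute
#'   `dropped_samples`.
#' @export
exclude_low_depth_samples <- function(x, min_reads) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.numeric(min_reads) || length(min_reads) != 1 || min_reads < 1)
    stop("min_reads must be >= 1", call. = FALSE)
  totals <- sample_totals(x)
  drop <- names(totals)[totals < min_reads]
  if (length(drop) == nrow(x$counts))
    stop("exclude_low_depth_samples would remove every sample", call. = FALSE)
  if (length(drop) > 0)
    nw_log("exclude_low_depth_samples",
           sprintf("dropped %d sample(s) below %g reads: %s",
                   length(drop), min_reads, paste(drop, collapse = ", ")))
  keep <- setdiff(rownames(x$counts), drop)
  out <- otu_table(x$counts[keep, , drop = FALSE],
                   x$metadata[x$metadata$sample %in% keep, , drop = FALSE])
  attr(out, "dropped_samples") <- drop
  out
}

#' Rarefy every sample to a common depth without replacement
#'
#' Each sample's counts are replaced by a multivariate hypergeometric
#' subsample of exactly `depth` reads (urn draw without replacement), the
#' standard normalization before comparing alpha diversity across samples.
#' Deterministic given `seed`.
#'
#' @param x an [otu_table]; every sample total must be `>= depth`
#'   (run [exclude_low_depth_samples] first).
#' @param depth target reads per sample.
#' @param seed integer RNG seed.
#' @return rarefied [otu_table] whose samples all total exactly `depth`.
#' @export
rarefy_table <- function(x, depth, seed = 1L) {
  stopifnot(inherits(x, "otu_table"))
  totals <- sample_totals(x)
  low <- names(totals)[totals < depth]
  if (length(low) > 0)
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(low, collapse = ", "), call. = FALSE)
  counts <- with_seed(seed, suppressWarnings(vegan::rrarefy(x$counts, depth)))
  storage.mode(counts) <- "double"
  otu_table(counts, x$metadata)
}

#' Aggregate per-sample counts into a host-by-OTU interaction matrix
#'
#' Builds the bipartite network for one site: rows are the host plant species
#' sampled at that site, columns are the fungal OTUs observed there, and each
#' weight is the read count summed over that host's replicate samples
#' (replicate plots are pooled; pass `aggregate = "mean"` for averaged
#' weights). OTUs absent from the site are dropped.
#'
#' @param x an [otu_table].
#' @param site `"rural"` or `"urban"`.
#' @param aggregate pool replicate samples by `"sum"` (default) or `"mean"`
#'   (rounded to integer weights).
#' @return an [interaction_matrix] with hosts in rows (sorted) and the site's
#'   OTUs in columns (input order).
#' @export
aggregate_to_network <- function(x, site, aggregate = c("sum", "mean")) {
  stopifnot(inherits(x, "otu_table"))
  aggregate <- match.arg(aggregate)
  site <- match.arg(site, c("rural", "urban"))
  in_site <- x$metadata$site == site
  if (!any(in_site))
    stop("no samples at site '", site, "'", call. = FALSE)
  counts <- x$counts[in_site, , drop = FALSE]
  hosts <- x$metadata$host[in_site]
  if (length(unique(hosts)) < 2)
    stop("need at least 2 host species at site '", site, "'", call. = FALSE)
  w <- rowsum(counts, group = hosts)
  w <- w[order(rownames(w)), , drop = FALSE]
  if (aggregate == "mean") {
    reps <- as.vector(table(hosts)[rownames(w)])
    w <- round(w / reps)
  }
  w <- w[, colSums(w) > 0, drop = FALSE]
  interaction_matrix(w)
}
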