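#' Construct a bipartite host-by-OTU interaction matrix
#'
#' A quantitative bipartite network: host plants in rows, fungal OTUs in
#' columns, non-negative integer interaction weights (read counts) in cells.
#' The binary presence view, marginal totals and fill (number of realized
#' links) derive from it.
#'
#' @param weights non-negative integer matrix with row and column names.
#' @return the weight matrix with class `interaction_matrix`.
#' @examples
#' w <- matrix(c(5, 2, 0, 3), 2, 2,
#'             dimnames = list(c("hostA", "hostB"), c("otu1", "otu2")))
#' im <- interaction_matrix(w)
#' binary_view(im)
#' matrix_fill(im)
#' @export
interaction_matrix <- function(weights) {
  weights <- check_count_matrix(weights, "weights")
  if (is.null(rownames(weights)))
    rownames(weights) <- paste0("row", seq_len(nrow(weights)))
  if (is.null(colnames(weights)))
    colnames(weights) <- paste0("col", seq_len(ncol(weights)))
  if (anyDuplicated(rownames(weights)) || anyDuplicated(colnames(weights)))
    stop("row and column labels must be unique", call. = FALSE)
  if (sum(weights > 0) < 1)
    stop("interaction matrix has no realized links", call. = FALSE)
  structure(weights, class = c("interaction_matrix", class(matrix())))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d hosts x %d OTUs, fill %d (connectance %.3f)\n",
              nrow(x), ncol(x), sum(x > 0), sum(x > 0) / length(x)))
  w <- unclass(x)
  attributes(w)[setdiff(names(attributes(w)), c("dim", "dimnames"))] <- NULL
  print(w, ...)
  invisible(x)
}

# Accept an interaction_matrix, otu-free plain matrix, or data.frame; return a
# validated plain weight matrix.
as_weight_matrix <- function(x) {
  if (inherits(x, "interaction_matrix")) return(unclass(x))
  check_count_matrix(as.matrix(x), "weights")
}

# Validate/binarize input for binary-only metrics. Values must already be 0/1
# unless binarize = TRUE.
as_binary_matrix <- function(x, binarize = FALSE) {
  m <- if (inherits(x, "interaction_matrix")) unclass(x) else as.matrix(x)
  if (!is.numeric(m)) stop("binary matrix must be numeric", call. = FALSE)
  if (binarize) return((m > 0) + 0)
  if (any(m != 0 & m != 1))
    stop("matrix is not binary; binarize explicitly upstream", call. = FALSE)
  m + 0
}

#' Binary presence view of an interaction matrix
#' @param x an [interaction_matrix] or weight matrix.
#' @return 0/1 matrix, 1 exactly where the weight is positive.
#' @export
binary_view <- function(x) {
  (as_weight_matrix(x) > 0) + 0
}

#' Number of realized links (non-zero cells)
#' @param x an [interaction_matrix] or weight matrix.
#' @export
matrix_fill <- function(x) {
  sum(as_weight_matrix(x) > 0)
}

#' Marginal totals of an interaction matrix
#' @param x an [interaction_matrix] or weight matrix.
#' @param margin `"hosts"` (row totals) or `"fungi"` (column totals).
#' @export
marginal_totals <- function(x, margin = c("hosts", "fungi")) {
  margin <- match.arg(margin)
  w <- as_weight_matrix(x)
  if (margin == "hosts") rowSums(w) else colSums(w)
}

#' Read an interaction matrix from a TSV file
#'
#' Expects row labels in the first column and OTU ids in the header; ragged
#' rows are a hard error. Round-trips with [write_interaction_matrix].
#'
#' @param path TSV path.
#' @return an [interaction_matrix].
#' @export
read_interaction_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  interaction_matrix(read_tsv_matrix(path))
}

#' Write an interaction matrix to a TSV file
#' @param x an [interaction_matrix].
#' @param path output TSV path.
#' @return `x`, invisibly.
#' @export
write_interaction_matrix <- function(x, path) {
  write_tsv_matrix(as_weight_matrix(x), path, id_col = "host")
  invisible(x)
}
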