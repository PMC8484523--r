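# Preprocessing of semantic/visual embedding matrices, Jaccard similarity,
# and aggregation of the static training targets.

#' Read a representation matrix from CSV/TSV
#'
#' First column `item_id`, remaining columns real-valued dimensions.
#'
#' @param path file path; tab- or comma-separated decided by extension.
#' @return Numeric matrix with item ids as row names.
#' @export
read_representation <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("representation matrix contains missing values")
  m
}

#' Write a representation matrix to CSV/TSV
#'
#' @param m numeric matrix with item ids as row names.
#' @param path output path; extension `.tsv` selects tab separation.
#' @export
write_representation <- function(m, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- data.frame(item_id = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Replace outlying entries with the dimension median
#'
#' Per dimension (column), entries whose absolute z-score across items
#' exceeds `z_cut` are replaced by that dimension's median. Statistics
#' (mean, standard deviation, median) are computed once on the raw matrix;
#' the standard deviation uses the population (divide-by-n) convention.
#' Zero-variance dimensions are left untouched.
#'
#' @param m items-by-dims numeric matrix.
#' @param z_cut z-score threshold (default 2).
#' @return Matrix of the same shape.
#' @export
replace_outliers <- function(m, z_cut = 2) {
  m <- as.matrix(m)
  if (nrow(m) < 3L) stop("need at least 3 items to estimate outliers")
  mu <- colMeans(m)
  sdp <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  med <- apply(m, 2L, stats::median)
  out <- m
  for (j in seq_len(ncol(m))) {
    if (sdp[j] == 0) next
    z <- abs(m[, j] - mu[j]) / sdp[j]
    out[z > z_cut, j] <- med[j]
  }
  out
}

#' Reduce dimensionality by principal component analysis
#'
#' Projects the column-centered matrix onto its top `k` principal
#' components and reports the cumulative fraction of variance explained.
#'
#' @param m items-by-dims numeric matrix.
#' @param k number of components, `k <= min(items - 1, dims)`.
#' @return List with `scores` (items-by-`k` matrix, row names preserved)
#'   and `variance_explained` (scalar in `[0, 1]`).
#' @export
reduce_dims <- function(m, k) {
  m <- as.matrix(m)
  if (k < 1L || k > min(nrow(m) - 1L, ncol(m)))
    stop(sprintf("k = %d out of range; need 1 <= k <= min(items - 1, dims) = %d",
                 k, min(nrow(m) - 1L, ncol(m))))
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(m)
  list(scores = scores,
       variance_explained = if (tot > 0) sum(ev[seq_len(k)]) / tot else 1)
}

#' Binarize a matrix by per-dimension median split
#'
#' Entries strictly greater than their dimension's median map to 1, all
#' others (including values equal to the median) to 0; set
#' `ties = "above"` to send median-valued entries to 1 instead.
#'
#' @param m items-by-dims numeric matrix.
#' @param ties bin for entries equal to the median, `"below"` (default)
#'   or `"above"`.
#' @return Binary matrix of the same shape.
#' @export
binarize_by_median <- function(m, ties = c("below", "above")) {
  ties <- match.arg(ties)
  m <- as.matrix(m)
  med <- apply(m, 2L, stats::median)
  cmp <- sweep(m, 2L, med)
  out <- if (ties == "below") (cmp > 0) else (cmp >= 0)
  storage.mode(out) <- "double"
  dimnames(out) <- dimnames(m)
  out
}

#' Jaccard index of two binary vectors
#'
#' The ratio of the intersection to the union of the components set to 1.
#' Two all-zero vectors are identical and return 1.
#'
#' @param u,v binary vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(u, v) {
  if (length(u) != length(v))
    stop("jaccard: vectors must have equal length")
  inter <- sum(u == 1 & v == 1)
  uni <- sum(u == 1 | v == 1)
  if (uni == 0) 1 else inter / uni
}

#' Jaccard index of one binary vector against the rows of a binary matrix
#'
#' Vectorized companion of [jaccard()] used in recognition scoring.
#'
#' @param u binary vector.
#' @param m binary matrix with `ncol(m) == length(u)`.
#' @return Numeric vector of `nrow(m)` similarities.
#' @export
jaccard_rows <- function(u, m) {
  if (ncol(m) != length(u)) stop("jaccard_rows: dimension mismatch")
  ones <- m == 1
  inter <- as.numeric(ones %*% (u == 1))
  uni <- rowSums(ones) + sum(u == 1) - inter
  ifelse(uni == 0, 1, inter / uni)
}

#' Table of pairwise Jaccard indices
#'
#' All unordered item pairs (self-pairs excluded) of a binary
#' representation matrix.
#'
#' @param m items-by-dims binary matrix with item ids as row names.
#' @param kind optional label recorded in the `kind` column.
#' @return Data frame `item_a`, `item_b`, `kind`, `jaccard` with
#'   `n * (n - 1) / 2` rows.
#' @export
pairwise_jaccard_table <- function(m, kind = NA_character_) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("pairwise_jaccard_table: matrix must be binary")
  n <- nrow(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ones <- m == 1
  inter <- tcrossprod(ones)
  rs <- rowSums(ones)
  uni <- outer(rs, rs, "+") - inter
  jac <- ifelse(uni == 0, 1, inter / uni)
  idx <- which(upper.tri(jac), arr.ind = TRUE)
  data.frame(item_a = ids[idx[, 1L]], item_b = ids[idx[, 2L]],
             kind = kind, jaccard = jac[idx],
             stringsAsFactors = FALSE)
}

#' Look up one pair in a pairwise Jaccard table
#'
#' @param tab output of [pairwise_jaccard_table()].
#' @param a,b item ids (order irrelevant).
#' @return The Jaccard index of the pair.
#' @export
pair_jaccard <- function(tab, a, b) {
  hit <- (tab$item_a == a & tab$item_b == b) |
         (tab$item_a == b & tab$item_b == a)
  if (!any(hit)) stop(sprintf("pair (%s, %s) not in table", a, b))
  tab$jaccard[which(hit)[1L]]
}

#' Aggregate the static training target
#'
#' Concatenates the semantic, visual, and lexical binary vectors (in that
#' fixed order) into one target vector, recording segment boundaries.
#'
#' @param sem,vis,lex binary vectors (default expected lengths 100, 150,
#'   200; any consistent lengths are accepted).
#' @param dims optional named list/vector `c(semantic=, visual=, lexical=)`
#'   to validate against.
#' @return Numeric vector of length `sum(lengths)` with attribute
#'   `segments`, a named list of index ranges.
#' @export
aggregate_target <- function(sem, vis, lex, dims = NULL) {
  if (!is.null(dims)) {
    dims <- unlist(dims)
    got <- c(semantic = length(sem), visual = length(vis), lexical = length(lex))
    bad <- names(got)[got != dims[names(got)]]
    if (length(bad))
      stop(sprintf("segment length mismatch for %s", paste(bad, collapse = ", ")))
  }
  out <- c(sem, vis, lex)
  attr(out, "segments") <- target_segments(length(sem), length(vis), length(lex))
  out
}

#' Segment index ranges of an aggregated target
#'
#' @param n_sem,n_vis,n_lex segment lengths.
#' @return Named list of integer index vectors `semantic`, `visual`,
#'   `lexical`, and the combined `semvis`.
#' @export
target_segments <- function(n_sem, n_vis, n_lex) {
  list(semantic = seq_len(n_sem),
       visual = n_sem + seq_len(n_vis),
       lexical = n_sem + n_vis + seq_len(n_lex),
       semvis = seq_len(n_sem + n_vis))
}

#' Preprocess a semantic embedding matrix
#'
#' Outlier replacement ([replace_outliers()]) followed by median
#' binarization ([binarize_by_median()]); no dimensionality reduction.
#' Already-binary matrices are returned unchanged (synthetic semantic
#' matrices are generated directly in binarized form).
#'
#' @param m items-by-dims numeric matrix.
#' @param z_cut outlier z-score threshold.
#' @return Binary matrix, same shape.
#' @export
preprocess_semantic <- function(m, z_cut = 2) {
  m <- as.matrix(m)
  if (all(m %in% c(0, 1))) return(m)
  binarize_by_median(replace_outliers(m, z_cut))
}

#' Preprocess a visual embedding matrix
#'
#' Outlier replacement, principal component reduction to `k` dimensions,
#' then median binarization, in that order.
#'
#' @param m items-by-dims numeric matrix.
#' @param k target dimensionality (150 at full scale; bounded by
#'   `items - 1`).
#' @param z_cut outlier z-score threshold.
#' @return List with binary `matrix` (items by `k`) and
#'   `variance_explained`.
#' @export
preprocess_visual <- function(m, k = 150L, z_cut = 2) {
  red <- reduce_dims(replace_outliers(as.matrix(m), z_cut), k)
  list(matrix = binarize_by_median(red$scores),
       variance_explained = red$variance_explained)
}
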