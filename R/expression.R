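# Expression summarization: CPM normalization, log2 transform, expressed-gene
# flagging and hierarchical clustering of the log2-CPM matrix.

#' Read a count matrix TSV
#'
#' Genes in rows (first column = gene id), samples in columns, header row of
#' sample ids.
#'
#' @param path Path to the TSV.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = 1L)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  validate_count_matrix(m)
  m
}

validate_count_matrix <- function(m) {
  if (anyDuplicated(rownames(m))) stop2("duplicate gene ids in count matrix")
  if (anyDuplicated(colnames(m))) stop2("duplicate sample ids in count matrix")
  if (any(m < 0)) stop2("negative counts in count matrix")
  if (all(colSums(m) == 0)) stop2("count matrix has no nonzero column")
  invisible(m)
}

#' CPM normalization and log2 transform
#'
#' `cpm[g, s] = counts[g, s] * 1e6 / colsum[s]`, then
#' `log2(cpm + pseudocount)`.  The pseudocount (default 1, so a zero count
#' maps to 0) stabilizes the log at low counts.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param pseudocount Added to CPM before the log.
#' @return Numeric matrix of log2(CPM + pseudocount) values; the raw CPM
#'   matrix is attached as attribute `"cpm"`.
#' @export
cpm_log2 <- function(counts, pseudocount = 1) {
  validate_count_matrix(counts)
  libsize <- colSums(counts)
  zero <- libsize == 0
  if (any(zero)) {
    stop2("zero column sum for sample: ", colnames(counts)[zero][1L])
  }
  cpm <- sweep(counts, 2L, libsize, `/`) * 1e6
  out <- log2(cpm + pseudocount)
  attr(out, "cpm") <- cpm
  out
}

#' Flag expressed genes
#'
#' A gene is expressed iff its CPM reaches `min_cpm` in at least one sample.
#' The criterion (CPM >= 1 in >= 1 sample by default) is a conventional
#' presence filter, deliberately permissive; it is echoed into pipeline
#' summaries so downstream censuses are reproducible.
#'
#' @param log2cpm Matrix from [cpm_log2()] (its `"cpm"` attribute is used,
#'   falling back to inverting the log if absent).
#' @param min_cpm Minimum CPM.
#' @param pseudocount Pseudocount used in the transform (for the fallback
#'   inversion).
#' @return Named logical vector per gene.
#' @export
flag_expressed <- function(log2cpm, min_cpm = 1, pseudocount = 1) {
  cpm <- attr(log2cpm, "cpm") %||% (2^log2cpm - pseudocount)
  apply(cpm, 1L, function(x) any(x >= min_cpm))
}

#' Row and column orderings from hierarchical clustering
#'
#' Agglomerative clustering (via [stats::hclust()]) of genes and samples on
#' the log2-CPM matrix.  Euclidean distance with complete linkage by default;
#' average linkage available.  Leaf order is `hclust`'s deterministic order
#' (ties resolved by input index), so repeated runs agree.
#'
#' @param log2cpm Numeric matrix, genes x samples (>= 2 of each).
#' @param distance Distance metric (`"euclidean"`).
#' @param linkage `"complete"` or `"average"`.
#' @return A list with `gene_order`, `sample_order` (integer permutations),
#'   and the two dendrograms `gene_hclust`, `sample_hclust`.
#' @export
cluster_heatmap_order <- function(log2cpm, distance = "euclidean",
                                  linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance, "euclidean")
  stopifnot(nrow(log2cpm) >= 2L, ncol(log2cpm) >= 2L)
  gh <- stats::hclust(stats::dist(log2cpm, method = distance),
                      method = linkage)
  sh <- stats::hclust(stats::dist(t(log2cpm), method = distance),
                      method = linkage)
  list(gene_order = gh$order, sample_order = sh$order,
       gene_hclust = gh, sample_hclust = sh)
}
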