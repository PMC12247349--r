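# Duplicate-pair detection and classification: all-vs-all similarity scan,
# tandem / segmental / homoeolog labeling, tandem clusters and summaries.

#' Duplicate-pair criteria
#'
#' Defaults follow the standard gene-family duplication screen: members of a
#' pair must show at least 80% similarity with more than 80% alignment
#' coverage of both genes; qualifying pairs within 1 Mb on one chromosome are
#' tandem, all others segmental (or homoeologous in an allotetraploid).
#'
#' @param max_tandem_distance_bp Maximum separation for a tandem pair.
#' @param min_identity_pct Minimum percent similarity (inclusive).
#' @param min_coverage_pct Minimum percent coverage (exclusive, both genes).
#' @param distance_anchor `"start"` (start-to-start, default) or `"gap"`
#'   (end-to-start gap between the genes).
#' @return A list of class `duplication_criteria`.
#' @export
duplication_criteria <- function(max_tandem_distance_bp = 1000000L,
                                 min_identity_pct = 80,
                                 min_coverage_pct = 80,
                                 distance_anchor = c("start", "gap")) {
  stopifnot(max_tandem_distance_bp > 0, min_identity_pct > 0,
            min_coverage_pct > 0)
  structure(list(max_tandem_distance_bp = as.integer(max_tandem_distance_bp),
                 min_identity_pct = min_identity_pct,
                 min_coverage_pct = min_coverage_pct,
                 distance_anchor = match.arg(distance_anchor)),
            class = "duplication_criteria")
}

#' All-vs-all scan for candidate duplicate pairs
#'
#' Globally aligns every unordered pair of family representatives and retains
#' pairs with identity at or above `min_identity_pct` and coverage above
#' `min_coverage_pct` for *both* genes.  Each retained pair appears once,
#' with `gene_a < gene_b` lexicographically; self-pairs are never formed.
#' If three genes mutually qualify, all three pairs are reported (no
#' transitive reduction) — duplicate counts are pair counts.
#'
#' @param representatives Representative table from
#'   [select_longest_isoform()], restricted to family genes.
#' @param criteria A [duplication_criteria()] object.
#' @param scoring An [alignment_scoring()] object.
#' @return Data frame `gene_a`, `gene_b`, `identity_pct`, `coverage_a_pct`,
#'   `coverage_b_pct` (unlabeled pairs).
#' @export
candidate_pairs <- function(representatives,
                            criteria = duplication_criteria(),
                            scoring = alignment_scoring()) {
  genes <- representatives$gene_id
  seqs <- setNames(representatives$seq, genes)
  n <- length(genes)
  if (n < 2L) {
    return(empty_pair_frame())
  }
  rows <- list()
  for (i in seq_len(n - 1L)) {
    others <- seq(i + 1L, n)
    st <- align_stats_many(seqs[[i]], seqs[others], scoring)
    keep <- st$identity_pct >= criteria$min_identity_pct &
      st$coverage_a_pct > criteria$min_coverage_pct &
      st$coverage_b_pct > criteria$min_coverage_pct
    if (any(keep)) {
      kept <- others[keep]
      a <- pmin(genes[i], genes[kept]); b <- pmax(genes[i], genes[kept])
      swap <- genes[i] > genes[kept]
      cov_a <- ifelse(swap, st$coverage_b_pct[keep], st$coverage_a_pct[keep])
      cov_b <- ifelse(swap, st$coverage_a_pct[keep], st$coverage_b_pct[keep])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, identity_pct = st$identity_pct[keep],
        coverage_a_pct = cov_a, coverage_b_pct = cov_b,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_pair_frame())
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_pair_frame <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             identity_pct = numeric(), coverage_a_pct = numeric(),
             coverage_b_pct = numeric(), stringsAsFactors = FALSE)
}

#' Classify duplicate pairs as tandem, segmental or homoeolog
#'
#' A pair on one chromosome separated by at most the tandem distance is
#' tandem; otherwise, in subgenome mode, a pair sitting on homoeologous
#' partner chromosomes (same chromosome number, differing subgenome suffixes)
#' is a homoeolog pair — parental homologs inherited by the allotetraploid
#' rather than true duplications; everything else is segmental.  Distance is
#' measured start-to-start by default (`distance_anchor = "gap"` switches to
#' the end-to-start gap) and is only defined within a chromosome.
#'
#' @param pairs Data frame from [candidate_pairs()].
#' @param coords Gene-coordinate data frame covering all paired genes.
#' @param criteria A [duplication_criteria()] object.
#' @param subgenome_mode Logical; enable homoeolog labeling.
#' @param subgenome_suffixes Two single characters naming the subgenomes
#'   (defaults `c("c", "e")`, the maternal/paternal convention for an
#'   allotetraploid with labeled parental chromosomes).
#' @return `pairs` with `chrom_a`, `chrom_b`, `same_chromosome`,
#'   `distance_bp` (NA across chromosomes) and `label` columns.
#' @export
classify_pairs <- function(pairs, coords,
                           criteria = duplication_criteria(),
                           subgenome_mode = FALSE,
                           subgenome_suffixes = c("c", "e")) {
  gene_pos <- coords[!duplicated(coords$gene_id),
                     c("gene_id", "chromosome", "start", "end")]
  lookup <- function(g, what) {
    idx <- match(g, gene_pos$gene_id)
    if (anyNA(idx)) stop2("no coordinates for gene ", g[is.na(idx)][1L])
    gene_pos[[what]][idx]
  }
  pairs$chrom_a <- lookup(pairs$gene_a, "chromosome")
  pairs$chrom_b <- lookup(pairs$gene_b, "chromosome")
  pairs$same_chromosome <- pairs$chrom_a == pairs$chrom_b
  start_a <- lookup(pairs$gene_a, "start"); end_a <- lookup(pairs$gene_a, "end")
  start_b <- lookup(pairs$gene_b, "start"); end_b <- lookup(pairs$gene_b, "end")
  dist <- if (criteria$distance_anchor == "start") {
    abs(start_a - start_b)
  } else {
    pmax(pmax(start_a, start_b) - pmin(end_a, end_b), 0L)
  }
  pairs$distance_bp <- ifelse(pairs$same_chromosome, dist, NA_integer_)
  pa <- parse_chromosome(pairs$chrom_a)
  pb <- parse_chromosome(pairs$chrom_b)
  homoeologous <- subgenome_mode &
    !pairs$same_chromosome &
    !is.na(pa$number) & !is.na(pb$number) & pa$number == pb$number &
    !is.na(pa$suffix) & !is.na(pb$suffix) & pa$suffix != pb$suffix &
    pa$suffix %in% subgenome_suffixes & pb$suffix %in% subgenome_suffixes
  pairs$label <- ifelse(
    pairs$same_chromosome & pairs$distance_bp <= criteria$max_tandem_distance_bp,
    "tandem", ifelse(homoeologous, "homoeolog", "segmental"))
  pairs
}

#' Tandem duplicate clusters
#'
#' Connected components of the tandem-pair graph; every cluster has at least
#' two members.  Cluster membership comes solely from tandem-pair
#' connectivity (nearby non-duplicate neighbours are never pulled in).
#'
#' @param pairs Labeled pair table; only rows with `label == "tandem"` are
#'   used.
#' @param coords Optional coordinates to annotate each cluster's chromosome
#'   and span.
#' @return Data frame `cluster`, `genes` (comma-separated, sorted), `size`,
#'   and, when coordinates are given, `chromosome`, `span_start`, `span_end`.
#' @export
tandem_clusters <- function(pairs, coords = NULL) {
  tp <- pairs[pairs$label == "tandem", , drop = FALSE]
  if (nrow(tp) == 0L) {
    return(data.frame(cluster = integer(), genes = character(),
                      size = integer(), stringsAsFactors = FALSE))
  }
  genes <- sort(unique(c(tp$gene_a, tp$gene_b)))
  # union-find over gene indices
  parent <- seq_along(genes)
  findi <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(tp))) {
    i <- findi(match(tp$gene_a[r], genes))
    j <- findi(match(tp$gene_b[r], genes))
    if (i != j) parent[j] <- i
  }
  roots <- vapply(seq_along(genes), findi, integer(1))
  groups <- split(genes, roots)
  groups <- groups[order(vapply(groups, `[`, character(1), 1L))]
  out <- data.frame(cluster = seq_along(groups),
                    genes = vapply(groups, function(g)
                      paste(sort(g), collapse = ","), character(1)),
                    size = lengths(groups), stringsAsFactors = FALSE)
  if (!is.null(coords)) {
    gene_pos <- coords[!duplicated(coords$gene_id), ]
    out$chromosome <- vapply(groups, function(g) {
      unique(gene_pos$chromosome[match(g, gene_pos$gene_id)])[1L]
    }, character(1))
    out$span_start <- vapply(groups, function(g)
      min(gene_pos$start[match(g, gene_pos$gene_id)]), numeric(1))
    out$span_end <- vapply(groups, function(g)
      max(gene_pos$end[match(g, gene_pos$gene_id)]), numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Summary counts of duplicate pairs
#'
#' Reports both accounting conventions: `n_segmental_strict` counts only
#' non-homoeologous cross-chromosome pairs, while `n_segmental_incl_homoeolog`
#' folds homoeolog pairs into the segmental headline (the convention under
#' which an allotetraploid's homoeologous pairs are first reported as
#' segmental and then split out).
#'
#' @param pairs Labeled pair table.
#' @param species Optional species tag echoed into the output.
#' @return One-row data frame of counts.
#' @export
duplication_summary <- function(pairs, species = NA_character_) {
  stopifnot(all(pairs$label %in% c("tandem", "segmental", "homoeolog")))
  n_t <- sum(pairs$label == "tandem")
  n_s <- sum(pairs$label == "segmental")
  n_h <- sum(pairs$label == "homoeolog")
  data.frame(species = species, n_pairs = nrow(pairs), n_tandem = n_t,
             n_segmental_strict = n_s, n_homoeolog = n_h,
             n_segmental_incl_homoeolog = n_s + n_h,
             stringsAsFactors = FALSE)
}

#' Export a link table for circos-style plotting
#'
#' @param pairs Labeled pair table from [classify_pairs()].
#' @param coords Gene-coordinate data frame.
#' @return Data frame `chrom_a`, `start_a`, `chrom_b`, `start_b`, `label`.
#' @export
pair_link_table <- function(pairs, coords) {
  gene_pos <- coords[!duplicated(coords$gene_id), ]
  data.frame(chrom_a = pairs$chrom_a,
             start_a = gene_pos$start[match(pairs$gene_a, gene_pos$gene_id)],
             chrom_b = pairs$chrom_b,
             start_b = gene_pos$start[match(pairs$gene_b, gene_pos$gene_id)],
             label = pairs$label, stringsAsFactors = FALSE)
}
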