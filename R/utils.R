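#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats dhyper setNames rbinom rnbinom runif
#' @importFrom utils read.table write.table combn
NULL

# Natural-sort key for chromosome names.  Placed chromosomes are names of the
# form "<number><optional subgenome letter>" (e.g. "2", "2c", "11e"); anything
# else is treated as an unplaced contig and ordered after all placed
# chromosomes, alphabetically.
chrom_sort_key <- function(chrom) {
  placed <- grepl("^[0-9]+[A-Za-z]?$", chrom)
  num <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", chrom)))
  num[!placed] <- NA_integer_
  suffix <- ifelse(placed, sub("^[0-9]+", "", chrom), chrom)
  list(placed = placed, num = num, suffix = suffix)
}

#' Order genes by chromosome (natural sort), then start coordinate
#'
#' Chromosome names are sorted naturally (`2` before `10`), with subgenome
#' suffixes breaking ties alphabetically (`2c` before `2e`); unplaced contigs
#' come last in alphabetical order.  Within a chromosome, genes are ordered by
#' start coordinate, then by `gene_id`.
#'
#' @param coords A gene-coordinate data frame (see [read_coordinates()]), one
#'   row per gene (or per transcript; all rows of a gene share coordinates).
#' @return An integer permutation of `seq_len(nrow(coords))`.
#' @export
order_genes_by_position <- function(coords) {
  key <- chrom_sort_key(coords$chromosome)
  order(!key$placed, key$num, key$suffix, coords$start, coords$gene_id,
        na.last = TRUE)
}

# Split a chromosome label into (number, subgenome suffix); NA number for
# contigs.  The suffix convention ('c'/'e' in an allotetraploid coffee genome)
# is configurable downstream; this helper is purely lexical.
parse_chromosome <- function(chrom) {
  key <- chrom_sort_key(chrom)
  data.frame(chromosome = chrom, number = key$num,
             suffix = ifelse(key$placed, key$suffix, NA_character_),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
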