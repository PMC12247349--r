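# Family identification: longest-isoform representatives, domain-hit
# filtering at an E-value threshold, architecture-based subfamily calls and
# systematic nomenclature.

#' Identification thresholds
#'
#' E-value ceilings for accepting AP2 (PF00847) and B3 (PF02362) profile hits.
#' The default, 1e-5 for both, is the conventional cutoff for profile-HMM
#' domain searches in gene-family surveys.
#'
#' @param ap2_evalue_max Maximum E-value for an AP2 hit to qualify.
#' @param b3_evalue_max Maximum E-value for a B3 hit to qualify.
#' @return A list of class `identification_thresholds`.
#' @export
identification_thresholds <- function(ap2_evalue_max = 1e-5,
                                      b3_evalue_max = 1e-5) {
  stopifnot(ap2_evalue_max > 0, b3_evalue_max > 0)
  structure(list(ap2_evalue_max = ap2_evalue_max,
                 b3_evalue_max = b3_evalue_max),
            class = "identification_thresholds")
}

#' Select the longest protein isoform per gene
#'
#' For genes annotated with several splicing variants, the longest protein is
#' taken as the gene's representative.  Length ties are broken by the
#' lexicographically smallest `protein_id`, so output is deterministic.
#'
#' @param proteins Named character vector of protein sequences (names are
#'   protein ids), e.g. from [read_fasta()].
#' @param coords Gene-coordinate data frame (one row per transcript).
#' @return A data frame with one row per gene: `gene_id`, `protein_id`,
#'   `length`, `seq`.
#' @export
select_longest_isoform <- function(proteins, coords) {
  missing <- setdiff(coords$protein_id, names(proteins))
  if (length(missing) > 0L) {
    gene <- coords$gene_id[match(missing[1L], coords$protein_id)]
    stop2("no protein sequence for gene ", gene,
          " (protein ", missing[1L], ")")
  }
  df <- unique(coords[c("gene_id", "protein_id")])
  df$length <- nchar(proteins[df$protein_id])
  df <- df[order(df$gene_id, -df$length, df$protein_id), ]
  df <- df[!duplicated(df$gene_id), ]
  df$seq <- unname(proteins[df$protein_id])
  rownames(df) <- NULL
  df
}

# Merge overlapping AP2 hit envelopes on one protein: two hits whose
# alignment intervals share >= `overlap_frac` of the shorter interval are
# counted as one domain (split HMM matches should not inflate the domain
# count).  Returns the number of merged domains.
merge_domain_count <- function(starts, ends, overlap_frac = 0.5) {
  n <- length(starts)
  if (n <= 1L) return(n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ov <- min(ends[i], ends[j]) - max(starts[i], starts[j]) + 1L
      shorter <- min(ends[i] - starts[i], ends[j] - starts[j]) + 1L
      if (ov >= overlap_frac * shorter) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Identify AP2/ERF family members from domain hits
#'
#' A gene belongs to the family iff its representative protein carries at
#' least one AP2 hit with E-value at or below the threshold.  The number of
#' AP2 domains is the number of qualifying hits after merging overlapping
#' envelopes (hits sharing at least half of the shorter envelope count once).
#' B3 hits are only consulted for proteins that already qualify by AP2,
#' mirroring the two-step search (AP2 first, B3 within the selected set).
#'
#' @param hits Domain-hit data frame from [read_domain_table()].
#' @param representatives Representative table from
#'   [select_longest_isoform()].
#' @param thresholds An [identification_thresholds()] object.
#' @param ap2_profile,b3_profile Profile names as used in the hit table.
#' @return A data frame with one row per family gene: `gene_id`,
#'   `protein_id`, `ap2_domain_count`, `has_b3`.
#' @export
identify_family <- function(hits, representatives,
                            thresholds = identification_thresholds(),
                            ap2_profile = "AP2", b3_profile = "B3") {
  stopifnot(inherits(thresholds, "identification_thresholds"))
  hits <- hits[hits$protein_id %in% representatives$protein_id, , drop = FALSE]
  ap2 <- hits[hits$profile == ap2_profile &
                hits$evalue <= thresholds$ap2_evalue_max, , drop = FALSE]
  if (nrow(ap2) == 0L) {
    return(data.frame(gene_id = character(), protein_id = character(),
                      ap2_domain_count = integer(), has_b3 = logical(),
                      stringsAsFactors = FALSE))
  }
  counts <- vapply(split(ap2, ap2$protein_id), function(h) {
    merge_domain_count(h$ali_start, h$ali_end)
  }, integer(1))
  b3 <- hits[hits$profile == b3_profile &
               hits$evalue <= thresholds$b3_evalue_max, , drop = FALSE]
  out <- data.frame(protein_id = names(counts),
                    ap2_domain_count = unname(counts),
                    has_b3 = names(counts) %in% b3$protein_id,
                    stringsAsFactors = FALSE)
  out$gene_id <- representatives$gene_id[match(out$protein_id,
                                               representatives$protein_id)]
  out <- out[order(out$gene_id), c("gene_id", "protein_id",
                                   "ap2_domain_count", "has_b3")]
  rownames(out) <- NULL
  out
}

#' Provisional subfamily from domain architecture
#'
#' Two or more AP2 domains places a gene in the AP2 subfamily; a single AP2
#' domain together with a B3 domain defines RAV; a single AP2 domain alone is
#' provisionally ERF.  Provisional-ERF calls may later be revised to AP2 or
#' Soloist by tree position ([resolve_single_domain_overrides()]).
#'
#' @param architecture Output of [identify_family()].
#' @return The same table with columns `subfamily` and `subfamily_basis`
#'   added; basis is `"domain_architecture"` for every row at this stage.
#' @export
classify_subfamily <- function(architecture) {
  if (nrow(architecture) > 0 && any(architecture$ap2_domain_count < 1L)) {
    stop2("classify_subfamily: gene with ap2_domain_count < 1")
  }
  sub <- ifelse(architecture$ap2_domain_count >= 2L, "AP2",
                ifelse(architecture$has_b3, "RAV", "ERF"))
  architecture$subfamily <- sub
  architecture$subfamily_basis <- rep("domain_architecture",
                                      nrow(architecture))
  architecture
}

#' Assign systematic gene names within each subfamily
#'
#' Names follow the species-prefix nomenclature used in gene-family surveys:
#' AP2, RAV and Soloist members get `<prefix><subfamily>.<n>` with unpadded
#' 1-based numbering (`CaAP2.1`), ERF members get `<prefix>ERF<nnn>`
#' zero-padded to three digits (`CaERF001`).  Numbering within a subfamily
#' follows chromosome natural-sort order then start coordinate (unplaced
#' contigs last).  The ordering rule is this package's own convention —
#' published surveys rarely state theirs — so names are reproducible across
#' runs but will not match any particular publication gene-for-gene.
#'
#' @param calls Classification table with `gene_id` and `subfamily` columns.
#' @param species_prefix Short species prefix, e.g. `"Ca"`.
#' @param coords Gene-coordinate data frame.
#' @return `calls` with an `assigned_name` column, ordered by position.
#' @export
assign_names <- function(calls, species_prefix, coords) {
  gene_pos <- coords[!duplicated(coords$gene_id),
                     c("gene_id", "chromosome", "start", "end")]
  missing <- setdiff(calls$gene_id, gene_pos$gene_id)
  if (length(missing) > 0L) {
    stop2("no coordinates for gene ", missing[1L])
  }
  idx <- match(calls$gene_id, gene_pos$gene_id)
  calls$chromosome <- gene_pos$chromosome[idx]
  calls$start <- gene_pos$start[idx]
  calls$end <- gene_pos$end[idx]
  calls <- calls[order_genes_by_position(calls), , drop = FALSE]
  calls$assigned_name <- NA_character_
  for (sub in unique(calls$subfamily)) {
    sel <- calls$subfamily == sub
    n <- seq_len(sum(sel))
    calls$assigned_name[sel] <- if (sub == "ERF") {
      sprintf("%sERF%03d", species_prefix, n)
    } else {
      sprintf("%s%s.%d", species_prefix, sub, n)
    }
  }
  stopifnot(!anyDuplicated(calls$assigned_name))
  rownames(calls) <- NULL
  calls
}

#' Intron count from exon count
#'
#' @param coords Gene-coordinate data frame (or any object with an
#'   `exon_count` column) or an integer vector of exon counts.
#' @return Integer vector of intron counts (`exon_count - 1`).
#' @export
count_introns <- function(coords) {
  ec <- if (is.data.frame(coords)) coords$exon_count else coords
  stopifnot(all(ec >= 1L))
  as.integer(ec) - 1L
}
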