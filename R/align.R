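# Pairwise global alignment, codon back-translation, similarity statistics
# and p-distance matrices.  Alignment itself is delegated to
# Biostrings::pairwiseAlignment (Needleman-Wunsch with affine gaps); the
# statistics layered on top follow this package's documented definitions.

#' Alignment scoring scheme
#'
#' Defaults are CLUSTALW-like: BLOSUM62 with affine gap penalties of 10 to
#' open and 0.5 per gap position.  A gap of length L therefore costs
#' `gap_open + L * gap_extend`.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`) or a numeric matrix with
#'   residue dimnames (an NCBI-format matrix loaded by the caller).
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return A list of class `alignment_scoring`.
#' @export
alignment_scoring <- function(matrix = "BLOSUM62", gap_open = 10,
                              gap_extend = 0.5) {
  mat <- if (is.character(matrix)) {
    get(data(list = matrix, package = "Biostrings",
             envir = environment()))
  } else matrix
  stopifnot(is.matrix(mat), gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = mat, gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_scoring")
}

check_residues <- function(seq, id, scoring) {
  ok <- rownames(scoring$matrix)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% ok)
  if (length(bad) > 0L) {
    stop2("illegal residue '", chars[bad[1L]], "' at position ", bad[1L],
          " of ", id)
  }
  invisible(TRUE)
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, via
#' [Biostrings::pairwiseAlignment()].  The optimal score is unique; among
#' co-optimal tracebacks Biostrings returns one deterministically, so repeated
#' runs give identical alignments.
#'
#' @param a,b Protein sequences (character scalars).
#' @param id_a,id_b Sequence identifiers used in error messages and output.
#' @param scoring An [alignment_scoring()] object.
#' @return A list of class `pairwise_alignment` with elements `id_a`, `id_b`,
#'   `aligned_a`, `aligned_b` (gapped strings of equal length) and `score`.
#' @export
global_align <- function(a, b, id_a = "a", id_b = "b",
                         scoring = alignment_scoring()) {
  stopifnot(nzchar(a), nzchar(b))
  check_residues(a, id_a, scoring)
  check_residues(b, id_b, scoring)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "global")
  rows <- full_aligned_rows(aln, a, b)
  out <- list(id_a = id_a, id_b = id_b,
              aligned_a = rows[[1]], aligned_b = rows[[2]],
              score = Biostrings::score(aln))
  class(out) <- "pairwise_alignment"
  out
}

# Full gapped rows of a global pairwise alignment.  pattern()/subject() give
# the aligned core (with internal gaps) quickly but omit residues sitting in
# terminal gap columns; those flanks are re-attached here, stacking the
# pattern's flank before the subject's (column order within a terminal gap
# region does not affect score, statistics or back-translation).
full_aligned_rows <- function(aln, a, b) {
  p_core <- Biostrings::pattern(aln)
  s_core <- Biostrings::subject(aln)
  core_a <- as.character(p_core)
  core_b <- as.character(s_core)
  a_lead <- substr(a, 1L, BiocGenerics::start(p_core) - 1L)
  a_trail <- substr(a, BiocGenerics::end(p_core) + 1L, nchar(a))
  b_lead <- substr(b, 1L, BiocGenerics::start(s_core) - 1L)
  b_trail <- substr(b, BiocGenerics::end(s_core) + 1L, nchar(b))
  gap <- function(s) strrep("-", nchar(s))
  list(paste0(a_lead, gap(b_lead), core_a, a_trail, gap(b_trail)),
       paste0(gap(a_lead), b_lead, core_b, gap(a_trail), b_trail))
}

# All-vs-one vectorized alignment (used by the all-pairs duplicate scan);
# returns a data frame of alignment stats of `others` against `target`.
# Identity and coverage are derived from nmatch/nmismatch (residue-residue
# column counts) without materializing the aligned strings, which keeps the
# all-vs-all scan fast.
align_stats_many <- function(target, others, scoring = alignment_scoring()) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(others), Biostrings::AAString(target),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "global")
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  rr <- nm + nmm  # residue-residue columns
  data.frame(identity_pct = 100 * nm / rr,
             coverage_a_pct = 100 * rr / nchar(target),
             coverage_b_pct = 100 * rr / nchar(others),
             row.names = NULL)
}

alignment_stats_strings <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  both <- ca != "-" & cb != "-"
  n_both <- sum(both)
  if (n_both == 0L) stop2("alignment has no residue-residue column")
  list(identity_pct = 100 * sum(ca[both] == cb[both]) / n_both,
       coverage_a_pct = 100 * n_both / sum(ca != "-"),
       coverage_b_pct = 100 * n_both / sum(cb != "-"))
}

#' Identity and coverage statistics of a pairwise alignment
#'
#' Identity is computed over residue-residue columns only (gapped columns are
#' excluded from both numerator and denominator); coverage of each sequence
#' is the fraction of its residues sitting in residue-residue columns.  These
#' are the operational definitions behind the duplicate-pair criterion
#' ("similarity" = identity, "coverage" = aligned-residue fraction); a
#' BLAST-style "positives" similarity can be obtained by passing
#' `similarity = "positives"` together with a scoring object.
#'
#' @param aln A `pairwise_alignment` from [global_align()].
#' @param similarity `"identity"` (default) or `"positives"` (score > 0 in
#'   the substitution matrix counts as similar).
#' @param scoring Required when `similarity = "positives"`.
#' @return A list with `identity_pct`, `coverage_a_pct`, `coverage_b_pct`.
#' @export
alignment_stats <- function(aln, similarity = c("identity", "positives"),
                            scoring = NULL) {
  similarity <- match.arg(similarity)
  out <- alignment_stats_strings(aln$aligned_a, aln$aligned_b)
  if (similarity == "positives") {
    stopifnot(inherits(scoring, "alignment_scoring"))
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    both <- ca != "-" & cb != "-"
    pos <- scoring$matrix[cbind(ca[both], cb[both])] > 0
    out$identity_pct <- 100 * sum(pos) / sum(both)
  }
  out
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned protein column becomes one codon column; protein gaps become
#' `"---"`.  The CDS must be exactly three times the protein length (one
#' terminal stop codon, if present, is stripped) and must translate to the
#' protein under the standard genetic code.
#'
#' @param aln A `pairwise_alignment` over proteins.
#' @param cds_a,cds_b Unaligned coding sequences for the two proteins.
#' @return A list of class `codon_alignment` with `id_a`, `id_b` and
#'   `codons_a`, `codons_b` (character vectors of 3-mers or `"---"`).
#' @export
backtranslate <- function(aln, cds_a, cds_b) {
  codons_for <- function(aligned, cds, id) {
    protein <- gsub("-", "", aligned)
    cds <- toupper(cds)
    if (nchar(cds) == 3L * (nchar(protein) + 1L) &&
        substr(cds, nchar(cds) - 2L, nchar(cds)) %in% c("TAA", "TAG", "TGA")) {
      cds <- substr(cds, 1L, nchar(cds) - 3L)
    }
    if (nchar(cds) != 3L * nchar(protein)) {
      stop2("CDS/protein length mismatch for ", id, ": ", nchar(cds),
            " nt vs ", nchar(protein), " aa")
    }
    codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
    aa <- translate_codons(codons)
    mismatch <- which(aa != strsplit(protein, "")[[1]])
    if (length(mismatch) > 0L) {
      stop2("CDS of ", id, " does not translate to its protein at codon ",
            mismatch[1L], " (", codons[mismatch[1L]], " -> ",
            aa[mismatch[1L]], ")")
    }
    cols <- strsplit(aligned, "")[[1]]
    out <- rep("---", length(cols))
    out[cols != "-"] <- codons
    out
  }
  out <- list(id_a = aln$id_a, id_b = aln$id_b,
              codons_a = codons_for(aln$aligned_a, cds_a, aln$id_a),
              codons_b = codons_for(aln$aligned_b, cds_b, aln$id_b))
  class(out) <- "codon_alignment"
  out
}

# Translate a vector of codons under the standard genetic code; stop codons
# give "*", codons with non-ACGT characters give "X".
translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Pairwise p-distance matrix with partial deletion
#'
#' From a multiple alignment, sites whose non-gap coverage falls below
#' `min_site_coverage` are removed globally (partial deletion); for each
#' sequence pair the remaining columns where either row has a gap are skipped,
#' and the distance is the proportion of mismatching compared sites
#' (p-distance, uniform rates across sites).
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param min_site_coverage Minimum non-gap fraction for a site to be kept
#'   (default 0.9, i.e. sites with less than 90% data coverage are deleted).
#' @return A list of class `distance_matrix`: `labels`, `d` (symmetric
#'   matrix, zero diagonal), `sites_used`.
#' @export
pdistance_matrix <- function(msa, min_site_coverage = 0.9) {
  stopifnot(length(msa) >= 2L, !is.null(names(msa)))
  mat <- do.call(rbind, strsplit(unname(msa), ""))
  if (length(unique(nchar(msa))) != 1L) {
    stop2("aligned sequences differ in length")
  }
  gap <- mat == "-"
  coverage <- 1 - colMeans(gap)
  keep <- coverage >= min_site_coverage
  mat <- mat[, keep, drop = FALSE]
  gap <- gap[, keep, drop = FALSE]
  n <- length(msa)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop2("no comparable sites between ", names(msa)[i], " and ",
              names(msa)[j])
      }
      d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
    }
  }
  structure(list(labels = names(msa), d = d, sites_used = sum(keep)),
            class = "distance_matrix")
}

#' Naive progressive multiple alignment
#'
#' A deliberately simple progressive aligner for self-contained analyses and
#' tests: sequences are added in order of decreasing similarity to the
#' growing alignment, each new sequence is globally aligned against its most
#' similar already-aligned member, and gaps are propagated to all rows.  This
#' is *not* a reimplementation of MUSCLE; for publication-grade trees an
#' externally computed aligned FASTA (e.g. MUSCLE output) can be supplied to
#' [pdistance_matrix()] directly.
#'
#' @param seqs Named character vector of protein sequences (>= 2).
#' @param scoring An [alignment_scoring()] object.
#' @return Named character vector of equal-length aligned sequences, in the
#'   input order.
#' @export
progressive_align <- function(seqs, scoring = alignment_scoring()) {
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  if (n == 2L) {
    aln <- global_align(seqs[[1]], seqs[[2]], names(seqs)[1], names(seqs)[2],
                        scoring)
    out <- c(aln$aligned_a, aln$aligned_b)
    names(out) <- names(seqs)
    return(out)
  }
  # similarity = alignment score of each pair (cheap proxy for identity)
  sim <- matrix(-Inf, n, n)
  for (i in seq_len(n - 1L)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[seq(i + 1L, n)]),
      Biostrings::AAString(seqs[[i]]),
      substitutionMatrix = scoring$matrix, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, type = "global", scoreOnly = TRUE)
    sim[i, seq(i + 1L, n)] <- sim[seq(i + 1L, n), i] <- aln
  }
  start <- which(sim == max(sim), arr.ind = TRUE)[1L, ]
  in_msa <- sort(c(start[["row"]], start[["col"]]))
  aln0 <- global_align(seqs[[in_msa[1]]], seqs[[in_msa[2]]], scoring = scoring)
  msa <- c(aln0$aligned_a, aln0$aligned_b)
  names(msa) <- names(seqs)[in_msa]
  remaining <- setdiff(seq_len(n), in_msa)
  while (length(remaining) > 0L) {
    best_sim <- vapply(remaining, function(r) max(sim[r, in_msa]), numeric(1))
    nxt <- remaining[which.max(best_sim)]
    rep_idx <- in_msa[which.max(sim[nxt, in_msa])]
    msa <- msa_add(msa, names(seqs)[rep_idx], seqs[[nxt]], names(seqs)[nxt],
                   scoring)
    in_msa <- c(in_msa, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  msa[names(seqs)]
}

# Add sequence `s` to an MSA by aligning it to member `rep_name` and mapping
# new gaps through to every row.
msa_add <- function(msa, rep_name, s, s_name, scoring) {
  rep_gapped <- strsplit(msa[[rep_name]], "")[[1]]
  rep_plain <- gsub("-", "", msa[[rep_name]])
  aln <- global_align(rep_plain, s, rep_name, s_name, scoring)
  rep_aln <- strsplit(aln$aligned_a, "")[[1]]
  s_aln <- strsplit(aln$aligned_b, "")[[1]]
  # walk both gapped versions of the representative, merging gap patterns
  i <- 1L; j <- 1L
  cols <- list()  # each element: c(source_msa_col or NA, source_s_col or NA)
  ncol_msa <- length(rep_gapped); ncol_aln <- length(rep_aln)
  out_msa_idx <- integer(0)  # msa column index per output column, NA = gap
  out_s_chr <- character(0)  # character of s per output column
  while (i <= ncol_msa || j <= ncol_aln) {
    msa_res <- i <= ncol_msa && rep_gapped[i] != "-"
    aln_res <- j <= ncol_aln && rep_aln[j] != "-"
    if (i <= ncol_msa && !msa_res) {
      # gap column already in the MSA: s gets a gap
      out_msa_idx <- c(out_msa_idx, i); out_s_chr <- c(out_s_chr, "-")
      i <- i + 1L
    } else if (j <= ncol_aln && !aln_res) {
      # new gap in the representative: all MSA rows get a gap
      out_msa_idx <- c(out_msa_idx, NA_integer_)
      out_s_chr <- c(out_s_chr, s_aln[j])
      j <- j + 1L
    } else {
      # both are residues of the representative: columns correspond
      out_msa_idx <- c(out_msa_idx, i); out_s_chr <- c(out_s_chr, s_aln[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  new_msa <- vapply(msa, function(row) {
    chars <- strsplit(row, "")[[1]]
    paste(ifelse(is.na(out_msa_idx), "-", chars[out_msa_idx]), collapse = "")
  }, character(1))
  new_msa[[s_name]] <- paste(out_s_chr, collapse = "")
  new_msa
}
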