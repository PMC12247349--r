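# Readers and writers for the external formats the pipeline touches:
# FASTA (protein and CDS), HMMER3 per-domain tables, gene-coordinate TSVs and
# Newick trees.  All coordinates are 1-based, fully closed intervals (NCBI
# feature-table convention).

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' pipeline's sequence-record invariants: identifiers must be non-empty and
#' unique within a file, residues are uppercased, and the alphabet is checked
#' when `type` is given.
#'
#' @param path Path to a FASTA file.
#' @param type `"AA"`, `"DNA"` or `"any"`.  `"AA"` admits IUPAC one-letter
#'   amino-acid codes plus `X` and `*`; `"DNA"` admits `ACGTN`.
#' @return A named character vector of sequences; names are the first
#'   whitespace-delimited token of each header, the full headers are kept in
#'   the `"description"` attribute.
#' @export
read_fasta <- function(path, type = c("any", "AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop2("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop2("no records in FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(ids == "")) stop2("empty sequence identifier in ", path)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop2("duplicate identifier in ", path, ": ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop2("empty sequence for record: ", ids[!nzchar(seqs)][1L])
  }
  alphabet_check(seqs, ids, type)
  names(seqs) <- ids
  attr(seqs, "description") <- setNames(headers, ids)
  seqs
}

alphabet_check <- function(seqs, ids, type) {
  pattern <- switch(type,
    any = NULL,
    AA  = "^[ACDEFGHIKLMNPQRSTVWYBZJUOX*]+$",
    DNA = "^[ACGTN]+$")
  if (is.null(pattern)) return(invisible(TRUE))
  bad <- !grepl(pattern, seqs)
  if (any(bad)) {
    stop2("illegal ", if (type == "AA") "amino-acid" else "nucleotide",
          " residues in record: ", ids[bad][1L])
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a profile-domain hit table
#'
#' Parses per-domain hits for profile HMM searches (e.g. the AP2 profile
#' PF00847 and the B3 profile PF02362 run against a proteome).  Two dialects
#' are supported:
#'
#' * `"tsv"` — whitespace/tab-separated columns
#'   `protein_id, profile, evalue, ali_start, ali_end`, no header,
#'   `#` comments allowed.
#' * `"hmmer_domtblout"` — the per-domain table written by
#'   `hmmsearch --domtblout` (profile as query, protein as target); the
#'   independent (i-)E-value column is used as the hit E-value and the
#'   alignment coordinates as `ali_start`/`ali_end`.
#'
#' @param path Path to the hit table.
#' @param dialect `"tsv"` or `"hmmer_domtblout"`.
#' @return A data frame with columns `protein_id`, `profile`, `evalue`,
#'   `ali_start`, `ali_end`; zero rows for a comment-only file.
#' @export
read_domain_table <- function(path, dialect = c("tsv", "hmmer_domtblout")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(data.frame(protein_id = character(), profile = character(),
                      evalue = numeric(), ali_start = integer(),
                      ali_end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  pick <- switch(dialect,
    tsv = list(n_min = 5L, protein = 1L, profile = 2L, evalue = 3L,
               from = 4L, to = 5L),
    # domtblout columns: 1 target(protein) 4 query(profile) 13 i-Evalue
    # 18 ali_from 19 ali_to
    hmmer_domtblout = list(n_min = 19L, protein = 1L, profile = 4L,
                           evalue = 13L, from = 18L, to = 19L))
  parse_row <- function(i) {
    f <- fields[[i]]
    if (length(f) < pick$n_min) {
      stop2("malformed domain-table row at line ", lineno[i], " of ", path)
    }
    ev <- suppressWarnings(as.numeric(f[pick$evalue]))
    a <- suppressWarnings(as.integer(f[pick$from]))
    b <- suppressWarnings(as.integer(f[pick$to]))
    if (is.na(ev) || !is.finite(ev) || ev < 0 || is.na(a) || is.na(b) ||
        a < 1L || b < a) {
      stop2("malformed domain-table row at line ", lineno[i], " of ", path)
    }
    data.frame(protein_id = f[pick$protein], profile = f[pick$profile],
               evalue = ev, ali_start = a, ali_end = b,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_along(fields), parse_row))
}

COORD_COLUMNS <- c("gene_id", "chromosome", "start", "end", "strand",
                   "exon_count", "protein_id", "transcript_id")

#' Read a gene-coordinate table
#'
#' The coordinate contract is a flat tab-separated table distilled from an
#' NCBI-style annotation, with a header row naming the columns `gene_id`,
#' `chromosome`, `start`, `end`, `strand`, `exon_count`, `protein_id`,
#' `transcript_id` (one row per transcript; multi-isoform genes have several
#' rows).  Coordinates are 1-based closed intervals in bp.  Chromosome names
#' are kept verbatim, so subgenome-suffixed labels like `"1c"` survive.
#' Strand is carried through the pipeline but never used by downstream
#' computations (all distance/similarity criteria are strand-agnostic).
#'
#' @param path Path to the TSV.
#' @return A data frame with the eight typed columns above.
#' @export
read_coordinates <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                   quote = "", comment.char = "", stringsAsFactors = FALSE)
  missing <- setdiff(COORD_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop2("coordinate table ", path, " lacks columns: ",
          paste(missing, collapse = ", "))
  }
  df <- df[COORD_COLUMNS]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$exon_count <- as.integer(df$exon_count)
  if (any(is.na(df$start) | is.na(df$end) | is.na(df$exon_count))) {
    stop2("non-numeric start/end/exon_count in ", path)
  }
  if (any(df$start < 1L)) {
    stop2("coordinate error: start < 1 for gene ",
          df$gene_id[df$start < 1L][1L])
  }
  bad <- df$end < df$start
  if (any(bad)) {
    stop2("coordinate error: end < start for gene ", df$gene_id[bad][1L])
  }
  if (any(df$exon_count < 1L)) {
    stop2("coordinate error: exon_count < 1 for gene ",
          df$gene_id[df$exon_count < 1L][1L])
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop2("strand must be '+' or '-' in ", path)
  }
  if (anyDuplicated(df[c("gene_id", "transcript_id")])) {
    stop2("duplicate (gene_id, transcript_id) in ", path)
  }
  df
}

#' Write a gene-coordinate table
#'
#' @param coords Data frame as returned by [read_coordinates()].
#' @param path Output path.
#' @export
write_coordinates <- function(coords, path) {
  stopifnot(all(COORD_COLUMNS %in% names(coords)))
  write.table(coords[COORD_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#'
#' Serializes an [ape::phylo] tree with branch lengths and a terminating
#' semicolon.  Leaf labels containing Newick metacharacters or whitespace are
#' sanitized by `ape`'s convention: spaces become underscores.
#'
#' @param tree An object of class `phylo`.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop2("no tree in ", path)
  tree
}
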