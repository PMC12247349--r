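# Nei-Gojobori (1986) Ka/Ks estimation on codon alignments: synonymous /
# nonsynonymous site counting, pathway-averaged substitution counting,
# Jukes-Cantor correction, and Fisher's exact significance test.

NUCS <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# per-codon and per-codon-pair NG86 counts are cached (61 sense codons)
.ng86_cache <- new.env(parent = emptyenv())

codon_ok <- function(codon) {
  nchar(codon) == 3L & !is.na(Biostrings::GENETIC_CODE[codon]) &
    !(codon %in% STOP_CODONS)
}

#' Synonymous and nonsynonymous site counts of one codon (NG86)
#'
#' Each of the nine single-nucleotide changes contributes 1/3 of a site:
#' synonymous if the encoded amino acid is unchanged, otherwise
#' nonsynonymous.  Changes into stop codons count as nonsynonymous.  The two
#' counts always sum to 3.
#'
#' @param codon A sense codon over `ACGT`.
#' @return Named numeric vector `c(s = ..., n = ...)`.
#' @export
count_sites <- function(codon) {
  codon <- toupper(codon)
  if (!codon_ok(codon)) stop2("not a sense codon: ", codon)
  key <- paste0("s_", codon)
  cached <- .ng86_cache[[key]]
  if (!is.null(cached)) return(cached)
  aa <- Biostrings::GENETIC_CODE[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (!(mut %in% STOP_CODONS) &&
          Biostrings::GENETIC_CODE[[mut]] == aa) {
        s <- s + 1 / 3
      }
    }
  }
  out <- c(s = s, n = 3 - s)
  .ng86_cache[[key]] <- out
  out
}

#' Synonymous and nonsynonymous differences between two codons (NG86)
#'
#' Codons differing at one position are classified directly; at two or three
#' positions, the synonymous/nonsynonymous steps are averaged over all
#' orderings of the changes (2 or 6 pathways).  Pathways passing through a
#' stop codon are excluded from the average; in the degenerate case where
#' every pathway is blocked, all pathways are used with stop-crossing steps
#' classified normally (this cannot occur for typical sense-codon pairs and
#' is retained only as a documented fallback).
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(sd = ..., nd = ...)`; `sd + nd` equals the
#'   number of differing positions.
#' @export
count_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (!codon_ok(codon_a)) stop2("not a sense codon: ", codon_a)
  if (!codon_ok(codon_b)) stop2("not a sense codon: ", codon_b)
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  nd_pos <- length(diff_pos)
  if (nd_pos == 0L) return(c(sd = 0, nd = 0))
  key <- paste0("d_", codon_a, codon_b)
  cached <- .ng86_cache[[key]]
  if (!is.null(cached)) return(cached)
  code <- Biostrings::GENETIC_CODE
  paths <- perms(diff_pos)
  walk <- function(order) {
    cur <- codon_a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (nxt %in% STOP_CODONS) blocked <- TRUE
      if (!(cur %in% STOP_CODONS) && !(nxt %in% STOP_CODONS) &&
          code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  res <- lapply(paths, walk)
  open <- !vapply(res, `[[`, logical(1), "blocked")
  use <- if (any(open)) res[open] else res
  sd <- mean(vapply(use, `[[`, numeric(1), "sd"))
  nd <- mean(vapply(use, `[[`, numeric(1), "nd"))
  out <- c(sd = sd, nd = nd)
  .ng86_cache[[key]] <- out
  out
}

perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 Ka/Ks for one codon alignment
#'
#' Codon columns containing a gap, an ambiguous base or a stop codon in
#' either sequence are skipped (the number skipped is reported).  Site counts
#' are per-sequence NG86 counts averaged over the two sequences and summed
#' over compared columns; substitution counts are pathway-averaged.
#' Proportions are Jukes-Cantor corrected:
#' `Ks = -(3/4) log(1 - (4/3) pS)`, likewise `Ka`.  `Ks` (or `Ka`) is
#' undefined (`NA`) when its proportion reaches the 3/4 saturation bound, and
#' the result is flagged `saturated`; the ratio `Ka/Ks` is defined only when
#' `Ks > 0`.
#'
#' @param caln A `codon_alignment` from [backtranslate()].
#' @return A list of class `kaks_result`: `gene_a`, `gene_b`, `S_sites`,
#'   `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ratio`, `fisher_p`,
#'   `n_codons_compared`, `n_codons_skipped`, `saturated`.
#' @export
kaks_pair <- function(caln) {
  stopifnot(inherits(caln, "codon_alignment"))
  a <- caln$codons_a; b <- caln$codons_b
  usable <- codon_ok(a) & codon_ok(b)
  n_skip <- length(a) - sum(usable)
  if (!any(usable)) stop2("no comparable codon columns for ", caln$id_a,
                          " vs ", caln$id_b)
  a <- a[usable]; b <- b[usable]
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(a)) {
    sa <- count_sites(a[i]); sb <- count_sites(b[i])
    S <- S + (sa[["s"]] + sb[["s"]]) / 2
    N <- N + (sa[["n"]] + sb[["n"]]) / 2
    if (a[i] != b[i]) {
      dd <- count_differences(a[i], b[i])
      Sd <- Sd + dd[["sd"]]; Nd <- Nd + dd[["nd"]]
    }
  }
  pS <- Sd / S; pN <- Nd / N
  Ks <- jc_correct(pS); Ka <- jc_correct(pN)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  res <- structure(list(
    gene_a = caln$id_a, gene_b = caln$id_b, S_sites = S, N_sites = N,
    Sd = Sd, Nd = Nd, pS = pS, pN = pN, Ks = Ks, Ka = Ka, ratio = ratio,
    fisher_p = NA_real_, n_codons_compared = length(a),
    n_codons_skipped = n_skip, saturated = is.na(Ks) || is.na(Ka)),
    class = "kaks_result")
  # degenerate tables (possible on very short or saturated alignments,
  # where rounded substitution counts can exceed rounded site counts)
  # leave the significance undefined rather than aborting the pair
  res$fisher_p <- tryCatch(fisher_significance(res),
                           error = function(e) NA_real_)
  res
}

#' Fisher's exact test on NG86 counts
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[round(Sd), round(S - Sd)], [round(Nd), round(N - Nd)]]`
#' (substitutions vs unchanged sites, synonymous vs nonsynonymous; fractional
#' NG86 counts are rounded to integers, the convention of codon-based Ka/Ks
#' significance testing).  The p-value is the hypergeometric tail sum over
#' all tables with the observed margins whose probability does not exceed the
#' observed table's (with the customary 1e-7 relative tolerance for
#' floating-point ties).
#'
#' @param res A `kaks_result`, or a list with fields `Sd`, `S_sites`, `Nd`,
#'   `N_sites`.
#' @return The two-sided p-value.
#' @export
fisher_significance <- function(res) {
  a <- round(res$Sd); b <- round(res$S_sites - res$Sd)
  c_ <- round(res$Nd); d <- round(res$N_sites - res$Nd)
  if (min(a, b, c_, d) < 0) stop2("negative cell in Fisher table")
  fisher_exact_2x2(a, b, c_, d)
}

# Two-sided Fisher p for table [[a, b], [c, d]] via hypergeometric summation.
fisher_exact_2x2 <- function(a, b, c_, d) {
  m <- a + b      # row 1 total
  n <- c_ + d     # row 2 total
  k <- a + c_     # column 1 total
  if (m + n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Batch Ka/Ks over labeled duplicate pairs
#'
#' For each pair: global protein alignment, back-translation to codons, NG86
#' Ka/Ks, Fisher significance.  Per-pair failures (e.g. translation
#' mismatches) are collected, reported in the `failures` attribute, and do
#' not abort the batch.
#'
#' @param pairs Pair table with `gene_a`, `gene_b` (labels optional).
#' @param proteins Named character vector of representative proteins keyed by
#'   gene id.
#' @param cds Named character vector of representative CDS keyed by gene id.
#' @param scoring An [alignment_scoring()] object.
#' @return Data frame with one row per successful pair (`gene_a`, `gene_b`,
#'   `S_sites`, `N_sites`, `Sd`, `Nd`, `Ka`, `Ks`, `ratio`, `fisher_p`,
#'   `saturated`); attribute `"failures"` holds failed pair messages,
#'   attribute `"summary"` the min/mean/max of defined ratios.
#' @export
kaks_batch <- function(pairs, proteins, cds, scoring = alignment_scoring()) {
  rows <- list(); failures <- character(0)
  for (r in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[r]; gb <- pairs$gene_b[r]
    res <- tryCatch({
      if (is.na(proteins[ga]) || is.na(proteins[gb])) {
        stop2("missing protein for ", ga, " or ", gb)
      }
      if (is.na(cds[ga]) || is.na(cds[gb])) {
        stop2("missing CDS for ", ga, " or ", gb)
      }
      aln <- global_align(proteins[[ga]], proteins[[gb]], ga, gb, scoring)
      kk <- kaks_pair(backtranslate(aln, cds[[ga]], cds[[gb]]))
      data.frame(gene_a = ga, gene_b = gb, S_sites = kk$S_sites,
                 N_sites = kk$N_sites, Sd = kk$Sd, Nd = kk$Nd, Ka = kk$Ka,
                 Ks = kk$Ks, ratio = kk$ratio, fisher_p = kk$fisher_p,
                 saturated = kk$saturated, stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("%s/%s: %s", ga, gb, res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(),
               S_sites = numeric(), N_sites = numeric(), Sd = numeric(),
               Nd = numeric(), Ka = numeric(), Ks = numeric(),
               ratio = numeric(), fisher_p = numeric(), saturated = logical(),
               stringsAsFactors = FALSE)
  defined <- out$ratio[!is.na(out$ratio)]
  attr(out, "failures") <- failures
  attr(out, "summary") <- if (length(defined) > 0L) {
    c(min = min(defined), mean = mean(defined), max = max(defined))
  } else c(min = NA_real_, mean = NA_real_, max = NA_real_)
  out
}
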