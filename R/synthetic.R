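# Synthetic genome bundles with planted AP2/ERF-like families, duplication
# events, an allotetraploid merge and expression counts — all with full
# ground truth, so every pipeline stage can be exercised and scored without
# external data.
#
# Protein design: planted genes are built from fixed canonical domain blocks
# (an AP2-like 60-mer and a B3-like 100-mer) embedded in random linker
# sequence.  Each subfamily uses its own fixed variant of the AP2 block
# (8% diverged from the canonical), each Soloist-like gene a heavily diverged
# variant (35%), and each individual gene adds ~2% private substitutions.
# Domain-hit rows are emitted directly from the known block positions, so no
# HMM scoring is needed.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, frac) {
  chars <- strsplit(seq, "")[[1]]
  n_mut <- max(1L, round(frac * length(chars)))
  pos <- sample(length(chars), n_mut)
  for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
  paste(chars, collapse = "")
}

# Fixed canonical blocks and subfamily variants; deterministic constants
# (internal seeds), independent of any user seed.
canonical_blocks <- function() {
  with_seed(760847L, {
    canon_ap2 <- random_protein(60L)
    canon_b3 <- random_protein(100L)
    list(
      ap2_canonical = canon_ap2,
      b3 = canon_b3,
      variant_ap2sub = mutate_protein(canon_ap2, 0.08),
      variant_erf = mutate_protein(canon_ap2, 0.08),
      variant_rav = mutate_protein(canon_ap2, 0.08))
  })
}

soloist_block <- function(index) {
  blocks <- canonical_blocks()
  with_seed(902362L + index, mutate_protein(blocks$ap2_canonical, 0.35))
}

# Reverse-translate a protein with uniformly random synonymous codons.
protein_to_cds <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  codons <- vapply(strsplit(protein, "")[[1]], function(aa) {
    choices <- by_aa[[aa]]
    choices[sample.int(length(choices), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

# Evolve a CDS until its protein differs from the original at
# `target_aa_changes` positions.  Single-nucleotide proposals at uniform
# positions; proposals creating stop codons are rejected; synonymous changes
# are accepted with probability min(1, 1/omega) and nonsynonymous changes
# with probability min(1, omega), realizing a target Ka/Ks of approximately
# `omega`.
evolve_cds <- function(cds, target_aa_changes, omega) {
  code <- Biostrings::GENETIC_CODE
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa0 <- unname(code[codons])
  acc_n <- min(1, omega)
  acc_s <- min(1, 1 / omega)
  changed <- logical(length(codons))
  guard <- 0L
  while (sum(changed) < target_aa_changes) {
    guard <- guard + 1L
    if (guard > 10000L * length(codons)) {
      stop2("evolve_cds failed to reach target divergence")
    }
    ci <- sample.int(length(codons), 1L)
    pos <- sample.int(3L, 1L)
    old_nt <- substr(codons[ci], pos, pos)
    new_nt <- sample(setdiff(NUCS, old_nt), 1L)
    cand <- codons[ci]
    substr(cand, pos, pos) <- new_nt
    if (cand %in% STOP_CODONS) next
    syn <- code[[cand]] == code[[codons[ci]]]
    p_acc <- if (syn) acc_s else acc_n
    if (runif(1) > p_acc) next
    codons[ci] <- cand
    changed[ci] <- code[[cand]] != aa0[ci]
  }
  paste(codons, collapse = "")
}

#' Simulate a codon-sequence pair with a target Ka/Ks
#'
#' Draws a random ancestor of `n_codons` sense codons and evolves one copy by
#' `n_proposals` single-nucleotide proposals: proposals creating stop codons
#' are rejected, synonymous proposals are always accepted (for `omega <= 1`)
#' and nonsynonymous proposals are accepted with probability `omega`, so the
#' realized nonsynonymous/synonymous rate ratio approximates `omega`.
#'
#' @param n_codons Number of codons.
#' @param omega Target Ka/Ks.
#' @param n_proposals Number of mutation proposals along the branch.
#' @param seed RNG seed.
#' @return List with `cds_a` (ancestor), `cds_b` (derived copy) and the
#'   corresponding `codon_alignment` in `alignment`.
#' @export
simulate_codon_pair <- function(n_codons, omega, n_proposals = NULL,
                                seed = 1L) {
  if (is.null(n_proposals)) n_proposals <- round(0.5 * n_codons)
  with_seed(seed, {
    code <- Biostrings::GENETIC_CODE
    sense <- setdiff(names(code), STOP_CODONS)
    codons <- sample(sense, n_codons, replace = TRUE)
    cds_a <- paste(codons, collapse = "")
    acc_n <- min(1, omega)
    acc_s <- min(1, 1 / omega)
    done <- 0L
    while (done < n_proposals) {
      done <- done + 1L
      ci <- sample.int(length(codons), 1L)
      pos <- sample.int(3L, 1L)
      old_nt <- substr(codons[ci], pos, pos)
      new_nt <- sample(setdiff(NUCS, old_nt), 1L)
      cand <- codons[ci]
      substr(cand, pos, pos) <- new_nt
      if (cand %in% STOP_CODONS) next
      syn <- code[[cand]] == code[[codons[ci]]]
      p_acc <- if (syn) acc_s else acc_n
      if (runif(1) <= p_acc) codons[ci] <- cand
    }
    cds_b <- paste(codons, collapse = "")
    list(cds_a = cds_a, cds_b = cds_b,
         alignment = codon_alignment_from_cds(cds_a, cds_b, "sim_a", "sim_b"))
  })
}

#' Build a codon alignment from two equal-length ungapped CDS
#'
#' @param cds_a,cds_b Coding sequences of equal length divisible by 3.
#' @param id_a,id_b Identifiers.
#' @return A `codon_alignment` object (see [backtranslate()]).
#' @export
codon_alignment_from_cds <- function(cds_a, cds_b, id_a = "a", id_b = "b") {
  stopifnot(nchar(cds_a) == nchar(cds_b), nchar(cds_a) %% 3L == 0L)
  split3 <- function(x) substring(x, seq(1L, nchar(x), 3L),
                                  seq(3L, nchar(x), 3L))
  structure(list(id_a = id_a, id_b = id_b, codons_a = split3(toupper(cds_a)),
                 codons_b = split3(toupper(cds_b))),
            class = "codon_alignment")
}

#' Specification of a synthetic diploid genome
#'
#' Defaults describe a compact diploid carrying a realistic AP2/ERF-like
#' family structure: a two-domain AP2 class, a large single-domain ERF class,
#' a small RAV class (AP2 + B3 architecture), one or two divergent
#' Soloist-like genes, a handful of tandem and segmental duplication events
#' at 5% protein divergence, and unrelated background genes.
#'
#' @param seed RNG seed; the bundle is a pure function of the spec.
#' @param species Short species tag used as the gene-id prefix.
#' @param n_chromosomes,chrom_length_bp Genome shape.
#' @param n_two_domain,n_single_domain,n_rav,n_soloist_like Family
#'   composition.
#' @param n_tandem_events,n_segmental_events Planted duplication events
#'   (sources drawn from the single-domain class).
#' @param duplicate_divergence Per-site amino-acid divergence applied to
#'   duplicate copies (keep below ~0.2 for recoverable duplicates).
#' @param omega Target Ka/Ks realized in duplicate-copy CDS evolution.
#' @param n_isoforms_max Maximum number of isoforms per gene.
#' @param background_genes Number of unrelated genes (no qualifying domain
#'   hits).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, species = "spA", n_chromosomes = 11L,
                           chrom_length_bp = 40000000L, n_two_domain = 8L,
                           n_single_domain = 20L, n_rav = 3L,
                           n_soloist_like = 2L, n_tandem_events = 3L,
                           n_segmental_events = 2L,
                           duplicate_divergence = 0.05, omega = 0.3,
                           n_isoforms_max = 3L, background_genes = 10L) {
  stopifnot(n_chromosomes >= 2L, chrom_length_bp > 2e6,
            n_two_domain >= 0L, n_single_domain >= 0L, n_rav >= 0L,
            n_soloist_like >= 0L, n_tandem_events >= 0L,
            n_segmental_events >= 0L, duplicate_divergence >= 0,
            duplicate_divergence < 1, omega > 0, n_isoforms_max >= 1L,
            background_genes >= 0L)
  if (n_tandem_events + n_segmental_events > n_single_domain) {
    stop2("more duplication events than single-domain source genes")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# Internal: construct the family + background gene table (sequences and
# architectures) for one diploid.  Assumes the RNG is already seeded.
build_gene_set <- function(spec) {
  blocks <- canonical_blocks()
  linker <- function(n) random_protein(n)
  genes <- list()
  add_gene <- function(class, protein, layout) {
    genes[[length(genes) + 1L]] <<- list(class = class, protein = protein,
                                         layout = layout)
  }
  # linker lengths keep the conserved-domain fraction of every class near or
  # below half the protein, so non-duplicate same-class pairs cannot satisfy
  # the duplicate screen's identity and coverage criteria simultaneously
  for (i in seq_len(spec$n_two_domain)) {
    b1 <- mutate_protein(blocks$variant_ap2sub, 0.02)
    b2 <- mutate_protein(blocks$variant_ap2sub, 0.02)
    protein <- paste0(linker(40), b1, linker(40), b2, linker(40))
    add_gene("two_domain", protein,
             list(ap2 = list(c(41L, 100L), c(141L, 200L))))
  }
  for (i in seq_len(spec$n_single_domain)) {
    b <- mutate_protein(blocks$variant_erf, 0.02)
    protein <- paste0(linker(45), b, linker(45))
    add_gene("single_domain", protein, list(ap2 = list(c(46L, 105L))))
  }
  for (i in seq_len(spec$n_rav)) {
    b <- mutate_protein(blocks$variant_rav, 0.02)
    b3 <- mutate_protein(blocks$b3, 0.02)
    protein <- paste0(linker(60), b, linker(60), b3, linker(60))
    add_gene("rav", protein,
             list(ap2 = list(c(61L, 120L)), b3 = list(c(181L, 280L))))
  }
  for (i in seq_len(spec$n_soloist_like)) {
    b <- mutate_protein(soloist_block(i), 0.02)
    protein <- paste0(linker(45), b, linker(45))
    add_gene("soloist_like", protein, list(ap2 = list(c(46L, 105L))))
  }
  for (i in seq_len(spec$background_genes)) {
    add_gene("background", random_protein(sample(120:250, 1L)), list())
  }
  genes
}

class_to_subfamily <- c(two_domain = "AP2", single_domain = "ERF",
                        rav = "RAV", soloist_like = "Soloist",
                        background = NA_character_)

#' Generate a synthetic diploid genome bundle
#'
#' Produces, deterministically under the spec's seed, the full input set the
#' pipeline consumes — protein FASTA content, CDS, a coordinate table, a
#' domain-hit table — plus ground truth (true subfamily per gene, true
#' duplicate pairs with labels and generating omega).  Genes are placed
#' without overlap, round-robin across chromosomes at wide spacing; tandem
#' copies land 50-900 kb from their source on the same chromosome, segmental
#' copies on a different chromosome.  Duplicate copies are evolved at the
#' CDS level to the requested protein divergence with synonymous /
#' nonsynonymous acceptance probabilities realizing approximately the target
#' omega.  Domain-hit rows carry E-values of 1e-30; some background genes
#' receive a weak (above-threshold) AP2 hit as negative-control noise.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `genome_bundle`: `species`, `proteins`, `cds`
#'   (named vectors keyed by protein id), `coords` (data frame), `hits`
#'   (data frame), `truth` (list with `genes`, `pairs`, `spec`),
#'   `n_chromosomes`.
#' @export
generate_diploid <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    genes <- build_gene_set(spec)
    n <- length(genes)
    order_shuffled <- sample(n)
    # round-robin placement at 2 Mb spacing
    spacing <- 2000000L
    per_chrom <- floor((spec$chrom_length_bp - 1000000L) / spacing)
    if (per_chrom * spec$n_chromosomes <
        n + spec$n_tandem_events + spec$n_segmental_events) {
      stop2("chromosomes too short to place all genes")
    }
    chrom <- character(n); start <- integer(n)
    cursor <- rep(1000000L, spec$n_chromosomes)
    for (k in seq_len(n)) {
      g <- order_shuffled[k]
      ch <- ((k - 1L) %% spec$n_chromosomes) + 1L
      chrom[g] <- as.character(ch)
      start[g] <- cursor[ch]
      cursor[ch] <- cursor[ch] + spacing
    }
    ids <- sprintf("%s_g%03d", spec$species, seq_len(n))
    lineage <- sprintf("L%03d", seq_len(n))
    classes <- vapply(genes, `[[`, character(1), "class")
    proteins_full <- vapply(genes, `[[`, character(1), "protein")
    cds_full <- vapply(proteins_full, protein_to_cds, character(1))
    # duplication events: sources among single-domain genes
    singles <- which(classes == "single_domain")
    n_ev <- spec$n_tandem_events + spec$n_segmental_events
    sources <- singles[sample.int(length(singles), n_ev)]
    pair_rows <- list()
    for (e in seq_len(n_ev)) {
      src <- sources[e]
      tandem <- e <= spec$n_tandem_events
      idx <- length(ids) + 1L
      ids <- c(ids, sprintf("%s_g%03d", spec$species, idx))
      lineage <- c(lineage, sprintf("L%03d.d", src))
      classes <- c(classes, "single_domain")
      genes[[idx]] <- genes[[src]]
      target <- max(1L, round(spec$duplicate_divergence *
                                nchar(proteins_full[src])))
      new_cds <- evolve_cds(cds_full[[src]], target, spec$omega)
      cds_full <- c(cds_full, new_cds)
      prot <- paste(translate_codons(
        substring(new_cds, seq(1L, nchar(new_cds), 3L),
                  seq(3L, nchar(new_cds), 3L))), collapse = "")
      proteins_full <- c(proteins_full, prot)
      if (tandem) {
        chrom <- c(chrom, chrom[src])
        start <- c(start, start[src] + sample(50000:900000, 1L))
      } else {
        src_ch <- as.integer(chrom[src])
        other <- (src_ch %% spec$n_chromosomes) + 1L
        chrom <- c(chrom, as.character(other))
        start <- c(start, cursor[other])
        cursor[other] <- cursor[other] + spacing
      }
      pr <- sort(c(ids[src], ids[idx]))
      pair_rows[[e]] <- data.frame(
        gene_a = pr[1], gene_b = pr[2],
        label = if (tandem) "tandem" else "segmental",
        omega = spec$omega, stringsAsFactors = FALSE)
    }
    assemble_bundle(spec, ids, lineage, classes, proteins_full, cds_full,
                    chrom, start,
                    pairs = if (length(pair_rows) > 0L)
                      do.call(rbind, pair_rows) else empty_truth_pairs())
  })
}

empty_truth_pairs <- function() {
  data.frame(gene_a = character(), gene_b = character(), label = character(),
             omega = numeric(), stringsAsFactors = FALSE)
}

# Shared bundle assembly: isoforms, coordinates, hit table, truth tables.
# RNG must be seeded by the caller.
assemble_bundle <- function(spec, ids, lineage, classes, proteins_full,
                            cds_full, chrom, start, pairs) {
  n <- length(ids)
  prot_seqs <- character(0); cds_seqs <- character(0)
  coord_rows <- list(); hit_rows <- list()
  for (g in seq_len(n)) {
    len <- nchar(proteins_full[g])
    exon_count <- if (classes[g] %in% c("two_domain", "rav", "soloist_like")) {
      sample(4:11, 1L)
    } else if (classes[g] == "single_domain") {
      if (runif(1) < 0.7) 1L else sample(2:5, 1L)
    } else {
      sample(1:8, 1L)
    }
    span <- 3L * len + (exon_count - 1L) * 200L
    n_iso <- sample.int(spec$n_isoforms_max, 1L)
    for (iso in seq_len(n_iso)) {
      pid <- sprintf("%s.p%d", ids[g], iso)
      tid <- sprintf("%s.t%d", ids[g], iso)
      if (iso == 1L) {
        pseq <- proteins_full[g]; cseq <- cds_full[g]
      } else {
        keep <- len - sample(ceiling(len * 0.1):ceiling(len * 0.4), 1L)
        pseq <- substr(proteins_full[g], 1L, keep)
        cseq <- substr(cds_full[g], 1L, 3L * keep)
      }
      prot_seqs[pid] <- pseq
      cds_seqs[pid] <- cseq
      coord_rows[[length(coord_rows) + 1L]] <- data.frame(
        gene_id = ids[g], chromosome = chrom[g], start = start[g],
        end = start[g] + span - 1L, strand = sample(c("+", "-"), 1L),
        exon_count = exon_count, protein_id = pid, transcript_id = tid,
        stringsAsFactors = FALSE)
    }
    rep_pid <- sprintf("%s.p1", ids[g])
    layout <- if (classes[g] == "two_domain") {
      list(ap2 = list(c(41L, 100L), c(141L, 200L)))
    } else if (classes[g] == "rav") {
      list(ap2 = list(c(61L, 120L)), b3 = list(c(181L, 280L)))
    } else if (classes[g] %in% c("single_domain", "soloist_like")) {
      list(ap2 = list(c(46L, 105L)))
    } else {
      list()
    }
    for (profile in names(layout)) {
      for (env in layout[[profile]]) {
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          protein_id = rep_pid, profile = toupper(profile), evalue = 1e-30,
          ali_start = env[1], ali_end = env[2], stringsAsFactors = FALSE)
      }
    }
    if (classes[g] == "background" && runif(1) < 0.3) {
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        protein_id = rep_pid, profile = "AP2", evalue = 1e-3,
        ali_start = 5L, ali_end = 40L, stringsAsFactors = FALSE)
    }
  }
  truth_genes <- data.frame(
    gene_id = ids, lineage = lineage, class = classes,
    subfamily = unname(class_to_subfamily[classes]),
    chromosome = chrom, start = start, stringsAsFactors = FALSE)
  structure(list(
    species = spec$species,
    proteins = prot_seqs, cds = cds_seqs,
    coords = do.call(rbind, coord_rows),
    hits = do.call(rbind, hit_rows),
    truth = list(genes = truth_genes, pairs = pairs, spec = spec),
    n_chromosomes = spec$n_chromosomes), class = "genome_bundle")
}

#' Derive a sister diploid genome from an existing bundle
#'
#' Creates the second parent of a future allotetraploid: every gene of the
#' source bundle is carried over under a new species tag, with its CDS
#' evolved to `divergence` at the protein level (same omega as the source
#' spec), keeping coordinates, chromosome numbers and the lineage map — the
#' lineage ids define the ortholog (future homoeolog) relation.  Optionally
#' drops `n_drop` family genes (lineage extinction in the sister lineage).
#'
#' @param bundle A `genome_bundle` from [generate_diploid()].
#' @param species Species tag for the sister genome.
#' @param divergence Target per-site protein divergence from the source.
#' @param n_drop Number of family genes to drop from the sister.
#' @param drop_classes Gene classes eligible for dropping (default: any
#'   family class).
#' @param seed RNG seed.
#' @return A `genome_bundle`.
#' @export
derive_sister_genome <- function(bundle, species, divergence = 0.05,
                                 n_drop = 0L,
                                 drop_classes = c("two_domain",
                                                  "single_domain", "rav",
                                                  "soloist_like"),
                                 seed = 1L) {
  stopifnot(inherits(bundle, "genome_bundle"))
  spec <- bundle$truth$spec
  with_seed(seed, {
    tg <- bundle$truth$genes
    keep <- seq_len(nrow(tg))
    if (n_drop > 0L) {
      fam <- which(!is.na(tg$subfamily) & tg$class %in% drop_classes)
      if (length(fam) < n_drop) stop2("not enough droppable genes")
      drop <- fam[sample.int(length(fam), n_drop)]
      keep <- setdiff(keep, drop)
    }
    tg <- tg[keep, , drop = FALSE]
    ids <- sub(paste0("^", spec$species), species, tg$gene_id)
    rep_pids <- sprintf("%s.p1", tg$gene_id)
    classes <- tg$class
    proteins_full <- character(length(ids)); cds_full <- character(length(ids))
    for (i in seq_along(ids)) {
      cds0 <- bundle$cds[[rep_pids[i]]]
      len <- nchar(cds0) / 3L
      target <- max(1L, round(divergence * len))
      cds1 <- evolve_cds(cds0, target, spec$omega)
      cds_full[i] <- cds1
      proteins_full[i] <- paste(translate_codons(
        substring(cds1, seq(1L, nchar(cds1), 3L), seq(3L, nchar(cds1), 3L))),
        collapse = "")
    }
    spec2 <- spec
    spec2$species <- species
    # sister keeps the source's within-genome duplicate pairs (renamed),
    # restricted to surviving genes
    pr <- bundle$truth$pairs
    if (nrow(pr) > 0L) {
      pr$gene_a <- sub(paste0("^", spec$species), species, pr$gene_a)
      pr$gene_b <- sub(paste0("^", spec$species), species, pr$gene_b)
      pr <- pr[pr$gene_a %in% ids & pr$gene_b %in% ids, , drop = FALSE]
    }
    assemble_bundle(spec2, ids, tg$lineage, classes, proteins_full, cds_full,
                    tg$chromosome, tg$start, pairs = pr)
  })
}

#' Merge two diploid bundles into an allotetraploid
#'
#' Chromosomes of the first parent are suffixed with the first subgenome
#' letter (default `"c"`) and the second parent's with the second (`"e"`),
#' emulating an allotetraploid whose homoeologous chromosomes carry parental
#' origin labels.  Every pair of genes sharing a lineage id across the
#' parents is recorded as a true homoeolog pair.  A `loss_fraction` of family
#' genes is then deleted at random, and `post_hybrid_tandem` /
#' `post_hybrid_segmental` new duplicate copies are planted on subgenome
#' chromosomes; sources for post-hybridization events are drawn, when
#' possible, from single-domain family genes *without* a surviving homoeolog
#' partner, so each planted pair's similarity signal is confined to that
#' pair.
#'
#' @param parent_a,parent_b `genome_bundle`s with equal chromosome counts
#'   and a shared lineage map (see [derive_sister_genome()]).
#' @param loss_fraction Fraction of family genes deleted after merging.
#' @param post_hybrid_tandem,post_hybrid_segmental Numbers of planted
#'   post-hybridization duplication events.
#' @param seed RNG seed.
#' @param suffixes Two subgenome letters.
#' @return A `genome_bundle` whose `truth` additionally contains
#'   `homoeologs` (data frame `gene_a`, `gene_b`, `lineage`) and whose
#'   `truth$pairs` includes homoeolog pairs.
#' @export
generate_allotetraploid <- function(parent_a, parent_b, loss_fraction = 0,
                                    post_hybrid_tandem = 0L,
                                    post_hybrid_segmental = 0L, seed = 1L,
                                    suffixes = c("c", "e")) {
  stopifnot(inherits(parent_a, "genome_bundle"),
            inherits(parent_b, "genome_bundle"))
  if (parent_a$n_chromosomes != parent_b$n_chromosomes) {
    stop2("parents have different chromosome counts")
  }
  with_seed(seed, {
    relabel <- function(bundle, sfx) {
      bundle$coords$chromosome <- paste0(bundle$coords$chromosome, sfx)
      bundle$truth$genes$chromosome <-
        paste0(bundle$truth$genes$chromosome, sfx)
      bundle
    }
    a <- relabel(parent_a, suffixes[1]); b <- relabel(parent_b, suffixes[2])
    ga <- a$truth$genes; gb <- b$truth$genes
    shared <- intersect(ga$lineage[!is.na(ga$subfamily)],
                        gb$lineage[!is.na(gb$subfamily)])
    hom <- data.frame(
      gene_a = ga$gene_id[match(shared, ga$lineage)],
      gene_b = gb$gene_id[match(shared, gb$lineage)],
      lineage = shared, stringsAsFactors = FALSE)
    swap <- hom$gene_a > hom$gene_b
    tmp <- hom$gene_a[swap]; hom$gene_a[swap] <- hom$gene_b[swap]
    hom$gene_b[swap] <- tmp
    genes <- rbind(ga, gb)
    proteins <- c(a$proteins, b$proteins)
    cds <- c(a$cds, b$cds)
    coords <- rbind(a$coords, b$coords)
    hits <- rbind(a$hits, b$hits)
    pairs <- rbind(a$truth$pairs, b$truth$pairs,
                   data.frame(gene_a = hom$gene_a, gene_b = hom$gene_b,
                              label = "homoeolog", omega = NA_real_,
                              stringsAsFactors = FALSE))
    # random loss of family genes
    fam_idx <- which(!is.na(genes$subfamily))
    n_loss <- round(loss_fraction * length(fam_idx))
    if (n_loss > 0L) {
      lost <- genes$gene_id[fam_idx[sample.int(length(fam_idx), n_loss)]]
      genes <- genes[!genes$gene_id %in% lost, , drop = FALSE]
      coords <- coords[!coords$gene_id %in% lost, , drop = FALSE]
      keep_p <- coords$protein_id
      proteins <- proteins[names(proteins) %in% keep_p]
      cds <- cds[names(cds) %in% keep_p]
      hits <- hits[hits$protein_id %in% keep_p, , drop = FALSE]
      pairs <- pairs[!(pairs$gene_a %in% lost | pairs$gene_b %in% lost), ,
                     drop = FALSE]
      hom <- hom[!(hom$gene_a %in% lost | hom$gene_b %in% lost), ,
                 drop = FALSE]
    }
    # post-hybridization duplications
    spec <- a$truth$spec
    n_ev <- post_hybrid_tandem + post_hybrid_segmental
    if (n_ev > 0L) {
      partnered <- unique(c(hom$gene_a, hom$gene_b))
      cand <- genes$gene_id[genes$class == "single_domain" &
                              !genes$gene_id %in% partnered]
      if (length(cand) < n_ev) {
        cand <- c(cand, setdiff(
          genes$gene_id[genes$class == "single_domain"], cand))
      }
      if (length(cand) < n_ev) stop2("not enough source genes for ",
                                     "post-hybridization duplications")
      sources <- cand[seq_len(n_ev)]
      occupied <- split(coords$start[!duplicated(coords$gene_id)],
                        coords$chromosome[!duplicated(coords$gene_id)])
      new_rows <- list()
      for (e in seq_len(n_ev)) {
        src <- sources[e]
        tandem <- e <= post_hybrid_tandem
        src_row <- genes[genes$gene_id == src, ]
        new_id <- sprintf("%s_ph%03d", sub("_g.*$", "", src), e)
        rep_pid <- sprintf("%s.p1", src)
        cds0 <- cds[[rep_pid]]
        len <- nchar(cds0) / 3L
        target <- max(1L, round(spec$duplicate_divergence * len))
        cds1 <- evolve_cds(cds0, target, spec$omega)
        prot1 <- paste(translate_codons(
          substring(cds1, seq(1L, nchar(cds1), 3L),
                    seq(3L, nchar(cds1), 3L))), collapse = "")
        if (tandem) {
          new_chrom <- src_row$chromosome
          new_start <- src_row$start + sample(50000:900000, 1L)
        } else {
          pc <- parse_chromosome(src_row$chromosome)
          other_num <- (pc$number %% parent_a$n_chromosomes) + 1L
          new_chrom <- paste0(other_num, pc$suffix)
          used <- occupied[[new_chrom]] %||% 0
          new_start <- max(used) + 2000000L
        }
        occupied[[new_chrom]] <- c(occupied[[new_chrom]], new_start)
        span <- 3L * nchar(prot1)
        new_pid <- sprintf("%s.p1", new_id)
        proteins[new_pid] <- prot1
        cds[new_pid] <- cds1
        coords <- rbind(coords, data.frame(
          gene_id = new_id, chromosome = new_chrom, start = new_start,
          end = new_start + span - 1L, strand = sample(c("+", "-"), 1L),
          exon_count = 1L, protein_id = new_pid,
          transcript_id = sprintf("%s.t1", new_id),
          stringsAsFactors = FALSE))
        hits <- rbind(hits, data.frame(
          protein_id = new_pid, profile = "AP2", evalue = 1e-30,
          ali_start = 46L, ali_end = 105L, stringsAsFactors = FALSE))
        genes <- rbind(genes, data.frame(
          gene_id = new_id, lineage = paste0(src_row$lineage, ".ph"),
          class = "single_domain", subfamily = "ERF",
          chromosome = new_chrom, start = new_start,
          stringsAsFactors = FALSE))
        pr <- sort(c(src, new_id))
        pairs <- rbind(pairs, data.frame(
          gene_a = pr[1], gene_b = pr[2],
          label = if (tandem) "tandem" else "segmental",
          omega = spec$omega, stringsAsFactors = FALSE))
      }
    }
    rownames(genes) <- rownames(coords) <- rownames(pairs) <- NULL
    spec_merged <- spec
    spec_merged$species <- paste0(a$species, "x", b$species)
    structure(list(
      species = spec_merged$species, proteins = proteins, cds = cds,
      coords = coords, hits = hits,
      truth = list(genes = genes, pairs = pairs, homoeologs = hom,
                   spec = spec_merged),
      n_chromosomes = parent_a$n_chromosomes,
      subgenome_suffixes = suffixes), class = "genome_bundle")
  })
}

#' Simulate an allopolyploid gene family with planted duplication history
#'
#' Convenience constructor for the standard allotetraploid study scenario:
#' a diploid parent is generated, a sister parent is derived from it at the
#' stated divergence with some single-domain lineages lost, the two are
#' merged into an allotetraploid ('c'/'e' chromosome suffixes), and
#' post-hybridization tandem and segmental duplications are planted using
#' the lineages private to the first parent as sources.  The resulting truth
#' therefore contains exactly `n_homoeolog_pairs` homoeolog pairs,
#' `n_tandem_pairs` tandem pairs and `n_segmental_pairs` segmental pairs,
#' with no other gene pair expected to reach the duplicate similarity
#' criterion.
#'
#' @param seed RNG seed (all sub-steps derive their seeds from it).
#' @param n_homoeolog_pairs,n_tandem_pairs,n_segmental_pairs Planted pair
#'   counts per label.
#' @param divergence Protein divergence of duplicate copies and between the
#'   parental subgenomes.
#' @param n_two_domain,n_rav,n_soloist_like Family composition of the
#'   shared classes.
#' @param omega Target Ka/Ks for planted divergence.
#' @return A `genome_bundle` (see [generate_allotetraploid()]).
#' @export
simulate_allopolyploid_family <- function(seed = 1L,
                                          n_homoeolog_pairs = 77L,
                                          n_tandem_pairs = 12L,
                                          n_segmental_pairs = 11L,
                                          divergence = 0.05,
                                          n_two_domain = 8L, n_rav = 4L,
                                          n_soloist_like = 3L,
                                          omega = 0.3) {
  n_private <- n_tandem_pairs + n_segmental_pairs
  n_single <- n_homoeolog_pairs + n_private -
    (n_two_domain + n_rav + n_soloist_like)
  if (n_single < n_private) {
    stop2("family composition incompatible with requested pair counts")
  }
  spec_a <- synthetic_spec(
    seed = seed, species = "spC", n_two_domain = n_two_domain,
    n_single_domain = n_single, n_rav = n_rav,
    n_soloist_like = n_soloist_like, n_tandem_events = 0L,
    n_segmental_events = 0L, duplicate_divergence = divergence,
    omega = omega)
  parent_a <- generate_diploid(spec_a)
  parent_b <- derive_sister_genome(parent_a, species = "spE",
                                   divergence = divergence,
                                   n_drop = n_private,
                                   drop_classes = "single_domain",
                                   seed = seed + 1L)
  generate_allotetraploid(parent_a, parent_b, loss_fraction = 0,
                          post_hybrid_tandem = n_tandem_pairs,
                          post_hybrid_segmental = n_segmental_pairs,
                          seed = seed + 2L)
}

#' Generate an expression count matrix for a bundle
#'
#' A fixed fraction of family genes is designated expressed; their counts are
#' drawn from a negative binomial with the requested mean CPM (dispersion
#' 0.1 by default), unexpressed family genes are all-zero, and background
#' genes absorb the remaining library so that every sample totals exactly
#' one million reads — CPM values then equal raw counts.
#'
#' @param bundle A `genome_bundle`.
#' @param n_samples Number of samples.
#' @param expressed_fraction Fraction of family genes expressed.
#' @param mean_cpm_expressed Mean CPM of expressed genes.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param seed RNG seed.
#' @return List with `counts` (integer matrix, genes x samples) and
#'   `expressed_truth` (named logical over family genes).
#' @export
generate_counts <- function(bundle, n_samples = 3L, expressed_fraction = 0.5,
                            mean_cpm_expressed = 50, dispersion = 0.1,
                            seed = 1L) {
  stopifnot(inherits(bundle, "genome_bundle"))
  with_seed(seed, {
    tg <- bundle$truth$genes
    fam <- tg$gene_id[!is.na(tg$subfamily)]
    bg <- tg$gene_id[is.na(tg$subfamily)]
    n_expr <- round(expressed_fraction * length(fam))
    expressed <- sample(fam, n_expr)
    lib <- 1000000L
    counts <- matrix(0L, nrow = length(fam) + length(bg), ncol = n_samples,
                     dimnames = list(c(fam, bg),
                                     sprintf("sample_%d", seq_len(n_samples))))
    for (s in seq_len(n_samples)) {
      counts[expressed, s] <- rnbinom(n_expr, mu = mean_cpm_expressed,
                                      size = 1 / dispersion)
      rest <- lib - sum(counts[fam, s])
      if (rest < 0) stop2("expressed family counts exceed library size")
      if (length(bg) > 0L) {
        counts[bg, s] <- as.integer(stats::rmultinom(
          1L, rest, rep(1 / length(bg), length(bg))))
      }
    }
    list(counts = counts,
         expressed_truth = setNames(fam %in% expressed, fam))
  })
}
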