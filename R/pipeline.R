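# Orchestration: the end-to-end characterization (identification ->
# classification -> phylogeny -> nomenclature -> duplication -> Ka/Ks ->
# expression) and the cross-species comparison table.

#' Pipeline configuration
#'
#' Collects inputs and thresholds for one species.  Sequence/table inputs
#' may be given as file paths (FASTA / TSV, see the io readers) or as
#' already-loaded objects; a `genome_bundle` from [generate_diploid()] or
#' [generate_allotetraploid()] can be passed directly to
#' [run_characterize()] instead.
#'
#' All thresholds default to the standard survey values: domain E-value
#' 1e-5, tandem window 1 Mb, 80% identity / 80% coverage, 90% site coverage
#' for partial deletion, significance level 0.05; every threshold is echoed
#' into the report summary for provenance.
#'
#' @param species_prefix Nomenclature prefix (e.g. `"Ca"`).
#' @param proteins,cds,coords,hits Inputs (paths or objects).  CDS records
#'   must be keyed by the same protein ids as the protein FASTA.
#' @param hits_dialect Passed to [read_domain_table()].
#' @param counts Optional count matrix (path or matrix).
#' @param references,reference_subgroups Optional reference protein set with
#'   subgroup labels for ERF subgroup assignment.
#' @param subgenome_mode Logical: enable homoeolog classification.
#' @param subgenome_suffixes Subgenome chromosome suffixes.
#' @param thresholds An [identification_thresholds()].
#' @param criteria A [duplication_criteria()].
#' @param min_site_coverage Partial-deletion threshold for the family tree.
#' @param scoring An [alignment_scoring()].
#' @param min_cpm,pseudocount Expression settings.
#' @param alpha Significance level reported against Fisher p-values.
#' @param clade_k Reference-context size for tree-based classification.
#' @param output_dir Optional directory for report files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(species_prefix, proteins, cds, coords, hits,
                            hits_dialect = "tsv", counts = NULL,
                            references = NULL, reference_subgroups = NULL,
                            subgenome_mode = FALSE,
                            subgenome_suffixes = c("c", "e"),
                            thresholds = identification_thresholds(),
                            criteria = duplication_criteria(),
                            min_site_coverage = 0.9,
                            scoring = alignment_scoring(),
                            min_cpm = 1, pseudocount = 1, alpha = 0.05,
                            clade_k = 3L, output_dir = NULL) {
  structure(list(
    species_prefix = species_prefix, proteins = proteins, cds = cds,
    coords = coords, hits = hits, hits_dialect = hits_dialect,
    counts = counts, references = references,
    reference_subgroups = reference_subgroups,
    subgenome_mode = subgenome_mode,
    subgenome_suffixes = subgenome_suffixes, thresholds = thresholds,
    criteria = criteria, min_site_coverage = min_site_coverage,
    scoring = scoring, min_cpm = min_cpm, pseudocount = pseudocount,
    alpha = alpha, clade_k = clade_k, output_dir = output_dir),
    class = "pipeline_config")
}

load_input <- function(x, loader) {
  if (is.character(x) && length(x) == 1L) loader(x) else x
}

#' Run the end-to-end family characterization
#'
#' Executes, for one species: longest-isoform selection, domain-hit family
#' identification, architecture-based subfamily classification, family-tree
#' construction (progressive alignment, p-distance with partial deletion,
#' neighbor joining) with single-domain overrides and Soloist designation,
#' systematic naming, duplicate-pair detection and
#' tandem/segmental/homoeolog classification, NG86 Ka/Ks with Fisher's
#' exact test, and (when counts are provided) CPM-based expression
#' summarization.  Optional reference proteins add two-step ERF subgroup
#' assignment.
#'
#' The run is deterministic: identical inputs and configuration produce
#' identical reports, byte for byte when written to disk.
#'
#' @param config A [pipeline_config()], or a `genome_bundle` (then
#'   `...` is passed on to [pipeline_config()]).
#' @param ... When `config` is a bundle: extra [pipeline_config()] arguments
#'   (e.g. `counts`, `output_dir`, `subgenome_mode`).
#' @return A list of class `characterization_report`: tables `family`,
#'   `pairs`, `clusters`, `kaks`, `subgroups`, `expression`, the `tree`, and
#'   `summary` (headline counts plus echoed thresholds).
#' @export
run_characterize <- function(config, ...) {
  if (inherits(config, "genome_bundle")) {
    bundle <- config
    config <- pipeline_config(
      species_prefix = bundle$species, proteins = bundle$proteins,
      cds = bundle$cds, coords = bundle$coords, hits = bundle$hits,
      subgenome_mode = !is.null(bundle$subgenome_suffixes),
      subgenome_suffixes = bundle$subgenome_suffixes %||% c("c", "e"),
      ...)
  }
  stopifnot(inherits(config, "pipeline_config"))
  completed <- character(0)
  report <- list(species = config$species_prefix)
  finish <- function() {
    if (!is.null(config$output_dir)) {
      write_report(report, completed, config$output_dir)
    }
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      finish()
      stop2("stage '", name, "' failed: ", conditionMessage(e))
    })
    completed <<- c(completed, name)
    res
  }

  proteins <- load_input(config$proteins, function(p) read_fasta(p, "AA"))
  cds <- load_input(config$cds, function(p) read_fasta(p, "DNA"))
  coords <- load_input(config$coords, read_coordinates)
  hits <- load_input(config$hits, function(p)
    read_domain_table(p, config$hits_dialect))
  counts <- if (!is.null(config$counts)) {
    load_input(config$counts, read_count_matrix)
  } else NULL

  reps <- run_stage("representatives",
                    select_longest_isoform(proteins, coords))
  arch <- run_stage("identification",
                    identify_family(hits, reps, config$thresholds))
  calls <- run_stage("classification", classify_subfamily(arch))
  fam_reps <- reps[reps$gene_id %in% calls$gene_id, , drop = FALSE]

  tree <- NULL
  if (nrow(calls) >= 3L) {
    tree <- run_stage("tree", {
      msa <- progressive_align(setNames(fam_reps$seq, fam_reps$gene_id),
                               config$scoring)
      nj_tree(pdistance_matrix(msa, config$min_site_coverage))
    })
    calls <- run_stage("overrides",
                       resolve_single_domain_overrides(calls, tree,
                                                       config$clade_k))
  }
  calls <- run_stage("naming",
                     assign_names(calls, config$species_prefix, coords))
  report$family <- calls
  report$tree <- tree

  pairs <- run_stage("duplicates", {
    cp <- candidate_pairs(fam_reps, config$criteria, config$scoring)
    classify_pairs(cp, coords, config$criteria, config$subgenome_mode,
                   config$subgenome_suffixes)
  })
  report$pairs <- pairs
  report$clusters <- run_stage("tandem_clusters",
                               tandem_clusters(pairs, coords))

  kaks <- run_stage("kaks", {
    prot_by_gene <- setNames(fam_reps$seq, fam_reps$gene_id)
    cds_by_gene <- setNames(unname(cds[fam_reps$protein_id]),
                            fam_reps$gene_id)
    kaks_batch(pairs, prot_by_gene, cds_by_gene, config$scoring)
  })
  report$kaks <- kaks

  report$subgroups <- if (!is.null(config$references)) {
    run_stage("subgroups", {
      refs <- load_input(config$references, function(p) read_fasta(p, "AA"))
      erf_genes <- calls$gene_id[calls$subfamily == "ERF"]
      queries <- setNames(fam_reps$seq, fam_reps$gene_id)[erf_genes]
      bh <- best_reference_hits(queries, refs, config$reference_subgroups,
                                config$scoring)
      msa <- progressive_align(c(queries, refs), config$scoring)
      sub_tree <- nj_tree(pdistance_matrix(msa, config$min_site_coverage))
      assign_subgroups(erf_genes, bh, sub_tree, config$reference_subgroups,
                       config$clade_k)
    })
  } else NULL

  report$expression <- if (!is.null(counts)) {
    run_stage("expression", {
      lc <- cpm_log2(counts, config$pseudocount)
      expressed <- flag_expressed(lc, config$min_cpm, config$pseudocount)
      fam_expressed <- expressed[names(expressed) %in% calls$gene_id]
      clustering <- if (nrow(lc) >= 2L && ncol(lc) >= 2L) {
        cluster_heatmap_order(lc)
      } else NULL
      list(log2cpm = lc, expressed = expressed,
           n_family_expressed = sum(fam_expressed),
           n_family_in_matrix = length(fam_expressed),
           clustering = clustering)
    })
  } else NULL

  ratios <- kaks$ratio[!is.na(kaks$ratio)]
  subfam_counts <- table(factor(calls$subfamily,
                                levels = c("AP2", "ERF", "RAV", "Soloist")))
  label_counts <- table(factor(pairs$label,
                               levels = c("tandem", "segmental",
                                          "homoeolog")))
  report$summary <- list(
    species = config$species_prefix,
    n_family_genes = nrow(calls),
    subfamily_counts = as.list(setNames(as.integer(subfam_counts),
                                        names(subfam_counts))),
    n_pairs = nrow(pairs),
    pair_counts = as.list(setNames(as.integer(label_counts),
                                   names(label_counts))),
    n_segmental_incl_homoeolog =
      sum(pairs$label %in% c("segmental", "homoeolog")),
    n_tandem_clusters = nrow(report$clusters),
    kaks = list(
      n = nrow(kaks), n_ratio_defined = length(ratios),
      min = if (length(ratios)) min(ratios) else NA_real_,
      mean = if (length(ratios)) mean(ratios) else NA_real_,
      max = if (length(ratios)) max(ratios) else NA_real_,
      n_significant = sum(kaks$fisher_p <= config$alpha, na.rm = TRUE)),
    expression = if (!is.null(report$expression)) list(
      n_family_expressed = report$expression$n_family_expressed,
      n_family_in_matrix = report$expression$n_family_in_matrix
    ) else "not run",
    thresholds = list(
      ap2_evalue_max = config$thresholds$ap2_evalue_max,
      b3_evalue_max = config$thresholds$b3_evalue_max,
      max_tandem_distance_bp = config$criteria$max_tandem_distance_bp,
      min_identity_pct = config$criteria$min_identity_pct,
      min_coverage_pct = config$criteria$min_coverage_pct,
      min_site_coverage = config$min_site_coverage,
      min_cpm = config$min_cpm, alpha = config$alpha,
      clade_k = config$clade_k,
      subgenome_mode = config$subgenome_mode))
  class(report) <- "characterization_report"
  completed <- c(completed, "summary")
  finish()
  report
}

write_report <- function(report, completed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  wr(report$family, "family.tsv")
  wr(report$pairs, "pairs.tsv")
  wr(report$clusters, "tandem_clusters.tsv")
  wr(report$kaks, "kaks.tsv")
  wr(report$subgroups, "subgroups.tsv")
  if (!is.null(report$tree)) {
    write_newick(report$tree, file.path(dir, "family_tree.nwk"))
  }
  if (!is.null(report$expression)) {
    expr_df <- data.frame(gene_id = names(report$expression$expressed),
                          expressed = unname(report$expression$expressed))
    wr(expr_df, "expressed.tsv")
  }
  if (!is.null(report$summary)) {
    jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  writeLines(completed, file.path(dir, "MANIFEST"))
  invisible(dir)
}

#' Cross-species comparison of family composition
#'
#' Builds a long-format table (`species_or_subgenome` x `subfamily` x
#' `count`) from two or more characterization reports.  For species run in
#' subgenome mode, counts are additionally split by chromosome subgenome
#' suffix (one extra row block per suffix).  Subfamilies absent from a
#' species appear as zero-filled rows, not missing ones.  When reports carry
#' ERF subgroup assignments, a second table tallies subgroups the same way.
#'
#' @param reports List of `characterization_report` objects.
#' @return A list with `subfamily` (data frame) and, when available,
#'   `subgroup` (data frame).
#' @export
run_compare <- function(reports) {
  stopifnot(length(reports) >= 2L)
  ok <- vapply(reports, inherits, logical(1), "characterization_report")
  if (!all(ok)) stop2("run_compare expects characterization reports")
  subfams <- c("AP2", "ERF", "RAV", "Soloist")
  rows <- list()
  for (rep in reports) {
    fam <- rep$family
    sp <- rep$summary$species
    tally <- function(unit, df) {
      counts <- table(factor(df$subfamily, levels = subfams))
      data.frame(species_or_subgenome = unit, subfamily = subfams,
                 count = as.integer(counts), stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- tally(sp, fam)
    if (isTRUE(rep$summary$thresholds$subgenome_mode)) {
      sfx <- parse_chromosome(fam$chromosome)$suffix
      for (s in sort(unique(sfx[!is.na(sfx)]))) {
        rows[[length(rows) + 1L]] <-
          tally(paste0(sp, ":", s), fam[!is.na(sfx) & sfx == s, ,
                                        drop = FALSE])
      }
    }
  }
  out <- list(subfamily = do.call(rbind, rows))
  sub_reports <- Filter(function(r) !is.null(r$subgroups), reports)
  if (length(sub_reports) > 0L) {
    groups <- sort(unique(unlist(lapply(sub_reports, function(r)
      r$subgroups$final_subgroup))))
    groups <- groups[!is.na(groups)]
    srows <- lapply(sub_reports, function(r) {
      counts <- table(factor(r$subgroups$final_subgroup, levels = groups))
      data.frame(species_or_subgenome = r$summary$species,
                 subgroup = groups, count = as.integer(counts),
                 stringsAsFactors = FALSE)
    })
    out$subgroup <- do.call(rbind, srows)
  }
  out
}
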