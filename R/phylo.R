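# Neighbor-joining tree construction and the tree-dependent classification
# steps: subfamily override for single-AP2-domain genes, Soloist designation
# and two-step ERF subgroup assignment.

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining: at each step the pair minimizing the
#' Q-criterion is joined, with pendant branch lengths from the standard
#' two-point formulas; distances to the new node are
#' `(d(i,k) + d(j,k) - d(i,j)) / 2`.  Negative branch lengths are clamped to
#' zero (without redistribution).  Ties on Q are broken by the smallest
#' (i, j) pair of node creation indices, so the result is deterministic.
#' The tree terminates in the usual unrooted trifurcation.
#'
#' This implementation carries the package's documented tie-break and
#' clamping conventions; `ape::nj()` serves as an independent cross-check in
#' the test suite, not as the implementation.
#'
#' @param dm A `distance_matrix` from [pdistance_matrix()], or a plain
#'   symmetric numeric matrix with dimnames.
#' @return An [ape::phylo] tree whose leaves are the matrix labels.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else dm
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 3L) stop2("neighbor joining needs at least 3 taxa")
  # active nodes are newick fragments; creation index orders tie-breaking
  frags <- escape_newick(labels)
  active <- seq_len(n)           # positions into d/frags
  repeat {
    m <- length(active)
    if (m == 3L) break
    dm_act <- d[active, active, drop = FALSE]
    r <- rowSums(dm_act)
    q <- (m - 2) * dm_act - outer(r, r, `+`)
    diag(q) <- Inf
    # smallest Q; ties by smallest (i, j) creation-index pair
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        if (is.null(best) || q[i, j] < best$q - 1e-12) {
          best <- list(i = i, j = j, q = q[i, j])
        }
      }
    }
    i <- best$i; j <- best$j
    li <- dm_act[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dm_act[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    ai <- active[i]; aj <- active[j]
    new_frag <- sprintf("(%s:%s,%s:%s)", frags[ai], fmt_len(li),
                        frags[aj], fmt_len(lj))
    # distances from the new node u to every other active node
    others <- active[-c(i, j)]
    du <- (d[ai, others] + d[aj, others] - d[ai, aj]) / 2
    du <- pmax(du, 0)
    d <- rbind(cbind(d, 0), 0)
    u <- nrow(d)
    d[u, others] <- d[others, u] <- du
    frags <- c(frags, new_frag)
    active <- c(others, u)
  }
  # final trifurcation: three-point formulas
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- max((d[a, b] + d[a, c3] - d[b, c3]) / 2, 0)
  lb <- max((d[a, b] + d[b, c3] - d[a, c3]) / 2, 0)
  lc <- max((d[a, c3] + d[b, c3] - d[a, b]) / 2, 0)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", frags[a], fmt_len(la),
                    frags[b], fmt_len(lb), frags[c3], fmt_len(lc))
  ape::read.tree(text = newick)
}

fmt_len <- function(x) sprintf("%.12g", x)

escape_newick <- function(labels) {
  bad <- grepl("[\\s(),:;'\\[\\]]", labels, perl = TRUE)
  out <- labels
  out[bad] <- gsub("\\s", "_", labels[bad], perl = TRUE)
  out
}

# parent node of each node (0 for the root) and leaf sets per internal node
tree_parents <- function(tree) {
  parents <- integer(max(tree$edge))
  parents[tree$edge[, 2]] <- tree$edge[, 1]
  parents
}

leaves_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, leaves_under, tree = tree))
}

# Walk from a leaf toward the root; return, for the first ancestor holding at
# least k reference leaves, the reference labels under it together with the
# ancestor node id and whether that ancestor is the tree root.
clade_context_full <- function(tree, gene_id, reference_labels, k = 3L) {
  ntip <- length(tree$tip.label)
  leaf <- match(gene_id, tree$tip.label)
  if (is.na(leaf)) stop2("gene not in tree: ", gene_id)
  parents <- tree_parents(tree)
  root <- ntip + 1L
  node <- parents[leaf]
  while (node != 0L) {
    lv <- leaves_under(tree, node)
    refs <- reference_labels[names(reference_labels) %in% setdiff(lv, gene_id)]
    if (length(refs) >= k) {
      return(list(node = node, is_root = node == root, refs = refs))
    }
    node <- parents[node]
  }
  NULL
}

majority_label <- function(refs) {
  tab <- sort(table(refs), decreasing = TRUE)
  if (length(tab) == 0L) return(NA_character_)
  if (length(tab) > 1L && tab[1L] == tab[2L]) return(NA_character_)
  names(tab)[1L]
}

#' Subgroup context of a gene from its tree neighborhood
#'
#' Walks from the gene's leaf toward the root and, at the first ancestor
#' whose leaf set contains at least `k` reference leaves (the gene itself
#' excluded), returns the majority label among those references; a tie, or no
#' qualifying ancestor, yields `NA`.  This deterministic rule replaces the
#' by-eye "clustered with" judgement of manual tree curation.
#'
#' @param tree An [ape::phylo] tree.
#' @param gene_id A leaf label.
#' @param reference_labels Named character vector: names are reference leaf
#'   labels, values their subgroup (or subfamily) labels.
#' @param k Minimum number of reference leaves defining a usable context.
#' @return The majority label, or `NA_character_`.
#' @export
clade_context <- function(tree, gene_id, reference_labels, k = 3L) {
  ctx <- clade_context_full(tree, gene_id, reference_labels, k)
  if (is.null(ctx)) return(NA_character_)
  majority_label(ctx$refs)
}

#' Closest reference protein by global alignment
#'
#' For each query, aligns against every reference and reports the reference
#' with the highest percent identity, standing in for a BLASTP best hit when
#' the pipeline runs self-contained.
#'
#' @param queries Named character vector of query protein sequences.
#' @param references Named character vector of reference protein sequences.
#' @param reference_subgroups Named character vector mapping reference ids to
#'   subgroup labels.
#' @param scoring An [alignment_scoring()] object.
#' @return Data frame `gene_id`, `reference_id`, `subgroup`, `identity_pct`.
#' @export
best_reference_hits <- function(queries, references, reference_subgroups,
                                scoring = alignment_scoring()) {
  stopifnot(all(names(references) %in% names(reference_subgroups)))
  rows <- lapply(names(queries), function(q) {
    st <- align_stats_many(queries[[q]], references, scoring)
    best <- which.max(st$identity_pct)
    data.frame(gene_id = q, reference_id = names(references)[best],
               subgroup = unname(reference_subgroups[names(references)[best]]),
               identity_pct = st$identity_pct[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-step ERF subgroup assignment
#'
#' Each gene starts from the subgroup of its closest reference (BLAST-style
#' best hit); the NJ tree then confirms or refines the call: when the gene's
#' clade context (majority subgroup among the nearest `k`-strong set of
#' reference leaves) exists and differs from the best-hit subgroup, the tree
#' wins and the gene is flagged as reclassified.  Genes with neither a best
#' hit nor a tree context are reported unassigned rather than erroring.
#'
#' @param genes Character vector of gene ids to assign.
#' @param best_hits Data frame from [best_reference_hits()] (columns
#'   `gene_id`, `subgroup`); genes absent from it count as having no hit.
#' @param tree An [ape::phylo] tree containing the genes and references.
#' @param reference_labels Named character vector of reference subgroups.
#' @param k Context size passed to [clade_context()].
#' @return Data frame `gene_id`, `blast_subgroup`, `tree_subgroup`,
#'   `final_subgroup`, `reclassified`; unassigned genes carry NA finals.
#' @export
assign_subgroups <- function(genes, best_hits, tree, reference_labels,
                             k = 3L) {
  rows <- lapply(genes, function(g) {
    blast <- best_hits$subgroup[match(g, best_hits$gene_id)]
    tree_sub <- if (g %in% tree$tip.label) {
      clade_context(tree, g, reference_labels, k)
    } else NA_character_
    final <- if (!is.na(tree_sub)) tree_sub else blast
    data.frame(gene_id = g, blast_subgroup = blast, tree_subgroup = tree_sub,
               final_subgroup = final,
               reclassified = !is.na(final) && !is.na(blast) &&
                 final != blast,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tree-based subfamily overrides for single-AP2-domain genes
#'
#' Domain architecture alone cannot place every gene: some genes carry a
#' single AP2 domain yet belong with the two-domain AP2 subfamily, and a few
#' divergent single-domain genes (Soloists) group with neither clade.  Each
#' provisional-ERF gene is re-examined on the family tree.  References are
#' all other family genes labeled by architecture (AP2 for two-domain genes,
#' ERF for single-domain genes; RAV genes are not references).  Because the
#' placement of an NJ tree's final trifurcation is arbitrary, the rule works
#' on root-invariant patristic (branch-length path) distances:
#'
#' * A gene whose patristic distance to *every* reference exceeds the
#'   inter-clade scale — the median patristic distance between two-domain
#'   and single-domain genes — groups closely with neither subfamily and is
#'   designated Soloist.
#' * Otherwise the gene takes the majority architecture label among its `k`
#'   nearest reference leaves; a majority of AP2 overrides the call to AP2,
#'   a majority of ERF (or a tie) leaves the architecture call standing.
#'
#' When the family has no two-domain genes the inter-clade scale is
#' undefined and falls back to three times the median reference-reference
#' distance.
#'
#' @param calls Classification table from [classify_subfamily()].
#' @param tree Family tree over all genes in `calls`, with branch lengths on
#'   the p-distance scale.
#' @param k Number of nearest reference leaves voting on the label.
#' @return `calls` with `subfamily` and `subfamily_basis` updated
#'   (`"tree_override"` where the tree changed the architecture call).
#' @export
resolve_single_domain_overrides <- function(calls, tree, k = 3L) {
  missing <- setdiff(calls$gene_id, tree$tip.label)
  if (length(missing) > 0L) {
    stop2("family tree lacks gene ", missing[1L])
  }
  arch_labels <- setNames(calls$subfamily, calls$gene_id)
  refs <- arch_labels[arch_labels %in% c("AP2", "ERF")]
  ap2_genes <- names(refs)[refs == "AP2"]
  erf_genes <- names(refs)[refs == "ERF"]
  pd <- stats::cophenetic(tree)
  inter_scale <- if (length(ap2_genes) >= 1L && length(erf_genes) >= 1L) {
    stats::median(pd[ap2_genes, erf_genes, drop = FALSE])
  } else if (length(refs) >= 2L) {
    sub <- pd[names(refs), names(refs), drop = FALSE]
    3 * stats::median(sub[upper.tri(sub)])
  } else {
    Inf
  }
  for (idx in which(calls$subfamily == "ERF")) {
    g <- calls$gene_id[idx]
    others <- setdiff(names(refs), g)
    d <- pd[g, others]
    verdict <- if (length(d) == 0L || min(d) > inter_scale) {
      "Soloist"
    } else {
      nearest <- others[order(d, others)][seq_len(min(k, length(others)))]
      maj <- majority_label(refs[nearest])
      if (is.na(maj)) "ERF" else maj
    }
    if (verdict != "ERF") {
      calls$subfamily[idx] <- verdict
      calls$subfamily_basis[idx] <- "tree_override"
    }
  }
  calls
}
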