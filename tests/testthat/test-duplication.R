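mut_seq <- function(s, frac) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), round(frac * length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(aas, ch[p]), 1)
  paste(ch, collapse = "")
}

test_that("candidate pairs apply identity and bidirectional coverage", {
  set.seed(3)
  base <- random_aa_seq(150)
  reps <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    protein_id = paste0("p", 1:4),
    length = NA_integer_,
    seq = c(base, mut_seq(base, 0.05),           # 95% identity pair
            random_aa_seq(150),                  # unrelated
            substr(base, 1, 90)),                # fragment: coverage fails
    stringsAsFactors = FALSE)
  reps$length <- nchar(reps$seq)
  pairs <- candidate_pairs(reps)
  expect_identical(paste(pairs$gene_a, pairs$gene_b), "gA gB")
  expect_true(all(pairs$identity_pct >= 80))
  expect_true(all(pairs$gene_a < pairs$gene_b))
  # the fragment pair has high identity but fails the longer gene's coverage
  st <- alignment_stats(global_align(base, substr(base, 1, 90)))
  expect_gt(st$identity_pct, 80)
  expect_lt(st$coverage_a_pct, 80)
})

test_that("raising the identity floor never adds pairs", {
  b <- generate_diploid(synthetic_spec(seed = 19, background_genes = 0L))
  reps <- select_longest_isoform(b$proteins, b$coords)
  fam <- reps[reps$gene_id %in%
                identify_family(b$hits, reps)$gene_id, ]
  loose <- candidate_pairs(fam, duplication_criteria(min_identity_pct = 60))
  strict <- candidate_pairs(fam, duplication_criteria(min_identity_pct = 90))
  key <- function(df) paste(df$gene_a, df$gene_b)
  expect_true(all(key(strict) %in% key(loose)))
  expect_lte(nrow(strict), nrow(loose))
})

pair_df <- function(a, b) {
  data.frame(gene_a = a, gene_b = b, identity_pct = 95,
             coverage_a_pct = 95, coverage_b_pct = 95,
             stringsAsFactors = FALSE)
}

coord_df <- function(genes, chroms, starts) {
  data.frame(gene_id = genes, chromosome = chroms, start = starts,
             end = starts + 1000L, strand = "+", exon_count = 1L,
             protein_id = paste0(genes, ".p"),
             transcript_id = paste0(genes, ".t"), stringsAsFactors = FALSE)
}

test_that("pairs are labeled tandem / segmental / homoeolog by position", {
  coords <- coord_df(c("g1", "g2", "g3", "g4", "g5"),
                     c("2c", "2c", "2c", "2e", "3e"),
                     c(100000L, 600000L, 1200000L, 150000L, 100000L))
  crit <- duplication_criteria()
  # same chromosome, 0.5 Mb apart: tandem
  p <- classify_pairs(pair_df("g1", "g2"), coords, crit)
  expect_identical(p$label, "tandem")
  expect_equal(p$distance_bp, 500000L)
  # same chromosome, 1.1 Mb apart: segmental
  expect_identical(classify_pairs(pair_df("g1", "g3"), coords, crit)$label,
                   "segmental")
  # homoeologous chromosomes 2c/2e, subgenome mode on
  expect_identical(
    classify_pairs(pair_df("g1", "g4"), coords, crit,
                   subgenome_mode = TRUE)$label, "homoeolog")
  # same pair without subgenome mode: segmental
  expect_identical(classify_pairs(pair_df("g1", "g4"), coords, crit)$label,
                   "segmental")
  # non-partner chromosomes 2c/3e stay segmental even in subgenome mode
  expect_identical(
    classify_pairs(pair_df("g1", "g5"), coords, crit,
                   subgenome_mode = TRUE)$label, "segmental")
  expect_error(classify_pairs(pair_df("g1", "missing"), coords, crit),
               "missing")
})

test_that("the gap distance anchor measures end-to-start separation", {
  coords <- coord_df(c("g1", "g2"), c("1", "1"), c(100000L, 1050000L))
  crit_start <- duplication_criteria(distance_anchor = "start")
  crit_gap <- duplication_criteria(distance_anchor = "gap")
  expect_identical(classify_pairs(pair_df("g1", "g2"), coords,
                                  crit_start)$label, "tandem")
  expect_equal(classify_pairs(pair_df("g1", "g2"), coords,
                              crit_gap)$distance_bp, 949000L)
})

test_that("tandem clusters are connected components of the pair graph", {
  pairs <- rbind(pair_df("A", "B"), pair_df("B", "C"), pair_df("D", "E"))
  pairs$label <- "tandem"
  cl <- tandem_clusters(pairs)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$genes, c("A,B,C", "D,E"))
  expect_identical(sort(cl$size), c(2L, 3L))
  expect_equal(nrow(tandem_clusters(pairs[0, ])), 0L)
})

test_that("planted tandem events are recovered as clusters end to end", {
  b <- generate_diploid(synthetic_spec(seed = 29, n_tandem_events = 5L,
                                       n_segmental_events = 0L))
  reps <- select_longest_isoform(b$proteins, b$coords)
  fam <- reps[reps$gene_id %in% identify_family(b$hits, reps)$gene_id, ]
  labeled <- classify_pairs(candidate_pairs(fam), b$coords)
  cl <- tandem_clusters(labeled, b$coords)
  expect_equal(nrow(cl), 5L)
  expect_true(all(cl$size == 2L))
  expect_true(all(!is.na(cl$chromosome)))
})

test_that("summary counts report both segmental conventions", {
  labels <- c(rep("tandem", 12), rep("homoeolog", 77), rep("segmental", 11))
  pairs <- data.frame(gene_a = sprintf("a%03d", seq_along(labels)),
                      gene_b = sprintf("b%03d", seq_along(labels)),
                      label = labels, stringsAsFactors = FALSE)
  s <- duplication_summary(pairs, "Ca")
  expect_equal(s$n_pairs, 100L)
  expect_equal(s$n_tandem, 12L)
  expect_equal(s$n_homoeolog, 77L)
  expect_equal(s$n_segmental_strict, 11L)
  expect_equal(s$n_segmental_incl_homoeolog, 88L)

  empty <- duplication_summary(pairs[0, ])
  expect_equal(empty$n_pairs, 0L)
  expect_equal(empty$n_tandem + empty$n_segmental_strict +
                 empty$n_homoeolog, 0L)

  set.seed(4)
  rnd <- pairs[sample(nrow(pairs), 40), ]
  srnd <- duplication_summary(rnd)
  expect_equal(srnd$n_tandem + srnd$n_segmental_strict + srnd$n_homoeolog,
               srnd$n_pairs)
})

test_that("link tables carry both anchors and labels", {
  coords <- coord_df(c("g1", "g2"), c("1c", "1e"), c(1000L, 2000L))
  p <- classify_pairs(pair_df("g1", "g2"), coords, subgenome_mode = TRUE)
  link <- pair_link_table(p, coords)
  expect_identical(link$chrom_a, "1c")
  expect_equal(link$start_b, 2000L)
  expect_identical(link$label, "homoeolog")
})
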