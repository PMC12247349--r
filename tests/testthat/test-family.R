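coords_row <- function(gene, protein, transcript = paste0(protein, ".t"),
                       chrom = "1", start = 1000L, end = 2000L,
                       exons = 1L) {
  data.frame(gene_id = gene, chromosome = chrom, start = start, end = end,
             strand = "+", exon_count = exons, protein_id = protein,
             transcript_id = transcript, stringsAsFactors = FALSE)
}

test_that("longest isoform wins, with lexicographic tie-break", {
  proteins <- c(p_long = random_aa_seq(250), p_short = random_aa_seq(200),
                q1 = random_aa_seq(150))
  coords <- rbind(coords_row("g1", "p_long"), coords_row("g1", "p_short"),
                  coords_row("g2", "q1"))
  reps <- select_longest_isoform(proteins, coords)
  expect_identical(reps$protein_id[reps$gene_id == "g1"], "p_long")
  expect_identical(reps$protein_id[reps$gene_id == "g2"], "q1")

  tie <- c(pB = random_aa_seq(200), pA = random_aa_seq(200))
  coords2 <- rbind(coords_row("g1", "pB"), coords_row("g1", "pA"))
  expect_identical(select_longest_isoform(tie, coords2)$protein_id, "pA")

  expect_error(select_longest_isoform(proteins,
                                      rbind(coords, coords_row("g3", "zz"))),
               "g3")
})

test_that("family membership follows the AP2 E-value threshold", {
  reps <- data.frame(gene_id = c("g1", "g2", "g3"),
                     protein_id = c("p1", "p2", "p3"),
                     length = c(200L, 200L, 200L),
                     seq = replicate(3, random_aa_seq(200)),
                     stringsAsFactors = FALSE)
  hits <- data.frame(
    protein_id = c("p1", "p2", "p3", "p3", "p3"),
    profile = c("AP2", "AP2", "AP2", "AP2", "B3"),
    evalue = c(1e-6, 1e-4, 1e-30, 1e-12, 1e-8),
    ali_start = c(10L, 10L, 10L, 120L, 200L),
    ali_end = c(70L, 70L, 70L, 180L, 280L), stringsAsFactors = FALSE)
  fam <- identify_family(hits, reps)
  expect_setequal(fam$gene_id, c("g1", "g3"))  # 1e-4 hit is above threshold
  expect_equal(fam$ap2_domain_count[fam$gene_id == "g1"], 1L)
  expect_equal(fam$ap2_domain_count[fam$gene_id == "g3"], 2L)
  expect_true(fam$has_b3[fam$gene_id == "g3"])
  expect_false(fam$has_b3[fam$gene_id == "g1"])
})

test_that("overlapping AP2 hit envelopes are merged into one domain", {
  reps <- data.frame(gene_id = "g1", protein_id = "p1", length = 300L,
                     seq = random_aa_seq(300), stringsAsFactors = FALSE)
  # two hits sharing 40 of the shorter's 61 positions: one merged domain
  hits <- data.frame(protein_id = "p1", profile = "AP2",
                     evalue = c(1e-20, 1e-10),
                     ali_start = c(10L, 30L), ali_end = c(70L, 90L),
                     stringsAsFactors = FALSE)
  expect_equal(identify_family(hits, reps)$ap2_domain_count, 1L)
  # disjoint envelopes stay two domains
  hits$ali_start <- c(10L, 150L); hits$ali_end <- c(70L, 210L)
  expect_equal(identify_family(hits, reps)$ap2_domain_count, 2L)
})

test_that("tightening the E-value threshold never adds family genes", {
  set.seed(11)
  reps <- data.frame(gene_id = paste0("g", 1:30),
                     protein_id = paste0("p", 1:30), length = 200L,
                     seq = replicate(30, random_aa_seq(50)),
                     stringsAsFactors = FALSE)
  hits <- data.frame(
    protein_id = sample(reps$protein_id, 60, replace = TRUE),
    profile = "AP2", evalue = 10^runif(60, -30, 0),
    ali_start = 1L, ali_end = 50L, stringsAsFactors = FALSE)
  cutoffs <- 10^seq(-2, -20, by = -2)
  sets <- lapply(cutoffs, function(cut) {
    identify_family(hits, reps, identification_thresholds(cut, cut))$gene_id
  })
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("architecture maps to subfamily, provisionally for single-domain", {
  arch <- data.frame(gene_id = c("a", "b", "c"),
                     protein_id = c("pa", "pb", "pc"),
                     ap2_domain_count = c(2L, 1L, 1L),
                     has_b3 = c(FALSE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  calls <- classify_subfamily(arch)
  expect_identical(calls$subfamily, c("AP2", "RAV", "ERF"))
  expect_identical(unique(calls$subfamily_basis), "domain_architecture")

  arch$ap2_domain_count[1] <- 0L
  expect_error(classify_subfamily(arch), "ap2_domain_count")
})

test_that("systematic names follow the documented nomenclature grammar", {
  n <- 173L
  calls <- data.frame(gene_id = sprintf("g%03d", 1:n),
                      subfamily = "ERF", stringsAsFactors = FALSE)
  coords <- do.call(rbind, lapply(1:n, function(i) {
    coords_row(sprintf("g%03d", i), sprintf("p%03d", i),
               chrom = as.character((i %% 11) + 1), start = i * 1000L)
  }))
  named <- assign_names(calls, "Ca", coords)
  expect_setequal(named$assigned_name, sprintf("CaERF%03d", 1:n))
  expect_identical(named$assigned_name[1], "CaERF001")

  sol <- data.frame(gene_id = "s1", subfamily = "Soloist",
                    stringsAsFactors = FALSE)
  expect_identical(
    assign_names(sol, "Cc", coords_row("s1", "sp1"))$assigned_name,
    "CcSoloist.1")

  # natural chromosome order: chr 2 before chr 10, contigs last
  calls2 <- data.frame(gene_id = c("x", "y", "z"), subfamily = "ERF",
                       stringsAsFactors = FALSE)
  coords2 <- rbind(coords_row("x", "px", chrom = "10", start = 100L),
                   coords_row("y", "py", chrom = "2", start = 500L),
                   coords_row("z", "pz", chrom = "scaffold_3", start = 1L))
  named2 <- assign_names(calls2, "Ca", coords2)
  expect_identical(named2$gene_id[named2$assigned_name == "CaERF001"], "y")
  expect_identical(named2$gene_id[named2$assigned_name == "CaERF003"], "z")
})

test_that("intron counts are exon counts minus one", {
  expect_identical(count_introns(c(1L, 4L, 11L)), c(0L, 3L, 10L))
  expect_identical(count_introns(coords_row("g", "p", exons = 4L)), 3L)
})

test_that("every identified family gene gets exactly one subfamily", {
  b <- generate_diploid(synthetic_spec(seed = 3))
  reps <- select_longest_isoform(b$proteins, b$coords)
  calls <- classify_subfamily(identify_family(b$hits, reps))
  expect_false(anyDuplicated(calls$gene_id) > 0)
  expect_true(all(calls$subfamily %in% c("AP2", "ERF", "RAV")))
  # planted AP2/RAV architectures are recovered exactly from the hit table
  truth <- b$truth$genes
  expect_setequal(calls$gene_id[calls$subfamily == "AP2"],
                  truth$gene_id[truth$class == "two_domain"])
  expect_setequal(calls$gene_id[calls$subfamily == "RAV"],
                  truth$gene_id[truth$class == "rav"])
  # all planted single-domain genes land in provisional ERF
  expect_true(all(truth$gene_id[truth$class %in%
                                  c("single_domain", "soloist_like")] %in%
                    calls$gene_id[calls$subfamily == "ERF"]))
})
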