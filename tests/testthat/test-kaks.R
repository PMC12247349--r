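test_that("NG86 site counts match enumeration for canonical codons", {
  expect_equal(count_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(count_sites("ATG"), c(s = 0, n = 3))
  # every sense codon conserves s + n = 3
  for (codon in sense_codons()) {
    cs <- count_sites(codon)
    expect_equal(unname(cs["s"] + cs["n"]), 3, info = codon)
  }
  expect_error(count_sites("TAA"), "sense codon")
  expect_error(count_sites("ANT"), "sense codon")
})

test_that("difference counts classify single changes and average pathways", {
  expect_equal(count_differences("AAA", "AAG"), c(sd = 1, nd = 0))
  expect_equal(count_differences("AAA", "AAC"), c(sd = 0, nd = 1))
  expect_equal(count_differences("ACG", "ACG"), c(sd = 0, nd = 0))
  # TTT -> GTA: two pathways, one synonymous step on one of them
  expect_equal(count_differences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  # pathway counts always sum to the number of differing positions
  set.seed(61)
  codons <- sense_codons()
  for (i in 1:40) {
    a <- sample(codons, 1); b <- sample(codons, 1)
    dd <- count_differences(a, b)
    ndiff <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(dd["sd"] + dd["nd"]), ndiff, info = paste(a, b))
    expect_equal(count_differences(a, b), count_differences(b, a)[c(1, 2)],
                 tolerance = 1e-12)
  }
})

test_that("identical sequences give zero divergence and undefined ratio", {
  cds <- "ATGAAAGGGTTTCCCGAT"
  res <- kaks_pair(codon_alignment_from_cds(cds, cds))
  expect_equal(res$Ka, 0)
  expect_equal(res$Ks, 0)
  expect_true(is.na(res$ratio))
  expect_equal(res$fisher_p, 1)
})

test_that("purely synonymous divergence yields Ka = 0 and JC-corrected Ks", {
  set.seed(71)
  # 100 codons from the two fully synonymous third-position families,
  # then 4 synonymous third-position changes
  fams <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  codons <- paste0(sample(fams, 100, TRUE), sample(c("A", "C", "G", "T"),
                                                   100, TRUE))
  cds_a <- paste(codons, collapse = "")
  mut <- codons
  for (i in sample(100, 4)) {
    third <- substr(mut[i], 3, 3)
    substr(mut[i], 3, 3) <- sample(setdiff(c("A", "C", "G", "T"), third), 1)
  }
  cds_b <- paste(mut, collapse = "")
  res <- kaks_pair(codon_alignment_from_cds(cds_a, cds_b))
  expect_equal(res$Ka, 0)
  expect_equal(res$Nd, 0)
  expect_equal(res$Sd, 4)
  # independent recount: S sites via the enumeration oracle, then JC
  S <- sum(sapply(codons, function(cod) oracle_count_sites(cod)["s"]) +
             sapply(mut, function(cod) oracle_count_sites(cod)["s"])) / 2
  pS <- 4 / S
  expect_equal(res$Ks, -0.75 * log(1 - 4 * pS / 3), tolerance = 1e-12)
  expect_gt(res$Ks, 0)
})

test_that("Ka/Ks is symmetric and conserves site totals", {
  sim <- simulate_codon_pair(120, omega = 0.4, seed = 5)
  ab <- kaks_pair(sim$alignment)
  ba <- kaks_pair(codon_alignment_from_cds(sim$cds_b, sim$cds_a))
  for (f in c("S_sites", "N_sites", "Sd", "Nd", "Ka", "Ks", "ratio")) {
    expect_equal(ab[[f]], ba[[f]], info = f)
  }
  expect_equal(ab$S_sites + ab$N_sites, 3 * ab$n_codons_compared)
})

test_that("gap and stop codon columns are skipped with a count", {
  aln <- structure(list(id_a = "a", id_b = "b",
                        codons_a = c("ATG", "---", "TAA", "AAA"),
                        codons_b = c("ATG", "CCC", "GGG", "AAG")),
                   class = "codon_alignment")
  res <- kaks_pair(aln)
  expect_equal(res$n_codons_compared, 2L)
  expect_equal(res$n_codons_skipped, 2L)
  expect_equal(res$Sd, 1)
  # so few sites that the rounded Fisher table degenerates: p undefined
  expect_true(is.na(res$fisher_p))
})

test_that("saturated synonymous divergence is flagged, not NaN", {
  # serine third positions fully degenerate: every column one syn change
  codons_a <- rep("TCT", 30)
  codons_b <- rep("TCA", 30)
  res <- kaks_pair(codon_alignment_from_cds(paste(codons_a, collapse = ""),
                                            paste(codons_b, collapse = "")))
  expect_true(res$saturated)
  expect_true(is.na(res$Ks))
  expect_true(is.na(res$ratio))
})

test_that("Fisher's exact test matches enumeration and stats::fisher.test", {
  res0 <- list(Sd = 0, S_sites = 50, Nd = 0, N_sites = 150)
  expect_equal(fisher_significance(res0), 1)

  p <- ap2erf:::fisher_exact_2x2(3, 97, 0, 300)
  expect_equal(p, oracle_fisher_p(3, 97, 0, 300), tolerance = 1e-12)

  set.seed(81)
  for (i in 1:25) {
    a <- sample(0:20, 1); b <- sample(0:40, 1)
    c_ <- sample(0:20, 1); d <- sample(0:40, 1)
    ours <- ap2erf:::fisher_exact_2x2(a, b, c_, d)
    expect_equal(ours, oracle_fisher_p(a, b, c_, d), tolerance = 1e-12)
    # row swap leaves the two-sided p unchanged
    expect_equal(ours, ap2erf:::fisher_exact_2x2(c_, d, a, b))
    ft <- stats::fisher.test(matrix(c(a, c_, b, d), 2))$p.value
    expect_equal(ours, ft, tolerance = 1e-9)
  }
  expect_error(fisher_significance(list(Sd = 5, S_sites = 3, Nd = 0,
                                        N_sites = 10)), "negative")
})

test_that("batch Ka/Ks runs pairs end to end and summarizes ratios", {
  set.seed(91)
  b <- generate_diploid(synthetic_spec(seed = 37, n_tandem_events = 3L,
                                       n_segmental_events = 2L))
  reps <- select_longest_isoform(b$proteins, b$coords)
  fam <- reps[reps$gene_id %in% identify_family(b$hits, reps)$gene_id, ]
  pairs <- classify_pairs(candidate_pairs(fam), b$coords)
  prot <- setNames(fam$seq, fam$gene_id)
  cds <- setNames(unname(b$cds[fam$protein_id]), fam$gene_id)
  out <- kaks_batch(pairs, prot, cds)
  expect_equal(nrow(out), nrow(pairs))
  expect_true(all(out$fisher_p >= 0 & out$fisher_p <= 1))
  expect_true(all(out$Ka >= 0 & out$Ks >= 0, na.rm = TRUE))
  s <- attr(out, "summary")
  expect_true(s[["min"]] <= s[["mean"]] && s[["mean"]] <= s[["max"]])

  empty <- kaks_batch(pairs[0, ], prot, cds)
  expect_equal(nrow(empty), 0L)
  expect_true(all(is.na(attr(empty, "summary"))))

  # failures are collected, not fatal
  broken <- kaks_batch(pairs[1, , drop = FALSE],
                       prot, setNames("ATG", names(cds)[1]))
  expect_equal(nrow(broken), 0L)
  expect_length(attr(broken, "failures"), 1L)
})

test_that("mean estimated ratio is monotone in the generating omega", {
  means <- sapply(c(0.1, 0.5, 1.0), function(om) {
    mean(sapply(1:10, function(i) {
      kaks_pair(simulate_codon_pair(200, om, n_proposals = 100,
                                    seed = 7000 + 100 * om + i)$alignment)$ratio
    }))
  })
  expect_true(all(diff(means) > 0))
})
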