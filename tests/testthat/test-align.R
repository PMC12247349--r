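test_that("self-alignment is gapless with 100% identity", {
  aln <- global_align("ACDE", "ACDE")
  expect_identical(aln$aligned_a, "ACDE")
  expect_identical(aln$aligned_b, "ACDE")
  st <- alignment_stats(aln)
  expect_equal(st$identity_pct, 100)
  expect_equal(st$coverage_a_pct, 100)
})

test_that("global alignment score equals the brute-force optimum", {
  sc <- alignment_scoring()
  # the worked micro-example
  aln <- global_align("ACDE", "ACE")
  expect_equal(aln$score,
               brute_global_score("ACDE", "ACE", sc$matrix, 10, 0.5))
  # random tiny pairs, exhaustive enumeration oracle
  set.seed(23)
  for (i in 1:20) {
    a <- random_aa_seq(sample(3:8, 1))
    b <- random_aa_seq(sample(3:8, 1))
    expect_equal(global_align(a, b)$score,
                 brute_global_score(a, b, sc$matrix, 10, 0.5),
                 info = paste(a, b))
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  }
})

test_that("alignments satisfy their structural invariants", {
  set.seed(31)
  for (i in 1:25) {
    a <- random_aa_seq(sample(5:60, 1))
    b <- random_aa_seq(sample(5:60, 1))
    aln <- global_align(a, b)
    expect_equal(nchar(aln$aligned_a), nchar(aln$aligned_b))
    expect_identical(gsub("-", "", aln$aligned_a), a)
    expect_identical(gsub("-", "", aln$aligned_b), b)
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
  }
  expect_error(global_align("AC1E", "ACE"), "illegal residue.*position 3")
})

test_that("identity and coverage follow their definitions", {
  mk <- function(a, b) structure(list(id_a = "a", id_b = "b", aligned_a = a,
                                      aligned_b = b, score = 0),
                                 class = "pairwise_alignment")
  st <- alignment_stats(mk("ACDE", "AC-E"))
  expect_equal(st$identity_pct, 100)
  expect_equal(st$coverage_a_pct, 75)
  expect_equal(st$coverage_b_pct, 100)
  expect_equal(alignment_stats(mk("AAAA", "AAAT"))$identity_pct, 75)
  expect_error(alignment_stats(mk("AA--", "--TT")), "no residue-residue")
})

test_that("batch alignment statistics agree with the single-pair route", {
  # mutated copies of one sequence: the optimal alignment is unique, so the
  # vectorized scan and the single-pair route must agree exactly
  set.seed(7)
  target <- random_aa_seq(60)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), k)) ch[p] <- sample(setdiff(aas, ch[p]), 1)
    paste(ch, collapse = "")
  }
  others <- setNames(sapply(c(2, 5, 9, 14), mutate, s = target),
                     paste0("o", 1:4))
  st <- ap2erf:::align_stats_many(target, others)
  for (i in seq_along(others)) {
    single <- alignment_stats(global_align(target, others[[i]]))
    expect_equal(st$identity_pct[i], single$identity_pct)
    expect_equal(st$coverage_a_pct[i], single$coverage_a_pct)
    expect_equal(st$coverage_b_pct[i], single$coverage_b_pct)
  }
})

test_that("back-translation maps protein columns to codons", {
  aln <- structure(list(id_a = "a", id_b = "b", aligned_a = "MK",
                        aligned_b = "MK", score = 0),
                   class = "pairwise_alignment")
  caln <- backtranslate(aln, "ATGAAA", "ATGAAG")
  expect_identical(caln$codons_a, c("ATG", "AAA"))
  expect_identical(caln$codons_b, c("ATG", "AAG"))

  aln2 <- structure(list(id_a = "a", id_b = "b", aligned_a = "MK-V",
                         aligned_b = "MKAV", score = 0),
                    class = "pairwise_alignment")
  caln2 <- backtranslate(aln2, "ATGAAAGTT", "ATGAAAGCAGTT")
  expect_identical(caln2$codons_a[3], "---")
  expect_identical(caln2$codons_b[3], "GCA")

  # terminal stop codons are stripped
  expect_silent(backtranslate(aln, "ATGAAATAA", "ATGAAG"))
  expect_error(backtranslate(aln, "ATGAAAAA", "ATGAAG"), "length mismatch")
  expect_error(backtranslate(aln, "ATGATT", "ATGAAG"),
               "does not translate.*codon 2")
})

test_that("p-distances apply partial deletion then pairwise gap skipping", {
  expect_equal(pdistance_matrix(c(x = "AAAA", y = "AAAT"))$d["x", "y"], 0.25)

  dm <- pdistance_matrix(c(a = "A-A", b = "AAA", c = "AAA"),
                         min_site_coverage = 0.9)
  expect_equal(dm$sites_used, 2L)  # middle site has 2/3 coverage
  expect_true(all(dm$d == 0))

  # gap-free alignment: the filter removes nothing even at coverage 1.0
  msa <- c(r1 = "ACDEFG", r2 = "ACDEFF", r3 = "ACDFFG")
  expect_equal(pdistance_matrix(msa, 1.0)$sites_used, 6L)

  expect_error(pdistance_matrix(c(a = "A-", b = "-A")), "no comparable")
})

test_that("p-distance matrix equals a naive column recount", {
  set.seed(13)
  aas <- c("A", "C", "D", "E", "-")
  msa <- setNames(replicate(5, paste(sample(aas, 60, TRUE, prob = c(rep(0.22,
    4), 0.12)), collapse = "")), paste0("s", 1:5))
  # guard against all-gap pair columns in the random draw
  dm <- pdistance_matrix(msa, 0.9)
  expect_equal(dm$d, oracle_pdistance(msa, 0.9))
  expect_true(isSymmetric(dm$d))
  expect_true(all(diag(dm$d) == 0))
  expect_true(all(dm$d >= 0 & dm$d <= 1))
})

test_that("progressive alignment preserves sequences and aligns relatives", {
  set.seed(17)
  base <- random_aa_seq(80)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(LETTERS[LETTERS %in% ch], ch[p]),
                                   1)
    paste(ch, collapse = "")
  }
  seqs <- c(a = base, b = mut(base, 5), c = mut(base, 8),
            d = random_aa_seq(60))
  msa <- progressive_align(seqs)
  expect_equal(length(unique(nchar(msa))), 1L)
  expect_identical(gsub("-", "", msa[names(seqs)]), seqs)
})
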