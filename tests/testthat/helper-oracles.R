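# Independent oracles used across tests.  These deliberately re-derive
# quantities by different routes (exhaustive enumeration, closed forms,
# third-party code) than the implementation under test.

# Optimal global alignment score by exhaustive recursion over move sequences
# with affine gap costs (gap of length L costs open + L * ext).  Exponential;
# only for tiny strings.
brute_global_score <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(ca)) {  # gap in b
      cost <- if (last == "gb") ext else open + ext
      best <- max(best, -cost + rec(i + 1, j, "gb"))
    }
    if (j <= length(cb)) {  # gap in a
      cost <- if (last == "ga") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1, "ga"))
    }
    best
  }
  rec(1, 1, "m")
}

# NG86 site counts of a codon using seqinr's translation (independent of the
# implementation's Biostrings-based genetic code lookup).
oracle_count_sites <- function(codon) {
  translate1 <- function(cod) {
    seqinr::translate(strsplit(tolower(cod), "")[[1]])
  }
  aa <- translate1(codon)
  nucs <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(nucs, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      mut_aa <- translate1(mut)
      if (mut_aa != "*" && mut_aa == aa) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

# NG86 pathway-averaged difference counts by explicit enumeration of change
# orderings, using seqinr translation.
oracle_count_differences <- function(codon_a, codon_b) {
  translate1 <- function(cod) {
    seqinr::translate(strsplit(tolower(cod), "")[[1]])
  }
  stops <- c("TAA", "TAG", "TGA")
  pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  orderings <- if (length(pos) == 1) list(pos) else {
    perm_idx <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (r in perm_idx(v[-i])) out[[length(out) + 1]] <- c(v[i], r)
      }
      out
    }
    perm_idx(pos)
  }
  paths <- lapply(orderings, function(ord) {
    cur <- codon_a; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon_b, p, p)
      if (nxt %in% stops) blocked <- TRUE
      if (!(cur %in% stops) && !(nxt %in% stops) &&
          translate1(cur) == translate1(nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  open <- Filter(function(p) !p$blocked, paths)
  use <- if (length(open) > 0) open else paths
  c(sd = mean(sapply(use, `[[`, "sd")), nd = mean(sapply(use, `[[`, "nd")))
}

# Two-sided Fisher exact p-value for [[a, b], [c, d]] by direct enumeration
# with probabilities computed from log-binomial coefficients (independent of
# stats::dhyper).
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k <- a + c_
  if (r1 + r2 == 0) return(1)
  support <- max(0, k - r2):min(k, r1)
  logp <- lchoose(r1, support) + lchoose(r2, k - support) -
    lchoose(r1 + r2, k)
  probs <- exp(logp)
  p_obs <- exp(lchoose(r1, a) + lchoose(r2, k - a) - lchoose(r1 + r2, k))
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

# Naive column-by-column p-distance recount (partial deletion included).
oracle_pdistance <- function(msa, min_cov) {
  rows <- strsplit(unname(msa), "")
  width <- length(rows[[1]])
  n <- length(rows)
  keep <- sapply(seq_len(width), function(col) {
    mean(sapply(rows, `[`, col) != "-") >= min_cov
  })
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- 0; den <- 0
      for (col in which(keep)) {
        x <- rows[[i]][col]; y <- rows[[j]][col]
        if (x != "-" && y != "-") {
          den <- den + 1
          if (x != y) num <- num + 1
        }
      }
      d[i, j] <- d[j, i] <- num / den
    }
  }
  d
}

random_aa_seq <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len,
               replace = TRUE), collapse = "")
}

sense_codons <- function() {
  nucs <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(nucs, nucs, paste0), nucs, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}
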