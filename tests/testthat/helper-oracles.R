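# Independent oracles used across the suite. These deliberately reimplement
# the checked operations by brute force and stay out of the package.

# Smith-Waterman local alignment with affine gaps, plain O(nm) dynamic
# programming; N mismatches everything.
sw_affine <- function(a, b, match = 1, mismatch = -1, gap_open = 2,
                      gap_extend = 1) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0)
  H <- matrix(0, n + 1, m + 1)   # best ending in match/mismatch or fresh start
  E <- matrix(-Inf, n + 1, m + 1)  # gap in b (consume a)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1] && a[i - 1] != "N") match else mismatch
      E[i, j] <- max(H[i - 1, j] - gap_open, E[i - 1, j] - gap_extend)
      F[i, j] <- max(H[i, j - 1] - gap_open, F[i, j - 1] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Exact two-sided Wilcoxon rank-sum p-value by enumeration of all
# choose(n1 + n2, n1) group arrangements (tie-free data), using the standard
# doubling rule for the two-sided p.
wilcox_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Mutate a DNA string at the given positions (substitution to a different base).
mutate_seq <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

write_fastq_records <- function(path, seqs) {
  if (length(seqs) == 0) {
    writeLines(character(0), path)
  } else {
    writeLines(as.vector(rbind(sprintf("@r%03d", seq_along(seqs)), seqs, "+",
                               strrep("I", nchar(seqs)))), path)
  }
  path
}
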