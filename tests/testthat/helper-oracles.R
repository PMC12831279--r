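# Independent oracles, deliberately naive: plain dynamic programming and
# exhaustive enumeration, sharing no code with the package's implementations.

# Smith-Waterman with affine gaps (Gotoh), plain R matrices
sw_oracle <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)   # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1) # gap in b (deletion from a's view)
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      s <- mat[a[i], b[j]]
      M[i + 1, j + 1] <- max(0, s + max(M[i, j], X[i, j], Y[i, j]))
      best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

# exhaustive two-exon placement: best (donor, acceptor) split of a transcript
# against a toy genome, scored by exact matches of the two pieces
two_split_oracle <- function(transcript, genome_seq, min_intron = 30) {
  L <- nchar(transcript)
  G <- nchar(genome_seq)
  best <- NULL
  for (cut in 1:(L - 1)) {
    left <- substr(transcript, 1, cut)
    right <- substr(transcript, cut + 1, L)
    l_hits <- gregexpr(left, genome_seq, fixed = TRUE)[[1]]
    r_hits <- gregexpr(right, genome_seq, fixed = TRUE)[[1]]
    if (l_hits[1] == -1 || r_hits[1] == -1) next
    for (ls in l_hits) for (rs in r_hits) {
      intron <- rs - (ls + cut)
      if (intron < min_intron) next
      cand <- list(cut = cut, exon1 = c(ls, ls + cut - 1),
                   exon2 = c(rs, rs + (L - cut) - 1), intron = intron)
      if (is.null(best) || cand$intron < best$intron) best <- cand
    }
  }
  best
}

# hypergeometric upper tail by direct enumeration over all n-subsets is
# infeasible; enumerate the distribution over overlap sizes combinatorially
hyper_tail_oracle <- function(k, K, N, n) {
  js <- max(0, n - (N - K)):min(n, K)
  p <- sum(vapply(js[js >= k], function(j) {
    choose(K, j) * choose(N - K, n - j)
  }, numeric(1))) / choose(N, n)
  p
}

# brute-force mutual-best pairing over a score matrix (no margin rule)
rbh_oracle <- function(sc) {
  pairs <- list()
  for (i in seq_len(nrow(sc))) {
    j <- which.max(sc[i, ])
    if (which.max(sc[, j]) == i) {
      pairs[[length(pairs) + 1L]] <- c(rownames(sc)[i], colnames(sc)[j])
    }
  }
  do.call(rbind, pairs)
}

random_protein <- function(n, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate a protein: substitutions at the given rate, never into itself
mutate_protein <- function(seq, rate,
                           alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(alphabet, ch[i]), 1)
  paste(ch, collapse = "")
}
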