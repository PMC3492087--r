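# Independent oracles used across the suite.  These deliberately share no
# code with the package implementation.

# textbook local alignment with affine gaps, full matrix, score only;
# a gap of length g costs open + (g - 1) * extend
swOracleScore <- function(query, target, match = 1, mismatch = -3,
                          open = -5, extend = -2) {
  q <- strsplit(query, "")[[1L]]
  t <- strsplit(target, "")[[1L]]
  m <- length(q)
  n <- length(t)
  NEG <- -1e9
  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(NEG, m + 1L, n + 1L)
  F <- matrix(NEG, m + 1L, n + 1L)
  best <- 0
  for (i in seq_len(m) + 1L) {
    for (j in seq_len(n) + 1L) {
      E[i, j] <- max(H[i, j - 1L] + open, E[i, j - 1L] + extend)
      F[i, j] <- max(H[i - 1L, j] + open, F[i - 1L, j] + extend)
      s <- if (q[i - 1L] == t[j - 1L]) match else mismatch
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# average pairwise Hamming distance over all haplotype pairs, summed over
# sites, by direct enumeration
piOracle <- function(hapMatrix) {
  n <- nrow(hapMatrix)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      tot <- tot + sum(hapMatrix[i, ] != hapMatrix[j, ])
    }
  }
  tot / choose(n, 2L)
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcompOracle <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

# brute-force per-base depth recount by interval stabbing over aligned spans
depthOracle <- function(placements, ref_length) {
  depth <- integer(ref_length)
  mapped <- placements[placements$mapped, , drop = FALSE]
  for (r in seq_len(nrow(mapped))) {
    t <- mapped$pos[r] + 1L
    cig <- mapped$cigar[r]
    for (piece in regmatches(cig, gregexpr("[0-9]+[=XMIDS]", cig))[[1L]]) {
      len <- as.integer(sub("[=XMIDS]", "", piece))
      op <- sub("[0-9]+", "", piece)
      if (op %in% c("=", "X", "M", "D")) {
        depth[t:(t + len - 1L)] <- depth[t:(t + len - 1L)] + 1L
        t <- t + len
      }
    }
  }
  depth
}
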