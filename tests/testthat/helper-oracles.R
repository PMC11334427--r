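# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / closed form, independent of the package code
# paths they check.

# Gotoh affine-gap global alignment, score only. Same convention as
# align_pair: a gap of length L costs gap_open + L * gap_ext.
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = 4, gap_ext = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  open <- gap_open + gap_ext
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a char over gap)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + gap_ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + gap_ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - gap_ext,
                             Y[i, j + 1] - open)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open, X[i + 1, j] - open,
                             Y[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Benjamini-Hochberg step-up from its definition: sort, p * m / rank,
# cumulative minimum from the largest rank down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Minimum Hamming distance from a window to any concrete expansion of a
# degenerate primer.
oracle_min_hamming <- function(iupac, window) {
  variants <- markerlens::iupac_expand(iupac)
  vm <- do.call(rbind, strsplit(variants, "", fixed = TRUE))
  wv <- strsplit(window, "", fixed = TRUE)[[1]]
  min(rowSums(sweep(vm, 2, wv, "!=")))
}

# K80 closed form, evaluated independently of compute_k80.
oracle_k80 <- function(P, Q) {
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
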