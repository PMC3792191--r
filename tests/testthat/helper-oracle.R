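# Independent brute-force reference implementations used as oracles.
# Deliberately naive: explicit loops over all 441 ordered pairs and all
# subsites, no shared code with the package internals.

ORACLE_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "Z")

oracle_residue_rank <- function(ch) which(ORACLE_ALPHABET == ch)

# All 441 ordered pair strings in lexicographic order of (first, second).
oracle_pairs <- function() {
  out <- character(0)
  for (a in ORACLE_ALPHABET) for (b in ORACLE_ALPHABET) out <- c(out, paste0(a, b))
  out
}

# 441 x n_subsites frequency matrix for one gap, counted pair by pair.
oracle_pair_freq <- function(windows, gap, window_length = 21L) {
  pairs <- oracle_pairs()
  ns <- window_length - (gap + 2L) + 1L
  f <- matrix(0, nrow = length(pairs), ncol = ns, dimnames = list(pairs, NULL))
  for (j in seq_len(ns)) {
    for (w in windows) {
      pr <- paste0(substr(w, j, j), substr(w, j + gap + 1L, j + gap + 1L))
      for (i in seq_along(pairs)) {
        if (pairs[i] == pr) f[i, j] <- f[i, j] + 1
      }
    }
  }
  f / length(windows)
}

oracle_psdp <- function(pos_windows, neg_windows, gap, window_length = 21L) {
  oracle_pair_freq(pos_windows, gap, window_length) -
    oracle_pair_freq(neg_windows, gap, window_length)
}

# 39-component feature vector of one window via direct lookup.
oracle_encode <- function(window, z0, z1, window_length = 21L) {
  n0 <- window_length - 1L
  n1 <- window_length - 2L
  psi <- numeric(n0 + n1)
  for (u in seq_len(n0)) {
    pr <- paste0(substr(window, u, u), substr(window, u + 1L, u + 1L))
    psi[u] <- z0[pr, u]
  }
  for (v in seq_len(n1)) {
    pr <- paste0(substr(window, v, v), substr(window, v + 2L, v + 2L))
    psi[n0 + v] <- z1[pr, v]
  }
  psi
}

oracle_norm <- function(windows, z0, z1, window_length = 21L) {
  mat <- t(vapply(windows, oracle_encode, numeric(2L * window_length - 3L),
                  z0, z1, window_length))
  colMeans(mat)
}

oracle_distance <- function(a, b) sqrt(sum((a - b)^2))

# Random valid windows: 'C' at the center, other residues uniform over the
# 20 amino acids plus an occasional pad symbol.
random_windows <- function(n, window_length = 21L, pad_prob = 0.05) {
  center <- (window_length + 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    res <- sample(ORACLE_ALPHABET[1:20], window_length, replace = TRUE)
    pad <- runif(window_length) < pad_prob
    res[pad] <- "Z"
    res[center] <- "C"
    paste0(res, collapse = "")
  }, character(1))
}

# Two handcrafted 21-mers sharing no gap-0 or gap-1 pair at any subsite.
disjoint_pair_windows <- function() {
  c(pos = "ACDEFGHIKLCMNPQRSTVWY",
    neg = "YWVTSRQPNMCLKIHGFEDCA")
}
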