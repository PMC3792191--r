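#' Position-specific pair frequencies
#'
#' Tallies, for one residue-pair gap, the occurrence frequency of each of the
#' 441 ordered pairs at each subsite over a set of equal-length windows.
#' Gap 0 pairs adjacent residues (R_u, R_{u+1}); gap 1 pairs residues
#' separated by one position (R_u, R_{u+2}). There are 20 gap-0 and 19 gap-1
#' subsites in a 21-mer. Pairs containing the padding symbol are tallied like
#' any other pair.
#'
#' @param windows Character vector of validated peptide windows.
#' @param gap Integer, 0 or 1.
#' @param config A [window_config()].
#' @param pseudocount Additive smoothing constant per (pair, subsite) cell;
#'   default 0 (unseen pairs have frequency exactly 0).
#' @return An object of class `pair_freq`: list with `gap`, `counts` and
#'   `freq` (441 x n_subsites matrices, rows named by pair), `n_samples`,
#'   `pseudocount`. Each frequency column sums to 1.
#' @export
pair_frequencies <- function(windows, gap, config = window_config(),
                             pseudocount = 0) {
  gap <- as.integer(gap)
  if (!gap %in% c(0L, 1L))
    sno_error("snopair_config_error", "gap must be 0 or 1")
  if (length(windows) == 0L)
    sno_error("snopair_empty_dataset",
              "cannot compute pair frequencies from an empty window set")
  if (pseudocount < 0)
    sno_error("snopair_config_error", "pseudocount must be >= 0")
  pm <- pair_index_matrix(windows, gap, config)
  npair <- ALPHABET_SIZE^2
  counts <- vapply(seq_len(ncol(pm)),
                   function(j) tabulate(pm[, j], nbins = npair),
                   numeric(npair))
  dimnames(counts) <- list(pair_labels(config$pad_symbol), NULL)
  n <- length(windows)
  freq <- (counts + pseudocount) / (n + npair * pseudocount)
  structure(list(gap = gap, counts = counts, freq = freq,
                 n_samples = n, pseudocount = pseudocount),
            class = "pair_freq")
}

#' Position-specific dipeptide propensity (PSDP) matrix
#'
#' The elementwise difference between the positive-class and negative-class
#' pair-frequency matrices: each entry is the propensity of a pair at a
#' subsite, positive when the pair is over-represented among SNO windows.
#'
#' @param freq_pos,freq_neg [pair_frequencies()] results for the same gap and
#'   shape, from the positive and negative class respectively.
#' @return An object of class `psdp_matrix`: list with `gap` and `values`
#'   (441 x n_subsites, entries in \[-1, 1\]).
#' @export
psdp <- function(freq_pos, freq_neg) {
  if (!inherits(freq_pos, "pair_freq") || !inherits(freq_neg, "pair_freq"))
    sno_error("snopair_config_error", "inputs must be pair_freq objects")
  if (freq_pos$gap != freq_neg$gap ||
      !identical(dim(freq_pos$freq), dim(freq_neg$freq)))
    sno_error("snopair_incompatible_matrices",
              "pair-frequency matrices differ in gap or shape")
  structure(list(gap = freq_pos$gap,
                 values = freq_pos$freq - freq_neg$freq),
            class = "psdp_matrix")
}

#' Encode windows as pairwise-coupling feature vectors
#'
#' Each window maps to a vector of `omega = 39` components (at `xi = 10`):
#' component u (1..20) is the gap-0 propensity of the pair starting at
#' subsite u; component 20 + v (v = 1..19) is the gap-1 propensity of the
#' pair starting at subsite v. This is the pairwise-coupling pseudo amino
#' acid composition of the window under the trained propensity matrices.
#'
#' @param windows Character vector of peptide windows.
#' @param z0,z1 [psdp()] matrices for gap 0 and gap 1.
#' @param config A [window_config()].
#' @return Numeric matrix, `length(windows)` x omega; each row a feature
#'   vector with components in \[-1, 1\].
#' @export
encode_windows <- function(windows, z0, z1, config = window_config()) {
  if (!inherits(z0, "psdp_matrix") || z0$gap != 0L)
    sno_error("snopair_config_error", "z0 must be a gap-0 psdp_matrix")
  if (!inherits(z1, "psdp_matrix") || z1$gap != 1L)
    sno_error("snopair_config_error", "z1 must be a gap-1 psdp_matrix")
  n0 <- n_subsites(config, 0L)
  n1 <- n_subsites(config, 1L)
  if (ncol(z0$values) != n0 || ncol(z1$values) != n1)
    sno_error("snopair_incompatible_matrices",
              "PSDP matrix width does not match the window configuration")
  p0 <- pair_index_matrix(windows, 0L, config)
  p1 <- pair_index_matrix(windows, 1L, config)
  n <- length(windows)
  psi <- matrix(0, nrow = n, ncol = n0 + n1)
  for (u in seq_len(n0)) psi[, u] <- z0$values[cbind(p0[, u], u)]
  for (v in seq_len(n1)) psi[, n0 + v] <- z1$values[cbind(p1[, v], v)]
  colnames(psi) <- c(paste0("g0.", seq_len(n0)), paste0("g1.", seq_len(n1)))
  psi
}
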