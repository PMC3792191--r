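#' The 20 native amino acids in single-letter alphabetic order
#'
#' Residues are ranked by the alphabetic order of their single-letter codes,
#' giving numerical codes 1..20; the padding symbol (default `"Z"`) is rank 21.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default padding symbol for residues beyond the protein termini
#' @format Character scalar.
#' @export
PAD_SYMBOL <- "Z"

# Letters sometimes seen in FASTA but outside the 20-letter alphabet.
NONSTANDARD_LETTERS <- c("B", "J", "O", "U", "X")

ALPHABET_SIZE <- 21L

sno_error <- function(subclass, message, ...) {
  stop(structure(
    class = c(subclass, "snopair_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

full_alphabet <- function(pad_symbol = PAD_SYMBOL) c(AA_ALPHABET, pad_symbol)

#' Numerical code of a residue
#'
#' Maps each residue to its rank in the alphabetically ordered 20-letter
#' amino-acid alphabet (A=1, C=2, ..., Y=20); the padding symbol maps to 21.
#'
#' @param residue Character vector of single residues.
#' @param pad_symbol Padding symbol treated as alphabet member 21.
#' @return Integer vector of codes in 1..21.
#' @examples
#' residue_index(c("A", "C", "Z"))
#' @export
residue_index <- function(residue, pad_symbol = PAD_SYMBOL) {
  idx <- match(residue, full_alphabet(pad_symbol))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    sno_error("snopair_invalid_residue",
              sprintf("invalid residue '%s' at element %d (alphabet is %s)",
                      residue[bad], bad,
                      paste0(c(AA_ALPHABET, pad_symbol), collapse = "")))
  }
  idx
}

#' Index of an ordered residue pair
#'
#' Ordered pairs over the 21-letter alphabet are ranked lexicographically:
#' AA=1, AC=2, ..., ZY=440, ZZ=441.
#'
#' @param first,second Character vectors of single residues.
#' @inheritParams residue_index
#' @return Integer vector of pair indices in 1..441.
#' @examples
#' pair_index("A", "C")   # 2
#' pair_index("Z", "Z")   # 441
#' @export
pair_index <- function(first, second, pad_symbol = PAD_SYMBOL) {
  (residue_index(first, pad_symbol) - 1L) * ALPHABET_SIZE +
    residue_index(second, pad_symbol)
}

#' Two-letter labels for all ordered residue pairs
#'
#' @inheritParams residue_index
#' @return Character vector of length 441 in pair-index order.
#' @export
pair_labels <- function(pad_symbol = PAD_SYMBOL) {
  ab <- full_alphabet(pad_symbol)
  as.vector(t(outer(ab, ab, paste0)))
}

# Decode a pair index back to its two residues.
pair_decode <- function(index, pad_symbol = PAD_SYMBOL) {
  ab <- full_alphabet(pad_symbol)
  cbind(ab[(index - 1L) %/% ALPHABET_SIZE + 1L],
        ab[(index - 1L) %% ALPHABET_SIZE + 1L])
}
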