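#' Window extraction configuration
#'
#' Peptide windows are cysteine-centered fragments of `2 * xi + 1` residues;
#' positions falling outside the protein are filled with the padding symbol.
#'
#' @param xi Flank length in residues on each side of the central cysteine.
#'   The default 10 gives the standard 21-mer window.
#' @param pad_symbol Dummy residue used for positions beyond the termini;
#'   must not be one of the 20 native amino-acid letters.
#' @param min_protein_length_warning Proteins shorter than this are flagged as
#'   fragments when predicting (default 50 residues).
#' @return An object of class `window_config`.
#' @examples
#' window_config()
#' @export
window_config <- function(xi = 10L, pad_symbol = PAD_SYMBOL,
                          min_protein_length_warning = 50L) {
  xi <- as.integer(xi)
  if (is.na(xi) || xi < 1L)
    sno_error("snopair_config_error", "xi must be an integer >= 1")
  if (!is.character(pad_symbol) || nchar(pad_symbol) != 1L ||
      pad_symbol %in% AA_ALPHABET)
    sno_error("snopair_config_error",
              "pad_symbol must be a single character outside the 20 amino-acid letters")
  structure(list(xi = xi,
                 window_length = 2L * xi + 1L,
                 pad_symbol = pad_symbol,
                 min_protein_length_warning = as.integer(min_protein_length_warning)),
            class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("Window config: xi = %d (window length %d), pad = '%s'\n",
              x$xi, x$window_length, x$pad_symbol))
  invisible(x)
}

# Number of pair subsites for a given gap (gap 0: adjacent, gap 1: next-nearest).
n_subsites <- function(config, gap) config$window_length - (gap + 2L) + 1L

# Feature dimension: subsites for gap 0 plus gap 1 (39 at xi = 10).
omega_dim <- function(config) n_subsites(config, 0L) + n_subsites(config, 1L)

#' A protein sequence record
#'
#' @param id Accession string (first whitespace-delimited token of a FASTA
#'   header).
#' @param sequence Amino-acid sequence; lowercase letters are accepted and
#'   uppercased on ingest.
#' @param map_nonstandard If `TRUE`, the non-standard letters B, J, O, U, X are
#'   mapped to the padding symbol; by default they are rejected with an error,
#'   since silently coercing them would corrupt pair frequencies.
#' @param pad_symbol Padding symbol used when mapping non-standard letters.
#' @return An object of class `protein_record` with fields `id` and `sequence`.
#' @examples
#' protein_record("P1", "MKVCDEF")
#' @export
protein_record <- function(id, sequence, map_nonstandard = FALSE,
                           pad_symbol = PAD_SYMBOL) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    sno_error("snopair_validation_error",
              sprintf("protein '%s': sequence must be a non-empty string", id))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    if (map_nonstandard && all(chars[bad] %in% NONSTANDARD_LETTERS)) {
      chars[bad] <- pad_symbol
      sequence <- paste0(chars, collapse = "")
    } else {
      i <- which(bad)[1]
      sno_error("snopair_invalid_residue",
                sprintf(paste0("protein '%s': invalid residue '%s' at position %d",
                               " (use map_nonstandard = TRUE to map B/J/O/U/X",
                               " to the pad symbol)"),
                        id, chars[i], i))
    }
  }
  structure(list(id = as.character(id), sequence = sequence),
            class = "protein_record")
}

#' Extract a cysteine-centered peptide window
#'
#' Returns the `xi` residues upstream, the central cysteine, and the `xi`
#' residues downstream; positions outside the protein contribute the padding
#' symbol.
#'
#' @param protein A [protein_record()].
#' @param position 1-based index of a cysteine in the protein.
#' @param config A [window_config()].
#' @return A single string of length `config$window_length`.
#' @examples
#' extract_window(protein_record("p", "C"), 1)
#' @export
extract_window <- function(protein, position, config = window_config()) {
  n <- nchar(protein$sequence)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > n)
    sno_error("snopair_bounds_error",
              sprintf("protein '%s': position %s outside 1..%d",
                      protein$id, position, n))
  if (substr(protein$sequence, position, position) != "C")
    sno_error("snopair_not_cysteine",
              sprintf("protein '%s': residue at position %d is '%s', not 'C'",
                      protein$id, position,
                      substr(protein$sequence, position, position)))
  lo <- position - config$xi
  hi <- position + config$xi
  core <- substr(protein$sequence, max(lo, 1L), min(hi, n))
  paste0(strrep(config$pad_symbol, max(0L, 1L - lo)),
         core,
         strrep(config$pad_symbol, max(0L, hi - n)))
}

#' Enumerate windows at every cysteine of a protein
#'
#' One window per cysteine, in ascending position order. A site is labeled
#' `"SNO"` iff its position appears in `annotations` with label SNO; every
#' other cysteine is `"non-SNO"`.
#'
#' @inheritParams extract_window
#' @param annotations Optional data frame with columns `protein_id`,
#'   `position`, `label` (values `"SNO"` / `"non-SNO"`); rows for other
#'   proteins are ignored.
#' @return A peptide table: data frame with columns `protein_id`, `position`,
#'   `label`, `window`. Zero rows if the protein has no cysteine.
#' @export
cysteine_windows <- function(protein, annotations = NULL,
                             config = window_config()) {
  pos <- which(strsplit(protein$sequence, "", fixed = TRUE)[[1]] == "C")
  labels <- rep("non-SNO", length(pos))
  if (!is.null(annotations)) {
    ann <- annotations[annotations$protein_id == protein$id, , drop = FALSE]
    if (nrow(ann) > 0) {
      bad <- setdiff(as.integer(ann$position), pos)
      if (length(bad) > 0)
        sno_error("snopair_annotation_error",
                  sprintf("protein '%s': annotated position %d is not a cysteine",
                          protein$id, bad[1]))
      labels[match(as.integer(ann$position[ann$label == "SNO"]), pos)] <- "SNO"
    }
  }
  data.frame(protein_id = rep(protein$id, length(pos)),
             position = pos,
             label = labels,
             window = vapply(pos, function(p) extract_window(protein, p, config),
                             character(1)),
             stringsAsFactors = FALSE)
}

# Validate a character vector of windows: right length, 'C' at the center.
validate_windows <- function(windows, config = window_config(),
                             what = "window") {
  if (length(windows) == 0L) return(invisible(windows))
  len <- nchar(windows)
  if (any(len != config$window_length)) {
    i <- which(len != config$window_length)[1]
    sno_error("snopair_validation_error",
              sprintf("%s %d has length %d, expected %d",
                      what, i, len[i], config$window_length))
  }
  center <- substr(windows, config$xi + 1L, config$xi + 1L)
  if (any(center != "C")) {
    i <- which(center != "C")[1]
    sno_error("snopair_validation_error",
              sprintf("%s %d has '%s' at the center, expected 'C'",
                      what, i, center[i]))
  }
  invisible(windows)
}

# Windows (character vector) -> integer matrix of residue codes, n x L.
window_matrix <- function(windows, config = window_config()) {
  validate_windows(windows, config)
  chars <- strsplit(windows, "", fixed = TRUE)
  m <- matrix(residue_index(unlist(chars), config$pad_symbol),
              nrow = length(windows), ncol = config$window_length,
              byrow = TRUE)
  m
}

# Pair-index matrix for one gap: n x n_subsites, entries in 1..441.
pair_index_matrix <- function(windows, gap, config = window_config()) {
  m <- window_matrix(windows, config)
  ns <- n_subsites(config, gap)
  (m[, seq_len(ns), drop = FALSE] - 1L) * ALPHABET_SIZE +
    m[, seq_len(ns) + gap + 1L, drop = FALSE]
}
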