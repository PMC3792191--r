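#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (possibly line-wrapped) multi-record FASTA file.
#' @param map_nonstandard Map B/J/O/U/X to the padding symbol instead of
#'   erroring; see [protein_record()].
#' @return List of [protein_record()] objects; IDs are the first
#'   whitespace-delimited token of each header.
#' @export
read_protein_fasta <- function(path, map_nonstandard = FALSE) {
  if (!file.exists(path))
    sno_error("snopair_io_error", sprintf("file not found: %s", path))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L)
    sno_error("snopair_io_error", sprintf("no FASTA records in %s", path))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  mapply(function(id, s) protein_record(id, s, map_nonstandard),
         ids, as.character(seqs), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to FASTA
#'
#' @param proteins List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  lines <- unlist(lapply(proteins, function(p) c(paste0(">", p$id), p$sequence)))
  writeLines(lines, path)
  invisible(path)
}

PEPTIDE_COLUMNS <- c("protein_id", "position", "label", "window")

#' Read a labeled peptide-window table
#'
#' TSV with columns `protein_id`, `position` (1-based), `label`
#' (`SNO`/`non-SNO`), `window`. A header row is detected; without one the
#' four columns are taken positionally. Every row is validated (window
#' length, central cysteine, known label); errors name the offending line.
#'
#' @param path Path to the TSV file.
#' @param config A [window_config()] the windows must conform to.
#' @return A peptide table data frame.
#' @export
read_peptide_table <- function(path, config = window_config()) {
  if (!file.exists(path))
    sno_error("snopair_io_error", sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  has_header <- identical(strsplit(first, "\t")[[1]][1:2],
                          PEPTIDE_COLUMNS[1:2])
  tab <- utils::read.delim(path, header = has_header,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4L)
    sno_error("snopair_io_error",
              sprintf("%s: expected 4 tab-separated columns, found %d",
                      path, ncol(tab)))
  names(tab)[1:4] <- PEPTIDE_COLUMNS
  tab <- tab[, PEPTIDE_COLUMNS]
  offset <- if (has_header) 1L else 0L
  line_of <- function(i) i + offset
  pos <- suppressWarnings(as.integer(tab$position))
  for (i in seq_len(nrow(tab))) {
    where <- sprintf("%s line %d", path, line_of(i))
    if (is.na(pos[i]) || pos[i] < 1L)
      sno_error("snopair_validation_error",
                sprintf("%s: position '%s' is not a positive integer",
                        where, tab$position[i]))
    if (!tab$label[i] %in% c("SNO", "non-SNO"))
      sno_error("snopair_validation_error",
                sprintf("%s: unknown label '%s'", where, tab$label[i]))
    w <- tab$window[i]
    if (nchar(w) != config$window_length)
      sno_error("snopair_validation_error",
                sprintf("%s: window has length %d, expected %d",
                        where, nchar(w), config$window_length))
    if (substr(w, config$xi + 1L, config$xi + 1L) != "C")
      sno_error("snopair_validation_error",
                sprintf("%s: window center is '%s', expected 'C'",
                        where, substr(w, config$xi + 1L, config$xi + 1L)))
  }
  validate_windows(tab$window, config)
  tab$position <- pos
  if (anyDuplicated(tab[, c("protein_id", "position")]))
    sno_error("snopair_validation_error",
              sprintf("%s: duplicated (protein_id, position) pair", path))
  tab
}

#' Write a peptide table to TSV
#'
#' @param table Peptide table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(table, path) {
  utils::write.table(table[, PEPTIDE_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy redundancy filter over equal-length windows
#'
#' Scans windows in input order, keeping the first of any redundant group: a
#' window is removed iff its ungapped positional identity to an
#' already-kept window reaches `threshold`. Identity is the fraction of
#' positions with identical residues over the full window; windows are
#' fixed-length and center-aligned, so no alignment is involved.
#'
#' @param windows Character vector of windows (or a peptide table, filtered
#'   by its `window` column).
#' @param threshold Identity fraction at or above which a window is
#'   considered redundant (default 0.40).
#' @param count_pad If `FALSE`, positions where either window carries the
#'   padding symbol are excluded from both numerator and denominator.
#' @param config A [window_config()].
#' @return List with `kept` and `removed` (same type as the input) and the
#'   corresponding index vectors `kept_idx`, `removed_idx`.
#' @export
redundancy_filter <- function(windows, threshold = 0.40, count_pad = TRUE,
                              config = window_config()) {
  if (!(threshold > 0 && threshold <= 1))
    sno_error("snopair_config_error", "threshold must be in (0, 1]")
  tab <- if (is.data.frame(windows)) windows else NULL
  wins <- as_windows(windows)
  n <- length(wins)
  if (n == 0L)
    return(list(kept = windows, removed = windows[0],
                kept_idx = integer(), removed_idx = integer()))
  m <- matrix(unlist(strsplit(wins, "", fixed = TRUE)),
              nrow = n, byrow = TRUE)
  pad <- config$pad_symbol
  identity_to <- function(i, j) {
    same <- m[i, ] == m[j, ]
    if (count_pad) return(mean(same))
    use <- m[i, ] != pad & m[j, ] != pad
    if (!any(use)) return(0)
    mean(same[use])
  }
  kept_idx <- integer()
  for (i in seq_len(n)) {
    redundant <- any(vapply(kept_idx, function(j) identity_to(i, j) >= threshold,
                            logical(1)))
    if (!redundant) kept_idx <- c(kept_idx, i)
  }
  removed_idx <- setdiff(seq_len(n), kept_idx)
  subset_in <- function(idx) {
    if (is.null(tab)) wins[idx] else tab[idx, , drop = FALSE]
  }
  list(kept = subset_in(kept_idx), removed = subset_in(removed_idx),
       kept_idx = kept_idx, removed_idx = removed_idx)
}

MODEL_FORMAT_VERSION <- "1.0"

# Doubles <-> strings that round-trip bit-identically through JSON.
num_to_chr <- function(x) sprintf("%.17g", x)
chr_to_num <- function(x) as.numeric(x)

#' Save a trained model to a JSON file
#'
#' The file holds the window configuration, both propensity matrices at full
#' double precision (values serialized as strings so they reload
#' bit-identically), both class norms, the class counts and metadata, plus a
#' mandatory format-version field.
#'
#' @param model A fitted [sno_fit()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_sno_model <- function(model, path) {
  doc <- list(
    format = "snopair-model",
    format_version = MODEL_FORMAT_VERSION,
    config = list(xi = model$config$xi,
                  pad_symbol = model$config$pad_symbol,
                  min_protein_length_warning =
                    model$config$min_protein_length_warning),
    pair_labels = pair_labels(model$config$pad_symbol),
    z0 = num_to_chr(model$z0$values),
    z0_ncol = ncol(model$z0$values),
    z1 = num_to_chr(model$z1$values),
    z1_ncol = ncol(model$z1$values),
    norm_pos = num_to_chr(model$norm_pos),
    norm_neg = num_to_chr(model$norm_neg),
    n_pos = model$n_pos,
    n_neg = model$n_neg,
    metadata = model$metadata
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' Load a trained model saved by [save_sno_model()]
#'
#' @param path Path to the model JSON file.
#' @return An `sno_model` object reproducing the saved model's predictions
#'   bit-identically.
#' @export
load_sno_model <- function(path) {
  if (!file.exists(path))
    sno_error("snopair_io_error", sprintf("file not found: %s", path))
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    sno_error("snopair_corrupt_model",
                              sprintf("cannot parse model file %s: %s",
                                      path, conditionMessage(e))))
  if (!identical(doc$format, "snopair-model"))
    sno_error("snopair_corrupt_model",
              sprintf("%s is not a snopair model file", path))
  if (!identical(doc$format_version, MODEL_FORMAT_VERSION))
    sno_error("snopair_version_error",
              sprintf("model format version '%s' not supported (expected '%s')",
                      doc$format_version, MODEL_FORMAT_VERSION))
  required <- c("config", "z0", "z0_ncol", "z1", "z1_ncol",
                "norm_pos", "norm_neg", "n_pos", "n_neg")
  missing <- setdiff(required, names(doc))
  if (length(missing) > 0)
    sno_error("snopair_corrupt_model",
              sprintf("model file %s is missing field(s): %s",
                      path, paste(missing, collapse = ", ")))
  config <- window_config(doc$config$xi, doc$config$pad_symbol,
                          doc$config$min_protein_length_warning)
  lab <- pair_labels(config$pad_symbol)
  as_psdp <- function(values, ncols, gap) {
    v <- matrix(chr_to_num(values), ncol = ncols)
    rownames(v) <- lab
    structure(list(gap = gap, values = v), class = "psdp_matrix")
  }
  structure(list(config = config,
                 z0 = as_psdp(doc$z0, doc$z0_ncol, 0L),
                 z1 = as_psdp(doc$z1, doc$z1_ncol, 1L),
                 norm_pos = chr_to_num(doc$norm_pos),
                 norm_neg = chr_to_num(doc$norm_neg),
                 n_pos = doc$n_pos, n_neg = doc$n_neg,
                 metadata = doc$metadata),
            class = "sno_model")
}

#' Write a PSDP matrix to TSV
#'
#' Row label is the 2-letter pair; one column per subsite. Values are written
#' at full round-trip precision.
#'
#' @param psdp_matrix A [psdp()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psdp_tsv <- function(psdp_matrix, path) {
  v <- psdp_matrix$values
  df <- data.frame(pair = rownames(v),
                   matrix(num_to_chr(v), nrow = nrow(v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- paste0("subsite_", seq_len(ncol(v)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
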