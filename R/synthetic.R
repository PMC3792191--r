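#' Configuration for the synthetic benchmark generator
#'
#' Generates cysteine-centered windows whose two classes differ by a planted,
#' position-specific residue bias: negatives draw every non-center position
#' i.i.d. from the background distribution; positives do the same except at
#' the biased positions, where the planted residue is emitted with
#' probability `effect_size + (1 - effect_size) * background(residue)`. At
#' `effect_size = 0` the classes are exchangeable (a null dataset); at 1 the
#' planted residues are deterministic and the classes are fully separable.
#'
#' @param n_pos,n_neg Windows per class (default 400 each).
#' @param effect_size Probability mass shifted toward the planted residues in
#'   the positive class, in \[0, 1\]; default 1 (a clean separable benchmark).
#' @param biased_positions Window positions carrying the planted bias;
#'   default `c(8, 9, 12, 13)`, the two pairs flanking the central cysteine,
#'   so both the adjacent-pair and the next-nearest-pair encodings see
#'   signal. Must not include the center.
#' @param planted_residues Named character vector mapping each biased
#'   position to its planted residue.
#' @param background Probability vector over the 20 amino acids (default
#'   uniform); `"natural"` selects an approximate natural-abundance preset.
#' @param seed Integer seed; all generation is reproducible from it.
#' @param protein_mode If `TRUE`, [generate_proteins()] output is intended
#'   (whole sequences plus site annotations).
#' @param n_proteins,protein_length,n_cys_per_protein,n_sno_per_protein
#'   Protein-mode shape parameters (defaults 14 proteins of 150 residues
#'   with 4 designated cysteines, 1 of them an SNO site).
#' @param config A [window_config()].
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pos = 400L, n_neg = 400L, effect_size = 1,
                             biased_positions = c(8L, 9L, 12L, 13L),
                             planted_residues = NULL,
                             background = "uniform", seed = 1L,
                             protein_mode = FALSE, n_proteins = 14L,
                             protein_length = 150L,
                             n_cys_per_protein = 4L,
                             n_sno_per_protein = 1L,
                             config = window_config()) {
  if (effect_size < 0 || effect_size > 1)
    sno_error("snopair_config_error", "effect_size must be in [0, 1]")
  center <- config$xi + 1L
  biased_positions <- as.integer(biased_positions)
  if (center %in% biased_positions)
    sno_error("snopair_config_error",
              "biased positions must not include the central cysteine")
  if (any(biased_positions < 1L | biased_positions > config$window_length))
    sno_error("snopair_config_error", "biased position outside the window")
  if (is.null(planted_residues)) {
    defaults <- c("K", "L", "E", "S", "D", "G", "R", "V")
    planted_residues <- stats::setNames(
      rep_len(defaults, length(biased_positions)),
      as.character(biased_positions))
  }
  if (!all(as.character(biased_positions) %in% names(planted_residues)))
    sno_error("snopair_config_error",
              "planted_residues must name every biased position")
  if (!all(planted_residues %in% AA_ALPHABET))
    sno_error("snopair_config_error",
              "planted residues must be native amino acids")
  background <- resolve_background(background)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 effect_size = effect_size,
                 biased_positions = biased_positions,
                 planted_residues = planted_residues,
                 background = background, seed = as.integer(seed),
                 protein_mode = isTRUE(protein_mode),
                 n_proteins = as.integer(n_proteins),
                 protein_length = as.integer(protein_length),
                 n_cys_per_protein = as.integer(n_cys_per_protein),
                 n_sno_per_protein = as.integer(n_sno_per_protein),
                 config = config),
            class = "synthetic_config")
}

# Approximate vertebrate proteome residue abundances (fractions).
NATURAL_ABUNDANCE <- c(A = 0.074, C = 0.025, D = 0.054, E = 0.068, F = 0.047,
                       G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
                       M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
                       S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)

resolve_background <- function(background) {
  if (is.character(background) && length(background) == 1L) {
    background <- switch(background,
      uniform = stats::setNames(rep(1 / 20, 20), AA_ALPHABET),
      natural = NATURAL_ABUNDANCE / sum(NATURAL_ABUNDANCE),
      sno_error("snopair_config_error",
                sprintf("unknown background preset '%s'", background)))
  }
  if (length(background) != 20L || is.null(names(background)) ||
      !setequal(names(background), AA_ALPHABET))
    sno_error("snopair_config_error",
              "background must name all 20 amino acids")
  background <- background[AA_ALPHABET]
  if (any(background < 0) || abs(sum(background) - 1) > 1e-8)
    sno_error("snopair_config_error",
              "background must be a probability distribution")
  background
}

# One position's residues for n windows under the positive-class rule.
draw_position <- function(n, cfg, biased, planted) {
  res <- sample(AA_ALPHABET, n, replace = TRUE, prob = cfg$background)
  if (biased && cfg$effect_size > 0) {
    plant <- stats::runif(n) < cfg$effect_size
    res[plant] <- planted
  }
  res
}

#' Generate labeled synthetic peptide windows
#'
#' @param cfg A [synthetic_config()].
#' @return List with `positives` and `negatives`, character vectors of
#'   windows (possibly empty when the requested counts are 0).
#' @export
generate_windows <- function(cfg) {
  wc <- cfg$config
  center <- wc$xi + 1L
  with_local_seed(cfg$seed, {
    gen_class <- function(n, positive) {
      if (n == 0L) return(character())
      cols <- lapply(seq_len(wc$window_length), function(p) {
        if (p == center) return(rep("C", n))
        biased <- positive && p %in% cfg$biased_positions
        draw_position(n, cfg, biased,
                      if (biased) cfg$planted_residues[[as.character(p)]]
                      else NA_character_)
      })
      do.call(paste0, cols)
    }
    list(positives = gen_class(cfg$n_pos, TRUE),
         negatives = gen_class(cfg$n_neg, FALSE))
  })
}

#' Synthetic windows as a labeled peptide table
#'
#' @param cfg A [synthetic_config()].
#' @return A peptide table data frame; synthetic windows get IDs
#'   `SYNPOS_*` / `SYNNEG_*` and the nominal in-parent position equal to the
#'   window center.
#' @export
generate_peptide_table <- function(cfg) {
  w <- generate_windows(cfg)
  data.frame(
    protein_id = c(sprintf("SYNPOS_%04d", seq_along(w$positives)),
                   sprintf("SYNNEG_%04d", seq_along(w$negatives))),
    position = rep(cfg$config$xi + 1L,
                   length(w$positives) + length(w$negatives)),
    label = rep(c("SNO", "non-SNO"),
                c(length(w$positives), length(w$negatives))),
    window = c(w$positives, w$negatives),
    stringsAsFactors = FALSE)
}

#' Generate synthetic annotated proteins
#'
#' Emits whole protein sequences with designated cysteines, a subset marked
#' SNO whose flanking context follows the positive window distribution, the
#' rest the negative one; background positions may contain additional
#' incidental cysteines, which count as (unannotated) non-SNO sites, as in
#' real whole-protein evaluation.
#'
#' @param cfg A [synthetic_config()] with `protein_mode = TRUE`.
#' @return List with `proteins` (list of [protein_record()]) and
#'   `annotations` (data frame `protein_id`, `position`, `label` covering
#'   the designated sites).
#' @export
generate_proteins <- function(cfg) {
  if (!cfg$protein_mode)
    sno_error("snopair_config_error",
              "generate_proteins needs protein_mode = TRUE")
  wc <- cfg$config
  center <- wc$xi + 1L
  with_local_seed(cfg$seed, {
    proteins <- vector("list", cfg$n_proteins)
    ann <- vector("list", cfg$n_proteins)
    for (i in seq_len(cfg$n_proteins)) {
      len <- cfg$protein_length
      res <- sample(AA_ALPHABET, len, replace = TRUE, prob = cfg$background)
      # spread designated cysteines so their windows do not collide
      slots <- round(seq(wc$xi + 1, len - wc$xi,
                         length.out = cfg$n_cys_per_protein))
      res[slots] <- "C"
      sno_slots <- sample(slots, min(cfg$n_sno_per_protein, length(slots)))
      for (site in sno_slots) {
        for (p in cfg$biased_positions) {
          at <- site + (p - center)
          if (at >= 1L && at <= len && !(at %in% slots) &&
              stats::runif(1) < cfg$effect_size)
            res[at] <- cfg$planted_residues[[as.character(p)]]
        }
      }
      id <- sprintf("SYNPROT_%02d", i)
      proteins[[i]] <- protein_record(id, paste0(res, collapse = ""))
      ann[[i]] <- data.frame(protein_id = id, position = slots,
                             label = ifelse(slots %in% sno_slots,
                                            "SNO", "non-SNO"),
                             stringsAsFactors = FALSE)
    }
    list(proteins = proteins, annotations = do.call(rbind, ann))
  })
}
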