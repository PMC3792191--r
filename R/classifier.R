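# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Train the nearest-class-norm SNO predictor
#'
#' Builds the gap-0 and gap-1 propensity matrices from the two classes,
#' encodes every training window against them, and stores the per-class
#' componentwise mean feature vectors (the class norms). Prediction assigns
#' the class whose norm is nearest in Euclidean distance.
#'
#' @param positives,negatives Character vectors of labeled peptide windows
#'   (SNO and non-SNO respectively), or peptide tables with a `window` column.
#' @param config A [window_config()].
#' @param pseudocount Additive smoothing for pair frequencies (default 0).
#' @param keep_windows If `TRUE`, the training windows are retained in the
#'   model metadata, enabling automatic train/test disjointness checks.
#' @return An object of class `sno_model`: `config`, `z0`, `z1`, `norm_pos`,
#'   `norm_neg`, `n_pos`, `n_neg`, `metadata`.
#' @examples
#' pos <- "ACDEFGHIKLCMNPQRSTVWY"
#' neg <- "YWVTSRQPNMCLKIHGFEDCA"
#' m <- sno_fit(pos, neg)
#' predict(m, pos)
#' @export
sno_fit <- function(positives, negatives, config = window_config(),
                    pseudocount = 0, keep_windows = FALSE) {
  positives <- as_windows(positives)
  negatives <- as_windows(negatives)
  if (length(positives) == 0L || length(negatives) == 0L)
    sno_error("snopair_empty_dataset",
              "both classes must contain at least one window")
  z0 <- psdp(pair_frequencies(positives, 0L, config, pseudocount),
             pair_frequencies(negatives, 0L, config, pseudocount))
  z1 <- psdp(pair_frequencies(positives, 1L, config, pseudocount),
             pair_frequencies(negatives, 1L, config, pseudocount))
  norm_pos <- colMeans(encode_windows(positives, z0, z1, config))
  norm_neg <- colMeans(encode_windows(negatives, z0, z1, config))
  metadata <- list(version = "1.0",
                   package_version = as.character(utils::packageVersion("snopair")),
                   pseudocount = pseudocount)
  if (keep_windows)
    metadata$train_windows <- c(positives, negatives)
  structure(list(config = config, z0 = z0, z1 = z1,
                 norm_pos = norm_pos, norm_neg = norm_neg,
                 n_pos = length(positives), n_neg = length(negatives),
                 metadata = metadata),
            class = "sno_model")
}

# Accept either a character vector of windows or a peptide table.
as_windows <- function(x) {
  if (is.data.frame(x)) {
    if (!"window" %in% names(x))
      sno_error("snopair_validation_error",
                "peptide table must have a 'window' column")
    return(as.character(x$window))
  }
  as.character(x)
}

#' @export
print.sno_model <- function(x, ...) {
  cat(sprintf(paste0("Nearest-norm SNO predictor (xi = %d, omega = %d)\n",
                     "  trained on %d SNO / %d non-SNO windows\n"),
              x$config$xi, omega_dim(x$config), x$n_pos, x$n_neg))
  invisible(x)
}

#' Euclidean distance between a feature vector and a class norm
#'
#' @param features,norm Numeric vectors of equal length.
#' @return Nonnegative scalar `sqrt(sum((features - norm)^2))`.
#' @export
feature_distance <- function(features, norm) {
  if (length(features) != length(norm))
    sno_error("snopair_incompatible_matrices",
              sprintf("dimension mismatch: %d vs %d",
                      length(features), length(norm)))
  sqrt(sum((features - norm)^2))
}

#' Predict SNO status of peptide windows
#'
#' Each window is encoded against the model's propensity matrices and
#' assigned the class whose norm vector is nearest in Euclidean distance
#' (default rule). Exact distance ties are broken by a seeded uniform draw
#' and flagged in the output.
#'
#' @param object A fitted [sno_fit()] model.
#' @param windows Character vector of peptide windows or a peptide table.
#' @param seed Integer seed used only for tie-breaking draws.
#' @param rule `"nearest"` (default) assigns SNO when the window is closer to
#'   the SNO norm; `"literal"` applies the opposite, farther-from-norm
#'   direction, retained for auditing the decision-rule convention.
#' @param ... Unused.
#' @return Data frame with columns `window`, `d_pos`, `d_neg`, `label`, `tie`.
#' @export
predict.sno_model <- function(object, windows, seed = 1L,
                              rule = c("nearest", "literal"), ...) {
  rule <- match.arg(rule)
  windows <- as_windows(windows)
  psi <- encode_windows(windows, object$z0, object$z1, object$config)
  d_pos <- sqrt(rowSums(sweep(psi, 2, object$norm_pos)^2))
  d_neg <- sqrt(rowSums(sweep(psi, 2, object$norm_neg)^2))
  tie <- d_pos == d_neg
  sno <- if (rule == "nearest") d_pos < d_neg else d_pos > d_neg
  if (any(tie))
    sno[tie] <- with_local_seed(seed, stats::runif(sum(tie)) < 0.5)
  data.frame(window = windows, d_pos = d_pos, d_neg = d_neg,
             label = ifelse(sno, "SNO", "non-SNO"), tie = tie,
             stringsAsFactors = FALSE)
}

#' Predict SNO sites across a whole protein
#'
#' Extracts a window at every cysteine and classifies each. Proteins shorter
#' than the configured fragment threshold (default 50 residues) trigger a
#' warning, since fragment input degrades the flanking context the encoding
#' relies on.
#'
#' @param model A fitted [sno_fit()] model.
#' @param protein A [protein_record()].
#' @param seed Tie-breaking seed.
#' @param rule Decision rule, see [predict.sno_model()].
#' @return Data frame with columns `protein_id`, `position`, `window`,
#'   `d_pos`, `d_neg`, `label`, `tie`; zero rows if the protein has no
#'   cysteine.
#' @export
predict_protein <- function(model, protein, seed = 1L,
                            rule = c("nearest", "literal")) {
  if (nchar(protein$sequence) < model$config$min_protein_length_warning)
    warning(sprintf(paste0("protein '%s' has %d residues (< %d): sequences this",
                           " short are generally fragments and predictions may",
                           " be unreliable"),
                    protein$id, nchar(protein$sequence),
                    model$config$min_protein_length_warning),
            call. = FALSE)
  tab <- cysteine_windows(protein, config = model$config)
  if (nrow(tab) == 0L)
    return(data.frame(protein_id = character(), position = integer(),
                      window = character(), d_pos = numeric(),
                      d_neg = numeric(), label = character(),
                      tie = logical(), stringsAsFactors = FALSE))
  pred <- predict(model, tab$window, seed = seed, rule = rule)
  cbind(tab[, c("protein_id", "position")], pred)
}
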