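#' Repeated (stratified) k-fold cross-validation
#'
#' Per repeat: windows are shuffled with a repeat-derived seed and split into
#' `k` folds, stratified by class by default; each fold is predicted by a
#' model trained on the other `k - 1`; the k folds' predictions are pooled
#' into one confusion table and scored; metric values are then averaged over
#' repeats.
#'
#' @param positives,negatives Character vectors of windows (or peptide
#'   tables) for the two classes.
#' @param k Number of folds (default 10).
#' @param repeats Number of repeated subsampling rounds (default 50).
#' @param seed Base seed; repeat r uses `seed + r - 1` for its shuffle and
#'   tie-breaks.
#' @param stratified If `TRUE` (default), folds preserve the class ratio to
#'   within one sample; otherwise the pooled data are split irrespective of
#'   class.
#' @param config A [window_config()].
#' @param pseudocount,rule Passed to [sno_fit()] / [predict.sno_model()].
#' @return An object of class `sno_cv`: `mean` and `sd` (named vectors over
#'   sn/sp/acc/mcc), `per_repeat` (data frame, one row per repeat with metric
#'   values, counts and the repeat seed), and the settings used.
#' @export
kfold_cv <- function(positives, negatives, k = 10L, repeats = 50L, seed = 1L,
                     stratified = TRUE, config = window_config(),
                     pseudocount = 0, rule = "nearest") {
  positives <- as_windows(positives)
  negatives <- as_windows(negatives)
  k <- as.integer(k); repeats <- as.integer(repeats)
  if (k < 2L || repeats < 1L)
    sno_error("snopair_config_error", "need k >= 2 and repeats >= 1")
  if (length(positives) < k || length(negatives) < k)
    sno_error("snopair_infeasible_fold",
              sprintf("each class needs >= k = %d windows (have %d / %d)",
                      k, length(positives), length(negatives)))
  windows <- c(positives, negatives)
  truth <- rep(c("SNO", "non-SNO"), c(length(positives), length(negatives)))
  n <- length(windows)

  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    rseed <- seed + r - 1L
    folds <- with_local_seed(rseed, {
      f <- integer(n)
      if (stratified) {
        for (cls in c("SNO", "non-SNO")) {
          idx <- sample(which(truth == cls))
          f[idx] <- rep_len(seq_len(k), length(idx))
        }
      } else {
        f[sample(n)] <- rep_len(seq_len(k), n)
      }
      f
    })
    predicted <- character(n)
    for (fold in seq_len(k)) {
      held <- folds == fold
      model <- sno_fit(windows[!held & truth == "SNO"],
                       windows[!held & truth == "non-SNO"],
                       config = config, pseudocount = pseudocount)
      predicted[held] <- predict(model, windows[held], seed = rseed,
                                 rule = rule)$label
    }
    rep_metrics <- classification_metrics(confusion_counts(truth, predicted))
    per_repeat[[r]] <- cbind(repeat_seed = rseed,
                             as.data.frame(rep_metrics))
  }
  per_repeat <- do.call(rbind, per_repeat)
  cols <- c("sn", "sp", "acc", "mcc")
  structure(list(mean = colMeans(per_repeat[cols]),
                 sd = vapply(per_repeat[cols], stats::sd, numeric(1)),
                 per_repeat = per_repeat,
                 k = k, repeats = repeats, seed = seed,
                 stratified = stratified, rule = rule),
            class = "sno_cv")
}

#' @export
print.sno_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repeats (stratified: %s)\n",
              x$k, x$repeats, x$stratified))
  cat(sprintf("  mean Sn = %.1f%%  Sp = %.1f%%  Acc = %.1f%%  MCC = %.2f\n",
              100 * x$mean[["sn"]], 100 * x$mean[["sp"]],
              100 * x$mean[["acc"]], x$mean[["mcc"]]))
  invisible(x)
}

#' Check that two window sets share no exact 21-mer
#'
#' @param train,test Character vectors of windows or peptide tables.
#' @return Invisibly, the character vector of overlapping windows (empty when
#'   disjoint).
#' @export
window_overlap <- function(train, test) {
  invisible(intersect(as_windows(train), as_windows(test)))
}

#' Independent-set test of a trained model
#'
#' Scores a model on labeled test windows that must be disjoint (by exact
#' window identity) from the training set. The check runs against
#' `train_windows`, or against windows retained in the model when it was
#' fitted with `keep_windows = TRUE`; with neither available it is skipped
#' (the caller asserts disjointness).
#'
#' @param model A fitted [sno_fit()] model.
#' @param positives,negatives Test windows for the two classes; either may be
#'   empty (the corresponding rate is then reported missing).
#' @param seed Tie-breaking seed.
#' @param train_windows Optional training windows for the leakage check.
#' @param rule Decision rule.
#' @return An `sno_metrics` report over all test windows.
#' @export
independent_test <- function(model, positives, negatives, seed = 1L,
                             train_windows = model$metadata$train_windows,
                             rule = "nearest") {
  positives <- as_windows(positives)
  negatives <- as_windows(negatives)
  if (length(positives) + length(negatives) == 0L)
    sno_error("snopair_empty_dataset", "no test windows supplied")
  if (!is.null(train_windows)) {
    leak <- window_overlap(train_windows, c(positives, negatives))
    if (length(leak) > 0)
      sno_error("snopair_leakage_error",
                sprintf("%d test window(s) occur in the training set (e.g. %s)",
                        length(leak), leak[1]))
  }
  truth <- rep(c("SNO", "non-SNO"),
               c(length(positives), length(negatives)))
  pred <- predict(model, c(positives, negatives), seed = seed, rule = rule)
  classification_metrics(confusion_counts(truth, pred$label))
}

#' Whole-protein evaluation against site annotations
#'
#' Predicts every cysteine of every protein and scores the pooled predictions
#' against the annotations; any cysteine without an SNO annotation counts as
#' a true non-SNO site.
#'
#' @param model A fitted [sno_fit()] model.
#' @param proteins List of [protein_record()] objects.
#' @param annotations Data frame with columns `protein_id`, `position`,
#'   `label`.
#' @param seed Tie-breaking seed.
#' @param rule Decision rule.
#' @return An `sno_metrics` report; the per-site table is attached as
#'   attribute `"sites"`.
#' @export
evaluate_proteins <- function(model, proteins, annotations, seed = 1L,
                              rule = "nearest") {
  per_protein <- lapply(proteins, function(p) {
    truth <- cysteine_windows(p, annotations, model$config)
    if (nrow(truth) == 0L) return(NULL)
    pred <- predict(model, truth$window, seed = seed, rule = rule)
    cbind(truth[, c("protein_id", "position", "window")],
          truth_label = truth$label,
          pred[, c("d_pos", "d_neg", "label", "tie")])
  })
  sites <- do.call(rbind, per_protein)
  if (is.null(sites) || nrow(sites) == 0L)
    sno_error("snopair_empty_dataset", "no cysteine sites to evaluate")
  out <- classification_metrics(confusion_counts(sites$truth_label,
                                                 sites$label))
  attr(out, "sites") <- sites
  out
}
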