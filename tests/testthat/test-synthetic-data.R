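test_that("generation is reproducible and respects requested sizes", {
  cfg <- synthetic_config(n_pos = 30, n_neg = 20, effect_size = 0.5,
                          seed = 1)
  a <- generate_windows(cfg)
  b <- generate_windows(cfg)
  expect_identical(a, b)
  expect_length(a$positives, 30L)
  expect_length(a$negatives, 20L)
  expect_no_error(sno_fit(a$positives, a$negatives))
  empty <- generate_windows(synthetic_config(n_pos = 0, n_neg = 0, seed = 1))
  expect_length(empty$positives, 0L)
  expect_length(empty$negatives, 0L)
  # different seeds give different data
  expect_false(identical(
    a, generate_windows(synthetic_config(n_pos = 30, n_neg = 20,
                                         effect_size = 0.5, seed = 2))))
})

test_that("a full-strength effect plants its residues deterministically", {
  cfg <- synthetic_config(n_pos = 25, n_neg = 25, effect_size = 1, seed = 3)
  w <- generate_windows(cfg)
  for (p in cfg$biased_positions) {
    planted <- cfg$planted_residues[[as.character(p)]]
    expect_true(all(substr(w$positives, p, p) == planted))
  }
  # and the trained propensities at the planted pairs are positive
  m <- sno_fit(w$positives, w$negatives)
  # positions 8 and 9 are adjacent: their planted pair feeds the gap-0 matrix
  pr <- paste0(cfg$planted_residues[["8"]], cfg$planted_residues[["9"]])
  expect_gt(m$z0$values[pr, 8], 0)
  # positions 9 and 11 (the center) feed the gap-1 matrix
  expect_gt(m$z1$values[paste0(cfg$planted_residues[["9"]], "C"), 9], 0)
})

test_that("all windows are centered cysteines with valid residues", {
  w <- generate_windows(synthetic_config(n_pos = 15, n_neg = 15,
                                         effect_size = 0.3, seed = 6))
  all_w <- c(w$positives, w$negatives)
  expect_true(all(nchar(all_w) == 21L))
  expect_true(all(substr(all_w, 11, 11) == "C"))
  expect_false(any(grepl("[^A-Y]", all_w)))
})

test_that("a null effect leaves the two classes exchangeable under CV", {
  w <- generate_windows(synthetic_config(n_pos = 100, n_neg = 100,
                                         effect_size = 0, seed = 9))
  res <- kfold_cv(w$positives, w$negatives, k = 5, repeats = 2, seed = 10)
  se <- sqrt(0.25 / 200)
  expect_lt(abs(res$mean[["acc"]] - 0.5), 3 * se)
})

test_that("negative-class residue frequencies fit the background", {
  w <- generate_windows(synthetic_config(n_pos = 0, n_neg = 250,
                                         effect_size = 1, seed = 12))
  # pool all non-center positions; expected uniform over the 20 residues
  res <- unlist(strsplit(paste0(substr(w$negatives, 1, 10),
                                substr(w$negatives, 12, 21)), ""))
  counts <- table(factor(res, levels = AA_ALPHABET))
  gof <- stats::chisq.test(counts, p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 0.01)
})

test_that("the natural-abundance preset is a valid, non-uniform background", {
  cfg <- synthetic_config(n_pos = 5, n_neg = 5, background = "natural",
                          seed = 2)
  expect_equal(sum(cfg$background), 1)
  expect_gt(cfg$background[["L"]], cfg$background[["W"]])
  expect_error(synthetic_config(background = "martian"),
               class = "snopair_config_error")
  expect_error(synthetic_config(effect_size = 1.2),
               class = "snopair_config_error")
  expect_error(synthetic_config(biased_positions = c(10, 11)),
               class = "snopair_config_error")
})

test_that("protein mode emits consistent sequences and annotations", {
  cfg <- synthetic_config(effect_size = 1, seed = 14, protein_mode = TRUE,
                          n_proteins = 4, protein_length = 120,
                          n_cys_per_protein = 3, n_sno_per_protein = 1)
  gen <- generate_proteins(cfg)
  expect_length(gen$proteins, 4L)
  expect_identical(nrow(gen$annotations), 12L)
  # every annotated position is a cysteine in its protein
  for (i in seq_len(nrow(gen$annotations))) {
    ann <- gen$annotations[i, ]
    p <- Filter(function(x) x$id == ann$protein_id, gen$proteins)[[1]]
    expect_identical(substr(p$sequence, ann$position, ann$position), "C")
  }
  # extract-then-label recovers the planted SNO context at full effect
  sno <- gen$annotations[gen$annotations$label == "SNO", ]
  for (i in seq_len(nrow(sno))) {
    p <- Filter(function(x) x$id == sno$protein_id[i], gen$proteins)[[1]]
    w <- extract_window(p, sno$position[i])
    hits <- vapply(cfg$biased_positions, function(bp)
      substr(w, bp, bp) == cfg$planted_residues[[as.character(bp)]],
      logical(1))
    expect_true(all(hits))
  }
  # reproducible bytes
  gen2 <- generate_proteins(cfg)
  expect_identical(gen, gen2)
  expect_error(generate_proteins(synthetic_config(seed = 1)),
               class = "snopair_config_error")
})
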