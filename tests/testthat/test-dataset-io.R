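make_table <- function(windows, labels) {
  data.frame(protein_id = sprintf("P%02d", seq_along(windows)),
             position = rep(11L, length(windows)),
             label = labels, window = windows, stringsAsFactors = FALSE)
}

test_that("peptide tables round-trip through TSV and are validated on read", {
  set.seed(61)
  tab <- make_table(random_windows(4), c("SNO", "SNO", "non-SNO", "non-SNO"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(tab, path)
  back <- read_peptide_table(path)
  expect_identical(back, tab)
  # headerless four-column files are accepted positionally
  writeLines(apply(tab, 1, paste, collapse = "\t"), path)
  expect_identical(read_peptide_table(path)$window, tab$window)
})

test_that("malformed peptide rows are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  good <- "ZZZZZZZZZZCZZZZZZZZZZ"
  writeLines(c("protein_id\tposition\tlabel\twindow",
               paste("P1", 11, "SNO", good, sep = "\t"),
               paste("P2", 11, "SNO", substr(good, 1, 20), sep = "\t")),
             path)
  expect_error(read_peptide_table(path), "line 3",
               class = "snopair_validation_error")
  writeLines(c("protein_id\tposition\tlabel\twindow",
               paste("P1", 11, "maybe", good, sep = "\t")), path)
  expect_error(read_peptide_table(path), "label",
               class = "snopair_validation_error")
  writeLines(c("protein_id\tposition\tlabel\twindow",
               paste("P1", 11, "SNO", gsub("C", "A", good), sep = "\t")),
             path)
  expect_error(read_peptide_table(path), "center",
               class = "snopair_validation_error")
  # duplicate (protein, position) keys are rejected
  writeLines(c("protein_id\tposition\tlabel\twindow",
               paste("P1", 11, "SNO", good, sep = "\t"),
               paste("P1", 11, "non-SNO", good, sep = "\t")), path)
  expect_error(read_peptide_table(path), "duplicated",
               class = "snopair_validation_error")
})

test_that("FASTA reading handles wrapped records and maps IDs to first token", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">sp|P001|TEST some description",
               "MKV", "CDE",
               ">P002", "AAAC"), path)
  prots <- read_protein_fasta(path)
  expect_length(prots, 2L)
  expect_identical(prots[[1]]$id, "sp|P001|TEST")
  expect_identical(prots[[1]]$sequence, "MKVCDE")
  expect_identical(prots[[2]]$sequence, "AAAC")
  # write-then-read round trip
  out <- withr::local_tempfile(fileext = ".fa")
  write_protein_fasta(prots, out)
  again <- read_protein_fasta(out)
  expect_identical(lapply(again, `[[`, "sequence"),
                   lapply(prots, `[[`, "sequence"))
  # non-standard residues obey the mapping flag
  writeLines(c(">PX", "MXC"), path)
  expect_error(read_protein_fasta(path), class = "snopair_invalid_residue")
  expect_identical(read_protein_fasta(path, map_nonstandard = TRUE)[[1]]$sequence,
                   "MZC")
})

test_that("the redundancy filter applies the 40% identity rule greedily", {
  w1 <- "ACDEFGHIKLCMNPQRSTVWY"
  # identical windows: the second is removed
  res <- redundancy_filter(c(w1, w1))
  expect_identical(res$kept, w1)
  expect_identical(res$removed_idx, 2L)
  # agreement at 8/21 positions (~38.1%) keeps both at threshold 0.40
  w_8 <- paste0("ACDEFGH", "WWW", "C", strrep("A", 10))
  agree8 <- sum(strsplit(w1, "")[[1]] == strsplit(w_8, "")[[1]])
  expect_identical(agree8, 8L)
  expect_length(redundancy_filter(c(w1, w_8))$kept, 2L)
  # agreement at 9/21 positions (~42.9%) removes the second
  w_9 <- paste0("ACDEFGHI", "WW", "C", strrep("A", 10))
  agree9 <- sum(strsplit(w1, "")[[1]] == strsplit(w_9, "")[[1]])
  expect_identical(agree9, 9L)
  expect_identical(redundancy_filter(c(w1, w_9))$kept, w1)
})

test_that("kept windows are pairwise below threshold and partition the input", {
  set.seed(71)
  wins <- c(random_windows(15),
            vapply(random_windows(5), function(w)
              paste0(substr(w, 1, 10), "C", substr(w, 12, 16), "AAAAA"),
              character(1)))
  res <- redundancy_filter(wins, threshold = 0.35)
  expect_setequal(c(res$kept_idx, res$removed_idx), seq_along(wins))
  ident <- function(a, b)
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  kept <- res$kept
  if (length(kept) > 1) {
    for (i in seq_along(kept)[-1])
      for (j in seq_len(i - 1))
        expect_lt(ident(kept[i], kept[j]), 0.35)
  }
  # a peptide table input is subset as a table
  tab <- make_table(wins[1:4], rep(c("SNO", "non-SNO"), 2))
  res_tab <- redundancy_filter(tab, threshold = 0.35)
  expect_true(is.data.frame(res_tab$kept))
})

test_that("pad positions can be excluded from the identity computation", {
  a <- "ZZZZZZZZZZCZZZZZZZZZZ"
  b <- "ZZZZZZZZZMCMZZZZZZZZZ"
  # counting pads: 19/21 identity -> redundant
  expect_identical(redundancy_filter(c(a, b))$removed_idx, 2L)
  # excluding pads: only the center is comparable -> 1/1, still redundant
  expect_identical(redundancy_filter(c(a, b), count_pad = FALSE)$removed_idx,
                   2L)
  c_ <- paste0(substr(a, 1, 10), "C", "MAAAAAAAAA")
  d_ <- paste0("MYYYYYYYYY", "C", substr(a, 12, 21))
  # overlap only at the center when pads are excluded
  expect_length(redundancy_filter(c(c_, d_), count_pad = FALSE)$removed,
                1L)
  expect_length(redundancy_filter(c(c_, d_), threshold = 0.9)$kept, 2L)
})

test_that("model files round-trip bit-identically and reject corruption", {
  set.seed(81)
  m <- sno_fit(random_windows(7), random_windows(6), keep_windows = TRUE)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_sno_model(m, f1)
  m2 <- load_sno_model(f1)
  expect_equal(m2$z0$values, m$z0$values, tolerance = 0)
  expect_identical(m2$norm_pos, unname(m$norm_pos))
  # save -> load -> save is byte-identical
  save_sno_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # loaded model reproduces predictions bit-identically
  q <- random_windows(5)
  expect_identical(predict(m, q), predict(m2, q))
  # corruption and version handling
  truncated <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(f1), collapse = ""), 1, 50), truncated)
  expect_error(load_sno_model(truncated), class = "snopair_corrupt_model")
  doc <- jsonlite::read_json(f1)
  doc$format_version <- "99.0"
  future <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, future, auto_unbox = TRUE)
  expect_error(load_sno_model(future), class = "snopair_version_error")
  expect_error(load_sno_model("/nonexistent/model.json"),
               class = "snopair_io_error")
})
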