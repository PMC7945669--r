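test_that("short sequences drop below the minbp threshold only", {
  rs <- make_record_set(c("AA000001.1", "AA000002.1"),
                        c(random_seq(150), random_seq(250)))
  expect_equal(nrow(drop_short_sequences(rs, 0)$records), 2L)
  out <- suppressMessages(drop_short_sequences(rs, 200))
  expect_equal(out$records$accession_id, "AA000002.1")
  all_long <- make_record_set(sprintf("AB%06d.1", 1:3),
                              vapply(1:3, function(i) random_seq(300 + i), ""))
  expect_equal(nrow(drop_short_sequences(all_long, 200)$records), 3L)
})

test_that("identical sequences align gap-free and unchanged", {
  s <- random_seq(40)
  aln <- align_sequences(setNames(rep(s, 3), c("a1", "a2", "a3")))
  expect_equal(unname(aln$matrix), rep(s, 3))
  expect_equal(aln$ncol, 40L)
})

test_that("a single-base deletion produces one gap column at the right score", {
  aln <- align_sequences(c(x = "ACGTACGT", y = "ACGACGT"))
  expect_equal(unname(aln$matrix[["x"]]), "ACGTACGT")
  expect_equal(unname(aln$matrix[["y"]]), "ACG-ACGT")
  pw <- pairwise_align("ACGTACGT", "ACGACGT")
  expect_equal(pw$score, enum_overlap_score("ACGTACGT", "ACGACGT"))
})

test_that("pairwise DP scores equal exhaustive enumeration on short pairs", {
  set.seed(61)
  for (i in 1:80) {
    a <- random_seq(sample(1:8, 1))
    b <- random_seq(sample(1:8, 1))
    expect_equal(pairwise_align(a, b)$score, enum_overlap_score(a, b),
                 info = paste(a, b))
  }
})

test_that("pairwise scores agree with an independent aligner on longer pairs", {
  skip_if_not_installed("Biostrings")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(62)
  for (i in 1:15) {
    a <- random_seq(sample(30:80, 1))
    b <- random_seq(sample(30:80, 1))
    bs <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "overlap", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2))
    expect_equal(pairwise_align(a, b)$score, bs)
  }
})

test_that("every alignment row degaps back to its input sequence", {
  set.seed(63)
  anc <- random_seq(30)
  seqs <- setNames(c(anc, vapply(1:4, function(i) mutate_seq(anc, sample(1:4, 1)), "")),
                   sprintf("s%d", 1:5))
  # vary lengths too
  seqs[[3]] <- substr(seqs[[3]], 1, 22)
  seqs[[5]] <- substr(seqs[[5]], 5, 30)
  aln <- align_sequences(seqs)
  for (id in names(seqs))
    expect_equal(gsub("-", "", aln$matrix[[id]]), unname(seqs[[id]]))
})

test_that("alignment input validation names the offending accession", {
  expect_error(align_sequences(c(a = "ACGT")), "at least 2")
  expect_error(align_sequences(c(a = "ACGT", b = "AXZT")), "b")
})

test_that("cropping keeps exactly the window covered by every row", {
  rows <- c(r1 = "ACGTACGTAC", r2 = "--GTACGTAC", r3 = "ACGTACGT--")
  aln <- mtcurate:::new_alignment(rows)
  out <- crop_to_overlap(aln)
  expect_equal(out$alignment$ncol, 6L)  # columns 3..8
  expect_equal(unname(out$alignment$matrix[["r1"]]), "GTACGT")
  expect_equal(out$summary$overlap_length, 6L)
  # idempotent
  again <- crop_to_overlap(out$alignment)
  expect_equal(again$alignment$matrix, out$alignment$matrix)
  # full-length rows: nothing removed
  full <- mtcurate:::new_alignment(c(a = "ACGT", b = "ACGT"))
  expect_equal(crop_to_overlap(full)$alignment$ncol, 4L)
})

test_that("heavy cropping from one short sequence is flagged", {
  set.seed(64)
  anc <- random_seq(1000)
  seqs <- setNames(c(replicate(5, anc), substr(anc, 1, 450)),
                   sprintf("s%d", 1:6))
  aln <- align_sequences(seqs)
  out <- suppressMessages(crop_to_overlap(aln, heavy_loss_bp = 500))
  expect_equal(out$alignment$ncol, 450L)
  expect_setequal(out$summary$flagged, sprintf("s%d", 1:5))
  expect_true(all(out$summary$trim_log[sprintf("s%d", 1:5)] >= 550))
})

test_that("an empty overlap window is an error advising removal", {
  rows <- c(a = "ACGT----", b = "----ACGT")
  expect_error(crop_to_overlap(mtcurate:::new_alignment(rows)),
               "empty overlap")
})

test_that("ambiguous and gapped columns are removed exactly", {
  set.seed(65)
  for (rep in 1:10) {
    n <- sample(3:6, 1); L <- sample(20:40, 1)
    mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
    k <- sample(0:5, 1)
    cols <- if (k > 0) sample(L, k) else integer(0)
    for (cc in cols)
      mat[sample(n, 1), cc] <- sample(c("N", "?", "-", "R", "Y"), 1)
    rows <- setNames(apply(mat, 1, paste, collapse = ""), sprintf("s%d", 1:n))
    out <- suppressMessages(remove_ambiguous_columns(mtcurate:::new_alignment(rows)))
    expect_equal(attr(out, "removed_columns"), k)
    expect_equal(out$ncol, L - k)
  }
  clean <- mtcurate:::new_alignment(c(a = "ACGT", b = "ACGT"))
  expect_equal(remove_ambiguous_columns(clean)$matrix, clean$matrix)
  all_bad <- mtcurate:::new_alignment(c(a = "NN", b = "AC"))
  expect_error(remove_ambiguous_columns(all_bad), "no unambiguous")
})

test_that("length summaries report the overlap consistent with cleaning", {
  single <- mtcurate:::new_alignment(c(only = random_seq(700)))
  ls1 <- summarise_lengths(NULL, single)
  expect_equal(ls1$overlap_length, 700L)

  set.seed(66)
  anc <- random_seq(1000)
  seqs <- setNames(c(replicate(5, anc), substr(anc, 1, 450)), sprintf("s%d", 1:6))
  aln <- align_sequences(seqs)
  ls2 <- summarise_lengths(NULL, aln)
  expect_lte(ls2$overlap_length, 450L)

  # overlap_length = cleaned ncol + ambiguity columns removed
  seqs[["s2"]] <- mutate_seq(seqs[["s2"]], 0, positions = integer(0))
  ch <- strsplit(seqs[["s2"]], "")[[1]]; ch[100:102] <- "N"
  seqs[["s2"]] <- paste(ch, collapse = "")
  aln <- align_sequences(seqs)
  cropped <- crop_to_overlap(aln)$alignment
  cleaned <- suppressMessages(remove_ambiguous_columns(cropped))
  expect_equal(summarise_lengths(NULL, aln)$overlap_length,
               cleaned$ncol + attr(cleaned, "removed_columns"))
})

test_that("final alignment width never exceeds any input length", {
  set.seed(67)
  anc <- random_seq(120)
  seqs <- setNames(lapply(1:6, function(i) {
    s <- mutate_seq(anc, sample(0:3, 1), positions = sample(1:80, sample(1:3, 1)))
    substr(s, 1, sample(90:120, 1))
  }), sprintf("s%d", 1:6))
  seqs <- unlist(seqs)
  aln <- align_sequences(seqs)
  cropped <- crop_to_overlap(aln)$alignment
  cleaned <- remove_ambiguous_columns(cropped)
  expect_lte(cleaned$ncol, min(nchar(seqs)))
})

test_that("external alignments can be imported from FASTA", {
  rows <- c(a = "AC-GT", b = "ACTGT")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rows, f)
  aln <- import_alignment(f)
  expect_equal(aln$ncol, 5L)
  expect_equal(unname(aln$matrix), unname(rows))
})
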