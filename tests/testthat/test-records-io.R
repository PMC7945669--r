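test_that("accession lists are read, trimmed and deduplicated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession", "AY703261.1", " AY703261.1", "NC_025609.1"), f)
  acc <- load_accession_list(f)
  expect_equal(as.character(acc), c("AY703261.1", "NC_025609.1"))
  expect_equal(attr(acc, "n_duplicates"), 1L)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_warning(out <- load_accession_list(empty), "empty")
  expect_length(out, 0)

  many <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession", sprintf("SX%06d.1", 1:525)), many)
  expect_length(load_accession_list(many), 525)
})

test_that("GenBank entries parse with computed lengths and study hashes", {
  seq <- paste(rep("ACGT", 30), collapse = "")
  entry <- mtcurate:::format_gb_entry("TT000001.1", "Motacilla alba", seq,
                                      "A study title", "Someone,A.",
                                      c("ND2", "nd2"))
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(entry, f)
  rs <- parse_genbank_records(f)
  expect_s3_class(rs, "record_set")
  expect_equal(nrow(rs$records), 1L)
  expect_equal(rs$records$accession_id, "TT000001.1")
  expect_equal(rs$records$organism_raw, "Motacilla alba")
  expect_equal(rs$records$seq_length, nchar(seq))
  expect_equal(rs$records$sequence, seq)  # upper-cased from lower-case ORIGIN
  expect_match(rs$records$study_id, "^study:")
  expect_false(rs$records$is_refseq)
})

test_that("records without an ORIGIN sequence are skipped with a warning", {
  seq <- paste(rep("ACGT", 30), collapse = "")
  good <- mtcurate:::format_gb_entry("TT000001.1", "Motacilla alba", seq,
                                     "T", "A,A.", "ND2")
  broken <- good[!grepl("^(ORIGIN|\\s{8,9}\\d)", good)]
  broken[broken == "//"] <- "//"
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(broken, good), f)
  expect_warning(rs <- parse_genbank_records(f), "no ORIGIN")
  expect_equal(nrow(rs$records), 1L)
})

test_that("generated record files reproduce the generator's composition", {
  spec <- fixture_spec(seed = 11, species = list(
    fixture_species_spec(n_samples = 17, n_haplotypes = 5,
                         n_refseq_duplicates = 3)))
  g <- generate_records(spec, withr::local_tempdir())
  rs <- parse_genbank_records(g$paths[["gb"]])
  expect_equal(nrow(rs$records), 20L)  # 17 samples + 3 RefSeq re-publications
  expect_equal(sum(rs$records$is_refseq), 3L)
  items <- scrape_feature_items(rs)
  tags <- g$ledger[[1]]$per_record_gene_tags
  expect_equal(nrow(items), sum(tags))
  # per-record tag counts match the ledger exactly
  per_rec <- table(items$accession_id)
  expect_equal(as.integer(per_rec[names(tags)]), unname(tags))
})

test_that("feature scraping yields one item per gene-bearing tag", {
  seq <- paste(rep("ACGT", 30), collapse = "")
  two_tags <- mtcurate:::format_gb_entry("TT000001.1", "Testus avis", seq,
                                         "T", "A,A.", c("ND2", "ND2"))
  source_only <- mtcurate:::format_gb_entry("TT000002.1", "Testus avis", seq,
                                            "T", "A,A.", character(0))
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(two_tags, source_only), f)
  rs <- parse_genbank_records(f)
  items <- scrape_feature_items(rs)
  expect_equal(sum(items$accession_id == "TT000001.1"), 2L)  # gene + CDS
  expect_equal(sum(items$accession_id == "TT000002.1"), 0L)
})

test_that("RefSeq duplicates of present originals are removed, orphans kept", {
  spec <- fixture_spec(seed = 3, species = list(
    fixture_species_spec(n_samples = 20, n_haplotypes = 4,
                         n_refseq_duplicates = 2)))
  g <- generate_records(spec, withr::local_tempdir())
  rs <- parse_genbank_records(g$paths[["gb"]])
  rs2 <- suppressMessages(remove_refseq_duplicates(rs))
  expect_equal(nrow(rs2$records), 20L)
  expect_setequal(attr(rs2, "removed_accessions"),
                  g$ledger[[1]]$refseq_accessions)
  # idempotent
  rs3 <- remove_refseq_duplicates(rs2)
  expect_equal(rs3$records$accession_id, rs2$records$accession_id)
  # invariant: no identical (sequence, organism) pair with exactly one RefSeq
  rec <- rs2$records
  for (i in which(rec$is_refseq)) {
    twin <- !rec$is_refseq & rec$sequence == rec$sequence[[i]] &
      rec$organism_raw == rec$organism_raw[[i]]
    expect_false(any(twin))
  }

  # no underscores: untouched
  seqs <- vapply(1:3, function(i) random_seq(100), "")
  plain <- make_record_set(sprintf("AA%06d.1", 1:3), seqs)
  expect_equal(nrow(remove_refseq_duplicates(plain)$records), 3L)

  # a lone RefSeq record with no original present is retained
  lone <- make_record_set("NC_000001.1", random_seq(100))
  lone$records$dbsource <- "ZZ999999.1"
  expect_equal(remove_refseq_duplicates(lone)$records$accession_id,
               "NC_000001.1")
})

test_that("record sets round-trip to metadata + FASTA files", {
  seqs <- vapply(1:4, function(i) random_seq(60), "")
  rs <- make_record_set(sprintf("AB%06d.1", 1:4), seqs)
  prefix <- file.path(withr::local_tempdir(), "out")
  write_records(rs, prefix)
  meta <- read.delim(paste0(prefix, "_metadata.tsv"))
  expect_equal(meta$accession_id, rs$records$accession_id)
  back <- read_fasta(paste0(prefix, ".fasta"))
  expect_equal(unname(back), seqs)
})
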