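test_that("identical rows collapse into haplotypes with summed frequencies", {
  ht <- make_haplotype_table(c("A1", "A2", "A3"), c("AAA", "AAA", "AAT"), "s1")
  expect_equal(nrow(ht$table), 2L)
  expect_setequal(ht$table$frequency, c(2L, 1L))
  expect_equal(sample_count(ht), 3L)

  distinct <- make_haplotype_table(sprintf("B%d", 1:4),
                                   c("AAAA", "AAAT", "AATT", "ATTT"), "s1")
  expect_equal(nrow(distinct$table), 4L)
  expect_true(all(distinct$table$frequency == 1L))
})

test_that("collapse recovers the generator's haplotype structure", {
  spec <- fixture_spec(seed = 21, species = list(
    fixture_species_spec(n_samples = 30, n_haplotypes = 6)))
  g <- generate_records(spec, withr::local_tempdir())
  rs <- parse_genbank_records(g$paths[["gb"]])
  aln <- align_sequences(setNames(rs$records$sequence, rs$records$accession_id))
  clean <- remove_ambiguous_columns(crop_to_overlap(aln)$alignment)
  ht <- collapse_haplotypes(clean, rs)
  expect_equal(sort(ht$table$frequency),
               sort(unname(g$ledger[[1]]$true_hap_freqs)))
  expect_equal(sample_count(ht), g$ledger[[1]]$n_samples_total)
})

test_that("studies whose every contribution is unique are flagged", {
  ht <- make_haplotype_table(c("A1", "A2", "A3", "B1", "B2"),
                             c("AAA", "AAA", "AAT", "ACT", "AGT"),
                             c("A", "A", "A", "B", "B"))
  expect_equal(flag_unique_only_studies(ht), "B")

  all_dup <- make_haplotype_table(c("A1", "A2", "B1", "B2"),
                                  c("AAA", "AAA", "AAT", "AAT"),
                                  c("A", "A", "B", "B"))
  expect_length(flag_unique_only_studies(all_dup), 0L)
})

test_that("flagging matches a brute-force per-study uniqueness check", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:14, 1)
    hap_pool <- c("AAAA", "AAAT", "AATT", "ATTT", "TTTT")
    seqs <- sample(hap_pool, n, replace = TRUE)
    studies <- sample(c("s1", "s2", "s3"), n, replace = TRUE)
    ht <- make_haplotype_table(sprintf("X%03d", seq_len(n)), seqs, studies)
    brute <- sort(Filter(function(st) {
      tab <- table(seqs[studies == st])
      length(tab) > 0 && all(tab == 1)
    }, unique(studies)))
    expect_equal(flag_unique_only_studies(ht), as.character(brute))
  }
})

test_that("magnification restores sampled frequencies and totals", {
  ht <- make_haplotype_table(c("A1", "A2"), c("AAA", "AAT"), "s1")
  mt <- load_magnify_table(data.frame(accession_id = "A1",
                                      sampled_frequency = 50))
  out <- magnify_to_sampled_freq(ht, mt)
  expect_equal(out$table$frequency[out$table$haplotype_id ==
                 out$members$haplotype_id[out$members$accession_id == "A1"]], 50L)
  expect_equal(sample_count(out), sample_count(ht) + 49L)

  # identity when the table value equals the current contribution
  same <- magnify_to_sampled_freq(ht, data.frame(accession_id = "A2",
                                                 sampled_frequency = 1))
  expect_equal(same$table$frequency, ht$table$frequency)

  expect_error(magnify_to_sampled_freq(ht, data.frame(accession_id = "ZZ",
                                                      sampled_frequency = 5)),
               "ZZ")
  big <- magnify_to_sampled_freq(ht, data.frame(accession_id = "A1",
                                                sampled_frequency = 10))
  expect_error(magnify_to_sampled_freq(big, data.frame(accession_id = "A1",
                                                       sampled_frequency = 3)),
               "below its current contribution")
})

test_that("magnification increases the total by the sum of differences", {
  set.seed(32)
  ht <- make_haplotype_table(sprintf("M%d", 1:5),
                             c("AAAA", "AAAT", "AATT", "ATTT", "TTTT"), "s1")
  targets <- sample(2:20, 3)
  mt <- data.frame(accession_id = c("M1", "M3", "M5"),
                   sampled_frequency = targets)
  out <- magnify_to_sampled_freq(ht, mt)
  expect_equal(sample_count(out), sample_count(ht) + sum(targets - 1L))
})

test_that("two haplotypes a base apart give a single unit edge", {
  ht <- make_haplotype_table(c("A1", "A2"), c("AAAA", "AAAT"), "s1")
  net <- build_haplotype_network(ht)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 1L)
  expect_equal(unname(net$min_dist), c(1L, 1L))
})

test_that("a star of singletons wires every edge to the center", {
  set.seed(33)
  anc <- random_seq(40)
  k <- 5
  seqs <- c(anc, vapply(1:k, function(i) mutate_seq(anc, 1,
                                                    positions = i), ""))
  ht <- make_haplotype_table(sprintf("S%d", 0:k), seqs, "s1",
                             n_samples = c(5L, rep(1L, k)))
  net <- build_haplotype_network(ht)
  center <- ht$members$haplotype_id[[1]]
  expect_equal(nrow(net$edges), k)
  expect_true(all(net$edges$from == center | net$edges$to == center))
  expect_true(all(net$edges$weight == 1L))
})

test_that("network weight equals the brute-force spanning-tree minimum", {
  set.seed(34)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    seqs <- unique(vapply(seq_len(n), function(i) random_seq(15), ""))
    ht <- make_haplotype_table(sprintf("T%02d", seq_along(seqs)), seqs, "s1")
    net <- build_haplotype_network(ht)
    expect_equal(nrow(net$edges), length(seqs) - 1L)
    d <- mtcurate:::hamming_matrix(ht$table$sequence)
    expect_equal(sum(net$edges$weight), brute_mst_weight(d))
  }
})

test_that("a single haplotype yields a one-node, edgeless network", {
  ht <- make_haplotype_table(c("A1", "A2"), c("AAA", "AAA"), "s1")
  net <- build_haplotype_network(ht)
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(nrow(net$edges), 0L)
  expect_true(is.na(net$min_dist))
})

test_that("Hamming distance behaves as a metric", {
  set.seed(35)
  for (rep in 1:20) {
    seqs <- vapply(1:3, function(i) random_seq(25), "")
    d <- mtcurate:::hamming_matrix(seqs)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_lte(d[1, 3], d[1, 2] + d[2, 3])
  }
})

test_that("divergent singletons are dropped at a strict threshold", {
  set.seed(36)
  anc <- random_seq(80)
  near <- mutate_seq(anc, 2, positions = 1:2)
  at30 <- mutate_seq(anc, 30, positions = 11:40)
  at31 <- mutate_seq(anc, 31, positions = 41:71)
  ht <- make_haplotype_table(c("C1", "C2", "C3", "F30", "F31"),
                             c(anc, anc, near, at30, at31), "s1")
  out <- suppressMessages(drop_outliers(ht, threshold = 30))
  removed_acc <- unlist(strsplit(out$removed$accessions, ";"))
  expect_equal(removed_acc, "F31")           # 31 > 30 removed
  expect_true("F30" %in% out$table$members$accession_id)  # exactly 30 retained
  # frequency-2 haplotype at distance 31 is retained
  ht2 <- make_haplotype_table(c("C1", "C2", "D1", "D2"),
                              c(anc, anc, at31, at31), "s1")
  out2 <- drop_outliers(ht2, threshold = 30)
  expect_equal(nrow(out2$removed), 0L)
})

test_that("outlier removal recomputes distances most-divergent-first", {
  set.seed(37)
  anc <- random_seq(120)
  far40 <- mutate_seq(anc, 40, positions = 1:40)
  far32 <- mutate_seq(anc, 32, positions = 51:82)
  ht <- make_haplotype_table(c("C1", "C2", "O40", "O32"),
                             c(anc, anc, far40, far32), "s1")
  out <- suppressMessages(drop_outliers(ht, threshold = 30))
  expect_equal(out$removed$min_dist, c(40L, 32L))  # most divergent first
  expect_equal(nrow(out$table$table), 1L)
  # idempotent at a fixed threshold
  again <- drop_outliers(out$table, threshold = 30)
  expect_equal(nrow(again$removed), 0L)
})

test_that("post-outlier sequences are written as FASTA per accession", {
  anc <- paste(rep("ACGT", 10), collapse = "")
  ht <- make_haplotype_table(c("A1", "A2"), c(anc, anc), "s1")
  f <- withr::local_tempfile(fileext = ".fasta")
  out <- drop_outliers(ht, threshold = 30, fasta = f)
  back <- read_fasta(f)
  expect_setequal(names(back), c("A1", "A2"))
  expect_equal(unname(back[["A1"]]), anc)
})
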