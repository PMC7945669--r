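# Seeded synthetic-data generator. Emits GenBank-style flat files, FASTA,
# and magnification tables that exhibit, by construction, the pathologies a
# multi-study repository harvest runs into: species/subspecies name
# variants, inconsistent gene-name spellings, RefSeq duplicate accessions,
# heterogeneous sequence lengths, study-structured haplotype frequencies,
# unique-haplotypes-only deposition, and divergent singleton outliers.
# Every generated dataset comes with a ground-truth ledger so pipeline
# output can be checked exactly. Haplotype sequences are produced by
# mutating a random ancestor at recorded, pairwise-disjoint positions, so
# all Hamming distances are known by construction; haplotype frequencies
# are drawn, not evolved (no coalescent realism is attempted).

#' Specification of one synthetic species dataset
#'
#' @param name species binomial used in the organism field.
#' @param n_studies number of depositing studies (default 2).
#' @param n_samples total individuals sampled across studies (default 40).
#' @param n_haplotypes number of distinct haplotypes (default 8; must not
#'   exceed `n_samples`).
#' @param haplotype_freqs optional integer vector of length `n_haplotypes`
#'   summing to `n_samples`; drawn from a decreasing-weight spectrum when
#'   `NULL`.
#' @param min_length,max_length per-record sequence length range in bp
#'   (records are suffix-truncated copies of their haplotype; default
#'   600-700).
#' @param subspecies_rate probability a record's organism field carries a
#'   subspecies epithet (default 0.2).
#' @param gene_variants pool of gene-name spellings used in feature tags.
#' @param n_refseq_duplicates how many records are re-published under a
#'   RefSeq (underscore) accession with a DBSOURCE back-reference (default 0).
#' @param n_outliers number of injected divergent singleton samples
#'   (default 0).
#' @param outlier_divergence base differences separating each outlier from
#'   the ancestor (default 35; must be > 0).
#' @param unique_only_studies indices of studies that deposit one record per
#'   haplotype instead of one per individual (their true counts go into the
#'   magnification table).
#' @return object of class `fixture_species_spec`.
#' @export
fixture_species_spec <- function(name = "Synthetica borealis",
                                 n_studies = 2, n_samples = 40,
                                 n_haplotypes = 8, haplotype_freqs = NULL,
                                 min_length = 600, max_length = 700,
                                 subspecies_rate = 0.2,
                                 gene_variants = c("ND2", "nd2", "NADH2",
                                                   "NADH dehydrogenase subunit 2",
                                                   "ND-2"),
                                 n_refseq_duplicates = 0, n_outliers = 0,
                                 outlier_divergence = 35,
                                 unique_only_studies = integer(0)) {
  stopifnot(n_studies >= 1, n_samples >= 1, n_haplotypes >= 1,
            n_refseq_duplicates >= 0, n_outliers >= 0,
            min_length >= 50, max_length >= min_length)
  if (n_haplotypes > n_samples)
    stop("n_haplotypes cannot exceed n_samples")
  if (n_outliers > n_samples)
    stop("more outliers than samples requested")
  if (n_outliers > 0 && outlier_divergence <= 0)
    stop("outlier_divergence must be > 0")
  if (!is.null(haplotype_freqs)) {
    haplotype_freqs <- as.integer(haplotype_freqs)
    if (length(haplotype_freqs) != n_haplotypes ||
        sum(haplotype_freqs) != n_samples || any(haplotype_freqs < 1L))
      stop("haplotype_freqs must be ", n_haplotypes,
           " positive integers summing to ", n_samples)
  }
  if (any(unique_only_studies < 1 | unique_only_studies > n_studies))
    stop("unique_only_studies indices out of range")
  structure(list(name = name, n_studies = as.integer(n_studies),
                 n_samples = as.integer(n_samples),
                 n_haplotypes = as.integer(n_haplotypes),
                 haplotype_freqs = haplotype_freqs,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 subspecies_rate = subspecies_rate,
                 gene_variants = gene_variants,
                 n_refseq_duplicates = as.integer(n_refseq_duplicates),
                 n_outliers = as.integer(n_outliers),
                 outlier_divergence = as.integer(outlier_divergence),
                 unique_only_studies = as.integer(unique_only_studies)),
            class = "fixture_species_spec")
}

#' Specification of a complete synthetic dataset
#'
#' @param seed RNG seed; generation is deterministic given the seed.
#' @param species list of [fixture_species_spec()] objects.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, species = list(fixture_species_spec())) {
  if (inherits(species, "fixture_species_spec")) species <- list(species)
  stopifnot(length(species) >= 1,
            all(vapply(species, inherits, logical(1), "fixture_species_spec")))
  structure(list(seed = as.integer(seed), species = species),
            class = "fixture_spec")
}

#' Generate a synthetic GenBank dataset with a ground-truth ledger
#'
#' Writes `records.gb` (GenBank flat file), `sequences.fasta`,
#' `accessions.csv` (one accession per row) and `magnify.csv` (accession,
#' sampled_frequency; present only when some study deposits unique
#' haplotypes only or an outlier lands in such a study) under `dir`.
#' Output is byte-identical for the same spec and seed.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (named character vector) and `ledger` (ground
#'   truth per species; see Details).
#'
#' @details The ledger records, per species: true haplotype frequencies
#' (individuals per haplotype, after magnification, outliers labelled
#' `OUT*`), total sample count, injected RefSeq and outlier accessions,
#' per-record gene-bearing tag counts, the study ids (hashes matching what
#' the parser derives) of studies expected to be flagged as
#' unique-haplotypes-only, and the expected cleaned alignment length (the
#' shortest deposited record).
#' @export
generate_records <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  with_seed(spec$seed, {
    acc_counter <- 0L
    refseq_counter <- 0L
    gb_blocks <- character(0)
    fasta <- character(0)
    magnify <- data.frame(accession_id = character(0),
                          sampled_frequency = integer(0),
                          stringsAsFactors = FALSE)
    ledger <- list()
    for (sp in spec$species) {
      g <- generate_species(sp, acc_counter, refseq_counter)
      acc_counter <- g$acc_counter
      refseq_counter <- g$refseq_counter
      gb_blocks <- c(gb_blocks, g$gb_blocks)
      fasta <- c(fasta, g$fasta)
      magnify <- rbind(magnify, g$magnify)
      ledger[[sp$name]] <- g$ledger
    }
    paths <- c(gb = file.path(dir, "records.gb"),
               fasta = file.path(dir, "sequences.fasta"),
               accessions = file.path(dir, "accessions.csv"),
               magnify = file.path(dir, "magnify.csv"))
    writeLines(gb_blocks, paths[["gb"]])
    write_fasta(fasta, paths[["fasta"]])
    writeLines(c("accession", names(fasta)), paths[["accessions"]])
    utils::write.csv(magnify, paths[["magnify"]], row.names = FALSE, quote = FALSE)
    check_ledger(ledger, fasta, magnify)
    list(paths = paths, ledger = ledger)
  })
}

# One species' records; returns GenBank text blocks, sequences and ledger.
generate_species <- function(sp, acc_counter, refseq_counter) {
  H <- sp$n_haplotypes
  freqs <- sp$haplotype_freqs
  if (is.null(freqs)) {
    freqs <- rep(1L, H)
    rem <- sp$n_samples - H
    if (rem > 0) {
      extra <- sample.int(H, rem, replace = TRUE, prob = 1 / seq_len(H))
      freqs <- freqs + tabulate(extra, nbins = H)
    }
  }
  # haplotype sequences: hap 1 is the ancestor; hap i (i >= 2) mutates at
  # 1 + (i %% 3) positions of its own; outliers at outlier_divergence
  # positions of their own. All positions are disjoint and inside the
  # guaranteed overlap window, so Hamming distances and post-crop haplotype
  # identity are known by construction.
  k_mut <- if (H > 1) 1L + (2:H %% 3L) else integer(0)
  n_pos_needed <- sum(k_mut) + sp$n_outliers * sp$outlier_divergence
  safe <- sp$min_length - 10L
  if (n_pos_needed > safe)
    stop("not enough sequence for the requested divergence; increase min_length")
  ancestor <- paste(sample(c("A", "C", "G", "T"), sp$max_length, replace = TRUE),
                    collapse = "")
  pos_pool <- sample.int(safe, n_pos_needed)
  mutate_at <- function(seq, pos) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (p in pos) ch[[p]] <- setdiff(c("A", "C", "G", "T"), ch[[p]])[[1]]
    paste(ch, collapse = "")
  }
  haps <- character(H)
  haps[[1]] <- ancestor
  used <- 0L
  hap_positions <- vector("list", H)
  for (i in seq_len(H)[-1]) {
    pos <- pos_pool[(used + 1L):(used + k_mut[[i - 1L]])]
    used <- used + k_mut[[i - 1L]]
    hap_positions[[i]] <- pos
    haps[[i]] <- mutate_at(ancestor, pos)
  }
  out_haps <- character(sp$n_outliers)
  for (o in seq_len(sp$n_outliers)) {
    pos <- pos_pool[(used + 1L):(used + sp$outlier_divergence)]
    used <- used + sp$outlier_divergence
    out_haps[[o]] <- mutate_at(ancestor, pos)
  }
  # studies and their deposition style
  styles <- rep("all", sp$n_studies)
  styles[sp$unique_only_studies] <- "unique"
  study_titles <- sprintf("Population genetics of %s, study %d",
                          sp$name, seq_len(sp$n_studies))
  study_authors <- sprintf("Author%d,A.", seq_len(sp$n_studies))
  study_ids <- study_hash(paste(study_titles, study_authors, sep = "|"))
  # assign individuals (hap index repeated freq times) to studies round-robin
  individuals <- rep(seq_len(H), freqs)
  study_of <- rep(seq_len(sp$n_studies), length.out = length(individuals))
  # outliers go to the first all-style study, else study 1
  outlier_study <- if (any(styles == "all")) which(styles == "all")[[1]] else 1L
  gb_blocks <- character(0)
  fasta <- character(0)
  magnify <- data.frame(accession_id = character(0),
                        sampled_frequency = integer(0), stringsAsFactors = FALSE)
  tag_counts <- integer(0)
  refseq_acc <- character(0)
  outlier_acc <- character(0)
  record_lengths <- integer(0)
  emit <- function(seq_full, study, organism) {
    acc_counter <<- acc_counter + 1L
    acc <- sprintf("SX%06d.1", acc_counter)
    len <- if (sp$min_length == sp$max_length) sp$min_length
           else sp$min_length + sample.int(sp$max_length - sp$min_length + 1L, 1L) - 1L
    seq <- substr(seq_full, 1L, len)
    n_tags <- if (stats::runif(1) < 0.5) 2L else 1L
    variants <- sample(sp$gene_variants, n_tags, replace = TRUE)
    gb_blocks <<- c(gb_blocks,
                    format_gb_entry(acc, organism, seq, study_titles[[study]],
                                    study_authors[[study]], variants,
                                    dbsource = NULL))
    fasta[[acc]] <<- seq
    tag_counts[[acc]] <<- n_tags
    record_lengths <<- c(record_lengths, len)
    acc
  }
  first_study_first_acc <- character(0)  # candidates for RefSeq duplication
  for (s in seq_len(sp$n_studies)) {
    idx <- individuals[study_of == s]
    if (!length(idx)) next
    organism_for <- function() {
      if (stats::runif(1) < sp$subspecies_rate)
        paste(sp$name, "borealis") else sp$name
    }
    if (styles[[s]] == "all") {
      for (h in idx) {
        acc <- emit(haps[[h]], s, organism_for())
        if (s == 1L) first_study_first_acc <- c(first_study_first_acc, acc)
      }
    } else {
      per_hap <- table(idx)
      for (h in as.integer(names(per_hap))) {
        acc <- emit(haps[[h]], s, organism_for())
        magnify <- rbind(magnify, data.frame(
          accession_id = acc,
          sampled_frequency = as.integer(per_hap[[as.character(h)]]),
          stringsAsFactors = FALSE))
        if (s == 1L) first_study_first_acc <- c(first_study_first_acc, acc)
      }
    }
  }
  for (o in seq_len(sp$n_outliers)) {
    acc <- emit(out_haps[[o]], outlier_study, sp$name)
    outlier_acc <- c(outlier_acc, acc)
    if (styles[[outlier_study]] == "unique")
      magnify <- rbind(magnify, data.frame(accession_id = acc,
                                           sampled_frequency = 1L,
                                           stringsAsFactors = FALSE))
  }
  # RefSeq duplicates of already-present records
  if (sp$n_refseq_duplicates > length(first_study_first_acc))
    stop("not enough records in study 1 to duplicate as RefSeq")
  for (r in seq_len(sp$n_refseq_duplicates)) {
    orig <- first_study_first_acc[[r]]
    refseq_counter <- refseq_counter + 1L
    acc <- sprintf("NC_%06d.1", refseq_counter)
    seq <- fasta[[orig]]
    gb_blocks <- c(gb_blocks,
                   format_gb_entry(acc, sp$name, seq, study_titles[[1]],
                                   study_authors[[1]],
                                   sample(sp$gene_variants, 1L),
                                   dbsource = orig))
    fasta[[acc]] <- seq
    tag_counts[[acc]] <- 1L
    refseq_acc <- c(refseq_acc, acc)
  }
  # ground truth: per-haplotype individual counts, outliers as OUT*
  true_freqs <- setNames(as.integer(freqs), sprintf("H%d", seq_len(H)))
  if (sp$n_outliers > 0)
    true_freqs <- c(true_freqs,
                    setNames(rep(1L, sp$n_outliers),
                             sprintf("OUT%d", seq_len(sp$n_outliers))))
  # studies expected to be flagged: unique-style always (every deposited
  # record is a distinct haplotype), all-style when no haplotype repeats
  # within the study's contribution
  flagged <- character(0)
  for (s in seq_len(sp$n_studies)) {
    idx <- individuals[study_of == s]
    extra <- if (s == outlier_study) rep(-seq_len(sp$n_outliers), 1L) else integer(0)
    contrib <- c(idx, extra)
    if (!length(contrib)) next
    if (styles[[s]] == "unique" || all(table(contrib) == 1L))
      flagged <- c(flagged, study_ids[[s]])
  }
  ledger <- list(
    species = sp$name,
    true_hap_freqs = true_freqs,
    n_samples_total = sum(true_freqs),
    n_records = length(fasta),
    n_records_after_dedup = length(fasta) - length(refseq_acc),
    refseq_accessions = refseq_acc,
    outlier_accessions = outlier_acc,
    per_record_gene_tags = tag_counts,
    expected_flagged_studies = sort(unique(flagged)),
    expected_seq_length = min(record_lengths),
    study_ids = study_ids,
    study_styles = styles,
    hap_mutation_positions = hap_positions)
  list(gb_blocks = gb_blocks, fasta = fasta, magnify = magnify,
       ledger = ledger, acc_counter = acc_counter,
       refseq_counter = refseq_counter)
}

# Format one GenBank flat-file entry.
format_gb_entry <- function(accession, organism, seq, title, authors,
                            gene_variants, dbsource = NULL) {
  plain_acc <- sub("\\.[0-9]+$", "", accession)
  len <- nchar(seq)
  lines <- c(
    sprintf("LOCUS       %-12s %8d bp    DNA     linear   VRT 01-JAN-2020",
            plain_acc, len),
    sprintf("DEFINITION  %s NADH dehydrogenase subunit 2 gene, partial cds.",
            organism),
    sprintf("ACCESSION   %s", plain_acc),
    sprintf("VERSION     %s", accession))
  if (!is.null(dbsource))
    lines <- c(lines, sprintf("DBSOURCE    REFSEQ: accession %s", dbsource))
  lines <- c(lines,
    "KEYWORDS    .",
    sprintf("SOURCE      mitochondrion %s", organism),
    sprintf("  ORGANISM  %s", organism),
    "            Eukaryota; Metazoa; Chordata; Aves.",
    sprintf("REFERENCE   1  (bases 1 to %d)", len),
    sprintf("  AUTHORS   %s", authors),
    sprintf("  TITLE     %s", title),
    "  JOURNAL   Unpublished",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len),
    sprintf("                     /organism=\"%s\"", organism),
    "                     /organelle=\"mitochondrion\"")
  kinds <- c("gene", "CDS")
  for (i in seq_along(gene_variants)) {
    lines <- c(lines,
      sprintf("     %-15s 1..%d", kinds[[min(i, 2L)]], len),
      sprintf("                     /gene=\"%s\"", gene_variants[[i]]))
  }
  lines <- c(lines, "ORIGIN      ", format_gb_origin(seq), "//")
  lines
}

format_gb_origin <- function(seq) {
  seq <- tolower(seq)
  starts <- seq(1L, nchar(seq), by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, nchar(seq)))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    sprintf("%9d %s", s, paste(groups, collapse = " "))
  }, character(1))
}

# Internal consistency of the ledger against the emitted sequences.
check_ledger <- function(ledger, fasta, magnify) {
  for (lg in ledger) {
    stopifnot(lg$n_samples_total == sum(lg$true_hap_freqs),
              lg$n_records_after_dedup ==
                lg$n_records - length(lg$refseq_accessions),
              all(lg$refseq_accessions %in% names(fasta)),
              all(lg$outlier_accessions %in% names(fasta)))
  }
  if (nrow(magnify)) stopifnot(all(magnify$accession_id %in% names(fasta)))
  invisible(TRUE)
}

#' Generate an AR(1) trace series
#'
#' Exercises the ESS estimator with a series of known autocorrelation: for
#' lag-1 autocorrelation `rho`, the integrated autocorrelation time is
#' `(1 + rho) / (1 - rho)`, so ESS should approach `n (1 - rho) / (1 + rho)`.
#'
#' @param n series length (>= 10).
#' @param rho lag-1 autocorrelation, `|rho| < 1`.
#' @param seed RNG seed.
#' @return a [trace_series()] with no burn-in.
#' @export
generate_trace <- function(n, rho = 0, seed = 1) {
  if (abs(rho) >= 1) stop("rho must satisfy |rho| < 1")
  if (n < 10) stop("n must be >= 10")
  vals <- with_seed(seed, {
    if (rho == 0) rnorm(n)
    else as.numeric(arima.sim(model = list(ar = rho), n = n))
  })
  trace_series(vals, name = sprintf("ar1_rho%.2f", rho), burn_in = 0)
}
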