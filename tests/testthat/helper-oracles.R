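# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: alignment scores come from exhaustive
# enumeration over monotone matchings, spanning-tree minima from explicit
# enumeration of all labelled trees (Pruefer sequences).

# Exhaustive overlap-alignment score: maximise over every set of aligned
# column pairs (monotone matchings). Unmatched characters between the first
# and last pair cost `gap` each; leading/trailing overhangs are free on one
# sequence per end (the other end's overhang pays `gap` per character),
# matching the free-end-gap convention. Empty matching scores 0.
enum_overlap_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(A); n <- length(B)
  best <- 0
  for (k in seq_len(min(m, n))) {
    ca <- utils::combn(m, k); cb <- utils::combn(n, k)
    if (!is.matrix(ca)) ca <- matrix(ca, nrow = k)
    if (!is.matrix(cb)) cb <- matrix(cb, nrow = k)
    SA <- matrix(A[ca], nrow = k); SB <- matrix(B[cb], nrow = k)
    s <- matrix(0, ncol(ca), ncol(cb))
    for (base in unique(c(A, B)))
      s <- s + crossprod(SA == base, SB == base)
    intA <- ca[k, ] - ca[1, ] + 1 - k   # unmatched inside a's span
    intB <- cb[k, ] - cb[1, ] + 1 - k
    la <- ca[1, ] - 1; ta <- m - ca[k, ]
    lb <- cb[1, ] - 1; tb <- n - cb[k, ]
    gap_cols <- outer(intA, intB, "+") +
      outer(la, lb, pmin) + outer(ta, tb, pmin)
    sc <- match * s + mismatch * (k - s) + gap * gap_cols
    best <- max(best, max(sc))
  }
  best
}

# All labelled trees on n nodes as linear-index rows into an n x n matrix
# (decoded Pruefer sequences; n^(n-2) trees), cached per n.
.prufer_cache <- new.env(parent = emptyenv())

prufer_decode <- function(p, n) {
  deg <- tabulate(p, n) + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_along(p)) {
    leaf <- which(deg == 1L)[[1]]
    edges[k, ] <- c(leaf, p[[k]])
    deg[[leaf]] <- 0L
    deg[[p[[k]]]] <- deg[[p[[k]]]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

prufer_tree_index <- function(n) {
  key <- as.character(n)
  if (!is.null(.prufer_cache[[key]])) return(.prufer_cache[[key]])
  stopifnot(n >= 2)
  trees <- if (n == 2) list(matrix(c(1L, 2L), 1)) else {
    seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
    lapply(seq_len(nrow(seqs)), function(i) prufer_decode(seqs[i, ], n))
  }
  idx <- t(vapply(trees, function(e) (e[, 2] - 1L) * n + e[, 1],
                  integer(n - 1)))
  if (n == 2) idx <- matrix(idx, ncol = 1)
  .prufer_cache[[key]] <- idx
  idx
}

# Minimum spanning tree weight by exhaustive enumeration (n <= 7 sensible).
brute_mst_weight <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  idx <- prufer_tree_index(n)
  min(rowSums(matrix(d[as.vector(idx)], nrow(idx), n - 1L)))
}

# Random nucleotide string helper.
random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Mutate `seq` at `k` distinct positions (guaranteed base change).
mutate_seq <- function(seq, k, positions = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (is.null(positions)) positions <- sample.int(length(ch), k)
  for (p in positions) ch[[p]] <- setdiff(c("A", "C", "G", "T"), ch[[p]])[[1]]
  paste(ch, collapse = "")
}

# Build a record_set directly (bypassing GenBank text) for unit tests.
make_record_set <- function(accessions, sequences, organisms = "Testus avis",
                            studies = "study:test") {
  n <- length(accessions)
  organisms <- rep_len(organisms, n)
  studies <- rep_len(studies, n)
  records <- data.frame(accession_id = accessions, organism_raw = organisms,
                        sequence = sequences, seq_length = nchar(sequences),
                        study_id = studies,
                        is_refseq = grepl("_", accessions, fixed = TRUE),
                        dbsource = "", stringsAsFactors = FALSE)
  mtcurate:::new_record_set(records, mtcurate:::empty_features_df())
}

# Build a haplotype_table from parallel member vectors.
make_haplotype_table <- function(accessions, hap_sequences, studies,
                                 n_samples = 1L) {
  rows <- setNames(hap_sequences, accessions)
  aln <- mtcurate:::new_alignment(rows)
  rs <- make_record_set(accessions, hap_sequences, studies = studies)
  ht <- collapse_haplotypes(aln, rs)
  ht$members$n_samples <- rep_len(as.integer(n_samples), nrow(ht$members))
  mtcurate:::recompute_frequencies(ht)
}
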