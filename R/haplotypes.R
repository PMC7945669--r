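# Haplotype collapse, deposition-style audit, frequency magnification,
# minimum-spanning-tree networks, and removal of divergent singleton
# outliers. Haplotype frequency drives skyline estimates of Ne, so sampled
# frequencies must be real counts of individuals, not counts of deposited
# records.

new_haplotype_table <- function(table, members) {
  structure(list(table = table, members = members), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table> ", nrow(x$table), " haplotypes, ",
      sum(x$table$frequency), " samples, ",
      length(unique(x$members$study_id)), " study(ies)\n", sep = "")
  invisible(x)
}

#' Total sample count of a haplotype table
#' @param ht a `haplotype_table`.
#' @return integer sum of haplotype frequencies.
#' @export
sample_count <- function(ht) {
  stopifnot(inherits(ht, "haplotype_table"))
  sum(ht$table$frequency)
}

recompute_frequencies <- function(ht) {
  freq <- tapply(ht$members$n_samples, ht$members$haplotype_id, sum)
  ht$table$frequency <- as.integer(freq[ht$table$haplotype_id])
  ht
}

#' Collapse aligned sequences into unique haplotypes
#'
#' Identical rows of a cleaned, cropped alignment merge into one haplotype;
#' frequency is the member count and contributing studies are unioned.
#' Haplotype ids are assigned in order of first appearance.
#'
#' @param aln a cleaned `mt_alignment` (equal-length, gap-free rows).
#' @param rs the `record_set` supplying study ids for the aligned accessions.
#' @return a `haplotype_table` with elements `table` (haplotype_id, sequence,
#'   frequency) and `members` (accession_id, haplotype_id, study_id,
#'   n_samples).
#' @export
collapse_haplotypes <- function(aln, rs) {
  stopifnot(inherits(aln, "mt_alignment"), inherits(rs, "record_set"))
  rows <- aln$matrix
  if (length(unique(nchar(rows))) > 1L) stop("alignment rows differ in length")
  seq_first <- rows[!duplicated(rows)]
  hap_ids <- sprintf("H%03d", seq_along(seq_first))
  names(hap_ids) <- seq_first
  study <- setNames(rs$records$study_id, rs$records$accession_id)
  members <- data.frame(
    accession_id = aln$seq_ids,
    haplotype_id = unname(hap_ids[rows]),
    study_id = unname(study[aln$seq_ids]),
    n_samples = 1L,
    stringsAsFactors = FALSE)
  if (anyNA(members$study_id))
    stop("aligned accession(s) missing from record set: ",
         paste(members$accession_id[is.na(members$study_id)], collapse = ", "))
  table <- data.frame(haplotype_id = unname(hap_ids),
                      sequence = names(hap_ids),
                      frequency = 0L, stringsAsFactors = FALSE)
  rownames(table) <- NULL
  recompute_frequencies(new_haplotype_table(table, members))
}

#' Flag studies that deposited only unique haplotypes
#'
#' A study whose every contributed sequence occurs exactly once within its
#' own contribution may have uploaded one representative record per
#' haplotype rather than one per individual sampled; such datasets bias
#' skyline inference and need manual review (and, if confirmed, a
#' magnification table restoring the true sampled frequencies).
#'
#' @param ht a `haplotype_table`.
#' @return character vector of flagged study ids.
#' @export
flag_unique_only_studies <- function(ht) {
  stopifnot(inherits(ht, "haplotype_table"))
  out <- character(0)
  for (s in unique(ht$members$study_id)) {
    m <- ht$members[ht$members$study_id == s, , drop = FALSE]
    per_hap <- tapply(m$n_samples, m$haplotype_id, sum)
    if (all(per_hap == 1L)) out <- c(out, s)
  }
  sort(out)
}

#' Load a magnification table
#'
#' Two-column delimited text with a header: `accession_id`,
#' `sampled_frequency` — the number of individuals each deposited accession
#' actually represents, recovered manually from the source publication.
#'
#' @param path path to the table, or a data frame with those columns.
#' @return validated data frame of class `magnify_table`.
#' @export
load_magnify_table <- function(path) {
  mt <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession_id", "sampled_frequency")
  if (!all(need %in% names(mt)))
    stop("magnify table must have columns: ", paste(need, collapse = ", "))
  mt$sampled_frequency <- as.integer(mt$sampled_frequency)
  if (any(mt$sampled_frequency < 1L))
    stop("sampled_frequency must be >= 1")
  if (anyDuplicated(mt$accession_id))
    stop("duplicate accession id(s) in magnify table")
  structure(mt[, need], class = c("magnify_table", "data.frame"))
}

#' Magnify deposited haplotypes to their sampled frequencies
#'
#' Each listed accession's contribution is raised so the accession represents
#' `sampled_frequency` individuals; haplotype frequencies and the total
#' sample count follow.
#'
#' @param ht a `haplotype_table`.
#' @param mt a `magnify_table` (or path / data frame accepted by
#'   [load_magnify_table()]).
#' @return the updated `haplotype_table`.
#' @export
magnify_to_sampled_freq <- function(ht, mt) {
  stopifnot(inherits(ht, "haplotype_table"))
  if (!inherits(mt, "magnify_table")) mt <- load_magnify_table(mt)
  for (i in seq_len(nrow(mt))) {
    acc <- mt$accession_id[[i]]
    j <- match(acc, ht$members$accession_id)
    if (is.na(j)) stop("magnify accession not in haplotype table: ", acc)
    if (mt$sampled_frequency[[i]] < ht$members$n_samples[[j]])
      stop("sampled_frequency for ", acc,
           " is below its current contribution (",
           ht$members$n_samples[[j]], ")")
    ht$members$n_samples[[j]] <- mt$sampled_frequency[[i]]
  }
  recompute_frequencies(ht)
}

# Pairwise Hamming distances between equal-length sequences.
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  if (length(unique(nchar(seqs))) > 1L)
    stop("sequences must have equal length for Hamming distances")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  d <- matrix(0L, n, n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
  }
  d
}

#' Build a haplotype network (minimum spanning tree)
#'
#' Pairwise Hamming distances are computed on the cleaned haplotype
#' sequences and a minimum spanning tree is built by Kruskal's algorithm
#' with deterministic tie-breaking (weight, then lexicographic edge ids).
#' `min_dist` — each haplotype's distance to its nearest other haplotype —
#' comes from the full distance matrix, not only tree edges.
#'
#' @param ht a `haplotype_table` with >= 1 haplotype.
#' @return a `haplotype_network`: `nodes` (haplotype_id, frequency), `edges`
#'   (from, to, weight), `min_dist` (named integer vector; `NA` for a
#'   single-haplotype network).
#' @export
build_haplotype_network <- function(ht) {
  stopifnot(inherits(ht, "haplotype_table"))
  tab <- ht$table
  n <- nrow(tab)
  if (n < 1L) stop("haplotype table is empty")
  nodes <- data.frame(haplotype_id = tab$haplotype_id,
                      frequency = tab$frequency, stringsAsFactors = FALSE)
  if (n == 1L) {
    net <- list(nodes = nodes,
                edges = data.frame(from = character(0), to = character(0),
                                   weight = integer(0), stringsAsFactors = FALSE),
                min_dist = setNames(NA_integer_, tab$haplotype_id),
                dist = matrix(0L, 1, 1))
    return(structure(net, class = "haplotype_network"))
  }
  d <- hamming_matrix(tab$sequence)
  dimnames(d) <- list(tab$haplotype_id, tab$haplotype_id)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  cand <- data.frame(from = tab$haplotype_id[pairs[, 1]],
                     to = tab$haplotype_id[pairs[, 2]],
                     weight = d[pairs], stringsAsFactors = FALSE)
  swap <- cand$from > cand$to
  tmp <- cand$from[swap]; cand$from[swap] <- cand$to[swap]; cand$to[swap] <- tmp
  cand <- cand[order(cand$weight, cand$from, cand$to), , drop = FALSE]
  # Kruskal with union-find
  parent <- seq_len(n)
  names(parent) <- tab$haplotype_id
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  edges <- cand[0, , drop = FALSE]
  for (k in seq_len(nrow(cand))) {
    a <- find(match(cand$from[[k]], tab$haplotype_id))
    b <- find(match(cand$to[[k]], tab$haplotype_id))
    if (a != b) {
      parent[[a]] <- b
      edges <- rbind(edges, cand[k, , drop = FALSE])
      if (nrow(edges) == n - 1L) break
    }
  }
  rownames(edges) <- NULL
  diag(d) <- NA_integer_
  min_dist <- apply(d, 1, min, na.rm = TRUE)
  structure(list(nodes = nodes, edges = edges,
                 min_dist = setNames(as.integer(min_dist), tab$haplotype_id),
                 dist = d),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", nrow(x$nodes), " haplotypes, ",
      nrow(x$edges), " edges, total weight ",
      sum(x$edges$weight), "\n", sep = "")
  invisible(x)
}

#' Plot a haplotype network
#'
#' Nodes are placed by classical multidimensional scaling of the Hamming
#' distance matrix; node area scales with haplotype frequency and edges are
#' labelled with the number of base differences.
#'
#' @param x a `haplotype_network`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.haplotype_network <- function(x, ...) {
  n <- nrow(x$nodes)
  if (n == 1L) {
    plot(0, 0, pch = 21, bg = "steelblue", cex = 3, axes = FALSE,
         xlab = "", ylab = "", main = "Haplotype network", ...)
    text(0, 0, x$nodes$haplotype_id, pos = 3, offset = 1.2)
    return(invisible(x))
  }
  d <- x$dist
  d[is.na(d)] <- 0
  xy <- cmdscale(d, k = 2)
  plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
       main = "Haplotype network", ...)
  for (k in seq_len(nrow(x$edges))) {
    i <- match(x$edges$from[[k]], x$nodes$haplotype_id)
    j <- match(x$edges$to[[k]], x$nodes$haplotype_id)
    segments(xy[i, 1], xy[i, 2], xy[j, 1], xy[j, 2], col = "grey50")
    text(mean(xy[c(i, j), 1]), mean(xy[c(i, j), 2]),
         x$edges$weight[[k]], cex = 0.7, col = "grey30")
  }
  points(xy, pch = 21, bg = adjustcolor("steelblue", 0.7),
         cex = 1.5 + 2 * sqrt(x$nodes$frequency / max(x$nodes$frequency)))
  text(xy, labels = x$nodes$haplotype_id, pos = 3, cex = 0.8)
  invisible(x)
}

#' Write a network edge list to a text file
#'
#' @param net a `haplotype_network`.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(net, path) {
  stopifnot(inherits(net, "haplotype_network"))
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop extreme outlier haplotypes
#'
#' An extreme outlier is a haplotype represented by a single sample and
#' separated from every other haplotype by strictly more than `threshold`
#' base differences. Such sequences may be genuine but more often reflect
#' immigrants, mislabelled samples, nuclear copies of mitochondrial genes or
#' poor sequencing, and they distort coalescent inference. Outliers are
#' removed most-divergent-first, recomputing nearest-neighbour distances
#' after each removal so the result does not depend on processing order.
#'
#' @param ht a `haplotype_table`.
#' @param threshold base-difference threshold (default 30; strict inequality,
#'   so a singleton at exactly `threshold` is retained).
#' @param fasta optional path: write the retained sequences (one record per
#'   member accession) to this FASTA file.
#' @return list with `table` (pruned `haplotype_table`), `removed` (data
#'   frame of haplotype_id, min_dist, accessions) and `fasta` (path or
#'   `NULL`).
#' @export
drop_outliers <- function(ht, threshold = 30, fasta = NULL) {
  stopifnot(inherits(ht, "haplotype_table"), threshold >= 0)
  removed <- data.frame(haplotype_id = character(0), min_dist = integer(0),
                        accessions = character(0), stringsAsFactors = FALSE)
  repeat {
    if (nrow(ht$table) < 2L) break
    net <- build_haplotype_network(ht)
    singleton <- ht$table$frequency == 1L
    far <- net$min_dist[ht$table$haplotype_id] > threshold
    cand <- ht$table$haplotype_id[singleton & far]
    if (!length(cand)) break
    cand <- cand[order(-net$min_dist[cand], cand)]
    worst <- cand[[1]]
    accs <- ht$members$accession_id[ht$members$haplotype_id == worst]
    removed <- rbind(removed, data.frame(
      haplotype_id = worst, min_dist = unname(net$min_dist[[worst]]),
      accessions = paste(accs, collapse = ";"), stringsAsFactors = FALSE))
    ht$table <- ht$table[ht$table$haplotype_id != worst, , drop = FALSE]
    ht$members <- ht$members[ht$members$haplotype_id != worst, , drop = FALSE]
    rownames(ht$table) <- rownames(ht$members) <- NULL
  }
  if (nrow(removed))
    message("outlier haplotype(s) removed (> ", threshold, " bp): ",
            paste(removed$haplotype_id, collapse = ", "))
  out_fasta <- NULL
  if (!is.null(fasta)) {
    seqs <- setNames(
      ht$table$sequence[match(ht$members$haplotype_id, ht$table$haplotype_id)],
      ht$members$accession_id)
    write_fasta(seqs, fasta)
    out_fasta <- fasta
  }
  list(table = ht, removed = removed, fasta = out_fasta)
}

#' Write a haplotype table to delimited text
#'
#' @param ht a `haplotype_table`.
#' @param path output path; member accessions are written `;`-separated.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(ht, path) {
  stopifnot(inherits(ht, "haplotype_table"))
  tab <- ht$table
  tab$member_accessions <- vapply(tab$haplotype_id, function(h)
    paste(ht$members$accession_id[ht$members$haplotype_id == h], collapse = ";"),
    character(1))
  tab$study_ids <- vapply(tab$haplotype_id, function(h)
    paste(sort(unique(ht$members$study_id[ht$members$haplotype_id == h])),
          collapse = ";"), character(1))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
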