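# Length filtering, center-star multiple alignment, overlap cropping and
# ambiguity-column removal. Sequences of the same gene pooled from many
# studies differ mainly in the stretch of the gene each study sequenced, so
# a simple center-star alignment around the longest sequence is adequate and
# keeps the pipeline free of external aligner dependencies; an externally
# produced FASTA alignment can be imported instead via import_alignment().

new_alignment <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) stop("alignment rows differ in length")
  cov <- t(vapply(rows, function(r) {
    ng <- which(strsplit(r, "", fixed = TRUE)[[1]] != "-")
    if (!length(ng)) c(NA_integer_, NA_integer_) else range(ng)
  }, integer(2)))
  structure(list(seq_ids = names(rows), matrix = rows,
                 ncol = unname(widths[[1]]),
                 coverage = data.frame(first = cov[, 1], last = cov[, 2],
                                       row.names = names(rows)),
                 trim_log = setNames(rep(0L, length(rows)), names(rows))),
            class = "mt_alignment")
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("<mt_alignment> ", length(x$seq_ids), " sequences x ", x$ncol,
      " columns\n", sep = "")
  invisible(x)
}

#' Drop sequences shorter than a minimum length
#'
#' Very short deposits carry too little signal for demographic inference and
#' force heavy cropping of everything else; they are removed before
#' alignment. There is no universal cut-off — the default of 200 bp is a
#' baseline suitable for a single mitochondrial gene.
#'
#' @param rs a `record_set`.
#' @param minbp minimum sequence length in bp (default 200).
#' @return the filtered `record_set`; dropped accessions are logged.
#' @export
drop_short_sequences <- function(rs, minbp = 200) {
  stopifnot(inherits(rs, "record_set"), minbp >= 0)
  short <- rs$records$accession_id[rs$records$seq_length < minbp]
  if (length(short))
    message(length(short), " sequence(s) below ", minbp, " bp dropped: ",
            paste(short, collapse = ", "))
  subset_records(rs, setdiff(rs$records$accession_id, short),
                 sprintf("drop_short_sequences:minbp=%d", as.integer(minbp)))
}

#' Pairwise alignment by dynamic programming
#'
#' Linear gap penalty, fill ties resolved diagonal > up > left. By default an
#' overlap alignment: leading and trailing gaps in either sequence are free,
#' which is the appropriate formulation when the two inputs are fragments of
#' the same gene sequenced over different spans (charging terminal gaps makes
#' scattered, co-optimal placements of a short fragment's tail possible;
#' free end gaps make the contiguous placement strictly optimal). Set
#' `free_ends = FALSE` for a classical global Needleman-Wunsch alignment.
#'
#' @param a,b nucleotide strings.
#' @param match,mismatch,gap scoring parameters (defaults +1/-1/-2).
#' @param free_ends leave terminal gaps unpenalised? Default `TRUE`.
#' @return list with `score`, `a`, `b` (gapped strings).
#' @export
pairwise_align <- function(a, b, match = 1, mismatch = -1, gap = -2,
                           free_ends = TRUE) {
  nw_align_cpp(a, b, match, mismatch, gap, free_ends)
}

#' Center-star multiple alignment
#'
#' The center is the longest input sequence (ties broken by lexicographically
#' smallest id); every other sequence is aligned to the center by dynamic
#' programming ([pairwise_align()], overlap scoring) and the pairwise
#' alignments are merged under the once-a-gap-always-a-gap rule. Deleting the
#' gaps from any output row recovers the corresponding input exactly.
#'
#' @param seqs named character vector (>= 2 sequences of one species/gene).
#' @param match,mismatch,gap scoring parameters (defaults +1/-1/-2).
#' @return an `mt_alignment`.
#' @export
align_sequences <- function(seqs, match = 1, mismatch = -1, gap = -2) {
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by accession")
  seqs <- toupper(seqs)
  ok <- vapply(seqs, is_iupac, logical(1))
  if (any(!ok))
    stop("non-IUPAC characters in sequence(s): ",
         paste(names(seqs)[!ok], collapse = ", "))
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("input sequences must be ungapped")
  ord <- order(-nchar(seqs), names(seqs))
  center_id <- names(seqs)[ord[[1]]]
  center <- seqs[[center_id]]
  others <- setdiff(names(seqs), center_id)
  pw <- lapply(others, function(id)
    nw_align_cpp(center, seqs[[id]], match, mismatch, gap))
  names(pw) <- others
  L <- nchar(center)
  # ins[[k]][p+1]: gaps inserted into the center before residue p+1
  # (p = 0..L; p = L means after the last residue)
  ins <- lapply(pw, function(al) gap_profile(al$a, L))
  master <- if (length(ins)) do.call(pmax, ins) else rep(0L, L + 1L)
  rows <- c(setNames(list(expand_row(NULL, NULL, center,
                                     rep(0L, L + 1L), master)),
                     center_id),
            lapply(others, function(id)
              expand_row(pw[[id]]$a, pw[[id]]$b, center, ins[[id]], master)))
  names(rows) <- c(center_id, others)
  rows <- rows[names(seqs)]  # preserve input order
  new_alignment(unlist(rows))
}

# Count gap runs in the gapped center string before each center residue.
gap_profile <- function(center_aln, L) {
  chars <- strsplit(center_aln, "", fixed = TRUE)[[1]]
  prof <- integer(L + 1L)
  p <- 1L
  run <- 0L
  for (ch in chars) {
    if (ch == "-") run <- run + 1L
    else { prof[[p]] <- run; run <- 0L; p <- p + 1L }
  }
  prof[[L + 1L]] <- run
  prof
}

# Rebuild one row of the merged alignment: pad each inter-residue segment of
# the pairwise alignment with extra gaps up to the master profile.
expand_row <- function(center_aln, seq_aln, center, ins, master) {
  L <- nchar(center)
  if (is.null(seq_aln)) {           # the center row itself
    segs <- character(L + 1L)
    segs[seq_len(L + 1L)] <- strrep("-", master)
    res <- c(strsplit(center, "", fixed = TRUE)[[1]], "")
    return(paste0(paste0(segs[seq_len(L)], res[seq_len(L)], collapse = ""),
                  segs[[L + 1L]]))
  }
  ca <- strsplit(center_aln, "", fixed = TRUE)[[1]]
  sa <- strsplit(seq_aln, "", fixed = TRUE)[[1]]
  segs <- character(L + 1L)   # seq chars aligned to gap runs before residue p
  res <- character(L)         # seq char aligned to center residue p
  p <- 1L
  buf <- character(0)
  for (i in seq_along(ca)) {
    if (ca[[i]] == "-") buf <- c(buf, sa[[i]])
    else {
      segs[[p]] <- paste(buf, collapse = "")
      res[[p]] <- sa[[i]]
      buf <- character(0)
      p <- p + 1L
    }
  }
  segs[[L + 1L]] <- paste(buf, collapse = "")
  pad <- master - ins
  out <- character(0)
  for (p in seq_len(L))
    out <- c(out, strrep("-", pad[[p]]), segs[[p]], res[[p]])
  paste0(paste(out, collapse = ""), strrep("-", pad[[L + 1L]]), segs[[L + 1L]])
}

#' Import an externally produced alignment from FASTA
#'
#' Hook for users who prefer a full progressive MSA program: read its aligned
#' FASTA output into the pipeline's alignment container.
#'
#' @param path aligned FASTA file.
#' @return an `mt_alignment`.
#' @export
import_alignment <- function(path) {
  new_alignment(read_fasta(path))
}

#' Crop an alignment to the maximum overlap window
#'
#' Removes columns outside `[max(first non-gap), min(last non-gap)]` over all
#' rows, so that every retained column is covered by every sequence. Cropping
#' to the overlap can silently discard a lot of data when one short sequence
#' is included, so per-sequence losses are recorded and rows losing more than
#' `heavy_loss_bp` are flagged for review.
#'
#' @param aln an `mt_alignment`.
#' @param heavy_loss_bp flag rows losing more than this many bp (default 500).
#' @return list with `alignment` (cropped) and `summary` (a `length_summary`).
#' @export
crop_to_overlap <- function(aln, heavy_loss_bp = 500) {
  stopifnot(inherits(aln, "mt_alignment"))
  w1 <- max(aln$coverage$first)
  w2 <- min(aln$coverage$last)
  if (is.na(w1) || is.na(w2) || w1 > w2)
    stop("empty overlap window: remove non-overlapping sequences and re-align")
  orig_bp <- vapply(aln$matrix, function(r) sum(strsplit(r, "")[[1]] != "-"),
                    integer(1))
  rows <- substr(aln$matrix, w1, w2)
  names(rows) <- aln$seq_ids
  out <- new_alignment(rows)
  kept_bp <- vapply(out$matrix, function(r) sum(strsplit(r, "")[[1]] != "-"),
                    integer(1))
  out$trim_log <- orig_bp - kept_bp
  flagged <- names(out$trim_log)[out$trim_log > heavy_loss_bp]
  if (length(flagged))
    message("heavy cropping (> ", heavy_loss_bp, " bp lost): ",
            paste(flagged, collapse = ", "))
  summary <- new_length_summary(orig_bp, overlap_length = w2 - w1 + 1L,
                                flagged = flagged, trim_log = out$trim_log)
  list(alignment = out, summary = summary)
}

new_length_summary <- function(original_bp, overlap_length, flagged = character(0),
                               trim_log = NULL) {
  structure(list(original_bp = original_bp,
                 overlap_length = as.integer(overlap_length),
                 flagged = flagged, trim_log = trim_log),
            class = "length_summary")
}

#' @export
print.length_summary <- function(x, ...) {
  cat("<length_summary> ", length(x$original_bp), " sequences, ",
      "lengths ", min(x$original_bp), "-", max(x$original_bp),
      " bp, overlap ", x$overlap_length, " bp\n", sep = "")
  if (length(x$flagged))
    cat("  heavily cropped: ", paste(x$flagged, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Remove columns containing gaps or ambiguity codes
#'
#' Sequencing standards vary across studies, so any column holding a gap,
#' `N`, `?` or other non-ACGT IUPAC code in any row is deleted; downstream
#' analyses then see a gap-free, unambiguous block.
#'
#' @param aln an `mt_alignment` (normally already cropped).
#' @return the cleaned `mt_alignment`, with the number of columns removed in
#'   attribute `"removed_columns"`.
#' @export
remove_ambiguous_columns <- function(aln) {
  stopifnot(inherits(aln, "mt_alignment"))
  mat <- do.call(rbind, strsplit(aln$matrix, "", fixed = TRUE))
  bad <- apply(mat, 2, function(col) any(!col %in% c("A", "C", "G", "T")))
  if (all(bad)) stop("no unambiguous columns remain after cleaning")
  if (any(bad)) {
    mat <- mat[, !bad, drop = FALSE]
    message(sum(bad), " ambiguous/gapped column(s) removed")
  }
  rows <- apply(mat, 1, paste, collapse = "")
  names(rows) <- aln$seq_ids
  out <- new_alignment(rows)
  attr(out, "removed_columns") <- sum(bad)
  out
}

#' Summarise sequence lengths and the overlap window
#'
#' Produces the data behind the trimming diagnostic: a histogram-ready table
#' of original sequence lengths with the maximum-overlap length marked, so
#' the user can see how much sequence the overlap crop discards.
#'
#' @param rs a `record_set` (original lengths); may be `NULL` to use the
#'   alignment's row lengths.
#' @param aln an `mt_alignment`.
#' @return a `length_summary` with a `histogram` element (output of
#'   [graphics::hist()] with `plot = FALSE`).
#' @export
summarise_lengths <- function(rs, aln) {
  stopifnot(inherits(aln, "mt_alignment"))
  if (!is.null(rs)) {
    stopifnot(inherits(rs, "record_set"))
    keep <- rs$records$accession_id %in% aln$seq_ids
    original_bp <- setNames(rs$records$seq_length[keep],
                            rs$records$accession_id[keep])
  } else {
    original_bp <- vapply(aln$matrix,
                          function(r) sum(strsplit(r, "")[[1]] != "-"),
                          integer(1))
  }
  w1 <- max(aln$coverage$first)
  w2 <- min(aln$coverage$last)
  out <- new_length_summary(original_bp, overlap_length = w2 - w1 + 1L)
  out$histogram <- hist(original_bp, plot = FALSE)
  out
}

#' Plot the sequence-length histogram with the overlap marker
#'
#' @param x a `length_summary`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.length_summary <- function(x, ...) {
  hist(x$original_bp, xlab = "Sequence length (bp)",
       main = "Sequence lengths before processing", col = "grey85", ...)
  abline(v = x$overlap_length, col = "red", lwd = 2)
  invisible(x)
}
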