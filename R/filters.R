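# Final information-content filter cascade. A skyline analysis of a single
# mitochondrial gene needs enough haplotypes, samples and sequence to say
# anything about past demography; datasets below the thresholds are dropped
# with the reasons reported. The defaults (6 haplotypes / 20 samples /
# 600 bp) suit a single-gene analysis and should be re-assessed per study —
# there is no out-of-the-box value.

#' Filter thresholds for species summaries
#'
#' Boundary semantics are strictly-less-than: a species with exactly
#' `min_haplotypes` haplotypes (or `min_samples` samples, `min_bp` bp)
#' passes.
#'
#' @param min_haplotypes minimum number of haplotypes (default 6).
#' @param min_samples minimum sample size (default 20).
#' @param min_bp minimum cleaned sequence length in bp (default 600).
#' @return object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_haplotypes = 6, min_samples = 20,
                              min_bp = 600) {
  stopifnot(min_haplotypes >= 0, min_samples >= 0, min_bp >= 0)
  structure(list(min_haplotypes = min_haplotypes, min_samples = min_samples,
                 min_bp = min_bp), class = "filter_thresholds")
}

#' Summarise a processed species dataset
#'
#' @param ht the species' `haplotype_table` after processing.
#' @param aln the species' cleaned `mt_alignment` (or `NULL` for an empty
#'   dataset).
#' @param species_name species binomial.
#' @return one-row data frame: `species_name`, `n_haplotypes`, `seq_length`,
#'   `sample_size`.
#' @export
summarise_species <- function(ht, aln, species_name = "unknown") {
  n_hap <- if (is.null(ht)) 0L else nrow(ht$table)
  n_samp <- if (is.null(ht)) 0L else sample_count(ht)
  len <- if (is.null(aln)) 0L else aln$ncol
  if (n_hap == 0L) { n_samp <- 0L; len <- 0L }  # empty dataset summarises to zeros
  data.frame(species_name = species_name,
             n_haplotypes = as.integer(n_hap),
             seq_length = as.integer(len),
             sample_size = as.integer(n_samp),
             stringsAsFactors = FALSE)
}

#' Apply the information-content filter cascade
#'
#' A species is dropped when `n_haplotypes < min_haplotypes` OR
#' `sample_size < min_samples` OR `seq_length < min_bp`; a dropped species
#' carries every failing reason. The three predicates commute, so the order
#' in which they are applied never changes the retained set.
#'
#' @param summaries data frame of species summaries (rows as produced by
#'   [summarise_species()]).
#' @param thresholds a `filter_thresholds` object.
#' @return list with `retained` (data frame) and `dropped` (data frame with a
#'   `reasons` column; reasons are `;`-separated among
#'   `haplotypes`, `samples`, `length`).
#' @export
apply_filters <- function(summaries, thresholds = filter_thresholds()) {
  stopifnot(is.data.frame(summaries), inherits(thresholds, "filter_thresholds"))
  need <- c("species_name", "n_haplotypes", "seq_length", "sample_size")
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns: ", paste(need, collapse = ", "))
  reasons <- vapply(seq_len(nrow(summaries)), function(i) {
    r <- character(0)
    if (summaries$n_haplotypes[[i]] < thresholds$min_haplotypes) r <- c(r, "haplotypes")
    if (summaries$sample_size[[i]] < thresholds$min_samples) r <- c(r, "samples")
    if (summaries$seq_length[[i]] < thresholds$min_bp) r <- c(r, "length")
    paste(r, collapse = ";")
  }, character(1))
  keep <- !nzchar(reasons)
  dropped <- summaries[!keep, , drop = FALSE]
  dropped$reasons <- reasons[!keep]
  rownames(dropped) <- NULL
  retained <- summaries[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, dropped = dropped)
}

#' Read/write species summary tables
#'
#' @param path delimited text file with the summary columns.
#' @return data frame of species summaries.
#' @export
read_species_summaries <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_name", "n_haplotypes", "seq_length", "sample_size")
  if (!all(need %in% names(tab)))
    stop("summary table must have columns: ", paste(need, collapse = ", "))
  tab[, need]
}

#' @rdname read_species_summaries
#' @param summaries data frame of species summaries.
#' @export
write_species_summaries <- function(summaries, path) {
  write.table(summaries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
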