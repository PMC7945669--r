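# Internal helpers shared across the pipeline.

# IUPAC nucleotide alphabet accepted on input; '?' is tolerated as missing
# data and removed with the other ambiguity codes during cleaning.
IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "?", "-")

is_iupac <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  all(chars %in% IUPAC_CHARS)
}

# Deterministic 31-bit string hash (djb2) used to derive study identifiers
# from reference metadata; stable across sessions and platforms.
study_hash <- function(x) {
  vapply(x, function(s) {
    bytes <- utf8ToInt(enc2utf8(s))
    h <- 5381
    for (b in bytes) h <- (h * 33 + b) %% 2147483647
    sprintf("study:%08x", h)
  }, character(1), USE.NAMES = FALSE)
}

# Normalisation applied before comparing gene names to conversion-table
# variants: case-fold, strip ".,-_" and all whitespace.
normalise_gene_key <- function(x) {
  gsub("[.,_\\s-]+", "", tolower(x), perl = TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  setNames(toupper(vapply(x, function(s) as.character(s)[1], character(1))),
           names(x))
}

# Local, restorable RNG scope so generators are deterministic given a seed
# without clobbering the caller's random state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
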