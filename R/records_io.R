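# Reading GenBank flat files and accession lists into a record_set.

new_record_set <- function(records, features, provenance = NULL) {
  if (is.null(provenance)) {
    provenance <- data.frame(operation = character(0),
                             before = integer(0), after = integer(0),
                             stringsAsFactors = FALSE)
  }
  structure(list(records = records, features = features,
                 provenance = provenance),
            class = "record_set")
}

empty_records_df <- function() {
  data.frame(accession_id = character(0), organism_raw = character(0),
             sequence = character(0), seq_length = integer(0),
             study_id = character(0), is_refseq = logical(0),
             dbsource = character(0), stringsAsFactors = FALSE)
}

empty_features_df <- function() {
  data.frame(accession_id = character(0), feature_kind = character(0),
             gene_name_raw = character(0), gene_name_std = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

add_provenance <- function(rs, operation, before, after) {
  rs$provenance <- rbind(rs$provenance,
                         data.frame(operation = operation,
                                    before = as.integer(before),
                                    after = as.integer(after),
                                    stringsAsFactors = FALSE))
  rs
}

# Keep only the given accessions, dropping their features alongside.
subset_records <- function(rs, keep, operation = NULL) {
  before <- nrow(rs$records)
  rs$records <- rs$records[rs$records$accession_id %in% keep, , drop = FALSE]
  rownames(rs$records) <- NULL
  rs$features <- rs$features[rs$features$accession_id %in% keep, , drop = FALSE]
  rownames(rs$features) <- NULL
  if (!is.null(operation)) rs <- add_provenance(rs, operation, before, nrow(rs$records))
  rs
}

#' @export
print.record_set <- function(x, ...) {
  cat("<record_set> ", nrow(x$records), " records, ",
      nrow(x$features), " feature rows\n", sep = "")
  if (nrow(x$records)) {
    org <- table(x$records$organism_raw)
    cat("  organisms: ",
        paste0(names(org), " (", as.integer(org), ")", collapse = ", "),
        "\n", sep = "")
    cat("  RefSeq records: ", sum(x$records$is_refseq), "\n", sep = "")
  }
  if (nrow(x$provenance)) {
    cat("  provenance:\n")
    for (i in seq_len(nrow(x$provenance)))
      cat(sprintf("    %s: %d -> %d\n", x$provenance$operation[i],
                  x$provenance$before[i], x$provenance$after[i]))
  }
  invisible(x)
}

#' Read a one-column accession list
#'
#' Reads a delimited text file with one accession per row (an optional header
#' row without digits is skipped), trims whitespace, and removes exact
#' duplicates, reporting how many were dropped.
#'
#' @param path path to the accession list.
#' @return character vector of unique accessions in file order, with the
#'   number of duplicates removed in attribute `"n_duplicates"`.
#' @export
load_accession_list <- function(path) {
  if (!file.exists(path)) stop("cannot read accession list: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- vapply(strsplit(ln, "[,\t;]"),
               function(x) if (length(x)) trimws(x[[1]]) else "", character(1))
  ln <- ln[nzchar(ln)]
  if (length(ln) && !grepl("[0-9]", ln[[1]])) ln <- ln[-1]  # header row
  if (!length(ln)) {
    warning("accession list is empty: ", path)
    return(structure(character(0), n_duplicates = 0L))
  }
  dup <- duplicated(ln)
  if (any(dup))
    message(sum(dup), " duplicate accession(s) removed from ", basename(path))
  structure(ln[!dup], n_duplicates = sum(dup))
}

#' Parse a multi-entry GenBank flat file
#'
#' Reads LOCUS/DEFINITION/FEATURES/ORIGIN blocks into a `record_set`. The
#' organism is taken verbatim from the ORGANISM line, the sequence is
#' upper-cased, and `seq_length` is computed from the ORIGIN letters rather
#' than trusted from the LOCUS line. Records without an ORIGIN sequence are
#' skipped with a warning; a record missing both ACCESSION and VERSION is a
#' parse error naming the offending LOCUS. The study identifier is a hash of
#' the first REFERENCE block's title and authors (`"unknown:<accession>"`
#' when the entry carries no reference).
#'
#' @param path path to a GenBank flat file (one or more entries).
#' @return a `record_set`.
#' @export
parse_genbank_records <- function(path) {
  if (!file.exists(path)) stop("cannot read GenBank file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("no LOCUS entries found in ", path)
  ends <- grep("^//\\s*$", lines)
  rec_rows <- vector("list", length(starts))
  feat_rows <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    e <- ends[ends >= starts[k]]
    if (!length(e)) e <- length(lines) else e <- e[[1]]
    entry <- parse_gb_entry(lines[starts[k]:e])
    if (is.null(entry)) next
    rec_rows[[k]] <- entry$record
    feat_rows[[k]] <- entry$features
  }
  records <- do.call(rbind, c(list(empty_records_df()), rec_rows))
  features <- do.call(rbind, c(list(empty_features_df()), feat_rows))
  # accession collisions on input: keep first occurrence, log the rest
  dup <- duplicated(records$accession_id)
  if (any(dup)) {
    warning("duplicate accession id(s) on input, keeping first occurrence: ",
            paste(unique(records$accession_id[dup]), collapse = ", "))
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  rs <- new_record_set(records, features)
  add_provenance(rs, "parse_genbank_records", length(starts), nrow(records))
}

# Parse one LOCUS..// block; returns NULL for entries skipped (no ORIGIN).
parse_gb_entry <- function(block) {
  locus_name <- {
    tok <- strsplit(trimws(block[[1]]), "\\s+")[[1]]
    if (length(tok) >= 2) tok[[2]] else "<unnamed>"
  }
  pick_line <- function(pattern) {
    i <- grep(pattern, block)
    if (length(i)) block[[i[[1]]]] else NA_character_
  }
  version_line <- pick_line("^VERSION")
  accession_line <- pick_line("^ACCESSION")
  if (is.na(version_line) && is.na(accession_line))
    stop("malformed GenBank entry (no ACCESSION/VERSION) at LOCUS ", locus_name)
  accession <- if (!is.na(version_line)) {
    strsplit(trimws(sub("^VERSION", "", version_line)), "\\s+")[[1]][[1]]
  } else {
    strsplit(trimws(sub("^ACCESSION", "", accession_line)), "\\s+")[[1]][[1]]
  }
  org_line <- pick_line("^\\s{1,4}ORGANISM")
  organism <- if (is.na(org_line)) "" else trimws(sub("^\\s*ORGANISM", "", org_line))
  dbsource_line <- pick_line("^DBSOURCE")
  dbsource <- ""
  if (!is.na(dbsource_line)) {
    m <- regmatches(dbsource_line,
                    regexpr("[A-Z]{1,4}_?[0-9]+(\\.[0-9]+)?", dbsource_line))
    if (length(m)) dbsource <- m[[1]]
  }
  study_id <- gb_study_id(block, accession)
  sequence <- gb_origin_sequence(block)
  if (!nzchar(sequence)) {
    warning("record ", accession, " has no ORIGIN sequence; skipped")
    return(NULL)
  }
  feats <- gb_parse_features(block, accession)
  record <- data.frame(accession_id = accession, organism_raw = organism,
                       sequence = sequence, seq_length = nchar(sequence),
                       study_id = study_id,
                       is_refseq = grepl("_", accession, fixed = TRUE),
                       dbsource = dbsource, stringsAsFactors = FALSE)
  list(record = record, features = feats)
}

gb_study_id <- function(block, accession) {
  ref_i <- grep("^REFERENCE", block)
  if (!length(ref_i)) return(paste0("unknown:", accession))
  # collect AUTHORS/TITLE (with wrapped continuation lines) of reference 1
  stop_i <- grep("^(REFERENCE|FEATURES|ORIGIN|COMMENT)", block)
  stop_i <- stop_i[stop_i > ref_i[[1]]]
  end <- if (length(stop_i)) stop_i[[1]] - 1L else length(block)
  sec <- block[(ref_i[[1]] + 1L):max(ref_i[[1]] + 1L, end)]
  grab <- function(tag) {
    i <- grep(paste0("^\\s{1,4}", tag), sec)
    if (!length(i)) return("")
    out <- trimws(sub(paste0("^\\s*", tag), "", sec[[i[[1]]]]))
    j <- i[[1]] + 1L
    while (j <= length(sec) && grepl("^\\s{10,}", sec[[j]])) {
      out <- paste(out, trimws(sec[[j]]))
      j <- j + 1L
    }
    out
  }
  authors <- grab("AUTHORS")
  title <- grab("TITLE")
  if (!nzchar(authors) && !nzchar(title)) return(paste0("unknown:", accession))
  study_hash(paste(title, authors, sep = "|"))
}

gb_origin_sequence <- function(block) {
  o <- grep("^ORIGIN", block)
  if (!length(o)) return("")
  e <- grep("^//\\s*$", block)
  e <- if (length(e)) e[[1]] - 1L else length(block)
  if (e <= o[[1]]) return("")
  toupper(gsub("[^A-Za-z]", "", paste(block[(o[[1]] + 1L):e], collapse = "")))
}

gb_parse_features <- function(block, accession) {
  f0 <- grep("^FEATURES", block)
  if (!length(f0)) return(empty_features_df())
  f1 <- grep("^(ORIGIN|BASE COUNT|CONTIG)", block)
  f1 <- f1[f1 > f0[[1]]]
  f1 <- if (length(f1)) f1[[1]] - 1L else length(block)
  if (f1 <= f0[[1]]) return(empty_features_df())
  sec <- block[(f0[[1]] + 1L):f1]
  key_i <- grep("^\\s{3,8}\\S", sec)
  if (!length(key_i)) return(empty_features_df())
  rows <- vector("list", length(key_i))
  bounds <- c(key_i, length(sec) + 1L)
  for (k in seq_along(key_i)) {
    ln <- sec[key_i[[k]]:(bounds[[k + 1L]] - 1L)]
    head_tok <- strsplit(trimws(ln[[1]]), "\\s+")[[1]]
    key <- head_tok[[1]]
    loc <- if (length(head_tok) >= 2) paste(head_tok[-1], collapse = "") else ""
    # location may wrap onto further non-qualifier lines
    for (j in seq_along(ln)[-1]) {
      if (grepl("^\\s*/", ln[[j]])) break
      loc <- paste0(loc, trimws(ln[[j]]))
    }
    qual <- function(name) {
      m <- unlist(regmatches(ln, regexpr(sprintf('/%s="[^"]*"', name), ln)))
      if (!length(m)) return("")
      sub('"$', "", sub(sprintf('^/%s="', name), "", m[[1]]))
    }
    gene <- qual("gene")
    if (!nzchar(gene)) gene <- qual("product")
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    kind <- if (key %in% c("source", "gene", "CDS")) key
            else if (key == "misc_feature") "misc" else "other"
    rows[[k]] <- data.frame(
      accession_id = accession, feature_kind = kind,
      gene_name_raw = gene, gene_name_std = "",
      start = if (length(nums)) min(nums) else NA_integer_,
      end = if (length(nums)) max(nums) else NA_integer_,
      strand = if (grepl("complement", loc)) "-"
               else if (length(nums)) "+" else "unknown",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Scrape gene-bearing feature tags into items
#'
#' One item per gene-bearing feature tag per record: a record annotating the
#' same gene under both a `gene` and a `CDS` tag contributes two items (the
#' redundancy is resolved later by [standardise_gene_names()] and
#' [gene_of_interest()]). `source` tags and tags without a gene/product
#' qualifier contribute nothing.
#'
#' @param rs a `record_set`.
#' @return data frame of feature items.
#' @export
scrape_feature_items <- function(rs) {
  stopifnot(inherits(rs, "record_set"))
  items <- rs$features
  items <- items[nzchar(items$gene_name_raw) & items$feature_kind != "source", ,
                 drop = FALSE]
  rownames(items) <- NULL
  items
}

#' Remove RefSeq duplicates of records already in the set
#'
#' RefSeq accessions (recognised by the underscore in the accession number)
#' re-publish records that may already be present under their source
#' accession. A RefSeq record is removed when its declared source accession
#' (DBSOURCE cross-reference) is present in the set, or when a non-RefSeq
#' record with an identical sequence and organism is present. RefSeq records
#' with no identifiable original are retained: dropping them would silently
#' lose the only copy of the data.
#'
#' @param rs a `record_set`.
#' @return the deduplicated `record_set`; removed accessions are recorded in
#'   attribute `"removed_accessions"` and the provenance log.
#' @export
remove_refseq_duplicates <- function(rs) {
  stopifnot(inherits(rs, "record_set"))
  rec <- rs$records
  drop <- character(0)
  for (i in which(rec$is_refseq)) {
    declared <- rec$dbsource[[i]]
    others <- rec[-i, , drop = FALSE]
    has_declared <- nzchar(declared) && declared %in% others$accession_id
    has_twin <- any(!others$is_refseq &
                    others$sequence == rec$sequence[[i]] &
                    others$organism_raw == rec$organism_raw[[i]])
    if (has_declared || has_twin) drop <- c(drop, rec$accession_id[[i]])
  }
  if (length(drop))
    message("RefSeq duplicate(s) removed: ", paste(drop, collapse = ", "))
  keep <- setdiff(rec$accession_id, drop)
  rs <- subset_records(rs, keep, "remove_refseq_duplicates")
  attr(rs, "removed_accessions") <- drop
  rs
}

#' Write a record set to a metadata table and FASTA file
#'
#' @param rs a `record_set`.
#' @param prefix output path prefix; writes `<prefix>_metadata.tsv` and
#'   `<prefix>.fasta`.
#' @return character vector of the two paths written, invisibly.
#' @export
write_records <- function(rs, prefix) {
  stopifnot(inherits(rs, "record_set"))
  meta_path <- paste0(prefix, "_metadata.tsv")
  fasta_path <- paste0(prefix, ".fasta")
  meta <- rs$records[, c("accession_id", "organism_raw", "seq_length",
                         "study_id", "is_refseq")]
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(setNames(rs$records$sequence, rs$records$accession_id), fasta_path)
  invisible(c(meta_path, fasta_path))
}
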