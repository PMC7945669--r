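# Nomenclature standardisation: gene names, organism names, gene-of-interest
# filtering. Repository submissions use a zoo of synonyms, abbreviations and
# misspellings for the same mitochondrial gene, and inconsistent taxonomic
# rank (subspecies vs species) in the organism field; both must be unified
# before records from different studies can be pooled.

#' Load a gene-name conversion table
#'
#' The table is long-format delimited text with a header and two columns,
#' `standard_name` and `variant`; one row per variant. Variants are compared
#' after case-folding and stripping `".,-_"` and whitespace, so `"nad2"`,
#' `"NADH2"` and `"ND-2"` all reach `ND2`. A variant that would map to two
#' different standard names is a load-time error. The default table shipped
#' with the package covers 18 commonly sequenced mitochondrial genes and can
#' be replaced by passing a path to a custom table.
#'
#' @param path path to a conversion table; `NULL` loads the packaged default.
#' @return object of class `gene_conversion_table`.
#' @export
load_gene_conversion_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gene_name_conversion.csv",
                        package = "mtcurate", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("standard_name", "variant")
  if (!all(need %in% names(tab)))
    stop("conversion table must have columns: ", paste(need, collapse = ", "))
  # every standard name is implicitly its own variant
  self_rows <- data.frame(standard_name = unique(tab$standard_name),
                          variant = unique(tab$standard_name),
                          stringsAsFactors = FALSE)
  tab <- unique(rbind(tab[, need], self_rows))
  key <- normalise_gene_key(tab$variant)
  conflict <- tapply(tab$standard_name, key,
                     function(s) length(unique(s)) > 1L)
  if (any(conflict))
    stop("conflicting variant(s) in gene conversion table: ",
         paste(names(conflict)[conflict], collapse = ", "))
  lookup <- setNames(tab$standard_name, key)
  lookup <- lookup[!duplicated(names(lookup))]
  structure(list(table = tab, lookup = lookup), class = "gene_conversion_table")
}

#' @export
print.gene_conversion_table <- function(x, ...) {
  cat("<gene_conversion_table> ", length(unique(x$table$standard_name)),
      " standard names, ", nrow(x$table), " variants\n", sep = "")
  invisible(x)
}

#' Standardise gene names across feature items
#'
#' Sets `gene_name_std` for every item whose raw name matches a conversion
#' table variant after normalisation; unmatched names are copied verbatim
#' into `gene_name_std` and listed in the report. The number of items is
#' never changed.
#'
#' @param items feature items from [scrape_feature_items()].
#' @param table a `gene_conversion_table`; default is the packaged table.
#' @return list with elements `items` (standardised) and `report`
#'   (data frame of `gene_name_raw`, `matched`, `n`).
#' @export
standardise_gene_names <- function(items, table = load_gene_conversion_table()) {
  stopifnot(is.data.frame(items), inherits(table, "gene_conversion_table"))
  if (!nrow(items)) return(list(items = items, report = data.frame(
    gene_name_raw = character(0), matched = logical(0), n = integer(0))))
  key <- normalise_gene_key(items$gene_name_raw)
  std <- unname(table$lookup[key])
  matched <- !is.na(std)
  items$gene_name_std <- ifelse(matched, std, items$gene_name_raw)
  tab <- table(items$gene_name_raw, matched[match(items$gene_name_raw, items$gene_name_raw)])
  report <- unique(data.frame(gene_name_raw = items$gene_name_raw,
                              matched = matched, stringsAsFactors = FALSE))
  report$n <- vapply(seq_len(nrow(report)), function(i)
    sum(items$gene_name_raw == report$gene_name_raw[[i]]), integer(1))
  rownames(report) <- NULL
  if (any(!report$matched))
    message("unmatched gene name(s): ",
            paste(report$gene_name_raw[!report$matched], collapse = ", "))
  list(items = items, report = report)
}

#' Load a species-name map
#'
#' Two-column delimited text with a header: `observed_name`,
#' `canonical_name`. Canonical names must be two-token binomials.
#'
#' @param path path to the map; `NULL` gives an empty map.
#' @return object of class `species_name_map`.
#' @export
load_species_name_map <- function(path = NULL) {
  if (is.null(path)) {
    map <- data.frame(observed_name = character(0),
                      canonical_name = character(0), stringsAsFactors = FALSE)
  } else {
    map <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("observed_name", "canonical_name")
    if (!all(need %in% names(map)))
      stop("species map must have columns: ", paste(need, collapse = ", "))
    ntok <- lengths(strsplit(trimws(map$canonical_name), "\\s+"))
    if (any(ntok != 2L))
      stop("canonical names must be two-token binomials: ",
           paste(map$canonical_name[ntok != 2L], collapse = ", "))
  }
  structure(list(map = map), class = "species_name_map")
}

#' Standardise organism names to species binomials
#'
#' Organism strings with three or more tokens (subspecies / trinomials) are
#' truncated to the first two tokens when `trinomial_truncation` is on;
#' explicit map entries override truncation. Names carrying hybrid or open
#' nomenclature markers (`" x "`, `"sp."`, `"cf."`) are never truncated and
#' are flagged for manual review instead.
#'
#' @param rs a `record_set`.
#' @param map a `species_name_map` (default: empty).
#' @param trinomial_truncation truncate trinomials to binomials? Default `TRUE`.
#' @return list with `record_set` (renamed), `report` (old -> new counts) and
#'   `flagged` (names needing manual review).
#' @export
standardise_spp_names <- function(rs, map = load_species_name_map(),
                                  trinomial_truncation = TRUE) {
  stopifnot(inherits(rs, "record_set"), inherits(map, "species_name_map"))
  old <- rs$records$organism_raw
  new <- old
  flagged <- character(0)
  for (i in seq_along(old)) {
    nm <- trimws(old[[i]])
    j <- match(nm, map$map$observed_name)
    if (!is.na(j)) { new[[i]] <- map$map$canonical_name[[j]]; next }
    if (grepl("(^|\\s)(x|sp\\.|cf\\.)(\\s|$)", nm, ignore.case = TRUE)) {
      flagged <- c(flagged, nm)
      next
    }
    tok <- strsplit(nm, "\\s+")[[1]]
    if (trinomial_truncation && length(tok) >= 3L)
      new[[i]] <- paste(tok[1:2], collapse = " ")
  }
  changed <- new != old
  if (any(changed)) {
    agg <- as.data.frame(table(old = old[changed], new = new[changed]),
                         stringsAsFactors = FALSE)
    report <- agg[agg$Freq > 0L, , drop = FALSE]
    names(report) <- c("old", "new", "n")
    rownames(report) <- NULL
  } else {
    report <- data.frame(old = character(0), new = character(0), n = integer(0))
  }
  rs$records$organism_raw <- new
  if (length(unique(flagged)))
    message("organism name(s) flagged for manual review: ",
            paste(unique(flagged), collapse = ", "))
  list(record_set = rs, report = report, flagged = unique(flagged))
}

#' Restrict records and items to a single gene of interest
#'
#' With `drop_other_genes`, items standardised to a different gene are
#' removed; with `require_gene`, records that carry no item for the gene are
#' removed (together with their features). Redundant items for the same
#' (accession, gene) pair — for example a `gene` and a `CDS` tag annotating
#' the same gene — collapse to one, preferring `gene` over `CDS` over other
#' tag kinds.
#'
#' @param rs a `record_set`.
#' @param items standardised feature items.
#' @param gene a standard gene name present in the conversion table.
#' @param drop_other_genes drop items for other genes? Default `TRUE`.
#' @param require_gene drop records lacking the gene? Default `TRUE`.
#' @param table conversion table used to validate `gene`.
#' @return list with `record_set` and `items`.
#' @export
gene_of_interest <- function(rs, items, gene, drop_other_genes = TRUE,
                             require_gene = TRUE,
                             table = load_gene_conversion_table()) {
  stopifnot(inherits(rs, "record_set"), is.data.frame(items))
  if (!gene %in% table$table$standard_name)
    stop("gene not in conversion table: ", gene)
  std <- ifelse(nzchar(items$gene_name_std), items$gene_name_std,
                items$gene_name_raw)
  if (drop_other_genes) {
    items <- items[std == gene, , drop = FALSE]
    std <- std[std == gene]
  }
  # collapse duplicates per (accession, standard name): gene > CDS > others
  pref <- match(items$feature_kind, c("gene", "CDS", "misc", "other"))
  pref[is.na(pref)] <- 5L
  ord <- order(items$accession_id, std, pref)
  items <- items[ord, , drop = FALSE]
  std <- std[ord]
  items <- items[!duplicated(paste(items$accession_id, std, sep = "\r")), ,
                 drop = FALSE]
  rownames(items) <- NULL
  if (require_gene) {
    std2 <- ifelse(nzchar(items$gene_name_std), items$gene_name_std,
                   items$gene_name_raw)
    with_gene <- unique(items$accession_id[std2 == gene])
    rs <- subset_records(rs, with_gene, paste0("gene_of_interest:", gene))
    items <- items[items$accession_id %in% with_gene, , drop = FALSE]
    rownames(items) <- NULL
  }
  list(record_set = rs, items = items)
}
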