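# Sequence input/output and taxonomy-aware filtering.

#' Read a multi-FASTA file into a sequence record table
#'
#' Loads DNA sequences from a (possibly line-wrapped) multi-FASTA file into a
#' tibble with one row per record. Bases are stored uppercase; ambiguity codes
#' such as `N` are retained and handled downstream at p-mer counting time.
#'
#' With `header_dialect = "greengenes"` the description line is scanned for
#' taxonomy annotations of two kinds: lineage fields with rank prefixes
#' (`k__Bacteria; p__Fusobacteria; ...`) and `key=value` fields. Both are
#' collected into the per-record `taxonomy` list column (a named character
#' vector, name = rank). Anything that does not parse stays verbatim in
#' `description`; parsing is lossless.
#'
#' @param path Path to a FASTA file.
#' @param header_dialect `"plain"` (default; no taxonomy parsing) or
#'   `"greengenes"`.
#' @return A tibble of class `seq_records` with columns `id`, `description`,
#'   `bases` and list column `taxonomy`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a k__Bacteria; p__Fusobacteria", "ACGTACGT"), fa)
#' read_fasta(fa, header_dialect = "greengenes")
#' @export
read_fasta <- function(path, header_dialect = c("plain", "greengenes")) {
  header_dialect <- match.arg(header_dialect)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) > 0 && !startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("Malformed FASTA: sequence data before any '>' header at line ",
         nonblank[1], " of ", path, call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop("Malformed FASTA: empty record id in ", path, call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("Duplicate sequence ids in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  taxonomy <- if (header_dialect == "greengenes") {
    lapply(desc, parse_greengenes_header)
  } else {
    rep(list(character(0)), length(ids))
  }
  new_seq_records(
    id = ids,
    description = desc,
    bases = toupper(as.character(set)),
    taxonomy = taxonomy
  )
}

new_seq_records <- function(id, description, bases, taxonomy) {
  stopifnot(length(id) == length(bases))
  out <- tibble::tibble(
    id = as.character(id),
    description = as.character(description),
    bases = toupper(as.character(bases)),
    taxonomy = taxonomy
  )
  class(out) <- c("seq_records", class(out))
  out
}

#' Construct a sequence record table from in-memory strings
#'
#' @param bases Named character vector of sequences (names become ids) or an
#'   unnamed vector (ids `seq1`, `seq2`, ...).
#' @param description Optional character vector of descriptions.
#' @param taxonomy Optional list of named character vectors (rank -> value).
#' @return A `seq_records` tibble.
#' @export
seq_records <- function(bases, description = NULL, taxonomy = NULL) {
  ids <- names(bases)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(bases))
  if (anyDuplicated(ids)) {
    stop("Duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(description)) description <- rep("", length(bases))
  if (is.null(taxonomy)) taxonomy <- rep(list(character(0)), length(bases))
  new_seq_records(ids, description, bases, taxonomy)
}

# Greengenes-style header grammar (tolerant): rank-prefixed lineage tokens
# ("k__X", "p__Y", ..., separated by ';') plus "key=value" fields. Tokens that
# match neither form are ignored here and survive in `description`.
.gg_ranks <- c(
  k = "kingdom", p = "phylum", c = "class", o = "order",
  f = "family", g = "genus", s = "species"
)

parse_greengenes_header <- function(description) {
  tax <- character(0)
  if (!nzchar(description)) return(tax)
  tokens <- trimws(strsplit(description, "[;,]")[[1]])
  for (tok in tokens) {
    if (grepl("^[kpcofgs]__", tok)) {
      rank <- .gg_ranks[[substr(tok, 1, 1)]]
      value <- trimws(substring(tok, 4))
      if (nzchar(value)) tax[rank] <- value
    } else if (grepl("^[^=[:space:]]+=[^=]*$", tok)) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      tax[trimws(kv[1])] <- trimws(kv[2])
    }
  }
  tax
}

#' Filter sequence records by a taxonomic rank value
#'
#' Keeps the records whose taxonomy at `rank` equals `value` (exact match,
#' case-insensitive). Records lacking the rank never match. Input order is
#' preserved; an empty result is valid.
#'
#' @param records A `seq_records` tibble.
#' @param rank Rank name, e.g. `"phylum"`.
#' @param value Value to match, e.g. `"Fusobacteria"`.
#' @return The matching subset of `records`.
#' @export
filter_by_taxon <- function(records, rank, value) {
  stopifnot(is.character(rank), length(rank) == 1L,
            is.character(value), length(value) == 1L)
  hit <- vapply(records$taxonomy, function(tax) {
    !is.null(tax) && rank %in% names(tax) &&
      tolower(tax[[rank]]) == tolower(value)
  }, logical(1))
  records[hit, ]
}

#' Write sequence records to a multi-FASTA file
#'
#' Headers are `id` followed by `description` when non-empty. Round-trips with
#' [read_fasta()] on (`id`, `bases`).
#'
#' @param records A `seq_records` tibble.
#' @param path Output file path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::DNAStringSet(records$bases)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Write a TSV manifest of a sequence collection
#'
#' One row per record with `id`, `length`, then one column per taxonomy rank
#' present anywhere in the collection (empty string where a record lacks the
#' rank).
#'
#' @param records A `seq_records` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sequence_manifest <- function(records, path) {
  ranks <- unique(unlist(lapply(records$taxonomy, names)))
  out <- data.frame(
    id = records$id,
    length = nchar(records$bases),
    stringsAsFactors = FALSE
  )
  for (r in ranks) {
    out[[r]] <- vapply(records$taxonomy, function(tax) {
      if (r %in% names(tax)) tax[[r]] else ""
    }, character(1))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
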