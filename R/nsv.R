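# Segmentation and numerical summarization vectors (NSVs).

#' Segmentation and p-mer parameters
#'
#' Controls how sequences are cut into segments and summarized. The defaults —
#' 100-base non-overlapping segments counted with 3-mers — are the standard
#' operating point for 16S rRNA scale sequences: 3-mers give 64-dimensional
#' count vectors that approximate segment similarity well while staying cheap
#' to compare.
#'
#' @param l Segment length in bases (default 100).
#' @param stride Distance between consecutive segment starts; `stride = l`
#'   (the default) gives non-overlapping segments. `stride < l` produces
#'   overlapping segments; downstream consensus calling over overlapping
#'   segments is supported but experimental, since segment ordinals no longer
#'   tile the sequence.
#' @param p Word (p-mer) size; count vectors have length `4^p` (default 3).
#' @param drop_partial Drop a trailing window shorter than `l` (default TRUE),
#'   so every NSV summarizes the same number of windows and distances stay
#'   comparable.
#' @return An object of class `segment_spec`.
#' @export
segment_spec <- function(l = 100L, stride = l, p = 3L, drop_partial = TRUE) {
  l <- as.integer(l); stride <- as.integer(stride); p <- as.integer(p)
  if (p < 1L) stop("word size p must be >= 1", call. = FALSE)
  if (l < p) stop("segment length l must be >= word size p", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  structure(
    list(l = l, stride = stride, p = p, drop_partial = isTRUE(drop_partial)),
    class = "segment_spec"
  )
}

#' @export
print.segment_spec <- function(x, ...) {
  cat(sprintf("segment_spec: l=%d stride=%d p=%d drop_partial=%s\n",
              x$l, x$stride, x$p, x$drop_partial))
  invisible(x)
}

#' Cut one sequence into position-tracked segments
#'
#' Segments start at 1-based positions 1, 1+stride, 1+2*stride, ... and each
#' spans exactly `l` bases (with `drop_partial = FALSE`, a trailing shorter
#' window is kept). A sequence shorter than `l` yields zero segments with a
#' warning, not an error, so whole-collection processing is never aborted by
#' one short sequence.
#'
#' @param record A single-row `seq_records` tibble, or a list/row with fields
#'   `id` and `bases`.
#' @param spec A [segment_spec()].
#' @return A tibble with columns `seq_id`, `start`, `end` (1-based inclusive),
#'   `index` (0-based segment ordinal) and `bases`.
#' @export
segment_sequence <- function(record, spec = segment_spec()) {
  id <- as.character(record$id)[1]
  bases <- toupper(as.character(record$bases)[1])
  L <- nchar(bases)
  empty <- tibble::tibble(
    seq_id = character(0), start = integer(0), end = integer(0),
    index = integer(0), bases = character(0)
  )
  if (L < spec$l) {
    if (spec$drop_partial || L < spec$p) {
      warning("sequence '", id, "' is shorter (", L,
              " bases) than segment length l=", spec$l, "; skipped",
              call. = FALSE)
      return(empty)
    }
  }
  starts <- seq.int(1L, L, by = spec$stride)
  ends <- pmin(starts + spec$l - 1L, L)
  keep <- if (spec$drop_partial) {
    (ends - starts + 1L) == spec$l
  } else {
    (ends - starts + 1L) >= spec$p  # too short to hold a single p-mer: drop
  }
  starts <- starts[keep]; ends <- ends[keep]
  tibble::tibble(
    seq_id = rep(id, length(starts)),
    start = as.integer(starts),
    end = as.integer(ends),
    index = seq_along(starts) - 1L,
    bases = substring(bases, starts, ends)
  )
}

#' Compute the p-mer count vector (NSV) of a segment
#'
#' Counts every length-`p` window of the segment into the `4^p` bins indexed
#' by p-mer in lexicographic order over A < C < G < T. Windows containing any
#' character outside `{A,C,G,T}` (e.g. `N`) are counted in no bin, so for a
#' clean segment the counts sum to `length - p + 1`. Counting is
#' case-insensitive and strand-specific (no reverse-complement collapsing).
#'
#' @param segment A segment's bases as a character scalar, or a row from
#'   [segment_sequence()] (anything with a `bases` field).
#' @param p Word size; must not exceed the segment length.
#' @return Named integer vector of length `4^p`.
#' @examples
#' compute_nsv("ACGT", p = 3)  # ACG = 1, CGT = 1
#' @export
compute_nsv <- function(segment, p = 3L) {
  bases <- if (is.character(segment)) segment[1] else as.character(segment$bases)[1]
  p <- as.integer(p)
  if (p < 1L) stop("word size p must be >= 1", call. = FALSE)
  if (nchar(bases) < p) {
    stop("word size p=", p, " exceeds segment length ", nchar(bases),
         call. = FALSE)
  }
  Biostrings::oligonucleotideFrequency(Biostrings::DNAString(toupper(bases)), p)
}

#' GC fraction of a DNA string
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; ambiguity characters are excluded from
#' both numerator and denominator. Returns 0 for a string with no unambiguous
#' bases.
#'
#' @param bases Character vector of DNA strings.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_fraction <- function(bases) {
  set <- Biostrings::DNAStringSet(toupper(bases))
  counts <- Biostrings::letterFrequency(set, letters = c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  ifelse(denom == 0, 0, (counts[, "C"] + counts[, "G"]) / denom)
}

#' Build the ordered NSV stream for a sequence collection
#'
#' Segments every sequence and computes all NSVs, preserving stream order:
#' sequence by sequence in input order, and within a sequence in segment
#' order. This ordered stream is the input to [build_genmodel()].
#'
#' @param records A `seq_records` tibble (or anything with `id` and `bases`
#'   columns).
#' @param spec A [segment_spec()].
#' @return An object of class `nsv_stream`: a list with `counts` (integer
#'   matrix, one row per segment, `4^p` p-mer columns), `segments` (tibble
#'   with `seq_id`, `start`, `end`, `index`, `gc_fraction`) and `spec`.
#' @export
nsv_stream <- function(records, spec = segment_spec()) {
  segs <- lapply(seq_len(nrow(records)), function(i) {
    segment_sequence(records[i, ], spec)
  })
  segs <- if (length(segs) == 0) NULL else do.call(rbind, segs)
  if (is.null(segs) || nrow(segs) == 0) {
    counts <- matrix(0L, nrow = 0, ncol = 4^spec$p,
                     dimnames = list(NULL, all_pmers(spec$p)))
    segments <- tibble::tibble(
      seq_id = character(0), start = integer(0), end = integer(0),
      index = integer(0), gc_fraction = numeric(0)
    )
  } else {
    set <- Biostrings::DNAStringSet(segs$bases)
    counts <- Biostrings::oligonucleotideFrequency(set, spec$p)
    segments <- tibble::tibble(
      seq_id = segs$seq_id, start = segs$start, end = segs$end,
      index = segs$index, gc_fraction = gc_fraction(segs$bases)
    )
  }
  structure(list(counts = counts, segments = segments, spec = spec),
            class = "nsv_stream")
}

#' @export
print.nsv_stream <- function(x, ...) {
  cat(sprintf("nsv_stream: %d NSVs (%d-dim, p=%d) from %d sequence(s)\n",
              nrow(x$counts), ncol(x$counts), x$spec$p,
              length(unique(x$segments$seq_id))))
  invisible(x)
}

#' All p-mers in lexicographic order
#'
#' @param p Word size.
#' @return Character vector of the `4^p` p-mers, A < C < G < T.
#' @export
all_pmers <- function(p) {
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), p)
}

#' Export an NSV stream as TSV
#'
#' Columns: `seq_id`, `start`, `end`, `index`, `gc_fraction`, then one count
#' column per p-mer (lexicographic order), reproducible bit-for-bit.
#'
#' @param stream An [nsv_stream()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_nsv_tsv <- function(stream, path) {
  out <- cbind(
    as.data.frame(stream$segments),
    as.data.frame(stream$counts)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
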