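# Synthetic sequence families with planted conserved windows, and the
# dynamic-programming edit distance used as a test oracle.

#' Specification of a synthetic sequence family
#'
#' Describes a family of sequences derived from one random ancestor:
#' designated segment windows are copied verbatim into every descendant
#' (planted conserved regions) while every other ("background") window
#' receives a fixed number of random point substitutions, and optionally
#' indels. The defaults describe the standard benchmark family: 20 sequences
#' of 10 non-overlapping 100-base segments with 3 planted conserved windows,
#' and 15 substitutions per background segment — enough divergence that
#' background segments from different descendants rarely fall within
#' Manhattan distance 30 of each other (a substitution moves a 3-mer profile
#' by at most 6), so only the planted windows co-cluster across the whole
#' family.
#'
#' Background divergence is an exact substitution count per segment rather
#' than a rate, so the separation between planted and background windows can
#' be engineered precisely.
#'
#' @param n_sequences Number of descendant sequences (default 20).
#' @param n_segments Number of segment windows per sequence (default 10).
#' @param segment_length Window length in bases (default 100).
#' @param conserved_windows 0-based ordinals of the windows copied verbatim
#'   (default `c(2, 5, 8)`).
#' @param n_substitutions Exact substitutions applied per background window
#'   (default 15).
#' @param indel_rate Per-base insertion/deletion probability in background
#'   windows (default 0). Indels shift all downstream coordinates, so with
#'   a positive rate the planted windows no longer sit on the segment grid —
#'   the documented failure mode of non-overlapping segmentation.
#' @param seed Integer RNG seed; all randomness flows from it.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_sequences = 20L, n_segments = 10L,
                        segment_length = 100L,
                        conserved_windows = c(2L, 5L, 8L),
                        n_substitutions = 15L, indel_rate = 0,
                        seed = 1L) {
  conserved_windows <- sort(unique(as.integer(conserved_windows)))
  if (length(conserved_windows) > 0 &&
      (min(conserved_windows) < 0L || max(conserved_windows) >= n_segments)) {
    stop("conserved_windows must lie in [0, n_segments)", call. = FALSE)
  }
  if (n_substitutions > segment_length) {
    stop("n_substitutions cannot exceed segment_length", call. = FALSE)
  }
  if (indel_rate < 0 || indel_rate > 1) {
    stop("indel_rate must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_sequences = as.integer(n_sequences),
    n_segments = as.integer(n_segments),
    segment_length = as.integer(segment_length),
    conserved_windows = conserved_windows,
    n_substitutions = as.integer(n_substitutions),
    indel_rate = as.numeric(indel_rate),
    seed = as.integer(seed)
  ), class = "family_spec")
}

#' Generate a synthetic sequence family with planted conserved windows
#'
#' Draws one uniform-random ancestor of `n_segments * segment_length` bases,
#' then derives each family member window by window: conserved windows are
#' copied verbatim, background windows get exactly `n_substitutions` random
#' substitutions (each to a different base) and, if `indel_rate > 0`,
#' per-base insertions/deletions. Deterministic for a given `spec$seed`; the
#' caller's RNG state is left untouched.
#'
#' @param spec A [family_spec()].
#' @return List with `records` (a `seq_records` tibble, ids `fam1`,
#'   `fam2`, ...), `truth` (tibble of planted conserved intervals in 1-based
#'   ancestor coordinates: `label`, `start`, `end`) and `ancestor` (the
#'   ancestral sequence string).
#' @export
generate_family <- function(spec = family_spec()) {
  with_preserved_seed(spec$seed, {
    alph <- c("A", "C", "G", "T")
    sl <- spec$segment_length
    ancestor_segs <- vapply(seq_len(spec$n_segments), function(i) {
      paste(sample(alph, sl, replace = TRUE), collapse = "")
    }, character(1))
    conserved <- (seq_len(spec$n_segments) - 1L) %in% spec$conserved_windows

    derive <- function() {
      segs <- vapply(seq_len(spec$n_segments), function(j) {
        if (conserved[j]) return(ancestor_segs[j])
        s <- strsplit(ancestor_segs[j], "", fixed = TRUE)[[1]]
        pos <- sample.int(sl, spec$n_substitutions)
        for (q in pos) {
          s[q] <- sample(setdiff(alph, s[q]), 1L)
        }
        if (spec$indel_rate > 0) {
          out <- character(0)
          for (base in s) {
            r <- stats::runif(1)
            if (r < spec$indel_rate / 2) {
              # deletion: skip the base
            } else if (r < spec$indel_rate) {
              out <- c(out, base, sample(alph, 1L))  # insertion after base
            } else {
              out <- c(out, base)
            }
          }
          s <- out
        }
        paste(s, collapse = "")
      }, character(1))
      paste(segs, collapse = "")
    }

    bases <- vapply(seq_len(spec$n_sequences), function(i) derive(),
                    character(1))
    names(bases) <- paste0("fam", seq_len(spec$n_sequences))
    truth <- tibble::tibble(
      label = paste0("conserved_", seq_along(spec$conserved_windows)),
      start = 1L + spec$conserved_windows * sl,
      end = spec$conserved_windows * sl + sl
    )
    list(records = seq_records(bases), truth = truth,
         ancestor = paste(ancestor_segs, collapse = ""))
  })
}

#' Write a synthetic family to FASTA plus a ground-truth BED
#'
#' @param family Output of [generate_family()].
#' @param fasta_path Output FASTA path.
#' @param bed_path Output BED path for the planted conserved windows
#'   (0-based half-open).
#' @return `fasta_path`, invisibly.
#' @export
write_family <- function(family, fasta_path, bed_path = NULL) {
  write_fasta(family$records, fasta_path)
  if (!is.null(bed_path)) {
    bed <- data.frame(
      chrom = "ancestor",
      start = family$truth$start - 1L,
      end = family$truth$end,
      name = family$truth$label
    )
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}

#' Unit-cost Levenshtein edit distance
#'
#' Standard Wagner-Fischer dynamic program over insertions, deletions and
#' substitutions, kept in the package as the independent oracle for the
#' q-gram lower-bound property (see [edit_distance_lower_bound()]).
#'
#' @param s1,s2 Character scalars.
#' @return Integer edit distance.
#' @examples
#' levenshtein("ACGT", "ACGA")  # 1
#' @export
levenshtein <- function(s1, s2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1] <- i
    cost <- as.integer(a[i] != b)
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L,  # deletion
                         cur[j] + 1L,        # insertion
                         prev[j] + cost[j])  # substitution/match
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Apply random point mutations to a DNA string
#'
#' Helper for building mutated test pairs: applies `n_sub` substitutions and
#' `n_indel` single-base insertions or deletions at random positions.
#' Randomness uses the current RNG state.
#'
#' @param bases DNA string.
#' @param n_sub Number of substitutions.
#' @param n_indel Number of single-base indels.
#' @return Mutated string.
#' @export
mutate_string <- function(bases, n_sub = 0L, n_indel = 0L) {
  alph <- c("A", "C", "G", "T")
  s <- strsplit(bases, "", fixed = TRUE)[[1]]
  if (n_sub > 0L) {
    pos <- sample.int(length(s), min(n_sub, length(s)))
    for (q in pos) s[q] <- sample(setdiff(alph, s[q]), 1L)
  }
  if (n_indel > 0L) {
    for (k in seq_len(n_indel)) {
      if (length(s) > 1L && stats::runif(1) < 0.5) {
        s <- s[-sample.int(length(s), 1L)]
      } else {
        at <- sample.int(length(s) + 1L, 1L)
        s <- append(s, sample(alph, 1L), after = at - 1L)
      }
    }
  }
  paste(s, collapse = "")
}
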