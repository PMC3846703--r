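# Conserved-region discovery from a GenModel: cluster ranking, per-segment
# consensus, region calling, and hypervariable-region annotation.

#' The k strongest quasi-alignments
#'
#' Ranks clusters by size (number of member segments) in decreasing order,
#' breaking ties by lower cluster id, and returns the top `k` rows. Strong
#' quasi-alignments — clusters most sequences pass through — are the
#' candidate conserved regions.
#'
#' @param model A `genmodel`.
#' @param k Number of clusters to return (at least 1); capped at the number
#'   of clusters in the model.
#' @return Tibble with columns `cluster_id`, `size`, `mean_gc`, ordered by
#'   rank.
#' @export
top_quasialignments <- function(model, k = 5L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  tab <- cluster_summary(model)
  if (nrow(tab) == 0L) return(tab)
  ord <- order(-tab$size, tab$cluster_id)
  tab[ord[seq_len(min(k, nrow(tab)))], ]
}

#' Per-segment-index consensus profile
#'
#' For every segment ordinal `j` (0-based) present in any sequence, finds the
#' *modal cluster* — the quasi-alignment holding the segments at index `j` of
#' the largest number of sequences — and the *consensus*: the fraction of
#' sequences having a segment at index `j` whose segment lies in that
#' cluster. Each sequence contributes at most one segment per index; ties in
#' the modal cluster go to the lower cluster id. High consensus at an index
#' means the corresponding stretch of bases is highly similar across the
#' family: a conserved region.
#'
#' With overlapping segments (stride < l) indices no longer tile the
#' sequence; the profile is still computed per ordinal but base-coordinate
#' interpretation is approximate.
#'
#' @param model A `genmodel` built from at least one sequence.
#' @return Tibble of class `consensus_profile` with columns `index`,
#'   `modal_cluster`, `n_sequences` (sequences with a segment at that index),
#'   `consensus`, plus attribute `segment_spec`.
#' @export
consensus_profile <- function(model) {
  mem <- model$members
  if (nrow(mem) == 0L) stop("model has no segments", call. = FALSE)
  idx <- sort(unique(mem$index))
  rows <- lapply(idx, function(j) {
    at_j <- mem[mem$index == j, ]
    # one segment per sequence per index (duplicates impossible for stride
    # >= 1, but guard anyway)
    at_j <- at_j[!duplicated(at_j$seq_id), ]
    counts <- table(at_j$cluster_id)
    modal <- as.integer(names(counts)[order(-counts, as.integer(names(counts)))[1]])
    tibble::tibble(
      index = j,
      modal_cluster = modal,
      n_sequences = nrow(at_j),
      consensus = max(counts) / nrow(at_j)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "segment_spec") <- model$segment_spec
  class(out) <- c("consensus_profile", class(out))
  out
}

#' Call conserved regions from a consensus profile
#'
#' A conserved region is a maximal run of consecutive segment indices whose
#' consensus is at least `min_consensus`, converted to 1-based inclusive base
#' coordinates: index `j` spans bases `1 + j*stride` to `j*stride + l`, and
#' adjacent qualifying indices merge into one region.
#'
#' The default `min_consensus = 0.9` calls an index conserved when at most
#' about one sequence in ten escapes the modal quasi-alignment — for a family
#' of a dozen sequences, "all except one". Raising the threshold can only
#' shrink or drop regions, never enlarge them.
#'
#' @param profile A [consensus_profile()].
#' @param min_consensus Calling threshold in (0, 1].
#' @param spec The [segment_spec()] used to build the model; defaults to the
#'   one carried by the profile.
#' @return Tibble with columns `start`, `end` (1-based inclusive),
#'   `index_first`, `index_last`, `min_region_consensus`, `cluster_ids`
#'   (comma-separated modal clusters of the covered indices). Regions are
#'   disjoint and sorted.
#' @export
call_conserved_regions <- function(profile, min_consensus = 0.9,
                                   spec = attr(profile, "segment_spec")) {
  if (!is.numeric(min_consensus) || length(min_consensus) != 1L ||
      min_consensus <= 0 || min_consensus > 1) {
    stop("min_consensus must be in (0, 1]", call. = FALSE)
  }
  if (is.null(spec)) stop("no segment_spec available", call. = FALSE)
  empty <- tibble::tibble(
    start = integer(0), end = integer(0), index_first = integer(0),
    index_last = integer(0), min_region_consensus = numeric(0),
    cluster_ids = character(0)
  )
  qual <- profile[profile$consensus >= min_consensus, ]
  if (nrow(qual) == 0L) return(empty)
  idx <- qual$index
  run_id <- cumsum(c(1L, diff(idx) != 1L))
  rows <- lapply(split(seq_len(nrow(qual)), run_id), function(rs) {
    block <- qual[rs, ]
    tibble::tibble(
      start = 1L + min(block$index) * spec$stride,
      end = max(block$index) * spec$stride + spec$l,
      index_first = min(block$index),
      index_last = max(block$index),
      min_region_consensus = min(block$consensus),
      cluster_ids = paste(block$modal_cluster, collapse = ",")
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$start), ]
}

#' Built-in 16S rRNA hypervariable region annotation (V1-V9)
#'
#' The nine hypervariable regions of the bacterial 16S rRNA gene in 1-based
#' inclusive nucleotide coordinates. Hypervariable regions differ between
#' species while their flanking stretches are conserved across broad clades,
#' so conserved regions discovered in mixed-species 16S families are expected
#' to fall between these intervals.
#'
#' @return Tibble with columns `label`, `start`, `end`.
#' @export
v_regions <- function() {
  tibble::tibble(
    label = paste0("V", 1:9),
    start = c(69L, 137L, 433L, 576L, 822L, 986L, 1117L, 1243L, 1435L),
    end = c(99L, 242L, 497L, 682L, 879L, 1043L, 1173L, 1294L, 1465L)
  )
}

#' Overlap report between conserved regions and labeled intervals
#'
#' For every conserved region, lists each annotation interval that shares at
#' least one base (`relation = "overlap"`, with the overlap width) and the
#' nearest non-overlapping annotation on each side (`relation = "upstream"` /
#' `"downstream"`, with the gap in bases between them).
#'
#' @param regions Output of [call_conserved_regions()] (needs `start`, `end`).
#' @param annotations Tibble/data.frame with `label`, `start`, `end` (1-based
#'   inclusive); defaults to the built-in [v_regions()].
#' @return Tibble with columns `region_start`, `region_end`, `label`,
#'   `relation`, `overlap_bp`, `gap_bp`.
#' @export
annotate_hypervariable <- function(regions, annotations = v_regions()) {
  if (any(annotations$end < annotations$start)) {
    bad <- which(annotations$end < annotations$start)
    stop("malformed annotation interval (end < start): ",
         paste(annotations$label[bad], collapse = ", "), call. = FALSE)
  }
  empty <- tibble::tibble(
    region_start = integer(0), region_end = integer(0), label = character(0),
    relation = character(0), overlap_bp = integer(0), gap_bp = integer(0)
  )
  if (nrow(regions) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    rs <- regions$start[i]; re <- regions$end[i]
    ov_bp <- pmin(re, annotations$end) - pmax(rs, annotations$start) + 1L
    hit <- ov_bp >= 1L
    out <- list()
    if (any(hit)) {
      out$overlap <- tibble::tibble(
        region_start = rs, region_end = re,
        label = annotations$label[hit], relation = "overlap",
        overlap_bp = as.integer(ov_bp[hit]), gap_bp = 0L
      )
    }
    up <- which(!hit & annotations$end < rs)
    if (length(up) > 0L) {
      j <- up[which.max(annotations$end[up])]
      out$up <- tibble::tibble(
        region_start = rs, region_end = re,
        label = annotations$label[j], relation = "upstream",
        overlap_bp = 0L, gap_bp = as.integer(rs - annotations$end[j] - 1L)
      )
    }
    down <- which(!hit & annotations$start > re)
    if (length(down) > 0L) {
      j <- down[which.min(annotations$start[down])]
      out$down <- tibble::tibble(
        region_start = rs, region_end = re,
        label = annotations$label[j], relation = "downstream",
        overlap_bp = 0L, gap_bp = as.integer(annotations$start[j] - re - 1L)
      )
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}
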