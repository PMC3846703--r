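# GenModel: single-pass data-stream clustering of the NSV stream into
# quasi-alignments plus a directed transition graph.

#' Build a GenModel by single-pass stream clustering of NSVs
#'
#' Processes the NSV stream in order, exactly once. Each NSV joins the
#' nearest existing cluster whose center lies within the threshold
#' (`spec$threshold`); ties go to the lowest cluster id. If no cluster
#' qualifies, a new cluster is created with the NSV as its center. On
#' assignment the center is updated according to `update_rule`:
#' `"mean"` (default) keeps the center at the running mean of all member
#' NSVs; `"first"` leaves the founding NSV as a fixed center.
#'
#' A cluster of segments is a *quasi-alignment*: its members have similar
#' p-mer profiles and hence (by the q-gram bound) small edit distance,
#' without ever being aligned. Order information is retained as a directed
#' edge multiset: for every pair of consecutive segments of the same
#' sequence, the transition count from the earlier segment's cluster to the
#' later one's is incremented. Sequence boundaries reset the previous-cluster
#' state, so no edge crosses sequences. The first segment of every sequence
#' increments its cluster's start count.
#'
#' The build is deterministic and order-sensitive: permuting the input
#' sequences may change cluster ids and composition.
#'
#' @param stream An [nsv_stream()].
#' @param spec A [distance_spec()].
#' @param update_rule `"mean"` or `"first"`.
#' @return An object of class `genmodel`: list with `segment_spec`,
#'   `distance_spec`, `update_rule`, `centers` (matrix, one row per cluster),
#'   `sizes`, `mean_gc`, `members` (tibble: `cluster_id`, `seq_id`, `start`,
#'   `end`, `index`, `gc_fraction`), `edges` (tibble: `from`, `to`, `count`),
#'   `start_counts` (named integer vector), `assignment_distances` (numeric,
#'   distance to the chosen center at assignment time; 0 for founders).
#' @export
build_genmodel <- function(stream, spec = distance_spec(),
                           update_rule = c("mean", "first")) {
  update_rule <- match.arg(update_rule)
  model <- empty_genmodel(stream$spec, spec, update_rule)
  cluster_stream(model, stream)
}

empty_genmodel <- function(segment_spec, distance_spec, update_rule) {
  dims <- 4^segment_spec$p
  structure(list(
    segment_spec = segment_spec,
    distance_spec = distance_spec,
    update_rule = update_rule,
    centers = matrix(numeric(0), nrow = 0, ncol = dims,
                     dimnames = list(NULL, all_pmers(segment_spec$p))),
    sizes = integer(0),
    mean_gc = numeric(0),
    members = tibble::tibble(
      cluster_id = integer(0), seq_id = character(0), start = integer(0),
      end = integer(0), index = integer(0), gc_fraction = numeric(0)
    ),
    edges = tibble::tibble(from = integer(0), to = integer(0),
                           count = integer(0)),
    start_counts = integer(0),
    assignment_distances = numeric(0)
  ), class = "genmodel")
}

# Core one-pass clustering. Resumable: called by both build_genmodel() and
# add_sequence() with the model's accumulated state.
cluster_stream <- function(model, stream) {
  n <- nrow(stream$counts)
  if (n == 0L) return(model)
  if (ncol(stream$counts) != ncol(model$centers)) {
    stop("NSV dimensionality ", ncol(stream$counts),
         " does not match model (", ncol(model$centers), ")", call. = FALSE)
  }

  m_max <- nrow(model$centers) + n
  centers <- rbind(model$centers,
                   matrix(NA_real_, nrow = n, ncol = ncol(model$centers)))
  sizes <- c(model$sizes, integer(n))
  gc_sum <- model$mean_gc * model$sizes
  gc_sum <- c(gc_sum, numeric(n))
  m <- nrow(model$centers)

  edges <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(model$edges))) {
    edges[[paste(model$edges$from[i], model$edges$to[i])]] <- model$edges$count[i]
  }
  starts <- new.env(parent = emptyenv())
  for (id in names(model$start_counts)) {
    starts[[id]] <- model$start_counts[[id]]
  }

  seq_ids <- stream$segments$seq_id
  gc <- stream$segments$gc_fraction
  assignment <- integer(n)
  assign_dist <- numeric(n)
  measure <- model$distance_spec$measure
  t_thresh <- model$distance_spec$threshold
  prev_cluster <- NA_integer_
  prev_seq <- NA_character_

  for (i in seq_len(n)) {
    x <- stream$counts[i, ]
    d <- dist_to_centers(x, centers[seq_len(m), , drop = FALSE], measure)
    ok <- which(d <= t_thresh)
    if (length(ok) > 0L) {
      # nearest qualifying cluster; which.min takes the lowest index on ties
      cid <- ok[which.min(d[ok])]
      assign_dist[i] <- d[cid]
      sizes[cid] <- sizes[cid] + 1L
      if (model$update_rule == "mean") {
        centers[cid, ] <- centers[cid, ] + (x - centers[cid, ]) / sizes[cid]
      }
    } else {
      m <- m + 1L
      cid <- m
      centers[cid, ] <- x
      sizes[cid] <- 1L
      assign_dist[i] <- 0
    }
    gc_sum[cid] <- gc_sum[cid] + gc[i]
    assignment[i] <- cid

    if (!is.na(prev_seq) && identical(prev_seq, seq_ids[i])) {
      key <- paste(prev_cluster, cid)
      edges[[key]] <- (if (is.null(edges[[key]])) 0L else edges[[key]]) + 1L
    } else {
      key <- as.character(cid)
      starts[[key]] <- (if (is.null(starts[[key]])) 0L else starts[[key]]) + 1L
    }
    prev_cluster <- cid
    prev_seq <- seq_ids[i]
  }

  centers <- centers[seq_len(m), , drop = FALSE]
  sizes <- sizes[seq_len(m)]
  gc_sum <- gc_sum[seq_len(m)]

  new_members <- tibble::tibble(
    cluster_id = assignment,
    seq_id = seq_ids,
    start = stream$segments$start,
    end = stream$segments$end,
    index = stream$segments$index,
    gc_fraction = gc
  )
  members <- rbind(model$members, new_members)

  ekeys <- ls(edges, sorted = FALSE)
  if (length(ekeys) > 0L) {
    parts <- do.call(rbind, strsplit(ekeys, " ", fixed = TRUE))
    etab <- tibble::tibble(
      from = as.integer(parts[, 1]),
      to = as.integer(parts[, 2]),
      count = vapply(ekeys, function(k) as.integer(edges[[k]]), integer(1),
                     USE.NAMES = FALSE)
    )
    etab <- etab[order(etab$from, etab$to), ]
  } else {
    etab <- model$edges[0, ]
  }

  skeys <- ls(starts, sorted = FALSE)
  start_counts <- vapply(skeys, function(k) as.integer(starts[[k]]), integer(1))
  names(start_counts) <- skeys
  start_counts <- start_counts[order(as.integer(names(start_counts)))]

  model$centers <- centers
  model$sizes <- sizes
  model$mean_gc <- gc_sum / sizes
  model$members <- members
  model$edges <- etab
  model$start_counts <- start_counts
  model$assignment_distances <- c(model$assignment_distances, assign_dist)
  model
}

#' Add sequences to an existing GenModel incrementally
#'
#' Continues the one-pass clustering with the new sequences' NSVs, which is
#' exactly equivalent to having appended them to the original stream
#' (incremental-equals-batch). Sequences shorter than the segment length are
#' skipped with a warning and leave the model unchanged.
#'
#' @param model A `genmodel`.
#' @param records A `seq_records` tibble (one or more sequences).
#' @return The updated `genmodel`.
#' @export
add_sequence <- function(model, records) {
  stream <- nsv_stream(records, model$segment_spec)
  cluster_stream(model, stream)
}

#' Number of clusters (quasi-alignments) in a GenModel
#' @param model A `genmodel`.
#' @return Integer cluster count.
#' @export
n_clusters <- function(model) length(model$sizes)

#' @export
print.genmodel <- function(x, ...) {
  cat(sprintf(
    "genmodel: %d quasi-alignments, %d segments from %d sequence(s)\n",
    n_clusters(x), nrow(x$members), length(unique(x$members$seq_id))))
  cat(sprintf("  l=%d stride=%d p=%d | %s distance, threshold %g, %s centers\n",
              x$segment_spec$l, x$segment_spec$stride, x$segment_spec$p,
              x$distance_spec$measure, x$distance_spec$threshold,
              x$update_rule))
  invisible(x)
}

#' Transition probabilities between quasi-alignments
#'
#' Row-normalizes the transition counts: for every cluster with at least one
#' outgoing transition, the probability of each successor cluster. Terminal
#' clusters (no outgoing transitions) are absent from the result.
#'
#' @param model A `genmodel`.
#' @return Tibble with columns `from`, `to`, `count`, `prob`; `prob` sums to
#'   1 within each `from`.
#' @export
transition_probabilities <- function(model) {
  e <- model$edges
  if (nrow(e) == 0L) {
    return(tibble::tibble(from = integer(0), to = integer(0),
                          count = integer(0), prob = numeric(0)))
  }
  totals <- tapply(e$count, e$from, sum)
  e$prob <- e$count / as.numeric(totals[as.character(e$from)])
  e
}

#' Summary table of quasi-alignments
#'
#' @param model A `genmodel`.
#' @return Tibble with one row per cluster: `cluster_id`, `size`, `mean_gc`.
#' @export
cluster_summary <- function(model) {
  tibble::tibble(
    cluster_id = seq_along(model$sizes),
    size = model$sizes,
    mean_gc = model$mean_gc
  )
}
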