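# Serialization and interchange: GenModel JSON, cluster/region tables,
# BED conversion, and graph exports.

#' Serialize a GenModel to JSON
#'
#' Writes the full model — parameters, clusters with centers and member
#' records, transition edge counts and start counts — as JSON with a fixed
#' key order and full numeric precision, so identical builds produce
#' byte-identical files.
#'
#' @param model A `genmodel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genmodel <- function(model, path) {
  clusters <- lapply(seq_along(model$sizes), function(i) {
    mem <- model$members[model$members$cluster_id == i, ]
    list(
      id = i,
      size = model$sizes[[i]],
      mean_gc = model$mean_gc[[i]],
      center = unname(model$centers[i, ]),
      members = lapply(seq_len(nrow(mem)), function(r) {
        list(seq_id = mem$seq_id[r], start = mem$start[r], end = mem$end[r],
             index = mem$index[r], gc_fraction = mem$gc_fraction[r])
      })
    )
  })
  obj <- list(
    format = "genmodel-json/1",
    params = list(
      segment = list(l = model$segment_spec$l, stride = model$segment_spec$stride,
                     p = model$segment_spec$p,
                     drop_partial = model$segment_spec$drop_partial),
      distance = list(measure = model$distance_spec$measure,
                      threshold = model$distance_spec$threshold),
      update_rule = model$update_rule
    ),
    clusters = clusters,
    edges = lapply(seq_len(nrow(model$edges)), function(r) {
      list(from = model$edges$from[r], to = model$edges$to[r],
           count = model$edges$count[r])
    }),
    start_counts = lapply(names(model$start_counts), function(k) {
      list(cluster = as.integer(k), count = model$start_counts[[k]])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a GenModel from JSON written by [write_genmodel()]
#'
#' @param path Path to a model JSON file.
#' @return A `genmodel`.
#' @export
read_genmodel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "genmodel-json/1")) {
    stop("not a GenModel JSON file: ", path, call. = FALSE)
  }
  sspec <- segment_spec(l = obj$params$segment$l,
                        stride = obj$params$segment$stride,
                        p = obj$params$segment$p,
                        drop_partial = obj$params$segment$drop_partial)
  dspec <- distance_spec(measure = obj$params$distance$measure,
                         threshold = obj$params$distance$threshold)
  model <- empty_genmodel(sspec, dspec, obj$params$update_rule)
  m <- length(obj$clusters)
  if (m > 0L) {
    model$centers <- do.call(rbind, lapply(obj$clusters, function(cl) {
      as.numeric(unlist(cl$center))
    }))
    colnames(model$centers) <- all_pmers(sspec$p)
    model$sizes <- vapply(obj$clusters, function(cl) as.integer(cl$size),
                          integer(1))
    model$mean_gc <- vapply(obj$clusters, function(cl) as.numeric(cl$mean_gc),
                            numeric(1))
    mem <- do.call(rbind, lapply(obj$clusters, function(cl) {
      do.call(rbind, lapply(cl$members, function(mr) {
        tibble::tibble(cluster_id = as.integer(cl$id),
                       seq_id = mr$seq_id, start = as.integer(mr$start),
                       end = as.integer(mr$end), index = as.integer(mr$index),
                       gc_fraction = as.numeric(mr$gc_fraction))
      }))
    }))
    model$members <- mem
  }
  if (length(obj$edges) > 0L) {
    model$edges <- tibble::tibble(
      from = vapply(obj$edges, function(e) as.integer(e$from), integer(1)),
      to = vapply(obj$edges, function(e) as.integer(e$to), integer(1)),
      count = vapply(obj$edges, function(e) as.integer(e$count), integer(1))
    )
  }
  if (length(obj$start_counts) > 0L) {
    sc <- vapply(obj$start_counts, function(s) as.integer(s$count), integer(1))
    names(sc) <- vapply(obj$start_counts, function(s) as.character(s$cluster),
                        character(1))
    model$start_counts <- sc
  }
  model
}

#' Export the cluster membership table as TSV
#'
#' One row per member segment: `cluster_id`, `size`, `mean_gc`, `seq_id`,
#' `start`, `end`, `index`.
#'
#' @param model A `genmodel`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(model, path) {
  mem <- as.data.frame(model$members)
  mem$size <- model$sizes[mem$cluster_id]
  mem$mean_gc <- model$mean_gc[mem$cluster_id]
  out <- mem[order(mem$cluster_id, mem$seq_id, mem$start),
             c("cluster_id", "size", "mean_gc", "seq_id", "start", "end",
               "index")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write conserved regions as BED
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention. The score column carries the region's minimum
#' consensus scaled to 0-1000.
#'
#' @param regions Output of [call_conserved_regions()].
#' @param path Output BED path.
#' @param chrom Chromosome/sequence name for column 1 (the regions live on
#'   the family's shared segment grid, not on one genome).
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, chrom = "family") {
  bed <- data.frame(
    chrom = chrom,
    start = regions$start - 1L,          # 0-based
    end = regions$end,                   # half-open
    name = paste0("conserved_", seq_len(nrow(regions))),
    score = round(1000 * regions$min_region_consensus)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read labeled intervals from BED or 3-column TSV
#'
#' BED input (`.bed`) is converted from 0-based half-open to the package's
#' 1-based inclusive convention; TSV input must have columns
#' `label`, `start`, `end` already 1-based inclusive.
#'
#' @param path Path to a `.bed` or TSV file.
#' @return Tibble with `label`, `start`, `end`.
#' @export
read_annotations <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    tibble::tibble(
      label = if (ncol(bed) >= 4) as.character(bed[[4]]) else
        paste0("interval_", seq_len(nrow(bed))),
      start = as.integer(bed[[2]]) + 1L,
      end = as.integer(bed[[3]])
    )
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    stopifnot(all(c("label", "start", "end") %in% names(tab)))
    tibble::tibble(label = as.character(tab$label),
                   start = as.integer(tab$start), end = as.integer(tab$end))
  }
}

#' Convert a GenModel to an igraph graph
#'
#' Vertices are clusters (attributes: `name` = cluster id, `size` = member
#' count, `mean_gc`, `start_count`); edges carry the transition `count` and
#' row-normalized `weight` (transition probability).
#'
#' @param model A non-empty `genmodel`.
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(model) {
  if (n_clusters(model) == 0L) stop("model is empty", call. = FALSE)
  probs <- transition_probabilities(model)
  verts <- data.frame(
    name = as.character(seq_along(model$sizes)),
    size = model$sizes,
    mean_gc = model$mean_gc,
    start_count = vapply(as.character(seq_along(model$sizes)), function(k) {
      if (k %in% names(model$start_counts)) model$start_counts[[k]] else 0L
    }, integer(1))
  )
  edges <- data.frame(
    from = as.character(probs$from),
    to = as.character(probs$to),
    count = probs$count,
    weight = probs$prob
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Export the GenModel graph as DOT or GraphML
#'
#' @param model A non-empty `genmodel`.
#' @param path Output path; format from extension (`.dot`/`.gv` or
#'   `.graphml`) unless given.
#' @param format `"dot"` or `"graphml"`; default inferred from `path`.
#' @return `path`, invisibly.
#' @export
write_genmodel_graph <- function(model, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
              else "dot"
  }
  g <- as_igraph(model)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
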