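# Visualization: GenModel transition graph, top-k quasi-alignment position
# tracks, and the consensus profile.

#' Plot the GenModel transition graph
#'
#' Draws clusters as circles labeled with their id, circle area proportional
#' to cluster size (number of member segments), and arrows for transitions
#' with line width proportional to the transition probability. The layout is
#' force-directed and deterministic for a given `layout_seed`.
#'
#' @param model A non-empty `genmodel`.
#' @param file Optional output file; format from extension (`.png`, `.svg`,
#'   `.pdf`). When `NULL`, draws on the current device.
#' @param layout_seed Integer seed for the layout.
#' @param vertex_scale Base vertex size multiplier.
#' @return Invisibly, a list with the `igraph` object and the layout matrix,
#'   so callers can inspect exactly what was drawn.
#' @export
plot_genmodel <- function(model, file = NULL, layout_seed = 42L,
                          vertex_scale = 12) {
  if (n_clusters(model) == 0L) {
    stop("cannot plot an empty model (no clusters)", call. = FALSE)
  }
  g <- as_igraph(model)
  coords <- with_preserved_seed(layout_seed, igraph::layout_with_fr(g))
  open_device(file)
  on.exit(if (!is.null(file)) grDevices::dev.off(), add = TRUE)
  sizes <- igraph::V(g)$size
  ew <- if (igraph::ecount(g) > 0) 0.5 + 3 * igraph::E(g)$weight else numeric(0)
  igraph::plot.igraph(
    g, layout = coords,
    vertex.size = vertex_scale * sqrt(sizes / max(sizes)),  # area ~ size
    vertex.label = igraph::V(g)$name,
    vertex.color = "lightsteelblue", vertex.frame.color = "grey30",
    edge.width = ew, edge.arrow.size = 0.4, edge.color = "grey40",
    edge.curved = 0.1
  )
  invisible(list(graph = g, layout = coords))
}

#' Plot member segment positions of the strongest quasi-alignments
#'
#' One horizontal track per sequence; the member segments of the `k` largest
#' clusters are drawn as bars spanning their base coordinates, colored and
#' labeled by cluster id. Annotation intervals (by default the 16S V1-V9
#' hypervariable regions) are drawn as labeled marks along the top. Segments
#' of the same cluster line up vertically when the region is conserved
#' across the family.
#'
#' @param model A non-empty `genmodel`.
#' @param k Number of top clusters to show.
#' @param annotations Optional tibble with `label`, `start`, `end`
#'   (1-based inclusive); `NULL` for none.
#' @return A `ggplot` object.
#' @export
plot_quasialignments <- function(model, k = 5L, annotations = NULL) {
  if (n_clusters(model) == 0L) stop("model is empty", call. = FALSE)
  top <- top_quasialignments(model, k)
  mem <- model$members[model$members$cluster_id %in% top$cluster_id, ]
  mem$cluster <- factor(mem$cluster_id, levels = top$cluster_id)
  seq_levels <- unique(model$members$seq_id)
  mem$seq_y <- as.integer(factor(mem$seq_id, levels = seq_levels))
  p <- ggplot2::ggplot(mem) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$seq_y, yend = .data$seq_y,
                   color = .data$cluster),
      linewidth = 2
    ) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(seq_levels), labels = seq_levels,
      expand = ggplot2::expansion(add = c(0.5, 1.5))
    ) +
    ggplot2::labs(x = "base position", y = NULL,
                  color = "quasi-alignment") +
    ggplot2::theme_minimal()
  if (!is.null(annotations) && nrow(annotations) > 0) {
    ann <- annotations
    ann$y <- length(seq_levels) + 1
    p <- p +
      ggplot2::geom_segment(
        data = ann,
        ggplot2::aes(x = .data$start, xend = .data$end,
                     y = .data$y, yend = .data$y),
        inherit.aes = FALSE, color = "blue", linewidth = 1.2
      ) +
      ggplot2::geom_text(
        data = ann,
        ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$y,
                     label = .data$label),
        inherit.aes = FALSE, vjust = -0.8, size = 3, color = "blue"
      )
  }
  p
}

#' Plot the consensus profile along the sequence
#'
#' Step plot of consensus (fraction of sequences in the modal
#' quasi-alignment) against base position; each segment index is drawn as a
#' flat step across the bases it covers. Peaks at 1.0 mark segments where
#' the whole family converges on one quasi-alignment — candidate conserved
#' regions.
#'
#' @param profile A [consensus_profile()].
#' @param spec The [segment_spec()]; defaults to the one carried by the
#'   profile.
#' @return A `ggplot` object.
#' @export
plot_consensus <- function(profile, spec = attr(profile, "segment_spec")) {
  if (nrow(profile) == 0L) stop("empty consensus profile", call. = FALSE)
  if (is.null(spec)) stop("no segment_spec available", call. = FALSE)
  dat <- tibble::tibble(
    start = 1L + profile$index * spec$stride,
    end = profile$index * spec$stride + spec$l,
    consensus = profile$consensus
  )
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$consensus, yend = .data$consensus),
      linewidth = 1
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "base position", y = "consensus") +
    ggplot2::theme_minimal()
}

#' Save a ggplot to PNG, SVG or PDF
#'
#' @param plot A `ggplot` object.
#' @param file Output path; format from extension.
#' @param width,height Size in inches.
#' @return `file`, invisibly.
#' @export
save_plot <- function(plot, file, width = 8, height = 5) {
  ggplot2::ggsave(file, plot = plot, width = width, height = height,
                  dpi = 150)
  invisible(file)
}

open_device <- function(file, width = 8, height = 6) {
  if (is.null(file)) return(invisible(NULL))
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    png = grDevices::png(file, width = width, height = height, units = "in",
                         res = 150),
    svg = grDevices::svg(file, width = width, height = height),
    pdf = grDevices::pdf(file, width = width, height = height),
    stop("unsupported plot format: .", ext, call. = FALSE)
  )
  invisible(NULL)
}

# Run code with a fixed RNG seed, restoring any pre-existing global RNG
# state afterwards; keeps plotting/layout and the synthetic generator from
# clobbering the caller's random stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
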