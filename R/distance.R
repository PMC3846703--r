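# Distance measures between NSVs and the edit-distance lower bound.

#' Distance measure and clustering threshold
#'
#' Chooses how NSVs are compared during stream clustering and how far an NSV
#' may lie from a cluster center and still join it. The default — Manhattan
#' distance with threshold 30 — has a direct interpretation through the
#' q-gram bound (see [edit_distance_lower_bound()]): with `p = 3`, two
#' segments must differ by an edit distance of at least `30 / (2 * 3) = 5` to
#' be forced into separate clusters.
#'
#' Only the Manhattan threshold carries this calibration; thresholds for the
#' other measures must be chosen empirically.
#'
#' @param measure One of `"manhattan"`, `"euclidean"`, `"squared_euclidean"`,
#'   `"kullback_leibler"`, `"matching_pmers"`.
#' @param threshold Non-negative clustering threshold (default 30).
#' @return An object of class `distance_spec`.
#' @export
distance_spec <- function(measure = c("manhattan", "euclidean",
                                      "squared_euclidean", "kullback_leibler",
                                      "matching_pmers"),
                          threshold = 30) {
  measure <- match.arg(measure)
  threshold <- as.numeric(threshold)
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  structure(list(measure = measure, threshold = threshold),
            class = "distance_spec")
}

#' @export
print.distance_spec <- function(x, ...) {
  cat(sprintf("distance_spec: %s, threshold=%g\n", x$measure, x$threshold))
  invisible(x)
}

#' Manhattan (L1) distance between two count vectors
#'
#' `sum(|x_i - y_i|)`: the number of p-mer occurrences by which two profiles
#' differ. Accepts real-valued vectors so it can compare an NSV against a
#' running-mean cluster center.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
manhattan <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vectors differ in length (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  sum(abs(x - y))
}

#' Lower bound on edit distance from Manhattan NSV distance
#'
#' A single insertion, deletion or substitution destroys at most `p` existing
#' p-mers and creates at most `p` new ones, so it can change the Manhattan
#' distance between two p-mer profiles by at most `2p`. Hence the edit
#' distance between two segments is at least their NSV Manhattan distance
#' divided by `2p`. This converts a clustering threshold into a guaranteed
#' minimum edit separation between segments in different clusters: threshold
#' 30 at `p = 3` means separated segments differ by at least 5 edits.
#'
#' @param d_manhattan Non-negative Manhattan distance between two NSVs.
#' @param p Word size used to build the NSVs.
#' @return `d_manhattan / (2 * p)`.
#' @export
edit_distance_lower_bound <- function(d_manhattan, p) {
  if (any(p < 1)) stop("word size p must be >= 1", call. = FALSE)
  if (any(d_manhattan < 0)) stop("distance must be non-negative", call. = FALSE)
  d_manhattan / (2 * p)
}

#' Distance between an NSV and a vector under a chosen measure
#'
#' Dispatches on `spec$measure`:
#' * `manhattan`, `euclidean`, `squared_euclidean` — the usual vector norms
#'   on raw counts.
#' * `kullback_leibler` — symmetric KL divergence `sum((px - py) *
#'   log(px / py))` on add-one-smoothed frequency vectors, so it is defined
#'   for counts with zeros and symmetric like the other measures.
#' * `matching_pmers` — a shared-word similarity turned into a
#'   dissimilarity: `max(sum(x), sum(y)) - sum(pmin(x, y))`; for two clean
#'   equal-length segments this equals `(l - p + 1)` minus the number of
#'   matching p-mers, so smaller still means more similar and one
#'   thresholding rule serves every measure.
#'
#' Both arguments may be real-valued (cluster centers are running means).
#'
#' @param x,y Numeric vectors of equal length (`4^p`).
#' @param spec A [distance_spec()].
#' @return Non-negative scalar distance.
#' @export
nsv_distance <- function(x, y, spec = distance_spec()) {
  if (length(x) != length(y)) {
    stop("vectors differ in length (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  switch(spec$measure,
    manhattan = sum(abs(x - y)),
    euclidean = sqrt(sum((x - y)^2)),
    squared_euclidean = sum((x - y)^2),
    kullback_leibler = kl_symmetric(x, y),
    matching_pmers = max(sum(x), sum(y)) - sum(pmin(x, y)),
    stop("unknown distance measure: ", spec$measure, call. = FALSE)
  )
}

kl_symmetric <- function(x, y) {
  px <- (x + 1) / sum(x + 1)
  py <- (y + 1) / sum(y + 1)
  sum((px - py) * log(px / py))
}

# Vectorized distances from one NSV to every row of a center matrix; the hot
# path of stream clustering, so the common measures avoid apply().
dist_to_centers <- function(x, centers, measure) {
  if (nrow(centers) == 0L) return(numeric(0))
  switch(measure,
    manhattan = rowSums(abs(sweep(centers, 2L, x))),
    euclidean = sqrt(rowSums(sweep(centers, 2L, x)^2)),
    squared_euclidean = rowSums(sweep(centers, 2L, x)^2),
    kullback_leibler = apply(centers, 1L, kl_symmetric, y = x),
    matching_pmers = {
      sx <- sum(x)
      apply(centers, 1L, function(cen) {
        max(sum(cen), sx) - sum(pmin(cen, x))
      })
    },
    stop("unknown distance measure: ", measure, call. = FALSE)
  )
}
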