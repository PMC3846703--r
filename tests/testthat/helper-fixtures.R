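# Shared fixtures and brute-force oracles, all built in code at test time.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Independent p-mer counting oracle: enumerate windows one by one with
# substring(), no Biostrings involved.
oracle_nsv <- function(bases, p) {
  bases <- toupper(bases)
  pmers <- all_pmers(p)
  counts <- stats::setNames(integer(length(pmers)), pmers)
  for (i in seq_len(nchar(bases) - p + 1)) {
    w <- substring(bases, i, i + p - 1)
    if (w %in% pmers) counts[w] <- counts[w] + 1L
  }
  counts
}

# Manhattan distance oracle: explicit loop.
oracle_manhattan <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(x[i] - y[i])
  s
}

# Hand-built NSV stream from an explicit count matrix, for clustering tests
# with exactly known pairwise distances. All segments pretend to tile one or
# more sequences on a 100-base grid.
fake_stream <- function(counts, seq_ids, p = 3L, l = 100L) {
  index <- integer(length(seq_ids))
  seen <- list()
  for (i in seq_along(seq_ids)) {
    k <- seq_ids[i]
    seen[[k]] <- if (is.null(seen[[k]])) 0L else seen[[k]] + 1L
    index[i] <- seen[[k]]
  }
  colnames(counts) <- all_pmers(p)
  structure(list(
    counts = counts,
    segments = tibble::tibble(
      seq_id = seq_ids,
      start = 1L + index * l,
      end = index * l + l,
      index = index,
      gc_fraction = rep(0.5, length(seq_ids))
    ),
    spec = segment_spec(l = l, p = p)
  ), class = "nsv_stream")
}

# A count row with `total` counts placed in one bin.
one_hot <- function(bin, total, p = 3L) {
  x <- numeric(4^p)
  x[bin] <- total
  x
}

# Random family records where sequences are mild mutants of one ancestor,
# for structural (not recovery) properties.
random_family_records <- function(n_seq, n_bases, n_sub, seed) {
  withr::with_seed(seed, {
    anc <- random_dna(n_bases)
    bases <- vapply(seq_len(n_seq), function(i) {
      mutate_string(anc, n_sub = n_sub)
    }, character(1))
    names(bases) <- paste0("s", seq_len(n_seq))
    seq_records(bases)
  })
}
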