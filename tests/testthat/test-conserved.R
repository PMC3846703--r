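# Minimal hand-built model for ranking/consensus tests: only the fields the
# conserved-region operations read.
toy_model <- function(sizes, members, l = 100L, stride = 100L) {
  structure(list(
    segment_spec = segment_spec(l = l, stride = stride),
    distance_spec = distance_spec(),
    update_rule = "mean",
    sizes = as.integer(sizes),
    mean_gc = rep(0.5, length(sizes)),
    members = members,
    edges = tibble::tibble(from = integer(0), to = integer(0),
                           count = integer(0)),
    start_counts = integer(0)
  ), class = "genmodel")
}

member_rows <- function(cluster_id, seq_id, index, l = 100L) {
  tibble::tibble(
    cluster_id = as.integer(cluster_id), seq_id = seq_id,
    start = 1L + as.integer(index) * l, end = as.integer(index) * l + l,
    index = as.integer(index), gc_fraction = 0.5
  )
}

test_that("top_quasialignments ranks by size with id tie-breaks", {
  m <- toy_model(c(5, 9, 2), member_rows(1, "a", 0))
  expect_equal(top_quasialignments(m, 2)$cluster_id, c(2, 1))
  expect_equal(top_quasialignments(m, 10)$cluster_id, c(2, 1, 3))
  m2 <- toy_model(c(4, 4, 7), member_rows(1, "a", 0))
  expect_equal(top_quasialignments(m2, 3)$cluster_id, c(3, 1, 2))
  expect_error(top_quasialignments(m, 0), "k must be")
})

test_that("top-k on a planted family returns the planted windows' clusters", {
  fam <- generate_family(family_spec(seed = 3))
  model <- build_genmodel(nsv_stream(fam$records))
  top <- top_quasialignments(model, 3)
  expect_equal(unname(top$size), rep(20L, 3))
  planted_idx <- (fam$truth$start - 1L) / 100L
  top_indices <- sort(vapply(top$cluster_id, function(cid) {
    unique(model$members$index[model$members$cluster_id == cid])
  }, integer(1)))
  expect_equal(top_indices, as.integer(planted_idx))
})

test_that("consensus is the modal-cluster fraction per segment index", {
  mem <- rbind(
    member_rows(c(1, 1, 1, 1), paste0("s", 1:4), 0),  # unanimous
    member_rows(c(2, 2, 2, 3), paste0("s", 1:4), 1),  # 3-1 split
    member_rows(c(4, 4, 5, 5), paste0("s", 1:4), 2)   # tie -> lower id
  )
  m <- toy_model(rep(2, 5), mem)
  prof <- consensus_profile(m)
  expect_equal(prof$consensus, c(1, 0.75, 0.5))
  expect_equal(prof$modal_cluster, c(1, 2, 4))
  expect_equal(prof$n_sequences, rep(4L, 3))
})

test_that("consensus depends only on the partition, not on cluster labels", {
  mem <- rbind(
    member_rows(c(1, 1, 2, 2, 2), paste0("s", 1:5), 0),
    member_rows(c(3, 3, 3, 3, 4), paste0("s", 1:5), 1)
  )
  relabel <- c(7L, 9L, 2L, 5L)  # arbitrary bijection
  mem2 <- mem
  mem2$cluster_id <- relabel[mem$cluster_id]
  p1 <- consensus_profile(toy_model(rep(1, 4), mem))
  p2 <- consensus_profile(toy_model(rep(1, 9), mem2))
  expect_equal(p1$consensus, p2$consensus)
})

test_that("identical sequences give consensus 1 at every index", {
  s <- random_dna(600)
  model <- build_genmodel(nsv_stream(seq_records(c(a = s, b = s, c = s))))
  prof <- consensus_profile(model)
  expect_equal(prof$consensus, rep(1, 6))
})

test_that("call_conserved_regions merges adjacent qualifying indices", {
  prof <- tibble::tibble(
    index = 0:3, modal_cluster = 1:4, n_sequences = 10L,
    consensus = c(1.0, 0.4, 1.0, 1.0)
  )
  attr(prof, "segment_spec") <- segment_spec(l = 100, stride = 100)
  regs <- call_conserved_regions(prof, 0.9)
  expect_equal(regs$start, c(1L, 201L))
  expect_equal(regs$end, c(100L, 400L))
  expect_equal(regs$cluster_ids, c("1", "3,4"))
  # disjoint and sorted
  expect_true(all(regs$start[-1] > regs$end[-nrow(regs)]))
  expect_error(call_conserved_regions(prof, 1.2), "min_consensus")
  expect_error(call_conserved_regions(prof, 0), "min_consensus")
})

test_that("all-identical families yield a single full-span region", {
  s <- random_dna(500)
  model <- build_genmodel(nsv_stream(seq_records(c(a = s, b = s))))
  regs <- call_conserved_regions(consensus_profile(model), 1.0)
  expect_equal(nrow(regs), 1)
  expect_equal(regs$start, 1L)
  expect_equal(regs$end, 500L)
})

test_that("raising min_consensus never enlarges a region", {
  withr::with_seed(57, {
    prof <- tibble::tibble(
      index = 0:19, modal_cluster = 1L, n_sequences = 10L,
      consensus = round(runif(20), 2)
    )
  })
  attr(prof, "segment_spec") <- segment_spec()
  cover <- function(regs) sum(regs$end - regs$start + 1)
  thresholds <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  covered <- vapply(thresholds,
                    function(t) cover(call_conserved_regions(prof, t)),
                    numeric(1))
  expect_true(all(diff(covered) <= 0))
})

test_that("planted windows are recovered exactly at full consensus", {
  fam <- generate_family(family_spec(seed = 101))
  model <- build_genmodel(nsv_stream(fam$records))
  regs <- call_conserved_regions(consensus_profile(model), 1.0)
  expect_equal(regs$start, fam$truth$start)
  expect_equal(regs$end, fam$truth$end)
  prof <- consensus_profile(model)
  planted <- prof$index %in% ((fam$truth$start - 1) / 100)
  expect_true(all(prof$consensus[planted] == 1))
  expect_true(all(prof$consensus[!planted] < 1))
})

test_that("hypervariable annotation reports overlaps and flanking gaps", {
  region <- tibble::tibble(start = 901L, end = 1000L,
                           min_region_consensus = 1)
  rep1 <- annotate_hypervariable(region)
  ov <- rep1[rep1$relation == "overlap", ]
  expect_equal(ov$label, "V6")
  expect_equal(ov$overlap_bp, 15L)
  up <- rep1[rep1$relation == "upstream", ]
  expect_equal(up$label, "V5")
  expect_equal(up$gap_bp, 21L)

  # exact coincidence with an annotation is a full-width overlap
  exact <- annotate_hypervariable(
    tibble::tibble(start = 822L, end = 879L, min_region_consensus = 1))
  ov2 <- exact[exact$relation == "overlap", ]
  expect_equal(ov2$label, "V5")
  expect_equal(ov2$overlap_bp, 879L - 822L + 1L)

  # disjoint from everything: no overlap rows
  far <- annotate_hypervariable(
    tibble::tibble(start = 5000L, end = 5100L, min_region_consensus = 1))
  expect_equal(nrow(far[far$relation == "overlap", ]), 0)

  expect_error(
    annotate_hypervariable(region,
                           tibble::tibble(label = "bad", start = 10L,
                                          end = 5L)),
    "malformed")
})
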