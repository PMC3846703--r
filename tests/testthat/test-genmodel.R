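test_that("two identical sequences give one chain of size-2 clusters", {
  s <- random_dna(500)
  rec <- seq_records(c(a = s, b = s))
  model <- build_genmodel(nsv_stream(rec))
  expect_equal(n_clusters(model), 5)
  expect_equal(unname(model$sizes), rep(2L, 5))
  expect_equal(model$edges$from, 1:4)
  expect_equal(model$edges$to, 2:5)
  expect_equal(model$edges$count, rep(2L, 4))
  expect_equal(unname(model$start_counts[["1"]]), 2L)
  # no edge crosses the sequence boundary: last cluster has no out-edge
  expect_false(5L %in% model$edges$from)
})

test_that("mutually distant NSVs each found their own singleton cluster", {
  # one-hot count vectors in different bins are 2 * 98 apart in L1
  counts <- rbind(one_hot(1, 98), one_hot(5, 98), one_hot(9, 98),
                  one_hot(13, 98))
  st <- fake_stream(counts, rep("s1", 4))
  model <- build_genmodel(st, distance_spec(threshold = 30))
  expect_equal(n_clusters(model), 4)
  expect_equal(unname(model$sizes), rep(1L, 4))
})

test_that("a close pair of consecutive NSVs merges with a self-edge", {
  # NSV3 and NSV4 are 20 apart (<= 30); everything else is >= 166 apart
  v3 <- one_hot(9, 98)
  v4 <- one_hot(9, 98); v4[9] <- 88; v4[10] <- 10
  counts <- rbind(one_hot(1, 98), one_hot(5, 98), v3, v4)
  st <- fake_stream(counts, rep("s1", 4))
  model <- build_genmodel(st, distance_spec(threshold = 30))
  expect_equal(n_clusters(model), 3)
  expect_equal(unname(model$sizes), c(1L, 1L, 2L))
  expect_equal(model$edges[order(model$edges$from), ]$from, c(1L, 2L, 3L))
  expect_equal(model$edges[order(model$edges$from), ]$to, c(2L, 3L, 3L))
  expect_equal(model$edges$count, rep(1L, 3))
  # running-mean center of the merged cluster
  expect_equal(unname(model$centers[3, 9]), (98 + 88) / 2)
  expect_equal(unname(model$centers[3, 10]), 5)
})

test_that("ties go to the lowest cluster id and assignment is sound", {
  # two founders equidistant from the third NSV
  f1 <- one_hot(1, 98)
  f2 <- one_hot(2, 98)
  x <- numeric(64); x[1] <- 49; x[2] <- 49
  st <- fake_stream(rbind(f1, f2, x), c("s1", "s2", "s3"))
  model <- build_genmodel(st, distance_spec(threshold = 120))
  expect_equal(model$members$cluster_id, c(1L, 2L, 1L))
  expect_true(all(model$assignment_distances <=
                    model$distance_spec$threshold))
})

test_that("cluster sizes always sum to the number of streamed segments", {
  withr::with_seed(29, {
    for (rep in 1:5) {
      rec <- random_family_records(n_seq = 6, n_bases = 400,
                                   n_sub = sample(c(5, 40), 1),
                                   seed = sample.int(1000, 1))
      st <- nsv_stream(rec)
      model <- build_genmodel(st)
      expect_equal(sum(model$sizes), nrow(st$segments))
      expect_equal(nrow(model$members), nrow(st$segments))
      expect_true(all(model$assignment_distances <=
                        model$distance_spec$threshold))
    }
  })
})

test_that("centers equal the mean of member NSVs", {
  rec <- random_family_records(n_seq = 8, n_bases = 600, n_sub = 10,
                               seed = 303)
  st <- nsv_stream(rec)
  model <- build_genmodel(st)
  for (cid in seq_len(n_clusters(model))) {
    rows <- which(model$members$cluster_id == cid)
    expect_equal(unname(model$centers[cid, ]),
                 unname(colMeans(st$counts[rows, , drop = FALSE])),
                 tolerance = 1e-9)
  }
})

test_that("with fixed centers the founder NSV is never updated", {
  v <- one_hot(9, 98)
  w <- v; w[9] <- 88; w[10] <- 10
  st <- fake_stream(rbind(v, w), c("s1", "s1"))
  model <- build_genmodel(st, distance_spec(threshold = 30),
                          update_rule = "first")
  expect_equal(n_clusters(model), 1)
  expect_equal(unname(model$centers[1, 9]), 98)
})

test_that("incremental add_sequence equals batch build", {
  withr::with_seed(41, {
    for (rep in 1:3) {
      rec <- random_family_records(n_seq = 6, n_bases = 500, n_sub = 12,
                                   seed = sample.int(1000, 1))
      batch <- build_genmodel(nsv_stream(rec))
      inc <- build_genmodel(nsv_stream(rec[1:3, ]))
      inc <- add_sequence(inc, rec[4:6, ])
      expect_equal(inc$centers, batch$centers)
      expect_equal(inc$sizes, batch$sizes)
      expect_equal(inc$members, batch$members)
      expect_equal(inc$edges, batch$edges)
      expect_equal(inc$start_counts, batch$start_counts)
    }
  })
})

test_that("adding to an empty model equals building from scratch", {
  rec <- seq_records(c(a = random_dna(300)))
  empty <- build_genmodel(nsv_stream(rec[0, ]))
  expect_equal(n_clusters(empty), 0)
  grown <- add_sequence(empty, rec)
  expect_equal(grown$members, build_genmodel(nsv_stream(rec))$members)
})

test_that("adding a too-short sequence warns and leaves the model unchanged", {
  rec <- seq_records(c(a = random_dna(300)))
  model <- build_genmodel(nsv_stream(rec))
  expect_warning(model2 <- add_sequence(model, seq_records(c(tiny = "ACGT"))),
                 "tiny")
  expect_equal(model2$sizes, model$sizes)
  expect_equal(model2$members, model$members)
})

test_that("transition probabilities row-normalize the edge counts", {
  # one sequence visits 1 -> 2 three times, 1 -> 3 once (via repeats)
  a <- one_hot(1, 98); b <- one_hot(5, 98); cc <- one_hot(9, 98)
  counts <- rbind(a, b, a, b, a, b, a, cc)
  st <- fake_stream(counts, rep("s1", 8))
  model <- build_genmodel(st, distance_spec(threshold = 30))
  tp <- transition_probabilities(model)
  out1 <- tp[tp$from == 1, ]
  expect_equal(out1$prob[out1$to == 2], 0.75)
  expect_equal(out1$prob[out1$to == 3], 0.25)
  sums <- tapply(tp$prob, tp$from, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("an empty stream produces an empty model without error", {
  st <- nsv_stream(seq_records(character(0)))
  model <- build_genmodel(st)
  expect_equal(n_clusters(model), 0)
  expect_equal(nrow(model$edges), 0)
})

test_that("GenModel JSON round-trips and is byte-stable", {
  rec <- random_family_records(n_seq = 4, n_bases = 400, n_sub = 8,
                               seed = 77)
  model <- build_genmodel(nsv_stream(rec))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_genmodel(model, p1)
  write_genmodel(model, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_genmodel(p1)
  expect_equal(back$sizes, model$sizes)
  expect_equal(back$centers, model$centers)
  # members are stored grouped by cluster; compare as sets of rows
  sort_members <- function(m) m[order(m$cluster_id, m$seq_id, m$start), ]
  expect_equal(sort_members(back$members), sort_members(model$members),
               ignore_attr = TRUE)
  expect_equal(back$edges, model$edges)
  expect_equal(back$segment_spec, model$segment_spec)
})
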