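test_that("elo_update follows the logistic rule and conserves score", {
  up <- elo_update(1000, 1000, K = 200)
  expect_equal(up$winner, 1100)
  expect_equal(up$loser, 900)

  up2 <- elo_update(3200, 0, K = 200)
  expect_lt(up2$winner - 3200, 1e-4)

  set.seed(5)
  for (i in 1:20) {
    w <- runif(1, 0, 2000); l <- runif(1, 0, 2000); K <- runif(1, 10, 400)
    up <- elo_update(w, l, K)
    expect_equal(up$winner + up$loser, w + l)
  }
})

test_that("randomized Elo recovers forced orderings exactly", {
  ds <- make_events(rep(c("A", "B", "A"), each = 10),
                    rep(c("B", "C", "C"), each = 10))
  h <- elo_hierarchy(ds, n_orderings = 50, seed = 1)
  expect_equal(h$id[order(h$rank)], c("A", "B", "C"))
  expect_equal(sort(h$rank), 1:3)
  expect_equal(range(h$norm_score), c(0, 1))

  # reversing every winner/loser reverses the rank order
  rev_ds <- make_events(rep(c("B", "C", "C"), each = 10),
                        rep(c("A", "B", "A"), each = 10))
  h_rev <- elo_hierarchy(rev_ds, n_orderings = 50, seed = 1)
  expect_equal(h_rev$id[order(h_rev$rank)], c("C", "B", "A"))

  # complete transitive round-robin: exact recovery of the true order
  ids <- paste0("m", 1:6)
  h_rr <- elo_hierarchy(transitive_dataset(ids, reps = 4),
                        n_orderings = 100, seed = 2)
  expect_equal(h_rr$id[order(h_rr$rank)], ids)
})

test_that("submissive events credit the recipient as winner", {
  # A submits to B throughout: B is dominant
  ds <- make_events(rep("A", 10), rep("B", 10), type_code = "SUB")
  h <- elo_hierarchy(ds, n_orderings = 20, seed = 1)
  expect_equal(h$id[h$rank == 1], "B")
})

test_that("rank order is invariant to the input ordering of events", {
  set.seed(8)
  ds <- simulate_dominance(abm_config(N = 10, X = 300, G = 4, seed = 31))
  shuffled <- ds[sample(nrow(ds)), ]
  shuffled$order <- seq_len(nrow(shuffled))
  shuffled <- interactions(as.data.frame(shuffled))
  h1 <- elo_hierarchy(ds, n_orderings = 300, seed = 4)
  h2 <- elo_hierarchy(shuffled, n_orderings = 300, seed = 5)
  expect_gt(cor(h1$rank, h2$rank[match(h1$id, h2$id)],
                method = "spearman"), 0.95)
})

test_that("individuals with no interactions are excluded with a warning", {
  ds <- make_events(c("A", "B"), c("B", "A"),
                    present = list(c("A", "B", "Z"), c("A", "B")))
  expect_warning(h <- elo_hierarchy(ds, n_orderings = 10, seed = 1),
                 "no interactions: Z")
  expect_setequal(h$id, c("A", "B"))
})

test_that("rank and score differences are signed and antisymmetric", {
  h <- manual_hierarchy(LETTERS[1:7])
  # actor ranked 4, recipient ranked 6: difference -2 one way, +2 the other
  expect_equal(rank_difference(h, "D", "F"), -2)
  expect_equal(rank_difference(h, "F", "D"), 2)
  expect_equal(rank_difference(h, "C", "C"), 0)
  # top acting on bottom: -1, matching the rank-difference sign convention
  expect_equal(score_difference(h, "A", "G"), -1)
  expect_equal(score_difference(h, "G", "A"), 1)
  for (pair in list(c("A", "D"), c("B", "G"), c("E", "C"))) {
    expect_equal(rank_difference(h, pair[1], pair[2]),
                 -rank_difference(h, pair[2], pair[1]))
    expect_equal(score_difference(h, pair[1], pair[2]),
                 -score_difference(h, pair[2], pair[1]))
  }
  # equally spaced scores: score difference is rank difference / (N - 1)
  expect_equal(score_difference(h, "B", "F"),
               rank_difference(h, "B", "F") / 6)
  expect_error(rank_difference(h, "A", "Q"), "not ranked")
})

test_that("hierarchy correlation behaves at the identity and reversal", {
  h <- manual_hierarchy(LETTERS[1:8])
  expect_equal(hierarchy_correlation(h, h), 1)
  h_rev <- h
  h_rev$rank <- rev(h_rev$rank)
  expect_equal(hierarchy_correlation(h, h_rev), -1)
  expect_error(hierarchy_correlation(manual_hierarchy(c("A", "B")),
                                     manual_hierarchy(c("A", "B"))),
               "three shared")
  expect_warning(hierarchy_correlation(h, manual_hierarchy(LETTERS[1:5])),
                 "shared")
})

test_that("repeatability is high for deterministic data and null for coin flips", {
  ids <- paste0("m", 1:8)
  det <- transitive_dataset(ids, reps = 8)
  r_det <- repeatability(det, n_repeats = 8, n_orderings = 50, seed = 1)
  expect_gt(r_det$mean_rs, 0.95)

  # equals decided by coin flips: expected correlation between halves is 0
  set.seed(33)
  pairs <- t(replicate(400, sample(ids, 2)))
  flip <- runif(400) < 0.5
  coin <- make_events(ifelse(flip, pairs[, 1], pairs[, 2]),
                      ifelse(flip, pairs[, 2], pairs[, 1]))
  r_coin <- repeatability(coin, n_repeats = 12, n_orderings = 50, seed = 2)
  se <- sd(r_coin$rs) / sqrt(length(r_coin$rs))
  expect_lt(abs(r_coin$mean_rs), 3 * se + 0.05)
})
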