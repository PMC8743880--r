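test_that("assortment kernel matches the sd-2 Gaussian density closed form", {
  # closed form evaluated independently of dnorm
  expect_equal(assortment_weight(5, 5), 1 / (2 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(assortment_weight(7, 5),
               exp(-(7 - 5)^2 / 8) / (2 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(assortment_weight(7, 5), 0.12099, tolerance = 1e-4)
  for (k in 0:6)
    expect_equal(assortment_weight(10 + k, 10), assortment_weight(10 - k, 10))
})

test_that("membership probabilities follow the stated normalizations", {
  cfg_r <- abm_config(N = 20, G = 5, assorted = FALSE)
  expect_equal(as.vector(membership_probs(cfg_r)), rep(0.25, 20))

  cfg_a <- abm_config(N = 20, G = 5, assorted = TRUE)
  for (z in c(1, 5, 10, 20)) {
    p <- membership_probs(cfg_a, z = z)
    expect_true(all(p >= 0 & p <= 1))
    if (all(p < 1))
      expect_equal(sum(p), 5, tolerance = 1e-9)
  }
  # edge target rank loses Gaussian mass off the rank range, so the common
  # rescaling factor (and hence the peak probability) is larger
  p_edge <- membership_probs(cfg_a, z = 1)
  p_mid <- membership_probs(cfg_a, z = 10)
  expect_gt(max(p_edge), max(p_mid))
  expect_lt(sum(assortment_weight(1:20, 1)), sum(assortment_weight(1:20, 10)))

  expect_error(membership_probs(cfg_r, z = 3), "assorted")
  expect_error(membership_probs(cfg_a), "target rank")
})

test_that("subgroup draws respect certainties and the minimum size", {
  p1 <- stats::setNames(rep(1, 6), letters[1:6])
  expect_setequal(draw_subgroup(p1)$members, letters[1:6])

  p2 <- stats::setNames(c(1, 1, rep(0, 4)), letters[1:6])
  for (i in 1:5) expect_setequal(draw_subgroup(p2)$members, c("a", "b"))

  expect_error(draw_subgroup(stats::setNames(rep(0, 6), letters[1:6])),
               "size >= 2")
})

test_that("mean subgroup size matches the truncated-binomial expectation", {
  # oracle: E[S | S >= 2] for S ~ Binomial(20, 0.25), from the pmf directly
  k <- 0:20
  pmf <- dbinom(k, 20, 0.25)
  oracle <- sum(k[k >= 2] * pmf[k >= 2]) / sum(pmf[k >= 2])
  set.seed(7)
  probs <- stats::setNames(rep(0.25, 20), sprintf("i%02d", 1:20))
  sizes <- replicate(3000, length(draw_subgroup(probs)$members))
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - oracle), 3 * se)
  expect_gt(oracle, 5) # conditioning on >= 2 pulls the mean slightly above G
})

test_that("the contest-outcome model has the stated closed form and limits", {
  expect_equal(win_probability(0.9, 1), 0.9)
  expect_equal(win_probability(0.9, 2), 0.99)
  expect_equal(win_probability(1, c(1, 5, 19)), c(1, 1, 1))
  expect_error(win_probability(0.9, 0), "r_d")
  # strictly increasing in r_d (P_w < 1) and non-decreasing in P_w
  p <- win_probability(0.8, 1:19)
  expect_true(all(diff(p) > 0))
  expect_true(all(win_probability(0.95, 1:19) >= win_probability(0.6, 1:19)))
})

test_that("simulated contests record the winner as actor at the model rate", {
  ranks <- stats::setNames(1:20, sprintf("i%02d", 1:20))
  # maximal rank difference: dominant nearly always wins
  set.seed(1)
  top_wins <- sum(replicate(500, {
    it <- simulate_interaction(c("i01", "i20"), ranks, P_w = 0.9)
    it$actor == "i01"
  }))
  expect_gte(top_wins, 498) # P = 1 - 0.1^19

  set.seed(2)
  for (i in 1:20) {
    it <- simulate_interaction(c("i03", "i07", "i11"), ranks, P_w = 1)
    expect_lt(ranks[it$actor], ranks[it$recipient])
  }

  set.seed(3)
  wins <- sum(replicate(4000, {
    it <- simulate_interaction(c("i05", "i06"), ranks, P_w = 0.9)
    it$actor == "i05"
  }))
  se <- sqrt(0.9 * 0.1 / 4000)
  expect_lt(abs(wins / 4000 - 0.9), 3 * se)

  expect_error(simulate_interaction("i01", ranks, 0.9), "two members")
})

test_that("simulated datasets honour the configuration and determinism", {
  ds <- simulate_dominance(abm_config(N = 20, X = 100, G = 5, P_w = 0.9,
                                      seed = 11))
  expect_equal(nrow(ds), 100)
  expect_equal(ds$order, 1:100)
  expect_true(all(lengths(ds$present) >= 2))

  two <- simulate_dominance(abm_config(N = 2, X = 10, G = 2, seed = 1))
  expect_setequal(unique(c(two$actor, two$recipient)), c("i01", "i02"))

  a <- simulate_dominance(abm_config(N = 12, X = 40, G = 4, seed = 99))
  b <- simulate_dominance(abm_config(N = 12, X = 40, G = 4, seed = 99))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("rank assortment shrinks co-member rank distances", {
  mean_pair_dist <- function(ds) {
    tr <- attr(ds, "true_ranks")
    mean(vapply(ds$present, function(m) {
      r <- tr[m]
      mean(abs(outer(r, r, "-"))[lower.tri(diag(length(r)))])
    }, numeric(1)))
  }
  da <- simulate_dominance(abm_config(N = 20, X = 1000, G = 5,
                                      assorted = TRUE, seed = 21))
  dr <- simulate_dominance(abm_config(N = 20, X = 1000, G = 5,
                                      assorted = FALSE, seed = 22))
  expect_lt(mean_pair_dist(da), mean_pair_dist(dr) - 1)
})
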