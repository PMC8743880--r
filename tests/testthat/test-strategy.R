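test_that("side-split splines reproduce penalty-null-space fits exactly", {
  # straight line: zero roughness penalty, reproduced exactly on both sides
  x <- c(-(10:1), 1:10)
  pts <- data.frame(diff = x, tendency = 0.5 * x + 2)
  fit <- fit_strategy_spline(pts, grid = x, lambda = 0.04)
  expect_equal(fit$pred, 0.5 * fit$diff + 2, tolerance = 1e-6)
  expect_false(any(fit$extrapolated))

  const <- data.frame(diff = x, tendency = rep(3, length(x)))
  fitc <- fit_strategy_spline(const, grid = x, lambda = 0.04)
  expect_equal(fitc$pred, rep(3, nrow(fitc)), tolerance = 1e-8)

  # too few distinct abscissae on one side: that side flagged absent
  few <- data.frame(diff = c(-2, -1, 1:8), tendency = rnorm(10))
  fitf <- fit_strategy_spline(few, grid = c(-3:-1, 1:8), lambda = 0.04)
  expect_true(all(is.na(fitf$pred[fitf$diff < 0])))
  expect_true(all(!is.na(fitf$pred[fitf$diff > 0])))

  # grid points beyond the data range are flagged as extrapolated
  fite <- fit_strategy_spline(pts, grid = c(-15, x, 15), lambda = 0.04)
  expect_true(fite$extrapolated[fite$diff == -15])
  expect_true(fite$extrapolated[fite$diff == 15])
})

test_that("spline fits agree with an independent matched-df penalized oracle", {
  skip_if_not_installed("mgcv")
  set.seed(42)
  x <- rep(1:19, each = 4)
  y <- sin(x / 3) + rnorm(length(x), 0, 0.1)
  grid <- 1:19
  ours <- fit_strategy_spline(data.frame(diff = x, tendency = y),
                              grid = grid, df = 5, lambda = NULL)
  # oracle: cubic regression spline, ridge penalty solved so that the trace
  # of the hat matrix equals the same effective df, fitted from scratch
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = 12),
                        data = data.frame(x = x))[[1]]
  X <- sm$X; S <- sm$S[[1]]
  edf <- function(loglam)
    sum(diag(X %*% solve(crossprod(X) + exp(loglam) * S, t(X))))
  ll <- stats::uniroot(function(l) edf(l) - 5, c(-10, 25))$root
  beta <- solve(crossprod(X) + exp(ll) * S, crossprod(X, y))
  oracle <- drop(mgcv::PredictMat(sm, data.frame(x = grid)) %*% beta)
  expect_lt(max(abs(ours$pred - oracle)), 0.05)
})

test_that("band classification labels follow the 95%-range rule", {
  expect_equal(classify_band(0.1, 0.5), "above")
  expect_equal(classify_band(-0.5, -0.1), "below")
  expect_equal(classify_band(-0.1, 0.1), "ns")
  expect_equal(classify_band(0, 0.2), "ns") # range touching zero is not above
  expect_equal(classify_band(c(0.1, NA), c(0.5, NA)),
               c("above", NA_character_))
})

test_that("fit_strategy returns a coherent band object", {
  ds <- simulate_dominance(abm_config(N = 10, X = 120, G = 4, seed = 51))
  fit <- fit_strategy(ds, n_iterations = 30, n_permutations = 300,
                      n_orderings = 50, seed = 3)
  expect_s3_class(fit, "strategy_fit")
  expect_equal(fit$band$diff, setdiff(-9:9, 0))
  expect_true(all(fit$band$lo <= fit$band$median + 1e-12))
  expect_true(all(fit$band$median <= fit$band$hi + 1e-12))
  expect_identical(fit$band$label,
                   classify_band(fit$band$lo, fit$band$hi))
  expect_equal(dim(fit$predictions), c(30, 18))
  # reproducibility under the master seed
  fit2 <- fit_strategy(ds, n_iterations = 30, n_permutations = 300,
                       n_orderings = 50, seed = 3)
  expect_identical(fit$predictions, fit2$predictions)
  # predict() returns the requested grid rows
  pr <- predict(fit, c(-1, 1))
  expect_equal(pr$diff, c(-1, 1))
  expect_error(predict(fit, 0.5), "grid")
})

test_that("score-based runs use the [-1, 1] evaluation grid", {
  ds <- simulate_dominance(abm_config(N = 10, X = 150, G = 4, seed = 52))
  fit <- fit_strategy(ds, n_iterations = 10, n_permutations = 200,
                      n_orderings = 50, difference = "score", seed = 4)
  expect_equal(length(fit$band$diff), 98)
  expect_true(all(abs(fit$band$diff) <= 1 & fit$band$diff != 0))
})

test_that("doubling the data doubles the tendency scale but not the labels", {
  kern <- function(d) if (d == -1) 1 else 0.05
  ds <- simulate_dominance(abm_config(N = 12, X = 600, G = 4, P_w = 0.9,
                                      strategy = kern, seed = 61))
  dbl <- as.data.frame(ds)
  dbl2 <- dbl
  dbl2$event_id <- paste0(dbl2$event_id, "b")
  dbl2$order <- dbl2$order + nrow(dbl)
  ds2 <- interactions(rbind(dbl, dbl2))

  fit1 <- fit_strategy(ds, n_iterations = 60, n_permutations = 1200,
                       n_orderings = 100, seed = 7)
  fit2 <- fit_strategy(ds2, n_iterations = 60, n_permutations = 2400,
                       n_orderings = 100, seed = 7)
  m1 <- predict(fit1, -1)$median
  m2 <- predict(fit2, -1)$median
  expect_gt(m2 / m1, 1.4)
  expect_lt(m2 / m1, 2.6)
  expect_identical(predict(fit1, -1)$label, "above")
  expect_identical(predict(fit2, -1)$label, "above")
})
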