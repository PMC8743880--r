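#' Permute interaction recipients within subgroup composition
#'
#' The null model for the tendency-to-interact statistic: a datastream
#' permutation that repeatedly (i) picks one interaction uniformly at random,
#' (ii) removes its actor from the individuals present at that interaction,
#' and (iii) redraws the recipient uniformly from the remainder (possibly the
#' original recipient). Actors, categories, present sets and the number of
#' events never change, so the permuted dataset preserves each individual's
#' rate of acting and the opportunity structure, while destroying any
#' recipient preference. The returned dataset is the state of the chain after
#' the final permutation.
#'
#' Because each step redraws one event's recipient independently of the
#' current state, the final dataset depends only on the last permutation that
#' touched each event; the implementation samples the sequence of touched
#' events and performs a single redraw per touched event, which is exactly
#' equivalent in distribution to the literal sequential chain.
#'
#' @param x An `interactions` object (every event must have at least two
#'   individuals present).
#' @param n_permutations Number of chain steps (default 100000).
#' @param seed Optional integer seed.
#' @return An `interactions` object with permuted recipients.
#' @export
permute_recipients <- function(x, n_permutations = 100000, seed = NULL) {
  stopifnot(n_permutations >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  if (n == 0) return(x)
  touched <- unique(sample.int(n, n_permutations, replace = TRUE))
  new_rec <- x$recipient
  for (i in touched) {
    candidates <- setdiff(x$present[[i]], x$actor[i])
    new_rec[i] <- if (length(candidates) == 1) candidates else
      sample(candidates, 1)
  }
  out <- x
  out$recipient <- new_rec
  out
}

#' Exact expected directed counts under the permutation null
#'
#' Closed-form stationary expectation of [permute_recipients()]: for each
#' event the recipient is uniform over the individuals present minus the
#' actor, so `expected[a, b]` is the sum over events with actor `a` of
#' `1 / (|present| - 1)` for each other individual `b` present. Serves as
#' the analytic oracle for the Monte-Carlo null; row sums equal the observed
#' row sums exactly.
#'
#' @param x An `interactions` object.
#' @param ids Individuals to index the matrix by; defaults to
#'   [individuals()] of `x`.
#' @return A real matrix, rows = actors, columns = recipients.
#' @export
expected_counts_exact <- function(x, ids = individuals(x)) {
  m <- matrix(0, nrow = length(ids), ncol = length(ids),
              dimnames = list(actor = ids, recipient = ids))
  for (i in seq_len(nrow(x))) {
    others <- setdiff(x$present[[i]], x$actor[i])
    m[x$actor[i], others] <- m[x$actor[i], others] + 1 / length(others)
  }
  m
}

#' Tendency-to-interact matrix
#'
#' Observed minus expected directed counts. Zero means a dyad interacts at
#' the frequency expected from opportunity alone; positive values mean the
#' actor targets that recipient more often than chance, negative less often.
#' Because permutation never changes actors, every actor's row of the
#' difference sums to zero exactly, and so does the grand total.
#'
#' @param observed,expected Directed count matrices with identical dimnames
#'   (e.g. from [directed_dyad_counts()] on the observed and a permuted
#'   dataset).
#' @return A list of class `tendency_matrix` with elements `values`
#'   (observed - expected), `observed` and `expected`.
#' @export
tendency_matrix <- function(observed, expected) {
  if (!identical(dimnames(observed), dimnames(expected)) ||
      !identical(dim(observed), dim(expected)))
    stop("observed and expected matrices must share dimensions and dimnames",
         call. = FALSE)
  structure(list(values = observed - expected, observed = observed,
                 expected = expected),
            class = "tendency_matrix")
}

#' Dyad-level series of tendency versus hierarchy difference
#'
#' Flattens a [tendency_matrix()] into one point per directed dyad: the
#' signed rank (or normalized-score) difference of the dyad against its
#' tendency to interact. With `N` ranked individuals there are `N * (N - 1)`
#' points, `N - k` of them at rank difference `-k` (and `+k`).
#'
#' @param tm A `tendency_matrix`.
#' @param h A `dom_hierarchy` ranking every individual in `tm`.
#' @param difference `"rank"` or `"score"`.
#' @return A data frame with columns `actor`, `recipient`, `diff`,
#'   `tendency`.
#' @export
dyad_series <- function(tm, h, difference = c("rank", "score")) {
  difference <- match.arg(difference)
  ids <- rownames(tm$values)
  grid <- expand.grid(actor = ids, recipient = ids,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$actor != grid$recipient, , drop = FALSE]
  dfun <- if (difference == "rank") rank_difference else score_difference
  grid$diff <- dfun(h, grid$actor, grid$recipient)
  grid$tendency <- tm$values[cbind(grid$actor, grid$recipient)]
  rownames(grid) <- NULL
  grid
}

#' Fit side-split smoothing splines to a dyad series
#'
#' Cubic smoothing splines fitted separately to the points at negative and
#' positive hierarchy differences, because strategies towards individuals
#' just below (-1) and just above (+1) in rank may differ sharply and a
#' single spline through zero would smear them together. Fits use
#' [stats::smooth.spline()]; when `lambda` is supplied it sets the roughness
#' penalty directly (it then takes precedence over `df`), otherwise the
#' penalty is chosen to match `df` effective degrees of freedom.
#'
#' @param points Data frame with columns `diff` and `tendency` (e.g. from
#'   [dyad_series()]).
#' @param grid Evaluation points (signed differences, excluding 0).
#' @param df Target effective degrees of freedom per side (default 3).
#' @param lambda Roughness penalty (default 0.04); set `NULL` to use `df`.
#' @return A data frame with columns `diff`, `pred` and `extrapolated`
#'   (logical: grid point outside that side's observed abscissa range).
#'   Sides with fewer than four distinct abscissae yield `NA` predictions.
#' @export
fit_strategy_spline <- function(points, grid, df = 3, lambda = 0.04) {
  stopifnot(df >= 2)
  fit_side <- function(side_pts, side_grid) {
    if (length(side_grid) == 0)
      return(data.frame(diff = numeric(0), pred = numeric(0),
                        extrapolated = logical(0)))
    out <- data.frame(diff = side_grid, pred = NA_real_,
                      extrapolated = NA)
    if (length(unique(side_pts$diff)) < 4) return(out)
    args <- list(x = side_pts$diff, y = side_pts$tendency,
                 all.knots = TRUE, keep.data = FALSE)
    if (!is.null(lambda)) args$lambda <- lambda else args$df <- df
    sp <- do.call(stats::smooth.spline, args)
    out$pred <- stats::predict(sp, side_grid)$y
    out$extrapolated <- side_grid < min(side_pts$diff) |
      side_grid > max(side_pts$diff)
    out
  }
  neg <- fit_side(points[points$diff < 0, , drop = FALSE], grid[grid < 0])
  pos <- fit_side(points[points$diff > 0, , drop = FALSE], grid[grid > 0])
  rbind(neg, pos)
}

#' Classify band grid points against zero
#'
#' A grid point is `"above"` when the entire 95% range of predicted
#' tendencies lies above zero, `"below"` when entirely below, `"ns"`
#' otherwise.
#'
#' @param lo,hi Lower (2.5%) and upper (97.5%) band limits.
#' @return Character vector of labels.
#' @export
classify_band <- function(lo, hi) {
  ifelse(is.na(lo) | is.na(hi), NA_character_,
         ifelse(lo > 0, "above", ifelse(hi < 0, "below", "ns")))
}

#' Fit the strategy band: repeated split / permute / smooth analysis
#'
#' The full inferential loop for one (group, category) dataset. Each
#' iteration (1) randomly splits the events into a hierarchy subset and a
#' strategy subset, (2) infers a randomized-Elo hierarchy from the first,
#' (3) counts directed dyadic interactions in the second, (4) builds one
#' permuted dataset under the subgroup-composition null and counts it,
#' (5) takes the observed-minus-expected tendency per directed dyad and fits
#' side-split smoothing splines against the signed hierarchy difference.
#' Across iterations the pointwise median and empirical 2.5/97.5 percentiles
#' of the spline predictions form the strategy band; grid points whose 95%
#' range excludes zero indicate interaction tendencies that differ from the
#' opportunity-only expectation.
#'
#' @param x An `interactions` object, one group and one interaction category.
#' @param n_iterations Number of outer split iterations (default 500).
#' @param hier_fraction Fraction of events used for hierarchy inference
#'   (default 0.3).
#' @param n_permutations Permutation-chain length per iteration
#'   (default 100000).
#' @param difference `"rank"` or `"score"` hierarchy differences.
#' @param df,lambda Spline smoothing controls, see [fit_strategy_spline()].
#' @param K,init_score,n_orderings Elo controls, see [elo_hierarchy()].
#' @param grid Evaluation grid; defaults to the integer differences
#'   `-(N-1)..-1, 1..N-1` for rank-based runs and 49 evenly spaced points
#'   per side on `[-1, 1]` for score-based runs.
#' @param seed Optional master seed; per-iteration child seeds are derived
#'   from it so iterations are individually reproducible.
#' @return An object of class `strategy_fit` with components `band` (data
#'   frame: `diff`, `median`, `lo`, `hi`, `label`, `extrapolation_share`),
#'   `predictions` (iterations x grid matrix), `n_iterations`, `n_failed`,
#'   `difference`, and `call`.
#' @examples
#' ds <- simulate_dominance(abm_config(N = 10, X = 80, seed = 1))
#' fit <- fit_strategy(ds, n_iterations = 20, n_permutations = 500,
#'                     n_orderings = 50, seed = 1)
#' summary(fit)
#' @export
fit_strategy <- function(x, n_iterations = 500, hier_fraction = 0.3,
                         n_permutations = 100000,
                         difference = c("rank", "score"),
                         df = 3, lambda = 0.04,
                         K = 200, init_score = 1000, n_orderings = 1000,
                         grid = NULL, seed = NULL) {
  difference <- match.arg(difference)
  stopifnot(n_iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- individuals(x)
  N <- length(ids)
  if (is.null(grid)) {
    grid <- if (difference == "rank") {
      setdiff(seq.int(-(N - 1), N - 1), 0)
    } else {
      c(seq(-1, -1 / 49, length.out = 49), seq(1 / 49, 1, length.out = 49))
    }
  }
  if (any(grid == 0)) stop("evaluation grid must exclude 0", call. = FALSE)
  grid <- sort(grid)
  child_seeds <- sample.int(.Machine$integer.max, n_iterations)
  preds <- matrix(NA_real_, nrow = n_iterations, ncol = length(grid))
  extrap <- matrix(NA, nrow = n_iterations, ncol = length(grid))
  n_failed <- 0L
  for (it in seq_len(n_iterations)) {
    set.seed(child_seeds[it])
    res <- tryCatch({
      sp <- split_dataset(x, hier_fraction)
      h <- suppressWarnings(
        elo_hierarchy(sp$hierarchy, K = K, init_score = init_score,
                      n_orderings = n_orderings))
      ranked <- h$id
      # the analysis is conditioned on the individuals rankable from the
      # hierarchy subset: events among them are kept and present sets are
      # intersected with them, so the permutation redraws recipients within
      # the analyzable set and per-actor counts are conserved exactly
      strat <- sp$strategy[sp$strategy$actor %in% ranked &
                             sp$strategy$recipient %in% ranked, ,
                           drop = FALSE]
      if (nrow(strat) == 0) stop("no usable strategy events")
      strat$present <- lapply(strat$present, intersect, ranked)
      obs <- directed_dyad_counts(strat, ids = ranked)
      perm <- permute_recipients(strat, n_permutations)
      exp_counts <- directed_dyad_counts(perm, ids = ranked)
      tm <- tendency_matrix(obs, exp_counts)
      pts <- dyad_series(tm, h, difference = difference)
      fit_strategy_spline(pts, grid = grid, df = df, lambda = lambda)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    preds[it, ] <- res$pred
    extrap[it, ] <- res$extrapolated
  }
  ok <- rowSums(!is.na(preds)) > 0
  if (!any(ok)) stop("all iterations failed", call. = FALSE)
  band <- data.frame(
    diff = grid,
    median = apply(preds, 2, stats::median, na.rm = TRUE),
    lo = apply(preds, 2, stats::quantile, probs = 0.025, na.rm = TRUE,
               names = FALSE),
    hi = apply(preds, 2, stats::quantile, probs = 0.975, na.rm = TRUE,
               names = FALSE),
    extrapolation_share = colMeans(extrap, na.rm = TRUE)
  )
  band$label <- classify_band(band$lo, band$hi)
  structure(list(band = band, predictions = preds,
                 n_iterations = n_iterations, n_failed = n_failed,
                 difference = difference, grid = grid,
                 hier_fraction = hier_fraction,
                 n_permutations = n_permutations,
                 seed = seed, call = match.call()),
            class = "strategy_fit")
}

#' @export
print.strategy_fit <- function(x, ...) {
  cat("Tendency-to-interact strategy band (", x$difference,
      " differences)\n", sep = "")
  cat("  iterations: ", x$n_iterations, " (", x$n_failed, " failed)",
      "; permutations per iteration: ", x$n_permutations, "\n", sep = "")
  sig <- x$band$label %in% c("above", "below")
  if (any(sig)) {
    cat("  significant grid points:\n")
    print(x$band[sig, c("diff", "median", "lo", "hi", "label")],
          row.names = FALSE, digits = 3)
  } else {
    cat("  no grid point's 95% range excludes zero (no detectable strategy)\n")
  }
  invisible(x)
}

#' @export
summary.strategy_fit <- function(object, ...) {
  cat("Strategy band over", length(object$grid), "grid points;",
      sum(object$band$label == "above", na.rm = TRUE), "above,",
      sum(object$band$label == "below", na.rm = TRUE), "below,",
      sum(object$band$label == "ns", na.rm = TRUE), "ns\n")
  print(object$band, digits = 3, row.names = FALSE)
  invisible(object$band)
}

#' @export
predict.strategy_fit <- function(object, diff = object$grid, ...) {
  i <- match(diff, object$grid)
  if (anyNA(i)) stop("requested differences not on the evaluation grid",
                     call. = FALSE)
  object$band[i, , drop = FALSE]
}

#' @export
plot.strategy_fit <- function(x, ...) {
  b <- x$band
  neg <- b[b$diff < 0, ]
  pos <- b[b$diff > 0, ]
  graphics::plot(NA, xlim = range(b$diff), ylim = range(c(b$lo, b$hi), na.rm = TRUE),
                 xlab = paste0("signed ", x$difference, " difference (actor - recipient)"),
                 ylab = "tendency to interact", ...)
  graphics::abline(h = 0, lty = 3)
  for (side in list(neg, pos)) {
    if (nrow(side) == 0) next
    graphics::polygon(c(side$diff, rev(side$diff)), c(side$lo, rev(side$hi)),
                      col = grDevices::adjustcolor("firebrick", 0.3),
                      border = NA)
    graphics::lines(side$diff, side$median, lwd = 2, col = "firebrick")
  }
  invisible(x)
}
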