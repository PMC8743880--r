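# Winner/loser extraction is centralized here: for aggressive categories the
# winner performs the act (winner = actor); for submissive categories the
# subordinate performs the signal, so the winner is the recipient.
winners_losers <- function(x) {
  submissive <- x$category == "submissive"
  data.frame(winner = ifelse(submissive, x$recipient, x$actor),
             loser = ifelse(submissive, x$actor, x$recipient),
             stringsAsFactors = FALSE)
}

#' One Elo rating update
#'
#' Classic logistic Elo: the expected win probability of the eventual winner
#' is `E = 1 / (1 + 10^((loser - winner) / 400))`; the winner gains
#' `K * (1 - E)` and the loser loses the same amount, so total score is
#' conserved exactly.
#'
#' @param winner_score,loser_score Current scores (vectorized).
#' @param K Update magnitude (> 0).
#' @return A list with `winner` and `loser` updated scores.
#' @export
elo_update <- function(winner_score, loser_score, K = 200) {
  stopifnot(K > 0)
  E <- 1 / (1 + 10^((loser_score - winner_score) / 400))
  delta <- K * (1 - E)
  list(winner = winner_score + delta, loser = loser_score - delta)
}

#' Infer a dominance hierarchy by randomized Elo rating
#'
#' Sequential Elo scores depend on the order in which interactions are
#' replayed; with intrinsically steep hierarchies the order carries no
#' information, so the scores are averaged over many uniformly random
#' replay orders (temporal randomization). Each of `n_orderings`
#' permutations of the event sequence is replayed with [elo_update()] from a
#' common starting score; an individual's mean final score across orderings
#' determines its rank (1 = most dominant). Winners are the actors of
#' aggressive events and the recipients of submissive ones.
#'
#' @param x An `interactions` object (typically the hierarchy subset of a
#'   [split_dataset()]).
#' @param K Elo update magnitude (default 200).
#' @param init_score Starting score for every individual (default 1000).
#' @param n_orderings Number of random replay orders to average over
#'   (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `dom_hierarchy`: a data frame with columns
#'   `id`, `rank`, `mean_score` and `norm_score` (min-max rescaled to
#'   `[0, 1]`), sorted by rank. Individuals appearing in no interaction are
#'   excluded with a warning. Ties in mean score are broken by id.
#' @examples
#' ds <- simulate_dominance(abm_config(N = 8, X = 200, seed = 1))
#' h <- elo_hierarchy(ds, n_orderings = 100, seed = 1)
#' h
#' @export
elo_hierarchy <- function(x, K = 200, init_score = 1000, n_orderings = 1000,
                          seed = NULL) {
  stopifnot(n_orderings >= 1)
  if (!is.null(seed)) set.seed(seed)
  wl <- winners_losers(x)
  ids <- sort(unique(c(wl$winner, wl$loser)))
  if (length(ids) < 2)
    stop("need interactions among at least two individuals", call. = FALSE)
  silent <- setdiff(individuals(x), ids)
  if (length(silent) > 0)
    warning("excluding individual(s) with no interactions: ",
            paste(silent, collapse = ", "), call. = FALSE)
  n_ev <- nrow(wl)
  n_id <- length(ids)
  w_idx <- match(wl$winner, ids)
  l_idx <- match(wl$loser, ids)
  # one column of scores per replay order, updated in lockstep across orders
  P <- vapply(seq_len(n_orderings), function(i) sample.int(n_ev),
              integer(n_ev))
  P <- matrix(P, nrow = n_ev)
  S <- matrix(init_score, nrow = n_id, ncol = n_orderings)
  col_off <- (seq_len(n_orderings) - 1L) * n_id
  for (t in seq_len(n_ev)) {
    ev <- P[t, ]
    wi <- w_idx[ev] + col_off
    li <- l_idx[ev] + col_off
    E <- 1 / (1 + 10^((S[li] - S[wi]) / 400))
    delta <- K * (1 - E)
    S[wi] <- S[wi] + delta
    S[li] <- S[li] - delta
  }
  mean_score <- rowMeans(S)
  ord <- order(-mean_score, ids)
  rng <- range(mean_score)
  norm <- if (diff(rng) > 0) (mean_score - rng[1]) / diff(rng)
          else rep(0.5, n_id)
  h <- data.frame(id = ids[ord], rank = seq_len(n_id),
                  mean_score = mean_score[ord],
                  norm_score = norm[ord],
                  stringsAsFactors = FALSE)
  rownames(h) <- NULL
  class(h) <- c("dom_hierarchy", "data.frame")
  h
}

h_lookup <- function(h, ids, what) {
  i <- match(ids, h$id)
  if (anyNA(i))
    stop("individual(s) not ranked: ",
         paste(unique(ids[is.na(i)]), collapse = ", "), call. = FALSE)
  h[[what]][i]
}

#' Signed rank difference of a directed dyad
#'
#' `rank(actor) - rank(recipient)`: negative when the actor outranks the
#' recipient (e.g. actor ranked 4, recipient ranked 6 gives -2), positive
#' when the act is directed up the hierarchy.
#'
#' @param h A `dom_hierarchy`.
#' @param actor,recipient Individual ids (vectorized).
#' @return Signed integer difference(s).
#' @export
rank_difference <- function(h, actor, recipient) {
  h_lookup(h, actor, "rank") - h_lookup(h, recipient, "rank")
}

#' Signed normalized-score difference of a directed dyad
#'
#' As [rank_difference()] but on the min-max normalized Elo score, giving a
#' signed value in `[-1, 1]` with the same sign convention as rank
#' differences: negative when the actor outranks the recipient (the top
#' individual acting on the bottom one gives -1). The score-based variant of
#' the analysis uses this instead of ranks.
#'
#' @inheritParams rank_difference
#' @return Signed real difference(s) in `[-1, 1]`.
#' @export
score_difference <- function(h, actor, recipient) {
  h_lookup(h, recipient, "norm_score") - h_lookup(h, actor, "norm_score")
}

#' Spearman correlation between two hierarchies
#'
#' Rank agreement between two inferred hierarchies on their shared
#' individuals, e.g. hierarchies built from different interaction categories.
#'
#' @param h1,h2 `dom_hierarchy` objects.
#' @return Spearman's rank correlation coefficient.
#' @export
hierarchy_correlation <- function(h1, h2) {
  shared <- intersect(h1$id, h2$id)
  if (length(shared) < 3)
    stop("fewer than three shared individuals", call. = FALSE)
  if (length(shared) < length(h1$id) || length(shared) < length(h2$id))
    warning("hierarchies do not cover the same individuals; using the ",
            length(shared), " shared ones", call. = FALSE)
  stats::cor(h_lookup(h1, shared, "rank"), h_lookup(h2, shared, "rank"),
             method = "spearman")
}

#' Split-half repeatability of an inferred hierarchy
#'
#' Estimates how much the inferred order depends on which interactions were
#' observed: repeatedly bisect the events 50/50 at random, infer a hierarchy
#' from each half, and correlate the two rank orders (Spearman). High mean
#' correlation means the data determine the hierarchy robustly.
#'
#' @param x An `interactions` object.
#' @param subset_fraction Fraction of events randomly selected (per repeat)
#'   before bisection; default 1 uses all supplied events. Pass e.g. 0.3 to
#'   probe the robustness of a 30% hierarchy subset directly.
#' @param n_repeats Number of random bisections (default 25).
#' @param n_orderings Replay orders per Elo fit (default 200).
#' @param seed Optional integer seed.
#' @return A list of class `repeatability` with `mean_rs`, `rs` (per-repeat
#'   values) and `ci` (empirical 2.5/97.5 percentiles).
#' @export
repeatability <- function(x, subset_fraction = 1, n_repeats = 25,
                          n_orderings = 200, seed = NULL) {
  stopifnot(subset_fraction > 0, subset_fraction <= 1, n_repeats >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  if (n < 4) stop("too few events for split-half repeatability",
                  call. = FALSE)
  rs <- vapply(seq_len(n_repeats), function(i) {
    keep <- if (subset_fraction < 1)
      sort(sample.int(n, max(4L, floor(subset_fraction * n + 0.5))))
    else seq_len(n)
    m <- length(keep)
    half <- sample(keep, floor(m / 2))
    h1 <- elo_hierarchy(x[sort(half), ], n_orderings = n_orderings)
    h2 <- elo_hierarchy(x[sort(setdiff(keep, half)), ],
                        n_orderings = n_orderings)
    hierarchy_correlation(h1, h2)
  }, numeric(1))
  structure(list(mean_rs = mean(rs), rs = rs,
                 ci = stats::quantile(rs, c(0.025, 0.975), names = FALSE)),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat("Split-half hierarchy repeatability\n")
  cat(sprintf("  mean Spearman r_s = %.3f  (95%% range %.3f to %.3f, %d repeats)\n",
              x$mean_rs, x$ci[1], x$ci[2], length(x$rs)))
  invisible(x)
}

#' @export
print.dom_hierarchy <- function(x, ...) {
  cat("Dominance hierarchy (randomized Elo), ", nrow(x),
      " individuals\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
coef.dom_hierarchy <- function(object, ...) {
  stats::setNames(object$mean_score, object$id)
}

#' @export
plot.dom_hierarchy <- function(x, ...) {
  graphics::plot(x$rank, x$mean_score, xlab = "rank (1 = most dominant)",
                 ylab = "mean Elo score", pch = 19, ...)
  graphics::text(x$rank, x$mean_score, x$id, pos = 4, cex = 0.7)
  invisible(x)
}
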