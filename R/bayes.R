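#' Probability of higher-cost aggression given rank difference
#'
#' For each signed rank difference `R` observed among aggressive events,
#' applies Bayes' rule to estimate the probability that an aggressive
#' interaction at that difference is of the higher-cost kind:
#' `P(A_h | R) = P(R | A_h) P(A_h) / P(R)`, where `P(A_h)` is the overall
#' share of higher-cost events (the baseline), `P(R | A_h)` the distribution
#' of rank differences among higher-cost events, and `P(R)` the distribution
#' over all aggressive events. Algebraically this equals the conditional
#' frequency `n_high(R) / (n_high(R) + n_low(R))`; the Bayes form is
#' computed literally and the identity is exploited as a test oracle.
#'
#' @param high,low `interactions` objects holding the higher- and lower-cost
#'   aggressive events (both non-empty).
#' @param h A `dom_hierarchy` ranking every actor and recipient; when `NULL`
#'   a randomized-Elo hierarchy is inferred from the pooled events.
#' @param n_orderings Replay orders for the pooled Elo fit when `h` is
#'   `NULL`.
#' @return A list of class `cost_allocation` with a data frame `table`
#'   (`rank_diff`, `n_high`, `n_low`, `p_high`) and scalar `baseline`
#'   (= `P(A_h)`).
#' @export
prob_high_given_rankdiff <- function(high, low, h = NULL,
                                     n_orderings = 1000) {
  if (nrow(high) == 0 || nrow(low) == 0)
    stop("both higher- and lower-cost event sets must be non-empty",
         call. = FALSE)
  if (is.null(h)) {
    pooled <- rbind(as.data.frame(high), as.data.frame(low))
    class(pooled) <- c("interactions", "data.frame")
    h <- suppressWarnings(elo_hierarchy(pooled, n_orderings = n_orderings))
  }
  Rh <- rank_difference(h, high$actor, high$recipient)
  Rl <- rank_difference(h, low$actor, low$recipient)
  all_R <- sort(unique(c(Rh, Rl)))
  n_high <- vapply(all_R, function(r) sum(Rh == r), numeric(1))
  n_low <- vapply(all_R, function(r) sum(Rl == r), numeric(1))
  p_Ah <- length(Rh) / (length(Rh) + length(Rl))
  p_R_given_Ah <- n_high / length(Rh)
  p_R <- (n_high + n_low) / (length(Rh) + length(Rl))
  p_high <- p_R_given_Ah * p_Ah / p_R
  structure(list(table = data.frame(rank_diff = all_R, n_high = n_high,
                                    n_low = n_low, p_high = p_high),
                 baseline = p_Ah, hierarchy = h),
            class = "cost_allocation")
}

#' Bootstrap confidence intervals for cost allocation
#'
#' Resamples the pooled aggressive events with replacement (preserving the
#' total count, so the replicate-level baseline varies as it should),
#' recomputes `P(A_h | R)` in each replicate, and reports the empirical
#' 2.5/97.5 percentiles per rank difference. Differences absent from a
#' replicate contribute no value to that replicate. Each point is then
#' labelled against the baseline `P(A_h)`: `"above"` when the whole interval
#' exceeds it, `"below"` when entirely under it, `"ns"` otherwise.
#'
#' @inheritParams prob_high_given_rankdiff
#' @param n_boot Number of bootstrap replicates (default 1000, minimum 100).
#' @param seed Optional integer seed.
#' @return A `cost_allocation` object whose `table` gains columns `lo`,
#'   `hi` and `label`, plus `n_boot`.
#' @examples
#' ds <- simulate_dominance(abm_config(N = 8, X = 400, seed = 2))
#' hi <- ds[seq(1, 400, by = 2), ]; lo <- ds[seq(2, 400, by = 2), ]
#' lo$type_code <- "PEC"; lo$category <- "lower_cost_aggressive"
#' fit <- bootstrap_allocation(hi, lo, n_boot = 200, seed = 1,
#'                             n_orderings = 100)
#' fit
#' @export
bootstrap_allocation <- function(high, low, h = NULL, n_boot = 1000,
                                 n_orderings = 1000, seed = NULL) {
  stopifnot(n_boot >= 100)
  if (!is.null(seed)) set.seed(seed)
  point <- prob_high_given_rankdiff(high, low, h = h,
                                    n_orderings = n_orderings)
  h <- point$hierarchy
  Rh <- rank_difference(h, high$actor, high$recipient)
  Rl <- rank_difference(h, low$actor, low$recipient)
  R_all <- c(Rh, Rl)
  is_high <- c(rep(TRUE, length(Rh)), rep(FALSE, length(Rl)))
  n <- length(R_all)
  diffs <- point$table$rank_diff
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(diffs))
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    Rb <- R_all[i]
    hb <- is_high[i]
    for (j in seq_along(diffs)) {
      at <- Rb == diffs[j]
      if (any(at)) reps[b, j] <- mean(hb[at])
    }
  }
  point$table$lo <- apply(reps, 2, stats::quantile, probs = 0.025,
                          na.rm = TRUE, names = FALSE)
  point$table$hi <- apply(reps, 2, stats::quantile, probs = 0.975,
                          na.rm = TRUE, names = FALSE)
  point$table$label <- deviation_from_baseline(point$table$lo,
                                               point$table$hi,
                                               point$baseline)
  point$n_boot <- n_boot
  point
}

#' Label deviations from the baseline cost mix
#'
#' `"above"` when the whole interval lies above the baseline probability of
#' higher-cost aggression, `"below"` when entirely below it, `"ns"` when the
#' baseline falls inside the interval.
#'
#' @param lo,hi Bootstrap interval limits per rank difference.
#' @param baseline The overall higher-cost share `P(A_h)`.
#' @return Character vector of labels.
#' @export
deviation_from_baseline <- function(lo, hi, baseline) {
  ifelse(is.na(lo) | is.na(hi), NA_character_,
         ifelse(lo > baseline, "above",
                ifelse(hi < baseline, "below", "ns")))
}

#' @export
print.cost_allocation <- function(x, ...) {
  cat("Cost allocation of aggressive interactions (Bayes' rule)\n")
  cat(sprintf("  baseline P(higher-cost) = %.3f", x$baseline))
  if (!is.null(x$n_boot)) cat("; ", x$n_boot, " bootstrap replicates",
                              sep = "")
  cat("\n")
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cost_allocation <- function(x, ...) {
  tb <- x$table
  graphics::plot(tb$rank_diff, tb$p_high, ylim = c(0, 1), pch = 19,
                 xlab = "signed rank difference (actor - recipient)",
                 ylab = "P(higher-cost | rank difference)", ...)
  if (!is.null(tb$lo))
    graphics::arrows(tb$rank_diff, tb$lo, tb$rank_diff, tb$hi,
                     angle = 90, code = 3, length = 0.03, col = "grey40")
  graphics::abline(h = x$baseline, lty = 3)
  invisible(x)
}
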