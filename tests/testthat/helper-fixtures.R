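# In-code fixtures shared across test files.

# Small hand-built dataset; `present` defaults to everyone involved.
make_events <- function(actor, recipient, type_code = "CHA",
                        present = NULL, group_id = "g1") {
  n <- length(actor)
  all_ids <- sort(unique(c(actor, recipient, unlist(present))))
  df <- data.frame(event_id = sprintf("e%03d", seq_len(n)),
                   order = seq_len(n), group_id = group_id,
                   actor = actor, recipient = recipient,
                   type_code = rep_len(type_code, n),
                   stringsAsFactors = FALSE)
  df$present <- if (is.null(present)) rep(list(all_ids), n) else present
  interactions(df)
}

# Perfectly transitive round-robin: every pair meets `reps` times and the
# individual earlier in `ids` always wins.
transitive_dataset <- function(ids, reps = 5) {
  pairs <- t(combn(ids, 2))
  actor <- rep(pairs[, 1], reps)
  recipient <- rep(pairs[, 2], reps)
  make_events(actor, recipient)
}

# A hand-specified hierarchy object (equally spaced scores).
manual_hierarchy <- function(ids) {
  n <- length(ids)
  h <- data.frame(id = ids, rank = seq_len(n),
                  mean_score = seq(1000, 500, length.out = n),
                  norm_score = seq(1, 0, length.out = n),
                  stringsAsFactors = FALSE)
  class(h) <- c("dom_hierarchy", "data.frame")
  h
}

# Events at chosen signed rank differences under a manual hierarchy: each
# event has rank(actor) - rank(recipient) = R, with the actor rank drawn
# uniformly among feasible ranks.
events_at_diffs <- function(diffs, h, type_code = "CHA") {
  n <- nrow(h)
  actor <- character(0); recipient <- character(0)
  for (R in diffs) {
    lo <- max(1, 1 + R); hi <- min(n, n + R)
    ar <- if (lo == hi) lo else sample(lo:hi, 1)
    actor <- c(actor, h$id[h$rank == ar])
    recipient <- c(recipient, h$id[h$rank == ar - R])
  }
  make_events(actor, recipient, type_code = type_code,
              present = rep(list(h$id), length(diffs)))
}
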