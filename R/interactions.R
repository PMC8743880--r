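#' @keywords internal
"_PACKAGE"

# Interaction-type vocabulary: a-priori cost categories of the eight dyadic
# dominance interaction types (grabs/spins, feather grabs and chases are
# higher-cost; pecks, displacements and gapes lower-cost; the two submissive
# signals form the least-cost category).
TYPE_CATEGORY <- c(
  SPI = "higher_cost_aggressive",
  TAI = "higher_cost_aggressive",
  CHA = "higher_cost_aggressive",
  PEC = "lower_cost_aggressive",
  DIS = "lower_cost_aggressive",
  GAP = "lower_cost_aggressive",
  SUV = "submissive",
  SUB = "submissive"
)

CATEGORIES <- c("higher_cost_aggressive", "lower_cost_aggressive", "submissive")

#' Interaction type and cost-category vocabulary
#'
#' The eight dyadic dominance interaction type codes and their a-priori cost
#' categories. `SPI`, `TAI` and `CHA` are higher-cost aggressive (substantial
#' physical contact or sustained pursuit), `PEC`, `DIS` and `GAP` lower-cost
#' aggressive (brief or contact-free), and `SUV`/`SUB` submissive signals
#' performed by the subordinate.
#'
#' @return A data frame with columns `type_code` and `category`.
#' @export
interaction_categories <- function() {
  data.frame(type_code = names(TYPE_CATEGORY),
             category = unname(TYPE_CATEGORY),
             stringsAsFactors = FALSE)
}

#' Construct a validated interaction dataset
#'
#' An interaction dataset records dyadic dominance interactions in observation
#' order: for each event the actor (the performer: the winner for aggressive
#' interactions, the subordinate signaller for submissive ones), the
#' recipient, the interaction type, its cost category, and the set of
#' individuals present in the (sub)group when the interaction occurred. The
#' present set is required because the permutation null model redraws
#' recipients from it.
#'
#' @param events A data frame with columns `event_id`, `order`, `group_id`,
#'   `actor`, `recipient`, `type_code`, and `present` (a list of character
#'   vectors, or a character vector of ";"-joined ids). A `category` column is
#'   optional; when absent it is derived from `type_code`.
#' @return An object of class `interactions`: a data frame with a `present`
#'   list-column, sorted by `order` (stable within ties).
#' @examples
#' ev <- data.frame(event_id = c("e1", "e2"), order = 1:2, group_id = "g1",
#'                  actor = c("A", "B"), recipient = c("B", "A"),
#'                  type_code = c("CHA", "PEC"))
#' ev$present <- list(c("A", "B", "C"), c("A", "B"))
#' interactions(ev)
#' @export
interactions <- function(events) {
  required <- c("event_id", "order", "group_id", "actor", "recipient",
                "type_code", "present")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ev <- as.data.frame(events, stringsAsFactors = FALSE)
  if (is.character(ev$present))
    ev$present <- strsplit(ev$present, ";", fixed = TRUE)
  if (!is.list(ev$present))
    stop("'present' must be a list of id vectors or a ';'-joined character vector",
         call. = FALSE)
  for (col in c("event_id", "group_id", "actor", "recipient", "type_code"))
    ev[[col]] <- as.character(ev[[col]])
  ev$order <- as.integer(ev$order)
  if (!"category" %in% names(ev)) {
    ev$category <- unname(TYPE_CATEGORY[ev$type_code])
  } else {
    ev$category <- as.character(ev$category)
  }
  ev <- ev[, c("event_id", "order", "group_id", "actor", "recipient",
               "type_code", "category", "present")]
  # stable sort on order; within ties the file sequence stands
  ev <- ev[order(ev$order), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("interactions", "data.frame")
  validate_interactions(ev)
  ev
}

#' Validate an interaction dataset
#'
#' Checks the structural invariants of an [interactions()] dataset: unique
#' event ids, actor distinct from recipient, both participants present in the
#' subgroup, at least two individuals present, known type codes, and
#' category consistent with type code. Errors name the offending event id and
#' the violated rule.
#'
#' @param x An `interactions` object (or coercible data frame).
#' @return `x`, invisibly, if valid.
#' @export
validate_interactions <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  if (anyDuplicated(x$event_id))
    stop("duplicate event_id: ",
         x$event_id[duplicated(x$event_id)][1], call. = FALSE)
  bad_type <- !(x$type_code %in% names(TYPE_CATEGORY))
  if (any(bad_type))
    stop("event ", x$event_id[bad_type][1], ": unknown type_code '",
         x$type_code[bad_type][1], "'", call. = FALSE)
  for (i in seq_len(nrow(x))) {
    id <- x$event_id[i]
    if (is.na(x$order[i]) || x$order[i] < 0)
      stop("event ", id, ": order must be a non-negative integer",
           call. = FALSE)
    if (x$actor[i] == x$recipient[i])
      stop("event ", id, ": actor equals recipient", call. = FALSE)
    pres <- x$present[[i]]
    if (length(pres) < 2)
      stop("event ", id, ": fewer than two individuals present",
           call. = FALSE)
    if (!(x$actor[i] %in% pres))
      stop("event ", id, ": actor not in present set", call. = FALSE)
    if (!(x$recipient[i] %in% pres))
      stop("event ", id, ": recipient not in present set", call. = FALSE)
    if (!identical(x$category[i], unname(TYPE_CATEGORY[x$type_code[i]])))
      stop("event ", id, ": category '", x$category[i],
           "' inconsistent with type_code '", x$type_code[i], "'",
           call. = FALSE)
  }
  invisible(x)
}

#' Individuals observed in a dataset
#'
#' The union of all actors, recipients and present-set members.
#'
#' @param x An `interactions` object.
#' @return Sorted character vector of individual ids.
#' @export
individuals <- function(x) {
  sort(unique(c(x$actor, x$recipient, unlist(x$present))))
}

#' Read an interaction dataset from delimited text
#'
#' Reads a comma- (`.csv`) or tab- (`.tsv`) delimited file with header
#' columns `event_id`, `order`, `group_id`, `actor`, `recipient`,
#' `type_code`, `present` and optionally `category`; `present` is a
#' ";"-joined id list. The result is validated; `category` is derived from
#' `type_code` when the column is absent.
#'
#' @param path Path to a `.csv` or `.tsv` file.
#' @return An `interactions` object.
#' @seealso [write_interactions()]
#' @export
read_interactions <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  required <- c("event_id", "order", "group_id", "actor", "recipient",
                "type_code", "present")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) {
    empty <- data.frame(event_id = character(0), order = integer(0),
                        group_id = character(0), actor = character(0),
                        recipient = character(0), type_code = character(0),
                        category = character(0), stringsAsFactors = FALSE)
    empty$present <- list()
    class(empty) <- c("interactions", "data.frame")
    return(empty)
  }
  interactions(df)
}

#' Write an interaction dataset to delimited text
#'
#' Inverse of [read_interactions()]: writes a `.csv` or `.tsv` (chosen from
#' the extension) that round-trips to an identical dataset. Ids containing
#' the ";" list delimiter are rejected.
#'
#' @param x An `interactions` object.
#' @param path Output path ending in `.csv` or `.tsv`.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path) {
  all_ids <- unique(c(x$actor, x$recipient, unlist(x$present)))
  if (any(grepl(";", all_ids, fixed = TRUE)))
    stop("individual ids must not contain the ';' list delimiter",
         call. = FALSE)
  out <- as.data.frame(x)[, c("event_id", "order", "group_id", "actor",
                              "recipient", "type_code", "category"),
                          drop = FALSE]
  out$present <- vapply(x$present, paste, character(1), collapse = ";")
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Randomly split a dataset into hierarchy and strategy subsets
#'
#' The first step of the analysis: the events are partitioned uniformly at
#' random (without replacement) into a subset used to infer the dominance
#' hierarchy and a disjoint subset used to measure interaction tendencies,
#' removing the circularity of estimating both from the same records. The
#' hierarchy subset receives `round(hier_fraction * n)` events
#' (half-up rounding). Repeating the split with fresh seeds re-allocates
#' membership, which is how the outer iterations of the strategy analysis
#' obtain uncertainty.
#'
#' @param x An `interactions` object with at least two events.
#' @param hier_fraction Proportion of events allocated to the hierarchy
#'   subset, strictly between 0 and 1 (default 0.3).
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `split_result` with elements `hierarchy` and
#'   `strategy` (both `interactions`, original order values preserved),
#'   `hier_fraction` and `seed`.
#' @export
split_dataset <- function(x, hier_fraction = 0.3, seed = NULL) {
  if (!(is.numeric(hier_fraction) && length(hier_fraction) == 1 &&
        hier_fraction > 0 && hier_fraction < 1))
    stop("hier_fraction must be a single number strictly between 0 and 1",
         call. = FALSE)
  n <- nrow(x)
  if (n < 2) stop("need at least two events to split", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_hier <- floor(hier_fraction * n + 0.5)
  n_hier <- max(1L, min(n - 1L, as.integer(n_hier)))
  idx <- sample.int(n, n_hier)
  take <- function(rows) {
    out <- x[rows, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("interactions", "data.frame")
    out
  }
  structure(list(hierarchy = take(sort(idx)),
                 strategy = take(setdiff(seq_len(n), idx)),
                 hier_fraction = hier_fraction,
                 seed = seed),
            class = "split_result")
}

#' Directed dyadic interaction counts
#'
#' Counts the directed interactions for each ordered (actor, recipient) pair.
#' Counts are kept at the dyad level rather than pooled by rank difference
#' because with `N` individuals there are `N - k` dyads at rank difference
#' `k`, so pooling builds in a mechanical gradient. Within a dyad the two
#' directions are counted separately and are generally asymmetric.
#'
#' @param x An `interactions` object.
#' @param ids Individuals to index the matrix by; defaults to
#'   [individuals()] of `x`.
#' @return An integer matrix with rows = actors, columns = recipients;
#'   `counts[a, b]` is the number of events with actor `a` and recipient `b`.
#' @export
directed_dyad_counts <- function(x, ids = individuals(x)) {
  m <- table(factor(x$actor, levels = ids),
             factor(x$recipient, levels = ids))
  m <- matrix(as.integer(m), nrow = length(ids),
              dimnames = list(actor = ids, recipient = ids))
  m
}

#' @export
print.interactions <- function(x, ...) {
  cat("Interaction dataset: ", nrow(x), " events, ",
      length(individuals(x)), " individuals, ",
      length(unique(x$group_id)), " group(s)\n", sep = "")
  if (nrow(x) > 0) {
    tab <- table(x$category)
    cat("Categories: ",
        paste(names(tab), tab, sep = " = ", collapse = ", "), "\n", sep = "")
    utils::head(as.data.frame(x)[, setdiff(names(x), "present")], 6) |>
      print()
  }
  invisible(x)
}

#' @export
summary.interactions <- function(object, ...) {
  cat("Events:        ", nrow(object), "\n")
  cat("Individuals:   ", length(individuals(object)), "\n")
  if (nrow(object) > 0) {
    cat("Groups:        ", paste(unique(object$group_id), collapse = ", "), "\n")
    cat("Mean subgroup size:",
        round(mean(lengths(object$present)), 2), "\n")
    print(table(category = object$category, type = object$type_code))
  }
  invisible(object)
}
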