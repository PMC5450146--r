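# Classification scoring: six outcome categories with "ranks off"
# distances, per-source aggregation, and per-clade breakdown.

OUTCOME_CATEGORIES <- c("correct", "undercalled", "overcalled",
                        "miscalled_sibling", "miscalled", "dropped")

# severity used for per-source tie-breaking; dropped is handled separately
SEVERITY <- c(correct = 0, undercalled = 1, overcalled = 2,
              miscalled_sibling = 3, miscalled = 4)

#' Score one read's classification against its true lineage
#'
#' The truth is truncated at the target rank (species or genus), giving T
#' of depth dT; the called lineage C is compared positionally. Outcomes:
#' \itemize{
#'  \item no call: `dropped`;
#'  \item C extends beyond the full truth lineage along its path:
#'    `overcalled`, ranks_off depth(C) - depth(full truth) (e.g. a strain
#'    called when the truth only reaches species);
#'  \item C reaches at least depth dT and agrees with T through dT:
#'    `correct` (ranks_off 0) -- a species-depth call scored at genus
#'    resolution is correct when the genus is right;
#'  \item C a strict ancestor of T: `undercalled`, ranks_off dT - depth(C)
#'    (right clade, insufficient resolution);
#'  \item C reaches depth dT, agreeing with T through the parent but
#'    differing at the target leaf: `miscalled_sibling`, ranks_off 1
#'    (wrong species, correct genus);
#'  \item otherwise: `miscalled`, ranks_off dT - lca_depth(T, C) (wrong
#'    clade; the distance back to the common ancestor).
#' }
#' Overcalling is judged against the truth's own depth, not the target
#' depth: a call that is deeper than the target but within the truth's
#' resolution carries no overconfidence. Ranks off counts every lineage
#' field, not only canonical ranks, so deep reference ladders yield
#' correspondingly large distances.
#'
#' @param true_lineage The source organism's `ranked_lineage` (must
#'   contain the target rank).
#' @param called_lineage The pipeline's `ranked_lineage`, or `NULL`/`NA`
#'   for a read lost before classification.
#' @param target_rank `"species"` or `"genus"`.
#' @param rank_labels Ladder used to locate `target_rank` when the lineage
#'   carries no rank labels; default [canonical_ranks()].
#' @return A list with `category` and `ranks_off`.
#' @export
per_read_outcome <- function(true_lineage, called_lineage, target_rank,
                             rank_labels = canonical_ranks()) {
  pos <- rank_position(true_lineage, target_rank, rank_labels)
  if (is.na(pos)) {
    stop("target rank '", target_rank, "' absent from true lineage")
  }
  truth <- truncate_lineage(true_lineage, pos)
  dT <- length(truth)
  none <- is.null(called_lineage) ||
    (length(called_lineage) == 1L && is.na(called_lineage))
  if (none) return(list(category = "dropped", ranks_off = NA_real_))
  called <- called_lineage
  dC <- length(called)
  dF <- length(true_lineage)
  if (dC > dF && lca_depth(true_lineage, called) == dF) {
    return(list(category = "overcalled", ranks_off = dC - dF))
  }
  d <- lca_depth(truth, called)
  if (dC >= dT && d == dT) {
    list(category = "correct", ranks_off = 0)
  } else if (dC < dT && d == dC) {
    list(category = "undercalled", ranks_off = dT - dC)
  } else if (dC >= dT && d == dT - 1L) {
    list(category = "miscalled_sibling", ranks_off = 1)
  } else {
    list(category = "miscalled", ranks_off = dT - d)
  }
}

#' Read-level outcomes for an OTU table against the mapping
#'
#' Joins every mapping read to its OTU-table row (absent or
#' empty-taxonomy rows score as `dropped`) and applies
#' [per_read_outcome()].
#'
#' @param otu An OTU-table data frame.
#' @param mapping A gold-standard mapping data frame.
#' @inheritParams per_read_outcome
#' @return Data frame: `read_id`, `community_id`, `source_accession`,
#'   `taxonomy_string` (truth), `category`, `ranks_off`.
#' @export
read_outcomes <- function(otu, mapping, target_rank,
                          rank_labels = canonical_ranks()) {
  idx <- match(mapping$read_id, otu$seq)
  called_str <- otu$taxonomy_string[idx]
  n <- nrow(mapping)
  category <- character(n); ranks_off <- numeric(n)
  true_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    ts <- mapping$taxonomy_string[i]
    truth <- get0(ts, envir = true_cache) %||% {
      lin <- parse_lineage(ts)
      assign(ts, lin, envir = true_cache)
      lin
    }
    called <- if (is.na(called_str[i]) || !nzchar(called_str[i])) NULL
              else parse_lineage(called_str[i])
    o <- per_read_outcome(truth, called, target_rank, rank_labels)
    category[i] <- o$category; ranks_off[i] <- o$ranks_off
  }
  data.frame(read_id = mapping$read_id,
             community_id = mapping$community_id,
             source_accession = mapping$source_accession,
             taxonomy_string = mapping$taxonomy_string,
             category = category, ranks_off = ranks_off,
             stringsAsFactors = FALSE)
}

#' Aggregate the reads of one source organism into one outcome
#'
#' If every read is dropped the source is `dropped`. Otherwise, under the
#' default `"plurality"` strategy the modal category among non-dropped
#' reads wins, ties broken towards the more severe category (miscalled >
#' miscalled_sibling > overcalled > undercalled > correct); under
#' `"worst_case"` the most severe category present wins regardless of
#' counts. Either way `ranks_off` is the median ranks_off of the reads in
#' the winning category.
#'
#' @param categories Character vector of read-level categories.
#' @param ranks_off Numeric vector of read-level ranks_off.
#' @param strategy `"plurality"` or `"worst_case"`.
#' @return A list with `category` and `ranks_off`.
#' @export
per_source_outcome <- function(categories, ranks_off,
                               strategy = c("plurality", "worst_case")) {
  strategy <- match.arg(strategy)
  stopifnot(length(categories) > 0L)
  live <- categories != "dropped"
  if (!any(live)) return(list(category = "dropped", ranks_off = NA_real_))
  cats <- categories[live]; ro <- ranks_off[live]
  winner <- if (strategy == "worst_case") {
    names(which.max(SEVERITY[unique(cats)]))
  } else {
    counts <- table(cats)
    top <- names(counts)[counts == max(counts)]
    top[which.max(SEVERITY[top])]
  }
  list(category = winner,
       ranks_off = stats::median(ro[cats == winner]))
}

#' Score a full classification run
#'
#' Computes read-level outcomes, then aggregates them per source organism
#' (one source = one accession within one community).
#'
#' @inheritParams read_outcomes
#' @param strategy Passed to [per_source_outcome()].
#' @return Data frame with one row per source: `community_id`,
#'   `source_accession`, `taxonomy_string`, `n_reads`, `category`,
#'   `ranks_off`. Read-level outcomes are in the `reads` attribute.
#' @export
evaluate_classification <- function(otu, mapping, target_rank,
                                    strategy = c("plurality", "worst_case"),
                                    rank_labels = canonical_ranks()) {
  strategy <- match.arg(strategy)
  reads <- read_outcomes(otu, mapping, target_rank, rank_labels)
  key <- paste(reads$community_id, reads$source_accession, sep = "\r")
  groups <- split(seq_len(nrow(reads)), key)
  rows <- lapply(groups, function(ix) {
    o <- per_source_outcome(reads$category[ix], reads$ranks_off[ix], strategy)
    data.frame(community_id = reads$community_id[ix[1]],
               source_accession = reads$source_accession[ix[1]],
               taxonomy_string = reads$taxonomy_string[ix[1]],
               n_reads = length(ix),
               category = o$category, ranks_off = o$ranks_off,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reads") <- reads
  out
}

#' Summarize source outcomes into a classification report
#'
#' Percent of source organisms per category (summing to 100), with
#' median (min--max) ranks-off for the undercalled, miscalled and
#' overcalled categories.
#'
#' @param source_outcomes Output of [evaluate_classification()] (or any
#'   data frame with `category` and `ranks_off` columns keyed by source).
#' @return A list with `percent` (named vector over all six categories),
#'   `ranks_off` (data frame: category, median, min, max) and `n_sources`.
#' @export
summarize_outcomes <- function(source_outcomes) {
  n <- nrow(source_outcomes)
  if (is.null(n) || n == 0L) stop("no source outcomes to summarize")
  counts <- table(factor(source_outcomes$category,
                         levels = OUTCOME_CATEGORIES))
  percent <- 100 * as.vector(counts) / n
  names(percent) <- OUTCOME_CATEGORIES
  ro <- do.call(rbind, lapply(c("undercalled", "miscalled", "overcalled"),
    function(cat) {
      x <- source_outcomes$ranks_off[source_outcomes$category == cat]
      if (length(x) == 0L) {
        data.frame(category = cat, median = NA_real_, min = NA_real_,
                   max = NA_real_, stringsAsFactors = FALSE)
      } else {
        data.frame(category = cat, median = stats::median(x), min = min(x),
                   max = max(x), stringsAsFactors = FALSE)
      }
    }))
  list(percent = percent, ranks_off = ro, n_sources = n)
}

#' Read-fraction summary of classification outcomes
#'
#' An alternative to per-source voting: each source contributes the
#' fraction of its reads falling in each category, and those fractions
#' are averaged over sources. Brackets the plurality and worst-case
#' per-source strategies.
#'
#' @inheritParams read_outcomes
#' @return Named numeric vector of percentages over the six categories.
#' @export
summarize_read_fractions <- function(otu, mapping, target_rank,
                                     rank_labels = canonical_ranks()) {
  reads <- read_outcomes(otu, mapping, target_rank, rank_labels)
  key <- paste(reads$community_id, reads$source_accession, sep = "\r")
  per_source <- t(vapply(split(reads$category, key), function(cats) {
    as.vector(table(factor(cats, levels = OUTCOME_CATEGORIES))) / length(cats)
  }, numeric(length(OUTCOME_CATEGORIES))))
  stats::setNames(100 * colMeans(per_source), OUTCOME_CATEGORIES)
}

#' Break classification outcomes down by clade
#'
#' Groups sources by the taxon at a named rank of their true lineage
#' (default "order") and reports per-clade percentages and mean ranks-off,
#' mirroring per-clade performance tables. Sources whose lineage does not
#' reach the requested rank are grouped under `"unresolved"`.
#'
#' @param source_outcomes Output of [evaluate_classification()].
#' @param rank Rank to group by, default `"order"`.
#' @param rank_labels Ladder used to locate `rank`; default
#'   [canonical_ranks()].
#' @return Data frame keyed by clade: `n_sources`, percent per category
#'   (`pct_correct`, `pct_miscalled`, `pct_undercalled`, `pct_overcalled`,
#'   `pct_miscalled_sibling`, `pct_dropped`) and mean ranks-off for
#'   miscalled and undercalled sources.
#' @export
aggregate_by_clade <- function(source_outcomes, rank = "order",
                               rank_labels = canonical_ranks()) {
  clade <- vapply(source_outcomes$taxonomy_string, function(ts) {
    lin <- parse_lineage(ts)
    pos <- rank_position(lin, rank, rank_labels)
    if (is.na(pos)) "unresolved" else unclass(lin)[pos]
  }, character(1), USE.NAMES = FALSE)
  rows <- lapply(split(seq_len(nrow(source_outcomes)), clade), function(ix) {
    d <- source_outcomes[ix, , drop = FALSE]
    counts <- table(factor(d$category, levels = OUTCOME_CATEGORIES))
    pct <- 100 * as.vector(counts) / nrow(d)
    names(pct) <- paste0("pct_", OUTCOME_CATEGORIES)
    mean_ro <- function(cat) {
      x <- d$ranks_off[d$category == cat]
      if (length(x)) mean(x) else NA_real_
    }
    cbind(data.frame(clade = clade[ix[1]], n_sources = nrow(d),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(pct)),
          data.frame(mean_ranks_off_miscalled = mean_ro("miscalled"),
                     mean_ranks_off_undercalled = mean_ro("undercalled")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
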