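# Elicitation: stakeholder vote panels -> criterion ranking, option scores,
# majority decisions, and SMART swing-weighted criterion weights.
#
# Aggregation conventions, fixed deliberately: the mean is used for rank
# votes and the median for option-score and importance-ratio votes (the
# median damps outlier votes in the open-scale quantities). The even-n
# median is the arithmetic midpoint of the two central values.

#' Construct a stakeholder vote panel
#'
#' @param rank_votes integer matrix, one row per participant and one column
#'   per criterion id; each row must be a permutation of 1..K
#'   (1 = most important).
#' @param ratio_votes optional numeric matrix, one row per participant and
#'   one column per adjacent rank pair ordered from (rank 1 vs rank 2) down
#'   to (rank K-1 vs rank K); entries are importance multipliers >= 1
#'   ("how much more important is the higher-ranked criterion?").
#' @param option_score_votes optional data.frame with columns `participant`,
#'   `criterion_id`, `option_label`, `score` (percentages in [0, 100]).
#' @param modification_votes optional named list of logical vectors, one per
#'   proposal.
#' @param participants participant ids; defaults to the rank-vote rownames
#'   or `p1..pn`.
#' @return an object of class `vote_panel`.
#' @export
vote_panel <- function(rank_votes, ratio_votes = NULL,
                       option_score_votes = NULL, modification_votes = NULL,
                       participants = NULL) {
  rank_votes <- as.matrix(rank_votes)
  if (is.null(colnames(rank_votes))) {
    abort_mcda("rank_votes must have criterion ids as column names",
               "mcda_validation_error")
  }
  K <- ncol(rank_votes)
  for (i in seq_len(nrow(rank_votes))) {
    if (!identical(sort(as.integer(rank_votes[i, ])), seq_len(K))) {
      abort_mcda(sprintf("rank vote of participant %d is not a permutation of 1..%d",
                         i, K), "mcda_validation_error")
    }
  }
  if (!is.null(ratio_votes)) {
    ratio_votes <- as.matrix(ratio_votes)
    if (ncol(ratio_votes) != K - 1) {
      abort_mcda(sprintf("ratio_votes needs %d adjacent-pair columns, got %d",
                         K - 1, ncol(ratio_votes)), "mcda_validation_error")
    }
    if (any(ratio_votes < 1 | !is.finite(ratio_votes))) {
      abort_mcda("all importance-ratio votes must be finite and >= 1",
                 "mcda_validation_error")
    }
  }
  if (!is.null(option_score_votes)) {
    stopifnot(all(c("participant", "criterion_id", "option_label", "score")
                  %in% names(option_score_votes)))
    if (any(option_score_votes$score < 0 | option_score_votes$score > 100)) {
      abort_mcda("option-score votes must lie in [0, 100]",
                 "mcda_validation_error")
    }
  }
  participants <- participants %||% rownames(rank_votes) %||%
    paste0("p", seq_len(nrow(rank_votes)))
  structure(
    list(participants = participants,
         rank_votes = rank_votes,
         ratio_votes = ratio_votes,
         option_score_votes = option_score_votes,
         modification_votes = modification_votes),
    class = "vote_panel"
  )
}

#' @export
print.vote_panel <- function(x, ...) {
  cat(sprintf("<vote_panel> %d participants, %d criteria%s%s\n",
              length(x$participants), ncol(x$rank_votes),
              if (!is.null(x$ratio_votes)) ", ratio votes" else "",
              if (!is.null(x$option_score_votes)) ", option-score votes" else ""))
  invisible(x)
}

#' Aggregate option-score votes to score fractions
#'
#' Each option's fraction is the median of its percentage votes divided by
#' 100; the median (rather than the mean) damps outlier votes. For an even
#' number of votes the median is the midpoint of the two central values.
#'
#' @param panel a [vote_panel()] carrying `option_score_votes`.
#' @return a data.frame with columns `criterion_id`, `option_label`,
#'   `score_fraction`, `n_votes`.
#' @export
aggregate_option_scores <- function(panel) {
  osv <- panel$option_score_votes
  if (is.null(osv) || nrow(osv) == 0) {
    abort_mcda("panel carries no option-score votes", "mcda_missing_votes")
  }
  key <- interaction(osv$criterion_id, osv$option_label, drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(osv, key), function(d) {
    data.frame(criterion_id = d$criterion_id[[1]],
               option_label = d$option_label[[1]],
               score_fraction = stats::median(d$score) / 100,
               n_votes = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$criterion_id, agg$option_label), , drop = FALSE]
}

#' Aggregate rank votes to a consensus criterion ordering
#'
#' Criteria are ordered by ascending mean rank across participants. Ties are
#' broken by ascending median rank, then lexicographic criterion id, so the
#' output is deterministic. Output positions are relabelled 1..K.
#'
#' @param panel a [vote_panel()].
#' @return a data.frame with columns `criterion_id`, `rank` (consensus,
#'   1..K), `mean_rank`, `median_rank`, ordered by consensus rank.
#' @export
aggregate_ranking <- function(panel) {
  rv <- panel$rank_votes
  means <- colMeans(rv)
  medians <- apply(rv, 2, stats::median)
  ord <- order(means, medians, colnames(rv))
  data.frame(criterion_id = colnames(rv)[ord],
             rank = seq_len(ncol(rv)),
             mean_rank = as.numeric(means[ord]),
             median_rank = as.numeric(medians[ord]),
             stringsAsFactors = FALSE)
}

#' Strict-majority decision on a modification proposal
#'
#' A proposal passes only when strictly more than half of the votes are in
#' favour: 9 of 16 passes, 8 of 16 (exactly half) does not.
#'
#' @param votes logical vector, one vote per participant.
#' @return `TRUE` iff yes-votes exceed half the vote count.
#' @export
majority_pass <- function(votes) {
  votes <- as.logical(votes)
  if (length(votes) == 0 || anyNA(votes)) {
    abort_mcda("votes must be a non-empty logical vector without NA",
               "mcda_validation_error")
  }
  sum(votes) > length(votes) / 2
}

#' SMART swing weights from adjacent importance ratios
#'
#' Given the elicited ratios r_k = (importance of the rank-k criterion) /
#' (importance of the rank-(k+1) criterion) for k = 1..K-1, the raw weight
#' of the last-ranked criterion is set to 1 and each higher rank multiplies
#' up: raw_k = r_k * raw_(k+1). Raw weights are then normalized to sum to
#' 100. Ratios >= 1 guarantee weights non-increasing in rank.
#'
#' @param adjacent_ratios numeric vector of K-1 ratios, ordered from the
#'   (rank 1 vs rank 2) comparison down to (rank K-1 vs rank K); all >= 1.
#' @param ids optional criterion ids in rank order (length K) used to name
#'   the result.
#' @return an object of class `weight_vector`: a named numeric vector of
#'   percentage weights summing to 100, in rank order, with a `provenance`
#'   attribute (`"elicited"`) and the raw pre-normalization weights in
#'   attribute `raw`.
#' @export
#' @examples
#' swing_weights(c(3))            # K = 2, 3:1 -> (75, 25)
#' swing_weights(rep(1, 3))       # K = 4, equal -> (25, 25, 25, 25)
swing_weights <- function(adjacent_ratios, ids = NULL) {
  K <- length(adjacent_ratios) + 1L
  if (!is.null(ids) && length(ids) != K) {
    abort_mcda(sprintf("%d criteria require %d adjacent ratios, got %d",
                       length(ids), length(ids) - 1L, length(adjacent_ratios)),
               "mcda_validation_error")
  }
  if (any(!is.finite(adjacent_ratios) | adjacent_ratios < 1)) {
    abort_mcda("all adjacent importance ratios must be finite and >= 1",
               "mcda_validation_error")
  }
  raw <- rev(cumprod(c(1, rev(adjacent_ratios))))
  w <- 100 * raw / sum(raw)
  if (!is.null(ids)) {
    names(w) <- ids
  } else {
    names(w) <- paste0("rank", seq_len(K))
  }
  structure(w, class = c("weight_vector", "numeric"),
            provenance = "elicited", raw = raw)
}

#' Aggregate per-pair importance-ratio votes
#'
#' The panel's consensus ratio for each adjacent rank pair is the median of
#' that pair's votes across participants (midpoint convention for even n).
#'
#' @param panel a [vote_panel()] carrying `ratio_votes`.
#' @return numeric vector of K-1 median ratios, in pair order.
#' @export
aggregate_ratio_votes <- function(panel) {
  rv <- panel$ratio_votes
  if (is.null(rv)) abort_mcda("panel carries no ratio votes", "mcda_missing_votes")
  if (any(is.na(rv))) {
    bad <- which(apply(rv, 2, anyNA))
    abort_mcda(paste0("missing ratio votes for adjacent pair(s): ",
                      paste(bad, collapse = ", ")), "mcda_missing_votes")
  }
  apply(rv, 2, stats::median)
}

#' Run the full weight-elicitation pipeline on a panel
#'
#' Ranks criteria by mean rank vote, aggregates the adjacent-pair importance
#' ratios by median, and converts them to normalized SMART swing weights.
#' The returned audit trail records every intermediate quantity.
#'
#' @param panel a [vote_panel()] with rank and ratio votes.
#' @return a list with elements `ranking` (from [aggregate_ranking()]),
#'   `ratios` (median per-pair ratios), `weights` (a `weight_vector` named
#'   by criterion id in consensus rank order), and `audit` (data.frame with
#'   per-rank raw and normalized weights).
#' @export
elicit_weights <- function(panel) {
  ranking <- aggregate_ranking(panel)
  ratios <- aggregate_ratio_votes(panel)
  w <- swing_weights(ratios, ids = ranking$criterion_id)
  audit <- data.frame(
    rank = ranking$rank,
    criterion_id = ranking$criterion_id,
    mean_rank_vote = ranking$mean_rank,
    ratio_to_next = c(ratios, NA),
    raw_weight = attr(w, "raw"),
    weight = as.numeric(w),
    display_weight = display_weights(as.numeric(w)),
    stringsAsFactors = FALSE
  )
  rownames(audit) <- NULL
  list(ranking = ranking, ratios = ratios, weights = w, audit = audit)
}

#' Write elicited weights into a configuration
#'
#' Replaces each criterion's rank and weight with the elicited consensus
#' values and clears the `weights_stale` flag.
#'
#' @param config an `mcda_config` whose criterion ids match the elicitation.
#' @param elicited result of [elicit_weights()].
#' @return a valid `mcda_config` with elicited ranks and weights.
#' @export
set_elicited_weights <- function(config, elicited) {
  ids <- criterion_ids(config)
  if (!setequal(ids, elicited$ranking$criterion_id)) {
    abort_mcda("elicitation criteria do not match the configuration",
               "mcda_validation_error")
  }
  crits <- lapply(config$criteria, function(cr) {
    i <- match(cr$id, elicited$ranking$criterion_id)
    cr$rank <- as.integer(elicited$ranking$rank[[i]])
    cr$weight <- as.numeric(elicited$weights[[cr$id]])
    cr
  })
  tool_config(crits, threshold = config$threshold,
              weight_tolerance = max(config$weight_tolerance, 1e-6),
              weights_stale = FALSE,
              schema_version = config$schema_version)
}

# ---- long-format vote table I/O -------------------------------------------
#
# Delimited long format, one vote per row:
#   participant, vote_type (rank | ratio | option_score | modification),
#   item, value
# rank:          item = criterion id,            value = rank 1..K
# ratio:         item = pair index 1..K-1,       value = ratio >= 1
# option_score:  item = "criterion_id|label",    value = percent 0..100
# modification:  item = proposal id,             value = 0/1

#' Read a vote panel from a long-format delimited table
#'
#' @param path CSV file with columns `participant`, `vote_type`, `item`,
#'   `value` (see package vignette for the row conventions).
#' @return a [vote_panel()].
#' @export
read_vote_panel <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("participant", "vote_type", "item", "value")
  if (!all(need %in% names(d))) {
    abort_mcda(paste0("vote table must have columns: ", paste(need, collapse = ", ")),
               "mcda_schema_error")
  }
  ranks <- d[d$vote_type == "rank", ]
  if (nrow(ranks) == 0) abort_mcda("vote table has no rank votes", "mcda_missing_votes")
  d$participant <- as.character(d$participant)
  d$item <- as.character(d$item)
  ranks <- d[d$vote_type == "rank", ]
  parts <- unique(d$participant)
  crit_ids <- unique(ranks$item)
  rank_votes <- matrix(NA_integer_, nrow = length(parts), ncol = length(crit_ids),
                       dimnames = list(parts, crit_ids))
  for (i in seq_len(nrow(ranks))) {
    rank_votes[ranks$participant[[i]], ranks$item[[i]]] <- as.integer(ranks$value[[i]])
  }
  if (anyNA(rank_votes)) {
    abort_mcda("incomplete rank votes: every participant must rank every criterion",
               "mcda_missing_votes")
  }
  ratios <- d[d$vote_type == "ratio", ]
  ratio_votes <- NULL
  if (nrow(ratios) > 0) {
    K <- length(crit_ids)
    pairs_seen <- sort(unique(as.integer(ratios$item)))
    if (!identical(pairs_seen, seq_len(K - 1))) {
      missing <- setdiff(seq_len(K - 1), pairs_seen)
      abort_mcda(paste0("missing ratio votes for adjacent pair(s): ",
                        paste(missing, collapse = ", ")), "mcda_missing_votes")
    }
    ratio_votes <- matrix(NA_real_, nrow = length(parts), ncol = K - 1,
                          dimnames = list(parts, paste0("pair", seq_len(K - 1))))
    for (i in seq_len(nrow(ratios))) {
      ratio_votes[ratios$participant[[i]], as.integer(ratios$item[[i]])] <-
        as.numeric(ratios$value[[i]])
    }
    if (anyNA(ratio_votes)) {
      abort_mcda("incomplete ratio votes: every participant must vote every pair",
                 "mcda_missing_votes")
    }
  }
  scores <- d[d$vote_type == "option_score", ]
  option_score_votes <- NULL
  if (nrow(scores) > 0) {
    split_items <- strsplit(scores$item, "|", fixed = TRUE)
    option_score_votes <- data.frame(
      participant = scores$participant,
      criterion_id = vapply(split_items, `[[`, character(1), 1),
      option_label = vapply(split_items, function(x) paste(x[-1], collapse = "|"),
                            character(1)),
      score = as.numeric(scores$value),
      stringsAsFactors = FALSE
    )
  }
  mods <- d[d$vote_type == "modification", ]
  modification_votes <- NULL
  if (nrow(mods) > 0) {
    modification_votes <- lapply(split(mods, mods$item),
                                 function(m) as.logical(as.numeric(m$value)))
  }
  vote_panel(rank_votes, ratio_votes, option_score_votes, modification_votes,
             participants = parts)
}

#' Write a vote panel as a long-format delimited table
#'
#' Inverse of [read_vote_panel()]: the written file can be fed back into the
#' elicitation pipeline verbatim.
#'
#' @param panel a [vote_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vote_panel <- function(panel, path) {
  rows <- list()
  rv <- panel$rank_votes
  for (p in seq_len(nrow(rv))) {
    rows[[length(rows) + 1]] <- data.frame(
      participant = panel$participants[[p]], vote_type = "rank",
      item = colnames(rv), value = as.numeric(rv[p, ]),
      stringsAsFactors = FALSE)
  }
  if (!is.null(panel$ratio_votes)) {
    qv <- panel$ratio_votes
    for (p in seq_len(nrow(qv))) {
      rows[[length(rows) + 1]] <- data.frame(
        participant = panel$participants[[p]], vote_type = "ratio",
        item = as.character(seq_len(ncol(qv))), value = as.numeric(qv[p, ]),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(panel$option_score_votes)) {
    osv <- panel$option_score_votes
    rows[[length(rows) + 1]] <- data.frame(
      participant = osv$participant, vote_type = "option_score",
      item = paste(osv$criterion_id, osv$option_label, sep = "|"),
      value = osv$score, stringsAsFactors = FALSE)
  }
  if (!is.null(panel$modification_votes)) {
    for (id in names(panel$modification_votes)) {
      v <- panel$modification_votes[[id]]
      rows[[length(rows) + 1]] <- data.frame(
        participant = panel$participants[seq_along(v)], vote_type = "modification",
        item = id, value = as.numeric(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
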