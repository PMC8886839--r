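# Configuration model: criteria, scoring functions, weights, threshold.
#
# A tender configuration is a list of weighted criteria. Every non-external
# criterion carries an ordered categorical scoring function (a list of
# labelled options mapping to fractions of the criterion weight); the
# pharmacovigilance criterion instead takes an externally supplied
# percentage from the national drug authority. Certain option levels are
# hard exclusion triggers that disqualify a bid outright.

#' Construct a scoring option
#'
#' One level of a criterion's categorical scoring function: a label, the
#' fraction of the criterion weight it earns, and whether selecting it is a
#' hard exclusion trigger. Trigger options must carry fraction 0.
#'
#' @param label short descriptive text, unique within its criterion.
#' @param score_fraction fraction of the criterion weight earned, in [0, 1].
#' @param exclusion_trigger logical; selecting this option disqualifies the
#'   bid from the tender regardless of any other score.
#' @param provisional logical; marks a placeholder fraction that a scoring
#'   committee is expected to revise (config data, freely editable).
#' @return an object of class `scoring_option`.
#' @export
#' @examples
#' scoring_option("full manufacturing in Egypt", 1)
#' scoring_option("no GMP certificate", 0, exclusion_trigger = TRUE)
scoring_option <- function(label, score_fraction, exclusion_trigger = FALSE,
                           provisional = FALSE) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  opt <- structure(
    list(
      label = label,
      score_fraction = as.numeric(score_fraction),
      exclusion_trigger = isTRUE(exclusion_trigger),
      provisional = isTRUE(provisional)
    ),
    class = "scoring_option"
  )
  viol <- validate_scoring_option(opt, path = label)
  if (nrow(viol) > 0) abort_mcda(format_violations(viol), "mcda_validation_error")
  opt
}

validate_scoring_option <- function(opt, path) {
  v <- violations()
  if (!is.numeric(opt$score_fraction) || length(opt$score_fraction) != 1L ||
      is.na(opt$score_fraction) ||
      opt$score_fraction < 0 || opt$score_fraction > 1) {
    v <- add_violation(v, paste0(path, ".score_fraction"),
                       "score_fraction must be a number in [0, 1]")
  } else if (opt$exclusion_trigger && opt$score_fraction != 0) {
    v <- add_violation(v, paste0(path, ".score_fraction"),
                       "an exclusion-trigger option must have score_fraction 0")
  }
  v
}

#' Construct a tender criterion
#'
#' @param id unique machine token (used as the column name in bid tables).
#' @param name display text.
#' @param rank importance position, 1 = most important; ranks across a
#'   configuration must form a permutation of 1..K.
#' @param weight criterion weight in percentage points (weights across a
#'   configuration sum to 100).
#' @param options list of [scoring_option()] levels, ordered best to worst
#'   by convention; empty for external-score criteria.
#' @param external_score logical; `TRUE` only for the pharmacovigilance
#'   criterion, whose fraction is supplied externally as a percentage rather
#'   than chosen from options.
#' @return an object of class `mcda_criterion`.
#' @export
criterion <- function(id, name, rank, weight, options = list(),
                      external_score = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  crit <- structure(
    list(
      id = id,
      name = as.character(name),
      rank = as.integer(rank),
      weight = as.numeric(weight),
      options = options,
      external_score = isTRUE(external_score)
    ),
    class = "mcda_criterion"
  )
  viol <- validate_criterion(crit, path = id)
  if (nrow(viol) > 0) abort_mcda(format_violations(viol), "mcda_validation_error")
  crit
}

validate_criterion <- function(crit, path) {
  v <- violations()
  if (is.na(crit$weight) || crit$weight < 0) {
    v <- add_violation(v, paste0(path, ".weight"), "weight must be >= 0")
  }
  if (is.na(crit$rank) || crit$rank < 1) {
    v <- add_violation(v, paste0(path, ".rank"), "rank must be a positive integer")
  }
  if (crit$external_score) {
    if (length(crit$options) > 0) {
      v <- add_violation(v, paste0(path, ".options"),
                         "an external-score criterion takes no options")
    }
  } else {
    if (length(crit$options) < 2) {
      v <- add_violation(v, paste0(path, ".options"),
                         "a scored criterion needs at least 2 options")
    }
    labels <- vapply(crit$options, function(o) o$label, character(1))
    if (anyDuplicated(labels)) {
      v <- add_violation(v, paste0(path, ".options"),
                         paste0("duplicate option labels: ",
                                paste(unique(labels[duplicated(labels)]),
                                      collapse = ", ")))
    }
    for (o in crit$options) {
      v <- rbind(v, validate_scoring_option(
        o, paste0(path, ".options.", o$label)))
    }
  }
  v
}

#' Construct a tool configuration
#'
#' @param criteria list of [criterion()] objects; ranks must be a
#'   permutation of 1..K and weights must sum to 100 within
#'   `weight_tolerance` (unless `weights_stale`).
#' @param threshold qualification threshold in points on the 0-100 scale; a
#'   bid qualifies for the financial phase iff it has no exclusion trigger
#'   and its total score is `>= threshold`.
#' @param weight_tolerance absolute tolerance for the sum-to-100 check.
#' @param weights_stale logical; `TRUE` marks a configuration whose criteria
#'   list changed after the weights were elicited (e.g. after
#'   [apply_modification()]), suspending the sum-to-100 check until weights
#'   are re-elicited.
#' @param schema_version integer config schema version.
#' @return an object of class `mcda_config`.
#' @export
tool_config <- function(criteria, threshold = 65, weight_tolerance = 0.01,
                        weights_stale = FALSE, schema_version = 1L) {
  cfg <- structure(
    list(
      schema_version = as.integer(schema_version),
      threshold = as.numeric(threshold),
      weight_tolerance = as.numeric(weight_tolerance),
      weights_stale = isTRUE(weights_stale),
      criteria = criteria
    ),
    class = "mcda_config"
  )
  viol <- validate_config(cfg)
  if (nrow(viol) > 0) abort_mcda(format_violations(viol), "mcda_validation_error")
  cfg
}

violations <- function() {
  data.frame(field = character(), message = character(),
             stringsAsFactors = FALSE)
}

add_violation <- function(v, field, message) {
  rbind(v, data.frame(field = field, message = message,
                      stringsAsFactors = FALSE))
}

format_violations <- function(v) {
  paste0("invalid configuration:\n",
         paste0("  - ", v$field, ": ", v$message, collapse = "\n"))
}

#' Validate a tool configuration
#'
#' Checks every structural invariant (rank permutation, weight sum, option
#' fractions, exclusion-trigger zeros, external-score shape) and returns the
#' violations as structured records rather than failing on the first.
#'
#' @param config an `mcda_config` (or a plain list with the same shape).
#' @return a data.frame with columns `field` (path of the offending field)
#'   and `message`; zero rows when the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- violations()
  if (length(config$criteria) == 0) {
    return(add_violation(v, "criteria", "criteria list must be non-empty"))
  }
  ids <- vapply(config$criteria, function(cr) cr$id, character(1))
  if (anyDuplicated(ids)) {
    v <- add_violation(v, "criteria",
                       paste0("duplicate criterion ids: ",
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  ranks <- vapply(config$criteria, function(cr) as.integer(cr$rank), integer(1))
  if (!identical(sort(ranks), seq_along(ranks))) {
    v <- add_violation(
      v, "criteria.rank",
      paste0("ranks (", paste(ranks, collapse = ", "),
             ") must be a permutation of 1..", length(ranks)))
  }
  if (!isTRUE(config$weights_stale)) {
    wsum <- sum(vapply(config$criteria, function(cr) cr$weight, numeric(1)))
    if (abs(wsum - 100) > config$weight_tolerance) {
      v <- add_violation(
        v, "criteria.weight",
        sprintf("weights sum to %.6g, not 100 within tolerance %g",
                wsum, config$weight_tolerance))
    }
  }
  if (is.na(config$threshold) || config$threshold <= 0 || config$threshold > 100) {
    v <- add_violation(v, "threshold", "threshold must lie in (0, 100]")
  }
  for (cr in config$criteria) {
    v <- rbind(v, validate_criterion(cr, paste0("criteria.", cr$id)))
  }
  v
}

criterion_ids <- function(config) {
  vapply(config$criteria, function(cr) cr$id, character(1))
}

get_criterion <- function(config, id) {
  for (cr in config$criteria) if (cr$id == id) return(cr)
  abort_mcda(paste0("unknown criterion id: ", id), "mcda_unknown_id")
}

config_weights <- function(config) {
  w <- vapply(config$criteria, function(cr) cr$weight, numeric(1))
  names(w) <- criterion_ids(config)
  w
}

#' @export
print.mcda_config <- function(x, ...) {
  cat(sprintf("<mcda_config> %d criteria, threshold %.4g%s\n",
              length(x$criteria), x$threshold,
              if (x$weights_stale) ", WEIGHTS STALE (re-elicit)" else ""))
  ord <- order(vapply(x$criteria, function(cr) cr$rank, integer(1)))
  w <- config_weights(x)
  disp <- if (x$weights_stale) w else display_weights(w)
  for (cr in x$criteria[ord]) {
    cat(sprintf("  %d. %-38s %6.2f%%%s\n", cr$rank, cr$name, disp[[cr$id]],
                if (cr$external_score) "  [external score]" else ""))
  }
  invisible(x)
}

default_manufacturing_quality_options <- function() {
  list(
    scoring_option("GMP certificate from a stringent regulatory authority", 1),
    scoring_option("national GMP certificate only", 0.5, provisional = TRUE),
    scoring_option("no GMP certificate", 0, exclusion_trigger = TRUE)
  )
}

#' The published seven-criterion default configuration
#'
#' The final tool adopted for the Egyptian national oncology tenders: seven
#' non-price criteria with SMART swing-weighted weights summing to 100
#' (use in reference countries 23.49, equivalence with the reference product
#' 18.79, manufacturing quality 15.53, pharmacovigilance services 12.94,
#' supply reliability 10.78, previous use in local settings 9.8,
#' macroeconomic benefit 8.67), a 65-point qualification threshold, and
#' three hard exclusion triggers (not marketed in the country of origin, no
#' GMP certificate, supply reliability below 25%). The pharmacovigilance
#' criterion is external-score: its fraction is the percentage reported by
#' the national drug authority.
#'
#' Intermediate option fractions that the published tool defines only in its
#' scoring-function table are shipped as provisional placeholders
#' (`provisional = TRUE`) on an evenly spaced ladder; they are config data
#' and are expected to be edited. Top levels earn the full weight and
#' exclusion triggers earn zero by construction.
#'
#' @return an `mcda_config` with 7 criteria and threshold 65.
#' @export
#' @examples
#' cfg <- default_config()
#' sum(sapply(cfg$criteria, `[[`, "weight"))
default_config <- function() {
  tool_config(
    criteria = list(
      criterion(
        "reference_country_use", "Use in reference countries", 1, 23.49,
        list(
          scoring_option("marketed and used in two or more reference countries", 1),
          scoring_option("marketed in the country of origin and one reference country",
                         0.5, provisional = TRUE),
          scoring_option("marketed in the country of origin only",
                         0.25, provisional = TRUE),
          scoring_option("not marketed in the country of origin", 0,
                         exclusion_trigger = TRUE)
        )
      ),
      criterion(
        "reference_equivalence", "Equivalence with the reference product", 2, 18.79,
        list(
          scoring_option("demonstrated equivalence with the reference product", 1),
          scoring_option("equivalence study submitted and under review",
                         0.5, provisional = TRUE),
          scoring_option("no equivalence evidence", 0)
        )
      ),
      criterion(
        "manufacturing_quality", "Manufacturing quality", 3, 15.53,
        default_manufacturing_quality_options()
      ),
      criterion(
        "pharmacovigilance", "Pharmacovigilance services", 4, 12.94,
        external_score = TRUE
      ),
      criterion(
        "supply_reliability", "Supply reliability", 5, 10.78,
        list(
          scoring_option("75% or more of orders on time and complete", 1),
          scoring_option("50% to less than 75%", 0.67, provisional = TRUE),
          scoring_option("25% to less than 50%", 0.33, provisional = TRUE),
          scoring_option("less than 25%", 0, exclusion_trigger = TRUE)
        )
      ),
      criterion(
        "local_use", "Previous use in local settings", 6, 9.8,
        list(
          scoring_option("previous local use with no reported problems", 1),
          scoring_option("limited previous local use", 0.5, provisional = TRUE),
          scoring_option("no previous use in local settings", 0)
        )
      ),
      criterion(
        "macroeconomic_benefit", "Macroeconomic benefit", 7, 8.67,
        list(
          scoring_option("full manufacturing in Egypt", 1),
          scoring_option("local packaging only in Egypt", 0.5, provisional = TRUE),
          scoring_option("no manufacturing activity in Egypt", 0)
        )
      )
    ),
    threshold = 65,
    weight_tolerance = 0.01
  )
}

generic_options <- function() {
  list(
    scoring_option("fully met", 1),
    scoring_option("partially met", 0.5, provisional = TRUE),
    scoring_option("not met", 0)
  )
}

#' The thirteen-criterion primary list
#'
#' The consolidated candidate list that entered the development workshop,
#' before stakeholder modifications reduced it to seven criteria. Weights
#' are equal placeholders and the configuration is marked `weights_stale`,
#' since weighting happens only after the criteria list is fixed. The
#' documented workshop decisions that turn this list into the final seven
#' criteria are returned by [workshop_modifications()].
#'
#' @return an `mcda_config` with 13 criteria and stale weights.
#' @seealso [workshop_modifications()], [apply_modification()]
#' @export
primary_config <- function() {
  nm <- c(
    reference_country_use = "Use in reference countries",
    reference_equivalence = "Equivalence with the reference product",
    api_manufacturing_quality = "Active pharmaceutical ingredient manufacturing quality",
    finished_product_quality = "Finished product manufacturing quality",
    pharmacovigilance = "Pharmacovigilance services",
    supply_reliability = "Supply reliability",
    local_use = "Previous use in local settings",
    macroeconomic_benefit = "Macroeconomic benefit",
    expired_refund = "Refund or replacement of expired products",
    expiry_date = "Expiry date",
    ease_of_use = "Ease of use",
    storage_conditions = "Storage conditions",
    production_capacity = "Production capacity and financial ability of the company"
  )
  crits <- vector("list", length(nm))
  for (i in seq_along(nm)) {
    id <- names(nm)[[i]]
    crits[[i]] <- criterion(
      id, nm[[i]], rank = i, weight = 100 / length(nm),
      options = if (id == "pharmacovigilance") list() else generic_options(),
      external_score = id == "pharmacovigilance"
    )
  }
  tool_config(crits, threshold = 65, weights_stale = TRUE)
}

#' Construct a criteria-list modification proposal
#'
#' Stakeholder panels revise the criteria list by voted proposals: excluding
#' criteria, merging redundant ones into a replacement, adding a new one, or
#' renaming. Proposals are applied with [apply_modification()], typically
#' after passing a [majority_pass()] vote.
#'
#' @param kind one of `"exclude"`, `"merge"`, `"add"`, `"rename"`.
#' @param target_ids criterion ids the proposal acts on (`merge` needs at
#'   least two; `add` takes none).
#' @param replacement a [criterion()] supplying the merged/added/renamed
#'   criterion (required for merge and add; for rename only its `name` is
#'   used).
#' @return an object of class `mcda_modification`.
#' @export
modification <- function(kind, target_ids = character(), replacement = NULL) {
  kind <- match.arg(kind, c("exclude", "merge", "add", "rename"))
  if (kind == "merge" && (length(target_ids) < 2 || is.null(replacement))) {
    abort_mcda("merge requires >= 2 target ids and a replacement criterion",
               "mcda_validation_error")
  }
  if (kind == "exclude" && length(target_ids) < 1) {
    abort_mcda("exclude requires at least one target id", "mcda_validation_error")
  }
  if (kind == "add" && is.null(replacement)) {
    abort_mcda("add requires a replacement criterion", "mcda_validation_error")
  }
  if (kind == "rename" && (length(target_ids) != 1 || is.null(replacement))) {
    abort_mcda("rename requires exactly one target id and a replacement",
               "mcda_validation_error")
  }
  structure(list(kind = kind, target_ids = target_ids, replacement = replacement),
            class = "mcda_modification")
}

#' Apply a modification proposal to a configuration
#'
#' Excludes or merges criteria, compacts ranks to 1..K' preserving the
#' surviving order, and marks the result `weights_stale`: weights are
#' elicited only after the criteria list is final, so they are never
#' auto-renormalized here.
#'
#' @param config an `mcda_config`.
#' @param proposal an [modification()] proposal whose target ids all exist
#'   in `config`.
#' @return a new `mcda_config` with `weights_stale = TRUE`.
#' @export
#' @examples
#' cfg <- primary_config()
#' for (m in workshop_modifications()) cfg <- apply_modification(cfg, m)
#' length(cfg$criteria)  # 7
apply_modification <- function(config, proposal) {
  stopifnot(inherits(proposal, "mcda_modification"))
  ids <- criterion_ids(config)
  missing <- setdiff(proposal$target_ids, ids)
  if (length(missing) > 0) {
    abort_mcda(paste0("unknown criterion id(s): ", paste(missing, collapse = ", ")),
               "mcda_unknown_id")
  }
  crits <- config$criteria
  if (proposal$kind == "exclude") {
    crits <- Filter(function(cr) !(cr$id %in% proposal$target_ids), crits)
  } else if (proposal$kind == "merge") {
    target_ranks <- vapply(
      Filter(function(cr) cr$id %in% proposal$target_ids, crits),
      function(cr) cr$rank, integer(1))
    repl <- proposal$replacement
    repl$rank <- min(target_ranks)
    crits <- Filter(function(cr) !(cr$id %in% proposal$target_ids), crits)
    crits <- c(crits, list(repl))
  } else if (proposal$kind == "add") {
    repl <- proposal$replacement
    repl$rank <- length(crits) + 1L
    crits <- c(crits, list(repl))
  } else if (proposal$kind == "rename") {
    crits <- lapply(crits, function(cr) {
      if (cr$id == proposal$target_ids) cr$name <- proposal$replacement$name
      cr
    })
  }
  if (length(crits) == 0) {
    abort_mcda("modification would leave an empty criteria list",
               "mcda_validation_error")
  }
  # compact ranks to 1..K' in the surviving order
  ord <- order(vapply(crits, function(cr) cr$rank, integer(1)))
  crits <- crits[ord]
  for (i in seq_along(crits)) crits[[i]]$rank <- i
  tool_config(crits,
              threshold = config$threshold,
              weight_tolerance = config$weight_tolerance,
              weights_stale = TRUE,
              schema_version = config$schema_version)
}

#' The documented workshop modification sequence
#'
#' The six voted decisions that reduced the 13-criterion primary list to the
#' final seven: exclude the expired-product refund/replacement criterion
#' (mandatory by tender rules anyway); merge the API and finished-product
#' manufacturing-quality criteria into a single "manufacturing quality"
#' criterion; exclude expiry date, ease of use and storage conditions (no
#' real differentiation between products); and exclude production capacity
#' (already reflected in supply reliability).
#'
#' @return a list of six [modification()] proposals, in workshop order.
#' @export
workshop_modifications <- function() {
  list(
    modification("exclude", "expired_refund"),
    modification("merge",
                 c("api_manufacturing_quality", "finished_product_quality"),
                 replacement = criterion(
                   "manufacturing_quality", "Manufacturing quality",
                   rank = 3, weight = 0,
                   options = default_manufacturing_quality_options())),
    modification("exclude", "expiry_date"),
    modification("exclude", "ease_of_use"),
    modification("exclude", "storage_conditions"),
    modification("exclude", "production_capacity")
  )
}
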