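# Scoring engine: per-criterion fractions, hard exclusions, weighted total
# on a 0-100 point scale, and qualification against the threshold.
#
# Total score S = sum_i w_i * s_i with weights w_i in percentage points and
# fractions s_i in [0, 1]; qualification is decided at full precision
# (display rounding never turns a 64.996 into a qualifying 65.00).

#' Construct a product bid
#'
#' @param product_id unique token.
#' @param active_ingredient active-pharmaceutical-ingredient token; bids are
#'   ranked within ingredient in the financial phase.
#' @param selections named character vector or list mapping each
#'   non-external criterion id to the chosen option label.
#' @param pharmacovigilance_percent externally supplied pharmacovigilance
#'   score, a percentage in [0, 100] (required when the configuration has an
#'   external-score criterion).
#' @param price positive offered price per comparable unit (currency units
#'   are carried through, never converted).
#' @return an object of class `product_bid`.
#' @export
product_bid <- function(product_id, active_ingredient, selections,
                        pharmacovigilance_percent = NA_real_, price) {
  stopifnot(is.character(product_id), length(product_id) == 1L)
  price <- as.numeric(price)
  if (!is.finite(price) || price <= 0) {
    abort_mcda(paste0("bid ", product_id, ": price must be > 0"),
               "mcda_validation_error")
  }
  pv <- as.numeric(pharmacovigilance_percent)
  if (!is.na(pv) && (pv < 0 || pv > 100)) {
    abort_mcda(paste0("bid ", product_id,
                      ": pharmacovigilance percent must lie in [0, 100]"),
               "mcda_validation_error")
  }
  structure(
    list(product_id = product_id,
         active_ingredient = as.character(active_ingredient),
         selections = as.list(selections),
         pharmacovigilance_percent = pv,
         price = price),
    class = "product_bid"
  )
}

validate_bid <- function(bid, config) {
  for (cr in config$criteria) {
    if (cr$external_score) {
      if (is.na(bid$pharmacovigilance_percent)) {
        abort_mcda(paste0("bid ", bid$product_id, ": missing external score for '",
                          cr$id, "'"), "mcda_missing_selection")
      }
    } else {
      sel <- bid$selections[[cr$id]]
      if (is.null(sel) || is.na(sel) || !nzchar(sel)) {
        abort_mcda(paste0("bid ", bid$product_id, ": missing selection for '",
                          cr$id, "'"), "mcda_missing_selection")
      }
      labels <- vapply(cr$options, function(o) o$label, character(1))
      if (!sel %in% labels) {
        abort_mcda(paste0("bid ", bid$product_id, ": unknown option '", sel,
                          "' for criterion '", cr$id, "'"), "mcda_unknown_option")
      }
    }
  }
  invisible(TRUE)
}

#' Score one criterion for a bid
#'
#' Non-external criteria return the selected option's configured fraction;
#' the external pharmacovigilance criterion returns the supplied percentage
#' divided by 100.
#'
#' @param bid a [product_bid()].
#' @param criterion an `mcda_criterion`.
#' @return the score fraction s_i in [0, 1].
#' @export
score_criterion <- function(bid, criterion) {
  if (criterion$external_score) {
    pv <- bid$pharmacovigilance_percent
    if (is.na(pv)) {
      abort_mcda(paste0("bid ", bid$product_id, ": missing external score for '",
                        criterion$id, "'"), "mcda_missing_selection")
    }
    if (pv < 0 || pv > 100) {
      abort_mcda(paste0("bid ", bid$product_id,
                        ": external percent outside [0, 100]"),
                 "mcda_validation_error")
    }
    return(pv / 100)
  }
  sel <- bid$selections[[criterion$id]]
  if (is.null(sel) || is.na(sel)) {
    abort_mcda(paste0("bid ", bid$product_id, ": missing selection for '",
                      criterion$id, "'"), "mcda_missing_selection")
  }
  for (o in criterion$options) if (o$label == sel) return(o$score_fraction)
  abort_mcda(paste0("bid ", bid$product_id, ": unknown option '", sel,
                    "' for criterion '", criterion$id, "'"), "mcda_unknown_option")
}

#' List all exclusion reasons triggered by a bid
#'
#' Scans every selected option and reports each one flagged as an exclusion
#' trigger, as `"criterion_id: option label"` codes. The list is complete —
#' all triggered reasons are returned, not just the first.
#'
#' @param bid a [product_bid()].
#' @param config an `mcda_config`.
#' @return character vector of exclusion reason codes (possibly empty).
#' @export
detect_exclusions <- function(bid, config) {
  reasons <- character()
  for (cr in config$criteria) {
    if (cr$external_score) next
    sel <- bid$selections[[cr$id]]
    for (o in cr$options) {
      if (o$label == sel && o$exclusion_trigger) {
        reasons <- c(reasons, paste0(cr$id, ": ", o$label))
      }
    }
  }
  reasons
}

#' Total weighted score of a bid
#'
#' S = sum_i w_i * s_i over all criteria, on the 0-100 point scale.
#' Independent of criterion ordering in the configuration.
#'
#' @param bid a [product_bid()].
#' @param config an `mcda_config`.
#' @return points in [0, 100], at full precision.
#' @export
total_score <- function(bid, config) {
  s <- vapply(config$criteria, function(cr) score_criterion(bid, cr), numeric(1))
  w <- vapply(config$criteria, function(cr) cr$weight, numeric(1))
  sum(w * s)
}

#' Evaluate a bid: fractions, exclusions, total score, qualification
#'
#' A bid qualifies for the financial phase iff it triggers no exclusion
#' reason and its total score is greater than or equal to the configured
#' threshold (65 points in the default tool); the comparison is inclusive
#' and made at full precision.
#'
#' @param bid a [product_bid()].
#' @param config an `mcda_config`.
#' @return an object of class `evaluation_result` with fields `product_id`,
#'   `active_ingredient`, `fractions`, `weighted_points`, `total_score`,
#'   `exclusion_reasons`, `qualified`, and `price` carried through for the
#'   financial phase.
#' @export
evaluate <- function(bid, config) {
  validate_bid(bid, config)
  ids <- criterion_ids(config)
  fractions <- vapply(config$criteria, function(cr) score_criterion(bid, cr),
                      numeric(1))
  names(fractions) <- ids
  w <- config_weights(config)
  weighted <- w * fractions
  total <- sum(weighted)
  reasons <- detect_exclusions(bid, config)
  structure(
    list(product_id = bid$product_id,
         active_ingredient = bid$active_ingredient,
         fractions = fractions,
         weighted_points = weighted,
         total_score = total,
         exclusion_reasons = reasons,
         qualified = length(reasons) == 0 && total >= config$threshold,
         price = bid$price),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s (%s): %.2f points, %s\n",
              x$product_id, x$active_ingredient, x$total_score,
              if (length(x$exclusion_reasons) > 0) {
                paste0("EXCLUDED (", paste(x$exclusion_reasons, collapse = "; "), ")")
              } else if (x$qualified) "qualified" else "below threshold"))
  invisible(x)
}

#' Evaluate a list of bids
#'
#' @param bids list of [product_bid()] objects.
#' @param config an `mcda_config`.
#' @return a list of `evaluation_result` objects, in input order.
#' @export
evaluate_bids <- function(bids, config) {
  lapply(bids, evaluate, config = config)
}

#' Flatten evaluation results to a report table
#'
#' One row per product with per-criterion weighted points, the total score
#' (displayed at 2 decimals elsewhere, stored at full precision here),
#' exclusion codes and the qualification flag. Row order is deterministic:
#' descending total score, then product id.
#'
#' @param results list of `evaluation_result` objects.
#' @return a data.frame.
#' @export
evaluation_report <- function(results) {
  if (length(results) == 0) {
    return(data.frame(product_id = character(), active_ingredient = character(),
                      total_score = numeric(), qualified = logical(),
                      exclusion_reasons = character(), price = numeric(),
                      stringsAsFactors = FALSE))
  }
  ids <- names(results[[1]]$fractions)
  base <- data.frame(
    product_id = vapply(results, `[[`, character(1), "product_id"),
    active_ingredient = vapply(results, `[[`, character(1), "active_ingredient"),
    stringsAsFactors = FALSE
  )
  for (id in ids) {
    base[[paste0("points_", id)]] <-
      vapply(results, function(r) r$weighted_points[[id]], numeric(1))
  }
  base$total_score <- vapply(results, `[[`, numeric(1), "total_score")
  base$qualified <- vapply(results, `[[`, logical(1), "qualified")
  base$exclusion_reasons <- vapply(
    results, function(r) paste(r$exclusion_reasons, collapse = "; "), character(1))
  base$price <- vapply(results, `[[`, numeric(1), "price")
  base[order(-base$total_score, base$product_id), , drop = FALSE]
}

#' Read product bids from a delimited table
#'
#' One row per product; columns `product_id`, `active_ingredient`, `price`,
#' `pharmacovigilance_percent` (when the config has an external-score
#' criterion) and one column per non-external criterion id holding the
#' selected option label. Malformed rows are isolated: valid rows are
#' returned as bids, invalid ones as error records with their row numbers.
#'
#' @param path CSV file path.
#' @param config an `mcda_config` the bids are validated against.
#' @return a list with `bids` (list of [product_bid()]) and `errors`
#'   (data.frame with columns `row`, `product_id`, `message`).
#' @export
read_bids <- function(path, config) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                       check.names = FALSE)
  non_ext <- Filter(function(cr) !cr$external_score, config$criteria)
  has_ext <- any(vapply(config$criteria, `[[`, logical(1), "external_score"))
  need <- c("product_id", "active_ingredient", "price",
            if (has_ext) "pharmacovigilance_percent",
            vapply(non_ext, `[[`, character(1), "id"))
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    abort_mcda(paste0("bid table missing column(s): ",
                      paste(missing_cols, collapse = ", ")), "mcda_schema_error")
  }
  bids <- list()
  errors <- data.frame(row = integer(), product_id = character(),
                       message = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(d))) {
    res <- tryCatch({
      sel <- as.list(d[i, vapply(non_ext, `[[`, character(1), "id"), drop = FALSE])
      b <- product_bid(
        product_id = as.character(d$product_id[[i]]),
        active_ingredient = as.character(d$active_ingredient[[i]]),
        selections = sel,
        pharmacovigilance_percent =
          if (has_ext) as.numeric(d$pharmacovigilance_percent[[i]]) else NA_real_,
        price = suppressWarnings(as.numeric(d$price[[i]]))
      )
      validate_bid(b, config)
      b
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors, data.frame(
        row = i, product_id = as.character(d$product_id[[i]]),
        message = conditionMessage(res), stringsAsFactors = FALSE))
    } else {
      bids[[length(bids) + 1]] <- res
    }
  }
  list(bids = bids, errors = errors)
}
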