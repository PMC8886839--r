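# Synthetic-data generators: bids and stakeholder vote panels with known
# ground truth, so the whole pipeline is testable without external data.
#
# Noise model (single, documented): multiplicative log-normal noise on
# importance-ratio votes truncated to >= 1; independent adjacent-pair swap
# noise on rank votes; additive jitter on option-score votes rounded to
# integers and clipped to [0, 100]. The default panel size is 35, the number
# of experts who voted in the development workshops.

#' Specify a synthetic fixture
#'
#' @param seed integer random seed; identical specs (including the seed)
#'   generate identical data.
#' @param n_products number of synthetic bids.
#' @param n_participants panel size (default 35 voters).
#' @param true_weights generating weight vector (named percentages summing
#'   to 100); defaults to the published seven-criterion weights. Vote panels
#'   are generated so that noiseless elicitation recovers it exactly.
#' @param vote_noise non-negative dispersion: standard deviation of the
#'   log-scale ratio noise, adjacent-swap probability for rank votes, and
#'   (times 100) the score-jitter standard deviation.
#' @param exclusion_rate probability that a generated bid selects at least
#'   one exclusion-trigger option.
#' @param price_range positive interval prices are drawn from, uniformly.
#' @param option_truth optional named vector of true option-score
#'   percentages, names `"criterion_id|option label"`, used to generate
#'   option-score votes.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_products = 10, n_participants = 35,
                         true_weights = NULL, vote_noise = 0,
                         exclusion_rate = 0, price_range = c(50, 500),
                         option_truth = NULL) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (is.null(true_weights)) {
    cfg <- default_config()
    ord <- order(vapply(cfg$criteria, `[[`, integer(1), "rank"))
    true_weights <- config_weights(cfg)[ord]
  }
  if (any(true_weights == 0)) {
    abort_mcda("true_weights must be strictly positive (adjacent quotients undefined)",
               "mcda_validation_error")
  }
  stopifnot(vote_noise >= 0, exclusion_rate >= 0, exclusion_rate <= 1,
            length(price_range) == 2, all(price_range > 0),
            price_range[1] <= price_range[2])
  structure(
    list(seed = as.integer(seed), n_products = as.integer(n_products),
         n_participants = as.integer(n_participants),
         true_weights = true_weights, vote_noise = vote_noise,
         exclusion_rate = exclusion_rate, price_range = price_range,
         option_truth = option_truth),
    class = "fixture_spec"
  )
}

#' Generate synthetic product bids
#'
#' Bids are valid against `config` by construction. A bid is designated
#' "excluded" with probability `exclusion_rate`; such a bid selects an
#' exclusion-trigger option on one randomly chosen trigger-bearing
#' criterion, while all other selections are drawn uniformly from the
#' non-trigger options. Ingredients are assigned from a small pool so that
#' several bids compete per ingredient.
#'
#' @param spec a [fixture_spec()].
#' @param config an `mcda_config`.
#' @return list of [product_bid()] objects.
#' @export
generate_bids <- function(spec, config) {
  non_ext <- Filter(function(cr) !cr$external_score, config$criteria)
  trigger_crits <- Filter(function(cr) {
    any(vapply(cr$options, `[[`, logical(1), "exclusion_trigger"))
  }, non_ext)
  if (spec$exclusion_rate > 0 && length(trigger_crits) == 0) {
    abort_mcda("config has no exclusion-trigger options but exclusion_rate > 0",
               "mcda_validation_error")
  }
  has_ext <- any(vapply(config$criteria, `[[`, logical(1), "external_score"))
  n_ing <- max(1L, ceiling(spec$n_products / 3))
  with_local_seed(spec$seed, {
    ingredients <- sample(sprintf("ingredient%02d", seq_len(n_ing)),
                          spec$n_products, replace = TRUE)
    lapply(seq_len(spec$n_products), function(i) {
      excluded <- stats::runif(1) < spec$exclusion_rate
      trigger_on <- if (excluded) {
        sample(vapply(trigger_crits, `[[`, character(1), "id"), 1)
      } else NA_character_
      sel <- lapply(non_ext, function(cr) {
        trig <- vapply(cr$options, `[[`, logical(1), "exclusion_trigger")
        pool <- if (identical(cr$id, trigger_on)) which(trig) else which(!trig)
        cr$options[[pool[sample.int(length(pool), 1)]]]$label
      })
      names(sel) <- vapply(non_ext, `[[`, character(1), "id")
      product_bid(
        product_id = sprintf("product%03d", i),
        active_ingredient = ingredients[[i]],
        selections = sel,
        pharmacovigilance_percent =
          if (has_ext) round(stats::runif(1, 0, 100), 1) else NA_real_,
        price = round(stats::runif(1, spec$price_range[1], spec$price_range[2]), 2)
      )
    })
  })
}

#' Generate a synthetic stakeholder vote panel
#'
#' With `vote_noise = 0` every participant's rank votes equal the true
#' ranking implied by `true_weights` and every ratio vote equals the
#' adjacent quotient of the true weights, so the elicitation pipeline
#' recovers the generating vector exactly. With noise, ratios are perturbed
#' multiplicatively on the log scale (truncated to >= 1), ranks by
#' independent adjacent swaps, and option scores by rounded additive jitter
#' clipped to [0, 100].
#'
#' @param spec a [fixture_spec()]; `true_weights` must be strictly positive.
#' @return a [vote_panel()].
#' @export
generate_vote_panel <- function(spec) {
  w <- spec$true_weights
  K <- length(w)
  ids <- names(w) %||% paste0("criterion", seq_len(K))
  ord <- order(-w, ids)             # rank 1 = largest weight
  w_sorted <- w[ord]
  ids_sorted <- ids[ord]
  true_ratios <- if (K > 1) {
    as.numeric(w_sorted[-K] / w_sorted[-1])
  } else numeric(0)
  if (any(true_ratios < 1)) {
    # guard against ties broken against the weight order
    true_ratios <- pmax(true_ratios, 1)
  }
  true_ranks <- integer(K)
  true_ranks[match(ids_sorted, ids)] <- seq_len(K)
  n <- spec$n_participants
  with_local_seed(spec$seed + 1L, {
    rank_votes <- matrix(rep(true_ranks, each = n), nrow = n,
                         dimnames = list(paste0("p", seq_len(n)), ids))
    if (spec$vote_noise > 0 && K > 1) {
      p_swap <- min(0.5, spec$vote_noise)
      for (p in seq_len(n)) {
        perm <- order(rank_votes[p, ])      # criterion index by rank position
        for (k in seq_len(K - 1)) {
          if (stats::runif(1) < p_swap) perm[c(k, k + 1)] <- perm[c(k + 1, k)]
        }
        rank_votes[p, perm] <- seq_len(K)
      }
    }
    ratio_votes <- NULL
    if (K > 1) {
      noise <- if (spec$vote_noise > 0) {
        matrix(stats::rnorm(n * (K - 1), 0, spec$vote_noise), nrow = n)
      } else matrix(0, nrow = n, ncol = K - 1)
      ratio_votes <- pmax(1, rep(true_ratios, each = n) * exp(noise))
      dim(ratio_votes) <- c(n, K - 1)
      dimnames(ratio_votes) <- list(paste0("p", seq_len(n)),
                                    paste0("pair", seq_len(K - 1)))
    }
    option_score_votes <- NULL
    if (!is.null(spec$option_truth)) {
      items <- names(spec$option_truth)
      split_items <- strsplit(items, "|", fixed = TRUE)
      truth <- rep(as.numeric(spec$option_truth), each = n)
      jitter <- if (spec$vote_noise > 0) {
        stats::rnorm(n * length(items), 0, 100 * spec$vote_noise)
      } else 0
      option_score_votes <- data.frame(
        participant = rep(paste0("p", seq_len(n)), times = length(items)),
        criterion_id = rep(vapply(split_items, `[[`, character(1), 1), each = n),
        option_label = rep(vapply(split_items, function(x)
          paste(x[-1], collapse = "|"), character(1)), each = n),
        score = pmin(100, pmax(0, round(truth + jitter))),
        stringsAsFactors = FALSE
      )
    }
    vote_panel(rank_votes, ratio_votes, option_score_votes,
               participants = paste0("p", seq_len(n)))
  })
}
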