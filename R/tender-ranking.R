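# Financial phase: price per point and per-ingredient ranking.
#
# Qualified bids are compared within their active ingredient by price per
# point (price / total score); the lowest price per point is the
# preferential option. Comparisons use full precision — the displayed 2.14
# for 150/70 is presentation rounding of 2.142857...

#' Price per point
#'
#' The financial-phase ranking statistic: offered price divided by the
#' total MCDA score. Lower is better.
#'
#' @param price positive price per comparable unit.
#' @param score total score in points; must be positive (only qualified
#'   bids, whose scores meet the threshold, reach the financial phase).
#' @return price / score at full precision.
#' @export
#' @examples
#' price_per_point(160, 80)  # 2
#' price_per_point(150, 70)  # 2.142857...
price_per_point <- function(price, score) {
  if (any(!is.finite(price) | price <= 0)) {
    abort_mcda("price must be positive", "mcda_validation_error")
  }
  if (any(!is.finite(score) | score <= 0)) {
    abort_mcda("score must be positive", "mcda_validation_error")
  }
  price / score
}

# Strict total order over bids within an ingredient: ascending price per
# point, then descending total score, then ascending price, then product id.
rank_order <- function(ppp, score, price, product_id) {
  order(ppp, -score, price, product_id)
}

#' Rank evaluated bids by price per point within each active ingredient
#'
#' Unqualified bids (exclusion triggers or sub-threshold totals) are never
#' ranked but are listed with their status so the financial committee sees
#' the full field. Within each ingredient, qualified bids are sorted by
#' ascending price per point; ties are broken by higher total score, then
#' lower price, then product id, making the output a deterministic strict
#' order. Rank 1 is flagged as the preferred option. An ingredient whose
#' bids all failed is reported with status `"no eligible supplier"` rather
#' than raising an error.
#'
#' @param results list of `evaluation_result` objects (from [evaluate()] or
#'   [evaluate_bids()]), carrying prices.
#' @return an object of class `tender_ranking`: a data.frame with columns
#'   `active_ingredient`, `product_id`, `total_score`, `price`,
#'   `price_per_point`, `rank_within_ingredient`, `preferred`, `status`,
#'   ordered by ingredient then rank (unranked rows last).
#' @export
rank_tender <- function(results) {
  rows <- data.frame(
    active_ingredient = vapply(results, `[[`, character(1), "active_ingredient"),
    product_id = vapply(results, `[[`, character(1), "product_id"),
    total_score = vapply(results, `[[`, numeric(1), "total_score"),
    price = vapply(results, `[[`, numeric(1), "price"),
    qualified = vapply(results, `[[`, logical(1), "qualified"),
    excluded = vapply(results, function(r) length(r$exclusion_reasons) > 0,
                      logical(1)),
    stringsAsFactors = FALSE
  )
  rows$price_per_point <- ifelse(rows$qualified,
                                 rows$price / rows$total_score, NA_real_)
  rows$status <- ifelse(rows$qualified, "qualified",
                        ifelse(rows$excluded, "excluded", "below threshold"))
  rows$rank_within_ingredient <- NA_integer_
  rows$preferred <- FALSE
  for (ing in unique(rows$active_ingredient)) {
    in_ing <- which(rows$active_ingredient == ing)
    q <- in_ing[rows$qualified[in_ing]]
    if (length(q) == 0) {
      rows$status[in_ing] <- paste0(rows$status[in_ing], "; no eligible supplier")
      next
    }
    ord <- q[rank_order(rows$price_per_point[q], rows$total_score[q],
                        rows$price[q], rows$product_id[q])]
    rows$rank_within_ingredient[ord] <- seq_along(ord)
    rows$preferred[ord[[1]]] <- TRUE
  }
  out <- rows[order(rows$active_ingredient,
                    is.na(rows$rank_within_ingredient),
                    rows$rank_within_ingredient,
                    rows$product_id), , drop = FALSE]
  out$qualified <- NULL
  out$excluded <- NULL
  rownames(out) <- NULL
  class(out) <- c("tender_ranking", "data.frame")
  out
}

#' @export
print.tender_ranking <- function(x, ...) {
  y <- as.data.frame(x)
  y$total_score <- sprintf("%.2f", y$total_score)
  y$price_per_point <- ifelse(is.na(y$price_per_point), "",
                              sprintf("%.2f", y$price_per_point))
  print(y, row.names = FALSE)
  invisible(x)
}
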