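#' Round half away from zero
#'
#' Display rounding for preference scores and score differences: exact
#' halves round away from zero (82.5 -> 83), unlike base R's banker's
#' rounding.  All comparisons in the package are made on unrounded values;
#' this is display-only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Swing-weighted category score
#'
#' The weighted average \eqn{\sum_j w_j p_j / \sum_j w_j} of the preference
#' values within one category.  Because the weights enter as ratios, any
#' common positive rescaling of the swing weights leaves the score
#' unchanged.
#'
#' @param preferences Preference values (0-100), one per criterion.
#' @param weights Swing weights, same length, summing to a positive value.
#' @return The category score, a scalar in `[0, 100]` when preferences are.
#' @examples
#' aggregate_category(c(82, 67, 75, 66), c(80, 60, 60, 100)) # 72.27
#' @export
aggregate_category <- function(preferences, weights) {
  if (length(preferences) != length(weights)) {
    stop("preferences and weights must have equal length", call. = FALSE)
  }
  if (length(preferences) == 0L) stop("empty category", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  sum(weights * preferences) / sum(weights)
}

#' Total benefit-risk score for one alternative
#'
#' Combines a benefit score and a risk score with the tree's top-level
#' weights: `total = benefit_weight * benefit + risk_weight * risk`.  The
#' risk score already encodes "higher = safer" (the risk partial value
#' function is reversed), so the total is a weighted *sum*, not a
#' difference.
#'
#' @param benefit,risk Category scores in `[0, 100]`.
#' @param tree A [value_tree()] supplying the top-level weights.
#' @param alternative Label for the alternative (default `"alternative"`).
#' @return A one-row data frame of class `"scorecard"` with columns
#'   `alternative`, `benefit_value`, `risk_value`, `total_value` and
#'   rounded display columns `benefit_disp`, `risk_disp`, `total_disp`.
#' @examples
#' tree <- nsclc_study()$tree
#' aggregate_total(72.27, 56, tree, "combination")
#' @export
aggregate_total <- function(benefit, risk, tree, alternative = "alternative") {
  if (any(c(benefit, risk) < 0) || any(c(benefit, risk) > 100)) {
    stop("category scores must lie in [0, 100]", call. = FALSE)
  }
  total <- tree$benefit_weight * benefit + tree$risk_weight * risk
  out <- data.frame(
    alternative = alternative,
    benefit_value = benefit, risk_value = risk, total_value = total,
    benefit_disp = round_half_up(benefit), risk_disp = round_half_up(risk),
    total_disp = round_half_up(total),
    stringsAsFactors = FALSE
  )
  class(out) <- c("scorecard", "data.frame")
  out
}

#' Scorecards for every alternative in a preference matrix
#'
#' Aggregates a long-form preference matrix into one row per alternative:
#' the swing-weighted benefit score, risk score, and total benefit-risk
#' score under the tree's weights.
#'
#' @param preferences A `"preference_matrix"` (see [score_alternatives()]).
#' @param tree A [value_tree()].
#' @return A `"scorecard"` data frame, one row per alternative.
#' @export
score_cards <- function(preferences, tree) {
  tree <- validate_value_tree(tree)
  cards <- lapply(unique(preferences$alternative), function(alt) {
    sub <- preferences[preferences$alternative == alt, , drop = FALSE]
    vals <- vapply(c("benefit", "risk"), function(cat) {
      cr <- tree$criteria[tree$criteria$category == cat, , drop = FALSE]
      if (nrow(cr) == 0L) return(0)
      p <- sub$preference[match(cr$id, sub$criterion_id)]
      if (anyNA(p)) {
        stop("alternative '", alt, "' is missing preference(s) for: ",
             paste(cr$id[is.na(p)], collapse = ", "), call. = FALSE)
      }
      aggregate_category(p, cr$swing_weight)
    }, numeric(1L))
    aggregate_total(vals[["benefit"]], vals[["risk"]], tree, alt)
  })
  out <- do.call(rbind, cards)
  class(out) <- c("scorecard", "data.frame")
  rownames(out) <- NULL
  out
}

#' Rank alternatives by total benefit-risk score
#'
#' Orders scorecards by descending total value (ties broken by benefit
#' value, then lexicographic id, and flagged) and reports the unrounded
#' score difference to the next-ranked alternative alongside its display
#' rounding.
#'
#' @param cards A `"scorecard"` data frame (>= 2 alternatives).
#' @return A data frame with columns `rank`, `alternative`,
#'   `benefit_value`, `risk_value`, `total_value`, `diff_to_next`,
#'   `diff_disp` and `tied` (logical, `TRUE` when tied with a neighbour on
#'   total value).
#' @export
rank_alternatives <- function(cards) {
  if (nrow(cards) < 2L) stop("ranking needs at least two alternatives", call. = FALSE)
  ord <- order(-cards$total_value, -cards$benefit_value, cards$alternative)
  out <- cards[ord, c("alternative", "benefit_value", "risk_value", "total_value")]
  out$rank <- seq_len(nrow(out))
  n <- nrow(out)
  out$diff_to_next <- c(out$total_value[-n] - out$total_value[-1L], NA_real_)
  out$diff_disp <- round_half_up(out$diff_to_next)
  tot <- out$total_value
  out$tied <- vapply(seq_len(n), function(i) {
    any(abs(tot[-i] - tot[i]) < 1e-9)
  }, logical(1L))
  rownames(out) <- NULL
  out[, c("rank", "alternative", "benefit_value", "risk_value", "total_value",
          "diff_to_next", "diff_disp", "tied")]
}
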