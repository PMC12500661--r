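#' Perturb one weight of a value tree
#'
#' Scales the swing weight of one criterion, or the top-level weight of one
#' category, and renormalizes so the tree stays valid.  For a category
#' target the sibling category absorbs the complement (benefit 0.75 scaled
#' by -20% gives 0.60/0.40).  For a criterion target the other swing
#' weights are untouched; since normalization is by within-category sum,
#' the perturbation spreads over siblings proportionally to their baseline
#' weights.  If scaling pushes a swing above 100, the whole category is
#' rescaled so its maximum swing is 100 (a pure change of scale that leaves
#' all normalized weights unchanged).
#'
#' @param tree A [value_tree()].
#' @param target A criterion id, `"benefit"`, or `"risk"`.
#' @param delta Signed perturbation. In `"relative"` mode the weight is
#'   multiplied by `1 + delta` (`|delta| <= 1`); in `"absolute"` mode
#'   `delta` is added to a category weight (fraction) or, for a criterion,
#'   `100 * delta` is added to the swing weight (points).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return The perturbed, revalidated [value_tree()].
#' @examples
#' tree <- nsclc_study()$tree
#' perturb_weight(tree, "benefit", -0.20)   # benefit 0.60 / risk 0.40
#' @export
perturb_weight <- function(tree, target, delta, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  tree <- validate_value_tree(tree)
  if (mode == "relative" && abs(delta) > 1) {
    stop("relative perturbation must satisfy |delta| <= 1", call. = FALSE)
  }
  if (target %in% c("benefit", "risk")) {
    w <- if (target == "benefit") tree$benefit_weight else tree$risk_weight
    new <- if (mode == "relative") w * (1 + delta) else w + delta
    if (new < 0 || new > 1) {
      stop(sprintf("perturbed %s weight %.4g is outside [0, 1]", target, new),
           call. = FALSE)
    }
    if (target == "benefit") {
      tree$benefit_weight <- new
      tree$risk_weight <- 1 - new
    } else {
      tree$risk_weight <- new
      tree$benefit_weight <- 1 - new
    }
  } else {
    j <- match(target, tree$criteria$id)
    if (is.na(j)) stop("unknown perturbation target: ", target, call. = FALSE)
    s <- tree$criteria$swing_weight[j]
    new <- if (mode == "relative") s * (1 + delta) else s + 100 * delta
    if (new <= 0) {
      stop(sprintf("perturbed swing weight for '%s' is %.4g (must stay positive)",
                   target, new), call. = FALSE)
    }
    tree$criteria$swing_weight[j] <- new
    cat <- tree$criteria$category[j]
    idx <- tree$criteria$category == cat
    mx <- max(tree$criteria$swing_weight[idx])
    if (mx > 100) {
      tree$criteria$swing_weight[idx] <- tree$criteria$swing_weight[idx] * 100 / mx
    }
  }
  validate_value_tree(tree)
}

#' Weight-sensitivity sweep
#'
#' Recomputes all scorecards under a grid of weight perturbations and
#' reports, for each (target, delta) pair, whether the ranking of
#' alternatives by total score changed relative to the baseline tree.
#' Preference values are weight-free, so they are held fixed while only
#' the aggregation weights move.
#'
#' @param preferences A `"preference_matrix"` covering every tree
#'   criterion for each alternative.
#' @param tree The baseline [value_tree()].
#' @param targets Criterion ids and/or `"benefit"`/`"risk"`; default: all
#'   criteria plus both categories.
#' @param deltas Signed perturbation grid (default `c(-0.2, 0.2)`, i.e. a
#'   20% decrease and increase).
#' @inheritParams perturb_weight
#' @return A data frame with one row per (target, delta): the perturbed
#'   per-alternative totals (columns `total_<alternative>`), the top-ranked
#'   alternative, and `rank_changed`.
#' @export
sensitivity_sweep <- function(preferences, tree,
                              targets = NULL, deltas = c(-0.2, 0.2),
                              mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  tree <- validate_value_tree(tree)
  if (is.null(targets)) targets <- c(tree$criteria$id, "benefit", "risk")
  base_rank <- rank_alternatives(score_cards(preferences, tree))
  base_order <- base_rank$alternative
  alts <- sort(unique(preferences$alternative))
  rows <- list()
  for (target in targets) {
    for (delta in deltas) {
      ptree <- perturb_weight(tree, target, delta, mode)
      cards <- score_cards(preferences, ptree)
      rk <- rank_alternatives(cards)
      row <- data.frame(target = target, delta = delta,
                        stringsAsFactors = FALSE)
      for (a in alts) {
        row[[paste0("total_", a)]] <- cards$total_value[cards$alternative == a]
      }
      row$top <- rk$alternative[1L]
      row$rank_changed <- !identical(rk$alternative, base_order)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Crossover weight between two alternatives
#'
#' For a two-alternative model the total score is affine in any single
#' weight parameter, so the weight at which the ranking flips (the
#' graphical crossover of a weight-sensitivity plot) solves a linear
#' equation.  For a category target the parameter is the category's
#' top-level weight in `[0, 1]`; for a criterion target it is that
#' criterion's normalized share of its category (its swing weight divided
#' by the category total), also in `[0, 1]`, with the remaining share
#' distributed over the sibling criteria in their baseline proportions.
#'
#' @inheritParams sensitivity_sweep
#' @param target A criterion id, `"benefit"`, or `"risk"`.
#' @return A list with `crossover` (the weight value in `[0, 1]` at which
#'   the totals are equal, or `NA` if no crossover exists in range) and
#'   `degenerate` (`TRUE` when the alternatives are tied at every weight).
#' @export
crossover_weight <- function(preferences, tree, target) {
  tree <- validate_value_tree(tree)
  alts <- sort(unique(preferences$alternative))
  if (length(alts) != 2L) {
    stop("crossover analysis supports exactly two alternatives (got ",
         length(alts), ")", call. = FALSE)
  }
  # total_i(x) = a_i + b_i * x for the scanned weight x; crossover where
  # the two lines meet.
  coefs <- lapply(alts, function(alt) {
    total_affine(preferences[preferences$alternative == alt, ], tree, target)
  })
  da <- coefs[[1L]]$a - coefs[[2L]]$a
  db <- coefs[[1L]]$b - coefs[[2L]]$b
  if (abs(db) < 1e-12) {
    if (abs(da) < 1e-9) return(list(crossover = NA_real_, degenerate = TRUE))
    return(list(crossover = NA_real_, degenerate = FALSE))
  }
  x <- -da / db
  if (x < 0 || x > 1) x <- NA_real_
  list(crossover = x, degenerate = FALSE)
}

## Total score of one alternative as an affine function a + b*x of the
## scanned weight parameter x for `target`.
total_affine <- function(pref, tree, target) {
  cr <- tree$criteria
  cat_score <- function(cat) {
    sub <- cr[cr$category == cat, , drop = FALSE]
    if (nrow(sub) == 0L) return(0)
    p <- pref$preference[match(sub$id, pref$criterion_id)]
    aggregate_category(p, sub$swing_weight)
  }
  if (target %in% c("benefit", "risk")) {
    B <- cat_score("benefit")
    R <- cat_score("risk")
    # x = weight of the target category; sibling takes 1 - x
    if (target == "benefit") list(a = R, b = B - R) else list(a = B, b = R - B)
  } else {
    j <- match(target, cr$id)
    if (is.na(j)) stop("unknown crossover target: ", target, call. = FALSE)
    cat <- cr$category[j]
    w_cat <- if (cat == "benefit") tree$benefit_weight else tree$risk_weight
    w_oth <- 1 - w_cat
    other_cat <- setdiff(c("benefit", "risk"), cat)
    oth_score <- if (any(cr$category == other_cat)) cat_score(other_cat) else 0
    p_j <- pref$preference[match(target, pref$criterion_id)]
    sib <- cr[cr$category == cat & cr$id != target, , drop = FALSE]
    if (nrow(sib) == 0L) {
      # lone criterion: its share is fixed at 1, no dependence on x
      return(list(a = w_cat * p_j + w_oth * oth_score, b = 0))
    }
    q <- aggregate_category(pref$preference[match(sib$id, pref$criterion_id)],
                            sib$swing_weight)
    # category score = x * p_j + (1 - x) * q
    list(a = w_cat * q + w_oth * oth_score, b = w_cat * (p_j - q))
  }
}
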