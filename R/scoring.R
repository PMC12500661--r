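#' Linear partial value (single-attribute utility) functions
#'
#' Map a raw pooled outcome `u` onto the 0-100 preference scale between two
#' anchors.  For a benefit criterion the preference grows with the outcome,
#' \deqn{U_{benefit} = \frac{u - u_{min}}{u_{max} - u_{min}} \times 100,}
#' so `u = u_min` scores 0 and `u = u_max` scores 100.  For a risk
#' criterion the scale is reversed,
#' \deqn{U_{risk} = \frac{u_{max} - u}{u_{max} - u_{min}} \times 100,}
#' so the *lowest* observed risk scores 100 ("higher = safer").  Both are
#' affine in `u`, which is what later makes Monte Carlo means of scores
#' coincide with scores of means.
#'
#' @param u Raw outcome value(s), in outcome units.
#' @param u_min,u_max Anchors with `u_min < u_max`, in the same units.
#' @return Preference value(s); within `[0, 100]` when `u` lies inside the
#'   anchor range.  Inputs are not clamped here; see [score_alternatives()].
#' @examples
#' partial_value_benefit(9.38, 2, 11) # 82
#' partial_value_risk(0.44, 0, 1)     # 56
#' @export
partial_value_benefit <- function(u, u_min, u_max) {
  check_anchors(u_min, u_max)
  (u - u_min) / (u_max - u_min) * 100
}

#' @rdname partial_value_benefit
#' @export
partial_value_risk <- function(u, u_min, u_max) {
  check_anchors(u_min, u_max)
  (u_max - u) / (u_max - u_min) * 100
}

check_anchors <- function(u_min, u_max) {
  if (any(!is.finite(u_min)) || any(!is.finite(u_max)) || any(u_max <= u_min)) {
    stop("anchors must be finite with u_min < u_max", call. = FALSE)
  }
  invisible(TRUE)
}

## Preference for raw value(s) u under one criterion row. The anchored form
## (u - worst) / (optimal - worst) * 100 covers both categories and both
## anchor orientations: it reduces to the benefit formula when optimal >
## worst and to the risk formula when optimal < worst.
criterion_preference <- function(u, cr, clamp = TRUE, warn = TRUE) {
  if (isTRUE(cr$magnitude)) u <- abs(u)
  lo <- min(cr$optimal, cr$worst)
  hi <- max(cr$optimal, cr$worst)
  out_of_range <- u < lo | u > hi
  if (any(out_of_range)) {
    if (!clamp) {
      stop("value outside [", lo, ", ", hi, "] for criterion '", cr$id, "'",
           call. = FALSE)
    }
    if (warn) {
      warning(sprintf("criterion '%s': %d value(s) outside anchor range [%g, %g] clamped",
                      cr$id, sum(out_of_range), lo, hi), call. = FALSE)
    }
    u <- pmin(pmax(u, lo), hi)
  }
  (u - cr$worst) / (cr$optimal - cr$worst) * 100
}

#' Score alternatives on the 0-100 preference scale
#'
#' Applies each criterion's linear partial value function to the pooled
#' estimates of every arm present in `pooled`, producing a preference
#' matrix in long form.  Criteria flagged `magnitude` in the tree have the
#' absolute value of their pooled estimate taken first (for outcomes
#' recorded as signed changes whose magnitude is anchored).  Values outside
#' the `[worst, optimal]` anchor range are clamped to the boundary with a
#' warning: the partial value function is only defined on the anchored
#' range, so out-of-range inputs map to preference 0 or 100.
#'
#' @param pooled A `"pooled_estimate"` data frame (one row per arm x
#'   criterion; see [pool_criteria()]).
#' @param tree A [value_tree()]; every tree criterion must be present for
#'   every arm.
#' @param warn Emit a warning when clamping occurs (default `TRUE`).
#' @return A data frame of class `"preference_matrix"` with columns
#'   `alternative`, `criterion_id`, `preference` and `provenance`
#'   (`"computed"` here; `"asserted"` marks externally supplied values, see
#'   [asserted_preferences()]).
#' @export
score_alternatives <- function(pooled, tree, warn = TRUE) {
  tree <- validate_value_tree(tree)
  arms <- unique(pooled$arm)
  rows <- list()
  for (arm in arms) {
    sub <- pooled[pooled$arm == arm, , drop = FALSE]
    miss <- setdiff(tree$criteria$id, sub$criterion_id)
    if (length(miss) > 0L) {
      stop("arm '", arm, "' has no pooled estimate for criterion: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (j in seq_len(nrow(tree$criteria))) {
      cr <- tree$criteria[j, ]
      u <- sub$estimate[match(cr$id, sub$criterion_id)]
      rows[[length(rows) + 1L]] <- data.frame(
        alternative = arm, criterion_id = cr$id,
        preference = criterion_preference(u, cr, clamp = TRUE, warn = warn),
        provenance = "computed", stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("preference_matrix", "data.frame")
  out
}

#' Mark externally supplied preference values
#'
#' Builds a `"preference_matrix"` from values taken verbatim from an
#' external source (for example a published scoring table), flagging them
#' `provenance = "asserted"` so reproduction reports can distinguish them
#' from values the package computed.
#'
#' @param df A data frame with columns `alternative`, `criterion_id`,
#'   `preference`.
#' @return A `"preference_matrix"` data frame.
#' @export
asserted_preferences <- function(df) {
  req <- c("alternative", "criterion_id", "preference")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(df$preference < 0 | df$preference > 100)) {
    stop("preference values must lie in [0, 100]", call. = FALSE)
  }
  out <- df[, req]
  out$provenance <- "asserted"
  class(out) <- c("preference_matrix", "data.frame")
  out
}
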