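#' Sample from a triangular distribution
#'
#' Inverse-CDF sampling from the triangular distribution with support
#' `[low, high]` and mode `mode`.  In uncertainty propagation each pooled
#' effect is represented as triangular with `low` and `high` at the 95%
#' confidence bounds and `mode` at the point estimate, the conventional
#' three-point mapping of an interval estimate onto a bounded
#' distribution.  A degenerate spec (`low == mode == high`) yields a point
#' mass.
#'
#' @param n Number of draws.
#' @param low,mode,high Distribution parameters, `low <= mode <= high`.
#' @return A numeric vector of `n` samples, all within `[low, high]`.
#' @export
sample_triangular <- function(n, low, mode, high) {
  if (!is.finite(low) || !is.finite(mode) || !is.finite(high) ||
      low > mode || mode > high) {
    stop("triangular spec needs low <= mode <= high (finite)", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (high == low) return(rep(low, n))
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

#' Triangular uncertainty specs from pooled estimates
#'
#' @param pooled A `"pooled_estimate"` data frame.
#' @return A data frame with columns `arm`, `criterion_id`, `low`, `mode`,
#'   `high` (`ci_low`, `estimate`, `ci_high` respectively).
#' @export
triangular_specs <- function(pooled) {
  out <- data.frame(
    arm = pooled$arm, criterion_id = pooled$criterion_id,
    low = pooled$ci_low, mode = pooled$estimate, high = pooled$ci_high,
    stringsAsFactors = FALSE
  )
  bad <- out$low > out$mode | out$mode > out$high
  if (any(bad)) {
    stop("pooled rows violate ci_low <= estimate <= ci_high: ",
         paste(out$criterion_id[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Monte Carlo propagation of effect uncertainty through the value model
#'
#' Each iteration draws every (arm, criterion) effect independently from
#' its triangular spec, converts the draws to preferences (with the same
#' orientation and clamping policy as [score_alternatives()]; clamping is
#' counted, not warned per sample), aggregates both arms, and records the
#' benefit, risk and total score differences (experimental minus control).
#' The probability of superiority is the fraction of iterations in which
#' the experimental total exceeds the control total.
#'
#' With the same `seed`, `n_iter` and model the result is bit-identical
#' across runs.
#'
#' @param tree A [value_tree()].
#' @param specs Triangular specs as from [triangular_specs()]: one row per
#'   (arm, criterion), arms `"experimental"` and `"control"`, covering
#'   every tree criterion.
#' @param n_iter Number of simulations (default 10000).
#' @param seed Integer seed for the single random generator used.
#' @return An object of class `"mc_result"`: a list with `n_iter`, `seed`,
#'   `diff` (data frame of per-iteration benefit/risk/total differences),
#'   `totals` (per-iteration totals per arm), `p_superiority`, and
#'   `n_clamped` (count of sampled effects clamped to the anchor range).
#' @export
run_mc <- function(tree, specs, n_iter = 10000, seed = 1L) {
  tree <- validate_value_tree(tree)
  arms <- c("experimental", "control")
  miss <- setdiff(arms, unique(specs$arm))
  if (length(miss) > 0L) {
    stop("specs missing arm(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (arm in arms) {
    absent <- setdiff(tree$criteria$id,
                      specs$criterion_id[specs$arm == arm])
    if (length(absent) > 0L) {
      stop("arm '", arm, "' is missing spec(s) for criterion: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  n_clamped <- 0L
  # preference draws per arm: n_iter x n_criteria matrices
  pref <- list()
  for (arm in arms) {
    m <- matrix(NA_real_, nrow = n_iter, ncol = nrow(tree$criteria),
                dimnames = list(NULL, tree$criteria$id))
    for (j in seq_len(nrow(tree$criteria))) {
      cr <- tree$criteria[j, ]
      sp <- specs[specs$arm == arm & specs$criterion_id == cr$id, , drop = FALSE]
      u <- sample_triangular(n_iter, sp$low[1L], sp$mode[1L], sp$high[1L])
      v <- if (isTRUE(cr$magnitude)) abs(u) else u
      lo <- min(cr$optimal, cr$worst); hi <- max(cr$optimal, cr$worst)
      n_clamped <- n_clamped + sum(v < lo | v > hi)
      m[, j] <- criterion_preference(u, cr, clamp = TRUE, warn = FALSE)
    }
    pref[[arm]] <- m
  }
  cat_scores <- function(m, cat) {
    idx <- tree$criteria$category == cat
    if (!any(idx)) return(rep(0, n_iter))
    w <- tree$criteria$swing_weight[idx]
    as.vector(m[, idx, drop = FALSE] %*% w) / sum(w)
  }
  res <- lapply(arms, function(arm) {
    b <- cat_scores(pref[[arm]], "benefit")
    r <- cat_scores(pref[[arm]], "risk")
    list(benefit = b, risk = r,
         total = tree$benefit_weight * b + tree$risk_weight * r)
  })
  names(res) <- arms
  diff <- data.frame(
    benefit = res$experimental$benefit - res$control$benefit,
    risk = res$experimental$risk - res$control$risk,
    total = res$experimental$total - res$control$total
  )
  structure(
    list(
      n_iter = n_iter, seed = as.integer(seed), diff = diff,
      totals = data.frame(experimental = res$experimental$total,
                          control = res$control$total),
      p_superiority = mean(diff$total > 0),
      n_clamped = n_clamped
    ),
    class = "mc_result"
  )
}

#' Summarize a Monte Carlo result
#'
#' Equal-tailed percentile summaries of the benefit, risk and total score
#' differences, plus the probability of superiority.
#'
#' @param result An `"mc_result"` from [run_mc()].
#' @param conf Interval coverage (default 0.95).
#' @return A data frame with one row per quantity (`benefit`, `risk`,
#'   `total`): `mean`, `ci_low`, `ci_high`; `p_superiority` is attached as
#'   an attribute and printed by the method.
#' @export
summarize_mc <- function(result, conf = 0.95) {
  if (result$n_iter < 2L) stop("need at least 2 iterations to summarize", call. = FALSE)
  a <- (1 - conf) / 2
  rows <- lapply(c("benefit", "risk", "total"), function(q) {
    x <- result$diff[[q]]
    data.frame(quantity = q, mean = mean(x),
               ci_low = unname(stats::quantile(x, a, type = 7)),
               ci_high = unname(stats::quantile(x, 1 - a, type = 7)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "p_superiority") <- result$p_superiority
  attr(out, "seed") <- result$seed
  out
}

#' @export
print.mc_result <- function(x, ...) {
  s <- summarize_mc(x)
  cat(sprintf("Monte Carlo uncertainty propagation: %d iterations (seed %d)\n",
              x$n_iter, x$seed))
  cat("Score differences (experimental - control):\n")
  print(data.frame(quantity = s$quantity,
                   mean = round(s$mean, 2),
                   ci_low = round(s$ci_low, 2),
                   ci_high = round(s$ci_high, 2)),
        row.names = FALSE)
  cat(sprintf("P(experimental total > control total) = %.2f%%\n",
              100 * x$p_superiority))
  if (x$n_clamped > 0L) {
    cat(sprintf("(%d sampled effect value(s) clamped to anchor range)\n",
                x$n_clamped))
  }
  invisible(x)
}
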