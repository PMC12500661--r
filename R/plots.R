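#' Weight-sensitivity line plot
#'
#' Total benefit-risk score of each alternative as a function of one
#' scanned weight (a category's top-level weight or a criterion's
#' within-category share), with the baseline weight marked.  A crossing of
#' the lines inside `[0, 1]` is the rank-reversal weight reported by
#' [crossover_weight()].
#'
#' @inheritParams crossover_weight
#' @param n_grid Number of grid points (default 101).
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(preferences, tree, target, n_grid = 101) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sensitivity requires the ggplot2 package", call. = FALSE)
  }
  tree <- validate_value_tree(tree)
  alts <- sort(unique(preferences$alternative))
  xs <- seq(0, 1, length.out = n_grid)
  rows <- do.call(rbind, lapply(alts, function(alt) {
    cf <- total_affine(preferences[preferences$alternative == alt, ], tree, target)
    data.frame(weight = xs, total = cf$a + cf$b * xs, alternative = alt)
  }))
  base <- if (target == "benefit") {
    tree$benefit_weight
  } else if (target == "risk") {
    tree$risk_weight
  } else {
    j <- match(target, tree$criteria$id)
    cat <- tree$criteria$category[j]
    s <- tree$criteria$swing_weight[tree$criteria$category == cat]
    tree$criteria$swing_weight[j] / sum(s)
  }
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$weight, y = .data$total,
                                     colour = .data$alternative)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = paste0("weight of '", target, "'"),
                  y = "total benefit-risk score",
                  title = paste0("Sensitivity to the weight of '", target, "'")) +
    ggplot2::theme_minimal()
}

#' Histograms of Monte Carlo score differences
#'
#' @param result An `"mc_result"` from [run_mc()].
#' @return A ggplot object faceted by quantity (benefit, risk, total).
#' @export
plot_mc <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_mc requires the ggplot2 package", call. = FALSE)
  }
  d <- result$diff
  long <- data.frame(
    quantity = rep(c("benefit", "risk", "total"), each = nrow(d)),
    difference = c(d$benefit, d$risk, d$total)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$difference)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = "score difference (experimental - control)",
                  y = "iterations") +
    ggplot2::theme_minimal()
}
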