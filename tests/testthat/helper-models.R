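# Shared fixtures: small value trees and a random-tree generator for
# property-style tests.

two_criterion_tree <- function(benefit_weight = 0.5) {
  value_tree(
    benefit_weight = benefit_weight, risk_weight = 1 - benefit_weight,
    criteria = data.frame(
      id = c("eff", "tox"),
      label = c("Efficacy", "Toxicity"),
      category = c("benefit", "risk"),
      swing_weight = c(100, 100),
      optimal = c(1, 0), worst = c(0, 1),
      direction = c("higher_is_better", "lower_is_better"),
      stringsAsFactors = FALSE
    )
  )
}

random_tree <- function(n_benefit = sample(1:4, 1), n_risk = sample(1:3, 1)) {
  bw <- runif(1, 0.05, 0.95)
  n <- n_benefit + n_risk
  value_tree(
    benefit_weight = bw, risk_weight = 1 - bw,
    criteria = data.frame(
      id = paste0("c", seq_len(n)),
      label = paste0("criterion ", seq_len(n)),
      category = rep(c("benefit", "risk"), c(n_benefit, n_risk)),
      swing_weight = runif(n, 1, 100),
      optimal = rep(1, n), worst = rep(0, n),
      direction = "higher_is_better",
      stringsAsFactors = FALSE
    )
  )
}

# Random preference matrix for the alternatives x criteria of a tree.
random_preferences <- function(tree, alternatives = c("experimental", "control")) {
  grid <- expand.grid(alternative = alternatives, criterion_id = tree$criteria$id,
                      stringsAsFactors = FALSE)
  grid$preference <- runif(nrow(grid), 0, 100)
  asserted_preferences(grid)
}
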