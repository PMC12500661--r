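test_that("weight perturbation scales the target and renormalizes siblings", {
  tree <- nsclc_study()$tree
  up <- perturb_weight(tree, "kps", 0.20)
  expect_equal(up$criteria$swing_weight[up$criteria$id == "kps"], 96)
  expect_identical(perturb_weight(tree, "kps", 0)$criteria, tree$criteria)
  down <- perturb_weight(tree, "benefit", -0.20)
  expect_equal(down$benefit_weight, 0.60)
  expect_equal(down$risk_weight, 0.40)
  # absolute mode adds points
  abs_up <- perturb_weight(tree, "benefit", 0.10, mode = "absolute")
  expect_equal(abs_up$benefit_weight, 0.85)
  expect_equal(perturb_weight(tree, "kps", 0.10, mode = "absolute")$criteria$swing_weight[
    tree$criteria$id == "kps"], 90)
  expect_error(perturb_weight(tree, "benefit", 0.40), "outside")
  expect_error(perturb_weight(tree, "kps", -1, mode = "relative"), "positive")
  expect_error(perturb_weight(tree, "nope", 0.1), "unknown")
})

test_that("scaling a swing past 100 rescales the category without changing weights", {
  tree <- nsclc_study()$tree
  up <- perturb_weight(tree, "fatigue", 0.20) # 100 -> 120, rescaled
  expect_lte(max(up$criteria$swing_weight), 100)
  w0 <- normalize_weights(tree)
  w1 <- normalize_weights(up)
  # fatigue share rises, ratios among the other benefit criteria unchanged
  expect_gt(w1[["fatigue"]], w0[["fatigue"]])
  expect_equal(w1[["kps"]] / w1[["ca211"]], w0[["kps"]] / w0[["ca211"]],
               tolerance = 1e-12)
})

test_that("perturbed trees always satisfy the tree invariants", {
  set.seed(21)
  for (i in 1:20) {
    tree <- random_tree(n_benefit = 3, n_risk = 2)
    target <- sample(c(tree$criteria$id, "benefit", "risk"), 1)
    delta <- runif(1, -0.5, 0.5)
    ptree <- tryCatch(perturb_weight(tree, target, delta), error = function(e) NULL)
    if (is.null(ptree)) next # perturbation pushed a weight out of range
    expect_s3_class(validate_value_tree(ptree), "value_tree")
    expect_equal(sum(normalize_weights(ptree)), 1, tolerance = 1e-12)
  }
})

test_that("the case-study ranking survives +/-20% perturbation of every weight", {
  cs <- nsclc_study()
  sw <- sensitivity_sweep(cs$preferences, cs$tree)
  expect_equal(nrow(sw), 14) # 5 criteria + 2 categories, 2 deltas each
  expect_false(any(sw$rank_changed))
  expect_true(all(sw$top == "experimental"))
  # the experimental arm dominates criterion-wise, so no single-weight
  # perturbation of any size can reverse the ranking
  big <- sensitivity_sweep(cs$preferences, cs$tree,
                           targets = cs$tree$criteria$id,
                           deltas = c(-0.99, -0.5, 0.5, 0.99))
  expect_false(any(big$rank_changed))
})

test_that("a zero-delta sweep reproduces the baseline exactly", {
  cs <- nsclc_study()
  sw <- sensitivity_sweep(cs$preferences, cs$tree, deltas = 0)
  cards <- score_cards(cs$preferences, cs$tree)
  expect_false(any(sw$rank_changed))
  expect_true(all(abs(sw$total_experimental -
                        cards$total_value[cards$alternative == "experimental"]) < 1e-9))
})

test_that("a constructed near-tie reverses at the analytically known crossover", {
  tree <- two_criterion_tree(benefit_weight = 0.5)
  pref <- asserted_preferences(data.frame(
    alternative = rep(c("A", "B"), each = 2),
    criterion_id = rep(c("eff", "tox"), 2),
    preference = c(100, 0, 0, 100)
  ))
  # total_A = 100x, total_B = 100(1-x): crossover at benefit weight 1/2
  cw <- crossover_weight(pref, tree, "benefit")
  expect_equal(cw$crossover, 0.5, tolerance = 1e-9)
  expect_false(cw$degenerate)
  # at benefit weight 0.6 baseline, a -20% relative perturbation lands
  # below the crossover and flips the ranking
  tree6 <- two_criterion_tree(benefit_weight = 0.6)
  sw <- sensitivity_sweep(pref, tree6, targets = "benefit", deltas = c(-0.2, 0.2))
  expect_true(sw$rank_changed[sw$delta == -0.2])
  expect_false(sw$rank_changed[sw$delta == 0.2])
})

test_that("no crossover exists for the dominated case study and ties are flagged", {
  cs <- nsclc_study()
  for (target in c(cs$tree$criteria$id, "benefit", "risk")) {
    cw <- crossover_weight(cs$preferences, cs$tree, target)
    expect_true(is.na(cw$crossover))
    expect_false(cw$degenerate)
  }
  same <- cs$preferences
  same$preference <- rep(same$preference[same$alternative == "experimental"], 2)
  cw <- crossover_weight(same, cs$tree, "kps")
  expect_true(cw$degenerate)
})

test_that("analytic crossover agrees with a 0.001-step grid scan", {
  grid_scan <- function(pref, tree, target) {
    xs <- seq(0, 1, by = 0.001)
    alts <- sort(unique(pref$alternative))
    totals <- function(x) {
      # rebuild a tree at scanned weight x and aggregate both alternatives
      t2 <- tree
      if (target %in% c("benefit", "risk")) {
        if (target == "benefit") {
          t2$benefit_weight <- x; t2$risk_weight <- 1 - x
        } else {
          t2$risk_weight <- x; t2$benefit_weight <- 1 - x
        }
      } else {
        j <- match(target, t2$criteria$id)
        cat <- t2$criteria$category[j]
        sib <- t2$criteria$category == cat & t2$criteria$id != target
        s <- sum(tree$criteria$swing_weight[sib])
        t2$criteria$swing_weight[j] <- if (x == 1) 1e9 else x / (1 - x) * s
        t2$criteria$swing_weight <- pmin(t2$criteria$swing_weight, 1e9)
        # bypass the (0,100] cap: normalize manually
        cards <- vapply(alts, function(alt) {
          sub <- pref[pref$alternative == alt, ]
          vals <- vapply(c("benefit", "risk"), function(cc) {
            cr <- t2$criteria[t2$criteria$category == cc, , drop = FALSE]
            p <- sub$preference[match(cr$id, sub$criterion_id)]
            sum(cr$swing_weight * p) / sum(cr$swing_weight)
          }, numeric(1))
          t2$benefit_weight * vals[["benefit"]] + t2$risk_weight * vals[["risk"]]
        }, numeric(1))
        return(cards)
      }
      cards <- score_cards(pref, t2)
      setNames(cards$total_value, cards$alternative)[alts]
    }
    sgn <- vapply(xs, function(x) {
      tt <- totals(x)
      sign(tt[1] - tt[2])
    }, numeric(1))
    flips <- which(diff(sign(sgn + 1e-15)) != 0)
    if (length(flips) == 0) NA_real_ else xs[flips[1]]
  }
  set.seed(33)
  found <- 0
  for (i in 1:12) {
    tree <- random_tree(n_benefit = 2, n_risk = 1)
    pref <- random_preferences(tree, alternatives = c("A", "B"))
    target <- sample(c(tree$criteria$id, "benefit"), 1)
    cw <- crossover_weight(pref, tree, target)$crossover
    gs <- grid_scan(pref, tree, target)
    if (is.na(cw)) {
      expect_true(is.na(gs))
    } else {
      found <- found + 1
      expect_lte(abs(cw - gs), 0.001)
    }
  }
  expect_gte(found, 1) # the random models produced at least one crossover
})
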