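#' Define a synthetic two-arm trial scenario
#'
#' Describes a set of small two-arm RCTs with the statistical structure
#' the pooling stage assumes: per-study true effects drawn around a common
#' mean with between-study heterogeneity, continuous outcomes reported as
#' the sample mean and SD of normal change scores, and binary outcomes as
#' binomial event counts.  The defaults emulate the NSCLC case study: six
#' trials of 20-45 patients per arm, true per-arm effects at the pooled
#' point estimates of the case study, and each study reporting only a
#' subset of the five outcomes (four trials report KPS; two report the
#' tumor markers, fatigue and gastrointestinal adverse reactions).
#'
#' For continuous criteria the between-study SD `tau` acts on the outcome
#' scale; for binary criteria it acts on the log-odds scale.
#'
#' @param n_studies Number of trials (default 6).
#' @param effects Data frame with columns `criterion_id`, `kind`,
#'   `experimental`, `control` (true per-arm effects: mean change for
#'   continuous, event rate for binary) and `within_sd` (per-patient SD,
#'   continuous only).  Default: the case-study calibration.
#' @param tau Between-study SD of the true effects (default 0, homogeneous
#'   studies).
#' @param arm_n Integer range (length 2) of per-arm sample sizes, drawn
#'   uniformly per study (default `c(20, 45)`).
#' @param availability Logical matrix (`n_studies` x criteria) marking
#'   which outcomes each study reports; `NULL` (default) uses the
#'   case-study reporting pattern when the default criteria are in play at
#'   `n_studies = 6`, otherwise full reporting.
#' @param seed Integer seed.
#' @return An object of class `"trial_scenario"`.
#' @export
trial_scenario <- function(n_studies = 6,
                           effects = default_effects(),
                           tau = 0,
                           arm_n = c(20, 45),
                           availability = NULL,
                           seed = 1L) {
  req <- c("criterion_id", "kind", "experimental", "control")
  miss <- setdiff(req, names(effects))
  if (length(miss) > 0L) {
    stop("effects table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!("within_sd" %in% names(effects))) effects$within_sd <- NA_real_
  binary <- effects$kind == "binary"
  rates <- c(effects$experimental[binary], effects$control[binary])
  if (any(rates < 0 | rates > 1)) {
    stop("binary true rates must lie in [0, 1]", call. = FALSE)
  }
  cont <- effects$kind == "continuous"
  if (any(!is.finite(effects$within_sd[cont]) | effects$within_sd[cont] <= 0)) {
    stop("continuous criteria need within_sd > 0", call. = FALSE)
  }
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (length(arm_n) != 2L || any(arm_n < 2)) {
    stop("arm_n must be a range with minimum >= 2", call. = FALSE)
  }
  if (is.null(availability)) {
    availability <- default_availability(n_studies, effects$criterion_id)
  }
  stopifnot(nrow(availability) == n_studies,
            ncol(availability) == nrow(effects))
  structure(
    list(n_studies = n_studies, effects = effects, tau = tau,
         arm_n = as.integer(arm_n), availability = availability,
         seed = as.integer(seed)),
    class = "trial_scenario"
  )
}

## True per-arm effects calibrated to the case study's pooled estimates
## (KPS on the magnitude scale); within-arm SDs are plausible clinical
## spreads consistent with the width of the pooled intervals.
default_effects <- function() {
  data.frame(
    criterion_id = c("kps", "ca211", "cea", "fatigue", "gi"),
    kind = c("continuous", "continuous", "continuous", "continuous", "binary"),
    experimental = c(9.38, 4.98, 9.96, 14.58, 0.44),
    control = c(3.63, 3.89, 7.58, 3.70, 0.76),
    within_sd = c(8, 2, 3.5, 9, NA),
    stringsAsFactors = FALSE
  )
}

## Reporting pattern of the six case-study trials: studies 2 and 3 report
## everything but fatigue; 1 and 5 report only fatigue; 4 and 6 only KPS.
default_availability <- function(n_studies, ids) {
  avail <- matrix(TRUE, n_studies, length(ids), dimnames = list(NULL, ids))
  if (n_studies == 6 && setequal(ids, c("kps", "ca211", "cea", "fatigue", "gi"))) {
    avail[] <- FALSE
    avail[c(2, 3), c("kps", "ca211", "cea", "gi")] <- TRUE
    avail[c(1, 5), "fatigue"] <- TRUE
    avail[c(4, 6), "kps"] <- TRUE
  }
  avail
}

#' Generate arm-level summaries for a synthetic scenario
#'
#' Simulates each trial of the scenario and reports the arm-level
#' summaries the pooling stage consumes.  Per study, a true effect is
#' drawn for every reported criterion (`Normal(effect, tau^2)` on the
#' outcome scale for continuous outcomes, `Normal` on the log-odds scale
#' for binary), then per-patient data are simulated and summarized: sample
#' mean and SD of `n` normal change scores, or a binomial event count.
#' With the same scenario (including its seed) the output table is
#' identical across calls.
#'
#' @param scenario A [trial_scenario()].
#' @return A trial-summary data frame (columns `study_id`, `arm`,
#'   `criterion_id`, `kind`, `n`, `mean`, `sd`, `events`) satisfying the
#'   arm-summary invariants.
#' @export
generate_trials <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  set.seed(scenario$seed)
  eff <- scenario$effects
  rows <- list()
  for (s in seq_len(scenario$n_studies)) {
    n_arm <- sample(seq(scenario$arm_n[1L], scenario$arm_n[2L]), 2, replace = TRUE)
    names(n_arm) <- c("experimental", "control")
    for (j in seq_len(nrow(eff))) {
      if (!scenario$availability[s, j]) next
      for (arm in c("experimental", "control")) {
        n <- n_arm[[arm]]
        true <- eff[[arm]][j]
        if (eff$kind[j] == "continuous") {
          theta <- stats::rnorm(1, true, scenario$tau)
          x <- stats::rnorm(n, theta, eff$within_sd[j])
          row <- data.frame(study_id = paste0("study", s), arm = arm,
                            criterion_id = eff$criterion_id[j],
                            kind = "continuous", n = n,
                            mean = mean(x), sd = stats::sd(x),
                            events = NA_real_, stringsAsFactors = FALSE)
        } else {
          rate <- stats::plogis(stats::rnorm(1, stats::qlogis(true), scenario$tau))
          row <- data.frame(study_id = paste0("study", s), arm = arm,
                            criterion_id = eff$criterion_id[j],
                            kind = "binary", n = n,
                            mean = NA_real_, sd = NA_real_,
                            events = stats::rbinom(1, n, rate),
                            stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The NSCLC chemotherapy case study
#'
#' The worked example shipped with the package: a published benefit-risk
#' comparison of chemotherapy alone (control) against chemotherapy plus an
#' adjuvant herbal decoction (experimental) in non-small cell lung cancer,
#' built on six small RCTs.  Returns the value tree (five criteria:
#' KPS change, CA211 and CEA reduction, Cancer Fatigue Scale change, and
#' gastrointestinal adverse-reaction incidence; top-level weights
#' 0.75/0.25), the per-arm pooled estimates with 95% CIs as reported
#' (mean differences for the continuous outcomes, incidence rates for the
#' binary one), and the preference values of the published scoring table,
#' flagged `provenance = "asserted"` because several of them cannot be
#' recomputed from the published anchors and pooled estimates (see
#' [reproduction_report()]).
#'
#' @return A list with elements `tree` (a [value_tree()]), `pooled` (a
#'   `"pooled_estimate"` data frame; heterogeneity columns are `NA`
#'   because only the combined results were reported) and `preferences`
#'   (an asserted `"preference_matrix"`).
#' @examples
#' cs <- nsclc_study()
#' score_cards(cs$preferences, cs$tree)
#' @export
nsclc_study <- function() {
  tree <- load_value_tree(system.file("extdata", "nsclc_value_tree.yaml",
                                      package = "brmcda"))
  pooled <- utils::read.csv(system.file("extdata", "nsclc_pooled.csv",
                                        package = "brmcda"),
                            stringsAsFactors = FALSE)
  pooled$Q <- NA_real_; pooled$I2 <- NA_real_; pooled$tau2 <- NA_real_
  pooled$model <- "reported"
  class(pooled) <- c("pooled_estimate", "data.frame")
  prefs <- asserted_preferences(
    utils::read.csv(system.file("extdata", "nsclc_preferences.csv",
                                package = "brmcda"),
                    stringsAsFactors = FALSE)
  )
  list(tree = tree, pooled = pooled, preferences = prefs)
}
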