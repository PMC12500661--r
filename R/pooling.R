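#' Read a trial-summary table from CSV
#'
#' The trial-summary format carries one row per study x arm x criterion
#' with columns `study_id`, `arm` (`"experimental"` or `"control"`),
#' `criterion_id`, `kind` (`"continuous"` or `"binary"`), `n`, and either
#' `mean`/`sd` (continuous change scores) or `events` (binary counts).
#'
#' @param path Path to a CSV file with a header row.
#' @return A data frame of arm summaries (unvalidated; see
#'   [validate_inputs()]).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial-summary file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("study_id", "arm", "criterion_id", "kind", "n")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("trial-summary CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("mean", "sd", "events")) if (!(col %in% names(df))) df[[col]] <- NA_real_
  df
}

## Cochran Q, Higgins I^2 and the DerSimonian-Laird moment estimator of the
## between-study variance, from per-study estimates y and variances v.
het_stats <- function(y, v) {
  k <- length(y)
  if (k <= 1L) return(list(Q = 0, I2 = 0, tau2 = 0))
  w <- 1 / v
  yhat <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yhat)^2)
  df <- k - 1
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (C > 0) max(0, (Q - df) / C) else 0
  list(Q = Q, I2 = I2, tau2 = tau2)
}

## Generic inverse-variance pool; tau2 > 0 gives the random-effects weights.
iv_pool <- function(y, v, tau2 = 0) {
  w <- 1 / (v + tau2)
  est <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  list(estimate = est, se = se)
}

pick_model <- function(model, I2) {
  model <- match.arg(model, c("auto", "fixed", "random"))
  if (model == "auto") {
    if (I2 > 50) "random" else "fixed"
  } else {
    model
  }
}

pooled_row <- function(criterion_id, arm, kind, est, lo, hi, k, het, model) {
  structure(
    data.frame(
      criterion_id = criterion_id, arm = arm, kind = kind,
      estimate = est, ci_low = lo, ci_high = hi, k = k,
      Q = het$Q, I2 = het$I2, tau2 = het$tau2, model = model,
      stringsAsFactors = FALSE
    ),
    class = c("pooled_estimate", "data.frame")
  )
}

check_one_cell <- function(data) {
  if (nrow(data) < 1L) stop("no summaries to pool", call. = FALSE)
  if (length(unique(data$criterion_id)) > 1L || length(unique(data$arm)) > 1L) {
    stop("summaries mix criteria or arms; pool one (criterion, arm) cell at a time",
         call. = FALSE)
  }
}

#' Pool continuous arm-level summaries (mean change)
#'
#' Inverse-variance pooling of per-study arm means with within-study
#' variance `sd^2 / n`.  The fixed-effect model forces the between-study
#' variance to zero; the random-effects model uses the DerSimonian-Laird
#' moment estimator, so study weights become `1 / (sd^2/n + tau2)`.  With
#' `model = "auto"` the random-effects model is selected when I\eqn{^2}
#' exceeds 50%, mirroring common systematic-review practice.  The 95%
#' interval is the normal approximation `estimate +/- z * SE` with
#' `z = qnorm(0.975)`.
#'
#' Pooling is per (criterion, arm) cell: this replicates workflows that
#' report per-arm combined results rather than a between-arm contrast.
#'
#' @param data A data frame of arm summaries for a single criterion and
#'   arm, with columns `n`, `mean`, `sd` (and `criterion_id`, `arm`).
#' @param model `"auto"` (default), `"fixed"`, or `"random"`.
#' @return A one-row data frame of class `"pooled_estimate"` with columns
#'   `criterion_id`, `arm`, `kind`, `estimate`, `ci_low`, `ci_high`, `k`,
#'   `Q`, `I2`, `tau2`, `model`.
#' @examples
#' d <- data.frame(study_id = c("a", "b"), arm = "experimental",
#'                 criterion_id = "kps", n = c(30, 60),
#'                 mean = c(10, 8), sd = c(4, 4))
#' pool_continuous(d, model = "fixed")
#' @export
pool_continuous <- function(data, model = c("auto", "fixed", "random")) {
  check_one_cell(data)
  n <- as.numeric(data$n)
  if (any(!is.finite(n) | n < 2)) {
    stop("continuous summaries need n >= 2 in every study", call. = FALSE)
  }
  if (any(!is.finite(data$mean))) stop("missing mean in continuous summary", call. = FALSE)
  if (any(!is.finite(data$sd) | data$sd <= 0)) {
    stop("continuous summaries need sd > 0 (zero-variance input)", call. = FALSE)
  }
  y <- as.numeric(data$mean)
  v <- as.numeric(data$sd)^2 / n
  het <- het_stats(y, v)
  model <- pick_model(model, het$I2)
  tau2 <- if (model == "random") het$tau2 else 0
  fit <- iv_pool(y, v, tau2)
  z <- stats::qnorm(0.975)
  pooled_row(data$criterion_id[1L], data$arm[1L], "continuous",
             fit$estimate, fit$estimate - z * fit$se, fit$estimate + z * fit$se,
             length(y), het, model)
}

#' Pool binary arm-level summaries (incidence rate)
#'
#' Pools per-study proportions `events / n` by inverse variance directly on
#' the proportion scale, so the pooled value is itself an incidence rate in
#' `[0, 1]`.  Within-study variance is `p (1 - p) / n`; studies at the 0 or
#' 1 boundary get a shrunken proportion `(events + 0.5) / (n + 1)` in the
#' *variance* only, keeping their estimate exact while avoiding infinite
#' weight.  A single study is reported with a Wilson score interval (the
#' normal approximation degenerates at the boundary); multi-study intervals
#' are normal-approximation, truncated to `[0, 1]`.
#'
#' @inheritParams pool_continuous
#' @param data A data frame with columns `n` and `events` for a single
#'   criterion and arm.
#' @return A one-row `"pooled_estimate"` data frame; `estimate` is a
#'   proportion.
#' @examples
#' d <- data.frame(study_id = c("a", "b"), arm = "control",
#'                 criterion_id = "gi", n = c(29, 30), events = c(13, 13))
#' pool_binary(d)
#' @export
pool_binary <- function(data, model = c("auto", "fixed", "random")) {
  check_one_cell(data)
  n <- as.numeric(data$n)
  ev <- as.numeric(data$events)
  if (any(!is.finite(n) | n < 1)) stop("binary summaries need n >= 1", call. = FALSE)
  if (any(!is.finite(ev) | ev < 0 | ev > n)) {
    stop("events must satisfy 0 <= events <= n", call. = FALSE)
  }
  p <- ev / n
  if (length(p) == 1L) {
    ci <- wilson_interval(ev, n)
    return(pooled_row(data$criterion_id[1L], data$arm[1L], "binary",
                      p, ci[1L], ci[2L], 1L, het_stats(p, 1),
                      pick_model(model, 0)))
  }
  p_var <- (ev + 0.5) / (n + 1) # variance floor at the 0/1 boundary
  v <- ifelse(p %in% c(0, 1), p_var * (1 - p_var) / n, p * (1 - p) / n)
  het <- het_stats(p, v)
  model <- pick_model(model, het$I2)
  tau2 <- if (model == "random") het$tau2 else 0
  fit <- iv_pool(p, v, tau2)
  z <- stats::qnorm(0.975)
  pooled_row(data$criterion_id[1L], data$arm[1L], "binary",
             min(max(fit$estimate, 0), 1),
             max(fit$estimate - z * fit$se, 0),
             min(fit$estimate + z * fit$se, 1),
             length(p), het, model)
}

wilson_interval <- function(events, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- events / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(ctr - hw, 0), min(ctr + hw, 1))
}

#' Heterogeneity statistics for a set of study summaries
#'
#' Computes Cochran's Q against the fixed-effect pooled value, Higgins
#' I\eqn{^2} as `max(0, (Q - df)/Q) * 100`, and the DerSimonian-Laird
#' between-study variance `tau2 = max(0, (Q - df)/C)` with
#' `C = sum(w) - sum(w^2)/sum(w)`.  A single study returns all zeros.
#'
#' @param data Arm summaries for one (criterion, arm) cell, continuous or
#'   binary (the `kind` column decides how study variances are formed).
#' @return A list with components `Q`, `I2` (percent) and `tau2`.
#' @export
heterogeneity <- function(data) {
  check_one_cell(data)
  kind <- unique(data$kind)
  if (length(kind) != 1L) stop("summaries mix kinds", call. = FALSE)
  if (kind == "continuous") {
    y <- as.numeric(data$mean)
    v <- as.numeric(data$sd)^2 / as.numeric(data$n)
  } else {
    n <- as.numeric(data$n)
    y <- as.numeric(data$events) / n
    pv <- (as.numeric(data$events) + 0.5) / (n + 1)
    v <- ifelse(y %in% c(0, 1), pv * (1 - pv) / n, y * (1 - y) / n)
  }
  het_stats(y, v)
}

#' Pool every (criterion, arm) cell of a trial-summary table
#'
#' Convenience wrapper applying [pool_continuous()] or [pool_binary()] to
#' each criterion x arm combination present in `data`, optionally checking
#' criterion ids against a value tree.
#'
#' @param data A trial-summary data frame (see [read_trials()]).
#' @param tree Optional [value_tree()]; criteria absent from the tree are
#'   an error.
#' @inheritParams pool_continuous
#' @return A `"pooled_estimate"` data frame with one row per cell.
#' @export
pool_criteria <- function(data, tree = NULL, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  if (!is.null(tree)) {
    unknown <- setdiff(unique(data$criterion_id), tree$criteria$id)
    if (length(unknown) > 0L) {
      stop("criteria in trial summaries absent from the value tree: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  cells <- unique(data[, c("criterion_id", "arm")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- data[data$criterion_id == cells$criterion_id[i] &
                   data$arm == cells$arm[i], , drop = FALSE]
    kind <- unique(cell$kind)
    if (length(kind) != 1L) {
      stop("criterion '", cells$criterion_id[i], "' mixes continuous and binary rows",
           call. = FALSE)
    }
    if (kind == "continuous") pool_continuous(cell, model) else pool_binary(cell, model)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pooled_estimate", "data.frame")
  rownames(out) <- NULL
  out
}
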