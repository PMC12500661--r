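#' Construct a benefit-risk value tree
#'
#' A value tree is the decision model at the heart of an additive MCDA
#' benefit-risk assessment: a two-level hierarchy in which a top-level
#' *benefit* category and a *risk* category split the total weight between
#' them, and each category carries one or more leaf criteria with swing
#' weights and outcome anchors.
#'
#' Swing weights are ratio-scale within a category: the most important
#' criterion conventionally receives 100 and the others are scaled against
#' it, so multiplying all swings in a category by a common positive factor
#' leaves the normalized weights (and every downstream score) unchanged.
#'
#' The `optimal` and `worst` anchors delimit the range over which the linear
#' partial value function for the criterion is defined; they are expressed
#' in the raw units of the pooled outcome (see [partial_value_benefit()]).
#'
#' @param benefit_weight,risk_weight Top-level category weights as
#'   fractions; they must sum to 1.
#' @param criteria A data frame with one row per leaf criterion and columns
#'   `id`, `label`, `category` (`"benefit"` or `"risk"`), `swing_weight`
#'   (in `(0, 100]`), `optimal`, `worst` (anchors, `optimal != worst`),
#'   `direction` (`"higher_is_better"` or `"lower_is_better"`, describing
#'   the raw outcome before anchoring) and optionally `magnitude` (logical;
#'   take the absolute value of the pooled estimate before anchoring, for
#'   outcomes recorded as signed changes whose magnitude is what the
#'   anchors refer to; defaults to `FALSE`).
#'
#' @return An object of class `"value_tree"`: a list with elements
#'   `benefit_weight`, `risk_weight` and `criteria` (the validated
#'   criterion table).
#'
#' @seealso [load_value_tree()] to read a tree from a YAML/JSON config,
#'   [normalize_weights()] for the hierarchical weight normalization.
#' @examples
#' tree <- value_tree(
#'   benefit_weight = 0.75, risk_weight = 0.25,
#'   criteria = data.frame(
#'     id = c("resp", "tox"),
#'     label = c("Response", "Toxicity"),
#'     category = c("benefit", "risk"),
#'     swing_weight = c(100, 100),
#'     optimal = c(1, 0), worst = c(0, 1),
#'     direction = c("higher_is_better", "lower_is_better")
#'   )
#' )
#' normalize_weights(tree)
#' @export
value_tree <- function(benefit_weight, risk_weight, criteria) {
  tree <- structure(
    list(
      benefit_weight = as.numeric(benefit_weight),
      risk_weight = as.numeric(risk_weight),
      criteria = as.data.frame(criteria, stringsAsFactors = FALSE)
    ),
    class = "value_tree"
  )
  validate_value_tree(tree)
}

#' @rdname value_tree
#' @param tree A `value_tree` object (or a bare list with the same fields).
#' @export
validate_value_tree <- function(tree) {
  cr <- tree$criteria
  req <- c("id", "category", "swing_weight", "optimal", "worst")
  miss <- setdiff(req, names(cr))
  if (length(miss) > 0L) {
    stop("value tree criteria are missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!("label" %in% names(cr))) cr$label <- cr$id
  if (!("direction" %in% names(cr))) cr$direction <- "higher_is_better"
  if (!("magnitude" %in% names(cr))) cr$magnitude <- FALSE
  cr$magnitude <- as.logical(cr$magnitude)
  cr$magnitude[is.na(cr$magnitude)] <- FALSE

  bw <- tree$benefit_weight
  rw <- tree$risk_weight
  for (w in list(benefit = bw, risk = rw)) {
    if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1) {
      stop("category weights must be single fractions in [0, 1]", call. = FALSE)
    }
  }
  if (abs(bw + rw - 1) > 1e-8) {
    stop(sprintf("benefit_weight + risk_weight must equal 1 (got %.4g + %.4g = %.4g)",
                 bw, rw, bw + rw), call. = FALSE)
  }
  if (nrow(cr) < 1L) stop("value tree needs at least one criterion", call. = FALSE)
  if (anyDuplicated(cr$id)) {
    stop("duplicate criterion id(s): ",
         paste(unique(cr$id[duplicated(cr$id)]), collapse = ", "), call. = FALSE)
  }
  bad_cat <- setdiff(unique(cr$category), c("benefit", "risk"))
  if (length(bad_cat) > 0L) {
    stop("unknown criterion category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  bad_dir <- setdiff(unique(cr$direction), c("higher_is_better", "lower_is_better"))
  if (length(bad_dir) > 0L) {
    stop("unknown criterion direction: ", paste(bad_dir, collapse = ", "),
         call. = FALSE)
  }
  bad_sw <- !is.finite(cr$swing_weight) | cr$swing_weight <= 0 | cr$swing_weight > 100
  if (any(bad_sw)) {
    stop("swing_weight must lie in (0, 100]; offending criterion: ",
         paste(cr$id[bad_sw], collapse = ", "), call. = FALSE)
  }
  bad_anchor <- !is.finite(cr$optimal) | !is.finite(cr$worst) | cr$optimal == cr$worst
  if (any(bad_anchor)) {
    stop("optimal and worst anchors must be finite and distinct; offending criterion: ",
         paste(cr$id[bad_anchor], collapse = ", "), call. = FALSE)
  }
  for (cat in c("benefit", "risk")) {
    w <- if (cat == "benefit") bw else rw
    if (w > 0 && !any(cr$category == cat)) {
      stop(sprintf("category '%s' has weight %.3g but no criteria", cat, w),
           call. = FALSE)
    }
  }
  tree$criteria <- cr[, c("id", "label", "category", "swing_weight",
                          "optimal", "worst", "direction", "magnitude")]
  rownames(tree$criteria) <- NULL
  class(tree) <- "value_tree"
  tree
}

#' Load a value tree from a YAML or JSON configuration file
#'
#' The configuration document holds a `version` field, the top-level
#' `benefit_weight` / `risk_weight` split, and a `criteria` list whose
#' entries carry the fields documented in [value_tree()].  Unknown keys
#' raise a warning (never silently ignored); any invariant violation is an
#' error naming the offending entry.  JSON is accepted because it is a
#' subset of the YAML the parser understands.
#'
#' @param path Path to the configuration file.
#' @return A validated [value_tree()] object.
#' @examples
#' cfg <- system.file("extdata", "nsclc_value_tree.yaml", package = "brmcda")
#' tree <- load_value_tree(cfg)
#' tree
#' @export
load_value_tree <- function(path) {
  doc <- yaml::read_yaml(path)
  known_top <- c("version", "benefit_weight", "risk_weight", "criteria")
  extra <- setdiff(names(doc), known_top)
  if (length(extra) > 0L) {
    warning("ignoring unknown top-level key(s) in value-tree config: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  for (f in c("benefit_weight", "risk_weight", "criteria")) {
    if (is.null(doc[[f]])) {
      stop("value-tree config is missing required field '", f, "'", call. = FALSE)
    }
  }
  known_cr <- c("id", "label", "category", "swing_weight", "optimal", "worst",
                "direction", "magnitude")
  rows <- lapply(seq_along(doc$criteria), function(i) {
    entry <- doc$criteria[[i]]
    # nested lists would mean a deeper hierarchy than the two-level tree supports
    if (any(vapply(entry, function(x) is.list(x), logical(1L)))) {
      stop("criterion entry ", i,
           " is nested; only a two-level tree (category -> criterion) is supported",
           call. = FALSE)
    }
    extra <- setdiff(names(entry), known_cr)
    if (length(extra) > 0L) {
      warning("criterion '", entry$id %||% i, "': ignoring unknown key(s) ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
    miss <- setdiff(c("id", "category", "swing_weight", "optimal", "worst"),
                    names(entry))
    if (length(miss) > 0L) {
      stop("criterion '", entry$id %||% i, "' is missing field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    data.frame(
      id = entry$id,
      label = entry$label %||% entry$id,
      category = entry$category,
      swing_weight = as.numeric(entry$swing_weight),
      optimal = as.numeric(entry$optimal),
      worst = as.numeric(entry$worst),
      direction = entry$direction %||% "higher_is_better",
      magnitude = isTRUE(entry$magnitude),
      stringsAsFactors = FALSE
    )
  })
  value_tree(doc$benefit_weight, doc$risk_weight, do.call(rbind, rows))
}

#' Normalized hierarchical criterion weights
#'
#' Converts the two-level weight structure (category weight times
#' within-category swing weight) into one relative weight per criterion:
#' for criterion \eqn{j} in category \eqn{c},
#' \deqn{\omega_j = w_c \, s_j / \sum_{k \in c} s_k,}
#' so the full vector sums to 1.  These are the weights that enter the
#' additive value model \eqn{U_i = \sum_j \omega_j U_{ij}}.
#'
#' @param tree A [value_tree()].
#' @return A named numeric vector of relative weights (names are criterion
#'   ids), summing to 1.
#' @export
normalize_weights <- function(tree) {
  tree <- validate_value_tree(tree)
  cr <- tree$criteria
  out <- numeric(nrow(cr))
  for (cat in c("benefit", "risk")) {
    idx <- cr$category == cat
    w <- if (cat == "benefit") tree$benefit_weight else tree$risk_weight
    if (!any(idx)) next
    s <- cr$swing_weight[idx]
    if (sum(s) <= 0 && w > 0) {
      stop("category '", cat, "' has zero total swing weight but weight ", w,
           call. = FALSE)
    }
    out[idx] <- if (w > 0) w * s / sum(s) else 0
  }
  names(out) <- cr$id
  out
}

#' @export
print.value_tree <- function(x, ...) {
  cat(sprintf("Benefit-risk value tree (%d criteria)\n", nrow(x$criteria)))
  cat(sprintf("  top-level weights: benefit %.3g / risk %.3g\n",
              x$benefit_weight, x$risk_weight))
  rel <- normalize_weights(x)
  tab <- x$criteria[, c("id", "label", "category", "swing_weight",
                        "optimal", "worst")]
  tab$relative <- round(rel[tab$id], 4)
  print(tab, row.names = FALSE, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
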