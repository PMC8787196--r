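# Pairwise group comparisons of behavioral features with Holm
# multiple-comparison correction. Each routine returns a comparison table
# whose full set of rows (every feature x every group pair) forms one Holm
# family -- the most conservative reading of "420 pairwise syntax
# comparisons" for 5 groups over 42 transitions.

#' Number of pairwise comparisons
#'
#' `choose(n_groups, 2) * n_features`: e.g. 5 groups over the 42 action
#' transitions give 420 comparisons, 4 groups give 252.
#'
#' @param n_groups Number of groups (>= 2).
#' @param n_features Features compared per group pair (default 42, the
#'   number of off-diagonal transitions among 7 actions).
#' @return Integer count.
#' @export
comparison_count <- function(n_groups, n_features = 42L) {
  if (n_groups < 2) stop("need at least 2 groups")
  choose(n_groups, 2) * n_features
}

#' Holm step-down multiple-comparison adjustment
#'
#' Sorts the raw p-values ascending, sets
#' `adj_(k) = max_{j <= k} ((m - j + 1) * p_(j))` capped at 1, and returns
#' the adjusted values in the input order. Controls the family-wise error
#' rate at the nominal level. (Thin wrapper over [stats::p.adjust()] with
#' input validation.)
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (`NA`s preserved).
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04))   # 0.02, 0.04
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

# Assemble a comparison table: for every unordered group pair and feature,
# run `test_fn(x, y)` -> list(statistic, p); then Holm over all testable rows.
.pairwise_table <- function(values_by_group, test_name, test_fn, alpha = 0.05) {
  gnames <- names(values_by_group)
  if (length(gnames) < 2L) stop("need at least 2 groups")
  feature_ids <- names(values_by_group[[1L]])
  pairs <- utils::combn(gnames, 2L)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    ga <- pairs[1L, k]; gb <- pairs[2L, k]
    for (f in feature_ids) {
      x <- values_by_group[[ga]][[f]]
      y <- values_by_group[[gb]][[f]]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) >= 2L && length(y) >= 2L) {
        res <- test_fn(x, y)
      } else {
        res <- list(statistic = NA_real_, p = NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = ga, group_b = gb, feature_id = f, test_name = test_name,
        statistic = res$statistic, p_raw = res$p,
        n_a = length(x), n_b = length(y), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- holm_adjust(tab$p_raw)
  tab$significant <- !is.na(tab$p_adjusted) & tab$p_adjusted < alpha
  class(tab) <- c("comparison_table", "data.frame")
  attr(tab, "alpha") <- alpha
  tab
}

# Per-group, per-transition probability values across flies, excluding flies
# whose syntax never observed that source (excluded, not imputed: imputation
# would manufacture zeros).
.syntax_values <- function(groups) {
  tp <- .transition_pairs()
  ids <- .transition_names()
  lapply(groups, function(flies) {
    vals <- lapply(seq_len(nrow(tp)), function(i) {
      s <- tp$source[i]; t <- tp$target[i]
      v <- vapply(flies, function(syn) {
        if (syn$missing[s]) NA_real_ else syn$prob[s, t]
      }, numeric(1))
      v[!is.na(v)]
    })
    setNames(vals, ids)
  })
}

.check_syntax_groups <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list")
  for (g in names(groups)) {
    if (length(groups[[g]]) < 2L)
      stop("group '", g, "' has fewer than 2 flies")
    stopifnot(all(vapply(groups[[g]], inherits, logical(1), "syntax_vector")))
  }
}

#' Pairwise rank-sum tests on transition probabilities
#'
#' For every action transition and every pair of groups, compares the
#' per-fly transition probability distributions with a two-sided Wilcoxon
#' rank-sum test (exact when both groups have <= 10 usable flies, otherwise
#' normal approximation with tie correction). Flies that never exhibit the
#' source action are excluded for that transition. Holm correction is
#' applied over the full table (all transitions x all pairs as one family).
#'
#' @param groups Named list: group name -> list of per-fly
#'   [syntax_vector()]s.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `comparison_table` data.frame (42 x `choose(n_groups, 2)`
#'   rows) with raw and Holm-adjusted p-values and a significance flag.
#' @export
pairwise_location_tests <- function(groups, alpha = 0.05) {
  .check_syntax_groups(groups)
  vals <- .syntax_values(groups)
  .pairwise_table(vals, "wilcoxon_rank_sum", function(x, y) {
    exact <- length(x) <= 10L && length(y) <= 10L
    ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
    list(statistic = unname(ht$statistic), p = ht$p.value)
  }, alpha = alpha)
}

#' Pairwise variance (variability) tests on transition probabilities
#'
#' As [pairwise_location_tests()] but comparing the spread rather than the
#' location of each transition's per-fly probability distribution, using
#' Levene's test with the median as center (the Brown-Forsythe variant,
#' robust for bounded, skewed probabilities). This is the variability
#' analysis: whether groups differ in their within-group range of syntax.
#'
#' @inheritParams pairwise_location_tests
#' @return A `comparison_table` data.frame.
#' @export
pairwise_variance_tests <- function(groups, alpha = 0.05) {
  .check_syntax_groups(groups)
  vals <- .syntax_values(groups)
  .pairwise_table(vals, "brown_forsythe_levene", function(x, y) {
    if (stats::sd(c(x, y)) == 0 ||
        (all(abs(x - median(x)) < 1e-15) && all(abs(y - median(y)) < 1e-15)))
      return(list(statistic = 0, p = 1))   # degenerate: no spread anywhere
    df <- data.frame(v = c(x, y),
                     g = factor(rep(c("a", "b"), c(length(x), length(y)))))
    lt <- car::leveneTest(v ~ g, data = df, center = median)
    stat <- lt[1L, "F value"]
    p <- lt[1L, "Pr(>F)"]
    if (!is.finite(stat) || !is.finite(p)) return(list(statistic = 0, p = 1))
    list(statistic = stat, p = p)
  }, alpha = alpha)
}

#' Pairwise Kolmogorov-Smirnov tests on bout-duration distributions
#'
#' For every action and every pair of groups, compares the pooled bout
#' duration samples with a two-sample KS test; Holm over the full family
#' (7 actions x all pairs). Actions absent in either group yield untestable
#' rows (`NA` p-values).
#'
#' @param groups Named list: group name -> bout data.frame (or list of
#'   per-fly bout data.frames, pooled within group).
#' @param alpha Family-wise significance level.
#' @return A `comparison_table` data.frame.
#' @export
duration_ks_tests <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  vals <- lapply(groups, function(g) {
    b <- if (is.data.frame(g)) g else do.call(rbind, g)
    setNames(lapply(.ACTIONS, function(a) b$duration_s[b$action == a]),
             .ACTIONS)
  })
  .pairwise_table(vals, "ks_two_sample", function(x, y) {
    ht <- suppressWarnings(ks.test(x, y))
    list(statistic = unname(ht$statistic), p = ht$p.value)
  }, alpha = alpha)
}
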