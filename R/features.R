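# Behavioral feature families extracted from ethograms: action proportions,
# temporal progression vectors, first-order transition-probability syntax,
# and bout-duration histograms.

#' Action proportions
#'
#' Fraction of frames spent in each of the seven actions, plus the
#' grooming/walking/standing triplet used for ternary plots.
#'
#' @param e An [ethogram()].
#' @return A list of class `"proportion_vector"` with `p` (named length-7
#'   vector summing to 1) and `triplet` (`grooming`, `walking`, `standing`).
#' @export
#' @examples
#' action_proportions(ethogram(c("F", "F", "H", "H", "F")))$p
action_proportions <- function(e) {
  stopifnot(inherits(e, "ethogram"))
  p <- as.vector(table(factor(e$labels, levels = .ACTIONS))) / length(e$labels)
  names(p) <- .ACTIONS
  structure(
    list(p = p,
         triplet = c(grooming = sum(p[.GROOMING]), walking = p[["Wk"]],
                     standing = p[["S"]])),
    class = "proportion_vector"
  )
}

#' Temporal progression vector
#'
#' Splits the recording into `n_windows` equal, contiguous, non-overlapping
#' windows (remainder frames go to the last window) and computes the
#' seven-action proportion vector inside each: with the default 10 windows
#' this is the 70-dimensional progression representation (a 50,000-frame
#' recording at 30 Hz gives 2.78-min windows).
#'
#' @param e An [ethogram()].
#' @param n_windows Number of windows (default 10).
#' @return A list of class `"progression_vector"` with `w` (`n_windows` x 7
#'   matrix, each row summing to 1) and `window_s` (window length, seconds).
#' @export
progression_vector <- function(e, n_windows = 10L) {
  stopifnot(inherits(e, "ethogram"))
  n <- length(e$labels)
  if (n < n_windows)
    stop("ethogram has fewer frames (", n, ") than windows (", n_windows, ")")
  base <- n %/% n_windows
  sizes <- rep(base, n_windows)
  sizes[n_windows] <- sizes[n_windows] + n %% n_windows
  idx <- rep(seq_len(n_windows), sizes)
  w <- t(vapply(seq_len(n_windows), function(k) {
    lab <- e$labels[idx == k]
    as.vector(table(factor(lab, levels = .ACTIONS))) / length(lab)
  }, numeric(7)))
  dimnames(w) <- list(paste0("w", seq_len(n_windows)), .ACTIONS)
  structure(list(w = w, window_s = base / e$frame_rate_hz),
            class = "progression_vector")
}

#' Grooming syntax: first-order bout transition probabilities
#'
#' Syntax is the set of first-order transition probabilities between actions
#' at the bout level. Run-length encoding makes self-transitions impossible,
#' so with seven states there are exactly 42 possible transitions; each
#' observed source's outgoing probabilities sum to 1, and sources never
#' observed as transition origins are flagged missing (all-zero rows).
#'
#' @param bouts A bout data.frame from [to_bouts()] (apply [denoise()]
#'   first for the standard analysis).
#' @return A list of class `"syntax_vector"` with `prob` and `counts`
#'   (7x7 matrices, `NA`/0 diagonal), `source_totals` (outgoing transition
#'   counts per action) and `missing` (logical per action).
#' @export
#' @examples
#' b <- to_bouts(ethogram(c("F", "H", "F", "A", "B")))
#' syntax_vector(b)$prob["F", ]
syntax_vector <- function(bouts) {
  counts <- matrix(0L, 7, 7, dimnames = list(.ACTIONS, .ACTIONS))
  n <- nrow(bouts)
  if (n < 2L) {
    warning("fewer than 2 bouts: syntax is all-missing")
  } else {
    src <- factor(bouts$action[-n], levels = .ACTIONS)
    tgt <- factor(bouts$action[-1L], levels = .ACTIONS)
    counts <- unclass(table(src, tgt))
    dimnames(counts) <- list(.ACTIONS, .ACTIONS)
  }
  source_totals <- rowSums(counts)
  prob <- counts / ifelse(source_totals > 0, source_totals, 1)
  diag(prob) <- NA_real_
  structure(
    list(prob = prob, counts = counts, source_totals = source_totals,
         missing = source_totals == 0),
    class = "syntax_vector"
  )
}

#' Flatten a syntax vector to its 42 off-diagonal transition probabilities
#'
#' @param syn A [syntax_vector()].
#' @param impute How to fill transitions from never-observed sources:
#'   `"zero"` (default; documented choice for classification) or
#'   `"uniform"` (1/6 each), or `"na"` to keep them missing.
#' @return Named numeric vector of length 42 (`<src>_to_<tgt>`).
#' @export
syntax_to_vector <- function(syn, impute = c("zero", "uniform", "na")) {
  impute <- match.arg(impute)
  tp <- .transition_pairs()
  v <- syn$prob[cbind(tp$source, tp$target)]
  miss <- syn$missing[tp$source]
  v[miss] <- switch(impute, zero = 0, uniform = 1 / 6, na = NA_real_)
  names(v) <- .transition_names()
  v
}

#' Bout-duration histograms
#'
#' Per-action normalized histograms of bout durations with `n_bins` bins of
#' equal width. Bin width is determined independently for grooming and
#' non-grooming actions (walking and standing are longer tailed): grooming
#' bins span the denoising cutoff up to the grooming-category maximum,
#' non-grooming bins span 0 up to the non-grooming maximum. With 7 actions
#' and 20 bins the flattened vector is 140-dimensional. Category maxima
#' default to this fly's bouts; pass `grooming_max`/`non_grooming_max`
#' (e.g. cohort-pooled maxima) for comparable bins across flies.
#'
#' @param bouts A denoised bout data.frame.
#' @param n_bins Number of bins per action (default 20).
#' @param cutoff_s Lower edge of the grooming bins (default 0.150).
#' @param grooming_max,non_grooming_max Upper edges (seconds); default: the
#'   maximum observed in the corresponding category.
#' @return A list of class `"duration_histogram"`: `h` (7 x `n_bins` matrix,
#'   each occurring action's row summing to 1), `bin_edges` (per category),
#'   `missing` (actions with no bouts).
#' @export
duration_histograms <- function(bouts, n_bins = 20L, cutoff_s = 0.150,
                                grooming_max = NULL, non_grooming_max = NULL) {
  is_groom <- bouts$action %in% .GROOMING
  gmax <- grooming_max %||% if (any(is_groom)) max(bouts$duration_s[is_groom]) else cutoff_s + 1
  ngmax <- non_grooming_max %||% if (any(!is_groom)) max(bouts$duration_s[!is_groom]) else 1
  gmax <- max(gmax, cutoff_s + 1e-6)
  ngmax <- max(ngmax, 1e-6)
  edges <- list(
    grooming = seq(cutoff_s, gmax, length.out = n_bins + 1L),
    non_grooming = seq(0, ngmax, length.out = n_bins + 1L)
  )
  h <- matrix(0, 7, n_bins, dimnames = list(.ACTIONS, paste0("bin", seq_len(n_bins))))
  missing <- setNames(rep(TRUE, 7), .ACTIONS)
  for (a in .ACTIONS) {
    d <- bouts$duration_s[bouts$action == a]
    if (length(d) == 0L) next
    missing[a] <- FALSE
    br <- if (a %in% .GROOMING) edges$grooming else edges$non_grooming
    d <- pmin(pmax(d, br[1L]), br[length(br)])   # clamp into range
    cnt <- tabulate(findInterval(d, br, all.inside = TRUE), nbins = n_bins)
    h[a, ] <- cnt / sum(cnt)
  }
  structure(list(h = h, bin_edges = edges, missing = missing, n_bins = n_bins),
            class = "duration_histogram")
}

#' Time to completion of half of a fly's total grooming
#'
#' The time of the first frame at which cumulative grooming frames reach 50%
#' of the fly's total grooming frames; a longitudinal summary of how
#' front-loaded grooming is within the session.
#'
#' @param e An [ethogram()].
#' @return Time in seconds, or `NA` (with a warning) if the fly never grooms.
#' @export
grooming_half_time <- function(e) {
  stopifnot(inherits(e, "ethogram"))
  g <- e$labels %in% .GROOMING
  tot <- sum(g)
  if (tot == 0L) {
    warning("no grooming frames; half-time undefined")
    return(NA_real_)
  }
  k <- which(cumsum(g) >= tot / 2)[1L]
  k / e$frame_rate_hz
}

#' Per-fly feature matrix for a cohort
#'
#' Assembles one row per ethogram for a named feature family, with pooled
#' duration-bin ranges computed across the cohort so histograms are
#' comparable between flies.
#'
#' @param ethograms List of [ethogram()] objects (denoise first for the
#'   standard analysis).
#' @param family One of `"syntax"`, `"proportions"`, `"progression"`,
#'   `"durations"`, `"non_grooming_only"` (walking/standing proportions and
#'   progressions only) or `"full"` (all of the above concatenated).
#' @param n_windows,n_bins Passed to the per-family extractors.
#' @return A numeric matrix with rownames = fly_ids and a
#'   `"labels"` attribute of group_ids.
#' @export
cohort_features <- function(ethograms,
                            family = c("syntax", "proportions", "progression",
                                       "durations", "non_grooming_only", "full"),
                            n_windows = 10L, n_bins = 20L) {
  family <- match.arg(family)
  stopifnot(length(ethograms) > 0L)
  all_bouts <- lapply(ethograms, to_bouts)
  pooled <- do.call(rbind, all_bouts)
  gmax <- max(c(pooled$duration_s[pooled$action %in% .GROOMING], 0.151))
  ngmax <- max(c(pooled$duration_s[!(pooled$action %in% .GROOMING)], 0.001))
  one <- function(e, b, family) {
    switch(family,
      proportions = action_proportions(e)$p,
      progression = {
        w <- progression_vector(e, n_windows)$w
        setNames(as.vector(t(w)),
                 as.vector(t(outer(rownames(w), colnames(w), paste, sep = "_"))))
      },
      syntax = syntax_to_vector(syntax_vector(b)),
      durations = {
        dh <- duration_histograms(b, n_bins, grooming_max = gmax,
                                  non_grooming_max = ngmax)
        setNames(as.vector(t(dh$h)),
                 as.vector(t(outer(rownames(dh$h), colnames(dh$h), paste, sep = "_"))))
      },
      non_grooming_only = {
        p <- action_proportions(e)$p[.NON_GROOMING]
        w <- progression_vector(e, n_windows)$w[, .NON_GROOMING, drop = FALSE]
        c(setNames(p, paste0("p_", .NON_GROOMING)),
          setNames(as.vector(t(w)),
                   as.vector(t(outer(rownames(w), colnames(w), paste, sep = "_")))))
      },
      full = {
        c(one(e, b, "proportions"), one(e, b, "progression"),
          one(e, b, "syntax"), one(e, b, "durations"))
      }
    )
  }
  rows <- mapply(one, ethograms, all_bouts,
                 MoreArgs = list(family = family), SIMPLIFY = FALSE)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(ethograms, function(e) e$fly_id, character(1))
  attr(m, "labels") <- vapply(ethograms, function(e) e$group_id, character(1))
  m
}
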