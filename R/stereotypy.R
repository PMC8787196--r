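# Stereotypy metrics: Markov entropy rate of the grooming syntax (rule-level
# stereotypy) and Levenshtein edit distance between anterior motif sequences
# (sequence-level stereotypy, a much stricter criterion).

#' Entropy rate of the grooming syntax
#'
#' `H = -sum_i w_i sum_{j != i} p_ij * log(p_ij)` in nats, with
#' `0 * log(0) == 0`. Zero indicates complete stereotypy (perfectly
#' predictable, repeated action sequences); with seven states and no
#' self-transitions the maximum is `log(6) ~= 1.79` (uniform rows). The
#' natural logarithm calibrates predictability as `exp(-H)`: an entropy rate
#' of one corresponds to a ~37% probability of correctly predicting the next
#' action.
#'
#' @param syn A [syntax_vector()].
#' @param weighting Source weights `w_i`: `"source_frequency"` (default;
#'   observed outgoing-transition frequency of each source) or
#'   `"stationary"` (stationary distribution of the transition matrix;
#'   requires all sources observed).
#' @return List of class `"entropy_result"`: `H` (nats), `predictability`
#'   (`exp(-H)`), `weights`.
#' @export
#' @examples
#' syn <- syntax_vector(to_bouts(ethogram(rep(c("F", "H"), 50))))
#' entropy_rate(syn)$H   # deterministic alternation: 0
entropy_rate <- function(syn, weighting = c("source_frequency", "stationary")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(syn, "syntax_vector"))
  if (all(syn$missing)) stop("all sources missing: entropy rate undefined")
  P <- syn$prob
  diag(P) <- 0
  if (weighting == "source_frequency") {
    w <- syn$source_totals / sum(syn$source_totals)
  } else {
    if (any(syn$missing))
      stop("stationary weighting requires every source to be observed")
    ev <- eigen(t(P))
    i <- which.min(abs(ev$values - 1))
    w <- Re(ev$vectors[, i])
    w <- w / sum(w)
    w <- setNames(pmax(w, 0) / sum(pmax(w, 0)), .ACTIONS)
  }
  row_h <- apply(P, 1L, function(p) {
    p <- p[p > 0]
    if (length(p) == 0L) 0 else -sum(p * log(p))
  })
  H <- sum(w * row_h)
  structure(list(H = H, predictability = exp(-H), weights = w,
                 weighting = weighting),
            class = "entropy_result")
}

#' Extract the first long continuous anterior motif run
#'
#' Finds the earliest maximal run of consecutive frames all labeled with
#' anterior motif actions (F or H) whose duration is at least
#' `min_duration_s` (default 30 s, long enough to exhibit stereotypy if
#' present). Symbols are returned at frame resolution.
#'
#' @param e A denoised [ethogram()].
#' @param min_duration_s Minimum run duration, seconds.
#' @return A list of class `"motif_run"` (`symbols`, `start_s`,
#'   `duration_s`, `fly_id`, `session_id`), or `NULL` if no run qualifies
#'   (callers should skip the fly and log the count).
#' @export
extract_anterior_run <- function(e, min_duration_s = 30) {
  stopifnot(inherits(e, "ethogram"))
  ant <- e$labels %in% .ANTERIOR
  r <- rle(ant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths        # 0-based start frames
  ok <- which(r$values & r$lengths / e$frame_rate_hz >= min_duration_s)
  if (length(ok) == 0L) return(NULL)
  i <- ok[1L]
  idx <- (starts[i] + 1L):ends[i]
  structure(
    list(symbols = e$labels[idx],
         start_s = starts[i] / e$frame_rate_hz,
         duration_s = r$lengths[i] / e$frame_rate_hz,
         fly_id = e$fly_id, session_id = e$session_id),
    class = "motif_run"
  )
}

.as_symbols <- function(x) {
  if (inherits(x, "motif_run")) return(x$symbols)
  x <- as.character(x)
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1L]]
  x
}

#' Levenshtein edit distance
#'
#' Minimum number of single-symbol substitutions, insertions, or deletions
#' needed to make two sequences identical (unit costs, dynamic programming).
#' Identical sequences have distance 0; maximally different sequences have a
#' distance equal to the longer sequence's length.
#'
#' @param a,b Character vectors of symbols (a single multi-character string
#'   is split into characters; [extract_anterior_run()] results are accepted
#'   directly).
#' @return Non-negative integer.
#' @export
#' @examples
#' edit_distance(c("F", "H", "F", "H"), c("F", "F", "H"))   # 1
edit_distance <- function(a, b) {
  levenshtein_cpp(.as_symbols(a), .as_symbols(b))
}

#' Normalized edit distance
#'
#' [edit_distance()] divided by the longer sequence's length: 0 for
#' identical sequences, 1 for maximally different ones.
#'
#' @inheritParams edit_distance
#' @return Fraction in `[0, 1]`.
#' @export
normalized_edit_distance <- function(a, b) {
  a <- .as_symbols(a); b <- .as_symbols(b)
  M <- max(length(a), length(b))
  if (M == 0L) stop("both sequences are empty")
  edit_distance(a, b) / M
}

#' Pairwise edit-distance stereotypy comparison across a cohort
#'
#' Extracts each session's first continuous anterior motif run of at least
#' `min_duration_s` and computes normalized edit distances between runs
#' paired per the design: `"within_fly_across_sessions"` compares each fly's
#' runs on consecutive sessions (sessions ordered by `session_id`);
#' `"between_fly_same_session"` compares the first session's runs across all
#' fly pairs. Distances are reported as percent differences; the summary
#' gives the minimum and median.
#'
#' @param ethograms List of denoised [ethogram()] objects carrying `fly_id`
#'   and `session_id` metadata.
#' @param design Pairing design (see above).
#' @param min_duration_s Minimum qualifying run duration (default 30 s).
#' @return List of class `"stereotypy_comparison"`: `distances` (data.frame
#'   with one row per eligible pair), `summary` (`min_percent`,
#'   `median_percent`), `n_runs`, `n_skipped` (sessions without a qualifying
#'   run).
#' @export
stereotypy_comparison <- function(ethograms,
                                  design = c("within_fly_across_sessions",
                                             "between_fly_same_session"),
                                  min_duration_s = 30) {
  design <- match.arg(design)
  runs <- lapply(ethograms, extract_anterior_run, min_duration_s = min_duration_s)
  found <- !vapply(runs, is.null, logical(1))
  n_skipped <- sum(!found)
  runs <- runs[found]
  if (length(runs) == 0L) stop("no session contains a qualifying anterior run")
  fly <- vapply(runs, `[[`, character(1), "fly_id")
  ses <- vapply(runs, `[[`, character(1), "session_id")
  pairs <- list()
  if (design == "within_fly_across_sessions") {
    for (f in unique(fly)) {
      i <- which(fly == f)[order(ses[fly == f])]
      if (length(i) >= 2L)
        for (k in seq_len(length(i) - 1L))
          pairs[[length(pairs) + 1L]] <- c(i[k], i[k + 1L])
    }
  } else {
    first <- min(ses)
    i <- which(ses == first)
    i <- i[!duplicated(fly[i])]
    if (length(i) >= 2L) {
      cmb <- utils::combn(i, 2L)
      pairs <- lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
    }
  }
  if (length(pairs) == 0L)
    stop("no eligible pairs under design '", design,
         "' (need >= 2 qualifying runs per comparison)")
  rows <- lapply(pairs, function(pr) {
    a <- runs[[pr[1L]]]; b <- runs[[pr[2L]]]
    nd <- normalized_edit_distance(a, b)
    data.frame(fly_a = a$fly_id, session_a = a$session_id,
               fly_b = b$fly_id, session_b = b$session_id,
               len_a = length(a$symbols), len_b = length(b$symbols),
               edit_distance = edit_distance(a, b),
               norm_distance = nd, percent_diff = 100 * nd,
               stringsAsFactors = FALSE)
  })
  distances <- do.call(rbind, rows)
  structure(
    list(distances = distances,
         summary = c(min_percent = min(distances$percent_diff),
                     median_percent = median(distances$percent_diff)),
         n_runs = length(runs), n_skipped = n_skipped, design = design),
    class = "stereotypy_comparison"
  )
}
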