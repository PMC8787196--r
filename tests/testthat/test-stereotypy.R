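test_that("entropy rate is zero for deterministic chains and ln 6 for uniform rows", {
  det <- syntax_vector(to_bouts(ethogram(rep(c("F", "H"), 40))))
  res <- entropy_rate(det)
  expect_equal(res$H, 0)
  expect_equal(res$predictability, 1)

  # uniform 1/6 over allowed targets from every source
  unif <- matrix(1, 7, 7, dimnames = list(ACTS, ACTS))
  diag(unif) <- 0
  set.seed(1)
  syn <- syntax_vector(markov_bouts(unif / 6, 4000))
  syn$prob[] <- unif / 6
  diag(syn$prob) <- NA
  expect_equal(entropy_rate(syn)$H, log(6))
  expect_equal(entropy_rate(syn, weighting = "stationary")$H, log(6))

  # calibration: one nat of entropy means ~37% predictability
  expect_equal(round(100 * exp(-1)), 37)
})

test_that("entropy rate respects bounds and weighting definitions", {
  set.seed(7)
  for (i in 1:10) {
    M <- matrix(rgamma(49, 1), 7, 7, dimnames = list(ACTS, ACTS))
    diag(M) <- 0
    M <- M / rowSums(M)
    syn <- syntax_vector(markov_bouts(M, 600))
    res <- entropy_rate(syn)
    expect_gte(res$H, 0)
    expect_lte(res$H, log(6) + 1e-12)
    expect_equal(res$predictability, exp(-res$H))
    expect_equal(sum(res$weights), 1)
    # hand recomputation with source-frequency weights
    w <- syn$source_totals / sum(syn$source_totals)
    P <- syn$prob; diag(P) <- 0
    hh <- sum(w * apply(P, 1, function(p) { p <- p[p > 0]; -sum(p * log(p)) }))
    expect_equal(res$H, hh)
  }
  expect_warning(empty <- syntax_vector(to_bouts(ethogram(rep("F", 9)))))
  expect_error(entropy_rate(empty), "all sources missing")
})

test_that("anterior run extraction applies the first-run-at-least-30s rule", {
  fr <- 30
  labs <- c(rep("S", 300), rep(c("F", "H"), 40 * fr / 2),  # 40 s anterior block
            rep("Wk", 200), rep("F", 35 * fr))             # later 35 s block
  run <- extract_anterior_run(ethogram(labs))
  expect_s3_class(run, "motif_run")
  expect_equal(length(run$symbols), 40 * fr)
  expect_equal(run$start_s, 10)
  expect_equal(run$duration_s, 40)
  expect_true(all(run$symbols %in% anterior_actions()))

  short <- ethogram(c(rep("F", 20 * fr), rep("S", 100), rep("H", 20 * fr)))
  expect_null(extract_anterior_run(short))
  expect_equal(length(extract_anterior_run(short, min_duration_s = 15)$symbols),
               20 * fr)
})

test_that("edit distance matches hand-derived values and handles empties", {
  expect_equal(edit_distance(c("F", "H", "F", "H"), c("F", "H", "F", "H")), 0)
  expect_equal(edit_distance(c("F", "H", "F", "H"), character(0)), 4)
  expect_equal(edit_distance(character(0), c("A", "B")), 2)
  expect_equal(edit_distance(c("F", "H", "F", "H"), c("F", "F", "H")), 1)
  expect_equal(edit_distance("FHFH", "FFH"), 1)   # string convenience form
  expect_equal(normalized_edit_distance(c("F", "H", "F", "H"), c("F", "F", "H")),
               0.25)
  expect_equal(normalized_edit_distance(c("A", "A"), c("B", "B")), 1)
  expect_equal(normalized_edit_distance(c("F"), c("F")), 0)
  expect_error(normalized_edit_distance(character(0), character(0)), "empty")
})

test_that("edit distance agrees with brute-force DP and satisfies metric axioms", {
  strs <- all_strings(c("a", "b", "c"), 3)
  n <- length(strs)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      dij <- edit_distance(strs[[i]], strs[[j]])
      expect_identical(dij, lev_oracle(strs[[i]], strs[[j]]))
      d[i, j] <- d[j, i] <- dij
      # length bounds
      li <- length(strs[[i]]); lj <- length(strs[[j]])
      expect_gte(dij, abs(li - lj))
      expect_lte(dij, max(li, lj))
      if (dij == 0) expect_identical(strs[[i]], strs[[j]])
    }
  }
  # triangle inequality, exhaustive over all ordered triples
  tri_ok <- TRUE
  for (k in seq_len(n)) {
    tri_ok <- tri_ok && all(d <= outer(d[, k], d[k, ], `+`))
  }
  expect_true(tri_ok)

  # longer random sequences against base R's generalized distance
  set.seed(12)
  as_str <- function(x) paste(letters[match(x, ACTS)], collapse = "")
  for (i in 1:10) {
    a <- sample(ACTS, sample(5:60, 1), replace = TRUE)
    b <- sample(ACTS, sample(5:60, 1), replace = TRUE)
    expect_equal(edit_distance(a, b),
                 drop(utils::adist(as_str(a), as_str(b))))
  }
})

test_that("stereotypy comparison pairs runs per design and summarizes distances", {
  fr <- 30
  mk <- function(fly, ses, labs) ethogram(labs, fly_id = fly, session_id = ses)
  block <- rep(c("F", "H"), 35 * fr / 2)
  filler <- rep("S", 120)
  # identical sequences within fly across sessions -> distance 0
  e1 <- mk("fly1", "day1", c(filler, block))
  e2 <- mk("fly1", "day2", c(filler, block))
  res <- stereotypy_comparison(list(e1, e2), "within_fly_across_sessions")
  expect_equal(nrow(res$distances), 1L)
  expect_equal(res$distances$norm_distance, 0)
  expect_equal(unname(res$summary["min_percent"]), 0)

  # independent draws from a high-entropy anterior chain: median well above 0
  set.seed(21)
  rand_block <- function() {
    b <- sample(c("F", "H"), 220, replace = TRUE)
    rep(b, rep_len(4:6, 220))[1:(35 * fr)]
  }
  ethos <- lapply(1:6, function(i) mk(paste0("fly", i), "day1",
                                      c(filler, rand_block())))
  res2 <- stereotypy_comparison(ethos, "between_fly_same_session")
  expect_equal(nrow(res2$distances), choose(6, 2))
  expect_gt(unname(res2$summary["median_percent"]), 10)

  # degenerate design: one fly, one session
  expect_error(stereotypy_comparison(list(e1), "within_fly_across_sessions"),
               "no eligible pairs")
  # sessions without qualifying runs are skipped and counted
  e3 <- mk("fly9", "day1", rep("S", 3000))
  res3 <- stereotypy_comparison(list(e1, e2, e3), "within_fly_across_sessions")
  expect_equal(res3$n_skipped, 1L)
})
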