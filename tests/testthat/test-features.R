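test_that("action proportions count frames and partition into the ternary triplet", {
  p <- action_proportions(ethogram(rep("Wk", 20)))$p
  expect_equal(unname(p["Wk"]), 1)
  expect_equal(sum(p), 1)

  p2 <- action_proportions(ethogram(c("F", "F", "H", "H", "F")))$p
  expect_equal(unname(p2["F"]), 0.6)
  expect_equal(unname(p2["H"]), 0.4)

  set.seed(3)
  for (i in 1:5) {
    ap <- action_proportions(ethogram(sample(ACTS, 200, replace = TRUE)))
    expect_equal(sum(ap$p), 1, tolerance = 1e-9)
    expect_equal(sum(ap$triplet), 1, tolerance = 1e-9)
    expect_equal(unname(ap$triplet["grooming"]),
                 sum(ap$p[grooming_actions()]))
  }
})

test_that("progression vectors partition the recording into 10 windows of 2.78 min", {
  e <- simulate_ethogram(generator_config(recording_frames = 50000), seed = 1)
  pv <- progression_vector(e)
  expect_equal(dim(pv$w), c(10L, 7L))
  expect_equal(pv$window_s / 60, 2.78, tolerance = 1e-3)
  expect_equal(unname(rowSums(pv$w)), rep(1, 10))

  hom <- progression_vector(ethogram(rep("S", 1000)))
  expect_true(all(apply(hom$w, 1, identical, hom$w[1, ])))

  half <- progression_vector(ethogram(c(rep("F", 500), rep("A", 500))))
  expect_equal(unname(half$w[1:5, "F"]), rep(1, 5))
  expect_equal(unname(half$w[6:10, "A"]), rep(1, 5))

  expect_error(progression_vector(ethogram(rep("F", 5)), n_windows = 10),
               "fewer frames")
})

test_that("progression rows equal the action proportions of the matching slice", {
  e <- simulate_ethogram(generator_config(recording_frames = 10007), seed = 2)
  pv <- progression_vector(e)
  n <- length(e$labels)
  base <- n %/% 10
  for (k in c(1, 4, 10)) {
    i0 <- (k - 1) * base + 1
    i1 <- if (k == 10) n else k * base
    expect_equal(unname(pv$w[k, ]),
                 unname(action_proportions(ethogram(e$labels[i0:i1]))$p))
  }
})

test_that("syntax vectors are 42-dimensional bout-transition probabilities", {
  b <- to_bouts(ethogram(rep(c("F", "H", "F", "A", "B"),
                             times = c(5, 5, 5, 5, 5))))
  syn <- syntax_vector(b)
  expect_equal(syn$prob["F", "H"], 0.5)
  expect_equal(syn$prob["F", "A"], 0.5)
  expect_equal(syn$prob["H", "F"], 1)
  expect_equal(syn$prob["A", "B"], 1)
  expect_equal(unname(syn$source_totals["F"]), 2)
  expect_true(syn$missing["W"])

  v <- syntax_to_vector(syn)
  expect_length(v, 42L)
  expect_equal(unname(v["F_to_H"]), 0.5)
  expect_true(all(v[grepl("^W_to_", names(v))] == 0))
  expect_true(all(is.na(syntax_to_vector(syn, impute = "na")[
    grepl("^W_to_", names(v))])))
  expect_equal(unname(syntax_to_vector(syn, impute = "uniform")["W_to_F"]), 1 / 6)

  alt <- syntax_vector(to_bouts(ethogram(rep(c("F", "H"), 30))))
  expect_equal(alt$prob["F", "H"], 1)
  expect_equal(alt$prob["H", "F"], 1)
  expect_equal(sum(alt$missing), 5L)

  expect_warning(sv <- syntax_vector(to_bouts(ethogram(rep("F", 9)))),
                 "fewer than 2 bouts")
  expect_true(all(sv$missing))

  # observed rows sum to 1
  set.seed(9)
  syn2 <- syntax_vector(markov_bouts(balanced_matrix(), 300))
  rs <- rowSums(syn2$prob, na.rm = TRUE)
  expect_equal(unname(rs[!syn2$missing]), rep(1, sum(!syn2$missing)))
})

test_that("duration histograms are 140-dimensional with category-wise equal bins", {
  e <- simulate_ethogram(generator_config(recording_frames = 20000), seed = 4)
  dh <- duration_histograms(to_bouts(denoise(e)))
  expect_equal(dim(dh$h), c(7L, 20L))
  expect_length(as.vector(dh$h), 140L)
  occ <- !dh$missing
  expect_equal(unname(rowSums(dh$h)[occ]), rep(1, sum(occ)))

  # one action, identical durations: all mass in one bin
  b1 <- data.frame(action = "F", start_frame = 0L, n_frames = 9L,
                   duration_s = 0.3)
  b1 <- b1[rep(1, 5), ]
  dh1 <- duration_histograms(b1, grooming_max = 0.75)
  expect_equal(max(dh1$h["F", ]), 1)
  expect_equal(sum(dh1$h["F", ] > 0), 1L)

  # fixed-width binning oracle on durations {0.2, 0.4, 0.6} over [0.15, 0.75]
  b2 <- data.frame(action = "H", start_frame = 0L, n_frames = 1L,
                   duration_s = c(0.2, 0.4, 0.6))
  dh2 <- duration_histograms(b2, grooming_max = 0.75)
  edges <- 0.15 + 0:20 * ((0.75 - 0.15) / 20)
  expected_bins <- vapply(c(0.2, 0.4, 0.6), function(x)
    min(sum(x >= edges[1:20]), 20L), numeric(1))
  expect_equal(unname(which(dh2$h["H", ] > 0)), sort(unique(expected_bins)))
  expect_equal(sum(dh2$h["H", ]), 1)
})

test_that("grooming half-time finds the 50% completion point", {
  expect_equal(grooming_half_time(ethogram(rep("F", 600))), 300 / 30)
  # single grooming frame at t
  labs <- rep("S", 100); labs[40] <- "H"
  expect_equal(grooming_half_time(ethogram(labs)), 40 / 30)
  # all grooming in the first quarter -> half-time within the first eighth
  labs2 <- c(rep("A", 250), rep("S", 750))
  expect_lte(grooming_half_time(ethogram(labs2)), 1000 / 30 / 8)
  expect_warning(ht <- grooming_half_time(ethogram(rep("S", 50))), "no grooming")
  expect_true(is.na(ht))
})

test_that("cohort feature matrices are deterministic with the expected shapes", {
  tpl <- group_template("g", generator_config(recording_frames = 4000))
  pop <- lapply(simulate_population(tpl, 4, seed = 6), denoise)
  for (fam in c("syntax", "proportions", "progression", "durations",
                "non_grooming_only", "full")) {
    m <- cohort_features(pop, fam)
    expect_equal(nrow(m), 4L)
    expect_equal(attr(m, "labels"), rep("g", 4))
    m2 <- cohort_features(pop, fam)
    expect_identical(m, m2)
  }
  expect_equal(ncol(cohort_features(pop, "syntax")), 42L)
  expect_equal(ncol(cohort_features(pop, "proportions")), 7L)
  expect_equal(ncol(cohort_features(pop, "progression")), 70L)
  expect_equal(ncol(cohort_features(pop, "durations")), 140L)
  expect_equal(ncol(cohort_features(pop, "non_grooming_only")), 22L)
  expect_equal(ncol(cohort_features(pop, "full")), 42L + 7L + 70L + 140L)
})
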