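test_that("a two-state deterministic chain yields strict F/H alternation", {
  M <- matrix(0, 7, 7, dimnames = list(ACTS, ACTS))
  M["F", "H"] <- 1; M["H", "F"] <- 1
  # remaining rows need off-diagonal mass to be valid, but are never visited
  for (a in setdiff(ACTS, c("F", "H"))) M[a, "F"] <- 1
  cfg <- generator_config(phase_matrices = list(early = M, late = M),
                          recording_frames = 3000)
  e <- simulate_ethogram(cfg, seed = 1)
  b <- to_bouts(e)
  expect_true(all(b$action %in% c("F", "H")))
  expect_true(all(b$action[-1] != b$action[-nrow(b)]))
  expect_equal(length(e$labels), 3000L)
})

test_that("simulation is deterministic under seed and leaves the RNG untouched", {
  cfg <- generator_config(recording_frames = 3000)
  set.seed(999)
  before <- .Random.seed
  e1 <- simulate_ethogram(cfg, seed = 7)
  expect_identical(.Random.seed, before)
  e2 <- simulate_ethogram(cfg, seed = 7)
  expect_identical(e1$labels, e2$labels)
  e3 <- simulate_ethogram(cfg, seed = 8)
  expect_false(identical(e1$labels, e3$labels))

  tpl <- group_template("g", cfg)
  p1 <- simulate_population(tpl, 3, seed = 11)
  p2 <- simulate_population(tpl, 3, seed = 11)
  expect_identical(lapply(p1, `[[`, "labels"), lapply(p2, `[[`, "labels"))
  expect_error(simulate_population(tpl, 0, seed = 1), ">= 1")
})

test_that("empirical bout-transition matrix converges to the generator matrix", {
  M <- balanced_matrix()
  errs <- vapply(c(30000, 120000, 480000), function(frames) {
    e <- simulate_ethogram(fast_config(M, frames), seed = 42)
    emp <- syntax_vector(to_bouts(e))$prob
    emp[is.na(emp)] <- 0
    max(abs(emp - M))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))          # shrinks with sequence length
  expect_lt(errs[3], 0.02)
})

test_that("pooled population syntax converges to the template matrix without jitter", {
  M <- balanced_matrix()
  tpl <- group_template("g", fast_config(M, 30000), jitter_kappa = Inf)
  pop <- simulate_population(tpl, 10, seed = 3)
  counts <- Reduce(`+`, lapply(pop, function(e) syntax_vector(to_bouts(e))$counts))
  pooled <- counts / rowSums(counts)
  expect_lt(max(abs(pooled - M)), 0.02)
  expect_equal(vapply(pop, `[[`, character(1), "fly_id"),
               paste0("g_fly", 1:10))
})

test_that("grooming bout durations peak between 500 and 750 ms", {
  e <- simulate_ethogram(generator_config(recording_frames = 200000), seed = 2)
  b <- to_bouts(e)
  d <- b$duration_s[b$action %in% grooming_actions()]
  expect_gt(length(d), 2000)
  h <- hist(d, breaks = seq(0, ceiling(max(d) * 10) / 10, by = 0.1),
            plot = FALSE)
  mode_s <- h$mids[which.max(h$counts)]
  expect_gte(mode_s, 0.5)
  expect_lte(mode_s, 0.75)
  expect_true(all(d >= 0.150))
})

test_that("the default two-phase config produces anterior-to-posterior progression", {
  for (seed in 1:3) {
    e <- simulate_ethogram(generator_config(recording_frames = 50000), seed = seed)
    w <- progression_vector(e)$w
    ant <- rowSums(w[, anterior_actions()])
    expect_gt(ant[1], ant[10])
  }
})

test_that("template divergence and jitter preserve row-stochasticity", {
  dv <- data.frame(source = c("F", "Wk"), target = c("H", "S"),
                   delta = c(-0.3, 0.25))
  tpl <- group_template("g", generator_config(), divergence = dv,
                        jitter_kappa = 30)
  for (m in tpl$config$phase_matrices) {
    expect_equal(unname(rowSums(m)), rep(1, 7))
    expect_equal(unname(diag(m)), rep(0, 7))
  }
  jc <- groomsyntax:::with_seed(5, groomsyntax:::.jitter_config(tpl$config, 30))
  for (m in jc$phase_matrices) {
    expect_equal(unname(rowSums(m)), rep(1, 7))
    expect_equal(unname(diag(m)), rep(0, 7))
    expect_false(identical(m, tpl$config$phase_matrices$early) &&
                   identical(m, tpl$config$phase_matrices$late))
  }
  expect_error(group_template("g", generator_config(),
                              divergence = data.frame(source = "F",
                                                      target = "F", delta = 1)),
               "diagonal")
})

test_that("degenerate transition matrices are rejected", {
  M <- balanced_matrix()
  M["A", ] <- 0
  expect_error(generator_config(phase_matrices = list(early = M, late = M)),
               "sum to 1")
})

test_that("optogenetic windows drive anterior grooming and validate geometry", {
  cfg <- generator_config(recording_frames = 30000)  # 1000 s
  win <- rbind(c(100, 280), c(400, 580), c(700, 880))
  e <- simulate_opto_session(cfg, windows = win, seed = 9)
  fr <- e$frame_rate_hz
  idx <- unlist(lapply(seq_len(nrow(win)), function(i)
    (floor(win[i, 1] * fr) + 1L):(win[i, 2] * fr)))
  expect_gte(mean(e$labels[idx] %in% anterior_actions()), 0.90)
  expect_equal(nrow(e$opto_windows), 3L)

  expect_error(simulate_opto_session(cfg, windows = rbind(c(0, 200), c(100, 300))),
               "overlap")
  expect_error(simulate_opto_session(cfg, windows = rbind(c(900, 1100))),
               "within the recording")

  # no windows: plain semi-Markov draw under the same seed
  e0 <- simulate_opto_session(cfg, windows = NULL, seed = 10)
  e1 <- simulate_ethogram(cfg, seed = 10)
  expect_identical(e0$labels, e1$labels)
})

test_that("full-recording stimulation matches the dwell-weighted stationary oracle", {
  cfg <- generator_config(recording_frames = 120000)  # 4000 s
  total_s <- cfg$recording_frames / cfg$frame_rate_hz
  e <- simulate_opto_session(cfg, windows = rbind(c(0, total_s)), seed = 4)
  A <- anterior_dominant_matrix()
  pi_b <- stationary_dist(A)
  dp <- cfg$duration_params
  mean_d <- vapply(seq_len(7), function(i)
    trunc_lnorm_mean(dp$meanlog[i], dp$sdlog[i], cfg$min_bout_s), numeric(1))
  frame_prop <- pi_b * mean_d / sum(pi_b * mean_d)
  expected_ant <- sum(frame_prop[match(anterior_actions(), ACTS)])
  observed_ant <- mean(e$labels %in% anterior_actions())
  expect_equal(observed_ant, expected_ant, tolerance = 0.05)
})
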