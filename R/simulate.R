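# Semi-Markov ethogram simulator.
#
# Bout actions follow a first-order transition matrix (zero diagonal, so
# consecutive bouts always differ) interpolated in bout-onset time between an
# early, anterior-biased phase and a late, posterior/activity-biased phase;
# bout dwell times are drawn per action from log-normal distributions
# truncated below at the denoising cutoff. This reproduces the statistical
# structure the downstream analysis assumes: motif-structured syntax,
# anterior-then-posterior progression, grooming bout durations with modal
# values in the 500-750 ms range, and heavier-tailed walking/standing bouts.

#' Default phase transition matrices
#'
#' Two 7x7 row-stochastic matrices with zero diagonal: an early phase with
#' strong anterior motif coupling (F<->H) and a late phase with increased
#' posterior grooming, walking and standing. Within-motif transition
#' probabilities are high in both phases, mirroring the anterior \{F,H\} and
#' posterior \{A,B,W\} grooming motifs.
#'
#' @return A list with elements `early` and `late`.
#' @export
default_phase_matrices <- function() {
  a <- .ACTIONS
  early <- matrix(0, 7, 7, dimnames = list(a, a))
  early["F", ] <- c(0,    0.70, 0.05, 0.02, 0.03, 0.12, 0.08)
  early["H", ] <- c(0.72, 0,    0.04, 0.02, 0.02, 0.12, 0.08)
  early["A", ] <- c(0.08, 0.04, 0,    0.55, 0.15, 0.10, 0.08)
  early["B", ] <- c(0.06, 0.04, 0.45, 0,    0.25, 0.12, 0.08)
  early["W", ] <- c(0.05, 0.03, 0.25, 0.40, 0,    0.17, 0.10)
  early["Wk", ] <- c(0.30, 0.15, 0.10, 0.05, 0.05, 0,   0.35)
  early["S", ] <- c(0.28, 0.14, 0.08, 0.06, 0.04, 0.40, 0)
  late <- matrix(0, 7, 7, dimnames = list(a, a))
  late["F", ] <- c(0,    0.45, 0.15, 0.08, 0.07, 0.15, 0.10)
  late["H", ] <- c(0.48, 0,    0.12, 0.08, 0.07, 0.15, 0.10)
  late["A", ] <- c(0.03, 0.02, 0,    0.55, 0.18, 0.12, 0.10)
  late["B", ] <- c(0.03, 0.02, 0.45, 0,    0.26, 0.14, 0.10)
  late["W", ] <- c(0.03, 0.02, 0.27, 0.38, 0,    0.18, 0.12)
  late["Wk", ] <- c(0.08, 0.04, 0.15, 0.10, 0.08, 0,   0.55)
  late["S", ] <- c(0.07, 0.04, 0.13, 0.10, 0.06, 0.60, 0)
  list(early = early, late = late)
}

#' Anterior-dominant transition matrix for optogenetic stimulation windows
#'
#' Near-deterministic matrix concentrating transition mass on the anterior
#' motif (F<->H), emulating optogenetic induction of anterior grooming.
#'
#' @return A 7x7 row-stochastic matrix with zero diagonal.
#' @export
anterior_dominant_matrix <- function() {
  a <- .ACTIONS
  m <- matrix(0, 7, 7, dimnames = list(a, a))
  for (src in a) {
    ant <- setdiff(.ANTERIOR, src)
    m[src, ant] <- 0.98 / length(ant)
    pos <- setdiff(.POSTERIOR, src)
    m[src, pos] <- 0.008 / length(pos)
    ng <- setdiff(.NON_GROOMING, src)
    m[src, ng] <- 0.012 / length(ng)
  }
  zero_diag_renorm(m)
}

#' Default per-action dwell-time parameters
#'
#' Log-normal location/scale per action, truncated below at 150 ms when
#' sampling. Grooming actions have modal durations of ~620 ms (within the
#' 500-750 ms band characteristic of grooming bouts); walking and standing
#' are heavier tailed.
#'
#' @return data.frame with rownames = action codes, columns `meanlog`,
#'   `sdlog`.
#' @export
default_duration_params <- function() {
  groom_meanlog <- log(0.62) + 0.5^2           # mode exp(meanlog - sdlog^2) = 0.62 s
  d <- data.frame(
    meanlog = c(rep(groom_meanlog, 5), log(1.2) + 0.9^2, log(1.0) + 1.0^2),
    sdlog = c(rep(0.5, 5), 0.9, 1.0),
    row.names = .ACTIONS
  )
  d
}

#' Generator configuration for the semi-Markov ethogram simulator
#'
#' @param phase_matrices List with `early` and `late` 7x7 row-stochastic,
#'   zero-diagonal matrices (defaults: [default_phase_matrices()]).
#' @param phase_switch List with `midpoint_s` and `steepness_s` of the
#'   logistic interpolation in bout-onset time between the two phases.
#'   Default `NULL`: midpoint at 24% and steepness at 7.2% of the recording
#'   length (400 s and 120 s for the standard 50,000-frame recording), so
#'   scaled-down recordings express the same relative anterior-to-posterior
#'   progression.
#' @param duration_params data.frame of per-action log-normal `meanlog`,
#'   `sdlog` (defaults: [default_duration_params()]).
#' @param min_bout_s Lower truncation of dwell times, seconds (default 0.150,
#'   the denoising cutoff, so simulated bouts survive denoising).
#' @param recording_frames Number of frames to simulate (default 50000).
#' @param frame_rate_hz Frame rate (default 30).
#' @param init_probs Length-7 initial action distribution (default: all mass
#'   on the anterior motif, as for freshly dusted flies).
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(phase_matrices = default_phase_matrices(),
                             phase_switch = NULL,
                             duration_params = default_duration_params(),
                             min_bout_s = 0.150,
                             recording_frames = 50000L,
                             frame_rate_hz = 30,
                             init_probs = c(F = 0.5, H = 0.5, A = 0, B = 0,
                                            W = 0, Wk = 0, S = 0)) {
  stopifnot(recording_frames >= 1, frame_rate_hz > 0, min_bout_s >= 0)
  phase_switch_auto <- is.null(phase_switch)
  if (phase_switch_auto) {
    total_s <- recording_frames / frame_rate_hz
    phase_switch <- list(midpoint_s = 0.24 * total_s,
                         steepness_s = 0.072 * total_s)
  }
  for (nm in c("early", "late")) {
    m <- phase_matrices[[nm]]
    stopifnot(is.matrix(m), all(dim(m) == 7L))
    if (is.null(rownames(m))) dimnames(m) <- list(.ACTIONS, .ACTIONS)
    if (any(diag(m) != 0)) stop("phase matrix '", nm, "' must have zero diagonal")
    if (any(abs(rowSums(m) - 1) > 1e-8))
      stop("phase matrix '", nm, "' rows must sum to 1")
    phase_matrices[[nm]] <- m
  }
  stopifnot(all(duration_params$sdlog > 0))
  init_probs <- init_probs / sum(init_probs)
  structure(
    list(phase_matrices = phase_matrices, phase_switch = phase_switch,
         duration_params = duration_params, min_bout_s = min_bout_s,
         recording_frames = as.integer(recording_frames),
         frame_rate_hz = frame_rate_hz, init_probs = init_probs,
         phase_switch_auto = phase_switch_auto),
    class = "generator_config"
  )
}

# Truncated log-normal dwell draw for action index `ai`.
.draw_dwell <- function(mu, sig, minb) {
  for (i in 1:100) {
    d <- rlnorm(1L, mu, sig)
    if (d >= minb) return(d)
  }
  minb
}

# Core bout sampler. `windows` is a 2-column matrix of (start_s, end_s);
# inside windows the transition row comes from `window_matrix`, and an
# ongoing bout is truncated at window onset (light onset interrupts).
.sim_bouts <- function(cfg, windows = NULL, window_matrix = NULL) {
  early <- cfg$phase_matrices$early
  late <- cfg$phase_matrices$late
  mid <- cfg$phase_switch$midpoint_s
  stp <- cfg$phase_switch$steepness_s
  fr <- cfg$frame_rate_hz
  N <- cfg$recording_frames
  mu <- cfg$duration_params$meanlog
  sig <- cfg$duration_params$sdlog
  minb <- cfg$min_bout_s
  min_frames <- max(1L, as.integer(ceiling(minb * fr)))
  win_starts_f <- if (!is.null(windows)) as.integer(floor(windows[, 1L] * fr)) else integer(0)

  cap <- N %/% min_frames + 2L
  acts <- integer(cap)
  nfrs <- integer(cap)
  cur <- sample.int(7L, 1L, prob = cfg$init_probs)
  t_frame <- 0L
  k <- 0L
  repeat {
    d <- .draw_dwell(mu[cur], sig[cur], minb)
    nf <- max(as.integer(round(d * fr)), min_frames)
    # truncate at next stimulation-window onset, and at the recording end
    upcoming <- win_starts_f[win_starts_f > t_frame & win_starts_f < t_frame + nf]
    if (length(upcoming) > 0L) nf <- min(upcoming) - t_frame
    nf <- min(nf, N - t_frame)
    k <- k + 1L
    acts[k] <- cur
    nfrs[k] <- nf
    t_frame <- t_frame + nf
    if (t_frame >= N) break
    t_s <- t_frame / fr
    in_win <- !is.null(windows) &&
      any(t_s >= windows[, 1L] & t_s < windows[, 2L])
    if (in_win) {
      row <- window_matrix[cur, ]
    } else {
      w <- plogis((t_s - mid) / stp)
      row <- (1 - w) * early[cur, ] + w * late[cur, ]
    }
    row[cur] <- 0
    s <- sum(row)
    if (s <= 0)
      stop("degenerate transition matrix: no off-diagonal mass from ",
           .ACTIONS[cur])
    nxt <- sample.int(7L, 1L, prob = row)
    # merge if truncation produced a same-action continuation (cannot happen
    # with zero-diagonal rows, kept as a guard)
    cur <- nxt
  }
  list(action = .ACTIONS[acts[seq_len(k)]], n_frames = nfrs[seq_len(k)])
}

#' Simulate one ethogram
#'
#' Semi-Markov draw under a [generator_config()]: bout actions follow the
#' phase-interpolated transition matrix evaluated at each bout's onset time,
#' and dwell times are drawn per action from truncated log-normals. The
#' output has exactly `recording_frames` frames and no two consecutive bouts
#' share an action.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed (draws are reproducible and do not disturb the
#'   caller's RNG state).
#' @param fly_id,group_id,session_id Metadata for the resulting ethogram.
#' @return An [ethogram()].
#' @export
#' @examples
#' e <- simulate_ethogram(generator_config(recording_frames = 2000), seed = 1)
#' e
simulate_ethogram <- function(cfg, seed = NULL, fly_id = "sim1",
                              group_id = "sim", session_id = "s1") {
  stopifnot(inherits(cfg, "generator_config"))
  b <- with_seed(seed, .sim_bouts(cfg))
  ethogram(rep(b$action, b$n_frames), fly_id = fly_id, group_id = group_id,
           session_id = session_id, frame_rate_hz = cfg$frame_rate_hz)
}

#' Simulate an optogenetic stimulation session
#'
#' Inside each stimulation window the bout transition matrix is replaced by
#' an anterior-dominant matrix (mass concentrated on F<->H) and light onset
#' interrupts the ongoing bout; outside the windows the baseline
#' phase-interpolated matrix applies. The default paradigm is three 3-minute
#' stimulation windows.
#'
#' @param cfg A [generator_config()].
#' @param windows Two-column matrix or list of `c(start_s, end_s)` pairs;
#'   must be non-overlapping and within the recording. Default: three 3-min
#'   windows.
#' @param seed Integer seed.
#' @param window_matrix Transition matrix used inside windows
#'   (default [anterior_dominant_matrix()]).
#' @param fly_id,group_id,session_id Metadata.
#' @return An [ethogram()] with the windows attached as `opto_windows`.
#' @export
simulate_opto_session <- function(cfg, windows = default_opto_windows(),
                                  seed = NULL,
                                  window_matrix = anterior_dominant_matrix(),
                                  fly_id = "opto1", group_id = "opto",
                                  session_id = "s1") {
  stopifnot(inherits(cfg, "generator_config"))
  windows <- as_windows(windows)
  if (nrow(windows) > 0L) {
    total_s <- cfg$recording_frames / cfg$frame_rate_hz
    if (any(windows[, 1L] >= windows[, 2L]))
      stop("each window must have start_s < end_s")
    if (any(windows[, 1L] < 0) || any(windows[, 2L] > total_s + 1e-9))
      stop("windows must lie within the recording (0 to ", round(total_s, 2), " s)")
    o <- order(windows[, 1L])
    windows <- windows[o, , drop = FALSE]
    if (nrow(windows) > 1L &&
        any(windows[-1L, 1L] < windows[-nrow(windows), 2L]))
      stop("stimulation windows must not overlap")
  }
  b <- with_seed(seed, .sim_bouts(cfg,
                                  windows = if (nrow(windows) > 0L) windows else NULL,
                                  window_matrix = window_matrix))
  ethogram(rep(b$action, b$n_frames), fly_id = fly_id, group_id = group_id,
           session_id = session_id, frame_rate_hz = cfg$frame_rate_hz,
           opto_windows = windows)
}

#' Default optogenetic stimulation paradigm: three 3-min windows
#' @return A 2-column matrix (`start_s`, `end_s`).
#' @export
default_opto_windows <- function() {
  m <- cbind(start_s = c(120, 660, 1200), end_s = c(300, 840, 1380))
  m
}

as_windows <- function(windows) {
  if (is.null(windows)) return(matrix(numeric(0), 0, 2,
                                      dimnames = list(NULL, c("start_s", "end_s"))))
  if (is.list(windows) && !is.data.frame(windows))
    windows <- do.call(rbind, windows)
  windows <- as.matrix(windows)
  if (length(windows) == 0L)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start_s", "end_s"))))
  stopifnot(ncol(windows) == 2L)
  colnames(windows) <- c("start_s", "end_s")
  windows
}

#' Group template: a generator configuration plus group-level structure
#'
#' A template bundles a [generator_config()] with a per-transition divergence
#' (offsets applied to the base phase matrices, then renormalized) and a
#' Dirichlet concentration controlling per-fly matrix jitter, emulating
#' between-group syntax variation and within-group individual variability.
#'
#' @param name Group name.
#' @param config A [generator_config()].
#' @param jitter_kappa Dirichlet concentration for per-fly row resampling
#'   (rows are drawn as `Dirichlet(kappa * row)`). Larger values give milder
#'   fly-to-fly jitter; `Inf` disables jitter. Default 150 (mild).
#' @param divergence Optional data.frame (`source`, `target`, `delta`) of
#'   additive offsets applied to both phase matrices before renormalization.
#' @return An object of class `"group_template"`.
#' @export
group_template <- function(name, config = generator_config(),
                           jitter_kappa = 150, divergence = NULL) {
  stopifnot(inherits(config, "generator_config"), jitter_kappa > 0)
  if (!is.null(divergence)) {
    stopifnot(all(c("source", "target", "delta") %in% names(divergence)))
    config$phase_matrices <- lapply(config$phase_matrices, function(m) {
      for (i in seq_len(nrow(divergence))) {
        s <- divergence$source[i]; t <- divergence$target[i]
        if (s == t) stop("divergence cannot target the diagonal")
        m[s, t] <- max(m[s, t] + divergence$delta[i], 0)
      }
      zero_diag_renorm(m)
    })
  }
  structure(list(name = as.character(name), config = config,
                 jitter_kappa = jitter_kappa, divergence = divergence),
            class = "group_template")
}

# Dirichlet-jitter the rows of each phase matrix (zero entries stay zero).
.jitter_config <- function(config, kappa) {
  if (!is.finite(kappa)) return(config)
  config$phase_matrices <- lapply(config$phase_matrices, function(m) {
    for (i in seq_len(nrow(m))) m[i, ] <- rdirichlet1(kappa * m[i, ])
    zero_diag_renorm(m)
  })
  config
}

#' Simulate a population of flies from a group template
#'
#' Draws `n` independent ethograms. Each fly receives its own transition
#' matrices, resampled around the template by a Dirichlet with concentration
#' `jitter_kappa` (within-group individual variability); the same seed always
#' reproduces the same cohort.
#'
#' @param template A [group_template()].
#' @param n Number of flies (>= 1).
#' @param seed Integer seed.
#' @param session_id Session identifier stamped on every fly.
#' @return List of [ethogram()] objects with fly_ids `<name>_fly<i>`.
#' @export
simulate_population <- function(template, n, seed = NULL, session_id = "s1") {
  stopifnot(inherits(template, "group_template"))
  if (n < 1) stop("n must be >= 1")
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max, 2L * n)
           else derive_seeds(seed, 2L * n)
  lapply(seq_len(n), function(i) {
    cfg_i <- with_seed(seeds[i], .jitter_config(template$config, template$jitter_kappa))
    simulate_ethogram(cfg_i, seed = seeds[n + i],
                      fly_id = paste0(template$name, "_fly", i),
                      group_id = template$name, session_id = session_id)
  })
}
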