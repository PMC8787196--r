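# Shared fixtures and independent oracles for the test suite.

ACTS <- c("F", "H", "A", "B", "W", "Wk", "S")

toy_ethogram <- function(labels, ...) ethogram(labels, ...)

# Structured 7x7 transition matrix with comparable occupancy across sources,
# used for parameter-recovery checks.
balanced_matrix <- function() {
  m <- matrix(0, 7, 7, dimnames = list(ACTS, ACTS))
  for (i in 1:7) {
    row <- c(0.30, 0.25, 0.18, 0.12, 0.08, 0.07)
    m[i, -i] <- row[order((seq_len(6) + i) %% 6)]
  }
  m / rowSums(m)
}

# Short-dwell config used where only the transition structure matters.
fast_config <- function(M, frames, seed_switch = NULL) {
  dp <- default_duration_params()
  dp$meanlog[] <- log(0.5)
  dp$sdlog[] <- 0.4
  generator_config(phase_matrices = list(early = M, late = M),
                   duration_params = dp, recording_frames = frames)
}

# Bout table from a bout-level Markov chain draw (unit dwell), for feeding
# syntax_vector() and the statistics layer cheaply.
markov_bouts <- function(M, n_bouts, start = "F") {
  labs <- character(n_bouts)
  labs[1] <- start
  for (i in 2:n_bouts) {
    labs[i] <- sample(ACTS, 1L, prob = M[labs[i - 1L], ])
  }
  data.frame(action = labs, start_frame = seq_len(n_bouts) - 1L,
             n_frames = 1L, duration_s = 1 / 30, stringsAsFactors = FALSE)
}

# Per-fly syntax vectors for a group drawn from matrix M.
group_syntax_from_matrix <- function(M, n_flies, n_bouts = 400L) {
  lapply(seq_len(n_flies), function(i) syntax_vector(markov_bouts(M, n_bouts)))
}

# --- Independent oracles ------------------------------------------------

# Brute-force Levenshtein DP in plain R (full table).
lev_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- min(d[i, j] + (a[i] != b[j]),
                               d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L)
    }
  }
  d[n + 1L, m + 1L]
}

# Hand step-down Holm adjustment.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    running <- max(running, (m - k + 1) * p[o[k]])
    adj[o[k]] <- min(running, 1)
  }
  adj
}

# Mean of a log-normal truncated below at L.
trunc_lnorm_mean <- function(mu, sig, L) {
  exp(mu + sig^2 / 2) * pnorm((log(L) - mu - sig^2) / sig, lower.tail = FALSE) /
    pnorm((log(L) - mu) / sig, lower.tail = FALSE)
}

# Stationary distribution of a row-stochastic matrix.
stationary_dist <- function(M) {
  ev <- eigen(t(M))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v / sum(v)
}

# All strings of length 0..max_len over `alphabet`, as a list of vectors.
all_strings <- function(alphabet, max_len) {
  out <- list(character(0))
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len), stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i)
      unlist(grid[i, ], use.names = FALSE)))
  }
  out
}
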