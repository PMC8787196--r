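# End-to-end experiment orchestration on synthetic or user-supplied
# ethograms: fixture generation, manifest I/O, and per-experiment analysis
# runs with machine-readable TSV/JSON outputs.

#' Named generator presets
#'
#' Ready-made cohorts of [group_template()]s emulating the study designs:
#' \describe{
#'   \item{`"five-species-like"`}{5 groups diverging mainly in within-motif
#'     transition probabilities (offsets 0.15-0.25), emulating species-level
#'     syntax variation.}
#'   \item{`"four-stocks-like"`}{4 groups diverging mainly in transitions to
#'     and from walking/standing, emulating stock-level activity differences.}
#'   \item{`"variability"`}{4 groups sharing one template and jitter level
#'     (stock-, isogenized- and outbred-like lines whose within-group
#'     variability does not differ).}
#'   \item{`"opto"`}{a single template plus the three 3-min stimulation
#'     windows of the optogenetic paradigm.}
#'   \item{`"within-individual"`}{a single template; flies are re-simulated
#'     over three sessions with fresh per-session jitter (sensory/internal
#'     variability).}
#' }
#' Divergences are illustrative of the direction and rough size of group
#' differences, not fitted to any data set.
#'
#' @param preset Preset name.
#' @return List of [group_template()]s; for `"opto"`, with a `windows`
#'   attribute.
#' @export
preset_templates <- function(preset = c("five-species-like", "four-stocks-like",
                                        "variability", "opto",
                                        "within-individual")) {
  preset <- tryCatch(match.arg(preset), error = function(e)
    stop("unknown preset '", preset[1L], "'; available: ",
         paste(eval(formals(preset_templates)$preset), collapse = ", "),
         call. = FALSE))
  dv <- function(...) {
    m <- matrix(c(...), ncol = 3L, byrow = TRUE)
    data.frame(source = m[, 1L], target = m[, 2L],
               delta = as.numeric(m[, 3L]), stringsAsFactors = FALSE)
  }
  base <- generator_config()
  out <- switch(preset,
    "five-species-like" = list(
      # species-level variation is broad: each template diverges from the
      # shared base across many transitions, within-motif ones included
      group_template("melanogaster-like", base),
      group_template("simulans-like", base,
                     divergence = dv("F", "H", -0.20, "H", "F", -0.20,
                                     "A", "B", 0.10, "B", "W", 0.10,
                                     "W", "A", 0.10, "F", "Wk", 0.10,
                                     "S", "Wk", 0.15, "Wk", "F", -0.10)),
      group_template("sechellia-like", base,
                     divergence = dv("A", "B", -0.15, "B", "A", -0.15,
                                     "W", "B", 0.15, "A", "W", 0.10,
                                     "F", "H", -0.10, "H", "S", 0.10,
                                     "Wk", "A", 0.10, "S", "F", -0.10)),
      group_template("erecta-like", base,
                     divergence = dv("Wk", "S", 0.20, "S", "Wk", 0.20,
                                     "F", "Wk", 0.15, "H", "Wk", 0.10,
                                     "B", "Wk", 0.10, "A", "B", 0.10,
                                     "W", "Wk", 0.10)),
      group_template("santomea-like", base,
                     divergence = dv("W", "Wk", 0.20, "B", "W", -0.15,
                                     "H", "F", -0.15, "F", "A", 0.10,
                                     "A", "F", 0.10, "Wk", "H", 0.10,
                                     "S", "H", 0.10))
    ),
    "four-stocks-like" = {
      # stocks differ mostly in overall activity: transitions to/from
      # walking/standing plus distinct walking/standing dwell times
      activity <- function(d_wk, d_s) {
        dp <- default_duration_params()
        dp["Wk", "meanlog"] <- dp["Wk", "meanlog"] + d_wk
        dp["S", "meanlog"] <- dp["S", "meanlog"] + d_s
        generator_config(duration_params = dp)
      }
      list(
        group_template("cantonS-like", activity(0.5, -0.3),
                       divergence = dv("S", "Wk", 0.20, "W", "Wk", 0.15)),
        group_template("oregonR-like", base),
        group_template("berlinK-like", activity(-0.4, 0.4),
                       divergence = dv("S", "Wk", -0.25, "Wk", "S", 0.15)),
        group_template("w1118-like", activity(0, 0.5),
                       divergence = dv("F", "S", 0.10, "H", "S", 0.10))
      )
    },
    "variability" = list(
      group_template("stock-like", base),
      group_template("iso1-like", base),
      group_template("iso2-like", base),
      group_template("maxvar-like", base)
    ),
    "opto" = {
      tl <- list(group_template("opto", base))
      attr(tl, "windows") <- default_opto_windows()
      tl
    },
    "within-individual" = {
      # Post-dusting behavior with tight early anterior coupling, so that
      # the first continuous anterior motif run reliably exceeds the 30 s
      # minimum the edit-distance protocol selects on.
      pm <- default_phase_matrices()
      pm$early["F", ] <- c(0, 0.93, 0.010, 0.005, 0.005, 0.030, 0.020)
      pm$early["H", ] <- c(0.93, 0, 0.010, 0.005, 0.005, 0.030, 0.020)
      list(group_template("cantonS-like",
                          generator_config(phase_matrices = pm)))
    }
  )
  out
}

#' Write / read a cohort manifest
#'
#' A manifest is a TSV with columns `fly_id`, `group_id`, `session_id`,
#' `path` (ethogram CSV path, relative to the manifest's directory) listing
#' the recordings of a cohort.
#'
#' @param manifest data.frame with the columns above.
#' @param path Manifest file path.
#' @return `read_manifest` returns the data.frame; `write_manifest` returns
#'   `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Load every ethogram listed in a manifest
#' @param manifest A manifest data.frame or path to one.
#' @param base_dir Directory that relative `path` entries are resolved
#'   against (defaults to the manifest's directory when a path is given).
#' @return List of [ethogram()]s.
#' @export
load_cohort <- function(manifest, base_dir = ".") {
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, manifest$path[i])
    read_ethogram(p)
  })
}

#' Generate a synthetic fixture cohort on disk
#'
#' Simulates a small cohort from a named preset and writes one ethogram CSV
#' per fly plus a manifest TSV. Byte-identical under a fixed seed. For the
#' `"opto"` preset the stimulation windows are annotated in the manifest;
#' for `"within-individual"` each fly is simulated over three sessions.
#'
#' @param preset Preset name (see [preset_templates()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_flies Flies per group (default 10).
#' @param recording_frames Frames per ethogram (default 10000).
#' @return The manifest data.frame, invisibly; written to
#'   `<out_dir>/manifest.tsv`.
#' @export
make_fixtures <- function(preset, out_dir, seed = 1L, n_flies = 10L,
                          recording_frames = 10000L) {
  templates <- preset_templates(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ethos <- simulate_preset(preset, templates, seed = seed, n_flies = n_flies,
                           recording_frames = recording_frames)
  rows <- lapply(ethos, function(e) {
    fn <- paste0(e$fly_id, "_", e$session_id, ".csv")
    write_ethogram(e, file.path(out_dir, fn))
    data.frame(fly_id = e$fly_id, group_id = e$group_id,
               session_id = e$session_id, path = fn, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  if (!is.null(attr(templates, "windows"))) {
    w <- attr(templates, "windows")
    manifest$opto_windows_s <- paste(apply(w, 1L, paste, collapse = "-"),
                                     collapse = ";")
  }
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

# Simulate the cohort for a preset entirely in memory.
simulate_preset <- function(preset, templates = preset_templates(preset),
                            seed = 1L, n_flies = 10L,
                            recording_frames = 10000L) {
  templates <- lapply(templates, function(tl) {
    tl$config$recording_frames <- as.integer(recording_frames)
    if (isTRUE(tl$config$phase_switch_auto)) {
      total_s <- recording_frames / tl$config$frame_rate_hz
      tl$config$phase_switch <- list(midpoint_s = 0.24 * total_s,
                                     steepness_s = 0.072 * total_s)
    }
    tl
  })
  seeds <- derive_seeds(seed, length(templates) * 3L + 1L)
  if (preset == "opto") {
    windows <- default_opto_windows()
    total_s <- recording_frames / templates[[1L]]$config$frame_rate_hz
    windows <- windows[windows[, 2L] <= total_s, , drop = FALSE]
    if (nrow(windows) < 3L)   # short recordings: scale the paradigm down
      windows <- matrix(c(0.1 * total_s, 0.3 * total_s,
                          0.4 * total_s, 0.6 * total_s,
                          0.7 * total_s, 0.9 * total_s), 3, 2, byrow = TRUE,
                        dimnames = list(NULL, c("start_s", "end_s")))
    fly_seeds <- derive_seeds(seeds[1L], n_flies)
    ethos <- lapply(seq_len(n_flies), function(i)
      simulate_opto_session(templates[[1L]]$config, windows = windows,
                            seed = fly_seeds[i],
                            fly_id = paste0("opto_fly", i), group_id = "opto"))
  } else if (preset == "within-individual") {
    ethos <- list()
    for (s in 1:3) {
      pop <- simulate_population(templates[[1L]], n_flies, seed = seeds[s],
                                 session_id = paste0("day", s))
      ethos <- c(ethos, pop)
    }
  } else {
    ethos <- list()
    for (g in seq_along(templates)) {
      pop <- simulate_population(templates[[g]], n_flies, seed = seeds[g])
      ethos <- c(ethos, pop)
    }
  }
  ethos
}

#' Extract a time slice of an ethogram
#' @param e An [ethogram()].
#' @param start_s,end_s Slice boundaries in seconds (frames with onset in
#'   `[start_s, end_s)`).
#' @param session_id Session id for the slice (default: parent's).
#' @return An [ethogram()].
#' @export
ethogram_slice <- function(e, start_s, end_s, session_id = e$session_id) {
  fr <- e$frame_rate_hz
  i0 <- max(1L, as.integer(floor(start_s * fr)) + 1L)
  i1 <- min(length(e$labels), as.integer(ceiling(end_s * fr)))
  if (i1 < i0) stop("empty slice")
  ethogram(e$labels[i0:i1], fly_id = e$fly_id, group_id = e$group_id,
           session_id = session_id, frame_rate_hz = fr)
}

# Split syntax vectors per group, as expected by the pairwise test routines.
.group_syntax <- function(ethos) {
  groups <- split(ethos, vapply(ethos, function(e) e$group_id, character(1)))
  lapply(groups, function(g) lapply(g, function(e) syntax_vector(to_bouts(e))))
}

.write_tsv <- function(df, path, meta = character(0)) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (length(meta) > 0L)
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a full analysis experiment
#'
#' Orchestrates denoise -> feature extraction -> per-experiment statistics,
#' stereotypy, and classification on a synthetic preset cohort or a manifest
#' of ethogram CSVs, writing flat TSV/JSON outputs (each stamped with the
#' run's seed and config hash) plus a run log. Deterministic under `seed`.
#'
#' Experiments: `"species_comparison"` (pairwise syntax rank-sum table,
#' syntax classification + permutation chance, per-fly entropy),
#' `"stock_comparison"` (as above plus non-grooming-only classification),
#' `"variability_comparison"` (pairwise Brown-Forsythe variance table),
#' `"within_individual"` (within/between-fly edit-distance summaries and
#' grooming half-times), `"opto"` (per-window entropy and within/between-fly
#' edit-distance summaries).
#'
#' @param experiment Experiment name (see above).
#' @param input A preset name (see [preset_templates()]) or a manifest TSV
#'   path.
#' @param output_dir Directory for outputs (created if needed).
#' @param seed Integer seed used for simulation, CV, and permutations.
#' @param n_flies,recording_frames Cohort size when `input` is a preset.
#' @param n_permutations Label permutations for chance estimation.
#' @param min_run_s Minimum anterior-run duration for edit-distance
#'   comparisons (30 s for full-length recordings; scaled-down runs use
#'   shorter cohorts, see the vignette).
#' @return Invisibly, a list with the computed tables and the paths written.
#' @export
run_experiment <- function(experiment = c("species_comparison",
                                          "stock_comparison",
                                          "variability_comparison",
                                          "within_individual", "opto"),
                           input = NULL, output_dir = tempfile("groomrun"),
                           seed = 1L, n_flies = 10L,
                           recording_frames = 10000L,
                           n_permutations = 100L, min_run_s = 30) {
  experiment <- match.arg(experiment)
  default_preset <- switch(experiment,
    species_comparison = "five-species-like",
    stock_comparison = "four-stocks-like",
    variability_comparison = "variability",
    within_individual = "within-individual",
    opto = "opto")
  input <- input %||% default_preset
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (is.character(input) && file.exists(input) && !dir.exists(input)) {
    ethos <- load_cohort(input)
    say("loaded %d ethograms from manifest %s", length(ethos), input)
  } else {
    ethos <- simulate_preset(input, seed = seed, n_flies = n_flies,
                             recording_frames = recording_frames)
    say("simulated preset '%s': %d ethograms x %d frames", input,
        length(ethos), recording_frames)
  }

  raw_bouts <- sum(vapply(ethos, function(e) nrow(to_bouts(e)), numeric(1)))
  ethos <- lapply(ethos, denoise)
  den_bouts <- sum(vapply(ethos, function(e) nrow(to_bouts(e)), numeric(1)))
  say("denoising removed %d of %d bouts (%.2f%%)", raw_bouts - den_bouts,
      raw_bouts, 100 * (raw_bouts - den_bouts) / max(raw_bouts, 1))

  cfg <- list(experiment = experiment, input = if (is.character(input)) input else "custom",
              seed = seed, n_flies = n_flies,
              recording_frames = recording_frames,
              n_permutations = n_permutations, min_run_s = min_run_s)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  meta <- c(config_hash = cfg_hash, seed = as.character(seed))
  out <- list(config = cfg, config_hash = cfg_hash, paths = character(0))
  addpath <- function(p) out$paths <<- c(out$paths, p)

  if (experiment %in% c("species_comparison", "stock_comparison")) {
    syn_groups <- .group_syntax(ethos)
    tab <- pairwise_location_tests(syn_groups)
    addpath(.write_tsv(tab, file.path(output_dir, "syntax_location_tests.tsv"), meta))
    out$location_tests <- tab
    say("syntax location table: %d rows, %d significant", nrow(tab),
        sum(tab$significant))
    feats <- cohort_features(ethos, "syntax")
    out$classification <- classify(feats, seed = seed)
    out$chance <- chance_level(feats, n_permutations = n_permutations,
                               seed = seed)
    if (experiment == "stock_comparison") {
      ng <- cohort_features(ethos, "non_grooming_only")
      out$classification_non_grooming <- classify(ng, seed = seed)
    }
    ent <- vapply(ethos, function(e)
      entropy_rate(syntax_vector(to_bouts(e)))$H, numeric(1))
    ent_df <- data.frame(fly_id = vapply(ethos, function(e) e$fly_id, character(1)),
                         group_id = vapply(ethos, function(e) e$group_id, character(1)),
                         entropy_nats = unname(ent))
    addpath(.write_tsv(ent_df, file.path(output_dir, "entropy.tsv"), meta))
    out$entropy <- ent_df
    cl <- list(classification = unclass(out$classification),
               chance = unclass(out$chance)[c("chance", "band")])
    if (!is.null(out$classification_non_grooming))
      cl$classification_non_grooming <- unclass(out$classification_non_grooming)
    p <- file.path(output_dir, "classification.json")
    jsonlite::write_json(cl, p, auto_unbox = TRUE, digits = NA)
    addpath(p)
  } else if (experiment == "variability_comparison") {
    syn_groups <- .group_syntax(ethos)
    tab <- pairwise_variance_tests(syn_groups)
    addpath(.write_tsv(tab, file.path(output_dir, "syntax_variance_tests.tsv"), meta))
    out$variance_tests <- tab
    say("syntax variance table: %d rows, %d significant", nrow(tab),
        sum(tab$significant))
  } else if (experiment == "within_individual") {
    within <- stereotypy_comparison(ethos, "within_fly_across_sessions",
                                    min_duration_s = min_run_s)
    between <- stereotypy_comparison(ethos, "between_fly_same_session",
                                     min_duration_s = min_run_s)
    addpath(.write_tsv(within$distances,
                       file.path(output_dir, "edit_distance_within.tsv"), meta))
    addpath(.write_tsv(between$distances,
                       file.path(output_dir, "edit_distance_between.tsv"), meta))
    out$within <- within; out$between <- between
    say("edit distances: %d within-fly pairs, %d between-fly pairs; %d sessions lacked a %gs run",
        nrow(within$distances), nrow(between$distances),
        within$n_skipped, min_run_s)
    ht <- data.frame(fly_id = vapply(ethos, function(e) e$fly_id, character(1)),
                     session_id = vapply(ethos, function(e) e$session_id, character(1)),
                     half_time_s = vapply(ethos, function(e)
                       suppressWarnings(grooming_half_time(e)), numeric(1)))
    addpath(.write_tsv(ht, file.path(output_dir, "grooming_half_time.tsv"), meta))
    out$half_time <- ht
    p <- file.path(output_dir, "edit_distance_summary.json")
    jsonlite::write_json(list(within = as.list(within$summary),
                              between = as.list(between$summary)),
                         p, auto_unbox = TRUE, digits = NA)
    addpath(p)
  } else if (experiment == "opto") {
    windows <- ethos[[1L]]$opto_windows
    if (is.null(windows)) {
      # loaded from manifest: reconstruct the default paradigm
      windows <- default_opto_windows()
    }
    act <- list()
    ent_rows <- list()
    for (e in ethos) {
      for (wi in seq_len(nrow(windows))) {
        sl <- ethogram_slice(e, windows[wi, 1L], windows[wi, 2L],
                             session_id = paste0("activation", wi))
        act[[length(act) + 1L]] <- sl
        syn <- syntax_vector(to_bouts(sl))
        ent_rows[[length(ent_rows) + 1L]] <- data.frame(
          fly_id = e$fly_id, window = wi,
          entropy_nats = entropy_rate(syn)$H)
      }
    }
    ent_df <- do.call(rbind, ent_rows)
    addpath(.write_tsv(ent_df, file.path(output_dir, "window_entropy.tsv"), meta))
    out$window_entropy <- ent_df
    win_len <- min(windows[, 2L] - windows[, 1L])
    run_s <- min(min_run_s, win_len / 3)
    within <- stereotypy_comparison(act, "within_fly_across_sessions",
                                    min_duration_s = run_s)
    between <- stereotypy_comparison(act, "between_fly_same_session",
                                     min_duration_s = run_s)
    out$within <- within; out$between <- between
    addpath(.write_tsv(within$distances,
                       file.path(output_dir, "edit_distance_within.tsv"), meta))
    addpath(.write_tsv(between$distances,
                       file.path(output_dir, "edit_distance_between.tsv"), meta))
    p <- file.path(output_dir, "edit_distance_summary.json")
    jsonlite::write_json(list(within = as.list(within$summary),
                              between = as.list(between$summary)),
                         p, auto_unbox = TRUE, digits = NA)
    addpath(p)
    say("opto: %d per-window entropies, %d within / %d between pairs",
        nrow(ent_df), nrow(within$distances), nrow(between$distances))
  }

  p <- file.path(output_dir, "run_config.json")
  jsonlite::write_json(c(cfg, list(config_hash = cfg_hash)), p,
                       auto_unbox = TRUE, digits = NA)
  addpath(p)
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  addpath(file.path(output_dir, "run_log.txt"))
  invisible(out)
}

#' Read a run configuration from YAML or JSON
#'
#' Convenience for scripted runs: the returned list can be passed to
#' [run_experiment()] via `do.call()`.
#'
#' @param path `.yaml`/`.yml` or `.json` file of `run_experiment()`
#'   arguments.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
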