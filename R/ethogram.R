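#' Construct an ethogram
#'
#' An ethogram is a frame-by-frame categorical record of a fly's behavior:
#' one action code per video frame over the seven-action alphabet (see
#' [action_alphabet()]), plus identifying metadata and the frame rate.
#'
#' @param labels Character vector of per-frame action codes.
#' @param fly_id,group_id,session_id Identifying metadata strings.
#' @param frame_rate_hz Frames per second (positive; 30 for the standard
#'   recording setup).
#' @param opto_windows Optional two-column matrix (`start_s`, `end_s`) of
#'   optogenetic stimulation windows, carried as metadata.
#' @return An object of class `"ethogram"`.
#' @export
#' @examples
#' e <- ethogram(c("F", "F", "H", "H", "F"), fly_id = "toy")
#' ethogram_duration_min(e)
ethogram <- function(labels, fly_id = "fly1", group_id = "group1",
                     session_id = "s1", frame_rate_hz = 30,
                     opto_windows = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("ethogram must contain at least one frame")
  .check_labels(labels)
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      is.na(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be a single positive number")
  structure(
    list(labels = labels, fly_id = as.character(fly_id),
         group_id = as.character(group_id), session_id = as.character(session_id),
         frame_rate_hz = as.numeric(frame_rate_hz),
         opto_windows = opto_windows),
    class = "ethogram"
  )
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> fly=%s group=%s session=%s: %d frames @ %g Hz (%.2f min)\n",
              x$fly_id, x$group_id, x$session_id, length(x$labels),
              x$frame_rate_hz, ethogram_duration_min(x)))
  tab <- table(factor(x$labels, levels = .ACTIONS))
  cat("  frame counts:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
length.ethogram <- function(x) length(x$labels)

#' Recording duration in minutes
#' @param e An [ethogram()].
#' @return Duration in minutes (`n_frames / frame_rate / 60`).
#' @export
ethogram_duration_min <- function(e) {
  stopifnot(inherits(e, "ethogram"))
  length(e$labels) / e$frame_rate_hz / 60
}

#' Read an ethogram from CSV
#'
#' The file dialect is a two-column CSV (`frame_index`, `label`) with a
#' header row, preceded by `# key: value` comment lines holding the metadata
#' (`fly_id`, `group_id`, `session_id`, `frame_rate_hz`). Frame indices must
#' be contiguous from 0. One fly per file.
#'
#' @param path Path to the CSV file.
#' @return An [ethogram()].
#' @export
read_ethogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty ethogram file: ", path)
  is_meta <- grepl("^\\s*#", lines)
  n_meta <- if (any(!is_meta)) which(!is_meta)[1L] - 1L else length(lines)
  meta <- list()
  if (n_meta > 0L) {
    kv <- sub("^\\s*#\\s*", "", lines[seq_len(n_meta)])
    kv <- kv[grepl(":", kv, fixed = TRUE)]
    for (line in kv) {
      key <- trimws(sub(":.*$", "", line))
      val <- trimws(sub("^[^:]*:", "", line))
      meta[[key]] <- val
    }
  }
  body <- lines[!is_meta]
  if (length(body) <= 1L) stop("no data rows in ethogram file: ", path)
  df <- read.csv(text = body, stringsAsFactors = FALSE,
                 colClasses = c("integer", "character"))
  if (!all(c("frame_index", "label") %in% names(df)))
    stop("ethogram CSV must have columns frame_index,label")
  bad <- which(!(df$label %in% .ACTIONS))
  if (length(bad) > 0L)
    stop("unknown action label '", df$label[bad[1L]], "' at data row ", bad[1L],
         " of ", path)
  if (!identical(df$frame_index, seq_len(nrow(df)) - 1L))
    stop("frame_index must be contiguous from 0 in ", path)
  ethogram(df$label,
           fly_id = meta$fly_id %||% "fly1",
           group_id = meta$group_id %||% "group1",
           session_id = meta$session_id %||% "s1",
           frame_rate_hz = as.numeric(meta$frame_rate_hz %||% 30))
}

#' Write an ethogram to CSV
#'
#' Inverse of [read_ethogram()]: metadata as `# key: value` header comments,
#' then `frame_index,label` rows. Round-trips label sequences exactly.
#'
#' @param e An [ethogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ethogram <- function(e, path) {
  stopifnot(inherits(e, "ethogram"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# fly_id: ", e$fly_id),
    paste0("# group_id: ", e$group_id),
    paste0("# session_id: ", e$session_id),
    paste0("# frame_rate_hz: ", format(e$frame_rate_hz, digits = 15)),
    "frame_index,label",
    paste0(seq_along(e$labels) - 1L, ",", e$labels)
  ), con)
  invisible(path)
}

#' Run-length encode an ethogram into bouts
#'
#' A bout is a maximal run of consecutive frames sharing one action label.
#' Bouts tile the ethogram without gaps or overlaps, and consecutive bouts
#' always carry distinct actions.
#'
#' @param e An [ethogram()].
#' @return A data.frame with columns `action`, `start_frame` (0-based),
#'   `n_frames`, `duration_s`.
#' @export
#' @examples
#' to_bouts(ethogram(c("F", "F", "H", "H", "F")))
to_bouts <- function(e) {
  stopifnot(inherits(e, "ethogram"))
  r <- rle(e$labels)
  ends <- cumsum(r$lengths)
  data.frame(
    action = r$values,
    start_frame = ends - r$lengths,
    n_frames = r$lengths,
    duration_s = r$lengths / e$frame_rate_hz,
    stringsAsFactors = FALSE
  )
}

#' Expand bouts back to a frame label sequence
#' @param bouts A bout data.frame as returned by [to_bouts()].
#' @return Character vector of per-frame labels.
#' @export
bouts_to_labels <- function(bouts) {
  rep(bouts$action, bouts$n_frames)
}

#' Denoise an ethogram by eliminating implausibly short grooming bouts
#'
#' Grooming bouts shorter than one complete leg sweep (cutoff 150 ms) are
#' treated as classifier glitches and eliminated: their frames are absorbed
#' by the preceding bout (merge-left; a short first bout merges right), and
#' adjacent same-action bouts are then re-merged. Non-grooming (walking,
#' standing) bouts are never removed. The rule keeps bouts with duration
#' `>= min_duration_s` — at 30 Hz a 4-frame grooming bout (133 ms) is
#' eliminated while a 5-frame bout (167 ms) survives. The total frame count
#' never changes; frames are only relabeled. The operation is idempotent.
#'
#' @param e An [ethogram()].
#' @param min_duration_s Cutoff in seconds (default 0.150).
#' @return A denoised [ethogram()].
#' @export
denoise <- function(e, min_duration_s = 0.150) {
  stopifnot(inherits(e, "ethogram"), min_duration_s >= 0)
  fr <- e$frame_rate_hz
  b <- to_bouts(e)
  if (nrow(b) == 1L) {
    if (b$action %in% .GROOMING && b$duration_s < min_duration_s)
      warning("ethogram is a single bout shorter than the cutoff; returned unchanged")
    return(e)
  }
  action <- b$action
  nfr <- b$n_frames
  repeat {
    short <- which(action %in% .GROOMING & nfr / fr < min_duration_s)
    if (length(short) == 0L) break
    i <- short[1L]
    j <- if (i == 1L) 2L else i - 1L     # merge left; first bout merges right
    action[i] <- action[j]
    # re-merge adjacent same-action bouts
    r <- rle(action)
    grp <- rep.int(seq_along(r$lengths), r$lengths)
    nfr <- as.vector(rowsum(nfr, grp))
    action <- r$values
    if (length(action) == 1L) break
  }
  out <- e
  out$labels <- rep(action, nfr)
  out
}
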