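# The seven-action behavioral alphabet.
#
# Five grooming actions -- front leg cleaning (F), head grooming (H),
# abdomen grooming (A), back leg cleaning (B), wing grooming (W) -- plus
# two non-grooming actions, walking (Wk) and standing (S). The grooming
# actions split into an anterior motif {F, H} (front-leg movements) and a
# posterior motif {A, B, W}.

.ACTIONS <- c("F", "H", "A", "B", "W", "Wk", "S")
.GROOMING <- c("F", "H", "A", "B", "W")
.ANTERIOR <- c("F", "H")
.POSTERIOR <- c("A", "B", "W")
.NON_GROOMING <- c("Wk", "S")

#' The behavioral action alphabet
#'
#' The seven action codes used in grooming ethograms: five grooming actions
#' (`F` front leg cleaning, `H` head grooming, `A` abdomen grooming, `B` back
#' leg cleaning, `W` wing grooming) and two non-grooming actions (`Wk`
#' walking, `S` standing).
#'
#' @return Character vector of the 7 action codes, in canonical order.
#' @export
#' @examples
#' action_alphabet()
action_alphabet <- function() .ACTIONS

#' @rdname action_alphabet
#' @export
grooming_actions <- function() .GROOMING

#' @rdname action_alphabet
#' @export
anterior_actions <- function() .ANTERIOR

#' @rdname action_alphabet
#' @export
posterior_actions <- function() .POSTERIOR

#' @rdname action_alphabet
#' @export
non_grooming_actions <- function() .NON_GROOMING

#' Action metadata table
#'
#' @return A data.frame with one row per action code and columns `code`,
#'   `category` (`"grooming"` or `"non_grooming"`) and `motif` (`"anterior"`,
#'   `"posterior"` or `"none"`).
#' @export
action_table <- function() {
  data.frame(
    code = .ACTIONS,
    category = ifelse(.ACTIONS %in% .GROOMING, "grooming", "non_grooming"),
    motif = ifelse(.ACTIONS %in% .ANTERIOR, "anterior",
                   ifelse(.ACTIONS %in% .POSTERIOR, "posterior", "none")),
    stringsAsFactors = FALSE
  )
}

.check_labels <- function(labels) {
  bad <- which(!(labels %in% .ACTIONS))
  if (length(bad) > 0L) {
    stop("unknown action label(s) ", paste(unique(labels[bad]), collapse = ", "),
         " at position(s) ", paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  invisible(TRUE)
}

# All 42 ordered (source, target) pairs, source != target, in canonical order.
.transition_pairs <- function() {
  grid <- expand.grid(target = .ACTIONS, source = .ACTIONS,
                      stringsAsFactors = FALSE)[, c("source", "target")]
  grid <- grid[grid$source != grid$target, ]
  rownames(grid) <- NULL
  grid
}

.transition_names <- function() {
  tp <- .transition_pairs()
  paste0(tp$source, "_to_", tp$target)
}
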