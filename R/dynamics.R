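#' Temporal-dynamics summary of a state sequence
#'
#' Decomposes a time-ordered sequence of state indices into the quantities
#' dynamic analyses report: occupancy (total time points spent in each
#' state), dwell episodes (maximal runs of consecutive identical states,
#' whose lengths are the dwell times), the maximum dwell time per state,
#' and non-self transition counts (exits from and entries into each state;
#' consecutive repeats of a state are dwelling, not transitions). The first
#' episode needs no entry and the last no exit, but both still count toward
#' occupancy and dwell.
#'
#' @param seq A \code{state_sequence} (or plain integer vector of state
#'   indices).
#' @param states_of_interest Optional state indices to restrict the
#'   reporting accessors to; all-state totals are always retained.
#' @return An object of class \code{dynamics_summary} with named-by-state
#'   components \code{occupancy}, \code{episodes} (list of episode
#'   lengths), \code{max_dwell}, \code{n_episodes}, \code{transitions_from}
#'   and \code{transitions_to}, plus \code{t_max} and
#'   \code{states_of_interest}.
#' @export
#' @examples
#' s <- summarize_dynamics(c(5, 5, 9, 9, 9, 5, 1))
#' s$occupancy      # 1:1, 5:3, 9:3
#' s$max_dwell["9"] # 3
summarize_dynamics <- function(seq, states_of_interest = NULL) {
  seq <- as.integer(seq)
  if (length(seq) == 0L) stop("state sequence is empty", call. = FALSE)
  r <- rle(seq)
  v <- as.character(r$values)
  states <- sort(unique(r$values))
  sn <- as.character(states)
  occupancy <- vapply(split(r$lengths, v), sum, numeric(1))[sn]
  episodes <- split(r$lengths, v)[sn]
  max_dwell <- vapply(episodes, max, numeric(1))
  n_episodes <- vapply(episodes, length, numeric(1))
  n_runs <- length(r$values)
  count_by_state <- function(x) {
    tab <- table(factor(as.character(x), levels = sn))
    stats::setNames(as.numeric(tab), sn)
  }
  transitions_from <- count_by_state(r$values[-n_runs])  # every run but the last exits
  transitions_to <- count_by_state(r$values[-1L])        # every run but the first is entered
  structure(
    list(occupancy = stats::setNames(as.numeric(occupancy), sn),
         episodes = episodes,
         max_dwell = max_dwell,
         n_episodes = n_episodes,
         transitions_from = transitions_from,
         transitions_to = transitions_to,
         t_max = length(seq),
         states_of_interest = states_of_interest),
    class = "dynamics_summary"
  )
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat("Temporal dynamics over", x$t_max, "time points;",
      length(x$occupancy), "states visited\n")
  top <- utils::head(sort(x$occupancy, decreasing = TRUE), 5L)
  cat("  most occupied:",
      paste(sprintf("S%s (%g)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

# Pull a per-state metric out of a summary, 0 for unvisited states.
dyn_metric <- function(summary, metric, states) {
  v <- summary[[metric]]
  out <- stats::setNames(numeric(length(states)), as.character(states))
  hit <- intersect(names(v), names(out))
  out[hit] <- v[hit]
  out
}

#' Group-level dynamics tables
#'
#' Aggregates per-subject dynamics summaries over a group for the given
#' states: the group maximum of per-subject maximum dwell times, the group
#' total visit count (occupancy: time points in the state summed over
#' subjects; an episode-count variant is reported alongside as
#' \code{total_episode_count}), and group totals of non-self transitions
#' from and to each state.
#'
#' @param summaries List of [summarize_dynamics()] results (one subject
#'   each).
#' @param states State indices to report.
#' @return A data frame with one row per state: \code{state},
#'   \code{max_dwell}, \code{total_visit_count}, \code{total_episode_count},
#'   \code{transitions_from}, \code{transitions_to}.
#' @export
aggregate_group_dynamics <- function(summaries, states) {
  stopifnot(length(summaries) >= 1L)
  states <- as.integer(states)
  pull <- function(metric) {
    vapply(summaries, dyn_metric, numeric(length(states)),
           metric = metric, states = states) |>
      matrix(nrow = length(states))
  }
  data.frame(
    state = states,
    max_dwell = apply(pull("max_dwell"), 1L, max),
    total_visit_count = rowSums(pull("occupancy")),
    total_episode_count = rowSums(pull("n_episodes")),
    transitions_from = rowSums(pull("transitions_from")),
    transitions_to = rowSums(pull("transitions_to"))
  )
}
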