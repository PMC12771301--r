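#' Enumerate all activity states of N regions
#'
#' An activity state assigns +1 (active) or -1 (inactive) to each of the
#' \code{n_rois} regions, so there are \code{2^n_rois} states. Row \code{k}
#' of the returned matrix is the state with index \code{k} under the
#' package's indexing convention (see [state_index()]).
#'
#' @param n_rois Number of regions (2 to 15; the exact-enumeration bound).
#' @return A \code{2^n_rois x n_rois} integer matrix with entries in
#'   \{-1, +1\}.
#' @seealso [state_index()], [index_to_state()]
#' @export
#' @examples
#' enumerate_states(2)
enumerate_states <- function(n_rois) {
  check_n_rois(n_rois)
  n_states <- 2L^n_rois
  words <- 0:(n_states - 1L)
  S <- matrix(-1L, nrow = n_states, ncol = n_rois)
  for (i in seq_len(n_rois)) {
    bit <- bitwAnd(words, bitwShiftL(1L, n_rois - i)) > 0L
    S[bit, i] <- 1L
  }
  S
}

#' State index of an activity pattern
#'
#' States are labelled 1 to 2^N by reading the pattern as a binary word
#' (-1 is bit 0, +1 is bit 1, first-listed region is the most significant
#' bit) and adding one. The all-inactive state is 1; the all-active state
#' is 2^N.
#'
#' @param state A length-N vector in \{-1, +1\}, or a matrix with one such
#'   state per row.
#' @return Integer index (or vector of indices) in \code{[1, 2^N]}.
#' @export
#' @examples
#' state_index(c(-1, -1, -1))  # 1
#' state_index(c(1, 1, 1))     # 8
state_index <- function(state) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1L)
  if (!all(state == 1L | state == -1L)) {
    stop("activity states must contain only -1 and +1", call. = FALSE)
  }
  n <- ncol(state)
  check_n_rois(n)
  weights <- 2^((n - 1L):0)
  as.integer(as.vector((state == 1L) %*% weights) + 1L)
}

#' @rdname state_index
#' @param k State index in \code{[1, 2^n]}.
#' @param n Number of regions.
#' @export
index_to_state <- function(k, n) {
  check_n_rois(n)
  k <- as.integer(k)
  if (any(k < 1L) || any(k > 2L^n)) {
    stop("state index out of range [1, 2^n]", call. = FALSE)
  }
  words <- k - 1L
  S <- matrix(-1L, nrow = length(k), ncol = n)
  for (i in seq_len(n)) {
    bit <- bitwAnd(words, bitwShiftL(1L, n - i)) > 0L
    S[bit, i] <- 1L
  }
  if (length(k) == 1L) drop(S) else S
}

#' Render states as 0/1 pattern strings
#'
#' Internally states are -1/+1; reports conventionally display inactive
#' regions as 0. The first character corresponds to the first-listed region.
#'
#' @param k State indices.
#' @param n Number of regions.
#' @return Character vector of 0/1 strings, e.g. \code{"0101101"}.
#' @export
state_pattern <- function(k, n) {
  S <- index_to_state(k, n)
  if (is.null(dim(S))) S <- matrix(S, nrow = 1L)
  apply(S, 1L, function(row) paste(ifelse(row > 0L, "1", "0"), collapse = ""))
}

# Hamming-1 neighbours of every state: row k lists the n states reached
# from state k by flipping one region.
neighbor_index_matrix <- function(n_rois) {
  n_states <- 2L^n_rois
  words <- 0:(n_states - 1L)
  nb <- matrix(0L, nrow = n_states, ncol = n_rois)
  for (i in seq_len(n_rois)) {
    nb[, i] <- bitwXor(words, bitwShiftL(1L, n_rois - i)) + 1L
  }
  nb
}

check_n_rois <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 1L) {
    stop("n_rois must be a single positive integer", call. = FALSE)
  }
  if (n > 15L) {
    stop("n_rois exceeds the exact-enumeration bound (15): 2^N states ",
         "must be enumerable", call. = FALSE)
  }
  invisible(as.integer(n))
}
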