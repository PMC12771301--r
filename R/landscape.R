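#' Local minima of an energy table
#'
#' A state is a local minimum when its energy is strictly below the
#' energies of all N single-flip (Hamming distance 1) neighbours; such
#' states are the attractors of the landscape. Strictness means plateau
#' states with an equal-energy neighbour are not minima — with
#' continuously fitted parameters exact ties have measure zero, and the
#' strict rule gives a unique, testable definition.
#'
#' @param et An \code{energy_table} from [boltzmann()].
#' @return A data frame with columns \code{state}, \code{energy} and
#'   \code{pattern} (0/1 string), sorted by energy ascending.
#' @export
find_local_minima <- function(et) {
  stopifnot(inherits(et, "energy_table"))
  E <- et$energies
  nb <- neighbor_index_matrix(et$n_rois)
  nb_min <- apply(nb, 1L, function(idx) min(E[idx]))
  k <- which(E < nb_min)
  k <- k[order(E[k], k)]
  data.frame(state = k, energy = E[k],
             pattern = state_pattern(k, et$n_rois),
             stringsAsFactors = FALSE)
}

#' Basin of attraction of every state
#'
#' From each state, steepest descent moves to the lowest-energy neighbour
#' (ties broken by smallest state index) as long as that neighbour is
#' strictly lower, terminating at a local minimum. The resulting map sends
#' every state to the minimum of its basin and is the identity on minima.
#'
#' @param et An \code{energy_table}.
#' @return Integer vector of length \code{2^N}; entry \code{k} is the state
#'   index of the minimum reached from state \code{k}.
#' @export
assign_basins <- function(et) {
  stopifnot(inherits(et, "energy_table"))
  E <- et$energies
  n_states <- length(E)
  nb <- neighbor_index_matrix(et$n_rois)
  basin <- integer(n_states)
  # Process states by ascending energy (ties by index): the steepest-descent
  # target of a state always has strictly lower energy, hence is already
  # resolved when the state is reached.
  for (k in order(E, seq_len(n_states))) {
    nbk <- nb[k, ]
    e_nb <- E[nbk]
    best <- nbk[which.min(e_nb)]  # which.min takes the first = smallest index
    basin[k] <- if (E[best] < E[k]) basin[best] else k
  }
  basin
}

#' Minimax energy barrier between two states
#'
#' The barrier between states \code{a} and \code{b} is the smallest, over
#' all single-flip paths on the hypercube from \code{a} to \code{b}, of the
#' maximum state energy along the path (endpoints included) — the height
#' the system must reach to travel between the two attractors. Computed by
#' a Dijkstra-style label-setting search with the max-along-path cost, so
#' it is exact and symmetric in \code{(a, b)}.
#'
#' @param et An \code{energy_table}.
#' @param a,b State indices. Intended for local minima; other states are
#'   accepted for diagnostic use.
#' @return The barrier energy. \code{barrier(et, a, a)} is \code{E(a)}.
#' @export
barrier <- function(et, a, b) {
  minimax_distances(et, a)[b]
}

# Single-source minimax (widest-path) distances over the hypercube:
# dist[v] = min over paths a -> v of max state energy along the path.
minimax_distances <- function(et, a) {
  E <- et$energies
  n_states <- length(E)
  nb <- neighbor_index_matrix(et$n_rois)
  dist <- rep(Inf, n_states)
  dist[a] <- E[a]
  done <- logical(n_states)
  for (step in seq_len(n_states)) {
    u <- which.min(dist + ifelse(done, Inf, 0))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (v in nb[u, ]) {
      if (!done[v]) dist[v] <- min(dist[v], max(dist[u], E[v]))
    }
  }
  dist
}

# All pairwise barriers between the given states (rows of one Dijkstra run
# per source).
barrier_matrix <- function(et, states) {
  m <- length(states)
  B <- matrix(0, m, m, dimnames = list(states, states))
  for (i in seq_len(m)) {
    d <- minimax_distances(et, states[i])
    B[i, ] <- d[states]
  }
  # the minimax objective is symmetric; enforce exactly
  B <- pmin(B, t(B))
  diag(B) <- et$energies[states]
  B
}

#' Disconnectivity tree of the local minima
#'
#' Merges minima by ascending pairwise barrier (single linkage): the two
#' clusters with the lowest connecting barrier join first, at a node whose
#' height is that barrier energy. Leaves carry the minima and their
#' energies; because the barrier is a minimax objective the merge heights
#' are non-decreasing toward the root (an ultrametric), which is what makes
#' the tree drawable as the classic disconnectivity graph.
#'
#' @param et An \code{energy_table}.
#' @param minima Optional minima data frame (from [find_local_minima()]);
#'   computed if missing.
#' @return A nested list: leaves are
#'   \code{list(type = "leaf", state, energy, height = energy)}; internal
#'   nodes are \code{list(type = "node", height, children)}. A single
#'   minimum yields a single leaf.
#' @export
build_disconnectivity_tree <- function(et, minima = NULL) {
  stopifnot(inherits(et, "energy_table"))
  if (is.null(minima)) minima <- find_local_minima(et)
  if (nrow(minima) < 1L) stop("landscape has no local minima", call. = FALSE)
  nodes <- lapply(seq_len(nrow(minima)), function(i) {
    list(type = "leaf", state = minima$state[i], energy = minima$energy[i],
         height = minima$energy[i])
  })
  if (length(nodes) == 1L) return(nodes[[1L]])
  B <- barrier_matrix(et, minima$state)
  active <- seq_along(nodes)
  members <- as.list(seq_along(nodes))
  while (length(active) > 1L) {
    best <- c(NA_integer_, NA_integer_)
    best_h <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1L)) {
        a <- active[ii]; b <- active[jj]
        h <- min(B[members[[a]], members[[b]]])  # single linkage
        if (h < best_h) { best_h <- h; best <- c(a, b) }
      }
    }
    a <- best[1L]; b <- best[2L]
    merged <- list(type = "node", height = best_h,
                   children = list(nodes[[a]], nodes[[b]]))
    nodes[[a]] <- merged
    members[[a]] <- c(members[[a]], members[[b]])
    active <- setdiff(active, b)
  }
  nodes[[active]]
}

#' Serialise a disconnectivity tree as a Newick string
#'
#' Branch lengths encode energy drops: each child's branch length is its
#' parent's merge height minus its own height, so leaf depths reproduce the
#' minima energies relative to the root barrier. Leaves are labelled
#' \code{S<state index>}.
#'
#' @param tree A tree from [build_disconnectivity_tree()].
#' @return A Newick string (terminated by \code{";"}), readable by standard
#'   phylogenetics tools.
#' @export
tree_to_newick <- function(tree) {
  render <- function(node) {
    if (node$type == "leaf") sprintf("S%d", node$state)
    else {
      kids <- vapply(node$children, function(ch) {
        sprintf("%s:%.10g", render(ch), node$height - ch$height)
      }, character(1))
      sprintf("(%s)", paste(kids, collapse = ","))
    }
  }
  paste0(render(tree), ";")
}

#' Full energy-landscape analysis of a fitted model
#'
#' Convenience wrapper: computes the exact energy table (if given
#' parameters or a fit), the local minima, the basin map, all pairwise
#' minimax barriers between minima, and the disconnectivity tree.
#'
#' @param x A [mem_params()] object, a [fit_mem()] result, or an
#'   \code{energy_table}.
#' @return An object of class \code{energy_landscape} with components
#'   \code{energy_table}, \code{minima}, \code{basin_of}, \code{barriers}
#'   and \code{tree}.
#' @export
#' @examples
#' p <- mem_params(h = c(0, 0), J = matrix(c(0, 1, 1, 0), 2))
#' energy_landscape(p)$minima
energy_landscape <- function(x) {
  et <- if (inherits(x, "energy_table")) x
        else if (inherits(x, "mem_fit")) boltzmann(x$params)
        else if (inherits(x, "mem_params")) boltzmann(x)
        else stop("cannot build a landscape from class ",
                  paste(class(x), collapse = "/"), call. = FALSE)
  minima <- find_local_minima(et)
  structure(
    list(energy_table = et,
         minima = minima,
         basin_of = assign_basins(et),
         barriers = barrier_matrix(et, minima$state),
         tree = build_disconnectivity_tree(et, minima)),
    class = "energy_landscape"
  )
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat("Energy landscape over", length(x$energy_table$energies), "states\n")
  cat("  local minima (", nrow(x$minima), "):\n", sep = "")
  print(x$minima, row.names = FALSE)
  basin_sizes <- table(x$basin_of)
  cat("  basin sizes:",
      paste(sprintf("S%s=%d", names(basin_sizes), basin_sizes),
            collapse = ", "), "\n")
  invisible(x)
}

#' Plot a disconnectivity graph
#'
#' Minimal base-graphics rendering: leaves at the bottom (labelled by state
#' index, y = minimum energy), merges drawn at their barrier heights.
#'
#' @param x An \code{energy_landscape}.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the leaf coordinates.
#' @export
plot.energy_landscape <- function(x, ...) {
  segs <- list()
  leaves <- list()
  counter <- new.env()
  counter$i <- 0
  walk <- function(node) {
    if (node$type == "leaf") {
      counter$i <- counter$i + 1
      leaves[[length(leaves) + 1L]] <<- node
      c(x = counter$i, y = node$height)
    } else {
      pos <- lapply(node$children, walk)
      xs <- vapply(pos, `[[`, numeric(1), "x")
      ys <- vapply(pos, `[[`, numeric(1), "y")
      for (ii in seq_along(pos)) {
        segs[[length(segs) + 1L]] <<- c(xs[ii], ys[ii], xs[ii], node$height)
      }
      segs[[length(segs) + 1L]] <<- c(min(xs), node$height, max(xs), node$height)
      c(x = mean(range(xs)), y = node$height)
    }
  }
  walk(x$tree)
  leaf_y <- vapply(leaves, `[[`, numeric(1), "height")
  all_y <- c(leaf_y, unlist(lapply(segs, function(s) s[c(2, 4)])))
  graphics::plot(NA, xlim = c(0.5, length(leaves) + 0.5), ylim = range(all_y),
                 xlab = "local minimum", ylab = "energy", xaxt = "n", ...)
  for (s in segs) graphics::segments(s[1], s[2], s[3], s[4])
  lx <- seq_along(leaves)
  graphics::points(lx, leaf_y, pch = 19)
  graphics::axis(1, at = lx,
                 labels = vapply(leaves, function(l) sprintf("S%d", l$state),
                                 character(1)), las = 2)
  invisible(data.frame(x = lx,
                       state = vapply(leaves, function(l) l$state, numeric(1)),
                       energy = leaf_y))
}
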