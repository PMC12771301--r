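# Independent brute-force oracles, deliberately naive: plain loops and
# recursion, no shared code with the package internals they check.

# Energy by term-by-term evaluation of the double sum.
naive_energy <- function(sigma, h, J) {
  n <- length(sigma)
  e <- 0
  for (i in seq_len(n)) e <- e - h[i] * sigma[i]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i) e <- e - 0.5 * J[i, j] * sigma[i] * sigma[j]
    }
  }
  e
}

# All states as rows, matching the package's indexing convention.
naive_all_states <- function(n) {
  as.matrix(rev(expand.grid(rev(lapply(seq_len(n), function(i) c(-1, 1))))))
}

naive_boltzmann <- function(h, J) {
  S <- naive_all_states(length(h))
  E <- apply(S, 1, naive_energy, h = h, J = J)
  w <- exp(-E)
  w / sum(w)
}

# Hamming-1 neighbours of state index k (1-based), by flipping each spin of
# the explicit pattern.
naive_neighbors <- function(k, n) {
  S <- naive_all_states(n)
  sigma <- S[k, ]
  vapply(seq_len(n), function(i) {
    s2 <- sigma
    s2[i] <- -s2[i]
    which(apply(S, 1, function(row) all(row == s2)))
  }, integer(1))
}

# Local minima by exhaustive neighbour checks.
naive_minima <- function(E, n) {
  which(vapply(seq_along(E), function(k) {
    all(E[k] < E[naive_neighbors(k, n)])
  }, logical(1)))
}

# Basin by recursive steepest descent (ties: smallest state index).
naive_basin <- function(k, E, n) {
  nb <- naive_neighbors(k, n)
  e_nb <- E[nb]
  best <- nb[order(e_nb, nb)][1]
  if (E[best] < E[k]) naive_basin(best, E, n) else k
}

# Minimax barrier by exhaustive DFS over all simple hypercube paths.
naive_barrier <- function(a, b, E, n) {
  best <- Inf
  visited <- logical(length(E))
  dfs <- function(k, height) {
    height <- max(height, E[k])
    if (height >= best) return(invisible(NULL))  # bound: cannot improve
    if (k == b) { best <<- height; return(invisible(NULL)) }
    visited[k] <<- TRUE
    for (v in naive_neighbors(k, n)) if (!visited[v]) dfs(v, height)
    visited[k] <<- FALSE
    invisible(NULL)
  }
  dfs(a, -Inf)
  best
}

# Random parameters with entries uniform in [-scale, scale].
random_params <- function(n, scale = 0.5, roi_names = NULL) {
  h <- stats::runif(n, -scale, scale)
  J <- matrix(0, n, n)
  J[upper.tri(J)] <- stats::runif(n * (n - 1) / 2, -scale, scale)
  mem_params(h, J + t(J), roi_names)
}

upper_tri_values <- function(M) M[upper.tri(M)]
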