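#' Pairwise maximum-entropy model parameters
#'
#' Container for the parameters of a pairwise maximum-entropy (Ising) model
#' over N regions: a length-N bias vector \code{h} (one per region) and an
#' N x N symmetric coupling matrix \code{J} with zero diagonal. Energies are
#' dimensionless (inverse temperature absorbed into the parameters).
#'
#' @param h Numeric length-N vector of per-region biases.
#' @param J Numeric N x N symmetric matrix of pairwise couplings; the
#'   diagonal must be zero. A scalar 0 is expanded to a zero matrix.
#' @param roi_names Optional character vector of region labels.
#' @return An object of class \code{mem_params}.
#' @export
#' @examples
#' mem_params(h = c(0, 0), J = matrix(c(0, 0.5, 0.5, 0), 2))
mem_params <- function(h, J = 0, roi_names = NULL) {
  h <- as.numeric(h)
  n <- length(h)
  check_n_rois(n)
  if (length(J) == 1L && J == 0) J <- matrix(0, n, n)
  J <- as.matrix(J)
  if (!all(dim(J) == c(n, n))) {
    stop("J must be ", n, " x ", n, " to match h", call. = FALSE)
  }
  if (!all(is.finite(h)) || !all(is.finite(J))) {
    stop("model parameters must be finite", call. = FALSE)
  }
  if (max(abs(J - t(J))) > 1e-12) {
    stop("J must be symmetric (within 1e-12)", call. = FALSE)
  }
  if (any(diag(J) != 0)) {
    stop("J must have a zero diagonal", call. = FALSE)
  }
  J <- (J + t(J)) / 2
  if (is.null(roi_names)) {
    roi_names <- paste0("ROI", seq_len(n))
  }
  if (length(roi_names) != n) {
    stop("roi_names must have one entry per region", call. = FALSE)
  }
  dimnames(J) <- list(roi_names, roi_names)
  names(h) <- roi_names
  structure(list(h = h, J = J, roi_names = roi_names, n_rois = n),
            class = "mem_params")
}

#' @export
print.mem_params <- function(x, ...) {
  cat("Pairwise maximum-entropy model parameters\n")
  cat("  regions:", x$n_rois, paste0("(", paste(x$roi_names, collapse = ", "), ")"), "\n")
  cat("  h range: [", signif(min(x$h), 3), ",", signif(max(x$h), 3), "]\n")
  off <- x$J[upper.tri(x$J)]
  cat("  J off-diagonal range: [", signif(min(off), 3), ",", signif(max(off), 3), "]\n")
  invisible(x)
}

#' Shift selected pairwise couplings
#'
#' Returns a copy of \code{params} in which the couplings for the listed
#' region pairs are shifted by \code{delta} (applied to both \code{J[i, j]}
#' and \code{J[j, i]}, so symmetry is preserved). Used to inject a
#' controlled between-group connectivity difference, e.g. sign-flipping one
#' coupling to emulate an antagonistic pair in one group.
#'
#' @param params A [mem_params()] object.
#' @param edges A two-column matrix (or list of length-2 vectors) of region
#'   pairs, given as indices or region names.
#' @param delta Amount added to each listed coupling.
#' @return A new \code{mem_params} object.
#' @export
#' @examples
#' p <- mem_params(h = rep(0, 3), roi_names = c("A", "B", "C"))
#' perturb_couplings(p, list(c("A", "C")), delta = 0.8)$J
perturb_couplings <- function(params, edges, delta) {
  stopifnot(inherits(params, "mem_params"))
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must be pairs of regions", call. = FALSE)
  J <- params$J
  for (r in seq_len(nrow(edges))) {
    i <- edge_to_index(edges[r, 1L], params$roi_names)
    j <- edge_to_index(edges[r, 2L], params$roi_names)
    if (i == j) stop("self-couplings are not defined (zero diagonal)", call. = FALSE)
    J[i, j] <- J[i, j] + delta
    J[j, i] <- J[i, j]
  }
  mem_params(params$h, J, params$roi_names)
}

edge_to_index <- function(x, roi_names) {
  if (is.character(x)) {
    i <- match(x, roi_names)
    if (is.na(i)) stop("unknown region name: ", x, call. = FALSE)
    return(i)
  }
  i <- as.integer(x)
  if (is.na(i) || i < 1L || i > length(roi_names)) {
    stop("region index out of range: ", x, call. = FALSE)
  }
  i
}
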