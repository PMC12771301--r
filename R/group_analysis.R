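#' Per-subject state-energy matrix
#'
#' Evaluates every subject's fitted model on all \code{2^N} states, giving
#' the subjects x states matrix of energies that the per-state group tests
#' operate on. Subjects whose fits did not converge are excluded (with a
#' warning naming them) unless \code{include_unconverged = TRUE}.
#'
#' @param fits A list of [fit_mem()] results (typically named by subject).
#' @param include_unconverged Keep unconverged fits? Default \code{FALSE}.
#' @return A numeric matrix, one row per retained subject (named), one
#'   column per state index.
#' @export
per_subject_energy_matrix <- function(fits, include_unconverged = FALSE) {
  stopifnot(length(fits) >= 1L)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!include_unconverged && any(!conv)) {
    warning("excluding ", sum(!conv), " unconverged fit(s): ",
            paste(names(fits)[!conv], collapse = ", "), call. = FALSE)
    fits <- fits[conv]
    if (length(fits) == 0L) stop("no converged fits remain", call. = FALSE)
  }
  n <- fits[[1L]]$params$n_rois
  S <- enumerate_states(n)
  M <- t(vapply(fits, function(f) energy(S, f$params), numeric(nrow(S))))
  rownames(M) <- names(fits)
  M
}

#' Per-state two-sample t-tests between groups
#'
#' For each state, compares the two groups' subject energies with a
#' two-sided two-sample t-test — pooled-variance by default (degrees of
#' freedom \code{n_a + n_b - 2}), Welch by option. Degenerate states where
#' both groups have zero variance yield \code{t = 0, p = 1} when the means
#' agree (with a warning) and are flagged with \code{p = 0} otherwise.
#'
#' @param energies_a,energies_b Subjects x states energy matrices (columns
#'   must align), e.g. from [per_subject_energy_matrix()].
#' @param var_equal Pooled variance (\code{TRUE}, default) or Welch.
#' @return A data frame with columns \code{state}, \code{t}, \code{p},
#'   \code{mean_a}, \code{mean_b}, \code{median_a}, \code{median_b}.
#' @export
state_ttests <- function(energies_a, energies_b, var_equal = TRUE) {
  Ea <- as.matrix(energies_a)
  Eb <- as.matrix(energies_b)
  if (ncol(Ea) != ncol(Eb)) stop("state columns must align", call. = FALSE)
  na <- nrow(Ea); nb <- nrow(Eb)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 subjects", call. = FALSE)
  ma <- colMeans(Ea); mb <- colMeans(Eb)
  va <- apply(Ea, 2L, stats::var); vb <- apply(Eb, 2L, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t_stat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  zero_se <- se == 0
  if (any(zero_se)) {
    equal <- zero_se & (ma == mb)
    t_stat[equal] <- 0; p[equal] <- 1
    t_stat[zero_se & !equal] <- sign(ma - mb)[zero_se & !equal] * Inf
    p[zero_se & !equal] <- 0
    warning(sum(zero_se), " state(s) with zero pooled variance", call. = FALSE)
  }
  data.frame(state = seq_along(t_stat), t = t_stat, p = p,
             mean_a = ma, mean_b = mb,
             median_a = apply(Ea, 2L, stats::median),
             median_b = apply(Eb, 2L, stats::median))
}

#' Bonferroni-significant states
#'
#' Applies the per-state Bonferroni rule: a state is significant when its
#' p-value is strictly below \code{alpha / n_states} (for 7 regions,
#' 0.05 / 128). A p-value exactly at the threshold is excluded.
#'
#' @param pvals Per-state p-values (position = state index).
#' @param alpha Family-wise level in (0, 1).
#' @param n_states Number of tested states (defaults to
#'   \code{length(pvals)}).
#' @return Integer vector of significant state indices.
#' @export
bonferroni_select <- function(pvals, alpha = 0.05, n_states = length(pvals)) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  which(pvals < alpha / n_states)
}

#' Signature states: significant states that are landscape minima
#'
#' A Bonferroni-significant state only counts as a connectivity signature
#' if it is an attractor — a local minimum of at least one group's energy
#' landscape. States that are merely neighbours of a minimum (visited while
#' descending into it) are dropped. The provenance records which group's
#' landscape contributed each retained state.
#'
#' @param significant Integer vector of Bonferroni-significant states.
#' @param minima_a,minima_b State indices of each group's local minima.
#' @return A data frame with columns \code{state}, \code{in_minima_a},
#'   \code{in_minima_b} (zero rows if no signature states).
#' @export
select_signature_states <- function(significant, minima_a, minima_b) {
  keep <- intersect(significant, union(minima_a, minima_b))
  data.frame(state = sort(keep),
             in_minima_a = sort(keep) %in% minima_a,
             in_minima_b = sort(keep) %in% minima_b)
}

#' Per-state two-group comparison table
#'
#' Runs the full inferential stage: per-state t-tests on subject energies,
#' Bonferroni correction at \code{alpha / 2^N}, minimum flags from the two
#' group-level landscapes, and the signature-state rule (significant AND a
#' minimum of either group's landscape).
#'
#' @param energies_a,energies_b Subjects x states energy matrices.
#' @param minima_a,minima_b State indices of each group's local minima
#'   (from group-level landscapes).
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_rois Number of regions (for pattern strings); inferred from the
#'   number of states if missing.
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @return An object of class \code{group_comparison}: a data frame with
#'   one row per state (\code{state}, \code{pattern}, group means/medians,
#'   \code{t}, \code{p}, \code{bonferroni_significant},
#'   \code{is_minimum_a}, \code{is_minimum_b}, \code{signature}) with the
#'   significance level and threshold as attributes.
#' @export
compare_groups <- function(energies_a, energies_b, minima_a, minima_b,
                           alpha = 0.05, n_rois = NULL, var_equal = TRUE) {
  tt <- state_ttests(energies_a, energies_b, var_equal = var_equal)
  n_states <- nrow(tt)
  if (is.null(n_rois)) {
    n_rois <- as.integer(round(log2(n_states)))
    if (2L^n_rois != n_states) {
      stop("cannot infer n_rois from ", n_states, " states", call. = FALSE)
    }
  }
  sig <- bonferroni_select(tt$p, alpha, n_states)
  tab <- data.frame(
    state = tt$state,
    pattern = state_pattern(tt$state, n_rois),
    tt[, c("mean_a", "mean_b", "median_a", "median_b", "t", "p")],
    bonferroni_significant = tt$state %in% sig,
    is_minimum_a = tt$state %in% minima_a,
    is_minimum_b = tt$state %in% minima_b
  )
  tab$signature <- tab$bonferroni_significant &
    (tab$is_minimum_a | tab$is_minimum_b)
  structure(tab, alpha = alpha, threshold = alpha / n_states,
            class = c("group_comparison", "data.frame"))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Per-state group comparison:", nrow(x), "states, Bonferroni threshold",
      format(attr(x, "threshold"), digits = 4), "\n")
  cat("  significant:", sum(x$bonferroni_significant),
      "| signature (significant & minimum):", sum(x$signature), "\n")
  if (any(x$signature)) {
    print(as.data.frame(x)[x$signature,
                           c("state", "pattern", "mean_a", "mean_b", "t", "p")],
          row.names = FALSE)
  }
  invisible(x)
}
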