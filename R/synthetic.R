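#' Default seven-region ground-truth parameters
#'
#' A baseline pairwise maximum-entropy model over the seven networks used
#' throughout the package's examples: superior temporal gyrus (STG),
#' temporooccipital inferior temporal gyrus (toITG), primary visual cortex
#' (Vis.Primary), auditory network (AUD), Cerebellum, basal ganglia (BSL)
#' and thalamus (THL). Biases are zero; three moderate positive couplings
#' encode the structure the cohort generator emulates: correlated auditory
#' and temporal activity (AUD-STG), cerebellar-visual co-activation
#' (Cerebellum-Vis.Primary) and a cerebellum-toITG coupling that the
#' two-group generator sign-flips in one group to create an antagonistic
#' pair.
#'
#' @return A [mem_params()] object over 7 named regions.
#' @export
default_ground_truth <- function() {
  rois <- c("STG", "toITG", "Vis.Primary", "AUD", "Cerebellum", "BSL", "THL")
  p <- mem_params(h = rep(0, 7), roi_names = rois)
  p <- perturb_couplings(p, list(c("AUD", "STG")), delta = 0.5)
  p <- perturb_couplings(p, list(c("Cerebellum", "Vis.Primary")), delta = 0.5)
  perturb_couplings(p, list(c("Cerebellum", "toITG")), delta = 0.8)
}

#' Specify a synthetic two-group cohort
#'
#' Describes everything needed to generate a reproducible two-group cohort
#' of ROI time series with known ground-truth model parameters. By default
#' group A uses [default_ground_truth()] and group B the same model with
#' the Cerebellum-toITG coupling sign-flipped (+0.8 to -0.8), giving a
#' known, localised between-group difference for power and specificity
#' studies; pass \code{params_b = params_a} for a null cohort.
#'
#' @param params_a,params_b [mem_params()] for each group.
#' @param n_subjects_per_group Subjects per group (>= 2).
#' @param t_max Time points per subject (>= 2); default 300, a typical
#'   resting-state run length in volumes.
#' @param sampler \code{"metropolis"} (single-spin-flip chain; produces the
#'   temporally persistent sequences real scans show) or \code{"iid"}
#'   (exact independent draws from the Boltzmann distribution).
#' @param emission \code{"bold"} wraps the +-1 states in a continuous
#'   signal (see [states_to_bold()]) so binarization is exercised;
#'   \code{"binary"} returns the states themselves as the time series.
#' @param bold_amplitude,bold_noise_sd Signal amplitude and Gaussian noise
#'   standard deviation for the \code{"bold"} emission.
#' @param burn_in Discarded initial Metropolis steps.
#' @param seed Cohort master seed; per-subject seeds are derived from it
#'   deterministically.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(params_a = default_ground_truth(),
                        params_b = perturb_couplings(
                          params_a, list(c("Cerebellum", "toITG")), delta = -1.6),
                        n_subjects_per_group = 20L,
                        t_max = 300L,
                        sampler = c("metropolis", "iid"),
                        emission = c("bold", "binary"),
                        bold_amplitude = 1,
                        bold_noise_sd = 0.5,
                        burn_in = 1000L,
                        seed = 1L) {
  sampler <- match.arg(sampler)
  emission <- match.arg(emission)
  stopifnot(inherits(params_a, "mem_params"), inherits(params_b, "mem_params"))
  if (params_a$n_rois != params_b$n_rois ||
      !identical(params_a$roi_names, params_b$roi_names)) {
    stop("the two groups must share regions", call. = FALSE)
  }
  if (n_subjects_per_group < 2L) stop("need >= 2 subjects per group", call. = FALSE)
  if (t_max < 2L) stop("t_max must be >= 2", call. = FALSE)
  if (bold_amplitude <= 0 || bold_noise_sd < 0) {
    stop("bold_amplitude must be > 0 and bold_noise_sd >= 0", call. = FALSE)
  }
  structure(list(n_rois = params_a$n_rois,
                 roi_names = params_a$roi_names,
                 params_a = params_a, params_b = params_b,
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 t_max = as.integer(t_max),
                 sampler = sampler, emission = emission,
                 bold_amplitude = bold_amplitude,
                 bold_noise_sd = bold_noise_sd,
                 burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw independent states from the exact Boltzmann distribution
#'
#' Each time point is an independent draw over all \code{2^N} states with
#' the exact Boltzmann probabilities (enumeration, N <= 15).
#'
#' @param params A [mem_params()] object.
#' @param t_max Number of time points.
#' @param seed Integer seed (draws are reproducible).
#' @return A \code{state_sequence} of length \code{t_max}.
#' @export
sample_states_iid <- function(params, t_max, seed) {
  stopifnot(t_max >= 1L)
  et <- boltzmann(params)
  idx <- with_local_seed(seed,
    sample.int(length(et$probabilities), size = t_max, replace = TRUE,
               prob = et$probabilities))
  structure(as.integer(idx), n_rois = params$n_rois, class = "state_sequence")
}

#' Sample states with a single-spin-flip Metropolis chain
#'
#' A Markov chain whose stationary distribution is the model's Boltzmann
#' distribution: at each step one region is chosen uniformly at random and
#' its sign flipped with probability \code{min(1, exp(-dE))}. Rejected
#' proposals repeat the current state, so the chain produces dwell episodes
#' longer than one time point — the temporal persistence that
#' dwell-time analyses measure. The first \code{burn_in} steps are
#' discarded.
#'
#' @inheritParams sample_states_iid
#' @param burn_in Discarded initial steps (default 1000).
#' @return A \code{state_sequence} of length \code{t_max}.
#' @export
sample_states_metropolis <- function(params, t_max, seed, burn_in = 1000L) {
  stopifnot(t_max >= 1L, burn_in >= 0L)
  n <- params$n_rois
  h <- params$h
  J <- params$J
  total <- burn_in + t_max
  with_local_seed(seed, {
    sigma <- sample(c(-1, 1), n, replace = TRUE)
    flips <- sample.int(n, total, replace = TRUE)
    u <- stats::runif(total)
    weights <- 2^((n - 1L):0)
    word <- sum((sigma == 1) * weights)
    out <- integer(t_max)
    for (s in seq_len(total)) {
      i <- flips[s]
      dE <- 2 * sigma[i] * (h[i] + sum(J[, i] * sigma))
      if (dE <= 0 || u[s] < exp(-dE)) {
        sigma[i] <- -sigma[i]
        word <- if (sigma[i] == 1) word + weights[i] else word - weights[i]
      }
      if (s > burn_in) out[s - burn_in] <- word + 1L
    }
    structure(as.integer(out), n_rois = n, class = "state_sequence")
  })
}

#' Wrap a state sequence in a continuous BOLD-like signal
#'
#' Emits \code{amplitude * sigma_i(t) + noise} for each region and time
#' point (per-region baseline 0, so the time-average binarization threshold
#' is unbiased). With \code{noise_sd = 0} the downstream [binarize()] step
#' recovers the sequence exactly whenever each region visits both signs.
#'
#' @param seq A \code{state_sequence} (from the samplers or
#'   [to_state_sequence()]).
#' @param amplitude Signal amplitude (> 0).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed for the noise.
#' @param roi_names Optional column labels.
#' @return A t_max x N numeric matrix.
#' @export
states_to_bold <- function(seq, amplitude = 1, noise_sd = 0.5, seed = 1L,
                           roi_names = NULL) {
  stopifnot(amplitude > 0, noise_sd >= 0)
  n <- attr(seq, "n_rois")
  if (is.null(n)) stop("seq must be a state_sequence with n_rois", call. = FALSE)
  S <- index_to_state(as.integer(seq), n)
  if (is.null(dim(S))) S <- matrix(S, nrow = 1L)
  ts <- amplitude * S
  if (noise_sd > 0) {
    ts <- ts + with_local_seed(seed,
      matrix(stats::rnorm(length(ts), sd = noise_sd), nrow = nrow(ts)))
  }
  colnames(ts) <- if (is.null(roi_names)) paste0("ROI", seq_len(n)) else roi_names
  ts
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject state sequences from each group's ground-truth model
#' (independent sub-seeds derived deterministically from the cohort seed)
#' and applies the configured emission, yielding one time-series matrix per
#' subject plus the true state sequences for validation.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class \code{cohort}: \code{subjects} (a list with
#'   \code{id}, \code{group}, \code{seed}, \code{ts}), \code{spec} and
#'   \code{true_state_sequences} (named list).
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects_per_group = 2, t_max = 50))
#' dim(co$subjects[[1]]$ts)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- list(A = spec$params_a, B = spec$params_b)
  subjects <- list()
  true_seqs <- list()
  for (g in 1:2) {
    gname <- names(groups)[g]
    for (k in seq_len(spec$n_subjects_per_group)) {
      sseed <- subject_seed(spec$seed, g, k)
      seq <- switch(spec$sampler,
        iid = sample_states_iid(groups[[g]], spec$t_max, sseed),
        metropolis = sample_states_metropolis(groups[[g]], spec$t_max, sseed,
                                              burn_in = spec$burn_in))
      ts <- switch(spec$emission,
        binary = {
          S <- index_to_state(as.integer(seq), spec$n_rois)
          if (is.null(dim(S))) S <- matrix(S, nrow = 1L)
          colnames(S) <- spec$roi_names
          S * 1.0
        },
        bold = states_to_bold(seq, amplitude = spec$bold_amplitude,
                              noise_sd = spec$bold_noise_sd,
                              seed = sseed + 1L,
                              roi_names = spec$roi_names))
      id <- sprintf("%s%02d", gname, k)
      subjects[[id]] <- list(id = id, group = gname, seed = sseed, ts = ts)
      true_seqs[[id]] <- seq
    }
  }
  structure(list(subjects = subjects, spec = spec,
                 true_state_sequences = true_seqs),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, character(1), "group")
  cat("Synthetic cohort:", length(x$subjects), "subjects (",
      paste(sprintf("%s=%d", names(table(groups)), table(groups)),
            collapse = ", "), ")\n")
  cat("  regions:", paste(x$spec$roi_names, collapse = ", "), "\n")
  cat("  t_max:", x$spec$t_max, "| sampler:", x$spec$sampler,
      "| emission:", x$spec$emission, "\n")
  invisible(x)
}
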