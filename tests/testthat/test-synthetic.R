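test_that("iid sampling reproduces the exact Boltzmann distribution", {
  # uniform model: every state frequency within 3 standard errors of 1/8
  p0 <- mem_params(h = rep(0, 3))
  sq <- sample_states_iid(p0, 80000, seed = 1)
  freq <- tabulate(as.integer(sq), 8) / 80000
  se <- sqrt((1 / 8) * (7 / 8) / 80000)
  expect_true(all(abs(freq - 1 / 8) < 3 * se))

  # N = 2 coupled model: P(++) at its closed form
  p2 <- mem_params(h = c(0, 0), J = matrix(c(0, 0.5, 0.5, 0), 2))
  sq2 <- sample_states_iid(p2, 200000, seed = 2)
  p_pp <- exp(0.5) / (2 * exp(0.5) + 2 * exp(-0.5))
  expect_equal(mean(as.integer(sq2) == 4), p_pp, tolerance = 0.01)
})

test_that("samplers are deterministic given a seed", {
  p <- random_params(4, roi_names = letters[1:4])
  expect_identical(sample_states_iid(p, 100, seed = 42),
                   sample_states_iid(p, 100, seed = 42))
  expect_identical(sample_states_metropolis(p, 100, seed = 42),
                   sample_states_metropolis(p, 100, seed = 42))
  expect_false(identical(as.integer(sample_states_iid(p, 100, seed = 42)),
                         as.integer(sample_states_iid(p, 100, seed = 43))))
})

test_that("iid samples pass chi-squared goodness of fit for 19/20 seeds", {
  set.seed(77)
  p <- random_params(4)
  et <- boltzmann(p)
  pass <- vapply(1:20, function(s) {
    sq <- sample_states_iid(p, 4000, seed = 300 + s)
    counts <- tabulate(as.integer(sq), 16)
    suppressWarnings(
      stats::chisq.test(counts, p = et$probabilities)$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 19)
})

test_that("the Metropolis chain has the Boltzmann vector as stationary law", {
  # analytic single-spin-flip transition matrix, N = 3
  set.seed(12)
  p <- random_params(3, scale = 1)
  et <- boltzmann(p)
  n_states <- 8
  Tm <- matrix(0, n_states, n_states)
  for (k in seq_len(n_states)) {
    sigma <- index_to_state(k, 3)
    for (i in 1:3) {
      s2 <- sigma; s2[i] <- -s2[i]
      k2 <- state_index(s2)
      dE <- et$energies[k2] - et$energies[k]
      Tm[k, k2] <- (1 / 3) * min(1, exp(-dE))
    }
    Tm[k, k] <- 1 - sum(Tm[k, ])
  }
  pi_b <- et$probabilities
  expect_lt(max(abs(drop(pi_b %*% Tm) - pi_b)), 1e-10)
})

test_that("long Metropolis runs converge to the exact distribution (small KL)", {
  p <- random_params(3, scale = 0.6, roi_names = c("x", "y", "z"))
  et <- boltzmann(p)
  sq <- sample_states_metropolis(p, 1e5, seed = 99)
  freq <- tabulate(as.integer(sq), 8) / 1e5
  obs <- freq > 0
  kl <- sum(freq[obs] * (log(freq[obs]) - log(et$probabilities[obs])))
  expect_lt(kl, 0.01)
})

test_that("a flat landscape accepts every flip: all dwell episodes length 1", {
  p0 <- mem_params(h = rep(0, 4))
  sq <- sample_states_metropolis(p0, 2000, seed = 5)
  expect_true(all(rle(as.integer(sq))$lengths == 1))
})

test_that("a deep double well dwells longer under Metropolis than iid", {
  J <- matrix(1.5, 4, 4); diag(J) <- 0
  p <- mem_params(h = rep(0, 4), J = J)
  for (s in 1:3) {
    mx_metro <- max(rle(as.integer(
      sample_states_metropolis(p, 2000, seed = 50 + s)))$lengths)
    mx_iid <- max(rle(as.integer(
      sample_states_iid(p, 2000, seed = 50 + s)))$lengths)
    expect_gt(mx_metro, mx_iid)
  }
})

test_that("BOLD emission flips signs at the Gaussian tail rate", {
  p0 <- mem_params(h = rep(0, 2))
  sq <- sample_states_iid(p0, 20000, seed = 8)
  S <- index_to_state(as.integer(sq), 2)
  ts <- states_to_bold(sq, amplitude = 1, noise_sd = 1, seed = 9)
  flip_rate <- mean(sign(ts) != S)
  expect_equal(flip_rate, stats::pnorm(-1), tolerance = 0.01)
})

test_that("an all-active sequence emits a constant signal caught by the tie rule", {
  sq <- structure(rep(4L, 10), n_rois = 2L, class = "state_sequence")
  ts <- states_to_bold(sq, amplitude = 1, noise_sd = 0)
  expect_warning(b <- binarize(ts), "constant region")
  expect_true(all(b$values == -1L))
})

test_that("coupling perturbation is local, symmetric and delta = 0 is identity", {
  set.seed(30)
  p <- random_params(5, roi_names = c("STG", "toITG", "Vis", "AUD", "Cereb"))
  expect_equal(perturb_couplings(p, list(c(1, 3)), 0), p)
  q <- perturb_couplings(p, list(c("Cereb", "toITG")), -1.6)
  expect_equal(q$J["Cereb", "toITG"], p$J["Cereb", "toITG"] - 1.6)
  expect_equal(q$J, t(q$J))
  untouched <- upper_tri_values(q$J - p$J)
  expect_equal(sum(untouched != 0), 1)
  expect_error(perturb_couplings(p, list(c(2, 2)), 1), "self")
})

test_that("sign-flipping a coupling moves mass from aligned to anti-aligned", {
  p <- mem_params(h = rep(0, 4), roi_names = letters[1:4])
  p <- perturb_couplings(p, list(c("a", "b")), 0.8)
  q <- perturb_couplings(p, list(c("a", "b")), -1.6)  # +0.8 -> -0.8
  S <- enumerate_states(4)
  aligned <- S[, 1] * S[, 2] == 1
  mass_p <- sum(boltzmann(p)$probabilities[aligned])
  mass_q <- sum(boltzmann(q)$probabilities[aligned])
  expect_gt(mass_p, 0.5)
  expect_lt(mass_q, 0.5)
  expect_equal(mass_p + sum(boltzmann(p)$probabilities[!aligned]), 1)
})

test_that("cohorts have the declared shape and are bit-identical across calls", {
  spec <- cohort_spec(n_subjects_per_group = 2, t_max = 50, seed = 7)
  co <- generate_cohort(spec)
  expect_length(co$subjects, 4)
  for (s in co$subjects) expect_equal(dim(s$ts), c(50, 7))
  expect_equal(sort(unique(vapply(co$subjects, `[[`, character(1), "group"))),
               c("A", "B"))
  co2 <- generate_cohort(cohort_spec(n_subjects_per_group = 2, t_max = 50,
                                     seed = 7))
  expect_identical(co, co2)
})

test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec(n_subjects_per_group = 1), ">= 2 subjects")
  expect_error(cohort_spec(t_max = 1), "t_max")
  expect_error(cohort_spec(bold_noise_sd = -1), "bold_noise_sd")
  p3 <- mem_params(h = rep(0, 3))
  expect_error(cohort_spec(params_a = default_ground_truth(), params_b = p3),
               "share regions")
})
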