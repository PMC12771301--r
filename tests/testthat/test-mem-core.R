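test_that("energy reproduces closed forms and the naive double-sum oracle", {
  p0 <- mem_params(h = rep(0, 3))
  expect_equal(energy(enumerate_states(3), p0), rep(0, 8))

  p2 <- mem_params(h = c(0, 0), J = matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(energy(c(1, 1), p2), -0.5)
  expect_equal(energy(c(-1, -1), p2), -0.5)
  expect_equal(energy(c(1, -1), p2), 0.5)
  expect_equal(energy(c(-1, 1), p2), 0.5)

  set.seed(42)
  for (rep in 1:5) {
    p <- random_params(3, scale = 1)
    S <- enumerate_states(3)
    expect_equal(energy(S, p),
                 apply(S, 1, naive_energy, h = p$h, J = p$J))
  }
})

test_that("Boltzmann probabilities are exact, normalised and gauge invariant", {
  # uniform when all parameters vanish
  et <- boltzmann(mem_params(h = rep(0, 7)))
  expect_equal(et$probabilities, rep(1 / 128, 128))

  # N = 2 closed form
  p2 <- mem_params(h = c(0, 0), J = matrix(c(0, 0.5, 0.5, 0), 2))
  et2 <- boltzmann(p2)
  p_pp <- exp(0.5) / (2 * exp(0.5) + 2 * exp(-0.5))
  expect_equal(et2$probabilities[4], p_pp, tolerance = 1e-12)
  expect_equal(et2$probabilities[1], p_pp, tolerance = 1e-12)
  expect_equal(sum(et2$probabilities), 1, tolerance = 1e-10)

  # probability order is the reverse of energy order
  set.seed(7)
  p <- random_params(4)
  et4 <- boltzmann(p)
  expect_equal(order(et4$probabilities), rev(order(et4$energies)))

  # adding a constant to all energies leaves the distribution unchanged:
  # realised by an explicit softmax of shifted energies
  shifted <- exp(-(et4$energies + 100 - min(et4$energies + 100)))
  expect_equal(et4$probabilities, shifted / sum(shifted), tolerance = 1e-12)
})

test_that("log-likelihood matches the uniform closed form and a direct product", {
  B <- matrix(sample(c(-1, 1), 60, replace = TRUE), ncol = 3)
  p0 <- mem_params(h = rep(0, 3))
  expect_equal(log_likelihood(p0, B), -20 * 3 * log(2))

  set.seed(11)
  p <- random_params(3)
  Btoy <- index_to_state(c(1, 5, 5, 8, 2), 3)
  probs <- naive_boltzmann(p$h, p$J)
  expect_equal(log_likelihood(p, Btoy),
               sum(log(probs[c(1, 5, 5, 8, 2)])))
})

test_that("a balanced design with vanishing moments fits to h = 0, J = 0", {
  B <- enumerate_states(3)  # every state once: all moments exactly zero
  fit <- fit_mem(B)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$h)), 1e-4)
  expect_lt(max(abs(fit$params$J)), 1e-4)
})

test_that("every converged fit satisfies moment matching, recomputed independently", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    p <- random_params(n)
    sq <- sample_states_iid(p, 500, seed = 1000 + rep)
    B <- index_to_state(as.integer(sq), n)
    fit <- fit_mem(B)
    expect_true(fit$converged)
    # recompute both moment sets from scratch
    emp1 <- colMeans(B)
    mod <- boltzmann(fit$params)
    S <- enumerate_states(n)
    mod1 <- colSums(S * mod$probabilities)
    expect_lt(max(abs(emp1 - mod1)), 1e-5)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        emp2 <- mean(B[, i] * B[, j])
        mod2 <- sum(S[, i] * S[, j] * mod$probabilities)
        expect_lt(abs(emp2 - mod2), 1e-5)
      }
    }
  }
})

test_that("gradient-ascent and Newton fits agree", {
  set.seed(5)
  p <- random_params(4)
  B <- index_to_state(as.integer(sample_states_iid(p, 800, seed = 3)), 4)
  f1 <- fit_mem(B, method = "newton")
  f2 <- fit_mem(B, method = "gradient")
  expect_true(f1$converged && f2$converged)
  expect_lt(max(abs(f1$params$h - f2$params$h)), 1e-3)
  expect_lt(max(abs(f1$params$J - f2$params$J)), 1e-3)
})

test_that("N = 2 fit agrees with a dense likelihood grid search", {
  # toy matrix with all four states present (the 2-spin pairwise model is
  # saturated, so an unobserved state would push the optimum to infinity)
  B <- index_to_state(c(1, 2, 3, 4, 4, 1), 2)
  fit <- fit_mem(B)
  best <- c(NA, NA, NA); best_ll <- -Inf
  grid <- seq(-1.5, 1.5, by = 0.05)
  for (h1 in grid) for (h2 in grid) for (j in grid) {
    p <- mem_params(c(h1, h2), matrix(c(0, j, j, 0), 2))
    ll <- log_likelihood(p, B)
    if (ll > best_ll) { best_ll <- ll; best <- c(h1, h2, j) }
  }
  expect_equal(unname(fit$params$h), best[1:2], tolerance = 0.05)
  expect_equal(fit$params$J[1, 2], best[3], tolerance = 0.05)
})

test_that("fits transform covariantly under global sign flip and region permutation", {
  set.seed(21)
  p <- random_params(4)
  B <- index_to_state(as.integer(sample_states_iid(p, 600, seed = 9)), 4)
  fit <- fit_mem(B)

  fit_neg <- fit_mem(-B)
  expect_equal(fit_neg$params$h, -fit$params$h, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(fit_neg$params$J, fit$params$J, tolerance = 1e-4,
               ignore_attr = TRUE)

  perm <- c(3, 1, 4, 2)
  fit_perm <- fit_mem(B[, perm])
  expect_equal(unname(fit_perm$params$h), unname(fit$params$h[perm]),
               tolerance = 1e-4)
  expect_equal(unname(fit_perm$params$J), unname(fit$params$J[perm, perm]),
               tolerance = 1e-4)
})

test_that("degenerate data (a region that never changes sign) is handled", {
  set.seed(8)
  B <- cbind(rep(1, 50), sample(c(-1, 1), 50, replace = TRUE))
  # the unpenalised optimum sits at infinity; the moment-gap stopping rule
  # halts at an extreme but finite bias rather than iterating forever
  fit <- fit_mem(B)
  expect_gt(fit$params$h[1], 5)
  # the optional ridge keeps the estimate finite and moderate, and the
  # penalty is recorded in the report
  fit_l2 <- fit_mem(B, l2 = 0.01)
  expect_true(fit_l2$converged)
  expect_equal(fit_l2$l2, 0.01)
  expect_lt(fit_l2$params$h[1], fit$params$h[1])
})

test_that("hitting the iteration cap is reported, never silent", {
  set.seed(9)
  B <- index_to_state(as.integer(sample_states_iid(random_params(3), 200,
                                                   seed = 2)), 3)
  fit <- fit_mem(B, max_iter = 1L, method = "gradient")
  expect_false(fit$converged)
  expect_equal(fit$iterations, 1L)
})

test_that("fit diagnostics compare the model against the independent baseline", {
  set.seed(33)
  p <- mem_params(h = c(0, 0, 0),
                  J = {J <- matrix(0, 3, 3); J[1, 2] <- J[2, 1] <- 1; J})
  B <- index_to_state(as.integer(sample_states_iid(p, 2000, seed = 4)), 3)
  fit <- fit_mem(B)
  # strongly coupled data: pairwise model must beat the independent one
  expect_lt(fit$kl_model, fit$kl_independent)
  expect_gt(fit$fit_accuracy, 0.9)
})
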