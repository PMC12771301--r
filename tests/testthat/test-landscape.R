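test_that("separable and ferromagnetic landscapes have the known minima", {
  # positive biases, no couplings: unique minimum all-active at energy -3
  l1 <- energy_landscape(mem_params(h = c(1, 1, 1)))
  expect_equal(l1$minima$state, 8)
  expect_equal(l1$minima$energy, -3)
  expect_true(all(l1$basin_of == 8))

  # uniform ferromagnet: exactly the two fully aligned minima
  J <- matrix(1, 4, 4); diag(J) <- 0
  l2 <- energy_landscape(mem_params(h = rep(0, 4), J = J))
  expect_equal(sort(l2$minima$state), c(1, 16))
  expect_equal(l2$minima$energy, c(-6, -6))
})

test_that("minima are idempotent under the basin map", {
  set.seed(60)
  for (rep in 1:5) {
    et <- boltzmann(random_params(4))
    mins <- find_local_minima(et)$state
    basin <- assign_basins(et)
    expect_equal(basin[mins], mins)
    expect_true(all(basin %in% mins))
  }
})

test_that("minima, basins and barriers match brute-force oracles on random landscapes", {
  set.seed(61)
  for (rep in 1:12) {
    p <- random_params(4, scale = 1)
    et <- boltzmann(p)
    E <- et$energies

    mins <- find_local_minima(et)
    expect_equal(mins$state, naive_minima(E, 4)[order(E[naive_minima(E, 4)])])

    basin <- assign_basins(et)
    expect_equal(basin,
                 vapply(1:16, naive_basin, integer(1), E = E, n = 4))

    states <- mins$state
    for (a in states) {
      for (b in states) {
        expect_equal(barrier(et, a, b), naive_barrier(a, b, E, 4))
      }
    }
  }
})

test_that("the N = 2 barrier has its closed form and barrier(a, a) = E(a)", {
  p <- mem_params(h = c(0, 0), J = matrix(c(0, 1, 1, 0), 2))
  et <- boltzmann(p)
  mins <- find_local_minima(et)$state
  expect_equal(sort(mins), c(1, 4))  # (--) and (++), energy -1 each
  expect_equal(barrier(et, 1, 4), 1)  # via either mixed state of energy +1
  expect_equal(barrier(et, 1, 1), et$energies[1])
  expect_equal(barrier(et, 4, 4), et$energies[4])
})

test_that("barriers are symmetric and bounded below by the endpoint energies", {
  set.seed(62)
  et <- boltzmann(random_params(5))
  mins <- find_local_minima(et)$state
  B <- elascape:::barrier_matrix(et, mins)
  expect_equal(B, t(B))
  for (i in seq_along(mins)) {
    for (j in seq_along(mins)) {
      expect_gte(B[i, j] + 1e-12,
                 max(et$energies[mins[i]], et$energies[mins[j]]))
    }
  }
})

test_that("disconnectivity trees have the right shape and ultrametric heights", {
  # one minimum -> a single leaf
  l1 <- energy_landscape(mem_params(h = c(1, 1, 1)))
  expect_equal(l1$tree$type, "leaf")
  expect_equal(l1$tree$state, 8)

  # two minima with barrier beta -> root at height beta
  p <- mem_params(h = c(0, 0), J = matrix(c(0, 1, 1, 0), 2))
  l2 <- energy_landscape(p)
  expect_equal(l2$tree$type, "node")
  expect_equal(l2$tree$height, 1)
  expect_setequal(vapply(l2$tree$children, `[[`, numeric(1), "state"), c(1, 4))

  # merge heights never decrease toward the root, leaves = minima
  set.seed(63)
  for (rep in 1:10) {
    l <- energy_landscape(random_params(4, scale = 1))
    leaves <- integer(0)
    check <- function(node, parent_height) {
      expect_lte(node$height, parent_height + 1e-12)
      if (node$type == "leaf") leaves <<- c(leaves, node$state)
      else for (ch in node$children) check(ch, node$height)
    }
    check(l$tree, Inf)
    expect_setequal(leaves, l$minima$state)
  }
})

test_that("probability rank of minima is the exact reverse of energy rank", {
  set.seed(64)
  for (rep in 1:5) {
    et <- boltzmann(random_params(5))
    mins <- find_local_minima(et)
    pr <- et$probabilities[mins$state]
    expect_equal(order(mins$energy), order(pr, decreasing = TRUE))
  }
})

test_that("the Newick serialisation is well formed and preserves leaf depths", {
  skip_if_not_installed("ape")
  set.seed(66)
  repeat {  # draw until the landscape has several minima (deterministic)
    l <- energy_landscape(random_params(4, scale = 1))
    if (nrow(l$minima) >= 2) break
  }
  phy <- ape::read.tree(text = tree_to_newick(l$tree))
  expect_equal(sort(phy$tip.label), sort(sprintf("S%d", l$minima$state)))
  # leaf depth below the root = root barrier height - minimum energy
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expected <- l$tree$height -
    l$minima$energy[match(phy$tip.label, sprintf("S%d", l$minima$state))]
  expect_equal(depths, expected, tolerance = 1e-8)
})

test_that("landscape output is deterministic", {
  p <- random_params(4, scale = 1)
  expect_identical(energy_landscape(p), energy_landscape(p))
})
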