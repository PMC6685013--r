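test_that("a branchless linear run reduces to the closed-form growth law", {
  sys <- simulate_root_system(growth_parameters(g = 1),
                              uniform_branching(0), times = c(2, 5),
                              law = "linear", seed = 1)
  expect_equal(vapply(sys$snapshots, `[[`, numeric(1), "primary_length"),
               c(2, 5))
  expect_true(all(vapply(sys$snapshots,
                         function(s) nrow(s$branches), integer(1)) == 0L))
})

test_that("simulation is reproducible under a fixed seed", {
  args <- list(growth_parameters(0.49, 20, 0.2), uniform_branching(0.6),
               times = c(5, 15))
  s1 <- do.call(simulate_root_system, c(args, seed = 99))
  s2 <- do.call(simulate_root_system, c(args, seed = 99))
  expect_identical(s1, s2)
})

test_that("primary growth in the simulator agrees with the elongation oracle", {
  sys <- simulate_root_system(growth_parameters(0.49, l_max = 1e6),
                              uniform_branching(0.3), times = 15, seed = 4)
  expect_equal(sys$snapshots[[1]]$primary_length,
               elongate(15, 0.49, l_max = 1e6), tolerance = 1e-10)
  # at alpha = 1 a lateral elongates exactly like a same-age primary
  sys2 <- simulate_root_system(growth_parameters(0.5, 20, alpha = 1),
                               uniform_branching(0.5), times = 12, seed = 5)
  br <- sys2$snapshots[[1]]$branches
  expect_gt(nrow(br), 0)
  expect_equal(br$length, elongate(12 - br$t_init, 0.5, 20))
})

test_that("uniform branching counts are Poisson(bT) in mean and variance", {
  set.seed(6)
  n <- 4000; b <- 0.6; horizon <- 15
  counts <- replicate(n, {
    s <- simulate_root_system(growth_parameters(0.5, 20, 0),
                              uniform_branching(b), times = horizon)
    nrow(s$snapshots[[1]]$branches)
  })
  lam <- b * horizon
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / n))
  se_var <- sqrt((lam + 2 * lam^2) / n)   # approx se of the sample variance
  expect_lt(abs(var(counts) - lam), 3 * se_var)
})

test_that("minimum-separation branches are pairwise at least delta apart", {
  for (seed in 1:30) {
    s <- simulate_root_system(growth_parameters(0.8, 20, 0),
                              min_separation_branching(b = 1.2, delta = 0.5),
                              times = 15, seed = seed)
    pos <- s$snapshots[[1]]$branches$position
    if (length(pos) > 1)
      expect_gte(min(dist(pos)), 0.5)
  }
})

test_that("fixed-spacing branches sit on exact multiples of d, capped at b_max", {
  s <- simulate_root_system(growth_parameters(1, 30, 0.2),
                            fixed_spacing_branching(d = 0.9, b_max = 5),
                            times = 15, seed = 7)
  pos <- s$snapshots[[1]]$branches$position
  expect_lte(length(pos), 5)
  expect_equal(pos, 0.9 * seq_along(pos))
  # emergence time is when the tip first reaches the branch position
  expect_equal(s$snapshots[[1]]$branches$t_init,
               time_to_length(pos, 1, 30))
})

test_that("snapshots are cumulative and lengths non-decreasing in time", {
  s <- simulate_root_system(growth_parameters(0.6, 15, 0.3),
                            uniform_branching(0.8),
                            times = c(3, 7, 11, 15), seed = 8)
  prim <- vapply(s$snapshots, `[[`, numeric(1), "primary_length")
  expect_true(all(diff(prim) > 0))
  nb <- vapply(s$snapshots, function(x) nrow(x$branches), integer(1))
  expect_true(all(diff(nb) >= 0))
  for (k in 2:4) {
    prev <- s$snapshots[[k - 1]]$branches
    cur <- s$snapshots[[k]]$branches
    # earlier branches persist with identical positions and longer laterals
    expect_equal(cur$position[seq_len(nrow(prev))], prev$position)
    expect_true(all(cur$length[seq_len(nrow(prev))] >= prev$length))
  }
})

test_that("simulation requests are validated", {
  g <- growth_parameters(1); b <- uniform_branching(0.5)
  expect_error(simulate_root_system(g, b, times = numeric()), "strictly")
  expect_error(simulate_root_system(g, b, times = c(5, 2)), "strictly")
  expect_error(simulate_root_system(g, b, times = c(0, 2)), "strictly")
})
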