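test_that("zero variability makes all plants identical", {
  spec <- fixture_spec("clone", law = "negative_exponential", g = 0.5,
                       l_max = 20, lateral_rate = 0.1,
                       branching = fixed_spacing_branching(0.3, 40),
                       growth_cv = 0, spacing_cv = 0, n_plants = 3,
                       days = c(5, 10))
  fx <- make_fixture(spec, seed = 51)
  obs <- fx$observations
  for (d in c(5, 10)) {
    rows <- obs[obs$day == d, -1]
    expect_true(all(apply(rows, 2, function(x) diff(range(x)) == 0)))
  }
  expect_true(all(fx$truth$per_plant$g == 0.5))
})

test_that("the Arabidopsis preset realises the stated mean rates", {
  fx <- make_fixture(arabidopsis_fixture_spec(n_plants = 300), seed = 52)
  expect_lt(abs(mean(fx$truth$per_plant$g) - 0.49), 0.01)
  expect_lt(abs(mean(fx$truth$per_plant$lateral_rate) - 0.08), 0.005)
  expect_lt(abs(sd(fx$truth$per_plant$g) / 0.49 - 0.1), 0.02)
  # generative record travels with the data
  expect_equal(fx$truth$g, 0.49)
  expect_equal(fx$truth$branching$d, 0.2)
})

test_that("the Lupinus preset spaces laterals at 0.9 cm on average", {
  # look at realised gaps directly through the simulator the preset uses
  set.seed(53)
  gaps <- unlist(lapply(1:200, function(i) {
    s <- simulate_root_system(growth_parameters(1, 30, 0.2),
                              fixed_spacing_branching(0.9, 50,
                                                      spacing_cv = 0.45),
                              times = 15)
    diff(c(0, s$snapshots[[1]]$branches$position))
  }))
  # mean gap: 0.9 times the mean of a zero-truncated unit Gaussian factor
  expect_lt(abs(mean(gaps) - 0.9) / 0.9, 0.05)
  expect_lt(abs(sd(gaps) / mean(gaps) - 0.45), 0.05)
  fx <- make_fixture(lupinus_fixture_spec(), seed = 54)
  expect_equal(fx$truth$g, 1)
  expect_equal(fx$truth$branching$d, 0.9)
})

test_that("fixture datasets are deterministic given spec and seed", {
  spec <- arabidopsis_fixture_spec(n_plants = 2)
  expect_identical(make_fixture(spec, seed = 55), make_fixture(spec, seed = 55))
})

test_that("phenotype pairs scale the primary rate as requested", {
  spec <- fixture_spec("wt", law = "linear", g = 0.8, lateral_rate = 0.2,
                       branching = fixed_spacing_branching(0.5, 30),
                       growth_cv = 0, spacing_cv = 0, n_plants = 2,
                       days = 10)
  pair <- make_phenotype_pair(spec, reduced_g_factor = 0.5, seed = 56)
  wt <- pair$wild_type$observations
  mut <- pair$mutant$observations
  # linear law: primary length at day 10 exactly halves
  expect_equal(mut$primary_length_cm, wt$primary_length_cm / 2)
  expect_equal(pair$mutant$truth$g, 0.4)
  # a factor of 1 reproduces the wild type exactly (no plant noise here)
  same <- make_phenotype_pair(spec, reduced_g_factor = 1, seed = 56)
  expect_equal(same$mutant$observations, same$wild_type$observations)
})

test_that("inference separates a reduced-growth phenotype from the wild type", {
  spec <- fixture_spec("wt", law = "linear", g = 0.8, lateral_rate = 0.24,
                       branching = uniform_branching(0.3),
                       growth_cv = 0, n_plants = 1, days = c(4, 8, 12))
  pair <- make_phenotype_pair(spec, reduced_g_factor = 0.5, seed = 57)
  mod <- linear_test_model()
  fit_wt <- abc_smc(pair$wild_type$observations, mod,
                    schedule = tolerance_schedule(1), n_particles = 100,
                    seed = 58)
  fit_mut <- abc_smc(pair$mutant$observations, mod,
                     schedule = tolerance_schedule(1), n_particles = 100,
                     seed = 59)
  ci_wt <- posterior_summary(fit_wt)
  ci_mut <- posterior_summary(fit_mut)
  # non-overlapping 95% credible intervals for g
  expect_gt(ci_wt[ci_wt$parameter == "g", "lower"],
            ci_mut[ci_mut$parameter == "g", "upper"])
})
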