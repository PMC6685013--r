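test_that("with an infinite tolerance the rejection posterior is the prior", {
  fx <- linear_test_fixture(seed = 31)
  mod <- linear_test_model()
  rej <- abc_rejection(fx$observations, mod, epsilon = 1e9, n_accept = 500,
                       seed = 32)
  expect_identical(rej$attempts, 500)
  for (p in c("g", "b")) {
    ks <- suppressWarnings(ks.test(rej$theta[, p], "punif", 0, 1.4))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("the first SMC population matches rejection ABC at the same tolerance", {
  fx <- linear_test_fixture(seed = 33)
  mod <- linear_test_model()
  eps <- 4
  rej <- abc_rejection(fx$observations, mod, epsilon = eps, n_accept = 300,
                       seed = 34)
  fit <- abc_smc(fx$observations, mod, schedule = eps, n_particles = 300,
                 seed = 35)
  pop <- fit$populations[[1]]
  for (p in c("g", "b")) {
    ks <- suppressWarnings(ks.test(rej$theta[, p], pop[[p]]))
    expect_gt(ks$p.value, 0.01)
  }
  # population-0 weights are uniform (normalised within the single model)
  expect_equal(pop$weight, rep(1 / 300, 300))
})

test_that("SMC populations respect tolerances, weights and the prior box", {
  fx <- linear_test_fixture(seed = 36)
  mod <- linear_test_model()
  fit <- abc_smc(fx$observations, mod, schedule = c(5, 3, 2),
                 n_particles = 200, seed = 37)
  for (t in seq_along(fit$schedule)) {
    pop <- fit$populations[[t]]
    expect_true(all(pop$distance < fit$schedule[t]))
    expect_equal(sum(pop$weight), 1)
    expect_true(all(pop$g > 0 & pop$g < 1.4 & pop$b > 0 & pop$b < 1.4))
  }
})

test_that("two identical competing models share the posterior evenly", {
  fx <- linear_test_fixture(seed = 38)
  m1 <- root_model("linear", "uniform",
                   priors = abc_priors(g = c(0, 1.4), b = c(0, 1.4)),
                   fixed = list(alpha = 0.3), name = "copy1")
  m2 <- root_model("linear", "uniform",
                   priors = abc_priors(g = c(0, 1.4), b = c(0, 1.4)),
                   fixed = list(alpha = 0.3), name = "copy2")
  fit <- abc_smc(fx$observations, list(m1, m2), schedule = c(5, 3),
                 n_particles = 300, seed = 39)
  probs <- model_probabilities(fit)[2, ]
  expect_lt(abs(probs["copy1"] - 0.5), 0.1)
  expect_equal(sum(probs), 1)
  # weights normalise within each model
  pop <- fit$populations[[2]]
  for (m in c("copy1", "copy2"))
    expect_equal(sum(pop$weight[pop$model == m]), 1)
})

test_that("acceptance gets harder as the tolerance shrinks", {
  fx <- linear_test_fixture(seed = 40)
  mod <- linear_test_model()
  loose <- abc_rejection(fx$observations, mod, epsilon = 6, n_accept = 100,
                         seed = 41)
  tight <- abc_rejection(fx$observations, mod, epsilon = 1.5, n_accept = 100,
                         seed = 41)
  expect_gt(tight$attempts, loose$attempts)
})

test_that("an unreachable tolerance raises a non-convergence error naming it", {
  fx <- linear_test_fixture(seed = 42)
  mod <- linear_test_model()
  expect_error(abc_rejection(fx$observations, mod, epsilon = 1e-9,
                             n_accept = 5, max_attempts = 300, seed = 43),
               "epsilon = 1e-09")
  expect_error(abc_smc(fx$observations, mod, schedule = c(2, 1e-9),
                       n_particles = 5, max_attempts = 500, seed = 44),
               "did not converge")
})

test_that("posterior summaries equal their brute-force definitions", {
  # hand-built two-particle fit object
  pop <- data.frame(population = 1, model = "m",
                    g = c(0.4, 0.8), weight = c(0.5, 0.5), distance = 0)
  fake <- structure(list(
    populations = list(pop),
    model_probabilities = matrix(1, 1, 1, dimnames = list(NULL, "m")),
    models = list(m = root_model("linear", "uniform",
                                 priors = abc_priors(g = c(0, 1.4)),
                                 fixed = list(b = 0.1, alpha = 0),
                                 name = "m")),
    schedule = 1, n_particles = 2), class = "root_abc")
  ps <- posterior_summary(fake)
  expect_equal(ps$mean, 0.6)
  expect_equal(ps$sd, 0.2)
  single <- fake
  single$populations[[1]] <- pop[1, ]
  ps1 <- posterior_summary(single)
  expect_equal(ps1$mean, 0.4)
  expect_equal(ps1$sd, 0)
  # weighted mean from a real fit equals sum(w * theta) / sum(w)
  fx <- linear_test_fixture(seed = 45)
  fit <- abc_smc(fx$observations, linear_test_model(), schedule = c(4, 2.5),
                 n_particles = 150, seed = 46)
  pop2 <- fit$populations[[2]]
  expect_equal(coef(fit)[["g"]], sum(pop2$weight * pop2$g) / sum(pop2$weight))
  expect_error(posterior_summary(fit, model = "absent"), "absent")
})

test_that("the weighted histogram mode tracks the heaviest bin", {
  pop <- data.frame(population = 1, model = "m",
                    g = c(0.1, 0.52, 0.5, 0.51, 0.9),
                    weight = c(0.05, 0.3, 0.3, 0.3, 0.05), distance = 0)
  fake <- structure(list(
    populations = list(pop),
    model_probabilities = matrix(1, 1, 1, dimnames = list(NULL, "m")),
    models = list(m = root_model("linear", "uniform",
                                 priors = abc_priors(g = c(0, 1.4)),
                                 fixed = list(b = 0.1, alpha = 0),
                                 name = "m")),
    schedule = 1, n_particles = 5), class = "root_abc")
  expect_lt(abs(posterior_mode(fake, "g", bins = 10) - 0.51), 0.06)
})

test_that("known generative rates are recovered across seeded repeats", {
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    fx <- linear_test_fixture(seed = 100 + r)
    fit <- abc_smc(fx$observations, linear_test_model(),
                   schedule = tolerance_schedule(1), n_particles = 100,
                   seed = 200 + r)
    ps <- posterior_summary(fit)
    g_row <- ps[ps$parameter == "g", ]
    if (g_row$lower <= 0.7 && 0.7 <= g_row$upper) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_rep)
})
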