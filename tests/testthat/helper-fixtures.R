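# Shared helpers for building small deterministic test inputs.

# hand-built snapshot, bypassing the simulator
make_snapshot <- function(time, primary_length, lengths = numeric(),
                          positions = seq_along(lengths)) {
  structure(list(time = time, primary_length = primary_length,
                 branches = data.frame(position = positions,
                                       t_init = rep(0, length(lengths)),
                                       length = lengths)),
            class = "root_snapshot")
}

# observation table built directly from (plant, day, B, L, l_hat) rows
make_obs <- function(...) {
  rows <- list(...)
  as_root_observations(do.call(rbind, lapply(rows, function(r)
    data.frame(plant_id = r[[1]], day = as.numeric(r[[2]]),
               n_branches = as.numeric(r[[3]]),
               primary_length_cm = as.numeric(r[[4]]),
               mean_lateral_length_cm = as.numeric(r[[5]])))))
}

# small linear-growth recovery setup shared by inference tests: one plant,
# exactly known generative parameters, no plant-to-plant noise
linear_test_fixture <- function(seed, g = 0.7, b = 0.3, alpha = 0.3,
                                days = c(4, 8, 12)) {
  spec <- fixture_spec("linear-test", law = "linear", g = g,
                       lateral_rate = alpha * g,
                       branching = uniform_branching(b),
                       growth_cv = 0, n_plants = 1L, days = days)
  make_fixture(spec, seed = seed)
}

linear_test_model <- function(alpha = 0.3) {
  root_model("linear", "uniform",
             priors = abc_priors(g = c(0, 1.4), b = c(0, 1.4)),
             fixed = list(alpha = alpha))
}
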