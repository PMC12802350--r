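test_that("noiseless simulation reproduces the model exactly", {
  g <- noiseless_grid("noncompetitive")
  mu <- predict_rate(g$substrate_uM, g$inhibitor_uM, ref_params,
                     "noncompetitive")
  expect_identical(g$rate, mu)
  expect_false(attr(g, "noisy"))
  expect_equal(attr(g, "metadata")$mode, "noncompetitive")
})

test_that("simulation is seed-deterministic without touching the global RNG", {
  d <- simulation_design(seed = 123)
  set.seed(555)
  before <- .Random.seed
  g1 <- simulate_rate_grid(ref_params, "noncompetitive", d)
  expect_identical(.Random.seed, before)  # global stream untouched
  g2 <- simulate_rate_grid(ref_params, "noncompetitive", d)
  expect_identical(g1$rate, g2$rate)      # bit-exact repeat in-process
  g3 <- simulate_rate_grid(ref_params, "noncompetitive",
                           simulation_design(seed = 124))
  expect_false(identical(g1$rate, g3$rate))
})

test_that("proportional noise realizes the requested coefficient of variation", {
  d <- simulation_design(substrate_levels = 100, inhibitor_levels = c(0, 0.5),
                         replicates = 1000, noise_type = "proportional",
                         noise_cv = 0.02, seed = 31)
  g <- simulate_rate_grid(ref_params, "noncompetitive", d)
  sub <- g[g$inhibitor_uM == 0.5, ]
  cv <- sd(sub$rate) / mean(sub$rate)
  expect_lt(abs(cv / 0.02 - 1), 0.15)
})

test_that("designs without the uninhibited level are rejected", {
  d <- simulation_design(inhibitor_levels = c(0.1, 0.5, 2))
  expect_error(simulate_rate_grid(ref_params, "noncompetitive", d),
               "zero-inhibitor")
})

test_that("simulated traces invert the rate conversion and are seeded", {
  q <- extinction_spec("quinonimine adduct", 26000, 515)
  tr0 <- simulate_absorbance_trace(0, q, duration = 5, sampling = 20)
  expect_true(all(tr0$absorbance == tr0$absorbance[1]))

  tr <- simulate_absorbance_trace(1, q, volume = 1, duration = 5,
                                  sampling = 30)
  est <- estimate_initial_rate(tr)
  expect_equal(est$slope, 0.026, tolerance = 1e-10)
  expect_equal(absorbance_to_rate(est$slope, q, 1), 1.0, tolerance = 1e-8)

  n1 <- simulate_absorbance_trace(1, q, noise_sd = 0.005, seed = 5)
  n2 <- simulate_absorbance_trace(1, q, noise_sd = 0.005, seed = 5)
  expect_identical(n1$absorbance, n2$absorbance)
})

test_that("simulate-then-fit closes the loop for every mode", {
  p_plain <- tb_params(Km = 173.8, Vmax = 12.98, Ki = 0.3, E = 0.2)
  gens <- list(noncompetitive = ref_params, competitive = p_plain,
               uncompetitive = p_plain)
  for (m in names(gens)) {
    g <- simulate_rate_grid(gens[[m]], m, noiseless_design())
    cmp <- compare_inhibition_modes(g)
    expect_identical(cmp$best_mode, m)
    fit <- cmp$fits[[m]]
    for (nm in c("Ki", "E")) {
      expect_lt(rel_err(fit$params[[nm]], gens[[m]][[nm]]), 1e-3)
    }
  }
})
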