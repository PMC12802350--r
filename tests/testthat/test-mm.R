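test_that("mm_velocity evaluates the hyperbola correctly", {
  expect_equal(mm_velocity(0, 173.8, 12.98), 0)
  expect_equal(mm_velocity(173.8, 173.8, 12.98), 12.98 / 2)
  expect_equal(mm_velocity(1000, 173.8, 12.98), 12.98 * 1000 / 1173.8,
               tolerance = 1e-12)
})

test_that("mm_velocity is strictly increasing in S and bounded by Vmax", {
  S <- sort(c(10^runif(50, -1, 4)))
  v <- mm_velocity(S, Km = 80, Vmax = 7)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < 7))
})

test_that("noiseless rates are recovered exactly and residuals vanish", {
  S <- c(20, 50, 100, 200, 500, 1000)
  d <- data.frame(substrate_uM = S, inhibitor_uM = 0, replicate = 1,
                  rate = mm_velocity(S, 173.8, 12.98))
  fit <- fit_michaelis_menten(d)
  expect_lt(rel_err(fit$Km, 173.8), 1e-4)
  expect_lt(rel_err(fit$Vmax, 12.98), 1e-4)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_false(fit$poorly_identified)
})

test_that("flat Km profiles in the near-linear regime are flagged", {
  # all substrate levels far below Km: rate ~ (Vmax/Km) * S, so only the
  # ratio is identified and se_Km/Km blows up
  S <- rep(c(0.5, 1, 2, 3.4), 3)
  d <- data.frame(substrate_uM = S, inhibitor_uM = 0,
                  rate = mm_velocity(S, 173.8, 12.98) *
                    (1 + 0.02 * rep(c(-1, 0, 1), each = 4)))
  expect_warning(fit <- fit_michaelis_menten(d), "poorly identified")
  expect_true(fit$poorly_identified)
})

test_that("fewer than 3 distinct substrate levels is an identifiability error", {
  d <- data.frame(substrate_uM = c(20, 20, 1000, 1000), inhibitor_uM = 0,
                  rate = c(1.3, 1.35, 11, 11.1))
  expect_error(fit_michaelis_menten(d), "identifiability")
})

test_that("Km recovery under proportional noise is accurate in the median", {
  S <- c(20, 50, 100, 200, 500, 1000)
  errs <- vapply(1:100, function(seed) {
    g <- simulate_rate_grid(
      ref_params, "noncompetitive",
      simulation_design(substrate_levels = S, inhibitor_levels = c(0, 0.5),
                        replicates = 3, noise_type = "proportional",
                        noise_cv = 0.02, seed = seed))
    fit <- fit_michaelis_menten(g)
    rel_err(fit$Km, ref_params$Km)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})
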