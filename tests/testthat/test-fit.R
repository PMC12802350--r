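test_that("joint fit recovers generating parameters exactly on noiseless grids", {
  g <- noiseless_grid("noncompetitive")
  fit <- fit_tight_binding(g, "noncompetitive", strategy = "joint")
  truth <- coef(fit)[c("Km", "Vmax", "Ki", "alpha", "E")]
  expect_lt(rel_err(fit$params$Ki, ref_params$Ki), 1e-3)
  expect_lt(rel_err(fit$params$Km, ref_params$Km), 1e-3)
  expect_lt(rel_err(fit$params$Vmax, ref_params$Vmax), 1e-3)
  expect_lt(rel_err(fit$params$alpha, ref_params$alpha), 1e-3)
  expect_lt(rel_err(fit$params$E, ref_params$E), 1e-3)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_equal(fit$k, 5L)
})

test_that("competitive noiseless grids are recovered under the competitive model", {
  p <- tb_params(Km = 100, Vmax = 10, Ki = 0.5, E = 0.2)
  g <- simulate_rate_grid(p, "competitive", noiseless_design())
  fit <- fit_tight_binding(g, "competitive", strategy = "joint")
  for (nm in c("Km", "Vmax", "Ki", "E")) {
    expect_lt(rel_err(fit$params[[nm]], p[[nm]]), 1e-3)
  }
  expect_equal(fit$k, 4L)
})

test_that("two-stage and joint strategies coincide on noiseless data", {
  g <- noiseless_grid("noncompetitive")
  f2 <- fit_tight_binding(g, "noncompetitive", strategy = "two_stage")
  fj <- fit_tight_binding(g, "noncompetitive", strategy = "joint")
  expect_equal(f2$params$Ki, fj$params$Ki, tolerance = 1e-6)
  expect_equal(f2$params$alpha, fj$params$alpha, tolerance = 1e-6)
  expect_equal(f2$params$E, fj$params$E, tolerance = 1e-6)
  expect_equal(f2$k, 3L)
  expect_setequal(f2$fixed, c("Km", "Vmax"))
})

test_that("fix_E holds the enzyme concentration and drops it from k", {
  g <- noiseless_grid("noncompetitive")
  fit <- fit_tight_binding(g, "noncompetitive", strategy = "two_stage",
                           fix_E = ref_params$E)
  expect_equal(fit$params$E, ref_params$E)
  expect_true("E" %in% fit$fixed)
  expect_equal(fit$k, 2L)
  expect_lt(rel_err(fit$params$Ki, ref_params$Ki), 1e-3)
})

test_that("grids without inhibitor information are rejected", {
  S <- c(20, 50, 100, 200, 500, 1000)
  d <- data.frame(substrate_uM = S, inhibitor_uM = 0, replicate = 1,
                  rate = mm_velocity(S, 173.8, 12.98))
  g <- rate_grid(d)
  expect_error(fit_tight_binding(g, "noncompetitive"), "identifiability")
})

test_that("least-squares AIC follows its defining arithmetic", {
  expect_equal(compute_aic(3.6, n = 36, k = 3), 36 * log(0.1) + 8,
               tolerance = 1e-12)
  expect_equal(compute_aic(3.6, n = 36, k = 3), -74.8931, tolerance = 1e-4)
  # one fewer parameter at equal rss lowers AIC by 2
  expect_equal(compute_aic(3.6, n = 36, k = 2),
               compute_aic(3.6, n = 36, k = 3) - 2)
  # halving rss at fixed n, k lowers AIC by n*ln(2)
  expect_equal(compute_aic(1.8, n = 36, k = 3),
               compute_aic(3.6, n = 36, k = 3) - 36 * log(2))
  aic0 <- compute_aic(0, n = 10, k = 2)
  expect_identical(as.numeric(aic0), -Inf)
  expect_true(attr(aic0, "exact_fit"))
})

test_that("noiseless comparisons recover the generating mode decisively", {
  p_plain <- tb_params(Km = 173.8, Vmax = 12.98, Ki = 0.3, E = 0.2)
  gens <- list(noncompetitive = ref_params, competitive = p_plain,
               uncompetitive = p_plain)
  for (m in names(gens)) {
    g <- simulate_rate_grid(gens[[m]], m, noiseless_design())
    cmp <- compare_inhibition_modes(g)
    expect_identical(cmp$best_mode, m)
    others <- cmp$table$delta_aic[cmp$table$mode != m]
    expect_true(all(others > 10))
  }
})

test_that("fit and comparison objects expose standard modelling methods", {
  g <- noiseless_grid("noncompetitive")
  fit <- fit_tight_binding(g, "noncompetitive", strategy = "joint")
  expect_named(coef(fit), c("Km", "Vmax", "Ki", "alpha", "E"))
  expect_equal(AIC(fit), fit$aic)
  expect_equal(predict(fit, data.frame(substrate_uM = 100,
                                       inhibitor_uM = 0.5)),
               predict_rate(100, 0.5, fit$params, "noncompetitive"))
  expect_equal(fitted(fit) + residuals(fit), g$rate)
  expect_output(print(fit), "noncompetitive")
  expect_output(print(summary(fit)), "AIC")

  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "rate_grid")
  expect_false(identical(sims[[1]]$rate, sims[[2]]$rate))
})
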