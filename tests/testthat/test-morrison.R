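test_that("ki_app algebraic reductions hold", {
  # alpha = 1 collapses the mixed form to Ki at any substrate
  for (S in c(1, 50, 173.8, 2000)) {
    expect_equal(ki_app("noncompetitive", S, Km = 173.8, Ki = 0.3,
                        alpha = 1), 0.3, tolerance = 1e-12)
  }
  # competitive at S = Km doubles Ki
  expect_equal(ki_app("competitive", 100, Km = 100, Ki = 0.3), 0.6)
  # mixed form at the reference parameters, against the independent
  # rearrangement Ki*alpha*(S+Km)/(alpha*Km + S)
  ka <- ki_app("noncompetitive", 173.8, Km = 173.8, Ki = 0.30775,
               alpha = 2.28419)
  expect_equal(ka, 0.30775 * 2.28419 * (173.8 + 173.8) /
                 (2.28419 * 173.8 + 173.8), tolerance = 1e-12)
  expect_equal(ka, 0.4281, tolerance = 1e-4)
  expect_error(ki_app("uncompetitive", 0, Km = 100, Ki = 0.3), "S = 0")
})

test_that("ki_app substrate dependence separates the three modes", {
  S <- c(5, 20, 100, 500, 2000)
  comp <- ki_app("competitive", S, Km = 100, Ki = 0.3)
  unc <- ki_app("uncompetitive", S, Km = 100, Ki = 0.3)
  expect_true(all(diff(comp) > 0))
  expect_true(all(diff(unc) < 0))
  for (alpha in c(0.3, 2.5)) {
    mix <- ki_app("noncompetitive", S, Km = 100, Ki = 0.3, alpha = alpha)
    expect_true(all(mix >= 0.3 * min(1, alpha) - 1e-12))
    expect_true(all(mix <= 0.3 * max(1, alpha) + 1e-12))
  }
})

test_that("morrison_ratio matches the binding-quadratic oracle", {
  expect_equal(morrison_ratio(0.5, 0, 0.3), 1)
  expect_equal(morrison_ratio(0.1, 0.1, 0.3), 0.7913, tolerance = 1e-4)
  # classical limit at vanishing enzyme
  expect_equal(morrison_ratio(1e-9, 0.3, 0.3), 0.5, tolerance = 1e-4)

  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    E <- 10^runif(1, -3, 3)
    I <- 10^runif(1, -3, 3)
    K <- 10^runif(1, -3, 3)
    r <- morrison_ratio(E, I, K)
    expect_gte(r, 0)
    expect_lte(r, 1)
    worst <- max(worst, abs(r - morrison_oracle(E, I, K)))
  }
  expect_lt(worst, 1e-9)
})

test_that("morrison_ratio is monotone in I and in Ki_app", {
  set.seed(11)
  for (i in 1:50) {
    E <- 10^runif(1, -3, 2)
    K <- 10^runif(1, -3, 2)
    I <- sort(10^runif(8, -3, 3))
    expect_true(all(diff(morrison_ratio(E, I, K)) <= 1e-12))
    Ks <- sort(10^runif(8, -3, 3))
    expect_true(all(diff(morrison_ratio(E, 0.5, Ks)) >= -1e-12))
  }
})

test_that("morrison_ratio converges to the classical isotherm for E << Ki_app", {
  set.seed(13)
  for (i in 1:50) {
    K <- 10^runif(1, -2, 2)
    I <- 10^runif(1, -2, 2)
    E <- 1e-6 * K
    expect_lt(abs(morrison_ratio(E, I, K) - K / (K + I)), 1e-4)
  }
  expect_error(morrison_ratio(0, 1, 0.3), "classical limit")
})

test_that("predict_rate composes the Michaelis-Menten and Morrison pieces", {
  p <- ref_params
  S <- c(20, 100, 1000)
  expect_equal(predict_rate(S, 0, p, "noncompetitive"),
               mm_velocity(S, p$Km, p$Vmax))
  # composition at one grid point equals the product of the verified parts
  ka <- ki_app("noncompetitive", 1000, p$Km, p$Ki, p$alpha)
  expect_equal(predict_rate(1000, 0.1, p, "noncompetitive"),
               mm_velocity(1000, p$Km, p$Vmax) *
                 morrison_ratio(p$E, 0.1, ka), tolerance = 1e-12)
})

test_that("the reaction essentially stops at 20 uM substrate and 2 uM inhibitor", {
  p <- ref_params
  vi <- predict_rate(20, 2, p, "noncompetitive")
  # residual rate relative to the maximal uninhibited velocity
  expect_lt(vi / p$Vmax, 0.05)
})

test_that("tight-binding IC50 closed form agrees with bisection and limits", {
  p <- ref_params
  ka <- ki_app("noncompetitive", 173.8, p$Km, p$Ki, p$alpha)
  ic <- ic50_tight_binding(p, "noncompetitive", 173.8)
  expect_equal(ic, ka + p$E / 2, tolerance = 1e-12)
  expect_equal(ic, 0.5371, tolerance = 1e-4)
  # numeric root of morrison_ratio = 1/2
  root <- uniroot(function(I) morrison_ratio(p$E, I, ka) - 0.5,
                  c(1e-6, 100), tol = 1e-12)$root
  expect_equal(ic, root, tolerance = 1e-8)

  # classical limit: IC50 -> Ki_app as E -> 0
  p0 <- tb_params(Km = p$Km, Vmax = p$Vmax, Ki = p$Ki, E = 1e-9,
                  alpha = p$alpha)
  expect_equal(ic50_tight_binding(p0, "noncompetitive", 173.8), ka,
               tolerance = 1e-6)

  # alpha = 1: IC50 independent of substrate
  p1 <- tb_params(Km = 100, Vmax = 10, Ki = 0.3, E = 0.2, alpha = 1)
  ics <- ic50_tight_binding(p1, "noncompetitive", c(10, 100, 1000))
  expect_equal(ics, rep(0.3 + 0.1, 3), tolerance = 1e-12)
})
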