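test_that("joint log-likelihood matches a 50-digit naive summation oracle", {
  # frozen from an independent extended-precision enumeration of the same
  # 12-point toy dataset and parameter values
  oracle <- -71.160559061920413607053060178311349755684917172838
  ll <- joint_loglik(toy_dataset(), "MX2-A-AD", toy_params())
  expect_equal(ll, oracle, tolerance = 1e-10)
})

test_that("log-likelihood is additive and respects the normal closed form", {
  # a single observation at the component mean with sigma^2 = 1/(2*pi) has
  # density exactly 1, i.e. zero log-likelihood contribution
  es <- segjoint:::.gen_estep(5, weights = 1, means = 5,
                              variance = 1 / (2 * pi))
  expect_equal(es$loglik, 0, tolerance = 1e-14)

  d1 <- toy_dataset()
  d2 <- six_gen_dataset(lapply(d1$samples, function(s) {
    generation_sample(s$generation, rep(s$values, 2))
  }))
  s <- build_structure("MX2-A-AD")
  expect_equal(joint_loglik(d2, s, toy_params()),
               2 * joint_loglik(d1, s, toy_params()), tolerance = 1e-12)
  expect_error(joint_loglik(d1, s, structure(list(
    mean = toy_params()$mean, sigma2_e = -1,
    sigma2_pg = c(F2 = 0, BC1P1 = 0, BC1P2 = 0)), class = "effect_params")),
    "variances must be positive")
})

test_that("no underflow for observations far from all components", {
  es <- segjoint:::.gen_estep(c(0, 40), weights = c(0.5, 0.5),
                              means = c(0, 1), variance = 1)
  expect_true(is.finite(es$loglik))
  expect_equal(rowSums(es$resp), c(1, 1), tolerance = 1e-10)
})

test_that("EM recovers a strong single-gene additive signal", {
  cfg <- sim_config("1MG-A", effect_params(m = 100, da = 20, sigma2_e = 25),
                    n = flat_n(200), seed = 11)
  d <- simulate_cross(cfg)
  f <- fit_model(d, "1MG-A", fit_config(n_starts = 5, seed = 2))
  expect_true(f$converged)
  expect_lt(abs(f$theta["da"] - 20), 2)
  # the ML fit must dominate the generating truth
  expect_gte(f$loglik, joint_loglik(d, "1MG-A", cfg$params))
  # FitResult invariants
  expect_equal(f$aic, -2 * f$loglik + 2 * f$k)
  expect_equal(diff(f$loglik_trace) >= -1e-8 * (1 + abs(f$loglik)),
               rep(TRUE, length(f$loglik_trace) - 1))
  for (g in names(f$posterior_responsibilities)) {
    expect_equal(rowSums(f$posterior_responsibilities[[g]]),
                 rep(1, nrow(f$posterior_responsibilities[[g]])),
                 tolerance = 1e-10)
  }
  # realized component means equal the design image of theta
  for (g in names(f$components)) {
    expect_equal(f$components[[g]]$means,
                 as.numeric(f$structure$generations[[g]]$design %*% f$theta),
                 tolerance = 1e-12)
  }
})

test_that("no genetic signal yields a near-zero major-gene effect", {
  set.seed(31)
  d <- six_gen_dataset(lapply(
    c("P1", "P2", "F1", "F2", "BC1P1", "BC1P2"),
    function(g) generation_sample(g, rnorm(500, 100, 10))))
  f <- fit_model(d, "1MG-A", fit_config(n_starts = 5, seed = 3))
  # 3 x rough standard error of a parental-contrast estimate of d_a
  expect_lt(abs(f$theta["da"]), 3 * 10 * sqrt(2 / 500))
})

test_that("estimates are location- and scale-equivariant", {
  cfg <- sim_config("1MG-AD",
                    effect_params(m = 50, da = 8, ha = 3, sigma2_e = 9),
                    n = flat_n(150), seed = 21)
  d <- simulate_cross(cfg)
  shift_gen <- function(d, a, b) six_gen_dataset(lapply(d$samples, function(s)
    generation_sample(s$generation, a + b * s$values)))
  cfgfit <- fit_config(n_starts = 3, seed = 4)
  f0 <- fit_model(d, "1MG-AD", cfgfit)
  fs <- fit_model(shift_gen(d, 100, 1), "1MG-AD", cfgfit)
  expect_equal(unname(fs$theta["m"] - f0$theta["m"]), 100, tolerance = 1e-5)
  expect_equal(fs$theta[c("da", "ha")], f0$theta[c("da", "ha")],
               tolerance = 1e-6)
  expect_equal(fs$params$sigma2_e, f0$params$sigma2_e, tolerance = 1e-5)
  fm <- fit_model(shift_gen(d, 0, 3), "1MG-AD", cfgfit)
  expect_equal(unname(fm$theta), unname(3 * f0$theta), tolerance = 1e-5)
  expect_equal(fm$params$sigma2_e, 9 * f0$params$sigma2_e, tolerance = 1e-4)
})

test_that("EM equals closed-form least squares in the single-component limit", {
  # PG-AD with the polygenic variances fixed at zero: every generation is a
  # single normal with mean A_g theta and variance sigma2_e, so the ML
  # solution is ordinary least squares on the stacked generation designs
  cfg <- sim_config("PG-AD",
                    effect_params(m = 100, pd = 15, ph = 5, sigma2_e = 36),
                    n = flat_n(80), seed = 41)
  d <- simulate_cross(cfg)
  f <- fit_model(d, "PG-AD",
                 fit_config(n_starts = 1, seed = 1, fix_pg_variance = 0))
  s <- build_structure("PG-AD")
  X <- do.call(rbind, lapply(names(d$samples), function(g) {
    n <- length(d$samples[[g]]$values)
    s$generations[[g]]$design[rep(1, n), , drop = FALSE]
  }))
  y <- unlist(lapply(d$samples, `[[`, "values"))
  ols <- unname(stats::coef(stats::lm(y ~ X - 1)))
  expect_equal(unname(f$theta), ols, tolerance = 1e-6)
  expect_equal(f$params$sigma2_e, mean((y - X %*% ols)^2), tolerance = 1e-4)
})

test_that("larger nested models attain at least the smaller model's likelihood", {
  cfg <- cross_fixture("crossA", seed = 9)
  d <- simulate_cross(cfg)
  cfgfit <- fit_config(n_starts = 4, tol = 1e-7, seed = 7)
  f_a <- fit_model(d, "2MG-A", cfgfit)
  f_ad <- fit_model(d, "2MG-AD", cfgfit)
  f_mx <- fit_model(d, "MX2-A-AD", cfgfit)
  expect_gte(f_ad$loglik, f_a$loglik - 1e-6)
  expect_gte(f_mx$loglik, f_a$loglik - 1e-6)
})

test_that("the mixed two-gene model dominates the bare one-gene model on AIC", {
  # data with polygenic variance and two major genes: a model without any
  # polygene component cannot absorb the segregating-generation variance
  cf <- fit_config(n_starts = 2, tol = 1e-6, max_iter = 500, seed = 1)
  for (s in c(2, 23, 71, 104)) {
    d <- simulate_cross(cross_fixture("crossA", seed = s))
    cf$seed <- s
    expect_lt(fit_model(d, "MX2-A-AD", cf)$aic, fit_model(d, "1MG-A", cf)$aic)
  }
})

test_that("the first major gene is reported as the larger additive effect", {
  cfg <- cross_fixture("crossB", seed = 13)
  d <- simulate_cross(cfg)
  f <- fit_model(d, "MX2-A-AD", fit_config(n_starts = 5, seed = 13))
  expect_gte(abs(f$theta["da"]), abs(f$theta["db"]))
})

test_that("fits are deterministic given the configuration seed", {
  cfg <- sim_config("1MG-A", effect_params(m = 100, da = 20, sigma2_e = 25),
                    n = flat_n(60), seed = 17)
  d <- simulate_cross(cfg)
  f1 <- fit_model(d, "1MG-AD", fit_config(n_starts = 4, seed = 5))
  f2 <- fit_model(d, "1MG-AD", fit_config(n_starts = 4, seed = 5))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loglik, f2$loglik)
})
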