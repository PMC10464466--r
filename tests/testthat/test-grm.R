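test_that("with zero slope the likelihood factors into marginal frequencies", {
  thr <- c(-0.8, 0, 0.9, 1.7)
  L <- loading_matrix(c("a", "b", "c"), NA, c(0, 0.5, 0.5), NA)
  spec <- bifactor_spec(L, thresholds = thr)
  m <- as_grm_model(spec)
  # single zero-slope item: loglik = sum of log implied category masses
  d1 <- simulate_responses(spec, 50, seed = 21)$responses
  one <- subset_items(d1, "a")
  m1 <- as_grm_model(bifactor_spec(loading_matrix("a", NA, 0, NA),
                                   thresholds = thr))
  pk <- diff(c(0, pnorm(thr), 1))
  expected <- sum(log(pk[response_matrix(one)[, 1]]))
  expect_equal(grm_loglik(m1, one), expected, tolerance = 1e-8)
})

test_that("quadrature log-likelihood matches a dense trapezoid oracle", {
  spec <- make_uni_spec(c(0.6, 0.7, 0.5))
  d <- simulate_responses(spec, 5, seed = 22)$responses
  m <- as_grm_model(spec, n_quad = 61)
  expect_equal(grm_loglik(m, d), oracle_loglik_uni(m, d), tolerance = 1e-6)
})

test_that("dimension-reduced bifactor likelihood equals naive quadrature", {
  spec <- make_toy_bifactor()
  d <- simulate_responses(spec, 8, seed = 23)$responses
  m <- as_grm_model(spec, n_quad = 21)
  expect_equal(grm_loglik(m, d), oracle_loglik_bifactor(m, d, 21),
               tolerance = 1e-4)
})

test_that("EM recovers unidimensional parameters and never decreases", {
  spec <- make_uni_spec()
  d <- simulate_responses(spec, 2000, seed = 24)$responses
  m <- fit_grm(d)
  expect_true(m$converged)
  expect_true(all(diff(m$loglik_trace) >= -1e-6 * abs(m$loglik)))
  tr <- loadings_to_slopes(spec$loadings)
  for (i in seq_along(m$items)) {
    expect_lt(abs(m$params[[i]]$a[1] - tr$a_general[i]), 0.15)
    expect_true(all(abs(m$params[[i]]$b -
                          spec$thresholds[[i]] /
                            sqrt(1 - spec$loadings$h2[i])) < 0.15))
  }
  # fitted likelihood beats the generating parameters on the sample
  expect_gte(grm_loglik(m, d), grm_loglik(as_grm_model(spec), d) - 1e-6)
})

test_that("degenerate single-category items are rejected, not fit silently", {
  d <- response_table(data.frame(
    subject_id = as.character(1:30), study_id = "s",
    i1 = rep(3L, 30), i2 = rep(1:5, 6), i3 = rep(c(1L, 4L), 15)))
  expect_error(fit_grm(d), "fewer than 2 observed categories")
  expect_error(fit_grm(subset_items(d, c("i2", "i3"))), "three items")
})

test_that("standardization has closed forms and round-trips", {
  L <- loading_matrix("x", NA, 1 / sqrt(2), NA)
  sl <- loadings_to_slopes(L)
  expect_equal(sl$a_general, 1, tolerance = 1e-12)
  spec <- make_toy_bifactor()
  m <- as_grm_model(spec)
  L2 <- standardize_loadings(m)
  expect_equal(L2$lambda_general, spec$loadings$lambda_general,
               tolerance = 1e-10)
  expect_equal(L2$lambda_specific, spec$loadings$lambda_specific,
               tolerance = 1e-10)
  # zero slope -> zero loading and zero communality
  L0 <- standardize_loadings(as_grm_model(
    bifactor_spec(loading_matrix(c("a", "b", "c"), NA, c(0, .5, .5), NA))))
  expect_equal(L0$lambda_general[1], 0)
  expect_equal(L0$h2[1], 0)
})

test_that("EAP scoring: prior fallback, information monotonicity, reliability", {
  spec <- make_uni_spec()
  d <- simulate_responses(spec, 1500, seed = 25)$responses
  m <- as_grm_model(spec)
  sc <- eap_scores(m, d)
  expect_true(all(sc$scores$sd_general > 0))
  expect_gte(sc$rho_xx, 0)
  expect_lte(sc$rho_xx, 1)

  # doubling all slopes strictly reduces mean posterior SD on the same data
  spec2 <- spec
  m2 <- as_grm_model(spec2)
  for (i in seq_along(m2$items)) m2$params[[i]]$a <- 2 * m2$params[[i]]$a
  sc2 <- eap_scores(m2, d)
  expect_lt(mean(sc2$scores$sd_general), mean(sc$scores$sd_general))

  # analytic reliability of the generating model vs estimated rho_xx
  # oracle: rho = var(EAP under truth) / 1, via large-sample EAP variance
  expect_lt(abs(sc$rho_xx - (1 - mean(sc$scores$sd_general^2))), 0.03)

  # subject with all responses missing for the model's items
  d2 <- subset_items(d[1:5, ], c("it1", "it2", "it3"))
  d2$it1[1] <- d2$it2[1] <- d2$it3[1] <- NA_integer_
  m3 <- as_grm_model(make_uni_spec(c(0.6, 0.7, 0.5)))
  sc3 <- eap_scores(m3, d2)
  expect_true(sc3$scores$flag_no_items[1])
  expect_equal(sc3$scores$eap_general[1], 0)
  expect_equal(sc3$scores$sd_general[1], 1)
})

test_that("plausible values behave like posterior draws", {
  spec <- make_uni_spec()
  d <- simulate_responses(spec, 2000, seed = 26)$responses
  m <- as_grm_model(spec)
  expect_error(plausible_values(m, d, M = 0), "M must be")
  pv1 <- plausible_values(m, d, M = 10, seed = 5)
  pv2 <- plausible_values(m, d, M = 10, seed = 5)
  expect_identical(pv1$draws, pv2$draws)

  # PV mean converges to the EAP
  pvL <- plausible_values(m, d[1:50, ], M = 400, seed = 6)
  sc <- eap_scores(m, d[1:50, ])
  expect_lt(max(abs(rowMeans(pvL$draws$general) - sc$scores$eap_general)),
            0.12)

  # PVs carry more between-subject variance than shrunken EAPs
  sc_full <- eap_scores(m, d)
  expect_gte(var(as.vector(pv1$draws$general[, 1])),
             var(sc_full$scores$eap_general))
})

test_that("conditioning plausible values on a covariate removes attenuation", {
  spec <- make_uni_spec()
  set.seed(28)
  n <- 3000
  traits <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "general"))
  x <- 0.4 * traits[, 1] + rnorm(n, 0, sqrt(1 - 0.16))
  # distinct seed: the response-noise stream must not overlap the
  # trait/covariate stream above
  d <- simulate_responses(spec, n, seed = 29, traits = traits)$responses
  m <- as_grm_model(spec)
  pv0 <- plausible_values(m, d, M = 5, seed = 9)
  pv1 <- plausible_values(m, d, M = 5, seed = 9, condition = x)
  r0 <- mean(apply(pv0$draws$general, 2, cor, y = x))
  r1 <- mean(apply(pv1$draws$general, 2, cor, y = x))
  rel <- eap_scores(m, d)$rho_xx
  expect_lt(abs(r0 - 0.4 * rel), 0.04)   # unconditioned: reliability-attenuated
  expect_lt(abs(r1 - 0.4), 0.04)         # conditioned: unbiased
  expect_gt(r1, r0)
})

test_that("models survive JSON serialization round-trips", {
  spec <- make_toy_bifactor()
  m <- as_grm_model(spec)
  f <- withr::local_tempfile(fileext = ".json")
  write_grm(m, f)
  m2 <- read_grm(f)
  d <- simulate_responses(spec, 30, seed = 27)$responses
  expect_equal(grm_loglik(m, d), grm_loglik(m2, d), tolerance = 1e-10)
})
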