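# helper: wrap plain trait draws as a plausible-value set
fake_pvs <- function(theta, study_id, M = 5, reliability = 0.9, seed = 1) {
  set.seed(seed)
  n <- length(theta)
  pv <- sapply(seq_len(M), function(m) {
    sqrt(reliability) * theta + rnorm(n, 0, sqrt(1 - reliability))
  })
  structure(list(draws = list(general = pv),
                 subject_id = as.character(seq_len(n)),
                 study_id = study_id, M = M, seed = seed),
            class = "plausible_value_set")
}

test_that("ROPE evidence classification has the right limits", {
  set.seed(71)
  prior <- rnorm(5000)
  rope <- c(-0.1, 0.1)
  # posterior identical to prior: no learning
  ev <- rope_evidence(prior, rope, prior)
  expect_equal(ev$log_bf, 0)
  expect_equal(ev$class, "inconclusive")
  # posterior entirely inside the ROPE
  post_in <- runif(5000, -0.05, 0.05)
  ev <- rope_evidence(post_in, rope, prior)
  expect_lte(ev$log_bf, -2.3)
  expect_equal(ev$class, "strong null")
  expect_true(ev$floored)
  # concentrated non-null posterior vs diffuse prior (closed-form check:
  # log BF ~ log[odds(N(0.3,0.05) in rope) ratio] >> 2.3)
  post_out <- rnorm(5e4, 0.3, 0.05)
  ev <- rope_evidence(post_out, rope, rnorm(5e4))
  expect_gt(ev$log_bf, 2.3)
  expect_equal(ev$class, "strong non-null")
  expect_lt(ev$p_rope, 0.001)
  # guards
  expect_error(rope_evidence(rnorm(100), rope, prior), "1000")
  expect_error(rope_evidence(prior, c(0.1, -0.1), prior), "ROPE")
})

test_that("ROPE width going to zero drives P_ROPE to zero", {
  set.seed(72)
  post <- rnorm(5000, 0.1, 0.2)
  prior <- rnorm(5000)
  p <- vapply(c(0.2, 0.05, 0.01, 0.001), function(w) {
    rope_evidence(post, c(-w, w), prior)$p_rope
  }, numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_lt(p[4], 0.01)
})

test_that("IDA preconditions: case rule and minimum study count", {
  set.seed(73)
  st <- rep(c("s1", "s2"), each = 30)
  pvs <- fake_pvs(rnorm(60), st, M = 2)
  cors <- data.frame(subject_id = as.character(1:60), study_id = st,
                     x = rnorm(60))
  res <- fit_ida(pvs, cors, min_cases = 100)
  expect_true(res$skipped)
  expect_match(res$reason, "< 100")

  one <- rep("s1", 120)
  pv1 <- fake_pvs(rnorm(120), one, M = 2)
  c1 <- data.frame(subject_id = as.character(1:120), study_id = one,
                   x = rnorm(120))
  expect_error(fit_ida(pv1, c1, min_cases = 100), "at least 2 studies")
})

test_that("a null binary effect is recovered as practically null", {
  set.seed(74)
  J <- 4; nj <- 250
  st <- rep(sprintf("s%d", 1:J), each = nj)
  theta <- rnorm(J * nj)
  x <- rbinom(J * nj, 1, 0.5)          # unrelated to theta
  pvs <- fake_pvs(theta, st, M = 3)
  cors <- data.frame(subject_id = as.character(seq_along(st)), study_id = st,
                     x = x)
  res <- fit_ida(pvs, cors, type = "binary", seed = 74,
                 n_adapt = 200, n_burn = 200, n_iter = 1000)
  expect_false(res$skipped)
  expect_equal(res$effect_label, "d")
  expect_lt(abs(res$effect_median), 0.2)
  if (res$converged) {
    expect_true(res$class %in% c("moderate null", "strong null"))
  }
  # heterogeneity invariants
  h <- heterogeneity(res)
  expect_gte(h$tau2, 0)
  expect_gte(h$icc, 0); expect_lte(h$icc, 1)
  expect_gte(h$i2, 0); expect_lte(h$i2, 1)
  expect_lt(h$prediction_interval[1], h$prediction_interval[2])
  # prediction interval at least as wide as the credible interval
  expect_lte(res$prediction_interval[1], res$ci[1] + 0.02)
  expect_gte(res$prediction_interval[2], res$ci[2] - 0.02)
})

test_that("pooling over plausible values widens the effect posterior", {
  set.seed(75)
  J <- 4; nj <- 120
  st <- rep(sprintf("s%d", 1:J), each = nj)
  theta <- rnorm(J * nj)
  x <- 0.3 * theta + rnorm(J * nj, 0, sqrt(0.91))
  cors <- data.frame(subject_id = as.character(seq_along(st)), study_id = st,
                     x = x)
  pvs_multi <- fake_pvs(theta, st, M = 5, reliability = 0.6, seed = 2)
  pvs_one <- pvs_multi
  pvs_one$draws$general <- pvs_multi$draws$general[, 1, drop = FALSE]
  pvs_one$M <- 1
  args <- list(correlates = cors, seed = 75, n_adapt = 200, n_burn = 200,
               n_iter = 800)
  res_m <- do.call(fit_ida, c(list(pvs_multi), args))
  res_1 <- do.call(fit_ida, c(list(pvs_one), args))
  expect_gte(sd(res_m$draws$b1), 0.9 * sd(res_1$draws$b1))
})
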