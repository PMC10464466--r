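# Index suite checks against the bundled reference solutions and on
# randomly generated loading matrices.

test_that("reference loading tables reproduce their published index values", {
  hyper <- compute_indices(reference_loadings("hyper"))
  hypo <- compute_indices(reference_loadings("hypo"))
  seek <- compute_indices(reference_loadings("seek"))

  expect_equal(hyper$ecv_g, 0.436, tolerance = 0.005)
  expect_equal(hypo$ecv_g, 0.398, tolerance = 0.005)
  expect_equal(seek$ecv_g, 0.533, tolerance = 0.005)
  expect_equal(hypo$omega_h, 0.653, tolerance = 0.005)

  ss <- function(idx, s) idx$subscales[idx$subscales$subscale == s, ]
  expect_equal(ss(hypo, "Speech")$ecv_ss, 0.793, tolerance = 0.005)
  expect_equal(ss(hypo, "PainTemperature")$ecv_ss, 0.698, tolerance = 0.005)
  expect_equal(ss(seek, "Visual")$ecv_ss, 0.347, tolerance = 0.005)
  expect_equal(ss(seek, "Tactile")$ecv_ss, 0.380, tolerance = 0.005)
  expect_equal(ss(seek, "OralTactile")$ecv_ss, 0.740, tolerance = 0.005)
})

test_that("without specific factors ECV_G is 1 and omega_H equals omega_T", {
  idx <- compute_indices(make_uni_spec()$loadings)
  expect_equal(idx$ecv_g, 1)
  expect_equal(idx$omega_h, idx$omega_t)
  expect_equal(nrow(idx$subscales), 0L)
})

test_that("omega matches a Monte-Carlo variance decomposition of sum scores", {
  set.seed(41)
  L <- loading_matrix(paste0("v", 1:8),
                      rep(c("A", "B"), each = 4),
                      runif(8, 0.35, 0.6), runif(8, 0.3, 0.6))
  idx <- compute_indices(L)
  n <- 2e5
  thg <- rnorm(n); tha <- rnorm(n); thb <- rnorm(n)
  Ys <- sapply(seq_len(8), function(i) {
    sp <- if (i <= 4) tha else thb
    L$lambda_general[i] * thg + L$lambda_specific[i] * sp +
      rnorm(n, 0, sqrt(1 - L$h2[i]))
  })
  tot <- rowSums(Ys)
  common_g <- sum(L$lambda_general) * thg
  common_s <- sum(L$lambda_specific[1:4]) * tha +
    sum(L$lambda_specific[5:8]) * thb
  omega_t_mc <- var(common_g + common_s) / var(tot)
  omega_h_mc <- var(common_g) / var(tot)
  se <- 3 / sqrt(n)  # generous MC slack on a variance ratio
  expect_lt(abs(idx$omega_t - omega_t_mc), 0.01)
  expect_lt(abs(idx$omega_h - omega_h_mc), 0.01)
})

test_that("index identities hold on fuzzed loading matrices", {
  set.seed(42)
  for (rep in 1:25) {
    p <- sample(6:14, 1)
    n_spec <- sample(1:3, 1)
    sub <- sample(c(LETTERS[seq_len(n_spec)], NA), p, replace = TRUE)
    if (all(is.na(sub))) sub[1] <- "A"
    lg <- runif(p, 0.1, 0.7)
    ls <- ifelse(is.na(sub), 0, runif(p, 0.1, 0.6))
    keep <- !is.na(sub) | TRUE
    L <- loading_matrix(paste0("v", 1:p), sub, lg, ls)
    idx <- compute_indices(L)
    expect_lte(idx$omega_h, idx$omega_t + 1e-12)
    expect_true(all(idx$subscales$omega_hs <= idx$subscales$omega_s + 1e-12))
    expect_true(all(idx$subscales$ecv_ss >= 0 & idx$subscales$ecv_ss <= 1))
    # global common-variance decomposition identity
    spec_share <- sum(vapply(split(seq_len(p), sub)[unique(na.omit(sub))],
                             function(i) sum(ls[i]^2), numeric(1))) /
      sum(lg^2 + ls^2)
    expect_equal(idx$ecv_g + spec_share, 1, tolerance = 1e-12)
    # permutation invariance
    perm <- sample(p)
    L2 <- loading_matrix(paste0("v", 1:p)[perm], sub[perm], lg[perm], ls[perm])
    idx2 <- compute_indices(L2)
    expect_equal(idx2$omega_t, idx$omega_t, tolerance = 1e-12)
    expect_equal(idx2$ecv_g, idx$ecv_g, tolerance = 1e-12)
  }
})

test_that("interpretability rules fire with inclusive thresholds", {
  fake <- function(oh, ecv) {
    structure(list(omega_t = max(oh, 0.9), omega_h = oh, ecv_g = ecv,
                   subscales = data.frame(), items = data.frame()),
              class = "bifactor_index_set")
  }
  r <- evaluate_interpretability(fake(0.800, 0.436))
  expect_true(r$interpretable)
  expect_equal(r$rule, "omega_h")
  r <- evaluate_interpretability(fake(0.653, 0.398))
  expect_false(r$interpretable)
  r <- evaluate_interpretability(fake(0.72, 0.61))
  expect_true(r$interpretable)
  expect_equal(r$rule, "omega_h_and_ecv")
  expect_false(evaluate_interpretability(fake(0.72, 0.59))$interpretable)
})

test_that("added-value rules respect the reliability tiers", {
  fake <- function(os, ohs, ecv) {
    structure(list(omega_t = 0.9, omega_h = 0.8, ecv_g = 0.5,
                   subscales = data.frame(subscale = "S", n_items = 4L,
                                          omega_s = os, omega_hs = ohs,
                                          ecv_ss = ecv, ecv_g_within = 1 - ecv),
                   items = data.frame()),
              class = "bifactor_index_set")
  }
  expect_false(evaluate_added_value(fake(0.743, 0.142, 0.227))$added_value)
  expect_true(evaluate_added_value(fake(0.927, 0.722, 0.793))$added_value)
  low <- evaluate_added_value(fake(0.65, 0.26, 0.10))
  expect_true(low$added_value)
  expect_equal(low$reliability_tier, "low")
  expect_equal(low$rule, "omega_hs")
  expect_false(evaluate_added_value(fake(0.65, 0.22, 0.40))$added_value)
})

test_that("loading matrices read/write and reject malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item_id,subscale,lambda_general,lambda_specific",
               "a,S,0.5,0.6", "b,S,0.4,0.5", "c,,0.7,"), f)
  L <- read_loadings(f)
  expect_equal(L$h2, c(0.61, 0.41, 0.49), tolerance = 1e-12)
  expect_equal(L$iecv[3], 1)
  expect_error(loading_matrix(character(0), character(0), numeric(0),
                              numeric(0)), "empty")
  expect_error(loading_matrix(c("a", "a"), NA, c(.5, .5), NA), "duplicated")
})
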