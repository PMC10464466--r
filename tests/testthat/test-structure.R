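test_that("polychoric estimation recovers known latent correlations", {
  set.seed(51)
  n <- 1e4
  z <- mvtnorm::rmvnorm(n, sigma = matrix(c(1, 0.5, 0.5, 1), 2))
  cuts <- c(-1, 0, 1, 2)
  x <- findInterval(z[, 1], cuts) + 1L
  y <- findInterval(z[, 2], cuts) + 1L
  expect_lt(abs(polychoric_pair(x, y) - 0.5), 0.03)

  # independent items
  x0 <- findInterval(rnorm(5000), cuts) + 1L
  y0 <- findInterval(rnorm(5000), cuts) + 1L
  expect_lt(abs(polychoric_pair(x0, y0)), 0.04)

  # identical latent variable, different cuts
  x1 <- findInterval(z[, 1], c(-0.5, 0.5)) + 1L
  y1 <- findInterval(z[, 1], c(-1, 0, 1)) + 1L
  expect_gte(polychoric_pair(x1, y1), 0.99)

  # degenerate margin
  expect_true(is.na(polychoric_pair(rep(2L, 100), y0[1:100])))
})

test_that("the internal bivariate normal CDF matches mvtnorm", {
  worst <- 0
  for (rho in c(-0.9, -0.4, 0, 0.3, 0.85, 0.99)) {
    for (h in c(-2, -0.3, 1.2)) {
      for (k in c(-1.5, 0.4, 2.1)) {
        a <- sensebifactor:::.pbinorm(h, k, rho)
        b <- mvtnorm::pmvnorm(upper = c(h, k),
                              corr = matrix(c(1, rho, rho, 1), 2))[1]
        worst <- max(worst, abs(a - b))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("pair policies mark small and degenerate pairs missing", {
  set.seed(52)
  d <- data.frame(
    subject_id = as.character(1:200), study_id = "s",
    a = sample(1:5, 200, TRUE), b = sample(1:5, 200, TRUE),
    c = c(sample(1:5, 20, TRUE), rep(NA, 180)))
  rt <- response_table(d)
  sm <- polychoric_matrix(rt, min_n = 30)
  expect_true(is.na(sm$rho["a", "c"]))
  expect_false(is.na(sm$rho["a", "b"]))
  expect_true(any(grepl("joint n", sm$dropped)))
  expect_equal(sm$rho, t(sm$rho))
})

test_that("item clustering recovers planted blocks and drops noise items", {
  R <- diag(1, 9)
  R[1:4, 1:4] <- 0.6
  R[5:8, 5:8] <- 0.6
  diag(R) <- 1
  colnames(R) <- rownames(R) <- paste0("i", 1:9)
  res <- iclust_refine(R)
  expect_setequal(res$retained, paste0("i", 1:8))
  expect_equal(res$removal_log$item, "i9")
  expect_equal(length(unique(res$clusters[paste0("i", 1:4)])), 1L)
  expect_equal(length(unique(res$clusters[paste0("i", 5:8)])), 1L)
  expect_false(res$clusters["i1"] == res$clusters["i5"])
  # determinism and reconstruction of the input set
  res2 <- iclust_refine(R)
  expect_identical(res, res2)
  expect_setequal(c(res$retained, res$removal_log$item), colnames(R))
})

test_that("three items form a single cluster with two merges", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  colnames(R) <- rownames(R) <- c("a", "b", "c")
  res <- iclust_refine(R)
  expect_equal(length(res$retained), 3L)
  expect_equal(nrow(res$merges), 2L)
  expect_equal(length(unique(res$clusters)), 1L)
})

test_that("EGA recovers planted communities from bifactor data", {
  L <- loading_matrix(paste0("v", 1:12),
                      rep(c("A", "B", "C"), each = 4),
                      rep(0.45, 12), rep(c(0.55, 0.6, 0.5), each = 4))
  spec <- bifactor_spec(L)
  sim <- simulate_responses(spec, 1200, seed = 53)
  eg <- ega(sim$responses)
  truth <- rep(1:3, each = 4)
  expect_gte(adjusted_rand(eg$membership, truth), 0.9)

  # community count invariant to item relabeling
  d2 <- sim$responses
  perm <- c("subject_id", "study_id", sample(item_columns(d2)))
  d2 <- d2[, perm]
  class(d2) <- c("response_table", "data.frame")
  attr(d2, "n_categories") <- 5L
  eg2 <- ega(d2)
  expect_equal(max(eg2$membership), max(eg$membership))
})

test_that("EGA degenerate structures: one factor and orthogonal doublets", {
  spec1 <- make_uni_spec(rep(0.65, 5))
  eg1 <- ega(simulate_responses(spec1, 800, seed = 54)$responses)
  expect_lte(max(eg1$membership), 2L)   # no specific structure to find

  L <- loading_matrix(paste0("d", 1:4), c("A", "A", "B", "B"),
                      rep(0.02, 4), rep(0.75, 4))
  eg2 <- ega(simulate_responses(bifactor_spec(L), 1500, seed = 55)$responses)
  expect_equal(max(eg2$membership), 2L)
})

test_that("graphical lasso collapses to the inverse at zero penalty", {
  set.seed(56)
  A <- matrix(rnorm(25), 5)
  S <- cov2cor(crossprod(A) + diag(5))
  g <- graphical_lasso(S, 0, tol = 1e-9, max_iter = 500)
  expect_equal(g$Theta, solve(S), tolerance = 1e-4, ignore_attr = TRUE)
  # heavy penalty empties the graph
  g2 <- graphical_lasso(S, 10)
  off <- g2$Theta[upper.tri(g2$Theta)]
  expect_true(all(abs(off) < 1e-8))
})

test_that("weighted topological overlap matches the brute-force oracle", {
  set.seed(57)
  W <- matrix(runif(36, -1, 1), 6)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(wto(W, i, j), oracle_wto(W, i, j), tolerance = 1e-12)
    }
  }
  W2 <- diag(0, 2)
  W2[1, 2] <- W2[2, 1] <- 1
  expect_equal(wto(W2, 1, 2), 1)
  W3 <- diag(0, 4)
  W3[1, 3] <- W3[3, 1] <- 0.8      # disjoint neighborhoods, w_ij = 0
  W3[2, 4] <- W3[4, 2] <- 0.6
  expect_equal(wto(W3, 1, 2), 0)
  expect_error(wto(W3, 2, 2), "undefined")
})
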