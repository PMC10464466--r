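# Shared fixtures and independent oracles for the test suite.

# small unidimensional loading matrix and spec
make_uni_spec <- function(lambdas = c(0.6, 0.7, 0.5, 0.65),
                          thresholds = NULL) {
  L <- loading_matrix(paste0("it", seq_along(lambdas)), NA, lambdas, NA)
  bifactor_spec(L, thresholds = thresholds)
}

# 6-item, 2-specific toy bifactor structure
make_toy_bifactor <- function() {
  L <- loading_matrix(
    paste0("it", 1:6),
    c("A", "A", "A", "B", "B", "B"),
    c(0.5, 0.45, 0.55, 0.5, 0.4, 0.6),
    c(0.55, 0.6, 0.5, 0.65, 0.55, 0.45)
  )
  bifactor_spec(L)
}

# subset a response table to given items, keeping class/attributes
subset_items <- function(data, items) {
  d <- data[, c("subject_id", "study_id", items)]
  class(d) <- c("response_table", "data.frame")
  attr(d, "n_categories") <- attr(data, "n_categories")
  d
}

# --- independent oracles ----------------------------------------------------

# brute-force marginal log-likelihood of a unidimensional GRM by trapezoid
# integration on a dense theta grid
oracle_loglik_uni <- function(model, data, grid = seq(-8, 8, length.out = 4001)) {
  Y <- response_matrix(data)
  h <- diff(grid)[1]
  dens <- dnorm(grid)
  ll <- 0
  for (p in seq_len(nrow(Y))) {
    f <- dens
    for (i in seq_along(model$items)) {
      y <- Y[p, model$items[i]]
      if (is.na(y)) next
      pa <- model$params[[i]]
      b <- pa$b
      cumk <- function(k) {
        if (k == 0) rep(1, length(grid))
        else if (k == length(b) + 1) rep(0, length(grid))
        else pnorm(pa$a[1] * grid - b[k])
      }
      f <- f * (cumk(y - 1) - cumk(y))
    }
    v <- sum((f[-1] + f[-length(f)]) / 2) * h
    ll <- ll + log(v)
  }
  ll
}

# naive full-dimensional quadrature for a bifactor GRM (general + one
# dimension per specific factor, no dimension reduction)
oracle_loglik_bifactor <- function(model, data, n_quad = 21) {
  q <- normal_quadrature(n_quad)
  subs <- unique(model$structure[!is.na(model$structure)])
  S <- length(subs)
  grids <- rep(list(seq_len(n_quad)), S + 1)
  nodes_idx <- as.matrix(expand.grid(grids))
  Y <- response_matrix(data)
  ll <- 0
  for (p in seq_len(nrow(Y))) {
    tot <- 0
    for (r in seq_len(nrow(nodes_idx))) {
      th_g <- q$nodes[nodes_idx[r, 1]]
      w <- q$weights[nodes_idx[r, 1]]
      th_s <- numeric(S)
      for (s in seq_len(S)) {
        th_s[s] <- q$nodes[nodes_idx[r, s + 1]]
        w <- w * q$weights[nodes_idx[r, s + 1]]
      }
      lik <- 1
      for (i in seq_along(model$items)) {
        y <- Y[p, model$items[i]]
        if (is.na(y)) next
        pa <- model$params[[i]]
        eta <- pa$a[1] * th_g
        if (!is.na(model$structure[i])) {
          eta <- eta + pa$a[2] * th_s[match(model$structure[i], subs)]
        }
        b <- pa$b
        cum <- c(1, pnorm(eta - b), 0)
        lik <- lik * (cum[y] - cum[y + 1])
      }
      tot <- tot + w * lik
    }
    ll <- ll + log(tot)
  }
  ll
}

# brute-force weighted topological overlap by explicit double loop
oracle_wto <- function(W, i, j) {
  W <- as.matrix(W)
  diag(W) <- 0
  p <- ncol(W)
  num <- 0
  for (u in seq_len(p)) {
    if (u == i || u == j) next
    num <- num + abs(W[i, u] * W[j, u])
  }
  ki <- 0; kj <- 0
  for (u in seq_len(p)) {
    if (u != i) ki <- ki + abs(W[i, u])
    if (u != j) kj <- kj + abs(W[j, u])
  }
  (num + abs(W[i, j])) / (min(ki, kj) + 1 - abs(W[i, j]))
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
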