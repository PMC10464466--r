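# Marginal maximum likelihood estimation of unidimensional and confirmatory
# bifactor graded response models (probit link), with EM on a fixed
# Gauss-Hermite-type quadrature grid and bifactor dimension reduction:
# the marginal likelihood integrates the general dimension crossed with one
# specific dimension per subscale block, so the cost is O(Q^2 * items)
# instead of Q^(1+S).

#' Gauss-Hermite quadrature for a standard normal density
#'
#' Golub-Welsch nodes/weights for integrals against the N(0,1) density:
#' nodes on the theta scale, weights summing to 1.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`.
#' @export
normal_quadrature <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  x <- e$values[ord]
  w <- e$vectors[1L, ord]^2
  list(nodes = x * sqrt(2), weights = w / sum(w))
}

# K x Q matrix of log category probabilities for one item at linear
# predictor values eta (length Q): P(Y = k) = Phi(eta - b_{k-1}) -
# Phi(eta - b_k), boundary cumulatives 1 and 0.
.item_logprob <- function(b, eta) {
  K <- length(b) + 1L
  cum <- rbind(1, stats::pnorm(outer(-b, eta, "+")), 0)
  P <- cum[seq_len(K), , drop = FALSE] - cum[seq_len(K) + 1L, , drop = FALSE]
  log(pmax(P, 1e-300))
}

# Expected complete-data log-likelihood for one item and its gradient,
# on unconstrained parameters par = (slopes, t) with thresholds
# b = cumsum(t[1], exp(t[-1])). `Theta` is a nodes x n_dims matrix and
# `r` a K x nodes matrix of expected counts.
.item_obj <- function(par, r, Theta) {
  d <- ncol(Theta)
  K <- nrow(r)
  a <- par[seq_len(d)]
  t <- par[-seq_len(d)]
  b <- cumsum(c(t[1L], exp(t[-1L])))
  eta <- drop(Theta %*% a)
  z <- outer(-b, eta, "+")              # (K-1) x Q, z_k = eta - b_k
  cum <- rbind(1, stats::pnorm(z), 0)
  P <- pmax(cum[seq_len(K), , drop = FALSE] -
              cum[seq_len(K) + 1L, , drop = FALSE], 1e-300)
  -sum(r * log(P))
}

.item_grad <- function(par, r, Theta) {
  d <- ncol(Theta)
  K <- nrow(r)
  a <- par[seq_len(d)]
  t <- par[-seq_len(d)]
  b <- cumsum(c(t[1L], exp(t[-1L])))
  eta <- drop(Theta %*% a)
  z <- outer(-b, eta, "+")
  phi <- stats::dnorm(z)
  cum <- rbind(1, stats::pnorm(z), 0)
  P <- pmax(cum[seq_len(K), , drop = FALSE] -
              cum[seq_len(K) + 1L, , drop = FALSE], 1e-300)
  ratio <- r / P
  # dL/dcum_{k}: boundary k enters P_k with -1 and P_{k+1} with +1
  g <- ratio[seq_len(K - 1L) + 1L, , drop = FALSE] -
    ratio[seq_len(K - 1L), , drop = FALSE]
  deta <- colSums(g * phi)              # dL/deta_q
  ga <- drop(crossprod(Theta, deta))
  gb <- -rowSums(g * phi)               # dL/db_k
  gt <- numeric(length(t))
  cs <- rev(cumsum(rev(gb)))            # sum_{k >= m} dL/db_k
  gt[1L] <- cs[1L]
  if (length(t) > 1L) gt[-1L] <- exp(t[-1L]) * cs[-1L]
  -c(ga, gt)
}

# Collapse empty observed categories into the adjacent lower category;
# returns remapped responses (1..K_new) and the remap vector.
.collapse_categories <- function(y, K) {
  cnt <- tabulate(y[!is.na(y)], nbins = K)
  remap <- cummax(cumsum(cnt > 0L))
  remap[remap == 0L] <- 1L              # leading empty categories join upward
  list(y = remap[y], remap = remap, K = max(remap))
}

.structure_subscales <- function(structure, items) {
  if (is.null(structure)) {
    structure <- rep(NA_character_, length(items))
    names(structure) <- items
  }
  structure <- structure[items]
  names(structure) <- items
  structure
}

#' Fit a graded response model by EM marginal maximum likelihood
#'
#' Fits a unidimensional GRM (no `structure`) or a confirmatory bifactor
#' GRM in which every item loads on the general factor and items mapped to
#' a subscale additionally load on that subscale's orthogonal specific
#' factor. Estimation is EM: the E-step computes posterior weights on a
#' fixed quadrature grid (with bifactor dimension reduction across
#' subscale blocks), the M-step maximizes each item's expected ordinal
#' likelihood by quasi-Newton with analytic gradients. The marginal
#' log-likelihood is non-decreasing across cycles; items whose observed
#' categories are empty are collapsed with a recorded remapping.
#'
#' @param data a `response_table`.
#' @param structure `NULL` for a unidimensional model, else a named
#'   character vector mapping item_id to subscale label (`NA` = loads on
#'   the general factor only).
#' @param n_quad quadrature nodes per dimension (default 21).
#' @param tol EM stopping tolerance on the log-likelihood change.
#' @param max_iter maximum EM cycles.
#' @param verbose print per-cycle log-likelihoods.
#' @return An object of class `grm_model`.
#' @export
fit_grm <- function(data, structure = NULL, n_quad = 21L, tol = 1e-5,
                    max_iter = 500L, verbose = FALSE) {
  stopifnot(inherits(data, "response_table"))
  items <- item_columns(data)
  if (length(items) < 3L) {
    stop("fewer than the requisite three items for a unidimensional GRM (",
         length(items), " supplied)")
  }
  Y <- response_matrix(data)
  K <- attr(data, "n_categories")
  structure <- .structure_subscales(structure, items)

  remaps <- vector("list", length(items))
  names(remaps) <- items
  Klist <- integer(length(items))
  for (i in seq_along(items)) {
    cc <- .collapse_categories(Y[, i], K)
    if (cc$K < 2L) {
      stop("item ", items[i], " has fewer than 2 observed categories ",
           "(degenerate, cannot be scaled)")
    }
    Y[, i] <- cc$y
    remaps[[i]] <- cc$remap
    Klist[i] <- cc$K
  }

  quad <- normal_quadrature(n_quad)
  # starting values: unit slopes, thresholds from observed margins
  params <- vector("list", length(items))
  names(params) <- items
  for (i in seq_along(items)) {
    has_spec <- !is.na(structure[i])
    nd <- 1L + has_spec
    props <- tabulate(Y[!is.na(Y[, i]), i], nbins = Klist[i])
    cum <- cumsum(props / sum(props))
    b0 <- stats::qnorm(pmin(pmax(cum[-Klist[i]], 1e-4), 1 - 1e-4)) * sqrt(1 + nd)
    b0 <- cummax(b0 + seq_along(b0) * 1e-6)
    params[[i]] <- list(a = rep(1, nd), b = b0)
  }

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    es <- .estep(params, structure, Y, quad)
    if (length(ll_trace) > 0L &&
        es$loglik < ll_old - 1e-6 * max(1, abs(ll_old))) {
      warning("EM log-likelihood decreased at cycle ", iter)
    }
    ll_trace <- c(ll_trace, es$loglik)
    if (is.finite(ll_old) && abs(es$loglik - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- es$loglik
    params <- .mstep(params, structure, es, quad, Y)
    if (verbose) cat(sprintf("cycle %3d  loglik %.6f\n", iter, es$loglik))
  }

  structure(list(items = items, params = params, structure = structure,
                 link = "probit", quad = quad, K = Klist, remap = remaps,
                 loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
                 converged = converged, n_iter = length(ll_trace),
                 n_obs = nrow(Y)),
            class = "grm_model")
}

# E-step with bifactor dimension reduction. Returns marginal loglik,
# posterior over the general grid, and per-block quantities needed for
# expected counts.
.estep <- function(params, structure, Y, quad) {
  n <- nrow(Y)
  Q <- length(quad$nodes)
  items <- names(params)
  subs <- unique(structure[!is.na(structure)])
  logw <- log(quad$weights)

  # log item probability tables
  # general-only items: K x Q over the general grid
  llg <- matrix(0, n, Q)                 # sum over general-only items
  blockC <- list()                       # per subscale: n x (Q*Q) log-lik
  for (i in seq_along(items)) {
    p <- params[[i]]
    obs <- which(!is.na(Y[, i]))
    if (is.na(structure[i])) {
      lp <- .item_logprob(p$b, p$a[1L] * quad$nodes)
      llg[obs, ] <- llg[obs, ] + lp[Y[obs, i], , drop = FALSE]
    } else {
      s <- structure[i]
      eta <- outer(p$a[1L] * quad$nodes, p$a[2L] * quad$nodes, "+") # Qg x Qs
      lp <- .item_logprob(p$b, as.vector(eta))  # K x (Qg*Qs)
      if (is.null(blockC[[s]])) blockC[[s]] <- matrix(0, n, Q * Q)
      blockC[[s]][obs, ] <- blockC[[s]][obs, ] + lp[Y[obs, i], , drop = FALSE]
    }
  }

  # A_s[p, qg] = sum_qs w_qs exp(C_s[p, qg, qs])
  blockA <- lapply(blockC, function(C) {
    E <- exp(C)
    dim(E) <- c(nrow(C), Q, Q)
    A <- matrix(0, nrow(C), Q)
    for (qs in seq_len(Q)) A <- A + quad$weights[qs] * E[, , qs]
    pmax(A, 1e-300)
  })

  llmix <- llg
  for (s in subs) llmix <- llmix + log(blockA[[s]])
  lw <- sweep(llmix, 2L, logw, "+")
  m <- apply(lw, 1L, max)
  Lp <- m + log(rowSums(exp(lw - m)))
  postG <- exp(lw - Lp)                  # n x Q posterior over general grid

  list(loglik = sum(Lp), postG = postG, blockC = blockC, blockA = blockA,
       Q = Q)
}

.mstep <- function(params, structure, es, quad, Y) {
  items <- names(params)
  Q <- es$Q
  Theta_uni <- matrix(quad$nodes, ncol = 1L)
  # joint grid in the same column-major layout as the block arrays:
  # column index qg + Q * (qs - 1)
  Theta_bi <- cbind(rep(quad$nodes, times = Q), rep(quad$nodes, each = Q))
  # joint posterior per block, reused across that block's items
  joint <- list()
  for (s in names(es$blockC)) {
    E <- exp(es$blockC[[s]])
    W <- es$postG / es$blockA[[s]]       # n x Qg
    J <- E * W[, rep(seq_len(Q), times = Q)]
    J <- sweep(J, 2L, rep(quad$weights, each = Q), "*")
    joint[[s]] <- J
  }
  for (i in seq_along(items)) {
    p <- params[[i]]
    obs <- which(!is.na(Y[, i]))
    K <- length(p$b) + 1L
    if (is.na(structure[i])) {
      post <- es$postG
      Theta <- Theta_uni
    } else {
      post <- joint[[structure[i]]]
      Theta <- Theta_bi
    }
    r <- matrix(0, K, ncol(post))
    agg <- rowsum(post[obs, , drop = FALSE], group = Y[obs, i])
    r[as.integer(rownames(agg)), ] <- agg
    par0 <- c(p$a, p$b[1L], log(diff(p$b)))
    if (length(p$b) == 1L) par0 <- c(p$a, p$b[1L])
    f0 <- .item_obj(par0, r, Theta)
    opt <- try(stats::optim(par0, .item_obj, .item_grad, r = r, Theta = Theta,
                            method = "BFGS",
                            control = list(maxit = 60L)), silent = TRUE)
    if (!inherits(opt, "try-error") && is.finite(opt$value) &&
        opt$value <= f0) {                # GEM guard: never move uphill
      d <- ncol(Theta)
      a <- opt$par[seq_len(d)]
      t <- opt$par[-seq_len(d)]
      b <- cumsum(c(t[1L], exp(t[-1L])))
      params[[i]] <- list(a = a, b = b)
    }
  }
  params
}

#' Marginal log-likelihood of a GRM at its current parameters
#'
#' Missing responses contribute no factor (full-information estimation
#' under ignorable missingness). Bifactor models use the dimension-reduced
#' integral.
#'
#' @param model a `grm_model`.
#' @param data a `response_table` whose items are a subset of the model's.
#' @return scalar log-likelihood.
#' @export
grm_loglik <- function(model, data) {
  stopifnot(inherits(model, "grm_model"), inherits(data, "response_table"))
  common <- intersect(model$items, item_columns(data))
  if (length(common) == 0L) stop("no overlap between model and data items")
  Ydat <- response_matrix(data)
  Y <- matrix(NA_integer_, nrow(Ydat), length(model$items),
              dimnames = list(rownames(Ydat), model$items))
  Y[, common] <- Ydat[, common]
  for (i in seq_along(model$items)) {
    Y[, i] <- model$remap[[i]][Y[, i]]
  }
  .estep(model$params, model$structure, Y, model$quad)$loglik
}

#' @export
print.grm_model <- function(x, ...) {
  subs <- unique(x$structure[!is.na(x$structure)])
  cat("Graded response model (probit):", length(x$items), "items,",
      if (length(subs)) paste("bifactor with", length(subs), "specific factors")
      else "unidimensional", "\n")
  cat(sprintf("loglik %.3f after %d EM cycles (%sconverged)\n",
              x$loglik, x$n_iter, if (x$converged) "" else "NOT "))
  invisible(x)
}
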