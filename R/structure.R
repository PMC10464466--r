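# Data-driven structure checks used during item refinement: hierarchical
# item clustering with iterative removal, a regularized partial-correlation
# network with community detection (EGA), and weighted topological overlap.

# Cronbach alpha of a unit-weight composite of `idx` items, from a
# correlation matrix.
.alpha_of <- function(R, idx) {
  k <- length(idx)
  if (k < 2L) return(0)
  S <- sum(R[idx, idx])
  (k / (k - 1)) * (1 - k / S)
}

# Revelle-style beta of merging clusters A and B: the (Rulon) split-half
# reliability of the combined composite with the merge as the split.
.beta_merge <- function(R, A, B) {
  vA <- sum(R[A, A])
  vB <- sum(R[B, B])
  cAB <- sum(R[A, B, drop = FALSE])
  4 * cAB / (vA + vB + 2 * cAB)
}

#' Iterative item refinement by hierarchical item clustering
#'
#' Agglomerative clustering on an item similarity matrix: at each step the
#' pair of clusters whose merge maximizes the worst-split reliability
#' (beta) of the merged composite is joined, unless the merge would lower
#' both alpha and beta below those of each component (that branch then
#' stops). After the tree is built, items whose correlation with their
#' cluster composite falls below `loading_cut`, or that ended in no
#' multi-item cluster, are removed; clustering repeats on the survivors
#' until an iteration removes nothing (a stable solution). Ties are broken
#' deterministically towards the lexicographically smallest item pair.
#'
#' @param sim a `similarity_matrix` (or plain correlation matrix).
#' @param loading_cut minimum item-cluster composite correlation (default
#'   0.30).
#' @param max_iter safety cap on refinement iterations.
#' @return list with `retained` (item names), `clusters` (named membership
#'   vector on the final solution), `merges` (data.frame log of the final
#'   tree), and `removal_log` (data.frame: item, iteration, reason).
#' @export
iclust_refine <- function(sim, loading_cut = 0.30, max_iter = 25L) {
  R0 <- if (inherits(sim, "similarity_matrix")) sim$rho else as.matrix(sim)
  if (is.null(colnames(R0))) colnames(R0) <- rownames(R0) <-
      paste0("V", seq_len(ncol(R0)))
  if (ncol(R0) < 3L) stop("need at least 3 items to cluster")
  R0[is.na(R0)] <- 0
  items <- colnames(R0)
  removal <- data.frame(item = character(0), iteration = integer(0),
                        reason = character(0), stringsAsFactors = FALSE)
  keep <- items
  clusters <- NULL
  merges <- NULL
  for (it in seq_len(max_iter)) {
    if (length(keep) == 0L) {
      stop("all items removed during refinement; removal log:\n",
           paste(removal$item, removal$reason, collapse = "; "))
    }
    if (length(keep) < 3L) break
    R <- R0[keep, keep]
    cl <- .iclust_tree(R)
    clusters <- cl$membership
    merges <- cl$merges
    # item loading = correlation with its cluster's unit-weight composite
    drop_items <- character(0)
    for (nm in names(clusters)) {
      memb <- names(clusters)[clusters == clusters[nm]]
      if (length(memb) < 2L) {
        drop_items <- c(drop_items, nm)
        removal <- rbind(removal, data.frame(
          item = nm, iteration = it, reason = "joined no cluster",
          stringsAsFactors = FALSE))
        next
      }
      load <- sum(R[nm, memb]) / sqrt(sum(R[memb, memb]))
      if (load < loading_cut) {
        drop_items <- c(drop_items, nm)
        removal <- rbind(removal, data.frame(
          item = nm, iteration = it,
          reason = sprintf("cluster loading %.3f < %.2f", load, loading_cut),
          stringsAsFactors = FALSE))
      }
    }
    if (length(drop_items) == 0L) break
    keep <- setdiff(keep, drop_items)
  }
  list(retained = keep, clusters = clusters, merges = merges,
       removal_log = removal)
}

# Build the cluster tree for one iteration; returns final membership and
# the merge log.
.iclust_tree <- function(R) {
  items <- colnames(R)
  cl <- as.list(items)
  names(cl) <- items
  stats <- lapply(items, function(i) c(alpha = 0, beta = 0))
  names(stats) <- items
  frozen <- logical(length(cl))
  merges <- data.frame(a = character(0), b = character(0), beta = numeric(0),
                       alpha = numeric(0), stringsAsFactors = FALSE)
  repeat {
    act <- which(!frozen)
    if (length(act) < 2L) break
    best <- NULL
    best_beta <- -Inf
    for (ii in seq_along(act)) {
      for (jj in seq_along(act)) {
        if (jj <= ii) next
        A <- cl[[act[ii]]]; B <- cl[[act[jj]]]
        bb <- .beta_merge(R, A, B)
        if (bb > best_beta + 1e-12) {
          best_beta <- bb
          best <- c(act[ii], act[jj])
        }
      }
    }
    A <- cl[[best[1L]]]; B <- cl[[best[2L]]]
    new_alpha <- .alpha_of(R, c(A, B))
    sA <- stats[[best[1L]]]; sB <- stats[[best[2L]]]
    # stop this branch if the merge worsens both alpha and beta
    if (length(A) + length(B) > 2L &&
        new_alpha < min(sA["alpha"], sB["alpha"]) &&
        best_beta < min(sA["beta"], sB["beta"])) {
      frozen[best[1L]] <- TRUE
      frozen[best[2L]] <- TRUE
      next
    }
    merges <- rbind(merges, data.frame(
      a = paste(A, collapse = "+"), b = paste(B, collapse = "+"),
      beta = best_beta, alpha = new_alpha, stringsAsFactors = FALSE))
    cl[[best[1L]]] <- c(A, B)
    stats[[best[1L]]] <- c(alpha = new_alpha, beta = best_beta)
    cl[[best[2L]]] <- NULL
    stats[[best[2L]]] <- NULL
    frozen <- frozen[-best[2L]]
  }
  membership <- integer(length(items))
  names(membership) <- items
  for (g in seq_along(cl)) membership[cl[[g]]] <- g
  list(membership = membership, merges = merges)
}

#' Graphical lasso estimate of a sparse inverse covariance
#'
#' Block coordinate descent (one lasso-regularized column update per
#' sweep) on a correlation/covariance matrix.
#'
#' @param S covariance or correlation matrix.
#' @param rho L1 penalty.
#' @param tol convergence tolerance on the average absolute change of W.
#' @param max_iter maximum sweeps.
#' @return list with `Theta` (precision), `W` (estimated covariance),
#'   `partial` (partial correlation matrix).
#' @export
graphical_lasso <- function(S, rho, tol = 1e-5, max_iter = 100L) {
  p <- ncol(S)
  W <- S + diag(rho, p)
  Beta <- matrix(0, p, p)
  off <- mean(abs(S[upper.tri(S)]))
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx]
      s12 <- S[idx, j]
      b <- Beta[idx, j]
      # inner lasso by coordinate descent
      for (inner in seq_len(200L)) {
        b_old <- b
        for (k in seq_along(idx)) {
          r <- s12[k] - sum(W11[k, -k] * b[-k])
          b[k] <- sign(r) * max(abs(r) - rho, 0) / W11[k, k]
        }
        if (max(abs(b - b_old)) < tol * max(off, 1e-8)) break
      }
      Beta[idx, j] <- b
      w12 <- W11 %*% b
      W[idx, j] <- W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)) < tol * max(off, 1e-8)) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    Theta[j, j] <- 1 / (W[j, j] - sum(W[idx, j] * Beta[idx, j]))
    Theta[idx, j] <- -Beta[idx, j] * Theta[j, j]
  }
  Theta <- (Theta + t(Theta)) / 2
  d <- sqrt(diag(Theta))
  partial <- -Theta / outer(d, d)
  diag(partial) <- 1
  dimnames(Theta) <- dimnames(partial) <- dimnames(W) <- dimnames(S)
  list(Theta = Theta, W = W, partial = partial)
}

#' Exploratory graph analysis of an ordinal response table
#'
#' Estimates a regularized partial-correlation network on the polychoric
#' correlation matrix (graphical lasso over a log-spaced penalty grid,
#' model chosen by EBIC with gamma = 0.5) and detects communities with the
#' (deterministic, seedless) walktrap random-walk algorithm on absolute
#' edge weights. Non-positive-definite input matrices are repaired by
#' eigenvalue clipping (logged).
#'
#' @param data a `response_table`, or a precomputed `similarity_matrix`.
#' @param n sample size (required when a matrix is supplied; taken from
#'   the data otherwise).
#' @param gamma EBIC hyperparameter.
#' @param n_penalties penalty grid size.
#' @param min_n passed to [polychoric_matrix()].
#' @return An object of class `community_solution`: `membership` (named,
#'   contiguous integer labels), `network` (partial-correlation weights),
#'   `penalty`, `ebic`, `repaired`, `modularity`.
#' @export
ega <- function(data, n = NULL, gamma = 0.5, n_penalties = 100L, min_n = 30L) {
  if (inherits(data, "response_table")) {
    sim <- polychoric_matrix(data, min_n = min_n)
    R <- sim$rho
    n <- nrow(data)
  } else {
    R <- if (inherits(data, "similarity_matrix")) data$rho else as.matrix(data)
    if (is.null(n)) stop("supply n when passing a correlation matrix")
  }
  R[is.na(R)] <- 0
  pd <- nearest_pd(R)
  R <- pd$R
  p <- ncol(R)
  rho_max <- max(abs(R[upper.tri(R)]))
  grid <- exp(seq(log(rho_max), log(rho_max * 0.01),
                  length.out = n_penalties))
  best <- NULL
  best_ebic <- Inf
  for (rho in grid) {
    g <- graphical_lasso(R, rho)
    E <- sum(abs(g$Theta[upper.tri(g$Theta)]) > 1e-8)
    ll <- (n / 2) * (determinant(g$Theta)$modulus[1] - sum(R * g$Theta))
    ebic <- -2 * ll + E * log(n) + 4 * gamma * E * log(p)
    if (ebic < best_ebic) {
      best_ebic <- ebic
      best <- list(g = g, penalty = rho, ebic = ebic)
    }
  }
  net <- best$g$partial
  diag(net) <- 0
  net[abs(net) < 1e-8] <- 0
  gr <- igraph::graph_from_adjacency_matrix(abs(net), mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  if (igraph::ecount(gr) == 0L) {
    membership <- stats::setNames(rep(1L, p), colnames(R))
    mod <- 0
  } else {
    wt <- igraph::cluster_walktrap(gr)
    membership <- igraph::membership(wt)
    membership <- stats::setNames(as.integer(factor(membership)), colnames(R))
    mod <- igraph::modularity(wt)
  }
  structure(list(membership = membership, network = net,
                 penalty = best$penalty, ebic = best$ebic,
                 repaired = pd$repaired, modularity = mod),
            class = "community_solution")
}

#' @export
print.community_solution <- function(x, ...) {
  cat("EGA solution:", max(x$membership), "communities over",
      length(x$membership), "items (penalty", signif(x$penalty, 3),
      ", modularity", round(x$modularity, 3), ")\n")
  invisible(x)
}

#' Weighted topological overlap between two network nodes
#'
#' wTO_ij = (sum_u |w_iu w_ju| + |w_ij|) / (min(k_i, k_j) + 1 - |w_ij|)
#' with k_i = sum_u |w_iu|, the sum over u excluding i and j.
#'
#' @param W weighted adjacency matrix (diagonal ignored).
#' @param i,j node names or indices (must differ).
#' @return scalar overlap.
#' @export
wto <- function(W, i, j) {
  W <- as.matrix(W)
  diag(W) <- 0
  if (is.character(i)) i <- match(i, colnames(W))
  if (is.character(j)) j <- match(j, colnames(W))
  if (is.na(i) || is.na(j)) stop("unknown node")
  if (i == j) stop("wTO is undefined for i == j")
  u <- setdiff(seq_len(ncol(W)), c(i, j))
  ki <- sum(abs(W[i, -i]))
  kj <- sum(abs(W[j, -j]))
  (sum(abs(W[i, u] * W[j, u])) + abs(W[i, j])) /
    (min(ki, kj) + 1 - abs(W[i, j]))
}
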