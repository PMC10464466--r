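# Two-step maximum-likelihood polychoric correlations: thresholds from the
# univariate margins (inverse-normal cumulative proportions), then a 1-D
# likelihood maximization over the latent bivariate-normal correlation.

# Vectorized standard bivariate normal CDF Phi2(h, k; rho) via the
# tetrachoric series integral Phi(h)Phi(k) + int_0^rho phi2(h, k; r) dr,
# evaluated with fixed Gauss-Legendre nodes. Accurate to ~1e-10 for
# |rho| <= 0.999.
.pbinorm <- function(h, k, rho) {
  h <- pmin(pmax(h, -8.2), 8.2)
  k <- pmin(pmax(k, -8.2), 8.2)
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (abs(rho) < 1e-12) return(base)
  gl <- .gauss_legendre_32
  r <- rho / 2 * (gl$x + 1)              # map [-1,1] -> [0, rho]
  wr <- abs(rho) / 2 * gl$w
  acc <- 0
  for (q in seq_along(r)) {
    rr <- r[q]
    om <- 1 - rr^2
    dens <- exp(-(h^2 - 2 * rr * h * k + k^2) / (2 * om)) /
      (2 * pi * sqrt(om))
    acc <- acc + sign(rho) * wr[q] * dens
  }
  base + acc
}

.gauss_legendre_32 <- local({
  n <- 32L
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = 2 * e$vectors[1L, ord]^2)
})

#' Polychoric correlation of two ordinal variables
#'
#' Two-step ML: thresholds fixed at the inverse-normal of the observed
#' cumulative margins, correlation maximizing the bivariate-normal
#' contingency-table likelihood over (-0.999, 0.999).
#'
#' @param x,y integer ordinal vectors (pairwise-complete cases used).
#' @return estimated latent correlation, or `NA` if a margin is degenerate
#'   (all observations in one category).
#' @export
polychoric_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x, y)
  tab <- tab[rowSums(tab) > 0L, colSums(tab) > 0L, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  n <- sum(tab)
  ta <- stats::qnorm(cumsum(rowSums(tab))[-nrow(tab)] / n)
  tb <- stats::qnorm(cumsum(colSums(tab))[-ncol(tab)] / n)
  A <- c(-Inf, ta, Inf)
  B <- c(-Inf, tb, Inf)
  gh <- as.vector(outer(A, B, function(a, b) a))   # row thresholds grid
  gk <- as.vector(outer(A, B, function(a, b) b))
  nr <- nrow(tab) + 1L                   # grid rows incl. +/- Inf boundaries
  nc <- ncol(tab) + 1L
  nll <- function(rho) {
    Cmat <- matrix(.pbinorm(gh, gk, rho), nr, nc)
    P <- Cmat[-1L, -1L, drop = FALSE] - Cmat[-nr, -1L, drop = FALSE] -
      Cmat[-1L, -nc, drop = FALSE] + Cmat[-nr, -nc, drop = FALSE]
    -sum(tab * log(pmax(P, 1e-12)))
  }
  stats::optimize(nll, c(-0.999, 0.999))$minimum
}

#' Pairwise polychoric (or Pearson) correlation matrix
#'
#' @param data a `response_table` (or integer matrix).
#' @param min_n minimum joint observations for a pair; below it the entry
#'   is `NA` (default 30).
#' @param method `"polychoric"` or `"pearson"` (fallback for unestimable
#'   polychorics when `fallback = TRUE`).
#' @param fallback replace unestimable polychoric entries (degenerate
#'   margins) by Pearson correlations where computable.
#' @return An object of class `similarity_matrix`: list with `rho`
#'   (symmetric, unit diagonal), `n` (pairwise sample sizes), and `dropped`
#'   (log of pairs set to `NA` and why).
#' @export
polychoric_matrix <- function(data, min_n = 30L,
                              method = c("polychoric", "pearson"),
                              fallback = TRUE) {
  method <- match.arg(method)
  Y <- if (inherits(data, "response_table")) response_matrix(data) else
    as.matrix(data)
  p <- ncol(Y)
  rho <- diag(1, p)
  npair <- matrix(0L, p, p)
  dimnames(rho) <- dimnames(npair) <- list(colnames(Y), colnames(Y))
  dropped <- character(0)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      ok <- !is.na(Y[, i]) & !is.na(Y[, j])
      nij <- sum(ok)
      npair[i, j] <- npair[j, i] <- nij
      if (nij < min_n) {
        rho[i, j] <- rho[j, i] <- NA_real_
        dropped <- c(dropped, sprintf("%s:%s joint n=%d < %d",
                                      colnames(Y)[i], colnames(Y)[j], nij,
                                      min_n))
        next
      }
      r <- if (method == "polychoric") polychoric_pair(Y[ok, i], Y[ok, j])
      else suppressWarnings(stats::cor(Y[ok, i], Y[ok, j]))
      if (is.na(r) && fallback && method == "polychoric") {
        r <- suppressWarnings(stats::cor(Y[ok, i], Y[ok, j]))
        dropped <- c(dropped, sprintf("%s:%s degenerate margin, Pearson used",
                                      colnames(Y)[i], colnames(Y)[j]))
      } else if (is.na(r)) {
        dropped <- c(dropped, sprintf("%s:%s degenerate margin",
                                      colnames(Y)[i], colnames(Y)[j]))
      }
      rho[i, j] <- rho[j, i] <- r
    }
  }
  diag(npair) <- colSums(!is.na(Y))
  structure(list(rho = rho, n = npair, dropped = dropped),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Similarity matrix:", ncol(x$rho), "items;",
      sum(is.na(x$rho[upper.tri(x$rho)])), "unestimable pair(s)\n")
  invisible(x)
}

#' Nearest positive-definite repair of a correlation matrix
#'
#' Eigenvalue clipping at `eps` followed by rescaling to unit diagonal.
#'
#' @param R symmetric matrix.
#' @param eps eigenvalue floor.
#' @return list with `R` (repaired) and `repaired` (logical).
#' @export
nearest_pd <- function(R, eps = 1e-6) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) > eps) return(list(R = R, repaired = FALSE))
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / outer(d, d)
  dimnames(R2) <- dimnames(R)
  list(R = R2, repaired = TRUE)
}
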