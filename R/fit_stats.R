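# Limited-information global fit for ordinal factor models: SRMR on the
# polychoric scale, a quadratic-form chi-square on univariate + bivariate
# margin residuals with sparse-cell collapsing, and the a priori adequacy
# gates.

#' Limited-information standardized root-mean-square residual
#'
#' Root mean square of the discrepancies between sample polychoric
#' correlations and the model-implied latent-response correlations
#' Lambda Lambda' over off-diagonal pairs. Pairs whose polychoric is
#' unestimable are excluded (logged in the attribute `n_pairs_used`).
#'
#' @param loadings a `loading_matrix`.
#' @param data a `response_table`, or a precomputed `similarity_matrix` /
#'   correlation matrix whose rows match the loading matrix items.
#' @param min_n minimum joint observations per pair.
#' @return scalar SRMR with attribute `n_pairs_used`.
#' @export
srmr <- function(loadings, data, min_n = 30L) {
  stopifnot(inherits(loadings, "loading_matrix"))
  S <- if (inherits(data, "response_table")) {
    polychoric_matrix(data, min_n = min_n)$rho
  } else if (inherits(data, "similarity_matrix")) data$rho else as.matrix(data)
  items <- loadings$item_id
  if (!all(items %in% colnames(S))) stop("sample matrix lacks model items")
  S <- S[items, items]
  spec <- bifactor_spec(loadings, thresholds = stats::qnorm(c(.25, .5, .75)))
  implied <- implied_correlation(spec)
  ut <- upper.tri(S)
  resid <- (S - implied)[ut]
  ok <- !is.na(resid)
  if (!any(ok)) stop("no estimable item pairs")
  out <- sqrt(mean(resid[ok]^2))
  attr(out, "n_pairs_used") <- sum(ok)
  out
}

# Model-implied category probabilities. Returns per item a K x Q matrix of
# P(category | general node) marginal over its specific factor, and for
# same-subscale pairs the full K x Q x Q conditional tables are rebuilt on
# demand.
.implied_tables <- function(model) {
  quad <- model$quad
  Q <- length(quad$nodes)
  lapply(seq_along(model$items), function(i) {
    p <- model$params[[i]]
    if (is.na(model$structure[i])) {
      exp(.item_logprob(p$b, p$a[1L] * quad$nodes))
    } else {
      eta <- outer(p$a[1L] * quad$nodes, p$a[2L] * quad$nodes, "+")
      P <- exp(.item_logprob(p$b, as.vector(eta)))       # K x (Qg*Qs)
      K <- nrow(P)
      dim(P) <- c(K, Q, Q)
      # marginal over the specific dimension
      Pm <- matrix(0, K, Q)
      for (qs in seq_len(Q)) Pm <- Pm + quad$weights[qs] * P[, , qs]
      attr(Pm, "joint") <- P
      Pm
    }
  })
}

# Collapse sparse categories of a bivariate expected/observed table until
# every expected cell reaches `min_expected`: repeatedly merge the margin
# category with the smallest expected mass into its adjacent category.
.collapse_bivariate <- function(obs, expd, min_expected = 1) {
  merge_margin <- function(O, E, margin) {
    sums <- if (margin == 1L) rowSums(E) else colSums(E)
    k <- which.min(sums)
    into <- if (k == 1L) 2L else k - 1L
    if (margin == 1L) {
      O[into, ] <- O[into, ] + O[k, ]; E[into, ] <- E[into, ] + E[k, ]
      list(O = O[-k, , drop = FALSE], E = E[-k, , drop = FALSE])
    } else {
      O[, into] <- O[, into] + O[, k]; E[, into] <- E[, into] + E[, k]
      list(O = O[, -k, drop = FALSE], E = E[, -k, drop = FALSE])
    }
  }
  while (min(expd) < min_expected && (nrow(expd) > 2L || ncol(expd) > 2L)) {
    pos <- which(expd == min(expd), arr.ind = TRUE)[1L, ]
    margin <- if (nrow(expd) > 2L &&
                  (ncol(expd) <= 2L ||
                     rowSums(expd)[pos[1L]] <= colSums(expd)[pos[2L]])) 1L
    else 2L
    m <- merge_margin(obs, expd, margin)
    obs <- m$O; expd <- m$E
  }
  list(obs = obs, expd = expd)
}

#' Limited-information chi-square fit statistic and derived indices
#'
#' A quadratic-form statistic built from univariate and bivariate margin
#' residuals of the fitted model: Pearson-type discrepancies between
#' observed and model-implied one- and two-way category tables, with
#' sparse bivariate cells collapsed to a minimum expected count, summed
#' over items and pairs. Degrees of freedom are the summed table degrees
#' of freedom minus the number of free item parameters. RMSEA =
#' sqrt(max(0, (X2 - df) / (df (N - 1)))); TLI is computed against an
#' independence baseline (thresholds only, zero loadings). SRMR is
#' appended from [srmr()].
#'
#' @param model a converged `grm_model`.
#' @param data a `response_table`.
#' @param min_expected minimum expected cell count before collapsing.
#' @param min_n minimum joint observations per pair for the SRMR
#'   polychorics.
#' @param sim optional precomputed `similarity_matrix` for the SRMR step
#'   (avoids re-estimating polychorics when several models are compared on
#'   the same data).
#' @return An object of class `fit_index_set` with fields `statistic`,
#'   `df`, `tli`, `rmsea`, `srmr`, `n`, `available`.
#' @export
limited_info_chisq <- function(model, data, min_expected = 1, min_n = 30L,
                               sim = NULL) {
  stopifnot(inherits(model, "grm_model"), inherits(data, "response_table"))
  Y <- .model_Y(model, data)
  N <- nrow(Y)
  quad <- model$quad
  Q <- length(quad$nodes)
  wg <- quad$weights
  p <- length(model$items)
  tabs <- .implied_tables(model)

  X2 <- 0
  df_model <- 0
  X2b <- 0
  df_base <- 0
  # univariate margins
  uni_obs <- vector("list", p)
  for (i in seq_len(p)) {
    obs <- tabulate(Y[!is.na(Y[, i]), i], nbins = model$K[i])
    uni_obs[[i]] <- obs / sum(obs)
    pi_i <- drop(tabs[[i]] %*% wg)
    E <- pi_i * sum(obs)
    X2 <- X2 + sum((obs - E)^2 / pmax(E, 1e-12))
    df_model <- df_model + model$K[i] - 1L
    df_base <- df_base + model$K[i] - 1L
  }
  # bivariate margins
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      ok <- !is.na(Y[, i]) & !is.na(Y[, j])
      nij <- sum(ok)
      if (nij == 0L) next
      obs <- table(factor(Y[ok, i], levels = seq_len(model$K[i])),
                   factor(Y[ok, j], levels = seq_len(model$K[j])))
      obs <- matrix(as.numeric(obs), model$K[i], model$K[j])
      si <- model$structure[i]
      sj <- model$structure[j]
      if (!is.na(si) && !is.na(sj) && si == sj) {
        Pi <- attr(tabs[[i]], "joint")
        Pj <- attr(tabs[[j]], "joint")
        piij <- matrix(0, model$K[i], model$K[j])
        for (qg in seq_len(Q)) {
          acc <- matrix(0, model$K[i], model$K[j])
          for (qs in seq_len(Q)) {
            acc <- acc + wg[qs] * tcrossprod(Pi[, qg, qs], Pj[, qg, qs])
          }
          piij <- piij + wg[qg] * acc
        }
      } else {
        Pi <- tabs[[i]]
        Pj <- tabs[[j]]
        piij <- matrix(0, model$K[i], model$K[j])
        for (qg in seq_len(Q)) {
          piij <- piij + wg[qg] * tcrossprod(Pi[, qg], Pj[, qg])
        }
      }
      cm <- .collapse_bivariate(obs, nij * piij, min_expected)
      X2 <- X2 + sum((cm$obs - cm$expd)^2 / pmax(cm$expd, 1e-12))
      df_model <- df_model + length(cm$expd) - 1L
      # baseline: product of observed univariate margins
      Eb <- nij * tcrossprod(uni_obs[[i]], uni_obs[[j]])
      cb <- .collapse_bivariate(obs, Eb, min_expected)
      X2b <- X2b + sum((cb$obs - cb$expd)^2 / pmax(cb$expd, 1e-12))
      df_base <- df_base + length(cb$expd) - 1L
    }
  }
  n_par <- sum(vapply(model$params,
                      function(pp) length(pp$a) + length(pp$b), 1L))
  n_thresh <- sum(vapply(model$params, function(pp) length(pp$b), 1L))
  df_model <- df_model - n_par
  df_base <- df_base - n_thresh

  available <- df_model > 0L
  rmsea <- if (available) {
    sqrt(max(0, (X2 - df_model) / (df_model * (N - 1))))
  } else NA_real_
  tli <- if (available && df_base > 0L && X2b / df_base > 1) {
    (X2b / df_base - X2 / df_model) / (X2b / df_base - 1)
  } else NA_real_
  L <- standardize_loadings(model, force = TRUE)
  sr <- try(srmr(L, if (is.null(sim)) data else sim, min_n = min_n),
            silent = TRUE)
  if (inherits(sr, "try-error")) sr <- NA_real_
  structure(list(statistic = X2, df = df_model, tli = tli, rmsea = rmsea,
                 srmr = as.numeric(sr), n = N, available = available,
                 baseline_statistic = X2b, baseline_df = df_base),
            class = "fit_index_set")
}

#' @export
print.fit_index_set <- function(x, ...) {
  if (x$available) {
    cat(sprintf("X2(%d) = %.1f, TLI = %.3f, RMSEA = %.3f, SRMR = %.3f (N = %d)\n",
                x$df, x$statistic, x$tli, x$rmsea, x$srmr, x$n))
  } else {
    cat(sprintf("chi-square unavailable (df <= 0); SRMR = %.3f (N = %d)\n",
                x$srmr, x$n))
  }
  invisible(x)
}

#' Apply the a priori psychometric adequacy gates
#'
#' A scale passes when TLI > 0.97, RMSEA < 0.089, SRMR < 0.05 (< 0.033 for
#' 3-item composites), marginal reliability rho_xx > 0.7, and omega total
#' > 0.7. Criteria whose inputs are unavailable are reported as such and
#' do not fail the scale.
#'
#' @param fit a `fit_index_set` (or `NULL` if no model-based fit exists).
#' @param rho_xx marginal reliability (or `NA`).
#' @param omega_t omega total (or `NA`).
#' @param n_items number of items on the composite.
#' @return list with per-criterion verdicts (`TRUE`/`FALSE`/`NA`) and
#'   `overall` (fails if any evaluated criterion fails).
#' @export
apply_gates <- function(fit, rho_xx = NA_real_, omega_t = NA_real_, n_items) {
  srmr_cut <- if (n_items == 3L) 0.033 else 0.05
  v <- list(
    tli = if (!is.null(fit) && !is.na(fit$tli)) fit$tli > 0.97 else NA,
    rmsea = if (!is.null(fit) && !is.na(fit$rmsea)) fit$rmsea < 0.089 else NA,
    srmr = if (!is.null(fit) && !is.na(fit$srmr)) fit$srmr < srmr_cut else NA,
    rho_xx = if (!is.na(rho_xx)) rho_xx > 0.7 else NA,
    omega_t = if (!is.na(omega_t)) omega_t > 0.7 else NA
  )
  evaluated <- !vapply(v, is.na, TRUE)
  v$overall <- if (!any(evaluated)) NA else all(unlist(v[evaluated]))
  v$srmr_cut <- srmr_cut
  v
}
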