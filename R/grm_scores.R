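# Latent trait scoring from a fitted (or constructed) GRM: EAP estimates,
# marginal reliability, and plausible values drawn from the quadrature
# posterior.

# Remap raw responses onto a model's collapsed category scale and align
# columns with the model's item set (absent items become missing).
.model_Y <- function(model, data) {
  Ydat <- response_matrix(data)
  common <- intersect(model$items, colnames(Ydat))
  if (length(common) == 0L) stop("no overlap between model and data items")
  Y <- matrix(NA_integer_, nrow(Ydat), length(model$items),
              dimnames = list(rownames(Ydat), model$items))
  Y[, common] <- Ydat[, common]
  for (i in seq_along(model$items)) Y[, i] <- model$remap[[i]][Y[, i]]
  Y
}

# Conditional posterior of a subscale's specific dimension given each
# general node: n x (Qg*Qs) matrix of P(qs | qg, data) * P(qg | data).
.joint_block_posterior <- function(es, s, quad) {
  Q <- es$Q
  E <- exp(es$blockC[[s]])
  W <- es$postG / es$blockA[[s]]
  J <- E * W[, rep(seq_len(Q), times = Q)]
  sweep(J, 2L, rep(quad$weights, each = Q), "*")
}

#' Expected a posteriori latent trait scores and marginal reliability
#'
#' EAP mean and posterior SD for the general trait (and, for bifactor
#' models, each specific trait) from the quadrature posterior. Marginal
#' reliability of the primary (general) trait is
#' rho_xx = Var(EAP) / (Var(EAP) + mean posterior variance). Subjects with
#' no non-missing modeled responses are scored at the prior (EAP 0, SD 1)
#' and flagged.
#'
#' @param model a converged `grm_model`.
#' @param data a `response_table`.
#' @param force score from a non-converged model anyway.
#' @return An object of class `score_set`: data.frame `scores` (one
#'   `eap_*`/`sd_*` column pair per trait, plus `flag_no_items`), scalar
#'   `rho_xx`.
#' @export
eap_scores <- function(model, data, force = FALSE) {
  stopifnot(inherits(model, "grm_model"))
  if (!model$converged && !force) {
    stop("model did not converge; pass force = TRUE to score anyway")
  }
  Y <- .model_Y(model, data)
  es <- .estep(model$params, model$structure, Y, model$quad)
  nodes <- model$quad$nodes
  Q <- length(nodes)
  no_items <- rowSums(!is.na(Y)) == 0L

  eap_g <- drop(es$postG %*% nodes)
  var_g <- drop(es$postG %*% nodes^2) - eap_g^2
  out <- data.frame(subject_id = data$subject_id, study_id = data$study_id,
                    eap_general = eap_g, sd_general = sqrt(pmax(var_g, 0)),
                    stringsAsFactors = FALSE)
  for (s in names(es$blockC)) {
    J <- .joint_block_posterior(es, s, model$quad)
    # marginalize over the general grid: column qg + Q*(qs-1) -> qs
    ms <- sapply(seq_len(Q), function(qs) {
      rowSums(J[, (qs - 1L) * Q + seq_len(Q), drop = FALSE])
    })
    eap_s <- drop(ms %*% nodes)
    var_s <- drop(ms %*% nodes^2) - eap_s^2
    out[[paste0("eap_", s)]] <- eap_s
    out[[paste0("sd_", s)]] <- sqrt(pmax(var_s, 0))
  }
  out$flag_no_items <- no_items
  out$eap_general[no_items] <- 0
  out$sd_general[no_items] <- 1

  rho_xx <- stats::var(out$eap_general) /
    (stats::var(out$eap_general) + mean(out$sd_general^2))
  structure(list(scores = out, rho_xx = rho_xx), class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("EAP scores for", nrow(x$scores), "subjects; marginal reliability",
      sprintf("rho_xx = %.3f\n", x$rho_xx))
  invisible(x)
}

#' Plausible values from the quadrature posterior
#'
#' Draws M independent values per subject per trait from the discrete
#' posterior over the quadrature grid, with uniform jitter of half the
#' local node spacing so draws are continuous. Deterministic given `seed`.
#'
#' When the plausible values feed a secondary analysis against a known
#' covariate, supply it as `condition`: the general-trait prior is then
#' tilted to the conditional distribution N(gamma x, 1 - gamma^2), with
#' gamma estimated by moment disattenuation (cov(EAP, x) divided by the
#' EAP variance). Unconditioned draws understate trait-covariate
#' covariances by the marginal reliability factor; conditioning removes
#' that bias, as in large-scale survey scoring practice.
#'
#' @param model a converged `grm_model`.
#' @param data a `response_table`.
#' @param M number of plausible values per subject (default 10).
#' @param seed integer seed.
#' @param condition optional numeric covariate, one value per row of
#'   `data` (NA = no tilt for that subject), used to condition the
#'   general-trait posterior.
#' @param force score from a non-converged model anyway.
#' @return An object of class `plausible_value_set`: list `draws` mapping
#'   trait name to an n x M matrix, plus `subject_id`, `study_id`, `seed`.
#' @export
plausible_values <- function(model, data, M = 10L, seed = 1L,
                             condition = NULL, force = FALSE) {
  stopifnot(inherits(model, "grm_model"))
  if (M < 1L) stop("M must be >= 1")
  if (!model$converged && !force) {
    stop("model did not converge; pass force = TRUE to draw anyway")
  }
  Y <- .model_Y(model, data)
  es <- .estep(model$params, model$structure, Y, model$quad)
  nodes <- model$quad$nodes
  if (!is.null(condition)) {
    if (length(condition) != nrow(Y)) {
      stop("condition must have one value per row of data")
    }
    x <- as.numeric(scale(condition))
    eap <- drop(es$postG %*% nodes)
    ok <- !is.na(x)
    rel <- stats::var(eap[ok])
    gam <- stats::cov(eap[ok], x[ok]) / max(rel, 1e-8)
    gam <- max(-0.95, min(0.95, gam))
    sd_c <- sqrt(1 - gam^2)
    tilt <- matrix(1, nrow(Y), length(nodes))
    tilt[ok, ] <- stats::dnorm(outer(gam * x[ok], nodes, function(m, q) q - m) /
                                 sd_c) / sd_c /
      rep(stats::dnorm(nodes), each = sum(ok))
    pg <- es$postG * tilt
    es$postG <- pg / rowSums(pg)
  }
  Q <- length(nodes)
  n <- nrow(Y)
  # half the local node spacing, per node
  gap <- diff(nodes)
  half <- c(gap[1L], (gap[-length(gap)] + gap[-1L]) / 2, gap[length(gap)]) / 2

  set.seed(seed)
  draws <- list()
  cumG <- t(apply(es$postG, 1L, cumsum))
  gen <- matrix(0, n, M)
  idxG <- matrix(0L, n, M)
  for (m in seq_len(M)) {
    u <- stats::runif(n)
    qi <- max.col(cumG >= u, ties.method = "first")
    idxG[, m] <- qi
    gen[, m] <- nodes[qi] + stats::runif(n, -half[qi], half[qi])
  }
  draws$general <- gen
  for (s in names(es$blockC)) {
    J <- .joint_block_posterior(es, s, model$quad)
    sp <- matrix(0, n, M)
    for (m in seq_len(M)) {
      # conditional P(qs | sampled qg): columns qg + Q*(qs-1)
      cols <- outer(idxG[, m], (seq_len(Q) - 1L) * Q, "+")
      cond <- matrix(J[cbind(rep(seq_len(n), Q), as.vector(cols))], n, Q)
      cond <- cond / pmax(rowSums(cond), 1e-300)
      cumS <- t(apply(cond, 1L, cumsum))
      qi <- max.col(cumS >= stats::runif(n), ties.method = "first")
      sp[, m] <- nodes[qi] + stats::runif(n, -half[qi], half[qi])
    }
    draws[[s]] <- sp
  }
  structure(list(draws = draws, subject_id = data$subject_id,
                 study_id = data$study_id, M = M, seed = seed),
            class = "plausible_value_set")
}

#' @export
print.plausible_value_set <- function(x, ...) {
  cat("Plausible values:", length(x$subject_id), "subjects x", x$M,
      "draws for trait(s):", paste(names(x$draws), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.plausible_value_set <- function(x, ...) {
  out <- data.frame(subject_id = x$subject_id, study_id = x$study_id,
                    stringsAsFactors = FALSE)
  for (tr in names(x$draws)) {
    m <- x$draws[[tr]]
    colnames(m) <- paste0("pv_", tr, "_", seq_len(ncol(m)))
    out <- cbind(out, as.data.frame(m))
  }
  out
}

#' Standardized loadings of a fitted GRM
#'
#' Converts slope parameters on the theta metric to fully standardized
#' loadings: lambda = a / sqrt(1 + sum(a^2)) under the probit link (logit
#' slopes are first rescaled by 1.702); communality h2 = sum(lambda^2) and
#' uniqueness 1 - h2 follow.
#'
#' @param model a converged `grm_model`.
#' @param force standardize a non-converged model anyway.
#' @return A `loading_matrix`.
#' @export
standardize_loadings <- function(model, force = FALSE) {
  stopifnot(inherits(model, "grm_model"))
  if (!model$converged && !force) {
    stop("model did not converge; pass force = TRUE to standardize anyway")
  }
  D <- if (model$link == "logit") 1.702 else 1
  lg <- ls <- numeric(length(model$items))
  for (i in seq_along(model$items)) {
    a <- model$params[[i]]$a / D
    s <- sqrt(1 + sum(a^2))
    lg[i] <- a[1L] / s
    ls[i] <- if (length(a) > 1L) a[2L] / s else 0
  }
  loading_matrix(model$items, unname(model$structure), lg, ls)
}

#' Convert standardized loadings back to theta-metric slopes
#'
#' Inverse of [standardize_loadings()]: a = lambda / sqrt(1 - h2).
#'
#' @param L a `loading_matrix`.
#' @return data.frame with `a_general`, `a_specific` per item.
#' @export
loadings_to_slopes <- function(L) {
  stopifnot(inherits(L, "loading_matrix"))
  u <- sqrt(1 - L$h2)
  data.frame(item_id = L$item_id, subscale = L$subscale,
             a_general = L$lambda_general / u,
             a_specific = L$lambda_specific / u, stringsAsFactors = FALSE)
}

#' Build a GRM with known parameters from a generating spec
#'
#' Maps a generating bifactor spec (standardized loadings + latent-response
#' thresholds) onto the slope/threshold parametrization of the estimation
#' engine: a = lambda / sqrt(1 - h2), b_k = tau_k / sqrt(1 - h2). Useful as
#' a fixed-parameter model for likelihood oracles, model-implied fit
#' statistics, and scoring without estimation.
#'
#' @param spec a `bifactor_spec`.
#' @param n_quad quadrature nodes per dimension.
#' @return A `grm_model` (flagged converged, zero EM cycles).
#' @export
as_grm_model <- function(spec, n_quad = 21L) {
  stopifnot(inherits(spec, "bifactor_spec"))
  L <- spec$loadings
  items <- L$item_id
  params <- vector("list", length(items))
  names(params) <- items
  Klist <- integer(length(items))
  remaps <- vector("list", length(items))
  names(remaps) <- items
  for (i in seq_along(items)) {
    u <- sqrt(1 - L$h2[i])
    a <- L$lambda_general[i] / u
    if (!is.na(L$subscale[i])) a <- c(a, L$lambda_specific[i] / u)
    b <- spec$thresholds[[i]] / u
    params[[i]] <- list(a = a, b = b)
    Klist[i] <- length(b) + 1L
    remaps[[i]] <- seq_len(Klist[i])
  }
  structure(list(items = items, params = params,
                 structure = stats::setNames(L$subscale, items),
                 link = "probit", quad = normal_quadrature(n_quad),
                 K = Klist, remap = remaps, loglik = NA_real_,
                 loglik_trace = numeric(0), converged = TRUE, n_iter = 0L,
                 n_obs = 0L),
            class = "grm_model")
}

#' Generating spec implied by a fitted GRM
#'
#' Inverse companion of [as_grm_model()]: converts fitted slopes and
#' thresholds back to standardized loadings and latent-response-scale
#' thresholds (tau_k = b_k sqrt(1 - h2)), yielding a `bifactor_spec` that
#' generates data from the fitted model (parametric bootstrap).
#'
#' @param model a `grm_model`.
#' @param force allow a non-converged model.
#' @return A `bifactor_spec`.
#' @export
as_bifactor_spec <- function(model, force = FALSE) {
  L <- standardize_loadings(model, force = force)
  thr <- lapply(seq_along(model$items), function(i) {
    model$params[[i]]$b * sqrt(1 - L$h2[i])
  })
  bifactor_spec(L, thresholds = thr)
}

#' Serialize a GRM to JSON
#' @param model a `grm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(model, path) {
  obj <- list(items = model$items,
              structure = as.list(stats::setNames(
                ifelse(is.na(model$structure), "", model$structure),
                model$items)),
              link = model$link,
              n_quad = length(model$quad$nodes),
              params = lapply(model$params, function(p) {
                list(a = p$a, b = p$b)
              }),
              remap = model$remap,
              loglik = model$loglik, converged = model$converged,
              n_iter = model$n_iter)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deserialize a GRM from JSON written by [write_grm()]
#' @param path JSON path.
#' @return A `grm_model`.
#' @export
read_grm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- obj$items
  structure_vec <- unlist(obj$structure)[items]
  structure_vec[structure_vec == ""] <- NA_character_
  params <- lapply(obj$params, function(p) list(a = p$a, b = p$b))[items]
  remaps <- lapply(obj$remap, as.integer)[items]
  structure(list(items = items, params = params, structure = structure_vec,
                 link = obj$link, quad = normal_quadrature(obj$n_quad),
                 K = vapply(params, function(p) length(p$b) + 1L, 1L),
                 remap = remaps, loglik = obj$loglik,
                 loglik_trace = numeric(0), converged = obj$converged,
                 n_iter = obj$n_iter, n_obs = 0L),
            class = "grm_model")
}
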