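# Bayesian random-effects integrative data analysis: a hierarchical linear
# model relating a standardized latent sensory score (entered as plausible
# values) to one correlate, with random study intercepts and slopes,
# ROPE-based evidence classification, and heterogeneity summaries.

.IDA_MODEL <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(b0 + u0[st[i]] + (b1 + u1[st[i]]) * x[i], prec_e)
  }
  # non-centered random effects: correlated intercept/slope deviations
  for (j in 1:J) {
    z0[j] ~ dnorm(0, 1)
    z1[j] ~ dnorm(0, 1)
    u0[j] <- tau0 * z0[j]
    u1[j] <- tau1 * (rho * z0[j] + sqrt(1 - rho * rho) * z1[j])
  }
  b0 ~ dnorm(0, 1)
  b1 ~ dnorm(0, 1)
  tau0 ~ dt(0, pow(0.5, -2), 3) T(0,)
  tau1 ~ dt(0, pow(0.5, -2), 3) T(0,)
  rho ~ dunif(-0.999, 0.999)
  sigma ~ dt(0, 1, 3) T(0,)
  prec_e <- pow(sigma, -2)
}"

#' ROPE-based evidence classification for an effect-size posterior
#'
#' P_ROPE is the posterior mass inside the region of practical equivalence;
#' BF_ROPE is the ratio of posterior to prior odds of lying outside versus
#' inside the ROPE. log(BF_ROPE) > 1.1 / > 2.3 (log 3 and log 10) give
#' moderate / strong evidence of a practically meaningful effect;
#' < -1.1 / < -2.3 give moderate / strong evidence of practical
#' equivalence to zero; values in between are inconclusive.
#'
#' @param posterior numeric vector of posterior effect draws (>= 1000).
#' @param rope length-2 interval, e.g. `c(-0.1, 0.1)` for r.
#' @param prior numeric vector of prior effect draws (>= 1000).
#' @return list with `p_rope`, `log_bf`, `class` ("strong non-null",
#'   "moderate non-null", "inconclusive", "moderate null", "strong null"),
#'   and `floored` (continuity floor applied to an empty side).
#' @export
rope_evidence <- function(posterior, rope, prior) {
  if (length(posterior) < 1000L || length(prior) < 1000L) {
    stop("need at least 1000 posterior and prior draws")
  }
  if (length(rope) != 2L || rope[1L] >= rope[2L]) stop("invalid ROPE interval")
  inside <- function(x) x >= rope[1L] & x <= rope[2L]
  floored <- FALSE
  odds <- function(x) {
    p_in <- mean(inside(x))
    if (p_in == 0 || p_in == 1) {
      p_in <- min(max(p_in, 1 / length(x)), 1 - 1 / length(x))
      floored <<- TRUE
    }
    (1 - p_in) / p_in
  }
  p_rope <- mean(inside(posterior))
  log_bf <- log(odds(posterior)) - log(odds(prior))
  cls <- if (log_bf > 2.3) "strong non-null"
  else if (log_bf > 1.1) "moderate non-null"
  else if (log_bf < -2.3) "strong null"
  else if (log_bf < -1.1) "moderate null"
  else "inconclusive"
  list(p_rope = p_rope, log_bf = log_bf, class = cls, floored = floored)
}

#' Fit a Bayesian random-effects IDA model
#'
#' Hierarchical linear model y_ij = (b0 + u0_j) + (b1 + u1_j) x_ij + e_ij
#' with jointly normal random study intercepts and slopes, fit by Gibbs
#' sampling once per plausible-value replicate and pooled by concatenating
#' posterior draws. The outcome is standardized overall; a continuous
#' predictor is standardized (so b1 is the correlation-scale effect r), a
#' binary predictor enters 0/1 (b1 is Cohen's d on the standardized
#' outcome). Weakly-informative priors: Normal(0,1) on b0 and b1,
#' half-Student-t(3, 0, 0.5) on random-effect SDs, Uniform(-1, 1) on their
#' correlation, half-Student-t(3, 0, 1) on the residual SD. Convergence
#' requires split-Rhat <= 1.01 for b1, the SDs and sigma in every
#' replicate fit.
#'
#' @param pvs a `plausible_value_set` (outcome construct).
#' @param correlates data.frame with `subject_id`, `study_id` and the
#'   predictor column.
#' @param predictor name of the predictor column.
#' @param trait which trait in `pvs` to model (default "general").
#' @param type `"continuous"` (effect reported as r) or `"binary"`
#'   (effect reported as d; predictor must be coded 0/1).
#' @param rope ROPE interval; default `c(-0.1, 0.1)` for r and
#'   `c(-0.2, 0.2)` for d.
#' @param min_cases minimum complete outcome-by-predictor cases (default
#'   100); below it no model is fit.
#' @param n_chains,n_adapt,n_burn,n_iter MCMC settings per chain per
#'   plausible-value replicate; when split-Rhat exceeds 1.01 the chains
#'   are extended by `n_iter` up to `max_extensions` times before the fit
#'   is flagged non-converged.
#' @param max_extensions maximum chain extensions per replicate fit.
#' @param seed integer seed driving the JAGS RNG streams and prior draws.
#' @return An object of class `ida_result`.
#' @export
fit_ida <- function(pvs, correlates, predictor = "x", trait = "general",
                    type = c("continuous", "binary"), rope = NULL,
                    min_cases = 100L, n_chains = 2L, n_adapt = 300L,
                    n_burn = 300L, n_iter = 1500L, max_extensions = 3L,
                    seed = 1L) {
  type <- match.arg(type)
  stopifnot(inherits(pvs, "plausible_value_set"))
  if (is.null(rope)) rope <- if (type == "continuous") c(-0.1, 0.1)
  else c(-0.2, 0.2)
  if (!trait %in% names(pvs$draws)) stop("trait '", trait, "' not in the PV set")
  pv <- pvs$draws[[trait]]
  idx <- match(pvs$subject_id, correlates$subject_id)
  x <- correlates[[predictor]][idx]
  st <- pvs$study_id
  ok <- !is.na(x) & rowSums(is.na(pv)) == 0L
  n_cases <- sum(ok)
  if (n_cases < min_cases) {
    return(structure(list(skipped = TRUE,
                          reason = sprintf("%d cases < %d required",
                                           n_cases, min_cases),
                          n_cases = n_cases),
                     class = "ida_result"))
  }
  x <- x[ok]; pv <- pv[ok, , drop = FALSE]; st <- st[ok]
  studies <- unique(st)
  if (length(studies) < 2L) {
    stop("random-effects IDA requires at least 2 studies (got ",
         length(studies), ")")
  }
  if (type == "continuous") {
    x <- as.numeric(scale(x))
  } else if (!all(x %in% c(0, 1))) {
    stop("binary predictor must be coded 0/1")
  }
  stj <- match(st, studies)
  M <- ncol(pv)
  monitors <- c("b0", "b1", "tau0", "tau1", "rho", "sigma")
  draws <- vector("list", M)
  rhat_max <- 0
  for (m in seq_len(M)) {
    y <- as.numeric(scale(pv[, m]))
    inits <- lapply(seq_len(n_chains), function(ch) {
      list(.RNG.name = "base::Wichmann-Hill",
           .RNG.seed = seed * 1000L + m * 10L + ch)
    })
    jm <- rjags::jags.model(textConnection(.IDA_MODEL),
                            data = list(y = y, x = x, st = stj,
                                        N = length(y), J = length(studies)),
                            inits = inits, n.chains = n_chains,
                            n.adapt = n_adapt, quiet = TRUE)
    stats::update(jm, n_burn, progress.bar = "none")
    sm <- rjags::coda.samples(jm, monitors, n_iter, progress.bar = "none")
    rhat_fit <- .split_rhat(sm, c("b0", "b1", "tau0", "tau1", "sigma"))
    ext <- 0L
    while (rhat_fit > 1.01 && ext < max_extensions) {
      more <- rjags::coda.samples(jm, monitors, n_iter, progress.bar = "none")
      sm <- .bind_mcmc(sm, more)
      rhat_fit <- .split_rhat(sm, c("b0", "b1", "tau0", "tau1", "sigma"))
      ext <- ext + 1L
    }
    rhat_max <- max(rhat_max, rhat_fit)
    draws[[m]] <- as.data.frame(as.matrix(sm))
  }
  post <- do.call(rbind, draws)
  converged <- is.finite(rhat_max) && rhat_max <= 1.01

  set.seed(seed)
  prior_b1 <- stats::rnorm(nrow(post))
  ev <- if (converged) rope_evidence(post$b1, rope, prior_b1) else
    list(p_rope = mean(post$b1 >= rope[1L] & post$b1 <= rope[2L]),
         log_bf = NA_real_, class = NA_character_, floored = FALSE)

  # heterogeneity summaries
  var_x <- if (type == "continuous") 1 else stats::var(x)
  tau2 <- post$tau1^2
  icc <- (post$tau0^2 + tau2 * var_x) / (post$tau0^2 + tau2 * var_x +
                                           post$sigma^2)
  # typical within-study sampling variance of the slope (Higgins-style)
  sg2 <- stats::median(post$sigma)^2
  vj <- vapply(studies, function(s) {
    i <- stj == match(s, studies)
    nv <- sum(i) * max(stats::var(x[i]), 1e-8)
    sg2 / nv
  }, numeric(1))
  w <- 1 / vj
  k <- length(w)
  s_tilde2 <- if (k > 1L) (k - 1L) * sum(w) / (sum(w)^2 - sum(w^2)) else
    mean(vj)
  i2 <- stats::median(tau2 / (tau2 + s_tilde2))
  pred <- post$b1 + stats::rnorm(nrow(post), 0, post$tau1)

  hdi <- .hdi(post$b1, 0.95)
  structure(list(
    skipped = FALSE, type = type, effect_label = if (type == "continuous")
      "r" else "d",
    n_cases = n_cases, n_studies = length(studies), M = M,
    effect_median = stats::median(post$b1), ci = hdi,
    p_rope = ev$p_rope, log_bf = ev$log_bf, class = ev$class,
    floored = ev$floored, rope = rope,
    tau = stats::median(post$tau1), tau2 = stats::median(tau2),
    i2 = i2, icc = stats::median(icc),
    prediction_interval = stats::quantile(pred, c(0.025, 0.975),
                                          names = FALSE),
    rhat_max = rhat_max, converged = converged,
    draws = post, prior_b1 = prior_b1),
    class = "ida_result")
}

# split-Rhat: each chain halved, potential scale reduction over the
# half-chains, maximized over the named parameters
.split_rhat <- function(sm, pars) {
  rh <- vapply(pars, function(p) {
    halves <- unlist(lapply(sm, function(ch) {
      v <- as.numeric(ch[, p])
      h <- length(v) %/% 2L
      list(v[seq_len(h)], v[h + seq_len(h)])
    }), recursive = FALSE)
    mns <- vapply(halves, mean, numeric(1))
    vrs <- vapply(halves, stats::var, numeric(1))
    n <- length(halves[[1L]])
    W <- mean(vrs)
    B <- n * stats::var(mns)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  max(rh)
}

.bind_mcmc <- function(a, b) {
  out <- lapply(seq_along(a), function(i) {
    coda::mcmc(rbind(as.matrix(a[[i]]), as.matrix(b[[i]])))
  })
  coda::mcmc.list(out)
}

# 95% highest-density interval of a draw vector
.hdi <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, floor(prob * n))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' @export
print.ida_result <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("IDA model skipped:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("%s = %.3f [%.3f, %.3f] (95%% HDI), N = %d, %d studies\n",
              x$effect_label, x$effect_median, x$ci[1L], x$ci[2L],
              x$n_cases, x$n_studies))
  cat(sprintf("P_ROPE = %.3f, log BF_ROPE = %s -> %s\n", x$p_rope,
              ifelse(is.na(x$log_bf), "NA", sprintf("%.2f", x$log_bf)),
              ifelse(is.na(x$class), "not classified (non-convergence)",
                     x$class)))
  cat(sprintf("tau = %.3f, tau^2 = %.4f, I^2 = %.2f, ICC = %.2f, 95%% PI [%.3f, %.3f]\n",
              x$tau, x$tau2, x$i2, x$icc, x$prediction_interval[1L],
              x$prediction_interval[2L]))
  if (!x$converged) cat(sprintf("WARNING: max Rhat = %.3f > 1.01\n", x$rhat_max))
  invisible(x)
}

#' Heterogeneity summaries of a fitted IDA model
#'
#' @param fit an `ida_result`.
#' @return list with `tau2` (posterior median of the random-slope
#'   variance), `tau`, `i2`, `icc`, and the 95% `prediction_interval` for
#'   the effect in a new study.
#' @export
heterogeneity <- function(fit) {
  stopifnot(inherits(fit, "ida_result"))
  if (isTRUE(fit$skipped)) stop("model was skipped: ", fit$reason)
  list(tau2 = fit$tau2, tau = fit$tau, i2 = fit$i2, icc = fit$icc,
       prediction_interval = fit$prediction_interval)
}
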