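#' Specify a generating bifactor graded-response structure
#'
#' Couples a standardized loading matrix with per-item response thresholds
#' on the latent-response scale. The generative model is the linear common
#' factor model under a probit link: for item i with general loading
#' lambda_G and specific loading lambda_s, the latent response is
#' y_i = lambda_G theta_G + lambda_s theta_s + e_i with orthogonal standard
#' normal traits and uniqueness variance 1 - h2, and the observed category
#' is 1 plus the count of thresholds below y_i. Default thresholds place
#' category masses at (35, 25, 20, 13, 7)%, the right-skewed shape typical
#' of caregiver-reported frequency ratings.
#'
#' @param loadings a `loading_matrix`.
#' @param thresholds list of strictly increasing numeric vectors (length
#'   K-1) per item, a single vector recycled to all items, or `NULL` for
#'   the default skewed 5-category thresholds.
#' @param link `"probit"` (native) or `"logit"` (converted with the 1.702
#'   scaling constant where slope metrics are needed).
#' @return An object of class `bifactor_spec`.
#' @export
bifactor_spec <- function(loadings, thresholds = NULL, link = c("probit", "logit")) {
  stopifnot(inherits(loadings, "loading_matrix"))
  link <- match.arg(link)
  p <- nrow(loadings)
  if (is.null(thresholds)) {
    thresholds <- stats::qnorm(cumsum(c(0.35, 0.25, 0.20, 0.13)))
  }
  if (is.numeric(thresholds)) thresholds <- rep(list(thresholds), p)
  if (length(thresholds) != p) stop("need one threshold vector per item")
  for (tt in thresholds) {
    if (any(diff(tt) <= 0)) stop("thresholds must be strictly increasing")
  }
  names(thresholds) <- loadings$item_id
  structure(list(loadings = loadings, thresholds = thresholds, link = link),
            class = "bifactor_spec")
}

#' Model-implied latent-response correlation matrix of a spec
#' @param spec a `bifactor_spec`.
#' @return correlation matrix Lambda Lambda' + diag(1 - h2).
#' @export
implied_correlation <- function(spec) {
  L <- spec$loadings
  subs <- unique(L$subscale[!is.na(L$subscale)])
  Lam <- cbind(general = L$lambda_general,
               sapply(subs, function(s) ifelse(L$subscale %in% s,
                                               L$lambda_specific, 0)))
  Lam <- matrix(as.numeric(Lam), nrow = nrow(L))
  R <- Lam %*% t(Lam)
  diag(R) <- 1
  dimnames(R) <- list(L$item_id, L$item_id)
  R
}

# Draw orthogonal standard-normal traits for a spec: general + one column
# per specific factor.
.draw_traits <- function(spec, n) {
  subs <- unique(spec$loadings$subscale[!is.na(spec$loadings$subscale)])
  th <- matrix(stats::rnorm(n * (1L + length(subs))), nrow = n)
  colnames(th) <- c("general", subs)
  th
}

.categorize <- function(y, thresholds) {
  findInterval(y, thresholds) + 1L
}

#' Simulate graded responses from a bifactor spec
#'
#' @param spec a `bifactor_spec`.
#' @param n number of subjects.
#' @param seed integer seed (the draw is deterministic given the seed).
#' @param study_id study label stamped on all rows.
#' @param traits optional pre-drawn trait matrix (n x 1+S, columns
#'   `general` then subscale names) overriding the internal draw.
#' @return list with `responses` (a `response_table`) and `traits` (the
#'   generating trait matrix).
#' @export
simulate_responses <- function(spec, n, seed = 1L, study_id = "S1",
                               traits = NULL) {
  stopifnot(inherits(spec, "bifactor_spec"), n >= 1)
  L <- spec$loadings
  if (any(L$h2 >= 1)) stop("invalid spec: h2 >= 1")
  set.seed(seed)
  if (is.null(traits)) traits <- .draw_traits(spec, n)
  p <- nrow(L)
  resp <- matrix(NA_integer_, nrow = n, ncol = p,
                 dimnames = list(NULL, L$item_id))
  for (i in seq_len(p)) {
    lam_s <- L$lambda_specific[i]
    eta <- L$lambda_general[i] * traits[, "general"]
    if (!is.na(L$subscale[i])) eta <- eta + lam_s * traits[, L$subscale[i]]
    y <- eta + stats::rnorm(n, sd = sqrt(1 - L$h2[i]))
    resp[, i] <- .categorize(y, spec$thresholds[[i]])
  }
  df <- data.frame(subject_id = sprintf("%s_%05d", study_id, seq_len(n)),
                   study_id = study_id, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(resp))
  K <- max(lengths(spec$thresholds)) + 1L
  list(responses = response_table(df, n_categories = K), traits = traits)
}

#' Describe a multi-site simulation design
#'
#' @param n_per_study integer vector of per-study sample sizes (its length
#'   sets the number of studies).
#' @param items_by_study optional list (one character vector per study) of
#'   administered items; items outside the subset are planned-missing for
#'   that study. `NULL` administers everything everywhere.
#' @param effect true standardized effect of the correlate (r for
#'   continuous, Cohen's d for binary) on the target trait.
#' @param effect_type `"continuous"` or `"binary"`.
#' @param tau between-study SD of the per-study effect.
#' @param target trait the correlate relates to: `"general"` or a subscale
#'   name in the generating spec.
#' @param seed master integer seed; per-study substreams are derived from
#'   it so that adding a study leaves earlier studies unchanged.
#' @return An object of class `multisite_design`.
#' @export
multisite_design <- function(n_per_study, items_by_study = NULL,
                             effect = 0.3, effect_type = c("continuous", "binary"),
                             tau = 0.05, target = "general", seed = 1L) {
  effect_type <- match.arg(effect_type)
  if (length(n_per_study) < 1L) stop("need at least one study")
  if (tau < 0) stop("tau must be >= 0")
  if (!is.null(items_by_study)) {
    if (length(items_by_study) != length(n_per_study)) {
      stop("items_by_study must have one entry per study")
    }
    if (any(lengths(items_by_study) == 0L)) {
      stop("administered item subsets must be nonempty")
    }
  }
  structure(list(n_per_study = as.integer(n_per_study),
                 items_by_study = items_by_study, effect = effect,
                 effect_type = effect_type, tau = tau, target = target,
                 seed = as.integer(seed)),
            class = "multisite_design")
}

#' Simulate a multi-site dataset with a correlated covariate
#'
#' Per study j a true effect beta_j = effect + N(0, tau^2) is drawn (and
#' clipped to (-0.99, 0.99) for continuous effects). For a continuous
#' correlate, x = beta_j * theta + N(0, 1 - beta_j^2), which makes the
#' within-study standardized slope of x on the target trait equal beta_j by
#' construction. For a binary correlate, x ~ Bernoulli(0.5) and the target
#' trait receives a mean shift of d = beta_j for the x = 1 group. Planned
#' missingness removes non-administered item columns per study.
#'
#' @param design a `multisite_design`.
#' @param spec a `bifactor_spec`.
#' @return list with `responses` (pooled `response_table`), `correlates`
#'   (subject_id, study_id, x), and `truth` (generating record: per-study
#'   effects, design, trait matrix).
#' @export
simulate_multisite <- function(design, spec) {
  stopifnot(inherits(design, "multisite_design"),
            inherits(spec, "bifactor_spec"))
  subs <- unique(spec$loadings$subscale[!is.na(spec$loadings$subscale)])
  if (!design$target %in% c("general", subs)) {
    stop("target trait '", design$target, "' absent from the spec")
  }
  J <- length(design$n_per_study)
  resp_list <- vector("list", J)
  cor_list <- vector("list", J)
  beta_j <- numeric(J)
  trait_list <- vector("list", J)
  for (j in seq_len(J)) {
    # per-study substream: master seed spawns independent study seeds
    set.seed(design$seed * 1000L + j)
    n <- design$n_per_study[j]
    beta <- design$effect + stats::rnorm(1L, sd = design$tau)
    if (design$effect_type == "continuous") beta <- max(-0.99, min(0.99, beta))
    beta_j[j] <- beta
    traits <- .draw_traits(spec, n)
    if (design$effect_type == "binary") {
      x <- stats::rbinom(n, 1L, 0.5)
      traits[, design$target] <- traits[, design$target] + beta * x
    } else {
      theta <- traits[, design$target]
      x <- beta * theta + stats::rnorm(n, sd = sqrt(1 - beta^2))
    }
    sim <- simulate_responses(spec, n, seed = design$seed * 1000L + 500L + j,
                              study_id = sprintf("study%02d", j),
                              traits = traits)
    r <- sim$responses
    if (!is.null(design$items_by_study)) {
      admin <- design$items_by_study[[j]]
      drop <- setdiff(item_columns(r), admin)
      for (d in drop) r[[d]] <- NA_integer_
      keep <- rowSums(!is.na(response_matrix(r))) > 0L
      r <- r[keep, , drop = FALSE]
      x <- x[keep]
      traits <- traits[keep, , drop = FALSE]
      class(r) <- c("response_table", "data.frame")
    }
    resp_list[[j]] <- as.data.frame(r)
    cor_list[[j]] <- data.frame(subject_id = r$subject_id,
                                study_id = r$study_id, x = x,
                                stringsAsFactors = FALSE)
    trait_list[[j]] <- traits
  }
  pooled <- do.call(rbind, resp_list)
  K <- max(lengths(spec$thresholds)) + 1L
  truth <- list(design = design, beta_j = beta_j,
                traits = do.call(rbind, trait_list))
  list(responses = response_table(pooled, n_categories = K),
       correlates = do.call(rbind, cor_list), truth = truth)
}

#' Write a simulated dataset in the package's CSV interchange formats
#'
#' Emits `responses_long.csv`, `responses_wide.csv`, `correlates.csv` and
#' `truth.json` (generating parameters) under `dir`.
#'
#' @param sim result of [simulate_multisite()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(melt_responses(sim$responses),
                   file.path(dir, "responses_long.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sim$responses),
                   file.path(dir, "responses_wide.csv"), row.names = FALSE)
  utils::write.csv(sim$correlates, file.path(dir, "correlates.csv"),
                   row.names = FALSE)
  truth <- sim$truth
  truth$traits <- NULL
  truth$design$items_by_study <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
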