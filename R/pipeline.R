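# Orchestration of the full workflow: refinement of single-modality
# subconstructs, bifactor modeling per response pattern with the
# interpretability/added-value decisions, and the correlate analysis.

# omega total of a unidimensional composite from standardized loadings
.omega_uni <- function(lambda) {
  sum(lambda)^2 / (sum(lambda)^2 + sum(1 - lambda^2))
}

.config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f)
  unname(tools::md5sum(f))
}

.stamp <- function(seed, config) {
  list(seed = seed, config_hash = .config_hash(config),
       package_version = as.character(utils::packageVersion("sensebifactor")))
}

#' Refine every single-modality subconstruct and gate its unidimensional model
#'
#' For each modality-by-pattern subconstruct in the item bank: items are
#' iteratively refined by hierarchical item clustering on polychoric
#' correlations; subconstructs starting with fewer than three items are
#' flagged not scalable (no model is fit); if fewer than three items
#' survive refinement, or the refined unidimensional graded response model
#' fails the a priori gates, the subconstruct is flagged for a single-item
#' fallback (the fallback item itself is a config decision, never chosen
#' automatically). Passing subconstructs get a summary row with fit
#' indices, marginal reliability and omega total.
#'
#' @param responses harmonized `response_table`.
#' @param bank an `item_bank` (harmonized items are its homolog groups).
#' @param loading_cut item-cluster loading cut for refinement.
#' @param min_n minimum joint observations per polychoric pair.
#' @param n_quad,tol,max_iter GRM estimation settings.
#' @return An object of class `refinement_report`: data.frame `table`
#'   (one row per subconstruct) and list `details` (per subconstruct:
#'   retained items, removal log, fitted model, fit indices, gates).
#' @export
run_refinement <- function(responses, bank, loading_cut = 0.30, min_n = 30L,
                           n_quad = 21L, tol = 1e-4, max_iter = 200L) {
  stopifnot(inherits(responses, "response_table"), inherits(bank, "item_bank"))
  meta <- unique(data.frame(group = bank$homolog_group,
                            modality = bank$modality, pattern = bank$pattern,
                            stringsAsFactors = FALSE))
  combos <- unique(meta[c("modality", "pattern")])
  rows <- list()
  details <- list()
  for (r in seq_len(nrow(combos))) {
    mod <- combos$modality[r]
    pat <- combos$pattern[r]
    key <- paste(pat, mod, sep = ":")
    its <- intersect(meta$group[meta$modality == mod & meta$pattern == pat],
                     item_columns(responses))
    det <- list(modality = mod, pattern = pat, initial_items = its)
    row <- data.frame(pattern = pat, modality = mod,
                      n_initial = length(its), n_final = NA_integer_,
                      tli = NA_real_, rmsea = NA_real_, srmr = NA_real_,
                      rho_xx = NA_real_, omega_t = NA_real_,
                      status = NA_character_, stringsAsFactors = FALSE)
    if (length(its) < 3L) {
      row$status <- "not scalable (<3 items)"
      det$flag <- "not_scalable"
      rows[[key]] <- row; details[[key]] <- det
      next
    }
    sub <- responses[, c("subject_id", "study_id", its)]
    class(sub) <- class(responses)
    attr(sub, "n_categories") <- attr(responses, "n_categories")
    keep <- rowSums(!is.na(response_matrix(sub))) > 0L
    sub <- sub[keep, , drop = FALSE]
    class(sub) <- c("response_table", "data.frame")
    attr(sub, "n_categories") <- attr(responses, "n_categories")
    sim <- polychoric_matrix(sub, min_n = min_n)
    ref <- iclust_refine(sim, loading_cut = loading_cut)
    det$removal_log <- ref$removal_log
    det$retained <- ref$retained
    row$n_final <- length(ref$retained)
    if (length(ref$retained) < 3L) {
      row$status <- "needs single-item fallback (<3 items survive)"
      det$flag <- "single_item_fallback"
      rows[[key]] <- row; details[[key]] <- det
      next
    }
    sub2 <- sub[, c("subject_id", "study_id", ref$retained)]
    class(sub2) <- c("response_table", "data.frame")
    attr(sub2, "n_categories") <- attr(responses, "n_categories")
    model <- fit_grm(sub2, n_quad = n_quad, tol = tol, max_iter = max_iter)
    fit <- limited_info_chisq(model, sub2, min_n = min_n)
    sc <- eap_scores(model, sub2, force = TRUE)
    L <- standardize_loadings(model, force = TRUE)
    omega_t <- .omega_uni(L$lambda_general)
    gates <- apply_gates(fit, sc$rho_xx, omega_t, length(ref$retained))
    det$model <- model; det$fit <- fit; det$gates <- gates
    row$tli <- fit$tli; row$rmsea <- fit$rmsea; row$srmr <- fit$srmr
    row$rho_xx <- sc$rho_xx; row$omega_t <- omega_t
    if (isTRUE(gates$overall)) {
      row$status <- "retained"
    } else {
      row$status <- "needs single-item fallback (gates failed)"
      det$flag <- "single_item_fallback"
    }
    rows[[key]] <- row; details[[key]] <- det
  }
  structure(list(table = do.call(rbind, rows), details = details),
            class = "refinement_report")
}

#' @export
print.refinement_report <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Bifactor modeling and score-interpretability decisions for one pattern
#'
#' Runs the structural stage for one response pattern: an exploratory
#' graph analysis structure check on the pooled refined items, a
#' confirmatory bifactor graded response model in which each multi-item
#' subconstruct defines a specific factor and single-item subconstructs
#' load only on the general factor, the limited-information fit gates,
#' and the bifactor index suite with the interpretability and added-value
#' decision rules. If the initial model fails the fit gates and
#' general-only single-item indicators are present, a revised model
#' excluding them is fit and both fits are recorded.
#'
#' @param responses harmonized `response_table`.
#' @param refined named list: subconstruct (modality) label to character
#'   vector of its retained items (length-1 entries are single-item
#'   indicators).
#' @param n_quad,tol,max_iter GRM estimation settings.
#' @param min_n polychoric pair minimum.
#' @return An object of class `bifactor_report`: `model`, `fit`, `gates`,
#'   `indices`, `interpretability`, `added_value`, `ega`, `revised`
#'   (logical), and when revised also `initial_model`/`initial_fit`.
#' @export
run_bifactor <- function(responses, refined, n_quad = 21L, tol = 1e-4,
                         max_iter = 200L, min_n = 30L) {
  stopifnot(inherits(responses, "response_table"))
  multi <- refined[lengths(refined) >= 2L]
  single <- refined[lengths(refined) == 1L]
  if (length(multi) < 2L) {
    stop("bifactor model requires at least two multi-item subconstructs; ",
         "use the unidimensional path instead")
  }
  items <- unlist(refined, use.names = FALSE)
  sub <- responses[, c("subject_id", "study_id", items)]
  class(sub) <- c("response_table", "data.frame")
  attr(sub, "n_categories") <- attr(responses, "n_categories")
  keep <- rowSums(!is.na(response_matrix(sub))) > 0L
  sub <- sub[keep, , drop = FALSE]
  class(sub) <- c("response_table", "data.frame")
  attr(sub, "n_categories") <- attr(responses, "n_categories")

  eg <- ega(sub, min_n = min_n)

  build_structure <- function(groups) {
    st <- stats::setNames(rep(NA_character_, length(unlist(groups))),
                          unlist(groups))
    for (nm in names(groups)) {
      if (length(groups[[nm]]) >= 2L) st[groups[[nm]]] <- nm
    }
    st
  }
  fit_one <- function(groups) {
    its <- unlist(groups, use.names = FALSE)
    d <- sub[, c("subject_id", "study_id", its)]
    class(d) <- c("response_table", "data.frame")
    attr(d, "n_categories") <- attr(sub, "n_categories")
    keep <- rowSums(!is.na(response_matrix(d))) > 0L
    d <- d[keep, , drop = FALSE]
    class(d) <- c("response_table", "data.frame")
    attr(d, "n_categories") <- attr(sub, "n_categories")
    m <- fit_grm(d, structure = build_structure(groups), n_quad = n_quad,
                 tol = tol, max_iter = max_iter)
    f <- limited_info_chisq(m, d, min_n = min_n)
    sc <- eap_scores(m, d, force = TRUE)
    idx <- compute_indices(standardize_loadings(m, force = TRUE))
    g <- apply_gates(f, sc$rho_xx, idx$omega_t, length(its))
    list(model = m, fit = f, gates = g, indices = idx, data = d)
  }

  first <- fit_one(refined)
  revised <- FALSE
  final <- first
  if (!isTRUE(first$gates$overall) && length(single) > 0L) {
    final <- fit_one(multi)             # drop single-item indicators
    revised <- TRUE
  }
  if (!final$model$converged) {
    stop("bifactor model did not converge",
         if (revised) " (after revision excluding single-item indicators)")
  }
  structure(list(model = final$model, fit = final$fit, gates = final$gates,
                 indices = final$indices, data = final$data,
                 interpretability = evaluate_interpretability(final$indices),
                 added_value = evaluate_added_value(final$indices),
                 ega = eg, revised = revised,
                 initial_model = if (revised) first$model,
                 initial_fit = if (revised) first$fit),
            class = "bifactor_report")
}

#' @export
print.bifactor_report <- function(x, ...) {
  print(x$model)
  print(x$fit)
  print(x$indices)
  cat("Supra-modal score interpretable:", x$interpretability$interpretable,
      if (!is.na(x$interpretability$rule))
        paste0("(rule: ", x$interpretability$rule, ")"), "\n")
  av <- x$added_value
  cat("Added value:", sum(av$added_value), "of", nrow(av), "subscales\n")
  if (x$revised) cat("(revised model: single-item indicators excluded)\n")
  invisible(x)
}

#' Correlate analysis across interpretable constructs
#'
#' Scores every interpretable construct with plausible values and fits one
#' Bayesian random-effects IDA model per construct-by-correlate pair that
#' reaches the minimum-cases rule, assembling an effect matrix with
#' ROPE-based evidence classes.
#'
#' @param constructs named list; each element a list with `model` (a
#'   `grm_model`), `data` (its `response_table`), and optionally `trait`
#'   (default "general").
#' @param correlates data.frame with `subject_id`, `study_id` and one
#'   column per correlate.
#' @param predictors character vector of correlate columns; default all
#'   non-id columns.
#' @param types named character vector ("continuous"/"binary") per
#'   predictor; unnamed predictors are treated as continuous unless coded
#'   0/1.
#' @param M plausible values per subject.
#' @param min_cases minimum complete cases per model (default 100).
#' @param seed master seed.
#' @param condition_pvs draw the plausible values for each pair with the
#'   predictor in the conditioning model (default TRUE; removes the
#'   reliability attenuation of the estimated effect).
#' @param ... further arguments passed to [fit_ida()].
#' @return An object of class `effect_matrix`: data.frame `table` (one
#'   row per construct x correlate) and list `fits`.
#' @export
run_correlates <- function(constructs, correlates, predictors = NULL,
                           types = NULL, M = 10L, min_cases = 100L,
                           seed = 1L, condition_pvs = TRUE, ...) {
  if (length(constructs) == 0L) {
    return(structure(list(
      table = data.frame(), fits = list(),
      note = "no interpretable constructs; no models fit"),
      class = "effect_matrix"))
  }
  if (is.null(predictors)) {
    predictors <- setdiff(names(correlates), c("subject_id", "study_id"))
  }
  rows <- list()
  fits <- list()
  ci <- 0L
  for (cn in names(constructs)) {
    ci <- ci + 1L
    cons <- constructs[[cn]]
    trait <- if (is.null(cons$trait)) "general" else cons$trait
    pvs_plain <- plausible_values(cons$model, cons$data, M = M,
                                  seed = seed + 31L * ci, force = TRUE)
    pi_ <- 0L
    for (pr in predictors) {
      pi_ <- pi_ + 1L
      v <- correlates[[pr]]
      ty <- if (!is.null(types) && pr %in% names(types)) types[[pr]]
      else if (all(stats::na.omit(v) %in% c(0, 1))) "binary" else "continuous"
      pvs <- if (condition_pvs) {
        cond <- v[match(cons$data$subject_id, correlates$subject_id)]
        plausible_values(cons$model, cons$data, M = M,
                         seed = seed + 31L * ci, condition = cond,
                         force = TRUE)
      } else pvs_plain
      res <- fit_ida(pvs, correlates, predictor = pr, trait = trait,
                     type = ty, min_cases = min_cases,
                     seed = seed + 101L * ci + pi_, ...)
      fits[[paste(cn, pr, sep = ":")]] <- res
      rows[[paste(cn, pr, sep = ":")]] <- if (isTRUE(res$skipped)) {
        data.frame(construct = cn, correlate = pr, effect_type = ty,
                   effect = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                   p_rope = NA_real_, log_bf = NA_real_,
                   class = sprintf("not fit (%s)", res$reason),
                   tau2 = NA_real_, i2 = NA_real_, icc = NA_real_,
                   pi_lower = NA_real_, pi_upper = NA_real_,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(construct = cn, correlate = pr, effect_type = res$effect_label,
                   effect = res$effect_median, ci_lower = res$ci[1L],
                   ci_upper = res$ci[2L], p_rope = res$p_rope,
                   log_bf = res$log_bf,
                   class = ifelse(is.na(res$class), "not classified",
                                  res$class),
                   tau2 = res$tau2, i2 = res$i2, icc = res$icc,
                   pi_lower = res$prediction_interval[1L],
                   pi_upper = res$prediction_interval[2L],
                   stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 stamp = .stamp(seed, list(predictors = predictors, M = M,
                                           min_cases = min_cases))),
            class = "effect_matrix")
}

#' @export
print.effect_matrix <- function(x, ...) {
  if (nrow(x$table) == 0L) {
    cat("Empty effect matrix:", x$note, "\n")
    return(invisible(x))
  }
  print(x$table[c("construct", "correlate", "effect_type", "effect",
                  "log_bf", "class")], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an effect matrix as a TSV (constructs x correlates)
#' @param em an `effect_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_effect_matrix <- function(em, path) {
  tab <- em$table
  if (nrow(tab) == 0L) {
    writeLines("empty effect matrix", path)
    return(invisible(path))
  }
  cons <- unique(tab$construct)
  cors <- unique(tab$correlate)
  out <- matrix("", length(cons), length(cors),
                dimnames = list(cons, cors))
  for (i in seq_len(nrow(tab))) {
    out[tab$construct[i], tab$correlate[i]] <-
      if (is.na(tab$effect[i])) tab$class[i] else
        sprintf("%s=%.3f [%s]", tab$effect_type[i], tab$effect[i],
                tab$class[i])
  }
  utils::write.table(cbind(construct = rownames(out), as.data.frame(out)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
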