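#' Construct a standardized bifactor loading matrix
#'
#' Container for fully standardized loadings of a confirmatory bifactor
#' solution: every item loads on the general factor and on at most one
#' specific (group) factor; all factors are orthogonal. Communality
#' h2 = lambda_G^2 + lambda_s^2 and item explained common variance
#' I-ECV = lambda_G^2 / h2 are derived fields.
#'
#' @param item_id character vector of item identifiers.
#' @param subscale specific-factor label per item, `NA` (or `""`) for items
#'   loading on the general factor only.
#' @param lambda_general standardized general-factor loadings.
#' @param lambda_specific standardized specific-factor loadings (`NA`/0 for
#'   general-only items).
#' @return An object of class `loading_matrix` (a data.frame with derived
#'   columns `h2` and `iecv`).
#' @export
loading_matrix <- function(item_id, subscale, lambda_general, lambda_specific) {
  item_id <- as.character(item_id)
  if (length(item_id) == 0L) stop("empty loading matrix")
  if (anyDuplicated(item_id)) stop("duplicated item_id in loading matrix")
  subscale <- as.character(subscale)
  subscale[!is.na(subscale) & !nzchar(subscale)] <- NA_character_
  lg <- as.numeric(lambda_general)
  ls <- as.numeric(lambda_specific)
  ls[is.na(ls)] <- 0
  if (any(!is.na(subscale) & ls == 0 & lg == 0)) {
    # allowed, but a zero row carries no information; keep it representable
  }
  if (any(is.na(subscale) & ls != 0)) {
    stop("nonzero specific loading for item(s) without a subscale label")
  }
  h2 <- lg^2 + ls^2
  if (any(h2 >= 1)) {
    stop("communality h2 = lambda_G^2 + lambda_s^2 must be < 1 (item ",
         item_id[which(h2 >= 1)[1L]], ")")
  }
  iecv <- ifelse(h2 > 0, lg^2 / h2, NA_real_)
  out <- data.frame(item_id = item_id, subscale = subscale,
                    lambda_general = lg, lambda_specific = ls,
                    h2 = h2, iecv = iecv, stringsAsFactors = FALSE)
  class(out) <- c("loading_matrix", "data.frame")
  out
}

#' Read a loadings CSV (item_id, subscale, lambda_general, lambda_specific)
#' @param path path to the CSV.
#' @return A `loading_matrix`.
#' @export
read_loadings <- function(path) {
  if (!file.exists(path)) stop("loadings file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("item_id", "subscale", "lambda_general", "lambda_specific")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0L) stop("loadings file missing column(s): ",
                              paste(miss, collapse = ", "))
  loading_matrix(d$item_id, d$subscale, d$lambda_general, d$lambda_specific)
}

#' Bundled reference loading matrices
#'
#' Returns one of the three reference standardized bifactor solutions for
#' caregiver-reported sensory reactivity shipped with the package: the
#' 23-item hyperreactivity (HYPER, 6 specific factors), 12-item
#' hyporeactivity (HYPO, 3 specific factors plus general-only single-item
#' indicators), and revised 18-item sensory seeking (SEEK, 4 specific
#' factors) solutions. These serve as worked examples for the index suite
#' and as generating structures for the synthetic-data module.
#'
#' @param which one of `"hyper"`, `"hypo"`, `"seek"`.
#' @return A `loading_matrix`.
#' @export
reference_loadings <- function(which = c("hyper", "hypo", "seek")) {
  which <- match.arg(which)
  read_loadings(system.file("extdata", paste0(which, "_loadings.csv"),
                            package = "sensebifactor", mustWork = TRUE))
}

#' Compute the bifactor reliability and dimensionality index suite
#'
#' Linear-composite (Rodriguez-style) formulas on standardized loadings:
#' with G = sum of general loadings, S_s = sum of specific loadings in
#' subscale s, and U = sum of uniquenesses (1 - h2),
#' omega_T = (G^2 + sum_s S_s^2) / (G^2 + sum_s S_s^2 + U) and
#' omega_H = G^2 / (same denominator); omega_S and omega_HS apply the same
#' formulas restricted to the items of one subscale. The explained-common-
#' variance family is ECV_G = sum lambda_G^2 / sum h2 (scale level),
#' ECV_SS(s) = sum_{i in s} lambda_s^2 / sum_{i in s} h2, the within-
#' subscale general share being its complement, and I-ECV per item.
#'
#' @param L a `loading_matrix`.
#' @return An object of class `bifactor_index_set`: scalars `omega_t`,
#'   `omega_h`, `ecv_g`; data.frame `subscales` with `omega_s`, `omega_hs`,
#'   `ecv_ss`, `ecv_g_within`, `n_items`; data.frame `items` with `h2`,
#'   `iecv`.
#' @export
compute_indices <- function(L) {
  stopifnot(inherits(L, "loading_matrix"))
  lg <- L$lambda_general
  ls <- L$lambda_specific
  h2 <- L$h2
  subs <- unique(L$subscale[!is.na(L$subscale)])
  if (length(subs) > 0L && any(table(L$subscale) < 1L)) {
    stop("subscale with zero items")
  }
  G2 <- sum(lg)^2
  S2 <- if (length(subs)) {
    vapply(subs, function(s) sum(ls[L$subscale %in% s])^2, numeric(1))
  } else numeric(0)
  U <- sum(1 - h2)
  denom <- G2 + sum(S2) + U
  omega_t <- (G2 + sum(S2)) / denom
  omega_h <- G2 / denom
  ecv_g <- sum(lg^2) / sum(h2)

  sub_df <- do.call(rbind, lapply(subs, function(s) {
    i <- which(L$subscale %in% s)
    g2 <- sum(lg[i])^2
    s2 <- sum(ls[i])^2
    u <- sum(1 - h2[i])
    data.frame(
      subscale = s,
      n_items = length(i),
      omega_s = (g2 + s2) / (g2 + s2 + u),
      omega_hs = s2 / (g2 + s2 + u),
      ecv_ss = sum(ls[i]^2) / sum(h2[i]),
      ecv_g_within = sum(lg[i]^2) / sum(h2[i]),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(sub_df)) {
    sub_df <- data.frame(subscale = character(0), n_items = integer(0),
                         omega_s = numeric(0), omega_hs = numeric(0),
                         ecv_ss = numeric(0), ecv_g_within = numeric(0))
  }
  out <- list(omega_t = omega_t, omega_h = omega_h, ecv_g = ecv_g,
              subscales = sub_df,
              items = data.frame(item_id = L$item_id, h2 = h2, iecv = L$iecv,
                                 stringsAsFactors = FALSE))
  class(out) <- "bifactor_index_set"
  out
}

#' @export
print.bifactor_index_set <- function(x, digits = 3, ...) {
  cat(sprintf("omega_T = %.3f  omega_H = %.3f  ECV_G = %.3f\n",
              x$omega_t, x$omega_h, x$ecv_g))
  if (nrow(x$subscales) > 0L) {
    print(cbind(x$subscales[1:2],
                round(x$subscales[3:6], digits)), row.names = FALSE)
  }
  invisible(x)
}

#' Interpretability of the supra-modal (general factor) score
#'
#' A general factor is judged strong enough to support interpretation of a
#' supra-modal total score when omega_H >= 0.80 (rule 1) or when
#' omega_H >= 0.70 together with ECV_G >= 0.60 (rule 2); comparisons are
#' inclusive.
#'
#' @param idx a `bifactor_index_set`.
#' @return list with `interpretable` (logical), `rule` ("omega_h",
#'   "omega_h_and_ecv", or NA) and the values examined.
#' @export
evaluate_interpretability <- function(idx) {
  stopifnot(inherits(idx, "bifactor_index_set"))
  rule <- NA_character_
  ok <- FALSE
  if (idx$omega_h >= 0.80) {
    ok <- TRUE; rule <- "omega_h"
  } else if (idx$omega_h >= 0.70 && idx$ecv_g >= 0.60) {
    ok <- TRUE; rule <- "omega_h_and_ecv"
  }
  list(interpretable = ok, rule = rule,
       omega_h = idx$omega_h, ecv_g = idx$ecv_g)
}

#' Added value of modality-specific subscale scores
#'
#' Decision rules conditioned on subscale reliability: a subscale with high
#' reliability (omega_S >= 0.70) has added value over the total score when
#' omega_HS >= 0.20 or ECV_SS >= 0.30; a subscale with low reliability
#' (omega_S < 0.70) requires omega_HS >= 0.25 or ECV_SS >= 0.45.
#'
#' @param idx a `bifactor_index_set`.
#' @return data.frame, one row per subscale: `reliability_tier`
#'   ("high"/"low"), `added_value`, `rule` fired (or NA).
#' @export
evaluate_added_value <- function(idx) {
  stopifnot(inherits(idx, "bifactor_index_set"))
  s <- idx$subscales
  if (nrow(s) == 0L) {
    return(data.frame(subscale = character(0), reliability_tier = character(0),
                      added_value = logical(0), rule = character(0)))
  }
  high <- s$omega_s >= 0.70
  cut_hs <- ifelse(high, 0.20, 0.25)
  cut_ecv <- ifelse(high, 0.30, 0.45)
  by_hs <- s$omega_hs >= cut_hs
  by_ecv <- s$ecv_ss >= cut_ecv
  data.frame(
    subscale = s$subscale,
    reliability_tier = ifelse(high, "high", "low"),
    omega_s = s$omega_s, omega_hs = s$omega_hs, ecv_ss = s$ecv_ss,
    added_value = by_hs | by_ecv,
    rule = ifelse(by_hs, "omega_hs", ifelse(by_ecv, "ecv_ss", NA_character_)),
    stringsAsFactors = FALSE
  )
}

#' Write a bifactor index set as a table-style TSV report
#' @param idx a `bifactor_index_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_index_report <- function(idx, path) {
  stopifnot(inherits(idx, "bifactor_index_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("scale\tomega_T\t%.3f\tomega_H\t%.3f\tECV_G\t%.3f",
                     idx$omega_t, idx$omega_h, idx$ecv_g), con)
  s <- idx$subscales
  for (i in seq_len(nrow(s))) {
    writeLines(sprintf("subscale\t%s\tomega_S\t%.3f\tomega_HS\t%.3f\tECV_SS\t%.3f",
                       s$subscale[i], s$omega_s[i], s$omega_hs[i], s$ecv_ss[i]),
               con)
  }
  invisible(path)
}
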