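# Default instrument precedence when one subject answered homologous items
# on more than one instrument: newest instrument version wins.
.DEFAULT_PRECEDENCE <- c("SEQ30", "SEQ21", "SP2", "SSP2", "SP1", "SSP1", "OTHER")

#' Harmonize raw per-instrument responses into one response table
#'
#' Applies the harmonization rules defined by the item bank: reverse-scored
#' instruments (SP1/SSP1, whose raw scales run opposite to the SEQ) have
#' responses x mapped to K+1-x so that 5 always represents more frequent
#' behaviour; analogous items from different instrument versions (same
#' `homolog_group`) are collapsed into a single harmonized item column.
#' A subject normally contributes to a homolog group from one instrument
#' only; if several instruments supply a response for the same subject and
#' group, the instrument earliest in `precedence` is retained.
#'
#' @param bank an `item_bank`.
#' @param raw long data.frame with columns `subject_id`, `study_id`,
#'   `instrument`, `item_id`, `response` (raw instrument scale, NA allowed).
#' @param precedence character vector of instruments, highest priority
#'   first; `NULL` forbids conflicts (an error if any subject has two
#'   instruments answering one homolog group).
#' @return A `response_table` with one column per homolog group.
#' @export
harmonize <- function(bank, raw, precedence = .DEFAULT_PRECEDENCE) {
  stopifnot(inherits(bank, "item_bank"))
  req <- c("subject_id", "study_id", "instrument", "item_id", "response")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0L) stop("raw responses missing column(s): ",
                              paste(miss, collapse = ", "))
  raw <- as.data.frame(raw)
  unknown <- setdiff(unique(raw$item_id), bank$item_id)
  if (length(unknown) > 0L) {
    stop("responses reference item(s) absent from the item bank: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  idx <- match(raw$item_id, bank$item_id)
  K <- bank$n_categories[idx]
  resp <- as.integer(raw$response)
  bad <- !is.na(resp) & (resp < 1L | resp > K)
  if (any(bad)) {
    stop("raw response outside 1..K for item ", raw$item_id[which(bad)[1L]],
         " (value ", resp[which(bad)[1L]], ")")
  }
  # reverse-scoring is an involution: x -> K + 1 - x
  rev_flag <- bank$reverse[idx]
  resp[rev_flag] <- K[rev_flag] + 1L - resp[rev_flag]

  out <- data.frame(
    subject_id = as.character(raw$subject_id),
    study_id = as.character(raw$study_id),
    instrument = as.character(raw$instrument),
    group = bank$homolog_group[idx],
    response = resp,
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$response), , drop = FALSE]

  key <- paste(out$subject_id, out$group, sep = "\r")
  if (anyDuplicated(key)) {
    if (is.null(precedence)) {
      d <- key[duplicated(key)][1L]
      stop("subject has responses from multiple instruments for one homolog ",
           "group and no precedence rule was supplied (first conflict: ",
           sub("\r", " / group ", d), ")")
    }
    pr <- match(out$instrument, precedence)
    pr[is.na(pr)] <- length(precedence) + 1L
    out <- out[order(key, pr), , drop = FALSE]
    out <- out[!duplicated(paste(out$subject_id, out$group, sep = "\r")), ,
               drop = FALSE]
  }

  groups <- unique(bank$homolog_group)
  subjects <- unique(out$subject_id)
  wide <- matrix(NA_integer_, nrow = length(subjects), ncol = length(groups),
                 dimnames = list(subjects, groups))
  wide[cbind(match(out$subject_id, subjects), match(out$group, groups))] <-
    out$response
  study <- out$study_id[match(subjects, out$subject_id)]
  Kmax <- max(bank$n_categories)
  df <- data.frame(subject_id = subjects, study_id = study,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(wide))
  names(df) <- c("subject_id", "study_id", groups)
  response_table(df, n_categories = Kmax)
}

#' Melt a harmonized response table back into long format
#'
#' Inverse of the wide layout produced by [harmonize()]; useful for writing
#' the long-CSV interchange format and for idempotence checks (a melted,
#' already-harmonized table re-harmonized against an identity bank is
#' unchanged).
#'
#' @param data a `response_table`.
#' @param instrument instrument label to stamp on the rows.
#' @return long data.frame (`subject_id`, `study_id`, `instrument`,
#'   `item_id`, `response`), missing responses omitted.
#' @export
melt_responses <- function(data, instrument = "OTHER") {
  items <- item_columns(data)
  m <- response_matrix(data)
  idx <- which(!is.na(m), arr.ind = TRUE)
  data.frame(
    subject_id = data$subject_id[idx[, 1L]],
    study_id = data$study_id[idx[, 1L]],
    instrument = instrument,
    item_id = items[idx[, 2L]],
    response = m[idx],
    stringsAsFactors = FALSE
  )
}

#' Identity item bank for an already-harmonized table
#'
#' Each harmonized item becomes its own (non-reversed) homolog group, so
#' that [harmonize()] acts as the identity on the melted table.
#'
#' @param data a `response_table`.
#' @param modality,pattern metadata stamped on every item.
#' @return An `item_bank`.
#' @export
identity_bank <- function(data, modality = "Unknown", pattern = "HYPER") {
  items <- item_columns(data)
  item_bank(data.frame(
    item_id = items, instrument = "OTHER", modality = modality,
    pattern = pattern, reverse = FALSE, homolog_group = items,
    n_categories = attr(data, "n_categories"), stringsAsFactors = FALSE
  ))
}
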