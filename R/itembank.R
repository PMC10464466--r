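#' @keywords internal
"_PACKAGE"

.INSTRUMENTS <- c("SP1", "SSP1", "SP2", "SSP2", "SEQ21", "SEQ30", "OTHER")
.PATTERNS <- c("HYPER", "HYPO", "SEEK")

#' Construct an item bank
#'
#' An item bank holds the metadata that drives harmonization of sensory
#' questionnaire items across instruments: which instrument each raw item
#' comes from, its sensory modality and response pattern (hyperreactivity,
#' hyporeactivity, seeking), whether its response scale runs opposite to the
#' harmonized direction (reverse-scored so that 5 = more frequent behaviour),
#' and the homolog group collapsing analogous items from different
#' instrument versions into one harmonized item.
#'
#' @param items data.frame with columns `item_id`, `instrument`, `modality`,
#'   `pattern`, `reverse`, `homolog_group`, `n_categories`.
#' @return An object of class `item_bank` (a validated data.frame).
#' @export
item_bank <- function(items) {
  req <- c("item_id", "instrument", "modality", "pattern", "reverse",
           "homolog_group", "n_categories")
  miss <- setdiff(req, names(items))
  if (length(miss) > 0L) {
    stop("item map is missing required column(s): ", paste(miss, collapse = ", "))
  }
  items <- as.data.frame(items)[req]
  items$item_id <- as.character(items$item_id)
  items$instrument <- as.character(items$instrument)
  items$modality <- as.character(items$modality)
  items$pattern <- as.character(items$pattern)
  items$homolog_group <- as.character(items$homolog_group)
  items$reverse <- .as_flag(items$reverse)
  items$n_categories <- as.integer(items$n_categories)

  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup) > 0L) {
    stop("duplicated item_id in item map: ", paste(unique(dup), collapse = ", "))
  }
  bad_inst <- !items$instrument %in% .INSTRUMENTS
  if (any(bad_inst)) {
    stop("unknown instrument value(s) in rows ",
         paste(which(bad_inst), collapse = ", "), ": ",
         paste(unique(items$instrument[bad_inst]), collapse = ", "))
  }
  bad_pat <- !items$pattern %in% .PATTERNS
  if (any(bad_pat)) {
    stop("unknown pattern value(s) in rows ",
         paste(which(bad_pat), collapse = ", "), ": ",
         paste(unique(items$pattern[bad_pat]), collapse = ", "))
  }
  if (any(is.na(items$n_categories)) || any(items$n_categories < 2L)) {
    stop("n_categories must be an integer >= 2 for every item")
  }
  if (any(is.na(items$homolog_group) | !nzchar(items$homolog_group))) {
    stop("homolog_group must be nonempty for every item")
  }
  class(items) <- c("item_bank", "data.frame")
  items
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes", "y")
}

#' Read an item map CSV into an item bank
#'
#' Expects a UTF-8 CSV with header
#' `item_id,instrument,modality,pattern,reverse,homolog_group,n_categories`.
#'
#' @param path path to the item map CSV.
#' @return An `item_bank`.
#' @export
read_item_map <- function(path) {
  if (!file.exists(path)) stop("item map file not found: ", path)
  item_bank(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
print.item_bank <- function(x, ...) {
  cat("Item bank:", nrow(x), "items,",
      length(unique(x$homolog_group)), "homolog groups\n")
  cat("Patterns:", paste(sort(unique(x$pattern)), collapse = ", "), "\n")
  cat("Modalities:", paste(sort(unique(x$modality)), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a harmonized response table
#'
#' A response table is a wide data.frame with `subject_id`, `study_id` and
#' one integer column per harmonized item; responses lie in 1..K with NA for
#' missing. The category count K is fixed by the table (not inferred from
#' the observed data) so that empty categories remain representable.
#'
#' @param df data.frame with `subject_id`, `study_id` and item columns.
#' @param n_categories fixed number of ordered categories K (default 5).
#' @return An object of class `response_table`.
#' @export
response_table <- function(df, n_categories = 5L) {
  if (!all(c("subject_id", "study_id") %in% names(df))) {
    stop("response table needs subject_id and study_id columns")
  }
  df <- as.data.frame(df)
  df$subject_id <- as.character(df$subject_id)
  df$study_id <- as.character(df$study_id)
  item_cols <- setdiff(names(df), c("subject_id", "study_id"))
  if (length(item_cols) == 0L) stop("response table has no item columns")
  K <- as.integer(n_categories)
  for (ic in item_cols) {
    v <- df[[ic]]
    v <- as.integer(v)
    bad <- !is.na(v) & (v < 1L | v > K)
    if (any(bad)) {
      stop("responses outside 1..", K, " for item ", ic, " (e.g. row ",
           which(bad)[1L], ")")
    }
    df[[ic]] <- v
  }
  resp_mat <- as.matrix(df[item_cols])
  all_missing <- rowSums(!is.na(resp_mat)) == 0L
  if (any(all_missing)) {
    stop("subject(s) with no non-missing responses: ",
         paste(utils::head(df$subject_id[all_missing], 5L), collapse = ", "))
  }
  attr(df, "n_categories") <- K
  class(df) <- c("response_table", "data.frame")
  df
}

#' Item columns of a response table
#' @param data a `response_table`.
#' @return character vector of item column names.
#' @export
item_columns <- function(data) {
  setdiff(names(data), c("subject_id", "study_id"))
}

#' Response matrix of a response table
#' @param data a `response_table`.
#' @return integer matrix (subjects x items), NA = missing.
#' @export
response_matrix <- function(data) {
  m <- as.matrix(as.data.frame(data)[item_columns(data)])
  storage.mode(m) <- "integer"
  rownames(m) <- data$subject_id
  m
}

#' @export
print.response_table <- function(x, ...) {
  cat("Response table:", nrow(x), "subjects,", length(item_columns(x)),
      "items, K =", attr(x, "n_categories"),
      ", studies:", length(unique(x$study_id)), "\n")
  invisible(x)
}
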