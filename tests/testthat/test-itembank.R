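test_that("item maps are parsed and validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "item_id,instrument,modality,pattern,reverse,homolog_group,n_categories",
    "SP1_Q1,SP1,Auditory,HYPER,TRUE,G1,5",
    "SP2_Q1,SP2,Auditory,HYPER,FALSE,G1,5",
    "SEQ3_Q9,SEQ30,Auditory,HYPER,FALSE,G2,5"
  ), f)
  bank <- read_item_map(f)
  expect_s3_class(bank, "item_bank")
  expect_equal(nrow(bank), 3L)
  expect_equal(length(unique(bank$homolog_group)), 2L)

  writeLines(c(
    "item_id,instrument,modality,pattern,reverse,homolog_group,n_categories",
    "SP1_Q1,SP1,Auditory,HYPER,TRUE,G1,5",
    "SP1_Q1,SP1,Visual,HYPER,TRUE,G2,5"
  ), f)
  expect_error(read_item_map(f), "SP1_Q1")

  writeLines(c(
    "item_id,instrument,modality,pattern,reverse,homolog_group,n_categories",
    "SP1_Q1,SPX,Auditory,HYPER,TRUE,G1,5"
  ), f)
  expect_error(read_item_map(f), "instrument")
  writeLines(c(
    "item_id,instrument,modality,pattern,reverse,homolog_group,n_categories",
    "SP1_Q1,SP1,Auditory,WOBBLE,TRUE,G1,5"
  ), f)
  expect_error(read_item_map(f), "pattern")
  writeLines(c("item_id,instrument,modality", "a,SP1,Auditory"), f)
  expect_error(read_item_map(f), "missing required column")
})

test_that("a bank mirroring the 23-item hyperreactivity table has 6 modality groups", {
  L <- reference_loadings("hyper")
  bank <- item_bank(data.frame(
    item_id = L$item_id, instrument = "OTHER", modality = L$subscale,
    pattern = "HYPER", reverse = FALSE, homolog_group = L$item_id,
    n_categories = 5
  ))
  expect_equal(nrow(bank), 23L)
  expect_equal(length(unique(bank$modality)), 6L)
})

make_small_bank <- function() {
  item_bank(data.frame(
    item_id = c("SP1_Q1", "SEQ30_Q9", "SEQ30_Q5"),
    instrument = c("SP1", "SEQ30", "SEQ30"),
    modality = "Auditory", pattern = "HYPER",
    reverse = c(TRUE, FALSE, FALSE),
    homolog_group = c("G1", "G1", "G2"),
    n_categories = 5
  ))
}

test_that("harmonization reverse-scores SP1 and leaves SEQ untouched", {
  bank <- make_small_bank()
  raw <- data.frame(
    subject_id = c("s1", "s2", "s2"), study_id = "st1",
    instrument = c("SP1", "SEQ30", "SEQ30"),
    item_id = c("SP1_Q1", "SEQ30_Q9", "SEQ30_Q5"),
    response = c(5L, 4L, 2L)
  )
  h <- harmonize(bank, raw)
  expect_equal(h$G1[h$subject_id == "s1"], 1L)   # 5 -> K + 1 - 5
  expect_equal(h$G1[h$subject_id == "s2"], 4L)
  expect_equal(h$G2[h$subject_id == "s2"], 2L)
  expect_error(
    harmonize(bank, transform(raw, response = c(6L, 4L, 2L))),
    "outside 1..K")
})

test_that("homolog conflicts follow the configured precedence", {
  bank <- make_small_bank()
  raw <- data.frame(
    subject_id = "s1", study_id = "st1",
    instrument = c("SP1", "SEQ30"),
    item_id = c("SP1_Q1", "SEQ30_Q9"),
    response = c(2L, 3L)
  )
  # SEQ30 first in default precedence: its value 3 wins over reversed SP1 (4)
  expect_equal(harmonize(bank, raw)$G1, 3L)
  expect_equal(harmonize(bank, raw, precedence = c("SP1", "SEQ30"))$G1, 4L)
  expect_error(harmonize(bank, raw, precedence = NULL), "precedence")
})

test_that("reverse scoring is an involution and harmonize is idempotent", {
  K <- 5L
  x <- 1:5
  expect_equal(K + 1L - (K + 1L - x), x)

  bank <- make_small_bank()
  raw <- data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 2),
    study_id = "st1",
    instrument = rep(c("SP1", "SEQ30"), 3),
    item_id = rep(c("SP1_Q1", "SEQ30_Q5"), 3),
    response = c(5L, 4L, 2L, NA, 1L, 1L)
  )
  h1 <- harmonize(bank, raw)
  h2 <- harmonize(identity_bank(h1), melt_responses(h1))
  expect_equal(as.data.frame(h1)[order(h1$subject_id), ],
               as.data.frame(h2)[order(h2$subject_id), ],
               ignore_attr = TRUE)
})

test_that("marginal missingness is preserved for non-merged items", {
  bank <- item_bank(data.frame(
    item_id = c("A1", "A2"), instrument = "SEQ30", modality = "Auditory",
    pattern = "HYPER", reverse = FALSE, homolog_group = c("A1", "A2"),
    n_categories = 5
  ))
  raw <- data.frame(
    subject_id = c("s1", "s1", "s2"), study_id = "st1", instrument = "SEQ30",
    item_id = c("A1", "A2", "A1"), response = c(3L, NA, 2L)
  )
  h <- harmonize(bank, raw)
  # s1's explicit NA for A2 and s2's never-asked A2 both stay missing
  expect_equal(sum(is.na(response_matrix(h))), 2L)
})

test_that("response tables enforce their invariants", {
  expect_error(response_table(data.frame(subject_id = "a", study_id = "b",
                                         i1 = 7L)), "outside 1..5")
  expect_error(response_table(data.frame(subject_id = "a", study_id = "b",
                                         i1 = NA_integer_)),
               "no non-missing")
  ok <- response_table(data.frame(subject_id = c("a", "b"), study_id = "s",
                                  i1 = c(1L, NA), i2 = c(NA, 5L)))
  expect_equal(item_columns(ok), c("i1", "i2"))
})
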