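make_wide_tsv <- function(df) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  f
}

parent60 <- paste(rep("ACDEFGHILM", 6), collapse = "")

test_that("wide quant tables read with control validation", {
  df <- data.frame(accession = "P1", start = c(1, 11, 21),
                   end = c(10, 20, 30),
                   sequence = substring(parent60, c(1, 11, 21), c(10, 20, 30)),
                   NPP = c(100, 50, NA), pH1 = c(200, NA, 70),
                   pH12 = c(90, 60, 80))
  f <- make_wide_tsv(df)
  tab <- read_quant_table(f, control = "NPP")
  expect_s3_class(tab, "quant_table")
  expect_equal(nrow(tab$observations), 3L)
  expect_equal(tab$conditions, c("NPP", "pH1", "pH12"))
  expect_equal(tab$control, "NPP")
  expect_error(read_quant_table(f, control = "missing"),
               "configuration error")
  df$NPP[1] <- -5
  expect_error(read_quant_table(make_wide_tsv(df), control = "NPP"),
               "negative intensity")
})

test_that("zero means not detected and empty rows are rejected", {
  obs <- data.frame(accession = "P1", start = c(1, 11), end = c(10, 20),
                    sequence = substring(parent60, c(1, 11), c(10, 20)),
                    ctl = c(0, 5), trt = c(NA, 3))
  expect_warning(tab <- quant_table(obs, c("ctl", "trt"), "ctl"),
                 "no detected intensity")
  expect_equal(nrow(tab$observations), 1L)
  expect_true(is.na(quant_table(
    data.frame(accession = "P1", start = 1, end = 10,
               sequence = substring(parent60, 1, 10),
               ctl = 0, trt = 3), c("ctl", "trt"),
    "ctl")$observations$ctl))
})

test_that("duplicate coordinates are a merge error", {
  obs <- data.frame(accession = "P1", start = c(1, 1), end = c(10, 10),
                    sequence = substring(parent60, 1, 10),
                    ctl = c(1, 2))
  expect_error(quant_table(obs, "ctl", "ctl"), "duplicate")
})

test_that("replicate columns sharing a condition prefix are averaged", {
  df <- data.frame(accession = "P1", start = 1, end = 10,
                   sequence = substring(parent60, 1, 10),
                   NPP_1 = 100, NPP_2 = 200, pH1 = 50)
  tab <- read_quant_table(make_wide_tsv(df), control = "NPP")
  expect_equal(tab$conditions, c("NPP", "pH1"))
  expect_equal(tab$observations$NPP, 150)
})

test_that("long-format tables pivot to the same result as wide", {
  long <- data.frame(accession = "P1", start = c(1, 1, 11),
                     end = c(10, 10, 20),
                     sequence = substring(parent60, c(1, 1, 11),
                                          c(10, 10, 20)),
                     condition = c("NPP", "pH1", "NPP"),
                     intensity = c(100, 200, 50))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(long, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_quant_table(f, control = "NPP", format = "long")
  expect_equal(tab$observations$NPP, c(100, 50))
  expect_equal(tab$observations$pH1, c(200, NA))
})

test_that("write/read round-trip preserves all populated cells", {
  obs <- data.frame(accession = "P1", start = c(1, 11), end = c(10, 20),
                    sequence = substring(parent60, c(1, 11), c(10, 20)),
                    NPP = c(100.25, NA), pH1 = c(7.5, 3))
  tab <- quant_table(obs, c("NPP", "pH1"), "NPP")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(tab, f)
  back <- read_quant_table(f, control = "NPP")
  expect_equal(back$observations, tab$observations)
})

test_that("detection filter removes out-of-window peptides, inclusively", {
  parent <- paste(rep("A", 100), collapse = "")
  rows <- data.frame(start = c(1, 1, 1, 1), end = c(4, 5, 45, 46),
                     ctl = 1, trt = 1)
  rows$end <- as.integer(rows$end)
  obs <- data.frame(accession = "P1", start = rows$start, end = rows$end,
                    sequence = substring(parent, rows$start, rows$end),
                    ctl = 1, trt = 1)
  # deduplicate starts for key uniqueness
  obs$start <- c(1L, 10L, 20L, 30L)
  obs$end <- obs$start + c(3L, 4L, 44L, 45L)
  obs$sequence <- substring(parent, obs$start, obs$end)
  tab <- quant_table(obs, c("ctl", "trt"), "ctl")
  expect_message(out <- apply_detection_filter(tab), "removed")
  expect_equal(nchar(out$observations$sequence), c(5L, 45L))
  # idempotent
  expect_equal(apply_detection_filter(out)$observations, out$observations)
  # empty table passes through
  empty <- tab
  empty$observations <- tab$observations[0, ]
  expect_equal(nrow(apply_detection_filter(empty)$observations), 0L)
})

test_that("sequence reconciliation re-anchors unique hits, drops ambiguous", {
  parent <- paste0("AAAAA", "WCDEF", "GGGGG", "WCDEF", "HHHHHHHH")
  prot <- toy_protein(parent)
  obs <- data.frame(accession = "P1",
                    start = c(20L, 5L, 11L),
                    end = c(27L, 9L, 15L),
                    sequence = c("HHHHHHHH",  # shifted coords, unique hit
                                 "WCDEF",     # wrong coords, two hits
                                 "GGGGG"),    # correct already
                    ctl = c(1, 1, 1), trt = c(2, 2, 2))
  tab <- quant_table(obs, c("ctl", "trt"), "ctl")
  res <- coerce_to_sequence_match(tab, prot)
  expect_setequal(res$report$action, c("reanchored", "excluded_ambiguous"))
  kept <- res$table$observations
  expect_equal(nrow(kept), 2L)
  expect_true(all(substring(parent, kept$start, kept$end) == kept$sequence))
  expect_error(coerce_to_sequence_match(tab, toy_protein("AAA", "OTHER")),
               "absent from the protein set")
})
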