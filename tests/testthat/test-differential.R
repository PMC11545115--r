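parent100 <- paste(rep("ACDEFGHILM", 10), collapse = "")

ra_table <- function(ctl, trt) {
  n <- length(ctl)
  starts <- seq(1L, by = 10L, length.out = n)
  toy_table(data.frame(start = starts, end = starts + 9L,
                       ctl = ctl, trt = trt), parent100)
}

test_that("relative abundance is treated over control, control at level 1", {
  tab <- ra_table(c(100, 100, NA, 80), c(1150, 100, 50, NA))
  d <- compute_ra(tab, "trt")
  expect_equal(d$ra, c(11.5, 1.0, NA, NA))
  expect_equal(d$category,
               c("increased", "unchanged", "only_in_treated",
                 "only_in_control"))
  expect_error(compute_ra(tab, "ctl"), "configuration error")
})

test_that("classification thresholds are strict; boundaries are unchanged", {
  ra <- c(0.49, 0.5, 1.0, 2.0, 2.01, 3.8, 11.5)
  expect_equal(classify_ra(ra),
               c("decreased", "unchanged", "unchanged", "unchanged",
                 "increased", "increased", "increased"))
  expect_error(classify_ra(-1), "positive")
})

test_that("each detected peptide gets exactly one category", {
  set.seed(7)
  for (i in 1:10) {
    ctl <- ifelse(runif(8) < 0.3, NA, runif(8, 10, 1000))
    trt <- ifelse(runif(8) < 0.3, NA, runif(8, 10, 1000))
    keep <- !(is.na(ctl) & is.na(trt))
    ctl <- ctl[keep]; trt <- trt[keep]
    if (!length(ctl)) next
    d <- compute_ra(ra_table(ctl, trt), "trt")
    expect_equal(nrow(d), length(ctl))
    expect_true(all(d$category %in% c("increased", "decreased", "unchanged",
                                      "only_in_control", "only_in_treated")))
    # monotone: sort by ra; increased never precedes decreased
    dd <- d[!is.na(d$ra), ]
    dd <- dd[order(dd$ra), ]
    lev <- match(dd$category, c("decreased", "unchanged", "increased"))
    expect_true(all(diff(lev) >= 0))
  }
})

test_that("swapping control and treated inverts RA and mirror categories", {
  ctl <- c(100, 100, 100, NA, 60)
  trt <- c(300, 30, 100, 50, NA)
  fwd <- compute_ra(ra_table(ctl, trt), "trt")
  swapped <- toy_table(data.frame(start = seq(1L, by = 10L, length.out = 5),
                                  end = seq(10L, by = 10L, length.out = 5),
                                  ctl = ctl, trt = trt),
                       parent100, control = "trt")
  rev <- compute_ra(swapped, "ctl")
  both <- !is.na(fwd$ra)
  expect_equal(rev$ra[both], 1 / fwd$ra[both])
  mirror <- c(increased = "decreased", decreased = "increased",
              unchanged = "unchanged", only_in_control = "only_in_treated",
              only_in_treated = "only_in_control")
  expect_equal(rev$category, unname(mirror[fwd$category]))
})

test_that("coverage equals direct set-union arithmetic", {
  prot <- toy_protein(parent100)
  tab <- toy_table(data.frame(start = c(1L, 21L), end = c(30L, 50L),
                              ctl = c(5, 5), trt = c(NA, 5)), parent100)
  cv <- peptide_coverage(tab, prot, "ctl")
  expect_equal(cv$coverage_percent, 50)    # |[1,30] U [21,50]| = 50
  expect_equal(cv$peptide_count, 2L)
  cv_trt <- peptide_coverage(tab, prot, "trt")
  expect_equal(cv_trt$coverage_percent, 30)
  expect_equal(cv_trt$peptide_count, 1L)

  none <- toy_table(data.frame(start = 1L, end = 10L, ctl = 1, trt = NA),
                    parent100)
  expect_equal(peptide_coverage(none, prot, "trt")$coverage_percent, 0)
  expect_equal(peptide_coverage(none, prot, "trt")$peptide_count, 0L)

  full <- toy_table(data.frame(start = 1L, end = 100L, ctl = 1, trt = 1),
                    parent100)
  expect_equal(peptide_coverage(full, prot, "ctl")$coverage_percent, 100)
})

test_that("coverage is order-invariant and bounded under fuzzing", {
  set.seed(17)
  prot <- toy_protein(parent100)
  for (i in 1:15) {
    n <- sample(1:12, 1)
    start <- sample(1:90, n)
    rows <- data.frame(start = start, end = pmin(100L, start + sample(0:30, n,
                                                                      TRUE)),
                       ctl = 1, trt = 1)
    rows <- rows[!duplicated(rows[c("start", "end")]), ]
    tab <- toy_table(rows, parent100)
    shuf <- toy_table(rows[sample(nrow(rows)), ], parent100)
    a <- peptide_coverage(tab, prot, "ctl")$coverage_percent
    b <- peptide_coverage(shuf, prot, "ctl")$coverage_percent
    expect_equal(a, b)
    expect_gte(a, 0)
    expect_lte(a, 100)
    expect_equal(a, length(covered_positions(tab, "P1", "ctl")))
  }
})

test_that("coverage summary rounds half away from zero and counts peptides", {
  parent200 <- paste(rep("ACDEFGHILM", 20), collapse = "")
  prot <- toy_protein(parent200)
  # 101 of 200 residues covered in ctl -> 50.5% -> rounds to 51
  tab <- toy_table(data.frame(start = c(1L, 51L), end = c(50L, 101L),
                              ctl = c(1, 1), trt = c(1, NA)), parent200)
  s <- coverage_summary(tab, prot)
  expect_equal(s$coverage_percent[s$condition == "ctl"], 51L)
  expect_equal(s$coverage_percent[s$condition == "trt"], 25L)
  expect_equal(s$peptides, c(2L, 1L))
  f <- withr::local_tempfile(fileext = ".tsv")
  coverage_summary(tab, prot, path = f)
  back <- read.delim(f)
  expect_equal(back$coverage_percent, c(51L, 25L))
})
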