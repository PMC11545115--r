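# build differential records directly: the site module only consumes
# (start, end, condition, category)
diff_rec <- function(start, end, category, condition = "trt") {
  data.frame(accession = "P1", start = start, end = end,
             sequence = strrep("A", end - start + 1), condition = condition,
             control_intensity = NA_real_, treated_intensity = NA_real_,
             ra = NA_real_, category = category, stringsAsFactors = FALSE)
}

sites_df <- function(pos, residue = "R") {
  data.frame(accession = "P1", position = as.integer(pos),
             residue = rep(residue, length.out = length(pos)),
             stringsAsFactors = FALSE)
}

test_that("each tryptic terminus testifies about its flanking site", {
  sites <- sites_df(c(93, 104))
  ev <- collect_site_evidence(diff_rec(94, 104, "only_in_treated"),
                              sites, 600)
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$terminus, c("N", "C"))
  expect_setequal(ev$position, c(93L, 104L))
  expect_true(all(ev$vote == 1L))

  # protein N-terminus carries no site information
  ev <- collect_site_evidence(diff_rec(1, 30, "unchanged"), sites_df(30), 600)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$terminus, "C")
  expect_equal(ev$vote, 0L)

  # no flanking sites in the set -> no evidence
  ev <- collect_site_evidence(diff_rec(10, 20, "increased"), sites_df(50), 600)
  expect_equal(nrow(ev), 0L)

  # ragged (non-tryptic) peptides are excluded entirely
  ev <- collect_site_evidence(diff_rec(5, 30, "increased"), sites_df(30), 600)
  expect_equal(nrow(ev), 0L)
})

test_that("evidence count equals the sum of flanking-site incidences", {
  sites <- sites_df(c(10, 20, 30))
  d <- rbind(diff_rec(11, 20, "increased"),   # two flanked termini
             diff_rec(21, 30, "decreased"),   # two flanked termini
             diff_rec(31, 50, "unchanged"))   # N-side only (C = protein end)
  ev <- collect_site_evidence(d, sites, 50)
  expect_equal(nrow(ev), 5L)
})

test_that("site calls follow the signed vote with a declared tie rule", {
  sites <- sites_df(c(121, 559, 700, 800, 900))
  d <- rbind(diff_rec(122, 559, "only_in_treated"),  # +1 at 121, +1 at 559?
             diff_rec(560, 700, "only_in_control"),  # -1 at 559, -1 at 700
             diff_rec(701, 800, "increased"),        # +1 at 700, +1 at 800
             diff_rec(801, 900, "decreased"),        # -1 at 800, -1 at 900
             diff_rec(901, 950, "unchanged"))        # 0 at 900
  ev <- collect_site_evidence(d, sites, 950)
  calls <- infer_sites(ev, sites, treated = "trt")
  st <- setNames(calls$state, calls$position)
  expect_equal(st[["121"]], "exposed")     # treated-only flanking peptide
  expect_equal(st[["700"]], "ambiguous")   # -1 and +1 mixed
  expect_equal(st[["800"]], "ambiguous")
  expect_equal(st[["559"]], "ambiguous")
  # single concordant votes
  calls1 <- infer_sites(collect_site_evidence(
    diff_rec(560, 700, "only_in_control"), sites_df(c(559, 700)), 950),
    sites_df(c(559, 700)), treated = "trt")
  expect_equal(calls1$state, c("masked", "masked"))
  # all-zero votes are unchanged; absent evidence is reported, not dropped
  calls0 <- infer_sites(collect_site_evidence(
    diff_rec(560, 700, "unchanged"), sites_df(c(559, 700, 900)), 950),
    sites_df(c(559, 700, 900)), treated = "trt")
  expect_equal(setNames(calls0$state, calls0$position),
               c("559" = "unchanged", "700" = "unchanged",
                 "900" = "no_evidence"))
})

test_that("inverting every vote swaps exposed and masked", {
  sites <- sites_df(c(10, 20, 30))
  d <- rbind(diff_rec(11, 20, "increased"),
             diff_rec(21, 30, "only_in_control"),
             diff_rec(1, 10, "unchanged"))
  mirror <- c(increased = "decreased", decreased = "increased",
              only_in_control = "only_in_treated",
              only_in_treated = "only_in_control", unchanged = "unchanged")
  d_inv <- d
  d_inv$category <- unname(mirror[d$category])
  calls <- infer_sites(collect_site_evidence(d, sites, 40), sites, "trt")
  calls_inv <- infer_sites(collect_site_evidence(d_inv, sites, 40), sites,
                           "trt")
  swap <- c(exposed = "masked", masked = "exposed", unchanged = "unchanged",
            ambiguous = "ambiguous", no_evidence = "no_evidence")
  expect_equal(calls_inv$state, unname(swap[calls$state]))
  expect_equal(calls_inv$score, -calls$score)
})

test_that("site reports label residues and key rows by condition", {
  f <- withr::local_tempfile(fileext = ".tsv")
  sites <- sites_df(93, "R")
  empty <- infer_sites(collect_site_evidence(diff_rec(94, 104, "increased")[0, ],
                                             sites, 600), sites[0, ], "trt")
  site_report(empty, f)
  expect_equal(readLines(f), "site\tcondition\tscore\tstate\tn_evidence")

  d2 <- rbind(diff_rec(94, 104, "only_in_treated", "pH1"),
              diff_rec(94, 104, "only_in_control", "pH12"))
  ev <- collect_site_evidence(d2, sites_df(c(93, 104)), 600)
  calls <- infer_sites(ev, sites_df(c(93, 104)), treated = c("pH1", "pH12"))
  rep <- site_report(calls)
  expect_equal(nrow(rep), 4L)
  expect_setequal(rep$condition, c("pH1", "pH12"))
  expect_true("R93" %in% rep$site)
  expect_equal(rep$state[rep$site == "R93" & rep$condition == "pH1"],
               "exposed")
  expect_equal(rep$state[rep$site == "R93" & rep$condition == "pH12"],
               "masked")
})
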