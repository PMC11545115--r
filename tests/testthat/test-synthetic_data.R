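test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42, preset = "noisy")
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$protein$sequence, b$protein$sequence)
  expect_identical(a$table$observations, b$table$observations)
  expect_identical(a$elisa, b$elisa)
  expect_identical(a$truth, b$truth)
  # and a different seed changes the draw
  c <- simulate_dataset(sim_config(seed = 43, preset = "noisy"))
  expect_false(identical(a$protein$sequence, c$protein$sequence))
})

test_that("kr_density controls cleavage-site placement", {
  cfg0 <- sim_config(seed = 1, kr_density = 0, protein_length = 200,
                     n_exposed = 0, n_masked = 0)
  sim <- simulate_protein(cfg0)
  expect_equal(nrow(sim$sites), 0L)
  expect_false(grepl("[KR]", sim$protein$sequence))

  # K/R count over many draws stays inside the pooled binomial 99% interval
  n_seeds <- 60
  len <- 200
  dens <- 0.08
  kr <- vapply(seq_len(n_seeds), function(s) {
    p <- simulate_protein(sim_config(seed = s, protein_length = len,
                                     kr_density = dens, n_exposed = 0,
                                     n_masked = 0))
    lengths(regmatches(p$protein$sequence,
                       gregexpr("[KR]", p$protein$sequence)))
  }, integer(1))
  total <- sum(kr)
  bounds <- qbinom(c(0.005, 0.995), n_seeds * len, dens)
  expect_gte(total, bounds[1])
  expect_lte(total, bounds[2])
})

test_that("planted accessibility changes produce one-sided peptides", {
  cfg <- sim_config(seed = 7, preset = "noiseless")
  ds <- simulate_quant_table(cfg)
  diffs <- do.call(rbind, lapply(cfg$treated, function(cc)
    compute_ra(ds$table, cc)))
  exposed <- ds$truth$sites[ds$truth$sites$direction == "exposed", ]
  for (i in seq_len(nrow(exposed))) {
    p <- exposed$position[i]
    cond <- exposed$condition[i]
    flank <- diffs[diffs$condition == cond &
                     (diffs$start == p + 1L | diffs$end == p), ]
    expect_gt(nrow(flank), 0)
    expect_true(all(flank$category == "only_in_treated"))
  }
  masked <- ds$truth$sites[ds$truth$sites$direction == "masked", ]
  for (i in seq_len(nrow(masked))) {
    p <- masked$position[i]
    cond <- masked$condition[i]
    flank <- diffs[diffs$condition == cond &
                     (diffs$start == p + 1L | diffs$end == p), ]
    expect_true(all(flank$category == "only_in_control"))
  }
})

test_that("planted fold changes reproduce exactly without noise", {
  cfg <- sim_config(seed = 9, preset = "noiseless")
  ds <- simulate_quant_table(cfg)
  diffs <- do.call(rbind, lapply(cfg$treated, function(cc)
    compute_ra(ds$table, cc)))
  rec <- assess_ra_recovery(diffs, ds$truth$ra)
  expect_equal(attr(rec, "rate"), 1)
  expect_equal(rec$observed_ra, rec$ra, tolerance = 1e-12)
  expect_true(11.5 %in% rec$ra && 3.8 %in% rec$ra)
})

test_that("with everything at probability 1 the table is the exact digest", {
  cfg <- sim_config(seed = 3, preset = "noiseless", n_exposed = 0,
                    n_masked = 0)
  ds <- simulate_quant_table(cfg)
  expected <- digest(ds$protein, digest_params(max_missed_cleavages = 0))
  obs <- ds$table$observations
  expect_equal(obs$start, expected$start)
  expect_equal(obs$end, expected$end)
  # every condition detects every window peptide
  for (cond in cfg$conditions) expect_false(anyNA(obs[[cond]]))
})

test_that("noiseless ELISA simulation closes the loop through the fit", {
  cfg <- sim_config(seed = 5, preset = "noiseless")
  el <- simulate_elisa(cfg)
  ir <- inhibition_ratio(el$measurements$b0, el$measurements$b1,
                         el$measurements$b2)
  fit <- fit_4pl(el$measurements$concentration, ir)
  expect_equal(ic50(fit), el$truth$ic50, tolerance = 1e-6)
  cf <- coef(fit)
  expect_equal(unname(cf["hill"]), el$truth$hill, tolerance = 1e-4)
  expect_error(sim_config(seed = 1, elisa = list(noise_sd = -1)),
               "non-negative")
})

test_that("dataset files round-trip through the package readers", {
  cfg <- sim_config(seed = 6, preset = "noiseless")
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(cfg, dir)
  expect_true(all(file.exists(unlist(ds$paths))))
  prot <- read_fasta(ds$paths$fasta)
  expect_equal(prot$sequence, ds$protein$sequence)
  tab <- read_quant_table(ds$paths$quant, control = cfg$control)
  expect_equal(tab$observations[c("start", "end")],
               ds$table$observations[c("start", "end")])
  reg <- load_epitope_registry(ds$paths$epitopes, prot)
  expect_true(all(reg$parent_match))
  expect_true(all(reg$length_consistent))
  truth <- jsonlite::read_json(ds$paths$truth, simplifyVector = TRUE)
  expect_setequal(names(truth), c("sites", "ra", "epitopes", "elisa"))
})

test_that("generator truth agrees with independent epitope coverage", {
  cfg <- sim_config(seed = 8, preset = "noisy")
  ds <- simulate_dataset(cfg)
  tr <- ds$truth$epitopes
  for (i in seq_len(nrow(tr))) {
    e <- list(accession = ds$protein$accession, start = tr$start[i],
              end = tr$end[i])
    expect_equal(epitope_coverage(e, ds$table, cfg$control)$intact,
                 tr$intact_control[i])
    expect_equal(epitope_coverage(e, ds$table, tr$condition[i])$intact,
                 tr$intact_treated[i])
  }
})
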