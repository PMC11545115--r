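# Seeded synthetic-data generator: proteins with known cleavage sites,
# label-free quant tables with planted site-accessibility changes, fold
# changes and epitopes, and 4PL-shaped ELISA plates — every stage of the
# pipeline gets inputs with recorded ground truth.

#' Simulation configuration
#'
#' Defines the emulated study: a control condition (`NPP`) and two
#' pH-shift-treated conditions, condition-dependent cleavage-site
#' accessibility, a hard 5-45 aa detection window, multiplicative
#' (log-normal) intensity noise with planted fold changes, planted linear
#' epitopes, and a 4PL-shaped inhibition curve. Presets:
#'
#' * `noiseless` (default): all site accessibilities 0/1, detection
#'   probability 1 inside the window, no intensity or ELISA noise —
#'   planted effects are recovered exactly.
#' * `noisy`: base accessibility 0.9 (planted sites 0.95/0.05), detection
#'   probability 0.9, log-scale intensity noise sd 0.3, ELISA noise 3
#'   percentage points.
#' * `hard`: a stress setting with weaker accessibility contrast and more
#'   noise.
#'
#' Planted relative abundances default to 11.5 and 3.8 for the first marker
#' peptide in the two treated conditions and 0.3 (a clear decrease) for the
#' second, spanning the increased/decreased/unchanged categories. The ELISA
#' truth defaults to bottom 0, top 100, IC50 0.22 ug/mL, hill 1 over 8
#' log-spaced concentrations.
#'
#' @param seed Integer seed; all generator output is byte-identical under a
#'   fixed seed.
#' @param preset One of `"noiseless"`, `"noisy"`, `"hard"` (`"default"` is
#'   accepted as an alias for `"noiseless"`).
#' @param protein_length Length of the simulated protein (residues).
#' @param kr_density Probability that a residue is K or R.
#' @param conditions Condition names, control first by convention.
#' @param control Control condition name.
#' @param n_exposed,n_masked Number of planted exposed/masked cleavage
#'   sites (per treated condition; the same sites are planted in both).
#' @param planted_ra Named list mapping each treated condition to the RA
#'   values planted on the marker peptides.
#' @param accessibility Optional list overriding `base`, `on`, `off`
#'   cleavage probabilities.
#' @param detection Optional list overriding `min_len`, `max_len`, `prob`.
#' @param intensity Optional list overriding `meanlog`, `sdlog`,
#'   `noise_sd`.
#' @param elisa Optional list overriding `bottom`, `top`, `ic50`, `hill`,
#'   `noise_sd`, `concentrations`, `replicates`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       preset = c("noiseless", "noisy", "hard", "default"),
                       protein_length = 800L, kr_density = 0.05,
                       conditions = c("NPP", "pH1.0_shift", "pH12.0_shift"),
                       control = "NPP",
                       n_exposed = 2L, n_masked = 2L,
                       planted_ra = NULL,
                       accessibility = NULL, detection = NULL,
                       intensity = NULL, elisa = NULL) {
  preset <- match.arg(preset)
  if (preset == "default") preset <- "noiseless"
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (!control %in% conditions) stop("control must be one of the conditions")
  if (length(conditions) < 2L) stop("need at least one treated condition")
  treated <- setdiff(conditions, control)
  base <- switch(preset,
    noiseless = list(acc = list(base = 1, on = 1, off = 0),
                     det = list(prob = 1), noise_sd = 0, elisa_sd = 0),
    noisy = list(acc = list(base = 0.9, on = 0.95, off = 0.05),
                 det = list(prob = 0.9), noise_sd = 0.3, elisa_sd = 3),
    hard = list(acc = list(base = 0.85, on = 0.9, off = 0.1),
                det = list(prob = 0.8), noise_sd = 0.6, elisa_sd = 6))
  acc <- utils::modifyList(base$acc, accessibility %||% list())
  det <- utils::modifyList(list(min_len = 5L, max_len = 45L,
                                prob = base$det$prob), detection %||% list())
  intens <- utils::modifyList(list(meanlog = log(1e6), sdlog = 1,
                                   noise_sd = base$noise_sd),
                              intensity %||% list())
  el <- utils::modifyList(list(bottom = 0, top = 100, ic50 = 0.22, hill = 1,
                               noise_sd = base$elisa_sd,
                               concentrations = 10^seq(-2, 2,
                                                       length.out = 8),
                               replicates = 1L), elisa %||% list())
  probs <- c(kr_density, unlist(acc), det$prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (intens$noise_sd < 0 || el$noise_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (is.null(planted_ra)) {
    planted_ra <- stats::setNames(rep(list(c(0.3, 1.0)), length(treated)),
                                  treated)
    planted_ra[[treated[1]]] <- c(11.5, 0.3, 1.0)
    if (length(treated) > 1L) planted_ra[[treated[2]]] <- c(3.8, 0.3, 1.0)
  }
  structure(list(seed = seed, preset = preset,
                 protein_length = as.integer(protein_length),
                 kr_density = kr_density, conditions = conditions,
                 control = control, treated = treated,
                 n_exposed = as.integer(n_exposed),
                 n_masked = as.integer(n_masked),
                 planted_ra = planted_ra, accessibility = acc,
                 detection = det, intensity = intens, elisa = el),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the scalar-x surprise
.resample <- function(x) x[sample.int(length(x))]

# fragment table for a boundary vector c(0, fired sites, L)
.fragments <- function(bounds) {
  data.frame(start = utils::head(bounds, -1) + 1L,
             end = bounds[-1])
}

#' Simulate a protein with known cleavage sites and planted features
#'
#' Draws a random amino-acid sequence with K/R placed at `kr_density`, then
#' deterministically selects the planted features used by
#' [simulate_quant_table()]:
#'
#' * `n_masked` + `n_exposed` cleavage sites whose flanking tryptic
#'   fragments fall inside the detection window; at least one masked and
#'   one exposed site are chosen so that the merged fragment (when the site
#'   does not cleave) exceeds the window, which guarantees a detectable
#'   coverage loss/gain. The protein is redrawn (deterministically, bounded
#'   attempts) until such sites exist.
#' * marker peptides for planted fold changes, away from any planted site;
#' * four planted epitopes with intended outcomes: one `retained` inside a
#'   stable peptide, one `reduced` on a decreased marker peptide, one
#'   `lost` straddling a masked site and one `gained` straddling an exposed
#'   site.
#'
#' @param config A [sim_config()].
#' @return list with `protein` (one-row `protein_set`), `sites` (full
#'   cleavage-site truth), `planted_sites` (position, residue, direction,
#'   merged length), `marker_peptides` and `epitopes` (with
#'   `intended_change`).
#' @export
simulate_protein <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_ra <- max(lengths(config$planted_ra))
  alphabet <- setdiff(AA_CANONICAL, c("K", "R"))
  plain <- config$n_exposed + config$n_masked == 0L
  empty_epi <- data.frame(label = character(0), start = integer(0),
                          end = integer(0), intended_change = character(0),
                          accession = character(0), sequence = character(0),
                          stringsAsFactors = FALSE)
  for (attempt in seq_len(50L)) {
    set.seed(config$seed + 7919L * (attempt - 1L))
    L <- config$protein_length
    is_kr <- stats::runif(L) < config$kr_density
    ch <- ifelse(is_kr, sample(c("K", "R"), L, replace = TRUE),
                 sample(alphabet, L, replace = TRUE))
    protein <- protein_record("SYN1", paste(ch, collapse = ""),
                              "synthetic protein")
    sites <- find_cleavage_sites(protein, digest_params())
    m <- nrow(sites)
    if (plain) {
      # nothing planted: return the protein and its site truth as-is
      return(list(protein = protein, sites = sites,
                  planted_sites = data.frame(position = integer(0),
                                             residue = character(0),
                                             direction = character(0),
                                             merged_length = integer(0),
                                             stringsAsFactors = FALSE),
                  marker_peptides = data.frame(start = integer(0),
                                               end = integer(0)),
                  epitopes = empty_epi))
    }
    if (m < 8L) next
    bounds <- c(0L, sites$position, L)
    frag <- .fragments(bounds)
    frag_len <- frag$end - frag$start + 1L
    win <- config$detection
    # site k separates fragments k and k+1
    k <- seq_len(m)
    left <- frag_len[k]
    right <- frag_len[k + 1L]
    eligible <- k >= 2L & k <= m - 1L &
      left >= max(6L, win$min_len) & left <= min(40L, win$max_len) &
      right >= max(6L, win$min_len) & right <= min(40L, win$max_len)
    merged <- left + right
    big <- eligible & merged > win$max_len
    pick <- function(pool, n, taken) {
      out <- integer(0)
      for (p in pool) {
        if (length(out) >= n) break
        if (all(abs(p - c(taken, out)) >= 2L)) out <- c(out, p)
      }
      out
    }
    ord_big <- .resample(which(big))
    ord_rest <- .resample(which(eligible & !big))
    masked1 <- pick(ord_big, 1L, integer(0))
    exposed1 <- pick(ord_big, 1L, masked1)
    if (length(masked1) < 1L || length(exposed1) < 1L) next
    masked_k <- c(masked1, pick(c(ord_big, ord_rest), config$n_masked - 1L,
                                c(masked1, exposed1)))
    exposed_k <- c(exposed1,
                   pick(c(ord_big, ord_rest), config$n_exposed - 1L,
                        c(masked_k, exposed1)))
    if (length(masked_k) < config$n_masked ||
        length(exposed_k) < config$n_exposed) next
    planted_k <- c(masked_k, exposed_k)
    planted_sites <- data.frame(
      position = sites$position[planted_k],
      residue = sites$residue[planted_k],
      direction = rep(c("masked", "exposed"),
                      c(length(masked_k), length(exposed_k))),
      merged_length = merged[planted_k], stringsAsFactors = FALSE)
    # marker peptides: window-sized fragments whose flanking sites are all
    # unplanted and not adjacent to a planted site
    frag_ok <- which(
      frag_len >= win$min_len & frag_len <= win$max_len &
        !(seq_along(frag_len) %in% c(planted_k, planted_k + 1L)) &
        frag_len >= 12L)
    frag_ok <- .resample(frag_ok)
    if (length(frag_ok) < n_ra + 1L) next
    marker <- frag[frag_ok[seq_len(n_ra)], , drop = FALSE]
    stable <- frag[frag_ok[n_ra + 1L], , drop = FALSE]
    dec_idx <- which(vapply(seq_len(n_ra), function(i)
      all(vapply(config$planted_ra, function(v) v[i] < 0.5, logical(1))),
      logical(1)))[1]
    if (is.na(dec_idx)) dec_idx <- min(2L, n_ra)
    epi <- data.frame(
      label = c("epi_retained", "epi_reduced", "epi_lost", "epi_gained"),
      start = c(stable$start + 1L, marker$start[dec_idx] + 1L,
                planted_sites$position[1] - 4L,
                planted_sites$position[length(masked_k) + 1L] - 4L),
      end = c(stable$start + 10L, marker$start[dec_idx] + 10L,
              planted_sites$position[1] + 5L,
              planted_sites$position[length(masked_k) + 1L] + 5L),
      intended_change = c("retained", "reduced", "lost", "gained"),
      stringsAsFactors = FALSE)
    epi$accession <- protein$accession
    epi$sequence <- substring(protein$sequence, epi$start, epi$end)
    rownames(planted_sites) <- rownames(marker) <- NULL
    return(list(protein = protein, sites = sites,
                planted_sites = planted_sites,
                marker_peptides = marker, epitopes = epi))
  }
  stop("could not place the planted features; ",
       "try a longer protein or lower kr_density")
}

#' Simulate a label-free peptide quantification table with ground truth
#'
#' For each condition every cleavage site fires with its accessibility
#' probability (planted masked sites fire in the control but not in the
#' treated conditions; exposed sites the reverse). The resulting fully
#' cleaved fragments inside the detection window are detected with the
#' configured probability; intensities are log-normal around a per-peptide
#' base abundance, multiplied by any planted fold change in the treated
#' conditions and by multiplicative noise.
#'
#' @param sim Output of [simulate_protein()] (or a `sim_config`, in which
#'   case the protein is simulated first).
#' @param config A [sim_config()].
#' @return list: `table` (a [quant_table()]), `truth` (planted site states
#'   per treated condition, planted RA values, epitope intactness per
#'   condition and intended changes), and `protein`/`sites` passed through.
#' @export
simulate_quant_table <- function(sim, config = NULL) {
  if (inherits(sim, "sim_config")) {
    config <- sim
    sim <- simulate_protein(config)
  }
  stopifnot(inherits(config, "sim_config"))
  protein <- sim$protein
  sites <- sim$sites
  L <- nchar(protein$sequence)
  set.seed(config$seed + 104729L)
  win <- config$detection
  acc_cfg <- config$accessibility
  # per-position latents give every possible fragment a reproducible base
  # abundance independent of which sites happened to fire
  u <- stats::rnorm(L)
  v <- stats::rnorm(L)
  base_intensity <- function(s, e)
    exp(config$intensity$meanlog +
          config$intensity$sdlog * (u[s] + v[e]) / sqrt(2))
  ra_tab <- do.call(rbind, lapply(config$treated, function(cond) {
    vals <- config$planted_ra[[cond]]
    k <- min(length(vals), nrow(sim$marker_peptides))
    data.frame(start = sim$marker_peptides$start[seq_len(k)],
               end = sim$marker_peptides$end[seq_len(k)],
               condition = rep(cond, k), ra = vals[seq_len(k)],
               stringsAsFactors = FALSE)
  }))
  ra_factor <- function(s, e, cond) {
    hit <- ra_tab$condition == cond & ra_tab$start == s & ra_tab$end == e
    if (any(hit)) ra_tab$ra[hit][1] else 1
  }
  site_acc <- function(cond) {
    a <- rep(acc_cfg$base, nrow(sites))
    idx <- match(sim$planted_sites$position, sites$position)
    on_treated <- sim$planted_sites$direction == "exposed"
    if (cond == config$control) {
      a[idx] <- ifelse(on_treated, acc_cfg$off, acc_cfg$on)
    } else {
      a[idx] <- ifelse(on_treated, acc_cfg$on, acc_cfg$off)
    }
    a
  }
  detected <- list()
  for (cond in config$conditions) {
    fired <- stats::runif(nrow(sites)) < site_acc(cond)
    frag <- .fragments(c(0L, sites$position[fired], L))
    len <- frag$end - frag$start + 1L
    in_win <- len >= win$min_len & len <= win$max_len
    det <- in_win & stats::runif(nrow(frag)) < win$prob
    frag <- frag[det, , drop = FALSE]
    noise <- if (config$intensity$noise_sd > 0)
      exp(stats::rnorm(nrow(frag), 0, config$intensity$noise_sd)) else
        rep(1, nrow(frag))
    fold <- vapply(seq_len(nrow(frag)), function(i)
      ra_factor(frag$start[i], frag$end[i], cond), numeric(1))
    frag$intensity <- base_intensity(frag$start, frag$end) * fold * noise
    detected[[cond]] <- frag
  }
  all_int <- unique(do.call(rbind, lapply(detected, function(d)
    d[c("start", "end")])))
  all_int <- all_int[order(all_int$start, all_int$end), , drop = FALSE]
  obs <- data.frame(accession = protein$accession, start = all_int$start,
                    end = all_int$end,
                    sequence = substring(protein$sequence, all_int$start,
                                         all_int$end),
                    stringsAsFactors = FALSE)
  for (cond in config$conditions) {
    d <- detected[[cond]]
    obs[[cond]] <- d$intensity[match(paste(obs$start, obs$end),
                                     paste(d$start, d$end))]
  }
  table <- quant_table(obs, config$conditions, config$control)
  intact_in <- function(epi, cond) {
    d <- detected[[cond]]
    if (!nrow(d)) return(FALSE)
    covered <- unique(unlist(Map(seq.int, d$start, d$end)))
    all(seq.int(epi$start, epi$end) %in% covered)
  }
  epi_truth <- do.call(rbind, lapply(config$treated, function(cond) {
    e <- sim$epitopes
    e$condition <- rep(cond, nrow(e))
    e$intact_control <- vapply(seq_len(nrow(e)), function(i)
      intact_in(e[i, ], config$control), logical(1))
    e$intact_treated <- vapply(seq_len(nrow(e)), function(i)
      intact_in(e[i, ], cond), logical(1))
    e
  }))
  site_truth <- do.call(rbind, lapply(config$treated, function(cond) {
    s <- sim$planted_sites
    s$condition <- rep(cond, nrow(s))
    s
  }))
  rownames(epi_truth) <- rownames(site_truth) <- NULL
  list(table = table, protein = protein, sites = sites,
       truth = list(sites = site_truth, ra = ra_tab, epitopes = epi_truth))
}

#' Simulate competitive-ELISA absorbance measurements
#'
#' Inhibition ratios are generated from the configured 4PL truth plus
#' additive Gaussian noise (percentage points), then inverted through the
#' inhibition-ratio equation into well absorbances with blank `b0 = 0.1`
#' and positive `b2 = 1.1`.
#'
#' @param config A [sim_config()].
#' @param sample Sample label written into the table.
#' @param seed_offset Added to the config seed so several independent
#'   plates can be drawn from one config.
#' @return list: `measurements` (data.frame `sample`, `concentration`,
#'   `b0`, `b1`, `b2`), `truth` (the generating 4PL parameters).
#' @export
simulate_elisa <- function(config, sample = "synthetic", seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  el <- config$elisa
  if (el$noise_sd < 0) stop("elisa noise_sd must be non-negative")
  set.seed(config$seed + 224737L + as.integer(seed_offset))
  conc <- rep(el$concentrations, each = el$replicates)
  ir <- four_pl(conc, el$bottom, el$top, el$ic50, el$hill)
  if (el$noise_sd > 0) ir <- ir + stats::rnorm(length(ir), 0, el$noise_sd)
  b0 <- 0.1
  b2 <- 1.1
  b1 <- b0 + (1 - ir / 100) * (b2 - b0)
  list(measurements = data.frame(sample = sample, concentration = conc,
                                 b0 = b0, b1 = pmax(b1, 0), b2 = b2,
                                 stringsAsFactors = FALSE),
       truth = el)
}

#' Generate and (optionally) write a complete synthetic dataset
#'
#' Produces every input the pipeline consumes — FASTA, wide quant TSV,
#' epitope registry TSV (source tagged `synthetic`), ELISA TSV — plus a
#' `truth.json` ground-truth record.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; created if missing.
#' @return list with `protein`, `sites`, `table`, `truth`, `epitopes`,
#'   `elisa`, and `paths` when written.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  sim <- simulate_protein(config)
  q <- simulate_quant_table(sim, config)
  el <- simulate_elisa(config)
  registry <- data.frame(accession = sim$epitopes$accession,
                         label = sim$epitopes$label,
                         start = sim$epitopes$start,
                         end = sim$epitopes$end,
                         sequence = sim$epitopes$sequence,
                         source = "synthetic", stringsAsFactors = FALSE)
  out <- list(protein = sim$protein, sites = sim$sites, table = q$table,
              truth = c(q$truth, list(elisa = el$truth)),
              epitopes = registry, elisa = el$measurements)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(out_dir, "protein.fasta"),
                  quant = file.path(out_dir, "quant.tsv"),
                  epitopes = file.path(out_dir, "epitopes.tsv"),
                  elisa = file.path(out_dir, "elisa.tsv"),
                  truth = file.path(out_dir, "truth.json"))
    write_fasta(sim$protein, paths$fasta)
    write_quant_table(q$table, paths$quant)
    utils::write.table(registry, paths$epitopes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(el$measurements, paths$elisa, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out$truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    out$paths <- paths
  }
  out
}

#' Score recovery of planted site states
#'
#' A planted site is eligible when the pipeline collected at least
#' `min_support` evidence peptides voting in the planted direction; it is
#' recovered when the called state equals the planted direction.
#'
#' @param evidence Output of [collect_site_evidence()] (all treated
#'   conditions pooled).
#' @param calls Output of [infer_sites()].
#' @param truth_sites `truth$sites` from [simulate_quant_table()].
#' @param min_support Minimum concordant evidence peptides (default 2).
#' @return data.frame per planted site x condition with `n_support`,
#'   `eligible`, `state`, `recovered`; the recovery rate over eligible
#'   sites is attached as attribute `rate`.
#' @export
assess_site_recovery <- function(evidence, calls, truth_sites,
                                 min_support = 2L) {
  rows <- lapply(seq_len(nrow(truth_sites)), function(i) {
    p <- truth_sites$position[i]
    cond <- truth_sites$condition[i]
    dir <- truth_sites$direction[i]
    want <- if (dir == "exposed") 1L else -1L
    ev <- evidence[evidence$position == p & evidence$condition == cond, ,
                   drop = FALSE]
    n_support <- sum(ev$vote == want)
    call <- calls[calls$position == p & calls$condition == cond, ,
                  drop = FALSE]
    state <- if (nrow(call)) call$state[1] else "no_evidence"
    data.frame(position = p, condition = cond, direction = dir,
               n_support = n_support,
               eligible = n_support >= min_support, state = state,
               recovered = state == dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  elig <- out[out$eligible, , drop = FALSE]
  attr(out, "rate") <- if (nrow(elig)) mean(elig$recovered) else NA_real_
  out
}

#' Score recovery of planted RA categories
#'
#' @param differentials Pooled [compute_ra()] output over the treated
#'   conditions.
#' @param truth_ra `truth$ra` from [simulate_quant_table()].
#' @param params The [diff_params()] used by the pipeline.
#' @return data.frame with observed `ra`/`category`, the expected category
#'   from the planted value, and `recovered`; category accuracy over
#'   two-sided detections attached as attribute `rate`.
#' @export
assess_ra_recovery <- function(differentials, truth_ra,
                               params = diff_params()) {
  d <- differentials
  key_d <- paste(d$start, d$end, d$condition)
  key_t <- paste(truth_ra$start, truth_ra$end, truth_ra$condition)
  idx <- match(key_t, key_d)
  out <- truth_ra
  out$observed_ra <- d$ra[idx]
  out$observed_category <- d$category[idx]
  out$expected_category <- classify_ra(out$ra, params)
  out$recovered <- !is.na(out$observed_category) &
    out$observed_category == out$expected_category
  scored <- out[!is.na(out$observed_ra), , drop = FALSE]
  attr(out, "rate") <- if (nrow(scored))
    mean(scored$observed_category == scored$expected_category) else NA_real_
  out
}

#' Score recovery of planted epitope changes
#'
#' Compares the pipeline's epitope change labels with the generator's
#' intended outcomes (`retained` / `reduced` / `lost` / `gained`) and with
#' the realised intact flags recorded in the truth.
#'
#' @param report Output of [epitope_report()].
#' @param truth_epitopes `truth$epitopes` from [simulate_quant_table()].
#' @return data.frame joining report and truth with `recovered`
#'   (change == intended) and `intact_agrees`; the recovery rate is
#'   attached as attribute `rate`.
#' @export
assess_epitope_recovery <- function(report, truth_epitopes) {
  key_r <- paste(report$label, report$condition)
  key_t <- paste(truth_epitopes$label, truth_epitopes$condition)
  idx <- match(key_t, key_r)
  out <- truth_epitopes
  out$change <- report$change[idx]
  out$report_intact_control <- report$intact_control[idx]
  out$report_intact_treated <- report$intact_treated[idx]
  out$recovered <- !is.na(out$change) & out$change == out$intended_change
  out$intact_agrees <- out$report_intact_control == out$intact_control &
    out$report_intact_treated == out$intact_treated
  attr(out, "rate") <- mean(out$recovered)
  out
}
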