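# Pipeline orchestration: one call running detection filter -> differential
# classification -> coverage summary -> site inference -> epitope report,
# writing auditable TSV outputs, plus a fixed-width text coverage map.

#' Pipeline configuration
#'
#' Inputs may be given as file paths (FASTA / TSVs) or as in-memory objects
#' (`protein_set`, `quant_table`, `epitope_registry`); file inputs are
#' validated at run start.
#'
#' @param fasta Protein FASTA path or a `protein_set`.
#' @param quant Quant-table TSV path or a `quant_table`.
#' @param epitopes Optional epitope-registry TSV path or registry object.
#' @param control Control condition name.
#' @param treated Treated condition name(s).
#' @param out_dir Output directory (created if missing).
#' @param digest A [digest_params()].
#' @param diff A [diff_params()].
#' @param require_single_peptide Stricter epitope-intactness rule; see
#'   [epitope_coverage()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, quant, epitopes = NULL, control, treated,
                            out_dir, digest = digest_params(),
                            diff = diff_params(),
                            require_single_peptide = FALSE) {
  for (x in list(fasta, quant, epitopes)) {
    if (is.character(x) && length(x) == 1L && !file.exists(x))
      stop("input file not found: ", x)
  }
  structure(list(fasta = fasta, quant = quant, epitopes = epitopes,
                 control = control, treated = treated, out_dir = out_dir,
                 digest = digest, diff = diff,
                 require_single_peptide = isTRUE(require_single_peptide)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full peptide-map analysis pipeline
#'
#' Executes, in order: detection-length filter, coordinate/sequence
#' reconciliation, relative-abundance classification for every treated
#' condition, coverage/peptide-count summary, cleavage-site state inference
#' and (when a registry is given) the epitope status report. Writes
#' `differential.tsv`, `summary.tsv`, `site_calls.tsv`,
#' `epitope_status.tsv`, `coverage_map.txt`, a deterministic
#' `config_snapshot.json`, and a timestamped `run.log`. All data outputs
#' are deterministic functions of the inputs: rerunning on the same inputs
#' reproduces them byte for byte (only `run.log` carries wall-clock
#' timestamps).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the result tables (`differential`,
#'   `summary`, `site_calls`, `epitope_status`), the rendered `map` lines
#'   and the output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  say("pepshift ", as.character(utils::packageVersion("pepshift")),
      " pipeline start")
  proteins <- .stage("read_fasta", {
    if (is.character(config$fasta)) read_fasta(config$fasta)
    else as_protein_set(config$fasta)
  })
  table <- .stage("read_quant", {
    if (is.character(config$quant))
      read_quant_table(config$quant, control = config$control)
    else config$quant
  })
  if (!identical(table$control, config$control))
    stop("pipeline stage 'read_quant' failed: table control '",
         table$control, "' differs from configured '", config$control, "'")
  registry <- .stage("read_epitopes", {
    if (is.null(config$epitopes)) NULL
    else if (is.character(config$epitopes))
      load_epitope_registry(config$epitopes, proteins)
    else config$epitopes
  })
  say("inputs: ", nrow(proteins), " protein(s), ",
      nrow(table$observations), " peptide observation(s)")
  table <- .stage("detection_filter",
                  suppressMessages(apply_detection_filter(table,
                                                          config$digest)))
  say("detection filter removed ", attr(table, "removed"),
      " observation(s)")
  coerced <- .stage("sequence_match",
                    coerce_to_sequence_match(table, proteins))
  table <- coerced$table
  say("sequence reconciliation: ", nrow(coerced$report), " row(s) flagged")
  differential <- .stage("differential", {
    do.call(rbind, lapply(config$treated, function(cond)
      compute_ra(table, cond, config$diff)))
  })
  summary_tab <- .stage("coverage", coverage_summary(
    table, proteins, conditions = c(config$control, config$treated)))
  site_calls <- .stage("sites", {
    rows <- lapply(unique(table$observations$accession), function(acc) {
      prot <- proteins[proteins$accession == acc, , drop = FALSE]
      sites <- find_cleavage_sites(prot, config$digest)
      d <- differential[differential$accession == acc, , drop = FALSE]
      ev <- collect_site_evidence(d, sites, nchar(prot$sequence))
      calls <- infer_sites(ev, sites, treated = config$treated)
      calls$accession <- rep(acc, nrow(calls))
      calls
    })
    do.call(rbind, rows)
  })
  epitope_status <- if (!is.null(registry)) .stage("epitopes",
    suppressMessages(epitope_report(
      registry, table, control = config$control, treated = config$treated,
      params = config$diff,
      require_single_peptide = config$require_single_peptide))) else NULL
  map_lines <- .stage("coverage_map", render_coverage_map(
    proteins[proteins$accession %in% table$observations$accession, ,
             drop = FALSE],
    table, epitopes = registry, params = config$diff))
  paths <- list(differential = file.path(config$out_dir, "differential.tsv"),
                summary = file.path(config$out_dir, "summary.tsv"),
                site_calls = file.path(config$out_dir, "site_calls.tsv"),
                epitope_status = file.path(config$out_dir,
                                           "epitope_status.tsv"),
                coverage_map = file.path(config$out_dir, "coverage_map.txt"),
                config = file.path(config$out_dir, "config_snapshot.json"),
                log = log_path)
  .stage("write_outputs", {
    utils::write.table(differential, paths$differential, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    utils::write.table(summary_tab, paths$summary, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    site_report(site_calls, paths$site_calls)
    if (!is.null(epitope_status))
      utils::write.table(epitope_status, paths$epitope_status, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    writeLines(map_lines, paths$coverage_map)
    snapshot <- list(
      package_version = as.character(utils::packageVersion("pepshift")),
      control = config$control, treated = config$treated,
      fasta = if (is.character(config$fasta)) config$fasta else "<object>",
      quant = if (is.character(config$quant)) config$quant else "<object>",
      epitopes = if (is.character(config$epitopes)) config$epitopes
                 else if (is.null(config$epitopes)) NULL else "<object>",
      digest = unclass(config$digest), diff = unclass(config$diff),
      require_single_peptide = config$require_single_peptide)
    jsonlite::write_json(snapshot, paths$config, auto_unbox = TRUE,
                         digits = NA, null = "null")
  })
  say("pipeline done; outputs in ", config$out_dir)
  writeLines(log_lines, log_path)
  invisible(list(differential = differential, summary = summary_tab,
                 site_calls = site_calls, epitope_status = epitope_status,
                 map = map_lines, paths = paths))
}

.draw_track <- function(track, peptides, glyph) {
  for (i in seq_len(nrow(peptides))) {
    idx <- seq.int(peptides$start[i], peptides$end[i])
    track[idx] <- glyph[i]
  }
  track
}

#' Render a fixed-width text coverage map
#'
#' One block per `width` residues: the sequence row, one aligned track row
#' per condition, and an epitope row. Track glyphs follow the differential
#' categories: `=` unchanged, `+` increased, `-` decreased, `C` detected in
#' the control only, `T` detected in the treated condition only; epitope
#' residues are marked `~`. Within each block every row has exactly `width`
#' columns (the last block is padded), so a peptide spanning a block break
#' continues on the next block without gaps. The number of non-blank
#' columns in a condition's track equals the number of residues covered by
#' peptides detected in that condition.
#'
#' @param proteins A `protein_set` (one map per protein).
#' @param table A [quant_table()].
#' @param epitopes Optional epitope registry; epitopes are drawn under their
#'   parent protein.
#' @param params A [diff_params()] for category glyphs.
#' @param width Residues per block (default 60).
#' @return Character vector of text lines.
#' @export
render_coverage_map <- function(proteins, table, epitopes = NULL,
                                params = diff_params(), width = 60L) {
  stopifnot(inherits(table, "quant_table"))
  proteins <- as_protein_set(proteins)
  control <- table$control
  treated <- setdiff(table$conditions, control)
  glyph_map <- c(unchanged = "=", decreased = "-", increased = "+",
                 only_in_control = "C", only_in_treated = "T")
  out <- c(paste0("# peptide coverage map; tracks per block: ",
                  paste(table$conditions, collapse = ", ")),
           "# glyphs: = unchanged  + increased  - decreased  C control-only  T treated-only  ~ epitope")
  diffs <- lapply(stats::setNames(treated, treated), function(cond)
    compute_ra(table, cond, params))
  for (i in seq_len(nrow(proteins))) {
    acc <- proteins$accession[i]
    L <- nchar(proteins$sequence[i])
    tracks <- list()
    # control track: "=" for covered residues, "C" where only peptides
    # absent from every treated condition reach
    det_c <- .detected_obs(table, acc, control)
    if (nrow(det_c)) {
      in_any_treated <- Reduce(`|`, lapply(treated, function(cond)
        !is.na(det_c[[cond]])), rep(FALSE, nrow(det_c)))
    } else in_any_treated <- logical(0)
    track <- rep(" ", L)
    track <- .draw_track(track, det_c[!in_any_treated, , drop = FALSE],
                         rep("C", sum(!in_any_treated)))
    track <- .draw_track(track, det_c[in_any_treated, , drop = FALSE],
                         rep("=", sum(in_any_treated)))
    tracks[[control]] <- track
    for (cond in treated) {
      d <- diffs[[cond]]
      d <- d[d$accession == acc & d$category != "only_in_control", ,
             drop = FALSE]
      d <- d[order(match(d$category, names(glyph_map))), , drop = FALSE]
      tracks[[cond]] <- .draw_track(rep(" ", L), d,
                                    unname(glyph_map[d$category]))
    }
    epi_row <- rep(" ", L)
    if (!is.null(epitopes)) {
      ep <- epitopes[epitopes$accession == acc & epitopes$end <= L, ,
                     drop = FALSE]
      epi_row <- .draw_track(epi_row, ep, rep("~", nrow(ep)))
    }
    out <- c(out, "", paste0("# ", acc, " (", L, " aa)"))
    seq_ch <- strsplit(proteins$sequence[i], "")[[1]]
    pad <- function(ch) {
      if (length(ch) < width) ch <- c(ch, rep(" ", width - length(ch)))
      paste(ch, collapse = "")
    }
    for (blk_start in seq(1L, L, by = width)) {
      blk <- seq.int(blk_start, min(blk_start + width - 1L, L))
      out <- c(out, paste0("# residues ", blk_start, "-", max(blk)),
               pad(seq_ch[blk]),
               vapply(table$conditions,
                      function(cond) pad(tracks[[cond]][blk]), character(1)),
               pad(epi_row[blk]))
    }
  }
  out
}
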