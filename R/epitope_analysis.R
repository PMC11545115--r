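# Linear IgE-binding epitope analysis: intactness (coverage by detected
# peptides) per condition and change labels relative to the control.

EPITOPE_CHANGES <- c("retained", "reduced", "lost", "gained", "not_detected")

.epitope_fields <- function(epitope) {
  if (is.data.frame(epitope)) {
    if (nrow(epitope) != 1L) stop("expected a single epitope row")
    epitope <- as.list(epitope)
  }
  if (is.null(epitope$accession) || is.null(epitope$start) ||
      is.null(epitope$end))
    stop("epitope needs accession, start and end")
  epitope
}

#' Epitope intactness and covering peptides in one condition
#'
#' An epitope is intact when every one of its residues lies inside at least
#' one peptide detected in the condition — the union of detected peptides,
#' not necessarily a single peptide, may cover it. Covering peptides are all
#' detected peptides overlapping the epitope by at least one residue.
#'
#' @param epitope One epitope (one-row registry data.frame or list with
#'   `accession`, `start`, `end`).
#' @param table A [quant_table()].
#' @param condition Condition name.
#' @param require_single_peptide If `TRUE`, intactness additionally requires
#'   a single detected peptide spanning the whole epitope (the stricter
#'   reading).
#' @return list with `intact` (logical) and `covering` (data.frame of
#'   overlapping detected peptides).
#' @export
epitope_coverage <- function(epitope, table, condition,
                             require_single_peptide = FALSE) {
  stopifnot(inherits(table, "quant_table"))
  e <- .epitope_fields(epitope)
  if (!e$accession %in% table$observations$accession &&
      !e$accession %in% unique(table$observations$accession))
    stop("epitope accession '", e$accession, "' absent from the table")
  det <- .detected_obs(table, e$accession, condition)
  covering <- det[det$start <= e$end & det$end >= e$start, , drop = FALSE]
  rownames(covering) <- NULL
  if (nrow(covering)) {
    covered <- unique(unlist(Map(seq.int, covering$start, covering$end)))
    intact <- all(seq.int(e$start, e$end) %in% covered)
    if (require_single_peptide)
      intact <- any(covering$start <= e$start & covering$end >= e$end)
  } else {
    intact <- FALSE
  }
  list(intact = intact, covering = covering)
}

#' Label how an epitope changed between control and a treated condition
#'
#' Labels: `lost` (intact in the control, not in the treated sample),
#' `gained` (the reverse), `reduced` (covered in both, but every covering
#' peptide was decreased or control-only, or the treated covering set is a
#' strict subset of the control's), `retained` (intact in both without the
#' reduction pattern), `not_detected` (intact in neither and no reduction
#' pattern). The abundance route and the detection route into `reduced` are
#' both explicit.
#'
#' @param epitope One epitope.
#' @param control_status,treated_status [epitope_coverage()] results for the
#'   control and the treated condition.
#' @param differentials `differential_records` for the same accession and
#'   treated condition.
#' @return One of `r paste(EPITOPE_CHANGES, collapse = ", ")`.
#' @export
epitope_change <- function(epitope, control_status, treated_status,
                           differentials) {
  icc <- isTRUE(control_status$intact)
  ict <- isTRUE(treated_status$intact)
  if (icc && !ict) return("lost")
  if (!icc && ict) return("gained")
  keyify <- function(df) if (nrow(df)) paste(df$start, df$end) else character(0)
  cov_c <- keyify(control_status$covering)
  cov_t <- keyify(treated_status$covering)
  all_keys <- union(cov_c, cov_t)
  d <- differentials
  cats <- d$category[match(all_keys, paste(d$start, d$end))]
  cats <- cats[!is.na(cats)]
  reduced_rule <-
    (length(cats) > 0L && all(cats %in% c("decreased", "only_in_control"))) ||
    (length(cov_c) > 0L && all(cov_t %in% cov_c) &&
       length(cov_t) < length(cov_c))
  if (icc && ict) return(if (reduced_rule) "reduced" else "retained")
  # intact in neither condition
  if (length(cov_c) && length(cov_t) && reduced_rule) return("reduced")
  "not_detected"
}

#' Epitope status report across treated conditions
#'
#' One row per epitope and treated condition: intact flags for the control
#' and the treated sample, the change label, and covering-peptide counts.
#' Epitopes whose registry validation flags failed (span/length mismatch,
#' non-canonical letters, parent mismatch) carry `flag_warning = TRUE`;
#' their stated coordinates are still used as printed.
#'
#' @param registry An `epitope_registry` (or compatible data.frame).
#' @param table A [quant_table()].
#' @param control Control condition (defaults to the table's control).
#' @param treated Treated condition name(s).
#' @param params A [diff_params()].
#' @param require_single_peptide Passed to [epitope_coverage()].
#' @param path Optional TSV output path (header-only when the registry is
#'   empty).
#' @return data.frame: `accession`, `label`, `start`, `end`, `condition`,
#'   `intact_control`, `intact_treated`, `change`, `n_covering_control`,
#'   `n_covering_treated`, `flag_warning`.
#' @export
epitope_report <- function(registry, table, control = table$control,
                           treated, params = diff_params(),
                           require_single_peptide = FALSE, path = NULL) {
  stopifnot(inherits(table, "quant_table"))
  if (!identical(control, table$control))
    stop("control must match the table's control condition")
  empty <- data.frame(accession = character(0), label = character(0),
                      start = integer(0), end = integer(0),
                      condition = character(0), intact_control = logical(0),
                      intact_treated = logical(0), change = character(0),
                      n_covering_control = integer(0),
                      n_covering_treated = integer(0),
                      flag_warning = logical(0), stringsAsFactors = FALSE)
  accs <- unique(table$observations$accession)
  usable <- registry[registry$accession %in% accs, , drop = FALSE]
  skipped <- nrow(registry) - nrow(usable)
  if (skipped > 0L)
    message(skipped, " epitope(s) skipped: accession not in the quant table")
  rows <- list()
  diffs <- lapply(stats::setNames(treated, treated), function(cond)
    compute_ra(table, cond, params))
  for (i in seq_len(nrow(usable))) {
    e <- usable[i, , drop = FALSE]
    flag <- (!is.null(e$length_consistent) && !isTRUE(e$length_consistent)) ||
      (!is.null(e$letters_canonical) && !isTRUE(e$letters_canonical)) ||
      (!is.null(e$parent_match) && isFALSE(e$parent_match))
    cs <- epitope_coverage(e, table, control, require_single_peptide)
    for (cond in treated) {
      ts <- epitope_coverage(e, table, cond, require_single_peptide)
      d <- diffs[[cond]]
      d <- d[d$accession == e$accession, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        accession = e$accession, label = e$label, start = e$start,
        end = e$end, condition = cond, intact_control = cs$intact,
        intact_treated = ts$intact,
        change = epitope_change(e, cs, ts, d),
        n_covering_control = nrow(cs$covering),
        n_covering_treated = nrow(ts$covering),
        flag_warning = flag, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
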