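# Relative-abundance (RA) computation against the control condition,
# category assignment, and coverage / peptide-count summaries.

#' Differential-classification parameters
#'
#' A peptide is called significantly increased when its relative abundance
#' (treated / control) exceeds `ra_increase_threshold` and significantly
#' decreased below `ra_decrease_threshold`; both comparisons are strict, so
#' the boundary values themselves fall in the unchanged band (the
#' conservative reading of strict-inequality significance rules).
#'
#' @param ra_increase_threshold Ratio above which a peptide is `increased`
#'   (default 2.0).
#' @param ra_decrease_threshold Ratio below which a peptide is `decreased`
#'   (default 0.5).
#' @return A `diff_params` list.
#' @export
diff_params <- function(ra_increase_threshold = 2.0,
                        ra_decrease_threshold = 0.5) {
  if (!(ra_decrease_threshold > 0 && ra_decrease_threshold < 1 &&
        ra_increase_threshold > 1))
    stop("need 0 < ra_decrease_threshold < 1 < ra_increase_threshold")
  structure(list(increase = ra_increase_threshold,
                 decrease = ra_decrease_threshold),
            class = "diff_params")
}

RA_CATEGORIES <- c("increased", "decreased", "unchanged",
                   "only_in_control", "only_in_treated")

#' Classify defined RA values
#'
#' @param ra Numeric vector of relative abundances (treated / control).
#' @param params A [diff_params()].
#' @return Character vector in `increased` / `decreased` / `unchanged`.
#' @examples
#' classify_ra(c(0.49, 0.5, 1, 2, 2.01, 3.8, 11.5))
#' @export
classify_ra <- function(ra, params = diff_params()) {
  if (any(!is.na(ra) & ra <= 0)) stop("RA must be positive")
  ifelse(ra > params$increase, "increased",
         ifelse(ra < params$decrease, "decreased", "unchanged"))
}

#' Compute relative abundances against the control
#'
#' For every peptide detected in at least one of the control and the treated
#' condition: detected in both gives `ra = treated / control` and a
#' threshold category; detected in the control only gives category
#' `only_in_control`; detected in the treated sample only gives
#' `only_in_treated`. One-sided detections keep an undefined (`NA`) RA —
#' no pseudo-count is ever introduced. Peptides abundant in the control are
#' thereby referenced at a level of 1.
#'
#' @param table A [quant_table()].
#' @param treated Treated condition name (must differ from the control).
#' @param params A [diff_params()].
#' @return A `differential_records` data.frame: `accession`, `start`, `end`,
#'   `sequence`, `condition`, `control_intensity`, `treated_intensity`,
#'   `ra`, `category`.
#' @export
compute_ra <- function(table, treated, params = diff_params()) {
  stopifnot(inherits(table, "quant_table"))
  control <- table$control
  if (identical(treated, control))
    stop("configuration error: treated condition equals the control ('",
         control, "')")
  if (!treated %in% table$conditions)
    stop("unknown treated condition: ", treated)
  obs <- table$observations
  ci <- obs[[control]]
  ti <- obs[[treated]]
  keep <- !is.na(ci) | !is.na(ti)
  out <- obs[keep, c("accession", "start", "end", "sequence"), drop = FALSE]
  ci <- ci[keep]
  ti <- ti[keep]
  out$condition <- rep(treated, nrow(out))
  out$control_intensity <- ci
  out$treated_intensity <- ti
  out$ra <- ifelse(!is.na(ci) & !is.na(ti), ti / ci, NA_real_)
  out$category <- ifelse(is.na(ci), "only_in_treated",
                         ifelse(is.na(ti), "only_in_control",
                                classify_ra(out$ra, params)))
  rownames(out) <- NULL
  class(out) <- c("differential_records", "data.frame")
  out
}

.detected_obs <- function(table, accession, condition) {
  obs <- table$observations
  obs[obs$accession == accession & !is.na(obs[[condition]]), , drop = FALSE]
}

#' Residue positions covered by detected peptides
#'
#' @param table A `quant_table`.
#' @param accession Protein accession.
#' @param condition Condition name.
#' @return Sorted integer vector of covered 1-based positions.
#' @export
covered_positions <- function(table, accession, condition) {
  det <- .detected_obs(table, accession, condition)
  if (!nrow(det)) return(integer(0))
  sort(unique(unlist(Map(seq.int, det$start, det$end))))
}

#' Per-protein sequence coverage and peptide count
#'
#' Coverage is the percentage of protein residues lying in at least one
#' peptide detected in the given condition; it is invariant to peptide
#' ordering and to duplicated intervals, and is not rounded here.
#'
#' @param table A `quant_table`.
#' @param proteins A `protein_set` covering all accessions in the table.
#' @param condition Condition name.
#' @return data.frame: `accession`, `condition`, `protein_length`,
#'   `coverage_percent` (exact), `peptide_count`.
#' @export
peptide_coverage <- function(table, proteins, condition) {
  stopifnot(inherits(table, "quant_table"))
  proteins <- as_protein_set(proteins)
  if (!condition %in% table$conditions)
    stop("unknown condition: ", condition)
  accs <- unique(table$observations$accession)
  missing_acc <- setdiff(accs, proteins$accession)
  if (length(missing_acc))
    stop("accession(s) absent from the protein set: ",
         paste(missing_acc, collapse = ", "))
  rows <- lapply(accs, function(a) {
    len <- nchar(proteins$sequence[match(a, proteins$accession)])
    det <- .detected_obs(table, a, condition)
    covered <- covered_positions(table, a, condition)
    data.frame(accession = a, condition = condition, protein_length = len,
               coverage_percent = 100 * length(covered) / len,
               peptide_count = nrow(det), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# round half away from zero (presentation rounding for coverage percents)
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Coverage / peptide-count summary across conditions
#'
#' One row per protein and condition with the integer-rounded coverage
#' percent (half away from zero) and the detected peptide count — the usual
#' per-allergen summary table of a label-free peptide-mapping experiment.
#'
#' @param table A `quant_table`.
#' @param proteins A `protein_set`.
#' @param conditions Conditions to summarise (default: all in the table).
#' @param path Optional TSV output path.
#' @return data.frame: `accession`, `condition`, `coverage_percent`
#'   (integer), `peptides`.
#' @export
coverage_summary <- function(table, proteins, conditions = table$conditions,
                             path = NULL) {
  rows <- lapply(conditions, function(cond) {
    cv <- peptide_coverage(table, proteins, cond)
    data.frame(accession = cv$accession, condition = cond,
               coverage_percent = as.integer(.round_half_up(
                 cv$coverage_percent)),
               peptides = cv$peptide_count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$accession, match(out$condition, conditions)), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
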