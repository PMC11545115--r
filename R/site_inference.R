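# Cleavage-site accessibility inference: which trypsin sites were exposed or
# masked by the treatment, argued from differential peptide evidence.
#
# A peptide whose N-terminus immediately follows a site, or whose C-terminus
# is a site, testifies about that site. A peptide that appears or increases
# after treatment suggests the flanking site became easier to cleave
# (exposed); one that disappears or decreases suggests it became harder
# (masked). Votes are summed per site with a declared tie rule, turning the
# narrative per-peptide argument into a reproducible call.

SITE_VOTE <- c(increased = 1L, only_in_treated = 1L,
               decreased = -1L, only_in_control = -1L, unchanged = 0L)

#' Collect per-site differential evidence
#'
#' Each fully tryptic peptide contributes one evidence item per flanking
#' cleavage site: an N-side item for the site at `start - 1` and a C-side
#' item for the site at `end`. Termini that coincide with the protein's own
#' termini carry no site information, and peptides with ragged (non-tryptic)
#' termini are excluded entirely — under trypsin assumptions they say
#' nothing about site accessibility.
#'
#' @param differentials A `differential_records` data.frame (one accession,
#'   one treated condition) from [compute_ra()].
#' @param sites Cleavage sites from [find_cleavage_sites()].
#' @param protein_length Parent protein length.
#' @return data.frame: `position`, `residue`, `peptide_start`,
#'   `peptide_end`, `terminus` ("N"/"C"), `condition`, `category`, `vote`.
#' @export
collect_site_evidence <- function(differentials, sites, protein_length) {
  empty <- data.frame(position = integer(0), residue = character(0),
                      peptide_start = integer(0), peptide_end = integer(0),
                      terminus = character(0), condition = character(0),
                      category = character(0), vote = integer(0),
                      stringsAsFactors = FALSE)
  d <- differentials
  if (is.null(d) || !nrow(d)) return(empty)
  ft <- is_fully_tryptic(d$start, d$end, sites$position, protein_length)
  d <- d[ft, , drop = FALSE]
  if (!nrow(d)) return(empty)
  mk <- function(pos, dsub, terminus) {
    data.frame(position = pos,
               residue = sites$residue[match(pos, sites$position)],
               peptide_start = dsub$start, peptide_end = dsub$end,
               terminus = rep(terminus, nrow(dsub)),
               condition = dsub$condition,
               category = dsub$category,
               vote = unname(SITE_VOTE[dsub$category]),
               stringsAsFactors = FALSE)
  }
  n_sel <- d$start > 1L & (d$start - 1L) %in% sites$position
  c_sel <- d$end < protein_length & d$end %in% sites$position
  out <- rbind(mk(d$start[n_sel] - 1L, d[n_sel, , drop = FALSE], "N"),
               mk(d$end[c_sel], d[c_sel, , drop = FALSE], "C"))
  out <- out[order(out$position, out$peptide_start, out$peptide_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call site states from collected evidence
#'
#' Per site and treated condition the votes are summed: a positive score
#' calls the site `exposed`, a negative score `masked`. A zero score with
#' evidence items that all vote 0 is `unchanged`; a zero score mixing +1 and
#' -1 votes is `ambiguous` (the declared tie rule). Sites with no evidence
#' at all — e.g. flanked only by peptides below the detection window — are
#' reported as `no_evidence` rather than dropped.
#'
#' @param evidence Output of [collect_site_evidence()].
#' @param sites The full site list (used to report evidence-free sites).
#' @param treated Treated condition name(s); defaults to the conditions
#'   present in `evidence`.
#' @return data.frame: `position`, `residue`, `condition`, `score`,
#'   `n_evidence`, `state`.
#' @export
infer_sites <- function(evidence, sites, treated = NULL) {
  if (is.null(treated)) treated <- unique(evidence$condition)
  if (!length(treated))
    stop("no treated condition given and none present in the evidence")
  rows <- list()
  for (cond in treated) {
    ev <- evidence[evidence$condition == cond, , drop = FALSE]
    for (i in seq_len(nrow(sites))) {
      p <- sites$position[i]
      sub <- ev[ev$position == p, , drop = FALSE]
      n <- nrow(sub)
      score <- if (n) sum(sub$vote) else 0L
      state <- if (n == 0L) "no_evidence"
               else if (score > 0L) "exposed"
               else if (score < 0L) "masked"
               else if (any(sub$vote > 0L) && any(sub$vote < 0L)) "ambiguous"
               else "unchanged"
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, residue = sites$residue[i], condition = cond,
        score = as.integer(score), n_evidence = n, state = state,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), residue = character(0),
               condition = character(0), score = integer(0),
               n_evidence = integer(0), state = character(0))
  rownames(out) <- NULL
  class(out) <- c("site_calls", "data.frame")
  out
}

#' Write a site-call report
#'
#' One row per site and treated condition with the residue label in the
#' usual notation (e.g. `R93`), the vote score, the called state and the
#' number of evidence items.
#'
#' @param calls Output of [infer_sites()] (an `accession` column, if
#'   present, is carried through).
#' @param path Optional TSV output path (header-only when `calls` is empty).
#' @return The report data.frame, invisibly when written to `path`.
#' @export
site_report <- function(calls, path = NULL) {
  out <- data.frame(site = if (nrow(calls))
    paste0(calls$residue, calls$position) else character(0),
    stringsAsFactors = FALSE)
  if (!is.null(calls$accession)) out$accession <- calls$accession
  out$condition <- calls$condition
  out$score <- calls$score
  out$state <- calls$state
  out$n_evidence <- calls$n_evidence
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
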