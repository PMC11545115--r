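# In-silico trypsin digestion: cleavage-site enumeration, fully tryptic
# peptide generation with missed cleavages, and the detection-length filter.

#' Digestion parameters
#'
#' Trypsin cleaves C-terminal of lysine (K) and arginine (R); with
#' `proline_rule = TRUE` (the Keil rule, the common search-engine default)
#' cleavage is suppressed when the next residue is proline. The
#' detection-length window defaults to 5-45 residues, the typical span of
#' peptides identifiable in a label-free LC-MS/MS experiment.
#'
#' @param enzyme Cleavage rule name; only `"trypsin"` is implemented.
#' @param proline_rule Suppress cleavage before proline?
#' @param max_missed_cleavages Maximum number of internal cleavage sites a
#'   peptide may retain (default 2, a common label-free search setting).
#' @param min_len,max_len Inclusive detection-length window in residues.
#' @return A `digest_params` list.
#' @export
digest_params <- function(enzyme = "trypsin", proline_rule = TRUE,
                          max_missed_cleavages = 2L,
                          min_len = 5L, max_len = 45L) {
  enzyme <- match.arg(enzyme, "trypsin")
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (max_missed_cleavages < 0L) stop("max_missed_cleavages must be >= 0")
  if (min_len < 1L) stop("min_len must be >= 1")
  if (max_len < min_len) stop("max_len must be >= min_len")
  structure(list(enzyme = enzyme, proline_rule = isTRUE(proline_rule),
                 max_missed_cleavages = max_missed_cleavages,
                 min_len = min_len, max_len = max_len),
            class = "digest_params")
}

#' Enumerate tryptic cleavage sites
#'
#' A site is the 1-based position of a K or R residue after which trypsin
#' cleaves. The C-terminal residue is never a site (there is nothing to
#' cleave after it), `X` never matches, and with the proline rule active a
#' K/R followed by P is skipped.
#'
#' @param protein A protein record or plain sequence string.
#' @param params A [digest_params()] object.
#' @return data.frame with columns `accession`, `position`, `residue`,
#'   ordered by position.
#' @examples
#' find_cleavage_sites("MAKRPQK")  # site at 3 only (R4 blocked by P5)
#' @export
find_cleavage_sites <- function(protein, params = digest_params()) {
  s <- .get_sequence(protein)
  acc <- .get_accession(protein)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  pos <- which(ch %in% c("K", "R"))
  pos <- pos[pos < n]
  if (params$proline_rule && length(pos))
    pos <- pos[ch[pos + 1L] != "P"]
  data.frame(accession = rep(acc, length(pos)), position = as.integer(pos),
             residue = ch[pos], stringsAsFactors = FALSE)
}

#' Generate fully tryptic peptides
#'
#' Enumerates every peptide whose N-terminus is the protein start or the
#' residue after a cleavage site and whose C-terminus is a cleavage site or
#' the protein end, with at most `max_missed_cleavages` internal sites, then
#' applies the detection-length window. Only fully tryptic peptides are
#' produced; semi-tryptic peptides are out of scope.
#'
#' @inheritParams find_cleavage_sites
#' @return data.frame with columns `accession`, `start`, `end`, `sequence`,
#'   `missed_cleavages`, sorted by (start, end), without duplicates.
#' @export
digest <- function(protein, params = digest_params()) {
  s <- .get_sequence(protein)
  acc <- .get_accession(protein)
  n <- nchar(s)
  sites <- find_cleavage_sites(protein, params)$position
  b <- c(0L, sites, n)
  nf <- length(b) - 1L
  starts <- ends <- missed <- integer(0)
  for (i in seq_len(nf)) {
    jmax <- min(i + params$max_missed_cleavages, nf)
    for (j in i:jmax) {
      len <- b[j + 1L] - b[i]
      if (len >= params$min_len && len <= params$max_len) {
        starts <- c(starts, b[i] + 1L)
        ends <- c(ends, b[j + 1L])
        missed <- c(missed, j - i)
      }
    }
  }
  out <- data.frame(accession = rep(acc, length(starts)),
                    start = starts, end = ends,
                    sequence = if (length(starts)) substring(s, starts, ends)
                               else character(0),
                    missed_cleavages = missed, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test whether an interval has fully tryptic termini
#'
#' TRUE iff the start is the protein N-terminus or immediately follows a
#' cleavage site, and the end is the protein C-terminus or is itself a
#' cleavage site. Vectorised over `start`/`end`.
#'
#' @param start,end 1-based inclusive peptide interval(s).
#' @param site_positions Integer vector of cleavage-site positions.
#' @param protein_length Parent protein length.
#' @return Logical vector.
#' @export
is_fully_tryptic <- function(start, end, site_positions, protein_length) {
  if (any(start < 1L) || any(end < start) || any(end > protein_length))
    stop("interval out of range")
  n_ok <- start == 1L | (start - 1L) %in% site_positions
  c_ok <- end == protein_length | end %in% site_positions
  n_ok & c_ok
}

#' @export
print.digest_params <- function(x, ...) {
  cat(sprintf(
    "%s digestion: proline rule %s, <=%d missed cleavages, window [%d, %d] aa\n",
    x$enzyme, if (x$proline_rule) "on" else "off",
    x$max_missed_cleavages, x$min_len, x$max_len))
  invisible(x)
}
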