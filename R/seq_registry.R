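# Protein and epitope bookkeeping: FASTA I/O, 1-based inclusive coordinates,
# and the packaged registry of published linear IgE-binding epitopes.

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
# X is tolerated in sequences but never matches a cleavage residue.
AA_ALLOWED <- c(AA_CANONICAL, "X")

#' Construct a protein record
#'
#' A protein set is a plain `data.frame` with columns `accession`, `name`
#' and `sequence`. All coordinates used throughout the package are 1-based
#' and inclusive, matching the residue notation used for allergen epitopes
#' (e.g. residues 294-303 of Ara h 1).
#'
#' @param accession Unique identifier (e.g. a UniProt accession).
#' @param sequence Amino-acid sequence; uppercased on construction. Only the
#'   20 canonical residues plus `X` are accepted.
#' @param name Optional free-text description.
#' @return A one-row `protein_set` data.frame.
#' @examples
#' protein_record("P1", "MKRAAA", "toy protein")
#' @export
protein_record <- function(accession, sequence, name = "") {
  as_protein_set(data.frame(accession = accession, name = name,
                            sequence = sequence, stringsAsFactors = FALSE))
}

#' Validate and class a data.frame of protein sequences
#'
#' @param df data.frame with columns `accession`, `name`, `sequence`.
#' @return The validated `protein_set`.
#' @export
as_protein_set <- function(df) {
  req <- c("accession", "name", "sequence")
  if (!all(req %in% names(df)))
    stop("protein set needs columns: ", paste(req, collapse = ", "))
  df$sequence <- toupper(df$sequence)
  if (any(nchar(df$sequence) < 1L))
    stop("empty sequence for record(s): ",
         paste(df$accession[nchar(df$sequence) < 1L], collapse = ", "))
  bad <- vapply(strsplit(df$sequence, ""), function(ch)
    any(!ch %in% AA_ALLOWED), logical(1))
  if (any(bad)) {
    letters_bad <- unique(unlist(lapply(strsplit(df$sequence[bad], ""),
                                        setdiff, y = AA_ALLOWED)))
    stop("non-canonical residue letter(s) ",
         paste(letters_bad, collapse = ", "), " in record(s): ",
         paste(df$accession[bad], collapse = ", "))
  }
  dup <- duplicated(df$accession)
  if (any(dup))
    stop("duplicate accession(s): ", paste(unique(df$accession[dup]),
                                           collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("protein_set", "data.frame")
  df
}

#' Read protein sequences from a FASTA file
#'
#' The description line is split into the accession (first whitespace token)
#' and the remaining free-text name. Sequences are uppercased; letters other
#' than the 20 canonical amino acids and `X` are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A `protein_set` data.frame (accession, name, sequence).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e)))
  if (length(aa) == 0L) stop("malformed FASTA '", path, "': no records")
  desc <- names(aa)
  accession <- sub("\\s.*$", "", desc)
  name <- ifelse(grepl("\\s", desc), sub("^\\S+\\s+", "", desc), "")
  seqs <- as.character(aa)
  empty <- nchar(seqs) == 0L
  if (any(empty))
    stop("malformed FASTA '", path, "': empty sequence for record ",
         paste(accession[empty], collapse = ", "))
  as_protein_set(data.frame(accession = accession, name = name,
                            sequence = seqs, stringsAsFactors = FALSE))
}

#' Write a protein set to FASTA
#'
#' Round-trips losslessly with [read_fasta()] for accession and sequence.
#'
#' @param proteins A `protein_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  proteins <- as_protein_set(proteins)
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- ifelse(nchar(proteins$name) > 0L,
                      paste(proteins$accession, proteins$name),
                      proteins$accession)
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

# Accept a one-row protein_set, a list with $sequence, or a bare string.
.get_sequence <- function(protein) {
  if (is.character(protein) && length(protein) == 1L) return(toupper(protein))
  if (is.data.frame(protein)) {
    if (nrow(protein) != 1L) stop("expected a single protein record")
    return(protein$sequence)
  }
  if (is.list(protein) && !is.null(protein$sequence)) return(protein$sequence)
  stop("cannot extract a sequence from the given object")
}

.get_accession <- function(protein) {
  if (is.data.frame(protein) || (is.list(protein) &&
                                 !is.null(protein$accession)))
    return(as.character(protein$accession)[1])
  NA_character_
}

#' Extract a subsequence by 1-based inclusive coordinates
#'
#' @param protein A one-row `protein_set`, a list with a `sequence` element,
#'   or a plain sequence string.
#' @param start,end 1-based inclusive residue positions.
#' @return The residues `start..end` as a string.
#' @examples
#' subsequence("MKR", 2, 3)  # "KR"
#' @export
subsequence <- function(protein, start, end) {
  s <- .get_sequence(protein)
  n <- nchar(s)
  if (any(start < 1L) || any(end > n) || any(start > end))
    stop("subsequence bounds out of range: [", start, ", ", end,
         "] on a sequence of length ", n)
  substr(rep(s, length.out = max(length(start), length(end))), start, end)
}

#' Load a linear-epitope registry from TSV
#'
#' The registry TSV must have columns
#' `accession label start end sequence source`. Entries are kept exactly as
#' stated, with explicit validation flags rather than silent correction:
#'
#' * `length_consistent` — `end - start + 1` equals the stated sequence
#'   length;
#' * `letters_canonical` — the stated sequence uses only canonical residue
#'   letters (plus `X`);
#' * `parent_match` — when the parent protein is supplied, whether the
#'   parent subsequence at `[start, end]` equals the stated sequence
#'   (`NA` when the parent is unavailable);
#' * `suggested_start` — on a parent mismatch, the first exact-substring
#'   position of the stated sequence in the parent (`NA` if none). The
#'   stated coordinates are never rewritten.
#'
#' @param path TSV path.
#' @param proteins Optional `protein_set` used for parent-sequence
#'   validation.
#' @return An `epitope_registry` data.frame with the flag columns above.
#' @export
load_epitope_registry <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("epitope registry not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  req <- c("accession", "label", "start", "end", "sequence", "source")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("epitope registry schema error; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[req]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 1L |
                 df$end < df$start)
  if (length(bad))
    stop("invalid epitope coordinates for label(s): ",
         paste(df$label[bad], collapse = ", "))
  df$sequence <- toupper(df$sequence)
  df$length_consistent <- (df$end - df$start + 1L) == nchar(df$sequence)
  df$letters_canonical <- vapply(strsplit(df$sequence, ""), function(ch)
    all(ch %in% AA_ALLOWED), logical(1))
  df$parent_match <- NA
  df$suggested_start <- NA_integer_
  if (!is.null(proteins)) {
    proteins <- as_protein_set(proteins)
    for (i in seq_len(nrow(df))) {
      j <- match(df$accession[i], proteins$accession)
      if (is.na(j)) next
      parent <- proteins$sequence[j]
      if (df$end[i] <= nchar(parent)) {
        df$parent_match[i] <-
          substr(parent, df$start[i], df$end[i]) == df$sequence[i]
      } else {
        df$parent_match[i] <- FALSE
      }
      if (!isTRUE(df$parent_match[i])) {
        hit <- regexpr(df$sequence[i], parent, fixed = TRUE)
        if (hit > 0L) df$suggested_start[i] <- as.integer(hit)
      }
    }
  }
  rownames(df) <- NULL
  class(df) <- c("epitope_registry", "data.frame")
  df
}

#' Packaged registry of published linear IgE-binding epitopes
#'
#' Loads the epitope registry shipped with the package: reported linear
#' IgE-binding epitopes of the major peanut allergens Ara h 1 (P43238),
#' Ara h 2 (Q6PSU2), Ara h 3 (O82580) and Ara h 6 (Q647G9). Entries are
#' shipped exactly as printed in the literature; one Ara h 3 entry has a
#' 15-residue sequence over a 16-position span and one Ara h 1 entry
#' contains the non-standard letter `O` — both are carried with their
#' validation flags raised rather than corrected.
#'
#' @inheritParams load_epitope_registry
#' @return An `epitope_registry` data.frame.
#' @export
packaged_epitope_registry <- function(proteins = NULL) {
  path <- system.file("extdata", "ige_epitopes.tsv", package = "pepshift")
  if (!nzchar(path)) stop("packaged epitope registry missing")
  load_epitope_registry(path, proteins)
}

#' @export
print.epitope_registry <- function(x, ...) {
  cat("Linear epitope registry:", nrow(x), "epitope(s),",
      length(unique(x$accession)), "protein(s)\n")
  n_flag <- sum(!x$length_consistent | !x$letters_canonical |
                  (!is.na(x$parent_match) & !x$parent_match))
  if (n_flag) cat("  validation flags raised on", n_flag, "entr",
                  if (n_flag == 1) "y" else "ies", "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
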