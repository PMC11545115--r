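# Label-free peptide quantification tables: reading, validation, the
# detection-length filter and coordinate/sequence reconciliation.

#' Construct a quantification table
#'
#' A `quant_table` holds one row per identified peptide with one intensity
#' column per condition. An empty cell (`NA`) means "not detected"; an
#' explicit 0 is coerced to not-detected as well, so ratios are never taken
#' against zero. Rows undetected in every condition are dropped with a
#' warning.
#'
#' @param observations data.frame with columns `accession`, `start`, `end`,
#'   `sequence` plus one numeric column per condition.
#' @param conditions Ordered condition names (column names in
#'   `observations`).
#' @param control The control condition name (e.g. `"NPP"`).
#' @return A `quant_table` object (list with `observations`, `conditions`,
#'   `control`).
#' @export
quant_table <- function(observations, conditions, control) {
  req <- c("accession", "start", "end", "sequence")
  if (!all(req %in% names(observations)))
    stop("observations need columns: ", paste(req, collapse = ", "))
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions))
    stop("condition names must be unique")
  if (!control %in% conditions)
    stop("control condition '", control, "' not among conditions")
  missing_cols <- setdiff(conditions, names(observations))
  if (length(missing_cols))
    stop("missing intensity column(s): ", paste(missing_cols, collapse = ", "))
  observations$start <- as.integer(observations$start)
  observations$end <- as.integer(observations$end)
  key <- paste(observations$accession, observations$start, observations$end)
  if (anyDuplicated(key))
    stop("duplicate (accession, start, end) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  ints <- as.matrix(observations[conditions])
  storage.mode(ints) <- "double"
  if (any(ints < 0, na.rm = TRUE))
    stop("negative intensity values are invalid")
  ints[!is.na(ints) & ints == 0] <- NA_real_
  observations[conditions] <- as.data.frame(ints)
  all_na <- rowSums(!is.na(ints)) == 0L
  if (any(all_na)) {
    warning(sum(all_na), " observation(s) with no detected intensity dropped")
    observations <- observations[!all_na, , drop = FALSE]
  }
  observations <- observations[c(req, conditions)]
  rownames(observations) <- NULL
  structure(list(observations = observations, conditions = conditions,
                 control = control), class = "quant_table")
}

#' Read a peptide quantification TSV
#'
#' The wide dialect has header
#' `accession start end sequence <cond1> <cond2> ...` with empty cells for
#' not-detected peptides. Replicate columns sharing a condition prefix
#' (`NPP_1`, `NPP_2`, ...) are averaged (mean over detected replicates)
#' before analysis. The long dialect has columns
#' `accession start end sequence condition intensity` and is pivoted on
#' read.
#'
#' @param path TSV path.
#' @param control Control condition name; an error is raised if absent.
#' @param format `"wide"` (default) or `"long"`.
#' @return A [quant_table()].
#' @export
read_quant_table <- function(path, control, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("quant table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  req <- c("accession", "start", "end", "sequence")
  missing_cols <- setdiff(if (format == "wide") req
                          else c(req, "condition", "intensity"), names(df))
  if (length(missing_cols))
    stop("quant table schema error; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (format == "long") {
    conds <- unique(df$condition)
    key <- paste(df$accession, df$start, df$end)
    wide <- df[!duplicated(key), req, drop = FALSE]
    wkey <- paste(wide$accession, wide$start, wide$end)
    for (cond in conds) {
      sub <- df[df$condition == cond, , drop = FALSE]
      wide[[cond]] <- sub$intensity[match(wkey, paste(sub$accession,
                                                      sub$start, sub$end))]
    }
    df <- wide
  }
  raw_conds <- setdiff(names(df), req)
  if (!length(raw_conds)) stop("quant table has no intensity columns")
  for (cc in raw_conds) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(!is.na(v) & v < 0)) stop("negative intensity in column '", cc, "'")
    v[!is.na(v) & v == 0] <- NA_real_
    df[[cc]] <- v
  }
  base <- sub("_[0-9]+$", "", raw_conds)
  conditions <- unique(base)
  for (cond in conditions) {
    cols <- raw_conds[base == cond]
    if (length(cols) > 1L || !identical(cols, cond)) {
      m <- as.matrix(df[cols])
      v <- rowMeans(m, na.rm = TRUE)
      v[is.nan(v)] <- NA_real_
      df[cols] <- NULL
      df[[cond]] <- v
    }
  }
  if (!control %in% conditions)
    stop("configuration error: control condition '", control,
         "' has no intensity column in ", path)
  quant_table(df[c(req, conditions)], conditions, control)
}

#' Write a quant table as wide TSV
#'
#' Not-detected cells are written empty, so read/write round-trips are
#' lossless for all populated cells.
#'
#' @param table A `quant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path) {
  stopifnot(inherits(table, "quant_table"))
  utils::write.table(table$observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the detection-length window
#'
#' Removes observations whose peptide length falls outside
#' `[min_len, max_len]` (both bounds inclusive; a 45-residue peptide is
#' retained under the default window). Idempotent.
#'
#' @param table A `quant_table`.
#' @param params A [digest_params()] carrying the window.
#' @return The filtered `quant_table`; the number of removed rows is
#'   attached as attribute `removed` and reported via `message()`.
#' @export
apply_detection_filter <- function(table, params = digest_params()) {
  stopifnot(inherits(table, "quant_table"))
  len <- nchar(table$observations$sequence)
  keep <- len >= params$min_len & len <= params$max_len
  removed <- sum(!keep)
  if (removed > 0L)
    message(removed, " observation(s) outside the [", params$min_len, ", ",
            params$max_len, "] aa detection window removed")
  table$observations <- table$observations[keep, , drop = FALSE]
  rownames(table$observations) <- NULL
  attr(table, "removed") <- removed
  table
}

#' Reconcile observation coordinates with parent sequences
#'
#' Each observation's `(start, end)` is checked against its stated peptide
#' sequence on the parent protein. Mismatching rows are re-anchored by exact
#' substring search when the stated sequence occurs exactly once in the
#' parent; rows whose sequence occurs zero or multiple times are excluded
#' and flagged. After this step every retained observation satisfies the
#' subsequence invariant.
#'
#' @param table A `quant_table`.
#' @param proteins A `protein_set` covering every accession in the table.
#' @return list with elements `table` (the reconciled `quant_table`) and
#'   `report` (data.frame of re-anchored/excluded rows with an `action`
#'   column).
#' @export
coerce_to_sequence_match <- function(table, proteins) {
  stopifnot(inherits(table, "quant_table"))
  proteins <- as_protein_set(proteins)
  obs <- table$observations
  missing_acc <- setdiff(unique(obs$accession), proteins$accession)
  if (length(missing_acc))
    stop("accession(s) absent from the protein set: ",
         paste(missing_acc, collapse = ", "))
  parent <- proteins$sequence[match(obs$accession, proteins$accession)]
  report <- list()
  keep <- rep(TRUE, nrow(obs))
  for (i in seq_len(nrow(obs))) {
    if (obs$end[i] <= nchar(parent[i]) &&
        substr(parent[i], obs$start[i], obs$end[i]) == obs$sequence[i])
      next
    hits <- gregexpr(obs$sequence[i], parent[i], fixed = TRUE)[[1]]
    n_hits <- if (hits[1] == -1L) 0L else length(hits)
    action <- if (n_hits == 1L) "reanchored"
              else if (n_hits == 0L) "excluded_no_match"
              else "excluded_ambiguous"
    report[[length(report) + 1L]] <- data.frame(
      accession = obs$accession[i], start = obs$start[i], end = obs$end[i],
      sequence = obs$sequence[i], action = action,
      new_start = if (n_hits == 1L) as.integer(hits[1]) else NA_integer_,
      stringsAsFactors = FALSE)
    if (n_hits == 1L) {
      obs$start[i] <- as.integer(hits[1])
      obs$end[i] <- as.integer(hits[1]) + nchar(obs$sequence[i]) - 1L
    } else {
      keep[i] <- FALSE
    }
  }
  obs <- obs[keep, , drop = FALSE]
  # a re-anchored row may now collide with an existing key; drop the copy
  key <- paste(obs$accession, obs$start, obs$end)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " re-anchored row(s) collided with existing ",
            "coordinates and were dropped")
    obs <- obs[!dup, , drop = FALSE]
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(accession = character(0), start = integer(0),
               end = integer(0), sequence = character(0),
               action = character(0), new_start = integer(0))
  list(table = quant_table(obs, table$conditions, table$control),
       report = report)
}

#' @export
print.quant_table <- function(x, ...) {
  cat("Peptide quant table:", nrow(x$observations), "peptides,",
      length(unique(x$observations$accession)), "protein(s)\n")
  cat("  conditions:", paste(x$conditions, collapse = ", "),
      "(control:", paste0(x$control, ")"), "\n")
  invisible(x)
}
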