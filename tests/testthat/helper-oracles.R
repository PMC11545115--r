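# Independent oracles and small fixture builders used across the suite.
# The digestion oracle deliberately shares no code with the package: it
# scans for sites with an explicit loop and enumerates every substring.

random_protein_seq <- function(len, kr_prob = 0.2) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
          "N", "P", "Q", "S", "T", "V", "W", "Y")
  ch <- ifelse(stats::runif(len) < kr_prob,
               sample(c("K", "R"), len, replace = TRUE),
               sample(aa, len, replace = TRUE))
  paste(ch, collapse = "")
}

oracle_sites <- function(seq, proline_rule = TRUE) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- integer(0)
  if (n >= 2L) for (i in 1:(n - 1L)) {
    if (ch[i] == "K" || ch[i] == "R") {
      if (proline_rule && ch[i + 1L] == "P") next
      out <- c(out, i)
    }
  }
  out
}

oracle_digest <- function(seq, max_mc, min_len, max_len,
                          proline_rule = TRUE) {
  n <- nchar(seq)
  sites <- oracle_sites(seq, proline_rule)
  rows <- list()
  for (s in 1:n) for (e in s:n) {
    len <- e - s + 1L
    if (len < min_len || len > max_len) next
    if (!(s == 1L || (s - 1L) %in% sites)) next
    if (!(e == n || e %in% sites)) next
    internal <- sum(sites >= s & sites <= e - 1L)
    if (internal > max_mc) next
    rows[[length(rows) + 1L]] <- c(s, e, internal)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      missed = integer(0)))
  m <- do.call(rbind, rows)
  out <- data.frame(start = m[, 1], end = m[, 2], missed = m[, 3])
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# quant table on a synthetic parent: `rows` is a data.frame with start, end
# and one column per condition (NA = not detected)
toy_table <- function(rows, parent, accession = "P1", control = "ctl") {
  conds <- setdiff(names(rows), c("start", "end"))
  obs <- data.frame(accession = accession, start = rows$start,
                    end = rows$end,
                    sequence = substring(parent, rows$start, rows$end),
                    stringsAsFactors = FALSE)
  for (cc in conds) obs[[cc]] <- rows[[cc]]
  quant_table(obs, conds, control)
}

toy_protein <- function(seq, accession = "P1") {
  protein_record(accession, seq, "toy")
}
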