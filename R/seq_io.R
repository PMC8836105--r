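## Sequence records, FASTA input/output, catalytic-domain trimming with
## preserved full-length numbering, and small per-proteome statistics
## (Ser/Thr counts, theoretical pI).

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a sequence record
#'
#' A lightweight container for a protein sequence that carries full-length
#' residue numbering: `offset` is the full-length position of the first stored
#' residue, so stored residue `i` sits at full-length position
#' `offset + i - 1`. This is how a trimmed catalytic domain (e.g. a PPZ domain
#' starting at residue 359) keeps reporting positions in whole-protein
#' coordinates.
#'
#' @param id Sequence identifier.
#' @param residues Uppercase amino-acid string; `X` allowed; `-` only in
#'   aligned records.
#' @param description Optional free-text description.
#' @param offset Full-length residue number of the first stored residue
#'   (integer >= 1).
#' @param aligned Logical; if `TRUE`, `-` gap characters are permitted.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, description = "", offset = 1L,
                       aligned = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 1L) stop("offset must be an integer >= 1")
  residues <- toupper(residues)
  # trailing stop codons are stripped silently; internal '*' is an error
  residues <- sub("\\*+$", "", residues)
  if (!nzchar(residues)) stop("record '", id, "': empty sequence")
  legal <- c(.aa20, "X", if (aligned) "-")
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% legal)
  if (length(bad)) {
    stop("record '", id, "': illegal character '", chars[bad[1]],
         "' at position ", bad[1])
  }
  structure(
    list(id = id, description = description, residues = residues,
         offset = offset),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  [%d residues, offset %d]\n",
              x$id, nchar(x$residues), x$offset))
  invisible(x)
}

#' Number of stored residues in a record
#' @param record A `seq_record`.
#' @return Integer length of the stored string (gaps included when aligned).
#' @export
seq_length <- function(record) nchar(record$residues)

.seq_chars <- function(record) strsplit(record$residues, "")[[1]]

#' Read a protein FASTA file
#'
#' Uses Biostrings for the FASTA parse, then applies the package's record
#' rules: residues are uppercased, trailing `*` stop characters stripped,
#' illegal characters rejected with the offending record and position named.
#' When `aligned = TRUE` all records must have equal length and may contain
#' `-` gaps.
#'
#' @param path FASTA file path.
#' @param aligned Logical; read as a fixed-width alignment.
#' @return List of `seq_record` objects in file order.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  recs <- vector("list", length(set))
  for (i in seq_along(set)) {
    recs[[i]] <- seq_record(ids[i], as.character(set[[i]]),
                            description = descs[i], aligned = aligned)
  }
  if (aligned) {
    lens <- vapply(recs, seq_length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("aligned = TRUE but record lengths differ: ",
           paste(unique(lens), collapse = ", "))
    }
  }
  recs
}

#' Write records to FASTA
#'
#' @param records List of `seq_record`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  lines <- character(0)
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    lines <- c(lines, paste0(">", hdr))
    s <- r$residues
    starts <- seq(1L, nchar(s), by = width)
    lines <- c(lines, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Trim a record to its catalytic domain
#'
#' Returns the suffix starting at `domain_start`, with `offset` set so that
#' full-length numbering is preserved (the default PPZ phosphatase domain
#' starts at residue 359 of ScPpz1).
#'
#' @param record A `seq_record` (unaligned).
#' @param domain_start Full-length position at which the domain begins.
#' @return A `seq_record` covering `domain_start..end` with
#'   `offset = domain_start`.
#' @export
trim_to_domain <- function(record, domain_start) {
  domain_start <- as.integer(domain_start)
  n <- seq_length(record)
  last <- record$offset + n - 1L
  if (domain_start < record$offset || domain_start > last) {
    stop("domain_start ", domain_start, " outside record '", record$id,
         "' (", record$offset, "..", last, ")")
  }
  i <- domain_start - record$offset + 1L
  seq_record(record$id, substr(record$residues, i, n),
             description = record$description, offset = domain_start)
}

#' Count Ser and Thr residues
#'
#' Counts are computed on uppercased residues with gaps excluded; `X` counts
#' as a non-Ser/Thr residue. `fraction` is (nSer + nThr) / length.
#'
#' @param records List of `seq_record`.
#' @return `data.frame` with columns id, n_ser, n_thr, length, fraction.
#' @export
count_ser_thr <- function(records) {
  if (length(records) == 0L) stop("no records")
  rows <- lapply(records, function(r) {
    ch <- .seq_chars(r)
    ch <- ch[ch != "-"]
    n_s <- sum(ch == "S")
    n_t <- sum(ch == "T")
    data.frame(id = r$id, n_ser = n_s, n_thr = n_t, length = length(ch),
               fraction = (n_s + n_t) / length(ch),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default pKa table for pI calculation
#'
#' Bjellqvist-style pKa values as used by common pI calculators: side chains
#' of D, E, C, Y, H, K, R plus the free termini. Swappable so alternative
#' scales can be used; exact agreement with any specific web tool is not
#' asserted.
#'
#' @return Named numeric vector of pKa values.
#' @export
pka_table <- function() {
  c(Nterm = 7.5, Cterm = 3.55,
    D = 4.05, E = 4.45, C = 9.0, Y = 10.0, H = 5.98, K = 10.0, R = 12.0)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and ionizable
#' side chains.
#'
#' @param record A `seq_record` with standard residues only.
#' @param pH pH value.
#' @param pka pKa table as from [pka_table()].
#' @return Net charge (elementary charges).
#' @export
net_charge <- function(record, pH, pka = pka_table()) {
  ch <- .seq_chars(record)
  if (any(ch %in% c("X", "-"))) {
    stop("net_charge/theoretical_pi require standard residues only")
  }
  pos_frac <- function(pk) 1 / (1 + 10^(pH - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - pH))
  q <- pos_frac(pka[["Nterm"]]) + neg_frac(pka[["Cterm"]])
  for (aa in c("K", "R", "H")) {
    n <- sum(ch == aa)
    if (n) q <- q + n * pos_frac(pka[[aa]])
  }
  for (aa in c("D", "E", "C", "Y")) {
    n <- sum(ch == aa)
    if (n) q <- q + n * neg_frac(pka[[aa]])
  }
  q
}

#' Theoretical isoelectric point
#'
#' The pH at which [net_charge()] is zero, found by bisection on `[0, 14]` to
#' a tolerance of 1e-4.
#'
#' @inheritParams net_charge
#' @return The pI (numeric).
#' @export
theoretical_pi <- function(record, pka = pka_table()) {
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH, positive at 0, negative at 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(record, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Read a group/clade labels sidecar table
#'
#' Tab-separated with columns `seq_id`, `group`, `clade`. `group` must be
#' `PP1` or `PPZ`.
#'
#' @param path TSV path.
#' @return `data.frame` with those three character columns.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("seq_id", "group", "clade")
  if (!all(need %in% names(df))) {
    stop("labels table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$group), c("PP1", "PPZ"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df[need]
}
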