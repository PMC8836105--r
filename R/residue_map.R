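## Coordinate transfer between alignment columns, pairwise alignments and
## full-length residue numbering, plus short-motif scanning. This is the
## machinery behind statements like "PP1 K210/K259 correspond to PPZ
## D566/D615": a global alignment of the two references carries a position
## from one numbering into the other.

#' Global pairwise alignment of two protein records
#'
#' Needleman-Wunsch with affine gaps, backed by
#' [Biostrings::pairwiseAlignment()] (defaults BLOSUM62, gap open 10, gap
#' extend 0.5). Offsets of both records are carried along so that
#' [transfer_position()] speaks full-length coordinates.
#'
#' @param a,b `seq_record`s (unaligned, standard residues).
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @return Object of class `pairwise_alignment` with fields `id_a`, `id_b`,
#'   `aligned_a`, `aligned_b`, `score`, `params`, `offset_a`, `offset_b`.
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  for (r in list(a, b)) {
    if (grepl("[X-]", r$residues)) {
      stop("global_align requires standard residues (record '", r$id, "')")
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  structure(list(
    id_a = a$id, id_b = b$id,
    aligned_a = as.character(Biostrings::alignedPattern(pa)),
    aligned_b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa),
    params = list(substitution_matrix = substitution_matrix,
                  gap_open = gap_open, gap_extend = gap_extend),
    offset_a = a$offset, offset_b = b$offset),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s  score %.1f (%s %g/%g)\n",
              x$id_a, x$id_b, x$score, x$params$substitution_matrix,
              x$params$gap_open, x$params$gap_extend))
  invisible(x)
}

#' Transfer a full-length position across a pairwise alignment
#'
#' Returns the full-length residue number in B occupying the same alignment
#' column as position `pos_in_a` of A, or `NA` (the gap signal) when B has a
#' gap there.
#'
#' @param pa A `pairwise_alignment`.
#' @param pos_in_a Full-length (offset-aware) position in sequence A.
#' @return Full-length integer position in B, or `NA_integer_`.
#' @export
transfer_position <- function(pa, pos_in_a) {
  ca <- strsplit(pa$aligned_a, "")[[1]]
  cb <- strsplit(pa$aligned_b, "")[[1]]
  target <- pos_in_a - pa$offset_a + 1L
  na <- sum(ca != "-")
  if (target < 1L || target > na) {
    stop("position ", pos_in_a, " outside sequence ", pa$id_a)
  }
  count <- 0L
  for (k in seq_along(ca)) {
    if (ca[k] != "-") {
      count <- count + 1L
      if (count == target) {
        if (cb[k] == "-") return(NA_integer_)
        return(pa$offset_b + sum(cb[seq_len(k)] != "-") - 1L)
      }
    }
  }
  stop("internal error: position not reached")  # nocov
}

#' Alignment column to full-length residue number
#'
#' Offset-aware count of non-gap characters of `seq_id` up to `column`;
#' returns `NA` when that sequence has a gap in the column.
#'
#' @param ags An `aligned_group_set`.
#' @param column Column index (1..ncol).
#' @param seq_id Sequence identifier.
#' @return Full-length integer position or `NA_integer_`.
#' @export
column_to_residue <- function(ags, column, seq_id) {
  column <- as.integer(column)
  if (column < 1L || column > ags$ncol) stop("column outside alignment")
  ids <- vapply(ags$records, function(r) r$id, character(1))
  i <- match(seq_id, ids)
  if (is.na(i)) stop("unknown seq_id: ", seq_id)
  ch <- .seq_chars(ags$records[[i]])
  if (ch[column] == "-") return(NA_integer_)
  ags$records[[i]]$offset + sum(ch[seq_len(column)] != "-") - 1L
}

#' Full-length residue number to alignment column (inverse of
#' [column_to_residue()])
#'
#' @param ags An `aligned_group_set`.
#' @param seq_id Sequence identifier.
#' @param pos Full-length residue number.
#' @return Column index.
#' @export
residue_to_column <- function(ags, seq_id, pos) {
  ids <- vapply(ags$records, function(r) r$id, character(1))
  i <- match(seq_id, ids)
  if (is.na(i)) stop("unknown seq_id: ", seq_id)
  rec <- ags$records[[i]]
  ch <- .seq_chars(rec)
  target <- pos - rec$offset + 1L
  nongap <- cumsum(ch != "-")
  if (target < 1L || target > nongap[length(nongap)]) {
    stop("position ", pos, " outside sequence ", seq_id)
  }
  which(nongap == target & ch != "-")[1]
}

#' Scan a sequence for a short motif
#'
#' The pattern grammar is the usual motif shorthand: residue letters,
#' `x` for any standard residue, and single-position character classes like
#' `[KR]`. Matches may overlap; positions are reported 1-based in full-length
#' coordinates (offset-aware). `x` never matches a gap or `X`.
#'
#' @param record A `seq_record`.
#' @param pattern Motif expression, e.g. `"[KR]VxF"`.
#' @return `data.frame`: start, end, match (full-length coordinates).
#' @export
scan_motif <- function(record, pattern) {
  toks <- list()
  i <- 1L; n <- nchar(pattern)
  while (i <= n) {
    c0 <- substr(pattern, i, i)
    if (c0 == "[") {
      j <- regexpr("]", substr(pattern, i, n), fixed = TRUE)
      if (j < 0) stop("malformed pattern: unclosed '[' in ", pattern)
      cls <- strsplit(substr(pattern, i + 1L, i + j - 2L), "")[[1]]
      if (!length(cls) || !all(cls %in% .aa20)) {
        stop("malformed pattern: bad character class in ", pattern)
      }
      toks[[length(toks) + 1L]] <- cls
      i <- i + j
    } else if (c0 == "x") {
      toks[[length(toks) + 1L]] <- .aa20
      i <- i + 1L
    } else if (c0 %in% .aa20) {
      toks[[length(toks) + 1L]] <- c0
      i <- i + 1L
    } else {
      stop("malformed pattern: illegal character '", c0, "' in ", pattern)
    }
  }
  L <- length(toks)
  if (L == 0L) stop("empty pattern")
  ch <- .seq_chars(record)
  hits <- list()
  for (s in seq_len(max(0L, length(ch) - L + 1L))) {
    ok <- TRUE
    for (k in seq_len(L)) {
      if (!(ch[s + k - 1L] %in% toks[[k]])) { ok <- FALSE; break }
    }
    if (ok) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = record$offset + s - 1L,
        end = record$offset + s + L - 2L,
        match = paste(ch[s:(s + L - 1L)], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}
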