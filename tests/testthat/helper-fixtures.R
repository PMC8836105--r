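# shared fixture builders and independent oracles

# tiny labelled alignment from character vectors of equal-length strings
make_ags <- function(pp1, ppz,
                     clades_pp1 = rep("CladeX", length(pp1)),
                     clades_ppz = rep("CladeX", length(ppz))) {
  ids <- c(sprintf("pp1_%02d", seq_along(pp1)),
           sprintf("ppz_%02d", seq_along(ppz)))
  recs <- mapply(function(id, s) seq_record(id, s, aligned = TRUE),
                 ids, c(pp1, ppz), SIMPLIFY = FALSE)
  labels <- data.frame(seq_id = ids,
                       group = rep(c("PP1", "PPZ"), c(length(pp1), length(ppz))),
                       clade = c(clades_pp1, clades_ppz),
                       stringsAsFactors = FALSE)
  aligned_group_set(recs, labels)
}

# independent tryptic-digest oracle: test every substring against the
# boundary/missed-cleavage definition (different route than the implementation,
# which constructs spans from fragment runs)
oracle_digest <- function(sequence, max_missed = 4L, proline_rule = TRUE) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  is_cut <- ch %in% c("K", "R") & seq_len(n) < n
  if (proline_rule) is_cut <- is_cut & c(ch[-1] != "P", FALSE)
  cuts <- which(is_cut)
  out <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      left_ok <- s == 1L || (s - 1L) %in% cuts
      right_ok <- e == n || e %in% cuts
      if (!left_ok || !right_ok) next
      internal <- sum(cuts >= s & cuts < e)
      if (internal > max_missed) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(ch[s:e], collapse = ""), start = s, end = e,
        missed = internal, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

# exhaustive affine-gap global alignment score (Biostrings convention:
# a gap of length L costs open + ext * L); feasible for lengths <= 5
brute_align_score <- function(a, b, open = 10, ext = 0.5) {
  sub <- get_blosum62()
  na <- nchar(a); nb <- nchar(b)
  rec <- function(i, j, state) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      best <- max(best, sub[substr(a, i, i), substr(b, j, j)] +
                    rec(i + 1L, j + 1L, "M"))
    }
    if (i <= na) {
      best <- max(best, rec(i + 1L, j, "I") -
                    ext - if (state != "I") open else 0)
    }
    if (j <= nb) {
      best <- max(best, rec(i, j + 1L, "D") -
                    ext - if (state != "D") open else 0)
    }
    best
  }
  rec(1L, 1L, "M")
}

get_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# split-based 4-taxon oracle: among the three pairings, additive trees
# minimize the sum of within-pair distances
oracle_quartet_split <- function(d) {
  taxa <- rownames(d)
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  sums <- vapply(pairings, function(p) d[p[1], p[2]] + d[p[3], p[4]],
                 numeric(1))
  p <- pairings[[which.min(sums)]]
  list(sort(taxa[p[1:2]]), sort(taxa[p[3:4]]))
}

# sibling-leaf partition of an unrooted 4-taxon newick, via ape
quartet_split_from_newick <- function(nwk) {
  tr <- ape::unroot(ape::read.tree(text = nwk))
  # the single internal edge partitions the four leaves 2|2
  pairs <- list()
  for (node in unique(tr$edge[, 1])) {
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    leafkids <- kids[kids <= length(tr$tip.label)]
    if (length(leafkids) == 2L) {
      pairs[[length(pairs) + 1L]] <- sort(tr$tip.label[leafkids])
    }
  }
  pairs[order(vapply(pairs, paste, character(1), collapse = ","))]
}
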