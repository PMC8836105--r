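## Per-column conservation profiling of a joint PP1/PPZ alignment,
## difference-class assignment (A-D), charge-swap scanning, motif-window
## reports, Shannon logo matrices, pairwise identity and neighbor joining.

#' Conservation analysis configuration
#'
#' Numeric thresholds behind the informal vocabulary of grouped-alignment
#' comparisons: "invariant or largely maintained" (`theta_cons`),
#' "substantial variation" (`theta_var`), "quite constant" charge categories
#' (`theta_charge`). All are configurable because the source procedure is
#' verbal, not numeric.
#'
#' @param theta_cons Dominant-frequency threshold for a column to count as
#'   constant/maintained within a group (default 0.90).
#' @param theta_var Upper dominant-frequency bound for "variable" (default
#'   0.70).
#' @param allow_simgroup If `TRUE`, a column whose residues stay within one
#'   similarity group may satisfy `theta_cons` for class A.
#' @param max_gap_conserved Maximum gap fraction for a column to qualify as
#'   conserved (default 0: the residue must be present in every sequence).
#' @param max_gap_class Maximum gap fraction tolerated during A-D
#'   classification (default 0.1).
#' @param similarity_groups Partition of the 20 residues into conservative
#'   substitution groups.
#' @param charge_categories Named list mapping `acidic` and `basic` to residue
#'   sets; everything else is neutral (H is neutral by default, pKa ~ 6).
#' @param theta_charge Modal-category frequency for a charge swap to count as
#'   "quite constant" (default 0.90).
#' @param exclude_clades Character vector of clade names dropped before
#'   profiling.
#' @param min_clade_seqs Minimum sequences per group within a clade for that
#'   clade to participate in class D detection (default 3).
#' @return A list of class `conservation_config`.
#' @export
conservation_config <- function(theta_cons = 0.90,
                                theta_var = 0.70,
                                allow_simgroup = TRUE,
                                max_gap_conserved = 0.0,
                                max_gap_class = 0.1,
                                similarity_groups = default_similarity_groups(),
                                charge_categories = list(acidic = c("D", "E"),
                                                         basic = c("K", "R")),
                                theta_charge = 0.90,
                                exclude_clades = character(0),
                                min_clade_seqs = 3L) {
  if (!(theta_var > 0 && theta_var <= theta_cons && theta_cons <= 1)) {
    stop("need 0 < theta_var <= theta_cons <= 1")
  }
  structure(list(theta_cons = theta_cons, theta_var = theta_var,
                 allow_simgroup = allow_simgroup,
                 max_gap_conserved = max_gap_conserved,
                 max_gap_class = max_gap_class,
                 similarity_groups = similarity_groups,
                 charge_categories = charge_categories,
                 theta_charge = theta_charge,
                 exclude_clades = exclude_clades,
                 min_clade_seqs = as.integer(min_clade_seqs)),
            class = "conservation_config")
}

#' Default conservative-substitution groups
#'
#' Boxshade-style partition: \{AVLIM\}, \{FWY\}, \{ST\}, \{NQ\}, \{DE\},
#' \{KR\}, \{H\}, \{C\}, \{G\}, \{P\}.
#'
#' @return Named list of character vectors.
#' @export
default_similarity_groups <- function() {
  list(aliphatic = c("A", "V", "L", "I", "M"),
       aromatic  = c("F", "W", "Y"),
       hydroxyl  = c("S", "T"),
       amide     = c("N", "Q"),
       acidic    = c("D", "E"),
       basic     = c("K", "R"),
       histidine = "H",
       cysteine  = "C",
       glycine   = "G",
       proline   = "P")
}

.simgroup_of <- function(cfg) {
  map <- character(0)
  for (g in names(cfg$similarity_groups)) {
    map[cfg$similarity_groups[[g]]] <- g
  }
  map
}

.charge_of <- function(cfg) {
  map <- rep("neutral", length(.aa20))
  names(map) <- .aa20
  map[cfg$charge_categories$acidic] <- "acidic"
  map[cfg$charge_categories$basic] <- "basic"
  map
}

#' Bundle an alignment with group/clade labels
#'
#' @param records List of aligned `seq_record`s (equal lengths, `-` gaps).
#' @param labels `data.frame` with columns seq_id, group (PP1/PPZ), clade.
#' @return Object of class `aligned_group_set` with fields `records`,
#'   `labels`, `ncol`.
#' @export
aligned_group_set <- function(records, labels) {
  lens <- vapply(records, seq_length, integer(1))
  if (length(unique(lens)) != 1L) stop("records are not aligned (unequal lengths)")
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  missing <- setdiff(ids, labels$seq_id)
  if (length(missing)) {
    stop("sequences without labels: ", paste(missing, collapse = ", "))
  }
  labels <- labels[match(ids, labels$seq_id), , drop = FALSE]
  structure(list(records = records, labels = labels, ncol = lens[1]),
            class = "aligned_group_set")
}

#' @export
print.aligned_group_set <- function(x, ...) {
  cat(sprintf("<aligned_group_set> %d sequences x %d columns (%s)\n",
              length(x$records), x$ncol,
              paste(sprintf("%s: %d", names(table(x$labels$group)),
                            table(x$labels$group)), collapse = ", ")))
  invisible(x)
}

# character matrix view of the alignment, rows = sequences
.aln_matrix <- function(ags) {
  do.call(rbind, lapply(ags$records, .seq_chars))
}

.apply_exclusions <- function(ags, cfg) {
  keep <- !(ags$labels$clade %in% cfg$exclude_clades)
  if (!any(keep)) stop("exclude_clades removes every sequence")
  structure(list(records = ags$records[keep],
                 labels = ags$labels[keep, , drop = FALSE],
                 ncol = ags$ncol),
            class = "aligned_group_set")
}

.profile_column_group <- function(col_chars, cfg, simgroup, charge) {
  res <- col_chars[col_chars != "-"]
  res <- res[res != "X"]
  gap_fraction <- mean(col_chars == "-")
  if (length(res) == 0L) {
    return(list(gap_fraction = gap_fraction, dominant = NA_character_,
                dominant_freq = NA_real_, simgroup_freq = NA_real_,
                acidic = NA_real_, basic = NA_real_, neutral = NA_real_,
                freqs = numeric(0)))
  }
  tab <- table(res)
  freqs <- as.numeric(tab) / length(res)
  names(freqs) <- names(tab)
  # deterministic dominant: highest frequency, ties by alphabetical residue
  ord <- order(-freqs, names(freqs))
  dominant <- names(freqs)[ord[1]]
  dominant_freq <- freqs[[dominant]]
  grp <- simgroup[[dominant]]
  members <- names(freqs)[simgroup[names(freqs)] == grp]
  simgroup_freq <- sum(freqs[members])
  cats <- charge[res]
  list(gap_fraction = gap_fraction,
       dominant = dominant,
       dominant_freq = dominant_freq,
       simgroup_freq = simgroup_freq,
       acidic = mean(cats == "acidic"),
       basic = mean(cats == "basic"),
       neutral = mean(cats == "neutral"),
       freqs = freqs)
}

#' Per-column, per-group conservation profiles
#'
#' For every alignment column and each group (PP1, PPZ): residue frequencies
#' over non-gap entries, gap fraction, dominant residue and its frequency, the
#' frequency of the dominant residue's similarity group, and charge-category
#' frequencies over \{acidic, basic, neutral\}.
#'
#' @param ags An `aligned_group_set`.
#' @param cfg A `conservation_config`; `exclude_clades` is applied before
#'   profiling.
#' @return `data.frame`, one row per column x group, columns: column, group,
#'   gap_fraction, dominant, dominant_freq, simgroup_freq, acidic, basic,
#'   neutral.
#' @export
column_profiles <- function(ags, cfg = conservation_config()) {
  ags <- .apply_exclusions(ags, cfg)
  groups <- c("PP1", "PPZ")
  cnt <- table(factor(ags$labels$group, levels = groups))
  if (any(cnt < 2L)) {
    stop("need >= 2 sequences per group after exclusions; have ",
         paste(sprintf("%s=%d", groups, cnt), collapse = ", "))
  }
  simgroup <- .simgroup_of(cfg)
  charge <- .charge_of(cfg)
  mat <- .aln_matrix(ags)
  out <- vector("list", 2L * ags$ncol)
  k <- 0L
  for (g in groups) {
    sub <- mat[ags$labels$group == g, , drop = FALSE]
    for (j in seq_len(ags$ncol)) {
      p <- .profile_column_group(sub[, j], cfg, simgroup, charge)
      k <- k + 1L
      out[[k]] <- data.frame(column = j, group = g,
                             gap_fraction = p$gap_fraction,
                             dominant = p$dominant,
                             dominant_freq = p$dominant_freq,
                             simgroup_freq = p$simgroup_freq,
                             acidic = p$acidic, basic = p$basic,
                             neutral = p$neutral,
                             stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df[order(df$column, df$group), , drop = FALSE]
}

#' Columns unanimously conserved within a group
#'
#' A column qualifies when every non-excluded sequence of the group carries
#' the identical residue and the gap fraction does not exceed
#' `max_gap_conserved` (default 0, i.e. present in all sequences).
#'
#' @param ags An `aligned_group_set`.
#' @param group `"PP1"` or `"PPZ"`.
#' @param cfg A `conservation_config`.
#' @return Sorted integer vector of column indices.
#' @export
conserved_positions <- function(ags, group, cfg = conservation_config()) {
  ags <- .apply_exclusions(ags, cfg)
  mat <- .aln_matrix(ags)
  sub <- mat[ags$labels$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) stop("group not present: ", group)
  hits <- integer(0)
  for (j in seq_len(ncol(sub))) {
    col <- sub[, j]
    gap_fraction <- mean(col == "-")
    res <- col[col != "-"]
    if (length(res) && gap_fraction <= cfg$max_gap_conserved &&
        length(unique(res)) == 1L && res[1] != "X") {
      hits <- c(hits, j)
    }
  }
  hits
}

.group_row <- function(profiles, j, g) {
  profiles[profiles$column == j & profiles$group == g, , drop = FALSE]
}

.passes_cons <- function(row, cfg) {
  if (is.na(row$dominant_freq) || row$gap_fraction > cfg$max_gap_class) {
    return(FALSE)
  }
  row$dominant_freq >= cfg$theta_cons ||
    (cfg$allow_simgroup && row$simgroup_freq >= cfg$theta_cons)
}

## A-style difference between two group profiles: dominants differ, and when
## both dominants share one similarity group the difference is only believed
## if each group is residue-level constant (the conserved V-vs-I case);
## a same-group dominant flip with simgroup-only conservation is sampling
## noise inside one conservative group, not a difference.
.a_style_difference <- function(p1, pz, cfg, simgroup) {
  if (is.na(p1$dominant) || is.na(pz$dominant)) return(FALSE)
  if (p1$dominant == pz$dominant) return(FALSE)
  if (!(.passes_cons(p1, cfg) && .passes_cons(pz, cfg))) return(FALSE)
  if (simgroup[[p1$dominant]] == simgroup[[pz$dominant]]) {
    return(p1$dominant_freq >= cfg$theta_cons &&
             pz$dominant_freq >= cfg$theta_cons)
  }
  TRUE
}

#' Classify alignment columns into difference classes A-D
#'
#' Class A: both groups pass `theta_cons` (residue-identical or, with
#' `allow_simgroup`, within one similarity group) with different dominant
#' residues; when the two dominants fall in the same similarity group the
#' difference is only accepted if both groups are residue-level constant. Class B: PP1 virtually constant (`dominant_freq >= theta_cons`)
#' while PPZ shows substantial variation (`dominant_freq < theta_var`).
#' Class C: the symmetric case. Class D: the class A pattern holds within at
#' least one clade (with `min_clade_seqs` sequences per group there) but not
#' globally. Precedence A > B > C > D; anything else is `none`.
#'
#' @param profiles Output of [column_profiles()] on the full (non-excluded)
#'   set.
#' @param cfg A `conservation_config`.
#' @param clade_profiles Optional named list of per-clade profile tables (as
#'   produced by [clade_column_profiles()]); required for class D detection.
#' @return `data.frame`: column, class (`A`,`B`,`C`,`D`,`none`),
#'   clade_restricted_to (comma-joined, class D only), charge-swap fields
#'   (swap_from, swap_to, swap_constant) where a charge swap co-occurs.
#' @export
classify_columns <- function(profiles, cfg = conservation_config(),
                             clade_profiles = NULL) {
  cols <- sort(unique(profiles$column))
  swaps <- charge_change_scan(profiles, cfg)
  simgroup <- .simgroup_of(cfg)
  out <- vector("list", length(cols))
  for (i in seq_along(cols)) {
    j <- cols[i]
    p1 <- .group_row(profiles, j, "PP1")
    pz <- .group_row(profiles, j, "PPZ")
    klass <- "none"
    clades <- NA_character_
    if (.a_style_difference(p1, pz, cfg, simgroup)) {
      klass <- "A"
    } else if (!is.na(p1$dominant_freq) && !is.na(pz$dominant_freq) &&
               p1$gap_fraction <= cfg$max_gap_class &&
               pz$gap_fraction <= cfg$max_gap_class &&
               p1$dominant_freq >= cfg$theta_cons &&
               pz$dominant_freq < cfg$theta_var) {
      klass <- "B"
    } else if (!is.na(p1$dominant_freq) && !is.na(pz$dominant_freq) &&
               p1$gap_fraction <= cfg$max_gap_class &&
               pz$gap_fraction <= cfg$max_gap_class &&
               pz$dominant_freq >= cfg$theta_cons &&
               p1$dominant_freq < cfg$theta_var) {
      klass <- "C"
    } else if (!is.null(clade_profiles)) {
      hit <- character(0)
      for (cl in names(clade_profiles)) {
        cp <- clade_profiles[[cl]]
        if (is.null(cp)) next
        q1 <- .group_row(cp, j, "PP1")
        qz <- .group_row(cp, j, "PPZ")
        if (nrow(q1) == 0L || nrow(qz) == 0L) next
        if (.a_style_difference(q1, qz, cfg, simgroup)) hit <- c(hit, cl)
      }
      if (length(hit)) {
        klass <- "D"
        clades <- paste(hit, collapse = ",")
      }
    }
    sw <- swaps[swaps$column == j, , drop = FALSE]
    out[[i]] <- data.frame(
      column = j, class = klass, clade_restricted_to = clades,
      pp1_dominant = p1$dominant, ppz_dominant = pz$dominant,
      swap_from = if (nrow(sw)) sw$pp1_category else NA_character_,
      swap_to = if (nrow(sw)) sw$ppz_category else NA_character_,
      swap_constant = if (nrow(sw)) sw$constant else NA,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-clade column profiles (for class D detection)
#'
#' Runs [column_profiles()] restricted to each clade that retains at least
#' `cfg$min_clade_seqs` sequences per group; clades below that floor are
#' dropped (value `NULL`).
#'
#' @param ags An `aligned_group_set`.
#' @param cfg A `conservation_config`.
#' @return Named list of profile tables (or `NULL`) per clade.
#' @export
clade_column_profiles <- function(ags, cfg = conservation_config()) {
  clades <- setdiff(unique(ags$labels$clade), cfg$exclude_clades)
  out <- stats::setNames(vector("list", length(clades)), clades)
  for (cl in clades) {
    keep <- ags$labels$clade == cl
    sub_labels <- ags$labels[keep, , drop = FALSE]
    cnt <- table(factor(sub_labels$group, levels = c("PP1", "PPZ")))
    if (any(cnt < cfg$min_clade_seqs)) next
    sub <- structure(list(records = ags$records[keep], labels = sub_labels,
                          ncol = ags$ncol), class = "aligned_group_set")
    out[[cl]] <- column_profiles(sub, cfg)
  }
  out
}

#' Scan columns for charge-category swaps
#'
#' Emits every column whose modal charge category (acidic/basic/neutral over
#' non-gap residues) differs between PP1 and PPZ; `constant` is `TRUE` when
#' both modal-category frequencies reach `theta_charge` ("quite constant").
#'
#' @param profiles Output of [column_profiles()].
#' @param cfg A `conservation_config`.
#' @return `data.frame`: column, pp1_category, ppz_category, pp1_freq,
#'   ppz_freq, constant, change (e.g. `"basic->acidic"`).
#' @export
charge_change_scan <- function(profiles, cfg = conservation_config()) {
  cats <- c("acidic", "basic", "neutral")
  modal <- function(row) {
    f <- c(row$acidic, row$basic, row$neutral)
    if (anyNA(f)) return(NULL)
    ord <- order(-f, cats)
    list(cat = cats[ord[1]], freq = f[ord[1]])
  }
  cols <- sort(unique(profiles$column))
  rows <- list()
  for (j in cols) {
    m1 <- modal(.group_row(profiles, j, "PP1"))
    mz <- modal(.group_row(profiles, j, "PPZ"))
    if (is.null(m1) || is.null(mz) || m1$cat == mz$cat) next
    rows[[length(rows) + 1L]] <- data.frame(
      column = j, pp1_category = m1$cat, ppz_category = mz$cat,
      pp1_freq = m1$freq, ppz_freq = mz$freq,
      constant = m1$freq >= cfg$theta_charge && mz$freq >= cfg$theta_charge,
      change = paste0(m1$cat, "->", mz$cat),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(column = integer(0), pp1_category = character(0),
                      ppz_category = character(0), pp1_freq = numeric(0),
                      ppz_freq = numeric(0), constant = logical(0),
                      change = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Identity and conservation of a motif window per group
#'
#' For a set of alignment columns covering a docking motif (RVxF, SILK, ...):
#' `identity_pct` is the percentage of motif columns whose within-group
#' consensus equals the reference sequence's residue; `conservation_pct`
#' additionally counts columns whose consensus falls in the reference
#' residue's similarity group.
#'
#' @param ags An `aligned_group_set`.
#' @param motif_columns Integer vector of alignment columns.
#' @param reference Sequence id of the reference protein in the alignment.
#' @param cfg A `conservation_config`.
#' @return `data.frame`: group, identity_pct, conservation_pct, n_columns.
#' @export
motif_report <- function(ags, motif_columns, reference,
                         cfg = conservation_config()) {
  if (!length(motif_columns)) stop("motif_columns is empty")
  motif_columns <- as.integer(motif_columns)
  if (any(motif_columns < 1L | motif_columns > ags$ncol)) {
    stop("motif column outside alignment (1..", ags$ncol, ")")
  }
  ids <- vapply(ags$records, function(r) r$id, character(1))
  ri <- match(reference, ids)
  if (is.na(ri)) stop("reference sequence not in alignment: ", reference)
  refchars <- .seq_chars(ags$records[[ri]])
  simgroup <- .simgroup_of(cfg)
  profiles <- column_profiles(ags, cfg)
  out <- list()
  for (g in c("PP1", "PPZ")) {
    ident <- 0L; cons <- 0L
    for (j in motif_columns) {
      refres <- refchars[j]
      if (refres == "-") next
      if (!refres %in% names(simgroup)) {
        stop("reference residue '", refres, "' at column ", j,
             "' not in the similarity table")
      }
      consensus <- .group_row(profiles, j, g)$dominant
      if (is.na(consensus)) next
      if (consensus == refres) {
        ident <- ident + 1L; cons <- cons + 1L
      } else if (simgroup[[consensus]] == simgroup[[refres]]) {
        cons <- cons + 1L
      }
    }
    out[[g]] <- data.frame(group = g,
                           identity_pct = 100 * ident / length(motif_columns),
                           conservation_pct = 100 * cons / length(motif_columns),
                           n_columns = length(motif_columns),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Shannon sequence-logo matrix
#'
#' Per selected column, information content `IC = log2(20) - H` with
#' `H = -sum f_a log2 f_a` over non-gap residue frequencies, and letter
#' heights `f_a * IC` (bits). Gap-only columns get IC 0. Optionally the IC is
#' scaled by the non-gap fraction (`scale_by_gaps`, off by default).
#'
#' @param ags An `aligned_group_set`.
#' @param group `"PP1"` or `"PPZ"`.
#' @param columns Integer vector of columns (default: all).
#' @param scale_by_gaps Multiply IC by (1 - gap_fraction)?
#' @return Numeric matrix, 20 rows (residues) x columns, of letter heights in
#'   bits; attribute `ic` holds the per-column information content.
#' @export
shannon_logo_matrix <- function(ags, group, columns = seq_len(ags$ncol),
                                scale_by_gaps = FALSE) {
  columns <- as.integer(columns)
  if (any(columns < 1L | columns > ags$ncol)) {
    stop("logo column outside alignment")
  }
  mat <- .aln_matrix(ags)
  sub <- mat[ags$labels$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) stop("group not present: ", group)
  heights <- matrix(0, nrow = length(.aa20), ncol = length(columns),
                    dimnames = list(.aa20, as.character(columns)))
  ic <- numeric(length(columns))
  for (k in seq_along(columns)) {
    col <- sub[, columns[k]]
    res <- col[!(col %in% c("-", "X"))]
    if (!length(res)) next
    f <- table(factor(res, levels = .aa20)) / length(res)
    f <- as.numeric(f)
    nz <- f > 0
    h <- -sum(f[nz] * log2(f[nz]))
    ic_k <- log2(20) - h
    if (scale_by_gaps) ic_k <- ic_k * (1 - mean(col == "-"))
    ic[k] <- ic_k
    heights[, k] <- f * ic_k
  }
  attr(heights, "ic") <- ic
  heights
}

#' Pairwise sequence identity within a group
#'
#' Identity = matching residues / mutually non-gap columns; diagonal 1; pairs
#' with no mutually non-gap columns are `NA`.
#'
#' @param ags An `aligned_group_set`.
#' @param group `"PP1"` or `"PPZ"`; `NULL` uses all sequences.
#' @return Symmetric numeric matrix with sequence ids as dimnames.
#' @export
pairwise_identity <- function(ags, group = NULL) {
  keep <- if (is.null(group)) rep(TRUE, length(ags$records)) else
    ags$labels$group == group
  recs <- ags$records[keep]
  if (length(recs) < 2L) stop("need >= 2 sequences")
  mat <- do.call(rbind, lapply(recs, .seq_chars))
  ids <- vapply(recs, function(r) r$id, character(1))
  n <- length(recs)
  out <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(out) <- 1
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) next
      v <- sum(mat[i, ok] == mat[j, ok]) / sum(ok)
      out[i, j] <- v; out[j, i] <- v
    }
  }
  out
}

#' Summary of within-group divergence
#'
#' @param m Symmetric identity (or distance) matrix.
#' @return `data.frame` with mean, sd, min, max over off-diagonal entries
#'   (NA removed).
#' @export
divergence_summary <- function(m) {
  v <- m[upper.tri(m)]
  v <- v[!is.na(v)]
  data.frame(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))
}

## ---- neighbor joining ------------------------------------------------------

#' Neighbor-joining tree (Saitou-Nei) with deterministic output
#'
#' Standard neighbor joining on a symmetric distance matrix, with two
#' reproducibility rules: ties in the Q criterion are broken by the
#' lexicographically lowest pair of cluster labels (a cluster is labelled by
#' its smallest member leaf), and negative branch lengths are clamped to zero
#' with the deficit shifted onto the sister branch. With three or more taxa
#' the output is an unrooted tree written with a trifurcating root; with two
#' taxa the distance is split evenly.
#'
#' @param dist Symmetric numeric matrix, zero diagonal.
#' @param labels Taxon labels (default from dimnames).
#' @return Newick string, terminated with `;`.
#' @export
nj_tree <- function(dist, labels = rownames(dist)) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (n < 2L) stop("need >= 2 taxa")
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric")
  }
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  newick <- labels          # partial newick per active cluster
  rep_lab <- labels         # representative (smallest) leaf label
  d <- dist
  while (length(newick) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    best <- NULL; best_q <- Inf; best_key <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * d[i, j] - r[i] - r[j]
        key <- paste(sort(c(rep_lab[i], rep_lab[j])), collapse = "\r")
        if (q < best_q - 1e-12 ||
            (abs(q - best_q) <= 1e-12 && !is.null(best_key) && key < best_key)) {
          best_q <- q; best <- c(i, j); best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    pair <- if (rep_lab[i] <= rep_lab[j]) {
      sprintf("(%s:%s,%s:%s)", newick[i], fmt(vi), newick[j], fmt(vj))
    } else {
      sprintf("(%s:%s,%s:%s)", newick[j], fmt(vj), newick[i], fmt(vi))
    }
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    d <- d2
    newick <- c(newick[keep], pair)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(i, j)]))
  }
  if (length(newick) == 2L) {
    half <- d[1, 2] / 2
    ord <- order(rep_lab)
    return(sprintf("(%s:%s,%s:%s);",
                   newick[ord[1]], fmt(half), newick[ord[2]], fmt(half)))
  }
  # star join of the final three clusters
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- c(v1, v2, v3)
  for (i in 1:3) if (v[i] < 0) {
    others <- setdiff(1:3, i)
    v[others] <- v[others] + v[i] / 2
    v[i] <- 0
  }
  ord <- order(rep_lab)
  parts <- sprintf("%s:%s", newick[ord], vapply(v[ord], fmt, character(1)))
  paste0("(", paste(parts, collapse = ","), ");")
}
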