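## BS3 cross-link identification: MGF ingestion, the charge/signature scan
## filter, tryptic digestion with missed cleavages, precursor-matched
## candidate enumeration at ppm tolerance, theoretical b/y fragments of
## cross-linked peptide pairs, and the both-peptides approval rule.

#' Cross-link search configuration
#'
#' Mass-spectrometric search parameters. All mass constants are monoisotopic
#' and computed from molecular formulas ([formula_mass()]), never typed as
#' decimals: BS3 bridge C8H10O2, BS3-water dead-end C8H12O3, BS3-ammonia
#' dead-end C8H13NO2, carbamidomethyl C2H3NO (fixed on Cys), oxidation O
#' (variable on Met).
#'
#' @param charge_min,charge_max Retained precursor charge range (default
#'   3..9, chosen to enrich highly charged cross-linked species).
#' @param ms1_tol_ppm Precursor mass tolerance in ppm (default 10).
#' @param ms2_tol_da Fragment tolerance in Da (default 0.10).
#' @param max_missed Maximum tryptic missed cleavages (default 4; cross-linked
#'   or dead-end lysines block cleavage, so high values are needed).
#' @param proline_rule No cleavage before proline (default TRUE).
#' @param signature_y1_masses y1 ion m/z values marking tryptic spectra
#'   (default: y1 of K and of R, computed from residue masses).
#' @param linker_signature_masses m/z values diagnostic of the cross-linker.
#'   The default (y1 of K carrying a BS3-water or BS3-ammonia dead-end) is a
#'   package choice: the upstream tool does not publish its list, so this is
#'   a config knob, not an asserted constant.
#' @param max_fragment_charge Fragment ion charges enumerated (default 2).
#' @param max_oxidations Maximum Met oxidations per candidate (default 2).
#' @param min_ions_per_peptide Matched-ion floor per peptide for approval
#'   (default 1: b- and/or y-ions from both peptides must be present).
#' @param min_pep_len Minimum peptide length emitted by digestion.
#' @return List of class `xlms_config` including derived mass constants
#'   (`bridge_mass`, `deadend_water_mass`, `deadend_ammonia_mass`,
#'   `carbamidomethyl_mass`, `oxidation_mass`, `proton_mass`, `water_mass`).
#' @export
xlms_config <- function(charge_min = 3L, charge_max = 9L,
                        ms1_tol_ppm = 10, ms2_tol_da = 0.10,
                        max_missed = 4L, proline_rule = TRUE,
                        signature_y1_masses = NULL,
                        linker_signature_masses = NULL,
                        max_fragment_charge = 2L,
                        max_oxidations = 2L,
                        min_ions_per_peptide = 1L,
                        min_pep_len = 1L) {
  y1 <- function(aa) .residue_mass_tab[[aa]] + .mass_water + .mass_proton
  if (is.null(signature_y1_masses)) {
    signature_y1_masses <- c(y1_K = y1("K"), y1_R = y1("R"))
  }
  if (is.null(linker_signature_masses)) {
    linker_signature_masses <- c(
      y1_K_bs3_h2o = y1("K") + .mass_bs3_deadend_h2o,
      y1_K_bs3_nh2 = y1("K") + .mass_bs3_deadend_nh2)
  }
  structure(list(
    charge_min = as.integer(charge_min), charge_max = as.integer(charge_max),
    ms1_tol_ppm = ms1_tol_ppm, ms2_tol_da = ms2_tol_da,
    max_missed = as.integer(max_missed), proline_rule = proline_rule,
    signature_y1_masses = signature_y1_masses,
    linker_signature_masses = linker_signature_masses,
    max_fragment_charge = as.integer(max_fragment_charge),
    max_oxidations = as.integer(max_oxidations),
    min_ions_per_peptide = as.integer(min_ions_per_peptide),
    min_pep_len = as.integer(min_pep_len),
    bridge_mass = .mass_bs3_bridge,
    deadend_water_mass = .mass_bs3_deadend_h2o,
    deadend_ammonia_mass = .mass_bs3_deadend_nh2,
    carbamidomethyl_mass = .mass_carbamidomethyl,
    oxidation_mass = .mass_oxidation,
    proton_mass = .mass_proton,
    water_mass = .mass_water), class = "xlms_config")
}

## ---- MGF -------------------------------------------------------------------

#' Read an MGF peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`, `CHARGE`
#' and peak lines. Blocks without `CHARGE` are skipped with a warning (MGF
#' dialects vary and the downstream filter discards unknown charges anyway);
#' a block without `PEPMASS` is an error naming the block index.
#'
#' @param path MGF file path.
#' @return List of `scan` objects (title, precursor_mz, charge, peaks matrix
#'   sorted by m/z) in file order.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  scans <- list()
  i <- 1L; block <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      block <- block + 1L
      j <- i + 1L
      title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_
      mz <- numeric(0); int <- numeric(0)
      while (j <= length(lines) && trimws(lines[j]) != "END IONS") {
        ln <- trimws(lines[j])
        if (startsWith(ln, "TITLE=")) {
          title <- sub("^TITLE=", "", ln)
        } else if (startsWith(ln, "PEPMASS=")) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                         "[ \t]+")[[1]][1])
        } else if (startsWith(ln, "CHARGE=")) {
          charge <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
        } else if (grepl("^[0-9]", ln)) {
          parts <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
          if (length(parts) < 2L || anyNA(parts[1:2])) {
            stop("malformed peak line in MGF block ", block, ": ", ln)
          }
          mz <- c(mz, parts[1]); int <- c(int, parts[2])
        } else if (nzchar(ln) && !grepl("=", ln, fixed = TRUE)) {
          stop("malformed line in MGF block ", block, ": ", ln)
        }
        j <- j + 1L
      }
      if (j > length(lines)) stop("MGF block ", block, " not terminated")
      if (is.na(pepmass)) stop("MGF block ", block, " has no PEPMASS")
      if (is.na(charge)) {
        warning("MGF block ", block, " has no CHARGE; scan skipped")
      } else {
        ord <- order(mz)
        scans[[length(scans) + 1L]] <- structure(
          list(title = if (is.na(title)) sprintf("scan_%d", block) else title,
               precursor_mz = pepmass, charge = charge,
               peaks = cbind(mz = mz[ord], intensity = int[ord])),
          class = "scan")
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  scans
}

#' Write scans to MGF
#'
#' @param scans List of `scan` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(scans, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in scans) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$title),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$charge),
                 sprintf("%.5f %.2f", s$peaks[, 1], s$peaks[, 2]),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Filter scans by charge and signature peaks
#'
#' A scan survives iff its charge lies in `[charge_min, charge_max]`, it
#' contains at least one peak within `ms2_tol_da` of a configured tryptic y1
#' signature mass, and at least one peak within `ms2_tol_da` of a configured
#' cross-linker signature mass.
#'
#' @param scans List of `scan`s.
#' @param cfg An `xlms_config`.
#' @return Retained scans; attribute `counts` holds the stage counts
#'   (input, after_charge, after_y1, after_linker).
#' @export
filter_scans <- function(scans, cfg = xlms_config()) {
  has_peak_near <- function(s, masses) {
    any(vapply(masses, function(m) {
      any(abs(s$peaks[, 1] - m) <= cfg$ms2_tol_da)
    }, logical(1)))
  }
  n0 <- length(scans)
  scans <- Filter(function(s) s$charge >= cfg$charge_min &&
                    s$charge <= cfg$charge_max, scans)
  n1 <- length(scans)
  scans <- Filter(function(s) nrow(s$peaks) > 0 &&
                    has_peak_near(s, cfg$signature_y1_masses), scans)
  n2 <- length(scans)
  scans <- Filter(function(s) has_peak_near(s, cfg$linker_signature_masses),
                  scans)
  attr(scans, "counts") <- c(input = n0, after_charge = n1,
                             after_y1 = n2, after_linker = length(scans))
  scans
}

## ---- digestion and masses --------------------------------------------------

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K/R (not before P when `proline_rule`) and emits all
#' peptides with 0..`max_missed` missed cleavages, with full-length
#' (offset-aware) coordinates.
#'
#' @param protein A `seq_record` with standard residues.
#' @param cfg An `xlms_config`.
#' @return `data.frame`: protein_id, sequence, start, end, missed.
#' @export
digest <- function(protein, cfg = xlms_config()) {
  ch <- .seq_chars(protein)
  if (any(ch %in% c("-", "X"))) stop("digest requires standard residues")
  n <- length(ch)
  # cleavage after position i
  cut <- which(ch %in% c("K", "R"))
  cut <- cut[cut < n]
  if (cfg$proline_rule) cut <- cut[ch[cut + 1L] != "P"]
  bounds <- c(0L, cut, n)           # fragment k spans bounds[k]+1 .. bounds[k+1]
  nf <- length(bounds) - 1L
  rows <- list()
  for (a in seq_len(nf)) {
    for (b in a:min(nf, a + cfg$max_missed)) {
      s <- bounds[a] + 1L; e <- bounds[b + 1L]
      if (e - s + 1L < cfg$min_pep_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = protein$id,
        sequence = paste(ch[s:e], collapse = ""),
        start = protein$offset + s - 1L,
        end = protein$offset + e - 1L,
        missed = b - a,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "protein_length") <- n
  attr(out, "protein_offset") <- protein$offset
  out
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus water; carbamidomethyl is applied to every Cys
#' automatically; `n_ox` Met oxidations add `n_ox` oxygen masses.
#'
#' @param sequence Peptide sequence (standard residues).
#' @param n_ox Number of oxidized methionines (must not exceed the Met
#'   count).
#' @param cfg An `xlms_config`.
#' @return Neutral mass in Da.
#' @export
peptide_mass <- function(sequence, n_ox = 0L, cfg = xlms_config()) {
  ch <- strsplit(sequence, "")[[1]]
  if (!all(ch %in% .aa20)) {
    stop("non-standard residue in peptide: ", sequence)
  }
  if (n_ox > sum(ch == "M")) {
    stop("oxidation count exceeds Met count in ", sequence)
  }
  sum(.residue_mass_tab[ch]) + cfg$water_mass +
    sum(ch == "C") * cfg$carbamidomethyl_mass +
    n_ox * cfg$oxidation_mass
}

# legal BS3 link sites of a digested peptide (full-length coordinates):
# internal K (a linked K cannot have been cleaved, so the C-terminal K of a
# peptide is excluded unless it is the protein C-terminus), plus the protein
# N-terminus when the peptide starts there.
.link_sites <- function(pep, protein_offset, protein_length) {
  ch <- strsplit(pep$sequence, "")[[1]]
  ks <- which(ch == "K") + pep$start - 1L
  prot_cterm <- protein_offset + protein_length - 1L
  ks <- ks[ks < pep$end | pep$end == prot_cterm]
  if (pep$start == protein_offset) ks <- unique(c(pep$start, ks))
  sort(ks)
}

## ---- candidates ------------------------------------------------------------

.neutral_precursor <- function(scan, cfg) {
  scan$precursor_mz * scan$charge - scan$charge * cfg$proton_mass
}

#' Enumerate precursor-matched cross-link and dead-end candidates
#'
#' For a scan with neutral precursor mass M, emits every peptide pair with
#' legal lysine (or protein N-terminus) link sites satisfying
#' `|mA + mB + bridge - M| / M <= ms1_tol_ppm`, every single-peptide
#' explanation carrying one BS3-water or BS3-ammonia dead-end, and plain
#' linear peptides. Met-oxidation positions are enumerated explicitly up to
#' `max_oxidations` per candidate so that downstream fragment masses stay
#' exact.
#'
#' @param peps_a,peps_b Digest tables from [digest()] of the two proteins
#'   (may be the same object for homodimeric links).
#' @param scan A `scan`.
#' @param cfg An `xlms_config`.
#' @return List of candidate objects (class `xl_candidate`): fields type
#'   (`crosslink`, `deadend_water`, `deadend_ammonia`, `linear`), pep_a,
#'   pep_b (NULL for single-peptide types), site_a, site_b, ox_a, ox_b
#'   (full-length positions of oxidized Met), neutral_mass,
#'   precursor_error_ppm.
#' @export
enumerate_candidates <- function(peps_a, peps_b, scan, cfg = xlms_config()) {
  M <- .neutral_precursor(scan, cfg)
  tol <- cfg$ms1_tol_ppm * 1e-6 * M
  out <- list()

  ix_a <- .digest_index(peps_a, cfg)
  ix_b <- if (identical(peps_a, peps_b)) ix_a else .digest_index(peps_b, cfg)

  push <- function(type, pa, pb, sa, sb, oa, ob, mass) {
    err <- (mass - M) / M * 1e6
    out[[length(out) + 1L]] <<- structure(
      list(type = type, pep_a = pa, pep_b = pb, site_a = sa, site_b = sb,
           ox_a = oa, ox_b = ob, neutral_mass = mass,
           precursor_error_ppm = err),
      class = "xl_candidate")
  }

  # cross-links: vectorized precursor-mass prefilter over all peptide pairs,
  # allowing up to max_oxidations oxygens on top of the base pair mass
  ox_mass <- cfg$oxidation_mass
  max_ox <- cfg$max_oxidations
  base <- outer(ix_a$masses, ix_b$masses, "+") + cfg$bridge_mass
  hits <- which(base >= M - max_ox * ox_mass - tol & base <= M + tol,
                arr.ind = TRUE)
  for (h in seq_len(nrow(hits))) {
    i <- hits[h, 1]; j <- hits[h, 2]
    sites_a <- ix_a$sites[[i]]
    sites_b <- ix_b$sites[[j]]
    if (!length(sites_a) || !length(sites_b)) next
    # the oxidation count is fixed by the mass gap; only matching splits run
    k <- round((M - base[i, j]) / ox_mass)
    if (k < 0L || k > max_ox) next
    mass <- base[i, j] + k * ox_mass
    if (abs(mass - M) > tol) next
    for (ka in 0:k) {
      oa_list <- ix_a$ox_by_k[[i]][[ka + 1L]]
      ob_list <- ix_b$ox_by_k[[j]][[k - ka + 1L]]
      if (is.null(oa_list) || is.null(ob_list)) next
      for (oa in oa_list) for (ob in ob_list) {
        for (sa in sites_a) for (sb in sites_b) {
          push("crosslink", ix_a$rows[[i]], ix_b$rows[[j]], sa, sb, oa, ob,
               mass)
        }
      }
    }
  }

  # dead-ends and linear peptides (single-peptide explanations)
  singles <- function(ix) {
    near <- which(ix$masses >= M - 2 * cfg$deadend_water_mass -
                    cfg$max_oxidations * cfg$oxidation_mass - tol &
                  ix$masses <= M + tol)
    for (i in near) {
      p <- ix$rows[[i]]
      sites <- ix$sites[[i]]
      for (oa in ix$ox_sets[[i]]) {
        m0 <- ix$masses[i] + length(oa) * cfg$oxidation_mass
        if (abs(m0 - M) <= tol) {
          push("linear", p, NULL, NA_integer_, NA_integer_, oa, integer(0), m0)
        }
        if (length(sites)) {
          for (dd in c("deadend_water", "deadend_ammonia")) {
            dm <- m0 + if (dd == "deadend_water") cfg$deadend_water_mass else
              cfg$deadend_ammonia_mass
            if (abs(dm - M) <= tol) {
              for (sa in sites) {
                push(dd, p, NULL, sa, NA_integer_, oa, integer(0), dm)
              }
            }
          }
        }
      }
    }
  }
  singles(ix_a)
  if (!identical(peps_a, peps_b)) singles(ix_b)
  out
}

# precomputed per-peptide view of a digest: plain list rows, neutral base
# masses, legal link sites and candidate Met-oxidation position sets
.digest_index <- function(peps, cfg) {
  po <- attr(peps, "protein_offset"); pl <- attr(peps, "protein_length")
  n <- nrow(peps)
  rows <- vector("list", n)
  sites <- vector("list", n)
  ox_sets <- vector("list", n)
  ox_by_k <- vector("list", n)
  masses <- numeric(n)
  for (i in seq_len(n)) {
    row <- list(protein_id = peps$protein_id[i], sequence = peps$sequence[i],
                start = peps$start[i], end = peps$end[i],
                missed = peps$missed[i])
    rows[[i]] <- row
    masses[i] <- peptide_mass(row$sequence, 0L, cfg)
    sites[[i]] <- .link_sites(row, po, pl)
    ch <- strsplit(row$sequence, "")[[1]]
    mpos <- which(ch == "M") + row$start - 1L
    by_k <- vector("list", cfg$max_oxidations + 1L)
    by_k[[1L]] <- list(integer(0))
    if (length(mpos) && cfg$max_oxidations > 0L) {
      for (k in seq_len(min(cfg$max_oxidations, length(mpos)))) {
        by_k[[k + 1L]] <- utils::combn(mpos, k, simplify = FALSE)
      }
    }
    ox_by_k[[i]] <- by_k
    ox_sets[[i]] <- unlist(by_k, recursive = FALSE)
  }
  list(rows = rows, masses = masses, sites = sites, ox_sets = ox_sets,
       ox_by_k = ox_by_k)
}

## ---- fragments and validation ----------------------------------------------

# neutral prefix masses of a peptide with mods applied per residue
.residue_mass_vector <- function(pep, ox_positions, cfg) {
  ch <- strsplit(pep$sequence, "")[[1]]
  m <- .residue_mass_tab[ch]
  m[ch == "C"] <- m[ch == "C"] + cfg$carbamidomethyl_mass
  local_ox <- ox_positions - pep$start + 1L
  m[local_ox] <- m[local_ox] + cfg$oxidation_mass
  unname(m)
}

.fragments_one <- function(pep, ox, link_local, partner_extra, origin, cfg) {
  rm <- .residue_mass_vector(pep, ox, cfg)
  n <- length(rm)
  if (n < 2L) {
    return(data.frame(series = character(0), ordinal = integer(0),
                      peptide = character(0), charge = integer(0),
                      mz = numeric(0), stringsAsFactors = FALSE))
  }
  pre <- cumsum(rm)
  i <- seq_len(n - 1L)
  b_neutral <- pre[i]
  y_neutral <- pre[n] - pre[n - i] + cfg$water_mass
  if (!is.na(link_local)) {
    b_neutral <- b_neutral + (link_local <= i) * partner_extra
    y_neutral <- y_neutral + (link_local >= n - i + 1L) * partner_extra
  }
  zs <- seq_len(cfg$max_fragment_charge)
  neutral <- c(rep(b_neutral, length(zs)), rep(y_neutral, length(zs)))
  series <- rep(c("b", "y"), each = (n - 1L) * length(zs))
  ordinal <- rep(rep(i, length(zs)), 2L)
  charge <- rep(rep(zs, each = n - 1L), 2L)
  data.frame(series = series, ordinal = ordinal, peptide = origin,
             charge = charge, mz = (neutral + charge * cfg$proton_mass) / charge,
             stringsAsFactors = FALSE)
}

#' Theoretical b/y fragment ions of a candidate
#'
#' For each peptide of a cross-link candidate, all b_i and y_i ions
#' (i = 1..n-1) at charges 1..`max_fragment_charge`; ions spanning the linked
#' residue carry the partner peptide's mass plus the BS3 bridge as a
#' modification. Dead-end candidates carry the dead-end mass on site-spanning
#' ions; linear candidates are unmodified.
#'
#' @param cand An `xl_candidate`.
#' @param cfg An `xlms_config`.
#' @return `data.frame`: series (b/y), ordinal, peptide (`A`/`B`), charge,
#'   mz.
#' @export
theoretical_fragments <- function(cand, cfg = xlms_config()) {
  local_site <- function(pep, site) {
    if (is.na(site)) NA_integer_ else site - pep$start + 1L
  }
  if (cand$type == "crosslink") {
    mass_a <- peptide_mass(cand$pep_a$sequence, length(cand$ox_a), cfg)
    mass_b <- peptide_mass(cand$pep_b$sequence, length(cand$ox_b), cfg)
    fa <- .fragments_one(cand$pep_a, cand$ox_a,
                         local_site(cand$pep_a, cand$site_a),
                         mass_b + cfg$bridge_mass, "A", cfg)
    fb <- .fragments_one(cand$pep_b, cand$ox_b,
                         local_site(cand$pep_b, cand$site_b),
                         mass_a + cfg$bridge_mass, "B", cfg)
    rbind(fa, fb)
  } else {
    extra <- switch(cand$type,
                    deadend_water = cfg$deadend_water_mass,
                    deadend_ammonia = cfg$deadend_ammonia_mass,
                    linear = 0)
    .fragments_one(cand$pep_a, cand$ox_a,
                   if (cand$type == "linear") NA_integer_ else
                     local_site(cand$pep_a, cand$site_a),
                   extra, "A", cfg)
  }
}

#' Match fragments against a scan and apply the approval rule
#'
#' A theoretical ion is matched when at least one peak lies within
#' `ms2_tol_da`. A cross-link candidate is approved iff each of its two
#' peptides has at least `min_ions_per_peptide` matched b/y ions (the
#' both-peptides rule); single-peptide candidates are approved when the one
#' peptide reaches the floor.
#'
#' @param scan A `scan`.
#' @param cand An `xl_candidate`.
#' @param cfg An `xlms_config`.
#' @return The candidate with added fields `matched` (per-peptide b/y counts),
#'   `n_matched` (total) and `approved`.
#' @export
validate_and_score <- function(scan, cand, cfg = xlms_config()) {
  frags <- theoretical_fragments(cand, cfg)
  mz <- scan$peaks[, 1]
  hit <- vapply(frags$mz, function(m) any(abs(mz - m) <= cfg$ms2_tol_da),
                logical(1))
  # an ion is counted once even if seen at both charges
  key <- paste(frags$series, frags$ordinal, frags$peptide)
  matched_keys <- unique(key[hit])
  counts <- c(bA = 0L, yA = 0L, bB = 0L, yB = 0L)
  for (k in matched_keys) {
    parts <- strsplit(k, " ")[[1]]
    nm <- paste0(parts[1], parts[3])
    counts[nm] <- counts[nm] + 1L
  }
  cand$matched <- counts
  cand$n_matched <- sum(counts)
  per_a <- counts["bA"] + counts["yA"]
  per_b <- counts["bB"] + counts["yB"]
  cand$approved <- if (cand$type == "crosslink") {
    per_a >= cfg$min_ions_per_peptide && per_b >= cfg$min_ions_per_peptide
  } else {
    per_a >= cfg$min_ions_per_peptide
  }
  cand
}

#' Full cross-link search over an MGF scan set
#'
#' Filter, digest both proteins, enumerate candidates per retained scan,
#' validate and rank (total matched ions, ties by absolute ppm error, then
#' by peptide sequences for determinism).
#'
#' @param scans List of `scan`s (e.g. from [read_mgf()]).
#' @param prot_a,prot_b `seq_record`s of the two proteins.
#' @param cfg An `xlms_config`.
#' @return `data.frame` of scored candidates (one row per candidate with
#'   rank within its scan); attribute `counts` carries the filter-stage and
#'   candidate counts.
#' @export
search_crosslinks <- function(scans, prot_a, prot_b, cfg = xlms_config()) {
  kept <- filter_scans(scans, cfg)
  counts <- attr(kept, "counts")
  peps_a <- digest(prot_a, cfg)
  peps_b <- digest(prot_b, cfg)
  rows <- list()
  n_cand <- 0L
  for (s in kept) {
    cands <- enumerate_candidates(peps_a, peps_b, s, cfg)
    n_cand <- n_cand + length(cands)
    if (!length(cands)) next
    cands <- lapply(cands, function(cd) validate_and_score(s, cd, cfg))
    score <- vapply(cands, function(cd) cd$n_matched, numeric(1))
    errs <- vapply(cands, function(cd) abs(cd$precursor_error_ppm), numeric(1))
    seqs <- vapply(cands, function(cd)
      paste(cd$pep_a$sequence, if (is.null(cd$pep_b)) "" else cd$pep_b$sequence),
      character(1))
    ord <- order(-score, errs, seqs)
    for (r in seq_along(ord)) {
      cd <- cands[[ord[r]]]
      rows[[length(rows) + 1L]] <- data.frame(
        scan_title = s$title, type = cd$type,
        pep_a = cd$pep_a$sequence,
        start_a = cd$pep_a$start, end_a = cd$pep_a$end,
        pep_b = if (is.null(cd$pep_b)) NA_character_ else cd$pep_b$sequence,
        start_b = if (is.null(cd$pep_b)) NA_integer_ else cd$pep_b$start,
        end_b = if (is.null(cd$pep_b)) NA_integer_ else cd$pep_b$end,
        site_a = cd$site_a, site_b = cd$site_b,
        n_ox = length(cd$ox_a) + length(cd$ox_b),
        error_ppm = cd$precursor_error_ppm,
        matched_b_a = cd$matched[["bA"]], matched_y_a = cd$matched[["yA"]],
        matched_b_b = cd$matched[["bB"]], matched_y_b = cd$matched[["yB"]],
        approved = cd$approved, rank = r,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(res, "counts") <- c(counts, candidates = n_cand)
  res
}
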