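## Ground-truthed generators: ortholog families with planted conservation
## structure, MGF spectra of known BS3 cross-links, and synthetic stand-ins
## for the reference proteins (built in code; no real database sequences are
## shipped).

.default_clades <- function(n_species = 6L, divergence = 0.05) {
  data.frame(
    name = c("Saccharomycotina", "Pezizomycotina", "Taphrinomycotina",
             "Basidiomycota", "Monokaryotic"),
    n_species = n_species,
    divergence = divergence,
    stringsAsFactors = FALSE)
}

#' Family simulator configuration
#'
#' Describes two paralogous ortholog groups (PP1 and PPZ) evolved over a
#' star-of-stars clade structure with planted difference columns. Defaults
#' emulate the analyzed data set's shape: five clades, ~30 species per
#' group, a catalytic-domain-sized alignment, and per-site substitution
#' probability 0.05 on species branches. Clade-root branches carry no
#' substitutions by default (`clade_divergence = 0`): shared clade-level
#' substitutions would create honestly-classified difference columns that
#' are not in the planted truth, which is exactly what a ground-truthed
#' generator must avoid (see the methods vignette).
#'
#' @param clades `data.frame` with columns name, n_species, divergence.
#' @param ncol Alignment length (default 340, a catalytic-domain size).
#' @param n_class_a,n_class_b,n_class_c,n_class_d Numbers of planted columns
#'   per difference class.
#' @param n_charge_swap Planted class A columns that are also acidic/basic
#'   charge swaps (e.g. K in PP1 vs D in PPZ).
#' @param clade_divergence Substitution probability on clade-root branches
#'   (default 0).
#' @param background One of `"simgroup"` (substitutions stay within the
#'   similarity group, conservative noise) or `"uniform"`.
#' @param seed Integer seed; all randomness flows from it.
#' @return List of class `family_sim_config`.
#' @export
family_sim_config <- function(clades = .default_clades(),
                              ncol = 340L,
                              n_class_a = 8L, n_class_b = 8L,
                              n_class_c = 4L, n_class_d = 4L,
                              n_charge_swap = 4L,
                              clade_divergence = 0,
                              background = c("simgroup", "uniform"),
                              seed = 1L) {
  background <- match.arg(background)
  stopifnot(all(clades$divergence >= 0 & clades$divergence < 1))
  structure(list(clades = clades, ncol = as.integer(ncol),
                 n_class_a = n_class_a, n_class_b = n_class_b,
                 n_class_c = n_class_c, n_class_d = n_class_d,
                 n_charge_swap = n_charge_swap,
                 clade_divergence = clade_divergence,
                 background = background, seed = as.integer(seed)),
            class = "family_sim_config")
}

# residues spread over 8 distinct similarity groups; cycling through them
# guarantees dominant frequency <= ceil(n/8)/n and similarity-group
# frequency well below any conservation threshold
.variable_pool <- c("G", "A", "S", "D", "K", "F", "P", "N")

#' Simulate a labelled two-group ortholog family with planted truth
#'
#' Draws a uniform ancestral sequence, evolves per-species copies for both
#' groups over the clade structure, then forces planted columns to their
#' class pattern: class A, two different (different-similarity-group)
#' residues fixed in PP1 vs PPZ; class B, fixed in PP1, per-sequence
#' variable in PPZ (cycling over 8 residues from 8 similarity groups);
#' class C the mirror; class D, the class A pattern inside one clade only;
#' charge-swap columns, class A with an acidic/basic pair. Planted columns
#' are noise-free; everything else mutates at the clade's divergence.
#'
#' @param cfg A `family_sim_config`.
#' @return List with `ags` (an [aligned_group_set()]) and `truth`
#'   (`data.frame`: column, class, clade, pp1_residue, ppz_residue,
#'   charge_pp1, charge_ppz).
#' @export
simulate_family <- function(cfg = family_sim_config()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)

  n_planted <- cfg$n_class_a + cfg$n_class_b + cfg$n_class_c +
    cfg$n_class_d + cfg$n_charge_swap
  if (n_planted > cfg$ncol) stop("more planted columns than alignment columns")
  planted_cols <- sort(sample.int(cfg$ncol, n_planted))
  split_idx <- rep(c("A", "B", "C", "D", "swap"),
                   times = c(cfg$n_class_a, cfg$n_class_b, cfg$n_class_c,
                             cfg$n_class_d, cfg$n_charge_swap))
  split_idx <- sample(split_idx)   # classes scattered over the columns
  simgroup <- .simgroup_of(conservation_config())

  ancestor <- sample(.aa20, cfg$ncol, replace = TRUE)

  # species table
  clades <- cfg$clades
  sp <- do.call(rbind, lapply(seq_len(nrow(clades)), function(i) {
    do.call(rbind, lapply(c("PP1", "PPZ"), function(g) {
      data.frame(seq_id = sprintf("%s_%s_sp%02d", g, clades$name[i],
                                  seq_len(clades$n_species[i])),
                 group = g, clade = clades$name[i],
                 divergence = clades$divergence[i],
                 stringsAsFactors = FALSE)
    }))
  }))

  mutate <- function(chars, p) {
    hit <- which(stats::runif(length(chars)) < p)
    for (k in hit) {
      if (cfg$background == "simgroup") {
        pool <- setdiff(default_similarity_groups()[[simgroup[[chars[k]]]]],
                        chars[k])
        if (!length(pool)) next
      } else {
        pool <- setdiff(.aa20, chars[k])
      }
      chars[k] <- if (length(pool) == 1L) pool else sample(pool, 1L)
    }
    chars
  }

  clade_roots <- list()
  for (cl in clades$name) {
    clade_roots[[cl]] <- mutate(ancestor, cfg$clade_divergence)
  }

  seqs <- matrix("", nrow = nrow(sp), ncol = cfg$ncol)
  for (i in seq_len(nrow(sp))) {
    seqs[i, ] <- mutate(clade_roots[[sp$clade[i]]], sp$divergence[i])
  }

  pick_pair <- function() {
    g1 <- sample(names(default_similarity_groups()), 2L)
    c(sample(default_similarity_groups()[[g1[1]]], 1L),
      sample(default_similarity_groups()[[g1[2]]], 1L))
  }
  charge_pairs <- list(c("K", "D"), c("R", "E"), c("D", "K"), c("E", "R"))
  charge_of <- .charge_of(conservation_config())

  truth <- list()
  d_clade_pool <- clades$name[clades$n_species >= 3L]
  for (t in seq_along(planted_cols)) {
    j <- planted_cols[t]
    kind <- split_idx[t]
    is_pp1 <- sp$group == "PP1"
    clade_used <- NA_character_
    if (kind == "A" || kind == "swap") {
      pair <- if (kind == "swap") {
        charge_pairs[[sample.int(length(charge_pairs), 1L)]]
      } else pick_pair()
      seqs[is_pp1, j] <- pair[1]
      seqs[!is_pp1, j] <- pair[2]
      r1 <- pair[1]; rz <- pair[2]
      kind <- "A"
    } else if (kind == "B") {
      r1 <- sample(.aa20, 1L)
      seqs[is_pp1, j] <- r1
      nz <- sum(!is_pp1)
      seqs[!is_pp1, j] <- rep_len(sample(.variable_pool), nz)
      rz <- NA_character_
    } else if (kind == "C") {
      rz <- sample(.aa20, 1L)
      seqs[!is_pp1, j] <- rz
      n1 <- sum(is_pp1)
      seqs[is_pp1, j] <- rep_len(sample(.variable_pool), n1)
      r1 <- NA_character_
    } else { # D
      pair <- pick_pair()
      clade_used <- sample(d_clade_pool, 1L)
      inside <- sp$clade == clade_used
      seqs[, j] <- pair[1]
      seqs[!is_pp1 & inside, j] <- pair[2]
      r1 <- pair[1]; rz <- pair[2]
    }
    truth[[t]] <- data.frame(
      column = j, class = kind, clade = clade_used,
      pp1_residue = r1, ppz_residue = rz,
      charge_pp1 = if (is.na(r1)) NA_character_ else charge_of[[r1]],
      charge_ppz = if (is.na(rz)) NA_character_ else charge_of[[rz]],
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(column = integer(0), class = character(0),
               clade = character(0), pp1_residue = character(0),
               ppz_residue = character(0), charge_pp1 = character(0),
               charge_ppz = character(0), stringsAsFactors = FALSE)
  truth <- truth[order(truth$column), , drop = FALSE]

  records <- lapply(seq_len(nrow(sp)), function(i) {
    seq_record(sp$seq_id[i], paste(seqs[i, ], collapse = ""), aligned = TRUE)
  })
  list(ags = aligned_group_set(records, sp[c("seq_id", "group", "clade")]),
       truth = truth)
}

## ---- synthetic reference stand-ins ----------------------------------------

#' Synthetic stand-ins for the reference proteins
#'
#' Builds three synthetic proteins that reproduce, by construction, the
#' coordinate geometry of the real reference system without shipping any
#' database sequence: a 312-residue PP1-like catalytic subunit ("Glc7"
#' stand-in); a 692-residue PPZ-like protein ("Ppz1" stand-in) consisting of
#' a random 358-residue N-terminal extension, a conservatively mutated copy
#' of the PP1 stand-in's residues 3..312 (so PP1 position p sits at PPZ
#' position 356 + p; K210/K259 in the PP1 stand-in become D566/D615), a
#' 24-residue tail, and lysines planted at the published cross-linked
#' positions; and a 562-residue inhibitor ("Hal3" stand-in) with the
#' RVxF-like motif KLHVLF planted at 263 and lysines at the published
#' partner positions. These are synthetic test articles, not biological
#' sequences.
#'
#' @param seed Integer seed.
#' @param core_identity Fraction of core positions kept identical between the
#'   PP1 and PPZ stand-ins (default 0.7, conservative substitutions
#'   elsewhere).
#' @return List with `seq_record`s `glc7`, `ppz1`, `hal3`.
#' @export
synthetic_reference_proteins <- function(seed = 101L, core_identity = 0.7) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  simgroup <- .simgroup_of(conservation_config())
  groups <- default_similarity_groups()

  glc7 <- sample(.aa20, 312L, replace = TRUE)
  glc7[210] <- "K"; glc7[259] <- "K"

  core <- glc7[3:312]
  flip <- which(stats::runif(length(core)) > core_identity)
  for (k in flip) {
    pool <- setdiff(groups[[simgroup[[core[k]]]]], core[k])
    if (length(pool)) core[k] <- pool[sample.int(length(pool), 1L)]
  }
  # anchors: PP1 K210/K259 are D in the PPZ-like core (full-length 566/615)
  core[210 - 2] <- "D"
  core[259 - 2] <- "D"
  nterm <- sample(.aa20, 358L, replace = TRUE)
  tail <- sample(.aa20, 24L, replace = TRUE)
  ppz1 <- c(nterm, core, tail)
  ppz1_k <- c(356L, 358L, 359L, 378L, 381L, 396L, 433L, 453L, 468L,
              496L, 502L, 584L, 589L, 664L)
  ppz1[ppz1_k] <- "K"
  stopifnot(ppz1[566] == "D", ppz1[615] == "D", length(ppz1) == 692L)

  hal3 <- sample(.aa20, 562L, replace = TRUE)
  hal3[263:268] <- strsplit("KLHVLF", "")[[1]]
  hal3_k <- c(29L, 39L, 41L, 90L, 113L, 197L, 201L, 210L, 236L, 280L,
              315L, 316L, 323L, 483L)
  hal3[hal3_k] <- "K"

  list(
    glc7 = seq_record("synthetic_Glc7", paste(glc7, collapse = "")),
    ppz1 = seq_record("synthetic_Ppz1", paste(ppz1, collapse = "")),
    hal3 = seq_record("synthetic_Hal3", paste(hal3, collapse = "")))
}

## ---- cross-link spectrum simulator ----------------------------------------

#' Cross-link spectrum simulator configuration
#'
#' @param prot_a,prot_b `seq_record`s of the two proteins (default: the
#'   synthetic PPZ stand-in trimmed to its catalytic construct, and the
#'   synthetic inhibitor stand-in).
#' @param true_links Two-column matrix/data.frame of (site_a, site_b)
#'   full-length lysine positions to cross-link.
#' @param noise_peaks_per_scan Uniform random peaks added per scan
#'   (default 0).
#' @param decoy_scans Number of charge-2 decoy scans (rejected by the charge
#'   filter) to append (default 0).
#' @param mass_jitter_ppm Gaussian ppm jitter on precursor masses
#'   (default 0: precursors exact).
#' @param xcfg An [xlms_config()] supplying masses and signature peaks.
#' @param seed Integer seed.
#' @return List of class `xlms_sim_config`.
#' @export
xlms_sim_config <- function(prot_a = NULL, prot_b = NULL,
                            true_links = NULL,
                            noise_peaks_per_scan = 0L,
                            decoy_scans = 0L,
                            mass_jitter_ppm = 0,
                            xcfg = xlms_config(),
                            seed = 1L) {
  if (is.null(prot_a) || is.null(prot_b)) {
    refs <- synthetic_reference_proteins()
    if (is.null(prot_a)) prot_a <- trim_to_domain(refs$ppz1, 345L)
    if (is.null(prot_b)) prot_b <- refs$hal3
  }
  if (is.null(true_links)) {
    true_links <- data.frame(site_a = c(358L, 396L, 433L, 584L, 589L),
                             site_b = c(29L, 236L, 210L, 90L, 90L))
  }
  true_links <- as.data.frame(true_links)
  names(true_links) <- c("site_a", "site_b")
  structure(list(prot_a = prot_a, prot_b = prot_b, true_links = true_links,
                 noise_peaks_per_scan = as.integer(noise_peaks_per_scan),
                 decoy_scans = as.integer(decoy_scans),
                 mass_jitter_ppm = mass_jitter_ppm,
                 xcfg = xcfg, seed = as.integer(seed)),
            class = "xlms_sim_config")
}

# smallest legal peptide of the digest covering a link site
.covering_peptide <- function(peps, site, po, pl) {
  ok <- peps$start <= site & peps$end >= site
  cand <- peps[ok, , drop = FALSE]
  legal <- vapply(seq_len(nrow(cand)), function(i)
    site %in% .link_sites(cand[i, ], po, pl), logical(1))
  cand <- cand[legal, , drop = FALSE]
  if (!nrow(cand)) stop("site ", site, " not coverable by any legal peptide")
  cand[order(cand$end - cand$start, cand$missed), ][1, ]
}

#' Simulate MGF spectra of known BS3 cross-links
#'
#' For each true link, picks the smallest legal tryptic peptide pair covering
#' the sites, computes the exact cross-linked precursor mass, and emits a
#' scan at a random charge in the configured retention range containing both
#' peptides' full b/y series (charges 1..2, cross-linker arithmetic
#' included), the configured y1 and linker signature peaks, and optional
#' uniform noise peaks. Decoy scans are emitted at charge 2 so the charge
#' filter must remove them. Deterministic given the seed; the written MGF is
#' byte-identical across reruns.
#'
#' @param cfg An `xlms_sim_config`.
#' @return List with `scans` (list of `scan`s) and `truth` (`data.frame`:
#'   title, pep_a, pep_b, site_a, site_b).
#' @export
simulate_xlms <- function(cfg = xlms_sim_config()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  x <- cfg$xcfg
  peps_a <- digest(cfg$prot_a, x)
  peps_b <- digest(cfg$prot_b, x)
  po_a <- attr(peps_a, "protein_offset"); pl_a <- attr(peps_a, "protein_length")
  po_b <- attr(peps_b, "protein_offset"); pl_b <- attr(peps_b, "protein_length")

  scans <- list(); truth <- list()
  for (i in seq_len(nrow(cfg$true_links))) {
    sa <- cfg$true_links$site_a[i]; sb <- cfg$true_links$site_b[i]
    pa <- .covering_peptide(peps_a, sa, po_a, pl_a)
    pb <- .covering_peptide(peps_b, sb, po_b, pl_b)
    mass <- peptide_mass(pa$sequence, 0L, x) + peptide_mass(pb$sequence, 0L, x) +
      x$bridge_mass
    if (cfg$mass_jitter_ppm > 0) {
      mass <- mass * (1 + stats::rnorm(1, 0, cfg$mass_jitter_ppm * 1e-6))
    }
    z <- sample(seq(x$charge_min, x$charge_max), 1L)
    cand <- structure(list(type = "crosslink", pep_a = pa, pep_b = pb,
                           site_a = sa, site_b = sb,
                           ox_a = integer(0), ox_b = integer(0),
                           neutral_mass = mass, precursor_error_ppm = 0),
                      class = "xl_candidate")
    frag_mz <- theoretical_fragments(cand, x)$mz
    mz <- c(frag_mz, unname(x$signature_y1_masses),
            unname(x$linker_signature_masses))
    if (cfg$noise_peaks_per_scan > 0L) {
      mz <- c(mz, stats::runif(cfg$noise_peaks_per_scan, 100, 1500))
    }
    intensity <- round(stats::runif(length(mz), 50, 1000), 2)
    ord <- order(mz)
    title <- sprintf("synthetic_xl_%03d", i)
    scans[[length(scans) + 1L]] <- structure(
      list(title = title,
           precursor_mz = (mass + z * x$proton_mass) / z,
           charge = z,
           peaks = cbind(mz = round(mz[ord], 5), intensity = intensity[ord])),
      class = "scan")
    truth[[i]] <- data.frame(title = title, pep_a = pa$sequence,
                             pep_b = pb$sequence, site_a = sa, site_b = sb,
                             stringsAsFactors = FALSE)
  }
  for (d in seq_len(cfg$decoy_scans)) {
    mz <- sort(stats::runif(30, 100, 1500))
    scans[[length(scans) + 1L]] <- structure(
      list(title = sprintf("synthetic_decoy_%03d", d),
           precursor_mz = stats::runif(1, 400, 900), charge = 2L,
           peaks = cbind(mz = round(mz, 5),
                         intensity = round(stats::runif(30, 50, 1000), 2))),
      class = "scan")
  }
  list(scans = scans, truth = do.call(rbind, truth))
}
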