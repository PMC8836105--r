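cfg <- conservation_config()

test_that("column profiles capture dominants, gaps and charge categories", {
  ags <- make_ags(pp1 = c("KA-", "KA-", "KAL"),
                  ppz = c("DAL", "DAL", "DGL"))
  prof <- column_profiles(ags, cfg)
  p1 <- prof[prof$column == 1 & prof$group == "PP1", ]
  pz <- prof[prof$column == 1 & prof$group == "PPZ", ]
  expect_equal(p1$dominant, "K"); expect_equal(p1$dominant_freq, 1)
  expect_equal(pz$dominant, "D"); expect_equal(pz$dominant_freq, 1)
  expect_equal(p1$basic, 1); expect_equal(pz$acidic, 1)
  # gap fractions and all-gap columns
  expect_equal(prof[prof$column == 3 & prof$group == "PP1", "gap_fraction"],
               2 / 3)
  all_gap <- make_ags(pp1 = c("A-", "A-"), ppz = c("AL", "AL"))
  pg <- column_profiles(all_gap, cfg)
  expect_true(is.na(pg[pg$column == 2 & pg$group == "PP1", "dominant"]))
  expect_equal(pg[pg$column == 2 & pg$group == "PP1", "gap_fraction"], 1)
  # charge frequencies sum to one on non-gap entries
  sums <- rowSums(prof[!is.na(prof$acidic), c("acidic", "basic", "neutral")])
  expect_equal(sums, rep(1, length(sums)), ignore_attr = TRUE)
  expect_error(column_profiles(make_ags("AA", c("AA", "AA"))), ">= 2 sequences")
})

test_that("conserved positions require unanimity and obey subset monotonicity", {
  ags <- make_ags(pp1 = c("ACDE", "ACDE", "ACDE"),
                  ppz = c("ACDE", "ACDE", "ACDE"))
  expect_equal(conserved_positions(ags, "PP1", cfg), 1:4)
  ags2 <- make_ags(pp1 = c("ACDE", "ACDE", "ACLE"),
                   ppz = c("AAAA", "AAAA", "AAAA"))
  expect_equal(conserved_positions(ags2, "PP1", cfg), c(1L, 2L, 4L))
  # dropping a clade can only grow the conserved set
  ags3 <- make_ags(pp1 = c("ACDE", "ACDE", "AKDE", "AKDE"),
                   ppz = rep("AAAA", 4),
                   clades_pp1 = c("C1", "C1", "C2", "C2"),
                   clades_ppz = c("C1", "C1", "C2", "C2"))
  all_c <- conserved_positions(ags3, "PP1", cfg)
  sub_c <- conserved_positions(
    ags3, "PP1", conservation_config(exclude_clades = "C2"))
  expect_true(all(all_c %in% sub_c))
})

test_that("classification follows the A/B/C/none rules and thresholds", {
  # class A with charge swap: unanimous K vs unanimous D
  ags_a <- make_ags(pp1 = rep("KLL", 3), ppz = rep("DLL", 3))
  cls <- classify_columns(column_profiles(ags_a, cfg), cfg)
  expect_equal(cls$class, c("A", "none", "none"))
  expect_equal(cls$swap_from[1], "basic")
  expect_equal(cls$swap_to[1], "acidic")
  expect_true(cls$swap_constant[1])

  # class B by hand application of the default thresholds:
  # PP1 all G (1.0 >= 0.9); PPZ G:0.5 A:0.3 S:0.2 (0.5 < 0.7)
  ags_b <- make_ags(pp1 = rep("G", 10),
                    ppz = c(rep("G", 5), rep("A", 3), rep("S", 2)))
  cls_b <- classify_columns(column_profiles(ags_b, cfg), cfg)
  expect_equal(cls_b$class, "B")
  # class C is the mirror
  ags_c <- make_ags(pp1 = c(rep("G", 5), rep("A", 3), rep("S", 2)),
                    ppz = rep("G", 10))
  expect_equal(classify_columns(column_profiles(ags_c, cfg), cfg)$class, "C")
  # identical columns are class none
  ags_n <- make_ags(pp1 = rep("L", 4), ppz = rep("L", 4))
  expect_equal(classify_columns(column_profiles(ags_n, cfg), cfg)$class, "none")
  # same-similarity-group dominant flip without residue-level constancy
  # on both sides is not a difference (and not variable enough for B)
  ags_st <- make_ags(pp1 = rep("T", 6), ppz = c(rep("S", 5), rep("T", 1)))
  expect_equal(classify_columns(column_profiles(ags_st, cfg), cfg)$class,
               "none")
  # ...but two residue-invariant same-group dominants are class A (V vs I)
  ags_vi <- make_ags(pp1 = rep("V", 6), ppz = rep("I", 6))
  expect_equal(classify_columns(column_profiles(ags_vi, cfg), cfg)$class, "A")
})

test_that("class D needs a clade-restricted difference and enough sequences", {
  clades <- rep(c("C1", "C2", "C3", "C4"), each = 3)
  # PP1 all K; PPZ: D in clade C1 only, K elsewhere. Global PPZ dominant is
  # K at 9/12 = 0.75 (above theta_var, below theta_cons) so no global class
  # fires, but the A-style difference holds within C1
  ags <- make_ags(pp1 = rep("KAAA", 12),
                  ppz = c(rep("DAAA", 3), rep("KAAA", 9)),
                  clades_pp1 = clades, clades_ppz = clades)
  prof <- column_profiles(ags, cfg)
  cp <- clade_column_profiles(ags, cfg)
  cls <- classify_columns(prof, cfg, cp)
  expect_equal(cls$class[1], "D")
  expect_equal(cls$clade_restricted_to[1], "C1")
  # without clade profiles no D can be assigned
  expect_equal(classify_columns(prof, cfg)$class[1], "none")
  # clades below the sequence floor are skipped entirely
  cp_small <- clade_column_profiles(
    ags, conservation_config(min_clade_seqs = 4L))
  expect_true(all(vapply(cp_small, is.null, logical(1))))
})

test_that("charge scan emits category changes with the constancy flag", {
  ags <- make_ags(pp1 = c("KED", "KEN", "KED"), ppz = c("DEN", "DEN", "DEN"))
  sw <- charge_change_scan(column_profiles(ags, cfg), cfg)
  # col1 basic->acidic constant; col2 same category (not emitted);
  # col3 acidic(2/3) vs neutral -> emitted, not constant
  expect_equal(sw$column, c(1L, 3L))
  expect_equal(sw$change[1], "basic->acidic")
  expect_true(sw$constant[1])
  expect_equal(sw$change[2], "acidic->neutral")
  expect_false(sw$constant[2])
  # all-E vs all-E not emitted; all-D vs all-N emitted and constant
  ags2 <- make_ags(pp1 = c("ED", "ED"), ppz = c("EN", "EN"))
  sw2 <- charge_change_scan(column_profiles(ags2, cfg), cfg)
  expect_equal(sw2$column, 2L)
  expect_equal(sw2$change, "acidic->neutral")
  expect_true(sw2$constant)
})

test_that("motif report reproduces the printed identity/conservation ratios", {
  # 26 columns: group consensus identical at 19, similar-only at 4,
  # different at 3 relative to the reference -> 73.1% / 88.5%
  ref <- paste(rep("L", 26), collapse = "")
  similar <- c(20, 21, 22, 23)   # L -> I (same aliphatic group)
  radical <- c(24, 25, 26)       # L -> G
  ppz <- strsplit(ref, "")[[1]]
  ppz[similar] <- "I"; ppz[radical] <- "G"
  ppz <- paste(ppz, collapse = "")
  ags <- make_ags(pp1 = rep(ref, 2), ppz = rep(ppz, 2))
  rep_out <- motif_report(ags, 1:26, "pp1_01", cfg)
  pz <- rep_out[rep_out$group == "PPZ", ]
  expect_equal(pz$identity_pct, 100 * 19 / 26, tolerance = 1e-6)
  expect_equal(pz$conservation_pct, 100 * 23 / 26, tolerance = 1e-6)
  p1 <- rep_out[rep_out$group == "PP1", ]
  expect_equal(p1$identity_pct, 100)
  expect_equal(p1$conservation_pct, 100)
  expect_error(motif_report(ags, c(1, 40), "pp1_01", cfg), "outside")
  expect_error(motif_report(ags, 1:3, "nope", cfg), "reference")
})

test_that("Shannon logo matrix matches the closed forms", {
  ags <- make_ags(pp1 = rep("AL", 10),
                  ppz = c(rep("LL", 5), rep("LV", 5)))
  lm <- shannon_logo_matrix(ags, "PP1", 1:2)
  ic <- attr(lm, "ic")
  expect_equal(ic[1], log2(20), tolerance = 1e-12)       # invariant column
  expect_equal(lm["A", 1], log2(20), tolerance = 1e-12)
  # 50/50 two-residue column: IC = log2(20) - 1, heights split evenly
  lmz <- shannon_logo_matrix(ags, "PPZ", 2)
  expect_equal(attr(lmz, "ic")[1], log2(20) - 1, tolerance = 1e-12)
  expect_equal(lmz["L", 1], (log2(20) - 1) / 2, tolerance = 1e-12)
  expect_equal(lmz["V", 1], (log2(20) - 1) / 2, tolerance = 1e-12)
  # uniform over the 20 residues -> IC 0
  u <- make_ags(pp1 = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                ppz = rep("A", 20))
  expect_equal(attr(shannon_logo_matrix(u, "PP1", 1), "ic")[1], 0,
               tolerance = 1e-12)
})

test_that("pairwise identity counts mutually non-gap matches", {
  ags <- make_ags(pp1 = c("ACDE", "ACDK"), ppz = c("AC-E", "ACDE"))
  m <- pairwise_identity(ags, "PP1")
  expect_equal(m["pp1_01", "pp1_02"], 0.75)
  expect_equal(diag(m), c(1, 1), ignore_attr = TRUE)
  expect_true(isSymmetric(m))
  mz <- pairwise_identity(ags, "PPZ")
  expect_equal(mz["ppz_01", "ppz_02"], 1)  # gap column excluded
  s <- divergence_summary(m)
  expect_equal(s$mean, 0.75)
})

test_that("neighbor joining matches closed forms and recovers quartets", {
  # two taxa: even split
  d2 <- matrix(c(0, .2, .2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(nj_tree(d2), "(A:0.1,B:0.1);")
  # three taxa: closed-form branch lengths
  dab <- 0.3; dac <- 0.5; dbc <- 0.6
  d3 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d3["A", "B"] <- d3["B", "A"] <- dab
  d3["A", "C"] <- d3["C", "A"] <- dac
  d3["B", "C"] <- d3["C", "B"] <- dbc
  nwk <- nj_tree(d3)
  tr <- ape::read.tree(text = nwk)
  bl <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                 tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(bl[["A"]], (dab + dac - dbc) / 2, tolerance = 1e-9)
  expect_equal(bl[["B"]], (dab + dbc - dac) / 2, tolerance = 1e-9)
  expect_equal(bl[["C"]], (dac + dbc - dab) / 2, tolerance = 1e-9)
  # four taxa from random additive trees: topology vs the split oracle
  set.seed(42)
  for (rep in 1:25) {
    v <- runif(5, 0.05, 1)   # a, b, m, c, d
    taxa <- c("A", "B", "C", "D")
    d4 <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
    d4["A", "B"] <- v[1] + v[2]
    d4["A", "C"] <- v[1] + v[3] + v[4]
    d4["A", "D"] <- v[1] + v[3] + v[5]
    d4["B", "C"] <- v[2] + v[3] + v[4]
    d4["B", "D"] <- v[2] + v[3] + v[5]
    d4["C", "D"] <- v[4] + v[5]
    d4 <- d4 + t(d4)
    got <- quartet_split_from_newick(nj_tree(d4))
    want <- oracle_quartet_split(d4)
    want <- want[order(vapply(want, paste, character(1), collapse = ","))]
    expect_equal(got, want)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("class counts respond monotonically to a stricter theta_cons", {
  sim <- simulate_family(family_sim_config(seed = 19))
  prof <- column_profiles(sim$ags, cfg)
  n_abc <- function(th) {
    c2 <- conservation_config(theta_cons = th)
    sum(classify_columns(prof, c2)$class %in% c("A", "B", "C"))
  }
  expect_gte(n_abc(0.90), n_abc(0.95))
  expect_gte(n_abc(0.95), n_abc(1.0))
})
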