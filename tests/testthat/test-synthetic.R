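test_that("family simulation is deterministic and honors planted truth", {
  cfg <- family_sim_config(seed = 5)
  s1 <- simulate_family(cfg)
  s2 <- simulate_family(cfg)
  expect_identical(lapply(s1$ags$records, `[[`, "residues"),
                   lapply(s2$ags$records, `[[`, "residues"))
  expect_identical(s1$truth, s2$truth)
  # planted columns disjoint, classes as configured
  expect_false(anyDuplicated(s1$truth$column) > 0)
  expect_equal(sum(s1$truth$class == "A"),
               cfg$n_class_a + cfg$n_charge_swap)
  expect_equal(sum(s1$truth$class == "D"), cfg$n_class_d)
})

test_that("zero divergence with no planting gives identical groups", {
  clades <- data.frame(name = c("C1", "C2"), n_species = 3L, divergence = 0)
  cfg <- family_sim_config(clades = clades, ncol = 50L, n_class_a = 0L,
                           n_class_b = 0L, n_class_c = 0L, n_class_d = 0L,
                           n_charge_swap = 0L, seed = 2)
  sim <- simulate_family(cfg)
  seqs <- vapply(sim$ags$records, `[[`, "", "residues")
  expect_length(unique(seqs), 1L)
  expect_equal(conserved_positions(sim$ags, "PP1"), 1:50)
  expect_equal(conserved_positions(sim$ags, "PPZ"), 1:50)
  cls <- classify_columns(column_profiles(sim$ags))
  expect_true(all(cls$class == "none"))
  expect_equal(nrow(sim$truth), 0L)
})

test_that("planted classes are recovered exactly at default divergence", {
  cfg <- family_sim_config(seed = 23)
  sim <- simulate_family(cfg)
  prof <- column_profiles(sim$ags)
  cp <- clade_column_profiles(sim$ags)
  cls <- classify_columns(prof, conservation_config(), cp)
  pred <- cls[cls$class != "none", c("column", "class")]
  truth <- sim$truth[, c("column", "class")]
  rownames(pred) <- rownames(truth) <- NULL
  expect_equal(pred, truth)
  # planted charge swaps all surface in the scan as constant changes
  swaps <- charge_change_scan(prof)
  # class D rows record within-clade charge pairs, which are not global
  # swaps; only globally planted (class A) category changes must surface
  planted_swaps <- sim$truth[sim$truth$class == "A" &
                               !is.na(sim$truth$charge_pp1) &
                               !is.na(sim$truth$charge_ppz) &
                               sim$truth$charge_pp1 != sim$truth$charge_ppz, ]
  expect_true(all(planted_swaps$column %in% swaps$column[swaps$constant]))
  # every constant charge-swap hit is a classified difference column
  expect_true(all(swaps$column[swaps$constant] %in%
                    cls$column[cls$class != "none"]))
})

test_that("per-column substitution frequency converges to the dial", {
  # law-of-large-numbers check: one clade, 200 species, uniform background
  clades <- data.frame(name = "C1", n_species = 200L, divergence = 0.08)
  cfg <- family_sim_config(clades = clades, ncol = 150L, n_class_a = 0L,
                           n_class_b = 0L, n_class_c = 0L, n_class_d = 0L,
                           n_charge_swap = 0L, background = "uniform",
                           seed = 31)
  sim <- simulate_family(cfg)
  mat <- do.call(rbind, lapply(sim$ags$records,
                               function(r) strsplit(r$residues, "")[[1]]))
  anc <- apply(mat, 2, function(col) names(sort(table(col),
                                                decreasing = TRUE))[1])
  sub_rate <- mean(t(mat) != anc)
  n <- length(mat)
  se <- sqrt(0.08 * 0.92 / n)
  expect_lt(abs(sub_rate - 0.08), 3 * se + 1 / ncol(mat)) # majority-vote bias margin
})

test_that("simulated spectra are exact, deterministic and filter-consistent", {
  cfg <- xlms_sim_config(decoy_scans = 3L, seed = 9)
  sim <- simulate_xlms(cfg)
  expect_length(sim$scans, nrow(cfg$true_links) + 3L)
  # precursor neutral mass equals pepA + pepB + bridge exactly
  x <- cfg$xcfg
  for (i in seq_len(nrow(sim$truth))) {
    s <- sim$scans[[i]]
    M <- s$precursor_mz * s$charge - s$charge * x$proton_mass
    want <- peptide_mass(sim$truth$pep_a[i], 0L, x) +
      peptide_mass(sim$truth$pep_b[i], 0L, x) + x$bridge_mass
    expect_equal(M, want, tolerance = 1e-6)
  }
  # charge filter retains exactly the true-link scans
  kept <- filter_scans(sim$scans, x)
  expect_equal(vapply(kept, `[[`, "", "title"), sim$truth$title)
  # byte-identical MGF on rerun
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_mgf(sim$scans, f1)
  write_mgf(simulate_xlms(cfg)$scans, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("unsatisfiable link sites are rejected", {
  prot <- seq_record("p", "AAAGGG")   # no lysine anywhere
  cfg <- xlms_sim_config(prot_a = prot, prot_b = prot,
                         true_links = data.frame(site_a = 2L, site_b = 2L),
                         seed = 1)
  expect_error(simulate_xlms(cfg), "not coverable")
})

test_that("synthetic reference proteins satisfy their construction contract", {
  refs <- synthetic_reference_proteins()
  refs2 <- synthetic_reference_proteins()
  expect_identical(refs$ppz1$residues, refs2$ppz1$residues)
  expect_equal(seq_length(refs$glc7), 312L)
  expect_equal(seq_length(refs$hal3), 562L)
  # planted lysines for the cross-link fixtures
  for (k in c(356, 358, 359, 378, 584, 664)) {
    expect_equal(substr(refs$ppz1$residues, k, k), "K")
  }
  for (k in c(29, 39, 90, 113, 315, 483)) {
    expect_equal(substr(refs$hal3$residues, k, k), "K")
  }
})
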