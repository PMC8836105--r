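xcfg <- xlms_config()

make_scan <- function(mz, charge = 4L, precursor_mz = 500, title = "t") {
  structure(list(title = title, precursor_mz = precursor_mz,
                 charge = as.integer(charge),
                 peaks = cbind(mz = sort(mz),
                               intensity = rep(100, length(mz)))),
            class = "scan")
}

scan_for_mass <- function(neutral, charge, mz = c(147.11, 500), ...) {
  make_scan(mz, charge,
            precursor_mz = (neutral + charge * xcfg$proton_mass) / charge, ...)
}

test_that("MGF read/write round-trips and flags malformed blocks", {
  scans <- list(make_scan(c(100.1, 200.22, 300.333), 4L, 512.34, "a"),
                make_scan(c(111.5), 3L, 600.1, "b"),
                make_scan(c(120, 130), 7L, 700.5, "c"))
  f <- withr::local_tempfile()
  write_mgf(scans, f)
  back <- read_mgf(f)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$title, scans[[i]]$title)
    expect_equal(back[[i]]$charge, scans[[i]]$charge)
    expect_equal(back[[i]]$precursor_mz, scans[[i]]$precursor_mz,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$peaks[, 1], scans[[i]]$peaks[, 1],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  no_charge <- withr::local_tempfile(lines = c(
    "BEGIN IONS", "TITLE=x", "PEPMASS=500.1", "100.0 1", "END IONS"))
  expect_warning(got <- read_mgf(no_charge), "no CHARGE")
  expect_length(got, 0L)
  no_pepmass <- withr::local_tempfile(lines = c(
    "BEGIN IONS", "TITLE=x", "CHARGE=3+", "100.0 1", "END IONS"))
  expect_error(read_mgf(no_pepmass), "no PEPMASS")
})

test_that("scan filter applies charge and signature rules and is idempotent", {
  y1k <- xcfg$signature_y1_masses[["y1_K"]]
  sig <- xcfg$linker_signature_masses[[1]]
  good <- make_scan(c(y1k + 0.02, sig - 0.05, 400), charge = 4L)
  bad_charge <- make_scan(c(y1k, sig), charge = 2L)
  high_charge <- make_scan(c(y1k, sig), charge = 10L)
  no_sig <- make_scan(c(y1k, 400), charge = 4L)
  no_y1 <- make_scan(c(sig, 400), charge = 4L)
  empty <- make_scan(numeric(0), charge = 4L)
  kept <- filter_scans(list(good, bad_charge, high_charge, no_sig, no_y1,
                            empty), xcfg)
  expect_length(kept, 1L)
  expect_equal(attr(kept, "counts"),
               c(input = 6L, after_charge = 4L, after_y1 = 2L,
                 after_linker = 1L))
  # idempotent
  again <- filter_scans(kept, xcfg)
  expect_equal(length(again), 1L)
  # property: nothing outside 3..9 ever survives
  set.seed(1)
  rnd <- lapply(1:40, function(i)
    make_scan(runif(5, 100, 1000), charge = sample(1:12, 1)))
  surv <- filter_scans(rnd, xcfg)
  expect_true(all(vapply(surv, `[[`, 1L, "charge") >= 3L))
  expect_true(all(vapply(surv, `[[`, 1L, "charge") <= 9L))
})

test_that("digestion matches the substring oracle and the worked examples", {
  cfg1 <- xlms_config(max_missed = 1L)
  p <- digest(seq_record("p", "AAKAAR"), cfg1)
  expect_setequal(p$sequence, c("AAK", "AAR", "AAKAAR"))
  # no cleavage sites -> the whole protein, zero missed
  w <- digest(seq_record("p", "AAGAAG"), xcfg)
  expect_equal(nrow(w), 1L)
  expect_equal(w$sequence, "AAGAAG")
  expect_equal(w$missed, 0L)
  # proline rule suppresses the internal site
  pr <- digest(seq_record("p", "AKPA"), xcfg)
  expect_equal(pr$sequence, "AKPA")
  # randomized equivalence with the independent substring-checking oracle
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    s <- paste(sample(aa, sample(5:60, 1), replace = TRUE), collapse = "")
    got <- digest(seq_record("p", s), xcfg)
    want <- oracle_digest(s, 4L, TRUE)
    got <- got[order(got$start, got$end), c("sequence", "start", "end", "missed")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("peptide masses come out of the elemental tables", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-5)
  expect_equal(peptide_mass("C"), 178.04121, tolerance = 1e-5)   # fixed CAM
  expect_equal(peptide_mass("M", n_ox = 1L), 165.04596, tolerance = 1e-5)
  expect_error(peptide_mass("G", n_ox = 1L), "exceeds Met count")
  expect_error(peptide_mass("GXG"), "non-standard")
  # BS3 arithmetic is formula-derived
  expect_equal(xcfg$bridge_mass, formula_mass("C8H10O2"))
  expect_equal(xcfg$deadend_water_mass - xcfg$bridge_mass,
               formula_mass("H2O"))
})

test_that("fragment series obey the closed forms and the sum rule", {
  lin <- structure(list(type = "linear",
                        pep_a = list(sequence = "AGK", start = 1L, end = 3L),
                        pep_b = NULL, site_a = NA_integer_,
                        site_b = NA_integer_, ox_a = integer(0),
                        ox_b = integer(0)), class = "xl_candidate")
  fr <- theoretical_fragments(lin, xcfg)
  b2 <- fr[fr$series == "b" & fr$ordinal == 2 & fr$charge == 1, "mz"]
  expect_equal(b2, 129.06585, tolerance = 1e-5)
  y1 <- fr[fr$series == "y" & fr$ordinal == 1 & fr$charge == 1, "mz"]
  expect_equal(y1, 147.11280, tolerance = 1e-5)  # y1 of K-terminated peptide
  # sum rule for random linear peptides: b_i + y_(n-i) neutralizes to M
  set.seed(3)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:10) {
    s <- paste(sample(aa, sample(4:12, 1), replace = TRUE), collapse = "")
    n <- nchar(s)
    cand <- structure(list(type = "linear",
                           pep_a = list(sequence = s, start = 1L, end = n),
                           pep_b = NULL, site_a = NA_integer_,
                           site_b = NA_integer_, ox_a = integer(0),
                           ox_b = integer(0)), class = "xl_candidate")
    fx <- theoretical_fragments(cand, xcfg)
    fx1 <- fx[fx$charge == 1, ]
    M <- peptide_mass(s, 0L, xcfg)
    for (i in seq_len(n - 1)) {
      bn <- fx1[fx1$series == "b" & fx1$ordinal == i, "mz"] - xcfg$proton_mass
      yn <- fx1[fx1$series == "y" & fx1$ordinal == n - i, "mz"] - xcfg$proton_mass
      expect_equal(bn + yn, M, tolerance = 1e-9)
    }
  }
})

test_that("candidate enumeration honors the ppm window and site legality", {
  prot_a <- seq_record("A", "AAKAGRGGW")
  prot_b <- seq_record("B", "LKAARGGW")
  peps_a <- digest(prot_a, xcfg)
  peps_b <- digest(prot_b, xcfg)
  target <- peptide_mass("AAKAGR", 0L, xcfg) + peptide_mass("LKAAR", 0L, xcfg) +
    xcfg$bridge_mass
  scan <- scan_for_mass(target, 3L)
  cands <- enumerate_candidates(peps_a, peps_b, scan, xcfg)
  xl <- Filter(function(cd) cd$type == "crosslink" &&
                 cd$pep_a$sequence == "AAKAGR" &&
                 cd$pep_b$sequence == "LKAAR", cands)
  expect_gte(length(xl), 1L)
  expect_equal(xl[[1]]$precursor_error_ppm, 0, tolerance = 1e-9)
  # the internal-K pairing is among the emitted site combinations (the
  # protein N-terminus, position 1, is also a legal site)
  sites <- vapply(xl, function(cd) paste(cd$site_a, cd$site_b), character(1))
  expect_true("3 2" %in% sites)
  # mass additivity holds for every emitted cross-link
  for (cd in Filter(function(cd) cd$type == "crosslink", cands)) {
    expect_equal(cd$neutral_mass,
                 peptide_mass(cd$pep_a$sequence, 0L, xcfg) +
                   peptide_mass(cd$pep_b$sequence, 0L, xcfg) +
                   xcfg$bridge_mass,
                 tolerance = 1e-9)
  }
  # ~15 ppm shift at M ~ 1300 falls outside the 10 ppm window
  shifted <- scan_for_mass(target + 0.02, 3L)
  cands2 <- enumerate_candidates(peps_a, peps_b, shifted, xcfg)
  expect_length(Filter(function(cd) cd$type == "crosslink", cands2), 0L)
  # peptides without a legal K site are never emitted: GGW has no K
  target3 <- peptide_mass("GGW", 0L, xcfg) + peptide_mass("LKAAR", 0L, xcfg) +
    xcfg$bridge_mass
  cands3 <- enumerate_candidates(peps_a, peps_b, scan_for_mass(target3, 3L),
                                 xcfg)
  expect_length(Filter(function(cd) cd$type == "crosslink" &&
                         cd$pep_a$sequence == "GGW", cands3), 0L)
})

test_that("dead-end explanations carry the right masses and sites", {
  prot_a <- seq_record("A", "AAKAGRGGW")
  peps_a <- digest(prot_a, xcfg)
  m <- peptide_mass("AAKAGR", 0L, xcfg) + xcfg$deadend_water_mass
  cands <- enumerate_candidates(peps_a, peps_a, scan_for_mass(m, 3L), xcfg)
  dd <- Filter(function(cd) cd$type == "deadend_water" &&
                 cd$pep_a$sequence == "AAKAGR", cands)
  expect_gte(length(dd), 1L)
  # protein N-terminus is a legal site: position 1 appears among sites
  expect_true(any(vapply(dd, `[[`, 1L, "site_a") == 1L))
})

test_that("the both-peptides rule decides approval and ranking", {
  prot_a <- seq_record("A", "AAKAGRGGW")
  prot_b <- seq_record("B", "LKAARGGW")
  peps_a <- digest(prot_a, xcfg)
  peps_b <- digest(prot_b, xcfg)
  mass <- peptide_mass("AAKAGR", 0L, xcfg) + peptide_mass("LKAAR", 0L, xcfg) +
    xcfg$bridge_mass
  cand <- structure(list(type = "crosslink",
                         pep_a = list(sequence = "AAKAGR", start = 1L, end = 6L),
                         pep_b = list(sequence = "LKAAR", start = 1L, end = 5L),
                         site_a = 3L, site_b = 2L,
                         ox_a = integer(0), ox_b = integer(0),
                         neutral_mass = mass, precursor_error_ppm = 0),
                    class = "xl_candidate")
  fr <- theoretical_fragments(cand, xcfg)
  full <- scan_for_mass(mass, 4L, mz = fr$mz)
  scored <- validate_and_score(full, cand, xcfg)
  expect_true(scored$approved)
  expect_equal(sum(scored$matched), length(unique(
    paste(fr$series, fr$ordinal, fr$peptide))))
  # only peptide A ions present -> not approved. Both tryptic peptides end
  # in R and so share y1 (and possibly more) m/z values; keep only A ions
  # that are not within tolerance of any B ion.
  mz_b <- fr$mz[fr$peptide == "B"]
  mz_a_only <- Filter(function(m) all(abs(m - mz_b) > 0.15),
                      fr$mz[fr$peptide == "A"])
  only_a <- scan_for_mass(mass, 4L, mz = unlist(mz_a_only))
  expect_false(validate_and_score(only_a, cand, xcfg)$approved)
  # a single peptide B ion is enough at the default floor
  one_b <- scan_for_mass(mass, 4L,
                         mz = c(fr$mz[fr$peptide == "A"],
                                fr$mz[fr$peptide == "B"][1]))
  expect_true(validate_and_score(one_b, cand, xcfg)$approved)
})
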