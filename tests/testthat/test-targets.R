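test_that("tryptic digestion applies the K/R-not-before-P rule", {
  expect_equal(digest_trypsin("MKAAARTEST")$sequence, c("MK", "AAAR", "TEST"))
  expect_equal(digest_trypsin("AKRP")$sequence, c("AK", "RP"))
  expect_equal(digest_trypsin("AAAGGG")$sequence, "AAAGGG")
  expect_error(digest_trypsin("AK9R"), "non-amino-acid")
})

test_that("missed-cleavage enumeration includes all joined spans", {
  d <- digest_trypsin("MKAAARTEST", max_missed = 2)
  expect_setequal(d$sequence,
                  c("MK", "AAAR", "TEST", "MKAAAR", "AAARTEST", "MKAAARTEST"))
  expect_equal(d$missed[d$sequence == "MKAAARTEST"], 2)
  # coordinates recover the peptide from the parent
  expect_equal(substring("MKAAARTEST", d$start, d$end), d$sequence)
})

test_that("zero-missed-cleavage peptides reconstruct the protein", {
  set.seed(11)
  for (i in 1:20) {
    seq <- paste(sample(names(AA_MONO), 60, replace = TRUE), collapse = "")
    d <- digest_trypsin(seq, max_missed = 0)
    expect_identical(paste(d$sequence, collapse = ""), seq)
  }
})

test_that("fragment m/z matches independent monoisotopic hand calculations", {
  # y1 of a peptide ending in K: residue + water + proton
  expect_equal(fragment_mz("AGK", "y", 1, 1), 147.1128, tolerance = 1e-6)
  # b2 of AG...: 71.03711 + 57.02146 + 1.00728
  expect_equal(fragment_mz("AGK", "b", 2, 1), 129.0659, tolerance = 1e-6)
  # phospho inside a y-fragment shifts m/z by +79.96633/charge
  mods <- data.frame(pos = 2, mass = PHOSPHO_MASS)
  for (z in 1:2) {
    expect_equal(fragment_mz("ASGK", "y", 3, z, mods) -
                   fragment_mz("ASGK", "y", 3, z),
                 PHOSPHO_MASS / z, tolerance = 1e-9)
  }
  # phospho outside the fragment leaves it unchanged
  expect_equal(fragment_mz("ASGK", "y", 2, 1, mods),
               fragment_mz("ASGK", "y", 2, 1))
  expect_error(fragment_mz("AGK", "y", 3, 1), "out of range")
})

test_that("b/y complementary fragments reconstruct the precursor mass", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:15, 1)
    pep <- paste(sample(names(AA_MONO), n, replace = TRUE), collapse = "")
    neutral <- precursor_mz(pep, 1) - PROTON_MASS
    for (ord in c(1, sample(seq_len(n - 1), 2))) {
      recon <- fragment_mz(pep, "b", ord, 1) +
        fragment_mz(pep, "y", n - ord, 1) - 2 * PROTON_MASS
      expect_lt(abs(recon - neutral), 1e-4)
    }
  }
})

test_that("proteotypic selection excludes shared, modified and Met peptides", {
  # P1's digest: unique peptides, one shared with P2, one with Met,
  # one overlapping the annotated phosphosite
  p1 <- protein_record("P1", "GGGAVLIEKFFNQDELRSSTSSVYKMAAAGGER",
                       mod_sites = data.frame(position = 19, label = "phospho"))
  p2 <- protein_record("P2", "WWHHDDEEKMAAAGGERVVVLLLK")
  peps <- digest_trypsin(p1$sequence)
  sel <- select_proteotypic(peps, p1, list(p1, p2), n_min = 2, n_max = 4,
                            length_bounds = c(7, 25))
  expect_setequal(sel$sequence, c("GGGAVLIEK", "FFNQDELR"))
  # shared peptide excluded
  expect_false("MAAAGGER" %in% sel$sequence)
  # phosphosite-overlapping peptide excluded
  expect_false("SSTSSVYK" %in% sel$sequence)
  # too few eligible peptides names the protein
  expect_error(
    select_proteotypic(peps, p1, list(p1, p2), n_min = 3, n_max = 4),
    "insufficient proteotypic peptides.*P1")
})

test_that("selection caps at n_max by summed library intensity, ties stable", {
  peps <- data.frame(
    sequence = c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK", "EEEEEEEK", "FFFFFFFK"),
    start = c(1, 9, 17, 25, 33), end = c(8, 16, 24, 32, 40), missed = 0)
  parent <- protein_record("P1", paste(peps$sequence, collapse = ""))
  lib <- make_spectral_library(cbind(peps, accession = "P1"), seed = 3)
  sel <- select_proteotypic(peps, parent, list(parent), n_min = 3, n_max = 4,
                            library = lib)
  expect_equal(nrow(sel), 4)
  sums <- tapply(lib$fragments$rel_intensity, lib$fragments$peptide_id, sum)
  ids <- peptide_id("P1", peps$start, peps$end)
  expect_equal(peptide_id("P1", sel$start, sel$end),
               ids[order(-sums[ids], peps$sequence)][1:4])
  # idempotent and independent of background enumeration order
  sel2 <- select_proteotypic(peps, parent, list(parent), n_min = 3, n_max = 4,
                             library = lib)
  expect_identical(sel, sel2)
})

test_that("transition lists carry both charge states and both forms", {
  targets <- data.frame(
    peptide_id = c("pp", "pp"), accession = "P1", sequence = "AASDEFGHK",
    form = c("phospho", "nonphospho"), site = "P1_S3",
    phospho_pos = 3L)
  lib <- make_spectral_library(
    data.frame(sequence = "AASDEFGHK", accession = "P1", start = 1, end = 9),
    n_fragments = 6, seed = 1)
  lib$fragments$peptide_id <- "pp"
  names(lib$irt) <- "pp"
  tl <- build_transition_list(lib, targets, charges = c(2L, 3L),
                              k_fragments = 3)
  expect_equal(nrow(tl), 2 * 2 * 3)  # forms x charges x fragments
  expect_setequal(unique(tl$precursor_charge), c(2L, 3L))
  expect_setequal(unique(tl$form), c("phospho", "nonphospho"))
  # phospho precursor shifted by +80/z
  for (z in c(2, 3)) {
    dmz <- tl$precursor_mz[tl$form == "phospho" & tl$precursor_charge == z][1] -
      tl$precursor_mz[tl$form == "nonphospho" & tl$precursor_charge == z][1]
    expect_equal(dmz, PHOSPHO_MASS / z, tolerance = 1e-9)
  }
  # k most intense fragments selected
  top3 <- lib$fragments$fragment[order(-lib$fragments$rel_intensity,
                                       lib$fragments$fragment)][1:3]
  expect_setequal(unique(tl$fragment), top3)
  expect_error(build_transition_list(lib, transform(targets,
                                                    peptide_id = "zz")),
               "absent from spectral library")
  expect_equal(nrow(build_transition_list(lib, targets[0, ])), 0)
})
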