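test_that("p-distance uses pairwise gap deletion", {
  msa <- as_msa(c(a = "AC-G", b = "AT-G"))
  expect_equal(p_distance(msa, "a", "b"), 1 / 3)
  expect_equal(p_distance(as_msa(c(a = "AAAA", b = "AAAA")), "a", "b"), 0)
  expect_equal(p_distance(as_msa(c(a = "AAAA", b = "AATT")), "a", "b"), 0.5)
  expect_error(p_distance(as_msa(c(a = "A---", b = "-AAA")), "a", "b"),
               "no comparable")
})

test_that("Jukes-Cantor correction matches its closed form", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.1, 20), 0.105665, tolerance = 1e-5)
  # exact closed form to 1e-12 across the domain
  p <- seq(0, 0.9, by = 0.045)
  expect_equal(jc_distance(p, 20), -(19 / 20) * log(1 - (20 / 19) * p),
               tolerance = 1e-12)
  # small-p limit: d -> p
  expect_lt(abs(jc_distance(1e-6) - 1e-6), 1e-10)
  expect_error(jc_distance(0.96), "saturates")
})

test_that("UPGMA joins closest clusters at half their distance", {
  m2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  tr2 <- upgma(m2)
  expect_equal(attr(tr2, "heights"), 0.1)
  m3 <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.6, 0.6, 0.6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgma(m3)
  expect_equal(attr(tr3, "heights"), c(0.1, 0.3))
  coph <- ape::cophenetic.phylo(tr3)
  expect_equal(coph["A", "B"], 0.2, tolerance = 1e-12)
  expect_equal(coph["A", "C"], 0.6, tolerance = 1e-12)
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B")))),
               "symmetric")
})

test_that("UPGMA agrees with a naive oracle and with average-linkage hclust", {
  set.seed(17)
  for (i in 1:40) {
    n <- 6
    m <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
    v <- runif(n * (n - 1) / 2, 0.05, 1)
    m[lower.tri(m)] <- v
    m <- m + t(m)
    tree <- upgma(m)
    coph <- ape::cophenetic.phylo(tree)[rownames(m), colnames(m)]
    expect_equal(coph, naive_upgma_cophenetic(m), tolerance = 1e-9)
    hc <- stats::cophenetic(hclust(as.dist(m), method = "average"))
    expect_equal(coph, as.matrix(hc)[rownames(m), colnames(m)],
                 tolerance = 1e-9)
  }
})

test_that("ultrametric matrices are recovered exactly", {
  set.seed(23)
  for (i in 1:30) {
    m <- random_ultrametric(sample(4:7, 1))
    coph <- ape::cophenetic.phylo(upgma(m))[rownames(m), colnames(m)]
    expect_equal(coph, m, tolerance = 1e-12)
  }
})

test_that("co-varying blocks get 100% bootstrap support, reproducibly", {
  msa <- block_alignment(60)
  bs <- bootstrap_support(msa, n_reps = 50, seed = 3)
  split_abc <- paste(sort(c("spD", "spE", "spF")), collapse = "|")
  # the two-block split is in every resampled tree
  expect_equal(unname(bs$support[split_abc]), 100)
  bs2 <- bootstrap_support(msa, n_reps = 50, seed = 3)
  expect_identical(bs$support, bs2$support)
  bs3 <- bootstrap_support(msa, n_reps = 50, seed = 4)
  expect_false(identical(bs$support, bs3$support))
  # single replicate: supports are 0 or 100
  bs1 <- bootstrap_support(msa, n_reps = 1, seed = 1)
  expect_true(all(bs1$support %in% c(0, 100)))
})

test_that("bootstrap supports are invariant to taxon input order", {
  msa <- block_alignment(60)
  bs <- bootstrap_support(msa, n_reps = 30, seed = 7)
  perm <- msa[c(4, 2, 6, 1, 3, 5)]
  bsp <- bootstrap_support(perm, n_reps = 30, seed = 7)
  expect_equal(bs$support[sort(names(bs$support))],
               bsp$support[sort(names(bsp$support))])
})

test_that("reference residues map through gaps to alignment columns", {
  msa <- as_msa(c(ref = "A-CS", sp1 = "AGC-", sp2 = "AGCS"))
  hit <- map_reference_position(msa, "ref", 3)  # the S
  expect_equal(hit$column, 4)
  expect_equal(unname(hit$residues), c("S", "-", "S"))
  expect_equal(unname(hit$is_ser), c(TRUE, FALSE, TRUE))
  # ungapped reference: column equals the residue index
  msa2 <- as_msa(c(ref = "MNPQ", sp = "MNPQ"))
  expect_equal(map_reference_position(msa2, "ref", 2)$column, 2)
  expect_error(map_reference_position(msa, "ref", 9), "beyond")
})

test_that("embedded BLOSUM62 matches the published matrix", {
  b <- blosum62()
  expect_equal(b["S", "T"], 1L)
  expect_equal(b["S", "W"], -3L)
  expect_true(isSymmetric(b))
  ref <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = ref)
  aa <- rownames(b)
  expect_identical(unname(b), unname(ref$BLOSUM62[aa, aa]))
})

test_that("window similarity scores columns against the consensus", {
  msa <- as_msa(c(a = "SAS-", b = "SAS-", c = "SAW-", d = "TAS-"))
  out <- window_similarity(msa, 1:4)
  # column 1 "SSST": S/T = 1 >= 1, all similar
  expect_equal(out$percent[1], 100)
  expect_equal(out$category[1], "black")
  # column 2: identical residues
  expect_equal(out$percent[2], 100)
  # column 3 "SSWS": S/W = -3 < 1 -> 75%, light-grey
  expect_equal(out$percent[3], 75)
  expect_equal(out$category[3], "light-grey")
  # all-gap column: undefined percent, uncolored
  expect_true(is.na(out$percent[4]))
  expect_equal(out$category[4], "uncolored")
  # row order does not matter
  out_perm <- window_similarity(msa[c(3, 1, 4, 2)], 1:4)
  expect_equal(out$percent, out_perm$percent)
  expect_equal(out$category, out_perm$category)
})

test_that("similarity bands are half-open with black reserved for 100%", {
  # 4 of 5 similar -> 80% lands in dark-grey, not black
  msa <- as_msa(c(a = "S", b = "S", c = "S", d = "T", e = "W"))
  out <- window_similarity(msa, 1)
  expect_equal(out$percent, 80)
  expect_equal(out$category, "dark-grey")
  # 3 of 5 -> 60% is light-grey; 2 of 5 -> uncolored
  msa2 <- as_msa(c(a = "S", b = "S", c = "T", d = "W", e = "F"))
  out2 <- window_similarity(msa2, 1)
  expect_equal(out2$consensus, "S")
  expect_equal(out2$percent, 60)
  expect_equal(out2$category, "light-grey")
  msa3 <- as_msa(c(a = "S", b = "S", c = "W", d = "F", e = "Y"))
  out3 <- window_similarity(msa3, 1)
  expect_equal(out3$percent, 40)
  expect_equal(out3$category, "uncolored")
  # modal ties resolve by higher BLOSUM62 self-score
  tied <- as_msa(c(a = "S", b = "S", c = "W", d = "W", e = "T"))
  expect_equal(window_similarity(tied, 1)$consensus, "W")
})

test_that("degenerate motif scanning finds overlapping matches", {
  expect_equal(motif_scan("RAAS", "R-x-x-S"), 1L)
  expect_equal(motif_scan("RAASRTTS", "R-x-x-S"), c(1L, 5L))
  expect_equal(motif_scan("AAAA", "R-x-x-S"), integer(0))
  # case-insensitive, bracketed alternatives, undashed patterns
  expect_equal(motif_scan("raat", "R-x-x-[ST]"), 1L)
  expect_equal(motif_scan("RAAT", "RxxT"), 1L)
  expect_error(motif_scan("RAAS", "R-x-("), "malformed")
  expect_error(motif_scan("RAAS", "[ST"), "malformed")
})

test_that("aligned FASTA files round-trip through read_alignment", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp1", "MK-AS", ">sp2", "MKTAS"), path)
  msa <- read_alignment(path)
  expect_equal(unname(msa), c("MK-AS", "MKTAS"))
  expect_equal(names(msa), c("sp1", "sp2"))
  writeLines(c(">sp1", "MKAS", ">sp2", "MK"), path)
  expect_error(read_alignment(path), "differ in length")
})
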