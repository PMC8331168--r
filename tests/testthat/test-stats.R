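test_that("pooled t test matches a hand computation and its conventions", {
  r <- two_group_test(c(0.9, 1.0, 1.1), c(1.9, 2.0, 2.1))
  expect_equal(abs(r$t), 12.2474, tolerance = 1e-4)  # 1 / (0.1 * sqrt(2/3))
  expect_equal(r$df, 4)
  expect_lt(r$p_value, 0.001)
  same <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  const <- two_group_test(c(1, 1), c(1, 1))
  expect_equal(const$p_value, 1)
  expect_warning(z <- two_group_test(c(1, 1), c(2, 2)), "zero within-group")
  expect_equal(z$p_value, 0)
})

check_biconditional <- function(ld) {
  for (i in seq_len(nrow(ld$pairwise))) {
    shares <- any(strsplit(ld$letters[[ld$pairwise$g1[i]]], "")[[1]] %in%
                    strsplit(ld$letters[[ld$pairwise$g2[i]]], "")[[1]])
    nonsig <- is.na(ld$pairwise$p_adj[i]) || ld$pairwise$p_adj[i] >= ld$alpha
    expect_identical(shares, nonsig,
                     label = paste(ld$pairwise$g1[i], ld$pairwise$g2[i]))
  }
  expect_true(all(nchar(ld$letters) > 0))
}

test_that("Tukey letters separate a shifted group and share otherwise", {
  set.seed(21)
  g <- rep(c("A", "B", "C"), each = 4)
  v <- rnorm(12, 0, 0.1)
  v[g == "C"] <- v[g == "C"] + 50  # far beyond within-group sd
  ld <- anova_tukey_letters(v, g)
  expect_false(any(strsplit(ld$letters[["C"]], "")[[1]] %in%
                     unlist(strsplit(ld$letters[c("A", "B")], ""))))
  expect_true(ld$letters[["A"]] == ld$letters[["B"]])
  check_biconditional(ld)
  # groups drawn identical share a single letter
  ld0 <- anova_tukey_letters(rep(c(5, 6, 7), times = 3),
                             rep(c("A", "B", "C"), each = 3))
  expect_equal(unname(ld0$letters), c("a", "a", "a"))
})

test_that("letter displays satisfy the sharing biconditional exhaustively", {
  set.seed(31)
  for (rep in 1:30) {
    k <- sample(3:6, 1)
    n <- sample(3:5, 1)
    shift <- sample(c(0, 0.5, 2, 8), k, replace = TRUE)
    g <- rep(LETTERS[1:k], each = n)
    v <- rnorm(k * n) + rep(shift, each = n)
    check_biconditional(anova_tukey_letters(v, g))
    check_biconditional(kruskal_lsd_letters(v, g))
  }
  # and for synthetic pairwise matrices fed straight to the constructor
  for (rep in 1:30) {
    k <- sample(3:6, 1)
    combos <- combn(LETTERS[1:k], 2)
    pw <- data.frame(g1 = combos[1, ], g2 = combos[2, ],
                     p_adj = sample(c(0.001, 0.2, 0.8), ncol(combos),
                                    replace = TRUE))
    lt <- cld_letters(LETTERS[1:k], pw, alpha = 0.05)
    for (i in seq_len(nrow(pw))) {
      shares <- any(strsplit(lt[[pw$g1[i]]], "")[[1]] %in%
                      strsplit(lt[[pw$g2[i]]], "")[[1]])
      expect_identical(shares, pw$p_adj[i] >= 0.05)
    }
  }
})

test_that("Kruskal-Wallis letters: gating, dominance and Bonferroni factor", {
  # identical groups: omnibus not significant, one shared letter
  ld0 <- kruskal_lsd_letters(rep(c(1, 2, 3), times = 3),
                             rep(c("A", "B", "C"), each = 3))
  expect_equal(unname(ld0$letters), c("a", "a", "a"))
  expect_true(all(is.na(ld0$pairwise$p_adj)))
  # a stochastically dominant group earns its own letter
  set.seed(5)
  g <- rep(c("A", "B", "C"), each = 6)
  v <- c(runif(6, 0, 1), runif(6, 0, 1), runif(6, 10, 11))
  ld <- kruskal_lsd_letters(v, g)
  expect_lt(ld$omnibus_p, 0.05)
  expect_false(any(strsplit(ld$letters[["C"]], "")[[1]] %in%
                     unlist(strsplit(ld$letters[c("A", "B")], ""))))
  # Bonferroni factor = number of pairs: verify against an independent
  # Conover computation for one pair
  r <- rank(v)
  N <- length(v); k <- 3
  H <- unname(kruskal.test(v, factor(g))$statistic)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  rb <- tapply(r, g, mean)
  tstat <- (rb["A"] - rb["B"]) / sqrt(S2 * (N - 1 - H) / (N - k) * (2 / 6))
  p_raw <- 2 * pt(-abs(tstat), N - k)
  got <- ld$pairwise$p_adj[ld$pairwise$g1 == "A" & ld$pairwise$g2 == "B"]
  expect_equal(got, unname(min(1, p_raw * choose(3, 2))), tolerance = 1e-12)
})

test_that("NRQ normalization follows the efficiency-corrected model", {
  # all Cq equal across samples: every NRQ = 1
  cq <- expand.grid(gene = c("tgt", "ref1", "ref2"),
                    sample = paste0("s", 1:4), stringsAsFactors = FALSE)
  cq$cq <- 24
  out <- nrq(cq, reference_genes = c("ref1", "ref2"))
  expect_equal(out$nrq, rep(1, nrow(out)))
  # target one cycle lower in s1 with E = 2: NRQ doubles there
  cq2 <- cq
  cq2$cq[cq2$gene == "tgt" & cq2$sample == "s1"] <- 23
  out2 <- nrq(cq2, reference_genes = c("ref1", "ref2"))
  tgt <- out2[out2$gene == "tgt", ]
  expect_equal(tgt$nrq[tgt$sample == "s1"] /
                 tgt$nrq[tgt$sample == "s2"], 2, tolerance = 1e-12)
  # uniform +1 cycle shift on every gene of one sample cancels
  cq3 <- cq2
  shift <- cq3$sample == "s3"
  cq3$cq[shift] <- cq3$cq[shift] + 1
  out3 <- nrq(cq3, reference_genes = c("ref1", "ref2"))
  expect_equal(out3$nrq[out3$gene == "tgt" & out3$sample %in% c("s3", "s4")],
               out2$nrq[out2$gene == "tgt" & out2$sample %in% c("s3", "s4")],
               tolerance = 1e-9)
  # missing reference Cq names the sample
  expect_error(nrq(cq[!(cq$gene == "ref1" & cq$sample == "s2"), ],
                   reference_genes = c("ref1", "ref2")), "s2")
})

test_that("NRQ standard errors propagate technical-replicate scatter", {
  cq <- rbind(
    expand.grid(gene = c("tgt", "ref1", "ref2"), sample = c("s1", "s2"),
                rep = 1:3, stringsAsFactors = FALSE))
  cq$cq <- 24 + rep(c(0, 0.1, -0.1), each = 6)
  out <- nrq(cq[, c("gene", "sample", "cq")],
             reference_genes = c("ref1", "ref2"))
  expect_true(all(out$nrq_se > 0))
  # single technical replicate: no scatter to propagate
  out1 <- nrq(unique(cq[cq$rep == 1, c("gene", "sample", "cq")]),
              reference_genes = c("ref1", "ref2"))
  expect_true(all(out1$nrq_se == 0))
})
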