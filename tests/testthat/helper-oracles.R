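# Independent oracles and fixture builders used across the suite.

# Dense-grid Gaussian/EMG trace on an offset baseline.
make_gaussian_trace <- function(amplitude, mu, sigma, offset = 0,
                                t0 = mu - 50 * sigma, t1 = mu + 50 * sigma,
                                step = 0.01) {
  time <- seq(t0, t1, by = step)
  list(time = time,
       intensity = amplitude * exp(-(time - mu)^2 / (2 * sigma^2)) + offset)
}

# Random fragment-area table in the layout integrate_chromatograms() emits.
random_area_table <- function(n_peptides = 3, n_fragments = 3, n_charges = 2,
                              sample = "s1", protein = "P") {
  rows <- expand.grid(pep = seq_len(n_peptides), frag = seq_len(n_fragments),
                      z = seq_len(n_charges))
  data.frame(sample_id = sample, protein = protein,
             peptide_id = paste0("pep", rows$pep),
             form = "nonphospho", site = NA_character_, role = "quant",
             precursor_charge = rows$z + 1L,
             fragment = paste0("y", rows$frag + 1L),
             area = runif(nrow(rows), 0, 100), flag = "ok")
}

# Brute-force double sum over peptides and fragments (Eq. 1 oracle).
brute_protein_abundance <- function(table, protein, sample) {
  total <- 0
  for (pep in unique(table$peptide_id)) {
    for (i in seq_len(nrow(table))) {
      if (table$peptide_id[i] == pep && table$protein[i] == protein &&
          table$sample_id[i] == sample && table$role[i] == "quant") {
        total <- total + table$area[i]
      }
    }
  }
  total
}

# Naive O(n^3) UPGMA returning the induced ultrametric (cophenetic) matrix,
# written independently of the package implementation: clusters are grown by
# scanning the full pairwise table each round; ties broken by the
# lexicographically smallest pair of alphabetically-first member labels.
naive_upgma_cophenetic <- function(dm) {
  labels <- rownames(dm)
  clusters <- lapply(labels, identity)
  coph <- matrix(0, nrow(dm), ncol(dm), dimnames = dimnames(dm))
  dist_between <- function(ca, cb) {
    tot <- 0
    for (x in ca) for (y in cb) tot <- tot + dm[x, y]
    tot / (length(ca) * length(cb))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf; best_key <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dd <- dist_between(clusters[[a]], clusters[[b]])
        key <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        better <- dd < best_d ||
          (dd == best_d && (key[1] < best_key[1] ||
                              (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) { best <- c(a, b); best_d <- dd; best_key <- key }
      }
    }
    for (x in clusters[[best[1]]]) for (y in clusters[[best[2]]]) {
      coph[x, y] <- coph[y, x] <- best_d
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  coph
}

# Random ultrametric matrix built from random sequential joins with
# increasing heights.
random_ultrametric <- function(n = 6) {
  labels <- paste0("t", seq_len(n))
  clusters <- lapply(labels, identity)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  h <- 0
  while (length(clusters) > 1L) {
    h <- h + runif(1, 0.05, 0.5)
    pick <- sample(length(clusters), 2)
    for (x in clusters[[pick[1]]]) for (y in clusters[[pick[2]]]) {
      m[x, y] <- m[y, x] <- 2 * h
    }
    clusters[[pick[1]]] <- c(clusters[[pick[1]]], clusters[[pick[2]]])
    clusters <- clusters[-pick[2]]
  }
  m
}

# Alignment of two co-varying blocks: taxa A,B,C share one sequence, D,E,F a
# sequence differing at every third column (p = 1/3, far from Jukes-Cantor
# saturation), plus one private substitution per non-reference taxon. Every
# bootstrap draw separates the blocks, so the ABC|DEF split has 100% support.
block_alignment <- function(n_cols = 200) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  base <- aa[(seq_len(n_cols) - 1L) %% 10L + 1L]
  other <- base
  third <- seq_len(n_cols) %% 3L == 0L
  other[third] <- aa[(match(base[third], aa) %% 10L) + 1L]
  jitter <- function(chars, at, ch) {
    chars[at] <- ch
    paste(chars, collapse = "")
  }
  c(spA = paste(base, collapse = ""),
    spB = jitter(base, 1, "W"), spC = jitter(base, 2, "Y"),
    spD = paste(other, collapse = ""),
    spE = jitter(other, 4, "V"), spF = jitter(other, 5, "M"))
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.eps)
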