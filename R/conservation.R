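# Phosphosite conservation analysis over a precomputed protein MSA:
# Jukes-Cantor distances generalized to the 20-state amino-acid alphabet,
# UPGMA trees with bootstrap support, reference-site column mapping, BLOSUM62
# window similarity, and degenerate motif scanning.

#' Read an aligned FASTA file into an MSA
#'
#' @param path aligned FASTA (protein, gap '-').
#' @return named uppercase character vector of equal-length rows (an `msa`).
#' @export
read_alignment <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  as_msa(setNames(toupper(unlist(seqs)), names(seqs)))
}

#' Validate a named character vector as a multiple alignment
#' @param rows named character vector, one aligned sequence per species.
#' @return the validated vector.
#' @export
as_msa <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 2L, !is.null(names(rows)),
            !anyDuplicated(names(rows)))
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  toupper(rows)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unname(msa), ""))
}

#' Observed proportion of differing sites between two aligned rows
#'
#' Pairwise deletion: columns where either row carries a gap are excluded.
#'
#' @param msa an alignment ([as_msa()]).
#' @param i,j row names or indices, i != j.
#' @return p in [0, 1].
#' @export
p_distance <- function(msa, i, j) {
  msa <- as_msa(msa)
  a <- strsplit(msa[[i]], "")[[1]]
  b <- strsplit(msa[[j]], "")[[1]]
  if (identical(msa[[i]], msa[[j]]) && identical(i, j)) {
    stop("i and j must differ", call. = FALSE)
  }
  ok <- a != "-" & b != "-"
  if (!any(ok)) stop("no comparable (gap-free) sites between rows",
                     call. = FALSE)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Jukes-Cantor corrected distance for a k-state alphabet
#'
#' The Poisson-corrected equal-rates distance
#' `d = -((k-1)/k) * log(1 - (k/(k-1)) * p)`, with k = 20 for proteins.
#'
#' @param p observed proportion(s) of differing sites; 0 <= p < (k-1)/k.
#' @param k alphabet size (default 20).
#' @return distance(s) in substitutions per site.
#' @export
jc_distance <- function(p, k = 20L) {
  stopifnot(all(p >= 0))
  if (any(p >= (k - 1) / k)) {
    stop("p >= (k-1)/k: Jukes-Cantor distance saturates", call. = FALSE)
  }
  -((k - 1) / k) * log(1 - (k / (k - 1)) * p)
}

#' Jukes-Cantor distance matrix of an alignment
#'
#' @param msa an alignment.
#' @param k alphabet size (default 20).
#' @return symmetric matrix of d (substitutions/site) with a `p` attribute
#'   holding the observed-difference matrix.
#' @export
jc_matrix <- function(msa, k = 20L) {
  msa <- as_msa(msa)
  n <- length(msa)
  p <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p[i, j] <- p[j, i] <- p_distance(msa, names(msa)[i], names(msa)[j])
    }
  }
  d <- jc_distance(p, k)
  attr(d, "p") <- p
  d
}

#' UPGMA tree from a distance matrix
#'
#' Unweighted pair-group method with arithmetic mean: iteratively merge the
#' closest pair of clusters; the merged cluster's distance to any other is
#' the size-weighted average of the members' distances, and the new node
#' sits at height d/2 (leaves at height 0). Tied minimal pairs are broken by
#' the lexicographically smallest pair of cluster representative labels
#' (each cluster represented by its alphabetically first leaf).
#'
#' @param dm symmetric distance matrix with row/col names.
#' @return an ultrametric `ape::phylo` tree with a `heights` attribute
#'   (merge heights in join order).
#' @export
upgma <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  stopifnot(n >= 2L, ncol(dm) == n, !is.null(rownames(dm)))
  if (!isTRUE(all.equal(dm, t(dm), check.attributes = FALSE)) ||
      any(diag(dm) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  labels <- rownames(dm)
  active <- seq_len(n)
  size <- rep(1L, n)
  height <- rep(0, n)
  rep_label <- labels
  newick <- labels
  d <- dm
  merge_heights <- numeric(0)
  while (length(active) > 1L) {
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        a <- active[ii]; b <- active[jj]
        dd <- d[a, b]
        key <- sort(c(rep_label[a], rep_label[b]))
        if (dd < best_d ||
            (dd == best_d &&
               (key[1] < best$key[1] ||
                  (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best_d <- dd
          best <- list(a = a, b = b, key = key)
        }
      }
    }
    a <- best$a; b <- best$b
    h <- best_d / 2
    merge_heights <- c(merge_heights, h)
    new <- length(size) + 1L
    size[new] <- size[a] + size[b]
    height[new] <- h
    rep_label[new] <- min(rep_label[a], rep_label[b])
    newick[new] <- sprintf("(%s:%.17g,%s:%.17g)", newick[a], h - height[a],
                           newick[b], h - height[b])
    others <- setdiff(active, c(a, b))
    d <- rbind(cbind(d, 0), 0)
    for (x in others) {
      d[new, x] <- d[x, new] <-
        (size[a] * d[a, x] + size[b] * d[b, x]) / size[new]
    }
    active <- c(others, new)
  }
  tree <- ape::read.tree(text = paste0(newick[active], ";"))
  attr(tree, "heights") <- merge_heights
  tree
}

split_key <- function(tips, all_tips) {
  first <- sort(all_tips)[1]
  if (first %in% tips) tips <- setdiff(all_tips, tips)
  paste(sort(tips), collapse = "|")
}

tree_splits <- function(tree) {
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(idx) split_key(tips[idx], tips), character(1))
  # drop the root (trivial) bipartition
  keys[vapply(parts, length, integer(1)) < length(tips)]
}

#' Bootstrap support for the UPGMA tree of an alignment
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' Jukes-Cantor/UPGMA tree per replicate, and scores every internal
#' bipartition of the full-alignment tree by the percentage of replicate
#' trees containing it. Deterministic given `seed` (stream `"bootstrap"`).
#'
#' @param msa an alignment.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed root seed.
#' @param k alphabet size for the distance correction.
#' @return list: `tree` (the full-alignment UPGMA tree with support
#'   percentages as internal node labels; root unlabelled), `support`
#'   (named percent vector keyed by bipartition), `n_reps`.
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L, k = 20L) {
  msa <- as_msa(msa)
  m <- msa_matrix(msa)
  stopifnot(ncol(m) >= 1L, n_reps >= 1L)
  base_tree <- upgma(jc_matrix(msa, k))
  base_splits <- tree_splits(base_tree)
  counts <- setNames(rep(0L, length(base_splits)), base_splits)
  with_seed(derive_seed(seed, "bootstrap"), {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_msa <- setNames(apply(m[, cols, drop = FALSE], 1L, paste,
                                collapse = ""), names(msa))
      rep_splits <- tree_splits(upgma(jc_matrix(rep_msa, k)))
      hit <- names(counts) %in% rep_splits
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- 100 * counts / n_reps
  # attach supports as node labels in internal-node order
  tips <- base_tree$tip.label
  parts <- ape::prop.part(base_tree)
  labs <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) == length(tips)) "" else
      sprintf("%g", support[[split_key(tips[parts[[i]]], tips)]])
  }, character(1))
  base_tree$node.label <- labs
  list(tree = base_tree, support = support, n_reps = as.integer(n_reps))
}

#' Map a reference residue position onto an alignment column
#'
#' Finds the alignment column holding the `ref_position`-th non-gap residue
#' of the reference row, reads every species' residue in that column, and
#' flags which species carry a serine there (gap rows flag FALSE).
#'
#' @param msa an alignment.
#' @param ref_id reference row name.
#' @param ref_position 1-based residue index in the ungapped reference.
#' @return list `column` (1-based), `residues` (named character),
#'   `is_ser` (named logical).
#' @export
map_reference_position <- function(msa, ref_id, ref_position) {
  msa <- as_msa(msa)
  stopifnot(ref_id %in% names(msa), ref_position >= 1L)
  ref <- strsplit(msa[[ref_id]], "")[[1]]
  res_count <- cumsum(ref != "-")
  if (ref_position > max(res_count)) {
    stop("ref_position ", ref_position, " beyond the ", max(res_count),
         " residues of ", ref_id, call. = FALSE)
  }
  column <- which(res_count == ref_position & ref != "-")[1]
  residues <- vapply(msa, function(s) substr(s, column, column), character(1))
  list(column = column, residues = residues, is_ser = residues == "S")
}

#' The BLOSUM62 substitution matrix (20 x 20)
#'
#' Standard published integer scores over the amino-acid alphabet.
#' @return integer matrix with residue dimnames.
#' @export
blosum62 <- function() {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  scores <- c(
     4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,
    -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,
    -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,
    -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,
     0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
    -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,
    -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,
     0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,
    -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,
    -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,
    -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,
    -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,
    -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,
    -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,
    -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,
     1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,
     0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,
    -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,
    -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,
     0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4)
  matrix(as.integer(scores), 20, 20, byrow = TRUE, dimnames = list(aa, aa))
}

#' Per-column window similarity with BLOSUM62 categories
#'
#' For every requested column: the consensus is the modal residue (ties
#' broken by higher BLOSUM62 self-score, then alphabetically); the
#' similarity percentage is the share of non-gap residues scoring at least
#' `threshold` against the consensus; and the display category follows the
#' bands black (= 100), dark-grey [80, 100), light-grey [60, 80),
#' uncoloured (< 60). All-gap columns report NA percent and "uncolored".
#'
#' @param msa an alignment.
#' @param columns integer vector of 1-based column indices.
#' @param matrix substitution matrix (default [blosum62()]).
#' @param threshold similarity score threshold (default 1).
#' @return data.frame `column`, `consensus`, `percent`, `category`.
#' @export
window_similarity <- function(msa, columns, matrix = blosum62(),
                              threshold = 1) {
  msa <- as_msa(msa)
  width <- nchar(msa[[1]])
  stopifnot(all(columns >= 1L), all(columns <= width))
  m <- msa_matrix(msa)
  out <- data.frame(column = columns, consensus = NA_character_,
                    percent = NA_real_, category = "uncolored")
  for (r in seq_along(columns)) {
    col <- m[, columns[r]]
    res <- col[col != "-"]
    if (length(res) == 0L) next
    tab <- table(res)
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1L) {
      self <- diag(matrix)[cand]
      cand <- cand[order(-self, cand)]
    }
    consensus <- cand[1]
    pct <- 100 * mean(matrix[res, consensus] >= threshold)
    out$consensus[r] <- consensus
    out$percent[r] <- pct
    out$category[r] <- if (pct >= 100) "black" else if (pct >= 80)
      "dark-grey" else if (pct >= 60) "light-grey" else "uncolored"
  }
  out
}

#' Scan a sequence for a degenerate motif
#'
#' Patterns use residue letters, `x` as a single-residue wildcard, and
#' bracketed alternatives (`[ST]`); positions may be dash-separated, as in
#' the basophilic kinase motif `"R-x-x-S"`. Matching is case-insensitive and
#' overlapping matches are all reported.
#'
#' @param sequence amino-acid string.
#' @param pattern degenerate motif.
#' @return integer vector of 1-based match start positions.
#' @export
motif_scan <- function(sequence, pattern) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.character(pattern), length(pattern) == 1L)
  flat <- gsub("-", "", toupper(pattern), fixed = TRUE)
  if (!grepl("^([A-WYZ]|X|\\[[A-WYZ]+\\])+$", flat) ||
      nchar(flat) == 0L) {
    stop("malformed motif pattern: ", pattern, call. = FALSE)
  }
  tokens <- regmatches(flat, gregexpr("\\[[A-WYZ]+\\]|[A-Z]", flat))[[1]]
  rx <- paste(vapply(tokens, function(tk) {
    if (tk == "X") "." else tk
  }, character(1)), collapse = "")
  hits <- gregexpr(paste0("(?=", rx, ")"), toupper(sequence), perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}
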