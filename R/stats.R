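#' Two-sided Student's t test between two groups
#'
#' Pooled-variance (classical Student) t test, as used for the pairwise
#' control-versus-treatment comparisons in the study design. Degenerate
#' zero-variance inputs follow the convention: equal means give p = 1,
#' unequal means give p = 0 with a warning.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param alpha significance level for the flag (default 0.05).
#' @return list `t`, `df`, `p_value`, `significant`.
#' @export
two_group_test <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  pooled_var <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p_value = 1,
                  significant = FALSE))
    }
    warning("zero within-group variance with unequal means; p = 0 by ",
            "convention")
    return(list(t = Inf, df = length(a) + length(b) - 2L, p_value = 0,
                significant = TRUE))
  }
  ht <- t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, significant = ht$p.value < alpha)
}

#' Compact letter display from a pairwise p-value table
#'
#' Insert-and-absorb construction: start from one letter covering all
#' groups; for every significant pair, split each letter column containing
#' both members into two columns excluding one member each; absorb columns
#' that became subsets of others. Letters are assigned in group input order.
#' The result satisfies the defining biconditional: two groups share a
#' letter if and only if their adjusted p-value is >= alpha (missing
#' p-values count as non-significant).
#'
#' @param groups character vector of group labels (display order).
#' @param pairwise data.frame with columns `g1`, `g2`, `p_adj`.
#' @param alpha significance level.
#' @return named character vector of letter strings, one per group.
#' @export
cld_letters <- function(groups, pairwise, alpha = 0.05) {
  stopifnot(!anyDuplicated(groups),
            all(c("g1", "g2", "p_adj") %in% names(pairwise)))
  cols <- list(groups)
  sig <- pairwise[!is.na(pairwise$p_adj) & pairwise$p_adj < alpha, ,
                  drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    gi <- sig$g1[i]; gj <- sig$g2[i]
    new_cols <- list()
    for (col in cols) {
      if (gi %in% col && gj %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, gi)), list(setdiff(col, gj)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop any column contained in another
    keep <- rep(TRUE, length(new_cols))
    for (u in seq_along(new_cols)) {
      for (v in seq_along(new_cols)) {
        if (u != v && keep[v] && all(new_cols[[u]] %in% new_cols[[v]]) &&
            !(length(new_cols[[u]]) == length(new_cols[[v]]) && u < v)) {
          keep[u] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  ord <- order(vapply(cols, function(col) min(match(col, groups)), numeric(1)))
  cols <- cols[ord]
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    lab <- if (i <= 26) letters[i] else paste0(letters[(i - 1) %/% 26],
                                               letters[(i - 1) %% 26 + 1])
    for (g in cols[[i]]) letters_out[g] <- paste0(letters_out[g], lab)
  }
  letters_out
}

group_summary <- function(values, groups) {
  labs <- unique(groups)
  data.frame(
    group = labs,
    mean = vapply(labs, function(g) mean(values[groups == g]), numeric(1)),
    sd = vapply(labs, function(g) sd(values[groups == g]), numeric(1)),
    n = vapply(labs, function(g) sum(groups == g), numeric(1))
  )
}

check_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups), is.numeric(values))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop("every group needs n >= 2 (offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "), ")", call. = FALSE)
  }
  invisible(NULL)
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Fits a one-way ANOVA, computes Tukey honestly-significant-difference
#' adjusted p-values for all group pairs, and encodes them as a compact
#' letter display at level `alpha`.
#'
#' @param values numeric measurements.
#' @param groups group labels (one per value); display order = input order.
#' @param alpha significance level (default 0.05).
#' @return list of class `letter_display`: `letters` (named character),
#'   `pairwise` (`g1`, `g2`, `p_adj`), `omnibus_p`, `alpha`, `summary`,
#'   `method`.
#' @export
anova_tukey_letters <- function(values, groups, alpha = 0.05) {
  check_groups(values, groups)
  labs <- unique(groups)
  f <- factor(groups, levels = labs)
  fit <- aov(values ~ f)
  omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$f
  combos <- combn(labs, 2)  # TukeyHSD rows follow this level-pair order
  stopifnot(nrow(tk) == ncol(combos))
  pairwise <- data.frame(g1 = combos[1, ], g2 = combos[2, ],
                         p_adj = unname(tk[, "p adj"]))
  structure(list(letters = cld_letters(labs, pairwise, alpha),
                 pairwise = pairwise, omnibus_p = omnibus_p, alpha = alpha,
                 summary = group_summary(values, groups),
                 method = "one-way ANOVA + Tukey HSD"),
            class = "letter_display")
}

#' Kruskal-Wallis test with rank-based LSD letters
#'
#' Kruskal-Wallis omnibus test on ranks; when (and only when) the omnibus
#' p-value is below `alpha`, all pairwise comparisons are performed with the
#' Conover rank least-significant-difference procedure and Bonferroni
#' correction over the number of pairs, then encoded as letters. When the
#' omnibus test is not significant all groups share one letter and the
#' pairwise p-values are reported as NA (post hoc not run).
#'
#' @inheritParams anova_tukey_letters
#' @return a `letter_display` (see [anova_tukey_letters()]).
#' @export
kruskal_lsd_letters <- function(values, groups, alpha = 0.05) {
  check_groups(values, groups)
  labs <- unique(groups)
  kw <- kruskal.test(values, factor(groups, levels = labs))
  omnibus_p <- kw$p.value
  n_pairs <- choose(length(labs), 2)
  combos <- combn(labs, 2)
  if (is.na(omnibus_p) || omnibus_p >= alpha) {
    pairwise <- data.frame(g1 = combos[1, ], g2 = combos[2, ],
                           p_adj = NA_real_)
  } else {
    r <- rank(values)
    N <- length(values)
    k <- length(labs)
    rbar <- vapply(labs, function(g) mean(r[groups == g]), numeric(1))
    ns <- vapply(labs, function(g) sum(groups == g), numeric(1))
    S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
    H <- unname(kw$statistic)
    scale2 <- S2 * (N - 1 - H) / (N - k)
    p_raw <- numeric(n_pairs)
    for (j in seq_len(n_pairs)) {
      g1 <- combos[1, j]; g2 <- combos[2, j]
      if (scale2 <= 0) {
        # perfect separation: the rank variance is fully between groups
        p_raw[j] <- if (rbar[g1] == rbar[g2]) 1 else 0
      } else {
        tstat <- (rbar[g1] - rbar[g2]) /
          sqrt(scale2 * (1 / ns[g1] + 1 / ns[g2]))
        p_raw[j] <- 2 * pt(-abs(tstat), df = N - k)
      }
    }
    pairwise <- data.frame(g1 = combos[1, ], g2 = combos[2, ],
                           p_adj = pmin(1, p_raw * n_pairs))
  }
  structure(list(letters = cld_letters(labs, pairwise, alpha),
                 pairwise = pairwise, omnibus_p = omnibus_p, alpha = alpha,
                 summary = group_summary(values, groups),
                 method = "Kruskal-Wallis + Conover LSD (Bonferroni)"),
            class = "letter_display")
}

#' @export
print.letter_display <- function(x, ...) {
  cat(x$method, " (alpha = ", x$alpha, ", omnibus p = ",
      signif(x$omnibus_p, 4), ")\n", sep = "")
  s <- x$summary
  s$letters <- x$letters[s$group]
  print(s, row.names = FALSE)
  invisible(x)
}

#' qPCR normalized relative quantities (NRQ)
#'
#' Efficiency-corrected relative quantities normalized to the geometric mean
#' of the reference-gene quantities: for gene g in sample s,
#' `RQ = E_g^(mean Cq_g - Cq_gs)` (mean-centred across samples, or centred
#' on a named calibrator sample), `NF_s = geometric mean of reference-gene
#' RQs`, `NRQ = RQ / NF`. Standard errors are propagated first-order from
#' the technical-replicate SD of each Cq mean (treating gene terms as
#' independent).
#'
#' @param cq data.frame with columns `gene`, `sample`, `cq` (one row per
#'   technical replicate; Cq in cycles, > 0).
#' @param efficiency named amplification-efficiency vector per gene
#'   (fold/cycle, 1 < E <= 2); genes missing from it default to 2.
#' @param reference_genes character vector (>= 2 recommended) of reference
#'   gene names.
#' @param calibrator optional sample id used as the centring point instead
#'   of the per-gene mean Cq.
#' @return data.frame `gene`, `sample`, `cq_mean`, `cq_se`, `rq`, `nf`,
#'   `nrq`, `nrq_se`.
#' @export
nrq <- function(cq, efficiency = NULL, reference_genes, calibrator = NULL) {
  stopifnot(all(c("gene", "sample", "cq") %in% names(cq)), all(cq$cq > 0),
            length(reference_genes) >= 1L)
  genes <- unique(cq$gene)
  samples <- unique(cq$sample)
  if (!all(reference_genes %in% genes)) {
    stop("reference gene(s) absent from the Cq table: ",
         paste(setdiff(reference_genes, genes), collapse = ", "),
         call. = FALSE)
  }
  E <- setNames(rep(2, length(genes)), genes)
  if (!is.null(efficiency)) {
    stopifnot(!is.null(names(efficiency)), all(efficiency > 1),
              all(efficiency <= 2))
    E[names(efficiency)] <- efficiency
  }
  agg <- aggregate(cq ~ gene + sample, data = cq, FUN = mean)
  names(agg)[3] <- "cq_mean"
  agg$cq_se <- mapply(function(g, s) {
    v <- cq$cq[cq$gene == g & cq$sample == s]
    if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
  }, agg$gene, agg$sample)
  for (g in reference_genes) {
    missing <- setdiff(samples, agg$sample[agg$gene == g])
    if (length(missing) > 0L) {
      stop("missing reference gene ", g, " Cq for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  centre <- vapply(genes, function(g) {
    if (is.null(calibrator)) mean(agg$cq_mean[agg$gene == g])
    else {
      v <- agg$cq_mean[agg$gene == g & agg$sample == calibrator]
      if (length(v) == 0L) stop("calibrator sample ", calibrator,
                                " missing for gene ", g, call. = FALSE)
      v
    }
  }, numeric(1))
  agg$rq <- E[agg$gene]^(centre[agg$gene] - agg$cq_mean)
  nf <- vapply(samples, function(s) {
    v <- agg$rq[agg$sample == s & agg$gene %in% reference_genes]
    exp(mean(log(v)))
  }, numeric(1))
  agg$nf <- nf[agg$sample]
  agg$nrq <- agg$rq / agg$nf
  R <- length(reference_genes)
  ref_var <- vapply(samples, function(s) {
    sum(vapply(reference_genes, function(g) {
      (log(E[g]) * agg$cq_se[agg$gene == g & agg$sample == s])^2
    }, numeric(1))) / R^2
  }, numeric(1))
  agg$nrq_se <- agg$nrq * sqrt((log(E[agg$gene]) * agg$cq_se)^2 +
                                 ref_var[agg$sample])
  agg[order(agg$gene, agg$sample), ]
}
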