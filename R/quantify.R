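#' Relative protein abundance from summed fragment areas
#'
#' The label-free PRM abundance estimate: the sum, over every targeted
#' proteotypic peptide of the protein, of its retained (most-intense)
#' fragment areas across all targeted precursor charges,
#' `A = sum_p sum_f f_pf`. Peptides flagged "no peak" contribute 0.
#'
#' @param table fragment-area table from [integrate_chromatograms()] (or any
#'   data.frame with `sample_id`, `protein`, `area`, and optionally `role`
#'   where only `"quant"` rows count).
#' @param protein protein accession.
#' @param sample sample id.
#' @return A, the relative protein abundance (a.u. * min).
#' @export
protein_abundance <- function(table, protein, sample) {
  stopifnot(all(c("sample_id", "protein", "area") %in% names(table)))
  if (!protein %in% table$protein) {
    stop("protein ", protein, " absent from the fragment-area table",
         call. = FALSE)
  }
  idx <- table$protein == protein & table$sample_id == sample
  if ("role" %in% names(table)) idx <- idx & table$role %in% "quant"
  if (!any(idx)) {
    stop("no targeted quantification peptides for protein ", protein,
         " in sample ", sample, call. = FALSE)
  }
  sum(table$area[idx])
}

#' Express abundances relative to a reference group
#'
#' Each sample's ratio is its value divided by the arithmetic mean of the
#' reference samples, so the reference group has mean ratio 1.
#'
#' @param A_by_sample named numeric vector (sample id -> A).
#' @param reference_samples character vector of reference sample ids.
#' @return named numeric vector of dimensionless ratios.
#' @export
normalize_to_reference <- function(A_by_sample, reference_samples) {
  stopifnot(!is.null(names(A_by_sample)),
            all(reference_samples %in% names(A_by_sample)))
  ref_mean <- mean(A_by_sample[reference_samples])
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    stop("reference group mean must be positive", call. = FALSE)
  }
  A_by_sample / ref_mean
}

#' Phosphosite stoichiometry from paired peptide forms
#'
#' The percentage of the phosphopeptide signal over the total signal of both
#' forms, `P = 100 * sum(pt) / (sum(t) + sum(pt))`, where the sums run over
#' the retained fragments and all targeted precursor charge states of the
#' phosphorylated (`pt`) and nonphosphorylated (`t`) forms. When both totals
#' are zero the stoichiometry is undefined and `NA` is returned (a flag, not
#' a number).
#'
#' @param phospho_areas numeric vector of phospho-form fragment areas.
#' @param nonphospho_areas numeric vector of nonphospho-form fragment areas.
#' @return P in percent, in [0, 100], or `NA_real_` when undefined.
#' @export
phospho_stoichiometry <- function(phospho_areas, nonphospho_areas) {
  stopifnot(all(phospho_areas >= 0), all(nonphospho_areas >= 0))
  spt <- sum(phospho_areas)
  st <- sum(nonphospho_areas)
  if (spt + st == 0) return(NA_real_)
  100 * spt / (st + spt)
}

#' Phosphorylation level relative to a reference mean
#'
#' @param P_sample stoichiometry (or vector of stoichiometries) to express.
#' @param P_reference_mean mean stoichiometry of the reference (e.g. wild
#'   type, control condition) replicates; must be > 0.
#' @return dimensionless ratio(s).
#' @export
relative_phosphorylation <- function(P_sample, P_reference_mean) {
  if (!is.finite(P_reference_mean) || P_reference_mean <= 0) {
    stop("reference phosphorylation mean must be positive", call. = FALSE)
  }
  P_sample / P_reference_mean
}

reference_sample_ids <- function(design, reference) {
  ids <- design$sample_id[design$genotype == reference$genotype &
                            design$condition == reference$condition]
  if (length(ids) == 0L) {
    stop("no samples match the reference group ", reference$genotype, "/",
         reference$condition, call. = FALSE)
  }
  ids
}

#' Per-sample protein quantification table
#'
#' Applies [protein_abundance()] to every protein x sample and expresses each
#' value relative to the mean of the reference genotype/condition replicates.
#'
#' @param table fragment-area table.
#' @param design sample design data.frame.
#' @param reference list with `genotype` and `condition` naming the reference
#'   cell.
#' @return data.frame `sample_id`, `protein`, `A`, `relative_abundance`,
#'   `flag`.
#' @export
quantify_proteins <- function(table, design,
                              reference = list(genotype = "WT",
                                               condition = "control")) {
  ref_ids <- reference_sample_ids(design, reference)
  proteins <- sort(unique(table$protein[
    if ("role" %in% names(table)) table$role %in% "quant" else TRUE]))
  out <- list()
  for (p in proteins) {
    A <- vapply(design$sample_id, function(s) protein_abundance(table, p, s),
                numeric(1))
    rel <- normalize_to_reference(A, ref_ids)
    flagged <- vapply(design$sample_id, function(s)
      any(table$flag[table$protein == p & table$sample_id == s] != "ok"),
      logical(1))
    out[[p]] <- data.frame(sample_id = design$sample_id, protein = p,
                           A = unname(A), relative_abundance = unname(rel),
                           flag = ifelse(flagged, "no_peak", "ok"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample phosphosite stoichiometry table
#'
#' Computes P for every phosphosite and sample from the paired phospho /
#' nonphospho fragment areas (summed over charge states), and the
#' phosphorylation level relative to the mean P of the reference replicates.
#'
#' @inheritParams quantify_proteins
#' @return data.frame `sample_id`, `site`, `P_percent`,
#'   `relative_phosphorylation`, `flag`.
#' @export
quantify_phospho <- function(table, design,
                             reference = list(genotype = "WT",
                                              condition = "control")) {
  stopifnot("site" %in% names(table), "form" %in% names(table))
  ref_ids <- reference_sample_ids(design, reference)
  sites <- sort(unique(table$site[!is.na(table$site)]))
  if (length(sites) == 0L) {
    stop("fragment-area table contains no phosphosite peptides",
         call. = FALSE)
  }
  out <- list()
  for (st in sites) {
    P <- vapply(design$sample_id, function(s) {
      idx <- !is.na(table$site) & table$site == st & table$sample_id == s
      phospho_stoichiometry(table$area[idx & table$form == "phospho"],
                            table$area[idx & table$form == "nonphospho"])
    }, numeric(1))
    ref_mean <- mean(P[ref_ids], na.rm = TRUE)
    rel <- if (is.finite(ref_mean) && ref_mean > 0)
      relative_phosphorylation(P, ref_mean) else rep(NA_real_, length(P))
    out[[st]] <- data.frame(
      sample_id = design$sample_id, site = st, P_percent = unname(P),
      relative_phosphorylation = unname(rel),
      flag = ifelse(is.na(P), "undefined", "ok"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
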