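#' Create a protein record
#'
#' @param accession protein identifier.
#' @param sequence amino-acid sequence (1-based residue numbering).
#' @param mod_sites data.frame with columns `position` (1-based) and `label`
#'   for annotated modification sites (e.g. known phosphosites); may be empty.
#' @return a `protein_record` list.
#' @export
protein_record <- function(accession, sequence,
                           mod_sites = data.frame(position = integer(),
                                                  label = character())) {
  assert_aa_sequence(sequence)
  stopifnot(is.character(accession), length(accession) == 1L)
  stopifnot(all(c("position", "label") %in% names(mod_sites)))
  if (nrow(mod_sites) > 0L &&
      any(mod_sites$position < 1L | mod_sites$position > nchar(sequence))) {
    stop("modification site position outside sequence for ", accession,
         call. = FALSE)
  }
  structure(list(accession = accession, sequence = sequence,
                 mod_sites = mod_sites), class = "protein_record")
}

#' Monoisotopic fragment ion m/z
#'
#' Computes the m/z of a b- or y-series fragment:
#' (sum of residue masses + series offset + modification masses on the
#' fragment + charge * proton) / charge. The y-series offset is one water;
#' the b-series offset is zero.
#'
#' @param peptide amino-acid sequence of the peptide.
#' @param series `"b"` or `"y"`.
#' @param ordinal fragment ordinal, 1 <= ordinal <= nchar(peptide) - 1.
#' @param charge product charge (>= 1).
#' @param mods data.frame with columns `pos` (1-based position in peptide) and
#'   `mass` (delta in Da); only modifications falling inside the fragment
#'   contribute.
#' @return m/z in Thomson.
#' @examples
#' fragment_mz("AGK", "y", 1, 1)  # C-terminal K: 147.1128
#' fragment_mz("AGK", "b", 2, 1)  # AG: 129.0659
#' @export
fragment_mz <- function(peptide, series = c("b", "y"), ordinal, charge = 1L,
                        mods = NULL) {
  assert_aa_sequence(peptide)
  series <- match.arg(series)
  n <- nchar(peptide)
  stopifnot(charge >= 1L)
  if (ordinal < 1L || ordinal > n - 1L) {
    stop("fragment ordinal ", ordinal, " out of range for a ", n,
         "-residue peptide", call. = FALSE)
  }
  chars <- strsplit(peptide, "")[[1]]
  positions <- if (series == "b") seq_len(ordinal) else (n - ordinal + 1L):n
  mass <- sum(AA_MONO[chars[positions]])
  if (series == "y") mass <- mass + WATER_MASS
  if (!is.null(mods) && nrow(mods) > 0L) {
    mass <- mass + sum(mods$mass[mods$pos %in% positions])
  }
  (mass + charge * PROTON_MASS) / charge
}

#' Monoisotopic precursor m/z
#'
#' @inheritParams fragment_mz
#' @param charge precursor charge (>= 1).
#' @export
precursor_mz <- function(peptide, charge, mods = NULL) {
  assert_aa_sequence(peptide)
  stopifnot(charge >= 1L)
  mass <- sum(AA_MONO[strsplit(peptide, "")[[1]]]) + WATER_MASS
  if (!is.null(mods) && nrow(mods) > 0L) mass <- mass + sum(mods$mass)
  (mass + charge * PROTON_MASS) / charge
}

#' Select proteotypic peptides for a protein
#'
#' A peptide is eligible when it (i) occurs in exactly one protein of the
#' background set (proteotypic), (ii) does not overlap any annotated
#' modification site of its parent, (iii) contains no methionine (oxidation
#' being a common variable modification), and (iv) has length within
#' `length_bounds`. Eligible peptides are ranked by descending summed library
#' fragment intensity (alphabetically when no library is given or on ties)
#' and the top `n_max` retained; fewer than `n_min` eligible peptides is an
#' error naming the protein.
#'
#' @param peptides data.frame from [digest_trypsin()] (columns `sequence`,
#'   `start`, `end`) for the parent protein.
#' @param parent the parent [protein_record()].
#' @param background list of [protein_record()] including the parent.
#' @param n_min,n_max required / maximal number of peptides (default 3, 4).
#' @param length_bounds inclusive peptide length window, default c(7, 25).
#' @param library optional spectral library from [make_spectral_library()]
#'   used for ranking.
#' @return subset of `peptides` rows, ranked, with an `accession` column.
#' @export
select_proteotypic <- function(peptides, parent, background,
                               n_min = 3L, n_max = 4L,
                               length_bounds = c(7L, 25L), library = NULL) {
  stopifnot(inherits(parent, "protein_record"))
  accs <- vapply(background, function(p) p$accession, character(1))
  if (!parent$accession %in% accs) {
    stop("background does not include parent protein ", parent$accession,
         call. = FALSE)
  }
  seqs <- vapply(background, function(p) p$sequence, character(1))
  len <- nchar(peptides$sequence)
  n_parents <- vapply(peptides$sequence, function(p)
    sum(vapply(seqs, function(s) grepl(p, s, fixed = TRUE), logical(1))),
    numeric(1))
  overlaps_mod <- rep(FALSE, nrow(peptides))
  if (nrow(parent$mod_sites) > 0L) {
    for (pos in parent$mod_sites$position) {
      overlaps_mod <- overlaps_mod | (peptides$start <= pos & peptides$end >= pos)
    }
  }
  eligible <- peptides[n_parents == 1L & !overlaps_mod &
                         !grepl("M", peptides$sequence, fixed = TRUE) &
                         len >= length_bounds[1] & len <= length_bounds[2], ,
                       drop = FALSE]
  eligible <- eligible[!duplicated(eligible$sequence), , drop = FALSE]
  if (nrow(eligible) < n_min) {
    stop("insufficient proteotypic peptides for protein ", parent$accession,
         " (", nrow(eligible), " eligible, ", n_min, " required)",
         call. = FALSE)
  }
  score <- rep(0, nrow(eligible))
  if (!is.null(library)) {
    ids <- peptide_id(parent$accession, eligible$start, eligible$end)
    score <- vapply(ids, function(id)
      sum(library$fragments$rel_intensity[library$fragments$peptide_id == id]),
      numeric(1))
  }
  ord <- order(-score, eligible$sequence)
  out <- eligible[ord[seq_len(min(n_max, nrow(eligible)))], , drop = FALSE]
  out$accession <- parent$accession
  rownames(out) <- NULL
  out
}

peptide_id <- function(accession, start, end) {
  paste0(accession, ".", start, "-", end)
}

#' Build a synthetic spectral library
#'
#' Assigns each peptide a fixed fragment relative-intensity pattern (drawn
#' once from a symmetric Dirichlet over its y-ion series and frozen) and an
#' iRT value spread evenly over `irt_range` in input order. The pattern plays
#' the role of a reference spectral library: phosphorylated forms of a
#' peptide reuse the pattern of the unmodified form.
#'
#' @param peptides data.frame with columns `sequence` and (optionally)
#'   `accession`, `start`, `end` used to form stable peptide ids.
#' @param n_fragments number of y-ions per peptide (capped by length - 2).
#' @param concentration Dirichlet concentration for intensity draws.
#' @param seed root seed; the draw uses the derived stream `"library"`.
#' @param irt_range numeric length-2, dimensionless iRT span.
#' @return list with `fragments` (data.frame `peptide_id`, `fragment`,
#'   `ordinal`, `rel_intensity`) and `irt` (named numeric).
#' @export
make_spectral_library <- function(peptides, n_fragments = 6L,
                                  concentration = 2, seed = 1L,
                                  irt_range = c(0, 100)) {
  stopifnot(nrow(peptides) > 0L)
  ids <- if (all(c("accession", "start", "end") %in% names(peptides))) {
    peptide_id(peptides$accession, peptides$start, peptides$end)
  } else peptides$sequence
  stopifnot(!anyDuplicated(ids))
  rows <- with_seed(derive_seed(seed, "library"), {
    lapply(seq_len(nrow(peptides)), function(i) {
      len <- nchar(peptides$sequence[i])
      ords <- seq(2L, len - 1L)
      ords <- head(ords, n_fragments)
      g <- rgamma(length(ords), shape = concentration)
      data.frame(peptide_id = ids[i],
                 fragment = paste0("y", ords),
                 ordinal = ords,
                 rel_intensity = g / sum(g))
    })
  })
  irt <- if (nrow(peptides) == 1L) mean(irt_range) else
    seq(irt_range[1], irt_range[2], length.out = nrow(peptides))
  list(fragments = do.call(rbind, rows), irt = setNames(irt, ids))
}

#' Build a transition list
#'
#' For every targeted peptide form and precursor charge, the `k_fragments`
#' most intense library fragments become transitions (ties broken by ion
#' label); retention-time schedule windows come from a linear iRT-to-RT
#' mapping. Phosphorylated forms carry the +79.96633 Da shift on precursor
#' m/z and on every y-fragment containing the site.
#'
#' @param library spectral library from [make_spectral_library()].
#' @param targets data.frame of peptide targets with columns `peptide_id`,
#'   `accession`, `sequence`, `form` (`"nonphospho"` or `"phospho"`), `site`
#'   (phosphosite label or NA) and `phospho_pos` (1-based position in the
#'   peptide, NA for nonphospho).
#' @param charges integer precursor charges targeted for every form
#'   (default 2+ and 3+).
#' @param k_fragments transitions per peptide/charge (default 3).
#' @param irt_slope,irt_intercept linear iRT-to-RT calibration (min per iRT
#'   unit, min).
#' @param rt_window full scheduled window width (min) centred on the
#'   predicted RT.
#' @return data.frame of transitions, one row per
#'   (peptide form, precursor charge, fragment).
#' @export
build_transition_list <- function(library, targets, charges = c(2L, 3L),
                                  k_fragments = 3L, irt_slope = 0.45,
                                  irt_intercept = 5, rt_window = 5) {
  stopifnot(nrow(targets) > 0L || is.data.frame(targets))
  if (nrow(targets) == 0L) {
    return(empty_transition_table())
  }
  missing <- setdiff(targets$peptide_id, unique(library$fragments$peptide_id))
  if (length(missing) > 0L) {
    stop("peptide(s) absent from spectral library: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    frags <- library$fragments[library$fragments$peptide_id == tg$peptide_id, ]
    frags <- frags[order(-frags$rel_intensity, frags$fragment), , drop = FALSE]
    frags <- head(frags, k_fragments)
    mods <- NULL
    if (tg$form == "phospho") {
      stopifnot(!is.na(tg$phospho_pos))
      mods <- data.frame(pos = tg$phospho_pos, mass = PHOSPHO_MASS)
    }
    rt_center <- irt_intercept + irt_slope * library$irt[[tg$peptide_id]]
    for (z in charges) {
      pre <- precursor_mz(tg$sequence, z, mods)
      for (j in seq_len(nrow(frags))) {
        prod <- fragment_mz(tg$sequence, "y", frags$ordinal[j], 1L, mods)
        out[[length(out) + 1L]] <- data.frame(
          transition_id = paste(tg$peptide_id, tg$form, paste0(z, "+"),
                                frags$fragment[j], sep = "_"),
          protein = tg$accession, peptide_id = tg$peptide_id,
          peptide = tg$sequence, form = tg$form,
          site = if (is.na(tg$site)) NA_character_ else tg$site,
          phospho_pos = tg$phospho_pos,
          precursor_charge = z, fragment = frags$fragment[j],
          ordinal = frags$ordinal[j], product_charge = 1L,
          precursor_mz = pre, product_mz = prod,
          rel_intensity = frags$rel_intensity[j],
          rt_center = rt_center,
          rt_start = rt_center - rt_window / 2,
          rt_end = rt_center + rt_window / 2
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_transition_table <- function() {
  data.frame(transition_id = character(), protein = character(),
             peptide_id = character(), peptide = character(),
             form = character(), site = character(), phospho_pos = integer(),
             precursor_charge = integer(), fragment = character(),
             ordinal = integer(), product_charge = integer(),
             precursor_mz = numeric(), product_mz = numeric(),
             rel_intensity = numeric(), rt_center = numeric(),
             rt_start = numeric(), rt_end = numeric())
}
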