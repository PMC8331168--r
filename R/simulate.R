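#' Configuration for a synthetic targeted-MS experiment
#'
#' Returns the default study configuration — a genotype x condition x
#' replicate design with injected protein fold-changes and phosphosite
#' occupancies — optionally overridden field by field. Defaults emulate the
#' kind of design the pipeline is meant for: two genotypes (a wild type and a
#' mutant with a 2.5-fold abundance increase), two conditions under which a
#' regulatory phosphosite moves from 12% to 40% occupancy, and n = 3
#' biological replicates per cell.
#'
#' @param ... named overrides of the default fields (see Details).
#' @details Fields: `genotypes`, `conditions`, `replicates`; `n_proteins`,
#'   `peptides_per_protein`; `baseline_abundance` (a.u., the total integrated
#'   signal of one peptide at fold 1); `fold` (data.frame `protein`,
#'   `genotype`, `condition`, `fold`; NULL means fold 1 everywhere);
#'   `occupancy` (data.frame `site`, `genotype`, `condition`, `occupancy` in
#'   [0,1]; NULL means no phosphosite); `cv` (multiplicative log-normal
#'   per-point CV), `baseline_level` (a.u.), `drift_slope` (a.u./min);
#'   `sigma_rt`, `tau_rt` (min, peak width and exponential tail), `rt_jitter_sd`
#'   (min, per-sample RT wobble); `gradient` (min, length 2), `time_step`
#'   (min), `rt_window` (min, scheduled window width); `charges`,
#'   `charge_weights`, `k_fragments`, `n_fragments_lib`,
#'   `dirichlet_concentration`, `irt_slope`, `irt_intercept`,
#'   `reference_genotype`, `reference_condition`.
#'
#'   The default fold/occupancy tables refer to the synthetic accessions
#'   `P01`, `P02`, ... and the site label `P01_phosphosite`; they are filled
#'   in by [simulate_dataset()] if left NULL.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  config <- list(
    genotypes = c("WT", "mut"),
    conditions = c("control", "treated"),
    replicates = 3L,
    n_proteins = 2L,
    peptides_per_protein = 3L,
    baseline_abundance = 2000,
    fold = NULL,
    occupancy = NULL,
    mutant_fold = 2.5,
    occupancy_by_condition = c(control = 0.12, treated = 0.40),
    cv = 0.10,
    baseline_level = 5,
    drift_slope = 0.05,
    sigma_rt = 0.05,
    tau_rt = 0.02,
    rt_jitter_sd = 0.02,
    gradient = c(0, 60),
    time_step = 0.01,
    rt_window = 5,
    charges = c(2L, 3L),
    charge_weights = c(0.7, 0.3),
    k_fragments = 3L,
    n_fragments_lib = 6L,
    dirichlet_concentration = 2,
    irt_slope = 0.45,
    irt_intercept = 7,
    reference_genotype = "WT",
    reference_condition = "control"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0L) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config[names(overrides)] <- overrides
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

validate_sim_config <- function(config) {
  stopifnot(length(config$genotypes) >= 1L, length(config$conditions) >= 1L,
            !anyDuplicated(config$genotypes), !anyDuplicated(config$conditions),
            config$n_proteins >= 1L)
  if (config$replicates < 2L) stop("replicates must be >= 2", call. = FALSE)
  if (!is.null(config$occupancy)) {
    occ <- config$occupancy$occupancy
    if (any(occ < 0 | occ > 1)) {
      stop("occupancy must lie in [0, 1]", call. = FALSE)
    }
  }
  if (any(config$occupancy_by_condition < 0 | config$occupancy_by_condition > 1)) {
    stop("occupancy must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(config$fold) && any(config$fold$fold <= 0)) {
    stop("fold-changes must be strictly positive", call. = FALSE)
  }
  stopifnot(config$cv >= 0, config$baseline_level >= 0, config$sigma_rt > 0,
            config$tau_rt >= 0, config$time_step > 0,
            abs(sum(config$charge_weights) - 1) < 1e-9)
  invisible(config)
}

#' Enumerate the sample design and ground truth
#'
#' Expands the genotype x condition x replicate grid into samples and fills
#' the ground-truth maps: per (protein, genotype, condition) true abundance
#' (baseline x fold) and per (phosphosite, genotype, condition) occupancy.
#' When the configuration supplies `fold` or `occupancy` tables they must
#' cover every declared cell; a missing entry is a configuration error.
#' Deterministic given `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer root seed (recorded in the design).
#' @param proteins character vector of protein accessions (defaults to
#'   `P01..`); `sites` character vector of phosphosite labels.
#' @param sites phosphosite labels; default one site on the first protein.
#' @return list with `design` (data.frame `sample_id`, `genotype`,
#'   `condition`, `replicate`) and `truth` (lists `abundance`, `occupancy`,
#'   `noise`, `peak`).
#' @export
make_design <- function(config, seed = 1L,
                        proteins = sprintf("P%02d", seq_len(config$n_proteins)),
                        sites = "P01_phosphosite") {
  validate_sim_config(config)
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      condition = config$conditions,
                      genotype = config$genotypes,
                      stringsAsFactors = FALSE)
  design <- data.frame(
    sample_id = sprintf("%s_%s_r%d", grid$genotype, grid$condition,
                        grid$replicate),
    genotype = grid$genotype, condition = grid$condition,
    replicate = grid$replicate
  )
  cells <- expand.grid(genotype = config$genotypes,
                       condition = config$conditions,
                       stringsAsFactors = FALSE)

  fold <- config$fold
  if (is.null(fold)) {
    fold <- do.call(rbind, lapply(proteins, function(p) {
      data.frame(protein = p, genotype = cells$genotype,
                 condition = cells$condition,
                 fold = ifelse(cells$genotype == config$reference_genotype,
                               1, config$mutant_fold))
    }))
  }
  abundance <- merge(expand.grid(protein = proteins,
                                 genotype = config$genotypes,
                                 condition = config$conditions,
                                 stringsAsFactors = FALSE),
                     fold, all.x = TRUE)
  if (any(is.na(abundance$fold))) {
    bad <- abundance[is.na(abundance$fold), ]
    stop("missing fold-change for declared contrast(s): ",
         paste(bad$protein, bad$genotype, bad$condition, sep = "/",
               collapse = ", "), call. = FALSE)
  }
  abundance$abundance <- config$baseline_abundance * abundance$fold
  stopifnot(all(abundance$abundance > 0))

  occupancy <- config$occupancy
  if (is.null(occupancy) && length(sites) > 0L) {
    occupancy <- do.call(rbind, lapply(sites, function(s) {
      data.frame(site = s, genotype = cells$genotype,
                 condition = cells$condition,
                 occupancy = unname(
                   config$occupancy_by_condition[cells$condition]))
    }))
  }
  if (!is.null(occupancy)) {
    if (any(is.na(occupancy$occupancy))) {
      stop("missing occupancy for a declared phosphosite cell", call. = FALSE)
    }
    if (any(occupancy$occupancy < 0 | occupancy$occupancy > 1)) {
      stop("occupancy must lie in [0, 1]", call. = FALSE)
    }
  }

  truth <- list(
    abundance = abundance[, c("protein", "genotype", "condition", "fold",
                              "abundance")],
    occupancy = occupancy,
    noise = list(cv = config$cv, baseline_level = config$baseline_level,
                 drift_slope = config$drift_slope),
    peak = list(sigma_rt = config$sigma_rt, tau_rt = config$tau_rt),
    seed = as.integer(seed)
  )
  list(design = design, truth = truth)
}

#' Exponentially modified Gaussian peak profile
#'
#' Chromatographic peak model: a Gaussian of width `sigma` convolved with an
#' exponential decay of time constant `tau` (tailing); `tau = 0` reduces
#' exactly to the Gaussian. `amplitude` is the apex height of the underlying
#' Gaussian, so the integrated area is `amplitude * sigma * sqrt(2*pi)`
#' independent of `tau` (convolution preserves area). Evaluated in the
#' numerically stable scaled-complementary-error-function form.
#'
#' @param time numeric vector (min).
#' @param amplitude Gaussian apex height (a.u.).
#' @param rt peak centre of the Gaussian component (min).
#' @param sigma Gaussian width (min, > 0).
#' @param tau exponential tail time constant (min, >= 0).
#' @return intensities (a.u.) at `time`.
#' @export
emg_peak <- function(time, amplitude, rt, sigma, tau = 0) {
  stopifnot(sigma > 0, tau >= 0)
  amplitude * sigma * sqrt(2 * pi) * emg_density(time, rt, sigma, tau)
}

# erfcx(x) = exp(x^2) erfc(x), stable for large x via the asymptotic series
erfcx_stable <- function(x) {
  out <- numeric(length(x))
  small <- x < 25
  out[small] <- pracma::erfcx(x[small])
  if (any(!small)) {
    b <- x[!small]
    t2 <- 1 / (2 * b^2)
    out[!small] <- (1 - t2 + 3 * t2^2 - 15 * t2^3) / (b * sqrt(pi))
  }
  out
}

emg_density <- function(time, mu, sigma, tau) {
  if (tau < 1e-10 * sigma) {
    return(dnorm(time, mu, sigma))
  }
  dt <- time - mu
  z <- (sigma / tau - dt / sigma) / sqrt(2)
  out <- numeric(length(time))
  pos <- z >= 0
  # leading side: erfcx form is stable
  out[pos] <- (1 / (2 * tau)) * exp(-dt[pos]^2 / (2 * sigma^2)) *
    erfcx_stable(z[pos])
  # tailing side: erfc(z) = 2 - erfc(-z); both exponents decay
  if (any(!pos)) {
    zp <- -z[!pos]
    out[!pos] <- (1 / (2 * tau)) *
      (2 * exp(sigma^2 / (2 * tau^2) - dt[!pos] / tau) -
         erfcx_stable(zp) * exp(-dt[!pos]^2 / (2 * sigma^2)))
  }
  pmax(out, 0)
}

#' Simulate extracted-ion chromatograms for a transition list
#'
#' Each (sample, transition) pair gets one trace on a fixed grid over the
#' transition's scheduled RT window: an exponentially modified Gaussian whose
#' integrated area equals
#' `true abundance x library fragment relative intensity x charge weight x
#' occupancy factor` (occupancy for the phospho form, 1 - occupancy for the
#' nonphospho form of a phosphopeptide, 1 for unmodified quant peptides),
#' multiplied by per-point log-normal noise with the configured CV, plus a
#' constant baseline with linear drift. Negative values are clipped to zero.
#'
#' @param truth ground truth from [make_design()].
#' @param transitions transition list from [build_transition_list()], with a
#'   `charge_weight` column attached (see [simulate_dataset()]).
#' @param design sample design from [make_design()].
#' @param config a [sim_config()].
#' @param seed root seed; per-sample streams are derived by name.
#' @return long data.frame `sample_id`, `transition_id`, `time_min`,
#'   `intensity` with strictly increasing fixed-step time per trace.
#' @export
simulate_xics <- function(truth, transitions, design, config, seed = 1L) {
  stopifnot(nrow(transitions) > 0L)
  unknown <- setdiff(transitions$protein, truth$abundance$protein)
  if (length(unknown) > 0L) {
    stop("transition references unknown protein(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sites <- unique(transitions$site[!is.na(transitions$site)])
  if (length(sites) > 0L) {
    known <- if (is.null(truth$occupancy)) character() else
      unique(truth$occupancy$site)
    if (length(setdiff(sites, known)) > 0L) {
      stop("transition references unknown phosphosite(s): ",
           paste(setdiff(sites, known), collapse = ", "), call. = FALSE)
    }
  }
  if (!"charge_weight" %in% names(transitions)) {
    w <- setNames(config$charge_weights, as.character(config$charges))
    transitions$charge_weight <- unname(w[as.character(
      transitions$precursor_charge)])
  }
  if (any(transitions$rt_end <= config$gradient[1] |
          transitions$rt_start >= config$gradient[2])) {
    stop("transition RT schedule falls outside the gradient window",
         call. = FALSE)
  }

  sigma <- config$sigma_rt
  tau <- config$tau_rt
  step <- config$time_step
  sdlog <- sqrt(log(1 + config$cv^2))

  # precompute per-transition time grids and static annotation
  n_tr <- nrow(transitions)
  grids <- lapply(seq_len(n_tr), function(i) {
    seq(max(transitions$rt_start[i], config$gradient[1]),
        min(transitions$rt_end[i], config$gradient[2]), by = step)
  })
  n_samples <- nrow(design)
  times_out <- vector("list", n_samples * n_tr)
  ys_out <- vector("list", n_samples * n_tr)
  k <- 0L
  for (s in seq_len(n_samples)) {
    smp <- design[s, ]
    ab_map <- truth$abundance[truth$abundance$genotype == smp$genotype &
                                truth$abundance$condition == smp$condition, ]
    ab <- setNames(ab_map$abundance, ab_map$protein)[transitions$protein]
    occ_factor <- rep(1, n_tr)
    if (!is.null(truth$occupancy)) {
      occ_map <- truth$occupancy[truth$occupancy$genotype == smp$genotype &
                                   truth$occupancy$condition ==
                                     smp$condition, ]
      occ <- setNames(occ_map$occupancy, occ_map$site)[transitions$site]
      has <- !is.na(transitions$site)
      occ_factor[has] <- ifelse(transitions$form[has] == "phospho",
                                occ[has], 1 - occ[has])
    }
    areas <- unname(ab) * transitions$rel_intensity *
      transitions$charge_weight * occ_factor
    sample_seed <- derive_seed(seed, paste0("xic-", smp$sample_id))
    with_seed(sample_seed, {
      rt_shift <- rnorm(1L, 0, config$rt_jitter_sd)
      for (i in seq_len(n_tr)) {
        time <- grids[[i]]
        y <- areas[i] * emg_density(time, transitions$rt_center[i] + rt_shift,
                                    sigma, tau)
        if (config$cv > 0) {
          y <- y * rlnorm(length(y), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        }
        k <- k + 1L
        times_out[[k]] <- time
        ys_out[[k]] <- pmax(y + config$baseline_level +
                              config$drift_slope * time, 0)
      }
    })
  }
  lens <- lengths(times_out)
  data.frame(
    sample_id = rep(rep(design$sample_id, each = n_tr), times = lens),
    transition_id = rep(rep(transitions$transition_id, times = n_samples),
                        times = lens),
    time_min = unlist(times_out, use.names = FALSE),
    intensity = unlist(ys_out, use.names = FALSE)
  )
}

#' Simulate a complete synthetic targeted-proteomics dataset
#'
#' End-to-end generator: builds synthetic proteins (assembled from unique
#' tryptic peptides, one of which carries an annotated phosphoserine on the
#' first protein), digests them, draws a frozen spectral library, selects
#' proteotypic quantification peptides, adds the phospho/nonphospho target
#' pair for the phosphosite, schedules transitions, enumerates the design and
#' ground truth, and simulates all chromatograms.
#'
#' @param config a [sim_config()].
#' @param seed integer root seed for all streams.
#' @return list with `config`, `proteins`, `library`, `targets`,
#'   `transitions`, `design`, `truth`, `xics`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  validate_sim_config(config)
  prot <- make_synthetic_proteins(
    n_proteins = config$n_proteins,
    peptides_per_protein = config$peptides_per_protein,
    seed = derive_seed(seed, "proteins"))
  proteins <- prot$records

  digests <- lapply(proteins, function(p) {
    d <- digest_trypsin(p$sequence, max_missed = 0L)
    d$accession <- p$accession
    d
  })
  all_peptides <- do.call(rbind, digests)

  library <- make_spectral_library(
    all_peptides, n_fragments = config$n_fragments_lib,
    concentration = config$dirichlet_concentration, seed = seed)

  targets <- list()
  for (i in seq_along(proteins)) {
    sel <- select_proteotypic(digests[[i]], proteins[[i]], proteins,
                              n_min = min(3L, config$peptides_per_protein),
                              n_max = config$peptides_per_protein,
                              library = library)
    targets[[i]] <- data.frame(
      peptide_id = peptide_id(sel$accession, sel$start, sel$end),
      accession = sel$accession, sequence = sel$sequence,
      form = "nonphospho", site = NA_character_, phospho_pos = NA_integer_,
      role = "quant")
  }
  # phospho / nonphospho pair for the annotated site on protein 1
  pp <- prot$phosphopeptide
  pair_id <- peptide_id(pp$accession, pp$start, pp$end)
  targets[[length(targets) + 1L]] <- data.frame(
    peptide_id = pair_id, accession = pp$accession, sequence = pp$sequence,
    form = c("phospho", "nonphospho"), site = pp$site_label,
    phospho_pos = pp$phospho_pos_in_peptide, role = "phospho_pair")
  targets <- do.call(rbind, targets)

  transitions <- build_transition_list(
    library, targets, charges = config$charges,
    k_fragments = config$k_fragments, irt_slope = config$irt_slope,
    irt_intercept = config$irt_intercept, rt_window = config$rt_window)
  transitions <- merge(transitions,
                       targets[, c("peptide_id", "form", "role")],
                       by = c("peptide_id", "form"), sort = FALSE)
  w <- setNames(config$charge_weights, as.character(config$charges))
  transitions$charge_weight <- unname(w[as.character(
    transitions$precursor_charge)])

  dt <- make_design(config, seed,
                    proteins = vapply(proteins, `[[`, character(1),
                                      "accession"),
                    sites = pp$site_label)
  dt$truth$peak$rt_center <- setNames(
    config$irt_intercept + config$irt_slope * library$irt, names(library$irt))

  xics <- simulate_xics(dt$truth, transitions, dt$design, config, seed)

  list(config = config, proteins = proteins, library = library,
       targets = targets, transitions = transitions,
       design = dt$design, truth = dt$truth, xics = xics)
}

#' Construct synthetic proteins from unique tryptic peptides
#'
#' Each protein is a concatenation of randomly drawn tryptic peptides (8-14
#' residues from the alphabet excluding M/K/R/P, terminated by K or R), so
#' its zero-missed-cleavage digest is exactly the designed peptide set. The
#' first protein additionally carries a phosphopeptide with an annotated
#' phosphoserine, and every protein ends with a shared (non-proteotypic)
#' peptide plus one methionine-containing peptide so that the selection rules
#' are exercised.
#'
#' @param n_proteins number of proteins.
#' @param peptides_per_protein proteotypic peptides available per protein.
#' @param seed integer seed.
#' @return list `records` (list of [protein_record()]) and `phosphopeptide`
#'   (accession, sequence, start, end, site_label, phospho_pos_in_peptide).
#' @export
make_synthetic_proteins <- function(n_proteins = 2L,
                                    peptides_per_protein = 3L, seed = 1L) {
  stopifnot(n_proteins >= 1L, peptides_per_protein >= 1L)
  pool <- setdiff(AA_ALPHABET, c("M", "K", "R", "P"))
  with_seed(seed, {
    draw_peptide <- function(len, force_ser_at = NA) {
      body <- sample(pool, len - 1L, replace = TRUE)
      if (!is.na(force_ser_at)) body[force_ser_at] <- "S"
      paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
    }
    seen <- character()
    unique_peptide <- function(len, force_ser_at = NA) {
      repeat {
        p <- draw_peptide(len, force_ser_at)
        if (!p %in% seen) {
          seen <<- c(seen, p)
          return(p)
        }
      }
    }
    shared <- unique_peptide(sample(8:12, 1L))
    records <- vector("list", n_proteins)
    phospho <- NULL
    for (i in seq_len(n_proteins)) {
      acc <- sprintf("P%02d", i)
      peps <- vapply(seq_len(peptides_per_protein),
                     function(j) unique_peptide(sample(8:14, 1L)),
                     character(1))
      met_pep <- sub("^.", "M", unique_peptide(sample(8:12, 1L)))
      parts <- c(peps, met_pep, shared)
      mod_sites <- data.frame(position = integer(), label = character())
      if (i == 1L) {
        len <- sample(9:12, 1L)
        ser_at <- sample(3:(len - 3L), 1L)
        ppep <- unique_peptide(len, force_ser_at = ser_at)
        parts <- append(parts, ppep, after = peptides_per_protein)
        offset <- sum(nchar(peps))
        site_pos <- offset + ser_at
        site_label <- sprintf("%s_S%d", acc, site_pos)
        mod_sites <- data.frame(position = site_pos,
                                label = "phospho")
        phospho <- list(accession = acc, sequence = ppep,
                        start = offset + 1L, end = offset + nchar(ppep),
                        site_label = site_label,
                        phospho_pos_in_peptide = ser_at)
      }
      records[[i]] <- protein_record(acc, paste(parts, collapse = ""),
                                     mod_sites)
    }
    list(records = records, phosphopeptide = phospho)
  })
}
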