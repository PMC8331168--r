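#' Estimate the chromatographic background level
#'
#' The background is the mean of the lowest decile of intensities inside the
#' window — robust as long as the peak occupies less than ~90% of the window.
#' The result is clipped at zero.
#'
#' @param time,intensity the trace (min, a.u.); times strictly increasing.
#' @param window optional numeric length-2 time range (min); default the full
#'   trace.
#' @return background level (a.u., >= 0).
#' @export
estimate_baseline <- function(time, intensity, window = range(time)) {
  stopifnot(length(time) == length(intensity), length(time) >= 5L,
            all(diff(time) > 0))
  idx <- time >= window[1] & time <= window[2]
  if (!any(idx)) stop("window does not overlap the time grid", call. = FALSE)
  v <- sort(intensity[idx])
  k <- max(1L, ceiling(0.1 * length(v)))
  max(0, mean(v[seq_len(k)]))
}

#' Locate a peak and its integration boundaries
#'
#' The apex is the intensity maximum within `expected_rt +/- window/2`.
#' Boundaries extend outward from the apex to the first point whose
#' baseline-subtracted intensity falls to <= 1% of the baseline-subtracted
#' apex, or to a local minimum, whichever comes first. An apex not exceeding
#' the background by `3 x MAD` of the trace (the conventional 3-sigma rule)
#' yields a "no peak" result rather than an error.
#'
#' @param time,intensity the trace.
#' @param expected_rt scheduled retention time (min).
#' @param window full search window width (min).
#' @param background background level; default [estimate_baseline()] on the
#'   whole trace.
#' @return list of class `peak_result`: `start`, `end`, `apex_time`,
#'   `apex_intensity`, `background`, `no_peak`.
#' @export
detect_peak <- function(time, intensity, expected_rt, window,
                        background = estimate_baseline(time, intensity)) {
  stopifnot(length(time) == length(intensity), length(time) >= 5L,
            all(diff(time) > 0))
  region <- which(time >= expected_rt - window / 2 &
                    time <= expected_rt + window / 2)
  if (length(region) == 0L) {
    stop("search window lies outside the time grid", call. = FALSE)
  }
  apex_rel <- which.max(intensity[region])
  apex <- region[apex_rel]
  apex_val <- intensity[apex]
  noise <- mad(intensity)
  if (apex_val <= background || apex_val < background + 3 * noise) {
    return(structure(list(start = NA_real_, end = NA_real_,
                          apex_time = NA_real_, apex_intensity = apex_val,
                          background = background, no_peak = TRUE),
                     class = "peak_result"))
  }
  cut <- background + 0.01 * (apex_val - background)
  half <- background + 0.5 * (apex_val - background)
  n <- length(time)
  # Walk outward until the 1% cutoff, or until a valley: a running minimum
  # below half height followed by a climb exceeding 1.5x the valley height
  # plus 3x the trace MAD (so noise dips on a peak flank do not truncate
  # the peak, but the saddle before a neighbouring peak does).
  walk <- function(step) {
    i <- apex
    runmin <- apex
    while ((step < 0 && i > 1L) || (step > 0 && i < n)) {
      i <- i + step
      if (intensity[i] <= cut) return(i)
      if (intensity[i] < intensity[runmin]) runmin <- i
      if (intensity[runmin] <= half &&
          intensity[i] - background >
            1.5 * (intensity[runmin] - background) + 3 * noise) {
        return(runmin)
      }
    }
    i
  }
  left <- walk(-1L)
  right <- walk(1L)
  structure(list(start = time[left], end = time[right],
                 apex_time = time[apex], apex_intensity = apex_val,
                 background = background, no_peak = FALSE),
            class = "peak_result")
}

#' Integrate a peak
#'
#' Trapezoidal integral of the background-subtracted intensity, clipped at
#' zero, over `[start, end]`.
#'
#' @param time,intensity the trace.
#' @param bounds numeric length-2 `(start, end)` in min, or a `peak_result`.
#' @param background background level (a.u.).
#' @return area in a.u. * min (>= 0).
#' @export
integrate_peak <- function(time, intensity, bounds, background = 0) {
  if (inherits(bounds, "peak_result")) {
    if (isTRUE(bounds$no_peak)) return(0)
    background <- bounds$background
    bounds <- c(bounds$start, bounds$end)
  }
  stopifnot(length(bounds) == 2L)
  if (bounds[1] > bounds[2]) stop("inverted integration bounds", call. = FALSE)
  idx <- which(time >= bounds[1] & time <= bounds[2])
  if (length(idx) < 2L) return(0)
  y <- pmax(intensity[idx] - background, 0)
  pracma::trapz(time[idx], y)
}

#' Select the k most intense fragments
#'
#' Returns the `k` largest areas, ties broken by ion label ascending. If
#' fewer than `k` fragments exist all are returned and a warning attribute
#' `"short"` is set.
#'
#' @param areas named non-negative numeric vector (fragment -> area).
#' @param k number of fragments to keep (default 3).
#' @return named numeric vector in rank order.
#' @export
top_k_fragments <- function(areas, k = 3L) {
  stopifnot(is.numeric(areas), !is.null(names(areas)), all(areas >= 0))
  ord <- order(-areas, names(areas))
  short <- length(areas) < k
  out <- areas[ord[seq_len(min(k, length(areas)))]]
  attr(out, "short") <- short
  out
}

#' Integrate all chromatograms of a dataset into a fragment-area table
#'
#' For every (sample, transition) trace: estimate the background, locate the
#' peak around the scheduled RT, and integrate. Per (sample, peptide form,
#' precursor charge) only the `k` most intense fragments are retained.
#' Transitions with no detectable peak contribute area 0 with flag
#' `"no_peak"` so that downstream sums stay defined.
#'
#' @param xics long chromatogram data.frame (`sample_id`, `transition_id`,
#'   `time_min`, `intensity`).
#' @param transitions transition list carrying `rt_center` and the peptide
#'   annotation columns.
#' @param search_window full apex search window width (min), default 1.
#' @param k fragments retained per peptide/charge (default 3).
#' @return data.frame `sample_id`, `transition_id`, `protein`, `peptide_id`,
#'   `peptide`, `form`, `site`, `role`, `precursor_charge`, `fragment`,
#'   `area`, `flag`.
#' @export
integrate_chromatograms <- function(xics, transitions, search_window = 1,
                                    k = 3L) {
  stopifnot(all(c("sample_id", "transition_id", "time_min", "intensity")
                %in% names(xics)))
  tr_idx <- match(xics$transition_id, transitions$transition_id)
  if (anyNA(tr_idx)) {
    stop("chromatogram references unknown transition(s)", call. = FALSE)
  }
  key <- paste(xics$sample_id, xics$transition_id, sep = "\r")
  groups <- split(seq_len(nrow(xics)), key)
  ng <- length(groups)
  tr_row <- integer(ng)
  sample_id <- character(ng)
  area <- numeric(ng)
  flag <- character(ng)
  for (g in seq_len(ng)) {
    idx <- groups[[g]]
    ti <- match(xics$transition_id[idx[1]], transitions$transition_id)
    tr_row[g] <- ti
    sample_id[g] <- xics$sample_id[idx[1]]
    time <- xics$time_min[idx]
    y <- xics$intensity[idx]
    if (is.unsorted(time)) {
      ord <- order(time)
      time <- time[ord]; y <- y[ord]
    }
    pk <- detect_peak(time, y, expected_rt = transitions$rt_center[ti],
                      window = search_window)
    area[g] <- integrate_peak(time, y, pk)
    flag[g] <- if (pk$no_peak) "no_peak" else "ok"
  }
  tab <- data.frame(
    sample_id = sample_id,
    transition_id = transitions$transition_id[tr_row],
    protein = transitions$protein[tr_row],
    peptide_id = transitions$peptide_id[tr_row],
    peptide = transitions$peptide[tr_row],
    form = transitions$form[tr_row],
    site = transitions$site[tr_row],
    role = if ("role" %in% names(transitions))
      transitions$role[tr_row] else NA_character_,
    precursor_charge = transitions$precursor_charge[tr_row],
    fragment = transitions$fragment[tr_row],
    area = area, flag = flag
  )
  # retain top-k fragments per sample x peptide form x charge
  grp <- paste(tab$sample_id, tab$peptide_id, tab$form, tab$precursor_charge,
               sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(tab)), grp), function(idx) {
    a <- setNames(tab$area[idx], tab$fragment[idx])
    idx[tab$fragment[idx] %in% names(top_k_fragments(a, k))]
  }), use.names = FALSE)
  tab <- tab[sort(keep), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
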