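#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every lysine (K) or arginine (R) that is
#' not followed by proline, and enumerates all peptides carrying up to
#' `max_missed` internal (missed) cleavage sites, with 1-based coordinates in
#' the parent sequence.
#'
#' @param sequence amino-acid string over the 20-letter alphabet.
#' @param max_missed maximum number of missed cleavages (>= 0).
#' @return data.frame with columns `sequence`, `start`, `end`, `missed`,
#'   ordered by `start` then `missed`.
#' @examples
#' digest_trypsin("MKAAARTEST", max_missed = 0)$sequence  # MK, AAAR, TEST
#' @export
digest_trypsin <- function(sequence, max_missed = 0L) {
  assert_aa_sequence(sequence)
  stopifnot(length(max_missed) == 1L, max_missed >= 0)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  # cleavage sites: after position i when chars[i] is K/R and chars[i+1] != P
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | chars[pmin(cut_after + 1L, n)] != "P"]
  starts <- c(1L, cut_after[cut_after < n] + 1L)
  ends <- c(cut_after[cut_after < n], n)
  base <- data.frame(start = starts, end = ends)
  out <- list()
  for (m in 0:max_missed) {
    i <- seq_len(nrow(base) - m)
    if (length(i) == 0L) break
    out[[m + 1L]] <- data.frame(
      start = base$start[i], end = base$end[i + m], missed = m
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$missed), , drop = FALSE]
  res$sequence <- substring(sequence, res$start, res$end)
  rownames(res) <- NULL
  res[, c("sequence", "start", "end", "missed")]
}
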