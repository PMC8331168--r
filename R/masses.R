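# Monoisotopic masses (Da). Residue masses are for amino-acid residues within a
# chain (i.e. minus water); the standard values used across targeted proteomics.

AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

#' Monoisotopic mass shift of phosphorylation (Da)
#'
#' The HPO3 addition on Ser/Thr/Tyr: +79.96633 Da.
#' @export
PHOSPHO_MASS <- 79.96633

#' The twenty amino-acid one-letter codes
#' @keywords internal
AA_ALPHABET <- names(AA_MONO)

assert_aa_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  bad <- setdiff(strsplit(sequence, "")[[1]], AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("sequence contains non-amino-acid characters: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(sequence)
}
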