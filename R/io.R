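# Plain-text persistence for synthetic datasets: config as YAML, design /
# transitions / targets as CSV, ground truth and spectral library as JSON,
# chromatograms as a four-column TSV. Numeric columns are written with 15
# significant digits so a write -> read round trip reproduces values well
# below 1e-9 relative error, and formatting is deterministic so identical
# objects produce byte-identical files.

fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

write_table_formatted <- function(df, path, sep = ",") {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- fmt_num(out[[nm]])
    }
  }
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
              eol = "\n", fileEncoding = "UTF-8")
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Persists `config.yaml`, `design.csv`, `ground_truth.json`,
#' `library.json`, `targets.csv`, `transitions.csv` and
#' `chromatograms.tsv` (header
#' `sample_id<TAB>transition_id<TAB>time_min<TAB>intensity`).
#'
#' @param dataset list from [simulate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  cfg <- unclass(dataset$config)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  write_table_formatted(dataset$design, file.path(out_dir, "design.csv"))
  jsonlite::write_json(dataset$truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null", pretty = TRUE)
  jsonlite::write_json(list(fragments = dataset$library$fragments,
                            irt = as.list(dataset$library$irt)),
                       file.path(out_dir, "library.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE)
  write_table_formatted(dataset$targets, file.path(out_dir, "targets.csv"))
  write_table_formatted(dataset$transitions,
                        file.path(out_dir, "transitions.csv"))
  write_table_formatted(dataset$xics, file.path(out_dir, "chromatograms.tsv"),
                        sep = "\t")
  invisible(out_dir)
}

read_csv_plain <- function(path, sep = ",") {
  read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

json_to_df <- function(x) {
  if (is.null(x)) return(NULL)
  as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `config`, `design`, `truth`, `library`, `targets`,
#'   `transitions`, `xics`.
#' @export
read_dataset <- function(dir) {
  need <- c("config.yaml", "design.csv", "ground_truth.json", "library.json",
            "targets.csv", "transitions.csv", "chromatograms.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0L) {
    stop("dataset directory ", dir, " is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  for (nm in c("fold", "occupancy")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.data.frame(cfg[[nm]])
  }
  for (nm in c("replicates", "n_proteins", "peptides_per_protein",
               "charges", "k_fragments", "n_fragments_lib")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  cfg <- do.call(sim_config, cfg)

  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  truth <- list(abundance = as.data.frame(gt$abundance),
                occupancy = json_to_df(gt$occupancy),
                noise = gt$noise,
                peak = list(sigma_rt = gt$peak$sigma_rt,
                            tau_rt = gt$peak$tau_rt,
                            rt_center = unlist(gt$peak$rt_center)),
                seed = as.integer(gt$seed))

  lib <- jsonlite::read_json(file.path(dir, "library.json"),
                             simplifyVector = TRUE)
  library <- list(fragments = as.data.frame(lib$fragments),
                  irt = unlist(lib$irt))

  xics <- read_chromatograms(file.path(dir, "chromatograms.tsv"))
  list(config = cfg,
       design = read_csv_plain(file.path(dir, "design.csv")),
       truth = truth, library = library,
       targets = read_csv_plain(file.path(dir, "targets.csv")),
       transitions = read_csv_plain(file.path(dir, "transitions.csv")),
       xics = xics)
}

#' Read a chromatogram TSV
#'
#' Expects the four-column dialect written by [write_dataset()]; a malformed
#' or truncated file raises a parse error naming the offending line.
#'
#' @param path TSV file.
#' @return data.frame `sample_id`, `transition_id`, `time_min`, `intensity`.
#' @export
read_chromatograms <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "")
  bad <- which(is.na(nf) | nf != 4L)
  if (length(bad) > 0L) {
    stop("parse error in ", path, " at line ", bad[1],
         ": expected 4 tab-separated fields", call. = FALSE)
  }
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "character"))
  expected <- c("sample_id", "transition_id", "time_min", "intensity")
  if (!identical(names(df), expected)) {
    stop("parse error in ", path, " at line 1: header must be ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  for (nm in c("time_min", "intensity")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v)) {
      stop("parse error in ", path, " at line ",
           which(is.na(v))[1] + 1L, ": non-numeric ", nm, call. = FALSE)
    }
    df[[nm]] <- v
  }
  df
}

#' Export a transition list in the documented CSV dialect
#'
#' Header: `protein,peptide_modified_sequence,precursor_charge,fragment_ion,
#' product_charge,precursor_mz,product_mz,rt_start_min,rt_end_min`, with
#' phosphorylation written in `S[+80.0]` style on the modified residue.
#'
#' @param transitions transition table from [build_transition_list()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(transitions, path) {
  modseq <- mapply(function(seq, form, pos) {
    if (!is.na(pos) && form == "phospho") {
      paste0(substr(seq, 1, pos), "[+80.0]",
             substr(seq, pos + 1L, nchar(seq)))
    } else seq
  }, transitions$peptide, transitions$form, transitions$phospho_pos)
  out <- data.frame(
    protein = transitions$protein,
    peptide_modified_sequence = unname(modseq),
    precursor_charge = transitions$precursor_charge,
    fragment_ion = transitions$fragment,
    product_charge = transitions$product_charge,
    precursor_mz = transitions$precursor_mz,
    product_mz = transitions$product_mz,
    rt_start_min = transitions$rt_start,
    rt_end_min = transitions$rt_end
  )
  write_table_formatted(out, path)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file of protein sequences.
#' @return list of [protein_record()] (no annotated modification sites).
#' @export
read_protein_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  lapply(names(seqs), function(nm)
    protein_record(nm, toupper(seqs[[nm]])))
}

#' Write protein records to FASTA
#' @param proteins list of [protein_record()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  seqinr::write.fasta(lapply(proteins, `[[`, "sequence"),
                      names = vapply(proteins, `[[`, character(1),
                                     "accession"),
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}
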