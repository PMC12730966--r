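# Plain-text readers and writers: FASTA genomes, BED-like methylome tracks,
# TSV band matrices, CSV Ct tables, YAML configs.

#' Read / write a genome FASTA
#'
#' Thin wrappers over Biostrings keeping the package's working
#' representation (a named character vector of uppercase sequences).
#'
#' @param path File path.
#' @return `read_genome_fasta`: named character vector.
#' @export
read_genome_fasta <- function(path) {
  .as_genome(Biostrings::readDNAStringSet(path))
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- .as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read / write a CCGG methylome track
#'
#' Four-column BED-like TSV, no header: `seq_id`, `start` (0-based position
#' of the first C of the CCGG), `end` (`start + 4`), `state` (one of
#' [MSAP_STATES]).
#'
#' @param path File path.
#' @return `read_methylome_track`: data.frame `seq_id`, `start`, `state`.
#' @export
read_methylome_track <- function(path) {
  tr <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("seq_id", "start", "end", "state"))
  if (any(tr$end != tr$start + 4)) {
    stop("methylome track intervals must span exactly the 4 bp CCGG motif")
  }
  bad <- setdiff(unique(tr$state), MSAP_STATES)
  if (length(bad) > 0) {
    stop("unknown state(s) in track: ", paste(bad, collapse = ", "))
  }
  tr[, c("seq_id", "start", "state")]
}

#' @rdname read_methylome_track
#' @param track data.frame with columns `seq_id`, `start`, `state`.
#' @export
write_methylome_track <- function(track, path) {
  out <- data.frame(seq_id = track$seq_id, start = track$start,
                    end = track$start + 4L, state = track$state)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a band matrix
#'
#' TSV with a header row: a `locus` column followed by paired `<sample>_H`
#' and `<sample>_M` columns with cells in `{0, 1, NA}`. The reader validates
#' that every sample has both lanes and that cells are binary or missing.
#'
#' @param path File path.
#' @return `read_band_matrix`: validated band matrix data.frame.
#' @export
read_band_matrix <- function(path) {
  mat <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"locus" %in% names(mat)) stop("band matrix must have a locus column")
  samples <- .matrix_sample_cols(mat)
  locus <- as.character(mat$locus)
  for (s in samples) {
    .check_binary(mat[[paste0(s, "_H")]], "HpaII lane", locus, s,
                  allow_na = TRUE)
    .check_binary(mat[[paste0(s, "_M")]], "MspI lane", locus, s,
                  allow_na = TRUE)
  }
  mat
}

#' @rdname read_band_matrix
#' @param mat Band matrix data.frame.
#' @export
write_band_matrix <- function(mat, path) {
  .matrix_sample_cols(mat)
  write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Ct table
#'
#' CSV with columns `sample`, `condition`, `gene`, `replicate` (optional),
#' `ct`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "gene", "ct")
  if (!all(need %in% names(tab))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' Read an analysis configuration
#'
#' YAML file with optional keys `n_bp`, `gc_content`, `n_ecori_min`,
#' `n_ccgg_min`, `min_len`, `max_len`, `gel_mode`, `d`, `m`, `prior`
#' (named map over [MSAP_STATES]). Unknown keys are rejected.
#'
#' @param path File path.
#' @return Named list of settings.
#' @export
read_msap_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("n_bp", "gc_content", "n_ecori_min", "n_ccgg_min",
             "min_len", "max_len", "gel_mode", "d", "m", "prior")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$prior)) cfg$prior <- unlist(cfg$prior)
  cfg
}
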