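# In silico EcoRI + HpaII/MspI double digestion of a genome with a CCGG
# methylome track, and conversion of resolvable fragments into MSAP band
# matrices. Coordinates are 0-based half-open throughout.

.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  } else if (inherits(genome, "DNAString")) {
    genome <- as.character(genome)
  }
  if (!is.character(genome)) {
    stop("genome must be a character vector or a Biostrings DNAStringSet")
  }
  genome <- toupper(genome)
  if (is.null(names(genome))) {
    names(genome) <- if (length(genome) == 1) "seq1"
                     else paste0("seq", seq_along(genome))
  }
  genome
}

#' Locate EcoRI and CCGG sites in a sequence
#'
#' 0-based start positions of every `GAATTC` and every `CCGG` occurrence on
#' the forward strand. Both motifs are palindromic, so forward-strand
#' scanning covers both strands; windows containing `N` never match.
#'
#' @param sequence A single DNA sequence (character scalar or
#'   `Biostrings::DNAString`) over `A,C,G,T,N`.
#' @return List with integer vectors `ecori` and `ccgg` (0-based motif
#'   starts, sorted).
#' @examples
#' find_sites("AAGAATTCAACCGG")
#' @export
find_sites <- function(sequence) {
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1) {
    stop("sequence must be a single character string")
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) {
    return(list(ecori = integer(0), ccgg = integer(0)))
  }
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         substr(bad, 1, 5))
  }
  subj <- Biostrings::DNAString(sequence)
  scan1 <- function(motif) {
    if (nchar(sequence) < nchar(motif)) return(integer(0))
    as.integer(Biostrings::start(
      Biostrings::matchPattern(motif, subj, fixed = TRUE))) - 1L
  }
  list(ecori = scan1("GAATTC"), ccgg = scan1("CCGG"))
}

# Does the lane enzyme cut a CCGG in the given canonical state?
.state_cuts <- function(state, lane) {
  out <- logical(length(state))
  canon <- state %in% rownames(.STATE_FLAGS)
  if (any(canon)) {
    fl <- .STATE_FLAGS[state[canon], , drop = FALSE]
    out[canon] <- if (lane == "hpaii") {
      hpaii_cuts(fl[, 1], fl[, 2], fl[, 3], fl[, 4])
    } else {
      mspi_cuts(fl[, 1], fl[, 2], fl[, 3], fl[, 4])
    }
  }
  out  # ABSENT (and anything non-canonical) is never cut
}

#' Double-digest a genome in one MSAP lane
#'
#' Cuts at every EcoRI site (methylation-insensitive, between the G and A of
#' `GAATTC`) and at every CCGG site whose methylation state permits cleavage
#' by the lane's enzyme (between the two Cs, `C|CGG`); see [hpaii_cuts()] for
#' the sensitivity model. CCGG sites not covered by the track are treated as
#' unmethylated; `ABSENT` sites are never cut, so the fragment they would
#' define does not appear. Returns the maximal uncut intervals.
#'
#' @param genome Named character vector of sequences (or `DNAStringSet`).
#' @param track Methylome track: data.frame with columns `seq_id`, `start`
#'   (0-based position of the first C of CCGG) and `state` (one of
#'   [MSAP_STATES]); `NULL` means fully unmethylated.
#' @param lane `"hpaii"` or `"mspi"`.
#' @return data.frame of fragments: `seq_id`, `start`, `end` (0-based
#'   half-open), `length`, `left_end`, `right_end` (one of `SEQ_START`,
#'   `SEQ_END`, `EcoRI`, `HpaII`/`MspI`).
#' @export
digest_genome <- function(genome, track = NULL, lane = c("hpaii", "mspi")) {
  lane <- match.arg(lane)
  genome <- .as_genome(genome)
  enzyme <- if (lane == "hpaii") "HpaII" else "MspI"
  if (!is.null(track)) {
    need <- c("seq_id", "start", "state")
    if (!all(need %in% names(track))) {
      stop("track must have columns seq_id, start, state")
    }
    bad_seq <- setdiff(unique(track$seq_id), names(genome))
    if (length(bad_seq) > 0) {
      stop("track references unknown sequence(s): ",
           paste(bad_seq, collapse = ", "))
    }
    bad_state <- setdiff(unique(track$state), MSAP_STATES)
    if (length(bad_state) > 0) {
      stop("track contains unknown state(s): ",
           paste(bad_state, collapse = ", "))
    }
  }
  res <- lapply(names(genome), function(sid) {
    seq <- genome[[sid]]
    len <- nchar(seq)
    sites <- find_sites(seq)
    states <- rep("UNMETHYLATED", length(sites$ccgg))
    if (!is.null(track)) {
      tr <- track[track$seq_id == sid, , drop = FALSE]
      if (anyDuplicated(tr$start)) {
        stop("duplicate track positions on ", sid)
      }
      idx <- match(tr$start, sites$ccgg)
      if (anyNA(idx)) {
        stop("track position ", tr$start[which(is.na(idx))[1]], " on ", sid,
             " does not address a CCGG site")
      }
      states[idx] <- tr$state
    }
    ccgg_cut <- sites$ccgg[.state_cuts(states, lane)]
    cuts <- c(sites$ecori + 1L, ccgg_cut + 1L)
    labels <- c(rep("EcoRI", length(sites$ecori)),
                rep(enzyme, length(ccgg_cut)))
    o <- order(cuts)
    cuts <- cuts[o]
    labels <- labels[o]
    bounds <- c(0L, cuts, len)
    endlab <- c("SEQ_START", labels, "SEQ_END")
    n <- length(bounds) - 1L
    data.frame(seq_id = rep(sid, n),
               start = bounds[-length(bounds)],
               end = bounds[-1],
               length = bounds[-1] - bounds[-length(bounds)],
               left_end = endlab[-length(endlab)],
               right_end = endlab[-1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Select gel-resolvable MSAP bands from a fragment set
#'
#' The adapter/primer scheme of the assay amplifies fragments with one EcoRI
#' end and one HpaII/MspI end; the length window models what a PAGE gel
#' resolves (default 50--700 bp).
#'
#' @param fragments Fragment data.frame from [digest_genome()].
#' @param min_len,max_len Inclusive fragment-length window in bp.
#' @param require_mixed_ends Keep only EcoRI x HpaII/MspI fragments.
#' @return Filtered fragment data.frame.
#' @export
select_bands <- function(fragments, min_len = 50, max_len = 700,
                         require_mixed_ends = TRUE) {
  if (min_len >= max_len) stop("min_len must be smaller than max_len")
  keep <- fragments$length >= min_len & fragments$length <= max_len
  if (require_mixed_ends) {
    msens <- c("HpaII", "MspI")
    mixed <- (fragments$left_end == "EcoRI" & fragments$right_end %in% msens) |
             (fragments$left_end %in% msens & fragments$right_end == "EcoRI")
    keep <- keep & mixed
  }
  fragments[keep, , drop = FALSE]
}

.locus_key <- function(bands) {
  paste0(bands$seq_id, ":", bands$start, "-", bands$end)
}

# CCGG motif start (0-based) defining the methylation-sensitive end of a
# mixed-end band: the cut is between the two Cs, one base right of the start.
.band_ccgg_start <- function(bands) {
  msens <- bands$right_end %in% c("HpaII", "MspI")
  ifelse(msens, bands$end - 1L, bands$start - 1L)
}

.union_loci <- function(band_sets) {
  all <- do.call(rbind, band_sets)
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(locus = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), ccgg_start = integer(0)))
  }
  key <- paste0(all$seq_id, ":", all$start, "-", all$end)
  first <- !duplicated(key)
  out <- data.frame(locus = key[first],
                    seq_id = all$seq_id[first],
                    start = all$start[first],
                    end = all$end[first],
                    length = all$length[first],
                    ccgg_start = .band_ccgg_start(all)[first],
                    stringsAsFactors = FALSE)
  out[order(out$seq_id, out$start, out$end), , drop = FALSE]
}

#' All scorable loci of a genome
#'
#' The EcoRI--CCGG fragments of the fully cleaved digest (every CCGG cut,
#' i.e. an unmethylated genome) that pass [select_bands()]. This is the locus
#' universe against which partial (methylated) digests are scored; each locus
#' carries the 0-based start of the CCGG site that defines its
#' methylation-sensitive end.
#'
#' @inheritParams digest_genome
#' @inheritParams select_bands
#' @return data.frame with columns `locus`, `seq_id`, `start`, `end`,
#'   `length`, `ccgg_start`.
#' @export
candidate_loci <- function(genome, min_len = 50, max_len = 700) {
  frags <- digest_genome(genome, track = NULL, lane = "hpaii")
  .union_loci(list(select_bands(frags, min_len, max_len)))
}

#' Score one sample's two lanes into a band-pair table
#'
#' A locus scores `h = 1` (resp. `m = 1`) iff its fragment appears in the
#' HpaII (resp. MspI) lane band set. In exact mode a fragment "appears" when
#' its coordinates match; in gel mode (`gel_mode = TRUE`) fragments comigrate
#' by length, so a band of the locus's length anywhere in the lane counts --
#' the realistic ambiguity of a PAGE gel.
#'
#' @param hpaii_bands,mspi_bands Band sets from [digest_genome()] +
#'   [select_bands()] on the same genome/track.
#' @param loci Locus universe (data.frame as from [candidate_loci()]);
#'   default: the union of the two lane band sets.
#' @param gel_mode Match bands by length instead of coordinates.
#' @return data.frame: `locus`, `seq_id`, `start`, `end`, `length`,
#'   `ccgg_start`, `h`, `m`.
#' @export
bands_to_matrix <- function(hpaii_bands, mspi_bands, loci = NULL,
                            gel_mode = FALSE) {
  if (is.null(loci)) loci <- .union_loci(list(hpaii_bands, mspi_bands))
  present <- function(bands) {
    if (gel_mode) as.integer(loci$length %in% bands$length)
    else as.integer(loci$locus %in% .locus_key(bands))
  }
  loci$h <- present(hpaii_bands)
  loci$m <- present(mspi_bands)
  loci
}

#' Digest and score one sample end to end
#'
#' Runs both lanes of the double digest, applies band selection, and scores
#' the loci.
#'
#' @inheritParams digest_genome
#' @inheritParams select_bands
#' @inheritParams bands_to_matrix
#' @return See [bands_to_matrix()].
#' @export
score_sample <- function(genome, track = NULL, min_len = 50, max_len = 700,
                         loci = NULL, gel_mode = FALSE) {
  h <- select_bands(digest_genome(genome, track, "hpaii"), min_len, max_len)
  m <- select_bands(digest_genome(genome, track, "mspi"), min_len, max_len)
  bands_to_matrix(h, m, loci = loci, gel_mode = gel_mode)
}
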