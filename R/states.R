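# CCGG methylation states and the HpaII/MspI sensitivity model.
#
# A CCGG duplex carries four potentially methylated cytosines: the external
# (5') and internal (3') C on each strand. The assay can only distinguish
# four canonical configurations plus fragment absence; the underlying
# representation keeps all 16 flag combinations so that the enzyme decision
# table is a total function.

#' Canonical CCGG methylation states
#'
#' The five states a CCGG locus can take in MSAP analysis:
#' `UNMETHYLATED` (no 5mC), `HEMI_EXTERNAL` (external C methylated on one
#' strand only), `FULL_INTERNAL` (internal C methylated on both strands),
#' `FULL_EXTERNAL` (external C methylated on both strands), and `ABSENT`
#' (the restriction fragment does not exist in this individual --
#' site polymorphism rather than methylation).
#'
#' @format Character vector of length 5.
#' @export
MSAP_STATES <- c("UNMETHYLATED", "HEMI_EXTERNAL", "FULL_INTERNAL",
                 "FULL_EXTERNAL", "ABSENT")

#' MSAP band types
#'
#' The four observable (HpaII, MspI) presence patterns: Type I (1,1)
#' unmethylated, Type II (1,0) hemi-methylated, Type III (0,1) internal
#' full methylation, Type IV (0,0) hypermethylated or absent.
#'
#' @format Character vector of length 4.
#' @export
BAND_TYPES <- c("I", "II", "III", "IV")

# Representative per-cytosine flags for each canonical state
# (ext_top, int_top, ext_bottom, int_bottom).
.STATE_FLAGS <- matrix(
  c(FALSE, FALSE, FALSE, FALSE,   # UNMETHYLATED
    TRUE,  FALSE, FALSE, FALSE,   # HEMI_EXTERNAL
    FALSE, TRUE,  FALSE, TRUE,    # FULL_INTERNAL
    TRUE,  FALSE, TRUE,  FALSE),  # FULL_EXTERNAL
  ncol = 4, byrow = TRUE,
  dimnames = list(MSAP_STATES[1:4],
                  c("ext_top", "int_top", "ext_bottom", "int_bottom")))

#' Enzyme cleavage decisions for a CCGG duplex
#'
#' The decision table that makes the band-type interpretation
#' self-consistent and matches canonical MSAP usage:
#' HpaII cleaves iff no internal cytosine is methylated and at most one
#' external cytosine is methylated (it tolerates hemi-methylation of the
#' external C but is blocked by full external methylation and by any
#' internal methylation); MspI cleaves iff no external cytosine is
#' methylated (it is indifferent to internal methylation).
#' Both functions are total over all 16 flag combinations.
#'
#' @param ext_top,int_top,ext_bottom,int_bottom Logical vectors: 5mC at the
#'   external/internal cytosine on the top/bottom strand.
#' @return Logical vector: does the enzyme cleave?
#' @export
hpaii_cuts <- function(ext_top, int_top, ext_bottom, int_bottom) {
  !(int_top | int_bottom) & ((ext_top + ext_bottom) <= 1L)
}

#' @rdname hpaii_cuts
#' @export
mspi_cuts <- function(ext_top, int_top, ext_bottom, int_bottom) {
  !(ext_top | ext_bottom)
}

#' Map per-cytosine methylation flags to a canonical state
#'
#' Deterministic on the four canonical flag patterns; any other combination
#' (e.g. simultaneous internal and external methylation) is permitted in the
#' representation but has no canonical name and returns `NA`.
#'
#' @inheritParams hpaii_cuts
#' @return Character vector over [MSAP_STATES] (never `"ABSENT"`), `NA` for
#'   non-canonical combinations.
#' @export
canonical_state <- function(ext_top, int_top, ext_bottom, int_bottom) {
  n_ext <- ext_top + ext_bottom
  n_int <- int_top + int_bottom
  out <- rep(NA_character_, length(n_ext))
  out[n_ext == 0 & n_int == 0] <- "UNMETHYLATED"
  out[n_ext == 1 & n_int == 0] <- "HEMI_EXTERNAL"
  out[n_ext == 0 & n_int == 2] <- "FULL_INTERNAL"
  out[n_ext == 2]              <- "FULL_EXTERNAL"
  out
}

#' Predicted band pair from per-cytosine flags
#'
#' Applies the enzyme decision table to all 16 flag combinations. A band is
#' present in a lane iff the lane's enzyme cleaves the site (the scored
#' EcoRI--HpaII/MspI fragment only exists when the methylation-sensitive cut
#' is made).
#'
#' @inheritParams hpaii_cuts
#' @return A data.frame with integer columns `h` and `m` (0/1).
#' @export
flags_to_bands <- function(ext_top, int_top, ext_bottom, int_bottom) {
  data.frame(
    h = as.integer(hpaii_cuts(ext_top, int_top, ext_bottom, int_bottom)),
    m = as.integer(mspi_cuts(ext_top, int_top, ext_bottom, int_bottom)))
}

#' Predicted band pair for canonical states
#'
#' `UNMETHYLATED -> (1,1)`, `HEMI_EXTERNAL -> (1,0)`,
#' `FULL_INTERNAL -> (0,1)`, `FULL_EXTERNAL -> (0,0)`, `ABSENT -> (0,0)`.
#' Total on [MSAP_STATES]; the canonical states go through the same decision
#' table as raw flags, `ABSENT` yields no band in either lane by definition.
#'
#' @param state Character vector over [MSAP_STATES].
#' @return A data.frame with integer columns `h` and `m` (0/1), one row per
#'   input state.
#' @export
predict_bands <- function(state) {
  bad <- setdiff(unique(state), MSAP_STATES)
  if (length(bad) > 0) {
    stop("unknown methylation state(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(h = integer(length(state)), m = integer(length(state)))
  canon <- state != "ABSENT"
  if (any(canon)) {
    fl <- .STATE_FLAGS[state[canon], , drop = FALSE]
    out[canon, ] <- flags_to_bands(fl[, 1], fl[, 2], fl[, 3], fl[, 4])
  }
  out
}

.check_binary <- function(x, what, locus = NULL, sample = NULL,
                          allow_na = FALSE) {
  ok <- x %in% c(0L, 1L)
  if (allow_na) ok <- ok | is.na(x)
  if (all(ok)) return(invisible(TRUE))
  i <- which(!ok)[1]
  ctx <- character(0)
  if (!is.null(locus)) ctx <- c(ctx, paste0("locus '", locus[i], "'"))
  if (!is.null(sample)) ctx <- c(ctx, paste0("sample '", sample, "'"))
  stop("non-binary ", what, " value '", x[i], "'",
       if (length(ctx)) paste0(" at ", paste(ctx, collapse = ", ")) else
         paste0(" at position ", i))
}

#' Classify a band pair into an MSAP band type
#'
#' `(1,1) -> I`, `(1,0) -> II`, `(0,1) -> III`, `(0,0) -> IV`. A bijection
#' between the four presence/absence patterns and the four band types.
#'
#' @param h,m Integer vectors of 0/1: band presence in the HpaII-EcoRI and
#'   MspI-EcoRI lanes.
#' @param locus Optional locus identifiers used in validation errors.
#' @param sample Optional sample name used in validation errors.
#' @return Character vector over [BAND_TYPES].
#' @examples
#' classify_band(1, 1)  # "I", unmethylated
#' classify_band(0, 1)  # "III", internal full methylation
#' @export
classify_band <- function(h, m, locus = NULL, sample = NULL) {
  if (length(h) != length(m)) stop("h and m must have equal length")
  .check_binary(h, "HpaII lane", locus, sample)
  .check_binary(m, "MspI lane", locus, sample)
  c("IV", "III", "II", "I")[2L * h + m + 1L]
}

#' Canonical states consistent with an observed band pair
#'
#' The inverse reading of [predict_bands()] over canonical states. All pairs
#' have a unique preimage except `(0,0)`, which is ambiguous by construction:
#' the band may be missing because the site is hypermethylated
#' (`FULL_EXTERNAL`) or because the fragment does not exist (`ABSENT`).
#'
#' @param h,m Scalars 0/1.
#' @return Character vector of canonical states (length 1 or 2).
#' @export
classify_state <- function(h, m) {
  if (length(h) != 1 || length(m) != 1) stop("classify_state takes one pair")
  .check_binary(h, "HpaII lane")
  .check_binary(m, "MspI lane")
  switch(paste0(h, m),
         "11" = "UNMETHYLATED",
         "10" = "HEMI_EXTERNAL",
         "01" = "FULL_INTERNAL",
         "00" = c("FULL_EXTERNAL", "ABSENT"))
}
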