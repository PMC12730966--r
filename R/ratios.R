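# Band-type counting and methylation ratio statistics for sample groups.

#' Round half away from zero
#'
#' Reported MSAP percentages are rounded half-away-from-zero (so 12.325
#' prints as 12.33), unlike base [round()]'s round-half-to-even. Internal
#' values stay unrounded; this is applied only for reporting.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # the 1e-8 guards against binary representation error at exact ties
  # (1.005 * 100 is stored fractionally below 100.5)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

.matrix_sample_cols <- function(mat) {
  cols <- setdiff(names(mat), "locus")
  h_cols <- grep("_H$", cols, value = TRUE)
  m_cols <- grep("_M$", cols, value = TRUE)
  samples_h <- sub("_H$", "", h_cols)
  samples_m <- sub("_M$", "", m_cols)
  if (!setequal(samples_h, samples_m) ||
      length(cols) != length(h_cols) + length(m_cols)) {
    stop("band matrix must have paired '<sample>_H' and '<sample>_M' columns")
  }
  samples_h
}

#' Samples present in a band matrix
#'
#' @param mat A band matrix: data.frame with a `locus` column and paired
#'   `<sample>_H` / `<sample>_M` 0/1 columns.
#' @return Character vector of sample names.
#' @export
band_matrix_samples <- function(mat) .matrix_sample_cols(mat)

#' Count MSAP band types over a sample group
#'
#' Tallies Type I--IV band pairs over all (locus, sample) cells of the
#' selected samples. Cells where either lane is `NA` are excluded pairwise
#' (the assay has no missing-data convention, so missing lanes simply do not
#' contribute a scorable cell); the number of exclusions is recorded.
#'
#' @param mat A band matrix (see [band_matrix_samples()]).
#' @param samples Character vector of sample names to pool; default all.
#' @return Named integer vector `c(I=, II=, III=, IV=)` of class
#'   `band_type_counts`, with attributes `n_cells` (scored cells) and
#'   `n_excluded` (cells dropped for missingness).
#' @examples
#' mat <- data.frame(locus = c("L1", "L2"), CK_H = c(1, 0), CK_M = c(1, 1))
#' count_band_types(mat, "CK")
#' @export
count_band_types <- function(mat, samples = NULL) {
  if (!is.data.frame(mat) || nrow(mat) == 0) {
    stop("band matrix must be a non-empty data.frame")
  }
  all_samples <- .matrix_sample_cols(mat)
  if (is.null(samples)) samples <- all_samples
  if (length(samples) == 0) stop("empty sample selection")
  unknown <- setdiff(samples, all_samples)
  if (length(unknown) > 0) {
    stop("unknown sample(s): ", paste(unknown, collapse = ", "))
  }
  locus <- if ("locus" %in% names(mat)) as.character(mat$locus)
           else as.character(seq_len(nrow(mat)))
  counts <- setNames(integer(4), BAND_TYPES)
  n_excl <- 0L
  for (s in samples) {
    h <- mat[[paste0(s, "_H")]]
    m <- mat[[paste0(s, "_M")]]
    .check_binary(h, "HpaII lane", locus, s, allow_na = TRUE)
    .check_binary(m, "MspI lane", locus, s, allow_na = TRUE)
    keep <- !is.na(h) & !is.na(m)
    n_excl <- n_excl + sum(!keep)
    if (any(keep)) {
      ty <- classify_band(h[keep], m[keep], locus = locus[keep], sample = s)
      tab <- table(factor(ty, levels = BAND_TYPES))
      counts <- counts + as.integer(tab)
    }
  }
  structure(counts, class = "band_type_counts",
            n_cells = sum(counts), n_excluded = n_excl)
}

#' @export
print.band_type_counts <- function(x, ...) {
  cat("MSAP band-type counts (", attr(x, "n_cells"), " cells",
      if (attr(x, "n_excluded") > 0)
        paste0(", ", attr(x, "n_excluded"), " excluded as missing"),
      ")\n", sep = "")
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}

.as_type_counts <- function(counts) {
  if (inherits(counts, "band_type_counts")) return(as.integer(counts))
  if (is.numeric(counts) && length(counts) == 4) {
    if (any(counts < 0) || any(counts != floor(counts))) {
      stop("band-type counts must be non-negative integers")
    }
    return(as.integer(counts))
  }
  stop("counts must be a band_type_counts object or a numeric vector ",
       "of length 4 (I, II, III, IV)")
}

#' Methylation ratio statistics from band-type counts
#'
#' The standard MSAP summary over a sample group, with `total = I+II+III+IV`:
#' \itemize{
#'   \item total methylated ratio = `(II+III+IV)/total * 100` (identical to
#'     the MSAP polymorphism percentage);
#'   \item fully methylated ratio = `(III+IV)/total * 100`;
#'   \item hemi-methylated ratio = `II/total * 100`;
#'   \item non-methylated ratio = `I/total * 100`.
#' }
#' Values are kept unrounded; the print method reports them rounded
#' half-away-from-zero to 2 decimals.
#'
#' @param counts A `band_type_counts` object or numeric vector
#'   `(I, II, III, IV)`.
#' @return A list of class `methylation_ratios` with elements `total_pct`,
#'   `full_pct`, `hemi_pct`, `non_pct` (unrounded, 0--100 scale), `counts`
#'   and `total`.
#' @examples
#' methylation_ratios(c(704, 40, 33, 26))  # total 12.33%, full 7.35%
#' @export
methylation_ratios <- function(counts) {
  n <- .as_type_counts(counts)
  total <- sum(n)
  if (total == 0) stop("no scorable loci: all band-type counts are zero")
  structure(list(
    total_pct = 100 * (n[2] + n[3] + n[4]) / total,
    full_pct  = 100 * (n[3] + n[4]) / total,
    hemi_pct  = 100 * n[2] / total,
    non_pct   = 100 * n[1] / total,
    counts = setNames(n, BAND_TYPES),
    total = total), class = "methylation_ratios")
}

#' @export
print.methylation_ratios <- function(x, digits = 2, ...) {
  cat("MSAP methylation ratios over", x$total, "bands\n")
  v <- round_half_up(c(total = x$total_pct, full = x$full_pct,
                       hemi = x$hemi_pct, non = x$non_pct), digits)
  cat(sprintf("  %-16s %6.2f %%\n",
              c("total methylated", "fully methylated", "hemi-methylated",
                "non-methylated"), v), sep = "")
  invisible(x)
}

#' @export
as.data.frame.methylation_ratios <- function(x, ..., digits = 2) {
  data.frame(statistic = c("total_pct", "full_pct", "hemi_pct", "non_pct"),
             percent = round_half_up(
               c(x$total_pct, x$full_pct, x$hemi_pct, x$non_pct), digits))
}

#' MSAP polymorphism percentage
#'
#' `100 * (II + III + IV) / (I + II + III + IV)` -- the fraction of scored
#' bands showing any methylation signature. Numerically identical to the
#' total methylated ratio of [methylation_ratios()]; both names are exposed
#' because both are used in the field.
#'
#' @inheritParams methylation_ratios
#' @return Unrounded percentage on the 0--100 scale.
#' @export
msap_polymorphism <- function(counts) methylation_ratios(counts)$total_pct

#' Annotation bookkeeping for sequenced fragments
#'
#' Percentage of excised MSAP fragments with / without a database annotation.
#'
#' @param n_annotated Number of fragments with a significant hit.
#' @param n_total Total sequenced fragments.
#' @return List with `annotated_pct` and `unannotated_pct` (unrounded,
#'   0--100).
#' @export
annotation_rates <- function(n_annotated, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_annotated < 0 || n_annotated > n_total) {
    stop("n_annotated must be between 0 and n_total")
  }
  list(annotated_pct = 100 * n_annotated / n_total,
       unannotated_pct = 100 * (n_total - n_annotated) / n_total)
}
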