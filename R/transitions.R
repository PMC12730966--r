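# Control-versus-treated band-pattern transitions: the fourteen standard
# classes (A1-A3 no change, B1-B5 demethylation, C1-C6 methylation) and the
# three summary rates.

# (control h, control m, treated h, treated m) for each labeled class.
.TRANSITIONS <- data.frame(
  label = c("A1", "A2", "A3",
            "B1", "B2", "B3", "B4", "B5",
            "C1", "C2", "C3", "C4", "C5", "C6"),
  category = c(rep("NO_CHANGE", 3), rep("DEMETHYLATION", 5),
               rep("METHYLATION", 6)),
  ch = c(1, 1, 0, 1, 0, 0, 0, 0, 1, 1, 1, 1, 1, 0),
  cm = c(1, 0, 1, 0, 1, 0, 0, 0, 1, 1, 1, 0, 0, 1),
  th = c(1, 1, 0, 1, 1, 1, 1, 0, 1, 0, 0, 0, 0, 0),
  tm = c(1, 0, 1, 1, 1, 1, 0, 1, 0, 1, 0, 1, 0, 0),
  stringsAsFactors = FALSE)
.TRANSITIONS$from_type <- classify_band(.TRANSITIONS$ch, .TRANSITIONS$cm)
.TRANSITIONS$to_type   <- classify_band(.TRANSITIONS$th, .TRANSITIONS$tm)
.TRANSITION_KEY <- with(.TRANSITIONS, paste(ch, cm, th, tm))

#' The transition-class lookup table
#'
#' The fourteen labeled control-to-treated band-pattern classes: A1--A3
#' (no change), B1--B5 (demethylation: the locus moves towards less
#' methylation, e.g. `II -> I`), C1--C6 (methylation, e.g. `I -> III`). Two
#' of the sixteen possible (control, treated) pattern pairs -- `III -> II`
#' and `IV -> IV` -- carry no standard label and classify as `UNCLASSIFIED`.
#'
#' @return A data.frame with columns `label`, `category`, `ch`, `cm`, `th`,
#'   `tm` (control/treated lane presences) and `from_type`, `to_type`.
#' @export
transition_patterns <- function() .TRANSITIONS

#' Classify a control/treated band-pair change
#'
#' Deterministic lookup of the (control, treated) pattern pair in the
#' fourteen-class table; the two pairs absent from the table return
#' `"UNCLASSIFIED"`.
#'
#' @param control_h,control_m,treated_h,treated_m Integer vectors of 0/1.
#' @param locus Optional locus identifiers for validation errors.
#' @return Character vector of class labels
#'   (`A1..A3`, `B1..B5`, `C1..C6`, `UNCLASSIFIED`).
#' @examples
#' classify_transition(1, 0, 1, 1)  # "B1": II -> I, demethylation
#' @export
classify_transition <- function(control_h, control_m, treated_h, treated_m,
                                locus = NULL) {
  lens <- c(length(control_h), length(control_m),
            length(treated_h), length(treated_m))
  if (length(unique(lens)) != 1) stop("band vectors must have equal length")
  .check_binary(control_h, "control HpaII lane", locus)
  .check_binary(control_m, "control MspI lane", locus)
  .check_binary(treated_h, "treated HpaII lane", locus)
  .check_binary(treated_m, "treated MspI lane", locus)
  key <- paste(control_h, control_m, treated_h, treated_m)
  idx <- match(key, .TRANSITION_KEY)
  out <- .TRANSITIONS$label[idx]
  out[is.na(idx)] <- "UNCLASSIFIED"
  out
}

#' Category (A/B/C) of a transition-class label
#'
#' @param label Character vector of class labels.
#' @return Character vector over `NO_CHANGE`, `DEMETHYLATION`,
#'   `METHYLATION`, `UNCLASSIFIED`.
#' @export
transition_category <- function(label) {
  idx <- match(label, .TRANSITIONS$label)
  out <- .TRANSITIONS$category[idx]
  out[label == "UNCLASSIFIED"] <- "UNCLASSIFIED"
  if (anyNA(out)) {
    stop("unknown transition label(s): ",
         paste(unique(label[is.na(out)]), collapse = ", "))
  }
  out
}

#' Summarise locus transitions between a control and a treated sample
#'
#' Classifies every locus and reports per-class counts and the three summary
#' rates. Percentages are computed over loci falling in the fourteen labeled
#' classes; `UNCLASSIFIED` loci (`III -> II`, `IV -> IV`, or a pair with a
#' missing lane) are counted and reported separately but excluded from the
#' denominator, which is the only convention consistent with the standard
#' printed rates.
#'
#' @inheritParams classify_transition
#' @param locus Optional locus identifiers; unclassified loci are reported by
#'   these ids.
#' @return A list of class `transition_summary`: `class_counts` (named counts
#'   over the 14 labels), `category_counts`, `n_classified`,
#'   `n_unclassified`, `unclassified_loci`, and unrounded `no_change_pct`,
#'   `demethylation_pct`, `methylation_pct` (0--100).
#' @examples
#' # one demethylated locus among three stable ones
#' transition_summary(c(1, 1, 0, 1), c(1, 0, 1, 0),
#'                    c(1, 1, 0, 1), c(1, 0, 1, 1))
#' @export
transition_summary <- function(control_h, control_m, treated_h, treated_m,
                               locus = NULL) {
  if (is.null(locus)) locus <- as.character(seq_along(control_h))
  keep <- !(is.na(control_h) | is.na(control_m) |
            is.na(treated_h) | is.na(treated_m))
  labels <- rep("UNCLASSIFIED", length(control_h))
  labels[keep] <- classify_transition(control_h[keep], control_m[keep],
                                      treated_h[keep], treated_m[keep],
                                      locus = locus[keep])
  class_counts <- table(factor(labels, levels = .TRANSITIONS$label))
  class_counts <- setNames(as.integer(class_counts), .TRANSITIONS$label)
  n_uncl <- sum(labels == "UNCLASSIFIED")
  n_class <- sum(class_counts)
  if (n_class == 0) {
    stop("no classifiable loci: every locus pattern is unclassified")
  }
  cat_counts <- vapply(c("NO_CHANGE", "DEMETHYLATION", "METHYLATION"),
                       function(cc) sum(class_counts[
                         .TRANSITIONS$label[.TRANSITIONS$category == cc]]),
                       integer(1))
  structure(list(
    class_counts = class_counts,
    category_counts = cat_counts,
    n_classified = n_class,
    n_unclassified = n_uncl,
    unclassified_loci = locus[labels == "UNCLASSIFIED"],
    no_change_pct = 100 * cat_counts[["NO_CHANGE"]] / n_class,
    demethylation_pct = 100 * cat_counts[["DEMETHYLATION"]] / n_class,
    methylation_pct = 100 * cat_counts[["METHYLATION"]] / n_class),
    class = "transition_summary")
}

#' Transition summary from per-class counts
#'
#' Convenience constructor when only the fourteen class counts are known
#' (e.g. re-analysing a published table).
#'
#' @param class_counts Numeric vector of length 14, named by class label or
#'   in table order (A1..A3, B1..B5, C1..C6).
#' @param n_unclassified Loci observed but not classifiable.
#' @return A `transition_summary` (see [transition_summary()]).
#' @export
transition_summary_from_counts <- function(class_counts, n_unclassified = 0) {
  if (length(class_counts) != 14) stop("expected 14 class counts")
  if (is.null(names(class_counts))) {
    names(class_counts) <- .TRANSITIONS$label
  }
  if (!setequal(names(class_counts), .TRANSITIONS$label)) {
    stop("class count names must be A1..A3, B1..B5, C1..C6")
  }
  # expand to per-locus pairs and reuse the main path
  cc <- class_counts[.TRANSITIONS$label]
  idx <- rep(seq_len(14), cc)
  s <- transition_summary(.TRANSITIONS$ch[idx], .TRANSITIONS$cm[idx],
                          .TRANSITIONS$th[idx], .TRANSITIONS$tm[idx])
  s$n_unclassified <- as.integer(n_unclassified)
  s$unclassified_loci <- character(0)
  s
}

#' @export
print.transition_summary <- function(x, digits = 2, ...) {
  cat("MSAP transition summary:", x$n_classified, "classified loci",
      if (x$n_unclassified > 0) paste0("(", x$n_unclassified,
                                       " unclassified, excluded)"), "\n")
  tab <- data.frame(class = names(x$class_counts),
                    category = .TRANSITIONS$category,
                    pattern = paste0(.TRANSITIONS$from_type, " -> ",
                                     .TRANSITIONS$to_type),
                    n = as.integer(x$class_counts))
  print(tab, row.names = FALSE)
  v <- round_half_up(c(x$no_change_pct, x$demethylation_pct,
                       x$methylation_pct), digits)
  cat(sprintf("  %-14s %6.2f %%\n",
              c("no change", "demethylation", "methylation"), v), sep = "")
  invisible(x)
}

#' Consensus band pair across replicate samples
#'
#' Pools replicate gels of one group into one consensus presence call per
#' locus and lane by majority vote; ties and all-missing loci yield `NA`.
#'
#' @param mat A band matrix (see [band_matrix_samples()]).
#' @param samples Samples to pool; default all.
#' @return data.frame with columns `locus`, `h`, `m` (0/1/NA).
#' @export
consensus_bands <- function(mat, samples = NULL) {
  all_samples <- .matrix_sample_cols(mat)
  if (is.null(samples)) samples <- all_samples
  unknown <- setdiff(samples, all_samples)
  if (length(unknown) > 0) {
    stop("unknown sample(s): ", paste(unknown, collapse = ", "))
  }
  vote <- function(cols) {
    v <- as.matrix(mat[, cols, drop = FALSE])
    apply(v, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r) == 0) return(NA_integer_)
      n1 <- sum(r == 1)
      if (2 * n1 > length(r)) 1L
      else if (2 * n1 < length(r)) 0L
      else NA_integer_
    })
  }
  data.frame(locus = as.character(mat$locus),
             h = vote(paste0(samples, "_H")),
             m = vote(paste0(samples, "_M")))
}
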