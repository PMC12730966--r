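# Relative gene expression by the 2^-ddCt method.

#' Relative expression by 2^-ddCt
#'
#' `dCt_trt = ct_gene_trt - ct_ref_trt`, `dCt_ctl = ct_gene_ctl - ct_ref_ctl`,
#' `ddCt = dCt_trt - dCt_ctl`, fold change `2^-ddCt`. Assumes perfect
#' (2-fold per cycle) amplification efficiency; no Pfaffl correction.
#'
#' @param ct_gene_trt,ct_ref_trt Ct of target and reference gene, treated.
#' @param ct_gene_ctl,ct_ref_ctl Ct of target and reference gene, control.
#' @return Fold change (vectorized).
#' @examples
#' relative_expression(24, 15, 25, 15)  # 2: one cycle earlier = 2-fold
#' @export
relative_expression <- function(ct_gene_trt, ct_ref_trt,
                                ct_gene_ctl, ct_ref_ctl) {
  vals <- cbind(ct_gene_trt, ct_ref_trt, ct_gene_ctl, ct_ref_ctl)
  if (any(!is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (ct_gene_trt - ct_ref_trt) - (ct_gene_ctl - ct_ref_ctl)
  2^(-ddct)
}

#' Per-condition fold changes from a Ct table
#'
#' Technical replicates (rows sharing sample and gene) are averaged first;
#' each sample is one biological replicate. Per sample,
#' `dCt = Ct(gene) - Ct(reference)`; the control baseline is the mean `dCt`
#' over control-condition samples; fold changes are computed per biological
#' replicate (`2^-(dCt - baseline)`) and then summarised as mean and SD per
#' condition -- the aggregation that matches per-replicate error bars.
#'
#' @param records data.frame with columns `sample`, `condition`, `gene`,
#'   `ct` (and optionally `replicate`; extra rows per (sample, gene) are
#'   treated as technical replicates).
#' @param gene Target gene id.
#' @param reference_gene Internal control gene id (e.g. 18S rRNA).
#' @param control_condition Condition defining fold change 1.
#' @return List of class `ddct_summary`: `per_sample` (sample, condition,
#'   dct, fold), `per_condition` (condition, n, mean_fold, sd_fold), plus the
#'   arguments.
#' @export
summarize_replicates <- function(records, gene, reference_gene,
                                 control_condition) {
  need <- c("sample", "condition", "gene", "ct")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(records$ct)) || any(records$ct <= 0)) {
    stop("all Ct values must be finite and positive")
  }
  if (!gene %in% records$gene) stop("gene '", gene, "' not in records")
  if (!reference_gene %in% records$gene) {
    stop("reference gene '", reference_gene, "' not in records")
  }
  sub <- records[records$gene %in% c(gene, reference_gene), , drop = FALSE]
  # average technical replicates
  agg <- aggregate(ct ~ sample + condition + gene, data = sub, FUN = mean)
  tgt <- agg[agg$gene == gene, ]
  ref <- agg[agg$gene == reference_gene, ]
  idx <- match(tgt$sample, ref$sample)
  if (anyNA(idx)) {
    stop("missing reference gene Ct for sample(s): ",
         paste(tgt$sample[is.na(idx)], collapse = ", "))
  }
  per_sample <- data.frame(sample = tgt$sample, condition = tgt$condition,
                           dct = tgt$ct - ref$ct[idx],
                           stringsAsFactors = FALSE)
  ctl <- per_sample$condition == control_condition
  if (!any(ctl)) {
    stop("no samples in control condition '", control_condition, "'")
  }
  baseline <- mean(per_sample$dct[ctl])
  per_sample$fold <- 2^(-(per_sample$dct - baseline))
  per_condition <- do.call(rbind, lapply(split(per_sample,
                                               per_sample$condition),
    function(g) data.frame(condition = g$condition[1], n = nrow(g),
                           mean_fold = mean(g$fold),
                           sd_fold = if (nrow(g) > 1) sd(g$fold) else 0)))
  rownames(per_condition) <- NULL
  structure(list(per_sample = per_sample, per_condition = per_condition,
                 gene = gene, reference_gene = reference_gene,
                 control_condition = control_condition),
            class = "ddct_summary")
}

#' @export
print.ddct_summary <- function(x, ...) {
  cat("2^-ddCt relative expression of", x$gene, "vs", x$reference_gene,
      "(control:", paste0(x$control_condition, ")\n"))
  print(x$per_condition, row.names = FALSE)
  invisible(x)
}

#' @importFrom stats aggregate
NULL
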