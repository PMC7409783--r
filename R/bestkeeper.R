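# BestKeeper -------------------------------------------------------------
#
# Purely descriptive: each candidate's Cq dispersion across samples, and its
# Pearson correlation with the BestKeeper index — the per-sample geometric
# mean of all candidates' Cq.  Works on Cq directly (not quantities), like
# the original spreadsheet tool.

#' BestKeeper descriptive summary
#'
#' Per gene: geometric and arithmetic mean Cq, min, max, dispersion ("SD")
#' and the Pearson correlation r with the BestKeeper index.  The default
#' dispersion is the mean absolute deviation from the arithmetic mean Cq
#' (the tool's documented "SD (+/- CP)"); the sample standard deviation is
#' available as an alternative.  Samples with any missing gene are excluded
#' from the index (listwise), since the index mixes all genes.
#'
#' @param ds a [cq_dataset()] (collapsed on demand).
#' @param sd_variant `"mad"` (mean absolute deviation, default) or `"sd"`.
#' @param sd_filter optional dispersion cut-off (cycles): genes above it are
#'   excluded from the index (the tool's SD < 1 pre-filter); `NULL` (default)
#'   includes all candidates.
#' @return An object of class `bestkeeper_summary`: `per_gene` data.frame
#'   (gene, geo_mean, ar_mean, min, max, sd, r, inconsistent flag for
#'   dispersion > 1 cycle), `index` (per-sample), `sd_variant`,
#'   `n_samples_used`.  A gene constant across samples gets `r = NA` with a
#'   diagnostic, never a silent 0.
#' @export
bestkeeper_summary <- function(ds, sd_variant = c("mad", "sd"), sd_filter = NULL) {
  sd_variant <- match.arg(sd_variant)
  ds <- ensure_collapsed(ds)
  cq <- ds$collapsed
  if (ncol(cq) < 2) rs_domain_error("BestKeeper requires at least 2 genes")
  keep <- stats::complete.cases(cq)
  if (sum(keep) < 3) rs_insufficient_data("fewer than 3 samples complete across all genes")
  cq <- cq[keep, , drop = FALSE]
  genes <- colnames(cq)

  disp_fun <- if (sd_variant == "mad") {
    function(x) mean(abs(x - mean(x)))
  } else {
    stats::sd
  }
  disp <- apply(cq, 2, disp_fun)

  index_genes <- genes
  if (!is.null(sd_filter)) index_genes <- genes[disp <= sd_filter]
  if (!length(index_genes)) rs_domain_error("sd_filter excluded every gene from the index")
  index <- apply(cq[, index_genes, drop = FALSE], 1, geo_mean)

  r <- vapply(genes, function(g) {
    if (stats::sd(cq[, g]) == 0 || stats::sd(index) == 0) NA_real_
    else stats::cor(cq[, g], index)
  }, numeric(1))

  per_gene <- data.frame(
    gene = genes,
    geo_mean = apply(cq, 2, geo_mean),
    ar_mean = colMeans(cq),
    min = apply(cq, 2, min),
    max = apply(cq, 2, max),
    sd = disp,
    r = r,
    inconsistent = disp > 1,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(per_gene = per_gene, index = index, sd_variant = sd_variant,
                 index_genes = index_genes, n_samples_used = sum(keep),
                 constant_genes = genes[is.na(r)]),
            class = "bestkeeper_summary")
}

#' @export
print.bestkeeper_summary <- function(x, ...) {
  cat(sprintf("<bestkeeper_summary> %d genes, %d samples, dispersion: %s\n",
              nrow(x$per_gene), x$n_samples_used, x$sd_variant))
  print(x$per_gene, digits = 4)
  invisible(x)
}

#' BestKeeper ranking
#'
#' Ranks genes by descending correlation with the BestKeeper index (rank 1 =
#' highest r).  Genes with undefined r (constant Cq) rank last, with a
#' diagnostic.  Genes with dispersion above 1 cycle are flagged inconsistent
#' but not removed.
#'
#' @param summary a [bestkeeper_summary()].
#' @return A `stability_result` with `method = "bestkeeper"` and
#'   `direction = "higher is better"`; `values` are the correlations.
#' @export
bestkeeper_rank <- function(summary) {
  stopifnot(inherits(summary, "bestkeeper_summary"))
  pg <- summary$per_gene
  r <- stats::setNames(pg$r, pg$gene)
  key <- ifelse(is.na(r), Inf, -r)            # descending r; NA last
  ranks <- rank_deterministic(key, names = pg$gene)
  tied <- duplicated(key) | duplicated(key, fromLast = TRUE)
  new_stability_result("bestkeeper", r, stats::setNames(ranks, pg$gene),
                       "higher is better",
                       list(summary = summary,
                            inconsistent = stats::setNames(pg$inconsistent, pg$gene),
                            undefined_r = pg$gene[is.na(pg$r)],
                            tied = stats::setNames(tied, pg$gene)))
}
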