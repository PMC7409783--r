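# geNorm -----------------------------------------------------------------
#
# A candidate reference gene is judged by how constant its expression ratio
# to every other candidate stays across samples: V_jk = sd over samples of
# log2(q_j/q_k), and the gene's M value is the mean of its V_jk over all
# partners.  Because ratios are taken within a sample, any per-sample
# loading offset cancels exactly.

new_stability_result <- function(method, values, ranks, direction, diagnostics = list()) {
  structure(list(method = method, values = values, ranks = ranks,
                 direction = direction, diagnostics = diagnostics),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  ord <- order(x$ranks)
  cat(sprintf("<stability_result> method: %s (%s)\n", x$method, x$direction))
  print(data.frame(gene = names(x$values)[ord],
                   value = unname(x$values)[ord],
                   rank = unname(x$ranks)[ord], row.names = NULL))
  invisible(x)
}

#' @export
as.data.frame.stability_result <- function(x, ...) {
  data.frame(gene = names(x$values), method = x$method,
             value = unname(x$values), rank = unname(x$ranks),
             stringsAsFactors = FALSE)
}

#' geNorm pairwise variation between two genes
#'
#' Sample standard deviation (n-1 denominator) of the per-sample
#' log2-ratio of the two genes' relative quantities, over the samples where
#' both are observed.
#'
#' @param qm a `quantity_matrix` from [to_quantities()].
#' @param gene_j,gene_k gene names.
#' @return A single non-negative number.
#' @export
pairwise_variation <- function(qm, gene_j, gene_k) {
  for (g in c(gene_j, gene_k)) {
    if (!g %in% colnames(qm$q)) rs_contract_error(sprintf("gene '%s' not in quantity matrix", g))
  }
  lr <- log2(qm$q[, gene_j]) - log2(qm$q[, gene_k])
  lr <- lr[is.finite(lr)]
  if (length(lr) < 3) {
    rs_insufficient_data(sprintf(
      "genes '%s' and '%s' share only %d samples (need >= 3)", gene_j, gene_k, length(lr)))
  }
  stats::sd(lr)
}

# All pairwise variations among `genes`, as a symmetric matrix.
pairwise_variation_matrix <- function(qm, genes = colnames(qm$q)) {
  n <- length(genes)
  v <- matrix(0, n, n, dimnames = list(genes, genes))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    v[a, b] <- v[b, a] <- pairwise_variation(qm, genes[a], genes[b])
  }
  v
}

#' geNorm expression stability (M values)
#'
#' `M_j` is the arithmetic mean of gene j's pairwise variations with every
#' other candidate; lower is more stable.  The primary mode ranks all genes
#' by their full-panel M in a single pass.  The classic stepwise mode
#' iteratively excludes the gene with the highest M and recomputes, ranking
#' by exclusion order (the final two genes cannot be separated and are
#' ranked by their M in the last pair, flagged as a tie).
#'
#' @param qm a `quantity_matrix`.
#' @param mode `"single"` (default) or `"stepwise"`.
#' @param stable_cutoff M threshold below which a gene is flagged stable
#'   (default 1.5, the conventional heterogeneous-panel cut-off).
#' @return A `stability_result` with `method = "genorm"`; diagnostics carry
#'   the pairwise-variation matrix, the stable flags and (for stepwise) the
#'   exclusion order.
#' @export
genorm_m <- function(qm, mode = c("single", "stepwise"), stable_cutoff = 1.5) {
  mode <- match.arg(mode)
  genes <- colnames(qm$q)
  if (length(genes) < 3) rs_domain_error("geNorm requires at least 3 genes")
  v <- pairwise_variation_matrix(qm, genes)
  m <- rowSums(v) / (length(genes) - 1)

  if (mode == "single") {
    ranks <- rank_deterministic(m, names = genes)
    tied <- duplicated(m) | duplicated(m, fromLast = TRUE)
    res <- new_stability_result("genorm", m, stats::setNames(ranks, genes),
                                "lower is better",
                                list(v_matrix = v, mode = mode,
                                     stable = m < stable_cutoff,
                                     tied = stats::setNames(tied, genes)))
    return(res)
  }

  # stepwise exclusion
  remaining <- genes
  excluded <- character()
  repeat {
    if (length(remaining) == 2L) break
    vm <- v[remaining, remaining]
    mm <- rowSums(vm) / (length(remaining) - 1)
    worst <- remaining[which.max(mm)]
    excluded <- c(worst, excluded)
    remaining <- setdiff(remaining, worst)
  }
  final_m <- stats::setNames(v[remaining[1], remaining[2]], NULL)
  order_best_first <- c(remaining, excluded)     # final pair tied at the top
  ranks <- stats::setNames(match(genes, order_best_first), genes)
  new_stability_result("genorm", m, ranks, "lower is better",
                       list(v_matrix = v, mode = mode,
                            stable = m < stable_cutoff,
                            exclusion_order = excluded,
                            final_pair = remaining, final_pair_m = final_m,
                            tied = stats::setNames(genes %in% remaining, genes)))
}

#' Normalization factor
#'
#' Per-sample geometric mean of the chosen reference genes' relative
#' quantities.
#'
#' @param qm a `quantity_matrix`.
#' @param genes ordered character vector of reference genes (>= 1).
#' @return Named numeric vector, one value per sample.
#' @export
normalization_factor <- function(qm, genes) {
  if (!length(genes)) rs_contract_error("at least one reference gene is required")
  miss <- setdiff(genes, colnames(qm$q))
  if (length(miss)) rs_contract_error(sprintf("gene(s) not in quantity matrix: %s",
                                              paste(miss, collapse = ", ")))
  sub <- qm$q[, genes, drop = FALSE]
  if (anyNA(sub)) {
    idx <- which(is.na(sub), arr.ind = TRUE)[1L, ]
    rs_insufficient_data(sprintf(
      "missing quantity for sample '%s', gene '%s'",
      rownames(sub)[idx[1]], genes[idx[2]]))
  }
  apply(sub, 1, geo_mean)
}

#' geNorm pairwise-variation series V and the how-many-genes rule
#'
#' `V_{n/n+1}` is the standard deviation across samples of
#' `log2(NF_n / NF_{n+1})`, where `NF_n` is the normalization factor built
#' from the n top-ranked genes.  The smallest n with `V < threshold` is the
#' recommended number of reference genes; if no n qualifies, all genes are
#' recommended.
#'
#' @param qm a `quantity_matrix`.
#' @param ranking a geNorm `stability_result` (computed with [genorm_m()] if
#'   omitted); must cover all genes of `qm`.
#' @param threshold decision threshold on V (default 0.15).
#' @return An object of class `pv_series`: list with `v` (named by n),
#'   `threshold`, `recommended_n` and `ranked_genes`.
#' @export
v_series <- function(qm, ranking = NULL, threshold = 0.15) {
  genes <- colnames(qm$q)
  if (length(genes) < 3) rs_domain_error("V series requires at least 3 genes")
  ranking <- ranking %||% genorm_m(qm)
  if (!setequal(names(ranking$ranks), genes)) {
    rs_contract_error("ranking does not cover the genes of the quantity matrix")
  }
  ordered <- names(sort(ranking$ranks))
  ns <- 2:(length(genes) - 1)
  # restrict to samples complete in all genes so every NF_n is defined
  keep <- stats::complete.cases(qm$q[, ordered, drop = FALSE])
  if (sum(keep) < 3) rs_insufficient_data("fewer than 3 samples complete across all genes")
  qc <- qm
  qc$q <- qm$q[keep, , drop = FALSE]
  v <- vapply(ns, function(n) {
    nf_n <- normalization_factor(qc, ordered[1:n])
    nf_n1 <- normalization_factor(qc, ordered[1:(n + 1)])
    stats::sd(log2(nf_n / nf_n1))
  }, numeric(1))
  names(v) <- paste0("V", ns, "/", ns + 1)
  below <- which(v < threshold)
  recommended_n <- if (length(below)) ns[below[1]] else length(genes)
  structure(list(v = v, n = ns, threshold = threshold,
                 recommended_n = recommended_n, ranked_genes = ordered,
                 n_samples_used = sum(keep)),
            class = "pv_series")
}

#' @export
print.pv_series <- function(x, ...) {
  cat(sprintf("<pv_series> threshold %.3g, recommended n = %d\n",
              x$threshold, x$recommended_n))
  print(data.frame(n = x$n, V = unname(x$v),
                   below_threshold = unname(x$v) < x$threshold, row.names = NULL))
  invisible(x)
}
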