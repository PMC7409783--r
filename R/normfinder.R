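# NormFinder -------------------------------------------------------------
#
# Model-based stability: log-scale expression is decomposed, per condition
# group, into sample effects (loading, removed), gene effects (removed),
# a gene-by-group interaction d (systematic condition response) and residual
# intra-group noise sigma^2.  The candidate's stability value combines the
# magnitude of its shrunken group bias with its intra-group standard error;
# lower is more stable.  Computed on log2 quantities, so per-gene and
# per-sample additive Cq shifts cancel.

#' NormFinder variance decomposition
#'
#' Returns all intermediates of the NormFinder model for inspection:
#' per-(group, gene) inter-group deviations `d`, intra-group variance
#' estimates `sigma2`, the between-gene variance of group deviations
#' `gamma2`, the shrunken deviations `d_shrunk`, and the per-gene stability
#' values.
#'
#' @param ds a [cq_dataset()] with group labels (collapsed on demand), or a
#'   `quantity_matrix`.
#' @param groups optional named character vector sample -> group overriding
#'   the dataset's labels.
#' @return An object of class `normfinder_decomposition`.
#' @details Samples with any missing gene are dropped (listwise) with a
#'   warning: the two-way decomposition needs a complete matrix.  With a
#'   single group the inter-group terms are zero and the stability value
#'   reduces to the intra-group standard error, reported with a warning.
#' @export
normfinder_decompose <- function(ds, groups = NULL) {
  if (inherits(ds, "cq_dataset")) {
    ds <- ensure_collapsed(ds)
    x_all <- -ds$collapsed            # log2 quantity up to per-gene constants (E = 2)
    groups <- groups %||% ds$groups
  } else if (inherits(ds, "quantity_matrix")) {
    x_all <- log2(ds$q)
    groups <- groups %||% ds$groups
  } else {
    rs_contract_error("input must be a cq_dataset or quantity_matrix")
  }
  genes <- colnames(x_all)
  k <- length(genes)
  if (k < 3) rs_domain_error("NormFinder requires at least 3 genes")

  keep <- stats::complete.cases(x_all)
  if (!all(keep)) {
    warning(sprintf("NormFinder: dropping %d sample(s) with missing genes (listwise)",
                    sum(!keep)))
  }
  x_all <- x_all[keep, , drop = FALSE]
  grp <- groups[rownames(x_all)]
  if (anyNA(grp)) rs_contract_error("every sample needs a group label")
  glev <- unique(grp)
  G <- length(glev)
  ng <- vapply(glev, function(g) sum(grp == g), integer(1))
  single_group <- G == 1L
  if (!single_group && any(ng < 2)) {
    rs_insufficient_data(sprintf("group '%s' has fewer than 2 samples",
                                 glev[which(ng < 2)[1]]))
  }
  if (single_group) warning("NormFinder: single group supplied; stability reduces to the intra-group term")

  # per-group double-centered residuals -> intra-group variances
  sigma2 <- z <- matrix(NA_real_, G, k, dimnames = list(glev, genes))
  for (gi in seq_len(G)) {
    xg <- x_all[grp == glev[gi], , drop = FALSE]
    n <- nrow(xg)
    r <- xg - outer(rowMeans(xg), rep(1, k)) -
      outer(rep(1, n), colMeans(xg)) + mean(xg)
    s <- colSums(r^2) / (n - 1)
    sbar <- mean(s)
    sigma2[gi, ] <- pmax(0, k / (k - 2) * (s - sbar / (k - 1)))
    z[gi, ] <- colMeans(xg) - mean(xg)
  }

  if (single_group) {
    d <- d_shrunk <- matrix(0, G, k, dimnames = list(glev, genes))
    gamma2 <- 0
    stability <- sqrt(sigma2[1, ])
  } else {
    w <- ng / sum(ng)
    zbar <- colSums(z * w)                     # size-weighted mean over groups
    d <- sweep(z, 2, zbar)
    sig_over_n <- sweep(sigma2, 1, ng, `/`)
    gamma2 <- max(0, sum(d^2) / ((G - 1) * (k - 1)) - mean(sig_over_n))
    shrink <- gamma2 / (gamma2 + sig_over_n)
    shrink[!is.finite(shrink)] <- 0            # 0/0 when both terms vanish
    d_shrunk <- d * shrink
    var_term <- gamma2 * sig_over_n / (gamma2 + sig_over_n)
    var_term[!is.finite(var_term)] <- 0
    stability <- colMeans(abs(d_shrunk) + sqrt(var_term))
  }

  structure(list(x = x_all, groups = grp, group_sizes = ng,
                 d = d, sigma2 = sigma2, gamma2 = gamma2,
                 d_shrunk = d_shrunk,
                 stability = stats::setNames(stability, genes)),
            class = "normfinder_decomposition")
}

#' @export
print.normfinder_decomposition <- function(x, ...) {
  cat(sprintf("<normfinder_decomposition> %d genes, groups: %s, gamma2 = %.4g\n",
              ncol(x$x), paste(rownames(x$d), collapse = "/"), x$gamma2))
  invisible(x)
}

#' NormFinder stability values and ranking
#'
#' @inheritParams normfinder_decompose
#' @return A `stability_result` with `method = "normfinder"`; diagnostics
#'   carry the decomposition (intra-group SDs and per-group deviations).
#' @export
normfinder_stability <- function(ds, groups = NULL) {
  dec <- normfinder_decompose(ds, groups)
  genes <- names(dec$stability)
  ranks <- rank_deterministic(dec$stability, names = genes)
  new_stability_result("normfinder", dec$stability,
                       stats::setNames(ranks, genes), "lower is better",
                       list(intra_sd = sqrt(dec$sigma2), intergroup_d = dec$d,
                            gamma2 = dec$gamma2, decomposition = dec))
}
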