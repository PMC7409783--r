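# Consensus ranking & recommendations ------------------------------------

#' Comprehensive ranking by geometric mean of method ranks
#'
#' Aggregates the per-method ranks (not the stability values) of several
#' stability analyses into one consensus: per gene, the geometric mean of
#' its ranks, re-ranked ascending.  Ties are broken by the arithmetic mean
#' rank, then lexicographic gene name, and reported.
#'
#' @param results a list of `stability_result` objects covering the same
#'   gene set, or a numeric matrix/data.frame of ranks (genes in rows with
#'   row names, one column per method).
#' @return An object of class `consensus_ranking`: data.frame `table` with
#'   one per-method rank column, `geo_mean_rank` and `comprehensive_rank`,
#'   plus `n_methods` and the tie report.
#' @export
comprehensive_rank <- function(results) {
  if (is.matrix(results) || is.data.frame(results)) {
    rank_mat <- as.matrix(results)
    if (is.null(rownames(rank_mat))) rs_contract_error("rank matrix needs gene row names")
    storage.mode(rank_mat) <- "double"
  } else {
    if (!length(results)) rs_contract_error("at least one stability result is required")
    gene_sets <- lapply(results, function(r) sort(names(r$ranks)))
    ref <- gene_sets[[1]]
    for (i in seq_along(gene_sets)) {
      if (!identical(gene_sets[[i]], ref)) {
        rs_contract_error(sprintf(
          "gene sets differ between methods: {%s} vs {%s}",
          paste(setdiff(ref, gene_sets[[i]]), collapse = ", "),
          paste(setdiff(gene_sets[[i]], ref), collapse = ", ")))
      }
    }
    genes <- names(results[[1]]$ranks)
    methods <- vapply(results, function(r) r$method, character(1))
    if (anyDuplicated(methods)) methods <- make.unique(methods)
    rank_mat <- vapply(results, function(r) as.numeric(r$ranks[genes]),
                       numeric(length(genes)))
    dimnames(rank_mat) <- list(genes, methods)
  }
  if (anyNA(rank_mat)) rs_contract_error("rank matrix contains missing ranks")

  geo <- apply(rank_mat, 1, geo_mean)
  mean_rank <- rowMeans(rank_mat)
  comp <- rank_deterministic(geo, tiebreak = mean_rank, names = rownames(rank_mat))
  tied <- duplicated(geo) | duplicated(geo, fromLast = TRUE)
  tab <- data.frame(gene = rownames(rank_mat), rank_mat,
                    geo_mean_rank = geo, comprehensive_rank = comp,
                    row.names = NULL, stringsAsFactors = FALSE, check.names = FALSE)
  structure(list(table = tab, n_methods = ncol(rank_mat),
                 tied = stats::setNames(tied, rownames(rank_mat))),
            class = "consensus_ranking")
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat(sprintf("<consensus_ranking> %d genes, %d methods\n",
              nrow(x$table), x$n_methods))
  print(x$table[order(x$table$comprehensive_rank), ], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Assemble a reference-gene recommendation
#'
#' Picks `n_required` genes (from the pairwise-variation series) off the
#' consensus ranking in order, honouring explicit exclusions (e.g. genes
#' flagged condition-responsive) and forced inclusions.  Every inclusion and
#' skip is logged in an audit trail — the recommendation never applies a
#' hidden heuristic.  Optionally attaches, per gene, the between-group mean
#' delta-Cq and its t-test p value so condition-responsiveness flags are
#' evidence-backed.
#'
#' @param consensus a [comprehensive_rank()] result.
#' @param v a [v_series()] result (supplies `n_required`), or an integer.
#' @param exclusions named character vector gene -> reason, or character
#'   vector of genes.
#' @param force_include genes placed at the head of the recommendation in
#'   the order given (still counted against `n_required`).
#' @param cq_diagnostic optional [cq_dataset()] with two groups: adds the
#'   per-gene between-group mean Cq difference and two-tailed t-test p.
#' @return An object of class `ref_gene_recommendation`: `recommended`
#'   (ordered genes), `n_required`, `excluded` (with reasons), `audit`
#'   (character log), and optionally `group_diagnostic`.
#' @export
recommend_references <- function(consensus, v, exclusions = character(),
                                 force_include = character(),
                                 cq_diagnostic = NULL) {
  stopifnot(inherits(consensus, "consensus_ranking"))
  n_required <- if (inherits(v, "pv_series")) v$recommended_n else as.integer(v)
  tab <- consensus$table[order(consensus$table$comprehensive_rank), ]
  genes <- tab$gene

  if (is.null(names(exclusions)) && length(exclusions)) {
    exclusions <- stats::setNames(rep("user exclusion", length(exclusions)), exclusions)
  }
  unknown <- setdiff(c(names(exclusions), force_include), genes)
  if (length(unknown)) rs_contract_error(sprintf(
    "unknown gene(s): %s", paste(unknown, collapse = ", ")))
  if (length(intersect(force_include, names(exclusions)))) {
    rs_contract_error("a gene cannot be both excluded and force-included")
  }

  audit <- character()
  recommended <- character()
  for (g in force_include) {
    recommended <- c(recommended, g)
    audit <- c(audit, sprintf("include %s: forced by user (consensus rank %d)",
                              g, tab$comprehensive_rank[tab$gene == g]))
  }
  for (g in setdiff(genes, force_include)) {
    if (length(recommended) >= n_required) break
    if (g %in% names(exclusions)) {
      audit <- c(audit, sprintf("skip %s (consensus rank %d): %s",
                                g, tab$comprehensive_rank[tab$gene == g],
                                exclusions[[g]]))
    } else {
      recommended <- c(recommended, g)
      audit <- c(audit, sprintf("include %s: consensus rank %d",
                                g, tab$comprehensive_rank[tab$gene == g]))
    }
  }
  if (length(recommended) < n_required) {
    rs_insufficient_data(sprintf(
      "exclusions leave only %d of the %d required reference genes",
      length(recommended), n_required))
  }
  recommended <- recommended[seq_len(n_required)]

  diag <- NULL
  if (!is.null(cq_diagnostic)) diag <- group_shift_diagnostic(cq_diagnostic)

  structure(list(recommended = recommended, n_required = n_required,
                 excluded = exclusions, audit = audit,
                 group_diagnostic = diag),
            class = "ref_gene_recommendation")
}

#' @export
print.ref_gene_recommendation <- function(x, ...) {
  cat(sprintf("<ref_gene_recommendation> n = %d: %s\n",
              x$n_required, paste(x$recommended, collapse = ", ")))
  cat(paste0("  ", x$audit, collapse = "\n"), "\n")
  invisible(x)
}

# Per-gene between-group mean Cq difference and two-tailed t-test p: the
# evidence behind a "condition-responsive" exclusion.
group_shift_diagnostic <- function(ds) {
  ds <- ensure_collapsed(ds)
  grp <- ds$groups[rownames(ds$collapsed)]
  glev <- unique(grp)
  if (length(glev) != 2) rs_contract_error("group diagnostic needs exactly 2 groups")
  out <- lapply(colnames(ds$collapsed), function(g) {
    a <- ds$collapsed[grp == glev[1], g]
    b <- ds$collapsed[grp == glev[2], g]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(gene = g, delta_cq = NA_real_, p_value = NA_real_))
    }
    tt <- stats::t.test(b, a, var.equal = TRUE)
    data.frame(gene = g, delta_cq = mean(b) - mean(a), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "contrast") <- sprintf("%s - %s", glev[2], glev[1])
  res
}
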