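# Primer efficiency & relative quantification ----------------------------

#' Build a dilution series
#'
#' @param dilution vector of dilution factors (1 = undiluted, 10 = 1/10,
#'   ...), one per well, strictly positive; at least 3 distinct levels.
#' @param cq Cq readings (cycles), same length; `NA` allowed (dropped).
#' @param gene gene label.
#' @return Object of class `dilution_series` with replicate-mean Cq per
#'   level.
#' @export
dilution_series <- function(dilution, cq, gene = "gene") {
  if (length(dilution) != length(cq)) rs_contract_error("dilution and cq lengths differ")
  ok <- !is.na(cq)
  dilution <- dilution[ok]; cq <- cq[ok]
  if (any(dilution <= 0)) rs_domain_error("dilution factors must be positive")
  levels <- sort(unique(dilution))
  mean_cq <- vapply(levels, function(d) mean(cq[dilution == d]), numeric(1))
  structure(list(gene = gene, dilution = levels, mean_cq = mean_cq,
                 n_reps = vapply(levels, function(d) sum(dilution == d), integer(1))),
            class = "dilution_series")
}

#' Fit primer amplification efficiency from a dilution series
#'
#' Ordinary least squares of replicate-mean Cq on log10 of the relative
#' template amount (`-log10(dilution factor)`).  The slope (cycles per
#' log10 template) gives the efficiency by `E% = (10^(-1/slope) - 1) * 100`;
#' a perfect doubling per cycle corresponds to slope -3.32 and 100%.
#'
#' @param series a [dilution_series()], needing >= 3 levels (2 levels are
#'   accepted in a diagnostic mode with a warning: the fit degenerates to the
#'   two-point slope).
#' @return Object of class `efficiency_result`: `slope`, `intercept`,
#'   `efficiency_pct`, `amplification_factor` (E as a factor, e.g. 2.0),
#'   `r_squared`.
#' @export
fit_efficiency <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  n <- length(series$dilution)
  if (n < 2) rs_insufficient_data("dilution series needs at least 2 levels")
  if (n == 2) warning("only 2 dilution levels: slope is the two-point estimate (diagnostic mode)")
  x <- -log10(series$dilution)       # log10 relative template amount
  fit <- stats::lm(series$mean_cq ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    rs_domain_error(sprintf("invalid dilution series: slope %.3f (Cq must rise with dilution)",
                            slope))
  }
  eff <- 10^(-1 / slope)
  # cor()^2 rather than summary.lm(): robust to a numerically perfect fit
  r2 <- if (n > 2) stats::cor(x, series$mean_cq)^2 else 1
  structure(list(gene = series$gene, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency_pct = (eff - 1) * 100,
                 amplification_factor = eff, r_squared = r2,
                 n_levels = n),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("<efficiency_result> %s: slope %.4f, E = %.2f%% (R2 = %.4f, %d levels)\n",
              x$gene, x$slope, x$efficiency_pct, x$r_squared, x$n_levels))
  invisible(x)
}

#' Relative target-gene quantification (delta-delta-Cq)
#'
#' Normalizes a target gene against the arithmetic-mean Cq of the chosen
#' reference genes (equivalently, the geometric mean of their quantities),
#' references each sample against the control-group mean delta-Cq, and
#' exponentiates: per-sample relative quantity `RQ = 2^(-ddCq)` (or
#' efficiency-corrected if `efficiency` is supplied).  The group comparison
#' is a two-tailed t test on the non-transformed delta-Cq values.
#'
#' @param ds a [cq_dataset()] with exactly two groups.
#' @param target target gene name.
#' @param references character vector of reference genes (must not contain
#'   the target).
#' @param control_group label of the reference condition (its mean RQ
#'   defines the unit).
#' @param method `"mean_of_rq"` (default): fold change = mean treatment RQ /
#'   mean control RQ; `"exp_mean"`: `2^(-mean treatment ddCq)`.
#' @param var_equal classic Student t test (`TRUE`, default) or Welch.
#' @param efficiency optional per-gene named amplification factors for
#'   efficiency-corrected quantification; default: all genes at `E = 2`
#'   (100%).
#' @return Object of class `expression_result`: per-sample RQ, group means,
#'   `fold_change`, per-group `sem` (on the exponentialized values),
#'   `t_statistic`, `p_value`, `df`.
#' @export
delta_delta_cq <- function(ds, target, references, control_group,
                           method = c("mean_of_rq", "exp_mean"),
                           var_equal = TRUE, efficiency = NULL) {
  method <- match.arg(method)
  ds <- ensure_collapsed(ds)
  cq <- ds$collapsed
  if (target %in% references) {
    rs_contract_error(sprintf("target '%s' cannot be one of its own references", target))
  }
  miss_gene <- setdiff(c(target, references), colnames(cq))
  if (length(miss_gene)) rs_contract_error(sprintf(
    "gene(s) not in dataset: %s", paste(miss_gene, collapse = ", ")))
  grp <- ds$groups[rownames(cq)]
  glev <- unique(grp)
  if (length(glev) != 2) rs_domain_error("delta-delta-Cq needs exactly 2 groups")
  if (!control_group %in% glev) rs_contract_error(sprintf(
    "control group '%s' not among groups: %s", control_group,
    paste(glev, collapse = ", ")))
  treatment_group <- setdiff(glev, control_group)

  sub <- cq[, c(target, references), drop = FALSE]
  if (anyNA(sub)) {
    idx <- which(is.na(sub), arr.ind = TRUE)[1L, ]
    rs_insufficient_data(sprintf("missing Cq for sample '%s', gene '%s'",
                                 rownames(sub)[idx[1]], colnames(sub)[idx[2]]))
  }

  # Efficiency correction works on "efficiency-scaled cycles": Cq * log2(E),
  # which reduces to plain Cq at E = 2.
  genes <- c(target, references)
  if (is.null(efficiency)) {
    le <- stats::setNames(rep(1, length(genes)), genes)    # log2(2)
  } else {
    missing_e <- setdiff(genes, names(efficiency))
    if (length(missing_e)) rs_contract_error(sprintf(
      "no efficiency for gene(s): %s", paste(missing_e, collapse = ", ")))
    le <- log2(efficiency[genes])
  }
  scaled <- sweep(sub, 2, le[colnames(sub)], `*`)
  dcq <- scaled[, target] - rowMeans(scaled[, references, drop = FALSE])
  ddcq <- dcq - mean(dcq[grp == control_group])
  rq <- 2^(-ddcq)

  ctrl <- rq[grp == control_group]
  trt <- rq[grp == treatment_group]
  fold_change <- switch(method,
    mean_of_rq = mean(trt) / mean(ctrl),
    exp_mean = 2^(-mean(ddcq[grp == treatment_group])))
  sem <- c(stats::sd(ctrl) / sqrt(length(ctrl)), stats::sd(trt) / sqrt(length(trt)))
  names(sem) <- c(control_group, treatment_group)

  # degenerate case: both groups constant in delta-Cq (e.g. identical panels)
  tt <- tryCatch(
    stats::t.test(dcq[grp == treatment_group], dcq[grp == control_group],
                  var.equal = var_equal),
    error = function(e) list(statistic = c(t = NA_real_),
                             parameter = c(df = NA_real_), p.value = NA_real_))
  structure(list(target = target, references = references,
                 control_group = control_group, treatment_group = treatment_group,
                 delta_cq = dcq, delta_delta_cq = ddcq, rq = rq,
                 group_means = c(stats::setNames(mean(ctrl), control_group),
                                 stats::setNames(mean(trt), treatment_group)),
                 fold_change = fold_change, sem = sem,
                 t_statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, method = method,
                 var_equal = var_equal),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("<expression_result> %s vs refs {%s}: fold change %.3f (%s/%s), p = %.4g\n",
              x$target, paste(x$references, collapse = ", "),
              x$fold_change, x$treatment_group, x$control_group, x$p_value))
  invisible(x)
}

#' Sensitivity of target-gene expression to the reference-gene set
#'
#' Runs [delta_delta_cq()] once per candidate reference set and tabulates the
#' fold changes and p values side by side, flagging sets that disagree on
#' direction or significance.
#'
#' @inheritParams delta_delta_cq
#' @param reference_sets named list of character vectors.
#' @param alpha significance threshold for the flag (default 0.05).
#' @return Object of class `reference_set_sensitivity`: `table`
#'   (set, n_refs, fold_change, p_value, significant), the per-set
#'   [delta_delta_cq()] results, and flags `direction_change` /
#'   `significance_change`.
#' @export
reference_set_sensitivity <- function(ds, target, reference_sets, control_group,
                                      method = c("mean_of_rq", "exp_mean"),
                                      var_equal = TRUE, alpha = 0.05) {
  method <- match.arg(method)
  if (!length(reference_sets)) rs_contract_error("at least one reference set is required")
  if (is.null(names(reference_sets))) {
    names(reference_sets) <- paste0("set", seq_along(reference_sets))
  }
  results <- lapply(reference_sets, function(refs) {
    delta_delta_cq(ds, target, refs, control_group,
                   method = method, var_equal = var_equal)
  })
  tab <- data.frame(
    set = names(results),
    n_refs = vapply(reference_sets, length, integer(1)),
    fold_change = vapply(results, function(r) r$fold_change, numeric(1)),
    p_value = vapply(results, function(r) r$p_value, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$significant <- tab$p_value < alpha
  structure(list(table = tab, results = results, target = target,
                 direction_change = length(unique(tab$fold_change > 1)) > 1,
                 significance_change = length(unique(tab$significant)) > 1),
            class = "reference_set_sensitivity")
}

#' @export
print.reference_set_sensitivity <- function(x, ...) {
  cat(sprintf("<reference_set_sensitivity> target %s (%d sets)%s%s\n", x$target,
              nrow(x$table),
              if (x$direction_change) " [direction changes]" else "",
              if (x$significance_change) " [significance changes]" else ""))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}
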