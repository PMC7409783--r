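# Synthetic Cq generator -------------------------------------------------
#
# Emulates the experimental design the stability analysis targets: two
# rearing conditions x a few biological replicates x a panel of candidate
# genes, with duplicate/triplicate technical replicates, per-sample loading
# offsets, per-gene condition effects, and occasional missing wells.
#
# Noise model, on the Cq scale (log2 expression):
#   Cq[g,i,j,rep] = baseline_cq[j] + delta[j]*1[group i = treatment]
#                   + L_i + eps_ij + tau_ijr
# with L ~ N(0, sample_loading_sd), eps ~ N(0, gene_noise_sd[j]),
# tau ~ N(0, replicate_sd); wells dropped independently at missing_rate.
#
# All noise is drawn as standard normals and then scaled, so two configs
# that differ only in an sd share the identical underlying draws for a
# given seed (used by the loading-invariance property tests).

#' Simulation configuration
#'
#' Defaults describe the emulated design: 2 condition groups x 5 biological
#' replicates x 8 genes, baselines spread over the observed 17-29 cycle
#' range, ideal references (no condition effect), 0.5-cycle sample loading
#' spread, 0.3-cycle biological gene noise, duplicate technical replicates
#' with 0.15-cycle repeatability, and no missing wells.
#'
#' @param n_genes number of candidate genes.
#' @param n_per_group biological replicates per condition group (>= 2).
#' @param groups two group labels; the second is the treatment (receives
#'   `condition_effect`).
#' @param baseline_cq per-gene baseline Cq (cycles); recycled/defaulted to
#'   an even spread over 17-29.
#' @param condition_effect per-gene Cq shift in the treatment group
#'   (cycles); 0 = ideal reference.
#' @param sample_loading_sd between-sample loading spread (cycles).
#' @param gene_noise_sd per-gene biological noise (cycles).
#' @param tech_replicates technical replicates per well (2-3 typical).
#' @param replicate_sd technical repeatability (cycles).
#' @param missing_rate independent well drop-out probability in [0, 1).
#' @param seed integer RNG seed.
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(n_genes = 8, n_per_group = 5,
                              groups = c("isolated", "crowded"),
                              baseline_cq = NULL,
                              condition_effect = 0,
                              sample_loading_sd = 0.5,
                              gene_noise_sd = 0.3,
                              tech_replicates = 2,
                              replicate_sd = 0.15,
                              missing_rate = 0,
                              seed = 1L) {
  baseline_cq <- baseline_cq %||% seq(17, 29, length.out = n_genes)
  baseline_cq <- rep_len(baseline_cq, n_genes)
  condition_effect <- rep_len(condition_effect, n_genes)
  gene_noise_sd <- rep_len(gene_noise_sd, n_genes)
  cfg <- structure(list(
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    groups = as.character(groups), baseline_cq = baseline_cq,
    condition_effect = condition_effect,
    sample_loading_sd = sample_loading_sd, gene_noise_sd = gene_noise_sd,
    tech_replicates = as.integer(tech_replicates),
    replicate_sd = replicate_sd, missing_rate = missing_rate,
    seed = as.integer(seed)), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  bad <- character()
  if (cfg$n_genes < 1) bad <- c(bad, "n_genes >= 1")
  if (cfg$n_per_group < 2) bad <- c(bad, "n_per_group >= 2")
  if (length(cfg$groups) != 2 || anyDuplicated(cfg$groups))
    bad <- c(bad, "groups must be 2 distinct labels")
  if (any(c(cfg$sample_loading_sd, cfg$gene_noise_sd, cfg$replicate_sd) < 0))
    bad <- c(bad, "all sd >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    bad <- c(bad, "0 <= missing_rate < 1")
  if (cfg$tech_replicates < 1) bad <- c(bad, "tech_replicates >= 1")
  if (length(bad)) rs_config_error(paste("invalid simulation config:",
                                         paste(bad, collapse = "; ")))
  invisible(cfg)
}

#' Simulate a Cq dataset with known ground truth
#'
#' @param cfg a [simulation_config()].
#' @return Object of class `synthetic_dataset`: `dataset` (a [cq_dataset()]
#'   of raw wells) and `truth` (the config plus the realized per-sample
#'   loading offsets and the planted per-gene instability
#'   `sqrt(condition_effect^2 + gene_noise_sd^2)`).  Bit-reproducible for a
#'   fixed seed.
#' @export
simulate_cq <- function(cfg) {
  validate_simulation_config(cfg)
  genes <- sprintf("G%02d", seq_len(cfg$n_genes))
  n <- 2L * cfg$n_per_group
  samples <- sprintf("s%02d", seq_len(n))
  group <- rep(cfg$groups, each = cfg$n_per_group)
  t <- cfg$tech_replicates

  with_seed(cfg$seed, {
    loading <- cfg$sample_loading_sd * stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * cfg$n_genes), n, cfg$n_genes)
    eps <- sweep(eps, 2, cfg$gene_noise_sd, `*`)
    tau <- array(cfg$replicate_sd * stats::rnorm(n * cfg$n_genes * t),
                 dim = c(n, cfg$n_genes, t))
    drop_u <- array(stats::runif(n * cfg$n_genes * t),
                    dim = c(n, cfg$n_genes, t))
  })

  wells <- expand.grid(rep = seq_len(t), sample = seq_len(n),
                       gene = seq_len(cfg$n_genes), KEEP.OUT.ATTRS = FALSE)
  cq <- cfg$baseline_cq[wells$gene] +
    cfg$condition_effect[wells$gene] * (group[wells$sample] == cfg$groups[2]) +
    loading[wells$sample] +
    eps[cbind(wells$sample, wells$gene)] +
    tau[cbind(wells$sample, wells$gene, wells$rep)]
  missing <- drop_u[cbind(wells$sample, wells$gene, wells$rep)] < cfg$missing_rate
  cq[missing] <- NA_real_

  df <- data.frame(sample_id = samples[wells$sample],
                   gene = genes[wells$gene],
                   replicate = wells$rep,
                   cq = cq,
                   group = group[wells$sample],
                   stringsAsFactors = FALSE)
  ds <- cq_dataset(df, cq_window = c(-Inf, Inf),
                   metadata = list(source = "simulate_cq", seed = cfg$seed))
  structure(list(
    dataset = ds,
    truth = list(config = cfg, genes = genes, samples = samples,
                 loading = stats::setNames(loading, samples),
                 planted_instability = stats::setNames(
                   sqrt(cfg$condition_effect^2 + cfg$gene_noise_sd^2), genes))),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("<synthetic_dataset> %d genes x %d+%d samples x %d tech reps (seed %d)\n",
              cfg$n_genes, cfg$n_per_group, cfg$n_per_group,
              cfg$tech_replicates, cfg$seed))
  invisible(x)
}

#' Shipped simulation presets
#'
#' * `"ideal"` — all genes stable, near-noiseless.
#' * `"one-bad-gene"` — one gene carries a 1-cycle condition effect over an
#'   otherwise quiet panel.
#' * `"piceifrons-like"` — a correlated block of seven condition-responsive
#'   genes around a single truly stable gene (G01): correlation-based
#'   methods mis-rank the stable gene because the responsive majority agrees
#'   with itself.
#' * `"americana-like"` — all genes stable under realistic noise.
#'
#' @param preset preset name.
#' @param seed RNG seed.
#' @param ... overrides passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
sim_preset <- function(preset = c("ideal", "one-bad-gene", "piceifrons-like",
                                  "americana-like"),
                       seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "ideal" = list(condition_effect = 0, gene_noise_sd = 0.05,
                   sample_loading_sd = 0.2, replicate_sd = 0.05),
    "one-bad-gene" = list(condition_effect = c(rep(0, 7), 1),
                          gene_noise_sd = 0.3),
    "piceifrons-like" = list(condition_effect = c(0, 0.8, 0.9, 1, 1, 1.1, 1.2, 1),
                             gene_noise_sd = 0.3),
    "americana-like" = list(condition_effect = 0, gene_noise_sd = 0.25))
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, c(args, list(seed = seed)))
}

#' Rank-recovery metrics against planted truth
#'
#' Compares a stability ranking with the planted stability order of a
#' synthetic dataset (ascending `sqrt(condition_effect^2 + gene_noise_sd^2)`).
#'
#' @param truth a [simulate_cq()] result.
#' @param result a `stability_result` computed on `truth$dataset`.
#' @param k top-k size for the hit rate (default 3, capped at n_genes).
#' @return List: `rank_correlation` (Spearman between planted instability
#'   and method ranks), `top_k_hit_rate`, `worst_gene_found` (did the method
#'   rank the most-planted-unstable gene last?).
#' @export
rank_recovery <- function(truth, result, k = 3) {
  stopifnot(inherits(truth, "synthetic_dataset"),
            inherits(result, "stability_result"))
  planted <- truth$truth$planted_instability
  if (!setequal(names(planted), names(result$ranks))) {
    rs_contract_error("gene sets of truth and result differ")
  }
  planted <- planted[names(result$ranks)]
  k <- min(k, length(planted))
  true_rank <- rank(planted, ties.method = "average")
  rho <- stats::cor(true_rank, result$ranks, method = "spearman")
  true_top <- names(sort(planted))[seq_len(k)]
  method_top <- names(sort(result$ranks))[seq_len(k)]
  worst_true <- names(planted)[which.max(planted)]
  list(rank_correlation = rho,
       top_k_hit_rate = length(intersect(true_top, method_top)) / k,
       worst_gene_found = result$ranks[worst_true] == length(planted))
}
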