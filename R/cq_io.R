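# Cq data model and I/O -------------------------------------------------
#
# A cq_dataset holds the raw per-well quantification cycles (one row per
# technical replicate) plus, after collapse_replicates(), a samples x genes
# matrix of per-cell mean (or median) Cq.  Missing wells are data, not
# errors: statistics downstream skip them and report effective n.

WELL_COLS <- c("sample_id", "gene", "replicate", "cq", "group", "tissue", "species")

#' Construct a Cq dataset from a table of wells
#'
#' @param wells data.frame with columns `sample_id`, `gene`, `cq` and
#'   optionally `replicate` (auto-numbered within sample x gene if absent),
#'   `group`, `tissue`, `species`.  `cq` is the quantification cycle in PCR
#'   cycles; `NA` marks a well with no amplification (or a reading removed
#'   upstream, e.g. for an aberrant melt curve).
#' @param cq_window plausible Cq window in cycles; values outside it are
#'   rejected (`on_out_of_window = "error"`) or flagged and excluded from
#'   collapsing (`"flag"`) — never silently used.
#' @param on_out_of_window `"error"` or `"flag"`.
#' @param metadata free-form list of annotations (instrument, threshold, ...).
#' @return An object of class `cq_dataset` with elements `wells`,
#'   `collapsed` (`NULL` until [collapse_replicates()] is called), `n_reps`,
#'   `groups` (named character, sample_id -> group) and `metadata`.
#' @export
cq_dataset <- function(wells, cq_window = c(5, 40),
                       on_out_of_window = c("error", "flag"),
                       metadata = list()) {
  on_out_of_window <- match.arg(on_out_of_window)
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  if (!nrow(wells)) rs_schema_error("input contains no data rows")

  for (col in c("sample_id", "gene")) {
    if (is.null(wells[[col]])) rs_schema_error(sprintf("missing mandatory column '%s'", col))
    wells[[col]] <- as.character(wells[[col]])
  }
  if (is.null(wells$cq)) rs_schema_error("missing mandatory column 'cq'")
  if (!is.numeric(wells$cq)) rs_parse_error("column 'cq' is not numeric")

  if (is.null(wells$replicate)) {
    wells$replicate <- stats::ave(seq_len(nrow(wells)),
                                  wells$sample_id, wells$gene,
                                  FUN = seq_along)
  }
  wells$replicate <- as.integer(wells$replicate)
  wells$group   <- as.character(wells$group   %||% rep("all", nrow(wells)))
  wells$tissue  <- as.character(wells$tissue  %||% rep(NA_character_, nrow(wells)))
  wells$species <- as.character(wells$species %||% rep(NA_character_, nrow(wells)))

  key <- paste(wells$sample_id, wells$gene, wells$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- wells[duplicated(key), , drop = FALSE][1L, ]
    rs_integrity_error(sprintf(
      "duplicate well (sample '%s', gene '%s', replicate %d)",
      dup$sample_id, dup$gene, dup$replicate))
  }

  bad <- !is.na(wells$cq) &
    (!is.finite(wells$cq) | wells$cq < cq_window[1] | wells$cq > cq_window[2])
  wells$flagged <- bad
  if (any(bad) && on_out_of_window == "error") {
    i <- which(bad)[1L]
    rs_domain_error(sprintf(
      "Cq %.3f outside plausible window [%g, %g] (sample '%s', gene '%s'); use on_out_of_window = \"flag\" to keep and exclude",
      wells$cq[i], cq_window[1], cq_window[2], wells$sample_id[i], wells$gene[i]))
  }

  # every sample must carry exactly one group label
  g <- unique(wells[, c("sample_id", "group")])
  if (anyDuplicated(g$sample_id)) {
    s <- g$sample_id[duplicated(g$sample_id)][1L]
    rs_integrity_error(sprintf("sample '%s' carries more than one group label", s))
  }
  groups <- stats::setNames(g$group, g$sample_id)

  structure(list(
    wells = wells[, c(WELL_COLS, "flagged")],
    collapsed = NULL, n_reps = NULL,
    groups = groups,
    metadata = c(metadata, list(cq_window = cq_window))
  ), class = "cq_dataset")
}

#' @export
print.cq_dataset <- function(x, ...) {
  cat(sprintf("<cq_dataset> %d wells, %d samples, %d genes, groups: %s\n",
              nrow(x$wells), length(unique(x$wells$sample_id)),
              length(unique(x$wells$gene)),
              paste(unique(x$groups), collapse = "/")))
  if (!is.null(x$collapsed)) {
    cat(sprintf("  collapsed: %d x %d matrix (%d missing cells)\n",
                nrow(x$collapsed), ncol(x$collapsed), sum(is.na(x$collapsed))))
  }
  invisible(x)
}

#' Read a long-format Cq table
#'
#' Expects delimited text with one row per qPCR well.  Empty Cq cells are
#' recorded as missing wells (no amplification observed, or the reading was
#' removed upstream) and later excluded from collapsing, never treated as 0.
#'
#' @param path file path; comma- or tab-delimited inferred from the extension
#'   (`.tsv`/`.txt` = tab) unless `sep` is given.
#' @param schema named list mapping the roles `sample`, `gene`, `cq` (and
#'   optionally `replicate`, `group`, `tissue`, `species`) to column names in
#'   the file.
#' @param sep field separator override.
#' @inheritParams cq_dataset
#' @return A [cq_dataset()].
#' @export
read_cq_table <- function(path,
                          schema = list(sample = "sample", gene = "gene",
                                        cq = "cq", replicate = "replicate",
                                        group = "group", tissue = "tissue",
                                        species = "species"),
                          sep = NULL, cq_window = c(5, 40),
                          on_out_of_window = c("error", "flag")) {
  if (!file.exists(path)) rs_schema_error(sprintf("file not found: %s", path))
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", na.strings = c("NA", ""))
  for (role in c("sample", "gene", "cq")) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      rs_schema_error(sprintf("input lacks required column '%s' (role: %s)",
                              col %||% role, role))
    }
  }
  cq_chr <- raw[[schema$cq]]
  cq <- suppressWarnings(as.numeric(cq_chr))
  bad <- which(!is.na(cq_chr) & is.na(cq))
  if (length(bad)) {
    rs_parse_error(sprintf("non-numeric Cq value '%s' at data row %d",
                           cq_chr[bad[1]], bad[1]))
  }
  pick <- function(role) if (!is.null(schema[[role]]) && schema[[role]] %in% names(raw))
    raw[[schema[[role]]]] else NULL
  wells <- data.frame(sample_id = raw[[schema$sample]],
                      gene = raw[[schema$gene]], cq = cq,
                      stringsAsFactors = FALSE)
  for (role in c("replicate", "group", "tissue", "species")) {
    v <- pick(role)
    if (!is.null(v)) wells[[role]] <- v
  }
  cq_dataset(wells, cq_window = cq_window, on_out_of_window = on_out_of_window)
}

#' Read a wide Cq matrix (genes as columns)
#'
#' For supplement-shaped tables: one row per technical replicate of a sample,
#' one column per gene.
#'
#' @param path file path (delimiter inferred as in [read_cq_table()]).
#' @param sample_col,group_col,tissue_col,species_col annotation column names
#'   (only `sample_col` is mandatory).
#' @param gene_cols columns holding Cq values; default: every column that is
#'   not an annotation column.
#' @inheritParams read_cq_table
#' @return A [cq_dataset()].
#' @export
read_cq_wide <- function(path, sample_col = "sample", group_col = "group",
                         tissue_col = "tissue", species_col = "species",
                         gene_cols = NULL, sep = NULL,
                         cq_window = c(5, 40),
                         on_out_of_window = c("error", "flag")) {
  if (!file.exists(path)) rs_schema_error(sprintf("file not found: %s", path))
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!sample_col %in% names(raw)) {
    rs_schema_error(sprintf("input lacks required column '%s' (role: sample)", sample_col))
  }
  ann <- intersect(c(sample_col, group_col, tissue_col, species_col), names(raw))
  gene_cols <- gene_cols %||% setdiff(names(raw), ann)
  if (!length(gene_cols)) rs_schema_error("no gene columns found")
  long <- do.call(rbind, lapply(gene_cols, function(g) {
    cq <- suppressWarnings(as.numeric(raw[[g]]))
    bad <- which(!is.na(raw[[g]]) & is.na(cq))
    if (length(bad)) rs_parse_error(sprintf(
      "non-numeric Cq value '%s' in column '%s', data row %d", raw[[g]][bad[1]], g, bad[1]))
    out <- data.frame(sample_id = as.character(raw[[sample_col]]), gene = g,
                      cq = cq, stringsAsFactors = FALSE)
    if (group_col %in% ann)   out$group   <- as.character(raw[[group_col]])
    if (tissue_col %in% ann)  out$tissue  <- as.character(raw[[tissue_col]])
    if (species_col %in% ann) out$species <- as.character(raw[[species_col]])
    out
  }))
  cq_dataset(long, cq_window = cq_window, on_out_of_window = on_out_of_window)
}

#' Collapse technical replicates
#'
#' Averages the available technical replicates of every (sample, gene) cell
#' into a single Cq (arithmetic mean by default, the qPCR convention; median
#' as an option).  Cells with no usable replicate stay missing.  Flagged
#' (out-of-window) wells never contribute.
#'
#' @param ds a [cq_dataset()].
#' @param policy `"mean"` or `"median"`.
#' @return The dataset with `collapsed` (samples x genes Cq matrix) and
#'   `n_reps` (contributing replicate counts) filled in; cells collapsed from
#'   a single replicate are listed in `metadata$low_replication`.
#' @export
collapse_replicates <- function(ds, policy = c("mean", "median")) {
  policy <- match.arg(policy)
  stopifnot(inherits(ds, "cq_dataset"))
  w <- ds$wells[!ds$wells$flagged, , drop = FALSE]
  samples <- unique(ds$wells$sample_id)
  genes <- unique(ds$wells$gene)
  f <- if (policy == "mean") mean else stats::median

  agg_val <- tapply(w$cq, list(factor(w$sample_id, samples), factor(w$gene, genes)),
                    function(x) if (all(is.na(x))) NA_real_ else f(x[!is.na(x)]))
  agg_n <- tapply(w$cq, list(factor(w$sample_id, samples), factor(w$gene, genes)),
                  function(x) sum(!is.na(x)))
  collapsed <- matrix(unlist(agg_val), nrow = length(samples),
                      dimnames = list(samples, genes))
  n_reps <- matrix(as.integer(unlist(agg_n)), nrow = length(samples),
                   dimnames = list(samples, genes))
  n_reps[is.na(n_reps)] <- 0L

  ds$collapsed <- collapsed
  ds$n_reps <- n_reps
  low <- which(n_reps == 1L, arr.ind = TRUE)
  ds$metadata$collapse_policy <- policy
  ds$metadata$low_replication <- if (nrow(low)) {
    data.frame(sample_id = samples[low[, 1]], gene = genes[low[, 2]],
               stringsAsFactors = FALSE)
  } else NULL
  ds
}

# Collapse with the default policy if the caller has not done so.
ensure_collapsed <- function(ds) {
  if (is.null(ds$collapsed)) collapse_replicates(ds) else ds
}

#' Convert collapsed Cq to linear-scale relative quantities
#'
#' For each gene, the sample with the lowest Cq (most template) defines the
#' unit: `q = E ^ (min Cq - Cq)`, so `q` is in (0, 1] under the default
#' anchor.  `E` is the per-cycle amplification factor (2 = 100% efficiency).
#' Any common anchor yields identical downstream stability values; the
#' per-gene minimum is the geNorm convention.
#'
#' @param ds a [cq_dataset()] (collapsed with the default mean policy if not
#'   collapsed yet).
#' @param efficiency scalar or per-gene named numeric amplification factor in
#'   (1, 2.2]; default 2.0, the 100%-efficiency assumption.
#' @return An object of class `quantity_matrix`: list with `q` (samples x
#'   genes matrix), `efficiency` (per-gene), `reference_cq` (per-gene anchor),
#'   `groups`.
#' @export
to_quantities <- function(ds, efficiency = 2.0) {
  ds <- ensure_collapsed(ds)
  cq <- ds$collapsed
  genes <- colnames(cq)
  if (length(efficiency) == 1L && is.null(names(efficiency))) {
    eff <- stats::setNames(rep(as.numeric(efficiency), length(genes)), genes)
  } else {
    miss <- setdiff(genes, names(efficiency))
    if (length(miss)) rs_contract_error(sprintf(
      "no efficiency supplied for gene(s): %s", paste(miss, collapse = ", ")))
    eff <- stats::setNames(as.numeric(efficiency[genes]), genes)
  }
  if (any(eff <= 1 | eff > 2.2)) {
    rs_domain_error("amplification efficiency must be in (1, 2.2]")
  }
  ref <- apply(cq, 2, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  q <- sweep(-cq, 2, ref, `+`)                    # ref - cq
  q <- sweep(q, 2, log(eff), `*`)
  q <- exp(q)
  structure(list(q = q, efficiency = eff, reference_cq = ref,
                 groups = ds$groups), class = "quantity_matrix")
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat(sprintf("<quantity_matrix> %d samples x %d genes, E in [%.3f, %.3f]\n",
              nrow(x$q), ncol(x$q), min(x$efficiency), max(x$efficiency)))
  invisible(x)
}

header_comment <- function(params = character()) {
  sprintf("# refstab %s%s",
          as.character(utils::packageVersion("refstab")),
          if (length(params)) paste0("; ", paste(names(params), params,
                                                 sep = "=", collapse = "; ")) else "")
}

#' Write collapsed Cq values as long-format TSV
#'
#' Values are written with full precision (`digits = 17`) so that a
#' write/read round trip is bit-identical.
#'
#' @param ds a collapsed [cq_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(ds, path) {
  ds <- ensure_collapsed(ds)
  long <- expand.grid(sample = rownames(ds$collapsed), gene = colnames(ds$collapsed),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$cq <- as.vector(ds$collapsed)
  long$n_reps <- as.vector(ds$n_reps)
  long$group <- unname(ds$groups[long$sample])
  long <- long[!is.na(long$cq), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comment(c(collapse = ds$metadata$collapse_policy %||% "mean")), con)
  writeLines(paste(c("sample", "gene", "cq", "n_reps", "group"), collapse = "\t"), con)
  writeLines(paste(long$sample, long$gene, format(long$cq, digits = 17),
                   long$n_reps, long$group, sep = "\t"), con)
  invisible(path)
}

#' Write a quantity matrix as TSV
#'
#' @param qm a `quantity_matrix` from [to_quantities()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quantities <- function(qm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comment(c(efficiency = paste(format(qm$efficiency, digits = 6),
                                                 collapse = ","))), con)
  writeLines(paste(c("sample", colnames(qm$q)), collapse = "\t"), con)
  apply_rows <- vapply(seq_len(nrow(qm$q)), function(i) {
    paste(c(rownames(qm$q)[i], format(qm$q[i, ], digits = 17)), collapse = "\t")
  }, character(1))
  writeLines(apply_rows, con)
  invisible(path)
}
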