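# Build a collapsed cq_dataset directly from a samples x genes Cq matrix.
make_ds <- function(cq, groups = NULL, window = c(-Inf, Inf)) {
  if (is.null(rownames(cq))) rownames(cq) <- sprintf("s%d", seq_len(nrow(cq)))
  if (is.null(colnames(cq))) colnames(cq) <- sprintf("g%d", seq_len(ncol(cq)))
  groups <- groups %||% rep("all", nrow(cq))
  long <- expand.grid(sample_id = rownames(cq), gene = colnames(cq),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$cq <- as.vector(cq)
  long$group <- groups[match(long$sample_id, rownames(cq))]
  collapse_replicates(cq_dataset(long, cq_window = window))
}

make_qm <- function(cq, groups = NULL, efficiency = 2) {
  to_quantities(make_ds(cq, groups), efficiency = efficiency)
}

`%||%` <- refstab:::`%||%`
with_seed <- refstab:::with_seed
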