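# Published benchmark tables ---------------------------------------------
#
# Plain-text transcriptions of published stability rankings, primer
# efficiencies and reference-gene suggestions for a four-species
# Schistocerca grasshopper panel (head/thorax, isolated vs crowded
# rearing).  These printed values serve as fixtures for the consensus and
# recommendation machinery; the underlying raw Cq tables are not shipped.

#' Published benchmark tables
#'
#' @param which one of `"rankings"` (per-method stability values and ranks
#'   for 8 genes x 4 species x 2 tissues), `"efficiencies"` (primer
#'   efficiencies per gene and species) or `"suggestions"` (recommended
#'   reference genes per species and tissue).
#' @return A data.frame.
#' @export
published_table <- function(which = c("rankings", "efficiencies", "suggestions")) {
  which <- match.arg(which)
  fname <- switch(which,
    rankings = "published_stability_rankings.tsv",
    efficiencies = "primer_efficiencies.tsv",
    suggestions = "suggested_reference_genes.tsv")
  path <- system.file("extdata", fname, package = "refstab")
  if (path == "") rs_schema_error(sprintf("bundled table '%s' not found", fname))
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
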