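#' Published per-residue binding energy components
#'
#' Published MM/PBSA per-residue component means (and standard deviations)
#' for the three cofactor-pocket residues K579, D590 and E755 of the
#' glucocorticoid receptor bound to TIF2, across five agonist-bound systems
#' (dexamethasone, AZ938, prednisolone, cortisone, dibC). Terms: `vdw`,
#' `ele`, `nonpolar`, `polar` (the continuum solvation row) and the printed
#' `binding` total; all kcal/mol. Used for identity checks of the
#' aggregation path [aggregate_binding()].
#'
#' @return data.frame with columns `residue`, `term`, `system`, `mean`, `sd`.
#' @export
reference_energy_table <- function() {
  path <- system.file("extdata", "reference_energy_components.tsv",
                      package = "allodyn", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
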