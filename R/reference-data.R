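# Packaged reference tables: published ligand-subsite distances, superposed
# per-atom displacements, and inhibition/catalysis constants for the four
# N-sulfamoyl complexes of carboxypeptidase T.

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "tsakit")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file) # pre-install use
  if (!file.exists(p)) stop("packaged reference file not found: ", file)
  p
}

#' Published ligand-to-subsite distances (long format)
#'
#' One row per (ligand, contact): the 16 catalytic-subsite contacts measured
#' in the four CPT + N-sulfamoyl complexes. For the SLeu complex the Tyr255
#' OH carboxylate partner is O15 (not O16), as published.
#'
#' @return data.frame: row, ligand, ligand_atom, partner_res, partner_seq,
#'   partner_atom, metal, distance (Angstrom).
#' @export
subsite_distance_reference <- function() {
  d <- utils::read.delim(.extdata("cpt_subsite_distances.tsv"),
                         stringsAsFactors = FALSE)
  d$partner_seq <- as.integer(d$partner_seq)
  d
}

#' Published per-atom displacements between superposed complexes
#'
#' Displacements of ligand and active-site atoms after Calpha superposition
#' of the SArg, SPhe and SLeu complexes onto the SGlu complex.
#'
#' @return data.frame: label, SGlu_SArg, SGlu_SPhe, SGlu_SLeu (Angstrom).
#' @export
superposition_displacement_reference <- function() {
  utils::read.delim(.extdata("cpt_superposition_displacements.tsv"),
                    stringsAsFactors = FALSE)
}

#' Published inhibition constants and catalytic efficiencies
#'
#' K_I of the four transition-state analogs and kcat/KM of the matching
#' ZAAX tripeptide substrates. The ZAAF efficiency is cited from earlier
#' work (source flag "cited"); the rest were measured alongside the
#' structures. Note: one summary passage elsewhere prints the SGlu constant
#' as 3.9e-3 M; the tabulated 3.09e-3 M is shipped.
#'
#' @return data.frame: ligand, K_I, K_I_sd (M), substrate, kcat_over_KM,
#'   kcat_over_KM_sd (1/(M s)), source.
#' @export
inhibition_kinetics_reference <- function() {
  utils::read.delim(.extdata("cpt_inhibition_kinetics.tsv"),
                    stringsAsFactors = FALSE)
}
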