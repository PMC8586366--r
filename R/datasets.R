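#' Frontier-orbital energies of the thiazolo[3,2-a]pyrimidine series
#'
#' HOMO/LUMO energies (eV) for the 2-aroyl-3-methyl-6,7-dihydro-5H-
#' thiazolo[3,2-a]pyrimidine derivatives 4a-4g, as obtained upstream by
#' force-field energy minimisation. These are consumed as inputs by
#' [descriptors_from_orbitals()]; the package never computes orbital
#' energies itself.
#'
#' @return Data frame with columns `compound_id`, `e_homo`, `e_lumo`.
#' @export
tzp_orbital_energies <- function() {
  data.frame(
    compound_id = c("4a", "4b", "4c", "4d", "4e", "4f", "4g"),
    e_homo = c(-6.314, -6.304, -6.284, -6.281, -6.276, -6.288, -6.261),
    e_lumo = c(-3.809, -3.589, -3.257, -3.059, -3.440, -3.225, -2.716),
    stringsAsFactors = FALSE)
}

#' Reported global reactivity descriptors for the series
#'
#' The descriptor values tabulated upstream (to three decimals) for
#' compounds 4a-4g: energy gap, ionisation potential, electron affinity,
#' hardness, chemical potential, softness, electronegativity and
#' electrophilicity. Useful as a cross-check target for
#' [descriptors_from_orbitals()]; agreement is to within 0.005 because the
#' tabulated intermediates were rounded.
#'
#' @return Data frame with columns `compound_id`, `delta_e`, `ip`, `ea`,
#'   `hardness_eta`, `chemical_potential_mu`, `softness_s`,
#'   `electronegativity_chi`, `electrophilicity_omega`.
#' @export
tzp_reported_descriptors <- function() {
  data.frame(
    compound_id = c("4a", "4b", "4c", "4d", "4e", "4f", "4g"),
    delta_e = c(2.505, 2.715, 3.027, 3.222, 2.836, 3.063, 3.545),
    ip = c(6.314, 6.304, 6.284, 6.281, 6.276, 6.288, 6.261),
    ea = c(3.809, 3.589, 3.257, 3.059, 3.440, 3.225, 2.716),
    hardness_eta = c(1.252, 1.357, 1.513, 1.611, 1.418, 1.531, 1.772),
    chemical_potential_mu = c(-5.061, -4.946, -4.770, -4.670, -4.858, -4.756, -4.488),
    softness_s = c(0.399, 0.368, 0.330, 0.310, 0.352, 0.326, 0.282),
    electronegativity_chi = c(5.061, 4.946, 4.770, 4.670, 4.858, 4.756, 4.488),
    electrophilicity_omega = c(10.229, 9.013, 7.519, 6.768, 8.321, 7.387, 5.683),
    stringsAsFactors = FALSE)
}

#' Molecular drug-likeness properties of the series
#'
#' Molecular weight, calculated lipophilicity (cLogP), total polar surface
#' area and hydrogen-bond/rotatable-bond counts for compounds 4a-4h, as
#' computed upstream by a property-prediction program. Consumed as inputs by
#' [lipinski_evaluate()]; the package never computes cLogP or TPSA.
#'
#' @return Data frame with columns `compound_id`, `mw`, `clogp`, `tpsa`,
#'   `n_hba`, `n_hbd`, `rotatable_bonds`.
#' @export
tzp_properties <- function() {
  data.frame(
    compound_id = c("4a", "4b", "4c", "4d", "4e", "4f", "4g", "4h"),
    tpsa = c(57.97, 57.97, 57.97, 57.97, 67.20, 67.20, 57.97, 86.21),
    mw = c(258, 272, 337, 276, 288, 288, 327, 264),
    clogp = c(2.28, 2.62, 3.00, 2.38, 2.21, 2.21, 3.49, 2.15),
    n_hba = c(3L, 3L, 3L, 3L, 4L, 4L, 3L, 3L),
    n_hbd = rep(0L, 8L),
    rotatable_bonds = c(2L, 2L, 2L, 2L, 3L, 3L, 2L, 2L),
    stringsAsFactors = FALSE)
}

#' Reported quenching and binding constants for ligand 4g
#'
#' Stern-Volmer constants, binding constants, site numbers and Gibbs free
#' energies tabulated upstream for the 2,4-dichloro derivative 4g titrated
#' against BSA (25/30/35 degC) and ct-DNA (25 degC). The raw titration
#' curves behind these fits were not published, so these serve as reference
#' values for identities (Kq = Ksv/tau0, dG = -RT ln Kb) and trends, not as
#' refittable data. Note the tabulated log10(Kb)/Kb/dG triplets are mutually
#' inconsistent at the ~0.1-0.2 kcal/mol level, reflecting rounding in the
#' source; comparisons should use correspondingly loose tolerances.
#'
#' @return Data frame with columns `macromolecule`, `temperature_K`, `ksv`,
#'   `kq`, `log10_kb`, `kb`, `n_sites`, `delta_g_kcal`.
#' @export
tzp_binding_constants <- function() {
  data.frame(
    macromolecule = c("BSA", "BSA", "BSA", "DNA"),
    temperature_K = c(298.15, 303.15, 308.15, 298.15),
    ksv = c(4.2e4, 4.1e4, 3.4e4, 1.2e4),
    kq = c(4.2e12, 4.1e12, 3.4e12, 1.2e12),
    log10_kb = c(5.2, 4.5, 4.3, 3.6),
    kb = c(1.8e5, 3.3e4, 2.2e4, 3.9e3),
    n_sites = c(1.1, 0.9, 0.9, 0.8),
    delta_g_kcal = c(-7.06, -6.21, -5.94, -4.8),
    stringsAsFactors = FALSE)
}
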