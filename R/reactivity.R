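#' Global reactivity descriptors from frontier-orbital energies
#'
#' Given HOMO and LUMO energies in eV, computes the conceptual-DFT global
#' reactivity descriptors under Koopmans' theorem:
#' \deqn{IP = -E_{HOMO}, \quad EA = -E_{LUMO}, \quad \Delta E = E_{LUMO}-E_{HOMO},}
#' \deqn{\eta = (IP-EA)/2, \quad S = 1/(2\eta), \quad \chi = (IP+EA)/2,}
#' \deqn{\mu = -(IP+EA)/2, \quad \omega = \mu^2/(2\eta).}
#' A small HOMO-LUMO gap marks a soft, reactive molecule; a degenerate gap
#' (zero hardness) leaves softness and electrophilicity undefined and is an
#' error.
#'
#' @param e_homo,e_lumo Numeric vectors of orbital energies in eV, with
#'   `e_lumo > e_homo` elementwise.
#' @param compound_id Optional character vector of labels.
#' @return A data frame with one row per compound and columns `compound_id`,
#'   `e_homo`, `e_lumo`, `delta_e`, `ip`, `ea`, `hardness_eta`, `softness_s`,
#'   `electronegativity_chi`, `chemical_potential_mu`, `electrophilicity_omega`
#'   (eV; softness in 1/eV).
#' @examples
#' descriptors_from_orbitals(-6.314, -3.809)
#' @export
descriptors_from_orbitals <- function(e_homo, e_lumo,
                                      compound_id = paste0("cmpd", seq_along(e_homo))) {
  if (length(e_homo) != length(e_lumo))
    stop_bindkit("length_mismatch", "e_homo and e_lumo differ in length")
  if (any(e_lumo <= e_homo))
    stop_bindkit("zero_hardness",
                 "e_lumo must exceed e_homo (zero gap leaves softness and omega undefined)")
  ip <- -e_homo
  ea <- -e_lumo
  delta_e <- ip - ea  # equals e_lumo - e_homo
  eta <- delta_e / 2
  mu <- -(ip + ea) / 2
  data.frame(compound_id = as.character(compound_id),
             e_homo = e_homo, e_lumo = e_lumo,
             delta_e = delta_e, ip = ip, ea = ea,
             hardness_eta = eta,
             softness_s = 1 / (2 * eta),
             electronegativity_chi = (ip + ea) / 2,
             chemical_potential_mu = mu,
             electrophilicity_omega = mu^2 / (2 * eta),
             stringsAsFactors = FALSE)
}

#' Rank compounds by reactivity (HOMO-LUMO gap)
#'
#' Orders a descriptor table by ascending energy gap: the smaller the gap,
#' the more polarisable and reactive the molecule. Ties share a rank.
#'
#' @param descriptors Data frame from [descriptors_from_orbitals()] (needs
#'   `compound_id` and `delta_e`).
#' @return The table sorted by `delta_e` with added `rank` (1 = most
#'   reactive), plus attributes `most_reactive` and `least_reactive`.
#' @export
rank_reactivity <- function(descriptors) {
  if (nrow(descriptors) < 2L)
    stop_bindkit("insufficient_data", "need at least two compounds to rank")
  out <- descriptors[order(descriptors$delta_e), , drop = FALSE]
  out$rank <- rank(out$delta_e, ties.method = "min")
  rownames(out) <- NULL
  attr(out, "most_reactive") <- out$compound_id[out$rank == 1L]
  attr(out, "least_reactive") <- out$compound_id[out$rank == max(out$rank)]
  out
}

#' Lipinski rule-of-five / TPSA drug-likeness evaluation
#'
#' Counts violations of the standard rule-of-five set - MW > 500, cLogP > 5,
#' H-bond acceptors > 10, H-bond donors > 5 (boundaries inclusive: a value
#' exactly at the limit does not violate) - and flags TPSA > 140 A^2, beyond
#' which passive absorption drops. The oral-bioavailability prediction
#' requires at most one rule violation and an acceptable TPSA.
#'
#' @param props Data frame with columns `compound_id`, `mw`, `clogp`, `tpsa`,
#'   `n_hba`, `n_hbd` (and optionally `rotatable_bonds`).
#' @return A data frame with one row per compound: `compound_id`,
#'   `violations` (0-4), `violated_rules` (comma-separated, "" when none),
#'   `tpsa_flag`, `clogp_flag`, `orally_bioavailable_prediction`.
#' @export
lipinski_evaluate <- function(props) {
  need <- c("compound_id", "mw", "clogp", "tpsa", "n_hba", "n_hbd")
  missing <- setdiff(need, names(props))
  if (length(missing))
    stop_bindkit("missing_column",
                 paste("missing column(s):", paste(missing, collapse = ", ")))
  if (any(props$mw <= 0) || any(props$n_hba < 0) || any(props$n_hbd < 0))
    stop_bindkit("bad_parameter", "mw must be > 0 and H-bond counts >= 0")
  rules <- cbind("MW > 500" = props$mw > 500,
                 "cLogP > 5" = props$clogp > 5,
                 "HBA > 10" = props$n_hba > 10,
                 "HBD > 5" = props$n_hbd > 5)
  violations <- rowSums(rules)
  violated <- apply(rules, 1L, function(r)
    paste(colnames(rules)[r], collapse = ", "))
  tpsa_flag <- props$tpsa > 140
  data.frame(compound_id = props$compound_id,
             violations = as.integer(violations),
             violated_rules = violated,
             tpsa_flag = tpsa_flag,
             clogp_flag = props$clogp > 5,
             orally_bioavailable_prediction = violations <= 1 & !tpsa_flag,
             stringsAsFactors = FALSE)
}
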