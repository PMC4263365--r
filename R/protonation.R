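# Ionizable-residue model: Henderson-Hasselbalch protonation probabilities,
# the pH score term, protonation-variant enumeration, and pH equilibration.

#' Probability of side-chain protonation
#'
#' Henderson-Hasselbalch form: `P = 1 / (1 + 10^(pH - IpKa))`, using the
#' intrinsic pKa of the residue type. Strictly decreasing in pH; equals 0.5
#' at the intrinsic pKa.
#'
#' @param res_type one of `"ASP"`, `"GLU"`, `"HIS"`, `"TYR"`, `"LYS"` (three-
#'   letter, case-insensitive).
#' @param ph solution pH.
#' @param table a [pka_table()].
#' @param state return the probability of the protonated (default) or the
#'   deprotonated state; the deprotonated form is computed by the mirrored
#'   formula `1 / (1 + 10^(IpKa - pH))`, which is numerically stable at
#'   extreme pH.
#' @return probability in `[0, 1]`.
#' @export
#' @examples
#' protonation_probability("HIS", 6.3)  # 0.5
protonation_probability <- function(res_type, ph, table = pka_table(),
                                    state = c("protonated", "deprotonated")) {
  res_type <- toupper(res_type)
  state <- match.arg(state)
  if (!res_type %in% IONIZABLE_AA)
    stop("domain error: ", res_type, " is not an ionizable residue type")
  ipka <- table$intrinsic_pka[[res_type]]
  if (state == "protonated") 1 / (1 + 10^(ph - ipka))
  else 1 / (1 + 10^(ipka - ph))
}

#' pH score term for a protonation state
#'
#' Boltzmann inversion of the state probability:
#' `E_pH = -kT * ln(P_state)`, where `P_state` is the protonation
#' probability for protonated labels and its complement for deprotonated
#' labels. Capped at `cap` kcal/mol to avoid infinities at extreme pH.
#'
#' @param label a protonation label (`"ASP"`, `"ASH1"`, `"HIP"`, ... or
#'   `"fixed"`, which scores 0).
#' @param ph solution pH.
#' @param table a [pka_table()].
#' @param cap maximum energy in kcal/mol (default 15).
#' @return energy in kcal/mol.
#' @export
#' @examples
#' ph_energy("HIP", 6.3)  # -0.59 * log(0.5) = 0.409
ph_energy <- function(label, ph, table = pka_table(), cap = 15) {
  if (label == "fixed") return(0)
  res_type <- label_res_type(label)
  ipka <- table$intrinsic_pka[[res_type]]
  # -kT ln P in log-space: ln P = -ln(1 + 10^(+/-(pH - IpKa)))
  z <- if (label_is_protonated(label)) ph - ipka else ipka - ph
  min(cap, table$kT * log1p(10^z))
}

#' Enumerate protonation variants of a residue type
#'
#' His has three variants (two neutral tautomers and the doubly protonated,
#' +1 form), Asp/Glu three (two proton placements on the carboxylate and the
#' deprotonated form), Tyr/Lys two. All other residue types, including Cys
#' (whose titration is coupled to redox equilibrium and is ignored), return
#' the single `"fixed"` variant.
#'
#' @param aa three-letter residue type.
#' @return character vector of protonation labels.
#' @export
#' @examples
#' enumerate_variants("HIS")  # "HID" "HIE" "HIP"
enumerate_variants <- function(aa) {
  aa <- toupper(aa)
  if (aa %in% IONIZABLE_AA) PROT_LABELS[[aa]] else "fixed"
}

#' Equilibrate protonation states with the solution pH
#'
#' Assigns every ionizable residue the protonation variant (and side-chain
#' rotamer, via the packer) minimizing the weighted score including the pH
#' term. Deterministic for a fixed seed.
#'
#' @param cx fullatom `ph_complex`.
#' @param ph solution pH.
#' @param weights a [score_weights()] set.
#' @param seed integer seed.
#' @return the complex with updated labels/side chains.
#' @export
equilibrate_protonation <- function(cx, ph = cx$ph,
                                    weights = score_weights("phdock"),
                                    seed = 1) {
  if (cx$representation != "fullatom")
    stop("state error: equilibrate_protonation requires fullatom input")
  designable <- which(cx$residues$prot != "fixed")
  if (!length(designable)) return(cx)
  cx$ph <- ph
  pack_sidechains(cx, packer_task(designable, ph = ph, weights = weights,
                                  seed = seed))
}
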