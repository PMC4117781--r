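#' Three-phase contrast model
#'
#' Electron-density bookkeeping for solvent, protein and DNA phases. Scattering
#' contrast of a bead is its excess electron density over solvent times its
#' volume. Adding sucrose raises the solvent density linearly until, at 50%
#' sucrose (weight fraction 0.5) and 0 M NaCl, it matches the protein phase:
#' protein beads then carry zero contrast ("protein blanking") and only DNA
#' scatters. NaCl also raises the solvent density slightly (default
#' +0.009 e/A^3 per mol/L), so at high salt the protein match is marginally
#' imperfect.
#'
#' @param rho_solv0 Solvent electron density at 0% sucrose, 0 M NaCl (e/A^3).
#' @param rho_prot Protein-phase electron density (e/A^3).
#' @param rho_dna DNA-phase electron density (e/A^3).
#' @param sucrose_slope Solvent density increase per unit sucrose weight
#'   fraction (e/A^3); the default puts the protein match point exactly at
#'   50% sucrose in a buffer containing `match_salt` mol/L NaCl.
#' @param nacl_slope Solvent density increase per mol/L NaCl (e/A^3/M).
#' @param match_salt NaCl concentration (mol/L) of the buffer in which the
#'   50% sucrose match is calibrated. Matching buffers are prepared per
#'   condition at the beamline, so simulations of an experiment at salt S
#'   use `contrast_model(match_salt = S)`; the default 0 makes
#'   `contrast_of("PROTEIN", 0.5)` exactly zero in plain buffer.
#' @param bead_volume_dna Volume per DNA backbone bead (A^3).
#' @param bead_volume_prot Volume per pseudo-histone bead (A^3); the default
#'   gives the 8-bead core an octamer-scale total volume.
#' @return A `contrast_model` list.
#' @examples
#' m <- contrast_model()
#' contrast_of("PROTEIN", sucrose = 0.5, model = m) # 0: protein blanked
#' @export
contrast_model <- function(rho_solv0 = 0.334,
                           rho_prot = 0.42,
                           rho_dna = 0.55,
                           nacl_slope = 0.009,
                           match_salt = 0,
                           sucrose_slope = (rho_prot - rho_solv0 -
                                              nacl_slope * match_salt) / 0.5,
                           bead_volume_dna = 300,
                           bead_volume_prot = 16000) {
  if (!(rho_dna > rho_prot && rho_prot >= rho_solv0)) {
    stop("need rho_dna > rho_prot >= rho_solv0", call. = FALSE)
  }
  if (sucrose_slope <= 0) stop("rho_solv must increase with sucrose",
                               call. = FALSE)
  structure(list(rho_solv0 = rho_solv0, rho_prot = rho_prot,
                 rho_dna = rho_dna, sucrose_slope = sucrose_slope,
                 nacl_slope = nacl_slope, bead_volume_dna = bead_volume_dna,
                 bead_volume_prot = bead_volume_prot),
            class = "contrast_model")
}

#' Solvent electron density at a given solvent composition
#'
#' @param model A [contrast_model()].
#' @param sucrose Sucrose weight fraction in [0, 0.6].
#' @param nacl NaCl concentration, mol/L.
#' @return Electron density, e/A^3.
#' @export
solvent_density <- function(model = contrast_model(), sucrose = 0, nacl = 0) {
  if (any(sucrose < 0 | sucrose > 0.6)) {
    stop("sucrose weight fraction must lie in [0, 0.6]", call. = FALSE)
  }
  model$rho_solv0 + model$sucrose_slope * sucrose + model$nacl_slope * nacl
}

#' Excess scattering weight per bead for a phase
#'
#' The per-bead contrast weight is (rho_phase - rho_solv) * bead_volume, in
#' electrons. At the protein match point (50% sucrose, 0 M NaCl) the protein
#' weight is exactly zero.
#'
#' @param phase `"DNA"` or `"PROTEIN"` (vectorised).
#' @param sucrose Sucrose weight fraction in [0, 0.6].
#' @param nacl NaCl concentration, mol/L.
#' @param model A [contrast_model()].
#' @return Excess scattering weight(s), electrons.
#' @export
contrast_of <- function(phase, sucrose = 0, nacl = 0,
                        model = contrast_model()) {
  if (!all(phase %in% c("DNA", "PROTEIN"))) {
    stop("phase must be 'DNA' or 'PROTEIN'", call. = FALSE)
  }
  rs <- solvent_density(model, sucrose, nacl)
  rho <- ifelse(phase == "DNA", model$rho_dna, model$rho_prot)
  vol <- ifelse(phase == "DNA", model$bead_volume_dna, model$bead_volume_prot)
  (rho - rs) * vol
}

# per-bead contrast weights of a conformer at a solvent condition
bead_weights <- function(conf, sucrose = 0, nacl = 0,
                         model = contrast_model()) {
  contrast_of(conf$phase, sucrose = sucrose, nacl = nacl, model = model)
}
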