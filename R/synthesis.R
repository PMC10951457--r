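# Mean molar mass of one double-stranded base pair (g/mol) and Avogadro's
# number; used to convert a plasmid length to the mass of a single molecule.
BP_MOLAR_MASS <- 650
AVOGADRO <- 6.02214076e23

#' Construct a DNA synthesis run
#'
#' Describes one DNA-production event from which the number of DNA doublings
#' is derived. In vivo runs start from the single plasmid molecule that
#' transformed the founding bacterium, so their input mass is the mass of one
#' plasmid. In vitro runs (PCR, RCA) start from a weighed template, but only
#' the amplified region is replicated, so the effective input is the template
#' mass scaled by the amplicon's share of the plasmid.
#'
#' @param method `"in_vivo"`, `"pcr"` or `"rca"`.
#' @param label Free-text strain or polymerase name.
#' @param plasmid_length_bp Length of the full template plasmid (bp).
#' @param amplicon_length_bp Length of the region copied in vitro (bp,
#'   <= plasmid length; defaults to the full plasmid).
#' @param template_mass_g Template mass added to an in vitro reaction (g);
#'   required for `"pcr"`/`"rca"`, ignored in vivo.
#' @param output_mass_g Mass of DNA recovered after synthesis (g).
#' @return An object of class `synthesis_run`.
#' @examples
#' synthesis_run("in_vivo", "DH5a", plasmid_length_bp = 5000,
#'               output_mass_g = 5e-6)
#' @export
synthesis_run <- function(method = c("in_vivo", "pcr", "rca"), label = method,
                          plasmid_length_bp,
                          amplicon_length_bp = plasmid_length_bp,
                          template_mass_g = NA_real_, output_mass_g) {
  method <- match.arg(method)
  check_scalar(plasmid_length_bp, "plasmid_length_bp", lower = 1)
  check_scalar(amplicon_length_bp, "amplicon_length_bp", lower = 1)
  check_scalar(output_mass_g, "output_mass_g", lower = 0,
               strict_lower = TRUE)
  if (amplicon_length_bp > plasmid_length_bp) {
    sutox_error("amplicon_length_bp cannot exceed plasmid_length_bp",
                "sutox_invalid_input")
  }
  if (method != "in_vivo") {
    if (!is_scalar_number(template_mass_g) || template_mass_g <= 0) {
      sutox_error(sprintf(
        "method '%s' requires a positive template_mass_g", method),
        "sutox_invalid_input")
    }
  }
  structure(
    list(method = method, label = as.character(label),
         plasmid_length_bp = plasmid_length_bp,
         amplicon_length_bp = amplicon_length_bp,
         template_mass_g = if (method == "in_vivo") NA_real_
                           else template_mass_g,
         output_mass_g = output_mass_g,
         single_molecule_input = method == "in_vivo"),
    class = "synthesis_run")
}

#' Mass of a single double-stranded plasmid molecule
#'
#' Uses the standard dsDNA approximation of 650 g/mol per base pair:
#' `length_bp * 650 / N_A` grams, with `N_A` Avogadro's number.
#'
#' @param length_bp Plasmid length in base pairs.
#' @param bp_molar_mass Mean molar mass per base pair (g/mol); default 650.
#' @return Mass in grams.
#' @examples
#' plasmid_molecule_mass(5000)  # ~5.4e-18 g
#' @export
plasmid_molecule_mass <- function(length_bp, bp_molar_mass = BP_MOLAR_MASS) {
  check_scalar(length_bp, "length_bp", lower = 0, strict_lower = TRUE)
  check_scalar(bp_molar_mass, "bp_molar_mass", lower = 0,
               strict_lower = TRUE)
  length_bp * bp_molar_mass / AVOGADRO
}

#' Effective DNA input mass of a synthesis run
#'
#' In vivo: the mass of one plasmid molecule (replication starts from the
#' single molecule that transformed the founder cell). In vitro: the template
#' mass multiplied by the amplified region's fraction of the plasmid, since
#' only that region is copied.
#'
#' @param run A [synthesis_run()].
#' @param bp_molar_mass Mean molar mass per base pair (g/mol).
#' @return Input mass in grams.
#' @export
dna_input_mass <- function(run, bp_molar_mass = BP_MOLAR_MASS) {
  if (!inherits(run, "synthesis_run")) {
    sutox_error("`run` must be a synthesis_run", "sutox_invalid_input")
  }
  if (run$method == "in_vivo") {
    plasmid_molecule_mass(run$plasmid_length_bp, bp_molar_mass)
  } else {
    run$template_mass_g * run$amplicon_length_bp / run$plasmid_length_bp
  }
}

#' Number of DNA doublings from input and output masses
#'
#' `log2(output/input)`: the number of times the input DNA mass doubled
#' during synthesis. This is the normalization unit for the mutation rate.
#'
#' @param input_mass_g,output_mass_g Masses in grams; output must be at
#'   least the input (otherwise there was no net synthesis).
#' @return Doublings (non-negative real).
#' @examples
#' dna_doublings(1e-9, 8e-9)  # 3
#' @export
dna_doublings <- function(input_mass_g, output_mass_g) {
  check_scalar(input_mass_g, "input_mass_g", lower = 0, strict_lower = TRUE)
  check_scalar(output_mass_g, "output_mass_g", lower = 0,
               strict_lower = TRUE)
  if (output_mass_g < input_mass_g) {
    sutox_error("output mass is below input mass: no net synthesis",
                "sutox_invalid_input")
  }
  log2(output_mass_g / input_mass_g)
}
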