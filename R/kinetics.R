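#' Validate a table of steady-state kinetic records
#'
#' Each record carries the peptide sequence, its maximal rate `vmax`
#' (umol/(min mg)) and Michaelis constant `km` (uM) for phosphorylation by
#' the kinase, plus a flag marking the reference (wild-type) peptide.
#' Exactly one record must be the reference.
#'
#' @param records data frame (or path to TSV/CSV) with columns `peptide`,
#'   `vmax`, `km`, `is_reference` (logical or 0/1).
#' @return the validated data frame.
#' @export
kinetic_table <- function(records) {
  if (is.character(records) && length(records) == 1L) {
    sep <- if (grepl("\\.csv$", records, ignore.case = TRUE)) "," else "\t"
    records <- read.delim(records, sep = sep, stringsAsFactors = FALSE,
                          comment.char = "#")
  }
  records <- as.data.frame(records)
  miss <- setdiff(c("peptide", "vmax", "km", "is_reference"), names(records))
  if (length(miss))
    stop("kinetics table lacks column(s): ", paste(miss, collapse = ", "))
  records$is_reference <- as.logical(records$is_reference)
  bad <- !is.finite(records$vmax) | records$vmax <= 0 |
         !is.finite(records$km) | records$km <= 0
  if (any(bad))
    stop("non-positive or missing kinetic constants for: ",
         paste(records$peptide[bad], collapse = ", "))
  nref <- sum(records$is_reference)
  if (nref != 1L)
    stop("exactly one reference peptide required, found ", nref)
  records
}

#' Catalytic efficiency Vmax/KM
#'
#' The ratio `vmax / km` on the input unit scale
#' ((umol/(min mg)) / uM); proportional to kcat/KM, the second-order rate
#' constant governing substrate discrimination.
#'
#' @param vmax maximal rate(s), > 0.
#' @param km Michaelis constant(s), > 0.
#' @export
catalytic_efficiency <- function(vmax, km) {
  if (any(!is.finite(vmax) | vmax <= 0) || any(!is.finite(km) | km <= 0))
    stop("vmax and km must be positive and finite")
  vmax / km
}

#' Binding free-energy shift from Michaelis constants
#'
#' Treating KM as an affinity proxy for the enzyme-substrate complex under
#' the quasi-equilibrium assumption, the variant-minus-reference shift in the
#' binding free energy is `R T ln(KM_variant / KM_reference)` (kcal/mol):
#' a weaker binder (larger KM) gives a positive, unfavourable shift.
#'
#' @param km_variant,km_reference Michaelis constants (same units), > 0.
#' @param temperature Kelvin; default 298.15.
#' @export
ddg_binding_from_km <- function(km_variant, km_reference,
                                temperature = 298.15) {
  if (any(km_variant <= 0) || any(km_reference <= 0) || temperature <= 0)
    stop("KM values and temperature must be positive")
  GAS_CONSTANT_KCAL * temperature * log(km_variant / km_reference)
}

#' Catalysis free-energy shift from catalytic efficiencies
#'
#' The shift in the free-energy change from free enzyme + substrate to the
#' rate-determining transition state:
#' `R T ln(eff_reference / eff_variant)` (kcal/mol). A less efficient
#' substrate gives a positive shift.
#'
#' @param eff_variant,eff_reference catalytic efficiencies, > 0.
#' @param temperature Kelvin; default 298.15.
#' @export
ddg_catalysis_from_efficiency <- function(eff_variant, eff_reference,
                                          temperature = 298.15) {
  if (any(eff_variant <= 0) || any(eff_reference <= 0) || temperature <= 0)
    stop("efficiencies and temperature must be positive")
  GAS_CONSTANT_KCAL * temperature * log(eff_reference / eff_variant)
}

#' Experimental free-energy shifts for a kinetics table
#'
#' Converts each record's (Vmax, KM) into the two experimental shifts
#' relative to the flagged reference: `ddg_binding` (from KM ratios) and
#' `ddg_catalysis` (from efficiency ratios). The reference row has both
#' shifts exactly 0.
#'
#' @param records a [kinetic_table()] (or anything it accepts).
#' @param temperature Kelvin; default 298.15.
#' @return data frame with columns `peptide`, `vmax`, `km`, `efficiency`,
#'   `ddg_binding`, `ddg_catalysis`, `is_reference`.
#' @export
shifts_table <- function(records, temperature = 298.15) {
  records <- kinetic_table(records)
  ref <- records[records$is_reference, ]
  eff <- catalytic_efficiency(records$vmax, records$km)
  out <- data.frame(
    peptide = records$peptide,
    vmax = records$vmax,
    km = records$km,
    efficiency = eff,
    ddg_binding = ddg_binding_from_km(records$km, ref$km, temperature),
    ddg_catalysis = ddg_catalysis_from_efficiency(
      eff, catalytic_efficiency(ref$vmax, ref$km), temperature),
    is_reference = records$is_reference,
    stringsAsFactors = FALSE)
  out$ddg_binding[out$is_reference] <- 0
  out$ddg_catalysis[out$is_reference] <- 0
  attr(out, "temperature") <- temperature
  out
}
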