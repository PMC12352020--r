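#' Default rRNA molar masses (g/mol)
#'
#' Computed from human rRNA lengths (18S: 1,869 nt; 28S: 5,070 nt) at a
#' mean nucleotide mass of 320.5 g/mol. Explicit config values: override
#' them for other organisms.
#'
#' @export
RRNA_MOLAR_MASS <- c("18S" = 1869 * 320.5, "28S" = 5070 * 320.5)

#' RNA sample metadata for the biochemical ribosome estimate
#'
#' Carries the quantities entering the subunits-per-cell equation:
#' instrument-measured 18S/28S mass concentrations, elution volume,
#' dilution factor (the measured concentrations are multiplied by it to
#' recover the undiluted eluate concentration — reversal is explicit
#' metadata, never inferred), the number of cells extracted, the RNA
#' integrity number and the per-species molar masses.
#'
#' @param rin RNA integrity number in `[1, 10]`.
#' @param concentration named numeric (`"18S"`, `"28S"`): measured (i.e.
#'   post-dilution) mass concentrations in ng/uL.
#' @param n_cells number of cells the RNA was extracted from.
#' @param elution_volume_ul elution volume in uL (default 50).
#' @param dilution_factor dilution applied before measurement (default 50).
#' @param molar_mass named numeric (`"18S"`, `"28S"`) molar masses in g/mol.
#' @return An object of class `RnaSample`.
#' @export
rna_sample <- function(rin, concentration, n_cells,
                       elution_volume_ul = 50, dilution_factor = 50,
                       molar_mass = RRNA_MOLAR_MASS) {
  stopifnot(rin >= 1, rin <= 10, n_cells >= 1,
            elution_volume_ul > 0, dilution_factor > 0,
            all(concentration >= 0))
  structure(list(rin = rin, concentration = concentration,
                 n_cells = n_cells, elution_volume_ul = elution_volume_ul,
                 dilution_factor = dilution_factor, molar_mass = molar_mass),
            class = "RnaSample")
}

#' Calibrate the concentration-to-area ratio from a ladder run
#'
#' The ladder trace has a known total RNA concentration; the ratio of that
#' concentration to the integrated area under the whole electropherogram
#' converts peak areas to concentrations.
#'
#' @param ladder_trace an [electropherogram()].
#' @param known_total_conc known total RNA concentration of the ladder.
#' @return the concentration-per-area ratio.
#' @export
calibrate_ladder <- function(ladder_trace, known_total_conc) {
  stopifnot(inherits(ladder_trace, "Electropherogram"),
            known_total_conc > 0)
  area <- pracma::trapz(ladder_trace$trace$position,
                        ladder_trace$trace$fluorescence)
  if (area <= 0) stop("ladder trace has nonpositive integrated area")
  known_total_conc / area
}

#' Integrate a peak above a baseline
#'
#' Trapezoidal integral of the trace between `left` and `right`, minus a
#' baseline: either the straight line joining the trace values at the two
#' bounds (`"linear"`, mirroring manual baseline adjustment under a peak)
#' or nothing (`"none"`). Negative baseline-subtracted values are clipped
#' at zero.
#'
#' @param e an [electropherogram()].
#' @param left,right integration bounds, `left < right`, inside the trace.
#' @param baseline `"linear"` or `"none"`.
#' @return the peak area.
#' @export
integrate_peak <- function(e, left, right, baseline = c("linear", "none")) {
  stopifnot(inherits(e, "Electropherogram"))
  baseline <- match.arg(baseline)
  pos <- e$trace$position; y <- e$trace$fluorescence
  if (left >= right) stop("inverted integration bounds")
  if (left < pos[1] || right > pos[length(pos)])
    stop("integration bounds outside trace extent")
  yl <- stats::approx(pos, y, xout = left)$y
  yr <- stats::approx(pos, y, xout = right)$y
  inside <- pos > left & pos < right
  px <- c(left, pos[inside], right)
  py <- c(yl, y[inside], yr)
  base <- if (baseline == "linear")
    yl + (yr - yl) * (px - left) / (right - left) else 0
  pracma::trapz(px, pmax(py - base, 0))
}

#' Gate RNA samples on RNA integrity number
#'
#' Keeps samples whose RIN is *strictly* greater than `min_rin`
#' (default 9): a sample at exactly 9.0 is excluded.
#'
#' @param samples list of [rna_sample()] objects.
#' @param min_rin exclusive lower RIN bound.
#' @return the gated list (possibly empty).
#' @export
rin_gate <- function(samples, min_rin = 9) {
  Filter(function(s) s$rin > min_rin, samples)
}

#' Number of 18S or 28S rRNA molecules per cell
#'
#' Avogadro-based extrapolation: the undiluted eluate concentration
#' (measured concentration times dilution factor, in ng/uL, converted to
#' g/uL) times the elution volume gives the extracted rRNA mass; dividing
#' by the molar mass and multiplying by the Avogadro constant counts
#' molecules, and dividing by the number of extracted cells yields the
#' per-cell count.
#'
#' @param s an [rna_sample()].
#' @param species `"18S"` or `"28S"`.
#' @return molecules of that subunit species per cell.
#' @export
subunits_per_cell <- function(s, species = c("18S", "28S")) {
  stopifnot(inherits(s, "RnaSample"))
  species <- match.arg(species)
  if (!species %in% names(s$concentration))
    stop("no measured concentration for species ", species)
  if (!species %in% names(s$molar_mass) || s$molar_mass[[species]] <= 0)
    stop("missing or nonpositive molar mass for species ", species)
  conc_g_per_ul <- s$concentration[[species]] * s$dilution_factor * 1e-9
  conc_g_per_ul * s$elution_volume_ul * AVOGADRO /
    (s$molar_mass[[species]] * s$n_cells)
}

#' Ribosomes per cell from both rRNA species
#'
#' One ribosome carries one 18S and one 28S molecule, so the mean of the
#' two per-cell subunit counts estimates the per-cell ribosome count.
#'
#' @param s an [rna_sample()].
#' @return estimated ribosomes per cell.
#' @export
ribosomes_per_cell <- function(s) {
  mean(c(subunits_per_cell(s, "18S"), subunits_per_cell(s, "28S")))
}

#' Forward-simulate measured rRNA concentrations from a ribosome count
#'
#' Inverse of [subunits_per_cell()] under ideal 1:1 stoichiometry: given a
#' true per-cell ribosome count, returns the measured (post-dilution)
#' 18S and 28S concentrations in ng/uL that a perfect extraction and
#' measurement would report. Used to close the round-trip validation loop.
#'
#' @param ribosomes_per_cell true ribosome count per cell.
#' @param n_cells number of cells extracted.
#' @param elution_volume_ul,dilution_factor,molar_mass as in
#'   [rna_sample()].
#' @return named numeric concentrations (ng/uL, post-dilution).
#' @export
simulate_rna_concentrations <- function(ribosomes_per_cell, n_cells,
                                        elution_volume_ul = 50,
                                        dilution_factor = 50,
                                        molar_mass = RRNA_MOLAR_MASS) {
  stopifnot(ribosomes_per_cell >= 0, n_cells >= 1)
  vapply(c("18S", "28S"), function(sp) {
    mass_g <- ribosomes_per_cell * n_cells * molar_mass[[sp]] / AVOGADRO
    mass_g / elution_volume_ul / dilution_factor / 1e-9
  }, numeric(1))
}
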