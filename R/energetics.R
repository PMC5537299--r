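# Mole-fraction dimerization energetics in detergent micelles.

# gas constant, kcal/(mol K)
.R_kcal <- 1.987e-3

#' Free energy of dimerization from micelle populations
#'
#' Standard mole-fraction dimerization equilibrium for a peptide in
#' detergent micelles: with monomer and dimer fractions `f_M`, `f_D` of the
#' total peptide and a detergent-to-protein mole ratio `LPR`, the
#' mole-fraction constant is `K_x = (f_D / 2) * LPR / f_M^2` (the factor
#' 1/2 converts peptide fraction to dimer particle count; LPR converts
#' fractions to mole fractions in the detergent phase), and
#' `dG = -R T ln K_x`.
#'
#' @param f_mono,f_dimer Monomer / dimer fractions of total peptide, both
#'   in (0, 1].
#' @param lpr Detergent-to-protein mole ratio (> 0).
#' @param temperature Kelvin (default 318.15, i.e. 45 C).
#' @return list with `K_x` (dimensionless) and `dG` (kcal/mol).
#' @examples
#' estimate_dimer_dG(0.5, 0.5, lpr = 100)$dG   # -2.91 kcal/mol
#' @export
estimate_dimer_dG <- function(f_mono, f_dimer, lpr, temperature = 318.15) {
  if (f_mono <= 0 || f_dimer <= 0) {
    stop("monomer and dimer fractions must both be positive")
  }
  if (f_mono > 1 || f_dimer > 1 || f_mono + f_dimer > 1 + 1e-9) {
    stop("fractions must lie in (0, 1] and sum to at most 1")
  }
  if (lpr <= 0) stop("lipid-to-protein ratio must be positive")
  K_x <- (f_dimer / 2) * lpr / f_mono^2
  list(K_x = K_x, dG = -.R_kcal * temperature * log(K_x))
}

#' Monomer/dimer populations versus lipid-to-protein ratio
#'
#' Inverse of [estimate_dimer_dG()]: given a standard free energy of
#' dimerization, solves the mole-fraction equilibrium for the monomer and
#' dimer fractions at each lipid-to-protein ratio (no higher oligomers).
#'
#' @param dG Standard free energy of dimerization (kcal/mol).
#' @param lpr Vector of detergent-to-protein mole ratios (> 0).
#' @param temperature Kelvin.
#' @return data.frame `lpr`, `f_mono`, `f_dimer`, `f_oligo` (always 0),
#'   `temperature`, `dG`.
#' @export
make_population_series <- function(dG, lpr, temperature = 318.15) {
  if (any(lpr <= 0)) stop("lipid-to-protein ratios must be positive")
  K_x <- exp(-dG / (.R_kcal * temperature))
  a <- 2 * K_x / lpr
  # f_M solves a f_M^2 + f_M - 1 = 0; positive root in a cancellation-free form
  f_mono <- 2 / (1 + sqrt(1 + 4 * a))
  data.frame(lpr = lpr, f_mono = f_mono, f_dimer = 1 - f_mono,
             f_oligo = 0, temperature = temperature, dG = dG)
}
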