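# Built-in reference tables and sequence fixtures.
#
# All tables are plain R objects built in code so they are versionable and
# inspectable; nothing is loaded from binary data files.

# Whole-residue water -> octanol transfer free energies (kcal/mol) of the
# experimentally determined Wimley-White scale, one value per residue
# including the peptide bond contribution.  Negative = partitions into the
# non-polar phase.  Charged-state alternatives are stored separately and
# swapped in by hydro_scale().
.ww_octanol <- c(
  A =  0.50, R =  1.81, N =  0.85, D =  3.64, C = -0.02,
  Q =  0.77, E =  3.63, G =  1.15, H =  0.11, I = -1.12,
  L = -1.25, K =  2.80, M = -0.67, F = -1.71, P =  0.14,
  S =  0.46, T =  0.25, W = -2.09, Y = -0.71, V = -0.46
)
# alternative protonation states
.ww_octanol_alt <- c(H_charged = 2.33, D_neutral = 0.43, E_neutral = 0.11)

#' Whole-residue hydrophobicity scale
#'
#' Returns the Wimley-White whole-residue water-to-octanol transfer
#' free-energy scale (kcal/mol per residue) under a chosen protonation
#' convention.  The default configuration -- histidine neutral (0.11
#' kcal/mol), Asp/Glu/Lys/Arg charged -- is the one used for juxtamembrane
#' hydrophobicity tables of single-pass receptors.
#'
#' @param his_state `"neutral"` (default) or `"charged"` histidine.
#' @param asp_glu_state `"charged"` (default) or `"neutral"` Asp/Glu.
#' @return An object of class `hydro_scale`: a list with `name`, `values`
#'   (named numeric, all 20 standard residues), `his_state`,
#'   `asp_glu_state`.
#' @examples
#' sc <- hydro_scale()
#' sc$values[["L"]]   # -1.25
#' sc$values[["K"]]   # +2.80 (charged lysine)
#' @export
hydro_scale <- function(his_state = c("neutral", "charged"),
                        asp_glu_state = c("charged", "neutral")) {
  his_state <- match.arg(his_state)
  asp_glu_state <- match.arg(asp_glu_state)
  vals <- .ww_octanol
  if (his_state == "charged") vals[["H"]] <- .ww_octanol_alt[["H_charged"]]
  if (asp_glu_state == "neutral") {
    vals[["D"]] <- .ww_octanol_alt[["D_neutral"]]
    vals[["E"]] <- .ww_octanol_alt[["E_neutral"]]
  }
  structure(
    list(name = "wimley-white-octanol", values = vals,
         his_state = his_state, asp_glu_state = asp_glu_state),
    class = "hydro_scale"
  )
}

#' Random-coil Calpha chemical shifts
#'
#' Random-coil 13C-alpha reference shifts (ppm) from the Wishart
#' random-coil compilation, used to compute secondary chemical shifts
#' (observed minus random coil).  No sequence-neighbour or temperature
#' corrections are applied.
#'
#' @return Named numeric vector, one value per one-letter residue code.
#' @export
random_coil_ca <- function() {
  c(A = 52.5, R = 56.0, N = 52.8, D = 54.2, C = 58.2,
    Q = 56.2, E = 56.6, G = 45.1, H = 55.0, I = 61.3,
    L = 55.1, K = 56.4, M = 55.3, F = 57.9, P = 63.1,
    S = 58.3, T = 62.1, W = 57.6, Y = 58.1, V = 62.3)
}

#' TLR4 expression-construct sequences
#'
#' The two cell-free-expressed human TLR4 fragments used throughout the
#' worked examples, with their UniProt-scheme numbering.  The leading Met
#' is the translation-start residue at position 623; native residues start
#' at N624.  `TM` spans the predicted transmembrane domain plus a few
#' juxtamembrane residues (624-657); `TMICL` additionally carries the full
#' intracellular linker (624-670).
#'
#' Note: the juxtamembrane hydrophobic-region row of the reference segment
#' table ([tlr_jm_segments()]) lists 653-665 as "KFYFHLMLLAGCI" while the
#' construct sequence reads "KFYFHLLMLAGCI" (an LML/LLM permutation of
#' identical composition); both spellings give the same summed
#' hydrophobicity.
#'
#' @return A list of two [seq_segment()] objects named `TM` and `TMICL`.
#' @export
tlr4_constructs <- function() {
  list(
    TM = seq_segment("MNITSQMNKTIIGVSVLSVLVVSVVAVLVYKFYFH",
                     start = 623, label = "TLR4-TM"),
    TMICL = seq_segment("MNITSQMNKTIIGVSVLSVLVVSVVAVLVYKFYFHLLMLAGCIKYGRG",
                        start = 623, label = "TLR4-TMICL")
  )
}

#' Reference juxtamembrane segment collection
#'
#' The juxtamembrane/hydrophobic-region segments of the human Toll-like
#' receptor family plus the amphipathic juxtamembrane helices of EGFR and
#' HER2, with UniProt numbering and the published summed/per-residue
#' hydrophobicities (kcal/mol, whole-residue octanol scale).
#'
#' Two rows are flagged `scale_consistent = FALSE`: the published totals of
#' TLR1 (-2.34) and TLR9 (-10.58) are not reproduced by summing the scale
#' over the printed sequences (which gives -2.36 and -10.28); they are
#' retained for completeness but excluded from reproduction checks.
#'
#' @return A data.frame with columns `label`, `start`, `end`, `sequence`,
#'   `published_total`, `published_per_residue`, `scale_consistent`.
#' @export
tlr_jm_segments <- function() {
  df <- data.frame(
    label = c("TLR4 TM", "TLR4 HR", "TLR1", "TLR2", "TLR3", "TLR5",
              "TLR6", "TLR7", "TLR8", "TLR9", "TLR10",
              "EGFR JMA", "HER2 JMA"),
    start = c(632L, 653L, 602L, 610L, 726L, 661L, 608L, 861L, 849L,
              840L, 598L, 676L, 683L),
    sequence = c(
      "TIIGVSVLSVLVVSVVAVLVY",  # TLR4 TM 632-652 (printed construct)
      "KFYFHLMLLAGCI",          # TLR4 HR 653-665
      "SYLDLPWYLRMVC",          # TLR1 602-614
      "HRFHGLWYMKMMWAWL",       # TLR2 610-625
      "EGWRISFYWNVSV",          # TLR3 726-738
      "TKFRGFCFICY",            # TLR5 661-671
      "YLDLPWYLRMVC",           # TLR6 608-619
      "HLYFWDVWYIYHF",          # TLR7 861-873
      "HHLFYWDVWFIY",           # TLR8 849-860
      "GWDLWYCFHLCLAWLPW",      # TLR9 840-856
      "CLHFDLPWYLRML",          # TLR10 598-610
      "KRTLRRLLQER",            # EGFR juxtamembrane 676-686
      "RKYTMRRLLQETEL"          # HER2 juxtamembrane 683-696
    ),
    published_total = c(-7.56, -5.13, -2.34, -6.72, -0.28, -0.99,
                        -2.82, -8.70, -7.99, -10.58, -4.50,
                        10.94, 11.63),
    published_per_residue = c(-0.36, -0.39, -0.18, -0.42, -0.02, -0.09,
                              -0.24, -0.67, -0.66, -0.60, -0.35,
                              0.99, 0.83),
    scale_consistent = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                         TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  df$end <- df$start + nchar(df$sequence) - 1L
  df[, c("label", "start", "end", "sequence", "published_total",
         "published_per_residue", "scale_consistent")]
}

#' Dimerization-perturbed methyl residues of TLR4-TMICL
#'
#' Residues whose methyl groups show the largest generalized chemical-shift
#' changes (> 0.02 ppm) upon dimerization of TLR4-TMICL in DPC micelles:
#' I634, V636, L639, L642, V643, V646, V647 in the TM core and L658-L661 in
#' the hydrophobic linker region.  Used as the CSP-flagged set for
#' buried-surface ranking of candidate dimer models.
#'
#' @return Integer vector of UniProt residue numbers.
#' @export
tlr4_flagged_residues <- function() {
  c(634L, 636L, 639L, 642L, 643L, 646L, 647L, 658L, 659L, 660L, 661L)
}

#' Unperturbed reporter groups of TLR4-TMICL
#'
#' Side-chain groups whose chemical shifts do NOT change upon dimerization
#' and therefore must not be buried at a candidate interface.  The K653
#' CepsilonH2 group is the reporter that discriminates between the two
#' top-ranked dimer conformations (a model burying K653 is inconsistent
#' with the spectra).
#'
#' @return data.frame with columns `resno`, `group`.
#' @export
tlr4_unperturbed_reporters <- function() {
  data.frame(resno = 653L, group = "CeH2", stringsAsFactors = FALSE)
}
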