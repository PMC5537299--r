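# Chemical-shift analytics: generalized CSPs, interface classification,
# secondary Calpha shifts, helix-stretch calling, exchange/intensity ratios.

#' Generalized chemical-shift perturbation
#'
#' Combines proton and carbon chemical-shift changes into a single
#' perturbation, `sqrt(ddH^2 + ddC^2 / 16)` (ppm), the standard weighting
#' for methyl 1H/13C pairs.  Symmetric under sign flips and absolutely
#' homogeneous: scaling both inputs by `k` scales the result by `|k|`.
#'
#' @param ddH Proton shift change (ppm), vectorized.
#' @param ddC Carbon shift change (ppm); `NA` is treated as 0 (proton-only
#'   perturbation) -- callers that need to distinguish this case should
#'   check [is.na()] before calling (see `csp_table()`'s `h_only` column).
#' @return Non-negative generalized perturbation (ppm).
#' @examples
#' generalized_csp(0.03, 0.20)   # 0.0583
#' @export
generalized_csp <- function(ddH, ddC = 0) {
  if (any(!is.finite(ddH))) stop("non-finite proton shift change")
  ddC[is.na(ddC)] <- 0
  if (any(!is.finite(ddC))) stop("non-finite carbon shift change")
  sqrt(ddH^2 + ddC^2 / 16)
}

#' Build a CSP table from two shift tables
#'
#' Joins per-group chemical shifts of two states (e.g. monomer and dimer)
#' on (residue, group) and computes the proton/carbon differences and the
#' generalized perturbation.  Rows whose carbon shift is missing in either
#' state get a proton-only perturbation and `h_only = TRUE`.
#'
#' @param state_a,state_b Shift tables (data.frames with columns `resno`,
#'   `restype`, `group`, `dH`, `dC`; see [read_shift_table()]), typically
#'   monomer and dimer.
#' @param groups Optional regular expression selecting group names (e.g.
#'   methyls only); default keeps everything except backbone `Ca`.
#' @return data.frame with columns `resno`, `restype`, `group`, `ddH`,
#'   `ddC`, `d_gen`, `h_only`.
#' @export
csp_table <- function(state_a, state_b, groups = "^(?!Ca$)") {
  a <- state_a[grepl(groups, state_a$group, perl = TRUE), ]
  b <- state_b[grepl(groups, state_b$group, perl = TRUE), ]
  m <- merge(a, b, by = c("resno", "group"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) {
    return(data.frame(resno = integer(), restype = character(),
                      group = character(), ddH = numeric(), ddC = numeric(),
                      d_gen = numeric(), h_only = logical()))
  }
  ddH <- m$dH_b - m$dH_a
  ddC <- m$dC_b - m$dC_a
  h_only <- is.na(ddC)
  ddC[h_only] <- 0
  out <- data.frame(resno = m$resno, restype = m$restype_a, group = m$group,
                    ddH = ddH, ddC = ddC,
                    d_gen = generalized_csp(ddH, ddC), h_only = h_only,
                    stringsAsFactors = FALSE)
  out[order(out$resno, out$group), , drop = FALSE]
}

#' Classify chemical-shift perturbations
#'
#' Assigns each record a class -- `strong` for generalized perturbations
#' exceeding `strong_cut`, `weak` for values in `(weak_cut, strong_cut]`,
#' `none` otherwise ("exceeding" is strict, so a value exactly at a
#' threshold falls in the lower class).  The per-residue class is the
#' maximum over that residue's groups, and the flagged set is the residues
#' of class `strong`: the candidate dimerization interface.
#'
#' @param records CSP records ([csp_table()] output: needs `resno`,
#'   `d_gen`).
#' @param strong_cut,weak_cut Class thresholds (ppm); defaults 0.02 / 0.01.
#' @return list with `records` (input plus `class` column), `residue_class`
#'   (data.frame `resno`, `class`), `flagged` (integer vector of strong
#'   residues, sorted).
#' @export
classify_csp <- function(records, strong_cut = 0.02, weak_cut = 0.01) {
  stopifnot(strong_cut > weak_cut, weak_cut > 0)
  lev <- c("none", "weak", "strong")
  if (nrow(records) == 0L) {
    return(list(records = cbind(records, class = character(0)),
                residue_class = data.frame(resno = integer(),
                                           class = character()),
                flagged = integer(0)))
  }
  cls <- ifelse(records$d_gen > strong_cut, "strong",
         ifelse(records$d_gen > weak_cut, "weak", "none"))
  records$class <- factor(cls, levels = lev)
  by_res <- tapply(as.integer(records$class), records$resno, max)
  residue_class <- data.frame(resno = as.integer(names(by_res)),
                              class = lev[by_res], stringsAsFactors = FALSE)
  residue_class <- residue_class[order(residue_class$resno), ]
  rownames(residue_class) <- NULL
  flagged <- residue_class$resno[residue_class$class == "strong"]
  list(records = records, residue_class = residue_class, flagged = flagged)
}

#' Secondary Calpha chemical shifts
#'
#' Observed Calpha shift minus the random-coil reference for the residue
#' type; positive values indicate helical conformation.
#'
#' @param table Shift table containing `Ca` rows (columns `resno`,
#'   `restype`, `group`, `dC`).
#' @param rc_table Named numeric map residue letter -> random-coil Calpha
#'   shift (ppm); default [random_coil_ca()].
#' @return data.frame `resno`, `restype`, `d_obs`, `d_rc`, `delta` (ppm),
#'   ordered by residue.
#' @export
secondary_shifts <- function(table, rc_table = random_coil_ca()) {
  ca <- table[table$group == "Ca", ]
  if (nrow(ca) == 0L) stop("no Ca rows in shift table")
  missing <- setdiff(unique(ca$restype), names(rc_table))
  if (length(missing)) {
    stop(sprintf("no random-coil reference for residue type(s): %s (residues %s)",
                 paste(missing, collapse = ", "),
                 paste(ca$resno[ca$restype %in% missing], collapse = ", ")))
  }
  out <- data.frame(resno = ca$resno, restype = ca$restype,
                    d_obs = ca$dC, d_rc = unname(rc_table[ca$restype]),
                    stringsAsFactors = FALSE)
  out$delta <- out$d_obs - out$d_rc
  out[order(out$resno), , drop = FALSE]
}

#' Call helical stretches from a secondary-shift profile
#'
#' Finds maximal runs of consecutive residues whose secondary Calpha shift
#' exceeds `min_delta`, keeping runs of at least `min_run` residues.
#' Single-residue gaps where no Calpha was observed are bridged (a missing
#' assignment should not split an otherwise continuous helix); an observed
#' sub-threshold residue always breaks the run.
#'
#' @param profile [secondary_shifts()] output (`resno`, `delta`).
#' @param min_delta Threshold (ppm), default 0.7.
#' @param min_run Minimum run length (residues), default 4.
#' @param bridge_gaps Bridge single missing residues (default TRUE).
#' @return data.frame `start`, `end`, `n_residues`, one row per stretch.
#' @export
call_helical_stretch <- function(profile, min_delta = 0.7, min_run = 4L,
                                 bridge_gaps = TRUE) {
  if (nrow(profile) == 0L) stop("empty secondary-shift profile")
  res <- seq(min(profile$resno), max(profile$resno))
  delta <- rep(NA_real_, length(res))
  delta[match(profile$resno, res)] <- profile$delta
  helical <- !is.na(delta) & delta > min_delta
  if (bridge_gaps) {
    for (i in seq_along(res)) {
      if (is.na(delta[i]) && i > 1L && i < length(res) &&
          helical[i - 1L] && !is.na(delta[i + 1L]) && delta[i + 1L] > min_delta) {
        helical[i] <- TRUE
      }
    }
  }
  r <- rle(helical)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = res[starts[keep]], end = res[ends[keep]],
             n_residues = r$lengths[keep])
}

#' Amide-proton solvent-exchange ratio
#'
#' Ratio of cross-peak intensity in a water-exchange (CLEANEX-type)
#' spectrum to the reference HSQC intensity, used as a measure of the
#' amide exchange rate; amides with ratios below `cutoff` are called
#' solvent-protected (membrane-embedded or hydrogen-bonded).
#'
#' @param I_cleanex,I_ref Intensities (vectorized); `I_ref` must be > 0.
#' @param cutoff Protection cutoff on the ratio (default 0.02; the cutoff
#'   is an analysis choice, not a spectrometer constant).
#' @return data.frame `ratio`, `protected`.
#' @export
exchange_ratio <- function(I_cleanex, I_ref, cutoff = 0.02) {
  if (any(I_ref <= 0)) stop("reference intensity must be positive")
  ratio <- I_cleanex / I_ref
  data.frame(ratio = ratio, protected = ratio < cutoff)
}

#' Relative cross-peak intensities with line-broadening flags
#'
#' Normalizes intensities to a maximum of 1; residues below `low_frac` of
#' the maximum are flagged as exchange-broadened (enhanced transverse
#' relaxation / microsecond-millisecond motions).
#'
#' @param I Intensity vector; at least one value must be positive.
#' @param low_frac Flagging fraction of the maximum (default 0.25).
#' @return data.frame `rel`, `broadened`.
#' @export
relative_intensity <- function(I, low_frac = 0.25) {
  if (all(I <= 0)) stop("all intensities non-positive")
  rel <- I / max(I)
  data.frame(rel = rel, broadened = rel < low_frac)
}
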