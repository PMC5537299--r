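# Buried-surface profiles, CSP-guided ranking of candidate dimer models,
# and a simple C2-symmetric candidate enumerator.

#' Per-residue buried surface on dimerization
#'
#' For each chain of a dimer, the buried area of a residue is its SASA with
#' the chain computed in isolation minus its SASA within the complex.  With
#' the deterministic point lattice this is non-negative by construction
#' (the partner chain can only occlude sampling points).
#'
#' @param dimer Two-chain [structure_model()].
#' @param chains The two chain ids (default `c("A", "B")`).
#' @param side_chain_only Aggregate burial over side-chain atoms only
#'   (backbone N, CA, C, O excluded); default FALSE (whole residue).
#' @inheritParams sasa
#' @return Object of class `burial_profile`: list with `residues`
#'   (data.frame `chain`, `resno`, `restype`, `area_alone`, `area_complex`,
#'   `burial`), `total_burial` (= SASA_A,alone + SASA_B,alone -
#'   SASA_complex) and the SASA parameters.
#' @export
burial_profile <- function(dimer, chains = c("A", "B"),
                           side_chain_only = FALSE, probe = 1.4,
                           n_points = 3840, radii = vdw_radii()) {
  present <- unique(dimer$chain)
  if (!all(chains %in% present)) {
    stop(sprintf("chain '%s' missing from model",
                 setdiff(chains, present)[1]))
  }
  both <- dimer[dimer$chain %in% chains, , drop = FALSE]
  class(both) <- c("structure_model", "data.frame")
  backbone <- c("N", "CA", "C", "O")
  sas_cx <- sasa(both, probe = probe, n_points = n_points, radii = radii)
  res <- list()
  total_alone <- 0
  for (ch in chains) {
    alone <- select_chain(dimer, ch)
    sas_al <- sasa(alone, probe = probe, n_points = n_points, radii = radii)
    total_alone <- total_alone + sas_al$total
    a <- sas_al$atoms
    b <- sas_cx$atoms[sas_cx$atoms$chain == ch, ]
    stopifnot(nrow(a) == nrow(b), all(a$atom == b$atom),
              all(a$resno == b$resno))
    keep <- if (side_chain_only) !(a$atom %in% backbone) else rep(TRUE, nrow(a))
    key <- a$resno[keep]
    al <- tapply(a$area[keep], key, sum)
    cx <- tapply(b$area[keep], key, sum)
    resno <- as.integer(names(al))
    restype <- a$restype[keep][match(resno, key)]
    res[[ch]] <- data.frame(chain = ch, resno = resno, restype = restype,
                            area_alone = as.numeric(al),
                            area_complex = as.numeric(cx),
                            burial = as.numeric(al - cx),
                            stringsAsFactors = FALSE)
  }
  residues <- do.call(rbind, res)
  residues <- residues[order(residues$chain, residues$resno), ]
  rownames(residues) <- NULL
  structure(list(residues = residues,
                 total_burial = total_alone - sas_cx$total,
                 probe = probe, n_points = n_points,
                 side_chain_only = side_chain_only),
            class = "burial_profile")
}

#' @export
print.burial_profile <- function(x, ...) {
  cat(sprintf("<burial_profile> total interface %.1f A^2 (%s burial, %d points)\n",
              x$total_burial,
              if (x$side_chain_only) "side-chain" else "whole-residue",
              x$n_points))
  invisible(x)
}

#' Rank candidate dimer models by CSP-consistent buried surface
#'
#' Scores each candidate dimer by the buried surface area of the residues
#' whose methyl chemical shifts are perturbed on dimerization (the flagged
#' set), summed over flagged residues and averaged over the two chains
#' (they agree up to sampling noise for C2-symmetric models).  Models are
#' ranked by descending score, ties broken by total interface area and
#' then model id.  A model is additionally marked `inconsistent` when any
#' unperturbed reporter residue buries more than `burial_cut` -- a reporter
#' at the interface would have shown a perturbation, so such a model
#' contradicts the spectra regardless of its score.
#'
#' @param models List of two-chain [structure_model()]s (or a single one).
#' @param flagged Integer vector of CSP-flagged residue numbers (non-empty).
#' @param reporters Optional data.frame `resno`, `group` of unperturbed
#'   reporter groups (e.g. [tlr4_unperturbed_reporters()]).
#' @param burial_cut Reporter burial threshold (Angstrom^2), default 15.
#' @param chains,side_chain_only,probe,n_points,radii Passed to
#'   [burial_profile()].
#' @return data.frame, one row per model, ordered by rank: `model_id`,
#'   `score`, `total_interface`, `verdict`, `offenders`, `rank`.
#' @export
rank_models <- function(models, flagged, reporters = NULL, burial_cut = 15,
                        chains = c("A", "B"), side_chain_only = FALSE,
                        probe = 1.4, n_points = 3840, radii = vdw_radii()) {
  if (inherits(models, "structure_model")) models <- list(models)
  if (length(models) == 0L) stop("empty model list")
  if (length(flagged) == 0L) stop("flagged residue set is empty")
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    id <- attr(m, "model_id")
    if (is.null(id)) id <- i
    bp <- burial_profile(m, chains = chains,
                         side_chain_only = side_chain_only,
                         probe = probe, n_points = n_points, radii = radii)
    r <- bp$residues
    fl <- r[r$resno %in% flagged, ]
    score <- sum(fl$burial) / length(chains)
    offenders <- character(0)
    if (!is.null(reporters) && nrow(reporters)) {
      for (k in seq_len(nrow(reporters))) {
        rb <- r[r$resno == reporters$resno[k], ]
        if (nrow(rb) && mean(tapply(rb$burial, rb$chain, sum)) > burial_cut) {
          offenders <- c(offenders,
                         sprintf("%d:%s", reporters$resno[k],
                                 reporters$group[k]))
        }
      }
    }
    data.frame(model_id = as.character(id), score = score,
               total_interface = bp$total_burial,
               verdict = if (length(offenders)) "inconsistent" else "consistent",
               offenders = paste(offenders, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$score, -out$total_interface, out$model_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Enumerate C2-symmetric dimer candidates
#'
#' Places two copies of a helix on a grid of crossing angles, inter-axis
#' distances, self-rotations and handednesses, producing C2-symmetric
#' candidate dimers; grid points whose copies approach closer than
#' `clash_cut` between heavy atoms are discarded as clashing.  This is a
#' deliberately simple geometric enumerator standing in for an external
#' docking step, so that the CSP-guided ranking pipeline is end-to-end
#' runnable on generated inputs.
#'
#' @param helix Single-chain [structure_model()] (an ideal or fitted
#'   helix); it is re-centred on its fitted axis before placement.
#' @param omega_grid Crossing angles (degrees).
#' @param d_grid Inter-axis distances (Angstrom).
#' @param phi_grid Rotations of the helix about its own axis (degrees).
#' @param handedness Subset of `c("right", "left")`.
#' @param clash_cut Interatomic clash threshold (Angstrom), default 2.2.
#' @return List of [structure_model()]s, each carrying a `params` attribute
#'   (`omega`, `handedness`, `d`, `phi`); empty (with a warning) if every
#'   grid point clashes.
#' @export
enumerate_symmetric_dimers <- function(helix, omega_grid, d_grid,
                                       phi_grid = 0,
                                       handedness = c("right", "left"),
                                       clash_cut = 2.2) {
  if (length(omega_grid) == 0L || length(d_grid) == 0L ||
      length(phi_grid) == 0L || length(handedness) == 0L) {
    stop("empty parameter grid")
  }
  canon <- .canonical_helix(helix)
  out <- list()
  for (hand in handedness) for (om in omega_grid) for (d in d_grid)
    for (phi in phi_grid) {
      dim <- .place_c2_dimer(canon, omega = om, handedness = hand, d = d,
                             phi_self = phi)
      if (.clash_distance(dim) < clash_cut) next
      attr(dim, "params") <- list(omega = om, handedness = hand, d = d,
                                  phi = phi)
      attr(dim, "model_id") <- sprintf("%s_om%g_d%g_phi%g", hand, om, d, phi)
      out[[length(out) + 1L]] <- dim
    }
  if (length(out) == 0L) {
    warning("all candidate dimers clash; returning an empty list")
  }
  out
}

# minimal interchain distance used by the clash filter.  Pseudo-atom side
# chains ("SC") are centroids, not atoms: two facing side chains in van der
# Waals contact legitimately bring their centroids within ~2 A, so only
# genuine atoms (backbone, or full side chains of real structures) count.
.clash_distance <- function(dimer, chains = c("A", "B")) {
  keep <- dimer$elem != "H" & dimer$atom != "SC"
  a <- .coords(dimer[keep & dimer$chain == chains[1], ])
  b <- .coords(dimer[keep & dimer$chain == chains[2], ])
  .min_interchain_distance(a, b)
}

.min_interchain_distance <- function(a, b) {
  # blockwise to keep memory flat for big chains
  mind <- Inf
  step <- 512L
  for (i0 in seq(1L, nrow(a), by = step)) {
    ii <- i0:min(i0 + step - 1L, nrow(a))
    d2 <- outer(rowSums(a[ii, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[ii, , drop = FALSE] %*% t(b)
    mind <- min(mind, min(d2))
  }
  sqrt(max(mind, 0))
}
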