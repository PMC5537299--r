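# Synthetic-data generators with known ground truth: ideal helices,
# C2-symmetric dimers, shift tables, titration curves.
#
# Every generator is deterministic given its arguments (and seed, where
# noise is involved), so analysis results on generated inputs are exactly
# reproducible.

# idealized cylindrical backbone geometry of an alpha-helix built along z:
# per-atom (radius, phase offset vs Calpha in degrees, axial offset in A)
.helix_backbone <- list(
  N  = c(r = 1.56, dphi = -28.0, dz = -0.90),
  CA = c(r = 2.30, dphi =   0.0, dz =  0.00),
  C  = c(r = 1.64, dphi =  26.0, dz =  0.65),
  O  = c(r = 1.99, dphi =  24.0, dz =  1.90)
)

# radial extent of the single pseudo-atom side chain beyond the Calpha
# cylinder, by residue type (A); glycine has none
.sc_radius <- c(A = 1.5, C = 1.7, D = 2.0, E = 2.6, F = 2.9, H = 2.6,
                I = 2.3, K = 3.2, L = 2.3, M = 2.9, N = 2.0, P = 1.5,
                Q = 2.6, R = 3.6, S = 1.7, T = 1.7, V = 1.9, W = 3.2,
                Y = 3.2)

#' Build an ideal alpha-helix
#'
#' Generates a straight ideal helix along the z axis, centred at the
#' origin: the Calpha trace lies on a cylinder of radius `ca_radius` with
#' the given rise and twist per residue; N, C and O are placed on their own
#' idealized cylinders, and (optionally) each residue carries a single
#' pseudo-atom side chain (`SC`, carbon) at a residue-type-specific radial
#' distance pointing away from the axis -- sufficient for axis fitting and
#' burial ranking, not a rotamer model.
#'
#' @param sequence One-letter sequence (>= 2 residues; a single residue has
#'   no defined axis).
#' @param start First residue number.
#' @param chain Chain id.
#' @param rise Rise per residue (Angstrom), default 1.5.
#' @param twist Twist per residue (degrees), default 100.
#' @param ca_radius Calpha cylinder radius (Angstrom), default 2.3.
#' @param side_chains Add pseudo-atom side chains (default TRUE).
#' @return [structure_model()] with the helix axis along z and the axial
#'   midpoint at z = 0.
#' @export
make_ideal_helix <- function(sequence, start = 1L, chain = "A", rise = 1.5,
                             twist = 100, ca_radius = 2.3,
                             side_chains = TRUE) {
  letters <- strsplit(toupper(sequence), "")[[1]]
  n <- length(letters)
  start <- as.integer(start)
  if (n < 2L) stop("need at least 2 residues; a single residue has no axis")
  bad <- setdiff(letters, names(.ww_octanol))
  if (length(bad)) stop(sprintf("invalid residue letter '%s'", bad[1]))
  rows <- list()
  for (i in seq_len(n)) {
    phi0 <- (i - 1) * twist * pi / 180
    z0 <- (i - 1 - (n - 1) / 2) * rise
    restype <- bio3d::aa123(letters[i])
    for (atom in names(.helix_backbone)) {
      g <- .helix_backbone[[atom]]
      r <- if (atom == "CA") ca_radius else g[["r"]]
      ang <- phi0 + g[["dphi"]] * pi / 180
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = start + i - 1L, restype = restype,
        atom = atom, elem = substr(atom, 1, 1),
        x = r * cos(ang), y = r * sin(ang), z = z0 + g[["dz"]],
        stringsAsFactors = FALSE)
    }
    if (side_chains && letters[i] != "G") {
      r <- ca_radius + .sc_radius[[letters[i]]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = start + i - 1L, restype = restype,
        atom = "SC", elem = "C",
        x = r * cos(phi0), y = r * sin(phi0), z = z0,
        stringsAsFactors = FALSE)
    }
  }
  structure_model(do.call(rbind, rows))
}

# rigid transform helpers ----------------------------------------------

.rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
.rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

.apply_transform <- function(model, R = diag(3), t = c(0, 0, 0)) {
  X <- .coords(model) %*% t(R)
  model$x <- X[, 1] + t[1]
  model$y <- X[, 2] + t[2]
  model$z <- X[, 3] + t[3]
  model
}

# re-centre an arbitrary single-chain helix into the canonical frame:
# fitted axis along z, axial midpoint at the origin
.canonical_helix <- function(helix) {
  ax <- fit_helix_axis(helix)
  centre <- ax$anchor + (ax$t_min + ax$t_max) / 2 * ax$direction
  u <- ax$direction
  z <- c(0, 0, 1)
  v <- c(u[2] * z[3] - u[3] * z[2], u[3] * z[1] - u[1] * z[3],
         u[1] * z[2] - u[2] * z[1])
  s <- sqrt(sum(v^2)); c_ <- sum(u * z)
  R <- if (s < 1e-12) {
    if (c_ > 0) diag(3) else diag(c(1, -1, -1))   # flip about x
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  }
  out <- helix
  X <- sweep(.coords(helix), 2, centre) %*% t(R)
  out$x <- X[, 1]; out$y <- X[, 2]; out$z <- X[, 3]
  out
}

# place a canonical helix (axis = z, centred) as an exact C2 dimer:
# chain A is self-rotated by phi_self, tilted by +/- omega/2 about x,
# shifted to x = -d/2 (and optionally along its own axis); chain B is the
# image of A under the C2 rotation about z.  With this construction the
# common perpendicular of the two axes lies along x, the crossing angle is
# omega, the closest inter-axis distance is d, and the torsion sign makes
# the "right" tilt right-handed under the dimer_geometry() convention.
.place_c2_dimer <- function(canon, omega, handedness, d, phi_self = 0,
                            axial_shift = 0) {
  tilt <- switch(handedness,
                 right = omega / 2,
                 left = -omega / 2,
                 parallel = 0,
                 stop("handedness must be 'right', 'left' or 'parallel'"))
  if (handedness == "parallel") omega <- 0
  A <- .apply_transform(canon, R = .rot_z(phi_self))
  A <- .apply_transform(A, R = .rot_x(tilt))
  dirA <- as.vector(.rot_x(tilt) %*% c(0, 0, 1))
  A <- .apply_transform(A, t = c(-d / 2, 0, 0) + axial_shift * dirA)
  A$chain <- "A"
  B <- .apply_transform(A, R = .rot_z(180))
  B$chain <- "B"
  out <- rbind(as.data.frame(A), as.data.frame(B))
  structure_model(out)
}

#' Build a C2-symmetric helix dimer with prescribed geometry
#'
#' Constructs two copies of an ideal helix arranged with exact C2 symmetry
#' about the z axis, with a prescribed crossing angle, handedness and
#' closest inter-axis distance -- the round-trip fixture for the dimer
#' geometry descriptors.
#'
#' @param sequence One-letter sequence of each protomer.
#' @param omega Crossing angle (degrees, >= 0).
#' @param handedness `"right"`, `"left"` or `"parallel"`.
#' @param d Closest inter-axis distance (Angstrom).
#' @param phi_self Rotation of the protomer about its own axis (degrees);
#'   selects which helix face forms the interface.
#' @param axial_shift Shift of each protomer along its own axis (Angstrom).
#' @param clash_cut Warn (but still return) if any interatomic distance
#'   falls below this (Angstrom), default 2.2.
#' @inheritParams make_ideal_helix
#' @return Two-chain [structure_model()] (chains A, B) with attributes
#'   `params` (the requested geometry) and `c2_axis` (`"z"`).
#' @export
make_symmetric_dimer <- function(sequence, omega, handedness, d,
                                 phi_self = 0, axial_shift = 0, start = 1L,
                                 rise = 1.5, twist = 100, ca_radius = 2.3,
                                 side_chains = TRUE, clash_cut = 2.2) {
  helix <- make_ideal_helix(sequence, start = start, rise = rise,
                            twist = twist, ca_radius = ca_radius,
                            side_chains = side_chains)
  dim <- .place_c2_dimer(helix, omega = omega, handedness = handedness,
                         d = d, phi_self = phi_self,
                         axial_shift = axial_shift)
  mind <- .clash_distance(dim)
  if (mind < clash_cut) {
    warning(sprintf("dimer has interchain contacts below %.1f A (min %.2f A)",
                    clash_cut, mind))
  }
  attr(dim, "params") <- list(omega = omega, handedness = handedness, d = d,
                              phi_self = phi_self, axial_shift = axial_shift)
  attr(dim, "c2_axis") <- "z"
  dim
}

# methyl-bearing residue types: group names and baseline (dH, dC) shifts
.methyl_groups <- list(
  A = list(c("bCH3", 1.39, 19.0)),
  V = list(c("g1CH3", 0.91, 21.5), c("g2CH3", 0.89, 20.7)),
  L = list(c("d1CH3", 0.90, 24.5), c("d2CH3", 0.86, 23.7)),
  I = list(c("d1CH3", 0.82, 13.1), c("g2CH3", 0.88, 17.4)),
  T = list(c("g2CH3", 1.15, 21.6)),
  M = list(c("eCH3", 2.05, 17.0))
)

#' Generate monomer/dimer methyl shift tables with a known interface
#'
#' Emulates the methyl chemical-shift-perturbation experiment: monomer
#' shifts are baseline values (random-coil Calpha plus a helix offset
#' inside `helix_range`; residue-type methyl baselines); dimer shifts add a
#' fixed (ddH, ddC) perturbation to every methyl of the interface residues
#' plus i.i.d. Gaussian noise on all methyl rows.  The recoverable ground
#' truth is the interface residues that actually carry methyl groups.
#'
#' @param sequence One-letter sequence.
#' @param start First residue number.
#' @param interface Residue numbers carrying the dimerization perturbation.
#' @param helix_range `c(first, last)` residues with helical Calpha offset
#'   (NULL = none).
#' @param dd_interface `c(ddH, ddC)` perturbation means (ppm); the default
#'   gives a generalized perturbation of about 0.032 ppm.
#' @param noise `c(sH, sC)` Gaussian noise sd (ppm) on dimer methyl rows.
#' @param helix_offset Helical secondary Calpha shift (ppm), default +2.8.
#' @param seed Integer seed (noise reproducibility).
#' @return list with `monomer`, `dimer` (shift tables), `truth` (integer
#'   vector: recoverable interface residues).
#' @export
make_shift_tables <- function(sequence, start = 1L, interface = integer(),
                              helix_range = NULL,
                              dd_interface = c(ddH = 0.025, ddC = 0.08),
                              noise = c(sH = 0, sC = 0), helix_offset = 2.8,
                              seed = NULL) {
  letters <- strsplit(toupper(sequence), "")[[1]]
  n <- length(letters)
  resno <- as.integer(start) + seq_len(n) - 1L
  interface <- as.integer(interface)
  if (length(interface) && !all(interface %in% resno)) {
    stop("interface residues outside the sequence")
  }
  if (!is.null(seed)) set.seed(seed)
  rc <- random_coil_ca()
  rows <- list()
  for (i in seq_len(n)) {
    helical <- !is.null(helix_range) && resno[i] >= helix_range[1] &&
      resno[i] <= helix_range[2]
    rows[[length(rows) + 1L]] <- data.frame(
      resno = resno[i], restype = letters[i], group = "Ca",
      dH = NA_real_,
      dC = rc[[letters[i]]] + if (helical) helix_offset else 0,
      stringsAsFactors = FALSE)
    for (g in .methyl_groups[[letters[i]]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        resno = resno[i], restype = letters[i], group = g[1],
        dH = as.numeric(g[2]), dC = as.numeric(g[3]),
        stringsAsFactors = FALSE)
    }
  }
  monomer <- do.call(rbind, rows)
  monomer$state <- "monomer"
  monomer$condition <- "synthetic"
  dimer <- monomer
  dimer$state <- "dimer"
  me <- dimer$group != "Ca"
  hit <- me & dimer$resno %in% interface
  dimer$dH[hit] <- dimer$dH[hit] + dd_interface[[1]]
  dimer$dC[hit] <- dimer$dC[hit] + dd_interface[[2]]
  if (noise[[1]] > 0) {
    dimer$dH[me] <- dimer$dH[me] + stats::rnorm(sum(me), 0, noise[[1]])
  }
  if (noise[[2]] > 0) {
    dimer$dC[me] <- dimer$dC[me] + stats::rnorm(sum(me), 0, noise[[2]])
  }
  has_methyl <- resno[letters %in% names(.methyl_groups)]
  list(monomer = monomer, dimer = dimer,
       truth = sort(intersect(interface, has_methyl)))
}

#' Generate a pH titration curve
#'
#' Hill-model shift-vs-pH data ([titration_model()]) with optional Gaussian
#' noise; the generating parameters are attached as the `truth` attribute.
#'
#' @param pKa,n,delta_a,delta_b Model parameters (defaults: the imidazole
#'   Hepsilon1 titration of a membrane-embedded histidine, pKa 6.16, Hill
#'   n 0.98).
#' @param pH pH grid (must span the transition).
#' @param sigma Noise sd (ppm).
#' @param seed Integer seed.
#' @return data.frame `pH`, `delta` with attribute `truth`.
#' @export
make_titration <- function(pKa = 6.16, n = 0.98, delta_a = 8.60,
                           delta_b = 7.70,
                           pH = seq(4.5, 8.5, length.out = 25), sigma = 0,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  delta <- titration_model(pH, pKa, n, delta_a, delta_b)
  if (sigma > 0) delta <- delta + stats::rnorm(length(pH), 0, sigma)
  out <- data.frame(pH = pH, delta = delta)
  attr(out, "truth") <- list(pKa = pKa, n = n, delta_a = delta_a,
                             delta_b = delta_b, sigma = sigma)
  out
}

#' Helix face turned towards the dimer partner
#'
#' For a protomer built by [make_ideal_helix()] and placed by
#' [make_symmetric_dimer()] with self-rotation `phi_self`, returns the
#' residues whose side chains point towards the partner (the +x
#' half-space), within an angular half-width.  This is the geometric ground
#' truth for which residues should be perturbed/buried at the interface.
#'
#' @param sequence One-letter sequence.
#' @param start First residue number.
#' @param phi_self Self-rotation used in the dimer construction (degrees).
#' @param twist Helix twist (degrees/residue).
#' @param half_width Angular half-width of the face (degrees), default 60.
#' @return Integer vector of residue numbers.
#' @export
interface_face <- function(sequence, start = 1L, phi_self = 0, twist = 100,
                           half_width = 60) {
  n <- nchar(sequence)
  resno <- as.integer(start) + seq_len(n) - 1L
  ang <- ((seq_len(n) - 1) * twist + phi_self) %% 360
  ang <- pmin(ang, 360 - ang)    # angular distance from the +x direction
  resno[ang <= half_width]
}
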