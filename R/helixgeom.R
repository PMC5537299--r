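# Helix-axis fitting and dimer geometry descriptors
# (crossing angle, handedness, minimal inter-axis distance).

.unit <- function(v) v / sqrt(sum(v^2))

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Fit a helix axis
#'
#' Estimates the straight axis of an alpha-helix from its Calpha trace
#' using the classic bisector construction: for each interior Calpha the
#' bisector `H_i = (Ca_{i-1} - Ca_i) + (Ca_{i+1} - Ca_i)` points radially
#' at the axis, so the cross product of consecutive bisectors is parallel
#' to the axis; the direction is the (sign-aligned) average of these cross
#' products and the axis position is the least-squares circle centre of the
#' Calpha projections onto the normal plane.  Both steps are exact on ideal
#' helices.  Perfectly collinear traces (a degenerate helix of radius 0)
#' fall back to the total-least-squares line through the points.
#'
#' The direction is oriented N-terminus to C-terminus and the axial extent
#' is taken from the projections of the first and last Calpha.
#'
#' @param model [structure_model()].
#' @param chain Chain id (default: the only chain present).
#' @param range Optional residue range `c(first, last)`.
#' @return Object of class `helix_axis`: list with `anchor` (point on the
#'   axis at the mean axial position), `direction` (unit vector, N->C),
#'   `t_min`, `t_max` (axial extent, Angstrom, relative to the anchor),
#'   `resno_range`, `rms_radius` (rms Calpha-to-axis distance).
#' @export
fit_helix_axis <- function(model, chain = NULL, range = NULL) {
  if (is.null(chain)) {
    chains <- unique(model$chain)
    if (length(chains) != 1L) {
      stop("model has several chains; specify `chain`")
    }
    chain <- chains
  }
  sel <- select_chain(model, chain, range)
  ca <- sel[sel$atom == "CA", ]
  ca <- ca[order(ca$resno), ]
  if (nrow(ca) < 7L) {
    stop(sprintf("need at least 7 Calpha atoms to fit an axis (got %d)",
                 nrow(ca)))
  }
  X <- .coords(ca)
  n <- nrow(X)
  span <- X[n, ] - X[1, ]
  # bisectors at interior residues point at the axis
  H <- X[1:(n - 2), , drop = FALSE] - 2 * X[2:(n - 1), , drop = FALSE] +
    X[3:n, , drop = FALSE]
  Hn <- sqrt(rowSums(H^2))
  straight <- all(Hn < 1e-8 * max(1, sqrt(sum(span^2))))
  if (straight) {
    # collinear trace: total-least-squares line
    centroid <- colMeans(X)
    dir <- svd(sweep(X, 2, centroid))$v[, 1]
    if (sum(span * dir) < 0) dir <- -dir
    dir <- .unit(dir)
    anchor <- centroid
  } else {
    m <- nrow(H)
    C <- t(vapply(seq_len(m - 1),
                  function(i) .cross3(H[i, ], H[i + 1, ]),
                  numeric(3)))
    Cn <- sqrt(rowSums(C^2))
    keep <- Cn > 1e-12
    C <- C[keep, , drop = FALSE] / Cn[keep]
    sgn <- sign(C %*% span)
    dir <- .unit(colSums(C * as.vector(sgn)))
    # least-squares circle centre in the plane normal to the axis
    e1 <- .unit(if (abs(dir[1]) < 0.9) .cross3(dir, c(1, 0, 0))
                else .cross3(dir, c(0, 1, 0)))
    e2 <- .cross3(dir, e1)
    centroid <- colMeans(X)
    Xc <- sweep(X, 2, centroid)
    u <- Xc %*% e1
    v <- Xc %*% e2
    co <- stats::lm.fit(cbind(2 * u, 2 * v, 1), u^2 + v^2)$coefficients
    anchor <- centroid + co[1] * e1 + co[2] * e2
  }
  dir <- unname(dir); anchor <- unname(anchor)
  t_all <- as.vector(sweep(X, 2, anchor) %*% dir)
  radial <- sweep(X, 2, anchor) - outer(t_all, dir)
  structure(
    list(anchor = anchor, direction = dir,
         t_min = t_all[1], t_max = t_all[n],
         resno_range = range(ca$resno),
         rms_radius = sqrt(mean(rowSums(radial^2)))),
    class = "helix_axis"
  )
}

#' @export
print.helix_axis <- function(x, ...) {
  cat(sprintf("<helix_axis> residues %d-%d, length %.1f A, rms radius %.2f A\n",
              x$resno_range[1], x$resno_range[2], helix_length(x),
              x$rms_radius))
  cat(sprintf("  direction (%.3f, %.3f, %.3f)\n",
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Helix length along its axis
#'
#' Axial span of the fitted residue range: the distance between the
#' projections of the first and the last Calpha onto the axis (so an ideal
#' n-residue helix with a 1.5 A rise measures `(n - 1) * 1.5` A).
#'
#' @param axis A [fit_helix_axis()] result.
#' @return Length in Angstrom.
#' @export
helix_length <- function(axis) {
  stopifnot(inherits(axis, "helix_axis"))
  axis$t_max - axis$t_min
}

# minimal distance between two finite 3D segments (standard clamped
# closest-approach algorithm); returns distance and the two closest points
.segment_distance <- function(p1, d1, t1, p2, d2, t2) {
  a1 <- p1 + t1[1] * d1; b1 <- p1 + t1[2] * d1
  a2 <- p2 + t2[1] * d2; b2 <- p2 + t2[2] * d2
  u <- b1 - a1; v <- b2 - a2; w <- a1 - a2
  a <- sum(u * u); b <- sum(u * v); c <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  D <- a * c - b * b
  sc <- sD <- D; tc <- tD <- D
  if (D < 1e-12) {            # nearly parallel
    sN <- 0; sD <- 1; tN <- e; tD <- c
  } else {
    sN <- b * e - c * d; tN <- a * e - b * d
    if (sN < 0) { sN <- 0; tN <- e; tD <- c }
    else if (sN > sD) { sN <- sD; tN <- e + b; tD <- c }
  }
  if (tN < 0) {
    tN <- 0
    if (-d < 0) sN <- 0 else if (-d > a) sN <- sD else { sN <- -d; sD <- a }
  } else if (tN > tD) {
    tN <- tD
    if ((-d + b) < 0) sN <- 0
    else if ((-d + b) > a) sN <- sD
    else { sN <- -d + b; sD <- a }
  }
  sc <- if (abs(sN) < 1e-15) 0 else sN / sD
  tc <- if (abs(tN) < 1e-15) 0 else tN / tD
  q1 <- a1 + sc * u; q2 <- a2 + tc * v
  list(distance = sqrt(sum((q1 - q2)^2)), point_a = q1, point_b = q2)
}

#' Dimer geometry descriptors from two helix axes
#'
#' Derives the crossing-angle magnitude, packing handedness and minimal
#' inter-axis distance of a helix pair.
#'
#' The crossing angle `omega` is the acute angle between the two axis
#' lines (0-90 degrees; N->C polarity only sets the `antiparallel` flag).
#' Handedness follows the torsion convention: with `w` the common
#' perpendicular at closest approach (pointing A to B), the sign of
#' `det[dir_A, dir_B, w]` classifies the packing -- negative torsion is
#' right-handed, positive is left-handed; pairs within `parallel_tol`
#' degrees of parallel are labelled `parallel`.  The minimal distance is
#' computed between the finite axial segments, so the parallel case stays
#' well-defined.
#'
#' @param axis_a,axis_b [fit_helix_axis()] results.
#' @param parallel_tol Angular tolerance (degrees) below which the pair is
#'   called parallel (default 2).
#' @return Object of class `dimer_geometry`: list with `omega` (degrees),
#'   `handedness` (`"right"`, `"left"` or `"parallel"`), `distance`
#'   (Angstrom), `antiparallel` (logical).
#' @export
dimer_geometry <- function(axis_a, axis_b, parallel_tol = 2) {
  stopifnot(inherits(axis_a, "helix_axis"), inherits(axis_b, "helix_axis"))
  if (axis_a$t_max <= axis_a$t_min || axis_b$t_max <= axis_b$t_min) {
    stop("zero-length axis")
  }
  da <- axis_a$direction; db <- axis_b$direction
  cosang <- sum(da * db)
  antiparallel <- cosang < 0
  # fold to the acute line-line angle
  omega <- acos(pmin(1, abs(cosang))) * 180 / pi
  seg <- .segment_distance(axis_a$anchor, da, c(axis_a$t_min, axis_a$t_max),
                           axis_b$anchor, db, c(axis_b$t_min, axis_b$t_max))
  if (omega < parallel_tol) {
    hand <- "parallel"
  } else {
    w <- seg$point_b - seg$point_a
    if (sqrt(sum(w^2)) < 1e-9) {
      hand <- "parallel"   # intersecting axes: torsion undefined
    } else {
      torsion <- det(cbind(da, db, .unit(w)))
      hand <- if (torsion < 0) "right" else "left"
    }
  }
  structure(
    list(omega = omega, handedness = hand, distance = seg$distance,
         antiparallel = antiparallel),
    class = "dimer_geometry"
  )
}

#' @export
print.dimer_geometry <- function(x, ...) {
  cat(sprintf("<dimer_geometry> omega = %.1f deg (%s%s), closest distance %.2f A\n",
              x$omega, x$handedness,
              if (x$antiparallel) ", antiparallel" else "", x$distance))
  invisible(x)
}

#' Geometry of a two-chain dimer model
#'
#' Convenience wrapper: fits both helix axes and reports the dimer
#' descriptors.
#'
#' @param model Two-chain [structure_model()].
#' @param chains Chain ids (default `c("A", "B")`).
#' @param range Optional residue range used for both axis fits.
#' @inheritParams dimer_geometry
#' @return A `dimer_geometry` object.
#' @export
measure_dimer <- function(model, chains = c("A", "B"), range = NULL,
                          parallel_tol = 2) {
  dimer_geometry(fit_helix_axis(model, chains[1], range),
                 fit_helix_axis(model, chains[2], range),
                 parallel_tol = parallel_tol)
}
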