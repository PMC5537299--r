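test_that("well-separated chains bury nothing", {
  far <- make_symmetric_dimer("VLVLVLVLVL", omega = 0,
                              handedness = "parallel", d = 40)
  bp <- burial_profile(far, n_points = 960)
  expect_true(all(abs(bp$residues$burial) < 1e-9))
  expect_equal(bp$total_burial, 0, tolerance = 1e-9)
})

test_that("burial is non-negative and satisfies the area balance", {
  dim <- make_symmetric_dimer(tm_sequence(), start = 632, omega = 28,
                              handedness = "right", d = 7.9)
  bp <- burial_profile(dim, n_points = 960)
  expect_true(all(bp$residues$burial >= -1e-6))
  sA <- sasa(select_chain(dim, "A"), n_points = 960)$total
  sB <- sasa(select_chain(dim, "B"), n_points = 960)$total
  sAB <- sasa(dim, n_points = 960)$total
  expect_equal(bp$total_burial, sA + sB - sAB, tolerance = 1e-9)
  expect_equal(sum(bp$residues$burial), bp$total_burial, tolerance = 1e-9)
})

test_that("burial localizes on the generator-defined interface face", {
  # parallel contact dimer: every residue of the facing helix face touches
  # the partner, the opposite face never does
  dim <- suppressWarnings(
    make_symmetric_dimer(tm_sequence(), start = 632, omega = 0,
                         handedness = "parallel", d = 9))
  bp <- burial_profile(dim, n_points = 960)
  face <- interface_face(tm_sequence(), start = 632, phi_self = 0,
                         half_width = 40)
  back <- interface_face(tm_sequence(), start = 632, phi_self = 180,
                         half_width = 40)
  r <- bp$residues[bp$residues$chain == "A", ]
  expect_true(all(r$burial[r$resno %in% face] > 1))
  expect_true(all(r$burial[r$resno %in% back] < 1))
  expect_error(burial_profile(select_chain(dim, "A")), "missing")
})

test_that("side-chain-only burial is bounded by whole-residue burial", {
  dim <- make_symmetric_dimer("VLISVTAMVL", omega = 20, handedness = "right",
                              d = 8)
  whole <- burial_profile(dim, n_points = 960)$residues
  sc <- burial_profile(dim, n_points = 960, side_chain_only = TRUE)$residues
  expect_true(all(sc$burial <= whole$burial + 1e-9))
})

test_that("ranking prefers the model that buries the flagged set", {
  helix <- make_ideal_helix(tm_sequence(), start = 632)
  cands <- enumerate_symmetric_dimers(helix, omega_grid = 28, d_grid = 7.9,
                                      phi_grid = c(0, 90, 180, 270),
                                      handedness = "right")
  flagged <- interface_face(tm_sequence(), start = 632, phi_self = 0)
  rk <- rank_models(cands, flagged = flagged, n_points = 960)
  expect_equal(nrow(rk), length(cands))
  expect_match(rk$model_id[1], "phi0$")
  # the model turning the flagged face away scores lowest
  expect_match(rk$model_id[nrow(rk)], "phi180$")
  expect_lt(rk$score[nrow(rk)], 0.1 * rk$score[1])
  expect_identical(rk$rank, seq_len(nrow(rk)))
})

test_that("ranking is invariant to the order of input models", {
  helix <- make_ideal_helix("VLISVTAMVLVL")
  cands <- enumerate_symmetric_dimers(helix, omega_grid = 20, d_grid = 8,
                                      phi_grid = c(0, 120, 240),
                                      handedness = "right")
  flagged <- interface_face("VLISVTAMVLVL", phi_self = 0)
  rk1 <- rank_models(cands, flagged = flagged, n_points = 480)
  rk2 <- rank_models(rev(cands), flagged = flagged, n_points = 480)
  expect_equal(rk1, rk2)
})

test_that("a model burying an unperturbed reporter is inconsistent", {
  helix <- make_ideal_helix(tm_sequence(), start = 632)
  cands <- enumerate_symmetric_dimers(helix, omega_grid = 28, d_grid = 7.9,
                                      phi_grid = c(0, 180),
                                      handedness = "right")
  flagged <- interface_face(tm_sequence(), start = 632, phi_self = 0)
  # a residue on the phi = 180 interface that is NOT on the phi = 0 face
  reporter <- setdiff(interface_face(tm_sequence(), start = 632,
                                     phi_self = 180), flagged)[1]
  rk <- rank_models(cands, flagged = flagged,
                    reporters = data.frame(resno = reporter, group = "CeH2"),
                    n_points = 960)
  v <- setNames(rk$verdict, rk$model_id)
  expect_equal(unname(v[grepl("phi0$", names(v))]), "consistent")
  expect_equal(unname(v[grepl("phi180$", names(v))]), "inconsistent")
  off <- rk$offenders[grepl("phi180$", rk$model_id)]
  expect_match(off, as.character(reporter))
})

test_that("rank_models validates its inputs", {
  expect_error(rank_models(list(), flagged = 1L), "empty model list")
  dim <- make_symmetric_dimer("VLVLVLVL", omega = 20, handedness = "right",
                              d = 9)
  expect_error(rank_models(dim, flagged = integer()), "flagged")
})

test_that("the enumerator reproduces a single requested geometry", {
  helix <- make_ideal_helix(tm_sequence(), start = 632)
  got <- enumerate_symmetric_dimers(helix, omega_grid = 28, d_grid = 7.9,
                                    phi_grid = 0, handedness = "right")
  expect_length(got, 1L)
  g <- measure_dimer(got[[1]])
  expect_lt(abs(g$omega - 28), 0.5)
  expect_lt(abs(g$distance - 7.9), 0.1)
  expect_equal(g$handedness, "right")
})

test_that("clashing grids are discarded and C2 symmetry is exact", {
  helix <- make_ideal_helix(strrep("V", 21))
  expect_warning(
    none <- enumerate_symmetric_dimers(helix, omega_grid = 28, d_grid = 2,
                                       phi_grid = 0, handedness = "right"),
    "clash")
  expect_length(none, 0L)
  expect_error(enumerate_symmetric_dimers(helix, omega_grid = numeric(),
                                          d_grid = 8), "empty parameter grid")

  cands <- enumerate_symmetric_dimers(helix, omega_grid = c(12, 28),
                                      d_grid = c(7.9, 10.1),
                                      phi_grid = c(0, 180))
  C2 <- matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3)
  for (m in cands) {
    A <- as.matrix(m[m$chain == "A", c("x", "y", "z")])
    B <- as.matrix(m[m$chain == "B", c("x", "y", "z")])
    expect_lt(sqrt(mean((A %*% t(C2) - B)^2)), 1e-6)
    keep <- m$atom != "SC"
    a <- as.matrix(m[keep & m$chain == "A", c("x", "y", "z")])
    b <- as.matrix(m[keep & m$chain == "B", c("x", "y", "z")])
    expect_gte(min(as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                                       nrow(a) + seq_len(nrow(b))]),
               2.2)
  }
})
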