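test_that("axis fit recovers the z axis of an ideal helix", {
  h <- make_ideal_helix(strrep("V", 33))
  ax <- fit_helix_axis(h)
  expect_lt(vec_angle(ax$direction, c(0, 0, 1)), 1e-4)
  expect_gt(sum(ax$direction * c(0, 0, 1)), 0)   # oriented N -> C
  expect_equal(ax$rms_radius, 2.3, tolerance = 0.01)
})

test_that("axis fit is equivariant under rigid-body transforms", {
  h <- make_ideal_helix(tm_sequence(), start = 632)
  ax <- fit_helix_axis(h)
  a <- 71 * pi / 180
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3) %*%
    matrix(c(1, 0, 0, 0, cos(0.4), sin(0.4), 0, -sin(0.4), cos(0.4)), 3, 3)
  t <- c(4, -7, 2.5)
  X <- as.matrix(h[, c("x", "y", "z")]) %*% t(R)
  h2 <- h; h2$x <- X[, 1] + t[1]; h2$y <- X[, 2] + t[2]; h2$z <- X[, 3] + t[3]
  ax2 <- fit_helix_axis(h2)
  expect_equal(as.vector(R %*% ax$direction), ax2$direction, tolerance = 1e-6)
  expect_equal(as.vector(R %*% ax$anchor) + t, ax2$anchor, tolerance = 1e-6)
  expect_equal(helix_length(ax), helix_length(ax2), tolerance = 1e-6)
})

test_that("a straight line of Calpha atoms yields that exact line", {
  n <- 10
  dir <- c(1, 2, 2) / 3
  pts <- outer(seq_len(n) * 1.5, dir)
  line <- structure_model(data.frame(
    chain = "A", resno = seq_len(n), restype = "GLY", atom = "CA",
    elem = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3]))
  ax <- fit_helix_axis(line)
  expect_lt(vec_angle(ax$direction, dir), 1e-9)
  expect_equal(ax$rms_radius, 0, tolerance = 1e-9)
  expect_equal(helix_length(ax), (n - 1) * 1.5, tolerance = 1e-9)
})

test_that("axial length matches the rise convention", {
  h <- make_ideal_helix(strrep("V", 33))
  expect_equal(helix_length(fit_helix_axis(h)), 32 * 1.5, tolerance = 1e-6)
  for (n in c(7, 12, 21)) {
    for (rise in c(1.4, 1.5, 1.6)) {
      hx <- make_ideal_helix(strrep("A", n), rise = rise)
      expect_equal(helix_length(fit_helix_axis(hx)) / (n - 1), rise,
                   tolerance = 1e-6)
    }
  }
  # a degenerate 2-residue span measured on a hand-built axis
  ax <- structure(list(anchor = c(0, 0, 0), direction = c(0, 0, 1),
                       t_min = 0, t_max = 1.5, resno_range = c(1L, 2L),
                       rms_radius = 0), class = "helix_axis")
  expect_equal(helix_length(ax), 1.5)
})

test_that("axis fit rejects short or missing traces", {
  h <- make_ideal_helix(strrep("V", 10))
  expect_error(fit_helix_axis(h, range = c(1, 6)), "at least 7")
  expect_error(fit_helix_axis(h, chain = "B"), "no atoms")
})

test_that("parallel helices: zero crossing angle at the set separation", {
  d <- make_symmetric_dimer(strrep("V", 21), omega = 0,
                            handedness = "parallel", d = 10)
  g <- measure_dimer(d)
  expect_lt(g$omega, 0.5)
  expect_equal(g$distance, 10, tolerance = 0.1)
  expect_equal(g$handedness, "parallel")
  expect_false(g$antiparallel)
})

test_that("builder dimers are measured back across the geometry grid", {
  seqs <- strrep("V", 25)
  for (hand in c("right", "left")) {
    for (omega in c(5, 15, 25, 35, 45)) {
      for (d in c(6, 9, 12)) {
        dim <- suppressWarnings(
          make_symmetric_dimer(seqs, omega = omega, handedness = hand, d = d))
        g <- measure_dimer(dim)
        expect_lt(abs(g$omega - omega), 0.5)
        expect_lt(abs(g$distance - d), 0.1)
        expect_equal(g$handedness, if (omega < 2) "parallel" else hand)
      }
    }
  }
})

test_that("dimer geometry is symmetric in the two axes", {
  dim <- make_symmetric_dimer(strrep("V", 21), omega = 28,
                              handedness = "right", d = 7.9)
  a <- fit_helix_axis(dim, "A"); b <- fit_helix_axis(dim, "B")
  g1 <- dimer_geometry(a, b); g2 <- dimer_geometry(b, a)
  expect_equal(g1$omega, g2$omega, tolerance = 1e-9)
  expect_equal(g1$distance, g2$distance, tolerance = 1e-9)
  expect_identical(g1$handedness, g2$handedness)
})

test_that("antiparallel pairs are flagged while the angle stays acute", {
  a <- structure(list(anchor = c(0, 0, 0), direction = c(0, 0, 1),
                      t_min = -10, t_max = 10, resno_range = c(1L, 14L),
                      rms_radius = 0), class = "helix_axis")
  bdir <- c(sin(170 * pi / 180), 0, cos(170 * pi / 180))
  b <- structure(list(anchor = c(8, 0, 0), direction = bdir,
                      t_min = -10, t_max = 10, resno_range = c(1L, 14L),
                      rms_radius = 0), class = "helix_axis")
  g <- dimer_geometry(a, b)
  expect_true(g$antiparallel)
  expect_equal(g$omega, 10, tolerance = 1e-6)
  expect_lte(g$omega, 90)
})
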