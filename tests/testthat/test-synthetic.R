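test_that("ideal helices lie on the requested cylinder", {
  h <- make_ideal_helix(strrep("V", 33))
  ca <- h[h$atom == "CA", ]
  expect_equal(sqrt(ca$x^2 + ca$y^2), rep(2.3, 33), tolerance = 1e-9)
  expect_equal(max(ca$z) - min(ca$z), 48.0, tolerance = 1e-9)
  expect_error(make_ideal_helix("V"), "at least 2")
  expect_error(make_ideal_helix("VXZ"), "invalid residue letter")
  # glycine carries no pseudo side chain
  hg <- make_ideal_helix("VGV")
  expect_false(any(hg$atom == "SC" & hg$resno == 2))
})

test_that("dimer construction warns on clashes but still returns them", {
  expect_warning(dim <- make_symmetric_dimer("VLVLVLVL", omega = 10,
                                             handedness = "left", d = 2),
                 "contacts below")
  expect_s3_class(dim, "structure_model")
  expect_setequal(unique(dim$chain), c("A", "B"))
})

test_that("requested dimer geometries carry their parameters", {
  dim <- make_symmetric_dimer(strrep("V", 25), omega = 12,
                              handedness = "left", d = 10.1, phi_self = 40)
  p <- attr(dim, "params")
  expect_equal(p$omega, 12)
  expect_equal(p$handedness, "left")
  g <- measure_dimer(dim)
  expect_lt(abs(g$omega - 12), 0.5)
  expect_lt(abs(g$distance - 10.1), 0.1)
  expect_equal(g$handedness, "left")
})

test_that("shift-table generation is seed-deterministic", {
  s1 <- make_shift_tables("VLISVTAM", interface = c(2L, 5L),
                          noise = c(0.003, 0.012), seed = 42)
  s2 <- make_shift_tables("VLISVTAM", interface = c(2L, 5L),
                          noise = c(0.003, 0.012), seed = 42)
  expect_identical(s1, s2)
  s3 <- make_shift_tables("VLISVTAM", interface = c(2L, 5L),
                          noise = c(0.003, 0.012), seed = 43)
  expect_false(identical(s1$dimer$dH, s3$dimer$dH))
})

test_that("noiseless shift tables are classified back to the exact truth", {
  tmicl <- tlr4_constructs()$TMICL
  tabs <- make_shift_tables(tmicl$sequence, start = tmicl$start,
                            interface = tlr4_flagged_residues(),
                            helix_range = c(631, 663))
  got <- classify_csp(csp_table(tabs$monomer, tabs$dimer))
  expect_identical(got$flagged, tabs$truth)
  expect_identical(tabs$truth, tlr4_flagged_residues())

  null <- make_shift_tables(tmicl$sequence, start = tmicl$start,
                            interface = integer(), helix_range = c(631, 663))
  expect_length(classify_csp(csp_table(null$monomer, null$dimer))$flagged, 0L)
  expect_error(make_shift_tables("VLIS", interface = 99L), "outside")
})

test_that("flagged-set recovery stays sharp under noise", {
  tmicl <- tlr4_constructs()$TMICL
  f1 <- vapply(1:30, function(s) {
    tabs <- make_shift_tables(tmicl$sequence, start = tmicl$start,
                              interface = tlr4_flagged_residues(),
                              helix_range = c(631, 663),
                              dd_interface = c(ddH = 0.025, ddC = 0.08),
                              noise = c(sH = 0.003, sC = 0.012), seed = s)
    fl <- classify_csp(csp_table(tabs$monomer, tabs$dimer))$flagged
    f1_score(fl, tabs$truth)
  }, numeric(1))
  expect_gte(mean(f1), 0.95)
})

test_that("titration curves are reproducible and carry their truth", {
  t1 <- make_titration(sigma = 0.005, seed = 7)
  t2 <- make_titration(sigma = 0.005, seed = 7)
  expect_identical(t1, t2)
  expect_equal(attr(t1, "truth")$pKa, 6.16)
  clean <- make_titration()
  expect_equal(clean$delta[which.min(abs(clean$pH - 6.16))],
               titration_model(clean$pH[which.min(abs(clean$pH - 6.16))],
                               6.16, 0.98, 8.60, 7.70))
})

test_that("the interface face follows the helical phase", {
  face0 <- interface_face(strrep("V", 19), phi_self = 0)
  expect_true(1L %in% face0)       # residue 1 points at the partner
  expect_true(19L %in% face0)      # 18 * 100 deg = 5 turns exactly
  expect_false(10L %in% face0)     # 900 deg -> 180 deg away
  face180 <- interface_face(strrep("V", 19), phi_self = 180)
  expect_true(10L %in% face180)
  expect_false(1L %in% face180)
})
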