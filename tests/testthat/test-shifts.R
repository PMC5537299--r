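test_that("generalized CSP combines proton and carbon changes", {
  expect_identical(generalized_csp(0, 0), 0)
  expect_equal(generalized_csp(0.03, 0.20), sqrt(0.03^2 + 0.20^2 / 16),
               tolerance = 1e-12)
  expect_equal(generalized_csp(0.03, 0.20), 0.0583, tolerance = 1e-3)
  expect_equal(generalized_csp(-0.03, 0.20), generalized_csp(0.03, 0.20))
  expect_equal(generalized_csp(0.03, -0.20), generalized_csp(0.03, 0.20))
  expect_error(generalized_csp(Inf, 0), "non-finite")
})

test_that("generalized CSP is non-negative, monotone and homogeneous", {
  set.seed(3)
  for (rep in 1:25) {
    h <- stats::rnorm(1, 0, 0.05); c <- stats::rnorm(1, 0, 0.3)
    k <- stats::runif(1, -3, 3)
    g <- generalized_csp(h, c)
    expect_gte(g, 0)
    expect_gte(generalized_csp(h * 1.5, c), g)
    expect_gte(generalized_csp(h, c * 1.5), g)
    expect_equal(generalized_csp(k * h, k * c), abs(k) * g, tolerance = 1e-12)
  }
})

test_that("CSP classes honour thresholds exactly, boundary to the lower class", {
  rec <- data.frame(resno = 1:5, restype = "V", group = "g1CH3",
                    ddH = 0, ddC = 0,
                    d_gen = c(0.025, 0.015, 0.02, 0.01, 0.005),
                    h_only = FALSE)
  cls <- classify_csp(rec)
  expect_equal(as.character(cls$records$class),
               c("strong", "weak", "weak", "none", "none"))
  expect_identical(cls$flagged, 1L)
})

test_that("per-residue class is the max over groups and order-invariant", {
  rec <- data.frame(resno = c(10L, 10L, 11L, 11L),
                    restype = "L", group = c("d1CH3", "d2CH3", "d1CH3", "d2CH3"),
                    ddH = 0, ddC = 0,
                    d_gen = c(0.005, 0.03, 0.015, 0.012), h_only = FALSE)
  cls <- classify_csp(rec)
  expect_identical(cls$flagged, 10L)
  expect_equal(cls$residue_class$class[cls$residue_class$resno == 11], "weak")
  shuffled <- classify_csp(rec[c(3, 1, 4, 2), ])
  expect_identical(shuffled$flagged, cls$flagged)
  expect_equal(shuffled$residue_class, cls$residue_class)

  empty <- classify_csp(rec[0, ])
  expect_length(empty$flagged, 0L)
})

test_that("csp_table joins states and flags proton-only groups", {
  mono <- data.frame(resno = c(1L, 2L), restype = c("V", "L"),
                     group = c("g1CH3", "d1CH3"),
                     dH = c(0.90, 0.88), dC = c(21.0, NA))
  dime <- mono
  dime$dH <- dime$dH + c(0.02, -0.01)
  dime$dC <- c(21.2, NA)
  tab <- csp_table(mono, dime)
  expect_equal(tab$ddH, c(0.02, -0.01), tolerance = 1e-12)
  expect_equal(tab$h_only, c(FALSE, TRUE))
  expect_equal(tab$d_gen[2], 0.01, tolerance = 1e-12)  # carbon treated as 0
})

test_that("secondary shifts subtract the random-coil reference", {
  rc <- random_coil_ca()
  tab <- data.frame(resno = 1:3, restype = c("A", "V", "G"), group = "Ca",
                    dH = NA, dC = rc[c("A", "V", "G")] + c(0, 2.5, 2.5))
  prof <- secondary_shifts(tab)
  expect_equal(prof$delta, c(0, 2.5, 2.5), tolerance = 1e-12)
  bad <- tab; bad$restype[1] <- "Z"
  expect_error(secondary_shifts(bad), "Z")
  expect_error(secondary_shifts(tab[tab$group != "Ca", ]), "no Ca rows")
})

test_that("helix calling finds the generated 33-residue stretch", {
  tabs <- make_shift_tables(tlr4_constructs()$TMICL$sequence, start = 623,
                            helix_range = c(631, 663))
  prof <- secondary_shifts(tabs$monomer)
  call <- call_helical_stretch(prof)
  expect_equal(nrow(call), 1L)
  expect_equal(call$start, 631L)
  expect_equal(call$end, 663L)
  expect_equal(call$n_residues, 33L)
})

test_that("helix calling respects run length, thresholds and gap bridging", {
  flat <- data.frame(resno = 1:20, delta = rep(0, 20))
  expect_equal(nrow(call_helical_stretch(flat)), 0L)

  # two runs of 3 with one observed sub-threshold residue between: no call
  prof <- data.frame(resno = 1:7, delta = c(2, 2, 2, 0.1, 2, 2, 2))
  expect_equal(nrow(call_helical_stretch(prof, min_run = 4)), 0L)

  # same pattern but the middle residue is unobserved: bridged into one run
  gap <- prof[prof$resno != 4, ]
  call <- call_helical_stretch(gap, min_run = 4)
  expect_equal(nrow(call), 1L)
  expect_equal(c(call$start, call$end), c(1L, 7L))
  expect_equal(nrow(call_helical_stretch(gap, min_run = 4, bridge_gaps = FALSE)),
               0L)
})

test_that("exchange ratios and protection flags", {
  r <- exchange_ratio(c(0, 5, 1), c(100, 100, 100))
  expect_equal(r$ratio, c(0, 0.05, 0.01))
  expect_equal(r$protected, c(TRUE, FALSE, TRUE))
  expect_error(exchange_ratio(1, 0), "positive")
})

test_that("relative intensities normalize to the maximum and flag broadening", {
  r <- relative_intensity(c(10, 5, 1))
  expect_equal(r$rel, c(1, 0.5, 0.1))
  expect_equal(r$broadened, c(FALSE, FALSE, TRUE))
  expect_equal(relative_intensity(7)$rel, 1)
  expect_false(any(relative_intensity(c(4, 4))$broadened))
  expect_error(relative_intensity(c(0, 0)), "non-positive")
})
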