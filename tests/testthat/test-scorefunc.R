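test_that("distance-dependent-dielectric Coulomb matches hand arithmetic", {
  # 332.064 * (+1)(-1) / (10 * 3^2), unshifted
  expect_equal(coulomb_ddd(1, -1, 3, shift = FALSE), -332.064 / 90,
               tolerance = 1e-9)
  expect_equal(coulomb_ddd(1, -1, 3, shift = FALSE), -3.690, tolerance = 1e-3)
  expect_identical(coulomb_ddd(0, 1, 2.5), 0)
  # zero at and beyond the outer clamp edge after shifting
  expect_identical(coulomb_ddd(1, -1, 5.5), 0)
  expect_identical(coulomb_ddd(1, -1, 8), 0)
  # clamped below 1.45 A
  expect_equal(coulomb_ddd(1, 1, 0.8), coulomb_ddd(1, 1, 1.45))
  expect_error(coulomb_ddd(1, 1, 0), "domain error")
})

test_that("pairwise terms vanish beyond all cutoffs", {
  cx <- two_atom_complex(50)
  bd <- score_complex(cx, score_weights("phdock"))
  expect_equal(unname(bd$terms[c("atr", "rep", "sol", "hb", "elec")]),
               rep(0, 5))
})

test_that("the Lennard-Jones split is flat inside and repulsive below the minimum", {
  # CA-CA pair: rmin = 3.8, eps = 0.12
  at_min <- score_complex(two_atom_complex(3.8))$terms
  inside <- score_complex(two_atom_complex(0.8 * 3.8))$terms
  deeper <- score_complex(two_atom_complex(0.6 * 3.8))$terms
  outside <- score_complex(two_atom_complex(4.6))$terms
  expect_equal(inside[["atr"]], at_min[["atr"]], tolerance = 1e-9)
  expect_equal(inside[["atr"]], deeper[["atr"]], tolerance = 1e-9)
  expect_equal(at_min[["atr"]], -0.12, tolerance = 1e-9)
  expect_gt(inside[["rep"]], 0)
  expect_gt(deeper[["rep"]], inside[["rep"]])
  expect_equal(at_min[["rep"]], 0, tolerance = 1e-9)
  expect_equal(outside[["rep"]], 0)
  expect_lt(outside[["atr"]], 0)
})

test_that("a charged His/carboxylate bridge scores favorable electrostatics and H-bonds", {
  cx <- make_fixture("salt_bridge_dimer", ph = 4.5)
  isc <- interface_score(cx, ph = 4.5, seed = 3)
  expect_lt(isc$per_term[["elec"]], 0)
  expect_lt(isc$per_term[["hb"]], 0)
  expect_lt(isc$isc, 0)
})

test_that("the weighted total is conserved term by term", {
  cx <- make_fixture("mini_complex", ph = 5)
  for (preset in c("phdock", "phdock_min", "rosettadock")) {
    w <- score_weights(preset)
    bd <- score_complex(cx, w)
    expect_equal(bd$total, sum(bd$weights * bd$terms), tolerance = 1e-9)
    expect_equal(bd$total, sum(bd$weighted), tolerance = 1e-9)
  }
})

test_that("the score is invariant under global rigid motion and partner swap", {
  cx <- make_fixture("salt_bridge_dimer", ph = 4.5)
  bd0 <- score_complex(cx)
  moved <- move_whole(cx)
  bd1 <- score_complex(moved)
  expect_equal(bd1$total, bd0$total, tolerance = 1e-6)
  swapped <- cx
  swapped$partner_split <- c(A = "ligand", B = "receptor")
  swapped$residues$partner <- unname(swapped$partner_split[swapped$residues$chain])
  expect_equal(score_complex(swapped)$total, bd0$total, tolerance = 1e-9)
})

test_that("separated partners have zero interface score", {
  cx <- make_fixture("salt_bridge_dimer", ph = 4.5)
  far <- phdock:::translate_partner(cx, "ligand", c(100, 0, 0))
  isc <- interface_score(far, ph = 4.5, seed = 2)
  expect_lt(abs(isc$isc), 1e-6)
  expect_length(isc$interface_residues, 0)
})

test_that("the pH term enters only pH-aware presets", {
  cx <- make_fixture("salt_bridge_dimer", ph = 4.5)
  i_ph <- interface_score(cx, score_weights("phdock"), ph = 4.5, seed = 2)
  i_rd <- interface_score(cx, score_weights("rosettadock"), ph = 4.5, seed = 2)
  expect_identical(unname(i_rd$weights[["ph"]]), 0)
  expect_identical(unname(i_rd$weighted[["ph"]]), 0)
  expect_gt(abs(i_ph$weights[["ph"]]), 0)
})

test_that("acidic pH strengthens the salt-bridge interface score", {
  # the qualitative pH-switch mechanism on the synthetic system: His pKa
  # 6.3, so dock at 4.3 vs 8.3 after re-equilibrating protonation
  cx <- make_fixture("salt_bridge_dimer")
  lo <- equilibrate_protonation(cx, ph = 4.3, seed = 5)
  hi <- equilibrate_protonation(cx, ph = 8.3, seed = 5)
  isc_lo <- interface_score(lo, ph = 4.3, seed = 9)$isc
  isc_hi <- interface_score(hi, ph = 8.3, seed = 9)$isc
  expect_lt(isc_lo, isc_hi)
})

test_that("weight fitting recovers the separating term", {
  set.seed(42)
  n <- 80
  near <- seq_len(n) <= 8
  terms <- cbind(
    atr = rnorm(n, -10, 0.5),
    hb = rnorm(n, -2, 0.2) - 2 * near,   # near-native have better H-bonds
    elec = rnorm(n, -1, 0.3))
  capri <- ifelse(near, "medium", "incorrect")
  fnat_v <- ifelse(near, 0.4, 0.05) + runif(n, 0, 0.01)
  erep <- runif(n, 0, 1)
  fit <- fit_weights(terms, capri, fnat_v, erep)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$weights >= 0))
  expect_identical(names(which.max(fit$weights)), "hb")
  expect_gt(fit$gap, 0)
  # identical per-term values cannot be separated
  flat <- matrix(1, n, 3, dimnames = list(NULL, c("atr", "hb", "elec")))
  expect_error(fit_weights(flat, capri, fnat_v, erep), "calibration error")
})

test_that("the energy gap is antisymmetric under class swap", {
  set.seed(7)
  terms <- matrix(rnorm(60), 20, 3)
  near <- c(rep(TRUE, 5), rep(FALSE, 15))
  w <- c(0.3, 0.5, 0.2)
  expect_equal(energy_gap(terms, near, w), -energy_gap(terms, !near, w),
               tolerance = 1e-12)
})
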