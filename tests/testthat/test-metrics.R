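test_that("ligand RMSD has the closed-form value for pure translation", {
  nat <- make_fixture("salt_bridge_dimer")
  expect_equal(lrmsd(nat, nat), 0, tolerance = 1e-9)
  shifted <- phdock:::translate_partner(nat, "ligand", c(0, 2, 0))
  expect_equal(lrmsd(shifted, nat), 2.0, tolerance = 1e-6)
  # invariant under global rigid motion of the model
  expect_equal(lrmsd(move_whole(shifted), nat), 2.0, tolerance = 1e-6)
})

test_that("interface RMSD is zero on identity and rigid copies", {
  nat <- make_fixture("salt_bridge_dimer")
  expect_equal(irmsd(nat, nat), 0, tolerance = 1e-9)
  expect_equal(irmsd(move_whole(nat), nat), 0, tolerance = 1e-6)
  shifted <- phdock:::translate_partner(nat, "ligand", c(0, 1.5, 0))
  expect_gt(irmsd(shifted, nat), 0)
})

test_that("fnat is a set-intersection ratio validated by direct enumeration", {
  nat <- make_fixture("salt_bridge_dimer")
  expect_equal(fnat(nat, nat), 1.0)
  far <- phdock:::translate_partner(nat, "ligand", c(100, 0, 0))
  expect_equal(fnat(far, nat), 0.0)
  # independent double-loop contact oracle on a perturbed pose
  contacts_oracle <- function(cx) {
    out <- character(0)
    rres <- which(cx$residues$partner == "receptor")
    lres <- which(cx$residues$partner == "ligand")
    for (i in rres) for (j in lres) {
      xi <- cx$xyz[cx$atoms$res == i & !cx$atoms$is_h, , drop = FALSE]
      xj <- cx$xyz[cx$atoms$res == j & !cx$atoms$is_h, , drop = FALSE]
      dmin <- sqrt(min(outer(rowSums(xi^2), rowSums(xj^2), "+") -
                         2 * tcrossprod(xi, xj)))
      if (dmin < 5) out <- c(out, paste(i, j, sep = ":"))
    }
    out
  }
  set.seed(3)
  dec <- make_decoy_set(nat, 3, c(2, 4, 8), seed = 12)
  for (m in dec$models) {
    expected <- length(intersect(contacts_oracle(m), contacts_oracle(nat))) /
      length(contacts_oracle(nat))
    expect_equal(fnat(m, nat), expected)
  }
})

test_that("CAPRI rating follows the stated classification rules", {
  # the worked medium-quality case: Irmsd 1.7 A, 49% contacts, Lrmsd > 1
  expect_identical(capri_rating(1.7, 4.7, 0.49), "medium")
  expect_identical(capri_rating(0, 0, 1.0), "high")
  expect_identical(capri_rating(12, 30, 0.0), "incorrect")
  expect_identical(capri_rating(3.5, 12, 0.35), "acceptable")
  # boundary: acceptable needs fnat >= 0.3 and Irmsd <= 4 by default
  expect_identical(capri_rating(4.0, 20, 0.30), "acceptable")
  expect_identical(capri_rating(4.1, 20, 0.30), "incorrect")
  # strict mode admits the wider fnat >= 0.1 tier
  expect_identical(capri_rating(6, 9, 0.15, strict = TRUE), "acceptable")
  expect_identical(capri_rating(6, 9, 0.15, strict = FALSE), "incorrect")
})

test_that("CAPRI rating is monotone in each metric", {
  lvl <- c(incorrect = 0, acceptable = 1, medium = 2, high = 3)
  set.seed(9)
  for (k in 1:200) {
    ir <- runif(1, 0, 8); lr <- runif(1, 0, 12); fn <- runif(1)
    base <- lvl[[capri_rating(ir, lr, fn)]]
    expect_gte(lvl[[capri_rating(ir * 0.5, lr, fn)]], base)
    expect_gte(lvl[[capri_rating(ir, lr * 0.5, fn)]], base)
    expect_gte(lvl[[capri_rating(ir, lr, min(1, fn + 0.2))]], base)
  }
})

test_that("interface hydrogen bonds are cross-partner only", {
  cx <- make_fixture("salt_bridge_dimer", ph = 4.5)
  hb <- interface_hbonds(cx)
  expect_gte(nrow(hb), 1)
  # every listed bond crosses the interface
  part <- cx$residues$partner
  expect_true(all(part[hb$don_res] != part[hb$acc_res]))
  far <- phdock:::translate_partner(cx, "ligand", c(100, 0, 0))
  expect_equal(nrow(interface_hbonds(far)), 0)
})

test_that("hydrogen-bond recovery is 1 on identity and 0 on disjoint sets", {
  cx <- make_fixture("salt_bridge_dimer", ph = 4.5)
  rec <- hbond_recovery(cx, cx)
  expect_equal(rec$fraction_recovered, 1.0)
  expect_equal(rec$n_model, rec$n_native)
  far <- phdock:::translate_partner(cx, "ligand", c(100, 0, 0))
  rec2 <- hbond_recovery(far, cx)
  expect_equal(rec2$fraction_recovered, 0.0)
})

test_that("discrimination score matches hand evaluation on the two-level toy", {
  # 10 near-native models at normalized score 0, 10 non-native at 1
  isc <- c(rep(0, 10), rep(1, 10))
  ir <- c(rep(0.5, 10), rep(5.0, 10))
  d <- discrimination_score(isc, ir)
  expect_equal(d$D, -1.0, tolerance = 1e-9)
  expect_equal(d$N_r, 6)  # r = 6 has an empty far side and is skipped
  # swapping classes flips the sign
  d2 <- discrimination_score(isc, rev(ir))
  expect_equal(d2$D, 1.0, tolerance = 1e-9)
})

test_that("discrimination score equals an independent brute-force implementation", {
  set.seed(17)
  for (k in 1:200) {
    n <- sample(5:50, 1)
    isc <- rnorm(n)
    ir <- runif(n, 0, 10)
    got <- tryCatch(discrimination_score(isc, ir)$D, error = function(e) NA)
    want <- tryCatch(brute_force_D(isc, ir), error = function(e) NA)
    expect_identical(got, want)
  }
})

test_that("N5 counts near-native models among the top five by score", {
  isc <- c(1, 2, 3, 4, 5, 6, 7)
  ir <- c(1.2, 3.9, 4.0, 4.1, 7.0, 0.1, 0.1)
  expect_equal(n5(isc, ir), 3)  # 4.0 is inclusive, 4.1 is not
  expect_equal(n5(rep(1, 6), rep(0, 6)), 5)
  expect_equal(n5(rep(1, 6), rep(10, 6)), 0)
  expect_error(n5(1:4, 1:4), "metric error")
})

test_that("bootstrap is deterministic per seed and degenerate on constant data", {
  isc <- c(rep(-1, 10), rep(1, 10))
  ir <- c(rep(1, 10), rep(6, 10))
  b1 <- bootstrap_funnel(isc, ir, "D", n_resamples = 200, seed = 5)
  b2 <- bootstrap_funnel(isc, ir, "D", n_resamples = 200, seed = 5)
  expect_identical(b1, b2)
  # all-identical models: sigma = 0
  bN <- bootstrap_funnel(rep(2, 12), rep(1.0, 12), "N5",
                         n_resamples = 100, seed = 1)
  expect_equal(bN$sigma, 0)
  expect_equal(bN$mu, 5)
  # mean near the plug-in statistic at moderate resample counts
  set.seed(31)
  isc3 <- rnorm(40); ir3 <- runif(40, 0, 8)
  d <- discrimination_score(isc3, ir3)$D
  b3 <- bootstrap_funnel(isc3, ir3, "D", n_resamples = 600, seed = 8)
  expect_lt(abs(b3$mu - d), 0.2)
})

test_that("all metrics are invariant under global rigid motion", {
  nat <- make_fixture("mini_complex", ph = 5)
  dec <- make_decoy_set(nat, 2, c(3), seed = 4)$models[[1]]
  moved <- move_whole(dec, angle = 73, axis = c(-1, 2, 0.5), t = c(8, 1, -4))
  expect_equal(irmsd(moved, nat), irmsd(dec, nat), tolerance = 1e-6)
  expect_equal(lrmsd(moved, nat), lrmsd(dec, nat), tolerance = 1e-6)
  expect_equal(fnat(moved, nat), fnat(dec, nat))
})
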