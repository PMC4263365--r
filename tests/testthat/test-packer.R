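test_that("rotamer sets are the chi-well x variant cross product plus the input", {
  cx <- make_fixture("mini_complex", ph = 5)
  count_for <- function(aa) {
    i <- which(cx$residues$aa == aa)[1]
    length(build_rotamers(cx, i))
  }
  # n_wells^n_chi * n_variants + 1 input conformation
  expect_equal(count_for("HIS"), 3^2 * 3 + 1)
  expect_equal(count_for("GLU"), 3^3 * 3 + 1)
  expect_equal(count_for("TYR"), 3^2 * 2 + 1)
  expect_equal(count_for("LYS"), 3^4 * 2 + 1)  # 81 chi combos, capped
  expect_equal(count_for("ALA"), 1)
})

test_that("single-residue packing matches exhaustive variant enumeration", {
  # oracle: apply every variant explicitly and score the full complex
  brute_label <- function(cx, i, ph) {
    labs <- enumerate_variants(cx$residues$aa[i])
    sc <- vapply(labs, function(l) {
      s <- phdock:::set_protonation(cx, i, l)
      s$ph <- ph
      score_complex(s, score_weights("phdock"), ph)$total
    }, 0)
    labs[which.min(sc)]
  }
  cases <- list(list(aa = "HIS", ph = 4.0, prot = TRUE),
                list(aa = "TYR", ph = 12.0, prot = FALSE),
                list(aa = "ASP", ph = 2.0, prot = TRUE),
                list(aa = "LYS", ph = 12.0, prot = FALSE))
  for (cs in cases) {
    cx <- single_residue_chain(cs$aa)
    packed <- pack_sidechains(cx, packer_task(3L, ph = cs$ph, seed = 4))
    got <- packed$residues$prot[3]
    expect_identical(phdock:::label_is_protonated(got), cs$prot,
                     label = paste(cs$aa, "at pH", cs$ph))
    # protonation class agrees with the brute-force oracle
    oracle <- brute_label(cx, 3L, cs$ph)
    expect_identical(phdock:::label_is_protonated(got),
                     phdock:::label_is_protonated(oracle))
  }
})

test_that("packer energy equals the brute-force minimum on a two-residue system", {
  cx <- make_fixture("salt_bridge_dimer", ph = 6.0)
  design <- c(4L, 11L)  # the His and the Asp
  ph <- 6.0
  w <- score_weights("phdock")
  packed <- pack_sidechains(cx, packer_task(design, ph = ph, seed = 2))
  e_packed <- score_complex(packed, w, ph)$total
  # independent brute force: apply every rotamer pair and score fully
  rots_a <- build_rotamers(cx, design[1], ph)
  rots_b <- build_rotamers(cx, design[2], ph)
  e_min <- Inf
  for (ra in rots_a) {
    ca <- phdock:::apply_rotamer(cx, design[1], ra)
    for (rb in rots_b) {
      cb <- phdock:::apply_rotamer(ca, design[2], rb)
      cb$ph <- ph
      e <- score_complex(cb, w, ph)$total
      if (e < e_min) e_min <- e
    }
  }
  expect_equal(e_packed, e_min, tolerance = 1e-6)
})

test_that("annealing with a cold finish matches exhaustive enumeration", {
  cx <- make_fixture("salt_bridge_dimer", ph = 5.0)
  design <- c(4L, 11L)
  exact <- pack_sidechains(cx, packer_task(design, ph = 5, seed = 3))
  e_exact <- score_complex(exact, ph = 5)$total
  annealed <- pack_sidechains(cx, packer_task(design, ph = 5, seed = 3,
                                              exhaustive_limit = 0,
                                              t_end = 0.05, n_sweeps = 60))
  e_anneal <- score_complex(annealed, ph = 5)$total
  expect_equal(e_anneal, e_exact, tolerance = 1e-6)
})

test_that("packing is deterministic and never moves the backbone", {
  cx <- make_fixture("mini_complex", ph = 5)
  design <- which(cx$residues$prot != "fixed")
  p1 <- pack_sidechains(cx, packer_task(design, ph = 5, seed = 11))
  p2 <- pack_sidechains(cx, packer_task(design, ph = 5, seed = 11))
  expect_identical(p1$residues$prot, p2$residues$prot)
  expect_identical(p1$xyz, p2$xyz)
  bb_names <- c("N", "CA", "C", "O")
  for (i in design) {
    for (b in bb_names) {
      a0 <- cx$xyz[which(cx$atoms$res == i & cx$atoms$name == b), ]
      a1 <- p1$xyz[which(p1$atoms$res == i & p1$atoms$name == b), ]
      expect_lt(max(abs(a0 - a1)), 1e-9)
    }
  }
  # empty designable set returns the input unchanged
  expect_identical(pack_sidechains(cx, packer_task(integer(0)))$xyz, cx$xyz)
})

test_that("minimization satisfies the descent contract", {
  cx <- make_fixture("salt_bridge_dimer", ph = 4.5)
  w <- score_weights("phdock_min")
  # stretch the bridge by pulling the ligand 1.5 A along the contact axis
  ne2 <- cx$xyz[which(cx$atoms$res == 4 & cx$atoms$name == "NE2"), ]
  od1 <- cx$xyz[which(cx$atoms$res == 11 & cx$atoms$name == "OD1"), ]
  axis <- (od1 - ne2) / sqrt(sum((od1 - ne2)^2))
  stretched <- phdock:::translate_partner(cx, "ligand", 1.5 * axis)
  s_in <- score_complex(stretched, w, 4.5)$total
  mini <- minimize_complex(stretched, "rigid_body", weights = w,
                           max_iter = 120, ph = 4.5)
  s_out <- score_complex(mini, w, 4.5)$total
  expect_lte(s_out, s_in)
  expect_lt(s_out, s_in)  # strictly better from a stretched start
  d_in <- sqrt(sum((stretched$xyz[which(stretched$atoms$res == 11 &
                                          stretched$atoms$name == "OD1"), ] - ne2)^2))
  d_out <- sqrt(sum((mini$xyz[which(mini$atoms$res == 11 &
                                      mini$atoms$name == "OD1"), ] - ne2)^2))
  expect_lt(d_out, d_in)
  expect_error(minimize_complex(cx, "both", max_iter = 0), "domain error")
})

test_that("minimization from a near-minimum start does not degrade the score", {
  cx <- make_fixture("salt_bridge_dimer", ph = 4.5)
  w <- score_weights("phdock_min")
  s0 <- score_complex(cx, w, 4.5)$total
  m <- minimize_complex(cx, "rigid_body", weights = w, max_iter = 40, ph = 4.5)
  expect_lte(score_complex(m, w, 4.5)$total, s0)
})
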