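test_that("PDB write/read round-trip preserves atoms, names and coordinates", {
  cx <- make_fixture("salt_bridge_dimer", ph = 4.5)
  f <- tempfile(fileext = ".pdb")
  write_pdb(cx, f)
  back <- read_pdb(f, c(A = "receptor", B = "ligand"), ph = 4.5)
  expect_equal(nrow(back$residues), nrow(cx$residues))
  expect_equal(nrow(back$atoms), nrow(cx$atoms))
  # match atoms by (residue, name); coordinates within 1e-3 A
  key_a <- paste(cx$atoms$res, cx$atoms$name)
  key_b <- paste(back$atoms$res, back$atoms$name)
  expect_setequal(key_a, key_b)
  m <- match(key_a, key_b)
  expect_lt(max(abs(cx$xyz - back$xyz[m, ])), 1e-3)
  # protonation labels survive the round trip (inferred from hydrogens)
  expect_identical(back$residues$prot, cx$residues$prot)
})

test_that("waters and HETATM records are dropped on read", {
  cx <- make_fixture("hbond_dimer")
  f <- tempfile(fileext = ".pdb")
  write_pdb(cx, f)
  lines <- readLines(f)
  end <- grep("^END", lines)[1]
  extra <- c(
    "HETATM 9001  O   HOH A 900      10.000  10.000  10.000  1.00  0.00           O",
    "HETATM 9002 C1   LIG B 901      12.000  12.000  12.000  1.00  0.00           C")
  writeLines(c(lines[seq_len(end - 1)], extra, lines[end:length(lines)]), f)
  back <- read_pdb(f, c(A = "receptor", B = "ligand"))
  expect_equal(nrow(back$residues), nrow(cx$residues))
  expect_false(any(back$residues$aa %in% c("HOH", "LIG")))
})

test_that("partner split naming an absent chain is a configuration error", {
  cx <- make_fixture("salt_bridge_dimer")
  f <- tempfile(fileext = ".pdb")
  write_pdb(cx, f)
  expect_error(read_pdb(f, c(Z = "receptor", B = "ligand")),
               "configuration error")
})

test_that("protonated His is written with both ring hydrogens", {
  cx <- make_fixture("salt_bridge_dimer", ph = 4.5)  # native His is HIP
  expect_identical(cx$residues$prot[4], "HIP")
  f <- tempfile(fileext = ".pdb")
  write_pdb(cx, f)
  lines <- readLines(f)
  his_lines <- grep(" HIS ", lines, value = TRUE)
  expect_true(any(grepl("HD1", his_lines)))
  expect_true(any(grepl("HE2", his_lines)))
})

test_that("centroid conversion places pseudo-atoms at side-chain centroids", {
  cx <- make_fixture("salt_bridge_dimer")
  cen <- to_centroid(cx)
  expect_identical(cen$representation, "centroid")
  # Ala: centroid equals CB
  i <- which(cx$residues$aa == "ALA")[1]
  cb <- cx$xyz[which(cx$atoms$res == i & cx$atoms$name == "CB"), ]
  cenp <- cen$xyz[which(cen$atoms$res == i & cen$atoms$name == "CEN"), ]
  expect_equal(as.numeric(cenp), as.numeric(cb), tolerance = 1e-9)
  # Asp: centroid equals the mean of CB, CG, OD1, OD2
  j <- which(cx$residues$aa == "ASP")[1]
  sc <- cx$xyz[which(cx$atoms$res == j &
                       cx$atoms$name %in% c("CB", "CG", "OD1", "OD2")), ]
  cenp2 <- cen$xyz[which(cen$atoms$res == j & cen$atoms$name == "CEN"), ]
  expect_equal(as.numeric(cenp2), as.numeric(colMeans(sc)), tolerance = 1e-9)
  # writing a centroid complex is a state error
  expect_error(write_pdb(cen, tempfile()), "state error")
})

test_that("Gly centroid falls back to CA", {
  res <- phdock:::build_helix_chain(c("ALA", "GLY", "ALA"), "A")
  res2 <- phdock:::build_helix_chain(c("ALA", "ALA", "ALA"), "B")
  for (k in seq_along(res2)) res2[[k]]$resnum <- res2[[k]]$resnum + 50L
  cx <- phdock:::assemble_complex(c(res, res2),
                                  c(A = "receptor", B = "ligand"))
  cen <- to_centroid(cx)
  ca <- cx$xyz[which(cx$atoms$res == 2 & cx$atoms$name == "CA"), ]
  cp <- cen$xyz[which(cen$atoms$res == 2 & cen$atoms$name == "CEN"), ]
  expect_equal(as.numeric(cp), as.numeric(ca))
})

test_that("restore_fullatom inverts to_centroid and follows rigid moves", {
  cx <- make_fixture("salt_bridge_dimer", ph = 4.5)
  cen <- to_centroid(cx)
  back <- restore_fullatom(cen, cx)
  expect_lt(max(abs(back$xyz - cx$xyz)), 1e-3)
  expect_identical(back$residues$prot, cx$residues$prot)
  # rigid 5 A ligand translation in centroid mode carries the side chains
  cen2 <- phdock:::translate_partner(cen, "ligand", c(5, 0, 0))
  back2 <- restore_fullatom(cen2, cx)
  lig <- phdock:::partner_atom_idx(cx, "ligand")
  expect_lt(max(abs(back2$xyz[lig, ] -
                      sweep(cx$xyz[lig, ], 2, c(5, 0, 0), "+"))), 1e-6)
  rec <- phdock:::partner_atom_idx(cx, "receptor")
  expect_lt(max(abs(back2$xyz[rec, ] - cx$xyz[rec, ])), 1e-6)
  # sequence mismatch is a configuration error
  other <- make_fixture("hbond_dimer")
  expect_error(restore_fullatom(cen, other), "configuration error")
})

test_that("partner split survives representation changes", {
  cx <- make_fixture("mini_complex")
  cen <- to_centroid(cx)
  expect_identical(cen$partner_split, cx$partner_split)
  back <- restore_fullatom(cen, cx)
  expect_identical(back$partner_split, cx$partner_split)
})
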