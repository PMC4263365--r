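# shared helpers: tiny hand-built complexes and an independent
# discrimination-score implementation used as oracle

# a complex of two single-atom residues (CA only), one per chain/partner,
# separated by `d` Angstrom along x; used to probe the pairwise terms
two_atom_complex <- function(d, aa = "GLY") {
  res <- list(
    list(aa = aa, chain = "A", resnum = 1,
         heavy = list(CA = c(0, 0, 0))),
    list(aa = aa, chain = "B", resnum = 1,
         heavy = list(CA = c(d, 0, 0))))
  phdock:::assemble_complex(res, c(A = "receptor", B = "ligand"), ph = 7)
}

# a single helical chain with one substituted residue at the center,
# assembled as a receptor-only complex
single_residue_chain <- function(aa, label = NULL, n_flank = 2, ph = 7) {
  seq_aa <- c(rep("ALA", n_flank), aa, rep("ALA", n_flank))
  labs <- stats::setNames(list(label), as.character(n_flank + 1))
  res <- phdock:::build_helix_chain(seq_aa, "A", labels = labs)
  phdock:::assemble_complex(res, c(A = "receptor"), ph = ph)
}

# independent, loop-based re-implementation of the discrimination score
brute_force_D <- function(isc, irmsd) {
  q05 <- as.numeric(stats::quantile(isc, 0.05, type = 7))
  q95 <- as.numeric(stats::quantile(isc, 0.95, type = 7))
  den <- q95 - q05
  if (den < 1e-12) den <- 1
  zh <- (isc - q05) / den
  cutoffs <- c(1.0, 1.5, 2.0, 2.5, 3.0, 4.0, 6.0)
  gaps <- numeric(0)
  for (r in cutoffs) {
    lo <- Inf; hi <- Inf
    for (k in seq_along(isc)) {
      if (irmsd[k] <= r) lo <- min(lo, zh[k]) else hi <- min(hi, zh[k])
    }
    if (is.finite(lo) && is.finite(hi)) gaps <- c(gaps, lo - hi)
  }
  if (!length(gaps)) stop("metric error")
  mean(gaps)
}

# rigid motion applied to a whole complex (rotation + translation)
move_whole <- function(cx, angle = 25, axis = c(1, 2, 3), t = c(5, -3, 2)) {
  R <- phdock:::rotation_about_axis(axis, angle)
  cx$xyz <- sweep(cx$xyz %*% R, 2, t, "+")
  cx
}

# fast docking configuration for protocol tests
tiny_cfg <- function(ph = 4.5, n_models = 4, seed = 7) {
  dock_config(ph = ph, n_models = n_models, lowres_cycles = 20,
              highres_mcm_cycles = 2, min_iter = 25, seed = seed)
}
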