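# Deterministic synthetic structure generator: ideal-geometry helical
# mini-proteins with substituted interface residues, pH-sensitive
# salt-bridge dimers, hydrogen-bond dimers, clash pairs, and decoy sets
# with controlled Irmsd spread. No external data required.

# Build one chain as an ideal alpha-helix (phi -57, psi -47, omega 180)
# with side chains at default chi (chi1 -60, others 180 unless overridden).
# Returns a list of residue entries for assemble_complex().
build_helix_chain <- function(seq_aa, chain_id, chi_overrides = list(),
                              labels = list()) {
  n <- length(seq_aa)
  phi <- -57; psi <- -47; omega <- 180
  Ns <- CAs <- Cs <- vector("list", n)
  Ns[[1]] <- c(0, 0, 0)
  CAs[[1]] <- c(1.458, 0, 0)
  ang <- deg2rad(111.2)
  Cs[[1]] <- CAs[[1]] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1)) {
    Np <- place_atom(Ns[[i]], CAs[[i]], Cs[[i]], 1.329, 116.2, psi)
    CAp <- place_atom(CAs[[i]], Cs[[i]], Np, 1.458, 121.7, omega)
    Cp <- place_atom(Cs[[i]], Np, CAp, 1.525, 111.2, phi)
    Ns[[i + 1]] <- Np; CAs[[i + 1]] <- CAp; Cs[[i + 1]] <- Cp
  }
  res_list <- vector("list", n)
  for (i in seq_len(n)) {
    aa <- seq_aa[i]
    heavy <- list(N = Ns[[i]], CA = CAs[[i]], C = Cs[[i]])
    heavy$O <- if (i < n)
      place_atom(Ns[[i]], CAs[[i]], Cs[[i]], 1.231, 120.8, psi + 180)
    else
      place_atom(Ns[[i]], CAs[[i]], Cs[[i]], 1.231, 120.8, psi + 180)
    nchi <- length(CHI_ATOMS[[aa]])
    chi <- if (!is.null(chi_overrides[[as.character(i)]]))
      chi_overrides[[as.character(i)]]
    else if (nchi > 0) c(-60, rep(180, nchi - 1)) else numeric(0)
    sc <- sidechain_coords(aa, heavy[c("N", "CA", "C")], chi)
    heavy <- c(heavy, sc)
    res_list[[i]] <- list(aa = aa, chain = chain_id, resnum = i,
                          heavy = heavy,
                          label = labels[[as.character(i)]])
  }
  res_list
}

# rotation taking unit vector u onto unit vector v
.rotation_u_to_v <- function(u, v) {
  u <- unit(u); v <- unit(v)
  d <- sum(u * v)
  if (d > 1 - 1e-10) return(diag(3))
  if (d < -1 + 1e-10) {
    # pick any perpendicular axis
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(pracma_cross(u, ref))
    return(rotation_about_axis(ax, 180))
  }
  ax <- pracma_cross(u, v)
  rotation_about_axis(ax, acos(d) * 180 / pi)
}

# minimal heavy-atom distance between the two partners
.min_cross_distance <- function(cx, exclude_res = integer()) {
  A <- cx$atoms
  heavy <- !A$is_h
  ir <- which(cx$residues$partner[A$res] == "receptor" & heavy &
                !(A$res %in% exclude_res))
  il <- which(cx$residues$partner[A$res] == "ligand" & heavy &
                !(A$res %in% exclude_res))
  if (!length(ir) || !length(il)) return(Inf)
  xr <- cx$xyz[ir, , drop = FALSE]; xl <- cx$xyz[il, , drop = FALSE]
  d2 <- outer(rowSums(xr^2), rowSums(xl^2), "+") - 2 * tcrossprod(xr, xl)
  sqrt(max(0, min(d2)))
}

#' Generate a synthetic two-chain complex
#'
#' Ideal-geometry helical chains with designated interface residues.
#' `"salt_bridge_dimer"` places a His on the receptor and an Asp on the
#' ligand with the His ring nitrogen at `contact_distance` from the
#' carboxylate oxygen, so that tight binding requires the protonated
#' (charged) His; the native labels are the acidic bound form (HIP/ASP).
#' `"hbond_dimer"` forms a neutral Ser-OH to Asn-OD1 hydrogen bond.
#' `"clash_pair"` overlaps two short helices (positive repulsive score).
#' `"mini_complex"` combines a His-Glu salt bridge with a Tyr and a Lys at
#' the interface.
#'
#' @param kind fixture kind.
#' @param contact_distance interface heteroatom contact distance (A,
#'   default 2.8).
#' @param n_flank alanine residues on each side of the interface residue
#'   (default 3).
#' @param ph solution pH recorded on the complex.
#' @param seed integer seed (construction is deterministic; the seed is
#'   recorded for provenance).
#' @return a fullatom `ph_complex` with chains A (receptor) and
#'   B (ligand).
#' @export
make_fixture <- function(kind = c("salt_bridge_dimer", "hbond_dimer",
                                  "clash_pair", "mini_complex"),
                         contact_distance = 2.8, n_flank = 3, ph = 7.0,
                         seed = 1) {
  kind <- match.arg(kind)
  if (contact_distance <= 0) stop("domain error: contact distance must be > 0")
  split <- c(A = "receptor", B = "ligand")
  flank <- rep("ALA", n_flank)
  mid <- n_flank + 1L

  if (kind == "clash_pair") {
    a <- build_helix_chain(c(flank, "ALA", flank), "A")
    b <- build_helix_chain(c(flank, "ALA", flank), "B")
    for (i in seq_along(b)) {
      b[[i]]$heavy <- lapply(b[[i]]$heavy, function(p) p + c(1.0, 0.5, 0.5))
      b[[i]]$resnum <- b[[i]]$resnum + 100L
    }
    return(assemble_complex(c(a, b), split, ph = ph))
  }

  spec <- switch(kind,
    salt_bridge_dimer = list(aa_a = "HIS", lab_a = "HIP",
                             aa_b = "ASP", lab_b = "ASP",
                             from = c("NE2", "HE2"), to = c("OD1", "CG")),
    hbond_dimer = list(aa_a = "SER", lab_a = NULL,
                       aa_b = "ASN", lab_b = NULL,
                       from = c("OG", "HG"), to = c("OD1", "CG")),
    mini_complex = list(aa_a = "HIS", lab_a = "HIP",
                        aa_b = "GLU", lab_b = "GLU",
                        from = c("NE2", "HE2"), to = c("OE1", "CD")))

  seq_a <- c(flank, spec$aa_a, flank)
  seq_b <- c(flank, spec$aa_b, flank)
  lab_a <- stats::setNames(list(spec$lab_a), as.character(mid))
  lab_b <- stats::setNames(list(spec$lab_b), as.character(mid))
  if (kind == "mini_complex") {
    seq_a[mid - 1] <- "TYR"
    seq_b[mid + 1] <- "LYS"
  }
  a <- build_helix_chain(seq_a, "A", labels = lab_a)
  b <- build_helix_chain(seq_b, "B", labels = lab_b)
  for (i in seq_along(b)) b[[i]]$resnum <- b[[i]]$resnum + 100L

  # provisional assembly of chain A alone to get hydrogen positions
  cx_a <- assemble_complex(a, c(A = "receptor"), ph = ph)
  idx_from <- vapply(spec$from, function(nm)
    which(cx_a$atoms$res == mid & cx_a$atoms$name == nm)[1], 0L)
  if (anyNA(idx_from)) stop("generation error: fixture anchor atoms missing")
  p_heavy <- cx_a$xyz[idx_from[1], ]        # e.g. His NE2
  p_h <- cx_a$xyz[idx_from[2], ]            # e.g. His HE2
  dir_ab <- unit(p_h - p_heavy)
  target <- p_heavy + contact_distance * dir_ab  # acceptor O position

  # orient chain B: its acceptor->carbon direction continues dir_ab
  b_res <- b[[mid]]
  o_b <- b_res$heavy[[spec$to[1]]]
  c_b <- b_res$heavy[[spec$to[2]]]
  R <- .rotation_u_to_v(c_b - o_b, dir_ab)
  place_b <- function(res_list, R2) {
    out <- res_list
    for (i in seq_along(out)) {
      out[[i]]$heavy <- lapply(out[[i]]$heavy, function(p)
        as.numeric((p - o_b) %*% t(R2)) + target)
    }
    out
  }
  # scan roll angles about the contact axis: among clash-free placements,
  # pick the most compact one (widest interface)
  best <- NULL; best_key <- c(-Inf, Inf)
  for (roll in seq(0, 330, by = 30)) {
    R2 <- rotation_about_axis(dir_ab, roll) %*% R
    cand <- assemble_complex(c(a, place_b(b, R2)), split, ph = ph)
    sep <- .min_cross_distance(cand, exclude_res = c(mid, length(a) + mid))
    ri <- partner_atom_idx(cand, "receptor")
    li <- partner_atom_idx(cand, "ligand")
    cdist <- vnorm(colMeans(cand$xyz[ri, , drop = FALSE]) -
                     colMeans(cand$xyz[li, , drop = FALSE]))
    ok <- sep >= 2.6
    key <- c(as.numeric(ok), -cdist)
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2])) {
      best_key <- key; best <- cand
    }
  }
  if (is.null(best)) stop("generation error: no placement found")
  best
}

#' Generate a decoy model set with controlled Irmsd spread
#'
#' Rigid-body perturbed copies of the native whose realized Irmsd is
#' within 15% of each requested target (targets are cycled through).
#' Target 0 yields an identity copy.
#'
#' @param native fullatom two-partner `ph_complex`.
#' @param n number of decoys (must be >= number of targets).
#' @param irmsd_targets requested Irmsd values (A).
#' @param seed integer seed.
#' @param max_tries perturbation retries per decoy before a generation
#'   error.
#' @return list of class `decoy_set`: `$models` (list of complexes),
#'   `$irmsd` (realized values), `$target`.
#' @export
make_decoy_set <- function(native, n, irmsd_targets, seed = 1,
                           max_tries = 60) {
  if (n < length(irmsd_targets))
    stop("domain error: n must be at least the number of targets")
  models <- vector("list", n)
  realized <- numeric(n)
  targets <- irmsd_targets[((seq_len(n) - 1) %% length(irmsd_targets)) + 1]
  lig_res <- which(native$residues$partner == "ligand")
  with_seed(seed, {
    for (m in seq_len(n)) {
      tgt <- targets[m]
      if (tgt <= 0) { models[[m]] <- native; realized[m] <- 0; next }
      mag <- tgt
      done <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- native
        dirv <- random_unit_vector()
        ang <- stats::runif(1, 0, min(20, 4 * tgt))
        axis <- random_unit_vector()
        lig_idx <- partner_atom_idx(cand, "ligand")
        cen <- colMeans(cand$xyz[lig_idx, , drop = FALSE])
        Rm <- rotation_about_axis(axis, ang)
        x <- sweep(cand$xyz[lig_idx, , drop = FALSE], 2, cen)
        cand$xyz[lig_idx, ] <- sweep(x %*% Rm, 2, cen + mag * dirv, "+")
        got <- irmsd(cand, native)
        if (abs(got - tgt) <= 0.15 * tgt) {
          models[[m]] <- cand; realized[m] <- got; done <- TRUE; break
        }
        if (got > 1e-9) mag <- max(0.05, mag * tgt / got)
      }
      if (!done)
        stop("generation error: could not realize Irmsd target ", tgt)
    }
  })
  structure(list(models = models, irmsd = realized, target = targets,
                 native = native),
            class = "decoy_set")
}
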