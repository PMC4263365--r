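# Discrete side-chain rotamer library extended with protonation variants,
# simulated-annealing packing, and torsion/rigid-body minimization.
#
# The packaged rotamer library is backbone-independent: ideal chi wells
# (gauche+/gauche-/trans per rotatable bond, capped at 81 chi combinations
# per residue) with uniform within-well priors, so E_dun = -ln(1/n_base).
# The input conformation is always included as an extra rotamer.

CHI_WELLS <- c(-60, 60, 180)

# measured chi angles of residue i (NULL when atoms are missing)
measure_chi <- function(cx, i) {
  aa <- cx$residues$aa[i]
  defs <- CHI_ATOMS[[aa]]
  if (is.null(defs)) return(numeric(0))
  idx <- which(cx$atoms$res == i)
  nm <- cx$atoms$name[idx]
  out <- numeric(length(defs))
  for (k in seq_along(defs)) {
    pos <- match(defs[[k]], nm)
    if (anyNA(pos)) return(NULL)
    q <- cx$xyz[idx[pos], , drop = FALSE]
    out[k] <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
  }
  out
}

# resolve a topology torsion spec against a chi vector
.resolve_tors <- function(t, chi) {
  if (is.numeric(t)) return(t)
  plus <- grepl("\\+180$", t)
  k <- as.integer(sub("chi", "", sub("\\+180$", "", t)))
  chi[k] + if (plus) 180 else 0
}

# side-chain heavy-atom coordinates from backbone + chi (named list)
sidechain_coords <- function(aa, bb, chi) {
  topo <- SIDECHAIN_TOPOLOGY[[aa]]
  if (is.null(topo)) return(list())
  coords <- bb
  for (row in topo) {
    coords[[row$name]] <- place_atom(coords[[row$r1]], coords[[row$r2]],
                                     coords[[row$r3]], row$b, row$a,
                                     .resolve_tors(row$t, chi))
  }
  coords[setdiff(names(coords), names(bb))]
}

#' Build the rotamer set of a residue
#'
#' Cross product of the residue's base chi rotamers (ideal wells) with its
#' protonation variants, plus the input conformation as an extra rotamer.
#'
#' @param cx fullatom `ph_complex`.
#' @param i residue index.
#' @param ph solution pH (stored with the rotamers for the pH term).
#' @return list of rotamers: `list(chi, label, prob, input)`.
#' @export
build_rotamers <- function(cx, i, ph = cx$ph) {
  aa <- cx$residues$aa[i]
  cur_label <- cx$residues$prot[i]
  cur_chi <- measure_chi(cx, i)
  variants <- enumerate_variants(aa)
  rots <- list()
  templated <- aa %in% TEMPLATED_AA && !is.null(cur_chi)
  n_chi <- length(CHI_ATOMS[[aa]])
  if (templated && n_chi > 0) {
    grid <- as.matrix(expand.grid(rep(list(CHI_WELLS), n_chi),
                                  KEEP.OUT.ATTRS = FALSE))
    if (nrow(grid) > 81) grid <- grid[seq_len(81), , drop = FALSE]
    p <- 1 / nrow(grid)
    for (v in variants)
      for (r in seq_len(nrow(grid)))
        rots[[length(rots) + 1L]] <- list(chi = as.numeric(grid[r, ]),
                                          label = v, prob = p, input = FALSE)
  }
  # chi-less residues contribute only the input conformation below
  rots[[length(rots) + 1L]] <- list(
    chi = if (is.null(cur_chi)) numeric(0) else cur_chi,
    label = cur_label,
    prob = if (templated && n_chi > 0) 1 / max(1, length(rots) / length(variants)) else 1,
    input = TRUE)
  rots
}

# ---- rotamer application ----------------------------------------------------

residue_bb_coords <- function(cx, i) {
  idx <- which(cx$atoms$res == i)
  nm <- cx$atoms$name[idx]
  out <- list()
  for (b in c("N", "CA", "C")) {
    k <- idx[nm == b]
    if (!length(k)) stop("configuration error: residue missing backbone atom ", b)
    out[[b]] <- cx$xyz[k[1], ]
  }
  out
}

# set residue i to the given chi vector and protonation label
set_residue_conformation <- function(cx, i, chi, label) {
  aa <- cx$residues$aa[i]
  if (aa %in% TEMPLATED_AA && length(chi)) {
    bb <- residue_bb_coords(cx, i)
    sc <- sidechain_coords(aa, bb, chi)
    idx <- which(cx$atoms$res == i)
    nm <- cx$atoms$name[idx]
    for (a in names(sc)) {
      k <- idx[nm == a]
      if (length(k)) cx$xyz[k[1], ] <- sc[[a]]
    }
  }
  lab <- if (aa %in% IONIZABLE_AA) label else cx$residues$prot[i]
  set_protonation(cx, i, lab)
}

apply_rotamer <- function(cx, i, rot) {
  cx <- set_residue_conformation(cx, i, rot$chi, rot$label)
  cx$residues$e_dun[i] <- -log(rot$prob)
  cx
}

# ---- rotamer interaction blocks ---------------------------------------------

# A block is the rigid side-chain atom set of one rotamer: coordinates plus
# the parameter columns needed by the pairwise terms, with donor-base
# coordinates stored per hydrogen (the block never bends internally).
build_rotamer_block <- function(cx, i, rot) {
  aa <- cx$residues$aa[i]
  chain <- cx$residues$chain[i]
  label <- if (aa %in% IONIZABLE_AA) rot$label else "fixed"
  key <- if (aa %in% IONIZABLE_AA) rot$label else aa
  bb <- residue_bb_coords(cx, i)
  if (aa %in% TEMPLATED_AA && length(rot$chi)) {
    sc <- sidechain_coords(aa, bb, rot$chi)
  } else {
    idx <- which(cx$atoms$res == i & !cx$atoms$is_bb & !cx$atoms$is_h)
    sc <- stats::setNames(lapply(idx, function(k) cx$xyz[k, ]),
                          cx$atoms$name[idx])
  }
  all_heavy <- c(bb, sc)
  hs <- list()
  for (row in sidechain_h_topology(aa, key)) {
    refs <- list(all_heavy[[row$r1]], all_heavy[[row$r2]], all_heavy[[row$r3]])
    if (any(vapply(refs, is.null, logical(1)))) next
    hs[[row$name]] <- list(
      xyz = place_atom(refs[[1]], refs[[2]], refs[[3]], row$b, row$a, row$t),
      base = all_heavy[[row$r3]])
  }
  nm <- c(names(sc), names(hs))
  n <- length(nm)
  if (!n) {
    return(list(xyz = matrix(0, 0, 3), n = 0, res = i, chain = chain,
                e_dun = -log(rot$prob),
                e_ph = ph_energy(if (aa %in% IONIZABLE_AA) rot$label else "fixed",
                                 cx$ph)))
  }
  xyz <- rbind(if (length(sc)) do.call(rbind, sc),
               if (length(hs)) do.call(rbind, lapply(hs, `[[`, "xyz")))
  el <- c(vapply(names(sc), element_from_name, ""), rep("H", length(hs)))
  charge <- vapply(nm, function(a) atom_charge(aa, key, a), 0)
  radius <- eps <- dgfree <- vol <- numeric(n); lambda <- rep(3.5, n)
  acc <- logical(n)
  for (k in seq_len(n)) {
    lj <- .lj_by_element[[el[k]]]; if (is.null(lj)) lj <- .lj_by_element$X
    radius[k] <- lj[["radius"]]; eps[k] <- lj[["eps"]]
    lk <- .lk_classes[[lk_class_for(aa, key, nm[k], el[k])]]
    dgfree[k] <- lk[["dgfree"]]; lambda[k] <- lk[["lambda"]]; vol[k] <- lk[["vol"]]
    acc[k] <- el[k] != "H" && is_acceptor_atom(aa, key, nm[k])
  }
  don_xyz <- matrix(NA_real_, n, 3)
  if (length(hs)) {
    hk <- length(sc) + seq_along(hs)
    don_xyz[hk, ] <- do.call(rbind, lapply(hs, `[[`, "base"))
  }
  list(xyz = xyz, n = n, res = i, chain = chain, name = nm,
       charge = charge, radius = radius, eps = eps, dgfree = dgfree,
       lambda = lambda, vol = vol, is_h = el == "H", acc = acc,
       don_xyz = don_xyz, e_dun = -log(rot$prob),
       e_ph = ph_energy(if (aa %in% IONIZABLE_AA) rot$label else "fixed", cx$ph))
}

# context block: all backbone atoms plus all atoms of non-designable residues
build_context_block <- function(cx, designable) {
  A <- cx$atoms
  keep <- A$is_bb | !(A$res %in% designable)
  idx <- which(keep)
  don_xyz <- matrix(NA_real_, length(idx), 3)
  db <- A$don_base[idx]
  has <- !is.na(db)
  don_xyz[has, ] <- cx$xyz[db[has], , drop = FALSE]
  list(xyz = cx$xyz[idx, , drop = FALSE], n = length(idx),
       res = A$res[idx], chain = cx$residues$chain[A$res[idx]],
       name = A$name[idx], charge = A$charge[idx], radius = A$radius[idx],
       eps = A$eps[idx], dgfree = A$dgfree[idx], lambda = A$lambda[idx],
       vol = A$vol[idx], is_h = A$is_h[idx], acc = A$acc[idx],
       don_xyz = don_xyz, e_dun = 0, e_ph = 0)
}

# weighted interaction energy between two blocks (atr/rep/sol/elec/hb)
block_energy <- function(a, b, w) {
  if (a$n == 0 || b$n == 0) return(0)
  d2 <- outer(rowSums(a$xyz^2), rowSums(b$xyz^2), "+") -
    2 * tcrossprod(a$xyz, b$xyz)
  d2[d2 < 1e-12] <- 1e-12
  sel <- d2 < PAIR_CUTOFF^2
  if (!any(sel)) return(0)
  pr <- which(sel, arr.ind = TRUE)
  ia <- pr[, 1]; ib <- pr[, 2]
  ra <- if (length(a$res) > 1) a$res[ia] else rep(a$res, length(ia))
  rb <- if (length(b$res) > 1) b$res[ib] else rep(b$res, length(ib))
  ca <- if (length(a$chain) > 1) a$chain[ia] else rep(a$chain, length(ia))
  cb <- if (length(b$chain) > 1) b$chain[ib] else rep(b$chain, length(ib))
  keep <- !(ra == rb | (ca == cb & abs(ra - rb) == 1L))
  if (!any(keep)) return(0)
  ia <- ia[keep]; ib <- ib[keep]
  d <- sqrt(d2[sel][keep])
  rmin <- a$radius[ia] + b$radius[ib]
  e <- sqrt(a$eps[ia] * b$eps[ib])
  sr6 <- (rmin / d)^6
  lj <- e * (sr6^2 - 2 * sr6)
  inside <- d < rmin
  atr <- sum(ifelse(inside, -e, lj))
  rep_ <- sum(ifelse(inside, lj + e, 0))
  cg <- 2 * pi^1.5
  xi <- (d - a$radius[ia]) / a$lambda[ia]
  xj <- (d - b$radius[ib]) / b$lambda[ib]
  sol <- -sum(a$dgfree[ia] * b$vol[ib] * exp(-xi^2) / (cg * a$lambda[ia] * d^2) +
              b$dgfree[ib] * a$vol[ia] * exp(-xj^2) / (cg * b$lambda[ib] * d^2))
  qq <- a$charge[ia] * b$charge[ib]
  nz <- qq != 0 & d < ELEC_RMAX
  elec <- if (any(nz)) {
    rc <- pmax(d[nz], ELEC_RMIN)
    sum(COULOMB_K * qq[nz] * (1 / (10 * rc^2) - 1 / (10 * ELEC_RMAX^2)))
  } else 0
  hb <- .block_hbond(a, b, ia, ib, d) + .block_hbond(b, a, ib, ia, d)
  w[["atr"]] * atr + w[["rep"]] * rep_ + w[["sol"]] * sol +
    w[["elec"]] * elec + w[["hb"]] * hb
}

# hydrogen bonds with donors in `a` and acceptors in `b`, over the
# preselected pair list
.block_hbond <- function(a, b, ia, ib, d) {
  ok <- a$is_h[ia] & !is.na(a$don_xyz[ia, 1]) & b$acc[ib] & d < HB_DMAX
  if (!any(ok)) return(0)
  ia <- ia[ok]; ib <- ib[ok]; d <- d[ok]
  u <- a$don_xyz[ia, , drop = FALSE] - a$xyz[ia, , drop = FALSE]
  v <- b$xyz[ib, , drop = FALSE] - a$xyz[ia, , drop = FALSE]
  ct <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  theta <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  f <- pmin(0, -1.5 * (1 - ((d - 1.9) / 0.7)^2))
  g <- pmin(1, pmax(0, (theta - 120) / 60))
  sum(f * g)
}

# ---- packing ----------------------------------------------------------------

#' Packer task description
#'
#' @param designable integer vector of residue indices to repack.
#' @param ph solution pH.
#' @param weights a [score_weights()] set.
#' @param t_start,t_end simulated-annealing temperature schedule (REU).
#' @param n_sweeps annealing sweeps.
#' @param seed integer seed.
#' @param exhaustive_limit combined rotamer-combination count up to which
#'   the packer enumerates exhaustively instead of annealing (default
#'   2000; set 0 to force annealing).
#' @return list of class `packer_task`.
#' @export
packer_task <- function(designable, ph = 7, weights = score_weights("phdock"),
                        t_start = 5, t_end = 0.3, n_sweeps = 20, seed = 1,
                        exhaustive_limit = 2000) {
  if (t_start < t_end || t_end <= 0)
    stop("domain error: need t_start >= t_end > 0")
  if (n_sweeps < 1) stop("domain error: n_sweeps must be >= 1")
  structure(list(designable = as.integer(designable), ph = ph,
                 weights = weights, t_start = t_start, t_end = t_end,
                 n_sweeps = n_sweeps, seed = seed,
                 exhaustive_limit = exhaustive_limit),
            class = "packer_task")
}

#' Pack side chains with protonation-state sampling
#'
#' Combinatorial optimization over one rotamer-by-protonation choice per
#' designable residue, scored with the weighted pairwise terms plus the
#' rotamer-probability and pH terms. Small systems (up to 2000 combined
#' rotamer combinations) are solved by exhaustive enumeration; larger ones
#' by simulated-annealing Monte Carlo with best-visited tracking.
#' Deterministic for a fixed seed; ties broken by lowest rotamer index.
#'
#' @param cx fullatom `ph_complex`.
#' @param task a [packer_task()].
#' @return the repacked complex.
#' @export
pack_sidechains <- function(cx, task) {
  if (cx$representation != "fullatom")
    stop("state error: pack_sidechains requires fullatom representation")
  design <- task$designable
  if (!length(design)) return(cx)
  cx_ph <- cx; cx_ph$ph <- task$ph
  w <- task$weights
  rotsets <- lapply(design, function(i) build_rotamers(cx_ph, i, task$ph))
  blocks <- lapply(seq_along(design), function(k)
    lapply(rotsets[[k]], function(r) build_rotamer_block(cx_ph, design[k], r)))
  ctx <- build_context_block(cx_ph, design)
  nres <- length(design)
  nrot <- vapply(blocks, length, 0L)

  # one-body energies (interaction with context + rotamer prior + pH term)
  e1 <- lapply(seq_len(nres), function(k)
    vapply(blocks[[k]], function(b)
      block_energy(b, ctx, w) + w[["dun"]] * b$e_dun + w[["ph"]] * b$e_ph, 0))

  # residue-pair proximity prefilter (side chains out of reach never interact)
  ca <- t(vapply(design, function(i) {
    idx <- which(cx$atoms$res == i & cx$atoms$name == "CA")
    cx$xyz[idx[1], ]
  }, numeric(3)))
  near <- function(k, l) sum((ca[k, ] - ca[l, ])^2) < 20^2

  e2 <- vector("list", nres * nres)  # lazy pair tables
  get_e2 <- function(k, l, rk, rl) {
    if (k > l) { tmp <- k; k <- l; l <- tmp; tmp <- rk; rk <- rl; rl <- tmp }
    if (!near(k, l)) return(0)
    key <- (k - 1) * nres + l
    tab <- e2[[key]]
    if (is.null(tab)) {
      tab <- matrix(NA_real_, nrot[k], nrot[l])
      e2[[key]] <<- tab
    }
    v <- tab[rk, rl]
    if (is.na(v)) {
      v <- block_energy(blocks[[k]][[rk]], blocks[[l]][[rl]], w)
      e2[[key]][rk, rl] <<- v
    }
    v
  }

  total_combos <- prod(as.double(nrot))
  limit <- if (is.null(task$exhaustive_limit)) 2000 else task$exhaustive_limit
  assign_best <- NULL
  if (total_combos <= limit) {
    combos <- as.matrix(expand.grid(lapply(nrot, seq_len),
                                    KEEP.OUT.ATTRS = FALSE))
    energies <- apply(combos, 1, function(as_) {
      e <- sum(vapply(seq_len(nres), function(k) e1[[k]][as_[k]], 0))
      if (nres > 1)
        for (k in seq_len(nres - 1))
          for (l in (k + 1):nres)
            e <- e + get_e2(k, l, as_[k], as_[l])
      e
    })
    assign_best <- combos[which.min(energies), ]
  } else {
    assign_best <- with_seed(task$seed, {
      cur <- vapply(rotsets, function(rs)
        which(vapply(rs, `[[`, FALSE, "input"))[1], 0L)
      cur_e1 <- vapply(seq_len(nres), function(k) e1[[k]][cur[k]], 0)
      best <- cur;
      etot <- function(as_) {
        e <- sum(vapply(seq_len(nres), function(k) e1[[k]][as_[k]], 0))
        if (nres > 1)
          for (k in seq_len(nres - 1))
            for (l in (k + 1):nres) e <- e + get_e2(k, l, as_[k], as_[l])
        e
      }
      e_cur <- etot(cur); e_best <- e_cur
      temps <- task$t_start * (task$t_end / task$t_start)^
        (seq(0, 1, length.out = task$n_sweeps))
      for (Tt in temps) {
        for (k in sample(seq_len(nres))) {
          if (nrot[k] < 2) next
          prop <- sample(seq_len(nrot[k] - 1), 1)
          prop <- if (prop >= cur[k]) prop + 1L else prop
          dE <- e1[[k]][prop] - e1[[k]][cur[k]]
          for (l in seq_len(nres)) if (l != k)
            dE <- dE + get_e2(k, l, prop, cur[l]) - get_e2(k, l, cur[k], cur[l])
          if (dE < 0 || stats::runif(1) < exp(-dE / Tt)) {
            cur[k] <- prop; e_cur <- e_cur + dE
            if (e_cur < e_best - 1e-12) { e_best <- e_cur; best <- cur }
          }
        }
      }
      best
    })
  }
  for (k in seq_len(nres))
    cx <- apply_rotamer(cx, design[k], rotsets[[k]][[assign_best[k]]])
  cx
}

# ---- minimization -----------------------------------------------------------

#' Minimize rigid-body and/or side-chain torsion degrees of freedom
#'
#' Gradient-free (Nelder-Mead) local descent over the ligand rigid-body
#' placement and/or the chi angles of selected residues, using the
#' minimization weight set (repulsive van der Waals weight raised).
#' Protonation states are held fixed. The returned score never exceeds the
#' input score.
#'
#' @param cx fullatom `ph_complex`.
#' @param dofs `"rigid_body"`, `"sidechain_chi"` or `"both"`.
#' @param weights a [score_weights()] set (default `"phdock_min"`).
#' @param max_iter maximum objective evaluations (must be >= 1).
#' @param chi_residues residue indices whose chi angles move (default: the
#'   ionizable interface residues).
#' @param ph solution pH.
#' @return the minimized complex.
#' @export
minimize_complex <- function(cx, dofs = c("both", "rigid_body", "sidechain_chi"),
                             weights = score_weights("phdock_min"),
                             max_iter = 60, chi_residues = NULL, ph = cx$ph) {
  dofs <- match.arg(dofs)
  if (max_iter < 1) stop("domain error: max_iter must be >= 1")
  if (cx$representation != "fullatom")
    stop("state error: minimize_complex requires fullatom representation")
  do_rb <- dofs %in% c("both", "rigid_body")
  do_chi <- dofs %in% c("both", "sidechain_chi")
  if (do_chi && is.null(chi_residues)) {
    iface <- interface_residues(cx, 4.0)
    chi_residues <- iface[cx$residues$prot[iface] != "fixed"]
  }
  chi_residues <- chi_residues[vapply(chi_residues, function(i)
    cx$residues$aa[i] %in% TEMPLATED_AA &&
      length(CHI_ATOMS[[cx$residues$aa[i]]]) > 0 &&
      !is.null(measure_chi(cx, i)), FALSE)]
  chi0 <- lapply(chi_residues, function(i) measure_chi(cx, i))
  lig_idx <- partner_atom_idx(cx, "ligand")
  lig_cen <- colMeans(cx$xyz[lig_idx, , drop = FALSE])

  par0 <- c(if (do_rb) rep(0, 6),
            if (do_chi && length(chi0)) unlist(chi0))
  build <- function(par) {
    out <- cx
    off <- 0
    if (do_rb) {
      tr <- par[1:3]; rv <- par[4:6]; off <- 6
      ang <- vnorm(rv)
      R <- if (ang > 1e-9) rotation_about_axis(rv, ang) else diag(3)
      x <- out$xyz[lig_idx, , drop = FALSE]
      x <- sweep(x, 2, lig_cen)
      x <- x %*% R
      x <- sweep(x, 2, lig_cen + tr, "+")
      out$xyz[lig_idx, ] <- x
    }
    if (do_chi && length(chi0)) {
      for (k in seq_along(chi_residues)) {
        nchi <- length(chi0[[k]])
        ch <- par[off + seq_len(nchi)]; off <- off + nchi
        out <- set_residue_conformation(out, chi_residues[k], ch,
                                        out$residues$prot[chi_residues[k]])
      }
    }
    out
  }
  obj <- function(par) score_complex(build(par), weights, ph)$total
  s0 <- score_complex(cx, weights, ph)$total
  if (!length(par0)) return(cx)
  scale <- c(if (do_rb) c(rep(0.25, 3), rep(2, 3)),
             if (do_chi && length(chi0)) rep(10, length(unlist(chi0))))
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = max_iter, parscale = scale,
                                     reltol = 1e-6))
  if (fit$value < s0) build(fit$par) else cx
}
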