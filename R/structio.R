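# Two-partner complex container and PDB input/output.
#
# A `ph_complex` keeps a flat atom table plus an n x 3 coordinate matrix and
# a per-residue table carrying the protonation label of every ionizable
# residue. Residue numbering follows the source PDB; a dense 1-based residue
# index (`res` column of the atom table) is used internally.

BB_NAMES <- c("N", "CA", "C", "O", "OXT", "H")

new_ph_complex <- function(atoms, xyz, residues, partner_split,
                           representation = "fullatom", ph = 7.0) {
  stopifnot(nrow(atoms) == nrow(xyz))
  if (ph < 0 || ph > 14) stop("domain error: ph must lie in [0, 14]")
  structure(list(atoms = atoms, xyz = xyz, residues = residues,
                 partner_split = partner_split,
                 representation = representation, ph = ph),
            class = "ph_complex")
}

is.ph_complex <- function(x) inherits(x, "ph_complex")

#' @export
print.ph_complex <- function(x, ...) {
  nrec <- sum(x$residues$partner == "receptor")
  nlig <- sum(x$residues$partner == "ligand")
  cat(sprintf("ph_complex: %d residues / %d atoms (%s representation)\n",
              nrow(x$residues), nrow(x$atoms), x$representation))
  cat(sprintf("  receptor: %d residues, ligand: %d residues, pH %.2f\n",
              nrec, nlig, x$ph))
  ion <- x$residues$prot != "fixed"
  if (any(ion)) {
    r <- x$residues[ion, ]
    cat("  ionizable:",
        paste(sprintf("%s%d:%s(%s)", r$chain, r$resnum, r$aa, r$prot),
              collapse = " "), "\n")
  }
  invisible(x)
}

# the Henderson-Hasselbalch majority state at a given pH, as a label
default_label <- function(aa, ph, table = pka_table()) {
  if (!aa %in% IONIZABLE_AA) return("fixed")
  p <- protonation_probability(aa, ph, table)
  labs <- PROT_LABELS[[aa]]
  if (p >= 0.5) {
    switch(aa, ASP = "ASH2", GLU = "GLH2", HIS = "HIP", TYR = "TYR",
           LYS = "LYS")
  } else {
    switch(aa, ASP = "ASP", GLU = "GLU", HIS = "HIE", TYR = "TYM",
           LYS = "LYN")
  }
}

# ---- assembly ---------------------------------------------------------------

# Build polar hydrogens for one residue given heavy-atom coordinates.
# `heavy` is a named list of 3-vectors; `prev` carries C and O of the
# preceding residue in the same chain (or NULL). Hydrogens present in
# `keep_h` (named list) are retained verbatim when their name is expected.
residue_build_h <- function(aa, label, heavy, prev = NULL, keep_h = list()) {
  out <- list()
  # backbone amide H (not for chain-initial residues or Pro)
  if (!is.null(prev) && aa != "PRO" &&
      all(c("N") %in% names(heavy)) &&
      all(c("C", "O") %in% names(prev))) {
    if ("H" %in% names(keep_h)) {
      out[["H"]] <- list(xyz = keep_h[["H"]], base = "N")
    } else {
      out[["H"]] <- list(
        xyz = place_atom(prev$O, prev$C, heavy$N, 1.01, 119.0, 180),
        base = "N")
    }
  }
  for (row in sidechain_h_topology(aa, label)) {
    refs <- list(heavy[[row$r1]], heavy[[row$r2]], heavy[[row$r3]])
    if (any(vapply(refs, is.null, logical(1)))) next
    if (row$name %in% names(keep_h)) {
      out[[row$name]] <- list(xyz = keep_h[[row$name]], base = row$r3)
    } else {
      out[[row$name]] <- list(
        xyz = place_atom(refs[[1]], refs[[2]], refs[[3]],
                         row$b, row$a, row$t),
        base = row$r3)
    }
  }
  out
}

# Assemble a fullatom complex from a list of residues.
# Each element: list(aa, chain, resnum, heavy = named list of 3-vectors,
#                    label = NULL, hydro = named list of 3-vectors (optional))
assemble_complex <- function(res_list, partner_split, ph = 7.0,
                             table = pka_table()) {
  chains <- unique(vapply(res_list, `[[`, "", "chain"))
  missing <- setdiff(names(partner_split), chains)
  if (length(missing))
    stop("configuration error: chain(s) not present in structure: ",
         paste(missing, collapse = ", "))
  if (!all(unname(partner_split) %in% c("receptor", "ligand")))
    stop("configuration error: partner roles must be receptor/ligand")

  res_rows <- list(); atom_rows <- list(); xyz_rows <- list()
  prev_by_chain <- list()
  for (i in seq_along(res_list)) {
    r <- res_list[[i]]
    aa <- r$aa
    label <- r$label
    if (is.null(label)) label <- default_label(aa, ph, table)
    heavy <- r$heavy
    prev <- prev_by_chain[[r$chain]]
    hs <- residue_build_h(aa, label, heavy, prev,
                          keep_h = if (is.null(r$hydro)) list() else r$hydro)
    nm <- c(names(heavy), names(hs))
    if (anyDuplicated(nm))
      stop("format error: duplicate atom names in residue ", r$chain, r$resnum)
    n_h <- length(hs)
    xyz <- rbind(do.call(rbind, lapply(heavy, as.numeric)),
                 if (n_h) do.call(rbind, lapply(hs, function(h) h$xyz)))
    atom_rows[[i]] <- data.frame(
      res = i, name = nm,
      element = c(vapply(names(heavy), element_from_name, ""),
                  rep("H", n_h)),
      h_base = c(rep(NA_character_, length(heavy)),
                 vapply(hs, function(h) h$base, "")),
      stringsAsFactors = FALSE)
    xyz_rows[[i]] <- xyz
    res_rows[[i]] <- data.frame(aa = aa, chain = r$chain, resnum = r$resnum,
                                prot = label, e_dun = 0,
                                stringsAsFactors = FALSE)
    prev_by_chain[[r$chain]] <- list(C = heavy$C, O = heavy$O)
  }
  atoms <- do.call(rbind, atom_rows)
  residues <- do.call(rbind, res_rows)
  residues$partner <- unname(partner_split[residues$chain])
  if (any(is.na(residues$partner)))
    stop("configuration error: chain(s) without partner assignment: ",
         paste(unique(residues$chain[is.na(residues$partner)]), collapse = ", "))
  xyz <- do.call(rbind, xyz_rows)
  dimnames(xyz) <- NULL
  cx <- new_ph_complex(atoms, xyz, residues, partner_split, "fullatom", ph)
  refresh_params(cx)
}

# Re-derive per-atom parameters (charge, LJ, LK, donor/acceptor flags) from
# the current residue labels. `only` limits the update to one residue's
# atoms (used after a protonation change; donor indices of that residue are
# still recomputed against the full table).
refresh_params <- function(cx, only = NULL) {
  a <- cx$atoms
  res <- cx$residues
  rows <- if (is.null(only)) seq_len(nrow(a)) else which(a$res %in% only)
  aa_all <- res$aa[a$res]; label_all <- res$prot[a$res]
  label_all[label_all == "fixed"] <- aa_all[label_all == "fixed"]
  if (is.null(only)) {
    a$charge <- 0; a$radius <- 0; a$eps <- 0; a$dgfree <- 0
    a$lambda <- 3.5; a$vol <- 0
    a$is_h <- a$element == "H"
    a$is_bb <- a$name %in% BB_NAMES
    a$acc <- FALSE
    a$don_base <- NA_integer_
  }
  for (i in rows) {
    nm <- a$name[i]; el <- a$element[i]
    a$is_h[i] <- el == "H"
    a$is_bb[i] <- nm %in% BB_NAMES
    if (nm == "CEN") {
      a$charge[i] <- 0; a$radius[i] <- 2.0; a$eps[i] <- 0
      a$dgfree[i] <- 0; a$lambda[i] <- 3.5; a$vol[i] <- 0
      a$acc[i] <- FALSE; a$don_base[i] <- NA_integer_
      next
    }
    a$charge[i] <- atom_charge(aa_all[i], label_all[i], nm)
    lj <- .lj_by_element[[el]]
    if (is.null(lj)) lj <- .lj_by_element[["X"]]
    a$radius[i] <- lj[["radius"]]; a$eps[i] <- lj[["eps"]]
    lk <- .lk_classes[[lk_class_for(aa_all[i], label_all[i], nm, el)]]
    a$dgfree[i] <- lk[["dgfree"]]; a$lambda[i] <- lk[["lambda"]]
    a$vol[i] <- lk[["vol"]]
    a$acc[i] <- el != "H" && is_acceptor_atom(aa_all[i], label_all[i], nm)
    a$don_base[i] <- NA_integer_
  }
  if (any(a$radius[rows] <= 0))
    stop("parameterization error: non-positive LJ radius")
  hi <- rows[a$is_h[rows]]
  for (i in hi) {
    base <- a$h_base[i]
    cand <- which(a$res == a$res[i] & a$name == base)
    if (length(cand)) a$don_base[i] <- cand[1]
  }
  cx$atoms <- a
  cx
}

# ---- protonation changes ----------------------------------------------------

# Assign a protonation label to residue i, rebuilding its polar hydrogens.
set_protonation <- function(cx, i, label) {
  if (cx$representation != "fullatom")
    stop("state error: protonation changes require fullatom representation")
  aa <- cx$residues$aa[i]
  if (label != "fixed" && label_res_type(label) != aa)
    stop("domain error: label ", label, " incompatible with ", aa)
  cx$residues$prot[i] <- label
  # drop this residue's side-chain hydrogens, keep backbone H
  drop <- which(cx$atoms$res == i & cx$atoms$element == "H" &
                cx$atoms$name != "H")
  if (length(drop)) {
    cx$atoms <- cx$atoms[-drop, , drop = FALSE]
    cx$xyz <- cx$xyz[-drop, , drop = FALSE]
  }
  idx <- which(cx$atoms$res == i)
  heavy_idx <- idx[cx$atoms$element[idx] != "H"]
  heavy <- stats::setNames(
    lapply(heavy_idx, function(k) cx$xyz[k, ]),
    cx$atoms$name[heavy_idx])
  rows <- sidechain_h_topology(aa, label)
  for (row in rows) {
    refs <- list(heavy[[row$r1]], heavy[[row$r2]], heavy[[row$r3]])
    if (any(vapply(refs, is.null, logical(1)))) next
    xyz_h <- place_atom(refs[[1]], refs[[2]], refs[[3]], row$b, row$a, row$t)
    cx$atoms <- rbind(cx$atoms,
      data.frame(res = i, name = row$name, element = "H", h_base = row$r3,
                 charge = 0, radius = 0, eps = 0, dgfree = 0, lambda = 3.5,
                 vol = 0, is_h = TRUE, is_bb = FALSE, acc = FALSE,
                 don_base = NA_integer_, stringsAsFactors = FALSE))
    cx$xyz <- rbind(cx$xyz, matrix(xyz_h, 1, 3))
  }
  rownames(cx$atoms) <- NULL
  cx <- refresh_params(cx, only = i)
  recompute_don_base(cx)  # row indices shifted by the drop/append above
}

# recompute donor-base indices for every hydrogen (they store row indices,
# which move whenever atom rows are inserted or removed)
recompute_don_base <- function(cx) {
  a <- cx$atoms
  a$don_base <- NA_integer_
  hi <- which(a$is_h)
  key <- paste(a$res, a$name)
  for (i in hi) {
    j <- match(paste(a$res[i], a$h_base[i]), key)
    if (!is.na(j)) a$don_base[i] <- j
  }
  cx$atoms <- a
  cx
}

# ---- PDB I/O ----------------------------------------------------------------

#' Read a two-partner complex from a PDB file
#'
#' Waters and HETATM records are dropped, alternate locations are resolved
#' to the highest occupancy (ties broken by first record), and polar
#' hydrogens are (re)built at ideal geometry. Hydrogens present in the file
#' whose names match the expected set for the inferred protonation state are
#' retained; all others are discarded. Protonation labels are inferred from
#' the hydrogen records when any are present, otherwise set to the
#' Henderson-Hasselbalch majority state at `ph`.
#'
#' @param path PDB file path.
#' @param partner_split named character vector mapping chain id to
#'   `"receptor"` or `"ligand"`, e.g. `c(A = "receptor", B = "ligand")`.
#' @param ph solution pH used for default protonation labels.
#' @return a `ph_complex` in fullatom representation.
#' @export
read_pdb <- function(path, partner_split, ph = 7.0) {
  if (!file.exists(path)) stop("configuration error: file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("format error: unparsable PDB: ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (!nrow(at)) stop("format error: no ATOM records in ", path)
  missing <- setdiff(names(partner_split), unique(at$chain))
  if (length(missing))
    stop("configuration error: chain(s) not in file: ",
         paste(missing, collapse = ", "))
  at <- at[at$chain %in% names(partner_split), , drop = FALSE]
  # altloc resolution: highest occupancy, ties by first record
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(match(key, unique(key)), -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
           drop = FALSE]
  # restore file order within residues
  at <- at[order(match(paste(at$chain, at$resno, at$insert),
                       unique(paste(at$chain, at$resno, at$insert)))), ,
           drop = FALSE]

  rid <- paste(at$chain, at$resno, at$insert)
  res_list <- list()
  for (u in unique(rid)) {
    rows <- at[rid == u, , drop = FALSE]
    el <- vapply(rows$elety, element_from_name, "")
    heavy <- rows[el != "H", , drop = FALSE]
    hyd <- rows[el == "H", , drop = FALSE]
    heavy_l <- stats::setNames(
      lapply(seq_len(nrow(heavy)),
             function(k) c(heavy$x[k], heavy$y[k], heavy$z[k])),
      heavy$elety)
    hyd_l <- stats::setNames(
      lapply(seq_len(nrow(hyd)),
             function(k) c(hyd$x[k], hyd$y[k], hyd$z[k])),
      hyd$elety)
    aa <- rows$resid[1]
    label <- if (aa %in% IONIZABLE_AA)
      infer_label(aa, names(hyd_l), nrow(hyd) > 0 || any(el == "H"),
                  heavy_l, hyd_l, ph)
    else "fixed"
    res_list[[length(res_list) + 1L]] <- list(
      aa = aa, chain = rows$chain[1], resnum = rows$resno[1],
      heavy = heavy_l, hydro = hyd_l, label = label)
  }
  assemble_complex(res_list, partner_split, ph = ph)
}

# infer the protonation label of an ionizable residue from hydrogen names
infer_label <- function(aa, hnames, has_h, heavy, hyd, ph) {
  if (!has_h) return(default_label(aa, ph))
  if (aa == "HIS") {
    hd1 <- "HD1" %in% hnames; he2 <- "HE2" %in% hnames
    if (hd1 && he2) return("HIP")
    if (hd1) return("HID")
    if (he2) return("HIE")
    return(default_label(aa, ph))
  }
  if (aa == "ASP") {
    if (!"HD2" %in% hnames) return("ASP")
    h <- hyd[["HD2"]]
    d1 <- if (!is.null(heavy$OD1)) vnorm(h - heavy$OD1) else Inf
    d2 <- if (!is.null(heavy$OD2)) vnorm(h - heavy$OD2) else Inf
    return(if (d1 < d2) "ASH1" else "ASH2")
  }
  if (aa == "GLU") {
    if (!"HE2" %in% hnames) return("GLU")
    h <- hyd[["HE2"]]
    d1 <- if (!is.null(heavy$OE1)) vnorm(h - heavy$OE1) else Inf
    d2 <- if (!is.null(heavy$OE2)) vnorm(h - heavy$OE2) else Inf
    return(if (d1 < d2) "GLH1" else "GLH2")
  }
  if (aa == "TYR") return(if ("HH" %in% hnames) "TYR" else "TYM")
  if (aa == "LYS") return(if ("HZ3" %in% hnames) "LYS" else "LYN")
  "fixed"
}

#' Write a complex to a PDB file
#'
#' Standard residue names are used throughout; the protonation state is
#' encoded by the hydrogen records present (e.g. HD1+HE2 for doubly
#' protonated His, HD2/HE2 for protonated Asp/Glu, absent HH for
#' deprotonated Tyr, absent HZ3 for neutral Lys).
#'
#' @param cx a fullatom `ph_complex`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(cx, path) {
  if (cx$representation != "fullatom")
    stop("state error: write_pdb requires fullatom representation")
  a <- cx$atoms
  res <- cx$residues
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(cx$xyz)),
                   resno = res$resnum[a$res],
                   chain = res$chain[a$res],
                   resid = res$aa[a$res],
                   elety = a$name,
                   eleno = seq_len(nrow(a)),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

# ---- representation changes -------------------------------------------------

#' Convert to centroid (coarse-grained) representation
#'
#' Side-chain atoms of each residue are replaced by a single pseudo-atom
#' (`CEN`) at the side-chain heavy-atom centroid; backbone N, CA, C, O are
#' kept and hydrogens dropped. Gly places the pseudo-atom on CA.
#'
#' @param cx fullatom `ph_complex`.
#' @return centroid-representation `ph_complex`.
#' @export
to_centroid <- function(cx) {
  if (cx$representation != "fullatom")
    stop("state error: to_centroid requires fullatom input")
  keep_names <- c("N", "CA", "C", "O")
  atom_rows <- list(); xyz_rows <- list()
  for (i in seq_len(nrow(cx$residues))) {
    idx <- which(cx$atoms$res == i)
    nm <- cx$atoms$name[idx]
    bb <- idx[nm %in% keep_names]
    sc <- idx[!(nm %in% BB_NAMES) & !cx$atoms$is_h[idx]]
    cen <- if (length(sc)) colMeans(cx$xyz[sc, , drop = FALSE])
           else cx$xyz[idx[nm == "CA"], ]
    atom_rows[[i]] <- data.frame(
      res = i, name = c(cx$atoms$name[bb], "CEN"),
      element = c(cx$atoms$element[bb], "X"),
      h_base = NA_character_, stringsAsFactors = FALSE)
    xyz_rows[[i]] <- rbind(cx$xyz[bb, , drop = FALSE], matrix(cen, 1, 3))
  }
  atoms <- do.call(rbind, atom_rows)
  xyz <- do.call(rbind, xyz_rows); dimnames(xyz) <- NULL
  out <- new_ph_complex(atoms, xyz, cx$residues, cx$partner_split,
                        "centroid", cx$ph)
  refresh_params(out)
}

#' Restore fullatom representation after rigid-body moves
#'
#' Side chains (and protonation labels) are taken from the fullatom
#' `reference` and placed on the current rigid-body pose: each partner's
#' backbone (N, CA, C) defines the least-squares transform applied to the
#' reference copy of that partner.
#'
#' @param cen centroid-representation `ph_complex` after rigid-body moves.
#' @param reference fullatom `ph_complex` with identical sequence.
#' @return fullatom `ph_complex`.
#' @export
restore_fullatom <- function(cen, reference) {
  if (cen$representation != "centroid")
    stop("state error: restore_fullatom expects a centroid complex")
  if (reference$representation != "fullatom")
    stop("configuration error: reference must be fullatom")
  if (nrow(cen$residues) != nrow(reference$residues) ||
      !all(cen$residues$aa == reference$residues$aa) ||
      !all(cen$residues$chain == reference$residues$chain) ||
      !all(cen$residues$resnum == reference$residues$resnum))
    stop("configuration error: sequence mismatch between complex and reference")
  out <- reference
  out$ph <- cen$ph
  for (p in c("receptor", "ligand")) {
    r_idx <- which(reference$residues$partner == p)
    bb_ref <- backbone_coords(reference, r_idx)
    bb_cur <- backbone_coords(cen, r_idx)
    fit <- kabsch(bb_ref, bb_cur)
    at_idx <- which(reference$atoms$res %in% r_idx)
    out$xyz[at_idx, ] <- apply_transform(reference$xyz[at_idx, , drop = FALSE],
                                         fit$R, fit$t)
  }
  out
}

# N/CA/C coordinates for a residue index set, in residue order
backbone_coords <- function(cx, r_idx) {
  rows <- list()
  for (i in r_idx) {
    idx <- which(cx$atoms$res == i & cx$atoms$name %in% c("N", "CA", "C"))
    idx <- idx[order(match(cx$atoms$name[idx], c("N", "CA", "C")))]
    rows[[length(rows) + 1L]] <- cx$xyz[idx, , drop = FALSE]
  }
  do.call(rbind, rows)
}

# ---- partner helpers --------------------------------------------------------

partner_atom_idx <- function(cx, partner) {
  which(cx$residues$partner[cx$atoms$res] == partner)
}

# apply a rigid transform to one partner's atoms
transform_partner <- function(cx, partner, R, t) {
  idx <- partner_atom_idx(cx, partner)
  cx$xyz[idx, ] <- apply_transform(cx$xyz[idx, , drop = FALSE], R, t)
  cx
}

translate_partner <- function(cx, partner, v) {
  idx <- partner_atom_idx(cx, partner)
  cx$xyz[idx, ] <- sweep(cx$xyz[idx, , drop = FALSE], 2, v, "+")
  cx
}

# extract one partner as a standalone complex (keeps both labels in split)
subset_partner <- function(cx, partner) {
  r_idx <- which(cx$residues$partner == partner)
  a_idx <- which(cx$atoms$res %in% r_idx)
  atoms <- cx$atoms[a_idx, , drop = FALSE]
  atoms$res <- match(atoms$res, r_idx)
  atoms$don_base <- NA_integer_  # recomputed by refresh_params
  residues <- cx$residues[r_idx, , drop = FALSE]
  rownames(residues) <- NULL; rownames(atoms) <- NULL
  out <- new_ph_complex(atoms, cx$xyz[a_idx, , drop = FALSE], residues,
                        cx$partner_split, cx$representation, cx$ph)
  refresh_params(out)
}
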