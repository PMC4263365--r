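# Packaged atom-parameter tables and ideal-geometry residue topologies.
#
# These tables are deliberately small, documented stand-ins: Lennard-Jones
# radii/well depths per element, Lazaridis-Karplus (EEF1-style) solvation
# parameters per atom class, and simplified partial charges per
# (residue, atom, protonation variant). Only polar hydrogens are explicit
# (the EEF1 united-atom convention); apolar hydrogens are never built.
#
# Charges are group-based: backbone amide dipole, side-chain polar groups,
# and integral formal charges on ionized groups. Magnitudes were fixed once
# so that a solvent-exposed His-carboxylate model pair titrates within about
# one pH unit above the His intrinsic pKa (see the methods vignette).

# ---- ionizable residue bookkeeping -----------------------------------------

IONIZABLE_AA <- c("ASP", "GLU", "HIS", "TYR", "LYS")

# protonation labels per residue type; first element = deprotonated-side
# reference, order is the deterministic tie-break order used by the packer
PROT_LABELS <- list(
  ASP = c("ASP", "ASH1", "ASH2"),   # deprotonated; H on OD1; H on OD2
  GLU = c("GLU", "GLH1", "GLH2"),   # deprotonated; H on OE1; H on OE2
  HIS = c("HID", "HIE", "HIP"),     # ND1 tautomer; NE2 tautomer; +1 both
  TYR = c("TYR", "TYM"),            # protonated (neutral); deprotonated (-1)
  LYS = c("LYS", "LYN")             # protonated (+1); deprotonated (neutral)
)

# is a label a "protonated" state in the Henderson-Hasselbalch sense?
label_is_protonated <- function(label) {
  label %in% c("ASH1", "ASH2", "GLH1", "GLH2", "HIP", "TYR", "LYS")
}

label_res_type <- function(label) {
  switch(label,
    ASP = , ASH1 = , ASH2 = "ASP",
    GLU = , GLH1 = , GLH2 = "GLU",
    HID = , HIE = , HIP = "HIS",
    TYR = , TYM = "TYR",
    LYS = , LYN = "LYS",
    stop("unknown protonation label: ", label))
}

# ---- pKa table --------------------------------------------------------------

#' Intrinsic pKa table
#'
#' Model-compound intrinsic pKa values for the five ionizable residue types
#' and the thermal energy used by the protonation potential.
#'
#' @param intrinsic_pka named numeric vector overriding any of the defaults
#'   (names among `"ASP"`, `"GLU"`, `"HIS"`, `"TYR"`, `"LYS"`).
#' @param kT thermal energy in kcal/mol (default 0.59, T = 298 K).
#' @return object of class `pka_table`.
#' @export
#' @examples
#' pka_table()$intrinsic_pka[["HIS"]]  # 6.3
pka_table <- function(intrinsic_pka = NULL, kT = 0.59) {
  pk <- c(ASP = 4.0, GLU = 4.4, HIS = 6.3, TYR = 10.0, LYS = 10.4)
  if (!is.null(intrinsic_pka)) {
    bad <- setdiff(names(intrinsic_pka), names(pk))
    if (length(bad)) stop("unknown residue type in pKa override: ",
                          paste(bad, collapse = ", "))
    pk[names(intrinsic_pka)] <- intrinsic_pka
  }
  if (any(pk <= 0 | pk >= 14)) stop("intrinsic pKa values must lie in (0, 14)")
  if (kT <= 0) stop("kT must be positive")
  structure(list(intrinsic_pka = pk, kT = kT), class = "pka_table")
}

# ---- Lennard-Jones and Lazaridis-Karplus parameters -------------------------

# per-element LJ parameters (radius = rmin/2 per atom, well depth kcal/mol)
.lj_by_element <- list(
  C = c(radius = 1.90, eps = 0.12),
  N = c(radius = 1.75, eps = 0.17),
  O = c(radius = 1.55, eps = 0.21),
  S = c(radius = 1.90, eps = 0.25),
  H = c(radius = 0.60, eps = 0.02),
  X = c(radius = 1.80, eps = 0.10)   # fallback for unrecognized elements
)

# LK solvation classes: dgfree (kcal/mol), lambda (A), volume (A^3)
.lk_classes <- list(
  C       = c(dgfree =   1.0, lambda = 3.5, vol = 14.7),
  N_pol   = c(dgfree =  -8.0, lambda = 3.5, vol = 11.2),
  N_chg   = c(dgfree = -20.0, lambda = 6.0, vol = 11.2),
  O_pol   = c(dgfree =  -6.0, lambda = 3.5, vol = 10.8),
  O_chg   = c(dgfree = -10.0, lambda = 6.0, vol = 10.8),
  S       = c(dgfree =  -4.1, lambda = 3.5, vol = 14.7),
  H       = c(dgfree =   0.0, lambda = 3.5, vol = 0.0)
)

# atoms carrying a formal-charge-bearing group, per label
.charged_group_atoms <- function(aa, label, name) {
  (label == "ASP" && name %in% c("OD1", "OD2")) ||
  (label == "GLU" && name %in% c("OE1", "OE2")) ||
  (label == "HIP" && name %in% c("ND1", "NE2")) ||
  (label == "TYM" && name == "OH") ||
  (label == "LYS" && name == "NZ") ||
  (aa == "ARG" && name %in% c("NE", "NH1", "NH2"))
}

lk_class_for <- function(aa, label, name, element) {
  if (element == "H") return("H")
  if (element == "S") return("S")
  if (element == "C") return("C")
  chg <- .charged_group_atoms(aa, label, name)
  if (element == "N") return(if (chg) "N_chg" else "N_pol")
  if (element == "O") return(if (chg) "O_chg" else "O_pol")
  "C"
}

# ---- partial charges ---------------------------------------------------------

.bb_charges <- c(N = -0.35, H = 0.25, CA = 0.10, C = 0.55, O = -0.55,
                 OXT = -0.55)

# side-chain charges per residue; ionizable residues keyed by label
.sc_charges <- list(
  SER = c(OG = -0.40, HG = 0.40),
  THR = c(OG1 = -0.40, HG1 = 0.40),
  CYS = c(SG = -0.20, HG = 0.20),
  ASN = c(CG = 0.55, OD1 = -0.55, ND2 = -0.60, HD21 = 0.30, HD22 = 0.30),
  GLN = c(CD = 0.55, OE1 = -0.55, NE2 = -0.60, HE21 = 0.30, HE22 = 0.30),
  TRP = c(NE1 = -0.35, HE1 = 0.35),
  ARG = c(NE = -0.40, HE = 0.40, CZ = 0.20, NH1 = -0.30, HH11 = 0.35,
          HH12 = 0.35, NH2 = -0.30, HH21 = 0.35, HH22 = 0.35),
  # ionizable, by protonation label
  ASP  = c(CG = 0.62, OD1 = -0.81, OD2 = -0.81),
  ASH1 = c(CG = 0.55, OD1 = -0.45, HD2 = 0.40, OD2 = -0.50),
  ASH2 = c(CG = 0.55, OD1 = -0.50, OD2 = -0.45, HD2 = 0.40),
  GLU  = c(CD = 0.62, OE1 = -0.81, OE2 = -0.81),
  GLH1 = c(CD = 0.55, OE1 = -0.45, HE2 = 0.40, OE2 = -0.50),
  GLH2 = c(CD = 0.55, OE1 = -0.50, OE2 = -0.45, HE2 = 0.40),
  HID  = c(ND1 = -0.40, HD1 = 0.40, NE2 = -0.30, CE1 = 0.30),
  HIE  = c(ND1 = -0.30, NE2 = -0.40, HE2 = 0.40, CE1 = 0.30),
  HIP  = c(ND1 = -0.30, HD1 = 0.45, NE2 = -0.30, HE2 = 0.45, CE1 = 0.50,
           CG = 0.20),
  TYR  = c(OH = -0.45, HH = 0.45),
  TYM  = c(OH = -0.85, CZ = -0.15),
  LYS  = c(NZ = -0.35, HZ1 = 0.45, HZ2 = 0.45, HZ3 = 0.45),
  LYN  = c(NZ = -0.90, HZ1 = 0.45, HZ2 = 0.45)
)

atom_charge <- function(aa, label, name) {
  if (name %in% names(.bb_charges)) return(unname(.bb_charges[[name]]))
  key <- if (aa %in% IONIZABLE_AA) label else aa
  tab <- .sc_charges[[key]]
  if (!is.null(tab) && name %in% names(tab)) return(unname(tab[[name]]))
  0
}

# hydrogen-bond acceptor heavy atoms, per residue/label
is_acceptor_atom <- function(aa, label, name) {
  if (name %in% c("O", "OXT")) return(TRUE)
  if (aa == "ASP" && name %in% c("OD1", "OD2")) {
    # the hydroxyl O of the protonated form donates, the carbonyl O accepts
    if (label == "ASH1" && name == "OD1") return(FALSE)
    if (label == "ASH2" && name == "OD2") return(FALSE)
    return(TRUE)
  }
  if (aa == "GLU" && name %in% c("OE1", "OE2")) {
    if (label == "GLH1" && name == "OE1") return(FALSE)
    if (label == "GLH2" && name == "OE2") return(FALSE)
    return(TRUE)
  }
  if (aa == "HIS") {
    if (label == "HID" && name == "NE2") return(TRUE)
    if (label == "HIE" && name == "ND1") return(TRUE)
    return(FALSE)
  }
  if (aa == "TYR" && name == "OH") return(TRUE)
  if (aa == "LYS" && label == "LYN" && name == "NZ") return(TRUE)
  if (aa == "ASN" && name == "OD1") return(TRUE)
  if (aa == "GLN" && name == "OE1") return(TRUE)
  if (aa %in% c("SER") && name == "OG") return(TRUE)
  if (aa %in% c("THR") && name == "OG1") return(TRUE)
  FALSE
}

# ---- ideal-geometry topologies ----------------------------------------------

# Each row: atom name, three reference atom names, bond (A), angle (deg),
# torsion (number, or "chiK"/"chiK+180" resolved against the chi vector).
# Reference atoms must already exist when the row is applied.
.topo_row <- function(name, r1, r2, r3, b, a, t) {
  list(name = name, r1 = r1, r2 = r2, r3 = r3, b = b, a = a, t = t)
}

# side-chain heavy-atom topologies (CB placement is shared)
.CB <- .topo_row("CB", "N", "C", "CA", 1.530, 110.1, 122.6)

SIDECHAIN_TOPOLOGY <- list(
  GLY = list(),
  ALA = list(.CB),
  SER = list(.CB,
    .topo_row("OG", "N", "CA", "CB", 1.417, 110.8, "chi1")),
  ASN = list(.CB,
    .topo_row("CG",  "N", "CA", "CB", 1.516, 112.6, "chi1"),
    .topo_row("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
    .topo_row("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2+180")),
  ASP = list(.CB,
    .topo_row("CG",  "N", "CA", "CB", 1.516, 112.6, "chi1"),
    .topo_row("OD1", "CA", "CB", "CG", 1.250, 118.4, "chi2"),
    .topo_row("OD2", "CA", "CB", "CG", 1.250, 118.4, "chi2+180")),
  GLU = list(.CB,
    .topo_row("CG",  "N", "CA", "CB", 1.520, 114.1, "chi1"),
    .topo_row("CD",  "CA", "CB", "CG", 1.520, 112.6, "chi2"),
    .topo_row("OE1", "CB", "CG", "CD", 1.250, 118.4, "chi3"),
    .topo_row("OE2", "CB", "CG", "CD", 1.250, 118.4, "chi3+180")),
  HIS = list(.CB,
    .topo_row("CG",  "N", "CA", "CB", 1.500, 113.8, "chi1"),
    .topo_row("ND1", "CA", "CB", "CG", 1.380, 122.7, "chi2"),
    .topo_row("CD2", "CA", "CB", "CG", 1.360, 129.7, "chi2+180"),
    .topo_row("CE1", "CB", "CG", "ND1", 1.320, 109.3, 180),
    .topo_row("NE2", "CB", "CG", "CD2", 1.370, 107.0, 180)),
  TYR = list(.CB,
    .topo_row("CG",  "N", "CA", "CB", 1.510, 113.9, "chi1"),
    .topo_row("CD1", "CA", "CB", "CG", 1.390, 120.8, "chi2"),
    .topo_row("CD2", "CA", "CB", "CG", 1.390, 120.8, "chi2+180"),
    .topo_row("CE1", "CB", "CG", "CD1", 1.390, 121.2, 180),
    .topo_row("CE2", "CB", "CG", "CD2", 1.390, 121.2, 180),
    .topo_row("CZ",  "CG", "CD1", "CE1", 1.390, 119.6, 0),
    .topo_row("OH",  "CD1", "CE1", "CZ", 1.380, 119.9, 180)),
  LYS = list(.CB,
    .topo_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
    .topo_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
    .topo_row("CE", "CB", "CG", "CD", 1.520, 111.3, "chi3"),
    .topo_row("NZ", "CG", "CD", "CE", 1.490, 111.9, "chi4"))
)

# chi-angle definitions (atom-name quadruples), per supported residue
CHI_ATOMS <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ"))
)

# polar side-chain hydrogens per residue/label
sidechain_h_topology <- function(aa, label) {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- .topo_row(...)
  if (aa == "SER") add("HG", "CA", "CB", "OG", 0.96, 109.5, 180)
  if (aa == "THR") add("HG1", "CA", "CB", "OG1", 0.96, 109.5, 180)
  if (aa == "CYS") add("HG", "CA", "CB", "SG", 1.34, 96.0, 180)
  if (aa == "ASN") {
    add("HD21", "CB", "CG", "ND2", 1.01, 120.0, 0)
    add("HD22", "CB", "CG", "ND2", 1.01, 120.0, 180)
  }
  if (aa == "GLN") {
    add("HE21", "CG", "CD", "NE2", 1.01, 120.0, 0)
    add("HE22", "CG", "CD", "NE2", 1.01, 120.0, 180)
  }
  if (aa == "TRP") add("HE1", "CG", "CD1", "NE1", 1.01, 125.0, 180)
  if (aa == "ARG") {
    add("HE", "CG", "CD", "NE", 1.01, 118.0, 180)  # approximate placements
    add("HH11", "NE", "CZ", "NH1", 1.01, 120.0, 0)
    add("HH12", "NE", "CZ", "NH1", 1.01, 120.0, 180)
    add("HH21", "NE", "CZ", "NH2", 1.01, 120.0, 0)
    add("HH22", "NE", "CZ", "NH2", 1.01, 120.0, 180)
  }
  if (aa == "ASP") {
    if (label == "ASH1") add("HD2", "CB", "CG", "OD1", 0.96, 110.0, 180)
    if (label == "ASH2") add("HD2", "CB", "CG", "OD2", 0.96, 110.0, 180)
  }
  if (aa == "GLU") {
    if (label == "GLH1") add("HE2", "CG", "CD", "OE1", 0.96, 110.0, 180)
    if (label == "GLH2") add("HE2", "CG", "CD", "OE2", 0.96, 110.0, 180)
  }
  if (aa == "HIS") {
    if (label %in% c("HID", "HIP")) add("HD1", "CB", "CG", "ND1", 1.01, 126.0, 0)
    if (label %in% c("HIE", "HIP")) add("HE2", "CG", "CD2", "NE2", 1.01, 125.5, 180)
  }
  if (aa == "TYR" && label != "TYM") add("HH", "CE1", "CZ", "OH", 0.96, 109.5, 180)
  if (aa == "LYS") {
    add("HZ1", "CG", "CD", "NZ", 1.01, 109.5, 60)
    add("HZ2", "CG", "CD", "NZ", 1.01, 109.5, 180)
    if (label != "LYN") add("HZ3", "CG", "CD", "NZ", 1.01, 109.5, -60)
  }
  rows
}

# residues with a full internal-coordinate template (rebuildable side chains)
TEMPLATED_AA <- names(SIDECHAIN_TOPOLOGY)

element_from_name <- function(name) {
  nm <- gsub("[0-9'']", "", name)
  e <- substr(nm, 1, 1)
  if (e %in% c("C", "N", "O", "S", "H")) e else "X"
}
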