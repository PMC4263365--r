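# Weighted multi-term energy: full-atom pairwise terms (split Lennard-Jones,
# Lazaridis-Karplus solvation, distance/angle hydrogen bonds, distance-
# dependent-dielectric Coulomb), one-body terms (rotamer probability, pH),
# the centroid-mode score, interface scoring with post-separation repacking,
# and weight calibration by non-negative logistic regression.

COULOMB_K <- 332.064       # kcal*A/(mol*e^2)
ELEC_RMIN <- 1.45          # clamp window for the eps = 10r Coulomb form
ELEC_RMAX <- 5.5
PAIR_CUTOFF <- 6.0         # vdW/solvation cutoff (A)
HB_DMAX <- 2.6             # H...acceptor distance where the well reaches 0
TERM_NAMES <- c("atr", "rep", "sol", "hb", "dun", "elec", "ph", "pair")

#' Score-term weight presets
#'
#' Named weight sets for the weighted total score. `"phdock"` is the
#' pH-aware sampling/ranking set; `"phdock_min"` raises the repulsive
#' van der Waals weight to the RosettaDock value for use during
#' minimization; `"rosettadock"` is the pH-blind reference set. The
#' statistical residue-pair term carries weight 0 in every preset.
#'
#' @param preset preset name.
#' @param ... named weight overrides (e.g. `rep = 0.01`).
#' @return named numeric vector of class `score_weights`.
#' @export
#' @examples
#' score_weights("phdock")[["ph"]]  # 0.21
score_weights <- function(preset = c("phdock", "phdock_min", "phdock_rank",
                                     "rosettadock"), ...) {
  preset <- match.arg(preset)
  w <- switch(preset,
    phdock      = c(atr = 0.377, rep = 0.005, sol = 0.225, hb = 0.249,
                    dun = 0.080, elec = 0.319, ph = 0.21, pair = 0),
    phdock_min  = c(atr = 0.377, rep = 0.044, sol = 0.225, hb = 0.249,
                    dun = 0.080, elec = 0.319, ph = 0.21, pair = 0),
    phdock_rank = c(atr = 0.377, rep = 0.005, sol = 0.225, hb = 0.249,
                    dun = 0.080, elec = 0.319, ph = 0.21, pair = 0),
    rosettadock = c(atr = 0.338, rep = 0.044, sol = 0.242, hb = 0.245,
                    dun = 0.036, elec = 0.026, ph = 0, pair = 0))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), TERM_NAMES)
    if (length(bad)) stop("unknown score term(s): ", paste(bad, collapse = ", "))
    w[names(over)] <- unlist(over)
  }
  if (any(w < 0)) stop("domain error: weights must be non-negative")
  structure(w, class = "score_weights", preset = preset)
}

#' Coulomb energy with distance-dependent dielectric
#'
#' `E = 332.064 q1 q2 / (10 r^2)` (dielectric `eps = 10r`), with the
#' distance clamped to `[1.45, 5.5]` Angstrom and the energy shifted so it
#' vanishes at the outer edge. Vectorized over its arguments.
#'
#' @param q1,q2 partial charges (elementary charges).
#' @param r interatomic distance (Angstrom), must be positive.
#' @param shift subtract the value at the outer clamp edge (default TRUE).
#' @return energy in kcal/mol.
#' @export
#' @examples
#' coulomb_ddd(1, -1, 3, shift = FALSE)  # -3.690
coulomb_ddd <- function(q1, q2, r, shift = TRUE) {
  if (any(r <= 0)) stop("domain error: r must be positive")
  rc <- pmin(pmax(r, ELEC_RMIN), ELEC_RMAX)
  e <- COULOMB_K * q1 * q2 / (10 * rc^2)
  if (shift) e <- e - COULOMB_K * q1 * q2 / (10 * ELEC_RMAX^2)
  e[r >= ELEC_RMAX] <- 0
  e
}

# ---- pairwise engine --------------------------------------------------------

# residue adjacency exclusion: pairs within one residue or between
# sequence-adjacent residues of the same chain are not scored
.excluded_pairs <- function(cx, ri, rj) {
  ch <- cx$residues$chain
  ri == rj | (ch[ri] == ch[rj] & abs(ri - rj) == 1L)
}

# atr/rep/sol/elec sums over atom pairs between idxA and idxB
# (idxB = NULL: all i<j pairs within idxA)
score_pairs <- function(cx, idxA, idxB = NULL) {
  out <- c(atr = 0, rep = 0, sol = 0, elec = 0)
  xa <- cx$xyz[idxA, , drop = FALSE]
  if (is.null(idxB)) { xb <- xa; idxB <- idxA; within <- TRUE }
  else { xb <- cx$xyz[idxB, , drop = FALSE]; within <- FALSE }
  if (!length(idxA) || !length(idxB)) return(out)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 1e-12] <- 1e-12
  sel <- d2 < PAIR_CUTOFF^2
  if (within) sel[lower.tri(sel, diag = TRUE)] <- FALSE
  pr <- which(sel, arr.ind = TRUE)
  if (!nrow(pr)) return(out)
  ia <- idxA[pr[, 1]]; ib <- idxB[pr[, 2]]
  keep <- !.excluded_pairs(cx, cx$atoms$res[ia], cx$atoms$res[ib])
  ia <- ia[keep]; ib <- ib[keep]
  if (!length(ia)) return(out)
  d <- sqrt(d2[sel][keep])
  A <- cx$atoms
  # Lennard-Jones split at the well minimum
  rmin <- A$radius[ia] + A$radius[ib]
  e <- sqrt(A$eps[ia] * A$eps[ib])
  live <- e > 0
  if (any(live)) {
    sr6 <- (rmin[live] / d[live])^6
    lj <- e[live] * (sr6^2 - 2 * sr6)
    inside <- d[live] < rmin[live]
    atr <- ifelse(inside, -e[live], lj)
    rep_ <- ifelse(inside, lj + e[live], 0)
    out[["atr"]] <- sum(atr)
    out[["rep"]] <- sum(rep_)
  }
  # Lazaridis-Karplus Gaussian-exclusion solvation (heavy atoms only;
  # hydrogens carry zero volume and dgfree)
  cgauss <- 2 * pi^1.5
  xi <- (d - A$radius[ia]) / A$lambda[ia]
  xj <- (d - A$radius[ib]) / A$lambda[ib]
  sol <- -(A$dgfree[ia] * A$vol[ib] * exp(-xi^2) / (cgauss * A$lambda[ia] * d^2) +
           A$dgfree[ib] * A$vol[ia] * exp(-xj^2) / (cgauss * A$lambda[ib] * d^2))
  out[["sol"]] <- sum(sol)
  # electrostatics
  qq <- A$charge[ia] * A$charge[ib]
  nz <- qq != 0 & d < ELEC_RMAX
  if (any(nz)) {
    rc <- pmax(d[nz], ELEC_RMIN)
    out[["elec"]] <- sum(COULOMB_K * qq[nz] *
                           (1 / (10 * rc^2) - 1 / (10 * ELEC_RMAX^2)))
  }
  out
}

# hydrogen-bond energies between donor hydrogens in idxA and acceptors in
# idxB (and vice versa when both = TRUE). Returns the energy sum and,
# if pairs = TRUE, a data.frame of individual bonds (energy < 0).
hbond_pairs <- function(cx, idxA, idxB = NULL, pairs = FALSE) {
  both <- !is.null(idxB)
  if (is.null(idxB)) idxB <- idxA
  A <- cx$atoms
  don_in <- function(ix) ix[A$is_h[ix] & !is.na(A$don_base[ix])]
  acc_in <- function(ix) ix[A$acc[ix]]
  eval_set <- function(hd, ac) {
    if (!length(hd) || !length(ac)) return(NULL)
    xh <- cx$xyz[hd, , drop = FALSE]; xa <- cx$xyz[ac, , drop = FALSE]
    d2 <- outer(rowSums(xh^2), rowSums(xa^2), "+") - 2 * tcrossprod(xh, xa)
    sel <- d2 < HB_DMAX^2 & d2 > 1e-12
    pr <- which(sel, arr.ind = TRUE)
    if (!nrow(pr)) return(NULL)
    ih <- hd[pr[, 1]]; ia <- ac[pr[, 2]]
    keep <- !.excluded_pairs(cx, A$res[ih], A$res[ia])
    ih <- ih[keep]; ia <- ia[keep]
    if (!length(ih)) return(NULL)
    d <- sqrt(d2[sel][keep])
    dn <- A$don_base[ih]
    u <- cx$xyz[dn, , drop = FALSE] - cx$xyz[ih, , drop = FALSE]
    v <- cx$xyz[ia, , drop = FALSE] - cx$xyz[ih, , drop = FALSE]
    ct <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
    theta <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
    f <- pmin(0, -1.5 * (1 - ((d - 1.9) / 0.7)^2))
    g <- pmin(1, pmax(0, (theta - 120) / 60))
    data.frame(h = ih, acc = ia, don = dn, d = d, theta = theta,
               energy = f * g)
  }
  res <- if (both) {
    rbind(eval_set(don_in(idxA), acc_in(idxB)),
          eval_set(don_in(idxB), acc_in(idxA)))
  } else {
    eval_set(don_in(idxA), acc_in(idxA))
  }
  if (is.null(res)) res <- data.frame(h = integer(), acc = integer(),
                                      don = integer(), d = numeric(),
                                      theta = numeric(), energy = numeric())
  res <- res[res$energy < 0, , drop = FALSE]
  if (pairs) res else sum(res$energy)
}

# ---- whole-complex scoring --------------------------------------------------

#' Score a fullatom complex
#'
#' Sums the pairwise terms (attractive/repulsive van der Waals split at the
#' potential minimum, Lazaridis-Karplus solvation, hydrogen bonds, Coulomb
#' with distance-dependent dielectric) over all atom pairs within the
#' cutoffs, plus the one-body rotamer-probability and pH terms. Intra- and
#' inter-partner contributions are both included.
#'
#' @param cx fullatom `ph_complex`.
#' @param weights a [score_weights()] set.
#' @param ph solution pH (defaults to the complex's pH).
#' @return object of class `score_breakdown` with raw per-term totals
#'   (`$terms`), the weight vector, and the weighted `$total` (REU).
#' @export
score_complex <- function(cx, weights = score_weights("phdock"), ph = cx$ph) {
  if (cx$representation != "fullatom")
    stop("state error: score_complex requires fullatom representation; use centroid_score")
  idx <- seq_len(nrow(cx$atoms))
  pe <- score_pairs(cx, idx)
  hb <- hbond_pairs(cx, idx)
  dun <- sum(cx$residues$e_dun)
  eph <- sum(vapply(cx$residues$prot, ph_energy, 0, ph = ph))
  terms <- c(atr = pe[["atr"]], rep = pe[["rep"]], sol = pe[["sol"]],
             hb = hb, dun = dun, elec = pe[["elec"]], ph = eph, pair = 0)
  new_score_breakdown(terms, weights)
}

new_score_breakdown <- function(terms, weights) {
  w <- as.numeric(weights)[match(TERM_NAMES, names(weights))]
  names(w) <- TERM_NAMES
  structure(list(terms = terms[TERM_NAMES], weights = w,
                 weighted = w * terms[TERM_NAMES],
                 total = sum(w * terms[TERM_NAMES])),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("score_breakdown (REU):\n")
  m <- rbind(raw = x$terms, weight = x$weights, weighted = x$weighted)
  print(round(m, 4))
  cat(sprintf("total: %.4f\n", x$total))
  invisible(x)
}

# centroid-mode score: smooth saturating contact attraction between
# cross-partner residue centroids (about -1 per pair, switching off around
# 6 A so that the rigid-body search feels a restoring gradient at the
# Metropolis temperature even for small interfaces) plus a soft quadratic
# clash penalty below 3.5 A on centroid and CA pairs
centroid_score <- function(cx) {
  if (cx$representation != "centroid")
    stop("state error: centroid_score requires centroid representation")
  A <- cx$atoms
  rec <- which(cx$residues$partner[A$res] == "receptor" & A$name %in% c("CEN", "CA"))
  lig <- which(cx$residues$partner[A$res] == "ligand" & A$name %in% c("CEN", "CA"))
  xr <- cx$xyz[rec, , drop = FALSE]; xl <- cx$xyz[lig, , drop = FALSE]
  d2 <- outer(rowSums(xr^2), rowSums(xl^2), "+") - 2 * tcrossprod(xr, xl)
  d <- sqrt(pmax(d2, 1e-12))
  cen_r <- A$name[rec] == "CEN"; cen_l <- A$name[lig] == "CEN"
  dc <- d[cen_r, cen_l, drop = FALSE]
  contact <- -sum(1 / (1 + exp(2 * (dc - 6.0))))
  clash <- sum(pmax(0, 3.5 - d)^2)
  contact + clash
}

# ---- interface score --------------------------------------------------------

# residues of each partner with any heavy atom closer than `cutoff` to a
# heavy atom of the other partner
interface_residues <- function(cx, cutoff = 4.0) {
  A <- cx$atoms
  heavy <- !A$is_h & A$name != "CEN"
  ir <- which(cx$residues$partner[A$res] == "receptor" & heavy)
  il <- which(cx$residues$partner[A$res] == "ligand" & heavy)
  if (!length(ir) || !length(il)) return(integer())
  xr <- cx$xyz[ir, , drop = FALSE]; xl <- cx$xyz[il, , drop = FALSE]
  d2 <- outer(rowSums(xr^2), rowSums(xl^2), "+") - 2 * tcrossprod(xr, xl)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  sort(unique(c(A$res[ir[hit[, 1]]], A$res[il[hit[, 2]]])))
}

#' Interface score with post-separation repacking
#'
#' For each score term, the interface contribution is the term in the
#' complex minus the sum over the separated partners, where each separated
#' partner has its ionizable interface residues repacked (side-chain rotamer
#' and protonation state) at the solution pH before scoring. Separation of
#' the partners exposes previously buried interface residues to solvent,
#' which can change their preferred protonation state.
#'
#' @param cx fullatom two-partner `ph_complex`.
#' @param weights a [score_weights()] set.
#' @param ph solution pH.
#' @param seed integer seed for the repacking step.
#' @return object of class `interface_score`: `$isc` (weighted, REU),
#'   `$per_term` (raw per-term interface contributions), `$weighted`.
#' @export
interface_score <- function(cx, weights = score_weights("phdock"),
                            ph = cx$ph, seed = 1) {
  if (cx$representation != "fullatom")
    stop("state error: interface_score requires fullatom representation")
  if (length(unique(cx$residues$partner)) < 2)
    stop("configuration error: interface_score needs two partners")
  whole <- score_complex(cx, weights, ph)
  iface <- interface_residues(cx, 4.0)
  part_terms <- numeric(length(TERM_NAMES)); names(part_terms) <- TERM_NAMES
  for (p in c("receptor", "ligand")) {
    sub <- subset_partner(cx, p)
    r_idx <- which(cx$residues$partner == p)
    design_local <- match(intersect(iface[cx$residues$prot[iface] != "fixed"],
                                    r_idx), r_idx)
    design_local <- design_local[!is.na(design_local)]
    if (length(design_local)) {
      sub <- pack_sidechains(sub, packer_task(design_local, ph = ph,
                                              weights = weights,
                                              seed = derive_seed(seed, match(p, c("receptor", "ligand")))))
    }
    bs <- score_complex(sub, weights, ph)
    part_terms <- part_terms + bs$terms
  }
  per_term <- whole$terms - part_terms
  w <- whole$weights
  structure(list(isc = sum(w * per_term), per_term = per_term,
                 weighted = w * per_term, weights = w,
                 interface_residues = iface),
            class = "interface_score")
}

#' @export
print.interface_score <- function(x, ...) {
  cat(sprintf("interface score: %.4f REU over %d interface residues\n",
              x$isc, length(x$interface_residues)))
  print(round(x$weighted, 4))
  invisible(x)
}

# ---- weight calibration -----------------------------------------------------

#' Fit score-term weights from labeled models
#'
#' Labels models near-native/non-native following the reweighting recipe:
#' the top 5% by CAPRI rating (high > medium > acceptable, ties broken by
#' higher fnat), restricted to models with repulsive van der Waals scores
#' below the 80th percentile, are near-native; the rest non-native. Fits
#' non-negative weights separating the classes on the per-term interface
#' values via logistic regression (non-negativity-constrained), returning
#' weights normalized to sum 1 and the achieved energy gap.
#'
#' @param per_term numeric matrix (models x score terms) of per-term
#'   interface contributions.
#' @param capri character vector of CAPRI ratings per model.
#' @param fnat numeric vector of native-contact fractions per model.
#' @param erep numeric vector of repulsive vdW scores per model.
#' @param fraction fraction labeled near-native (default 0.05).
#' @return list with `weights` (named, sum 1), `gap` (mean non-native minus
#'   mean near-native weighted score) and `labels`.
#' @export
fit_weights <- function(per_term, capri, fnat, erep, fraction = 0.05) {
  per_term <- as.matrix(per_term)
  n <- nrow(per_term)
  if (n < 20) stop("calibration error: need at least 20 models")
  rating_rank <- match(capri, c("high", "medium", "acceptable", "incorrect"))
  if (anyNA(rating_rank)) stop("domain error: invalid CAPRI rating")
  ord <- order(rating_rank, -fnat)
  eligible <- erep < stats::quantile(erep, 0.8, type = 7)
  k <- ceiling(fraction * n)
  near <- logical(n)
  near[ord[eligible[ord]][seq_len(min(k, sum(eligible)))]] <- TRUE
  if (!any(near) || all(near))
    stop("calibration error: both classes must be present")
  if (all(apply(per_term, 2, function(x) diff(range(x))) < 1e-12))
    stop("calibration error: per-term values identical, no separation possible")
  y <- as.integer(!near)  # 1 = non-native (higher energy expected)
  # ridge-stabilized logistic path: near-perfect separation makes the
  # unpenalized likelihood unbounded, so take the smallest lambda that the
  # warm-started path converged for
  fit <- suppressWarnings(
    glmnet::glmnet(per_term, y, family = "binomial", alpha = 0,
                   nlambda = 60, lambda.min.ratio = 1e-4,
                   lower.limits = 0, intercept = TRUE, standardize = TRUE))
  w <- as.numeric(fit$beta[, ncol(fit$beta)])
  names(w) <- colnames(per_term)
  w[w < 0] <- 0
  if (sum(w) < 1e-12)
    stop("calibration error: degenerate fit, all weights zero")
  w <- w / sum(w)
  gap <- energy_gap(per_term, near, w)
  list(weights = w, gap = gap, labels = ifelse(near, "near-native",
                                               "non-native"))
}

#' Weighted energy gap between model classes
#'
#' Mean weighted score of non-native models minus mean weighted score of
#' near-native models; antisymmetric under class swap.
#'
#' @param per_term numeric matrix (models x terms).
#' @param near logical vector, TRUE for near-native models.
#' @param weights named or plain numeric weight vector (length = terms).
#' @return numeric gap.
#' @export
energy_gap <- function(per_term, near, weights) {
  e <- as.matrix(per_term) %*% as.numeric(weights)
  mean(e[!near]) - mean(e[near])
}
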