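# Model-vs-native quality metrics (Lrmsd, Irmsd, fnat, CAPRI rating,
# interface hydrogen bonds and recovery) and docking-funnel statistics
# (discrimination score, N5, bootstrap resampling).
#
# Contact and interface definitions use heavy atoms only (crystal
# structures typically lack hydrogens).

ca_coords <- function(cx, r_idx) {
  rows <- matrix(NA_real_, length(r_idx), 3)
  for (k in seq_along(r_idx)) {
    i <- which(cx$atoms$res == r_idx[k] & cx$atoms$name == "CA")
    if (length(i)) rows[k, ] <- cx$xyz[i[1], ]
  }
  rows
}

#' Ligand RMSD
#'
#' Least-squares superposition of the receptor CA atoms of model onto
#' native, then RMSD over the ligand CA atoms.
#'
#' @param model,native matched `ph_complex` objects.
#' @return RMSD in Angstrom.
#' @export
lrmsd <- function(model, native) {
  check_matched(model, native)
  rec <- which(native$residues$partner == "receptor")
  lig <- which(native$residues$partner == "ligand")
  mr <- ca_coords(model, rec); nr <- ca_coords(native, rec)
  ml <- ca_coords(model, lig); nl <- ca_coords(native, lig)
  ok_r <- stats::complete.cases(mr) & stats::complete.cases(nr)
  ok_l <- stats::complete.cases(ml) & stats::complete.cases(nl)
  if (!any(ok_r) || !any(ok_l))
    stop("metric error: no shared CA atoms for superposition")
  fit <- kabsch(mr[ok_r, , drop = FALSE], nr[ok_r, , drop = FALSE])
  ml_fit <- apply_transform(ml[ok_l, , drop = FALSE], fit$R, fit$t)
  sqrt(mean(rowSums((ml_fit - nl[ok_l, , drop = FALSE])^2)))
}

# interface residues defined on the native complex (heavy-atom distance
# below `cutoff` to the other partner)
native_interface <- function(native, cutoff = 4.0) {
  interface_residues(native, cutoff)
}

#' Interface RMSD
#'
#' CA RMSD over the native-defined interface residues (both partners,
#' heavy-atom contact distance < 4 A) after least-squares superposition on
#' that same CA set.
#'
#' @param model,native matched `ph_complex` objects.
#' @return RMSD in Angstrom.
#' @export
irmsd <- function(model, native) {
  check_matched(model, native)
  iface <- native_interface(native, 4.0)
  if (!length(iface)) stop("metric error: native complex has no interface")
  mc <- ca_coords(model, iface); nc <- ca_coords(native, iface)
  ok <- stats::complete.cases(mc) & stats::complete.cases(nc)
  if (sum(ok) < 2) stop("metric error: fewer than 2 interface CA atoms")
  fit <- kabsch(mc[ok, , drop = FALSE], nc[ok, , drop = FALSE])
  m_fit <- apply_transform(mc[ok, , drop = FALSE], fit$R, fit$t)
  sqrt(mean(rowSums((m_fit - nc[ok, , drop = FALSE])^2)))
}

# cross-partner residue contacts: pairs with minimal heavy-atom distance
# below `cutoff`; returned as "i:j" keys with receptor index first
residue_contacts <- function(cx, cutoff = 5.0) {
  A <- cx$atoms
  heavy <- !A$is_h & A$name != "CEN"
  ir <- which(cx$residues$partner[A$res] == "receptor" & heavy)
  il <- which(cx$residues$partner[A$res] == "ligand" & heavy)
  if (!length(ir) || !length(il)) return(character())
  xr <- cx$xyz[ir, , drop = FALSE]; xl <- cx$xyz[il, , drop = FALSE]
  d2 <- outer(rowSums(xr^2), rowSums(xl^2), "+") - 2 * tcrossprod(xr, xl)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(character())
  unique(paste(A$res[ir[hit[, 1]]], A$res[il[hit[, 2]]], sep = ":"))
}

#' Fraction of native contacts recovered
#'
#' Contacts are cross-partner residue pairs with minimal heavy-atom
#' distance below 5 A. Returns the fraction of the native contacts present
#' in the model.
#'
#' @param model,native matched `ph_complex` objects.
#' @return fraction in `[0, 1]`.
#' @export
fnat <- function(model, native) {
  check_matched(model, native)
  nat <- residue_contacts(native, 5.0)
  if (!length(nat)) stop("metric error: native complex has no contacts")
  mod <- residue_contacts(model, 5.0)
  length(intersect(mod, nat)) / length(nat)
}

#' CAPRI structural quality rating
#'
#' `high` if fnat >= 0.5 and (Irmsd <= 1 or Lrmsd <= 1); else `medium` if
#' fnat >= 0.3 and (Irmsd <= 2 or Lrmsd <= 5); else `acceptable` if
#' fnat >= 0.3 and Irmsd <= 4 (default rule; `strict = TRUE` additionally
#' admits the standard fnat >= 0.1 with Lrmsd <= 10 acceptable tier);
#' else `incorrect`.
#'
#' @param irmsd,lrmsd RMSDs in Angstrom.
#' @param fnat fraction of native contacts.
#' @param strict use the wider standard acceptable tier.
#' @return one of `"incorrect"`, `"acceptable"`, `"medium"`, `"high"`.
#' @export
#' @examples
#' capri_rating(1.7, 8, 0.49)  # "medium"
capri_rating <- function(irmsd, lrmsd, fnat, strict = FALSE) {
  if (any(c(irmsd, lrmsd, fnat) < 0)) stop("domain error: negative metric")
  if (fnat >= 0.5 && (irmsd <= 1 || lrmsd <= 1)) return("high")
  if (fnat >= 0.3 && (irmsd <= 2 || lrmsd <= 5)) return("medium")
  if (fnat >= 0.3 && irmsd <= 4) return("acceptable")
  if (strict && fnat >= 0.1 && (lrmsd <= 10 || irmsd <= 4)) return("acceptable")
  "incorrect"
}

#' Full metric report for one model
#'
#' @param model,native matched fullatom `ph_complex` objects.
#' @param strict passed to [capri_rating()].
#' @return list with `irmsd`, `lrmsd`, `fnat`, `capri`,
#'   `n_interface_hbonds`, `fraction_native_hbonds`.
#' @export
metric_report <- function(model, native, strict = FALSE) {
  ir <- irmsd(model, native)
  lr <- lrmsd(model, native)
  fn <- fnat(model, native)
  hb <- tryCatch(hbond_recovery(model, native),
                 error = function(e) list(n_model = NA_integer_,
                                          fraction_recovered = NA_real_))
  list(irmsd = ir, lrmsd = lr, fnat = fn,
       capri = capri_rating(ir, lr, fn, strict),
       n_interface_hbonds = hb$n_model,
       fraction_native_hbonds = hb$fraction_recovered)
}

# ---- hydrogen bonds ---------------------------------------------------------

#' Cross-partner interface hydrogen bonds
#'
#' Donor-acceptor pairs across the interface whose hydrogen-bond term is
#' negative under the packaged distance/angle geometry.
#'
#' @param cx fullatom `ph_complex` with hydrogens built.
#' @return data.frame: donor residue/atom, acceptor residue/atom, energy.
#' @export
interface_hbonds <- function(cx) {
  if (cx$representation != "fullatom")
    stop("state error: interface_hbonds requires fullatom representation")
  if (!any(cx$atoms$is_h))
    stop("state error: structure has no hydrogens")
  idxR <- partner_atom_idx(cx, "receptor")
  idxL <- partner_atom_idx(cx, "ligand")
  hb <- hbond_pairs(cx, idxR, idxL, pairs = TRUE)
  if (!nrow(hb)) {
    return(data.frame(don_res = integer(), don_atom = character(),
                      acc_res = integer(), acc_atom = character(),
                      energy = numeric(), stringsAsFactors = FALSE))
  }
  A <- cx$atoms
  out <- data.frame(don_res = A$res[hb$don], don_atom = A$name[hb$don],
                    acc_res = A$res[hb$acc], acc_atom = A$name[hb$acc],
                    energy = hb$energy, stringsAsFactors = FALSE)
  out[!duplicated(out[, c("don_res", "don_atom", "acc_res", "acc_atom")]), ,
      drop = FALSE]
}

#' Hydrogen-bond recovery of a model against the native complex
#'
#' A native bond is recovered iff the same donor (residue, atom) and
#' acceptor (residue, atom) pair is present in the model. The ionizable
#' subset counts bonds whose donor or acceptor residue is Asp/Glu/His/
#' Tyr/Lys.
#'
#' @param model,native matched fullatom `ph_complex` objects.
#' @return list: `n_model`, `n_native`, `fraction_recovered`, and the
#'   ionizable-residue counterparts.
#' @export
hbond_recovery <- function(model, native) {
  check_matched(model, native)
  key <- function(df) paste(df$don_res, df$don_atom, df$acc_res, df$acc_atom)
  hm <- interface_hbonds(model)
  hn <- interface_hbonds(native)
  rec <- intersect(key(hm), key(hn))
  ion_rows <- function(df, cx) {
    aa_d <- cx$residues$aa[df$don_res]; aa_a <- cx$residues$aa[df$acc_res]
    df[aa_d %in% IONIZABLE_AA | aa_a %in% IONIZABLE_AA, , drop = FALSE]
  }
  hm_i <- ion_rows(hm, model); hn_i <- ion_rows(hn, native)
  rec_i <- intersect(key(hm_i), key(hn_i))
  list(n_model = nrow(hm), n_native = nrow(hn),
       fraction_recovered = if (nrow(hn)) length(rec) / nrow(hn) else NA_real_,
       n_model_ionizable = nrow(hm_i), n_native_ionizable = nrow(hn_i),
       fraction_recovered_ionizable =
         if (nrow(hn_i)) length(rec_i) / nrow(hn_i) else NA_real_)
}

# ---- funnel statistics ------------------------------------------------------

IRMSD_CUTOFFS <- c(1.0, 1.5, 2.0, 2.5, 3.0, 4.0, 6.0)

#' Docking-funnel discrimination score
#'
#' Interface scores are normalized by mapping the 5th percentile to 0 and
#' the 95th percentile to 1 (linear-interpolation percentiles). For each
#' Irmsd cutoff r in {1, 1.5, 2, 2.5, 3, 4, 6} A with models on both
#' sides, the gap is the minimum normalized score at Irmsd <= r minus the
#' minimum at Irmsd > r; D is the mean gap over usable cutoffs. D <= 0
#' marks a successful funnel.
#'
#' @param isc interface scores.
#' @param irmsd matching Irmsd values (A).
#' @return list with `D` and `N_r` (number of usable cutoffs).
#' @export
discrimination_score <- function(isc, irmsd) {
  if (length(isc) != length(irmsd) || length(isc) < 2)
    stop("metric error: need >= 2 (isc, irmsd) pairs")
  q <- stats::quantile(isc, c(0.05, 0.95), type = 7, names = FALSE)
  denom <- q[2] - q[1]
  if (denom < 1e-12) denom <- 1
  z <- (isc - q[1]) / denom
  gaps <- c()
  for (r in IRMSD_CUTOFFS) {
    below <- z[irmsd <= r]; above <- z[irmsd > r]
    if (length(below) && length(above))
      gaps <- c(gaps, min(below) - min(above))
  }
  if (!length(gaps))
    stop("metric error: all models on one side of every cutoff")
  list(D = mean(gaps), N_r = length(gaps))
}

#' N5 funnel metric
#'
#' Number of models with Irmsd <= 4 A among the five lowest-interface-score
#' models (ties broken by model id order). A docking run is called a
#' success when N5 >= 3.
#'
#' @param isc interface scores.
#' @param irmsd matching Irmsd values (A).
#' @param ids optional model ids for deterministic tie-breaking.
#' @return integer in `[0, 5]`.
#' @export
n5 <- function(isc, irmsd, ids = seq_along(isc)) {
  if (length(isc) < 5) stop("metric error: N5 needs at least 5 models")
  top <- order(isc, ids)[1:5]
  sum(irmsd[top] <= 4.0)
}

#' Bootstrap a funnel statistic
#'
#' Case-resamples the model set with replacement and recomputes the
#' statistic on each resample.
#'
#' @param isc,irmsd model scores and Irmsd values.
#' @param statistic `"D"` or `"N5"`.
#' @param n_resamples bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list with `mu` and `sigma`.
#' @export
bootstrap_funnel <- function(isc, irmsd, statistic = c("D", "N5"),
                             n_resamples = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  n <- length(isc)
  stat_fun <- switch(statistic,
    D = function(i) discrimination_score(isc[i], irmsd[i])$D,
    N5 = function(i) n5(isc[i], irmsd[i], ids = i))
  with_seed(seed, {
    vals <- vapply(seq_len(n_resamples), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      tryCatch(stat_fun(i), error = function(e) NA_real_)
    }, 0)
    vals <- vals[!is.na(vals)]
    list(mu = mean(vals), sigma = stats::sd(vals))
  })
}

#' Combined funnel statistics for a model set
#'
#' @param isc,irmsd model scores and Irmsd values.
#' @param n_resamples bootstrap resamples.
#' @param seed integer seed.
#' @return list of class `funnel_stats`: `D`, `N_r`, `N5`, `success`, and
#'   bootstrap mean/sd for both statistics.
#' @export
funnel_stats <- function(isc, irmsd, n_resamples = 1000, seed = 1) {
  d <- discrimination_score(isc, irmsd)
  nn5 <- n5(isc, irmsd)
  bd <- bootstrap_funnel(isc, irmsd, "D", n_resamples, derive_seed(seed, 1))
  bn <- bootstrap_funnel(isc, irmsd, "N5", n_resamples, derive_seed(seed, 2))
  structure(list(D = d$D, N_r = d$N_r, N5 = nn5,
                 success = d$D <= 0 && nn5 >= 3,
                 bootstrap_mu_D = bd$mu, bootstrap_sigma_D = bd$sigma,
                 bootstrap_mu_N5 = bn$mu, bootstrap_sigma_N5 = bn$sigma),
            class = "funnel_stats")
}

#' @export
print.funnel_stats <- function(x, ...) {
  cat(sprintf("D = %.3f over %d cutoffs (bootstrap %.3f +/- %.3f)\n",
              x$D, x$N_r, x$bootstrap_mu_D, x$bootstrap_sigma_D))
  cat(sprintf("N5 = %d (bootstrap %.2f +/- %.2f); %s\n",
              x$N5, x$bootstrap_mu_N5, x$bootstrap_sigma_N5,
              if (x$success) "successful funnel" else "no funnel"))
  invisible(x)
}
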