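# The docking trajectory: prepack -> initial rigid-body perturbation ->
# low-resolution centroid Monte Carlo -> high-resolution pack/minimize
# Monte Carlo-plus-minimization with dynamic protonation -> model
# generation, repulsive-score filtering and interface-score ranking.

#' Docking configuration
#'
#' @param ph solution pH.
#' @param n_models number of candidate models to generate (default 1000).
#' @param init_translation_max initial perturbation translation bound (A,
#'   default 3).
#' @param init_rotation_max initial perturbation rotation bound (degrees,
#'   default 8) about the axis joining the partner centers.
#' @param lowres_cycles centroid-stage Monte Carlo cycles (default 500).
#' @param highres_mcm_cycles high-resolution pack/minimize cycles
#'   (default 50).
#' @param mc_temperature Metropolis temperature in REU (default 0.8).
#' @param lowres_trans_sd,lowres_rot_sd Gaussian move sizes in the centroid
#'   stage (default 0.7 A / 5 degrees).
#' @param perturb_dist `"uniform"` within the stated bounds (default) or
#'   `"gaussian"` with the bounds as standard deviations.
#' @param min_iter objective evaluations per minimization call.
#' @param mode `"phdock"` (dynamic protonation at `ph`),
#'   `"fixed-protonation"` (equilibrate once, then freeze the labels), or
#'   `"ph7"` (force pH 7.0).
#' @param seed integer seed.
#' @return list of class `docking_config`.
#' @export
dock_config <- function(ph = 7.0, n_models = 1000,
                        init_translation_max = 3.0, init_rotation_max = 8.0,
                        lowres_cycles = 500, highres_mcm_cycles = 50,
                        mc_temperature = 0.8,
                        lowres_trans_sd = 0.7, lowres_rot_sd = 5.0,
                        perturb_dist = c("uniform", "gaussian"),
                        min_iter = 40,
                        mode = c("phdock", "fixed-protonation", "ph7"),
                        seed = 1) {
  if (init_translation_max < 0 || init_rotation_max < 0)
    stop("domain error: perturbation bounds must be non-negative")
  if (lowres_cycles < 0 || highres_mcm_cycles < 1 || n_models < 1)
    stop("domain error: cycle/model counts out of range")
  if (mc_temperature <= 0) stop("domain error: mc_temperature must be positive")
  mode <- match.arg(mode)
  if (mode == "ph7") ph <- 7.0
  structure(list(ph = ph, n_models = n_models,
                 init_translation_max = init_translation_max,
                 init_rotation_max = init_rotation_max,
                 lowres_cycles = lowres_cycles,
                 highres_mcm_cycles = highres_mcm_cycles,
                 mc_temperature = mc_temperature,
                 lowres_trans_sd = lowres_trans_sd,
                 lowres_rot_sd = lowres_rot_sd,
                 perturb_dist = match.arg(perturb_dist),
                 min_iter = min_iter, mode = mode, seed = seed),
            class = "docking_config")
}

#' Prepack a complex
#'
#' Separates the partners beyond interaction range, packs all ionizable
#' side chains (with protonation sampling) of each isolated partner at the
#' solution pH, then restores the input rigid-body placement.
#'
#' @param cx fullatom `ph_complex`.
#' @param ph solution pH.
#' @param weights a [score_weights()] set.
#' @param seed integer seed.
#' @return the prepacked complex, in the input placement.
#' @export
prepack <- function(cx, ph = cx$ph, weights = score_weights("phdock"),
                    seed = 1) {
  if (cx$representation != "fullatom")
    stop("state error: prepack requires fullatom representation")
  sep <- translate_partner(cx, "ligand", c(500, 0, 0))
  sep$ph <- ph
  designable <- which(sep$residues$prot != "fixed")
  if (length(designable))
    sep <- pack_sidechains(sep, packer_task(designable, ph = ph,
                                            weights = weights, seed = seed))
  out <- translate_partner(sep, "ligand", c(-500, 0, 0))
  out$ph <- ph
  out
}

#' Initial rigid-body perturbation
#'
#' Translates the ligand by a random vector of bounded magnitude and
#' rotates it about the axis joining the receptor and ligand centers by a
#' bounded random angle. The receptor never moves.
#'
#' @param cx two-partner `ph_complex` (any representation).
#' @param cfg a [dock_config()].
#' @param seed integer seed (NULL: use the current RNG stream).
#' @return the perturbed complex.
#' @export
initial_perturb <- function(cx, cfg, seed = NULL) {
  with_seed(seed, {
    rec_idx <- partner_atom_idx(cx, "receptor")
    lig_idx <- partner_atom_idx(cx, "ligand")
    rec_cen <- colMeans(cx$xyz[rec_idx, , drop = FALSE])
    lig_cen <- colMeans(cx$xyz[lig_idx, , drop = FALSE])
    if (cfg$perturb_dist == "uniform") {
      mag <- cfg$init_translation_max * stats::runif(1)^(1 / 3)
      ang <- cfg$init_rotation_max * stats::runif(1, -1, 1)
    } else {
      mag <- min(abs(stats::rnorm(1, 0, max(cfg$init_translation_max, 1e-12))),
                 cfg$init_translation_max)
      ang <- max(-cfg$init_rotation_max,
                 min(cfg$init_rotation_max,
                     stats::rnorm(1, 0, max(cfg$init_rotation_max, 1e-12))))
    }
    dirv <- random_unit_vector()
    axis <- lig_cen - rec_cen
    if (vnorm(axis) < 1e-9) axis <- c(0, 0, 1)
    out <- cx
    if (cfg$init_rotation_max > 0 && abs(ang) > 0) {
      R <- rotation_about_axis(axis, ang)
      x <- sweep(out$xyz[lig_idx, , drop = FALSE], 2, lig_cen)
      out$xyz[lig_idx, ] <- sweep(x %*% R, 2, lig_cen, "+")
    }
    if (cfg$init_translation_max > 0 && mag > 0)
      out <- translate_partner(out, "ligand", mag * dirv)
    out
  })
}

#' Low-resolution centroid Monte Carlo stage
#'
#' Gaussian rigid-body ligand moves scored with the centroid contact/clash
#' score and accepted by the Metropolis criterion. Returns the final
#' accepted pose; internal coordinates never change.
#'
#' @param cx centroid-representation `ph_complex`.
#' @param cfg a [dock_config()].
#' @param seed integer seed (NULL: current RNG stream).
#' @param temperature Metropolis temperature override (REU).
#' @param trace return the accepted-score sequence as attribute `"trace"`.
#' @return the final accepted complex.
#' @export
lowres_stage <- function(cx, cfg, seed = NULL,
                         temperature = cfg$mc_temperature, trace = FALSE) {
  if (cx$representation != "centroid")
    stop("state error: lowres_stage requires centroid representation")
  with_seed(seed, {
    cur <- cx
    e_cur <- centroid_score(cur)
    accepted <- e_cur
    lig_idx <- partner_atom_idx(cx, "ligand")
    if (cfg$lowres_cycles >= 1) for (cyc in seq_len(cfg$lowres_cycles)) {
      cand <- cur
      tr <- stats::rnorm(3, 0, cfg$lowres_trans_sd / sqrt(3))
      ang <- stats::rnorm(1, 0, cfg$lowres_rot_sd)
      axis <- random_unit_vector()
      cen <- colMeans(cand$xyz[lig_idx, , drop = FALSE])
      R <- rotation_about_axis(axis, ang)
      x <- sweep(cand$xyz[lig_idx, , drop = FALSE], 2, cen)
      cand$xyz[lig_idx, ] <- sweep(x %*% R, 2, cen + tr, "+")
      e_cand <- centroid_score(cand)
      dE <- e_cand - e_cur
      if (dE <= 0 || stats::runif(1) < exp(-dE / temperature)) {
        cur <- cand; e_cur <- e_cand
      }
      if (trace) accepted <- c(accepted, e_cur)
    }
    if (trace) attr(cur, "trace") <- accepted
    cur
  })
}

#' High-resolution pack/minimize Monte Carlo stage
#'
#' Cycles of {small rigid-body move -> interface side-chain packing with
#' protonation sampling -> rigid-body/chi minimization with the raised
#' repulsive weight -> Metropolis check on the sampling-preset score}.
#' Returns the lowest-scoring accepted structure together with its
#' interface score.
#'
#' @param cx fullatom `ph_complex` (after [restore_fullatom()]).
#' @param cfg a [dock_config()].
#' @param seed integer seed.
#' @param freeze_protonation keep the current labels fixed (the
#'   fixed-protonation control).
#' @return a `dock_model`: list with `$structure`, `$isc`
#'   (an `interface_score`), `$breakdown`, `$seed`.
#' @export
highres_stage <- function(cx, cfg, seed = 1, freeze_protonation = FALSE) {
  if (cx$representation != "fullatom")
    stop("state error: highres_stage requires fullatom representation")
  w_samp <- score_weights("phdock")
  w_min <- score_weights("phdock_min")
  if (freeze_protonation) { w_samp["ph"] <- 0; w_min["ph"] <- 0 }
  ph <- cfg$ph
  with_seed(seed, {
    refine <- function(s, pack_seed) {
      iface <- interface_residues(s, 4.0)
      design <- iface[s$residues$prot[iface] != "fixed"]
      if (length(design) && !freeze_protonation)
        s <- pack_sidechains(s, packer_task(design, ph = ph,
                                            weights = w_samp,
                                            seed = pack_seed))
      minimize_complex(s, "both", weights = w_min, max_iter = cfg$min_iter,
                       ph = ph)
    }
    cur <- refine(cx, derive_seed(seed, 0))
    e_cur <- score_complex(cur, w_samp, ph)$total
    best <- cur; e_best <- e_cur
    for (cyc in seq_len(cfg$highres_mcm_cycles)) {
      cand <- cur
      lig_idx <- partner_atom_idx(cand, "ligand")
      tr <- stats::rnorm(3, 0, 0.1 / sqrt(3))
      ang <- stats::rnorm(1, 0, 3.0)
      axis <- random_unit_vector()
      cen <- colMeans(cand$xyz[lig_idx, , drop = FALSE])
      R <- rotation_about_axis(axis, ang)
      x <- sweep(cand$xyz[lig_idx, , drop = FALSE], 2, cen)
      cand$xyz[lig_idx, ] <- sweep(x %*% R, 2, cen + tr, "+")
      cand <- refine(cand, derive_seed(seed, cyc))
      e_cand <- score_complex(cand, w_samp, ph)$total
      dE <- e_cand - e_cur
      if (dE <= 0 || stats::runif(1) < exp(-dE / cfg$mc_temperature)) {
        cur <- cand; e_cur <- e_cand
        if (e_cur < e_best) { best <- cur; e_best <- e_cur }
      }
    }
    isc <- interface_score(best, score_weights("phdock_rank"), ph,
                           seed = derive_seed(seed, 99991))
    structure(list(structure = best,
                   isc = isc,
                   breakdown = score_complex(best, w_samp, ph),
                   seed = seed),
              class = "dock_model")
  })
}

# ---- full protocol ----------------------------------------------------------

#' Generate docked models (the main entry point)
#'
#' Runs the full local-docking protocol: one prepack, then per trajectory
#' {initial perturbation -> centroid-stage Monte Carlo -> side-chain
#' restoration -> high-resolution pack/minimize with dynamic protonation},
#' producing `cfg$n_models` candidate models ranked by interface score.
#'
#' @param receptor,ligand either a single `ph_complex` holding both
#'   partners (pass it as `receptor` and leave `ligand` NULL) or two
#'   single-partner complexes sharing no chain ids. A list of ligand
#'   conformers may be supplied; one is chosen uniformly per trajectory.
#' @param native optional native complex for metric evaluation.
#' @param cfg a [dock_config()].
#' @return object of class `phdock_run`: ranked models, the prepacked
#'   start, the filter log, and (when `native` is given) per-model metrics.
#' @export
dock <- function(receptor, ligand = NULL, native = NULL, cfg = dock_config()) {
  ligand_set <- if (!is.null(ligand) && is.list(ligand) &&
                      !is.ph_complex(ligand)) ligand else NULL
  cx <- if (is.null(ligand)) receptor
        else merge_partners(receptor,
                            if (is.null(ligand_set)) ligand else ligand_set[[1]])
  if (!is.ph_complex(cx)) stop("configuration error: receptor must be a ph_complex")
  if (!is.null(native)) check_matched(cx, native)
  cx$ph <- cfg$ph
  start <- prepack(cx, cfg$ph, seed = derive_seed(cfg$seed, 555))
  freeze <- cfg$mode == "fixed-protonation"
  models <- vector("list", cfg$n_models)
  for (t in seq_len(cfg$n_models)) {
    tseed <- derive_seed(cfg$seed, t)
    traj <- with_seed(tseed, {
      s0 <- start
      if (!is.null(ligand_set)) {
        pick <- sample(length(ligand_set), 1)
        s0 <- merge_partners(subset_partner(start, "receptor"),
                             ligand_set[[pick]])
        s0$ph <- cfg$ph
        s0 <- prepack(s0, cfg$ph, seed = derive_seed(tseed, 7))
      }
      s1 <- initial_perturb(s0, cfg)
      s2 <- lowres_stage(to_centroid(s1), cfg)
      restore_fullatom(s2, s0)
    })
    m <- highres_stage(traj, cfg, seed = derive_seed(tseed, 17),
                       freeze_protonation = freeze)
    m$id <- t
    models[[t]] <- m
  }
  run <- new_phdock_run(models, native = native, cfg = cfg, start = start)
  run
}

merge_partners <- function(a, b) {
  if (!is.ph_complex(a) || !is.ph_complex(b))
    stop("configuration error: both partners must be ph_complex objects")
  if (length(intersect(unique(a$residues$chain), unique(b$residues$chain))))
    stop("configuration error: partner chain ids overlap")
  atoms <- rbind(a$atoms, transform(b$atoms, res = res + nrow(a$residues)))
  residues <- rbind(a$residues, b$residues)
  split <- c(stats::setNames(rep("receptor", length(unique(a$residues$chain))),
                             unique(a$residues$chain)),
             stats::setNames(rep("ligand", length(unique(b$residues$chain))),
                             unique(b$residues$chain)))
  residues$partner <- unname(split[residues$chain])
  rownames(atoms) <- NULL; rownames(residues) <- NULL
  out <- new_ph_complex(atoms, rbind(a$xyz, b$xyz), residues, split,
                        a$representation, a$ph)
  out <- refresh_params(out)
  recompute_don_base(out)
}

check_matched <- function(a, b) {
  if (nrow(a$residues) != nrow(b$residues) ||
      !all(a$residues$aa == b$residues$aa) ||
      !all(a$residues$chain == b$residues$chain) ||
      !all(a$residues$resnum == b$residues$resnum))
    stop("configuration error: sequences do not match")
  invisible(TRUE)
}

new_phdock_run <- function(models, native = NULL, cfg = NULL, start = NULL,
                           filter_log = list()) {
  isc <- vapply(models, function(m) m$isc$isc, 0)
  ids <- vapply(models, function(m) m$id, 0L)
  ord <- order(isc, ids)
  run <- structure(list(models = models[ord], native = native, cfg = cfg,
                        start = start, filter_log = filter_log),
                   class = "phdock_run")
  if (!is.null(native)) run <- add_metrics(run)
  run
}

# per-model metric table against the native complex
add_metrics <- function(run) {
  nat <- run$native
  tab <- lapply(run$models, function(m) {
    mr <- metric_report(m$structure, nat)
    data.frame(id = m$id, isc = m$isc$isc,
               erep = m$breakdown$terms[["rep"]],
               irmsd = mr$irmsd, lrmsd = mr$lrmsd, fnat = mr$fnat,
               capri = mr$capri,
               n_hbonds = mr$n_interface_hbonds,
               fnat_hbonds = mr$fraction_native_hbonds,
               stringsAsFactors = FALSE)
  })
  run$metrics <- do.call(rbind, tab)
  run
}

#' @export
print.phdock_run <- function(x, ...) {
  n <- length(x$models)
  cat(sprintf("phdock_run: %d models at pH %.2f (mode %s)\n",
              n, x$cfg$ph, x$cfg$mode))
  isc <- vapply(x$models, function(m) m$isc$isc, 0)
  cat(sprintf("  interface score: best %.3f, median %.3f REU\n",
              min(isc), stats::median(isc)))
  if (!is.null(x$metrics)) {
    top <- x$metrics[x$metrics$id == x$models[[1]]$id, ]
    cat(sprintf("  top model: Irmsd %.2f A, Lrmsd %.2f A, fnat %.2f (%s)\n",
                top$irmsd, top$lrmsd, top$fnat, top$capri))
  }
  invisible(x)
}

#' @export
summary.phdock_run <- function(object, n_resamples = 1000, seed = 1, ...) {
  out <- list(n = length(object$models),
              isc = vapply(object$models, function(m) m$isc$isc, 0))
  if (!is.null(object$metrics)) {
    sc <- object$metrics[, c("isc", "irmsd")]
    out$funnel <- funnel_stats(sc$isc, sc$irmsd, n_resamples = n_resamples,
                               seed = seed)
    out$capri_counts <- table(factor(object$metrics$capri,
                                     levels = c("incorrect", "acceptable",
                                                "medium", "high")))
  }
  structure(out, class = "summary.phdock_run")
}

#' @export
print.summary.phdock_run <- function(x, ...) {
  cat(sprintf("%d models; interface score range [%.3f, %.3f] REU\n",
              x$n, min(x$isc), max(x$isc)))
  if (!is.null(x$funnel)) {
    f <- x$funnel
    cat(sprintf("funnel: D = %.3f (bootstrap %.3f +/- %.3f), N5 = %d (%s)\n",
                f$D, f$bootstrap_mu_D, f$bootstrap_sigma_D, f$N5,
                ifelse(f$N5 >= 3, "success", "failure")))
    print(x$capri_counts)
  }
  invisible(x)
}

#' Funnel plot (interface score vs Irmsd)
#'
#' @param x a `phdock_run` docked with a native reference.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phdock_run <- function(x, ...) {
  if (is.null(x$metrics))
    stop("configuration error: plot requires a run docked with a native")
  cols <- c(incorrect = "grey60", acceptable = "orange", medium = "red3",
            high = "blue3")
  graphics::plot(x$metrics$irmsd, x$metrics$isc,
                 col = cols[x$metrics$capri], pch = 19,
                 xlab = "Irmsd (A)", ylab = "Interface score (REU)", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   cex = 0.8)
  invisible(x)
}

#' Filter models by steric or score quality
#'
#' `"phdock"` mode removes the `ceiling(fraction * N)` models with the
#' highest repulsive van der Waals scores; `"rosettadock"` mode removes the
#' same count with the highest (worst) interface scores.
#'
#' @param run a `phdock_run`.
#' @param mode `"phdock"` or `"rosettadock"`.
#' @param fraction fraction removed, in `[0, 1)` (default 0.05).
#' @return the filtered `phdock_run`; removed ids appear in `$filter_log`.
#' @export
filter_models <- function(run, mode = c("phdock", "rosettadock"),
                          fraction = 0.05) {
  mode <- match.arg(mode)
  if (fraction < 0 || fraction >= 1)
    stop("domain error: fraction must lie in [0, 1)")
  n <- length(run$models)
  if (!n) stop("configuration error: empty model set")
  k <- ceiling(fraction * n)
  if (k == 0) return(run)
  key <- if (mode == "phdock")
    vapply(run$models, function(m) m$breakdown$terms[["rep"]], 0)
  else
    vapply(run$models, function(m) m$isc$isc, 0)
  ids <- vapply(run$models, function(m) m$id, 0L)
  drop <- order(-key, ids)[seq_len(k)]
  removed <- ids[drop]
  run$models <- run$models[-drop]
  if (!is.null(run$metrics))
    run$metrics <- run$metrics[!(run$metrics$id %in% removed), , drop = FALSE]
  run$filter_log <- c(run$filter_log,
                      list(list(mode = mode, fraction = fraction,
                                removed = removed)))
  run
}
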