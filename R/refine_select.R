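# Refinement of fully reconstructed models and selection of the final
# model set: iterative small backbone perturbations with local chain
# re-closure and gradient-free minimization under a soft-sphere potential
# whose repulsive weight is ramped up, followed by the energy-rank
# truncation (1000 or up to 10 percent), greedy leader clustering of the
# TM region, and the five-largest-families selection rule.

#' Refinement schedule
#'
#' @param n_cycles perturbation/minimization cycles.
#' @param perturbation_magnitude sd of the backbone torsion noise
#'   (degrees).
#' @param repulsive_ramp strictly increasing clash-term weights ending at
#'   1.0, visited in order across cycles (recycled from the last value).
#' @param minimizer run the gradient-free local minimization step.
#' @param constraint_weight weight of the harmonic constraint term.
#' @return object of class `refine_schedule`.
#' @export
refine_schedule <- function(n_cycles = 3L, perturbation_magnitude = 2.0,
                            repulsive_ramp = c(0.25, 0.55, 1.0),
                            minimizer = TRUE, constraint_weight = 3.0) {
  if (any(diff(repulsive_ramp) <= 0) ||
      utils::tail(repulsive_ramp, 1L) != 1.0)
    stop("repulsive_ramp must be strictly increasing and end at 1.0")
  structure(list(n_cycles = as.integer(n_cycles),
                 perturbation_magnitude = perturbation_magnitude,
                 repulsive_ramp = repulsive_ramp,
                 minimizer = isTRUE(minimizer),
                 constraint_weight = constraint_weight),
            class = "refine_schedule")
}

# surrogate all-atom score: soft-sphere CA/CB clashes with a scalable
# repulsive weight, harmonic constraints, a mild phi-positivity penalty,
# and a helicity restraint on TMH torsions.  The helicity term encodes
# the expectation that membrane-embedded helices stay helical except in
# the bend window N-terminal to a proline (where distortion is the
# point); without it the centroid-level score would happily satisfy
# template constraints by denting a helix end.
refine_energy <- function(s, constraints, rep_weight, cst_weight,
                          clash_radius = 3.6, helix_weight = 3.0,
                          helix_band = 30, flex = NULL) {
  e_clash <- clash_score(s, clash_pairs(s), clash_radius)
  e_cst <- if (!is.null(constraints)) constraint_energy(s, constraints)
    else 0
  tor <- backbone_torsions(s)
  phi_viol <- pmax(0, tor$phi[!is.na(tor$phi)])    # positive phi penalized
  e_tor <- sum((phi_viol / 60)^2)
  tm <- which(!is.na(s$segment) & grepl("^TM", s$segment))
  e_helix <- 0
  if (length(tm)) {
    exempt <- unlist(lapply(which(s$aa == "P"), function(p)
      max(1L, p - 4L):p))
    # annotated flexible windows (bends being remodeled)
    for (rg in flex)
      exempt <- c(exempt, which(s$resno >= rg[1L] & s$resno <= rg[2L]))
    # helices fray at their ends: leave 2 residues per segment edge free
    segs <- split(tm, s$segment[tm])
    edge <- unlist(lapply(segs, function(rr)
      c(utils::head(rr, 2L), utils::tail(rr, 2L))))
    hrows <- setdiff(tm, c(1L, nres(s), exempt, edge))
    if (length(hrows)) {
      dphi <- pmax(0, abs(wrap_angle(tor$phi[hrows] - HELIX_PHI)) -
                     helix_band)
      dpsi <- pmax(0, abs(wrap_angle(tor$psi[hrows] - HELIX_PSI)) -
                     helix_band)
      dphi[is.na(dphi)] <- 0; dpsi[is.na(dpsi)] <- 0
      e_helix <- sum((dphi / helix_band)^2 + (dpsi / helix_band)^2)
    }
  }
  rep_weight * e_clash + cst_weight * e_cst + 0.5 * e_tor +
    helix_weight * e_helix
}

#' Refine a reconstructed model
#'
#' Each cycle applies a small random torsion perturbation to a local
#' 5-residue window, re-closes the chain with CCD so the move stays
#' local, re-derives the (virtual) side-chain CB atoms, optionally runs a
#' Nelder-Mead minimization of the window torsions, and accepts the cycle
#' by the Metropolis criterion.  The repulsive clash weight follows the
#' schedule's ramp.  The lowest-energy structure encountered (evaluated
#' at full repulsion) is returned, so refinement can never end above the
#' start.
#'
#' @param s a closed [tmh_structure()] (no chain breaks).
#' @param constraints optional `constraint_set`.
#' @param sched a [refine_schedule()].
#' @param kT Metropolis temperature.
#' @param flex residue intervals exempt from the helicity restraint
#'   (e.g. the bend window being remodeled).
#' @return list with `structure`, `energy` (full-repulsion score) and
#'   `ramp_log` (weights actually used per cycle).
#' @export
refine <- function(s, constraints = NULL, sched = refine_schedule(),
                   kT = 1.0, flex = NULL) {
  if (length(chain_breaks(s)))
    stop("structure has chain breaks; close them before refinement")
  n <- nres(s)
  cw <- sched$constraint_weight
  full_e <- function(x) refine_energy(x, constraints, 1.0, cw, flex = flex)
  best <- s; e_best <- full_e(s)
  cur <- s
  ramp_log <- numeric(sched$n_cycles)
  for (cyc in seq_len(sched$n_cycles)) {
    w <- sched$repulsive_ramp[min(cyc, length(sched$repulsive_ramp))]
    ramp_log[cyc] <- w
    e_cur <- refine_energy(cur, constraints, w, cw, flex = flex)
    cand <- cur
    if (sched$perturbation_magnitude > 0 && n >= 7L) {
      i <- sample(2:(n - 5L), 1L)
      first <- s$resno[i]; brk <- s$resno[i + 3L]
      rows <- i:(i + 2L)
      tor <- backbone_torsions(cand)
      dphi <- stats::rnorm(3L, 0, sched$perturbation_magnitude)
      dpsi <- stats::rnorm(3L, 0, sched$perturbation_magnitude)
      cand <- rebuild_window(cand, i, i + 3L,
                             phi = c(tor$phi[rows] + dphi, NA),
                             psi = c(tor$psi[rows] + dpsi, NA))
      closed <- ccd_close(cand, loop_window(first, s$resno[i + 4L], brk),
                          max_cycles = 20L)
      cand <- closed$structure
      if (sched$minimizer) {
        obj <- function(par) {
          x <- rebuild_window(cand, i, i + 3L,
                              phi = c(par[1:3], NA),
                              psi = c(par[4:6], NA))
          gap <- chain_break_deviation(x, brk)
          refine_energy(x, constraints, w, cw, flex = flex) + 100 * gap^2
        }
        tor2 <- backbone_torsions(cand)
        par0 <- c(tor2$phi[rows], tor2$psi[rows])
        opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                            control = list(maxit = 25L))
        if (opt$value < obj(par0)) {
          cand <- rebuild_window(cand, i, i + 3L,
                                 phi = c(opt$par[1:3], NA),
                                 psi = c(opt$par[4:6], NA))
          closed <- ccd_close(cand,
                              loop_window(first, s$resno[i + 4L], brk),
                              max_cycles = 20L)
          cand <- closed$structure
        }
      }
    }
    e_new <- refine_energy(cand, constraints, w, cw, flex = flex)
    if (e_new <= e_cur || stats::runif(1L) < exp(-(e_new - e_cur) / kT))
      cur <- cand
    e_full <- full_e(cur)
    if (e_full < e_best) { best <- cur; e_best <- e_full }
  }
  list(structure = best, energy = e_best, ramp_log = ramp_log)
}

#' Model ensemble container
#'
#' @param structures list of [tmh_structure()] models.
#' @param energies numeric vector of model energies.
#' @param ids optional model identifiers (default sequential integers).
#' @return object of class `model_ensemble` with fields `models`
#'   (list of structures), `energies`, `ids`, `cluster_labels`,
#'   `selected_ids`.
#' @export
model_ensemble <- function(structures, energies, ids = NULL) {
  if (length(structures) != length(energies))
    stop("structures and energies differ in length")
  if (any(!is.finite(energies))) stop("energies must be finite")
  if (is.null(ids)) ids <- seq_along(structures)
  structure(list(models = structures, energies = as.numeric(energies),
                 ids = ids, cluster_labels = NULL, selected_ids = NULL),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model_ensemble> %d models, energy [%.2f, %.2f]%s%s\n",
              length(x$models),
              if (length(x$models)) min(x$energies) else NA,
              if (length(x$models)) max(x$energies) else NA,
              if (!is.null(x$cluster_labels))
                sprintf(", %d clusters", length(unique(x$cluster_labels)))
              else "",
              if (!is.null(x$selected_ids))
                sprintf(", %d selected", length(x$selected_ids)) else ""))
  invisible(x)
}

#' Keep the 1000 (or up to 10 percent) lowest-energy models
#'
#' Retains `min(1000, ceiling(0.10 * N))` models by ascending energy,
#' ties broken deterministically by model id.
#'
#' @param e a [model_ensemble()].
#' @param max_keep absolute cap (default 1000).
#' @param fraction fraction cap (default 0.10).
#' @return truncated `model_ensemble`.
#' @export
rank_and_truncate <- function(e, max_keep = 1000L, fraction = 0.10) {
  n <- length(e$models)
  if (n < 1L) stop("empty ensemble")
  keep_n <- min(max_keep, ceiling(fraction * n))
  ord <- order(e$energies, e$ids)
  keep <- sort(ord[seq_len(keep_n)])
  model_ensemble(e$models[keep], e$energies[keep], e$ids[keep])
}

# CA RMSD over the TM region after superposition
tm_region_rmsd <- function(a, b, tm_ranges) {
  rows_a <- unlist(lapply(tm_ranges, function(rg)
    which(a$resno >= rg[1L] & a$resno <= rg[2L])))
  rows_b <- unlist(lapply(tm_ranges, function(rg)
    which(b$resno >= rg[1L] & b$resno <= rg[2L])))
  kabsch_rmsd(a$CA[rows_a, , drop = FALSE],
              b$CA[rows_b, , drop = FALSE])$rmsd
}

#' Cluster the transmembrane region into structural families
#'
#' Greedy leader clustering: models are visited in ascending energy; a
#' model joins the first existing cluster whose leader (founding model)
#' is within `radius` TM-region CA RMSD, otherwise it founds a new
#' cluster.
#'
#' @param e a [model_ensemble()].
#' @param tm_ranges list of TMH residue intervals.
#' @param radius cluster radius in Angstrom (default 2.0).
#' @return the ensemble with `cluster_labels` filled (integer per model,
#'   in cluster discovery order).
#' @export
cluster_tm <- function(e, tm_ranges, radius = 2.0) {
  n <- length(e$models)
  labels <- integer(n)
  ord <- order(e$energies, e$ids)
  leaders <- integer()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(leaders)) {
      if (tm_region_rmsd(e$models[[i]], e$models[[leaders[k]]],
                         tm_ranges) <= radius) {
        labels[i] <- k; placed <- TRUE; break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      labels[i] <- length(leaders)
    }
  }
  e$cluster_labels <- labels
  e
}

#' Select the final models: five largest families, lowest energy each
#'
#' Takes the five largest clusters (ties broken by the lower best energy
#' in the cluster) and returns the lowest-energy member of each; with
#' fewer than five clusters, one model per cluster.
#'
#' @param e a clustered [model_ensemble()].
#' @param n_families number of families to draw from (default 5).
#' @return the ensemble with `selected_ids` filled, in family-size order.
#' @export
select_final <- function(e, n_families = 5L) {
  if (length(e$models) == 0L) stop("empty ensemble")
  if (is.null(e$cluster_labels))
    stop("ensemble must be clustered first (see cluster_tm)")
  labs <- e$cluster_labels
  cl_ids <- unique(labs)
  sizes <- vapply(cl_ids, function(k) sum(labs == k), integer(1L))
  best_e <- vapply(cl_ids, function(k) min(e$energies[labs == k]),
                   numeric(1L))
  ord <- cl_ids[order(-sizes, best_e, cl_ids)]
  chosen <- utils::head(ord, n_families)
  sel <- vapply(chosen, function(k) {
    members <- which(labs == k)
    members[order(e$energies[members],
                  e$ids[members])][1L]
  }, integer(1L))
  e$selected_ids <- e$ids[sel]
  e
}

#' Most accurate selected model (benchmarking mode)
#'
#' When a reference structure is available, returns the selected model
#' with the lowest TM-region CA RMSD to it.
#'
#' @param e a selected [model_ensemble()].
#' @param reference reference [tmh_structure()].
#' @param tm_ranges list of TMH residue intervals.
#' @return list with `structure`, `id` and `rmsd`.
#' @export
most_accurate_model <- function(e, reference, tm_ranges) {
  if (is.null(e$selected_ids)) stop("run select_final first")
  idx <- match(e$selected_ids, e$ids)
  rmsds <- vapply(idx, function(i)
    tm_region_rmsd(e$models[[i]], reference, tm_ranges), numeric(1L))
  best <- idx[which.min(rmsds)]
  list(structure = e$models[[best]], id = e$ids[best],
       rmsd = min(rmsds))
}

#' Write an ensemble manifest as TSV
#' @param e a `model_ensemble`.
#' @param path output TSV (model_id, path, energy, cluster, selected).
#' @param model_paths optional character vector of per-model file paths.
#' @export
write_manifest <- function(e, path, model_paths = NA_character_) {
  df <- data.frame(model_id = e$ids,
                   path = rep_len(model_paths, length(e$ids)),
                   energy = e$energies,
                   cluster = if (is.null(e$cluster_labels)) NA_integer_
                     else e$cluster_labels,
                   selected = e$ids %in% (e$selected_ids %||% integer()))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
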