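# Rigid-body sampling of (kinked) TMH conformations under Metropolis Monte
# Carlo.  The move set follows the kinked-helix parameterization: the
# moveable (m) fragment's C-terminus is translated to a random point on a
# hemisphere of Gaussian radius 7.2 +/- 0.6 Angstrom originating at the
# fixed (f) fragment's N-terminus (+z only, z pointing from the f
# N-terminus back towards m), its axis is rotated to a random direction
# restricted to the +z/+x quadrants (-x pointing from the m C-terminus to
# the reference residue's CB), each fragment may spin about its own
# helical axis, and the whole kinked unit may move rigidly.  Energies come
# from a coarse-grained surrogate score: soft-sphere clashes on CA/CB,
# harmonic template constraints, a Gaussian restraint to the starting
# pose, and a membrane-slab span term.

# Precompute the atom-pair index lists for the soft-sphere clash term
# (the atom layout is invariant under rigid moves, so the pairing can be
# reused across an entire Monte Carlo run).
clash_pairs <- function(s, skip_rows = integer(), min_sep = 2L) {
  st <- atom_stack(s)
  keep <- !(st$resrow %in% skip_rows)
  idx <- which(keep)
  rr <- st$resrow[idx]
  n <- length(idx)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sep <- abs(rr[ut[, 1L]] - rr[ut[, 2L]])
  ok <- sep >= min_sep
  list(i = idx[ut[ok, 1L]], j = idx[ut[ok, 2L]])
}

clash_score <- function(s, pairs, clash_radius = 3.6) {
  st <- atom_stack(s)
  dx <- st$xyz[pairs$i, 1L] - st$xyz[pairs$j, 1L]
  dy <- st$xyz[pairs$i, 2L] - st$xyz[pairs$j, 2L]
  dz <- st$xyz[pairs$i, 3L] - st$xyz[pairs$j, 3L]
  d2 <- dx * dx + dy * dy + dz * dz
  close_ <- d2 < clash_radius^2
  if (!any(close_)) return(0)
  sum((clash_radius - sqrt(d2[close_]))^2)
}

#' Sampler move-set parameters
#'
#' @param translation_mean,translation_sd Gaussian radius of the
#'   hemisphere translation (Angstrom; defaults 7.2 and 0.6).
#' @param restraint_radius scale of the Gaussian start-pose restraint in
#'   Angstrom; must lie in \[1.0, 1.5\].
#' @param steps Monte Carlo steps, between 1000 and 5000 for production
#'   runs (smaller values are permitted for quick scans).
#' @param spin_max maximum axial spin per move (degrees).
#' @param whole_helix_moves allow rigid moves of the entire kinked unit.
#' @param whole_trans_sd,whole_rot_sd amplitudes of the whole-unit move.
#' @param kT_schedule Metropolis temperature(s); recycled over steps.
#' @return object of class `move_set`.
#' @export
move_set <- function(translation_mean = 7.2, translation_sd = 0.6,
                     restraint_radius = 1.25, steps = 1000L,
                     spin_max = 30, whole_helix_moves = TRUE,
                     whole_trans_sd = 0.5, whole_rot_sd = 5,
                     kT_schedule = 1.0) {
  if (restraint_radius < 1.0 || restraint_radius > 1.5)
    stop("restraint_radius must lie in [1.0, 1.5] Angstrom")
  if (steps < 1L) stop("steps must be >= 1")
  stopifnot(translation_mean > 0, translation_sd > 0, spin_max > 0,
            all(kT_schedule > 0))
  structure(list(translation_mean = translation_mean,
                 translation_sd = translation_sd,
                 restraint_radius = restraint_radius,
                 steps = as.integer(steps), spin_max = spin_max,
                 whole_helix_moves = isTRUE(whole_helix_moves),
                 whole_trans_sd = whole_trans_sd,
                 whole_rot_sd = whole_rot_sd,
                 kT_schedule = kT_schedule),
            class = "move_set")
}

#' Draw a kink-translation vector
#'
#' Direction uniform on the +z hemisphere, radius Gaussian with the
#' configured mean and sd (truncated at zero).  Coordinates are in the
#' f-helix frame (z >= 0 always).
#'
#' @param params a [move_set()].
#' @param n number of draws.
#' @return n x 3 matrix of displacement vectors.
#' @export
sample_kink_translation <- function(params = move_set(), n = 1L) {
  z <- stats::runif(n)                       # cos(polar) uniform: area-true
  az <- stats::runif(n, 0, 2 * pi)
  r <- stats::rnorm(n, params$translation_mean, params$translation_sd)
  while (any(bad <- r <= 0))
    r[bad] <- stats::rnorm(sum(bad), params$translation_mean,
                           params$translation_sd)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(r * s * cos(az), r * s * sin(az), r * z)
}

#' Draw a quadrant-restricted kink rotation
#'
#' Samples a new direction for the (outward-pointing) m-helix axis,
#' uniform over the part of the unit sphere with non-negative x and z
#' components in the kink frame, and returns the rotation carrying the
#' current axis onto it.
#'
#' @param frame kink frame (orthonormal `x`, `y`, `z`) from the f helix;
#'   see [measure_kink()] for the conventions.
#' @param m_dir current outward m-axis direction (unit vector, world
#'   coordinates, pointing from the bend towards the m N-terminus).
#' @param amplitude fraction of the full reorienting rotation applied
#'   (1 = rotate all the way to the sampled direction; 0 = identity).
#' @return 3x3 rotation matrix (world coordinates).
#' @export
sample_kink_rotation <- function(frame, m_dir, amplitude = 1.0) {
  B <- cbind(frame$x, frame$y, frame$z)
  if (max(abs(crossprod(B) - diag(3L))) > 1e-6)
    stop("kink frame is not orthonormal")
  u <- stats::rnorm(3L)
  u <- unitv(u)
  u[1L] <- abs(u[1L]); u[3L] <- abs(u[3L])   # reflect into +x, +z quadrants
  v <- as.vector(B %*% u)
  R <- rotation_between(unitv(m_dir), v)
  if (amplitude >= 1) return(R)
  if (amplitude <= 0) return(diag(3L))
  ang <- rad2deg(acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))))
  if (ang < 1e-9) return(diag(3L))
  ax <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L],
          R[2L, 1L] - R[1L, 2L])
  if (vnorm(ax) < 1e-12) return(diag(3L))
  rot_axis_angle(ax, amplitude * ang)
}

# outward m-axis direction: from the bend towards the m N-terminus
outward_m_dir <- function(s, spec) {
  m_rows <- res_rows(s, spec$m_range[1L], spec$m_range[2L])
  -fit_helix_axis(s$CA[m_rows, , drop = FALSE])$direction
}

#' Propose one rigid-body sampler move
#'
#' One of four move kinds, chosen uniformly: the hemisphere translation +
#' quadrant rotation of the m fragment, an axial spin of the f fragment,
#' an axial spin of the m fragment, or a small rigid move of the whole
#' kinked unit.  The bend window is never moved directly; it is left as a
#' (possibly broken) gap to be re-closed by the loop builder.
#'
#' @param s a [tmh_structure()].
#' @param spec a [kink_spec()].
#' @param params a [move_set()].
#' @return list with `structure` and `move_kind`.
#' @export
propose_move <- function(s, spec, params = move_set()) {
  kinds <- c("kink", "f_spin", "m_spin")
  if (params$whole_helix_moves) kinds <- c(kinds, "whole_unit")
  kind <- sample(kinds, 1L)
  m1 <- spec$m_range[1L]; m2 <- spec$m_range[2L]
  f1 <- spec$f_range[1L]; f2 <- spec$f_range[2L]
  if (kind == "kink") {
    fr <- kink_frame(s, spec)
    tv <- sample_kink_translation(params, 1L)[1L, ]
    world <- tv[1L] * fr$x + tv[2L] * fr$y + tv[3L] * fr$z
    ca_mc <- s$CA[res_rows(s, m2, m2), ]
    shift <- (fr$origin + world) - ca_mc
    s <- apply_rigid_transform(s, m1, m2, t = shift)
    R <- sample_kink_rotation(fr, outward_m_dir(s, spec))
    pivot <- s$CA[res_rows(s, m2, m2), ]
    s <- apply_rigid_transform(s, m1, m2, R = R, pivot = pivot)
  } else if (kind %in% c("f_spin", "m_spin")) {
    rng <- if (kind == "f_spin") c(f1, f2) else c(m1, m2)
    rows <- res_rows(s, rng[1L], rng[2L])
    ax <- fit_helix_axis(s$CA[rows, , drop = FALSE])
    ang <- stats::runif(1L, -params$spin_max, params$spin_max)
    s <- apply_rigid_transform(s, rng[1L], rng[2L],
                               R = rot_axis_angle(ax$direction, ang),
                               pivot = ax$origin)
  } else {
    rows <- res_rows(s, m1, f2)
    centroid <- colMeans(s$CA[rows, , drop = FALSE])
    ang <- stats::rnorm(1L, 0, params$whole_rot_sd)
    axis <- unitv(stats::rnorm(3L))
    t <- stats::rnorm(3L, 0, params$whole_trans_sd)
    s <- apply_rigid_transform(s, m1, f2, R = rot_axis_angle(axis, ang),
                               t = t, pivot = centroid)
  }
  list(structure = s, move_kind = kind)
}

#' Coarse-grained surrogate energy
#'
#' Weighted sum of a soft-sphere CA/CB clash term, the harmonic template
#' constraint score, a Gaussian restraint on each sampled fragment's CA
#' displacement from its starting pose, and a membrane-span term
#' penalizing TMH CA atoms outside the hydrophobic slab.
#'
#' @param s a [tmh_structure()].
#' @param constraints optional `constraint_set`.
#' @param membrane list with `half_width` (Angstrom, default 15); the
#'   membrane normal is the z axis of the input frame.
#' @param start optional starting structure for the restraint term.
#' @param anchors residue numbers whose CA displacement from `start` is
#'   restrained -- the rigid-body "jump" anchors of the sampled fragments
#'   (the m C-terminus and f N-terminus for a kinked TMH).  Restraining
#'   the anchors rather than whole-fragment RMS keeps the sampled
#'   translation within the stated 1-1.5 Angstrom band without the
#'   lever-arm amplification that would veto the kink rotations the move
#'   set is designed to sample.
#' @param restraint_radius Gaussian restraint scale (Angstrom).
#' @param weights named list of term weights (`clash`, `cst`,
#'   `restraint`, `membrane`).
#' @param clash_radius soft-sphere contact radius (Angstrom).
#' @param skip_rows residue rows excluded from the clash term (e.g. an
#'   open bend window).
#' @return list with `total` and the individual terms.
#' @export
coarse_energy <- function(s, constraints = NULL,
                          membrane = list(half_width = 15),
                          start = NULL, anchors = NULL,
                          restraint_radius = 1.25,
                          weights = list(clash = 1, cst = 3,
                                         restraint = 1, membrane = 0.1),
                          clash_radius = 3.6, skip_rows = integer()) {
  st <- atom_stack(s)
  keep <- !(st$resrow %in% skip_rows)
  xyz <- st$xyz[keep, , drop = FALSE]
  rr <- st$resrow[keep]
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(rr, rr, "-"))
  mask <- upper.tri(d) & sep >= 2L & d < clash_radius
  e_clash <- sum((clash_radius - d[mask])^2)

  e_cst <- if (!is.null(constraints)) constraint_energy(s, constraints)
    else 0

  e_restraint <- 0
  if (!is.null(start) && !is.null(anchors)) {
    rows <- match(anchors, s$resno)
    disp <- sqrt(rowSums((s$CA[rows, , drop = FALSE] -
                          start$CA[rows, , drop = FALSE])^2))
    e_restraint <- sum((disp / restraint_radius)^2)
  }

  e_mem <- 0
  if (!is.null(membrane)) {
    tm <- which(!is.na(s$segment) & grepl("^TM", s$segment))
    if (length(tm)) {
      zdev <- pmax(0, abs(s$CA[tm, 3L]) - membrane$half_width)
      e_mem <- sum(zdev^2)
    }
  }
  total <- weights$clash * e_clash + weights$cst * e_cst +
    weights$restraint * e_restraint + weights$membrane * e_mem
  list(total = total, clash = e_clash, cst = e_cst,
       restraint = e_restraint, membrane = e_mem)
}

#' Metropolis Monte Carlo run over the TMH move set
#'
#' @param start starting [tmh_structure()].
#' @param spec a [kink_spec()].
#' @param constraints optional `constraint_set`.
#' @param params a [move_set()].
#' @param membrane membrane slab parameters (see [coarse_energy()]).
#' @param energy_fn optional replacement energy: function(structure) ->
#'   numeric (used by toy-system tests); default is [coarse_energy()]
#'   with the start restraint over the m and f fragments.
#' @param log_trajectory keep a per-step data.frame (step, move_kind,
#'   energy, accepted).
#' @return object of class `sampler_state`: list with `structure` (final),
#'   `energy`, `best_structure`, `best_energy`, `accepted`, `proposed`
#'   and optionally `trajectory`.
#' @export
mc_run <- function(start, spec, constraints = NULL, params = move_set(),
                   membrane = list(half_width = 15), energy_fn = NULL,
                   log_trajectory = FALSE) {
  bend_rows <- res_rows(start, spec$bend_range[1L], spec$bend_range[2L])
  anchors <- c(spec$m_range[2L], spec$f_range[1L])
  if (is.null(energy_fn)) {
    # precomputed fast path; agrees with coarse_energy() term by term
    w <- list(clash = 1, cst = 3, restraint = 1, membrane = 0.1)
    pp <- clash_pairs(start, skip_rows = bend_rows)
    ci <- if (!is.null(constraints) && nrow(constraints) > 0L)
      match(constraints$res_i, start$resno) else integer()
    cj <- if (length(ci)) match(constraints$res_j, start$resno)
      else integer()
    arow <- match(anchors, start$resno)
    a0 <- start$CA[arow, , drop = FALSE]
    tmrow <- which(!is.na(start$segment) & grepl("^TM", start$segment))
    hw <- membrane$half_width %||% 15
    energy_fn <- function(s) {
      e <- w$clash * clash_score(s, pp)
      if (length(ci)) {
        d <- sqrt(rowSums((s$CA[ci, , drop = FALSE] -
                           s$CA[cj, , drop = FALSE])^2))
        excess <- pmax(0, abs(d - constraints$d0) - constraints$width)
        e <- e + w$cst * sum(constraints$weight * excess^2)
      }
      disp <- sqrt(rowSums((s$CA[arow, , drop = FALSE] - a0)^2))
      e <- e + w$restraint * sum((disp / params$restraint_radius)^2)
      if (length(tmrow)) {
        zdev <- pmax(0, abs(s$CA[tmrow, 3L]) - hw)
        e <- e + w$membrane * sum(zdev^2)
      }
      e
    }
  }

  cur <- start; e_cur <- energy_fn(cur)
  best <- cur; e_best <- e_cur
  accepted <- 0L
  kts <- rep_len(params$kT_schedule, params$steps)
  traj <- if (log_trajectory)
    data.frame(step = integer(), move_kind = character(),
               energy = numeric(), accepted = logical()) else NULL
  for (step in seq_len(params$steps)) {
    prop <- propose_move(cur, spec, params)
    e_new <- energy_fn(prop$structure)
    dE <- e_new - e_cur
    acc <- dE <= 0 || stats::runif(1L) < exp(-dE / kts[step])
    if (acc) {
      cur <- prop$structure; e_cur <- e_new
      accepted <- accepted + 1L
      if (e_cur < e_best) { best <- cur; e_best <- e_cur }
    }
    if (log_trajectory)
      traj[nrow(traj) + 1L, ] <- list(step, prop$move_kind, e_cur, acc)
  }
  structure(list(structure = cur, energy = e_cur, best_structure = best,
                 best_energy = e_best, accepted = accepted,
                 proposed = params$steps, trajectory = traj),
            class = "sampler_state")
}

#' @export
print.sampler_state <- function(x, ...) {
  cat(sprintf(
    "<sampler_state> %d/%d moves accepted (%.1f%%), energy %.3f (best %.3f)\n",
    x$accepted, x$proposed, 100 * x$accepted / max(1L, x$proposed),
    x$energy, x$best_energy))
  invisible(x)
}
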