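# Synthetic fixture generation: idealized kinked helical bundles standing
# in for target structures, geometrically perturbed/straightened copies
# standing in for homolog templates, and alignments / TMH annotations /
# proline profiles consistent with the edits.  Everything is deterministic
# given the spec's seed.
#
# The bundles emulate the geometry of native TMH proteins at the level the
# modeling protocol cares about: ~10 Angstrom inter-axis spacing,
# antiparallel packing, membrane normal along z, proline-anchored kinks
# with 4-residue bend windows.  They are not physically realistic beyond
# that (no lipids, no side chains beyond CB).

TMH_ALPHABET <- c("A", "L", "I", "V", "F", "G", "S", "T", "M", "W")

#' Bundle fixture specification
#'
#' @param n_helices number of TMHs (>= 1).
#' @param helix_length residues per TMH (>= 10).
#' @param loop_length residues per connecting loop.
#' @param kinks list of kinks, each `list(helix, kink_angle, swing)`:
#'   helix index, kink angle in degrees (0 to 90), azimuth of the kink
#'   direction in degrees.  The bend window is the 4 residues preceding
#'   the reference proline placed just past the helix midpoint.
#' @param seq_identity_target template sequence identity requested from
#'   [make_template_from_target()].
#' @param perturbation template coordinate noise (Angstrom).
#' @param seed RNG seed making the fixture deterministic.
#' @return object of class `bundle_spec`.
#' @export
bundle_spec <- function(n_helices = 3L, helix_length = 18L,
                        loop_length = 4L, kinks = list(),
                        seq_identity_target = 1.0, perturbation = 0.0,
                        seed = 1L) {
  if (n_helices < 1L) stop("n_helices must be >= 1")
  if (helix_length < 10L) stop("helix_length must be >= 10")
  for (k in kinks) {
    if (k$kink_angle < 0 || k$kink_angle > 90)
      stop("kink_angle must lie in [0, 90] degrees")
    if (k$helix < 1L || k$helix > n_helices)
      stop("kink refers to a helix outside the bundle")
  }
  structure(list(n_helices = as.integer(n_helices),
                 helix_length = as.integer(helix_length),
                 loop_length = as.integer(loop_length), kinks = kinks,
                 seq_identity_target = seq_identity_target,
                 perturbation = perturbation, seed = as.integer(seed)),
            class = "bundle_spec")
}

# global residue interval of helix k in the bundle chain
helix_interval <- function(spec, k) {
  per <- spec$helix_length + spec$loop_length
  first <- (k - 1L) * per + 1L
  c(first, first + spec$helix_length - 1L)
}

# kink_spec of the j-th kink in the bundle's residue numbering
bundle_kink_spec <- function(spec, j) {
  kk <- spec$kinks[[j]]
  h <- helix_interval(spec, kk$helix)
  ref <- h[1L] + spec$helix_length %/% 2L + 2L  # proline past midpoint
  bend <- c(ref - 4L, ref - 1L)
  kink_spec(m_range = c(h[1L], bend[1L] - 1L), bend_range = bend,
            f_range = c(ref, h[2L]), ref_residue = ref, strict = FALSE)
}

#' Generate a synthetic kinked TMH bundle
#'
#' Helices are placed on a circle with ~10 Angstrom spacing between
#' neighboring axes, alternating up/down (antiparallel), membrane normal
#' along z.  Kinks are applied by rotating the m fragment about an axis
#' through the bend, and the bend windows plus connecting loops are closed
#' de novo with the loop builder.
#'
#' @param spec a [bundle_spec()].
#' @return list with `structure` (the target), `annotations` (segment
#'   data.frame), `kinks` (list of [kink_spec()]), `sequence`.
#' @export
make_kinked_bundle <- function(spec) {
  set.seed(spec$seed)
  nh <- spec$n_helices; hl <- spec$helix_length; ll <- spec$loop_length
  n_total <- nh * hl + (nh - 1L) * ll

  # sequence: hydrophobic-biased, prolines only at kink reference sites
  aa <- sample(TMH_ALPHABET, n_total, replace = TRUE)
  kspecs <- lapply(seq_along(spec$kinks), function(j)
    bundle_kink_spec(spec, j))
  for (ks in kspecs) aa[ks$ref_residue] <- "P"

  # helix center positions on a circle of ~10 A neighbor spacing
  if (nh == 1L) {
    centers <- matrix(0, 1L, 2L)
  } else if (nh == 2L) {
    centers <- rbind(c(-5, 0), c(5, 0))
  } else {
    rc <- 10 / (2 * sin(pi / nh))
    th <- 2 * pi * (seq_len(nh) - 1L) / nh
    centers <- cbind(rc * cos(th), rc * sin(th))
  }
  half_span <- (hl - 1L) * HELIX_RISE / 2

  parts <- vector("list", nh)
  for (k in seq_len(nh)) {
    up <- k %% 2L == 1L
    dir <- if (up) c(0, 0, 1) else c(0, 0, -1)
    start <- c(centers[k, ], if (up) -half_span else half_span)
    h <- helix_interval(spec, k)
    parts[[k]] <- ideal_helix(hl, start = start, direction = dir,
                              sequence = paste(aa[h[1L]:h[2L]],
                                               collapse = ""),
                              resno = h[1L]:h[2L])
  }

  # assemble full chain: helices in place, loops initialized by ideal
  # continuation from the previous helix (broken at the next helix start)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n_total, 3L)
  seg <- rep(NA_character_, n_total)
  put <- function(dst, part, rows) {
    for (a in c("N", "CA", "C", "O", "CB")) dst[[a]][rows, ] <- part[[a]]
    dst
  }
  buf <- list(N = N, CA = CA, C = C, O = O, CB = CB)
  for (k in seq_len(nh)) {
    h <- helix_interval(spec, k)
    buf <- put(buf, parts[[k]], h[1L]:h[2L])
    seg[h[1L]:h[2L]] <- sprintf("TM%d", k)
    if (k < nh) {
      lo <- h[2L] + 1L; hi <- lo + ll - 1L
      seg[lo:hi] <- sprintf("L%d", k)
      anchor <- list(N = parts[[k]]$N[hl, ], CA = parts[[k]]$CA[hl, ],
                     C = parts[[k]]$C[hl, ], psi = -47, omega = 180)
      lp <- build_backbone(aa[lo:hi], phi = rep(-70, ll),
                           psi = rep(150, ll), anchor = anchor)
      buf <- put(buf, lp, lo:hi)
    }
  }
  s <- tmh_structure(resno = seq_len(n_total), aa = aa, N = buf$N,
                     CA = buf$CA, C = buf$C, O = buf$O, CB = buf$CB,
                     segment = seg, validate = FALSE)
  s <- rederive_oxy_cb(s)

  # apply kinks: tilt the outward m axis away from the reference CB in the
  # kink frame, so the resulting geometry lies inside the quadrant the
  # rigid-body sampler explores (kinks point away from the proline ring,
  # as in native kinked TMHs)
  for (j in seq_along(kspecs)) {
    ks <- kspecs[[j]]; kk <- spec$kinks[[j]]
    if (kk$kink_angle <= 0) next
    fr <- kink_frame(s, ks)
    sw <- deg2rad(kk$swing %||% 0)
    th <- deg2rad(kk$kink_angle)
    tilt_dir <- cos(sw) * fr$x + sin(sw) * fr$y
    new_out <- cos(th) * fr$z + sin(th) * tilt_dir
    R <- rotation_between(outward_m_dir(s, ks), new_out)
    pivot <- s$CA[res_rows(s, ks$m_range[2L], ks$m_range[2L]), ]
    s <- apply_rigid_transform(s, ks$m_range[1L], ks$m_range[2L],
                               R = R, pivot = pivot)
    # native kinks compress the bend: set the m C-terminus at the
    # canonical 7.2 Angstrom from the f N-terminus
    mc <- s$CA[res_rows(s, ks$m_range[2L], ks$m_range[2L]), ]
    dvec <- mc - fr$origin
    shift <- (fr$origin + 7.2 * unitv(dvec)) - mc
    s <- apply_rigid_transform(s, ks$m_range[1L], ks$m_range[2L],
                               t = shift)
  }

  # close bends and loops de novo
  lib <- build_fragment_library("ideal")
  close_around_kink <- function(s, ks) {
    s <- rebuild_region(s, loop_window(ks$bend_range[1L],
                                       ks$bend_range[2L]), lib)
    if (ks$m_range[1L] > 1L) {
      # the kinked TMH's upstream loop also needs re-closing
      lo <- ks$m_range[1L] - ll
      s <- rebuild_region(s, loop_window(lo, lo + ll - 1L), lib)
    }
    s
  }
  for (ks in kspecs) s <- close_around_kink(s, ks)
  for (k in seq_len(nh - 1L)) {
    h <- helix_interval(spec, k)
    lo <- h[2L] + 1L
    if (any(chain_breaks(s) %in% (lo - 1L):(lo + ll - 1L)) ||
        window_gap(s, lo, lo + ll - 1L) > 0.2)
      s <- rebuild_region(s, loop_window(lo, lo + ll - 1L), lib)
  }

  # corrective pass: window expansion during closure can bend the helix
  # edge and shift the realized kink; rotate the m fragment by the
  # residual (a small move the re-closure absorbs without expanding)
  for (iter in 1:3) {
    done <- TRUE
    for (j in seq_along(kspecs)) {
      ks <- kspecs[[j]]
      want <- spec$kinks[[j]]$kink_angle
      if (want <= 0) next
      mk <- measure_kink(s, ks)
      resid <- want - mk$kink_angle
      if (abs(resid) < 0.5) next
      done <- FALSE
      m_rows <- res_rows(s, ks$m_range[1L], ks$m_range[2L])
      f_rows <- res_rows(s, ks$f_range[1L], ks$f_range[2L])
      m_dir <- fit_helix_axis(s$CA[m_rows, , drop = FALSE])$direction
      f_dir <- fit_helix_axis(s$CA[f_rows, , drop = FALSE])$direction
      axis <- vcross(m_dir, f_dir)
      if (vnorm(axis) < 1e-6) axis <- unitv(vcross(f_dir, c(1, 0, 0)))
      pivot <- s$CA[res_rows(s, ks$m_range[2L], ks$m_range[2L]), ]
      s_try <- apply_rigid_transform(s, ks$m_range[1L], ks$m_range[2L],
                                     R = rot_axis_angle(axis, resid),
                                     pivot = pivot)
      if (abs(measure_kink(s_try, ks)$kink_angle - want) > abs(resid))
        s_try <- apply_rigid_transform(s, ks$m_range[1L], ks$m_range[2L],
                                       R = rot_axis_angle(axis, -resid),
                                       pivot = pivot)
      s <- close_around_kink(s_try, ks)
    }
    if (done) break
  }
  s <- rederive_oxy_cb(s)

  ann <- do.call(rbind, lapply(seq_len(nh), function(k) {
    h <- helix_interval(spec, k)
    rows <- data.frame(segment_id = sprintf("TM%d", k),
                       first_res = h[1L], last_res = h[2L], kind = "TMH",
                       stringsAsFactors = FALSE)
    if (k < nh)
      rows <- rbind(rows, data.frame(segment_id = sprintf("L%d", k),
                                     first_res = h[2L] + 1L,
                                     last_res = h[2L] + ll,
                                     kind = "loop",
                                     stringsAsFactors = FALSE))
    rows
  }))
  list(structure = s, annotations = ann, kinks = kspecs,
       sequence = paste(aa, collapse = ""))
}

#' Derive a synthetic homolog template from a target fixture
#'
#' The template is the same bundle rebuilt with kinks straightened (when
#' requested), per-atom Gaussian coordinate noise added, loop residues
#' optionally deleted (producing alignment gaps), and the sequence
#' mutated down to the requested identity.  Straightened kinks also lose
#' their proline in the template sequence, so the alignment-level bend
#' rule can detect the mismatch.  The returned alignment and proline
#' profile are consistent with the edits.
#'
#' @param target result of [make_kinked_bundle()].
#' @param spec the [bundle_spec()] used for the target (its
#'   `perturbation` and `seq_identity_target` fields drive the edits).
#' @param straighten_kinks replace kinked TMHs by straight ones in the
#'   template (default `TRUE` when the target has kinks).
#' @param delete_loop index of a loop whose residues are deleted from the
#'   template (`NULL` for none).
#' @return list with `structure`, `alignment` (a `pair_alignment`),
#'   `proline_profile`, `annotations`.
#' @export
make_template_from_target <- function(target, spec,
                                      straighten_kinks = TRUE,
                                      delete_loop = NULL) {
  straight_spec <- spec
  if (straighten_kinks) straight_spec$kinks <- list()
  tpl_bundle <- make_kinked_bundle(straight_spec)
  tpl <- tpl_bundle$structure
  set.seed(spec$seed + 104729L)

  # template keeps the target sequence except where edits demand
  tpl$aa <- target$structure$aa
  if (straighten_kinks)
    for (ks in target$kinks) tpl$aa[ks$ref_residue] <- "L"

  # mutate down to the requested identity (prolines and their template
  # replacements are left alone so bend bookkeeping stays consistent)
  ident <- spec$seq_identity_target
  n <- nres(tpl)
  protected <- unique(unlist(lapply(target$kinks, function(ks)
    ks$ref_residue)))
  if (ident < 1.0) {
    n_mut <- round((1 - ident) * n)
    eligible <- setdiff(seq_len(n), protected)
    mut <- sample(eligible, min(n_mut, length(eligible)))
    for (i in mut) {
      choices <- setdiff(c(AA1), c(tpl$aa[i], "P"))
      tpl$aa[i] <- sample(choices, 1L)
    }
  }

  if (spec$perturbation > 0) {
    for (a in c("N", "CA", "C"))
      tpl[[a]] <- tpl[[a]] + matrix(stats::rnorm(3L * n, 0,
                                                 spec$perturbation),
                                    n, 3L)
    tpl <- rederive_oxy_cb(tpl)
  }

  deleted <- integer()
  ann <- tpl_bundle$annotations
  if (!is.null(delete_loop)) {
    lid <- sprintf("L%d", delete_loop)
    row <- ann[ann$segment_id == lid, ]
    if (nrow(row) == 0L) stop("no such loop: ", lid)
    deleted <- row$first_res:row$last_res
    keep <- !(tpl$resno %in% deleted)
    tpl <- subset_structure(tpl, which(keep))
    tpl$resno <- seq_len(nres(tpl))    # template renumbered sequentially
  }

  tgt_seq <- strsplit(target$sequence, "")[[1L]]
  # template row: template residue letters, '-' at deleted columns
  tpl_row <- character(length(tgt_seq))
  ti <- 0L
  for (cc in seq_along(tgt_seq)) {
    if (cc %in% deleted) { tpl_row[cc] <- "-"; next }
    ti <- ti + 1L
    tpl_row[cc] <- tpl$aa[ti]
  }
  fasta <- c(">target", paste(tgt_seq, collapse = ""),
             ">template", paste(tpl_row, collapse = ""))
  aln <- parse_alignment(fasta)

  profile <- as.numeric(tgt_seq == "P")
  list(structure = tpl, alignment = aln, proline_profile = profile,
       annotations = ann)
}

#' Generate a feasible loop-closure problem
#'
#' Builds a two-helix fixture bundle with a connecting loop of the given
#' length, then "opens" the loop by randomizing its torsions (a chain
#' break appears at the loop end).  Since the closed conformation exists
#' by construction, the anchors are guaranteed feasible.
#'
#' @param loop_length loop residues (6 to 12 used by the closure suite).
#' @param seed RNG seed.
#' @return list with `structure` (opened), `window` (a [loop_window()]),
#'   `closed` (the original closed structure).
#' @export
make_loop_problem <- function(loop_length = 8L, seed = 1L) {
  sp <- bundle_spec(n_helices = 2L, helix_length = 14L,
                    loop_length = loop_length, seed = seed)
  b <- make_kinked_bundle(sp)
  s <- b$structure
  lo <- helix_interval(sp, 1L)[2L] + 1L
  hi <- lo + loop_length - 1L
  set.seed(seed + 7919L)
  nl <- loop_length
  open <- rebuild_window(s, lo, hi,
                         phi = stats::runif(nl, -150, -40),
                         psi = stats::runif(nl, -60, 160))
  list(structure = open, window = loop_window(lo, hi), closed = s)
}

#' Write a fixture set to disk (PDB + FASTA + TSV annotations + profile)
#'
#' @param target result of [make_kinked_bundle()].
#' @param template result of [make_template_from_target()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(target, template, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(write_pdb(target$structure, include_virtual_cb = TRUE),
             file.path(dir, "target.pdb"))
  writeLines(write_pdb(template$structure, include_virtual_cb = TRUE),
             file.path(dir, "template.pdb"))
  writeLines(c(">target", template$alignment$target_seq,
               ">template", template$alignment$template_seq),
             file.path(dir, "alignment.fasta"))
  write_segments(target$annotations, file.path(dir, "target_segments.tsv"))
  write_segments(template$annotations,
                 file.path(dir, "template_segments.tsv"))
  prof <- data.frame(column = seq_along(template$proline_profile),
                     fraction = template$proline_profile)
  utils::write.table(prof, file.path(dir, "proline_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
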