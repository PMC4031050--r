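# Helix construction, axis fitting and kink parameterization.
#
# A kinked TMH is treated as two quasi-straight helical fragments -- m
# ("moveable", N-terminal) and f ("fixed", C-terminal, starting at the
# bend-inducing residue such as a proline) -- separated by a short
# distorted bend (4-6 residues).  The kink is parameterized by the
# interhelical (tilt) angle between the two fitted axes, the translation
# between the m C-terminus CA and the f N-terminus CA, and the swing
# azimuth of the m N-terminus in the plane orthogonal to the f axis
# through the reference residue's CB.

HELIX_PHI <- -57
HELIX_PSI <- -47
HELIX_TWIST <- 100    # degrees per residue
HELIX_RISE <- 1.5     # Angstrom per residue

#' Kinked-helix specification
#'
#' @param m_range,bend_range,f_range length-2 integer vectors giving the
#'   closed residue intervals of the moveable helix, the bend window and
#'   the fixed helix.  They must be contiguous in that sequence order.
#' @param ref_residue index of the bend-inducing residue (e.g. the
#'   proline); conventionally the first residue of the f fragment.
#' @param kink_angle,translation,swing measured kink descriptors (degrees,
#'   Angstrom, degrees); usually filled in by [measure_kink()].
#' @param strict enforce the default 4-6 residue bend-window length.
#' @return object of class `kink_spec`.
#' @export
kink_spec <- function(m_range, bend_range, f_range, ref_residue,
                      kink_angle = NA_real_, translation = NA_real_,
                      swing = NA_real_, strict = TRUE) {
  m_range <- as.integer(m_range); f_range <- as.integer(f_range)
  bend_range <- as.integer(bend_range)
  if (m_range[2L] + 1L != bend_range[1L] ||
      bend_range[2L] + 1L != f_range[1L])
    stop("m_range, bend_range, f_range must be contiguous and in order")
  blen <- bend_range[2L] - bend_range[1L] + 1L
  if (strict && (blen < 4L || blen > 6L))
    stop("bend window must span 4 to 6 residues (got ", blen, ")")
  if (!is.na(kink_angle) && (kink_angle < 0 || kink_angle >= 180))
    stop("kink_angle must lie in [0, 180)")
  structure(list(m_range = m_range, bend_range = bend_range,
                 f_range = f_range, ref_residue = as.integer(ref_residue),
                 kink_angle = kink_angle, translation = translation,
                 swing = swing),
            class = "kink_spec")
}

#' @export
print.kink_spec <- function(x, ...) {
  cat(sprintf(
    "<kink_spec> m [%d-%d] | bend [%d-%d] | f [%d-%d], ref %d; angle %.1f deg, transl %.2f A, swing %.1f deg\n",
    x$m_range[1L], x$m_range[2L], x$bend_range[1L], x$bend_range[2L],
    x$f_range[1L], x$f_range[2L], x$ref_residue, x$kink_angle,
    x$translation, x$swing))
  invisible(x)
}

#' Build an ideal alpha-helix
#'
#' Canonical backbone (1.5 Angstrom rise, 100 degrees twist per residue,
#' standard internal geometry) with the helical axis along `direction` and
#' the first CA at `start`.
#'
#' @param n number of residues (>= 1).
#' @param start xyz of the first CA.
#' @param direction axis direction (need not be unit length).
#' @param sequence one-letter sequence (recycled "A" by default).
#' @param resno residue numbers (default `1:n`).
#' @return a [tmh_structure()].
#' @export
ideal_helix <- function(n, start = c(0, 0, 0), direction = c(0, 0, 1),
                        sequence = NULL, resno = seq_len(n)) {
  if (n < 1L) stop("n must be >= 1")
  if (is.null(sequence)) sequence <- strrep("A", n)
  aa <- strsplit(sequence, "")[[1L]]
  if (length(aa) == 1L && n > 1L) aa <- rep(aa, n)
  if (length(aa) != n) stop("sequence length must equal n")
  nb <- max(n, 12L)
  h <- build_backbone(c(aa, rep("A", nb - n)),
                      phi = rep(HELIX_PHI, nb), psi = rep(HELIX_PSI, nb))
  ax <- fit_helix_axis(h$CA)
  R <- rotation_between(ax$direction, direction)
  for (a in c("N", "CA", "C", "O", "CB"))
    h[[a]] <- transform_xyz(h[[a]], R = R)
  shift <- start - h$CA[1L, ]
  for (a in c("N", "CA", "C", "O", "CB"))
    h[[a]] <- transform_xyz(h[[a]], t = shift)
  h <- subset_structure(h, seq_len(n))
  h$resno <- as.integer(resno)
  h
}

#' Fit a helical axis through CA coordinates
#'
#' Each interior CA is projected towards the local helix center using its
#' two flanking residues (the flank-bisector points at the axis and the
#' axial components cancel); a total-least-squares line is then fit through
#' the centers.  This stays stable on fragments as short as 4 residues
#' where PCA on the raw CAs is biased by helical wobble.
#'
#' @param ca n x 3 matrix of CA coordinates in N-to-C order (n >= 4).
#' @return object of class `helix_axis` with fields `origin`, `direction`
#'   (unit, oriented N to C) and `rise_per_residue`.
#' @export
fit_helix_axis <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 4L) stop("need at least 4 CA positions to fit a helix axis")
  scale <- 2 * (1 - cos(deg2rad(HELIX_TWIST)))
  centers <- matrix(NA_real_, n - 2L, 3L)
  for (i in 2:(n - 1L)) {
    v <- (ca[i - 1L, ] - ca[i, ]) + (ca[i + 1L, ] - ca[i, ])
    if (vnorm(v) < 1e-6)
      stop("degenerate (collinear) CA trace: cannot fit a helix axis")
    centers[i - 1L, ] <- ca[i, ] + v / scale
  }
  org <- colMeans(centers)
  cc <- sweep(centers, 2L, org)
  dir <- svd(cc, nu = 0L, nv = 3L)$v[, 1L]
  if (sum(dir * (ca[n, ] - ca[1L, ])) < 0) dir <- -dir
  proj <- as.vector(ca %*% dir)
  rise <- (proj[n] - proj[1L]) / (n - 1L)
  if (rise <= 0.5 || rise >= 2.5)
    stop(sprintf("rise per residue %.2f outside (0.5, 2.5): not helical",
                 rise))
  structure(list(origin = org, direction = unitv(dir),
                 rise_per_residue = rise),
            class = "helix_axis")
}

# Orthonormal sampling/measurement frame of a kinked helix.
# z points from the f N-terminus back towards the m fragment (i.e. along
# -f axis); -x points from the m C-terminus CA towards the CB of the
# reference residue (projected orthogonal to z); y completes a
# right-handed frame.  `origin` is the CA of the f N-terminal residue.
kink_frame <- function(s, spec) {
  f_rows <- res_rows(s, spec$f_range[1L], spec$f_range[2L])
  f_ax <- fit_helix_axis(s$CA[f_rows, , drop = FALSE])
  z <- -f_ax$direction
  mc <- s$CA[res_rows(s, spec$m_range[2L], spec$m_range[2L]), ]
  ref_cb <- s$CB[res_rows(s, spec$ref_residue, spec$ref_residue), ]
  v <- ref_cb - mc
  v_perp <- v - sum(v * z) * z
  if (vnorm(v_perp) < 1e-6)
    stop("reference CB is collinear with the f helix axis: frame undefined")
  minus_x <- unitv(v_perp)
  x <- -minus_x
  y <- vcross(z, x)
  list(origin = s$CA[res_rows(s, spec$f_range[1L], spec$f_range[1L]), ],
       x = x, y = y, z = z, f_axis = f_ax)
}

#' Measure kink descriptors of a structure
#'
#' @param s a [tmh_structure()].
#' @param spec a [kink_spec()] giving the m/bend/f residue intervals and
#'   reference residue.
#' @return the `kink_spec` with `kink_angle`, `translation` and `swing`
#'   filled in from the coordinates.
#' @export
measure_kink <- function(s, spec) {
  m_rows <- res_rows(s, spec$m_range[1L], spec$m_range[2L])
  f_rows <- res_rows(s, spec$f_range[1L], spec$f_range[2L])
  if (length(m_rows) < 4L || length(f_rows) < 4L)
    stop("helix fragments must have at least 4 residues to measure a kink")
  m_ax <- fit_helix_axis(s$CA[m_rows, , drop = FALSE])
  f_ax <- fit_helix_axis(s$CA[f_rows, , drop = FALSE])
  cosang <- max(-1, min(1, sum(m_ax$direction * f_ax$direction)))
  spec$kink_angle <- rad2deg(acos(cosang))

  ca_mc <- s$CA[res_rows(s, spec$m_range[2L], spec$m_range[2L]), ]
  ca_fn <- s$CA[res_rows(s, spec$f_range[1L], spec$f_range[1L]), ]
  spec$translation <- vnorm(ca_mc - ca_fn)

  # swing: azimuth of the m N-terminus projection on the plane orthogonal
  # to f through the reference residue's CB, zero at the -x reference,
  # right-handed about the f axis (N to C)
  fr <- kink_frame(s, spec)
  zf <- f_ax$direction
  ref_cb <- s$CB[res_rows(s, spec$ref_residue, spec$ref_residue), ]
  p <- s$CA[res_rows(s, spec$m_range[1L], spec$m_range[1L]), ] - ref_cb
  p_perp <- p - sum(p * zf) * zf
  minus_x <- -fr$x
  spec$swing <- rad2deg(atan2(sum(vcross(minus_x, p_perp) * zf),
                              sum(minus_x * p_perp)))
  spec
}

#' Rigidly transform a residue range
#'
#' Atoms of residues in `[first, last]` are rotated about `pivot` and
#' translated; all other atoms are untouched (a chain break may appear at
#' the range boundary and will be reported by [chain_breaks()]).
#'
#' @param s a [tmh_structure()].
#' @param first,last closed residue interval.
#' @param R 3x3 rotation matrix.
#' @param t translation vector.
#' @param pivot rotation pivot point (default origin).
#' @return transformed structure.
#' @export
apply_rigid_transform <- function(s, first, last, R = NULL,
                                  t = c(0, 0, 0), pivot = c(0, 0, 0)) {
  rows <- res_rows(s, first, last)
  for (a in c("N", "CA", "C", "O", "CB")) {
    sub <- s[[a]][rows, , drop = FALSE]
    s[[a]][rows, ] <- transform_xyz(sub, R = R, t = t, pivot = pivot)
  }
  s
}
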