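# Internal-coordinate backbone machinery: building Cartesian backbones from
# (phi, psi, omega) torsions, extracting torsions, and ideal placement of
# carbonyl O and (virtual) CB atoms.  Ideal bond lengths/angles are the
# standard Engh-Huber values used by most modeling codes.

IDEAL <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5,
  omega_trans = 180
)

# Ideal CB direction from the backbone N, CA, C positions.  Decomposed in
# the (bisector, normal) frame of the N-CA / C-CA unit vectors; the normal
# component sign fixes L-chirality (verified against experimental
# structures shipped with bio3d).
place_cb <- function(n_xyz, ca_xyz, c_xyz) {
  u1 <- unitv(n_xyz - ca_xyz)
  u2 <- unitv(c_xyz - ca_xyz)
  bis <- unitv(u1 + u2)
  nrm <- unitv(vcross(u1, u2))
  dir <- unitv(-0.6177 * bis + 0.7864 * nrm)
  ca_xyz + IDEAL$b_ca_cb * dir
}

place_o <- function(n_xyz, ca_xyz, c_xyz, psi) {
  if (is.na(psi)) psi <- 140   # terminal residue: arbitrary trans-like value
  place_atom(n_xyz, ca_xyz, c_xyz, IDEAL$b_c_o, IDEAL$a_ca_c_o,
             wrap_angle(psi + 180))
}

# Re-derive O and CB for the given rows from the current N/CA/C coordinates.
rederive_oxy_cb <- function(s, rows = seq_len(nres(s))) {
  n <- nres(s)
  for (i in rows) {
    psi <- if (i < n)
      dihedral4(s$N[i, ], s$CA[i, ], s$C[i, ], s$N[i + 1L, ]) else NA_real_
    s$O[i, ] <- place_o(s$N[i, ], s$CA[i, ], s$C[i, ], psi)
    if (s$aa[i] == "G" || s$cb_virtual[i] || is.na(s$CB[i, 1L])) {
      s$CB[i, ] <- place_cb(s$N[i, ], s$CA[i, ], s$C[i, ])
      s$cb_virtual[i] <- TRUE
    } else {
      # preserve the observed CA-CB orientation in the local frame is out of
      # scope at backbone level; observed CBs are re-idealized once moved
      s$CB[i, ] <- place_cb(s$N[i, ], s$CA[i, ], s$C[i, ])
    }
  }
  s
}

#' Backbone torsion angles
#'
#' @param s a `tmh_structure`.
#' @return data.frame with columns `phi`, `psi`, `omega` in degrees;
#'   `phi[1]` and `psi[n]`, `omega[n]` are `NA`.  `omega[i]` is the peptide
#'   torsion between residues `i` and `i + 1`.
#' @export
backbone_torsions <- function(s) {
  n <- nres(s)
  phi <- psi <- omega <- rep(NA_real_, n)
  if (n > 1L) {
    i <- 2:n
    phi[i] <- batch_dihedral(s$C[i - 1L, , drop = FALSE],
                             s$N[i, , drop = FALSE],
                             s$CA[i, , drop = FALSE],
                             s$C[i, , drop = FALSE])
    j <- seq_len(n - 1L)
    psi[j] <- batch_dihedral(s$N[j, , drop = FALSE],
                             s$CA[j, , drop = FALSE],
                             s$C[j, , drop = FALSE],
                             s$N[j + 1L, , drop = FALSE])
    omega[j] <- batch_dihedral(s$CA[j, , drop = FALSE],
                               s$C[j, , drop = FALSE],
                               s$N[j + 1L, , drop = FALSE],
                               s$CA[j + 1L, , drop = FALSE])
  }
  data.frame(phi = phi, psi = psi, omega = omega)
}

# Build an n-residue backbone from torsions with ideal covalent geometry.
# phi[1] is ignored unless `anchor` provides the three atoms (N, CA, C) of
# a preceding residue together with its psi and omega.
build_backbone <- function(aa, phi, psi, omega = NULL, anchor = NULL,
                           resno = seq_along(aa), chain = "A") {
  n <- length(aa)
  if (is.null(omega)) omega <- rep(IDEAL$omega_trans, n)
  N <- CA <- C <- matrix(NA_real_, n, 3L)
  if (is.null(anchor)) {
    N[1L, ] <- c(0, 0, 0)
    CA[1L, ] <- c(IDEAL$b_n_ca, 0, 0)
    th <- deg2rad(180 - IDEAL$a_n_ca_c)
    C[1L, ] <- CA[1L, ] + IDEAL$b_ca_c * c(cos(th), sin(th), 0)
  } else {
    N[1L, ] <- place_atom(anchor$N, anchor$CA, anchor$C,
                          IDEAL$b_c_n, IDEAL$a_ca_c_n, anchor$psi)
    CA[1L, ] <- place_atom(anchor$CA, anchor$C, N[1L, ],
                           IDEAL$b_n_ca, IDEAL$a_c_n_ca, anchor$omega)
    C[1L, ] <- place_atom(anchor$C, N[1L, ], CA[1L, ],
                          IDEAL$b_ca_c, IDEAL$a_n_ca_c, phi[1L])
  }
  if (n > 1L) for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                         IDEAL$b_c_n, IDEAL$a_ca_c_n, psi[i - 1L])
    CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                          IDEAL$b_n_ca, IDEAL$a_c_n_ca, omega[i - 1L])
    C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                         IDEAL$b_ca_c, IDEAL$a_n_ca_c, phi[i])
  }
  s <- tmh_structure(resno = resno, aa = aa, N = N, CA = CA, C = C,
                     chain = chain, validate = FALSE)
  rederive_oxy_cb(s)
}

# Rebuild Cartesian coordinates for rows `start..stop` from torsions,
# anchored on the atoms preceding the window.  Overrides come from
# `phi`, `psi`, `omega` vectors indexed parallel to `start:stop` (NA means
# keep the current value).  Atoms after `stop` are untouched (a chain break
# may open or persist at `stop`).  O and CB of the affected rows are
# re-derived.
rebuild_window <- function(s, start, stop, phi = NULL, psi = NULL,
                           omega = NULL, rederive_start = FALSE) {
  n <- nres(s)
  stopifnot(start >= 1L, stop <= n, start <= stop)
  tor <- backbone_torsions(s)
  if (rederive_start && start > 1L) {
    # re-place N/CA of the first window residue by ideal continuation from
    # the preceding residue (heals a broken junction at the window start)
    s$N[start, ] <- place_atom(s$N[start - 1L, ], s$CA[start - 1L, ],
                               s$C[start - 1L, ], IDEAL$b_c_n,
                               IDEAL$a_ca_c_n, tor$psi[start - 1L])
    s$CA[start, ] <- place_atom(s$CA[start - 1L, ], s$C[start - 1L, ],
                                s$N[start, ], IDEAL$b_n_ca,
                                IDEAL$a_c_n_ca, tor$omega[start - 1L])
  }
  rows <- start:stop
  override <- function(cur, new) {
    if (is.null(new)) return(cur)
    keep <- is.na(new)
    new[keep] <- cur[keep]
    new
  }
  tphi <- override(tor$phi[rows], phi)
  tpsi <- override(tor$psi[rows], psi)
  tome <- override(tor$omega[rows], omega)

  for (k in seq_along(rows)) {
    i <- rows[k]
    # phi(i) re-places C(i) keeping N(i), CA(i) fixed (needs C(i-1))
    if (i > 1L && !is.na(tphi[k]))
      s$C[i, ] <- place_atom(s$C[i - 1L, ], s$N[i, ], s$CA[i, ],
                             IDEAL$b_ca_c, IDEAL$a_n_ca_c, tphi[k])
    if (i < stop) {
      s$N[i + 1L, ] <- place_atom(s$N[i, ], s$CA[i, ], s$C[i, ],
                                  IDEAL$b_c_n, IDEAL$a_ca_c_n, tpsi[k])
      s$CA[i + 1L, ] <- place_atom(s$CA[i, ], s$C[i, ], s$N[i + 1L, ],
                                   IDEAL$b_n_ca, IDEAL$a_c_n_ca, tome[k])
    }
  }
  rederive_oxy_cb(s, rows)
}
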