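# De novo rebuilding of loops and bend windows: torsion-fragment insertion
# scored by Metropolis Monte Carlo with a geometrically ramped chain-break
# penalty, and cyclic coordinate descent (CCD) closure of the chain break.
# If a window cannot be closed below the 0.2 Angstrom deviation threshold
# within twelve rebuilding cycles, it is expanded by one residue on both
# sides and the process repeats.

#' Loop rebuild window
#'
#' @param first,last closed residue interval to rebuild.
#' @param break_position residue index b such that the chain break sits
#'   between b and b+1 (defaults to `last`); must lie in `[first, last]`.
#' @return object of class `loop_window`.
#' @export
loop_window <- function(first, last, break_position = last) {
  if (break_position < first || break_position > last)
    stop("break_position must lie inside [first, last]")
  structure(list(first = as.integer(first), last = as.integer(last),
                 break_position = as.integer(break_position),
                 attempts = 0L),
            class = "loop_window")
}

# torsion templates used by the "ideal" library source
IDEAL_BASINS <- list(
  helix    = c(phi = -57, psi = -47),
  helix310 = c(phi = -49, psi = -26),
  pihelix  = c(phi = -57, psi = -70),
  extended = c(phi = -120, psi = 130),
  ppii     = c(phi = -75, psi = 145),
  turn     = c(phi = -90, psi = 0)
)

#' Build a torsion fragment library (sizes 9 and 3)
#'
#' @param source `"ideal"` (canonical secondary-structure templates plus
#'   helix/turn chimeras), `"ramachandran"` (torsions sampled from
#'   basin-restricted Gaussians) or `"file"` (user-supplied fragments).
#' @param path fragment TSV for `source = "file"`: whitespace-separated
#'   columns `frag_id`, `position`, `aa`, `phi`, `psi`, `omega`.
#' @param n_per_size fragments per size for `"ramachandran"`.
#' @return object of class `fragment_library`: list with element
#'   `fragments`, a list keyed by size ("3", "9") of data.frames with
#'   columns `phi`, `psi`, `omega` and attribute `ss`.
#' @export
build_fragment_library <- function(source = c("ideal", "ramachandran",
                                              "file"),
                                   path = NULL, n_per_size = 25L) {
  source <- match.arg(source)
  mk <- function(phi, psi, ss) {
    n <- length(phi)
    f <- data.frame(phi = phi, psi = psi, omega = rep(180, n))
    attr(f, "ss") <- ss
    f
  }
  lib <- list(fragments = list(`3` = list(), `9` = list()))
  if (source == "ideal") {
    for (size in c(3L, 9L)) {
      fr <- list()
      for (nm in names(IDEAL_BASINS)) {
        b <- IDEAL_BASINS[[nm]]
        fr[[length(fr) + 1L]] <- mk(rep(b["phi"], size),
                                    rep(b["psi"], size), nm)
      }
      # helix entered/exited through a turn residue: the chimeras that
      # close kink windows between helical anchors
      for (k in seq_len(size - 1L)) {
        phi <- rep(-57, size); psi <- rep(-47, size)
        phi[k] <- -90; psi[k] <- 0
        fr[[length(fr) + 1L]] <- mk(phi, psi, "helix_turn")
        phi2 <- rep(-57, size); psi2 <- rep(-47, size)
        phi2[k] <- -49; psi2[k] <- -26
        fr[[length(fr) + 1L]] <- mk(phi2, psi2, "helix_310")
      }
      lib$fragments[[as.character(size)]] <- fr
    }
  } else if (source == "ramachandran") {
    basins <- rbind(c(-63, -43, 10, 10, 0.55),   # alpha-R
                    c(-120, 135, 20, 20, 0.35),  # beta
                    c(60, 45, 10, 10, 0.10))     # alpha-L
    for (size in c(3L, 9L)) {
      fr <- vector("list", n_per_size)
      for (j in seq_len(n_per_size)) {
        which_b <- sample.int(3L, size, replace = TRUE,
                              prob = basins[, 5L])
        phi <- wrap_angle(stats::rnorm(size, basins[which_b, 1L],
                                       basins[which_b, 3L]))
        psi <- wrap_angle(stats::rnorm(size, basins[which_b, 2L],
                                       basins[which_b, 4L]))
        f <- mk(phi, psi, "rama")
        f$omega <- 180 + pmax(-10, pmin(10, stats::rnorm(size, 0, 3)))
        fr[[j]] <- f
      }
      lib$fragments[[as.character(size)]] <- fr
    }
  } else {
    if (is.null(path)) stop("source = 'file' requires a path")
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(ln) {
      fields <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
      if (ln == 1L && any(is.na(suppressWarnings(as.numeric(fields[4:6])))))
        return(NULL)  # header line
      if (length(fields) < 6L)
        stop("malformed fragment file at line ", ln,
             ": expected 6 whitespace-separated fields")
      num <- suppressWarnings(as.numeric(fields[4:6]))
      if (anyNA(num))
        stop("malformed fragment file at line ", ln,
             ": non-numeric torsion angle")
      data.frame(frag_id = fields[1L], position = as.integer(fields[2L]),
                 aa = fields[3L], phi = num[1L], psi = num[2L],
                 omega = num[3L])
    })
    df <- do.call(rbind, rows)
    for (fid in unique(df$frag_id)) {
      sub <- df[df$frag_id == fid, , drop = FALSE]
      sub <- sub[order(sub$position), , drop = FALSE]
      size <- nrow(sub)
      if (!size %in% c(3L, 9L))
        stop("fragment ", fid, " has size ", size, "; only 3 and 9 allowed")
      f <- mk(sub$phi, sub$psi, "file")
      f$omega <- sub$omega
      lib$fragments[[as.character(size)]] <-
        c(lib$fragments[[as.character(size)]], list(f))
    }
  }
  for (size in c("3", "9")) {
    for (f in lib$fragments[[size]]) {
      if (any(abs(wrap_angle(f$omega - 180)) > 10))
        stop("fragment omega angles must stay within 10 degrees of trans")
    }
    if (length(lib$fragments[[size]]) == 0L)
      stop("fragment library has no fragments of size ", size)
  }
  class(lib) <- "fragment_library"
  lib
}

#' Insert a torsion fragment into a rebuild window
#'
#' Replaces the backbone torsions of the covered residues and re-derives
#' the Cartesian coordinates of the moving side (from the insertion point
#' to the window's chain break); atoms upstream of the insertion and
#' beyond the break are untouched.
#'
#' @param s a [tmh_structure()].
#' @param window a [loop_window()].
#' @param frag a fragment data.frame (`phi`, `psi`, `omega`).
#' @param at first residue covered by the fragment (default: window
#'   start); the fragment must fit between `at` and the break position.
#' @return modified structure.
#' @export
insert_fragment <- function(s, window, frag, at = window$first) {
  size <- nrow(frag)
  b <- window$break_position
  if (at < window$first || at + size - 1L > b)
    stop("fragment does not fit between the insertion point and the break")
  rows <- at:b
  k <- seq_len(size)
  phi <- psi <- omega <- rep(NA_real_, length(rows))
  phi[k] <- frag$phi; psi[k] <- frag$psi; omega[k] <- frag$omega
  rebuild_window(s, at, b, phi = phi, psi = psi, omega = omega)
}

#' Chain-break closure deviation
#'
#' Deviation of the break peptide bond from ideal geometry: the absolute
#' difference between the C(b)-N(b+1) distance and the ideal C-N bond
#' length.
#'
#' @param s a [tmh_structure()].
#' @param break_position residue b with the break between b and b+1.
#' @return deviation in Angstrom.
#' @export
chain_break_deviation <- function(s, break_position) {
  b <- match(break_position, s$resno)
  if (is.na(b) || b >= nres(s))
    stop("invalid break position ", break_position)
  abs(vnorm(s$C[b, ] - s$N[b + 1L, ]) - IDEAL$b_c_n)
}

#' Worst junction deviation across a rebuild window
#'
#' Maximum [chain_break_deviation()] over every peptide bond touching the
#' moving side of the window: the anchor bond, the internal junctions and
#' the designated break.  A window only counts as closed when all of them
#' are near ideal.
#'
#' @param s a [tmh_structure()].
#' @param first,break_position the moving side `[first, break_position]`.
#' @return maximum deviation in Angstrom.
#' @export
window_gap <- function(s, first, break_position) {
  lo <- max(min(s$resno), first - 1L)
  devs <- vapply(lo:break_position, function(i)
    chain_break_deviation(s, i), numeric(1L))
  max(devs)
}

# re-derive the moving side from its anchor when a junction upstream of
# the designated break is broken (e.g. after a rigid-body move)
heal_window <- function(s, first, brk, threshold = 0.5) {
  lo <- max(min(s$resno), first - 1L)
  if (brk - 1L < lo) return(s)
  for (j in lo:(brk - 1L)) {
    if (chain_break_deviation(s, j) > threshold) {
      jrow <- match(j, s$resno)
      brow <- match(brk, s$resno)
      return(rebuild_window(s, jrow + 1L, brow, rederive_start = TRUE))
    }
  }
  s
}

#' Close a chain break by cyclic coordinate descent
#'
#' Iterates over the free phi/psi torsions of the moving side
#' (`first..break`), setting each in turn to the analytic angle that
#' minimizes the squared deviation between the moving copies of the
#' anchor atoms (N, CA, C of residue break+1, built by ideal continuation
#' of the moving chain) and their actual fixed positions.
#'
#' @param s a [tmh_structure()].
#' @param window a [loop_window()] whose break lies strictly before the
#'   last residue of `s`.
#' @param max_cycles CCD sweeps over the torsion list.
#' @param tolerance stop when the closure deviation (see
#'   [chain_break_deviation()]) drops below this value (Angstrom).
#' @return list with elements `structure` (O/CB re-derived over the
#'   window), `final_gap` and `cycles`.
#' @export
ccd_close <- function(s, window, max_cycles = 60L, tolerance = 0.02) {
  first <- match(window$first, s$resno)
  b <- match(window$break_position, s$resno)
  if (is.na(first) || is.na(b)) stop("window outside structure")
  if (b >= nres(s)) stop("no chain break found: break at chain terminus")
  target <- rbind(s$N[b + 1L, ], s$CA[b + 1L, ], s$C[b + 1L, ])

  gap <- chain_break_deviation(s, s$resno[b])
  if (gap <= tolerance) {
    s <- rederive_oxy_cb(s, first:b)
    return(list(structure = s, final_gap = gap, cycles = 0L))
  }

  # stack the moving backbone residue-major (N, CA, C per residue) plus
  # three ghost continuation atoms: where N, CA, C of residue b+1 would
  # sit if the moving chain continued with ideal geometry.  Every torsion
  # then moves a contiguous tail of this matrix.
  nm <- b - first + 1L
  M <- matrix(NA_real_, 3L * nm + 3L, 3L)
  for (k in seq_len(nm)) {
    r <- first + k - 1L
    M[3L * k - 2L, ] <- s$N[r, ]
    M[3L * k - 1L, ] <- s$CA[r, ]
    M[3L * k, ] <- s$C[r, ]
  }
  psi_b <- dihedral4(s$N[b, ], s$CA[b, ], s$C[b, ], s$N[b + 1L, ])
  gN <- place_atom(s$N[b, ], s$CA[b, ], s$C[b, ],
                   IDEAL$b_c_n, IDEAL$a_ca_c_n, psi_b)
  gCA <- place_atom(s$CA[b, ], s$C[b, ], gN,
                    IDEAL$b_n_ca, IDEAL$a_c_n_ca, 180)
  phi_b1 <- dihedral4(s$C[b, ], gN, gCA, target[3L, ])
  gC <- place_atom(s$C[b, ], gN, gCA,
                   IDEAL$b_ca_c, IDEAL$a_n_ca_c, phi_b1)
  grow <- 3L * nm
  M[grow + 1L, ] <- gN; M[grow + 2L, ] <- gCA; M[grow + 3L, ] <- gC


  # free torsions N- to C-terminal: phi rotates about N(i)-CA(i) and
  # moves rows > 3k-1; psi rotates about CA(i)-C(i) and moves rows > 3k
  tors <- list()
  for (k in seq_len(nm)) {
    i <- first + k - 1L
    if (i > 1L)
      tors[[length(tors) + 1L]] <- list(a = 3L * k - 2L, b = 3L * k - 1L,
                                        from = 3L * k)
    tors[[length(tors) + 1L]] <- list(a = 3L * k - 1L, b = 3L * k,
                                      from = 3L * k + 1L)
  }
  tmat <- do.call(rbind, lapply(tors, function(tq)
    c(tq$a, tq$b, tq$from)))
  storage.mode(tmat) <- "integer"
  res <- .ccd_cycles(M, target, tmat, grow, as.integer(max_cycles),
                     tolerance, IDEAL$b_c_n)
  M <- res$M
  cycles <- res$cycles
  for (k in seq_len(nm)) {
    r <- first + k - 1L
    s$N[r, ] <- M[3L * k - 2L, ]
    s$CA[r, ] <- M[3L * k - 1L, ]
    s$C[r, ] <- M[3L * k, ]
  }
  gap <- chain_break_deviation(s, s$resno[b])
  s <- rederive_oxy_cb(s, first:b)
  list(structure = s, final_gap = gap, cycles = cycles)
}

# clash + constraint score used while rebuilding a window (CA soft sphere,
# 4 A contact radius, window residues against everything).  The CA pair
# index list only depends on the window, so callers precompute it once.
loop_pairs <- function(n, wrows, min_sep = 2L) {
  other <- seq_len(n)
  ii <- rep(wrows, each = n)
  jj <- rep(other, times = length(wrows))
  keep <- jj - ii >= min_sep | ii - jj >= min_sep
  ii2 <- pmin(ii[keep], jj[keep]); jj2 <- pmax(ii[keep], jj[keep])
  key <- ii2 * (n + 1L) + jj2
  dup <- duplicated(key)
  list(i = ii2[!dup], j = jj2[!dup])
}

loop_score <- function(s, wrows, constraints = NULL, clash_radius = 4.0,
                       pairs = NULL) {
  if (is.null(pairs)) pairs <- loop_pairs(nres(s), wrows)
  ca <- s$CA
  dx <- ca[pairs$i, 1L] - ca[pairs$j, 1L]
  dy <- ca[pairs$i, 2L] - ca[pairs$j, 2L]
  dz <- ca[pairs$i, 3L] - ca[pairs$j, 3L]
  d2 <- dx * dx + dy * dy + dz * dz
  close_ <- d2 < clash_radius^2
  e <- if (any(close_)) sum((clash_radius - sqrt(d2[close_]))^2) else 0
  if (!is.null(constraints) && nrow(constraints) > 0L)
    e <- e + constraint_energy(s, constraints)
  e
}

#' Rebuild a window by fragment insertion with CCD closure
#'
#' Runs `n_cycles` Metropolis cycles of (random fragment insertion, CCD
#' closure) with a chain-break penalty whose weight doubles every cycle.
#' If the best closure deviation still exceeds `gap_threshold` after the
#' cycles, the window is expanded by one residue on both sides (the break
#' keeps its offset from the window end) and the process repeats, up to
#' `max_expansions` expansions.
#'
#' @param s a [tmh_structure()].
#' @param window a [loop_window()].
#' @param lib a [build_fragment_library()] result.
#' @param constraints optional `constraint_set` scored during rebuilding.
#' @param n_cycles rebuilding cycles per window size (default 12).
#' @param gap_threshold closure deviation accepted as closed (default
#'   0.2 Angstrom).
#' @param max_expansions maximum window expansions (default 5).
#' @param kT Metropolis temperature.
#' @param noise_prob probability that a cycle applies a small torsion
#'   perturbation to the whole window instead of a fragment insertion
#'   (diversifies the search beyond the discrete fragment templates).
#' @param noise_sd sd of that torsion noise (degrees).
#' @return the closed, lowest-score structure, with attributes
#'   `final_gap`, `expansions` and `window` describing the closure.  If
#'   no expansion closes the chain an error condition of class
#'   `tmh_closure_error` is signalled carrying the best-attempt structure
#'   in its `best` field.
#' @export
rebuild_region <- function(s, window, lib, constraints = NULL,
                           n_cycles = 12L, gap_threshold = 0.2,
                           max_expansions = 5L, kT = 1.0,
                           noise_prob = 0.5, noise_sd = 20) {
  if (window$last - window$first + 1L < 3L)
    stop("rebuild window must span at least 3 residues")
  best_global <- NULL; best_global_gap <- Inf
  for (expansion in 0:max_expansions) {
    first <- max(min(s$resno), window$first - expansion)
    last <- min(max(s$resno), window$last + expansion)
    boff <- window$last - window$break_position
    brk <- min(last - boff, s$resno[nres(s) - 1L])
    w <- loop_window(first, last, brk)
    wrows <- res_rows(s, first, brk)

    wp <- loop_pairs(nres(s), wrows)
    s_heal <- heal_window(s, first, brk)
    cur <- ccd_close(s_heal, w, max_cycles = 30L)
    s_cur <- cur$structure; gap_cur <- window_gap(s_cur, first, brk)
    e_cur <- loop_score(s_cur, wrows, constraints, pairs = wp)
    best <- s_cur; best_gap <- gap_cur; best_e <- e_cur

    for (cyc in seq_len(n_cycles)) {
      w_cb <- 2^(cyc - 1L)           # geometric chain-break penalty ramp
      sizes <- c(3L, 9L)
      sizes <- sizes[sizes <= (brk - first + 1L)]
      if (stats::runif(1L) < noise_prob || !length(sizes)) {
        # small torsion-noise move: diversifies the search beyond the
        # discrete fragment templates
        nl <- brk - first + 1L
        tor <- backbone_torsions(s_cur)
        rows <- match(first, s_cur$resno):match(brk, s_cur$resno)
        s_try <- rebuild_window(
          s_cur, rows[1L], rows[nl],
          phi = tor$phi[rows] + stats::rnorm(nl, 0, noise_sd),
          psi = tor$psi[rows] + stats::rnorm(nl, 0, noise_sd))
      } else {
        size <- if (length(sizes) > 1L) sample(sizes, 1L) else sizes[1L]
        frs <- lib$fragments[[as.character(size)]]
        frag <- frs[[sample.int(length(frs), 1L)]]
        at <- if (brk - size + 1L > first)
          sample(first:(brk - size + 1L), 1L) else first
        s_try <- insert_fragment(s_cur, w, frag, at = at)
      }
      res <- ccd_close(s_try, w, max_cycles = 30L)
      s_try <- res$structure
      gap_try <- window_gap(s_try, first, brk)
      e_try <- loop_score(s_try, wrows, constraints, pairs = wp)
      dE <- (e_try + w_cb * gap_try^2) - (e_cur + w_cb * gap_cur^2)
      if (dE <= 0 || stats::runif(1L) < exp(-dE / kT)) {
        s_cur <- s_try; gap_cur <- gap_try; e_cur <- e_try
      }
      closed_better <- (gap_cur <= gap_threshold &&
                          (best_gap > gap_threshold || e_cur < best_e)) ||
        (best_gap > gap_threshold && gap_cur < best_gap)
      if (closed_better) {
        best <- s_cur; best_gap <- gap_cur; best_e <- e_cur
      }
    }
    if (best_gap < best_global_gap) {
      best_global <- best; best_global_gap <- best_gap
    }
    if (best_gap <= gap_threshold) {
      out <- rederive_oxy_cb(best, res_rows(best, first, brk))
      attr(out, "final_gap") <- best_gap
      attr(out, "expansions") <- expansion
      attr(out, "window") <- w
      return(out)
    }
  }
  cond <- structure(
    class = c("tmh_closure_error", "error", "condition"),
    list(message = sprintf(
      "window [%d, %d] not closed below %.2f A after %d expansions (best gap %.3f A)",
      window$first, window$last, gap_threshold, max_expansions,
      best_global_gap),
      call = sys.call(-1L), best = best_global,
      best_gap = best_global_gap))
  stop(cond)
}

#' Remodel a helical bend window
#'
#' By default the bend of a kinked TMH is rebuilt as a four-residue loop
#' insertion (the annotated bend window); when the closed bend adopts a
#' distorted conformation a larger window of 5 to 8 residues centred on
#' the bend can be rebuilt instead.
#'
#' @param s a [tmh_structure()].
#' @param spec a [kink_spec()].
#' @param lib a fragment library.
#' @param window_size optional enlarged window size (5 to 8 residues).
#' @param ... passed to [rebuild_region()].
#' @return closed structure (see [rebuild_region()]).
#' @export
remodel_bend <- function(s, spec, lib, window_size = NULL, ...) {
  first <- spec$bend_range[1L]; last <- spec$bend_range[2L]
  if (!is.null(window_size)) {
    if (window_size < 5L || window_size > 8L)
      stop("window_size must be between 5 and 8")
    extra <- window_size - (last - first + 1L)
    if (extra > 0L) {
      first <- max(min(s$resno) + 1L, first - ceiling(extra / 2))
      last <- min(max(s$resno) - 1L, first + window_size - 1L)
    }
  }
  rebuild_region(s, loop_window(first, last), lib, ...)
}
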