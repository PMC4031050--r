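# Model accuracy metrics: Kabsch CA RMSD, GDT / GDT-HA, fraction of
# residues within a distance cutoff, bend dihedral deviations and
# TM-score.  All metrics take a residue correspondence that is positional:
# row i of the model CA matrix corresponds to row i of the native one
# (helpers below build the matched matrices from structures by residue
# number).

as_ca <- function(x) {
  if (inherits(x, "tmh_structure")) return(x$CA)
  as.matrix(x)
}

# matched CA matrices over the residues two structures share
matched_ca <- function(model, native, region = NULL) {
  if (!inherits(model, "tmh_structure") ||
      !inherits(native, "tmh_structure")) {
    A <- as_ca(model); B <- as_ca(native)
    if (nrow(A) != nrow(B)) stop("coordinate sets differ in length")
    return(list(model = A, native = B))
  }
  shared <- intersect(model$resno, native$resno)
  if (!is.null(region))
    shared <- shared[shared >= region[1L] & shared <= region[2L]]
  list(model = model$CA[match(shared, model$resno), , drop = FALSE],
       native = native$CA[match(shared, native$resno), , drop = FALSE],
       resno = shared)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of `A` onto `B` using the SVD form of the
#' Kabsch algorithm, restricted to proper rotations.
#'
#' @param A,B n x 3 CA coordinate matrices (or structures), equal length,
#'   n >= 3.
#' @return list with `rmsd` (Angstrom), `rotation` (3x3, proper),
#'   `translation` such that `A %*% t(rotation) + translation`
#'   superposes onto `B`.
#' @export
kabsch_rmsd <- function(A, B) {
  A <- as_ca(A); B <- as_ca(B)
  if (nrow(A) != nrow(B))
    stop("coordinate sets differ in length (", nrow(A), " vs ", nrow(B),
         ")")
  if (nrow(A) < 3L) stop("need at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Afit <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((Afit - Bc)^2)))
  list(rmsd = rmsd, rotation = R, translation = cb - as.vector(R %*% ca))
}

superpose_onto <- function(A, B, subset = seq_len(nrow(A))) {
  fit <- kabsch_rmsd(A[subset, , drop = FALSE], B[subset, , drop = FALSE])
  sweep(A %*% t(fit$rotation), 2L, fit$translation, "+")
}

gdt_thresholds <- function(mode = c("ha", "standard")) {
  mode <- match.arg(mode)
  if (mode == "ha") c(0.5, 1, 2, 4) else c(1, 2, 4, 8)
}

#' GDT / GDT-HA score
#'
#' Mean over four distance thresholds of the fraction of residues whose
#' CA lies within the threshold of the reference (thresholds 0.5/1/2/4
#' Angstrom for `"ha"`, 1/2/4/8 for `"standard"`).  `superposition`
#' selects the frame: `"none"` scores the coordinates as given,
#' `"kabsch"` applies the global least-squares superposition, and
#' `"multiseed"` additionally tries superpositions seeded from every
#' sliding window of 4, 8 and 16 residues and takes the per-threshold
#' maxima (a from-below approximation of the full GDT search).
#'
#' @param model,native CA matrices or structures (positional
#'   correspondence).
#' @param mode `"ha"` or `"standard"`.
#' @param superposition `"multiseed"`, `"kabsch"` or `"none"`.
#' @return GDT score in \[0, 1\].
#' @export
gdt_scores <- function(model, native, mode = c("ha", "standard"),
                       superposition = c("multiseed", "kabsch", "none")) {
  mode <- match.arg(mode)
  superposition <- match.arg(superposition)
  m <- matched_ca(model, native)
  A <- m$model; B <- m$native
  thr <- gdt_thresholds(mode)
  frac <- function(Afit) {
    d <- sqrt(rowSums((Afit - B)^2))
    vapply(thr, function(t) mean(d <= t), numeric(1L))
  }
  n <- nrow(A)
  if (superposition == "none") return(mean(frac(A)))
  best <- frac(superpose_onto(A, B))
  if (superposition == "multiseed") {
    best <- pmax(best, frac(A))   # the given frame is a candidate too
    for (wl in c(4L, 8L, 16L)) {
      if (wl > n) next
      for (st in seq_len(n - wl + 1L)) {
        f <- frac(superpose_onto(A, B, st:(st + wl - 1L)))
        best <- pmax(best, f)
      }
    }
  }
  mean(best)
}

#' Percentage of residues within a distance cutoff
#'
#' @param model,native CA matrices or structures.
#' @param cutoff distance cutoff in Angstrom.
#' @param superpose apply the Kabsch superposition over the evaluated
#'   region first (default `TRUE`); with `FALSE` the coordinates are
#'   compared in the frame given.
#' @return percentage in \[0, 100\].
#' @export
pct_within <- function(model, native, cutoff, superpose = TRUE) {
  m <- matched_ca(model, native)
  A <- m$model; B <- m$native
  if (superpose) A <- superpose_onto(A, B)
  100 * mean(sqrt(rowSums((A - B)^2)) <= cutoff)
}

#' Bend dihedral deviation
#'
#' Mean absolute circular difference of the phi and psi angles between
#' model and native over a residue window (the de novo rebuilt bend,
#' default width 5 in reporting).
#'
#' @param model,native structures containing the window plus one flanking
#'   residue on each side.
#' @param window length-2 residue interval.
#' @return named numeric: `dphi`, `dpsi` (degrees).
#' @export
bend_dihedral_deviation <- function(model, native, window) {
  grab <- function(s) {
    rows <- res_rows(s, window[1L], window[2L])
    if (min(rows) <= 1L || max(rows) >= nres(s))
      stop("window touches a chain terminus: flanking atoms missing")
    tor <- backbone_torsions(s)
    list(phi = tor$phi[rows], psi = tor$psi[rows])
  }
  tm <- grab(model); tn <- grab(native)
  c(dphi = mean(abs(wrap_angle(tm$phi - tn$phi))),
    dpsi = mean(abs(wrap_angle(tm$psi - tn$psi))))
}

#' TM-score
#'
#' Length-normalized structural similarity in (0, 1]:
#' `max over superpositions of mean(1 / (1 + (d_i/d0)^2))` with
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`.  The maximization seeds
#' superpositions from sliding windows (full length, halves, quarters,
#' down to 4 residues) and iteratively re-superposes on the residues
#' currently within range, keeping the best score found.
#'
#' @param model,native CA matrices or structures (positional
#'   correspondence).
#' @param normalization_length length L used for d0 and the score mean
#'   (default: the number of matched residues); must be >= 16.
#' @return TM-score.
#' @export
tm_score <- function(model, native, normalization_length = NULL) {
  m <- matched_ca(model, native)
  A <- m$model; B <- m$native
  n <- nrow(A)
  L <- if (is.null(normalization_length)) n else normalization_length
  if (L < 16L) stop("normalization length must be >= 16 (d0 undefined)")
  d0 <- 1.24 * (L - 15)^(1 / 3) - 1.8
  score_of <- function(Afit) {
    d2 <- rowSums((Afit - B)^2)
    sum(1 / (1 + d2 / d0^2)) / L
  }
  refine <- function(subset) {
    best_local <- -Inf
    for (iter in 1:10) {
      if (length(subset) < 3L) break
      Afit <- superpose_onto(A, B, subset)
      sc <- score_of(Afit)
      if (sc > best_local) best_local <- sc
      d <- sqrt(rowSums((Afit - B)^2))
      new_subset <- which(d < max(d0, 4.5))
      if (length(new_subset) < 3L || identical(new_subset, subset)) break
      subset <- new_subset
    }
    best_local
  }
  best <- -Inf
  wl <- n
  lengths <- integer()
  while (wl >= 4L) { lengths <- c(lengths, wl); wl <- wl %/% 2L }
  for (w in unique(pmax(lengths, 4L))) {
    step <- max(1L, w %/% 2L)
    starts <- unique(c(seq(1L, n - w + 1L, by = step), n - w + 1L))
    for (st in starts) {
      sc <- refine(st:(st + w - 1L))
      if (sc > best) best <- sc
    }
  }
  best
}

#' Full accuracy report for a model against a reference
#'
#' @param model,native structures (matched by residue number).
#' @param tmh_ranges optional list of TMH residue intervals defining the
#'   TM region.
#' @param bend_window optional residue interval for bend dihedral
#'   deviations.
#' @return data.frame with one row per region (`full`, and `tmh` when
#'   ranges are given): CA RMSD, GDT, GDT-HA, percent within 1 and 2
#'   Angstrom, TM-score, and bend dihedral deviations on the `full` row.
#' @export
accuracy_report <- function(model, native, tmh_ranges = NULL,
                            bend_window = NULL) {
  regions <- list(full = NULL)
  if (!is.null(tmh_ranges)) regions$tmh <- tmh_ranges
  rows <- list()
  for (rn in names(regions)) {
    if (rn == "full") {
      mm <- model; nn <- native
    } else {
      keep_m <- unlist(lapply(tmh_ranges, function(rg)
        which(model$resno >= rg[1L] & model$resno <= rg[2L])))
      keep_n <- unlist(lapply(tmh_ranges, function(rg)
        which(native$resno >= rg[1L] & native$resno <= rg[2L])))
      mm <- subset_structure(model, sort(unique(keep_m)))
      nn <- subset_structure(native, sort(unique(keep_n)))
    }
    m <- matched_ca(mm, nn)
    fit <- kabsch_rmsd(m$model, m$native)
    rows[[rn]] <- data.frame(
      region = rn,
      n_res = nrow(m$model),
      ca_rmsd = fit$rmsd,
      gdt = gdt_scores(m$model, m$native, "standard"),
      gdt_ha = gdt_scores(m$model, m$native, "ha"),
      pct_within_1A = pct_within(m$model, m$native, 1),
      pct_within_2A = pct_within(m$model, m$native, 2),
      tm_score = if (nrow(m$model) >= 16L)
        tm_score(m$model, m$native) else NA_real_,
      dphi = NA_real_, dpsi = NA_real_)
  }
  out <- do.call(rbind, rows)
  if (!is.null(bend_window)) {
    dd <- bend_dihedral_deviation(model, native, bend_window)
    out$dphi[out$region == "full"] <- dd[["dphi"]]
    out$dpsi[out$region == "full"] <- dd[["dpsi"]]
  }
  rownames(out) <- NULL
  out
}
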