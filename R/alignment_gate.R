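# Target-template alignment handling: the per-TMH rebuild decision and the
# derivation of harmonic CA-CA distance restraints used during sampling and
# refinement.
#
# A TMH is rebuilt when the alignment gives reason to distrust the template
# helix: gaps inside the helix, bend-inducing (proline) positions that are
# unaligned or not conserved, or annotated helix lengths that differ
# substantially.  Restraints are placed between conserved-or-similar
# residue pairs that are in spatial vicinity in the template, with widths
# that grow with the template distance and a count budget that shrinks as
# the homologs get more distant.

# residue groups treated as interchangeable for constraint eligibility
SIMILARITY_CLASSES <- list(
  aliphatic = c("I", "L", "V", "M", "F"),
  basic     = c("K", "R"),
  acidic    = c("D", "E"),
  hydroxyl  = c("S", "T"),
  amide     = c("N", "Q"),
  aromatic  = c("F", "Y", "W")
)

residues_similar <- function(a, b) {
  if (a == b && a != "-" && a != "X") return(TRUE)
  for (cl in SIMILARITY_CLASSES) if (a %in% cl && b %in% cl) return(TRUE)
  FALSE
}

#' Parse a pairwise target-template alignment
#'
#' @param fasta_text aligned-FASTA text (exactly two records of equal
#'   gapped length, gaps as `-`; target first, template second) or a path
#'   to such a file.
#' @return object of class `pair_alignment` with gapped sequences,
#'   column-to-residue maps (`NA` at gap columns) and the fraction of
#'   identical residues over mutually aligned columns (`identity_full`;
#'   `identity_modeled` starts equal and may be recomputed over a region
#'   with [alignment_identity()]).
#' @export
parse_alignment <- function(fasta_text) {
  if (length(fasta_text) == 1L && file.exists(fasta_text)) {
    path <- fasta_text
  } else {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(paste(fasta_text, collapse = "\n"), path)
  }
  raw <- readLines(path)
  rec_lens <- integer(); cur <- NA_integer_
  for (ln in raw) {
    if (startsWith(ln, ">")) {
      rec_lens <- c(rec_lens, 0L)
    } else if (length(rec_lens)) {
      rec_lens[length(rec_lens)] <- rec_lens[length(rec_lens)] +
        nchar(gsub("\\s", "", ln))
    }
  }
  if (length(rec_lens) != 2L)
    stop("alignment must contain exactly 2 records, got ",
         length(rec_lens))
  if (rec_lens[1L] != rec_lens[2L])
    stop("aligned sequences differ in gapped length (",
         rec_lens[1L], " vs ", rec_lens[2L], ")")
  aln <- bio3d::read.fasta(path)
  tgt <- toupper(aln$ali[1L, ])
  tpl <- toupper(aln$ali[2L, ])
  if (length(tgt) != length(tpl))
    stop("aligned sequences differ in gapped length")
  target_map <- ifelse(tgt == "-", NA_integer_, cumsum(tgt != "-"))
  template_map <- ifelse(tpl == "-", NA_integer_, cumsum(tpl != "-"))
  both <- tgt != "-" & tpl != "-"
  idf <- if (any(both)) mean(tgt[both] == tpl[both]) else 0
  structure(list(target_seq = paste(tgt, collapse = ""),
                 template_seq = paste(tpl, collapse = ""),
                 target_chars = tgt, template_chars = tpl,
                 target_map = as.integer(target_map),
                 template_map = as.integer(template_map),
                 identity_full = idf, identity_modeled = idf,
                 ids = aln$id),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("<pair_alignment> %d columns, identity %.1f%%\n",
              length(x$target_chars), 100 * x$identity_full))
  invisible(x)
}

#' Sequence identity over a column subset
#' @param a a `pair_alignment`.
#' @param columns alignment column indices (default all).
#' @return fraction of identical residues over the mutually aligned
#'   columns of the subset.
#' @export
alignment_identity <- function(a, columns = seq_along(a$target_chars)) {
  tc <- a$target_chars[columns]; pc <- a$template_chars[columns]
  both <- tc != "-" & pc != "-"
  if (!any(both)) return(0)
  mean(tc[both] == pc[both])
}

# columns of the alignment whose target residues fall in [first, last]
target_columns <- function(a, first, last) {
  which(!is.na(a$target_map) & a$target_map >= first &
        a$target_map <= last)
}

#' Decide which TMHs must be rebuilt
#'
#' A TMH is rebuilt when any of three alignment conditions holds:
#' `gap_in_tmh` (a gap column falls inside the aligned helix span),
#' `bend_mismatch` (a bend-inducing position -- proline in the target or
#' present in at least 10 percent of homolog sequences -- is unaligned or
#' not matched by a proline in the other sequence), or `length_mismatch`
#' (annotated helix lengths differ by more than `length_margin`).
#'
#' @param a a `pair_alignment`.
#' @param target_tmhs,template_tmhs segment annotation data.frames (see
#'   [read_segments()]); TMH rows are paired in order.
#' @param proline_profile optional numeric vector of per-column proline
#'   fractions from a homolog set (length = alignment columns), or `NULL`.
#' @param length_margin allowed TMH length difference in residues
#'   (default 4, about one helical turn).
#' @param profile_threshold homolog proline fraction that makes a column
#'   bend-inducing (default 0.1).
#' @return data.frame with columns `tmh_id`, `rebuild`, `reasons`
#'   (comma-separated subset of the three rule names).
#' @export
gate_tmh <- function(a, target_tmhs, template_tmhs, proline_profile = NULL,
                     length_margin = 4L, profile_threshold = 0.1) {
  tt <- target_tmhs[target_tmhs$kind == "TMH", , drop = FALSE]
  pt <- template_tmhs[template_tmhs$kind == "TMH", , drop = FALSE]
  if (nrow(tt) != nrow(pt))
    stop("target and template annotate different numbers of TMHs")
  ncol_aln <- length(a$target_chars)
  n_tgt <- max(a$target_map, na.rm = TRUE)
  out <- data.frame(tmh_id = tt$segment_id, rebuild = FALSE,
                    reasons = "", stringsAsFactors = FALSE)
  if (is.null(proline_profile)) proline_profile <- numeric(ncol_aln)
  if (length(proline_profile) != ncol_aln)
    stop("proline profile length must equal the alignment column count")
  for (k in seq_len(nrow(tt))) {
    if (tt$last_res[k] > n_tgt || tt$first_res[k] < 1L)
      stop("TMH annotation ", tt$segment_id[k],
           " lies outside the aligned target sequence")
    cols <- target_columns(a, tt$first_res[k], tt$last_res[k])
    span <- seq(min(cols), max(cols))
    reasons <- character()

    if (any(a$target_chars[span] == "-" | a$template_chars[span] == "-"))
      reasons <- c(reasons, "gap_in_tmh")

    bend_target <- a$target_chars[span] == "P" |
      proline_profile[span] >= profile_threshold
    bend_template <- a$template_chars[span] == "P"
    mism <- (bend_target &
               (a$template_chars[span] == "-" | !bend_template)) |
            (bend_template & !bend_target)
    if (any(mism)) reasons <- c(reasons, "bend_mismatch")

    len_t <- tt$last_res[k] - tt$first_res[k] + 1L
    len_p <- pt$last_res[k] - pt$first_res[k] + 1L
    if (abs(len_t - len_p) > length_margin)
      reasons <- c(reasons, "length_mismatch")

    out$rebuild[k] <- length(reasons) > 0L
    out$reasons[k] <- paste(reasons, collapse = ",")
  }
  out
}

# flat-bottom width as a function of the template distance: 0.2 A up to
# 5 A contacts, 0.5 A at 8 A, linear in between
constraint_width <- function(d0) {
  pmin(0.5, pmax(0.2, 0.2 + 0.3 * (d0 - 5) / 3))
}

# fraction of modeled residues allowed as constraints for a given
# alignment identity; Inf = keep every candidate
constraint_budget_fraction <- function(identity) {
  if (identity >= 0.25) return(Inf)
  if (identity >= 0.20) return(0.05 + 0.05 * (identity - 0.20) / 0.05)
  0.05
}

#' Derive harmonic CA-CA constraints from the template
#'
#' Candidate pairs are aligned columns whose target and template residues
#' are identical or similar (see `SIMILARITY_CLASSES`), at least 4 residues
#' apart in sequence, within `vicinity` Angstrom in the template, and not
#' inside a region being rebuilt de novo.  For distant homologs the
#' candidate list is truncated to a budget proportional to the number of
#' modeled residues (5 percent below 20 percent identity, growing to 10
#' percent at 25 percent identity, unbudgeted above), keeping the
#' shortest-range contacts first.
#'
#' @param a a `pair_alignment`.
#' @param template a [tmh_structure()] indexed by template residue number
#'   (sequential, 1-based).
#' @param identity_modeled alignment identity over the modeled region;
#'   defaults to `a$identity_modeled`.
#' @param rebuilt_regions optional list of length-2 target-residue
#'   intervals excluded from constraints.
#' @param vicinity template CA-CA distance cutoff in Angstrom (default 8).
#' @param min_separation minimum target sequence separation (default 4).
#' @return object of class `constraint_set`: data.frame with columns
#'   `res_i`, `res_j` (target residue numbers), `d0`, `width`, `weight`.
#' @export
derive_constraints <- function(a, template, identity_modeled = NULL,
                               rebuilt_regions = NULL, vicinity = 8.0,
                               min_separation = 4L) {
  if (is.null(identity_modeled)) identity_modeled <- a$identity_modeled
  cols <- which(!is.na(a$target_map) & !is.na(a$template_map))
  ok <- vapply(cols, function(cc)
    residues_similar(a$target_chars[cc], a$template_chars[cc]), logical(1L))
  cols <- cols[ok]
  in_rebuilt <- function(res) {
    if (is.null(rebuilt_regions)) return(FALSE)
    any(vapply(rebuilt_regions, function(rg)
      res >= rg[1L] && res <= rg[2L], logical(1L)))
  }
  cols <- cols[!vapply(a$target_map[cols], in_rebuilt, logical(1L))]

  empty <- function() {
    warning("no candidate constraint pairs found")
    as_constraint_set(data.frame(res_i = integer(), res_j = integer(),
                                 d0 = numeric(), width = numeric(),
                                 weight = numeric()))
  }
  if (length(cols) < 2L) return(empty())

  tres <- a$target_map[cols]
  pres <- a$template_map[cols]
  prow <- match(pres, template$resno)
  keep <- !is.na(prow)
  cols <- cols[keep]; tres <- tres[keep]; prow <- prow[keep]
  n <- length(cols)
  if (n < 2L) return(empty())

  ca <- template$CA[prow, , drop = FALSE]
  dmat <- as.matrix(stats::dist(ca))
  sep <- abs(outer(tres, tres, "-"))
  cand <- which(upper.tri(dmat) & dmat <= vicinity & sep >= min_separation,
                arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty())

  df <- data.frame(res_i = tres[cand[, 1L]], res_j = tres[cand[, 2L]],
                   d0 = dmat[cand], width = constraint_width(dmat[cand]),
                   weight = 1.0)
  swap <- df$res_i > df$res_j
  tmp <- df$res_i[swap]; df$res_i[swap] <- df$res_j[swap]
  df$res_j[swap] <- tmp

  frac <- constraint_budget_fraction(identity_modeled)
  if (is.finite(frac)) {
    n_modeled <- sum(!is.na(a$target_map) & !is.na(a$template_map))
    budget <- max(1L, round(frac * n_modeled))
    df <- df[order(df$d0, -abs(df$res_j - df$res_i)), , drop = FALSE]
    df <- utils::head(df, budget)
  }
  df <- df[order(df$res_i, df$res_j), , drop = FALSE]
  rownames(df) <- NULL
  as_constraint_set(df)
}

as_constraint_set <- function(df) {
  class(df) <- c("constraint_set", "data.frame")
  df
}

#' Flat-bottom harmonic constraint energy
#'
#' Zero while the CA-CA distance stays within `width` of the assigned
#' distance; quadratic in the excess deviation (spring scale `sigma`,
#' 1 Angstrom) beyond that.
#'
#' @param s a [tmh_structure()] (residues addressed by `resno`).
#' @param constraints a `constraint_set` from [derive_constraints()].
#' @param sigma harmonic scale in Angstrom.
#' @return total constraint score (non-negative).
#' @export
constraint_energy <- function(s, constraints, sigma = 1.0) {
  if (nrow(constraints) == 0L) return(0)
  ri <- match(constraints$res_i, s$resno)
  rj <- match(constraints$res_j, s$resno)
  if (anyNA(ri) || anyNA(rj))
    stop("constrained residue missing from structure: ",
         paste(unique(c(constraints$res_i[is.na(ri)],
                        constraints$res_j[is.na(rj)])), collapse = ", "))
  d <- sqrt(rowSums((s$CA[ri, , drop = FALSE] -
                     s$CA[rj, , drop = FALSE])^2))
  excess <- pmax(0, abs(d - constraints$d0) - constraints$width)
  sum(constraints$weight * (excess / sigma)^2)
}

#' Write / read a constraint set as TSV
#' @param constraints a `constraint_set`.
#' @param path TSV path.
#' @export
write_constraints <- function(constraints, path) {
  utils::write.table(as.data.frame(constraints), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  as_constraint_set(df)
}

#' Read a per-column proline profile
#' @param path TSV with columns `column`, `fraction`.
#' @param n_columns total alignment columns (fills missing with 0).
#' @return numeric vector of proline fractions per column.
#' @export
read_proline_profile <- function(path, n_columns) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  prof <- numeric(n_columns)
  prof[df$column] <- df$fraction
  prof
}
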