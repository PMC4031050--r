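# The backbone Structure container used throughout the package.
#
# A `tmh_structure` holds an ordered polypeptide backbone: for each residue
# the author residue number, one-letter amino-acid code and the Cartesian
# coordinates of N, CA, C and (optionally) O and CB.  CB may be a rebuilt
# "virtual" atom (always so for glycine); `cb_virtual` records this.
# `segment` carries optional TMH/loop labels per residue.

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA123 <- structure(names(AA321), names = unname(AA321))

#' Construct a backbone structure
#'
#' @param resno integer vector of 1-based author residue numbers, strictly
#'   increasing within the chain.
#' @param aa character vector of one-letter amino-acid codes (or "X").
#' @param N,CA,C,O,CB n x 3 coordinate matrices (Angstrom); `O` and `CB`
#'   may be `NULL` or contain `NA` rows.
#' @param chain single chain identifier.
#' @param segment optional character vector of per-residue segment labels
#'   (TMH or loop ids), `NA` where unassigned.
#' @param cb_virtual logical vector flagging geometrically rebuilt CB atoms.
#' @param insert character vector of PDB insertion codes ("" when absent).
#' @param validate check invariants (finite coordinates, increasing
#'   numbering, CA-CB distance when CB present).
#' @return an object of class `tmh_structure`.
#' @export
tmh_structure <- function(resno, aa, N, CA, C, O = NULL, CB = NULL,
                          chain = "A", segment = NULL, cb_virtual = NULL,
                          insert = NULL, validate = TRUE) {
  n <- length(resno)
  as_mat <- function(m) {
    if (is.null(m)) return(matrix(NA_real_, n, 3L))
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  }
  s <- structure(list(
    resno = as.integer(resno),
    aa = toupper(as.character(aa)),
    chain = as.character(chain)[1L],
    insert = if (is.null(insert)) rep("", n) else as.character(insert),
    N = as_mat(N), CA = as_mat(CA), C = as_mat(C),
    O = as_mat(O), CB = as_mat(CB),
    cb_virtual = if (is.null(cb_virtual)) rep(FALSE, n) else cb_virtual,
    segment = if (is.null(segment)) rep(NA_character_, n) else
      as.character(segment)
  ), class = "tmh_structure")
  if (validate) validate_structure(s)
  s
}

#' Number of residues in a structure
#' @param s a `tmh_structure`.
#' @return integer count.
#' @export
nres <- function(s) length(s$resno)

#' @export
print.tmh_structure <- function(x, ...) {
  br <- chain_breaks(x)
  cat(sprintf("<tmh_structure> chain %s, %d residues (%d-%d)%s\n",
              x$chain, nres(x),
              if (nres(x)) min(x$resno) else NA,
              if (nres(x)) max(x$resno) else NA,
              if (length(br)) sprintf(", %d chain break(s)", length(br))
              else ""))
  invisible(x)
}

validate_structure <- function(s) {
  n <- nres(s)
  if (n == 0L) return(invisible(s))
  if (any(diff(s$resno) <= 0L) && !any(nzchar(s$insert)))
    stop("residue numbering must be strictly increasing within the chain")
  if (!all(s$aa %in% c(AA1, "X")))
    stop("unknown amino-acid code(s): ",
         paste(unique(s$aa[!(s$aa %in% c(AA1, "X"))]), collapse = ", "))
  for (atom in c("N", "CA", "C")) {
    bad <- !is.finite(s[[atom]])
    if (any(bad))
      stop(sprintf("missing/non-finite %s coordinate at residue %s", atom,
                   paste(s$resno[rowSums(bad) > 0][1L], collapse = ",")))
  }
  has_cb <- !is.na(s$CB[, 1L])
  if (any(has_cb)) {
    d <- sqrt(rowSums((s$CA[has_cb, , drop = FALSE] -
                       s$CB[has_cb, , drop = FALSE])^2))
    if (any(d <= 1.2 | d >= 1.8))
      stop("CA-CB distance outside (1.2, 1.8) Angstrom at residue ",
           s$resno[has_cb][which(d <= 1.2 | d >= 1.8)[1L]])
  }
  invisible(s)
}

#' Detect chain breaks
#'
#' A break is flagged between consecutive residues whose C(i)-N(i+1)
#' distance falls outside (1.0, 2.0) Angstrom.
#'
#' @param s a `tmh_structure`.
#' @return integer vector of residue numbers i such that the bond between
#'   i and the following residue is broken (empty when the chain is
#'   continuous).
#' @export
chain_breaks <- function(s) {
  n <- nres(s)
  if (n < 2L) return(integer())
  d <- sqrt(rowSums((s$N[-1L, , drop = FALSE] -
                     s$C[-n, , drop = FALSE])^2))
  s$resno[-n][d <= 1.0 | d >= 2.0]
}

# Row indices for a closed residue-number interval [first, last].
res_rows <- function(s, first, last) {
  if (first > last) stop("first must be <= last")
  idx <- which(s$resno >= first & s$resno <= last)
  if (!any(s$resno == first) || !any(s$resno == last))
    stop(sprintf("residue range [%d, %d] not fully present", first, last))
  idx
}

#' Extract a residue range as a new structure
#'
#' Intervals are 1-based and closed at both ends, matching PDB author
#' numbering conventions.
#'
#' @param s a `tmh_structure`.
#' @param first,last residue numbers bounding the closed interval.
#' @return a `tmh_structure` restricted to `[first, last]`; segment labels
#'   are preserved.
#' @export
extract_segment <- function(s, first, last) {
  idx <- res_rows(s, first, last)
  subset_structure(s, idx)
}

subset_structure <- function(s, idx) {
  tmh_structure(resno = s$resno[idx], aa = s$aa[idx],
                N = s$N[idx, , drop = FALSE], CA = s$CA[idx, , drop = FALSE],
                C = s$C[idx, , drop = FALSE], O = s$O[idx, , drop = FALSE],
                CB = s$CB[idx, , drop = FALSE], chain = s$chain,
                segment = s$segment[idx], cb_virtual = s$cb_virtual[idx],
                insert = s$insert[idx], validate = FALSE)
}

# Stack all backbone+CB atoms of selected rows into one matrix (for clash
# terms); returns list(xyz, resrow).
atom_stack <- function(s, rows = seq_len(nres(s)), atoms = c("CA", "CB")) {
  xs <- list(); rr <- list()
  for (a in atoms) {
    m <- s[[a]][rows, , drop = FALSE]
    ok <- !is.na(m[, 1L])
    xs[[a]] <- m[ok, , drop = FALSE]
    rr[[a]] <- rows[ok]
  }
  list(xyz = do.call(rbind, xs), resrow = unlist(rr, use.names = FALSE))
}
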