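# PDB-format input/output for backbone structures.  Parsing is delegated to
# bio3d; this layer resolves altLocs, enforces backbone completeness and
# rebuilds missing CB atoms at ideal geometry so that downstream code can
# always rely on an (at least virtual) CB.

#' Read a backbone structure from PDB text
#'
#' Retains the N, CA, C, O and CB atoms of one chain.  Alternate locations
#' are resolved to the highest-occupancy record (ties broken alphabetically
#' by altLoc id).  Residues lacking a CB (glycine, or truncated side
#' chains) get a virtual CB placed at ideal tetrahedral geometry.
#'
#' @param pdb_text character scalar (or vector of lines) of PDB ATOM/HETATM
#'   records.
#' @param chain chain identifier to extract (default "A").
#' @return a [tmh_structure()].
#' @export
read_backbone <- function(pdb_text, chain = "A") {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(paste(pdb_text, collapse = "\n"), tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  chains <- unique(at$chain)
  if (!chain %in% chains)
    stop(sprintf("chain '%s' not found; available chains: %s", chain,
                 paste(chains, collapse = ", ")))
  at <- at[at$chain == chain & at$elety %in% c("N", "CA", "C", "O", "CB"), ,
           drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altLoc resolution: within (resno, insert, atom name) keep the highest
  # occupancy, ties alphabetically; file record order is then restored
  at$.ord <- seq_len(nrow(at))
  key <- paste(at$resno, at$insert, at$elety, sep = "\r")
  at <- at[order(key, -at$o, at$alt), , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety, sep = "\r")), ,
           drop = FALSE]
  at <- at[order(at$.ord), , drop = FALSE]

  rid <- unique(paste(at$resno, at$insert, sep = "\r"))
  nr <- length(rid)
  grab <- function(elety) {
    m <- matrix(NA_real_, nr, 3L)
    sub <- at[at$elety == elety, , drop = FALSE]
    idx <- match(paste(sub$resno, sub$insert, sep = "\r"), rid)
    m[idx, ] <- cbind(sub$x, sub$y, sub$z)
    m
  }
  N <- grab("N"); CA <- grab("CA"); C <- grab("C")
  O <- grab("O"); CB <- grab("CB")
  resno <- as.integer(sub("\r.*", "", rid))
  insert <- sub(".*\r", "", rid)
  if (anyNA(CA[, 1L]))
    stop("missing CA atom for residue ", resno[which(is.na(CA[, 1L]))[1L]])
  if (anyNA(N[, 1L]))
    stop("missing N atom for residue ", resno[which(is.na(N[, 1L]))[1L]])
  if (anyNA(C[, 1L]))
    stop("missing C atom for residue ", resno[which(is.na(C[, 1L]))[1L]])

  res3 <- at$resid[match(paste(resno, insert, sep = "\r"),
                         paste(at$resno, at$insert, sep = "\r"))]
  aa <- unname(AA321[res3])
  aa[is.na(aa)] <- "X"

  cb_virtual <- is.na(CB[, 1L]) | aa == "G"
  for (i in which(cb_virtual))
    CB[i, ] <- place_cb(N[i, ], CA[i, ], C[i, ])

  tmh_structure(resno = resno, aa = aa, N = N, CA = CA, C = C, O = O,
                CB = CB, chain = chain, cb_virtual = cb_virtual,
                insert = insert)
}

#' Write a structure as PDB text
#'
#' Emits standard fixed-width ATOM records (N, CA, C, O, CB per residue,
#' virtual CBs excluded) terminated by TER.
#'
#' @param s a [tmh_structure()].
#' @param include_virtual_cb also write geometrically rebuilt CB atoms
#'   (default `FALSE`).
#' @return character scalar of PDB text.
#' @export
write_pdb <- function(s, include_virtual_cb = FALSE) {
  lines <- character()
  serial <- 0L
  for (i in seq_len(nres(s))) {
    res3 <- if (s$aa[i] %in% names(AA123)) AA123[[s$aa[i]]] else "UNK"
    atoms <- c("N", "CA", "C", "O", "CB")
    for (a in atoms) {
      xyz <- s[[a]][i, ]
      if (is.na(xyz[1L])) next
      if (a == "CB" && s$cb_virtual[i] && !include_virtual_cb) next
      serial <- serial + 1L
      elem <- substr(a, 1L, 1L)
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", a), " ", res3, s$chain, s$resno[i],
        ifelse(nzchar(s$insert[i]), s$insert[i], " "),
        xyz[1L], xyz[2L], xyz[3L], 1, 0, elem))
    }
  }
  if (length(lines))
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", serial + 1L,
                              if (s$aa[nres(s)] %in% names(AA123))
                                AA123[[s$aa[nres(s)]]] else "UNK",
                              s$chain, s$resno[nres(s)]))
  paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
}

#' Read segment annotations (TMH / loop spans)
#'
#' @param path TSV file with columns `segment_id`, `first_res`, `last_res`,
#'   `kind` (`TMH` or `loop`).
#' @return data.frame of annotations.
#' @export
read_segments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("segment_id", "first_res", "last_res", "kind")
  if (!all(need %in% names(df)))
    stop("segment annotation file must have columns: ",
         paste(need, collapse = ", "))
  if (!all(df$kind %in% c("TMH", "loop")))
    stop("segment kind must be 'TMH' or 'loop'")
  df
}

#' Write segment annotations
#' @param segments data.frame as returned by [read_segments()].
#' @param path output TSV path.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Apply segment labels from an annotation data.frame onto a structure.
label_segments <- function(s, segments) {
  for (k in seq_len(nrow(segments))) {
    idx <- which(s$resno >= segments$first_res[k] &
                 s$resno <= segments$last_res[k])
    s$segment[idx] <- segments$segment_id[k]
  }
  s
}
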