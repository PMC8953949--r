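# Structure I/O and geometry. PDB parsing/writing is delegated to bio3d;
# the package-level container is a flat atom table with author residue
# numbering (insertion codes appended), which is what every user-facing
# report uses.

#' Structure container
#'
#' A `structure3d` holds ATOM-level records of one model as a flat data
#' frame: `chain`, `resno` (author number, integer), `ins` (insertion
#' code, "" if none), `resid` (author number with insertion code, the
#' user-facing residue identifier), `resname`, `elety` (atom name),
#' `x`, `y`, `z` (Angstrom), `occ`. Residues are kept in file order.
#'
#' @param atoms Data frame with at least `chain`, `resno`, `resname`,
#'   `elety`, `x`, `y`, `z`; `ins` and `occ` default to `""`/`1`.
#' @return A `structure3d`.
#' @export
structure3d <- function(atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resname", "elety", "x", "y", "z")
                %in% names(atoms)))
  if (nrow(atoms) == 0)
    stop("empty-structure: no ATOM records", call. = FALSE)
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  atoms$resid <- paste0(atoms$resno, atoms$ins)
  atoms$calpha <- atoms$elety == "CA"
  for (ch in unique(atoms$chain)) {
    r <- atoms[atoms$chain == ch, ]
    if (anyDuplicated(unique(r[, c("resid", "resname")])$resid))
      stop("author residue numbers not unique in chain ", ch, call. = FALSE)
  }
  structure(list(atoms = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  ch <- split(x$atoms, x$atoms$chain)
  cat("structure3d:",
      paste(sprintf("%s (%d res, %d atoms)", names(ch),
                    vapply(ch, function(a) length(unique(a$resid)), 0L),
                    vapply(ch, nrow, 0L)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Chains of a structure
#' @param s A [structure3d].
#' @return Character vector of chain identifiers.
#' @export
chains <- function(s) unique(s$atoms$chain)

chain_atoms <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain, ]
  if (nrow(a) == 0) stop("key-error: no chain '", chain, "'", call. = FALSE)
  a
}

# per-chain residue table in file order: resid, resname
chain_residues <- function(s, chain) {
  a <- chain_atoms(s, chain)
  a[!duplicated(a$resid), c("resid", "resno", "ins", "resname")]
}

#' Read a PDB structure
#'
#' First model only; HETATM records are skipped; for alternate locations
#' the highest-occupancy conformer of each atom is kept (first on ties).
#' Insertion codes are appended to author numbers in the `resid` field.
#'
#' @param path PDB file path.
#' @return A [structure3d].
#' @export
read_structure <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e)
                    stop("empty-structure: ", conditionMessage(e),
                         call. = FALSE))
  a <- pdb$atom
  a <- a[a$type == "ATOM", ]
  if (nrow(a) == 0)
    stop("empty-structure: no ATOM records in ", path, call. = FALSE)
  a$insert[is.na(a$insert)] <- ""
  a$o[is.na(a$o)] <- 1
  # altLoc: keep the highest-occupancy conformer per atom site
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  ord <- order(key, -a$o)
  a <- a[ord, ][!duplicated(key[ord]), ]
  a <- a[order(as.integer(rownames(a))), ]  # restore file order
  structure3d(data.frame(chain = a$chain, resno = a$resno, ins = a$insert,
                         resname = a$resid, elety = a$elety,
                         x = a$x, y = a$y, z = a$z, occ = a$o,
                         stringsAsFactors = FALSE))
}

#' Write a structure as a PDB file
#'
#' @param s A [structure3d].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   elety = a$elety, insert = ifelse(nzchar(a$ins), a$ins, ""),
                   o = a$occ)
  invisible(path)
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' One-letter sequence observed in a chain
#' @param s A [structure3d].
#' @param chain Chain id.
#' @return Character scalar; unknown residue names become `X`.
#' @export
chain_sequence <- function(s, chain) {
  r <- chain_residues(s, chain)
  one <- AA3TO1[r$resname]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Interface residues between two chains
#'
#' A residue of chain `a` is an interface member iff the minimum distance
#' between any of its atoms and any atom of chain `b` is at or below
#' `cutoff` (the boundary is inclusive). For Calpha-only structures a
#' wider Calpha-Calpha cutoff is appropriate; see `Details`.
#'
#' @details The default `cutoff = 5` Angstrom is an any-atom contact
#'   threshold. When the structure carries only Calpha atoms (as the
#'   synthetic complexes do), pass `cutoff = 8` (the conventional
#'   Calpha-Calpha contact distance). The clustering tests use only the
#'   distance ordering, which is cutoff-independent.
#'
#' @param s A [structure3d].
#' @param a,b Chain ids (query chain `a`, partner `b`).
#' @param cutoff Distance threshold in Angstrom.
#' @return An `interface_set`: data frame with `resid`, `resno`, `ins`,
#'   `min_dist` (minimum inter-chain atom distance per chain-`a`
#'   residue, ordered as in the file) and attribute `members`, the
#'   `resid`s at or below the cutoff.
#' @export
interface_residues <- function(s, a, b, cutoff = 5.0) {
  aa <- chain_atoms(s, a); ab <- chain_atoms(s, b)
  dm <- cross_dist(as.matrix(aa[, c("x", "y", "z")]),
                   as.matrix(ab[, c("x", "y", "z")]))
  mind <- tapply(apply(dm, 1, min), factor(aa$resid, levels = unique(aa$resid)),
                 min)
  r <- chain_residues(s, a)
  out <- data.frame(resid = r$resid, resno = r$resno, ins = r$ins,
                    min_dist = as.numeric(mind[r$resid]),
                    stringsAsFactors = FALSE)
  attr(out, "members") <- out$resid[out$min_dist <= cutoff]
  attr(out, "cutoff") <- cutoff
  class(out) <- c("interface_set", "data.frame")
  out
}

#' Map an ungapped sequence onto a structure chain
#'
#' Global (Needleman-Wunsch) alignment of the query sequence against the
#' chain's observed one-letter sequence (match +1, mismatch -1, gap -2);
#' aligned positions become map pairs regardless of identity, so
#' substituted homologs map through. The map is colinear: strictly
#' increasing in both coordinates.
#'
#' @param seq Ungapped amino-acid string.
#' @param s A [structure3d].
#' @param chain Chain id.
#' @return A `residue_map`: data frame (`seq_pos`, `resid`, `resno`,
#'   `match`) with attributes `coverage` (mapped fraction of the query)
#'   and `low_identity` (TRUE when alignment identity < 30%).
#' @export
map_seq_to_structure <- function(seq, s, chain) {
  seq <- toupper(gsub("[-.]", "", seq))
  chseq <- chain_sequence(s, chain)
  letters24 <- c(AA20, "X", "B", "Z", "*")
  m <- matrix(-1, length(letters24), length(letters24),
              dimnames = list(letters24, letters24))
  diag(m) <- 1
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq), Biostrings::AAString(chseq),
    substitutionMatrix = m, gapOpening = 0, gapExtension = 2,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  r <- chain_residues(s, chain)
  ip <- 0L; is_ <- 0L
  seq_pos <- integer(0); str_idx <- integer(0)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ip <- ip + 1L
    if (sa[k] != "-") is_ <- is_ + 1L
    if (pa[k] != "-" && sa[k] != "-") {
      seq_pos <- c(seq_pos, ip); str_idx <- c(str_idx, is_)
    }
  }
  ident <- if (length(seq_pos))
    mean(substring(seq, seq_pos, seq_pos) ==
           substring(chseq, str_idx, str_idx)) else 0
  out <- data.frame(seq_pos = seq_pos,
                    resid = r$resid[str_idx], resno = r$resno[str_idx],
                    match = substring(seq, seq_pos, seq_pos) ==
                      substring(chseq, str_idx, str_idx),
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- length(seq_pos) / nchar(seq)
  attr(out, "low_identity") <- ident < 0.30
  if (ident < 0.30)
    warning("sequence-to-structure alignment identity below 30% (",
            sprintf("%.0f%%", 100 * ident), "); map may be unreliable",
            call. = FALSE)
  class(out) <- c("residue_map", "data.frame")
  out
}

#' Transfer residue positions between homologs through an alignment
#'
#' Converts positions of a source sequence (1-based, ungapped) to their
#' alignment columns and reads off the aligned residue of the destination
#' sequence, as used to carry subfamily pattern residues from one homolog
#' onto another's structure.
#'
#' @param x An [msa].
#' @param src_id,dst_id Sequence ids present in `x`.
#' @param positions Integer vector of 1-based ungapped source positions.
#' @return Data frame `src_pos`, `column` (MSA column), `dst_pos`
#'   (1-based ungapped destination position, `NA` where the destination
#'   is gapped), `dst_residue` (`NA` for gap).
#' @export
transfer_residues <- function(x, src_id, dst_id, positions) {
  stopifnot(inherits(x, "msa"))
  i <- match(src_id, x$ids); j <- match(dst_id, x$ids)
  if (is.na(i) || is.na(j))
    stop("sequence id not found in alignment", call. = FALSE)
  sv <- strsplit(x$seqs[i], "")[[1]]
  dv <- strsplit(x$seqs[j], "")[[1]]
  src_cols <- which(sv != "-")
  if (any(positions < 1) || any(positions > length(src_cols)))
    stop("domain-error: position out of range for ", src_id, call. = FALSE)
  cols <- src_cols[positions]
  dst_cum <- cumsum(dv != "-")
  gap <- dv[cols] == "-"
  data.frame(src_pos = as.integer(positions), column = cols,
             dst_pos = ifelse(gap, NA_integer_, dst_cum[cols]),
             dst_residue = ifelse(gap, NA_character_, dv[cols]),
             stringsAsFactors = FALSE)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' corresponding points, via singular value decomposition of the
#' covariance matrix with the usual determinant sign correction.
#'
#' @param mobile,target Numeric n x 3 matrices of corresponding points
#'   (n >= 3, not collinear).
#' @return List with `rotation` (3 x 3, det +1), `translation` (length
#'   3; the fitted transform is `p %*% t(rotation) + translation`),
#'   `rmsd` (post-fit, Angstrom) and `transform(points)`, a function
#'   applying the fit.
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3, ncol(target) == 3,
            nrow(mobile) == nrow(target))
  n <- nrow(mobile)
  if (n < 3) stop("degenerate-geometry: need >= 3 point pairs", call. = FALSE)
  cm <- colMeans(mobile); ct <- colMeans(target)
  X <- sweep(mobile, 2, cm); Y <- sweep(target, 2, ct)
  if (any(svd(X)$d[2] < 1e-8 * max(svd(X)$d[1], 1)))
    stop("degenerate-geometry: collinear points", call. = FALSE)
  H <- t(X) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- ct - as.numeric(R %*% cm)
  fit <- sweep(mobile %*% t(R), 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((fit - target)^2)))
  list(rotation = R, translation = trans, rmsd = rmsd,
       transform = function(p) sweep(as.matrix(p) %*% t(R), 2, trans, "+"))
}

#' Calpha coordinates of a chain
#' @param s A [structure3d].
#' @param chain Chain id.
#' @return Numeric matrix n x 3 (one row per residue with a Calpha).
#' @export
chain_ca <- function(s, chain) {
  a <- chain_atoms(s, chain)
  a <- a[a$calpha, ]
  as.matrix(a[, c("x", "y", "z")])
}
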