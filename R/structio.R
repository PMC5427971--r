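#' Coarse macromolecular structure
#'
#' A `viasm_structure` holds atom records (name, 1-based residue index, chain,
#' residue name, coordinates in Angstrom) for one subunit or one assembled
#' complex. Only `ATOM` records of standard residues are kept when reading PDB
#' files; the scoring model is Calpha/Cbeta level throughout, so ligands and
#' hydrogens are irrelevant.
#'
#' @param atoms data.frame with columns `elety` (atom name), `resno`
#'   (1-based integer residue index), `chain`, `resid` (residue name) and
#'   numeric `x`, `y`, `z`.
#' @return An object of class `viasm_structure`.
#' @export
viasm_structure <- function(atoms) {
  need <- c("elety", "resno", "chain", "resid", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atoms is missing column(s): %s", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms[, need], stringsAsFactors = FALSE)
  atoms$resno <- as.integer(atoms$resno)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) == 0L) stopf("structure has no atoms")
  if (!all(is.finite(xyz))) stopf("structure has non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stopf("duplicate atom records (chain/residue/atom): %s",
          key[duplicated(key)][1L])
  structure(list(atoms = atoms), class = "viasm_structure")
}

#' @export
print.viasm_structure <- function(x, ...) {
  a <- x$atoms
  ch <- unique(a$chain)
  cat(sprintf("viasm_structure: %d atoms, %d residues, %d chain%s (%s)\n",
              nrow(a), length(unique(paste(a$chain, a$resno))), length(ch),
              if (length(ch) == 1L) "" else "s",
              paste(head(ch, 10), collapse = "")))
  invisible(x)
}

n_chains <- function(s) length(unique(s$atoms$chain))

structure_xyz <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

set_structure_xyz <- function(s, xyz) {
  s$atoms[, c("x", "y", "z")] <- xyz
  s
}

#' Read a PDB file into a coarse structure
#'
#' Keeps `ATOM` records only. Alternate locations are resolved by keeping the
#' highest-occupancy record (ties: first in file). Insertion codes, if present,
#' are folded into the residue ordering chain-wise and trigger a warning.
#'
#' @param path path to a PDB file.
#' @return A [viasm_structure()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atom_lines <- which(rec == "ATOM  ")
  if (!length(atom_lines)) stopf("no ATOM records in %s", path)
  for (i in atom_lines) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stopf("malformed coordinate field at line %d of %s", i, path)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(a)) stopf("no ATOM records in %s", path)
  # altloc: keep highest occupancy, ties -> first occurrence
  occ <- a$o
  occ[is.na(occ)] <- 1
  ins <- a$insert
  ins[is.na(ins)] <- ""
  key <- paste(a$chain, a$resno, ins, a$elety)
  ord <- order(match(key, unique(key)), -occ, seq_len(nrow(a)))
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]
  if (any(!is.na(a$insert) & nzchar(a$insert)))
    warning("insertion codes present; residue indices taken as printed")
  viasm_structure(data.frame(
    elety = a$elety, resno = a$resno,
    chain = ifelse(is.na(a$chain) | !nzchar(a$chain), "A", a$chain),
    resid = a$resid, x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE))
}

#' Write a structure to a PDB file
#'
#' One chain identifier per subunit copy; coordinates at the format's
#' 3-decimal precision, so `read_pdb(write_pdb(s))` round-trips coordinates
#' to 1e-3 Angstrom.
#'
#' @param s a [viasm_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  if (!inherits(s, "viasm_structure")) stopf("`s` must be a viasm_structure")
  a <- s$atoms
  if (!nrow(a)) stopf("cannot write an empty structure")
  if (length(unique(a$chain)) > length(chain_alphabet))
    stopf("more than %d chains: PDB chain-ID alphabet exhausted", length(chain_alphabet))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resid,
                   elety = a$elety)
  invisible(path)
}

#' Coordinates of one atom type per residue
#'
#' @param s a [viasm_structure()].
#' @param resno residue indices (1-based, as in the input file).
#' @param atom `"CA"` or `"CB"`.
#' @param chain chain identifier; `NULL` means the only chain (error if several).
#' @return numeric matrix, one row per requested residue.
#' @export
atom_coords <- function(s, resno, atom = c("CA", "CB"), chain = NULL) {
  atom <- match.arg(atom)
  a <- s$atoms
  if (is.null(chain)) {
    ch <- unique(a$chain)
    if (length(ch) > 1L) stopf("structure has several chains; specify `chain`")
    chain <- ch
  }
  sel <- a[a$chain == chain & a$elety == atom, , drop = FALSE]
  idx <- match(resno, sel$resno)
  if (anyNA(idx))
    stopf("residue %s of chain %s has no %s atom",
          paste(resno[is.na(idx)], collapse = ","), chain, atom)
  m <- as.matrix(sel[idx, c("x", "y", "z"), drop = FALSE])
  rownames(m) <- resno
  m
}

#' All Calpha coordinates of a chain (or whole structure)
#'
#' @param s a [viasm_structure()].
#' @param chain chain id, or `NULL` for all chains in atom order.
#' @return numeric matrix of Calpha coordinates, rownames = residue indices.
#' @export
ca_coords <- function(s, chain = NULL) {
  a <- s$atoms
  sel <- a$elety == "CA"
  if (!is.null(chain)) sel <- sel & a$chain == chain
  m <- as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
  rownames(m) <- a$resno[sel]
  m
}

#' Fixed-frame RMSD between two coordinate sets
#'
#' Root-mean-square deviation of corresponding atoms without any
#' superposition. This is the metric used when clustering candidate
#' assemblies, which all live in the same symmetry frame: superposing first
#' would merge genuinely different radii and orientations.
#'
#' @param A,B numeric matrices (n x 3) of corresponding atoms.
#' @return RMSD in Angstrom.
#' @export
rmsd_fixed_frame <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stopf("coordinate sets differ in size")
  if (nrow(A) < 1L) stopf("empty coordinate sets")
  sqrt(mean(rowSums((A - B)^2)))
}

#' Minimal RMSD after optimal rigid superposition
#'
#' Kabsch-style least-squares superposition (proper rotations only), as used
#' when comparing predicted assemblies with a solved reference structure.
#' With fewer than 3 non-collinear points the rotation is underdetermined and
#' a translation-only (centroid) alignment is used with a warning.
#'
#' @inheritParams rmsd_fixed_frame
#' @return RMSD in Angstrom; always `<= rmsd_fixed_frame(A, B)` up to
#'   numerical tolerance.
#' @export
rmsd_superposed <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stopf("coordinate sets differ in size")
  n <- nrow(A)
  if (n < 1L) stopf("empty coordinate sets")
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  sv <- svd(crossprod(Bc, Ac))
  # rank >= 2 (non-collinear) determines the rotation; planar sets are fine
  # because the smallest singular direction carries the chirality correction
  rank2 <- n >= 3L && sv$d[2] > 1e-8 * max(sv$d[1], 1e-300)
  if (!rank2) {
    warning("fewer than 3 non-collinear points: translation-only superposition")
    return(rmsd_fixed_frame(Ac, Bc))
  }
  # proper rotation: flip the smallest singular direction if det < 0
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  rmsd_fixed_frame(Ac, Bc %*% t(R))
}
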