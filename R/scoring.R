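#' Parameters of the coarse 9-6 Lennard-Jones potential
#'
#' Defaults: `sigma = 4.7` Angstrom, `epsilon = 1` kcal/mol, truncation
#' cutoff 12 Angstrom. The potential is truncated (not shifted) at the
#' cutoff; the resulting discontinuity, `4*eps*((sigma/12)^9 - (sigma/12)^6)
#' ~ -0.0136` kcal/mol, is accepted as in typical coarse scoring.
#'
#' @param sigma,epsilon,cutoff positive numbers.
#' @return list of class `viasm_lj`.
#' @export
lj_params <- function(sigma = 4.7, epsilon = 1, cutoff = 12) {
  check_number(sigma, "sigma", lower = 1e-9)
  check_number(epsilon, "epsilon", lower = 1e-9)
  check_number(cutoff, "cutoff", lower = 1e-9)
  structure(list(sigma = sigma, epsilon = epsilon, cutoff = cutoff),
            class = "viasm_lj")
}

#' 9-6 Lennard-Jones pair energy
#'
#' `4*eps*((sigma/r)^9 - (sigma/r)^6)` for `r < cutoff`, 0 beyond.
#' Zero at `r = sigma`; minimum `-16*eps/27` at `r = sigma*(3/2)^(1/3)`.
#'
#' @param r pairwise distance(s) in Angstrom, `> 0`.
#' @param p an [lj_params()].
#' @return energy in kcal/mol (vectorised over `r`).
#' @export
lj_96 <- function(r, p = lj_params()) {
  if (any(r <= 0)) stopf("lj_96 requires r > 0")
  s <- p$sigma / r
  e <- 4 * p$epsilon * (s^9 - s^6)
  e[r >= p$cutoff] <- 0
  e
}

#' Coarse steric energy of an assembly
#'
#' Sum of [lj_96()] over all unique inter-subunit Calpha pairs within the
#' cutoff. All copy pairs are considered (not only adjacent copies): in a
#' closed ring, non-adjacent copies can clash and must be penalised.
#' Intra-subunit pairs are excluded.
#'
#' @param assembly a multi-chain [viasm_structure()] (one chain per copy).
#' @param p an [lj_params()].
#' @return energy in kcal/mol; 0 with a warning for a single-chain structure.
#' @export
e_phys <- function(assembly, p = lj_params()) {
  a <- assembly$atoms
  sel <- a$elety == "CA"
  ch <- a$chain[sel]
  if (length(unique(ch)) < 2L) {
    warning("single-subunit structure: E_phys = 0")
    return(0)
  }
  lj_energy_cpp(as.matrix(a[sel, c("x", "y", "z")]),
                match(ch, unique(ch)), p$sigma, p$epsilon, p$cutoff)
}

#' An inter-subunit residue distance restraint
#'
#' Restrains the distance between an atom of residue `residue_a` on subunit
#' copy 1 and residue `residue_b` on the adjacent copy 2 to
#' `target +/- tolerance` (in Cn symmetry all adjacent interfaces are
#' equivalent). The default tolerance of 2 Angstrom absorbs typical
#' experimental noise on the target measure.
#'
#' @param residue_a,residue_b 1-based residue indices in the subunit.
#' @param target target distance in Angstrom, `> 0`.
#' @param tolerance half-width of the allowed interval, `>= 0`.
#' @param atom `"CA"` or `"CB"`.
#' @param is_true optional truth label used by constraint audits.
#' @return one-row data.frame of class `viasm_constraints`.
#' @export
distance_constraint <- function(residue_a, residue_b, target, tolerance = 2,
                                atom = c("CA", "CB"), is_true = NA) {
  atom <- match.arg(atom)
  check_number(target, "target", lower = 1e-9)
  check_number(tolerance, "tolerance", lower = 0)
  df <- data.frame(residue_a = as.integer(residue_a),
                   residue_b = as.integer(residue_b),
                   atom = atom, target = target, tolerance = tolerance,
                   lower = target - tolerance, upper = target + tolerance,
                   is_true = is_true, stringsAsFactors = FALSE)
  class(df) <- c("viasm_constraints", "data.frame")
  df
}

#' Combine restraints into one table
#' @param ... `viasm_constraints` rows or tables.
#' @return a `viasm_constraints` data.frame.
#' @export
constraint_set <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("viasm_constraints", "data.frame")
  df
}

#' Read/write a restraint table
#'
#' Plain-text format, one restraint per line:
#' `residue_a residue_b atom target tolerance [truth_label]`, with a
#' versioned comment header.
#'
#' @param path file path.
#' @return [read_constraints()] returns a `viasm_constraints` table.
#' @export
read_constraints <- function(path) {
  if (!file.exists(path)) stopf("constraint file not found: %s", path)
  df <- read.table(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("residue_a", "residue_b", "atom", "target", "tolerance")
  if (!all(need %in% names(df)))
    stopf("constraint file must have columns: %s", paste(need, collapse = " "))
  if (is.null(df$is_true)) df$is_true <- NA
  do.call(constraint_set, lapply(seq_len(nrow(df)), function(i)
    distance_constraint(df$residue_a[i], df$residue_b[i], df$target[i],
                        df$tolerance[i], df$atom[i], df$is_true[i])))
}

#' @rdname read_constraints
#' @param constraints a `viasm_constraints` table.
#' @export
write_constraints <- function(constraints, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# viasm restraint table v1", con)
  df <- as.data.frame(constraints)[, c("residue_a", "residue_b", "atom",
                                       "target", "tolerance", "is_true")]
  suppressWarnings(write.table(df, con, row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Observed restraint distances and violations in an assembly
#'
#' Measures each restraint between copy 1 and copy 2 of the assembly
#' (chains in order of appearance) and reports the interval violation
#' `max(0, lower - o, o - upper)`.
#'
#' @param assembly a multi-chain [viasm_structure()].
#' @param constraints a `viasm_constraints` table.
#' @return data.frame with columns `observed`, `lower`, `upper`, `violation`.
#' @export
constraint_distances <- function(assembly, constraints) {
  ch <- unique(assembly$atoms$chain)
  if (length(ch) < 2L) stopf("assembly must have at least 2 subunit copies")
  df <- as.data.frame(constraints)
  obs <- vapply(seq_len(nrow(df)), function(i) {
    pa <- tryCatch(
      atom_coords(assembly, df$residue_a[i], df$atom[i], chain = ch[1]),
      error = function(e) stopf("constraint %d: %s", i, conditionMessage(e)))
    pb <- tryCatch(
      atom_coords(assembly, df$residue_b[i], df$atom[i], chain = ch[2]),
      error = function(e) stopf("constraint %d: %s", i, conditionMessage(e)))
    sqrt(sum((pa - pb)^2))
  }, numeric(1))
  data.frame(observed = obs, lower = df$lower, upper = df$upper,
             violation = pmax(0, df$lower - obs, obs - df$upper))
}

#' Root of summed squared restraint deviations
#'
#' `sqrt(sum((observed - target)^2))`: the aggregated data term of the
#' reference (weighted-fitness) scoring mode.
#'
#' @param observed,targets equal-length numeric vectors in Angstrom.
#' @return non-negative scalar, 0 iff all observations hit their targets.
#' @export
e_data <- function(observed, targets) {
  if (length(observed) != length(targets) || !length(observed))
    stopf("observed and targets must have equal length >= 1")
  sqrt(sum((observed - targets)^2))
}

#' Weighted aggregate of steric and data terms
#'
#' `w * E_phys + (1 - w) * E_data` with default weight `w = 0.2`. This is the
#' single-objective reference scoring; the viability-evolution protocols never
#' use it — constraints are handled independently there.
#'
#' @param e_phys,e_data scalars.
#' @param w weight in `[0, 1]`.
#' @return scalar fitness (to be minimised).
#' @export
aggregated_fitness <- function(e_phys, e_data, w = 0.2) {
  check_number(w, "w", lower = 0, upper = 1)
  w * e_phys + (1 - w) * e_data
}

#' Population diversity of a candidate
#'
#' `sqrt(sum_i ||x - X_i||^2) / n` over the `n` search-unit parameter vectors
#' `X_i`. Both the candidate and the population must be expressed in the
#' normalised unit box (angles / 2*pi, radius / x_max); otherwise the
#' Euclidean metric would mix radians with Angstrom.
#'
#' @param x numeric parameter vector.
#' @param population matrix with one unit parameter vector per row.
#' @return non-negative scalar; larger = farther from the population.
#' @export
diversity <- function(x, population) {
  population <- as.matrix(population)
  if (!nrow(population)) stopf("empty population")
  if (ncol(population) != length(x)) stopf("dimension mismatch")
  sqrt(sum(sweep(population, 2, x)^2)) / nrow(population)
}

#' Positive predictive value of restraint satisfaction
#'
#' `TP / (TP + FP)`: the precision with which a model satisfies correct
#' restraints (TP) rather than wrong ones (FP). 1 means only correct
#' restraints were satisfied.
#'
#' @param tp,fp non-negative counts, `tp + fp >= 1`.
#' @return value in `[0, 1]`.
#' @export
ppv <- function(tp, fp) {
  check_number(tp, "tp", lower = 0)
  check_number(fp, "fp", lower = 0)
  if (tp + fp < 1) stopf("PPV undefined: no satisfied constraints (tp + fp = 0)")
  tp / (tp + fp)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with the degenerate cases turned into
#' errors (used as an optimisation objective, where NA would poison a run).
#'
#' @param x,y equal-length numeric vectors, length `>= 3`, nonzero variance.
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stopf("pearson needs equal lengths >= 3")
  if (stats::var(x) <= 0 || stats::var(y) <= 0)
    stopf("pearson undefined: zero variance")
  stats::cor(x, y)
}

#' Fractional crosslinking profile
#'
#' Maps residue indices to the experimentally observed fraction of disulfide
#' crosslinked species, which is roughly monotone (decreasing) in the
#' inter-subunit Cbeta distance of the residue.
#'
#' @param resno integer residue indices.
#' @param fraction crosslinked fractions in `[0, 1]`.
#' @return data.frame of class `viasm_xlprofile`.
#' @export
crosslink_profile <- function(resno, fraction) {
  if (length(resno) != length(fraction)) stopf("lengths differ")
  if (any(fraction < 0 | fraction > 1)) stopf("fractions must lie in [0, 1]")
  df <- data.frame(resno = as.integer(resno), fraction = as.numeric(fraction))
  class(df) <- c("viasm_xlprofile", "data.frame")
  df
}

#' Read/write a crosslink profile (`residue_index fraction` per line)
#' @param path file path.
#' @export
read_crosslink_profile <- function(path) {
  df <- read.table(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  crosslink_profile(df$resno, df$fraction)
}

#' @rdname read_crosslink_profile
#' @param profile a `viasm_xlprofile`.
#' @export
write_crosslink_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# viasm crosslink profile v1", con)
  suppressWarnings(write.table(as.data.frame(profile), con,
                               row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Crosslink-correlation objective for a homodimer
#'
#' For every profiled residue, measures the Cbeta-Cbeta distance between the
#' two copies (same residue index on each), and correlates these distances
#' with the crosslinking fractions. The magnitude `|R|` is the quantity to
#' maximise; the signed value is reported alongside (physically one expects a
#' negative sign: more crosslinking at shorter distance).
#'
#' @param assembly a two-chain [viasm_structure()].
#' @param profile a [crosslink_profile()] with `>= 3` residues.
#' @return list with `R` (signed), `abs_R`, and the per-residue `table`
#'   (`resno`, `fraction`, `distance`).
#' @export
crosslink_objective <- function(assembly, profile) {
  ch <- unique(assembly$atoms$chain)
  if (length(ch) != 2L) stopf("crosslink objective requires a dimer (2 chains)")
  if (nrow(profile) < 3L) stopf("need >= 3 profiled residues")
  pa <- atom_coords(assembly, profile$resno, "CB", chain = ch[1])
  pb <- atom_coords(assembly, profile$resno, "CB", chain = ch[2])
  d <- sqrt(rowSums((pa - pb)^2))
  r <- pearson(profile$fraction, d)
  list(R = r, abs_R = abs(r),
       table = data.frame(resno = profile$resno, fraction = profile$fraction,
                          distance = d))
}
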