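# Synthetic fixtures: toy subunits, ground-truth Cn assemblies, true/false
# restraints and noisy crosslink profiles. Everything is a pure function of
# its seed so end-to-end recovery experiments are reproducible offline.

#' Generate a toy subunit
#'
#' Calpha trace plus a pseudo-Cbeta 1.5 Angstrom along a fixed local
#' direction (radially outward from the subunit centroid, which is all the
#' coarse Calpha/Cbeta scoring model needs). `"helix"` uses ideal alpha-helix
#' parameters (rise 1.5 A, 100 degrees per residue, radius 2.3 A), giving
#' consecutive Calpha distances of ~3.8 A; `"compact"` grows a
#' rejection-sampled self-avoiding cluster with 3.8 A steps and a minimum
#' pairwise separation of 3.8 A.
#'
#' @param n_residues number of residues (`>= 5`).
#' @param geometry `"helix"` or `"compact"`.
#' @param seed RNG seed (only `"compact"` consumes random numbers).
#' @return a single-chain [viasm_structure()] with CA and CB atoms.
#' @export
make_toy_subunit <- function(n_residues = 20, geometry = c("helix", "compact"),
                             seed = 1) {
  geometry <- match.arg(geometry)
  n <- as.integer(n_residues)
  if (n < 5L) stopf("n_residues must be >= 5")
  if (geometry == "helix") {
    i <- seq_len(n) - 1L
    theta <- i * 100 * pi / 180
    ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  } else {
    st <- rng_state(seed)
    rmax <- 3.8 * (1.5 * n)^(1/3) + 3.8
    ca <- with_rng(st, {
      pos <- matrix(0, n, 3)
      for (k in 2:n) {
        ok <- FALSE
        for (try in 1:2000) {
          u <- rnorm(3)
          dir <- u / sqrt(sum(u^2))
          # bias the step toward the running centroid to stay compact
          ctr <- colMeans(pos[seq_len(k - 1L), , drop = FALSE])
          pull <- ctr - pos[k - 1L, ]
          np <- sqrt(sum(pull^2))
          if (np > 1e-9) dir <- dir + 0.3 * pull / max(np, 3.8)
          dir <- dir / sqrt(sum(dir^2))
          cand <- pos[k - 1L, ] + 3.8 * dir
          dmin <- min(sqrt(rowSums(sweep(pos[seq_len(k - 1L), , drop = FALSE],
                                         2, cand)^2)))
          if (dmin >= 3.8 && sqrt(sum(cand^2)) <= rmax) { ok <- TRUE; break }
        }
        if (!ok) stopf("could not grow a self-avoiding cluster (residue %d)", k)
        pos[k, ] <- cand
      }
      pos
    })$value
  }
  ctr <- colMeans(ca)
  rad <- sweep(ca, 2, ctr)
  nr <- sqrt(rowSums(rad^2))
  nr[nr < 1e-9] <- 1
  cb <- ca + 1.5 * rad / nr
  atoms <- data.frame(
    elety = rep(c("CA", "CB"), n),
    resno = rep(seq_len(n), each = 2L),
    chain = "A", resid = "ALA",
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3])),
    stringsAsFactors = FALSE)
  viasm_structure(atoms)
}

#' Build a ground-truth Cn reference assembly
#'
#' Draws a random subunit orientation (seeded) and chooses the assembly
#' radius by a line search: the smallest radius at which the coarse energy is
#' attractive (`E_phys < 0`) while no inter-subunit atom pair comes closer
#' than 3 Angstrom — contact without clash.
#'
#' @param subunit a [viasm_structure()].
#' @param n symmetry order (`>= 2`).
#' @param seed RNG seed for the orientation.
#' @param step radius line-search step in Angstrom.
#' @return list with `assembly` ([viasm_structure()]), `params`
#'   ([assembly_params()]) and `n`.
#' @export
make_reference_assembly <- function(subunit, n, seed = 1, step = 0.25) {
  n <- as.integer(n)
  if (n < 2L) stopf("n must be >= 2")
  ang <- with_rng(rng_state(seed), runif(3, 0, 2 * pi))$value
  bounds <- default_bounds(subunit, n)
  p <- lj_params()
  M <- structure_xyz(subunit)
  ctr <- colMeans(ca_coords(subunit))
  Mc <- sweep(M, 2, ctr)
  is_ca <- subunit$atoms$elety == "CA"
  copy <- rep(seq_len(n), each = nrow(M))[rep(is_ca, n)]
  for (x in seq(0, bounds$upper[4], by = step)) {
    xyz <- sym_xyz(Mc, ang[1], ang[2], ang[3], x, n)[rep(is_ca, n), , drop = FALSE]
    if (min_intercopy_dist_cpp(xyz, copy) >= 3.0 &&
        lj_energy_cpp(xyz, copy, p$sigma, p$epsilon, p$cutoff) < 0) {
      params <- assembly_params(ang[1], ang[2], ang[3], x)
      return(list(assembly = build_symmetric(subunit, params, n),
                  params = params, n = n))
    }
  }
  stopf("no radius gives contact without clash for this subunit")
}

# Cross-interface Calpha pairs (copy 1 vs copy 2) with their distances.
interface_pairs <- function(assembly) {
  ch <- unique(assembly$atoms$chain)
  a <- ca_coords(assembly, ch[1])
  b <- ca_coords(assembly, ch[2])
  d <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
  data.frame(residue_a = as.integer(rep(rownames(a), ncol(d))),
             residue_b = as.integer(rep(rownames(b), each = nrow(d))),
             distance = as.vector(d))
}

#' Derive true restraints from a reference assembly
#'
#' Samples `k` cross-interface Calpha pairs closer than `max_dist` (contacting
#' residues) and restrains each to its true distance `+/- tolerance`.
#'
#' @param assembly the ground-truth assembly.
#' @param k number of restraints.
#' @param tolerance half-width in Angstrom (default 2).
#' @param seed RNG seed for the pair sampling.
#' @param max_dist contact definition (default 8 A).
#' @return a `viasm_constraints` table labelled `is_true = TRUE`.
#' @export
derive_constraints <- function(assembly, k, tolerance = 2, seed = 1,
                               max_dist = 8) {
  pr <- interface_pairs(assembly)
  pr <- pr[pr$distance < max_dist, , drop = FALSE]
  if (nrow(pr) < k)
    stopf("interface too sparse: %d contacting pairs < %g A, need %d",
          nrow(pr), max_dist, k)
  pick <- with_rng(rng_state(seed + 7L), sample.int(nrow(pr), k))$value
  do.call(constraint_set, lapply(pick, function(i)
    distance_constraint(pr$residue_a[i], pr$residue_b[i], pr$distance[i],
                        tolerance, "CA", is_true = TRUE)))
}

#' Derive deliberately wrong restraints
#'
#' Picks cross-interface pairs whose true distance exceeds the upper bound of
#' a plausible contact interval (`target + tolerance`) by at least `margin`
#' (default 5 A), so no correct geometry can satisfy them; the stated target
#' is a plausible contact value (6 A). Disjoint from any true-restraint pair
#' by construction (true pairs are < 8 A, wrong pairs are >= 13 A away).
#'
#' @param assembly the ground-truth assembly.
#' @param k number of wrong restraints.
#' @param seed RNG seed.
#' @param target stated (wrong) target distance.
#' @param tolerance half-width in Angstrom.
#' @param margin minimum excess of the true distance over `target + tolerance`.
#' @return a `viasm_constraints` table labelled `is_true = FALSE`.
#' @export
derive_wrong_constraints <- function(assembly, k, seed = 1, target = 6,
                                     tolerance = 2, margin = 5) {
  pr <- interface_pairs(assembly)
  pr <- pr[pr$distance >= target + tolerance + margin, , drop = FALSE]
  if (nrow(pr) < k) stopf("cannot find %d sufficiently wrong pairs", k)
  pick <- with_rng(rng_state(seed + 13L), sample.int(nrow(pr), k))$value
  do.call(constraint_set, lapply(pick, function(i)
    distance_constraint(pr$residue_a[i], pr$residue_b[i], target,
                        tolerance, "CA", is_true = FALSE)))
}

#' Simulate a fractional crosslinking profile from a dimer
#'
#' Emulates disulfide-scanning data: the crosslinked fraction of residue `i`
#' is a decreasing logistic function of its inter-subunit Cbeta distance,
#' `clamp(logistic((d0 - d_i)/s) + noise, 0, 1)`, with midpoint `d0 = 12` A
#' and slope scale `s = 3` A, plus Gaussian noise.
#'
#' @param assembly a two-chain ground-truth assembly.
#' @param residues residue indices to profile (must have Cbeta).
#' @param noise_sd Gaussian noise SD on the fractions.
#' @param seed RNG seed.
#' @param d0,s logistic midpoint and scale in Angstrom.
#' @return a [crosslink_profile()].
#' @export
synth_crosslink_profile <- function(assembly, residues, noise_sd = 0.05,
                                    seed = 1, d0 = 12, s = 3) {
  ch <- unique(assembly$atoms$chain)
  if (length(ch) != 2L) stopf("crosslink profiles require a dimer (2 chains)")
  pa <- atom_coords(assembly, residues, "CB", chain = ch[1])
  pb <- atom_coords(assembly, residues, "CB", chain = ch[2])
  d <- sqrt(rowSums((pa - pb)^2))
  fr <- plogis((d0 - d) / s)
  if (noise_sd > 0)
    fr <- fr + with_rng(rng_state(seed + 23L),
                        rnorm(length(fr), 0, noise_sd))$value
  crosslink_profile(residues, pmin(pmax(fr, 0), 1))
}
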