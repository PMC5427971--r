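# Shared fixtures, built once per test run.

fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name, build) {
    if (!exists(name, cache)) assign(name, build(), cache)
    get(name, cache)
  }
})

toy_helix <- function() fx("helix", function() make_toy_subunit(20, "helix"))
toy_compact <- function() fx("compact", function() make_toy_subunit(20, "compact", seed = 11))

ref_c5 <- function() fx("ref_c5", function()
  make_reference_assembly(toy_helix(), 5, seed = 3))

ref_dimer <- function() fx("ref_dimer", function()
  make_reference_assembly(toy_compact(), 2, seed = 5))

# 3-atom single-residue PDB text used by parser tests
mini_pdb_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  CB  ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "END")

# random rigid transform (proper rotation + translation), seeded by caller
random_rigid <- function() {
  ang <- runif(3, 0, 2 * pi)
  list(R = viasm:::euler_zyz(ang[1], ang[2], ang[3]), t = runif(3, -20, 20))
}

# Residues of a dimer whose inter-subunit Cbeta distance falls in the
# responsive band of the crosslinking logistic (what a disulfide scan of the
# interface region measures).
profiled_residues <- function(assembly, band = c(4, 22), min_n = 8) {
  ch <- unique(assembly$atoms$chain)
  resn <- unique(assembly$atoms$resno)
  pa <- atom_coords(assembly, resn, "CB", ch[1])
  pb <- atom_coords(assembly, resn, "CB", ch[2])
  d <- sqrt(rowSums((pa - pb)^2))
  sel <- resn[d >= band[1] & d <= band[2]]
  if (length(sel) < min_n) sel <- resn[order(d)][seq_len(min_n)]
  sort(sel)
}

# independent complete-linkage oracle: naive agglomeration by merge enumeration
naive_complete_linkage <- function(D, threshold) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (is.null(best) || h < best$h) best <- list(i = i, j = j, h = h)
    }
    if (is.null(best) || best$h >= threshold) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  lapply(clusters, sort)
}
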