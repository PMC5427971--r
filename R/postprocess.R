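#' Complete-linkage clustering of candidate assemblies
#'
#' Agglomerative clustering on fixed-frame Calpha RMSD, cut so that every
#' cluster's maximum pairwise RMSD stays below `threshold` (the complete-
#' linkage guarantee; candidate assemblies share one symmetry frame, so no
#' superposition is applied). The centroid of a cluster is the member
#' minimising the summed RMSD to the other members (ties: lowest candidate
#' id).
#'
#' @param coords list of n x 3 Calpha coordinate matrices, one per candidate,
#'   all with identical atom correspondence.
#' @param threshold RMSD cut in Angstrom (default 1).
#' @return object of class `viasm_clusters`: list with `assignment` (cluster
#'   id per candidate), `clusters` (member ids), `centroids` (candidate id
#'   per cluster), `max_rmsd` (within-cluster max pairwise RMSD), and the
#'   pairwise distance matrix.
#' @export
cluster_solutions <- function(coords, threshold = 1.0) {
  if (!length(coords)) stopf("no candidates to cluster")
  flat <- do.call(rbind, lapply(coords, function(m) as.vector(t(m))))
  D <- rmsd_matrix_cpp(flat)
  if (length(coords) == 1L) {
    assignment <- 1L
  } else {
    hc <- hclust(as.dist(D), method = "complete")
    assignment <- cutree(hc, h = threshold * (1 - 1e-9))
  }
  ids <- seq_along(coords)
  clusters <- split(ids, assignment)
  centroids <- vapply(clusters, function(mem) {
    if (length(mem) == 1L) return(mem)
    ssum <- rowSums(D[mem, mem, drop = FALSE])
    mem[which.min(ssum)]          # which.min takes the first (lowest id) tie
  }, integer(1))
  max_rmsd <- vapply(clusters, function(mem) {
    if (length(mem) == 1L) return(0)
    max(D[mem, mem])
  }, numeric(1))
  structure(list(assignment = assignment, clusters = clusters,
                 centroids = centroids, max_rmsd = max_rmsd,
                 threshold = threshold, dist = D),
            class = "viasm_clusters")
}

#' @export
print.viasm_clusters <- function(x, ...) {
  cat(sprintf("viasm_clusters: %d candidates in %d clusters (complete linkage, %.2g A)\n",
              length(x$assignment), length(x$clusters), x$threshold))
  sizes <- lengths(x$clusters)
  cat("largest clusters:", paste(head(sort(sizes, decreasing = TRUE), 5),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Rank candidate models by cross-correlation against a density map
#'
#' Each model is (optionally) rigid-fitted into the map with [fit_to_map()]
#' and ranked by descending ccc; ties are broken by candidate id, so the
#' ranking is invariant to input order.
#'
#' @param models list of [viasm_structure()]s or Calpha coordinate matrices.
#' @param map reference [density_map()].
#' @param mode `"plain"` or `"laplace"` (passed to [fit_to_map()]).
#' @param fit if `FALSE`, models are assumed already posed in the map frame
#'   and scored directly without refitting.
#' @param n_start,maxit fitting effort (see [fit_to_map()]).
#' @return object of class `viasm_ranked`: data.frame `ranking` with columns
#'   `id`, `ccc` (ordered), plus the fitted models.
#' @export
rank_by_ccc <- function(models, map, mode = c("plain", "laplace"), fit = TRUE,
                        n_start = 6, maxit = 80) {
  mode <- match.arg(mode)
  if (!length(models)) stopf("no models to rank")
  scores <- numeric(length(models))
  fitted <- vector("list", length(models))
  target <- if (mode == "laplace") laplace_filter(map) else map
  tvec <- as.vector(target$grid)
  for (i in seq_along(models)) {
    if (fit) {
      f <- fit_to_map(models[[i]], map, mode = mode, n_start = n_start,
                      maxit = maxit)
      scores[i] <- f$ccc
      fitted[[i]] <- f$xyz
    } else {
      xyz <- extract_ca_xyz(models[[i]])
      m <- simulate_on_grid(xyz, map, map$resolution)
      if (mode == "laplace") m <- laplace_filter(m)
      v <- as.vector(m$grid)
      scores[i] <- masked_cor_cpp(v, tvec, 1e-6 * max(v, 0), 1e-6 * max(tvec))
      fitted[[i]] <- xyz
    }
  }
  ord <- order(-scores, seq_along(models))
  structure(list(ranking = data.frame(id = ord, ccc = scores[ord]),
                 models = fitted[ord], mode = mode, fit = fit),
            class = "viasm_ranked")
}

#' @export
print.viasm_ranked <- function(x, ...) {
  cat(sprintf("viasm_ranked: %d models (%s-mode ccc%s). Top 5:\n",
              nrow(x$ranking), x$mode, if (x$fit) ", refitted" else ""))
  print(head(x$ranking, 5), row.names = FALSE)
  invisible(x)
}

#' Top-k view of a ranking
#' @param ranked a `viasm_ranked`.
#' @param k how many models.
#' @return data.frame of the top `k` rows.
#' @export
top_models <- function(ranked, k = 5) head(ranked$ranking, k)

#' Audit a model against labelled restraints
#'
#' A restraint is satisfied iff its observed distance lies inside its own
#' `[lower, upper]` interval (no extra slack). TP counts satisfied
#' true-labelled restraints, FP satisfied false-labelled ones; precision is
#' `TP / (TP + FP)` (NA with a note when the model satisfies no restraint).
#'
#' @param model a multi-chain [viasm_structure()].
#' @param constraints a `viasm_constraints` table with `is_true` labels.
#' @return list with `tp`, `fp`, `ppv`, `n_satisfied` and the per-restraint
#'   satisfaction table.
#' @export
audit_constraints <- function(model, constraints) {
  df <- as.data.frame(constraints)
  if (anyNA(df$is_true)) stopf("audit requires truth labels on all constraints")
  cd <- constraint_distances(model, constraints)
  sat <- cd$violation <= 0
  tp <- sum(sat & df$is_true)
  fp <- sum(sat & !df$is_true)
  list(tp = tp, fp = fp,
       ppv = if (tp + fp >= 1) tp / (tp + fp) else NA_real_,
       n_satisfied = sum(sat),
       table = cbind(df[, c("residue_a", "residue_b", "atom", "is_true")],
                     cd, satisfied = sat))
}

#' Calpha RMSD of a model to a reference assembly
#'
#' Optimal-superposition RMSD minimised over the `n` cyclic relabelings of
#' the subunit chains (copy `k` of the model matched to copy `k + s` of the
#' reference for every shift `s`), since a Cn assembly is only defined up to
#' a cyclic chain permutation. Reflections are not considered by default.
#'
#' @param model,reference [viasm_structure()]s with the same per-subunit atom
#'   count and the same number of chains.
#' @param superpose if `FALSE`, uses fixed-frame RMSD instead (map frame).
#' @return minimal Calpha RMSD in Angstrom.
#' @export
compare_to_reference <- function(model, reference, superpose = TRUE) {
  A <- ca_coords(model)
  B <- ca_coords(reference)
  if (!all(dim(A) == dim(B))) stopf("model and reference atom counts differ")
  n <- n_chains(model)
  if (n != n_chains(reference)) stopf("model and reference symmetry order differ")
  m <- nrow(A) / n
  f <- if (superpose) rmsd_superposed else rmsd_fixed_frame
  best <- Inf
  for (s in 0:(n - 1)) {
    idx <- as.vector(vapply(0:(n - 1), function(k)
      ((k + s) %% n) * m + seq_len(m), numeric(m)))
    best <- min(best, f(A, B[idx, , drop = FALSE]))
  }
  best
}
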