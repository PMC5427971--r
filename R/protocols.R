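# Experiment protocols: each one wires the scoring terms, the mViE engine
# and the postprocessing chain (cluster -> centroid -> ccc ranking) into one
# of the supported prediction modes.

#' Configuration of an assembly-prediction protocol
#'
#' Collects every input of the `protocol_*()` functions and validates the
#' mode-specific requirements. File paths are accepted for `subunit`
#' (PDB), `constraints` (restraint table), `map` (MRC/SITUS) and `profile`
#' (crosslink profile) and are read on the spot.
#'
#' @param mode one of `"diversity"`, `"energy_objective"`, `"ccc_objective"`,
#'   `"blind_dock"`, `"crosslink"`, `"audit"`, `"aggregated_reference"`.
#' @param subunit subunit structure or PDB path.
#' @param n_subunits cyclic symmetry order.
#' @param constraints restraint table or path (modes with distance restraints).
#' @param map density map or path (ccc-based modes; optional for ranking in
#'   others).
#' @param resolution map resolution used when simulating model maps.
#' @param profile crosslink profile or path (crosslink mode).
#' @param anchor list `(residue, lower, upper)`: Cbeta-Cbeta interval of the
#'   top-crosslinked residue (crosslink mode; no default is assumed).
#' @param budget evaluation budget per run.
#' @param n_units mViE population size.
#' @param seed master seed; trial loops use `seed + trial index`.
#' @param trials independent repetitions (audit mode).
#' @param w aggregate weight (aggregated_reference mode).
#' @param lj [lj_params()].
#' @param x_max radius upper bound override (default from [default_bounds()]).
#' @param optimizer extra control entries passed to [mvie_run()].
#' @param max_models cap on archived candidates taken into clustering
#'   (evenly thinned).
#' @param rank_clusters how many of the largest clusters are ccc-ranked.
#' @param rank_mode `"laplace"` (default) or `"plain"`: whether centroids are
#'   scored on Laplacian-filtered maps. Filtering sharpens shape boundaries
#'   and is what makes low-resolution maps discriminative in ranking.
#' @param refit_every evaluations between 6-dof map re-alignments
#'   (ccc_objective mode).
#' @return list of class `viasm_config`.
#' @export
protocol_config <- function(mode, subunit, n_subunits = 2, constraints = NULL,
                            map = NULL, resolution = 15, profile = NULL,
                            anchor = NULL, budget = 20000, n_units = 20,
                            seed = 1, trials = 1, w = 0.2, lj = lj_params(),
                            x_max = NULL, optimizer = list(),
                            max_models = 300, rank_clusters = 40,
                            rank_mode = c("laplace", "plain"),
                            refit_every = 1000) {
  rank_mode <- match.arg(rank_mode)
  mode <- match.arg(mode, c("diversity", "energy_objective", "ccc_objective",
                            "blind_dock", "crosslink", "audit",
                            "aggregated_reference"))
  if (is.character(subunit)) subunit <- read_pdb(subunit)
  if (is.character(constraints)) constraints <- read_constraints(constraints)
  if (is.character(map)) map <- read_map(map)
  if (is.character(profile)) profile <- read_crosslink_profile(profile)
  if (!is.null(map) && is.na(map$resolution)) map$resolution <- resolution
  need_constraints <- mode %in% c("diversity", "energy_objective",
                                  "ccc_objective", "audit",
                                  "aggregated_reference")
  if (need_constraints && is.null(constraints))
    stopf("mode '%s' requires distance constraints", mode)
  if (mode %in% c("diversity", "ccc_objective", "blind_dock") && is.null(map))
    stopf("mode '%s' requires a density map", mode)
  if (mode == "crosslink") {
    if (is.null(profile) || nrow(profile) < 3L)
      stopf("crosslink mode requires a profile with >= 3 residues")
    if (is.null(anchor) || !all(c("residue", "lower", "upper") %in% names(anchor)))
      stopf("crosslink mode requires an anchor = list(residue, lower, upper)")
    if (n_subunits != 2L) stopf("crosslink mode models a homodimer (n_subunits = 2)")
  }
  structure(list(mode = mode, subunit = subunit, n_subunits = as.integer(n_subunits),
                 constraints = constraints, map = map, resolution = resolution,
                 profile = profile, anchor = anchor, budget = budget,
                 n_units = n_units, seed = seed, trials = trials, w = w,
                 lj = lj, x_max = x_max, optimizer = optimizer,
                 max_models = max_models, rank_clusters = rank_clusters,
                 rank_mode = rank_mode, refit_every = refit_every),
            class = "viasm_config")
}

# ---- scene: precomputed geometry for fast candidate evaluation ------------
# Scoring atoms are the subunit Calphas plus any Cbeta referenced by a
# restraint or profile, centred on the Calpha centroid. Restraints are
# measured between copy 1 and copy 2.
make_scene <- function(config) {
  sub <- config$subunit
  n <- config$n_subunits
  ca <- ca_coords(sub)
  resno_ca <- as.integer(rownames(ca))
  rows <- data.frame(resno = resno_ca, atom = "CA", stringsAsFactors = FALSE)
  need_cb <- integer(0)
  if (!is.null(config$constraints)) {
    df <- as.data.frame(config$constraints)
    need_cb <- c(need_cb, df$residue_a[df$atom == "CB"], df$residue_b[df$atom == "CB"])
  }
  if (!is.null(config$profile)) need_cb <- c(need_cb, config$profile$resno)
  if (!is.null(config$anchor)) need_cb <- c(need_cb, config$anchor$residue)
  need_cb <- sort(unique(need_cb))
  S <- ca
  if (length(need_cb)) {
    cb <- atom_coords(sub, need_cb, "CB")
    S <- rbind(S, cb)
    rows <- rbind(rows, data.frame(resno = need_cb, atom = "CB"))
  }
  ctr <- colMeans(ca)
  S <- sweep(S, 2, ctr)
  m <- nrow(S)
  row_of <- function(resno, atom) {
    i <- which(rows$resno == resno & rows$atom == atom)
    if (!length(i)) stopf("residue %d has no %s atom", resno, atom)
    i
  }
  cons_idx <- NULL
  if (!is.null(config$constraints)) {
    df <- as.data.frame(config$constraints)
    cons_idx <- cbind(
      a = vapply(seq_len(nrow(df)), function(i) row_of(df$residue_a[i], df$atom[i]), integer(1)),
      b = vapply(seq_len(nrow(df)), function(i) row_of(df$residue_b[i], df$atom[i]), integer(1)) + m)
  }
  bounds <- default_bounds(sub, n, x_max = config$x_max)
  list(S = S, m = m, n = n, rows = rows,
       ca_rows_all = as.vector(outer(seq_len(nrow(ca)), (seq_len(n) - 1L) * m, "+")),
       ca_copy = rep(seq_len(n), each = nrow(ca)),
       cons_idx = cons_idx,
       cons_lower = if (!is.null(config$constraints)) config$constraints$lower,
       cons_upper = if (!is.null(config$constraints)) config$constraints$upper,
       cons_target = if (!is.null(config$constraints)) config$constraints$target,
       x_max = bounds$upper[4], lj = config$lj, row_of = row_of)
}

decode_params <- function(u, scene) {
  assembly_params(u[1] * 2 * pi, u[2] * 2 * pi, u[3] * 2 * pi, u[4] * scene$x_max)
}

# Render all scoring atoms of the assembly for unit-box parameters u[1:4].
scene_xyz <- function(scene, u) {
  sym_xyz(scene$S, u[1] * 2 * pi, u[2] * 2 * pi, u[3] * 2 * pi,
          u[4] * scene$x_max, scene$n)
}

scene_ephys <- function(scene, xyz) {
  lj_energy_cpp(xyz[scene$ca_rows_all, , drop = FALSE], scene$ca_copy,
                scene$lj$sigma, scene$lj$epsilon, scene$lj$cutoff)
}

scene_cons_dist <- function(scene, xyz) {
  if (is.null(scene$cons_idx)) return(numeric(0))
  sqrt(rowSums((xyz[scene$cons_idx[, "a"], , drop = FALSE] -
                  xyz[scene$cons_idx[, "b"], , drop = FALSE])^2))
}

cons_violation <- function(d, lower, upper) pmax(0, lower - d, d - upper)

# Strict E_phys < 0 viability: zero energy (no contact at all) is not viable,
# so the bound is enforced with a tiny negative margin.
ephys_violation <- function(e) max(0, e + 1e-6)

# Build the full structure for unit-box parameters (plus optional pose).
scene_structure <- function(scene, config, u, pose = NULL) {
  s <- build_symmetric(config$subunit, decode_params(u, scene), scene$n)
  if (!is.null(pose)) s <- set_structure_xyz(s, transform_xyz(
    structure_xyz(s), euler_zyz(pose[1], pose[2], pose[3]), pose[4:6]))
  s
}

# Shared post-run chain: archive -> thin -> cluster -> centroids -> rank.
finish_protocol <- function(run, scene, config, render, pose_of = NULL) {
  if (!run$feasible) {
    return(structure(list(run = run, feasible = FALSE, config = config,
                          message = "no viable solutions within budget"),
                     class = "viasm_protocol"))
  }
  idx <- seq_len(run$archive$n)
  if (length(idx) > config$max_models)
    idx <- unique(round(seq(1, run$archive$n, length.out = config$max_models)))
  coords <- lapply(idx, function(i) render(run$archive$params[i, ]))
  cl <- cluster_solutions(coords, threshold = 1.0)
  ord <- order(-lengths(cl$clusters), vapply(cl$clusters, min, integer(1)))
  keep <- head(ord, config$rank_clusters)
  cent_coords <- lapply(cl$centroids[keep], function(i) coords[[i]])
  cent_arc <- idx[cl$centroids[keep]]
  if (!is.null(config$map)) {
    posed <- !is.null(pose_of)
    ranked <- rank_by_ccc(cent_coords, config$map, mode = config$rank_mode,
                          fit = !posed)
    score_name <- "ccc"
  } else {
    sc <- vapply(cent_arc, function(i) {
      xyz <- scene_xyz(scene, run$archive$params[i, ])
      scene_ephys(scene, xyz)
    }, numeric(1))
    ord2 <- order(sc, cent_arc)
    ranked <- structure(list(ranking = data.frame(id = ord2, e_phys = sc[ord2]),
                             models = cent_coords[ord2], mode = "energy",
                             fit = FALSE), class = "viasm_ranked")
    score_name <- "e_phys"
  }
  top_ids <- cent_arc[ranked$ranking$id[seq_len(min(5, nrow(ranked$ranking)))]]
  models <- lapply(top_ids, function(i) {
    u <- run$archive$params[i, ]
    scene_structure(scene, config, u,
                    pose = if (!is.null(pose_of)) pose_of(u))
  })
  structure(list(run = run, feasible = TRUE, clusters = cl, ranked = ranked,
                 models = models, archive_ids = cent_arc,
                 score = score_name, config = config),
            class = "viasm_protocol")
}

#' @export
print.viasm_protocol <- function(x, ...) {
  cat(sprintf("viasm protocol '%s': ", x$config$mode))
  if (!x$feasible) {
    cat("FAILED -", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("%d viable models, %d clusters\n",
              x$run$archive$n, length(x$clusters$clusters)))
  cat("top-ranked models:\n")
  print(head(x$ranked$ranking, 5), row.names = FALSE)
  invisible(x)
}

# mvie control assembled from a config
run_control <- function(config, extra = list()) {
  modifyList(modifyList(list(), config$optimizer), extra)
}

#' Diversity-objective assembly protocol
#'
#' The flagship viability mode: every distance restraint interval and
#' `E_phys < 0` are independent viability constraints; once candidates are
#' viable the optimizer maximises population diversity to spread them over
#' the feasible region. The archive is clustered at 1 Angstrom Calpha RMSD
#' and cluster centroids are ranked by ccc against the input map.
#'
#' @param config a [protocol_config()] with mode `"diversity"`.
#' @return a `viasm_protocol` result.
#' @export
protocol_diversity <- function(config) {
  stopifnot(config$mode == "diversity")
  scene <- make_scene(config)
  evaluate <- function(u, pop, need_obj) {
    xyz <- scene_xyz(scene, u)
    d <- scene_cons_dist(scene, xyz)
    viol <- c(cons_violation(d, scene$cons_lower, scene$cons_upper),
              ephys_violation(scene_ephys(scene, xyz)))
    list(objective = if (need_obj) diversity(u, pop) else NA_real_,
         viol = viol)
  }
  problem <- mvie_problem(4, evaluate = evaluate, sense = "max",
                          n_constraints = length(scene$cons_lower) + 1L)
  run <- mvie_run(problem, config$budget, config$n_units, config$seed,
                  run_control(config))
  finish_protocol(run, scene, config,
                  render = function(u) scene_xyz(scene, u)[scene$ca_rows_all, , drop = FALSE])
}

#' Energy-objective assembly protocol
#'
#' Minimises the coarse steric energy subject to the distance restraints as
#' viability constraints (no energy constraint: the energy is the objective).
#'
#' @param config a [protocol_config()] with mode `"energy_objective"`.
#' @return a `viasm_protocol` result.
#' @export
protocol_energy_objective <- function(config) {
  stopifnot(config$mode == "energy_objective")
  scene <- make_scene(config)
  evaluate <- function(u, pop, need_obj) {
    xyz <- scene_xyz(scene, u)
    d <- scene_cons_dist(scene, xyz)
    list(objective = scene_ephys(scene, xyz),
         viol = cons_violation(d, scene$cons_lower, scene$cons_upper))
  }
  problem <- mvie_problem(4, evaluate = evaluate, sense = "min",
                          n_constraints = length(scene$cons_lower))
  run <- mvie_run(problem, config$budget, config$n_units, config$seed,
                  run_control(config))
  finish_protocol(run, scene, config,
                  render = function(u) scene_xyz(scene, u)[scene$ca_rows_all, , drop = FALSE])
}

#' Density-fit-objective assembly protocol
#'
#' Distance restraints and `E_phys < 0` stay viability constraints; the
#' objective is the cross-correlation of the 4-parameter assembly against the
#' input map, computed in a slowly refreshed alignment frame: every
#' `refit_every` evaluations the current best model is rigid-fitted into the
#' map in 6 dof and the frame is updated, keeping the search itself
#' 4-dimensional.
#'
#' @param config a [protocol_config()] with mode `"ccc_objective"`.
#' @return a `viasm_protocol` result.
#' @export
protocol_ccc_objective <- function(config) {
  stopifnot(config$mode == "ccc_objective")
  scene <- make_scene(config)
  map <- config$map
  tvec <- as.vector(map$grid)
  thr_t <- 1e-6 * max(tvec)
  frame <- new.env(parent = emptyenv())
  frame$R <- diag(3)
  frame$t <- map_com(map)     # canonical assembly is centred at the origin
  frame$best_u <- NULL
  frame$best_obj <- -Inf
  obj_ccc <- function(xyz_ca) {
    y <- sweep(xyz_ca %*% t(frame$R), 2, frame$t, "+")
    mm <- simulate_on_grid(y, map, map$resolution)
    v <- as.vector(mm$grid)
    r <- masked_cor_cpp(v, tvec, 1e-6 * max(v, 0), thr_t)
    if (is.na(r)) -1 else r
  }
  evaluate <- function(u, pop, need_obj) {
    xyz <- scene_xyz(scene, u)
    d <- scene_cons_dist(scene, xyz)
    viol <- c(cons_violation(d, scene$cons_lower, scene$cons_upper),
              ephys_violation(scene_ephys(scene, xyz)))
    obj <- NA_real_
    if (need_obj) {
      obj <- obj_ccc(xyz[scene$ca_rows_all, , drop = FALSE])
      if (obj > frame$best_obj) { frame$best_obj <- obj; frame$best_u <- u }
    }
    list(objective = obj, viol = viol)
  }
  callback <- function(n_eval) {
    if (is.null(frame$best_u)) return(invisible())
    xyz <- scene_xyz(scene, frame$best_u)[scene$ca_rows_all, , drop = FALSE]
    f <- fit_to_map(xyz, map, n_start = 4, maxit = 80)
    frame$R <- euler_zyz(f$pose[1], f$pose[2], f$pose[3])
    frame$t <- f$pose[4:6] + colMeans(xyz) - colMeans(xyz %*% t(frame$R))
    frame$best_obj <- -Inf      # rescore in the new frame
    invisible()
  }
  problem <- mvie_problem(4, evaluate = evaluate, sense = "max",
                          n_constraints = length(scene$cons_lower) + 1L)
  run <- mvie_run(problem, config$budget, config$n_units, config$seed,
                  run_control(config, list(callback = callback,
                                           callback_every = config$refit_every)))
  res <- finish_protocol(run, scene, config,
                         render = function(u) {
                           xyz <- scene_xyz(scene, u)[scene$ca_rows_all, , drop = FALSE]
                           sweep(xyz %*% t(frame$R), 2, frame$t, "+")
                         },
                         pose_of = NULL)
  res
}

#' Blind docking into a density map
#'
#' No distance restraints: a 10-parameter search (4 assembly parameters plus
#' a 6-dof global pose after translating the ring to the map's centre of
#' mass) maximising ccc with `E_phys < 0` as the sole viability constraint.
#'
#' @param config a [protocol_config()] with mode `"blind_dock"`.
#' @return a `viasm_protocol` result; ranked models are already posed in the
#'   map frame, so ranking does not refit.
#' @export
protocol_blind_dock <- function(config) {
  stopifnot(config$mode == "blind_dock")
  scene <- make_scene(config)
  map <- config$map
  com <- map_com(map)
  ext <- dim(map$grid) * map$voxel
  laplace_obj <- isTRUE(config$optimizer$dock_laplace_objective)
  target <- if (laplace_obj) laplace_filter(map) else map
  tvec <- as.vector(target$grid)
  thr_t <- 1e-6 * max(tvec)
  decode_pose <- function(u) {
    c(u[5] * 2 * pi, u[6] * 2 * pi, u[7] * 2 * pi,
      com + (u[8:10] - 0.5) * ext / 2)
  }
  posed_ca <- function(u) {
    xyz <- scene_xyz(scene, u)[scene$ca_rows_all, , drop = FALSE]
    pose <- decode_pose(u)
    sweep(xyz %*% t(euler_zyz(pose[1], pose[2], pose[3])), 2, pose[4:6], "+")
  }
  evaluate <- function(u, pop, need_obj) {
    xyz <- scene_xyz(scene, u)
    viol <- ephys_violation(scene_ephys(scene, xyz))   # pose-invariant
    obj <- NA_real_
    if (need_obj) {
      y <- posed_ca(u)
      mm <- simulate_on_grid(y, map, map$resolution)
      if (laplace_obj) mm <- laplace_filter(mm)
      v <- as.vector(mm$grid)
      r <- masked_cor_cpp(v, tvec, 1e-6 * max(v, 0), thr_t)
      obj <- if (is.na(r)) -1 else r
    }
    list(objective = obj, viol = viol)
  }
  problem <- mvie_problem(10, evaluate = evaluate, sense = "max",
                          n_constraints = 1L)
  run <- mvie_run(problem, config$budget, config$n_units, config$seed,
                  run_control(config))
  finish_protocol(run, scene, config, render = posed_ca,
                  pose_of = decode_pose)
}

#' Crosslink-correlation assembly of a homodimer
#'
#' Viability constraints: the Cbeta-Cbeta anchor interval on the most highly
#' crosslinked residue and `E_phys < 0`. Objective: the magnitude of the
#' Pearson correlation between inter-subunit Cbeta distances and the
#' fractional crosslinking profile, maximised.
#'
#' @param config a [protocol_config()] with mode `"crosslink"`.
#' @return object of class `viasm_crosslink`: best model, signed `R`,
#'   `abs_R`, the per-residue `(fraction, distance)` table and the raw run.
#' @export
protocol_crosslink <- function(config) {
  stopifnot(config$mode == "crosslink")
  scene <- make_scene(config)
  m <- scene$m
  prof_rows <- vapply(config$profile$resno, scene$row_of, integer(1),
                      atom = "CB")
  anchor_row <- scene$row_of(config$anchor$residue, "CB")
  fr <- config$profile$fraction
  if (stats::var(fr) <= 0) stopf("crosslink profile has zero variance")
  evaluate <- function(u, pop, need_obj) {
    xyz <- scene_xyz(scene, u)
    d_anchor <- sqrt(sum((xyz[anchor_row, ] - xyz[anchor_row + m, ])^2))
    viol <- c(cons_violation(d_anchor, config$anchor$lower, config$anchor$upper),
              ephys_violation(scene_ephys(scene, xyz)))
    obj <- NA_real_
    if (need_obj) {
      d <- sqrt(rowSums((xyz[prof_rows, , drop = FALSE] -
                           xyz[prof_rows + m, , drop = FALSE])^2))
      obj <- if (stats::var(d) <= 0) 0 else abs(stats::cor(fr, d))
    }
    list(objective = obj, viol = viol)
  }
  problem <- mvie_problem(4, evaluate = evaluate, sense = "max",
                          n_constraints = 2L)
  run <- mvie_run(problem, config$budget, config$n_units, config$seed,
                  run_control(config))
  if (!run$feasible)
    return(structure(list(run = run, feasible = FALSE, config = config,
                          message = "no viable solutions within budget"),
                     class = "viasm_crosslink"))
  best <- scene_structure(scene, config, run$best$params)
  xl <- crosslink_objective(best, config$profile)
  structure(list(run = run, feasible = TRUE, model = best, R = xl$R,
                 abs_R = xl$abs_R, table = xl$table,
                 low_correlation = xl$abs_R < 0.5, config = config),
            class = "viasm_crosslink")
}

#' @export
print.viasm_crosslink <- function(x, ...) {
  if (!x$feasible) {
    cat("viasm crosslink protocol: FAILED -", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("viasm crosslink protocol: |R| = %.3f (signed R = %.3f)%s\n",
              x$abs_R, x$R,
              if (x$low_correlation) "  [flagged: weak correlation]" else ""))
  invisible(x)
}

#' Wrong-restraint audit protocol
#'
#' For each trial, samples `n_true` correct and `n_false` wrong restraints
#' from labelled pools (seeded with `seed + trial`) and runs the diversity
#' protocol with ALL sampled restraints as viability constraints. Because a
#' genuinely wrong restraint can contradict the true set, strict viability
#' may be unreachable; the search units then converge to the least-violating
#' models — the ones satisfying the most restraints — and those final
#' personal bests (together with any fully viable archive) form the
#' selection pool. Models satisfying the most restraints are kept (ties: all
#' kept) and their precision `PPV = TP / (TP + FP)` is averaged.
#'
#' @param config a [protocol_config()] with mode `"audit"`; its
#'   `constraints` must carry `is_true` labels and contain both classes.
#' @param n_true,n_false how many restraints of each class per trial.
#' @return object of class `viasm_audit`: per-trial table and `mean_ppv`.
#' @export
protocol_audit <- function(config, n_true, n_false) {
  stopifnot(config$mode == "audit")
  pool <- as.data.frame(config$constraints)
  if (anyNA(pool$is_true)) stopf("audit pools need is_true labels")
  tp_pool <- which(pool$is_true)
  fp_pool <- which(!pool$is_true)
  if (length(tp_pool) < n_true || length(fp_pool) < n_false)
    stopf("pools too small for requested mixture (%dT + %dF)", n_true, n_false)
  rows <- vector("list", config$trials)
  for (tr in seq_len(config$trials)) {
    pick <- with_rng(rng_state(config$seed + tr), {
      c(sample(tp_pool, n_true), sample(fp_pool, n_false))
    })$value
    cons <- pool[pick, , drop = FALSE]
    class(cons) <- c("viasm_constraints", "data.frame")
    sub_cfg <- config
    sub_cfg$constraints <- cons
    scene <- make_scene(sub_cfg)
    evaluate <- function(u, pop, need_obj) {
      xyz <- scene_xyz(scene, u)
      d <- scene_cons_dist(scene, xyz)
      viol <- c(cons_violation(d, scene$cons_lower, scene$cons_upper),
                ephys_violation(scene_ephys(scene, xyz)))
      list(objective = if (need_obj) diversity(u, pop) else NA_real_,
           viol = viol)
    }
    problem <- mvie_problem(4, evaluate = evaluate, sense = "max",
                            n_constraints = nrow(cons) + 1L)
    run <- suppressMessages(
      mvie_run(problem, config$budget, config$n_units, config$seed + tr,
               run_control(config)))
    # selection pool: viable archive (if any) plus the final unit bests
    pars <- run$population$params
    if (run$archive$n > 0L) {
      idx <- seq_len(run$archive$n)
      if (length(idx) > 100L)
        idx <- unique(round(seq(1, run$archive$n, length.out = 100L)))
      pars <- rbind(pars, run$archive$params[idx, , drop = FALSE])
    }
    # deduplicate near-identical models (1 A clusters) so that the PPV
    # average counts distinct structures, not how many search units happened
    # to converge to the same one
    coords <- lapply(seq_len(nrow(pars)), function(i)
      scene_xyz(scene, pars[i, ])[scene$ca_rows_all, , drop = FALSE])
    cl <- cluster_solutions(coords, threshold = 1.0)
    pars <- pars[cl$centroids, , drop = FALSE]
    sat <- vapply(seq_len(nrow(pars)), function(i) {
      xyz <- scene_xyz(scene, pars[i, ])
      d <- scene_cons_dist(scene, xyz)
      cons_violation(d, cons$lower, cons$upper) <= 0
    }, logical(nrow(cons)))
    sat <- matrix(sat, nrow = nrow(cons))
    counts <- colSums(sat)
    keep <- which(counts == max(counts))
    tp <- colSums(sat[cons$is_true, keep, drop = FALSE])
    fp <- colSums(sat[!cons$is_true, keep, drop = FALSE])
    ok <- (tp + fp) >= 1
    rows[[tr]] <- data.frame(trial = tr, n_true = n_true, n_false = n_false,
                             n_models = length(keep),
                             max_satisfied = max(counts),
                             tp = mean(tp), fp = mean(fp),
                             ppv = if (any(ok)) mean(tp[ok] / (tp[ok] + fp[ok]))
                                   else NA_real_)
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, mean_ppv = mean(tab$ppv, na.rm = TRUE),
                 config = config),
            class = "viasm_audit")
}

#' @export
print.viasm_audit <- function(x, ...) {
  cat(sprintf("viasm audit (%dT + %dF per trial): mean PPV = %.3f over %d trials\n",
              x$table$n_true[1], x$table$n_false[1], x$mean_ppv, nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Aggregated-fitness reference protocol
#'
#' The single-objective baseline the viability scheme replaces: unconstrained
#' minimisation of `w * E_phys + (1 - w) * E_data` (default `w = 0.2`) by the
#' same search engine, with the same clustering/ranking downstream. Kept for
#' comparison experiments; the viability protocols never aggregate.
#'
#' @param config a [protocol_config()] with mode `"aggregated_reference"`.
#' @return a `viasm_protocol` result.
#' @export
protocol_aggregated_reference <- function(config) {
  stopifnot(config$mode == "aggregated_reference")
  scene <- make_scene(config)
  evaluate <- function(u, pop, need_obj) {
    xyz <- scene_xyz(scene, u)
    d <- scene_cons_dist(scene, xyz)
    list(objective = aggregated_fitness(scene_ephys(scene, xyz),
                                        e_data(d, scene$cons_target),
                                        config$w),
         viol = numeric(0))
  }
  problem <- mvie_problem(4, evaluate = evaluate, sense = "min",
                          n_constraints = 0L)
  run <- mvie_run(problem, config$budget, config$n_units, config$seed,
                  run_control(config))
  finish_protocol(run, scene, config,
                  render = function(u) scene_xyz(scene, u)[scene$ca_rows_all, , drop = FALSE])
}
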