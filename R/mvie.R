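#' Define a constrained optimisation problem for the mViE engine
#'
#' The optimizer works in the normalised unit box internally; `lower`/`upper`
#' define the linear decoding to physical parameters (the protocol layer
#' decodes angles and radius itself and usually leaves these at `[0, 1]`).
#'
#' The problem is evaluated through a single callable so that one expensive
#' model build can serve every constraint and the objective at once:
#' `evaluate(u, pop, need_obj)` receives the candidate in unit coordinates,
#' the matrix of current search-unit means (for diversity-style objectives)
#' and a flag saying whether the objective value is needed, and returns
#' `list(objective =, viol =)` where `viol` is the vector of non-negative
#' violations of each constraint's final bound. Alternatively pass
#' `objective` + `constraints` and the callable is assembled for you.
#'
#' @param dimension number of search parameters.
#' @param evaluate combined evaluator (see Details); overrides
#'   `objective`/`constraints`.
#' @param objective function of the unit-coordinate vector (and optionally
#'   the population matrix as second argument).
#' @param sense `"min"` or `"max"`.
#' @param constraints list of `list(fn, lower, upper)`: `fn(u)` returns the
#'   constraint value, viable when within `[lower, upper]` (use `-Inf`/`Inf`
#'   for one-sided bounds such as an energy ceiling).
#' @param lower,upper decoding box (length `dimension`).
#' @return object of class `mvie_problem`.
#' @export
mvie_problem <- function(dimension, evaluate = NULL, objective = NULL,
                         sense = c("min", "max"), constraints = list(),
                         lower = rep(0, dimension), upper = rep(1, dimension),
                         n_constraints = length(constraints)) {
  sense <- match.arg(sense)
  dimension <- as.integer(dimension)
  if (dimension < 1L) stopf("dimension must be >= 1")
  if (is.null(evaluate)) {
    if (is.null(objective) && !length(constraints))
      stopf("a problem needs an objective and/or constraints")
    obj_takes_pop <- !is.null(objective) && length(formals(objective)) >= 2L
    lo <- lower; up <- upper
    evaluate <- function(u, pop, need_obj) {
      xph <- lo + u * (up - lo)
      viol <- vapply(constraints, function(cs) {
        v <- cs$fn(xph)
        max(0, cs$lower - v, v - cs$upper)
      }, numeric(1))
      obj <- NA_real_
      if (need_obj && !is.null(objective))
        obj <- if (obj_takes_pop) objective(u, pop) else objective(xph)
      list(objective = obj, viol = viol)
    }
  }
  structure(list(dimension = dimension, evaluate = evaluate, sense = sense,
                 n_constraints = n_constraints,
                 lower = lower, upper = upper),
            class = "mvie_problem")
}

# ---- per-unit RNG streams -------------------------------------------------
# Each search unit owns an isolated RNG state derived from the master seed by
# a fixed offset, so results do not depend on scheduling details.

rng_state <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  st <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  st
}

with_rng <- function(state, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", state, globalenv())
  val <- force(expr)
  new_state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(value = val, state = new_state)
}

# ---- candidate comparison -------------------------------------------------
# Lexicographic viability ordering: fewer boundary-violated constraints, then
# smaller total excess over the boundaries, then (both boundary-viable) the
# better objective. Ties keep the incumbent.
compare_candidates <- function(cand, incumbent, boundaries, sense) {
  tol <- 1e-12
  va <- cand$viol; vb <- incumbent$viol
  na_ <- sum(va > boundaries + tol)
  nb_ <- sum(vb > boundaries + tol)
  if (na_ != nb_) return(na_ < nb_)
  ea <- sum(pmax(0, va - boundaries))
  eb <- sum(pmax(0, vb - boundaries))
  if (abs(ea - eb) > tol) return(ea < eb)
  if (na_ == 0L) {
    oa <- cand$objective; ob <- incumbent$objective
    if (is.na(oa) || is.na(ob)) return(FALSE)
    if (sense == "max") { if (oa > ob + tol) return(TRUE) } else
      if (oa < ob - tol) return(TRUE)
  }
  FALSE
}

new_unit <- function(mean, dim, sigma0, seed) {
  list(mean = mean, A = diag(dim), sigma = sigma0, best = NULL,
       rng = rng_state(seed))
}

# ---- optimizer ------------------------------------------------------------

#' Run the memetic Viability Evolution optimizer
#'
#' Evolves a population of (1+1)-CMA-ES local search units under adaptive
#' per-constraint viability boundaries, periodically recombined by
#' Differential Evolution (DE/rand/1/bin). Boundaries start at the worst
#' initial violation of each constraint (so the whole initial population is
#' viable with respect to them) and tighten monotonically to the true bounds,
#' reaching them after a fraction `t_tighten` of the budget. Only candidates
#' that satisfy every final bound enter the archive; the objective is only
#' consulted between candidates that are viable under the current boundaries.
#'
#' @param problem an [mvie_problem()].
#' @param budget maximum number of candidate evaluations.
#' @param n_units population size (`>= 4`; DE needs 4 distinct vectors).
#' @param seed master seed; per-unit streams are derived by fixed offsets.
#' @param control list of tunables: `F` (DE scale, 0.7), `CR` (crossover,
#'   0.9), `G_local` (local generations per recombination sweep, 10),
#'   `t_tighten` (fraction of budget at which boundaries reach zero, 0.5),
#'   `sigma0` (initial step size in the unit box, 0.3), `archive_max`
#'   (archive capacity; evenly thinned beyond it), `callback` +
#'   `callback_every` (hook run every so many evaluations, e.g. to refresh a
#'   map-alignment frame).
#' @return object of class `mvie_result`: `best` (candidate), `feasible`
#'   flag, `archive` (unit-box params, objectives, violations of all final-
#'   bound-satisfying candidates), `population` (the final personal-best
#'   candidate of every search unit — the least-violating models when no
#'   candidate is fully viable), `n_eval`, per-generation `trace`, and the
#'   final `boundaries`.
#' @export
mvie_run <- function(problem, budget, n_units = 20, seed = 1,
                     control = list()) {
  if (!inherits(problem, "mvie_problem")) stopf("`problem` must be mvie_problem()")
  n_units <- as.integer(n_units)
  if (n_units < 4L) stopf("n_units must be >= 4 (DE needs 4 distinct vectors)")
  if (budget < n_units) stopf("budget must cover at least one evaluation per unit")
  ctl <- modifyList(list(F = 0.7, CR = 0.9, G_local = 10, t_tighten = 0.5,
                         sigma0 = 0.3, archive_max = 20000L,
                         callback = NULL, callback_every = 1000L), control)
  d <- problem$dimension
  nc <- problem$n_constraints
  sense <- problem$sense
  seed <- as.integer(seed) %% 100000L

  # archive storage (grown by doubling)
  arc_par <- matrix(NA_real_, 256L, d)
  arc_obj <- numeric(256L)
  arc_viol <- matrix(NA_real_, 256L, max(nc, 1L))
  arc_n <- 0L
  add_archive <- function(u, obj, viol) {
    if (arc_n == nrow(arc_par)) {
      arc_par <<- rbind(arc_par, matrix(NA_real_, nrow(arc_par), d))
      arc_obj <<- c(arc_obj, numeric(length(arc_obj)))
      arc_viol <<- rbind(arc_viol, matrix(NA_real_, nrow(arc_viol), ncol(arc_viol)))
    }
    arc_n <<- arc_n + 1L
    arc_par[arc_n, ] <<- u
    arc_obj[arc_n] <<- obj
    if (nc) arc_viol[arc_n, ] <<- viol
  }

  n_eval <- 0L
  least_viol <- NULL   # fallback when no viable solution is ever found
  pop_means <- matrix(NA_real_, n_units, d)

  evaluate <- function(u) {
    n_eval <<- n_eval + 1L
    res <- problem$evaluate(u, pop_means, TRUE)
    viol <- if (nc) res$viol else numeric(0)
    cand <- list(params = u, objective = res$objective, viol = viol)
    if (all(viol <= 1e-9)) {
      add_archive(u, res$objective, viol)
    } else {
      tv <- sum(viol)
      if (is.null(least_viol) || tv < sum(least_viol$viol)) least_viol <<- cand
    }
    if (!is.null(ctl$callback) && n_eval %% ctl$callback_every == 0L)
      ctl$callback(n_eval)
    cand
  }

  # --- initialisation: uniform means, boundaries from worst initial violation
  master <- rng_state(seed)
  init <- with_rng(master, matrix(runif(n_units * d), n_units, d))
  master <- init$state
  pop_means <- init$value
  units <- lapply(seq_len(n_units), function(i)
    new_unit(pop_means[i, ], d, ctl$sigma0, seed * 131L + i))
  for (i in seq_len(n_units)) units[[i]]$best <- evaluate(units[[i]]$mean)
  b0 <- if (nc) apply(do.call(rbind, lapply(units, function(u) u$best$viol)), 2, max)
        else numeric(0)
  boundaries <- b0

  trace <- list()
  gen <- 0L
  p_target <- 2 / 11
  damp <- 1 + d / 2
  c_cov <- 2 / (d^2 + 6)

  local_step <- function(unit) {
    step <- with_rng(unit$rng, {
      z <- NULL; y <- NULL
      for (k in 1:10) {                # resample-clip hybrid box handling
        z <- rnorm(d)
        y <- unit$mean + unit$sigma * as.vector(unit$A %*% z)
        if (all(y >= 0 & y <= 1)) break
      }
      list(z = z, y = pmin(pmax(y, 0), 1))
    })
    unit$rng <- step$state
    z <- step$value$z
    cand <- evaluate(step$value$y)
    success <- compare_candidates(cand, unit$best, boundaries, sense)
    if (success) {
      unit$mean <- cand$params
      unit$best <- cand
      zn2 <- sum(z^2)
      if (zn2 > 0) {
        fac <- sqrt(1 - c_cov)
        unit$A <- fac * unit$A +
          (fac / zn2) * (sqrt(1 + c_cov / (1 - c_cov) * zn2) - 1) *
            (unit$A %*% z) %*% t(z)
      }
    }
    unit$sigma <- unit$sigma *
      exp((1 / damp) * (((if (success) 1 else 0) - p_target) / (1 - p_target)))
    unit$sigma <- min(max(unit$sigma, 1e-12), 1)
    unit
  }

  repeat {
    gen <- gen + 1L
    # local phase
    for (g in seq_len(ctl$G_local)) {
      for (i in seq_len(n_units)) {
        if (n_eval >= budget) break
        units[[i]] <- local_step(units[[i]])
        pop_means[i, ] <- units[[i]]$mean
      }
      if (n_eval >= budget) break
    }
    # recombination sweep (DE/rand/1/bin over unit means)
    if (n_eval < budget) {
      de <- with_rng(master, {
        trials <- matrix(NA_real_, n_units, d)
        for (i in seq_len(n_units)) {
          r <- sample(setdiff(seq_len(n_units), i), 3)
          tv <- pop_means[r[1], ] + ctl$F * (pop_means[r[2], ] - pop_means[r[3], ])
          jrand <- sample.int(d, 1)
          cross <- runif(d) < ctl$CR
          cross[jrand] <- TRUE
          tv <- ifelse(cross, tv, pop_means[i, ])
          trials[i, ] <- pmin(pmax(tv, 0), 1)
        }
        trials
      })
      master <- de$state
      for (i in seq_len(n_units)) {
        if (n_eval >= budget) break
        cand <- evaluate(de$value[i, ])
        if (compare_candidates(cand, units[[i]]$best, boundaries, sense)) {
          units[[i]]$mean <- cand$params
          units[[i]]$best <- cand
          units[[i]]$A <- diag(d)
          units[[i]]$sigma <- ctl$sigma0
          pop_means[i, ] <- cand$params
        }
      }
    }
    # boundary update: monotone, zero from t_tighten * budget onwards
    if (nc) {
      vmax <- apply(do.call(rbind, lapply(units, function(u) u$best$viol)), 2, max)
      sched <- b0 * max(0, 1 - n_eval / (ctl$t_tighten * budget))
      boundaries <- pmax(0, pmin(boundaries, vmax, sched))
    }
    n_feas <- sum(vapply(units, function(u) all(u$best$viol <= 1e-9), logical(1)))
    trace[[gen]] <- c(n_eval = n_eval, feasible_frac = n_feas / n_units,
                      if (nc) setNames(boundaries, paste0("b", seq_len(nc))))
    if (n_eval >= budget) break
  }

  arc_par <- arc_par[seq_len(arc_n), , drop = FALSE]
  arc_obj <- arc_obj[seq_len(arc_n)]
  arc_viol <- arc_viol[seq_len(arc_n), , drop = FALSE]
  if (arc_n > ctl$archive_max) {      # even thinning preserves coverage
    keep <- unique(round(seq(1, arc_n, length.out = ctl$archive_max)))
    arc_par <- arc_par[keep, , drop = FALSE]
    arc_obj <- arc_obj[keep]
    arc_viol <- arc_viol[keep, , drop = FALSE]
  }
  feasible <- arc_n > 0L
  if (feasible) {
    ibest <- if (all(is.na(arc_obj))) 1L
             else if (sense == "max") which.max(arc_obj) else which.min(arc_obj)
    best <- list(params = arc_par[ibest, ], objective = arc_obj[ibest],
                 viol = if (nc) arc_viol[ibest, ] else numeric(0))
  } else {
    best <- least_viol
    message("mViE: no viable solutions within budget")
  }
  pop_best <- list(
    params = do.call(rbind, lapply(units, function(u) u$best$params)),
    objective = vapply(units, function(u) u$best$objective, numeric(1)),
    viol = do.call(rbind, lapply(units, function(u)
      if (nc) u$best$viol else numeric(0))))
  structure(list(best = best, feasible = feasible,
                 archive = list(params = arc_par, objective = arc_obj,
                                viol = arc_viol, n = nrow(arc_par)),
                 population = pop_best,
                 n_eval = n_eval, boundaries = boundaries, b0 = b0,
                 trace = do.call(rbind, trace), seed = seed,
                 sense = sense, dimension = d),
            class = "mvie_result")
}

#' @export
print.mvie_result <- function(x, ...) {
  cat(sprintf("mViE run: %d evaluations, %d archived viable candidates\n",
              x$n_eval, x$archive$n))
  if (x$feasible)
    cat(sprintf("best (%simised) objective: %.6g\n",
                if (x$sense == "max") "max" else "min", x$best$objective))
  else
    cat(sprintf("no viable solutions; least total violation %.4g\n",
                sum(x$best$viol)))
  invisible(x)
}

#' @export
summary.mvie_result <- function(object, ...) {
  tr <- object$trace
  cat(sprintf(
    "mViE: %d evals, %d generations, %d viable archived (%.1f%% of evals)\n",
    object$n_eval, nrow(tr), object$archive$n,
    100 * object$archive$n / object$n_eval))
  cat(sprintf("final feasible fraction of units: %.2f\n",
              tr[nrow(tr), "feasible_frac"]))
  if (length(object$boundaries))
    cat("final boundaries:", paste(signif(object$boundaries, 3), collapse = " "), "\n")
  invisible(object)
}

#' Trace plot of an mViE run
#'
#' Shows the viability-boundary schedule and the fraction of feasible search
#' units against the evaluation count.
#'
#' @param x an `mvie_result`.
#' @param ... ignored.
#' @export
plot.mvie_result <- function(x, ...) {
  tr <- x$trace
  bcols <- grep("^b", colnames(tr))
  op <- par(mfrow = c(if (length(bcols)) 2 else 1, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  if (length(bcols)) {
    m <- tr[, bcols, drop = FALSE]
    plot(tr[, "n_eval"], m[, 1], type = "n", ylim = range(0, m),
         xlab = "evaluations", ylab = "viability boundary",
         main = "boundary schedule")
    for (j in seq_along(bcols)) lines(tr[, "n_eval"], m[, j], col = j)
  }
  plot(tr[, "n_eval"], tr[, "feasible_frac"], type = "l", ylim = c(0, 1),
       xlab = "evaluations", ylab = "feasible unit fraction")
  invisible(x)
}
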