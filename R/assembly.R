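#' Search parameters of a symmetric assembly
#'
#' The four parameters that define a Cn assembly from one subunit:
#' `alpha`, `beta`, `gamma` are the Euler angles (radians, intrinsic ZYZ)
#' orienting the subunit about its Calpha centroid, and `x` is the radius of
#' the symmetric assembly in Angstrom (distance of the subunit centroid from
#' the symmetry axis). An optional 6-dof `global_pose` (3 rotation angles +
#' 3 translation components) places the whole ring, used in blind docking.
#'
#' @param alpha,beta,gamma Euler angles in radians; reduced to `[0, 2*pi)`.
#' @param x assembly radius in Angstrom, `>= 0`.
#' @param global_pose optional numeric length-6 vector
#'   `(alpha, beta, gamma, tx, ty, tz)`.
#' @return An object of class `viasm_params`.
#' @export
assembly_params <- function(alpha = 0, beta = 0, gamma = 0, x = 0,
                            global_pose = NULL) {
  check_number(x, "x", lower = 0)
  p <- list(alpha = wrap_angle(alpha), beta = wrap_angle(beta),
            gamma = wrap_angle(gamma), x = x)
  if (!is.null(global_pose)) {
    if (length(global_pose) != 6L || !all(is.finite(global_pose)))
      stopf("global_pose must be 6 finite numbers")
    p$global_pose <- as.numeric(global_pose)
  }
  structure(p, class = "viasm_params")
}

#' @export
print.viasm_params <- function(x, ...) {
  cat(sprintf("assembly params: alpha=%.4f beta=%.4f gamma=%.4f rad, x=%.3f A\n",
              x$alpha, x$beta, x$gamma, x$x))
  if (!is.null(x$global_pose))
    cat(sprintf("  global pose: rot=(%.4f,%.4f,%.4f) t=(%.2f,%.2f,%.2f)\n",
                x$global_pose[1], x$global_pose[2], x$global_pose[3],
                x$global_pose[4], x$global_pose[5], x$global_pose[6]))
  invisible(x)
}

# Fast path: transform a centred coordinate matrix into its n symmetric
# copies. Returns an (n*m) x 3 matrix, copies stacked in order.
sym_xyz <- function(M_centered, alpha, beta, gamma, x, n) {
  m1 <- transform_xyz(M_centered, euler_zyz(alpha, beta, gamma), c(x, 0, 0))
  if (n == 1L) return(m1)
  out <- matrix(0, nrow(m1) * n, 3)
  out[seq_len(nrow(m1)), ] <- m1
  for (k in seq_len(n - 1L)) {
    out[k * nrow(m1) + seq_len(nrow(m1)), ] <- m1 %*% t(rot_z(2 * pi * k / n))
  }
  out
}

#' Build a Cn-symmetric assembly from one subunit
#'
#' The subunit is centred on its Calpha centroid, rotated by the Euler angles
#' (intrinsic ZYZ, about the centroid), translated to `(x, 0, 0)`, and copies
#' `k = 0..n-1` are generated by rotation about the z axis by `2*pi*k/n`.
#' The symmetry axis is z through the origin; the first copy sits on +x.
#'
#' @param subunit a [viasm_structure()] with a single chain.
#' @param params an [assembly_params()] (any `global_pose` is ignored here;
#'   see [apply_global_pose()]).
#' @param n_subunits number of copies (cyclic symmetry order), `>= 1`.
#' @return A [viasm_structure()] with `n_subunits` chains named `A`, `B`, ...
#' @export
build_symmetric <- function(subunit, params, n_subunits) {
  if (!inherits(subunit, "viasm_structure")) stopf("`subunit` must be a viasm_structure")
  if (!inherits(params, "viasm_params")) stopf("`params` must be assembly_params()")
  n <- as.integer(n_subunits)
  if (is.na(n) || n < 1L) stopf("n_subunits must be >= 1")
  if (n > length(chain_alphabet))
    stopf("n_subunits > %d exhausts the chain-ID alphabet", length(chain_alphabet))
  M <- structure_xyz(subunit)
  ctr <- colMeans(ca_coords(subunit))
  xyz <- sym_xyz(sweep(M, 2, ctr), params$alpha, params$beta, params$gamma,
                 params$x, n)
  a <- subunit$atoms[rep(seq_len(nrow(M)), n), , drop = FALSE]
  a$chain <- rep(chain_alphabet[seq_len(n)], each = nrow(M))
  a[, c("x", "y", "z")] <- xyz
  rownames(a) <- NULL
  viasm_structure(a)
}

#' Apply a rigid global pose to an assembly
#'
#' Rotates the structure about its Calpha centroid by the intrinsic ZYZ Euler
#' angles of the pose, then translates. Inter-atomic distances are preserved
#' exactly, so the coarse potential and all restraint distances are invariant.
#'
#' @param s a [viasm_structure()].
#' @param pose numeric length-6 vector `(alpha, beta, gamma, tx, ty, tz)`.
#' @return The transformed [viasm_structure()].
#' @export
apply_global_pose <- function(s, pose) {
  if (!inherits(s, "viasm_structure")) stopf("`s` must be a viasm_structure")
  if (length(pose) != 6L || !all(is.finite(pose)))
    stopf("pose must be 6 finite numbers")
  ctr <- colMeans(ca_coords(s))
  R <- euler_zyz(pose[1], pose[2], pose[3])
  xyz <- sweep(structure_xyz(s), 2, ctr)
  xyz <- sweep(xyz %*% t(R), 2, ctr + pose[4:6], "+")
  set_structure_xyz(s, xyz)
}

#' Default search box for the assembly parameters
#'
#' Angles span `[0, 2*pi)`; the radius spans `[0, x_max]` with
#' `x_max = factor * (subunit bounding-sphere radius) * n_subunits`
#' (default factor 2), which comfortably contains any ring of touching copies.
#'
#' @param subunit a [viasm_structure()].
#' @param n_subunits symmetry order.
#' @param factor multiplier of the default radius rule.
#' @param x_max explicit override of the radius upper bound.
#' @return list with numeric `lower` and `upper` of length 4
#'   (`alpha`, `beta`, `gamma`, `x`).
#' @export
default_bounds <- function(subunit, n_subunits, factor = 2, x_max = NULL) {
  ca <- ca_coords(subunit)
  rb <- sqrt(max(rowSums(sweep(ca, 2, colMeans(ca))^2)))
  if (is.null(x_max)) x_max <- factor * rb * n_subunits
  list(lower = c(0, 0, 0, 0), upper = c(2 * pi, 2 * pi, 2 * pi, x_max))
}
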