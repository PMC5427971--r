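# Rotation helpers. All angles in radians; matrices act on column vectors,
# coordinates stored as rows, so points transform as  X %*% t(R).

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE)
}

# Intrinsic ZYZ Euler rotation: R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma).
euler_zyz <- function(alpha, beta, gamma) {
  rot_z(alpha) %*% rot_y(beta) %*% rot_z(gamma)
}

# Reduce angles to [0, 2*pi).
wrap_angle <- function(a) {
  a <- a %% (2 * pi)
  a[a < 0] <- a[a < 0] + 2 * pi
  a
}

transform_xyz <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, t, "+")
}

# Chain identifier alphabet for assembly copies (62 symbols, PDB limit).
chain_alphabet <- c(LETTERS, letters, as.character(0:9))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a finite number in [%g, %g]", name, lower, upper)
  invisible(x)
}
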