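#' A 3-D density map
#'
#' Regular scalar grid with isotropic voxel spacing. `origin` is the position
#' (Angstrom) of the centre of grid voxel `[1, 1, 1]`; `resolution` is the
#' nominal resolution label of the map (NA for measured/unknown).
#'
#' @param grid 3-D numeric array.
#' @param origin numeric length-3.
#' @param voxel voxel spacing in Angstrom, `> 0`.
#' @param resolution nominal resolution in Angstrom.
#' @return object of class `viasm_map`.
#' @export
density_map <- function(grid, origin, voxel, resolution = NA_real_) {
  if (length(dim(grid)) != 3L || !length(grid)) stopf("grid must be a 3-D array")
  if (!all(is.finite(grid))) stopf("grid has non-finite values")
  check_number(voxel, "voxel", lower = 1e-9)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stopf("origin must be 3 finite numbers")
  structure(list(grid = grid, origin = as.numeric(origin), voxel = voxel,
                 resolution = resolution), class = "viasm_map")
}

#' @export
print.viasm_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("viasm_map: %dx%dx%d voxels at %.3g A, origin (%.1f, %.1f, %.1f)%s\n",
              d[1], d[2], d[3], x$voxel, x$origin[1], x$origin[2], x$origin[3],
              if (is.na(x$resolution)) "" else sprintf(", %g A resolution", x$resolution)))
  invisible(x)
}

same_geometry <- function(a, b) {
  all(dim(a$grid) == dim(b$grid)) &&
    isTRUE(all.equal(a$voxel, b$voxel, tolerance = 1e-9)) &&
    max(abs(a$origin - b$origin)) < 1e-6
}

map_sigma <- function(resolution) resolution / (2 * sqrt(2 * log(2)))

# Intensity-weighted centre of mass of a map (Angstrom).
map_com <- function(map) {
  d <- dim(map$grid)
  w <- as.vector(map$grid)
  w <- pmax(w, 0)
  ax <- map$origin[1] + (seq_len(d[1]) - 1) * map$voxel
  ay <- map$origin[2] + (seq_len(d[2]) - 1) * map$voxel
  az <- map$origin[3] + (seq_len(d[3]) - 1) * map$voxel
  sw <- sum(w)
  c(sum(w * ax[slice.index(map$grid, 1)]) / sw,
    sum(w * ay[slice.index(map$grid, 2)]) / sw,
    sum(w * az[slice.index(map$grid, 3)]) / sw)
}

extract_ca_xyz <- function(structure_or_xyz) {
  if (inherits(structure_or_xyz, "viasm_structure")) ca_coords(structure_or_xyz)
  else as.matrix(structure_or_xyz)
}

#' Simulate a density map from a structure
#'
#' Places a unit-weight isotropic Gaussian at every Calpha position with
#' `sigma_kernel = resolution / (2*sqrt(2*log(2)))` (i.e. kernel FWHM equals
#' the nominal resolution), truncated spherically at `3*sigma_kernel`. The
#' grid is padded by `3*sigma_kernel` beyond the structure's bounding box.
#'
#' @param s a [viasm_structure()] or an n x 3 Calpha coordinate matrix.
#' @param resolution nominal resolution in Angstrom; must be
#'   `>= 2*voxel` (Nyquist).
#' @param voxel voxel spacing; default `resolution / 3`.
#' @return a [density_map()].
#' @export
simulate_map <- function(s, resolution, voxel = resolution / 3) {
  xyz <- extract_ca_xyz(s)
  if (!nrow(xyz)) stopf("empty structure")
  check_number(resolution, "resolution", lower = 1e-9)
  if (resolution < 2 * voxel)
    stopf("resolution (%g) must be >= 2 * voxel (%g)", resolution, 2 * voxel)
  sk <- map_sigma(resolution)
  pad <- 3 * sk
  # grid anchored on the voxel lattice, so equal shifts give equal grids
  lo <- floor((apply(xyz, 2, min) - pad) / voxel) * voxel
  hi <- apply(xyz, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / voxel)) + 1L
  g <- splat_gaussian_cpp(xyz, dims, lo, voxel, sk, 3)
  density_map(array(g, dims), lo, voxel, resolution)
}

# Splat a structure onto the geometry of an existing map (for ccc scoring).
simulate_on_grid <- function(xyz, ref_map, resolution = ref_map$resolution) {
  sk <- map_sigma(resolution)
  g <- splat_gaussian_cpp(as.matrix(xyz), dim(ref_map$grid), ref_map$origin,
                          ref_map$voxel, sk, 3)
  density_map(array(g, dim(ref_map$grid)), ref_map$origin, ref_map$voxel,
              resolution)
}

#' Cross-correlation coefficient of two maps
#'
#' Pearson correlation of voxel values over the union of voxels where either
#' map exceeds `1e-6` of its maximum (so empty space does not dominate the
#' score). Both maps must share the same grid geometry.
#'
#' @param map_a,map_b [density_map()] objects on the same grid.
#' @return value in `[-1, 1]`; `ccc(m, m) = 1`.
#' @export
ccc <- function(map_a, map_b) {
  if (!same_geometry(map_a, map_b))
    stopf("maps differ in grid geometry; resample first")
  a <- as.vector(map_a$grid)
  b <- as.vector(map_b$grid)
  r <- masked_cor_cpp(a, b, 1e-6 * max(a), 1e-6 * max(b))
  if (is.na(r)) stopf("ccc undefined: zero variance over the scored voxels")
  r
}

#' Discrete Laplacian filter of a map
#'
#' 6-neighbour stencil (`neighbour sum - 6 * centre`) with zero-gradient
#' borders (out-of-grid neighbours replicate the edge voxel). Enhances
#' surface detail before fitting, the classic contour-based trick for
#' low-resolution maps.
#'
#' @param map a [density_map()] with at least 3 voxels per axis.
#' @return a [density_map()] of the same shape.
#' @export
laplace_filter <- function(map) {
  d <- dim(map$grid)
  if (any(d < 3L)) stopf("grid must have >= 3 voxels per axis")
  g <- map$grid
  shift <- function(arr, axis, by) {
    idx <- lapply(d, seq_len)
    i <- idx[[axis]] - by
    i[i < 1L] <- 1L
    i[i > d[axis]] <- d[axis]
    idx[[axis]] <- i
    do.call(`[`, c(list(arr), idx))
  }
  L <- shift(g, 1, -1) + shift(g, 1, 1) + shift(g, 2, -1) + shift(g, 2, 1) +
    shift(g, 3, -1) + shift(g, 3, 1) - 6 * g
  density_map(L, map$origin, map$voxel, map$resolution)
}

# Fixed multistart orientation table (ZYZ Euler angles) for rigid fitting.
fit_starts <- function(n_start) {
  tab <- rbind(
    c(0, 0, 0), c(pi, 0, 0), c(0, pi / 2, 0), c(0, pi, 0),
    c(pi / 2, pi / 2, 0), c(pi, pi / 2, 0), c(3 * pi / 2, pi / 2, 0),
    c(0, pi / 2, pi), c(pi / 2, pi, 0), c(pi / 2, 0, 0),
    c(3 * pi / 2, 0, 0), c(pi / 4, pi / 2, pi / 4))
  tab[seq_len(min(n_start, nrow(tab))), , drop = FALSE]
}

#' Rigid-body fit of a structure into a density map
#'
#' Maximises the cross-correlation between the map simulated from the posed
#' structure and the target map over the 6 rigid degrees of freedom, by
#' Nelder-Mead local search from a fixed grid of starting orientations with
#' the translation initialised by centre-of-mass alignment. With
#' `mode = "laplace"` both maps are Laplacian-filtered before correlation.
#' Deterministic: no random numbers are used.
#'
#' @param s a [viasm_structure()] or Calpha coordinate matrix.
#' @param map target [density_map()]; its `resolution` (or `resolution`
#'   argument) sets the simulation kernel.
#' @param mode `"plain"` or `"laplace"`.
#' @param n_start number of starting orientations (max 12).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param resolution kernel resolution for simulating the model map.
#' @return list with `pose` (length-6: ZYZ angles then translation, applied
#'   about the structure's Calpha centroid), `ccc`, and `xyz` (posed Calpha
#'   coordinates).
#' @export
fit_to_map <- function(s, map, mode = c("plain", "laplace"), n_start = 8,
                       maxit = 120, resolution = map$resolution) {
  mode <- match.arg(mode)
  xyz <- extract_ca_xyz(s)
  if (!nrow(xyz)) stopf("empty structure")
  if (is.na(resolution)) stopf("map has no resolution label; pass `resolution`")
  target <- if (mode == "laplace") laplace_filter(map) else map
  tvec <- as.vector(target$grid)
  thr_t <- 1e-6 * max(tvec)
  ctr <- colMeans(xyz)
  t0 <- map_com(map) - ctr
  score <- function(pose) {
    R <- euler_zyz(pose[1], pose[2], pose[3])
    y <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + pose[4:6], "+")
    m <- simulate_on_grid(y, map, resolution)
    if (mode == "laplace") m <- laplace_filter(m)
    v <- as.vector(m$grid)
    r <- masked_cor_cpp(v, tvec, 1e-6 * max(v, 0), thr_t)
    if (is.na(r)) -1 else r
  }
  best <- NULL
  for (k in seq_len(nrow(fit_starts(n_start)))) {
    p0 <- c(fit_starts(n_start)[k, ], t0)
    opt <- stats::optim(p0, function(p) -score(p), method = "Nelder-Mead",
                        control = list(maxit = maxit,
                                       parscale = c(rep(0.5, 3), rep(map$voxel, 3))))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  cc <- -best$value
  if (cc < 0.2)
    warning("poor overlap between structure and map; best-effort fit returned")
  pose <- best$par
  pose[1:3] <- wrap_angle(pose[1:3])
  R <- euler_zyz(pose[1], pose[2], pose[3])
  list(pose = pose, ccc = cc,
       xyz = sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + pose[4:6], "+"))
}

#' Read and write density maps (MRC/CCP4 mode 2 and SITUS ASCII)
#'
#' The format is chosen by file extension: `.sit`/`.situs` for the SITUS
#' ASCII dialect (`voxel ox oy oz nx ny nz` header followed by values,
#' x fastest), anything else is MRC/CCP4 binary, mode 2 (float32). Grids
#' round-trip at float32 precision through MRC and full precision through
#' SITUS ASCII.
#'
#' @param path file path.
#' @return [read_map()] returns a [density_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stopf("map file not found: %s", path)
  if (grepl("\\.(sit|situs)$", path, ignore.case = TRUE)) read_situs(path)
  else read_mrc(path)
}

#' @rdname read_map
#' @param map a [density_map()].
#' @export
write_map <- function(map, path) {
  if (grepl("\\.(sit|situs)$", path, ignore.case = TRUE)) write_situs(map, path)
  else write_mrc(map, path)
  invisible(path)
}

read_situs <- function(path) {
  vals <- tryCatch(scan(path, quiet = TRUE),
                   error = function(e) stopf("cannot parse SITUS file %s: %s",
                                             path, conditionMessage(e)))
  if (length(vals) < 7) stopf("truncated SITUS file: %s", path)
  voxel <- vals[1]
  origin <- vals[2:4]
  dims <- as.integer(vals[5:7])
  n <- prod(dims)
  if (length(vals) != 7 + n)
    stopf("truncated SITUS file %s: expected %d values, found %d",
          path, n, length(vals) - 7)
  density_map(array(vals[-(1:7)], dims), origin, voxel)
}

write_situs <- function(map, path) {
  d <- dim(map$grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%.6f %.6f %.6f %.6f %d %d %d", map$voxel,
                     map$origin[1], map$origin[2], map$origin[3],
                     d[1], d[2], d[3]), con)
  writeLines(paste(format(as.vector(map$grid), digits = 10, trim = TRUE,
                          scientific = TRUE), collapse = " "), con)
}

read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stopf("truncated MRC file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  dims <- hdr_i[1:3]
  mode <- hdr_i[4]
  if (any(dims < 1) || any(dims > 1e4) || !(mode %in% 0:2))
    stopf("unrecognised MRC header in %s", path)
  if (mode != 2) stopf("only MRC mode 2 (float32) is supported, got mode %d", mode)
  cella <- {seek(con, 40); readBin(con, "numeric", n = 3, size = 4, endian = "little")}
  mxyz <- {seek(con, 28); readBin(con, "integer", n = 3, size = 4, endian = "little")}
  mapcrs <- {seek(con, 64); readBin(con, "integer", n = 3, size = 4, endian = "little")}
  if (!all(mapcrs == 1:3))
    stopf("MRC axis order %s not supported (only 1,2,3)", paste(mapcrs, collapse = ","))
  nsymbt <- {seek(con, 92); readBin(con, "integer", n = 1, size = 4, endian = "little")}
  origin <- {seek(con, 196); readBin(con, "numeric", n = 3, size = 4, endian = "little")}
  magic <- {seek(con, 208); readChar(con, 4, useBytes = TRUE)}
  if (!identical(substr(magic, 1, 3), "MAP"))
    stopf("unknown format magic in %s", path)
  voxel <- cella[1] / mxyz[1]
  n <- prod(dims)
  if (sz < 1024 + nsymbt + 4 * n) stopf("truncated MRC file: %s", path)
  seek(con, 1024 + nsymbt)
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  nxstart <- hdr_i[5:7]
  if (max(abs(origin)) < 1e-12 && any(nxstart != 0)) origin <- nxstart * voxel
  density_map(array(vals, dims), origin, voxel)
}

write_mrc <- function(map, path) {
  d <- dim(map$grid)
  v <- as.vector(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                         # NX NY NZ
  wi(2)                         # MODE 2 = float32
  wi(c(0, 0, 0))                # NXSTART..
  wi(d)                         # MX MY MZ
  wf(d * map$voxel)             # CELLA
  wf(c(90, 90, 90))             # CELLB
  wi(1:3)                       # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(c(1, 0))                   # ISPG, NSYMBT
  wi(rep(0, 25))                # EXTRA (words 25-49)
  wf(map$origin)                # ORIGIN (words 50-52)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(v))              # RMS
  wi(0)                         # NLABL
  writeBin(raw(800), con)       # labels
  wf(v)
}
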