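test_that("simulated maps put the kernel peak on the atom and conserve mass", {
  xyz <- matrix(c(0, 0, 0), 1)
  m <- simulate_map(xyz, resolution = 15, voxel = 5)
  # single atom sitting on a voxel centre: the grid maximum is that voxel
  peak <- which(m$grid == max(m$grid), arr.ind = TRUE)[1, ]
  pk_pos <- m$origin + (peak - 1) * m$voxel
  expect_equal(unname(pk_pos), c(0, 0, 0))

  # discrete kernel mass: per-atom mass from direct numerical integration
  sk <- 15 / (2 * sqrt(2 * log(2)))
  gr <- seq(-3 * sk, 3 * sk, by = 5)
  g3 <- expand.grid(gr, gr, gr)
  r2 <- rowSums(g3^2)
  mass1 <- sum(exp(-r2[r2 <= (3 * sk)^2] / (2 * sk^2)))
  expect_equal(sum(m$grid), mass1, tolerance = 0.01)

  # several well-separated interior atoms: total mass = n * kernel mass
  xyz5 <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0), c(0, 0, 40), c(40, 40, 40))
  m5 <- simulate_map(xyz5, 15, voxel = 5)
  expect_equal(sum(m5$grid) / (5 * mass1), 1, tolerance = 0.01)

  expect_error(simulate_map(xyz, resolution = 8, voxel = 5), "Nyquist|>=")
})

test_that("map simulation is shift-equivariant at voxel granularity", {
  set.seed(3)
  xyz <- matrix(runif(30, 0, 20), ncol = 3)
  m1 <- simulate_map(xyz, 15, voxel = 5)
  m2 <- simulate_map(sweep(xyz, 2, c(5, 0, 0), "+"), 15, voxel = 5)
  # same dims; origin shifted by exactly one voxel
  expect_equal(dim(m2$grid), dim(m1$grid))
  expect_equal(m2$origin, m1$origin + c(5, 0, 0))
  expect_equal(m2$grid, m1$grid, tolerance = 1e-12)
})

test_that("cross-correlation is affine-invariant and symmetric in its extremes", {
  m <- simulate_map(ca_coords(ref_c5()$assembly), 15)
  expect_equal(ccc(m, m), 1.0)
  m2 <- m; m2$grid <- 3.7 * m$grid + 0.2
  expect_equal(ccc(m, m2), 1.0, tolerance = 1e-12)
  m3 <- m; m3$grid <- -m$grid
  expect_equal(ccc(m, m3), -1.0, tolerance = 1e-12)
  bad <- m; bad$voxel <- m$voxel * 2
  expect_error(ccc(m, bad), "geometry")
})

test_that("the Laplacian stencil behaves on constants, impulses and ramps", {
  z <- array(1, c(5, 5, 5))
  expect_true(all(laplace_filter(density_map(z, c(0, 0, 0), 1))$grid == 0))

  imp <- array(0, c(5, 5, 5)); imp[3, 3, 3] <- 1
  L <- laplace_filter(density_map(imp, c(0, 0, 0), 1))$grid
  expect_equal(L[3, 3, 3], -6)
  expect_equal(L[2, 3, 3], 1); expect_equal(L[4, 3, 3], 1)
  expect_equal(L[3, 2, 3], 1); expect_equal(L[3, 4, 3], 1)
  expect_equal(L[3, 3, 2], 1); expect_equal(L[3, 3, 4], 1)
  expect_equal(sum(abs(L)), 12)     # nothing else is touched

  ramp <- array(rep(1:5, 25), c(5, 5, 5))   # linear in x
  Lr <- laplace_filter(density_map(ramp, c(0, 0, 0), 1))$grid
  expect_true(all(abs(Lr[2:4, 2:4, 2:4]) < 1e-12))

  expect_error(laplace_filter(density_map(array(1, c(2, 5, 5)), c(0, 0, 0), 1)),
               ">= 3")
})

test_that("rigid fitting recovers self-fits and known translations", {
  asm <- ref_c5()$assembly
  map <- simulate_map(asm, 15, voxel = 5)
  f <- fit_to_map(asm, map, n_start = 4, maxit = 100)
  expect_gte(f$ccc, 0.999)

  # translation recovery needs an asymmetric structure (a Cn map has n
  # equivalent fit optima); the compact blob has a unique one
  blob <- toy_compact()
  bmap <- simulate_map(blob, 15, voxel = 5)
  moved <- apply_global_pose(blob, c(0, 0, 0, 5, 0, 0))
  f2 <- fit_to_map(moved, bmap, n_start = 6, maxit = 200)
  expect_gte(f2$ccc, 0.99)
  # recovered coordinates land within one voxel of the original
  expect_lt(rmsd_fixed_frame(f2$xyz, ca_coords(blob)), bmap$voxel)
})

test_that("a Cn assembly has n equivalent fit optima with equal ccc", {
  asm <- ref_c5()$assembly
  map <- simulate_map(asm, 15, voxel = 5)
  base <- viasm:::simulate_on_grid(ca_coords(asm), map, 15)
  cccs <- vapply(0:4, function(k) {
    rot <- ca_coords(asm) %*% t(viasm:::rot_z(2 * pi * k / 5))
    ccc(viasm:::simulate_on_grid(rot, map, 15), base)
  }, numeric(1))
  expect_lt(max(cccs) - min(cccs), 1e-6)
})

test_that("MRC and SITUS round-trips preserve the grid", {
  m <- simulate_map(ca_coords(toy_helix()), 15, voxel = 5)
  fm <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, fm)
  back <- read_map(fm)
  expect_equal(dim(back$grid), dim(m$grid))
  expect_equal(back$voxel, m$voxel, tolerance = 1e-6)
  expect_equal(back$origin, m$origin, tolerance = 1e-4)
  expect_lt(max(abs(back$grid - m$grid)), 1e-6)   # float32 precision

  fs <- withr::local_tempfile(fileext = ".sit")
  write_map(m, fs)
  back2 <- read_map(fs)
  expect_equal(back2$origin, m$origin, tolerance = 1e-5)
  expect_lt(max(abs(back2$grid - m$grid)), 1e-8)

  # truncated files are rejected loudly
  sz <- file.info(fm)$size
  con <- file(fm, "r+b"); truncate_at <- sz - 200
  raw <- readBin(con, "raw", truncate_at); close(con)
  ft <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw, ft)
  expect_error(read_map(ft), "truncated")
  writeLines("5.0 0 0 0 4 4 4", ft)
  file.rename(ft, sub("mrc$", "sit", ft))
  expect_error(read_situs_ <- viasm:::read_situs(sub("mrc$", "sit", ft)), "truncated")
})
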