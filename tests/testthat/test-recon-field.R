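test_that("forward dipole field matches the brute-force spatial sum", {
  g <- unit_geometry(16)
  # single voxel source
  chi <- array(0, dim = g$shape)
  chi[8, 8, 8] <- 0.1
  f <- forward_dipole_field(chi, g)$values / g$larmor_mhz
  oracle <- oracle_dipole_sum(chi, g)
  idx <- as.matrix(expand.grid(1:16, 1:16, 1:16))
  rad <- sqrt(rowSums((idx - 8)^2))
  sel <- idx[rad >= 3, , drop = FALSE]
  rel <- sqrt(sum((f[sel] - oracle[sel])^2)) / sqrt(sum(oracle[sel]^2))
  expect_lt(rel, 0.05)

  # sparse random multi-source distribution on a 12^3 anisotropic grid
  g2 <- vol_geometry(c(12, 12, 12), c(0.53, 0.53, 0.8))
  set.seed(11)
  chi2 <- array(0, dim = g2$shape)
  chi2[sample(12^3, 5)] <- stats::runif(5, -0.2, 0.3)
  f2 <- forward_dipole_field(chi2, g2)$values / g2$larmor_mhz
  o2 <- oracle_dipole_sum(chi2, g2)
  expect_lt(max(abs(f2 - o2)) / max(abs(o2)), 0.05)
})

test_that("uniform susceptibility produces no field under the k = 0 convention", {
  g <- unit_geometry(16)
  f <- forward_dipole_field(array(0.1, g$shape), g, pad = FALSE)
  expect_equal(max(abs(f$values)), 0)
})

test_that("a uniform sphere shows the classic inside/outside dipole pattern", {
  sf <- sphere_fixture()
  f_ppm <- sf$field$values / sf$geometry$larmor_mhz
  co <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  rad <- array(sqrt((co$x - 16.5)^2 + (co$y - 16.5)^2 + (co$z - 16.5)^2),
               dim = c(32, 32, 32))
  # Lorentz-corrected field vanishes inside a uniform sphere
  well_inside <- rad <= 4
  expect_lt(sqrt(mean(f_ppm[well_inside]^2)), 0.005 * 0.1)
  # dipole lobes outside: positive at the poles, negative at the equator
  expect_gt(f_ppm[17, 17, 25], 0)
  expect_lt(f_ppm[25, 17, 17], 0)
})

test_that("forward operator is linear", {
  sf <- sphere_fixture()
  f2 <- forward_dipole_field(2 * sf$chi, sf$geometry)
  expect_equal(f2$values, 2 * sf$field$values, tolerance = 1e-12)
})

test_that("Laplacian unwrapping restores smooth wrapped phase", {
  g <- unit_geometry(32)
  # constant phase: output constant (up to a global constant)
  u <- laplacian_unwrap(array(0.3, g$shape), g)
  expect_lt(stats::sd(u), 1e-9)

  co <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  r2 <- array((co$x - 16.5)^2 + (co$y - 16.5)^2 + (co$z - 16.5)^2,
              dim = g$shape)
  interior <- r2 < 100
  # no wraps: identity up to < 1e-3 rad in the interior
  phi <- 2 * exp(-r2 / 72)
  u <- laplacian_unwrap(phi, g)
  dd <- (u - phi)[interior]
  expect_lt(sqrt(mean((dd - mean(dd))^2)), 1e-3)
  # 10 rad peak, wrapped into (-pi, pi]: interior RMS < 0.05 rad
  phi <- 10 * exp(-r2 / 72)
  u <- laplacian_unwrap(Arg(exp(1i * phi)), g)
  dd <- (u - phi)[interior]
  expect_lt(sqrt(mean((dd - mean(dd))^2)), 0.05)
  expect_error(laplacian_unwrap(array(NaN, g$shape), g), "finite")
})

test_that("coil combination recovers receiver phases and aligns channels", {
  # one channel with zero receiver phase: combination is the identity
  spec <- phantom_spec(grid_shape = c(24, 24, 16), noise_sd = 0, n_channels = 1)
  truth <- build_phantom(spec)
  truth$coil_sens[] <- Mod(truth$coil_sens) # strip phases
  gre <- simulate_multiecho_gre(truth, spec)
  comb <- combine_coils(gre)
  expect_equal(comb$data[, , , , 1], gre$data[, , , , 1], tolerance = 1e-12)

  # two equal-magnitude channels at +1 / -1 rad: aligned sum doubles magnitude
  s2 <- gre
  s2$data <- array(c(gre$data * exp(1i), gre$data * exp(-1i)),
                   dim = c(dim(gre$data)[1:4], 2))
  comb2 <- combine_coils(multiecho_gre(s2$data, gre$te_s, gre$geometry))
  expect_equal(Mod(comb2$data[, , , , 1]), 2 * Mod(gre$data[, , , , 1]),
               tolerance = 1e-9)

  # 4-channel noiseless: receiver phase maps recovered almost exactly
  spec4 <- phantom_spec(grid_shape = c(24, 24, 16), noise_sd = 0, n_channels = 4)
  truth4 <- build_phantom(spec4)
  gre4 <- simulate_multiecho_gre(truth4, spec4)
  comb4 <- combine_coils(gre4)
  err <- Arg(exp(1i * (attr(comb4, "receiver_phase") - Arg(truth4$coil_sens))))
  brain4 <- array(truth4$masks$brain, dim = dim(err))
  expect_lt(sqrt(mean(err[brain4]^2)), 1e-8)

  expect_error(combine_coils(multiecho_gre(gre$data[, , , 1, , drop = FALSE],
                                           gre$te_s[1], gre$geometry)),
               "at least 2 echoes")
})

test_that("V-SHARP suppresses external fields and preserves internal sources", {
  g <- vol_geometry(c(48, 48, 48), c(1, 1, 1))
  co <- expand.grid(x = 1:48, y = 1:48, z = 1:48)
  rad <- array(sqrt((co$x - 24.5)^2 + (co$y - 24.5)^2 + (co$z - 24.5)^2),
               dim = g$shape)
  brain <- rad <= 16

  # zero field in, zero field out
  vs0 <- vsharp_background_removal(field_map(array(0, g$shape), geometry = g),
                                   brain, max_radius_mm = 12)
  expect_equal(max(abs(vs0$local_field$values)), 0)

  # dipole source outside the mask: local field < 10% of the input RMS
  chi_ext <- array(0, g$shape)
  chi_ext[44, 24, 24] <- 5
  f_ext <- forward_dipole_field(chi_ext, g)
  vs <- vsharp_background_removal(f_ext, brain, max_radius_mm = 12)
  m <- vs$mask_eroded
  expect_lt(sqrt(mean(vs$local_field$values[m]^2)) /
              sqrt(mean(f_ext$values[m]^2)), 0.10)

  # internal point source far from the boundary: preserved within 15% RMS
  chi_int <- array(0, g$shape)
  chi_int[24, 24, 24] <- 1
  f_int <- forward_dipole_field(chi_int, g)
  vs2 <- vsharp_background_removal(f_int, brain, max_radius_mm = 12)
  shell <- rad >= 3 & rad <= 6 & vs2$mask_eroded
  rel <- sqrt(mean((vs2$local_field$values[shell] - f_int$values[shell])^2)) /
    sqrt(mean(f_int$values[shell]^2))
  expect_lt(rel, 0.15)

  # mask smaller than the smallest kernel
  tiny <- array(FALSE, g$shape)
  tiny[24, 24, 24] <- TRUE
  expect_error(vsharp_background_removal(f_int, tiny, max_radius_mm = 12),
               "smaller than")
})

test_that("dipole inversion round-trips a sphere and is linear", {
  sf <- sphere_fixture()
  # zero field -> zero susceptibility
  z <- invert_dipole(field_map(array(0, sf$geometry$shape),
                               geometry = sf$geometry), method = "tkd")
  expect_equal(max(abs(z$values)), 0)

  chi_rec <- invert_dipole(sf$field, method = "tkd")
  d <- mean(chi_rec$values[sf$inside]) - mean(chi_rec$values[!sf$inside])
  expect_lt(abs(d - 0.1) / 0.1, 0.10)

  f2 <- sf$field
  f2$values <- 2 * f2$values
  chi2 <- invert_dipole(f2, method = "tkd")
  expect_equal(chi2$values, 2 * chi_rec$values, tolerance = 1e-12)

  # the two-pass scheme also recovers the sphere and demeans over the mask
  chi_star <- invert_dipole(sf$field, method = "star2pass")
  d_star <- mean(chi_star$values[sf$inside]) - mean(chi_star$values[!sf$inside])
  expect_lt(abs(d_star - 0.1) / 0.1, 0.10)
  expect_lt(abs(mean(chi_star$values[chi_star$mask])), 1e-10)

  expect_error(invert_dipole(sf$field, method = "nonsense"))
})
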