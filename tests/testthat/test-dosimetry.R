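# Pointwise SAR, total power, cube-grown 10 g averaging, CP mode.

test_that("pointwise SAR closed form, air handling and quadratic scaling", {
  tt <- default_tissue_table()
  tt$conductivity_S_per_m[tt$name == "muscle"] <- 0.5
  tt$density_kg_per_m3[tt$name == "muscle"] <- 1000
  lab <- array(tt$label[tt$name == "muscle"], c(3, 3, 3))
  lab[1, 1, 1] <- 0L
  m <- voxel_model(lab, 2, tt)
  E <- array(complex(real = 100 / sqrt(3)), c(3, 3, 3, 3))  # |E| = 100 V/m
  s <- pointwise_sar(E, m)
  expect_equal(s[2, 2, 2], 0.5 * 100^2 / (2 * 1000))  # 2.5 W/kg
  expect_equal(s[1, 1, 1], 0)                          # air
  expect_equal(pointwise_sar(2 * E, m), 4 * s, tolerance = 1e-12)
})

test_that("total absorbed power: closed form and mass-weighted identity", {
  # uniform |E| = 100, sigma = 0.5, volume 1e-3 m3 -> 2.5 W
  tt <- default_tissue_table()
  tt$conductivity_S_per_m[tt$name == "muscle"] <- 0.5
  n <- 5
  lab <- array(tt$label[tt$name == "muscle"], rep(n, 3))
  vox <- (1e-3 / n^3)^(1 / 3) * 1000  # mm, so total volume = 1e-3 m3
  m <- voxel_model(lab, vox, tt)
  E <- array(complex(real = 100 / sqrt(3)), c(rep(n, 3), 3))
  expect_equal(total_absorbed_power(E, m), 2.5, tolerance = 1e-9)
  expect_equal(total_absorbed_power(E * 0, m), 0)
  # identity: mass-weighted mean SAR x head mass = total power
  mod <- fx_model()
  f <- fx_fields()
  w <- generate_shims(1, 8, 5, seed = 5)[, 1]
  Etot <- combine_fields(mod_f <- f, w)$E
  hm <- head_mask(mod)
  sar <- pointwise_sar(Etot, mod)
  rho <- ptxsar:::tissue_lookup(mod, "density_kg_per_m3")
  voxvol <- prod(mod$voxel_size) * 1e-9
  mass <- rho * voxvol
  lhs <- sum(sar[hm] * mass[hm])  # mass-weighted mean x total mass
  expect_equal(lhs, total_absorbed_power(Etot, mod, hm), tolerance = 1e-9)
})

test_that("sar_10g: uniform value, 11-voxel cube arithmetic, monotonicity", {
  u <- fx_uniform_model(n = 16, voxel = 2, density = 1000)  # 8 mg voxels
  sar <- array(3.25, dim(u$labels))
  s10 <- sar_10g(sar, u, mask = u$labels > 0)
  ctr <- s10$sar10g[8, 8, 8]
  expect_equal(ctr, 3.25, tolerance = 1e-9)     # uniform SAR passes through
  expect_equal(s10$side[8, 8, 8], 11L)          # 11^3 x 8 mg = 10.648 g >= 10
  f_expect <- (0.010 - 0.005832) / (0.010648 - 0.005832)
  expect_equal(s10$frac[8, 8, 8], f_expect, tolerance = 1e-9)
  expect_lte(max(s10$sar10g), max(sar) * (1 + 1e-12))
  # scaling pointwise SAR by k scales sar10g by k
  s10b <- sar_10g(3 * sar, u, mask = u$labels > 0)
  expect_equal(s10b$sar10g, 3 * s10$sar10g, tolerance = 1e-9)
  # a head lighter than 10 g errors
  tiny <- fx_uniform_model(n = 3, voxel = 2)
  expect_error(sar_10g(array(1, c(3, 3, 3)), tiny, mask = tiny$labels > 0),
               "lighter")
})

test_that("sar_10g max never exceeds pointwise max; painted voxels covered", {
  m <- fx_model()
  f <- fx_fields()
  w <- generate_shims(1, 8, 5, seed = 6)[, 1]
  sar <- pointwise_sar(combine_fields(f, w)$E, m)
  s10 <- sar_10g(sar, m)
  expect_lte(s10$max, max(sar))
  hm <- s10$mask & m$labels > 0
  expect_true(all(s10$sar10g[hm & !s10$valid] > 0))  # painting reached all
})

test_that("cp_mode: 2 uT at isocenter, scale invariance, power identity", {
  m <- fx_model()
  f <- fx_fields()
  coil <- coil_model()
  cp <- cp_mode(f, coil, m)
  d <- dim(m$labels)
  iso <- ptxsar:::nearest_voxel(m$world, d, c(0, 0, 0))
  expect_equal(Mod(cp$b1p_map[iso[1], iso[2], iso[3]]), 2, tolerance = 1e-9)
  expect_equal(cp$sar_head_w_per_kg * cp$head_mass_kg, cp$total_power_w,
               tolerance = 1e-6 * cp$total_power_w)
  # halving all channel fields doubles V but leaves normalized SAR unchanged
  fh <- f
  fh$E <- f$E / 2
  fh$b1p <- f$b1p / 2
  cph <- cp_mode(fh, coil, m)
  expect_equal(cph$normalization_factor, 2 * cp$normalization_factor,
               tolerance = 1e-12)
  expect_equal(cph$sar_head_w_per_kg, cp$sar_head_w_per_kg, tolerance = 1e-12)
  expect_equal(cph$sar10g_max_w_per_kg, cp$sar10g_max_w_per_kg,
               tolerance = 1e-12)
})
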