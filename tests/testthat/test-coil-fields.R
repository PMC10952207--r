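# Surrogate field generator: normalization, linearity, channel symmetry.

test_that("per-channel deposited power is 1 W after normalization", {
  m <- fx_model()
  f <- fx_fields()
  sigma <- ptxsar:::tissue_lookup(m, "conductivity_S_per_m")
  voxvol <- prod(m$voxel_size) * 1e-9
  for (c in seq_len(dim(f$b1p)[4])) {
    e2 <- rowSums(matrix(Mod(f$E[, , , , c])^2, ncol = 3))
    p <- sum(sigma * e2) / 2 * voxvol
    expect_equal(p, 1, tolerance = 1e-6)
  }
})

test_that("combine_fields is strictly linear in the shim", {
  f <- fx_fields()
  one_hot <- complex(real = c(0, 0, 1, 0, 0, 0, 0, 0))
  c3 <- combine_fields(f, one_hot)
  expect_identical(c3$E, array(f$E[, , , , 3], dim(c3$E)))
  # scaling a channel's drive by 2 doubles E and B1+
  c6 <- combine_fields(f, 2 * one_hot)
  expect_equal(c6$E, 2 * c3$E, tolerance = 1e-15)
  # w and -w: fields negated, |E| identical
  w <- generate_shims(1, 8, 5, seed = 2)[, 1]
  cp <- combine_fields(f, w)
  cm <- combine_fields(f, -w)
  expect_equal(cm$E, -cp$E, tolerance = 1e-15)
  expect_equal(Mod(cm$b1p), Mod(cp$b1p), tolerance = 1e-12)
  expect_error(combine_fields(f, w[1:5]), "channels")
})

test_that("deposited power of a shim equals the bilinear form", {
  m <- fx_model()
  f <- fx_fields()
  sigma <- ptxsar:::tissue_lookup(m, "conductivity_S_per_m")
  voxvol <- prod(m$voxel_size) * 1e-9
  nch <- dim(f$b1p)[4]
  # pairwise power matrix P[c,c'] = sum sigma E_c' . conj(E_c) dV / 2
  Emat <- matrix(f$E, ncol = nch)   # (nvox*3) x nch
  W <- rep(sigma, 3) * voxvol / 2
  P <- t(Conj(Emat)) %*% (W * Emat)
  for (s in 1:5) {
    w <- generate_shims(5, nch, 5, seed = 11)[, s]
    etot <- combine_fields(f, w)$E
    p_direct <- sum(sigma * rowSums(matrix(Mod(etot)^2, ncol = 3))) / 2 * voxvol
    p_form <- Re(Conj(w) %*% P %*% w)[1, 1]
    expect_equal(p_direct, p_form, tolerance = 1e-9)
  }
})

test_that("channel symmetry: 90-degree rotation maps channel c to c+1", {
  # 4-fold symmetric phantom (equal x/y semi-axes, no internal asymmetry)
  spec <- phantom_spec(semi_axes = c(70, 70, 90),
                       cereb_semi = c(0, 0, 0), vent_semi = c(0, 0, 0),
                       neck_slab = FALSE, surf_amp = 0)
  m <- make_phantom(spec, voxel_size = 5)
  coil4 <- coil_model(n_channels = 4)
  f <- simulate_channel_fields(coil4, m)
  d <- dim(m$labels)
  expect_equal(d[1], d[2])
  rot90 <- function(v) {  # +90 deg about z in ij-plane (x->y)
    aperm(v[d[1]:1, , , drop = FALSE], c(2, 1, 3))
  }
  tis <- m$labels > 0
  expect_identical(rot90(m$labels), m$labels)  # phantom itself symmetric
  b1 <- Mod(f$b1p[, , , 1])
  rels <- sapply(c(2, 4), function(c) {  # +/-90 deg neighbor, either handed
    bc <- Mod(f$b1p[, , , c])
    sqrt(mean((rot90(b1)[tis] - bc[tis])^2)) / sqrt(mean(bc[tis]^2))
  })
  expect_lt(min(rels), 0.01)
})

test_that("efield_sq_difference: zeros, scaling, masks", {
  m <- fx_model()
  f <- fx_fields()
  w <- generate_shims(1, 8, 5, seed = 3)[, 1]
  d0 <- efield_sq_difference(f, f, m, m, w)
  expect_true(all(d0$diff == 0) && d0$mean == 0)
  f2 <- f
  f2$E <- 2 * f$E
  d1 <- efield_sq_difference(f, f2, m, m, w)
  e2 <- combine_fields(f, w)$E
  e2m <- array(rowSums(matrix(Mod(e2)^2, ncol = 3)), dim(m$labels))
  expect_equal(d1$diff, 3 * e2m, tolerance = 1e-12)
  expect_gte(d1$mean, 0)
})

test_that("field simulation errors on degenerate inputs", {
  tt <- default_tissue_table()
  air <- voxel_model(array(0L, c(4, 4, 4)), 5, tt)
  expect_error(simulate_channel_fields(coil_model(), air), "no tissue")
  big <- phantom_spec(semi_axes = c(160, 70, 90), neck_slab = FALSE)
  mbig <- make_phantom(big, voxel_size = 8)
  expect_error(simulate_channel_fields(coil_model(), mbig), "outside")
})
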