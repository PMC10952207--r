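# Phantom generation, T1 synthesis, segmentation perturbation, transforms,
# resampling.

test_that("make_phantom is deterministic and honors degenerate shells", {
  spec <- phantom_spec(thickness = c(skin = 0, fat = 0, skull = 0, csf = 0,
                                     gm = 0),
                       cereb_semi = c(0, 0, 0), vent_semi = c(0, 0, 0),
                       neck_slab = FALSE, surf_amp = 0)
  m <- make_phantom(spec, voxel_size = 4)
  expect_length(setdiff(unique(as.vector(m$labels)), 0L), 1)
  m2 <- make_phantom(spec, voxel_size = 4)
  expect_identical(m$labels, m2$labels)
  # distinct specs give distinct phantoms
  m3 <- make_phantom(builtin_phantom_specs()$subject1, voxel_size = 4)
  expect_false(identical(dim(m$labels), dim(m3$labels)) &&
                 identical(m$labels, m3$labels))
})

test_that("phantom volume matches the analytic ellipsoid volume within 2%", {
  spec <- phantom_spec(semi_axes = c(90, 70, 100),
                       cereb_semi = c(0, 0, 0), vent_semi = c(0, 0, 0),
                       neck_slab = FALSE, surf_amp = 0)
  m <- make_phantom(spec, voxel_size = 2)
  v_analytic <- 4 / 3 * pi * 90 * 70 * 100
  v_vox <- sum(m$labels > 0) * prod(m$voxel_size)
  expect_lt(abs(v_vox / v_analytic - 1), 0.02)
})

test_that("invalid phantom specs error", {
  expect_error(phantom_spec(semi_axes = c(10, 10, 10),
                            thickness = c(skin = 5, fat = 5, skull = 5,
                                          csf = 0, gm = 0)),
               "exceed")
  expect_error(phantom_spec(thickness = c(skin = -1)), ">= 0")
})

test_that("synthesize_t1 is seeded Gaussian noise around tissue means", {
  m <- fx_model()
  img0 <- synthesize_t1(m, noise_sd = 0)
  mu <- ptxsar:::tissue_lookup(m, "t1w_mean")
  expect_equal(img0$intensities, mu, ignore_attr = TRUE)
  expect_identical(synthesize_t1(m, seed = 9L)$intensities,
                   synthesize_t1(m, seed = 9L)$intensities)
  expect_false(identical(synthesize_t1(m, seed = 9L)$intensities,
                         synthesize_t1(m, seed = 10L)$intensities))
  # law of large numbers: sample sd within 5% on a >= 1e5-voxel region
  big <- fx_uniform_model(n = 50, voxel = 2)
  imgn <- synthesize_t1(big, noise_sd = 10, seed = 3L)
  expect_lt(abs(sd(imgn$intensities) / 10 - 1), 0.05)
})

test_that("perturb_segmentation conserves support and obeys p", {
  m <- fx_model()
  expect_identical(perturb_segmentation(m, list(boundary_flip(0)))$labels,
                   m$labels)
  # split_tissue: union of old + new equals old support exactly
  # (a solid skull block, thick enough for the 1-voxel erosion core)
  tt <- default_tissue_table()
  blk <- voxel_model(array(tt$label[tt$name == "skull"], c(8, 8, 8)), 2, tt)
  sp <- perturb_segmentation(blk, list(split_tissue("skull", "cancellous_bone")))
  lb <- function(mm, nm) mm$tissue$label[mm$tissue$name == nm]
  old_sup <- blk$labels == lb(blk, "skull")
  new_sup <- sp$labels == lb(sp, "skull") |
    sp$labels == lb(sp, "cancellous_bone")
  expect_identical(old_sup, new_sup)
  expect_equal(sum(sp$labels == lb(sp, "cancellous_bone")), 6^3)
  # insert_layer: nonzero support untouched, dura appears at the interface
  ins <- perturb_segmentation(m, list(insert_layer("csf", "skull", "dura")))
  expect_identical(ins$labels > 0, m$labels > 0)
  expect_gt(sum(ins$labels == lb(ins, "dura")), 0)
  expect_error(perturb_segmentation(m, list(insert_layer("csf", "dura",
                                                         "dura"))),
               "not present")
  # boundary_flip: flipped fraction within binomial 99% bounds of p
  p <- 0.3
  fl <- perturb_segmentation(m, list(boundary_flip(p)), seed = 4L)
  expect_identical(fl$labels > 0, m$labels > 0)
  d <- dim(m$labels)
  set.seed(1)
  iface <- ptxsar:::flip_interface(m$labels, d, 1)  # p = 1 flips all
  n_iface <- sum(iface != m$labels)
  n_flip <- sum(fl$labels != m$labels)
  ci <- qbinom(c(0.005, 0.995), n_iface, p)
  expect_gte(n_flip, ci[1])
  expect_lte(n_flip, ci[2])
})

test_that("apply_transform_to_model: identity, translation, round trip", {
  m <- fx_model()
  expect_identical(apply_transform_to_model(m, affine_transform(), m)$labels,
                   m$labels)
  # pure translation by exactly 2 voxels along x
  k <- 2L
  tr <- affine_from_params(translation = c(k * m$voxel_size[1], 0, 0))
  shifted <- apply_transform_to_model(m, tr, m)
  d <- dim(m$labels)
  expect_identical(shifted$labels[(k + 1):d[1], , ],
                   m$labels[1:(d[1] - k), , ])
  # random affine then its inverse: DSC >= 0.98 per tissue (nearest-
  # neighbor round-trip loss only; run near the native model resolution,
  # where the thinnest shell spans >= 2 voxels)
  mf <- make_phantom(builtin_phantom_specs()$subject1, voxel_size = 1.5)
  aff <- affine_from_params(translation = c(3.2, -2.1, 1.7),
                            rotation_deg = c(4, -6, 3),
                            scale = c(1.05, 0.95, 1.02))
  fwd <- apply_transform_to_model(mf, aff, mf)
  back <- apply_transform_to_model(fwd, affine_transform(solve(aff$matrix)), mf)
  dsc <- dice(back, mf)
  expect_true(all(dsc$dsc[!is.na(dsc$dsc)] >= 0.98))
  expect_error(apply_transform_to_model(m, affine_transform(diag(4) * 0 +
    diag(c(1, 1, 0, 1))), m))
})

test_that("resample: identity, uniform images, volume and mass conservation", {
  m <- fx_model()
  expect_identical(resample(m, m$voxel_size)$labels, m$labels)
  u <- synthetic_image(array(7, dim(m$labels)), m)
  expect_true(all(resample(u, 7.5)$intensities == 7))
  # 2x downsample of a label sphere: volume within 5%
  spec <- phantom_spec(semi_axes = c(60, 60, 60),
                       cereb_semi = c(0, 0, 0), vent_semi = c(0, 0, 0),
                       neck_slab = FALSE, surf_amp = 0)
  sph <- make_phantom(spec, voxel_size = 2)
  down <- resample(sph, 4)
  v1 <- sum(sph$labels > 0) * prod(sph$voxel_size)
  v2 <- sum(down$labels > 0) * prod(down$voxel_size)
  expect_lt(abs(v2 / v1 - 1), 0.05)
  # tissue mass change < 5% under resampling by a factor <= 2
  mass <- function(mm) {
    rho <- ptxsar:::tissue_lookup(mm, "density_kg_per_m3")
    sum(rho) * prod(mm$voxel_size) * 1e-9
  }
  m2 <- resample(fx_model(), fx_model()$voxel_size * 2)
  expect_lt(abs(mass(m2) / mass(fx_model()) - 1), 0.05)
})

test_that("voxel model and tissue table validation", {
  tt <- default_tissue_table()
  expect_error(voxel_model(array(99L, c(2, 2, 2)), 1, tt), "not in tissue")
  bad <- tt
  bad$conductivity_S_per_m[2] <- -1
  expect_error(ptxsar:::validate_tissue_table(bad), "negative")
  expect_error(ptxsar:::validate_tissue_table(tt[, 1:3]), "missing columns")
})
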