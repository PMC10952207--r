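# Brain masks, Dice, property maps, and basic registration behavior.
# Heavy synthetic-transform recovery lives in test-acceptance.R.

test_that("dice matches the overlap formula and is symmetric", {
  tt <- default_tissue_table()
  mk <- function(idx) {
    lab <- array(0L, c(5, 1, 1))
    lab[idx] <- tt$label[tt$name == "muscle"]
    voxel_model(lab, 1, tt)
  }
  a <- mk(1:3)   # |X| = 3
  b <- mk(3:4)   # |Y| = 2, overlap 1
  expect_equal(dice(a, b)$dsc[dice(a, b)$group == "muscle"], 0.4)
  expect_equal(dice(a, a)$dsc[dice(a, a)$group == "muscle"], 1.0)
  d0 <- dice(mk(1:2), mk(4:5))
  expect_equal(d0$dsc[d0$group == "muscle"], 0.0)
  dab <- dice(a, b)
  dba <- dice(b, a)
  expect_equal(dab$dsc[order(dab$group)], dba$dsc[order(dba$group)])
  m <- fx_model()
  ds <- dice(m, m)
  expect_true(all(ds$dsc[ds$n_a + ds$n_b > 0] == 1))
  expect_true(all(ds$dsc >= 0 & ds$dsc <= 1, na.rm = TRUE))
  expect_error(dice(m, mk(1)), "grid")
})

test_that("brain mask: label mode exact, threshold mode close, errors", {
  m <- make_phantom(builtin_phantom_specs()$reference, voxel_size = 4)
  img <- synthesize_t1(m, noise_sd = 0)
  truth <- extract_brain_mask(img, m)
  nm <- m$tissue$name
  brain_labels <- m$tissue$label[nm %in% c("gray_matter", "white_matter",
                                           "cerebellum")]
  base <- array(m$labels %in% brain_labels, dim(m$labels))
  expect_true(all(truth[base]))        # contains the brain labels
  thr <- extract_brain_mask(img)       # threshold mode, no model
  dsc <- 2 * sum(thr & truth) / (sum(thr) + sum(truth))
  expect_gte(dsc, 0.95)
  zero <- synthetic_image(array(0, dim(m$labels)), m)
  expect_error(extract_brain_mask(zero), "empty")
})

test_that("property difference maps: zeros, single voxel, closed-form mass", {
  m <- fx_model()
  p0 <- property_difference_maps(m, m)
  expect_true(all(p0$conductivity_diff == 0) && p0$mean_density_diff == 0)
  # one voxel WM -> CSF
  tt <- m$tissue
  wm <- tt$label[tt$name == "white_matter"]
  csf <- tt$label[tt$name == "csf"]
  idx <- which(m$labels == wm)[1]
  m2 <- m
  m2$labels[idx] <- csf
  p1 <- property_difference_maps(m, m2)
  dsig <- abs(tt$conductivity_S_per_m[tt$label == csf] -
              tt$conductivity_S_per_m[tt$label == wm])
  expect_equal(p1$conductivity_diff[idx], dsig)
  expect_equal(sum(p1$conductivity_diff != 0), 1)
  # uniform phantom, 1000 kg/m3, 8 mm3 voxels, N voxels -> 8e-6 N kg
  u <- fx_uniform_model(n = 10, voxel = 2, density = 1000)
  pu <- property_difference_maps(u, u)
  expect_equal(unname(pu$head_mass_kg["a"]), 8e-6 * 1000 / 1000 * 10^3,
               tolerance = 1e-12)
})

test_that("affine registration of an image to itself is near identity", {
  m <- make_phantom(builtin_phantom_specs()$reference, voxel_size = 4)
  img <- synthesize_t1(m, noise_sd = 0)
  bm <- extract_brain_mask(img, m)
  tr <- suppressWarnings(
    register_affine(img, img, moving_mask = bm, fixed_mask = bm,
                    dof = 12, levels = c(4, 2), maxit = 400))
  L <- tr$matrix[1:3, 1:3]
  expect_lt(sqrt(sum(tr$matrix[1:3, 4]^2)), 0.1)          # translation, mm
  expect_lt(max(abs(svd(L)$d - 1)), 0.002)                # scale, 0.2%
})

test_that("affine serialization round-trips", {
  tr <- affine_from_params(translation = c(1.5, -2, 3),
                           rotation_deg = c(3, 1, -2), scale = c(1.1, 1, 0.9))
  f <- tempfile(fileext = ".txt")
  write_affine(tr, f)
  expect_equal(read_affine(f)$matrix, tr$matrix, tolerance = 1e-12,
               ignore_attr = TRUE)
})
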