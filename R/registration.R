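# Brain-mask extraction, 12-DOF affine and demons-style nonlinear
# registration between synthetic T1 images, and overlap/property metrics.
#
# Transforms map moving -> fixed world coordinates (mm). Deformation fields
# live on the fixed grid and store per-voxel world-mm displacements that are
# added to the fixed-voxel world position before pulling back through the
# affine initialization (pull-back resampling).

#' Affine transform (world mm to world mm)
#'
#' @param matrix 4x4 matrix with last row `(0, 0, 0, 1)` and a nonsingular
#'   upper-left 3x3 block.
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(4)) {
  stopifnot(all(dim(matrix) == c(4, 4)))
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row of an affine must be (0,0,0,1)", call. = FALSE)
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop("singular affine transform", call. = FALSE)
  structure(list(matrix = matrix), class = "affine_transform")
}

#' Build an affine from translation / rotation / scale / shear parameters
#'
#' The transform is `T(t) C R Sh S C^{-1}` with `C` the translation to
#' `center`: rotation, shear and scaling act about `center`.
#'
#' @param translation mm (3); @param rotation_deg xyz Euler angles, degrees.
#' @param scale per-axis factors; @param shear xy, xz, yz components.
#' @param center rotation/scaling center, world mm.
#' @export
affine_from_params <- function(translation = c(0, 0, 0),
                               rotation_deg = c(0, 0, 0),
                               scale = c(1, 1, 1),
                               shear = c(0, 0, 0),
                               center = c(0, 0, 0)) {
  R <- euler_xyz(rotation_deg)
  Sh <- diag(3)
  Sh[1, 2] <- shear[1]
  Sh[1, 3] <- shear[2]
  Sh[2, 3] <- shear[3]
  L <- R %*% Sh %*% diag(rep_len(scale, 3), 3)
  m <- diag(4)
  m[1:3, 1:3] <- L
  m[1:3, 4] <- translation + center - L %*% center
  affine_transform(m)
}

#' @rdname affine_transform
#' @param x affine transform; @param path text file (4x4 whitespace matrix).
#' @export
write_affine <- function(x, path) {
  write.table(format(x$matrix, digits = 17), path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname affine_transform
#' @export
read_affine <- function(path) {
  affine_transform(as.matrix(read.table(path)))
}

#' Deformation field
#'
#' @param displacement array `c(dims, 3)` of world-mm displacements on the
#'   fixed grid.
#' @param init_affine affine initialization (moving -> fixed world).
#' @param reference fixed-grid model/image supplying geometry.
#' @export
deformation_field <- function(displacement, init_affine, reference) {
  stopifnot(all(is.finite(displacement)), length(dim(displacement)) == 4,
            dim(displacement)[4] == 3)
  structure(list(displacement = displacement, init_affine = init_affine,
                 voxel_size = reference$voxel_size, world = reference$world),
            class = "deformation_field")
}

#' Write / read a deformation field as 4D NIfTI (mm displacements)
#' @param field deformation field; @param path `.nii` path.
#' @export
write_deformation_field <- function(field, path) {
  write_nifti(field$displacement, path, world = field$world,
              datatype = "float64")
  write_affine(field$init_affine, paste0(path, ".affine.txt"))
  invisible(path)
}

#' Extract a brain mask
#'
#' With a label model ("ground-truth mode") the mask is the union of gray
#' matter, white matter and cerebellum plus fully enclosed (interior) CSF.
#' Without one, Otsu thresholding keeps bright tissue, the largest
#' 6-connected component (the brain, separated from the scalp by the dark
#' skull/CSF shell) is retained, then closed and hole-filled.
#'
#' @param image `synthetic_image`.
#' @param model optional `voxel_model` on the same grid.
#' @param closing_radius voxels, for threshold mode.
#' @return logical 3D mask.
#' @export
extract_brain_mask <- function(image, model = NULL, closing_radius = 2L) {
  if (!is.null(model)) {
    stopifnot(identical(vm_dims(model), dim3(image$intensities)))
    nm <- model$tissue$name
    brain_labels <- model$tissue$label[nm %in%
      c("gray_matter", "white_matter", "cerebellum")]
    m <- array(model$labels %in% brain_labels, dim(model$labels))
    m <- fill_holes(m)
    if (!any(m)) stop("empty brain mask", call. = FALSE)
    return(m)
  }
  v <- image$intensities
  if (all(v == 0)) stop("empty brain mask: all-zero image", call. = FALSE)
  thr <- otsu_threshold(v[v > max(v) * 0.02])
  bright <- array(v >= thr, dim(v))
  cc <- cpp_cc6(bright, dim3(v))
  sizes <- attr(cc, "sizes")
  if (!length(sizes)) stop("empty brain mask", call. = FALSE)
  m <- array(cc == which.max(sizes), dim(v))
  d <- dim3(v)
  m <- cpp_box_morph(cpp_box_morph(m, d, closing_radius, TRUE), d,
                     closing_radius, FALSE)
  m <- fill_holes(array(m, dim(v)))
  if (!any(m)) stop("empty brain mask", call. = FALSE)
  m
}

# fill internal cavities: background components not touching the grid border
fill_holes <- function(mask) {
  d <- dim3(mask)
  bg <- !mask
  cc <- cpp_cc6(bg, d)
  border <- unique(c(cc[1, , ], cc[d[1], , ], cc[, 1, ], cc[, d[2], ],
                     cc[, , 1], cc[, , d[3]]))
  border <- border[border > 0]
  holes <- bg & !(array(cc %in% border, d))
  mask | holes
}

otsu_threshold <- function(x, nbins = 256) {
  h <- tabulate(cut(x, nbins, labels = FALSE), nbins)
  p <- h / sum(h)
  mids <- seq(min(x), max(x), length.out = nbins + 1)
  mids <- (mids[-1] + mids[-(nbins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  bet <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bet[!is.finite(bet)] <- 0
  mids[which.max(bet)]
}

ncc_cost_fun <- function(p, dof, center, fixed, moving, mask) {
  par <- c(rep(0, 3), rep(0, 3), rep(0, 3), rep(0, 3))
  par[seq_along(p)] <- p
  A <- affine_from_params(par[1:3], par[4:6] * 180 / pi,
                          exp(par[7:9]), par[10:12], center)$matrix
  P <- solve(moving$world) %*% solve(A)
  cpp_ncc_cost(fixed$intensities, mask, dim3(fixed$intensities),
               moving$intensities, dim3(moving$intensities),
               P, fixed$world)$cost
}

# anti-aliased pyramid level: Gaussian smooth (sigma ~ factor/2 voxels),
# then resample to factor x coarser grid
pyramid_level <- function(image, factor) {
  if (factor <= 1) return(image)
  sm <- cpp_gauss_smooth(image$intensities, dim3(image$intensities),
                         rep(factor / 2, 3))
  smi <- synthetic_image(array(sm, dim(image$intensities)), image)
  resample(smi, image$voxel_size * factor)
}

mask_centroid <- function(mask, world) {
  idx <- which(mask) - 1L
  d <- dim3(mask)
  i <- idx %% d[1]
  j <- (idx %/% d[1]) %% d[2]
  k <- idx %/% (d[1] * d[2])
  colMeans(cbind(i, j, k) %*% t(world[1:3, 1:3])) + world[1:3, 4]
}

resample_mask <- function(mask, like, new_voxel_size) {
  img <- synthetic_image(array(as.numeric(mask), dim(mask)), like)
  r <- resample(img, new_voxel_size)
  array(r$intensities >= 0.5, dim(r$intensities))
}

#' Affine registration by masked NCC and multi-resolution Nelder-Mead
#'
#' Maximizes the normalized cross-correlation between the fixed image and
#' the pulled-back moving image over the fixed-space mask, through a 3-level
#' coarse-to-fine pyramid. `dof = 6` restricts to rigid (translation +
#' rotation); `dof = 12` adds per-axis scaling and shear. Initialization is
#' center-of-mass alignment of the two masks. Deterministic.
#'
#' @param moving,fixed `synthetic_image`s.
#' @param moving_mask,fixed_mask logical masks (e.g. brain masks) on the
#'   native grids; default: intensity above 2% of maximum.
#' @param dof 6 or 12.
#' @param levels pyramid voxel-size factors, coarse to fine.
#' @param maxit Nelder-Mead iteration cap per level and pass.
#' @return `affine_transform` (moving -> fixed world mm) with attributes
#'   `cost` (final 1 - NCC) and `converged`.
#' @export
register_affine <- function(moving, fixed, moving_mask = NULL,
                            fixed_mask = NULL, dof = 12,
                            levels = c(4, 2, 1), maxit = 800) {
  stopifnot(dof %in% c(6, 12))
  if (is.null(fixed_mask))
    fixed_mask <- array(fixed$intensities > 0.02 * max(fixed$intensities),
                        dim(fixed$intensities))
  if (is.null(moving_mask))
    moving_mask <- array(moving$intensities > 0.02 * max(moving$intensities),
                         dim(moving$intensities))
  center <- mask_centroid(fixed_mask, fixed$world)
  t0 <- center - mask_centroid(moving_mask, moving$world)
  npar <- if (dof == 6) 6L else 12L
  p <- c(t0, rep(0, npar - 3))
  parscale <- c(rep(5, 3), rep(0.05, 3), rep(0.05, 3), rep(0.03, 3))[1:npar]
  conv <- 0L
  for (f in levels) {
    vs <- fixed$voxel_size * f
    fx <- pyramid_level(fixed, f)
    mv <- pyramid_level(moving, f)
    fm <- if (f > 1) resample_mask(fixed_mask, fixed, vs) else fixed_mask
    for (pass in 1:2) {
      o <- optim(p, ncc_cost_fun, dof = dof, center = center, fixed = fx,
                 moving = mv, mask = fm, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10,
                                parscale = parscale / pass))
      p <- o$par
      conv <- o$convergence
    }
  }
  par <- c(rep(0, 9), rep(0, 3))
  par[seq_along(p)] <- p
  out <- affine_from_params(par[1:3], par[4:6] * 180 / pi, exp(par[7:9]),
                            par[10:12], center)
  attr(out, "cost") <- o$value
  attr(out, "converged") <- conv == 0L
  attr(out, "params") <- p
  if (conv != 0L)
    warning("affine registration reached the iteration cap; ",
            "returning best-so-far transform")
  out
}

#' Nonlinear registration (demons-style) initialized by an affine
#'
#' Multi-resolution demons on the whole-head images: intensity-difference
#' forces along the warped-image gradient, Gaussian-smoothed update (fluid
#' regularization) and field (diffusion regularization). The result is a
#' dense per-voxel displacement field on the fixed grid, composed with the
#' affine initialization at application time.
#'
#' @param moving,fixed `synthetic_image`s (whole head drives the match).
#' @param init `affine_transform` initialization (moving -> fixed).
#' @param iters demons iterations per pyramid level (coarse to fine).
#' @param levels pyramid voxel-size factors.
#' @param sigma_fluid_vox,sigma_diff_vox Gaussian sigmas (voxels) for the
#'   update and field smoothing.
#' @return `deformation_field` on the fixed grid.
#' @export
register_nonlinear <- function(moving, fixed, init = affine_transform(),
                               iters = c(60, 60, 30), levels = c(4, 2, 1),
                               sigma_fluid_vox = 1.2, sigma_diff_vox = 0.6) {
  if (!all(is.finite(moving$intensities)) || !all(is.finite(fixed$intensities)))
    stop("non-finite intensities", call. = FALSE)
  u <- NULL
  for (li in seq_along(levels)) {
    f <- levels[li]
    fx <- pyramid_level(fixed, f)
    mv <- pyramid_level(moving, f)
    P <- solve(mv$world) %*% solve(init$matrix)
    d <- dim3(fx$intensities)
    if (is.null(u)) {
      u <- array(0, c(d, 3))
    } else {
      u <- upsample_field(u, oldw = oldw, newdims = d, neww = fx$world)
    }
    u <- cpp_demons(fx$intensities, d, mv$intensities, dim3(mv$intensities),
                    P, fx$world, u, fx$voxel_size, iters[li],
                    sigma_fluid_vox, sigma_diff_vox,
                    cap_mm = max(fx$voxel_size))
    oldw <- fx$world
  }
  if (!all(is.finite(u))) stop("non-finite deformation field", call. = FALSE)
  deformation_field(u, init, fixed)
}

# trilinear upsampling of a displacement field between pyramid levels
upsample_field <- function(u, oldw, newdims, neww) {
  d_old <- dim(u)[1:3]
  P <- solve(oldw)
  out <- array(0, c(newdims, 3))
  for (c in 1:3)
    out[, , , c] <- cpp_resample(u[, , , c], as.integer(d_old), P, neww,
                                 NULL, as.integer(newdims), FALSE, 0)
  out
}

#' Dice similarity coefficients per tissue group
#'
#' DSC = 2|X∩Y| / (|X| + |Y|) over voxel sets, computed per `dsc_group`
#' (labels sharing a group, e.g. deep gray nuclei with gray matter, are
#' pooled). Groups absent from both models are reported as `NA`.
#'
#' @param a,b voxel models on the same grid.
#' @return data.frame `group`, `dsc`, `n_a`, `n_b`.
#' @export
dice <- function(a, b) {
  if (!same_grid(a, b)) stop_grid_mismatch()
  groups <- unique(c(a$tissue$dsc_group, b$tissue$dsc_group))
  groups <- setdiff(groups, "air")
  res <- lapply(groups, function(g) {
    la <- a$tissue$label[a$tissue$dsc_group == g]
    lb_ <- b$tissue$label[b$tissue$dsc_group == g]
    X <- a$labels %in% la
    Y <- b$labels %in% lb_
    nx <- sum(X)
    ny <- sum(Y)
    dsc <- if (nx + ny == 0) NA_real_ else 2 * sum(X & Y) / (nx + ny)
    data.frame(group = g, dsc = dsc, n_a = nx, n_b = ny)
  })
  do.call(rbind, res)
}

#' Conductivity/density difference maps and head masses
#'
#' Voxelwise absolute differences of conductivity (S/m) and density (kg/m3)
#' between two models on the same grid; means over the mask where at least
#' one model has tissue (`mask = "union"`, default) or both do
#' (`"intersection"`); and each model's head mass (sum of density times
#' voxel volume).
#'
#' @param a,b voxel models on the same grid.
#' @param mask `"union"` or `"intersection"`.
#' @return list with `conductivity_diff`, `density_diff` (arrays), `mask`,
#'   `mean_conductivity_diff`, `mean_density_diff`, `head_mass_kg` (named).
#' @export
property_difference_maps <- function(a, b, mask = c("union", "intersection")) {
  if (!same_grid(a, b)) stop_grid_mismatch()
  mask <- match.arg(mask)
  sa <- tissue_lookup(a, "conductivity_S_per_m")
  sb <- tissue_lookup(b, "conductivity_S_per_m")
  ra <- tissue_lookup(a, "density_kg_per_m3")
  rb <- tissue_lookup(b, "density_kg_per_m3")
  m <- if (mask == "union") a$labels > 0 | b$labels > 0
       else a$labels > 0 & b$labels > 0
  voxvol <- prod(a$voxel_size) * 1e-9
  list(conductivity_diff = abs(sa - sb),
       density_diff = abs(ra - rb),
       mask = m,
       mean_conductivity_diff = mean(abs(sa - sb)[m]),
       mean_density_diff = mean(abs(ra - rb)[m]),
       head_mass_kg = c(a = sum(ra) * voxvol, b = sum(rb) * voxvol))
}
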