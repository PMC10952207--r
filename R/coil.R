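# Quasi-static surrogate for the per-channel RF fields of a cylindrical
# loop array. Each element is a rectangular current loop on the coil
# cylinder; B comes from a Biot-Savart line integral, E from the quasi-static
# -i*omega*A of the same loop, and both are attenuated inside tissue by
# exp(-d / delta) with d the in-tissue path length from the element center
# and delta the voxel-local skin depth. No claim of full-wave fidelity: the
# surrogate preserves linear superposition, tissue-dependent loss and the
# qualitative center-brightening / periphery-loading structure.

MU0 <- 4e-7 * pi

#' Coil model for an n-channel cylindrical loop array
#'
#' @param n_channels number of loop elements (default 8).
#' @param diameter_mm coil cylinder diameter (default 300).
#' @param elem_width_mm,elem_length_mm element lateral (azimuthal arc) and
#'   longitudinal size (defaults 110 x 220).
#' @param azimuths_rad element center azimuths; default evenly spaced.
#' @param frequency_hz Larmor frequency (default 297.2e6, 7 T protons).
#' @param n_seg_side polyline segments per loop side.
#' @return object of class `coil_model`.
#' @export
coil_model <- function(n_channels = 8L, diameter_mm = 300,
                       elem_width_mm = 110, elem_length_mm = 220,
                       azimuths_rad = NULL, frequency_hz = 297.2e6,
                       n_seg_side = 12L) {
  stopifnot(n_channels >= 1, diameter_mm > 0, frequency_hz > 0)
  if (is.null(azimuths_rad))
    azimuths_rad <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  if (anyDuplicated(round(azimuths_rad, 9)))
    stop("element azimuths must be distinct", call. = FALSE)
  structure(list(n_channels = as.integer(n_channels),
                 radius_mm = diameter_mm / 2,
                 elem_width_mm = elem_width_mm,
                 elem_length_mm = elem_length_mm,
                 azimuths_rad = azimuths_rad,
                 frequency_hz = frequency_hz,
                 n_seg_side = as.integer(n_seg_side)),
            class = "coil_model")
}

# rectangular loop vertices (mm) on the coil cylinder for channel c
loop_polyline <- function(coil, channel) {
  r <- coil$radius_mm
  az <- coil$azimuths_rad[channel]
  half_phi <- (coil$elem_width_mm / 2) / r
  half_z <- coil$elem_length_mm / 2
  n <- coil$n_seg_side
  phis <- seq(az - half_phi, az + half_phi, length.out = n + 1)
  top <- cbind(r * cos(phis), r * sin(phis), half_z)
  bottom <- cbind(r * cos(rev(phis)), r * sin(rev(phis)), -half_z)
  zs <- seq(half_z, -half_z, length.out = n + 1)[-c(1, n + 1)]
  right <- cbind(r * cos(az + half_phi), r * sin(az + half_phi), zs)
  left <- cbind(r * cos(az - half_phi), r * sin(az - half_phi), rev(zs))
  rbind(top, right, bottom, left)
}

skin_depth_mm <- function(sigma, frequency_hz) {
  out <- rep(Inf, length(sigma))
  pos <- sigma > 0
  out[pos] <- sqrt(2 / (2 * pi * frequency_hz * MU0 * sigma[pos])) * 1000
  out
}

#' Simulate per-channel complex E and B1+ fields
#'
#' One single-active-channel excitation per element, each normalized so the
#' power deposited in the model equals `eta` x 1 W ("conducted power" is
#' defined as deposited power; the surrogate has no radiation or coil-loss
#' channel). B1+ is `(Bx + i By) / 2` with the static field along +z.
#'
#' @param coil [coil_model()].
#' @param model `voxel_model`, positioned inside the coil cylinder.
#' @param eta coil efficiency (deposited / conducted power), default 1.
#' @param attenuation apply the skin-depth attenuation (default TRUE).
#' @param step_mm ray-marching step for the in-tissue path length.
#' @return object of class `channel_field_set`: complex `E` (V/m, dims
#'   `c(grid, 3, n_channels)`), complex `b1p` (uT, dims
#'   `c(grid, n_channels)`), `power_per_channel_W`, geometry, `coil`.
#' @export
simulate_channel_fields <- function(coil, model, eta = 1,
                                    attenuation = TRUE, step_mm = NULL) {
  d <- vm_dims(model)
  nvox <- prod(d)
  co <- voxel_coords(d, model$world)
  tiss <- as.vector(model$labels) != 0L
  if (!any(tiss)) stop("cannot normalize: model contains no tissue",
                       call. = FALSE)
  rad <- sqrt(co[, 1]^2 + co[, 2]^2)
  if (max(rad[tiss]) > coil$radius_mm)
    stop("model extends outside the coil cylinder", call. = FALSE)
  if (is.null(step_mm)) step_mm <- min(model$voxel_size)
  sigma <- as.vector(tissue_lookup(model, "conductivity_S_per_m"))
  delta <- skin_depth_mm(sigma, coil$frequency_hz)
  omega <- 2 * pi * coil$frequency_hz
  voxvol <- prod(model$voxel_size) * 1e-9
  W2V <- solve(model$world)
  nch <- coil$n_channels
  E <- array(complex(real = 0), c(d, 3, nch))
  b1p <- array(complex(real = 0), c(d, nch))
  pw <- numeric(nch)
  for (c in seq_len(nch)) {
    lp <- loop_polyline(coil, c)
    ba <- cpp_loop_fields(co / 1000, lp / 1000, rmin = 2e-3)
    fac <- rep(1, nvox)
    if (attenuation) {
      src <- c(coil$radius_mm * cos(coil$azimuths_rad[c]),
               coil$radius_mm * sin(coil$azimuths_rad[c]), 0)
      depth <- as.vector(cpp_ray_depth(model$labels, d, model$world, W2V,
                                       src, step_mm))
      fac[tiss] <- exp(-depth[tiss] / delta[tiss])
    }
    Ec <- complex(imaginary = -omega) * ba$A * fac   # V/m, peak phasor
    Bc <- ba$B * fac                                  # Tesla
    p <- sum(sigma * (abs(Ec[, 1])^2 + abs(Ec[, 2])^2 + abs(Ec[, 3])^2)) /
      2 * voxvol
    if (p <= 0) stop("cannot normalize: zero deposited power", call. = FALSE)
    s <- sqrt(eta / p)
    E[, , , , c] <- array(Ec * s, c(d, 3))
    b1p[, , , c] <- array((Bc[, 1] + 1i * Bc[, 2]) / 2 * s * 1e6, d)
    pw[c] <- eta
  }
  structure(list(E = E, b1p = b1p, power_per_channel_W = pw, coil = coil,
                 voxel_size = model$voxel_size, world = model$world,
                 normalized = TRUE), class = "channel_field_set")
}

#' @export
print.channel_field_set <- function(x, ...) {
  d <- dim(x$b1p)
  cat(sprintf("<channel_field_set> %d channels on %d x %d x %d grid, 1 W/channel\n",
              d[4], d[1], d[2], d[3]))
  invisible(x)
}

#' Combine per-channel fields under a complex shim
#'
#' Strict linear superposition: `E_tot = sum_c w_c E_c`,
#' `B1+_tot = sum_c w_c B1+_c`.
#'
#' @param fields `channel_field_set`.
#' @param shim complex weight vector, length `n_channels` (a column of a
#'   [generate_shims()] matrix works).
#' @return list with complex arrays `E` (dims `c(grid, 3)`) and `b1p`.
#' @export
combine_fields <- function(fields, shim) {
  shim <- as.complex(shim)
  nch <- dim(fields$b1p)[4]
  if (length(shim) != nch)
    stop("shim length ", length(shim), " != ", nch, " channels", call. = FALSE)
  d <- dim(fields$b1p)[1:3]
  E <- matrix(fields$E, ncol = nch) %*% shim
  b1 <- matrix(fields$b1p, ncol = nch) %*% shim
  list(E = array(E, c(d, 3)), b1p = array(b1, d))
}

#' Voxelwise |E|^2 difference between two models under the same shim
#'
#' @param fieldsA,fieldsB `channel_field_set`s on the same grid.
#' @param modelA,modelB the corresponding models (for the comparison mask).
#' @param shim complex weight vector applied to both.
#' @param mask `"union"` (voxels with tissue in at least one model, default)
#'   or `"intersection"`.
#' @return list with `diff` (array of absolute |E|^2 differences, (V/m)^2),
#'   `mean` over the mask, and `mask`.
#' @export
efield_sq_difference <- function(fieldsA, fieldsB, modelA, modelB, shim,
                                 mask = c("union", "intersection")) {
  mask <- match.arg(mask)
  if (!identical(dim(fieldsA$b1p), dim(fieldsB$b1p))) stop_grid_mismatch()
  if (!same_grid(modelA, modelB)) stop_grid_mismatch()
  ea <- combine_fields(fieldsA, shim)$E
  eb <- combine_fields(fieldsB, shim)$E
  d <- dim(ea)[1:3]
  e2a <- array(rowSums(matrix(Mod(ea)^2, ncol = 3)), d)
  e2b <- array(rowSums(matrix(Mod(eb)^2, ncol = 3)), d)
  m <- if (mask == "union") modelA$labels > 0 | modelB$labels > 0
       else modelA$labels > 0 & modelB$labels > 0
  dmap <- abs(e2a - e2b)
  list(diff = dmap, mean = mean(dmap[m]), mask = m)
}
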