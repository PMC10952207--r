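# Random shim generation, per-region Q-matrix construction, exact per-shim
# maximum 10 g SAR, and VOP compression with a bounded overestimation.
#
# The Q matrix of a 10 g region R satisfies w^H Q_R w = 10 g-averaged SAR of
# region R under the shim w, for fields normalized to 1 W per channel. This
# is the core pTx trick: build the (expensive) region set once, evaluate any
# shim with an 8x8 quadratic form.

#' Generate random RF shim sets
#'
#' Per-channel magnitudes ~ Uniform(0, 1) and phases ~ Uniform(0, 2*pi),
#' then each shim is globally rescaled so the total conducted power
#' `sum |w_c|^2 x 1 W` equals `total_power_W` (5 W by default for the 8
#' channel pTx assessment). Seeded and reproducible.
#'
#' @param n number of shim sets.
#' @param n_channels channels per shim (default 8).
#' @param total_power_W total conducted power after rescaling (default 5).
#' @param seed RNG seed.
#' @return complex matrix `n_channels x n` of class `shim_set` with
#'   attribute `total_power_W`.
#' @export
generate_shims <- function(n, n_channels = 8L, total_power_W = 5, seed = 1L) {
  stopifnot(n >= 1, total_power_W > 0)
  w <- with_seed(seed, {
    mag <- matrix(runif(n * n_channels), n_channels, n)
    ph <- matrix(runif(n * n_channels, 0, 2 * pi), n_channels, n)
    w <- mag * exp(1i * ph)
    p <- colSums(Mod(w)^2)
    while (any(p == 0)) {  # probability-zero guard: redraw degenerate shims
      bad <- which(p == 0)
      w[, bad] <- matrix(runif(length(bad) * n_channels), n_channels) *
        exp(1i * matrix(runif(length(bad) * n_channels, 0, 2 * pi), n_channels))
      p <- colSums(Mod(w)^2)
    }
    sweep(w, 2, sqrt(total_power_W / p), "*")
  })
  structure(w, class = c("shim_set", class(w)), total_power_W = total_power_W)
}

#' Write / read shim sets as CSV (`shim_id, channel, magnitude, phase_rad`)
#' @param shims `shim_set` matrix; @param path CSV path.
#' @export
write_shims <- function(shims, path) {
  df <- data.frame(shim_id = rep(seq_len(ncol(shims)), each = nrow(shims)),
                   channel = rep(seq_len(nrow(shims)), ncol(shims)),
                   magnitude = as.vector(Mod(shims)),
                   phase_rad = as.vector(Arg(shims)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shims
#' @export
read_shims <- function(path) {
  df <- read.csv(path)
  nch <- max(df$channel)
  n <- max(df$shim_id)
  w <- matrix(complex(modulus = df$magnitude, argument = df$phase_rad),
              nch, n)
  structure(w, class = c("shim_set", class(w)),
            total_power_W = sum(Mod(w[, 1])^2))
}

#' Build per-region 10 g SAR Q matrices
#'
#' Regions are the voxel-centered cubes found by the mass-based growth rule
#' of [sar_10g()] (one per tissue voxel whose cube stays within `max_side`).
#' Each region's Hermitian `n_channels x n_channels` matrix accumulates
#' `f_v sigma_v (E_c'(v) . conj(E_c(v))) dV / (2 m_R)` with `f_v` the
#' fractional outer-layer weight, guaranteeing `w^H Q_R w` equals the 10 g
#' SAR of the region under shim `w`. Regions are stored sorted by
#' descending largest eigenvalue (worst-case unit-power SAR).
#'
#' @param fields normalized `channel_field_set`.
#' @param model voxel model on the same grid.
#' @param target_mass_g,max_side cube-growth settings (10 g, 15 voxels).
#' @param mask eligible region centers; default [head_mask()].
#' @param thin keep only regions whose largest eigenvalue is at least
#'   `thin` times the global maximum (0 = keep all; must be 0 for oracle
#'   comparisons).
#' @return object of class `qmatrix_set`.
#' @export
build_q_matrices <- function(fields, model, target_mass_g = 10,
                             max_side = 15L, mask = head_mask(model),
                             thin = 0) {
  d <- vm_dims(model)
  stopifnot(identical(dim(fields$b1p)[1:3], d))
  rho <- tissue_lookup(model, "density_kg_per_m3")
  voxvol <- prod(model$voxel_size) * 1e-9
  mass <- rho * voxvol
  target_kg <- target_mass_g / 1000
  grow <- cpp_sar10g(mass, array(0, d), d, mask, target_kg,
                     as.integer(max_side))
  centers <- which(grow$valid) - 1L
  if (!length(centers)) stop("no valid 10 g regions", call. = FALSE)
  sigma <- tissue_lookup(model, "conductivity_S_per_m")
  nch <- dim(fields$b1p)[4]
  pack <- cpp_qpack(fields$E, d, nch, sigma, centers,
                    grow$side[grow$valid], grow$frac[grow$valid],
                    voxvol, target_kg)
  eig <- cpp_pack_eigmax(pack, nch)
  o <- order(eig, decreasing = TRUE)
  qs <- structure(list(pack = pack[, o, drop = FALSE], eigmax = eig[o],
                       centers = centers[o], side = grow$side[grow$valid][o],
                       frac = grow$frac[grow$valid][o],
                       n_channels = nch, dims = d,
                       region_mass_kg = target_kg),
                  class = "qmatrix_set")
  if (thin > 0) {
    keep <- qs$eigmax >= thin * qs$eigmax[1]
    qs$pack <- qs$pack[, keep, drop = FALSE]
    qs$eigmax <- qs$eigmax[keep]
    qs$centers <- qs$centers[keep]
    qs$side <- qs$side[keep]
    qs$frac <- qs$frac[keep]
  }
  qs
}

#' @export
print.qmatrix_set <- function(x, ...) {
  cat(sprintf("<qmatrix_set> %d regions x %d channels, worst-case eig %.4g W/kg\n",
              ncol(x$pack), x$n_channels, x$eigmax[1]))
  invisible(x)
}

#' Materialize one region's Hermitian Q matrix
#' @param qset `qmatrix_set`; @param i region index (1-based, sorted order).
#' @export
q_matrix <- function(qset, i) {
  nch <- qset$n_channels
  Q <- matrix(complex(real = 0), nch, nch)
  q <- 1
  col <- qset$pack[, i]
  for (c2 in seq_len(nch))
    for (c1 in seq_len(c2)) {
      Q[c1, c2] <- col[q]
      Q[c2, c1] <- Conj(col[q])
      q <- q + 1
    }
  diag(Q) <- Re(diag(Q))
  Q
}

#' Exact per-shim maximum 10 g SAR over all Q regions
#'
#' `max_R Re(w^H Q_R w)` for each shim. With `prune = TRUE` (default)
#' regions are scanned in descending worst-case-eigenvalue order and the
#' scan stops once `eigmax x |w|^2` can no longer beat the current best;
#' this is exact, not approximate.
#'
#' @param qset `qmatrix_set`; @param shims `shim_set` matrix.
#' @param prune use the (exact) eigenvalue bound to stop early.
#' @return numeric vector (W/kg) with attribute `which` (argmax region).
#' @export
max10g_exact <- function(qset, shims, prune = TRUE) {
  if (!ncol(qset$pack)) stop("empty region set", call. = FALSE)
  if (nrow(shims) != qset$n_channels)
    stop("shim/Q channel mismatch", call. = FALSE)
  r <- cpp_eval_exact(qset$pack, qset$n_channels, qset$eigmax,
                      as.matrix(shims), prune)
  structure(r$max, which = r$which + 1L)
}

#' Compress Q matrices to virtual observation points (VOPs)
#'
#' Greedy pass over regions sorted by descending spectral norm: a region
#' joins an existing VOP core `V` when `V + Z - Q` is positive
#' semi-definite, else it seeds a new VOP. Two overestimation terms are
#' available: `"proportional"` (default) uses `Z = lambda V`, which
#' guarantees the per-shim relative overestimation never exceeds `lambda`;
#' `"scaled_identity"` uses the global `Z = lambda ||Q||_max I`, which
#' bounds the absolute overestimation by `lambda ||Q||_max |w|^2` but not
#' the per-shim relative error (see the methods vignette).
#'
#' @param qset `qmatrix_set` (thinning must be off for oracle checks).
#' @param lambda overestimation margin (default 0.05, i.e. 5%).
#' @param z_mode `"proportional"` or `"scaled_identity"`.
#' @return object of class `vop_set`.
#' @export
compress_vop <- function(qset, lambda = 0.05,
                         z_mode = c("proportional", "scaled_identity")) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  z_mode <- match.arg(z_mode)
  mode <- if (z_mode == "proportional") 1L else 2L
  r <- cpp_vop_compress(qset$pack, qset$n_channels, qset$eigmax, lambda, mode)
  structure(list(cores = r$cores + 1L,
                 pack = qset$pack[, r$cores + 1L, drop = FALSE],
                 assign = r$assign, n_vop = r$n_vop,
                 n_source = ncol(qset$pack), lambda = lambda,
                 z_mode = z_mode, normmax = qset$eigmax[1],
                 n_channels = qset$n_channels),
            class = "vop_set")
}

#' @export
print.vop_set <- function(x, ...) {
  cat(sprintf("<vop_set> %d VOPs from %d regions (lambda = %g, %s Z)\n",
              x$n_vop, x$n_source, x$lambda, x$z_mode))
  invisible(x)
}

#' Per-shim VOP upper bound on maximum 10 g SAR
#'
#' `max_V Re(w^H (V + Z) w)`; never underestimates [max10g_exact()] on the
#' source region set.
#'
#' @param vops `vop_set`; @param shims `shim_set` matrix.
#' @return numeric vector (W/kg).
#' @export
max10g_vop <- function(vops, shims) {
  if (!vops$n_vop) stop("empty VOP set", call. = FALSE)
  if (nrow(shims) != vops$n_channels)
    stop("shim/VOP channel mismatch", call. = FALSE)
  mode <- if (vops$z_mode == "proportional") 1L else 2L
  cpp_vop_eval(vops$pack, vops$n_channels,
               seq_len(vops$n_vop) - 1L, vops$lambda, mode,
               vops$normmax, as.matrix(shims))
}
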