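# Synthetic multi-tissue head phantoms of controllable morphometry.
# A phantom is a nest of confocal-ish ellipsoid shells (skin, fat, skull,
# CSF, gray matter, white matter from the outside in), a distinct cerebellum
# lobe, CSF ventricles, an optional muscle neck slab, and a low-order
# azimuthal surface modulation that gives each "subject" an individual
# (but deterministic) head shape.

#' Phantom geometry specification
#'
#' All lengths in mm. The subject's anatomy is the reference nest of shells
#' anisotropically scaled by `scale`, rotated by `rotation_deg` (xyz Euler),
#' with cerebellum/ventricles shifted by `internal_offset`.
#'
#' @param semi_axes outer (skin surface) semi-axes, mm (x = left-right,
#'   y = anterior-posterior, z = inferior-superior).
#' @param thickness named shell thicknesses, mm: `skin`, `fat`, `skull`,
#'   `csf`, `gm` (white matter fills the remainder).
#' @param cereb_center,cereb_semi cerebellum ellipsoid (anatomy frame, mm).
#' @param vent_center,vent_semi lateral-ventricle ellipsoid; mirrored in x.
#' @param internal_offset translation applied to cerebellum + ventricles.
#' @param scale,rotation_deg subject morphometry relative to the reference.
#' @param neck_slab attach a muscle/skin neck slab below the head.
#' @param surf_amp amplitude of the low-order surface modulation (fraction).
#' @param seed integer; fixes the modulation phases (deterministic).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes = c(75, 90, 100),
                         thickness = c(skin = 4, fat = 3, skull = 7,
                                       csf = 3, gm = 5),
                         cereb_center = c(0, -40, -55),
                         cereb_semi = c(42, 32, 26),
                         vent_center = c(14, 8, 8),
                         vent_semi = c(9, 22, 11),
                         internal_offset = c(0, 0, 0),
                         scale = c(1, 1, 1),
                         rotation_deg = c(0, 0, 0),
                         neck_slab = TRUE,
                         surf_amp = 0.02,
                         seed = 1L) {
  th <- c(skin = 0, fat = 0, skull = 0, csf = 0, gm = 0)
  th[names(thickness)] <- thickness
  if (any(th < 0)) stop("shell thicknesses must be >= 0", call. = FALSE)
  if (any(semi_axes <= sum(th)))
    stop("invalid phantom spec: shell thicknesses exceed the semi-axes",
         call. = FALSE)
  structure(list(semi_axes = semi_axes, thickness = th,
                 cereb_center = cereb_center, cereb_semi = cereb_semi,
                 vent_center = vent_center, vent_semi = vent_semi,
                 internal_offset = internal_offset, scale = rep_len(scale, 3),
                 rotation_deg = rep_len(rotation_deg, 3),
                 neck_slab = isTRUE(neck_slab), surf_amp = surf_amp,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Built-in phantom specifications
#'
#' One reference head plus two target "subjects" that differ from it by
#' anisotropic scaling (8-10% per axis), a global rotation (< 10 degrees),
#' shifted internal structures and slightly different shell thicknesses, so
#' rigid-only alignment leaves a visible morphometric mismatch.
#'
#' @return named list of `phantom_spec`: `reference`, `subject1`, `subject2`.
#' @export
builtin_phantom_specs <- function() {
  list(
    reference = phantom_spec(seed = 11L),
    subject1 = phantom_spec(
      thickness = c(skin = 4, fat = 4, skull = 8, csf = 3, gm = 5),
      scale = c(0.90, 1.10, 0.96), rotation_deg = c(4, -3, 7),
      internal_offset = c(3, -6, 4), seed = 12L),
    subject2 = phantom_spec(
      thickness = c(skin = 5, fat = 3, skull = 7, csf = 4, gm = 5),
      scale = c(1.08, 0.92, 1.05), rotation_deg = c(-5, 2, -6),
      internal_offset = c(-4, 5, -5), seed = 13L))
}

euler_xyz <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Generate a labeled head phantom
#'
#' Deterministic given the spec: the same spec yields a bit-identical label
#' grid. The grid is centered on the world origin (the coil isocenter).
#'
#' @param spec [phantom_spec()].
#' @param table tissue table; needs the labels skin/fat/muscle/skull/csf/
#'   gray_matter/white_matter/cerebellum.
#' @param voxel_size mm, scalar or length 3.
#' @param margin_mm air margin around the head.
#' @return `voxel_model`.
#' @export
make_phantom <- function(spec, table = default_tissue_table(), voxel_size = 2,
                         margin_mm = 8) {
  stopifnot(inherits(spec, "phantom_spec"), all(voxel_size > 0))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  lb <- function(nm) {
    i <- match(nm, table$name)
    if (is.na(i)) stop("tissue table lacks a '", nm, "' row", call. = FALSE)
    table$label[i]
  }
  R <- euler_xyz(spec$rotation_deg)
  S <- spec$scale
  a0 <- spec$semi_axes * (1 + abs(spec$surf_amp))
  ext <- abs(R) %*% (S * a0) + margin_mm
  zlo <- ext[3] + if (spec$neck_slab) 45 else 0
  nd <- c(2 * ceiling(ext[1] / voxel_size[1]) + 1,
          2 * ceiling(ext[2] / voxel_size[2]) + 1,
          ceiling((zlo + ext[3]) / voxel_size[3]) + 1)
  origin <- c(-(nd[1] - 1) / 2 * voxel_size[1],
              -(nd[2] - 1) / 2 * voxel_size[2], -zlo)
  world <- make_world(voxel_size, origin)
  co <- voxel_coords(nd, world)
  # anatomy frame: undo rotation then scaling
  q <- co %*% R %*% diag(1 / S, 3)      # (R^T x)_i / S_i, row-wise
  # low-order surface modulation, seeded phases
  ph <- with_seed(spec$seed, runif(3, 0, 2 * pi))
  rr <- sqrt(rowSums(q^2))
  theta <- atan2(q[, 2], q[, 1])
  phi <- acos(ifelse(rr > 0, q[, 3] / rr, 1))
  mod <- 1 + spec$surf_amp * sin(3 * theta + ph[1]) * cos(2 * phi + ph[2])
  e_in <- function(semi) {
    rowSums(sweep(q, 2, semi, "/")^2) <= mod^2
  }
  th <- spec$thickness
  b <- list(spec$semi_axes)
  for (t in th) b <- c(b, list(b[[length(b)]] - t))
  if (any(unlist(b) <= 0))
    stop("invalid phantom spec: shells exceed semi-axes", call. = FALSE)
  lab <- integer(nrow(co))
  shells <- c(lb("skin"), lb("fat"), lb("skull"), lb("csf"),
              lb("gray_matter"), lb("white_matter"))
  for (i in seq_along(shells)) lab[e_in(b[[i]])] <- shells[i]
  # cerebellum: replaces brain tissue inside its lobe (semi <= 0 disables)
  if (all(spec$cereb_semi > 0)) {
    brain <- e_in(b[[5]])
    qc <- sweep(q, 2, spec$cereb_center + spec$internal_offset)
    cereb <- brain & rowSums(sweep(qc, 2, spec$cereb_semi, "/")^2) <= 1
    lab[cereb] <- lb("cerebellum")
  }
  # lateral ventricles (CSF), mirrored in x (semi <= 0 disables)
  if (all(spec$vent_semi > 0)) {
    wm <- lab == lb("white_matter")
    for (sx in c(-1, 1)) {
      vc <- spec$vent_center * c(sx, 1, 1) + spec$internal_offset
      qv <- sweep(q, 2, vc)
      vent <- wm & rowSums(sweep(qv, 2, spec$vent_semi, "/")^2) <= 1
      lab[vent] <- lb("csf")
    }
  }
  neck_plane_z <- -Inf
  if (spec$neck_slab) {
    neck_plane_z <- -0.55 * spec$semi_axes[3] * S[3]
    in_neck_z <- co[, 3] < neck_plane_z
    r_neck <- sqrt((co[, 1] / (0.55 * spec$semi_axes[1] * S[1]))^2 +
                   (co[, 2] / (0.60 * spec$semi_axes[2] * S[2]))^2)
    free <- lab == 0 & in_neck_z
    lab[free & r_neck <= 1] <- lb("muscle")
    lab[free & r_neck > 1 & r_neck <= 1.12] <- lb("skin")
  }
  dim(lab) <- nd
  voxel_model(lab, voxel_size, table, world = world,
              meta = list(neck_plane_z = neck_plane_z, spec = spec))
}

#' Synthesize a T1-weighted image from a labeled model
#'
#' Each voxel takes its tissue's `t1w_mean` plus Gaussian noise. With
#' `noise_sd = NULL` the per-tissue `t1w_sd` column is used; a scalar
#' `noise_sd` applies globally (0 gives a piecewise-constant image). Air has
#' mean 0.
#'
#' @param model voxel model (every label needs a `t1w_mean`).
#' @param noise_sd scalar intensity sd, or NULL for per-tissue `t1w_sd`.
#' @param seed RNG seed (reproducible).
#' @return `synthetic_image`.
#' @export
synthesize_t1 <- function(model, noise_sd = NULL, seed = 1L) {
  mu <- tissue_lookup(model, "t1w_mean")
  if (anyNA(mu)) stop("tissue table lacks t1w_mean for some labels")
  sdv <- if (is.null(noise_sd)) tissue_lookup(model, "t1w_sd")
         else array(noise_sd, dim(mu))
  img <- with_seed(seed, mu + rnorm(length(mu), 0, as.vector(sdv)))
  dim(img) <- dim(mu)
  synthetic_image(img, model)
}

#' Segmentation perturbation operations
#'
#' Constructors for the operations understood by [perturb_segmentation()]:
#' `boundary_flip(p)` relabels tissue-tissue interface voxels to a
#' neighboring tissue with probability `p`; `split_tissue(label, new_label,
#' depth)` relabels the eroded core of a tissue (e.g. skull into cancellous
#' bone inside a cortical rim); `insert_layer(from, at, new_label,
#' thickness)` relabels `from` voxels within `thickness` voxels of `at`
#' (e.g. a dura layer carved from CSF at the skull interface).
#'
#' @param p flip probability in `[0, 1]`.
#' @return op object consumed by [perturb_segmentation()].
#' @export
boundary_flip <- function(p) {
  stopifnot(p >= 0, p <= 1)
  structure(list(p = p), class = c("pseg_flip", "pseg_op"))
}

#' @rdname boundary_flip
#' @param label,new_label tissue names (as in the tissue table).
#' @param depth erosion depth in voxels for the core.
#' @export
split_tissue <- function(label, new_label, depth = 1L) {
  structure(list(label = label, new_label = new_label, depth = as.integer(depth)),
            class = c("pseg_split", "pseg_op"))
}

#' @rdname boundary_flip
#' @param from,at interface tissue names: voxels of `from` adjacent to `at`.
#' @param thickness layer thickness in voxels.
#' @export
insert_layer <- function(from, at, new_label, thickness = 1L) {
  structure(list(from = from, at = at, new_label = new_label,
                 thickness = as.integer(thickness)),
            class = c("pseg_insert", "pseg_op"))
}

#' Perturb a model's segmentation without changing its morphometry
#'
#' Applies a list of [boundary_flip()] / [split_tissue()] / [insert_layer()]
#' operations in order. The grid and geometry are untouched; only labels
#' change, and nonzero support is conserved by every operation (air is never
#' created or consumed).
#'
#' @param model voxel model.
#' @param ops list of op objects.
#' @param seed RNG seed for `boundary_flip`.
#' @return perturbed `voxel_model`.
#' @export
perturb_segmentation <- function(model, ops, seed = 1L) {
  lab <- model$labels
  tt <- model$tissue
  name2lab <- function(nm) {
    i <- match(nm, tt$name)
    if (is.na(i)) stop("unknown tissue '", nm, "'", call. = FALSE)
    tt$label[i]
  }
  d <- dim3(lab)
  rng_seed <- seed
  for (op in ops) {
    if (inherits(op, "pseg_flip")) {
      if (op$p > 0) {
        lab <- with_seed(rng_seed, flip_interface(lab, d, op$p))
        rng_seed <- rng_seed + 1L
      }
    } else if (inherits(op, "pseg_split")) {
      old <- name2lab(op$label)
      new <- name2lab(op$new_label)
      if (!any(lab == old)) stop("split_tissue: no '", op$label,
                                 "' voxels present", call. = FALSE)
      core <- cpp_box_morph(lab == old, d, op$depth, FALSE)
      lab[core & lab == old] <- new
    } else if (inherits(op, "pseg_insert")) {
      from <- name2lab(op$from)
      at <- name2lab(op$at)
      if (!any(lab == from) || !any(lab == at))
        stop("insert_layer: interface ", op$from, "/", op$at,
             " not present", call. = FALSE)
      near <- cpp_box_morph(lab == at, d, op$thickness, TRUE)
      sel <- near & lab == from
      if (!any(sel))
        stop("insert_layer: tissues '", op$from, "' and '", op$at,
             "' share no interface", call. = FALSE)
      lab[sel] <- name2lab(op$new_label)
    } else stop("unknown perturbation op", call. = FALSE)
  }
  voxel_model(lab, model$voxel_size, tt, world = model$world, meta = model$meta)
}

# Relabel tissue-tissue interface voxels to a random differing neighbor
# tissue with probability p (6-neighborhood; air uninvolved).
flip_interface <- function(lab, d, p) {
  shift <- function(ax, s) {
    out <- array(0L, d)
    if (ax == 1) {
      if (s > 0) out[2:d[1], , ] <- lab[1:(d[1] - 1), , ]
      else out[1:(d[1] - 1), , ] <- lab[2:d[1], , ]
    } else if (ax == 2) {
      if (s > 0) out[, 2:d[2], ] <- lab[, 1:(d[2] - 1), ]
      else out[, 1:(d[2] - 1), ] <- lab[, 2:d[2], ]
    } else {
      if (s > 0) out[, , 2:d[3]] <- lab[, , 1:(d[3] - 1)]
      else out[, , 1:(d[3] - 1)] <- lab[, , 2:d[3]]
    }
    out
  }
  nb <- list(shift(1, 1), shift(1, -1), shift(2, 1),
             shift(2, -1), shift(3, 1), shift(3, -1))
  differs <- lapply(nb, function(s) lab > 0L & s > 0L & s != lab)
  iface <- Reduce(`|`, differs)
  idx <- which(iface)
  if (!length(idx)) return(lab)
  do_flip <- runif(length(idx)) < p
  idx <- idx[do_flip]
  if (!length(idx)) return(lab)
  # choose among differing neighbors, starting from a random direction
  start <- sample.int(6, length(idx), replace = TRUE)
  newlab <- lab[idx]
  for (o in 0:5) {
    dirs <- ((start + o - 1L) %% 6L) + 1L
    for (dd in 1:6) {
      sel <- dirs == dd & newlab == lab[idx]
      if (any(sel)) {
        cand <- nb[[dd]][idx[sel]]
        ok <- cand > 0L & cand != lab[idx[sel]]
        newlab[sel][ok] <- cand[ok]
      }
    }
  }
  lab[idx] <- newlab
  lab
}
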