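# VoxelModel: labeled 3D tissue grid + geometry + tissue table.
# SyntheticImage: real intensity grid sharing a model's geometry.

#' Construct a voxel model
#'
#' A voxel model couples a 3D integer label grid with its geometry (voxel
#' size in mm and a 4x4 affine mapping 0-based voxel indices to world mm)
#' and a tissue property table.
#'
#' @param labels 3D integer array; 0 is air.
#' @param voxel_size numeric(3), mm per axis (> 0).
#' @param tissue tissue table (see [default_tissue_table()]).
#' @param world optional 4x4 index-to-world affine; default places the grid
#'   center at the world origin.
#' @param meta optional list of free-form metadata (e.g. `neck_plane_z`).
#' @return object of class `voxel_model`.
#' @export
voxel_model <- function(labels, voxel_size, tissue, world = NULL, meta = list()) {
  stopifnot(length(dim(labels)) == 3, all(voxel_size > 0), all(dim(labels) >= 1))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (is.null(world)) {
    d <- dim(labels)
    origin <- -(d - 1) / 2 * voxel_size
    world <- make_world(voxel_size, origin)
  }
  storage.mode(labels) <- "integer"
  m <- structure(list(labels = labels, voxel_size = voxel_size, world = world,
                      tissue = tissue, meta = meta), class = "voxel_model")
  bad <- setdiff(unique(as.vector(labels)), tissue$label)
  if (length(bad)) stop("labels not in tissue table: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  m
}

#' @export
print.voxel_model <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<voxel_model> %d x %d x %d @ (%.2g, %.2g, %.2g) mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  tab <- table(factor(as.vector(x$labels), levels = x$tissue$label))
  present <- tab[tab > 0]
  nm <- x$tissue$name[match(as.integer(names(present)), x$tissue$label)]
  cat("  tissues:", paste(sprintf("%s(%d)", nm, present), collapse = " "), "\n")
  invisible(x)
}

#' Construct a synthetic image on a model's grid
#'
#' @param intensities 3D numeric array (finite).
#' @param like voxel model or synthetic image supplying the geometry.
#' @return object of class `synthetic_image`.
#' @export
synthetic_image <- function(intensities, like) {
  stopifnot(all(is.finite(intensities)),
            identical(dim3(intensities), dim3(like$labels %||% like$intensities)))
  structure(list(intensities = intensities, voxel_size = like$voxel_size,
                 world = like$world), class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<synthetic_image> %d x %d x %d, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], min(x$intensities), max(x$intensities)))
  invisible(x)
}

vm_dims <- function(m) dim3(m$labels %||% m$intensities)

#' Resample a model or image to a new voxel size
#'
#' Labels are resampled nearest-neighbor (categorical data), intensities by
#' trilinear interpolation; the world transform is updated so the resampled
#' grid covers the same world extent.
#'
#' @param x `voxel_model` or `synthetic_image`.
#' @param new_voxel_size numeric, mm (scalar or length 3, > 0).
#' @return object of the same class as `x`.
#' @export
resample <- function(x, new_voxel_size) UseMethod("resample")

resample_grid <- function(x, new_voxel_size) {
  new_voxel_size <- rep_len(as.numeric(new_voxel_size), 3)
  stopifnot(all(new_voxel_size > 0))
  d <- vm_dims(x)
  ext <- d * x$voxel_size
  nd <- pmax(1L, as.integer(round(ext / new_voxel_size)))
  # keep the world position of the first-voxel corner fixed
  corner <- x$world[1:3, 4] - x$voxel_size / 2
  origin <- corner + new_voxel_size / 2
  world <- x$world
  world[1:3, 1:3] <- x$world[1:3, 1:3] %*% diag(new_voxel_size / x$voxel_size, 3)
  world[1:3, 4] <- x$world[1:3, 1:3] %*%
    ((new_voxel_size / x$voxel_size - 1) / 2) + x$world[1:3, 4]
  list(dims = nd, world = world, voxel_size = new_voxel_size)
}

#' @export
resample.voxel_model <- function(x, new_voxel_size) {
  g <- resample_grid(x, new_voxel_size)
  if (isTRUE(all.equal(g$voxel_size, x$voxel_size))) return(x)
  P <- solve(x$world)
  lab <- cpp_resample(as.numeric(x$labels), vm_dims(x), P, g$world, NULL,
                      g$dims, TRUE, 0)
  storage.mode(lab) <- "integer"
  voxel_model(lab, g$voxel_size, x$tissue, world = g$world, meta = x$meta)
}

#' @export
resample.synthetic_image <- function(x, new_voxel_size) {
  g <- resample_grid(x, new_voxel_size)
  if (isTRUE(all.equal(g$voxel_size, x$voxel_size))) return(x)
  P <- solve(x$world)
  v <- cpp_resample(x$intensities, vm_dims(x), P, g$world, NULL,
                    g$dims, FALSE, 0)
  synthetic_image(v, list(voxel_size = g$voxel_size, world = g$world,
                          intensities = array(0, g$dims)))
}

#' Warp a voxel model onto a reference grid
#'
#' Pull-back resampling: for each voxel of `reference`, the transform is
#' inverted to find the corresponding point in `model` and the label is
#' sampled nearest-neighbor. Transforms map moving to fixed world coordinates
#' (an [affine_transform()] or a [deformation_field()]).
#'
#' @param model moving voxel model.
#' @param transform `affine_transform` or `deformation_field`.
#' @param reference voxel model supplying the output grid.
#' @return warped `voxel_model` on the reference grid.
#' @export
apply_transform_to_model <- function(model, transform, reference) {
  u <- NULL
  if (inherits(transform, "deformation_field")) {
    stopifnot(identical(dim3(transform$displacement), vm_dims(reference)))
    u <- transform$displacement
    aff <- transform$init_affine$matrix
  } else if (inherits(transform, "affine_transform")) {
    aff <- transform$matrix
  } else stop("transform must be an affine_transform or deformation_field")
  if (abs(det(aff[1:3, 1:3])) < 1e-12) stop("singular affine transform")
  P <- solve(model$world) %*% solve(aff)   # world(fixed) -> moving voxel idx
  lab <- cpp_resample(as.numeric(model$labels), vm_dims(model), P,
                      reference$world, u, vm_dims(reference), TRUE, 0)
  storage.mode(lab) <- "integer"
  voxel_model(lab, reference$voxel_size, model$tissue,
              world = reference$world, meta = model$meta)
}

# Warp a synthetic image (trilinear) onto a reference grid.
apply_transform_to_image <- function(image, transform, reference) {
  u <- NULL
  if (inherits(transform, "deformation_field")) {
    u <- transform$displacement
    aff <- transform$init_affine$matrix
  } else aff <- transform$matrix
  P <- solve(image$world) %*% solve(aff)
  v <- cpp_resample(image$intensities, vm_dims(image), P, reference$world, u,
                    vm_dims(reference), FALSE, 0)
  synthetic_image(v, reference)
}

#' Write / read a voxel model's label grid as NIfTI
#'
#' The tissue table travels separately as CSV (see [write_tissue_table()]).
#'
#' @param model voxel model.
#' @param path `.nii` output path.
#' @export
write_model_nifti <- function(model, path) {
  write_nifti(model$labels, path, world = model$world, datatype = "int32")
}

#' @rdname write_model_nifti
#' @param tissue tissue table to attach on read.
#' @export
read_model_nifti <- function(path, tissue) {
  n <- read_nifti(path)
  lab <- n$vol
  storage.mode(lab) <- "integer"
  voxel_model(lab, n$voxel_size, tissue, world = n$world)
}
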