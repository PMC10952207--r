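# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-stage substream seed, kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483629) + 1L
}

dim3 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) >= 3)
  as.integer(d[1:3])
}

# 4x4 voxel-index (0-based) -> world mm affine from spacing + origin.
make_world <- function(voxel_size, origin) {
  w <- diag(4)
  w[1:3, 1:3] <- diag(voxel_size, 3)
  w[1:3, 4] <- origin
  w
}

# world coordinates (mm) of every voxel center, as an n x 3 matrix
voxel_coords <- function(dims, world) {
  g <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                             k = 0:(dims[3] - 1)))
  sweep(g %*% t(world[1:3, 1:3]), 2, world[1:3, 4], "+")
}

# nearest voxel (1-based R index triplet) to a world point
nearest_voxel <- function(world, dims, point_mm) {
  ijk <- round(solve(world) %*% c(point_mm, 1))[1:3]
  ijk <- pmin(pmax(ijk, 0), dims - 1)
  as.integer(ijk) + 1L
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim3(a$labels %||% a$intensities), dim3(b$labels %||% b$intensities)) &&
    max(abs(a$world - b$world)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_grid_mismatch <- function() {
  stop("volumes are not on the same grid (dims/world transform differ)",
       call. = FALSE)
}
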