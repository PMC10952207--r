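# Tissue property table: one row per integer label carrying the dielectric
# and density values that drive SAR, synthetic T1-weighted intensity
# statistics, and the overlap-reporting group each label belongs to.

TISSUE_COLS <- c("label", "name", "conductivity_S_per_m", "rel_permittivity",
                 "density_kg_per_m3", "t1w_mean", "t1w_sd", "dsc_group")

#' Default tissue property table
#'
#' Representative electrical conductivity (S/m) and relative permittivity at
#' 297.2 MHz, mass density (kg/m3), synthetic T1-weighted intensity mean/sd
#' (arbitrary units), and the group used for Dice overlap reporting
#' (deep gray nuclei-style label sharing: cancellous bone reports under
#' "skull"). Label 0 is air.
#'
#' @return data.frame with one row per tissue label.
#' @export
default_tissue_table <- function() {
  path <- system.file("extdata", "tissue_table.csv", package = "ptxsar")
  read_tissue_table(path)
}

#' Read / write a tissue table as CSV
#'
#' @param path CSV path with header columns
#'   `label,name,conductivity_S_per_m,rel_permittivity,density_kg_per_m3,t1w_mean,t1w_sd,dsc_group`.
#' @return data.frame (validated).
#' @export
read_tissue_table <- function(path) {
  tt <- read.csv(path, stringsAsFactors = FALSE)
  validate_tissue_table(tt)
  tt
}

#' @rdname read_tissue_table
#' @param table tissue table data.frame.
#' @export
write_tissue_table <- function(table, path) {
  validate_tissue_table(table)
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_tissue_table <- function(tt) {
  miss <- setdiff(TISSUE_COLS, names(tt))
  if (length(miss)) stop("tissue table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tt$label)) stop("duplicate tissue labels", call. = FALSE)
  if (any(tt$conductivity_S_per_m < 0)) stop("negative conductivity", call. = FALSE)
  nonair <- tt$label != 0
  if (any(tt$density_kg_per_m3[nonair] <= 0))
    stop("non-air tissue must have density > 0", call. = FALSE)
  air <- tt[tt$label == 0, ]
  if (nrow(air) == 1 &&
      (air$conductivity_S_per_m != 0 || air$density_kg_per_m3 != 0))
    stop("air (label 0) must have zero conductivity and density", call. = FALSE)
  if (any(is.na(tt$dsc_group) | tt$dsc_group == ""))
    stop("dsc_group must be defined for every label", call. = FALSE)
  invisible(TRUE)
}

# Per-voxel lookup of a tissue property; unknown labels -> error.
tissue_lookup <- function(model, column) {
  tt <- model$tissue
  idx <- match(as.vector(model$labels), tt$label)
  if (anyNA(idx))
    stop("labels present in the grid but absent from the tissue table: ",
         paste(sort(unique(as.vector(model$labels)[is.na(idx)])), collapse = ", "),
         call. = FALSE)
  out <- tt[[column]][idx]
  dim(out) <- dim(model$labels)
  out
}
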