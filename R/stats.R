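# Agreement statistics between per-shim maximum 10 g SAR series (and field
# maps): Bland-Altman, percent-difference summaries with percentile margins,
# B1+ RMSE, and the segmentation-uncertainty comparison.

#' Bland-Altman analysis of paired per-shim values
#'
#' Differences `d_i = a_i - b_i` against means `(a_i + b_i)/2`; the
#' agreement lines sit at `mean(d) +/- k sd(d)` (`k = 1` by default, `1.96`
#' for conventional limits of agreement).
#'
#' @param a,b numeric vectors of paired values (length >= 2).
#' @param k spread-line multiplier.
#' @return list: `mean_diff`, `sd_diff`, `lines` (lower/upper), `points`
#'   (data.frame `mean`, `diff`).
#' @export
bland_altman <- function(a, b, k = 1) {
  if (length(a) != length(b) || length(a) < 2)
    stop("need >= 2 pairs of equal length", call. = FALSE)
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d)
  sdd <- sd(d)
  list(mean_diff = md, sd_diff = sdd,
       lines = c(lower = md - k * sdd, upper = md + k * sdd), k = k,
       points = data.frame(mean = m, diff = d))
}

#' Percent-difference summary of paired values
#'
#' Per-shim percent difference `100 |a_i - b_i| / ref_i` with the reference
#' either the target-model value `b_i` (default: errors are deviations from
#' the native target simulation) or the pairwise mean. Reports the mean, the
#' 95th and 99th percentiles and the full range (maximum).
#'
#' @param a,b numeric vectors; `b` is the target model series.
#' @param reference `"target"` or `"pairwise_mean"`.
#' @return list: `mean_abs_pct`, `p95_pct`, `p99_pct`, `full_range_pct`,
#'   `reference`, `per_shim_pct`.
#' @export
percent_diff_summary <- function(a, b, reference = c("target", "pairwise_mean")) {
  reference <- match.arg(reference)
  ref <- if (reference == "target") b else (a + b) / 2
  if (any(ref <= 0)) stop("nonpositive reference values", call. = FALSE)
  pd <- 100 * abs(a - b) / ref
  list(mean_abs_pct = mean(pd),
       p95_pct = unname(quantile(pd, 0.95)),
       p99_pct = unname(quantile(pd, 0.99)),
       full_range_pct = max(pd),
       reference = reference, per_shim_pct = pd)
}

#' RMS error between two |B1+| maps over a mask
#'
#' @param mapA,mapB complex (or magnitude) B1+ grids in uT, same dims.
#' @param mask logical mask (non-empty).
#' @return RMSE in uT.
#' @export
b1_rmse <- function(mapA, mapB, mask) {
  stopifnot(identical(dim3(mapA), dim3(mapB)))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  sqrt(mean((Mod(mapA)[mask] - Mod(mapB)[mask])^2))
}

#' Assemble a comparison report from per-shim series
#'
#' @param a per-shim max 10 g SAR of the morphed / perturbed model (W/kg).
#' @param b per-shim series of the target (native) model (W/kg).
#' @param reference percent-difference convention (see
#'   [percent_diff_summary()]).
#' @param k Bland-Altman spread-line multiplier.
#' @param extras named list merged into the report (e.g. `dsc`, `b1_rmse_uT`,
#'   `mean_conductivity_diff`).
#' @return object of class `comparison_report`.
#' @export
comparison_report <- function(a, b, reference = "target", k = 1,
                              extras = list()) {
  ba <- bland_altman(a, b, k = k)
  pct <- percent_diff_summary(a, b, reference = reference)
  rep <- c(list(pairs = data.frame(a = a, b = b),
                mean_abs_diff = mean(abs(a - b)),
                bland_altman = ba[c("mean_diff", "sd_diff", "lines", "k")],
                mean_abs_pct = pct$mean_abs_pct,
                p95_pct = pct$p95_pct, p99_pct = pct$p99_pct,
                full_range_pct = pct$full_range_pct,
                pct_reference = pct$reference),
           extras)
  structure(rep, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(paste0("<comparison_report> %d shims | mean |diff| %.3f W/kg | ",
                     "mean |pct| %.2f%% | p95 %.2f%% | p99 %.2f%% | range %.2f%%\n"),
              nrow(x$pairs), x$mean_abs_diff, x$mean_abs_pct, x$p95_pct,
              x$p99_pct, x$full_range_pct))
  invisible(x)
}

#' Write / read a comparison report (JSON summaries + CSV pairs)
#'
#' `path` is a stem: `<path>.json` and `<path>_pairs.csv` are produced.
#' Reading recomputes the summaries from the stored pairs, so the round trip
#' is lossless by construction.
#'
#' @param x `comparison_report`; @param path output stem.
#' @export
write_comparison_report <- function(x, path) {
  summ <- x[setdiff(names(x), c("pairs"))]
  summ$bland_altman$lines <- as.list(summ$bland_altman$lines)
  jsonlite::write_json(summ, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  write.csv(x$pairs, paste0(path, "_pairs.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparison_report
#' @export
read_comparison_report <- function(path) {
  summ <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pairs <- read.csv(paste0(path, "_pairs.csv"))
  extras <- summ[setdiff(names(summ), c("mean_abs_diff", "bland_altman",
                                        "mean_abs_pct", "p95_pct", "p99_pct",
                                        "full_range_pct", "pct_reference"))]
  comparison_report(pairs$a, pairs$b, reference = summ$pct_reference,
                    k = summ$bland_altman$k, extras = extras)
}

#' Segmentation-uncertainty comparison
#'
#' Evaluates the same shim list on the Q-matrix sets of two segmentation
#' variants that share one morphometry (no registration stage involved) and
#' reports the full agreement statistics, mirroring the version-1-vs-
#' version-3 analysis of a reference body model.
#'
#' @param qset_a,qset_b `qmatrix_set`s of the two variants (same channels).
#' @param shims `shim_set` matrix evaluated on both.
#' @param ... passed to [comparison_report()].
#' @return `comparison_report` with `morphometry_identical = TRUE`.
#' @export
uncertainty_comparison <- function(qset_a, qset_b, shims, ...) {
  if (qset_a$n_channels != qset_b$n_channels)
    stop("channel mismatch between variants", call. = FALSE)
  a <- as.numeric(max10g_exact(qset_a, shims))
  b <- as.numeric(max10g_exact(qset_b, shims))
  comparison_report(a, b, extras = list(morphometry_identical = TRUE), ...)
}
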