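# Shim generation, Q matrices, exact evaluation, VOP compression.

test_that("generate_shims: count, normalization, reproducibility, phases", {
  s <- generate_shims(5000, 8, 5, seed = 21)
  expect_equal(dim(s), c(8, 5000))
  expect_equal(colSums(Mod(s)^2), rep(5, 5000), tolerance = 1e-9)
  expect_identical(unclass(generate_shims(100, 8, 5, seed = 3)),
                   unclass(generate_shims(100, 8, 5, seed = 3)))
  # phases uniform on [0, 2pi) by Kolmogorov-Smirnov at alpha = 0.01
  ph <- (Arg(s) %% (2 * pi)) / (2 * pi)
  ks <- suppressWarnings(ks.test(as.vector(ph), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("shim CSV round-trips", {
  s <- generate_shims(7, 8, 5, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_shims(s, f)
  s2 <- read_shims(f)
  expect_equal(unclass(s2), unclass(s), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Q matrices are Hermitian and match the direct quadratic form", {
  q <- fx_qset()
  for (i in c(1, 5, ncol(q$pack))) {
    Q <- q_matrix(q, i)
    expect_equal(Q, Conj(t(Q)), tolerance = 1e-12)
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9 * max(abs(ev)))  # numerically PSD
  }
  # w^H Q w is real and quadratic in |w|
  w <- generate_shims(1, 8, 5, seed = 8)[, 1]
  Q <- q_matrix(q, 1)
  v <- Conj(w) %*% Q %*% w
  expect_lt(abs(Im(v)) / abs(Re(v)), 1e-9)
  expect_equal(oracle_quadform(Q, sqrt(2) * w), 2 * oracle_quadform(Q, w),
               tolerance = 1e-12)
})

test_that("single-channel Q reduces to the 10 g SAR under unit drive", {
  m <- fx_model()
  f <- fx_fields()
  f1 <- f
  f1$E <- f$E[, , , , 1, drop = FALSE]
  f1$b1p <- f$b1p[, , , 1, drop = FALSE]
  q1 <- build_q_matrices(f1, m)
  sar <- pointwise_sar(f$E[, , , , 1], m)
  s10 <- sar_10g(sar, m)
  expect_equal(max(Re(q1$pack[1, ])), max(s10$sar10g[s10$valid]),
               tolerance = 1e-9)
})

test_that("max10g_exact: one-hot, scaling, pruning = exhaustive, oracle", {
  q <- fx_qset()
  one_hot <- matrix(complex(real = c(1, rep(0, 7))), 8, 1)
  v <- max10g_exact(q, one_hot)
  expect_equal(as.numeric(v), max(Re(q$pack[1, ])), tolerance = 1e-12)
  shims <- generate_shims(50, 8, 5, seed = 31)
  ex <- max10g_exact(q, shims)
  ex2 <- max10g_exact(q, sqrt(2) * shims)
  expect_equal(as.numeric(ex2), 2 * as.numeric(ex), tolerance = 1e-9)
  exf <- max10g_exact(q, shims, prune = FALSE)
  expect_equal(as.numeric(ex), as.numeric(exf), tolerance = 0)
  # R-side oracle over materialized matrices on a thinned subset
  qs <- q
  keep <- seq_len(min(300, ncol(q$pack)))
  qs$pack <- q$pack[, keep]
  qs$eigmax <- q$eigmax[keep]
  w <- shims[, 1]
  vals <- vapply(keep, function(i) oracle_quadform(q_matrix(qs, i), w), 0)
  expect_equal(as.numeric(max10g_exact(qs, shims[, 1, drop = FALSE])),
               max(vals), tolerance = 1e-12)
})

test_that("VOP compression: degenerate cases and the upper-bound contract", {
  q <- fx_qset()
  # all Q identical, lambda = 0 -> exactly 1 VOP, zero overestimation
  qid <- q
  qid$pack <- q$pack[, rep(1, 20)]
  qid$eigmax <- rep(q$eigmax[1], 20)
  v1 <- compress_vop(qid, lambda = 0)
  expect_equal(v1$n_vop, 1L)
  shims <- generate_shims(50, 8, 5, seed = 41)
  expect_equal(max10g_vop(v1, shims), as.numeric(max10g_exact(qid, shims)),
               tolerance = 1e-12)
  expect_error(compress_vop(q, lambda = -0.1), "lambda")
  # domination: for every source Q assigned to V, (1+lambda)V - Q is PSD
  v <- compress_vop(q, lambda = 0.05)
  expect_lte(v$n_vop, ncol(q$pack))
  set.seed(7)
  for (i in sample(seq_len(ncol(q$pack)), 25)) {
    V <- q_matrix(list(pack = v$pack, n_channels = 8), v$assign[i])
    Q <- q_matrix(q, i)
    ev <- eigen((1 + v$lambda) * V - Q, symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * q$eigmax[1])
  }
})

test_that("scaled-identity Z mode never underestimates", {
  q <- fx_qset()
  shims <- generate_shims(100, 8, 5, seed = 51)
  ex <- as.numeric(max10g_exact(q, shims))
  v <- compress_vop(q, lambda = 0.05, z_mode = "scaled_identity")
  vb <- max10g_vop(v, shims)
  expect_true(all(vb - ex >= -1e-9 * max(ex)))
  expect_lt(v$n_vop, ncol(q$pack) / 10)  # strong compression in this mode
})
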