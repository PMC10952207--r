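# Independent oracles (brute-force / closed-form), kept free of the
# package's own computational paths.

# Exhaustive cube-growing 10 g average: direct summation per voxel, no
# prefix sums. Mirrors the stated rule, not the implementation.
oracle_sar10g <- function(sar, mass, head, target_kg, smax) {
  d <- dim(sar)
  power <- sar * mass
  out <- array(0, d)
  valid <- array(FALSE, d)
  side <- array(0L, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (!head[i, j, k] || mass[i, j, k] <= 0) next
    m_in <- 0
    p_in <- 0
    for (h in 0:((smax - 1) / 2)) {
      ii <- max(1, i - h):min(d[1], i + h)
      jj <- max(1, j - h):min(d[2], j + h)
      kk <- max(1, k - h):min(d[3], k + h)
      m <- sum(mass[ii, jj, kk])
      if (m >= target_kg) {
        p <- sum(power[ii, jj, kk])
        f <- if (m > m_in) (target_kg - m_in) / (m - m_in) else 1
        out[i, j, k] <- (p_in + f * (p - p_in)) / target_kg
        valid[i, j, k] <- TRUE
        side[i, j, k] <- 2L * h + 1L
        break
      }
      m_in <- m
      p_in <- sum(power[ii, jj, kk])
    }
  }
  # painting: invalid voxels take the max over valid cubes containing them
  painted <- out
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (!valid[i, j, k]) next
    h <- (side[i, j, k] - 1) / 2
    ii <- max(1, i - h):min(d[1], i + h)
    jj <- max(1, j - h):min(d[2], j + h)
    kk <- max(1, k - h):min(d[3], k + h)
    sub <- painted[ii, jj, kk]
    tgt <- !valid[ii, jj, kk] & head[ii, jj, kk] & mass[ii, jj, kk] > 0
    sub[tgt] <- pmax(sub[tgt], out[i, j, k])
    painted[ii, jj, kk] <- sub
  }
  list(sar10g = painted, valid = valid, side = side)
}

# Direct quadratic form w^H Q w from a materialized Q matrix.
oracle_quadform <- function(Q, w) Re(Conj(w) %*% Q %*% w)[1, 1]

# Analytic p-quantile of 100*|exp(X) - 1| for X ~ N(0, sigma^2):
# P(|e^X - 1| <= t) = Phi(log(1+t)/sigma) - Phi(log(1-t)/sigma), t < 1.
oracle_lognormal_pct_quantile <- function(p, sigma) {
  cdf <- function(t) {
    lo <- if (t < 1) pnorm(log(1 - t) / sigma) else 0
    pnorm(log(1 + t) / sigma) - lo
  }
  100 * uniroot(function(t) cdf(t) - p, c(1e-9, 50), tol = 1e-10)$root
}
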