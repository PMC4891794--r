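# Independent brute-force oracles used to validate the package's vectorized
# statistics. Each is a direct, loop-based transcription of the textbook
# formula, deliberately sharing no code with the implementation.

slow_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

slow_pearson_p <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

slow_paired_t <- function(d) {
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

slow_icc_double_entry <- function(x1, x2) {
  slow_pearson(c(x1, x2), c(x2, x1))
}

slow_ols <- function(y, X) {
  # normal equations with an intercept column
  A <- cbind(1, X)
  beta <- solve(t(A) %*% A, t(A) %*% y)
  resid <- y - A %*% beta
  df <- length(y) - ncol(A)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(s2 * solve(t(A) %*% A)))
  t <- drop(beta) / se
  list(beta = drop(beta), se = se, p = 2 * stats::pt(-abs(t), df = df))
}

slow_chisq <- function(tab) {
  # Pearson chi-square for an r x c contingency table
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

slow_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  t <- (mean(a) - mean(b)) / sqrt(va / na + vb / nb)
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df = df))
}

slow_count_overlaps <- function(bins, frags) {
  # bins, frags: data frames with start/end, 0-based half-open, one chrom
  vapply(seq_len(nrow(bins)), function(i) {
    sum(frags$start < bins$end[i] & frags$end > bins$start[i])
  }, numeric(1))
}

slow_classify_cpg <- function(bins, islands, shores) {
  hit <- function(b, track) {
    any(track$start < b$end & track$end > b$start &
          track$chrom == b$chrom)
  }
  vapply(seq_len(nrow(bins)), function(i) {
    b <- bins[i, ]
    if (nrow(islands) && hit(b, islands)) "island"
    else if (nrow(shores) && hit(b, shores)) "shore"
    else "open_sea"
  }, character(1))
}

slow_bh <- function(p, m, q) {
  # step-up over m tests; p may be shorter than m (rest implicitly 1)
  ord <- order(p)
  ps <- p[ord]
  k_max <- 0L
  for (k in seq_along(ps)) if (ps[k] <= k * q / m) k_max <- k
  if (k_max == 0L) integer() else sort(ord[seq_len(k_max)])
}

# small twin-data helper: exact sample moments via MASS::mvrnorm
exact_twin_pairs <- function(n, r, seed = 1) {
  withr::with_seed(seed, {
    MASS::mvrnorm(n, mu = c(0, 0),
                  Sigma = matrix(c(1, r, r, 1), 2), empirical = TRUE)
  })
}

# independent coarse grid-search maximizer of the AE twin likelihood over
# (h2, total variance), with the mean fixed at the grand mean; used as an
# oracle for fit_univariate on exact-moment (mean-zero) data
grid_ae_h2 <- function(mz, dz, h2_step = 1e-3) {
  vals <- c(as.vector(mz), as.vector(dz))
  mu <- mean(vals)
  stats_of <- function(m) {
    list(n = nrow(m),
         sxx = sum((m[, 1] - mu)^2), syy = sum((m[, 2] - mu)^2),
         sxy = sum((m[, 1] - mu) * (m[, 2] - mu)))
  }
  smz <- stats_of(mz); sdz <- stats_of(dz)
  ll_group <- function(s, v, rho) {
    -s$n * log(2 * pi) - 0.5 * s$n * log(v^2 * (1 - rho^2)) -
      0.5 * (s$sxx + s$syy - 2 * rho * s$sxy) / (v * (1 - rho^2))
  }
  v_marg <- mean((vals - mu)^2)
  best_h2 <- NA_real_; best_ll <- -Inf
  for (h2 in seq(0, 0.999, by = h2_step)) {
    for (vf in seq(0.7, 1.3, by = 0.005)) {
      v <- vf * v_marg
      ll <- ll_group(smz, v, h2) + ll_group(sdz, v, h2 / 2)
      if (ll > best_ll) { best_ll <- ll; best_h2 <- h2 }
    }
  }
  best_h2
}
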