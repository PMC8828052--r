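# Independent oracles used across the suite. Each deliberately re-derives the
# quantity with a different algorithm than the package implementation.

# Cox-de Boor recursion for a single B-spline basis function B_{i,k}(x)
# over the full (clamped) knot vector `kv`; k is the degree.
cox_de_boor <- function(x, kv, i, k) {
  if (k == 0) {
    # half-open intervals, closed at the right boundary
    if ((kv[i] <= x && x < kv[i + 1]) ||
        (x == kv[length(kv)] && kv[i] < x && x <= kv[i + 1])) 1 else 0
  } else {
    d1 <- kv[i + k] - kv[i]
    d2 <- kv[i + k + 1] - kv[i + 1]
    t1 <- if (d1 > 0) (x - kv[i]) / d1 * cox_de_boor(x, kv, i, k - 1) else 0
    t2 <- if (d2 > 0) (kv[i + k + 1] - x) / d2 * cox_de_boor(x, kv, i + 1, k - 1) else 0
    t1 + t2
  }
}

spline_basis_oracle <- function(x, kv, degree = 3) {
  nb <- length(kv) - degree - 1
  vapply(seq_len(nb), function(i) cox_de_boor(x, kv, i, degree), numeric(1))
}

# Evidence-maximizing Gaussian BLR via the EM-style fixed-point updates
# (gamma = effective number of parameters), an algorithm disjoint from the
# package's quasi-Newton route.
em_blr <- function(y, X, tol = 1e-13, max_iter = 10000) {
  n <- length(y); p <- ncol(X)
  S <- crossprod(X); Xty <- crossprod(X, y)
  alpha <- 1; beta <- 1
  for (i in seq_len(max_iter)) {
    A <- alpha * diag(p) + beta * S
    Ainv <- solve(A)
    m <- beta * Ainv %*% Xty
    gam <- p - alpha * sum(diag(Ainv))
    rss <- sum((y - X %*% m)^2)
    alpha_new <- gam / sum(m^2)
    beta_new <- (n - gam) / rss
    done <- abs(alpha_new - alpha) < tol * alpha &&
      abs(beta_new - beta) < tol * beta
    alpha <- alpha_new; beta <- beta_new
    if (done) break
  }
  list(m = drop(m), alpha = alpha, beta = beta)
}

# Direct Gaussian-BLR log evidence via the n x n marginal covariance
# C = I/beta + X X'/alpha (different algebra than the p x p route).
blr_log_evidence_direct <- function(y, X, alpha, beta) {
  n <- length(y)
  C <- diag(n) / beta + X %*% t(X) / alpha
  -n / 2 * log(2 * pi) - 0.5 * determinant(C)$modulus[1] -
    0.5 * drop(t(y) %*% solve(C, y))
}

# Welch's t-test from the textbook formulas.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Brute-force BH step-up: try every candidate k explicitly.
bh_brute <- function(p, q) {
  ok <- which(!is.na(p))
  m <- length(ok)
  out <- rep(NA, length(p))
  out[ok] <- FALSE
  if (m == 0) return(out)
  ord <- ok[order(p[ok])]
  kmax <- 0
  for (k in seq_len(m)) if (p[ord[k]] <= k * q / m) kmax <- k
  if (kmax > 0) out[ord[seq_len(kmax)]] <- TRUE
  out
}

# Jarque-Bera normality test p-value.
jarque_bera_p <- function(x) {
  n <- length(x)
  m <- mean(x); s2 <- mean((x - m)^2)
  S <- mean((x - m)^3) / s2^1.5
  K <- mean((x - m)^4) / s2^2
  stat <- n / 6 * (S^2 + (K - 3)^2 / 4)
  pchisq(stat, df = 2, lower.tail = FALSE)
}

# Wrap a bare matrix as a design_matrix (for fit-level tests that bypass the
# cohort/design machinery).
bare_design <- function(X, spec = NULL) {
  structure(
    list(values = X, spec = spec, row_ids = as.character(seq_len(nrow(X))),
         unknown_site_rows = integer(0)),
    class = "design_matrix"
  )
}

sample_skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}
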