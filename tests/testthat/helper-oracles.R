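# Independent oracles used across test files. These deliberately use
# different algorithms/arithmetic than the package implementation.

# Loop-based gap-segment first derivative: for output position j the two
# segments are x[j .. j+s-1] and x[j+s+g .. j+2s+g-1], divided by the
# centre-to-centre separation s + g.
oracle_gap_segment <- function(x, gap, segment) {
  n <- length(x)
  span <- 2 * segment + gap
  n_out <- n - span + 1
  out <- numeric(n_out)
  for (j in seq_len(n_out)) {
    lower <- mean(x[j:(j + segment - 1)])
    upper <- mean(x[(j + segment + gap):(j + 2 * segment + gap - 1)])
    out[j] <- (upper - lower) / (segment + gap)
  }
  out
}

# PLS1 via its Krylov-subspace characterisation: the k-factor fitted
# coefficient vector is the least-squares solution restricted to
# span{v, Av, ..., A^(k-1) v} with A = Xc'Xc and v = Xc'yc. Built with
# re-orthogonalised Arnoldi vectors; algebraically identical to NIPALS
# PLS1 but shares no code with it.
oracle_pls_krylov <- function(X, y, k) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  A <- crossprod(Xc)
  v <- crossprod(Xc, yc)[, 1]
  p <- ncol(X)
  K <- matrix(0, p, k)
  q <- v
  for (j in seq_len(k)) {
    for (pass in 1:2) if (j > 1)
      for (i in seq_len(j - 1)) q <- q - sum(q * K[, i]) * K[, i]
    nq <- sqrt(sum(q^2))
    if (nq < 1e-300) stop("Krylov basis degenerate at dimension ", j)
    K[, j] <- q / nq
    q <- (A %*% K[, j])[, 1]
  }
  M <- crossprod(K, A %*% K)
  b <- (K %*% solve(M, crossprod(K, v)))[, 1]
  list(b = b, x_mean = xm, y_mean = ym)
}

oracle_pls_predict <- function(or, Xnew) {
  or$y_mean + (sweep(Xnew, 2, or$x_mean) %*% or$b)[, 1]
}

# Brute-force LOOCV: refit from scratch (via the Krylov oracle) for every
# held-out sample and every factor count.
oracle_loocv_rmsecv <- function(X, y, max_factors) {
  n <- nrow(X)
  pred <- matrix(NA_real_, n, max_factors)
  for (i in seq_len(n)) {
    for (k in seq_len(max_factors)) {
      or <- oracle_pls_krylov(X[-i, , drop = FALSE], y[-i], k)
      pred[i, k] <- oracle_pls_predict(or, X[i, , drop = FALSE])
    }
  }
  sqrt(colMeans((pred - y)^2))
}

# Random regression problem with latent low-rank structure plus noise,
# convenient for PLS tests.
make_pls_problem <- function(n, p, seed, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  b <- rnorm(p)
  y <- drop(X %*% b) + rnorm(n, 0, noise)
  list(X = X, y = y)
}

# A smooth leaf-like test image: Gaussian blob on a constant background
# (decays to a constant at the borders, so it has negligible spectral
# leakage into the stripe notch).
smooth_test_image <- function(nr = 64, nc = 80) {
  outer(exp(-((seq_len(nr)) - nr / 2)^2 / (nr * 4)),
        exp(-((seq_len(nc)) - nc / 2)^2 / (nc * 5))) + 1
}

# Multiplicative column-gain stripes of given relative amplitude/period.
add_stripes <- function(image, amplitude = 0.1, period = 4, phase = 0) {
  gain <- 1 + amplitude * sin(2 * pi * seq_len(ncol(image)) / period +
                                phase)
  sweep(image, 2, gain, "*")
}

# Small, fast phantom configuration shared by pipeline tests; `...`
# overrides any default, including the peak tables.
test_phantom_config <- function(...) {
  args <- list(n_bands = 64L, wavelength_start_nm = 913,
               wavelength_step_nm = 25,
               analyte_peaks = data.frame(center_nm = c(1500, 2050),
                                          width_nm = c(60, 80),
                                          amplitude = c(1, 0.7)),
               interferent_peaks = data.frame(
                 center_nm = c(1450, 1940),
                 width_nm = c(70, 100),
                 amplitude = c(0.35, 0.45)))
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_config, args)
}
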