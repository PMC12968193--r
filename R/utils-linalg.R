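# Internal numerical helpers shared by the samplers and the simulator.

# Scaled-inverse-chi-square draw: X ~ df * scale / chisq(df).
rinvchisq <- function(df, scale) {
  df * scale / rchisq(1L, df)
}

# Inverse-Wishart draw with density parameterisation IW(df, S):
# X^{-1} ~ Wishart(df, S^{-1}).  Requires df > nrow(S) - 1.
riwish <- function(df, S) {
  p <- nrow(S)
  Sinv <- chol2inv(chol(sym(S)))
  W <- stats::rWishart(1L, df, sym(Sinv))[, , 1L]
  sym(chol2inv(chol(sym(W))))
}

# Force exact symmetry (guards against drift in repeated updates).
sym <- function(A) (A + t(A)) / 2

# Eigendecomposition of a symmetric PSD matrix with eigenvalues floored at
# `floor` so that 1/d never overflows after kernel jittering.
eigen_psd <- function(K, floor = 1e-10) {
  e <- eigen(sym(K), symmetric = TRUE)
  e$values <- pmax(e$values, floor)
  e
}

# Simultaneous diagonalisation of two symmetric positive-definite precision
# matrices: returns Phi, kappa with  t(Phi) %*% B %*% Phi = I  and
# t(Phi) %*% A %*% Phi = diag(kappa).  Used to vectorise the matrix-normal
# full conditionals: the posterior precision  A / d_i + B  shared by all
# rows i differs only through the scalar d_i.
simdiag <- function(A, B) {
  U <- chol(sym(B))
  Psi <- backsolve(U, diag(nrow(B)))
  M <- sym(t(Psi) %*% A %*% Psi)
  e <- eigen(M, symmetric = TRUE)
  list(Phi = Psi %*% e$vectors, kappa = pmax(e$values, 0))
}

# Draw from a matrix-normal MN(M, RowCov, ColCov) given the row/column
# covariance factors (lower-triangular or general square roots).
rmatnorm_chol <- function(M, row_sqrt, col_sqrt) {
  Z <- matrix(rnorm(nrow(M) * ncol(M)), nrow(M), ncol(M))
  M + row_sqrt %*% Z %*% t(col_sqrt)
}

# Effective sample size of a (thinned) chain via Geyer's initial positive
# sequence on the autocorrelation function.
ess_chain <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  rho <- as.numeric(stats::acf(x, lag.max = min(n - 2L, 500L),
                               plot = FALSE)$acf)[-1L]
  # pair consecutive lags; stop at the first non-positive pair sum
  m <- floor(length(rho) / 2L)
  s <- 0
  for (k in seq_len(m)) {
    g <- rho[2L * k - 1L] + rho[2L * k]
    if (g <= 0) break
    s <- s + g
  }
  max(1, n / (1 + 2 * s))
}

# Significance stars matching the usual 0.05 / 0.01 / 0.001 convention.
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

# Long-format tibble from a (dim)named array: one column per margin plus
# `value`, rows in column-major order.
array_to_tibble <- function(arr, margin_names, value_name = "value") {
  dn <- dimnames(arr)
  stopifnot(length(dn) == length(margin_names))
  sizes <- dim(arr)
  cols <- lapply(seq_along(dn), function(k) {
    rep(rep(dn[[k]], each = prod(sizes[seq_len(k - 1L)])),
        times = prod(sizes[-seq_len(k)]))
  })
  names(cols) <- margin_names
  cols[[value_name]] <- as.vector(arr)
  tibble::as_tibble(cols)
}

# Derive a reproducible sub-seed from a master seed so that each stochastic
# stage has its own independent stream.  Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 97 + offset) %% 2147483647)
}
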