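# Gibbs sampling engines for the GBLUP-family models.
#
# All four samplers work on complete data obtained by augmenting missing
# cells from their conditional normal each sweep, which makes every full
# conditional balanced and lets the matrix-normal updates be vectorised:
# after rotating to the eigenbasis of the kernel (and of Sigma_E for the
# G-by-E block), the rows of each random-effect matrix are conditionally
# independent with a posterior precision  Sigma^-1 / d_i + P_lik  that
# differs across rows only through the scalar d_i, so one simultaneous
# diagonalisation per sweep serves every row at once.

scalar_prior <- function(vary, nu0 = 5) {
  # scaled-inverse-chi-square with prior mode at half the phenotypic variance
  list(nu = nu0, s = 0.5 * vary * (nu0 + 2) / nu0)
}

mcmc_index <- function(n_iter, burn_in, thin) {
  keep <- seq.int(burn_in + 1L, n_iter)
  keep[(keep - burn_in - 1L) %% thin == 0L]
}

# ---------------------------------------------------------------- SE ------

sampler_se <- function(y, G, n_iter, burn_in, thin, seed, nu0 = 5, fix = NULL) {
  n <- length(y)
  eg <- eigen_psd(G)
  V <- eg$vectors; d <- eg$values
  obs <- !is.na(y)
  vary <- stats::var(y[obs])
  if (!is.finite(vary) || vary == 0) vary <- 1
  pg <- scalar_prior(vary, nu0); pe <- scalar_prior(vary, nu0)
  s2g <- fix$sigma_g2 %||% (vary / 2)
  s2e <- fix$sigma_e2 %||% (vary / 2)

  b <- mean(y[obs]); u <- numeric(n)
  ycur <- y; ycur[!obs] <- b
  keep <- mcmc_index(n_iter, burn_in, thin)
  n_keep <- length(keep)
  mean_u <- numeric(n); mean_fit <- numeric(n); mean_b <- 0
  draws <- matrix(NA_real_, n_keep, 2L,
                  dimnames = list(NULL, c("sigma_g2", "sigma_e2")))
  ki <- 0L
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    if (any(!obs)) {
      ycur[!obs] <- b + u[!obs] + rnorm(sum(!obs)) * sqrt(s2e)
    }
    b <- mean(ycur - u) + rnorm(1L) * sqrt(s2e / n)
    yt <- crossprod(V, ycur - b)
    vpost <- 1 / (1 / s2e + 1 / (d * s2g))
    a <- vpost * yt / s2e + sqrt(vpost) * rnorm(n)
    u <- as.numeric(V %*% a)
    if (is.null(fix$sigma_g2)) {
      s2g <- rinvchisq(pg$nu + n, (pg$nu * pg$s + sum(a^2 / d)) / (pg$nu + n))
    }
    if (is.null(fix$sigma_e2)) {
      e <- ycur - b - u
      s2e <- rinvchisq(pe$nu + n, (pe$nu * pe$s + sum(e^2)) / (pe$nu + n))
    }
    if (it > burn_in && (it - burn_in - 1L) %% thin == 0L) {
      ki <- ki + 1L
      mean_u <- mean_u + u; mean_b <- mean_b + b
      mean_fit <- mean_fit + b + u
      draws[ki, ] <- c(s2g, s2e)
    }
  }
  list(u = mean_u / ki, intercept = mean_b / ki, fitted = mean_fit / ki,
       sigma_g2 = mean(draws[, 1L]), sigma_e2 = mean(draws[, 2L]),
       draws = draws)
}

# ---------------------------------------------------------------- MT ------

# Group the rows of an incomplete matrix by missingness pattern.
missing_patterns <- function(M) {
  miss <- is.na(M)
  key <- apply(miss, 1L, paste, collapse = "")
  idx <- split(seq_len(nrow(M)), key)
  lapply(idx, function(i) list(rows = i, miss = miss[i[1L], ]))
}

# Augment missing cells of rows sharing mean matrix M and residual
# covariance R (rowwise conditional normal given the observed cells).
augment_rows <- function(Ycur, M, R, patterns) {
  for (p in patterns) {
    m <- p$miss
    if (!any(m)) next
    rows <- p$rows
    if (all(m)) {
      Z <- matrix(rnorm(length(rows) * ncol(Ycur)), length(rows))
      Ycur[rows, ] <- M[rows, , drop = FALSE] + Z %*% chol(sym(R))
      next
    }
    Roo <- R[!m, !m, drop = FALSE]
    Rmo <- R[m, !m, drop = FALSE]
    W <- Rmo %*% chol2inv(chol(sym(Roo)))
    Sc <- sym(R[m, m, drop = FALSE] - W %*% t(Rmo))
    resid_o <- Ycur[rows, !m, drop = FALSE] - M[rows, !m, drop = FALSE]
    mu_m <- M[rows, m, drop = FALSE] + resid_o %*% t(W)
    Z <- matrix(rnorm(length(rows) * sum(m)), length(rows))
    Ycur[rows, m] <- mu_m + Z %*% chol(Sc + diag(1e-12, nrow(Sc)))
  }
  Ycur
}

sampler_mt <- function(Y, G, n_iter, burn_in, thin, seed, nu0 = 5, fix = NULL) {
  n <- nrow(Y); Tt <- ncol(Y)
  eg <- eigen_psd(G)
  V <- eg$vectors; d <- eg$values
  vary <- apply(Y, 2L, stats::var, na.rm = TRUE)
  vary[!is.finite(vary) | vary == 0] <- 1
  nu_t <- Tt + 3; S_t0 <- 0.5 * diag(vary, Tt)
  nu_r <- Tt + 3; S_r0 <- 0.5 * diag(vary, Tt)
  St <- fix$Sigma_t %||% diag(vary / 2, Tt)
  R <- fix$R %||% diag(vary / 2, Tt)

  mu <- colMeans(Y, na.rm = TRUE); mu[is.na(mu)] <- 0
  U <- matrix(0, n, Tt)
  Ycur <- Y
  for (t in seq_len(Tt)) Ycur[is.na(Y[, t]), t] <- mu[t]
  patterns <- missing_patterns(Y)

  keep_iters <- mcmc_index(n_iter, burn_in, thin)
  mean_U <- matrix(0, n, Tt); mean_mu <- numeric(Tt)
  mean_fit <- matrix(0, n, Tt)
  mean_St <- matrix(0, Tt, Tt); mean_R <- matrix(0, Tt, Tt)
  nm <- c(paste0("Sigma_t.", seq_len(Tt), ".", seq_len(Tt)),
          paste0("R.", seq_len(Tt), ".", seq_len(Tt)))
  draws <- matrix(NA_real_, length(keep_iters), 2L * Tt,
                  dimnames = list(NULL, nm))
  ki <- 0L
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    M <- matrix(mu, n, Tt, byrow = TRUE) + U
    Ycur <- augment_rows(Ycur, M, R, patterns)
    Rinv <- chol2inv(chol(sym(R)))
    Stinv <- chol2inv(chol(sym(St)))
    # trait intercepts
    mu <- colMeans(Ycur - U) +
      as.numeric(t(chol(sym(R))) %*% rnorm(Tt)) / sqrt(n)
    # genetic effects, vectorised over lines in the kernel eigenbasis
    sdg <- simdiag(Stinv, Rinv)
    Wm <- outer(d, sdg$kappa, function(di, k) di / (di + k))
    Wt <- crossprod(V, sweep(Ycur, 2L, mu))
    A <- Wt %*% Rinv %*% sdg$Phi
    Means <- (A * Wm) %*% t(sdg$Phi)
    Z <- matrix(rnorm(n * Tt), n)
    Ut <- Means + (Z * sqrt(Wm)) %*% t(sdg$Phi)
    U <- V %*% Ut
    if (is.null(fix$Sigma_t)) {
      St <- riwish(nu_t + n, S_t0 + crossprod(Ut, Ut / d))
    }
    if (is.null(fix$R)) {
      E <- sweep(Ycur, 2L, mu) - U
      R <- riwish(nu_r + n, S_r0 + crossprod(E))
    }
    if (it > burn_in && (it - burn_in - 1L) %% thin == 0L) {
      ki <- ki + 1L
      mean_U <- mean_U + U; mean_mu <- mean_mu + mu
      mean_fit <- mean_fit + matrix(mu, n, Tt, byrow = TRUE) + U
      mean_St <- mean_St + St; mean_R <- mean_R + R
      draws[ki, ] <- c(diag(St), diag(R))
    }
  }
  list(u = mean_U / ki, intercept = mean_mu / ki, fitted = mean_fit / ki,
       Sigma_t = mean_St / ki, R = mean_R / ki, draws = draws)
}

# ---------------------------------------------------------------- ME ------

sampler_me <- function(Y, G, n_iter, burn_in, thin, seed, nu0 = 5, fix = NULL,
                       drop_line_effect = FALSE) {
  n <- nrow(Y); E <- ncol(Y)
  eg <- eigen_psd(G)
  V <- eg$vectors; d <- eg$values
  obs <- !is.na(Y)
  vary <- stats::var(as.numeric(Y[obs]))
  if (!is.finite(vary) || vary == 0) vary <- 1
  # the genetic variance share of the prior is partitioned across the
  # random terms (line, genomic, G-by-E), mirroring the equal-split default
  # of standard Bayesian GBLUP software
  n_terms <- if (drop_line_effect) 2 else 3
  pr <- scalar_prior(vary / n_terms, nu0)   # per random term
  pe <- scalar_prior(vary, nu0)             # residual
  s2L <- if (drop_line_effect) 0 else vary / 4
  s2g <- fix$sigma_g2 %||% (vary / 4)
  s2Eg <- fix$sigma_Eg2 %||% (vary / 4)
  s2e <- fix$sigma_e2 %||% (vary / 4)

  mu_e <- colMeans(Y, na.rm = TRUE); mu_e[is.na(mu_e)] <- 0
  L <- numeric(n); g <- numeric(n); Eg <- matrix(0, n, E)
  Ycur <- Y
  for (e in seq_len(E)) Ycur[is.na(Y[, e]), e] <- mu_e[e]

  keep_iters <- mcmc_index(n_iter, burn_in, thin)
  mean_fit <- matrix(0, n, E); mean_g <- numeric(n); mean_Eg <- matrix(0, n, E)
  mean_L <- numeric(n); mean_mu <- numeric(E)
  nm <- c("sigma_L2", "sigma_g2", "sigma_Eg2", "sigma_e2")
  draws <- matrix(NA_real_, length(keep_iters), 4L, dimnames = list(NULL, nm))
  ki <- 0L
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    M <- matrix(mu_e, n, E, byrow = TRUE) + L + g + Eg
    if (any(!obs)) {
      Ycur[!obs] <- M[!obs] + rnorm(sum(!obs)) * sqrt(s2e)
    }
    base <- Ycur - L - g - Eg
    mu_e <- colMeans(base) + rnorm(E) * sqrt(s2e / n)
    Resid0 <- sweep(Ycur, 2L, mu_e)
    if (!drop_line_effect) {
      rs <- rowSums(Resid0 - g - Eg)
      v <- 1 / (E / s2e + 1 / s2L)
      L <- v * rs / s2e + sqrt(v) * rnorm(n)
    }
    # genomic main effect
    rs <- rowSums(Resid0 - L - Eg)
    rt <- as.numeric(crossprod(V, rs))
    v <- 1 / (E / s2e + 1 / (d * s2g))
    at <- v * rt / s2e + sqrt(v) * rnorm(n)
    g <- as.numeric(V %*% at)
    # interaction: independent per environment given the rotation
    Rt <- crossprod(V, Resid0 - L - g)
    vEg <- 1 / (1 / s2e + 1 / (d * s2Eg))
    Egt <- Rt * (vEg / s2e) + sqrt(vEg) * matrix(rnorm(n * E), n)
    Eg <- V %*% Egt
    # variance components
    if (!drop_line_effect) {
      s2L <- rinvchisq(pr$nu + n, (pr$nu * pr$s + sum(L^2)) / (pr$nu + n))
    }
    if (is.null(fix$sigma_g2)) {
      s2g <- rinvchisq(pr$nu + n, (pr$nu * pr$s + sum(at^2 / d)) / (pr$nu + n))
    }
    if (is.null(fix$sigma_Eg2)) {
      s2Eg <- rinvchisq(pr$nu + n * E,
                        (pr$nu * pr$s + sum(Egt^2 / d)) / (pr$nu + n * E))
    }
    if (is.null(fix$sigma_e2)) {
      Ecur <- sweep(Ycur, 2L, mu_e) - L - g - Eg
      s2e <- rinvchisq(pe$nu + n * E,
                       (pe$nu * pe$s + sum(Ecur^2)) / (pe$nu + n * E))
    }
    if (it > burn_in && (it - burn_in - 1L) %% thin == 0L) {
      ki <- ki + 1L
      mean_fit <- mean_fit + matrix(mu_e, n, E, byrow = TRUE) + L + g + Eg
      mean_g <- mean_g + g; mean_Eg <- mean_Eg + Eg
      mean_L <- mean_L + L; mean_mu <- mean_mu + mu_e
      draws[ki, ] <- c(s2L, s2g, s2Eg, s2e)
    }
  }
  list(fitted = mean_fit / ki, g = mean_g / ki, Eg = mean_Eg / ki,
       L = mean_L / ki, env_means = mean_mu / ki,
       sigma_L2 = mean(draws[, 1L]), sigma_g2 = mean(draws[, 2L]),
       sigma_Eg2 = mean(draws[, 3L]), sigma_e2 = mean(draws[, 4L]),
       draws = draws)
}

# -------------------------------------------------------------- MTME ------

sampler_mtme <- function(Yarr, G, n_iter, burn_in, thin, seed, nu0 = 5,
                         fix = NULL, separate_sigma_t = FALSE) {
  n <- dim(Yarr)[1L]; E <- dim(Yarr)[2L]; Tt <- dim(Yarr)[3L]
  N <- n * E
  Ymat <- matrix(Yarr, N, Tt)  # cell rows: line fastest, env-major blocks
  eg <- eigen_psd(G)
  V <- eg$vectors; d <- eg$values
  env_of <- rep(seq_len(E), each = n)
  vary <- apply(Ymat, 2L, stats::var, na.rm = TRUE)
  vary[!is.finite(vary) | vary == 0] <- 1
  nu_t <- Tt + 3; S_t0 <- 0.5 * diag(vary, Tt)
  nu_r <- Tt + 3; S_r0 <- 0.5 * diag(vary, Tt)
  nu_E <- E + 3; S_E0 <- 0.5 * diag(E)

  St <- fix$Sigma_t %||% diag(vary / 2, Tt)
  St2 <- St                      # trait covariance of the G-by-E block
  SE <- fix$Sigma_E %||% diag(0.5, E)
  R <- fix$R %||% diag(vary / 2, Tt)
  beta <- matrix(0, E, Tt)
  for (e in seq_len(E)) {
    beta[e, ] <- colMeans(Ymat[env_of == e, , drop = FALSE], na.rm = TRUE)
  }
  beta[is.na(beta)] <- 0
  b1 <- matrix(0, n, Tt); b2 <- matrix(0, N, Tt)
  Ycur <- Ymat
  miss0 <- is.na(Ymat)
  Minit <- beta[env_of, , drop = FALSE]
  Ycur[miss0] <- Minit[miss0]
  patterns <- missing_patterns(Ymat)

  rep_b1 <- function(b1) b1[rep.int(seq_len(n), E), , drop = FALSE]
  xb <- function(beta) beta[env_of, , drop = FALSE]

  keep_iters <- mcmc_index(n_iter, burn_in, thin)
  mean_fit <- matrix(0, N, Tt); mean_b1 <- matrix(0, n, Tt)
  mean_b2 <- matrix(0, N, Tt); mean_beta <- matrix(0, E, Tt)
  mean_St <- matrix(0, Tt, Tt); mean_St2 <- matrix(0, Tt, Tt)
  mean_SE <- matrix(0, E, E); mean_R <- matrix(0, Tt, Tt)
  nm <- c(paste0("Sigma_t.", seq_len(Tt), ".", seq_len(Tt)),
          paste0("Sigma_E.", seq_len(E), ".", seq_len(E)),
          paste0("R.", seq_len(Tt), ".", seq_len(Tt)))
  draws <- matrix(NA_real_, length(keep_iters), 2L * Tt + E,
                  dimnames = list(NULL, nm))
  ki <- 0L
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    M <- xb(beta) + rep_b1(b1) + b2
    Ycur <- augment_rows(Ycur, M, R, patterns)
    Rinv <- chol2inv(chol(sym(R)))
    Stinv <- chol2inv(chol(sym(St)))
    St2inv <- chol2inv(chol(sym(St2)))
    ee <- eigen_psd(SE, floor = 1e-12)
    Q <- ee$vectors; lam <- ee$values
    # environment-by-trait fixed means
    res <- Ycur - rep_b1(b1) - b2
    Rch <- t(chol(sym(R)))
    for (e in seq_len(E)) {
      beta[e, ] <- colMeans(res[env_of == e, , drop = FALSE]) +
        as.numeric(Rch %*% rnorm(Tt)) / sqrt(n)
    }
    # genetic main effects b1 ~ MN(0, G, Sigma_t)
    W1 <- Ycur - xb(beta) - b2
    S1 <- matrix(0, n, Tt)
    for (t in seq_len(Tt)) {
      S1[, t] <- rowSums(matrix(W1[, t], n, E))
    }
    sdg <- simdiag(Stinv, E * Rinv)
    Wm <- outer(d, sdg$kappa, function(di, k) di / (di + k))
    A <- crossprod(V, S1) %*% Rinv %*% sdg$Phi
    Means <- (A * Wm) %*% t(sdg$Phi)
    Ut <- Means + (matrix(rnorm(n * Tt), n) * sqrt(Wm)) %*% t(sdg$Phi)
    b1 <- V %*% Ut
    # G-by-E effects b2 ~ MN(0, Sigma_E (x) G, Sigma_t)
    W2 <- Ycur - xb(beta) - rep_b1(b1)
    W2t <- matrix(0, N, Tt)
    for (t in seq_len(Tt)) {
      W2t[, t] <- as.numeric(crossprod(V, matrix(W2[, t], n, E)) %*% Q)
    }
    svec <- as.numeric(outer(d, lam))
    sdg2 <- simdiag(St2inv, Rinv)
    Wm2 <- outer(svec, sdg2$kappa, function(si, k) si / (si + k))
    A2 <- W2t %*% Rinv %*% sdg2$Phi
    Means2 <- (A2 * Wm2) %*% t(sdg2$Phi)
    B2t <- Means2 + (matrix(rnorm(N * Tt), N) * sqrt(Wm2)) %*% t(sdg2$Phi)
    for (t in seq_len(Tt)) {
      b2[, t] <- as.numeric(V %*% matrix(B2t[, t], n, E) %*% t(Q))
    }
    # covariance components
    Q1 <- crossprod(Ut, Ut / d)
    Q2 <- crossprod(B2t, B2t / svec)
    if (is.null(fix$Sigma_t)) {
      if (separate_sigma_t) {
        St <- riwish(nu_t + n, S_t0 + Q1)
        St2 <- riwish(nu_t + N, S_t0 + Q2)
      } else {
        St <- riwish(nu_t + n + N, S_t0 + Q1 + Q2)
        St2 <- St
      }
    }
    if (is.null(fix$Sigma_E)) {
      # scale update from per-environment blocks of b2 weighted by G^-1 and
      # the trait covariance of the interaction block
      Carr <- array(0, dim = c(n, Tt, E))
      inv_sqrt_d <- 1 / sqrt(d)
      for (e in seq_len(E)) {
        rows <- which(env_of == e)
        Carr[, , e] <- inv_sqrt_d * crossprod(V, b2[rows, , drop = FALSE])
      }
      Msc <- matrix(0, E, E)
      for (e in seq_len(E)) {
        CS <- Carr[, , e] %*% St2inv
        for (e2 in seq_len(e)) {
          Msc[e, e2] <- Msc[e2, e] <- sum(CS * Carr[, , e2])
        }
      }
      SE <- riwish(nu_E + n * Tt, S_E0 + Msc)
    }
    if (is.null(fix$R)) {
      Ecur <- Ycur - xb(beta) - rep_b1(b1) - b2
      R <- riwish(nu_r + N, S_r0 + crossprod(Ecur))
    }
    if (it > burn_in && (it - burn_in - 1L) %% thin == 0L) {
      ki <- ki + 1L
      fit_now <- xb(beta) + rep_b1(b1) + b2
      mean_fit <- mean_fit + fit_now
      mean_b1 <- mean_b1 + b1; mean_b2 <- mean_b2 + b2
      mean_beta <- mean_beta + beta
      mean_St <- mean_St + St; mean_St2 <- mean_St2 + St2
      mean_SE <- mean_SE + SE; mean_R <- mean_R + R
      draws[ki, ] <- c(diag(St), diag(SE), diag(R))
    }
  }
  list(fitted = array(mean_fit / ki, dim = c(n, E, Tt)),
       b1 = mean_b1 / ki, b2 = array(mean_b2 / ki, dim = c(n, E, Tt)),
       beta = mean_beta / ki,
       Sigma_t = mean_St / ki, Sigma_t_gxe = mean_St2 / ki,
       Sigma_E = mean_SE / ki, R = mean_R / ki,
       gbar = mean(diag(G)), draws = draws)
}
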