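#' Model specification for the Bayesian GBLUP family
#'
#' Describes which of the four models to fit and how to run its Gibbs
#' sampler. The four families are: `SE` (single trait, single environment),
#' `MT` (multi-trait, one environment; genetic effects matrix-normal with
#' row covariance the kernel and an unstructured trait covariance `Sigma_t`),
#' `ME` (one trait, multiple environments; genomic main effect plus a
#' G-by-E effect whose covariance is the Hadamard product of the genomic and
#' environment incidence cross-products), and `MTME` (joint trait and
#' environment model whose G-by-E effects have row covariance
#' `Sigma_E %x% G` and column covariance `Sigma_t`).
#'
#' Default priors are weakly informative: scaled-inverse-chi-square with 5
#' degrees of freedom and prior mode at half the phenotypic variance for
#' scalar variances; inverse-Wishart with `dim + 3` degrees of freedom and
#' scale one half the diagonal phenotypic covariance for `Sigma_t`,
#' `Sigma_E` and the residual covariance `R`.
#'
#' @param model one of `"SE"`, `"MT"`, `"ME"`, `"MTME"`.
#' @param n_iter,burn_in,thin MCMC chain length, burn-in, and thinning.
#' @param seed RNG seed for the sampler.
#' @param nu_scalar prior degrees of freedom for scalar variance components.
#' @param fix optional named list of variance components to hold fixed
#'   (e.g. `list(sigma_g2 = 1, sigma_e2 = 1)` for SE, `list(Sigma_t = , R = )`
#'   for MT) — used for closed-form oracle checks.
#' @param drop_line_effect ME only: drop the IID line effect, keeping only
#'   the genomic main effect.
#' @param separate_sigma_t MTME only: give the G-by-E block its own trait
#'   covariance instead of sharing `Sigma_t` with the main genetic block.
#' @return object of class `gp_spec`.
#' @export
gp_spec <- function(model = c("SE", "MT", "ME", "MTME"),
                    n_iter = 12000L, burn_in = 2000L, thin = 5L,
                    seed = 1L, nu_scalar = 5,
                    fix = NULL, drop_line_effect = FALSE,
                    separate_sigma_t = FALSE) {
  model <- match.arg(model)
  if (burn_in >= n_iter) abort("burn_in must be smaller than n_iter")
  if (burn_in < 0L || thin < 1L) abort("need burn_in >= 0 and thin >= 1")
  structure(list(model = model, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), nu_scalar = nu_scalar, fix = fix,
                 drop_line_effect = drop_line_effect,
                 separate_sigma_t = separate_sigma_t),
            class = "gp_spec")
}

#' @export
print.gp_spec <- function(x, ...) {
  cat(sprintf("<gp_spec> %s: %d iterations (burn-in %d, thin %d), seed %d\n",
              x$model, x$n_iter, x$burn_in, x$thin, x$seed))
  invisible(x)
}

# Assemble the lines x envs x traits BLUE array from the long tibble,
# hiding any cells listed in `mask`.
blues_tensor <- function(blues, traits = NULL, envs = NULL, mask = NULL) {
  blues <- tibble::as_tibble(blues)
  traits <- traits %||% unique(blues$trait)
  envs <- envs %||% unique(blues$env)
  blues <- dplyr::filter(blues, .data$trait %in% traits, .data$env %in% envs)
  lines <- sort(unique(blues$line))
  Y <- array(NA_real_, dim = c(length(lines), length(envs), length(traits)),
             dimnames = list(lines, envs, traits))
  Y[cbind(blues$line, blues$env, blues$trait)] <- blues$blue
  if (!is.null(mask) && nrow(mask)) {
    m <- dplyr::filter(tibble::as_tibble(mask),
                       .data$env %in% envs, .data$trait %in% traits,
                       .data$line %in% lines)
    if (nrow(m)) Y[cbind(m$line, m$env, m$trait)] <- NA_real_
  }
  Y
}

align_kernel <- function(kernel, lines) {
  K <- unclass(kernel)
  missing_ids <- setdiff(lines, rownames(K))
  if (length(missing_ids)) {
    abort(sprintf("lines absent from kernel: %s",
                  paste(head(missing_ids, 5L), collapse = ", ")))
  }
  K[lines, lines]
}

#' Fit a Bayesian GBLUP-family model
#'
#' Fits the model named in `spec` by Gibbs sampling on the BLUE set, with
#' masked/missing cells treated by data augmentation (so CV2-style partial
#' information is borrowed across traits and environments). Predictions are
#' the posterior means of the fitted cell values; for masked cells this is
#' the augmented predictive mean.
#'
#' @param blues BLUE set tibble (`line, env, trait, blue`).
#' @param kernel a validated [gp_kernel] covering every line in `blues`.
#' @param spec a [gp_spec()].
#' @param trait,env scope restriction: SE needs one of each, MT one
#'   environment, ME one trait; inferred when unambiguous.
#' @param mask optional tibble of cells (`line, env, trait`) to hide from
#'   the sampler (cross-validation masking).
#' @return object of class `gp_fit`: `predictions` (tibble `line, env,
#'   trait, observed, masked, .pred`), `posterior` (component posterior
#'   means), `ess` (effective sample sizes of the variance components),
#'   `spec`, `kernel_name`.
#' @export
fit_gp <- function(blues, kernel, spec, trait = NULL, env = NULL, mask = NULL) {
  stopifnot(inherits(spec, "gp_spec"))
  blues <- tibble::as_tibble(blues)
  all_traits <- sort(unique(blues$trait))
  all_envs <- sort(unique(blues$env))
  traits <- switch(spec$model,
    SE = trait %||% if (length(all_traits) == 1L) all_traits else
      abort("SE model needs `trait`"),
    ME = trait %||% if (length(all_traits) == 1L) all_traits else
      abort("ME model needs `trait`"),
    MT = ,
    MTME = trait %||% all_traits)
  envs <- switch(spec$model,
    SE = env %||% if (length(all_envs) == 1L) all_envs else
      abort("SE model needs `env`"),
    MT = env %||% if (length(all_envs) == 1L) all_envs else
      abort("MT model needs `env`"),
    ME = ,
    MTME = env %||% all_envs)

  Y <- blues_tensor(blues, traits, envs, mask)
  lines <- dimnames(Y)[[1L]]
  K <- align_kernel(kernel, lines)
  n_obs_lines <- sum(apply(!is.na(Y), 1L, any))
  if (n_obs_lines < 2L) abort("need at least two lines with observed cells")

  res <- switch(spec$model,
    SE = {
      yv <- Y[, 1L, 1L]
      out <- sampler_se(yv, K, spec$n_iter, spec$burn_in, spec$thin,
                        spec$seed, spec$nu_scalar, spec$fix)
      fitted <- array(out$fitted, dim = dim(Y))
      list(out = out, fitted = fitted,
           posterior = list(u = setNames(out$u, lines),
                            intercept = out$intercept,
                            sigma_g2 = out$sigma_g2, sigma_e2 = out$sigma_e2))
    },
    MT = {
      Ym <- Y[, 1L, , drop = TRUE]
      Ym <- matrix(Ym, nrow = length(lines), ncol = length(traits),
                   dimnames = list(lines, traits))
      out <- sampler_mt(Ym, K, spec$n_iter, spec$burn_in, spec$thin,
                        spec$seed, spec$nu_scalar, spec$fix)
      fitted <- array(out$fitted, dim = dim(Y))
      list(out = out, fitted = fitted,
           posterior = list(u = out$u, intercept = out$intercept,
                            Sigma_t = label_sq(out$Sigma_t, traits),
                            R = label_sq(out$R, traits)))
    },
    ME = {
      Ym <- Y[, , 1L, drop = TRUE]
      Ym <- matrix(Ym, nrow = length(lines), ncol = length(envs),
                   dimnames = list(lines, envs))
      out <- sampler_me(Ym, K, spec$n_iter, spec$burn_in, spec$thin,
                        spec$seed, spec$nu_scalar, spec$fix,
                        spec$drop_line_effect)
      fitted <- array(out$fitted, dim = dim(Y))
      list(out = out, fitted = fitted,
           posterior = list(g = setNames(out$g, lines), Eg = out$Eg,
                            L = setNames(out$L, lines),
                            env_means = setNames(out$env_means, envs),
                            sigma_L2 = out$sigma_L2, sigma_g2 = out$sigma_g2,
                            sigma_Eg2 = out$sigma_Eg2, sigma_e2 = out$sigma_e2))
    },
    MTME = {
      out <- sampler_mtme(Y, K, spec$n_iter, spec$burn_in, spec$thin,
                          spec$seed, spec$nu_scalar, spec$fix,
                          spec$separate_sigma_t)
      list(out = out, fitted = out$fitted,
           posterior = list(b1 = label_mat(out$b1, lines, traits),
                            b2 = out$b2, beta = label_mat(out$beta, envs, traits),
                            Sigma_t = label_sq(out$Sigma_t, traits),
                            Sigma_t_gxe = label_sq(out$Sigma_t_gxe, traits),
                            Sigma_E = label_sq(out$Sigma_E, envs),
                            R = label_sq(out$R, traits),
                            gbar = out$gbar))
    })

  dimnames(res$fitted) <- dimnames(Y)
  preds <- array_to_tibble(res$fitted, c("line", "env", "trait"), ".pred")
  preds$observed <- !is.na(Y)[cbind(preds$line, preds$env, preds$trait)]
  if (!is.null(mask) && nrow(mask)) {
    mk <- dplyr::mutate(dplyr::select(tibble::as_tibble(mask),
                                      "line", "env", "trait"), masked = TRUE)
    preds <- dplyr::left_join(preds, mk, by = c("line", "env", "trait")) |>
      dplyr::mutate(masked = !is.na(.data$masked))
  } else {
    preds$masked <- FALSE
  }

  ess <- ess_table(res$out$draws)
  low <- dplyr::filter(ess, .data$ess < 100)
  if (nrow(low)) {
    warn(sprintf("low effective sample size (< 100) for: %s",
                 paste(low$component, collapse = ", ")))
  }
  structure(list(predictions = preds, posterior = res$posterior,
                 draws = res$out$draws, ess = ess, spec = spec,
                 kernel_name = attr(kernel, "provenance") %||% "G",
                 traits = traits, envs = envs, lines = lines),
            class = "gp_fit")
}

label_sq <- function(M, nm) { dimnames(M) <- list(nm, nm); M }
label_mat <- function(M, rn, cn) { dimnames(M) <- list(rn, cn); M }

ess_table <- function(draws) {
  tibble::tibble(component = colnames(draws),
                 ess = vapply(seq_len(ncol(draws)),
                              function(j) ess_chain(draws[, j]), numeric(1L)))
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("<gp_fit> %s (kernel %s): %d lines, %d env(s), %d trait(s); min ESS %.0f\n",
              x$spec$model, x$kernel_name, length(x$lines), length(x$envs),
              length(x$traits), min(x$ess$ess)))
  invisible(x)
}

#' Convenience wrappers for the four model families
#'
#' Thin wrappers around [fit_gp()] with the family preset.
#'
#' @inheritParams fit_gp
#' @param ... passed to [gp_spec()].
#' @export
fit_se <- function(blues, kernel, trait = NULL, env = NULL, mask = NULL, ...) {
  fit_gp(blues, kernel, gp_spec("SE", ...), trait = trait, env = env, mask = mask)
}

#' @rdname fit_se
#' @export
fit_mt <- function(blues, kernel, env = NULL, mask = NULL, ...) {
  fit_gp(blues, kernel, gp_spec("MT", ...), env = env, mask = mask)
}

#' @rdname fit_se
#' @export
fit_me <- function(blues, kernel, trait = NULL, mask = NULL, ...) {
  fit_gp(blues, kernel, gp_spec("ME", ...), trait = trait, mask = mask)
}

#' @rdname fit_se
#' @export
fit_mtme <- function(blues, kernel, mask = NULL, ...) {
  fit_gp(blues, kernel, gp_spec("MTME", ...), mask = mask)
}

#' Predict cell values from a fitted model
#'
#' Returns the posterior predictive mean for each requested (line,
#' environment, trait) cell: the posterior mean fitted value for cells
#' observed during fitting, the augmented predictive mean for masked cells.
#'
#' @param object a `gp_fit`.
#' @param targets tibble with columns `line, env, trait` (an empty tibble
#'   returns an empty result; duplicated targets return duplicated rows).
#' @param ... unused.
#' @return `targets` with a `.pred` column appended.
#' @export
predict.gp_fit <- function(object, targets, ...) {
  targets <- tibble::as_tibble(targets)
  if (!nrow(targets)) {
    return(dplyr::mutate(targets, .pred = numeric(0)))
  }
  unknown <- setdiff(unique(targets$line), object$lines)
  if (length(unknown)) {
    abort(sprintf("unknown line(s): %s", paste(unknown, collapse = ", ")))
  }
  bad_env <- setdiff(unique(targets$env), object$envs)
  bad_tr <- setdiff(unique(targets$trait), object$traits)
  if (length(bad_env) || length(bad_tr)) {
    abort(sprintf("targets outside the fitted scope: %s",
                  paste(c(bad_env, bad_tr), collapse = ", ")))
  }
  dplyr::left_join(targets,
                   dplyr::select(object$predictions, "line", "env", "trait",
                                 ".pred"),
                   by = c("line", "env", "trait"))
}

#' @describeIn fit_gp genetic effects per line (and trait) as a tibble.
#' @param x a `gp_fit`.
#' @param ... unused.
#' @method tidy gp_fit
#' @export
tidy.gp_fit <- function(x, ...) {
  p <- x$posterior
  if (x$spec$model == "SE") {
    tibble::tibble(line = names(p$u), trait = x$traits, effect = unname(p$u))
  } else if (x$spec$model == "MT") {
    array_to_tibble(label_mat(p$u, x$lines, x$traits),
                    c("line", "trait"), "effect")
  } else if (x$spec$model == "ME") {
    tibble::tibble(line = names(p$g), trait = x$traits, effect = unname(p$g))
  } else {
    array_to_tibble(p$b1, c("line", "trait"), "effect")
  }
}

#' @describeIn fit_gp one-row model summary (variance components, minimum
#'   effective sample size).
#' @method glance gp_fit
#' @export
glance.gp_fit <- function(x, ...) {
  p <- x$posterior
  base <- tibble::tibble(model = x$spec$model, kernel = x$kernel_name,
                         n_lines = length(x$lines), n_envs = length(x$envs),
                         n_traits = length(x$traits),
                         n_iter = x$spec$n_iter, min_ess = min(x$ess$ess))
  extra <- switch(x$spec$model,
    SE = tibble::tibble(sigma_g2 = p$sigma_g2, sigma_e2 = p$sigma_e2,
                        h2 = p$sigma_g2 / (p$sigma_g2 + p$sigma_e2)),
    ME = tibble::tibble(sigma_g2 = p$sigma_g2, sigma_Eg2 = p$sigma_Eg2,
                        sigma_L2 = p$sigma_L2, sigma_e2 = p$sigma_e2),
    MT = tibble::tibble(mean_genetic_var = mean(diag(p$Sigma_t)),
                        mean_resid_var = mean(diag(p$R))),
    MTME = tibble::tibble(mean_genetic_var = mean(diag(p$Sigma_t)),
                          mean_gxe_scale = mean(diag(p$Sigma_E)),
                          mean_resid_var = mean(diag(p$R))))
  dplyr::bind_cols(base, extra)
}

#' Per-trait genomic heritability implied by a fitted model
#'
#' For each trait, the ratio of model genetic variance (main plus G-by-E
#' where the model has one) to genetic-plus-residual variance, averaged over
#' environments, on the BLUE scale. For an entry-mean simulation this
#' estimates the entry-mean heritability used to generate the data.
#'
#' @param fit a `gp_fit`.
#' @return tibble `trait, h2`.
#' @export
genomic_h2 <- function(fit) {
  p <- fit$posterior
  h2 <- switch(fit$spec$model,
    SE = p$sigma_g2 / (p$sigma_g2 + p$sigma_e2),
    MT = diag(as.matrix(p$Sigma_t)) /
      (diag(as.matrix(p$Sigma_t)) + diag(as.matrix(p$R))),
    ME = (p$sigma_g2 + p$sigma_Eg2 + p$sigma_L2) /
      (p$sigma_g2 + p$sigma_Eg2 + p$sigma_L2 + p$sigma_e2),
    MTME = {
      gbar <- p$gbar %||% 1
      vt <- diag(as.matrix(p$Sigma_t)) * gbar
      vge <- diag(as.matrix(p$Sigma_t_gxe)) * gbar * mean(diag(as.matrix(p$Sigma_E)))
      (vt + vge) / (vt + vge + diag(as.matrix(p$R)))
    })
  tibble::tibble(trait = fit$traits, h2 = as.numeric(h2))
}

#' Draw G-by-E effects from their matrix-variate prior
#'
#' Draws `n_draws` independent realisations of the G-by-E effect matrix
#' `b2 ~ MN(0, Sigma_E %x% G, Sigma_t)` and returns them vectorised (line
#' index fastest, then environment, then trait), so the covariance of the
#' returned draws is `Sigma_t %x% Sigma_E %x% G`. This exposes the exact
#' sampling route used inside the MTME Gibbs sampler for prior-predictive
#' checking.
#'
#' @param n_draws number of draws.
#' @param kernel line kernel G.
#' @param Sigma_E,Sigma_t environment and trait covariances.
#' @param seed RNG seed.
#' @return matrix `n_draws` x `(n_lines * n_envs * n_traits)`.
#' @export
sample_gxe_prior <- function(n_draws, kernel, Sigma_E, Sigma_t, seed = 1L) {
  G <- unclass(kernel)
  n <- nrow(G); E <- nrow(Sigma_E); Tt <- nrow(Sigma_t)
  eg <- eigen_psd(G, floor = 0)
  Lg <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
  ee <- eigen_psd(Sigma_E, floor = 0)
  Le <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), E)
  et <- eigen_psd(Sigma_t, floor = 0)
  Lt <- et$vectors %*% diag(sqrt(pmax(et$values, 0)), Tt)
  out <- matrix(0, n_draws, n * E * Tt)
  set.seed(seed)
  for (k in seq_len(n_draws)) {
    Z <- matrix(rnorm(n * E * Tt), n * E, Tt)
    # row transform (Le (x) Lg), column transform Lt'
    B <- matrix(0, n * E, Tt)
    for (t in seq_len(Tt)) {
      B[, t] <- as.numeric(Lg %*% matrix(Z[, t], n, E) %*% t(Le))
    }
    out[k, ] <- as.numeric(B %*% t(Lt))
  }
  out
}
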