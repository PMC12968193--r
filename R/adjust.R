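#' Per-environment adjusted means (BLUEs)
#'
#' Fits, for one trait in one environment, the plot-level linear mixed model
#' `value ~ genotype + (1 | rep) + (1 | rep:block)` by REML with the genotype
#' as a fixed effect, and returns the per-line adjusted means (BLUEs) on the
#' trait scale together with their standard errors. Variance components and
#' the entry-mean broad-sense heritability come from a companion refit with
#' the genotype as a random effect (same model otherwise) — the standard
#' two-stage practice for stage-one analysis of replicated trials.
#'
#' With a single replicate and a single block the design is singular for the
#' mixed model; the function then falls back to plain per-line means with a
#' warning.
#'
#' @param pheno plot-level phenotype table: columns `line, env, rep, block,
#'   trait, value`.
#' @param trait,env which trait/environment to adjust.
#' @return object of class `blue_fit` with elements `blues` (tibble `line,
#'   blue, se`), `varcomp` (named vector `sigma_g2, sigma_rep2, sigma_block2,
#'   sigma_eps2`), `h2`, `r_harmonic`, `trait`, `env`, `singular`.
#' @seealso [adjust_phenotypes()] for all trait-environment combinations.
#' @export
compute_blues <- function(pheno, trait, env) {
  dat <- dplyr::filter(tibble::as_tibble(pheno),
                       .data$trait == !!trait, .data$env == !!env,
                       !is.na(.data$value))
  if (!nrow(dat)) abort(sprintf("trait '%s' absent in environment '%s'", trait, env))
  if (dplyr::n_distinct(dat$line) < 2L)
    abort("need at least two lines with data")
  dat$line <- factor(dat$line)
  dat$rep_f <- factor(dat$rep)
  dat$blk_f <- factor(paste(dat$rep, dat$block, sep = ":"))

  reps_per_line <- table(dat$line)
  r_harm <- length(reps_per_line) / sum(1 / as.numeric(reps_per_line))

  singular_design <- dplyr::n_distinct(dat$rep_f) < 2L &&
    dplyr::n_distinct(dat$blk_f) < 2L
  if (singular_design) {
    warn("single replicate and block: falling back to plain line means")
    blues <- dat |>
      dplyr::group_by(line = as.character(.data$line)) |>
      dplyr::summarise(blue = mean(.data$value), se = NA_real_,
                       .groups = "drop")
    vc <- c(sigma_g2 = stats::var(blues$blue), sigma_rep2 = 0,
            sigma_block2 = 0, sigma_eps2 = NA_real_)
    return(structure(list(blues = blues, varcomp = vc, h2 = NA_real_,
                          r_harmonic = r_harm, trait = trait, env = env,
                          singular = TRUE),
                     class = "blue_fit"))
  }

  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8,
                                           maxeval = 2000L))
  # only keep random terms whose grouping factor has >= 2 levels
  rterms <- c(if (nlevels(dat$rep_f) > 1L) "(1 | rep_f)",
              if (nlevels(dat$blk_f) > 1L) "(1 | blk_f)")
  # genotype fixed, cell-mean coding so coefficients are per-line adjusted
  # means on the trait scale
  fml_f <- stats::reformulate(c("0", "line", rterms), response = "value")
  fml_r <- stats::reformulate(c("1", "(1 | line)", rterms), response = "value")
  fit_f <- suppressMessages(suppressWarnings(
    lme4::lmer(fml_f, data = dat, REML = TRUE, control = ctrl)))
  beta <- lme4::fixef(fit_f)
  se <- sqrt(Matrix::diag(stats::vcov(fit_f)))
  blues <- tibble::tibble(line = sub("^line", "", names(beta)),
                          blue = as.numeric(beta), se = as.numeric(se))

  # genotype random, same model otherwise, for variance components and h2
  fit_r <- suppressMessages(suppressWarnings(
    lme4::lmer(fml_r, data = dat, REML = TRUE, control = ctrl)))
  vcs <- as.data.frame(lme4::VarCorr(fit_r))
  pick <- function(g) {
    v <- vcs$vcov[vcs$grp == g]
    if (length(v)) v[1L] else 0
  }
  vc <- c(sigma_g2 = pick("line"), sigma_rep2 = pick("rep_f"),
          sigma_block2 = pick("blk_f"), sigma_eps2 = pick("Residual"))

  out <- structure(list(blues = blues, varcomp = vc, h2 = NA_real_,
                        r_harmonic = r_harm, trait = trait, env = env,
                        singular = FALSE, fit_random = fit_r),
                   class = "blue_fit")
  out$h2 <- estimate_h2(out)
  out
}

#' @export
print.blue_fit <- function(x, ...) {
  cat(sprintf("<blue_fit> trait %s, env %s: %d lines, h2 = %.3f\n",
              x$trait, x$env, nrow(x$blues), x$h2))
  invisible(x)
}

#' @describeIn compute_blues per-line adjusted means as a tibble.
#' @param x a `blue_fit`.
#' @param ... unused.
#' @method tidy blue_fit
#' @export
tidy.blue_fit <- function(x, ...) {
  dplyr::mutate(x$blues, env = x$env, trait = x$trait,
                .after = "line")
}

#' @describeIn compute_blues one-row summary (variance components, h2).
#' @method glance blue_fit
#' @export
glance.blue_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, env = x$env, n_lines = nrow(x$blues),
                 sigma_g2 = x$varcomp[["sigma_g2"]],
                 sigma_rep2 = x$varcomp[["sigma_rep2"]],
                 sigma_block2 = x$varcomp[["sigma_block2"]],
                 sigma_eps2 = x$varcomp[["sigma_eps2"]],
                 r_harmonic = x$r_harmonic, h2 = x$h2,
                 singular = x$singular)
}

#' Entry-mean broad-sense heritability
#'
#' `h2 = sigma_g2 / (sigma_g2 + sigma_eps2 / r)` with `r` the harmonic mean
#' of the per-line replicate counts (entry-mean basis, the repeatability of
#' genotype means). `basis = "plot"` gives the plot-level ratio
#' `sigma_g2 / (sigma_g2 + sigma_eps2)`; `basis = "cullis"` the
#' Cullis/Smith generalised heritability `1 - vBLUP / (2 sigma_g2)` using the
#' mean conditional variance of the genotype BLUPs.
#'
#' @param fit a `blue_fit` from [compute_blues()].
#' @param basis heritability definition, see Details.
#' @return scalar in \[0, 1\] (or `NA` with a warning when undefined).
#' @export
estimate_h2 <- function(fit, basis = c("entry_mean", "plot", "cullis")) {
  basis <- match.arg(basis)
  vc <- fit$varcomp
  sg <- vc[["sigma_g2"]]; se2 <- vc[["sigma_eps2"]]
  if (is.na(sg) || is.na(se2) || (sg + se2) == 0) {
    warn("heritability undefined: zero total variance")
    return(NA_real_)
  }
  switch(basis,
    entry_mean = sg / (sg + se2 / fit$r_harmonic),
    plot = sg / (sg + se2),
    cullis = {
      if (is.null(fit$fit_random)) {
        warn("Cullis heritability needs the random-genotype refit")
        return(NA_real_)
      }
      re <- lme4::ranef(fit$fit_random, condVar = TRUE)$line
      pv <- as.numeric(attr(re, "postVar"))
      # prediction-error variance of a difference ~ 2 * mean conditional var
      max(0, min(1, 1 - mean(pv) / sg))
    }
  )
}

#' Adjusted means for every trait-environment combination
#'
#' Runs [compute_blues()] over all (trait, environment) pairs present in the
#' data and returns the adjusted means as one long tibble (a "BLUE set"),
#' with the per-fit variance components and heritabilities retrievable via
#' [varcomp_table()].
#'
#' @param pheno plot-level phenotype table (`line, env, rep, block, trait,
#'   value`).
#' @param traits,envs optional subsets; default all present.
#' @return tibble `line, env, trait, blue, se` of class `blue_set`, carrying
#'   the individual `blue_fit` objects as attribute `"fits"`.
#' @export
adjust_phenotypes <- function(pheno, traits = NULL, envs = NULL) {
  pheno <- tibble::as_tibble(pheno)
  traits <- traits %||% unique(pheno$trait)
  envs <- envs %||% unique(pheno$env)
  grid <- tidyr::expand_grid(trait = traits, env = envs)
  fits <- purrr::pmap(grid, function(trait, env) {
    has <- any(pheno$trait == trait & pheno$env == env & !is.na(pheno$value))
    if (!has) return(NULL)
    compute_blues(pheno, trait, env)
  })
  fits <- fits[!vapply(fits, is.null, logical(1L))]
  out <- purrr::map_dfr(fits, tidy) |>
    dplyr::select("line", "env", "trait", "blue", "se")
  names(fits) <- vapply(fits, function(f) paste(f$trait, f$env, sep = "@"),
                        character(1L))
  structure(out, fits = fits, class = c("blue_set", class(out)))
}

#' @describeIn adjust_phenotypes variance components and heritabilities of
#'   every underlying fit, one row per trait-environment combination.
#' @param blues a `blue_set` from `adjust_phenotypes()`.
#' @export
varcomp_table <- function(blues) {
  fits <- attr(blues, "fits")
  if (is.null(fits)) abort("no fits attached: was this made by adjust_phenotypes()?")
  purrr::map_dfr(fits, glance)
}

#' Pairwise trait correlations within an environment
#'
#' Pearson correlations between per-line adjusted means of every trait pair,
#' with two-sided p-values and significance stars at 0.05 / 0.01 / 0.001.
#' Missing cells are handled pairwise-complete; pairs with fewer than three
#' complete observations are reported as `NA` with a warning.
#'
#' @param blues BLUE set tibble (`line, env, trait, blue`).
#' @param env environment to restrict to.
#' @return tibble `trait1, trait2, r, p, stars, n`.
#' @export
trait_correlations <- function(blues, env) {
  wide <- blues |>
    dplyr::filter(.data$env == !!env) |>
    tidyr::pivot_wider(id_cols = "line", names_from = "trait",
                       values_from = "blue")
  traits <- setdiff(names(wide), "line")
  pairs <- tidyr::expand_grid(trait1 = traits, trait2 = traits)
  purrr::pmap_dfr(pairs, function(trait1, trait2) {
    x <- wide[[trait1]]; y <- wide[[trait2]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L) {
      warn(sprintf("fewer than 3 complete pairs for %s-%s", trait1, trait2))
      return(tibble::tibble(trait1, trait2, r = NA_real_, p = NA_real_,
                            stars = NA_character_, n = sum(ok)))
    }
    if (identical(trait1, trait2)) {
      return(tibble::tibble(trait1, trait2, r = 1, p = 0, stars = "***",
                            n = sum(ok)))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(trait1, trait2, r = unname(ct$estimate), p = ct$p.value,
                   stars = p_stars(ct$p.value), n = sum(ok))
  })
}

#' Between-environment correlations for one trait
#'
#' Pearson correlation between the per-line adjusted means of each pair of
#' environments, with row/column order from average-linkage hierarchical
#' clustering on the dissimilarity `1 - r` (the order used by the heatmap
#' displays).
#'
#' @param blues BLUE set tibble (`line, env, trait, blue`).
#' @param trait trait to restrict to.
#' @return tibble `env1, env2, r, p, n` of class `env_cor`, with the
#'   clustering order in attribute `"order"`.
#' @export
env_correlations <- function(blues, trait) {
  wide <- blues |>
    dplyr::filter(.data$trait == !!trait) |>
    tidyr::pivot_wider(id_cols = "line", names_from = "env",
                       values_from = "blue")
  envs <- setdiff(names(wide), "line")
  M <- as.matrix(wide[envs])
  R <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  n_pair <- crossprod(!is.na(M))
  if (any(n_pair < 3L & upper.tri(n_pair)))
    warn("some environment pairs have fewer than 3 complete lines")
  R[n_pair < 3L] <- NA
  diag(R) <- 1
  D <- 1 - R
  D[is.na(D)] <- max(D, na.rm = TRUE)
  ord <- if (length(envs) > 2L) {
    envs[stats::hclust(stats::as.dist(D), method = "average")$order]
  } else envs
  out <- array_to_tibble(R, c("env1", "env2"), "r") |>
    dplyr::mutate(n = as.integer(n_pair[cbind(.data$env1, .data$env2)]))
  structure(out, order = ord, trait = trait,
            class = c("env_cor", class(out)))
}
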