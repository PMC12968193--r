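#' Simulation configuration for a replicated multi-environment trial
#'
#' Describes the generative world for a durum-wheat style panel: a set of
#' inbred lines genotyped at biallelic SNPs, a handful of characterised
#' target genes, and replicated plot trials across sowing-by-season
#' environments for several correlated traits. Defaults emulate the design
#' of a 186-line panel grown under three sowing dates over three seasons
#' (8 environments), with seven spike/phenology traits, strong positive
#' covariance among yield components and per-environment entry-mean
#' heritabilities in the 0.30-0.95 band.
#'
#' @param n_lines,n_markers panel size and SNP count.
#' @param maf_range bounds for the uniform draw of marker allele frequencies.
#' @param gene_spec list of target genes, each a list with elements `name`,
#'   `alleles` (labels), `freq` (summing to 1) and optionally `effects`
#'   (alleles-by-traits additive effect matrix, default all zero so the
#'   purely polygenic simulation is the base case).
#' @param env_labels environment labels, `"<sowing>_<season>"` strings.
#' @param trait_names trait labels.
#' @param Sigma_t trait-by-trait genetic covariance of the polygenic values.
#' @param Sigma_E environment-by-environment covariance of the G-by-E
#'   effects, on the scale of `Sigma_t` (i.e. `diag(Sigma_E)` is the G-by-E
#'   variance as a fraction of the main genetic variance).
#' @param env_means environments-by-traits matrix of fixed means.
#' @param h2_target entry-mean heritability target: scalar, per-trait vector,
#'   or environments-by-traits matrix, values in (0, 1].
#' @param n_reps,n_blocks_per_rep replication and incomplete-block counts.
#' @param rep_var_frac,block_var_frac replication and block(rep) variances as
#'   fractions of the total per-environment genetic variance.
#' @param missing_rate fraction of plots dropped at random (default 0).
#' @param seed single master seed; every stochastic stage derives its own
#'   sub-stream from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 186L,
                       n_markers = 2000L,
                       maf_range = c(0.05, 0.5),
                       gene_spec = default_gene_spec(trait_names),
                       env_labels = default_env_labels(),
                       trait_names = c("GN", "GW", "NS", "SL", "SW", "HD", "PH"),
                       Sigma_t = default_sigma_t(trait_names),
                       Sigma_E = default_sigma_e(env_labels),
                       env_means = default_env_means(env_labels, trait_names),
                       h2_target = default_h2(trait_names),
                       n_reps = 2L,
                       n_blocks_per_rep = 2L,
                       rep_var_frac = 0.05,
                       block_var_frac = 0.05,
                       missing_rate = 0,
                       seed = 1L) {
  if (length(maf_range) != 2L || maf_range[1L] <= 0 ||
      maf_range[1L] > maf_range[2L] || maf_range[2L] > 0.5) {
    abort("maf_range must satisfy 0 < low <= high <= 0.5")
  }
  if (anyDuplicated(env_labels)) abort("env_labels must be unique")
  n_envs <- length(env_labels)
  n_traits <- length(trait_names)
  Sigma_t <- as.matrix(Sigma_t)
  Sigma_E <- as.matrix(Sigma_E)
  check_psd <- function(S, name, dim_want) {
    if (!isTRUE(all.equal(dim(S), c(dim_want, dim_want))) )
      abort(sprintf("%s must be %d x %d", name, dim_want, dim_want))
    if (max(abs(S - t(S))) > 1e-8) abort(sprintf("%s must be symmetric", name))
    if (min(eigen(sym(S), symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      abort(sprintf("%s must be positive semidefinite", name))
  }
  check_psd(Sigma_t, "Sigma_t", n_traits)
  check_psd(Sigma_E, "Sigma_E", n_envs)
  dimnames(Sigma_t) <- list(trait_names, trait_names)
  dimnames(Sigma_E) <- list(env_labels, env_labels)

  # normalise h2 to an envs x traits matrix
  h2 <- h2_target
  if (is.null(dim(h2))) {
    if (length(h2) == 1L) h2 <- rep(h2, n_traits)
    if (length(h2) != n_traits) abort("h2_target must be scalar, per-trait, or envs x traits")
    h2 <- matrix(h2, n_envs, n_traits, byrow = TRUE)
  }
  h2 <- as.matrix(h2)
  dimnames(h2) <- list(env_labels, trait_names)
  if (any(h2 <= 0 | h2 > 1)) abort("h2_target values must lie in (0, 1]")

  env_means <- as.matrix(env_means)
  dimnames(env_means) <- list(env_labels, trait_names)

  for (g in gene_spec) {
    if (abs(sum(g$freq) - 1) > 1e-8)
      abort(sprintf("allele frequencies of gene '%s' must sum to 1", g$name))
    if (length(g$freq) != length(g$alleles))
      abort(sprintf("gene '%s': one frequency per allele required", g$name))
  }

  structure(list(
    n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
    maf_range = maf_range, gene_spec = gene_spec,
    env_labels = env_labels, n_envs = n_envs,
    trait_names = trait_names, n_traits = n_traits,
    Sigma_t = Sigma_t, Sigma_E = Sigma_E, env_means = env_means,
    h2_target = h2, n_reps = as.integer(n_reps),
    n_blocks_per_rep = as.integer(n_blocks_per_rep),
    rep_var_frac = rep_var_frac, block_var_frac = block_var_frac,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d lines, %d markers, %d envs, %d traits, %d reps, seed %d\n",
              x$n_lines, x$n_markers, x$n_envs, x$n_traits, x$n_reps, x$seed))
  invisible(x)
}

#' @rdname sim_config
#' @export
default_env_labels <- function() {
  c("1_2021-2022", "2_2021-2022", "3_2021-2022",
    "1_2022-2023", "2_2022-2023", "3_2022-2023",
    "2_2023-2024", "3_2023-2024")
}

#' @rdname sim_config
#' @export
default_gene_spec <- function(trait_names = c("GN", "GW", "NS", "SL", "SW", "HD", "PH")) {
  list(
    list(name = "Vrn-A1", alleles = c("winter", "spring"), freq = c(0.6, 0.4)),
    list(name = "Ppd-A1", alleles = c("sensitive", "insensitive"), freq = c(0.5, 0.5)),
    list(name = "Ppd-B1", alleles = c("a", "b", "c"), freq = c(0.4, 0.35, 0.25)),
    list(name = "Rht-B1", alleles = c("tall", "dwarf"), freq = c(0.7, 0.3))
  )
}

# Per-trait genetic standard deviations on the trait scale (spikes/plot
# means); chosen to sit inside the phenotypic ranges of a Mediterranean
# durum panel.
trait_scales <- function(trait_names) {
  scales <- c(GN = 6, GW = 0.3, NS = 1.2, SL = 0.8, SW = 0.4, HD = 4, PH = 7)
  out <- scales[trait_names]
  out[is.na(out)] <- 1
  names(out) <- trait_names
  out
}

#' @rdname sim_config
#' @export
default_sigma_t <- function(trait_names = c("GN", "GW", "NS", "SL", "SW", "HD", "PH")) {
  n <- length(trait_names)
  yield <- intersect(trait_names, c("GN", "GW", "NS", "SL", "SW"))
  R <- matrix(0.2, n, n, dimnames = list(trait_names, trait_names))
  R[yield, yield] <- 0.6   # strong positive covariance among yield components
  if (all(c("HD", "PH") %in% trait_names)) R["HD", "PH"] <- R["PH", "HD"] <- 0.3
  diag(R) <- 1
  s <- trait_scales(trait_names)
  sym(diag(s, n) %*% R %*% diag(s, n))
}

#' @rdname sim_config
#' @export
default_sigma_e <- function(env_labels = default_env_labels()) {
  n <- length(env_labels)
  # G-by-E variance = half the main genetic variance, mildly correlated
  # across environments
  R <- matrix(0.25, n, n)
  diag(R) <- 1
  0.5 * R
}

#' @rdname sim_config
#' @export
default_env_means <- function(env_labels = default_env_labels(),
                              trait_names = c("GN", "GW", "NS", "SL", "SW", "HD", "PH")) {
  base <- c(GN = 45, GW = 1.8, NS = 18, SL = 8.5, SW = 2.2, HD = 120, PH = 85)
  b <- base[trait_names]; b[is.na(b)] <- 0
  s <- trait_scales(trait_names)
  shift <- seq(-1, 1, length.out = length(env_labels))
  out <- outer(shift, 0.5 * s) + matrix(b, length(env_labels),
                                        length(trait_names), byrow = TRUE)
  dimnames(out) <- list(env_labels, trait_names)
  out
}

#' @rdname sim_config
#' @export
default_h2 <- function(trait_names = c("GN", "GW", "NS", "SL", "SW", "HD", "PH")) {
  h <- c(GN = 0.45, GW = 0.42, NS = 0.70, SL = 0.70, SW = 0.50,
         HD = 0.90, PH = 0.85)
  out <- h[trait_names]
  out[is.na(out)] <- 0.5
  names(out) <- trait_names
  out
}

#' Simulate SNP genotypes
#'
#' Marker allele frequencies are drawn uniformly within `maf_range` and
#' dosages sampled binomially (Hardy-Weinberg proportions), giving a panel
#' whose VanRaden kernel has expected unit mean diagonal.
#'
#' @param config a [sim_config()].
#' @return tibble: first column `line`, remaining columns marker dosages.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_lines < 2L || config$n_markers < 1L)
    abort("need n_lines >= 2 and n_markers >= 1")
  withr::with_seed(derive_seed(config$seed, 11L), {
    p <- runif(config$n_markers, config$maf_range[1L], config$maf_range[2L])
    M <- vapply(p, function(pi) rbinom(config$n_lines, 2L, pi),
                integer(config$n_lines))
  })
  dimnames(M) <- list(line_ids(config), sprintf("M%04d", seq_len(config$n_markers)))
  tibble::as_tibble(M, rownames = "line")
}

line_ids <- function(config) sprintf("L%03d", seq_len(config$n_lines))

#' Simulate target-gene allele calls
#'
#' One categorical allele label per line per gene, sampled from the declared
#' per-gene allele frequencies.
#'
#' @param config a [sim_config()].
#' @return tibble: column `line` plus one column per gene; the per-allele
#'   trait effects declared in `gene_spec` are attached as attribute
#'   `"effects"` for downstream truth injection.
#' @export
simulate_target_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$gene_spec)) abort("gene_spec is empty")
  withr::with_seed(derive_seed(config$seed, 23L), {
    cols <- lapply(config$gene_spec, function(g) {
      sample(g$alleles, config$n_lines, replace = TRUE, prob = g$freq)
    })
  })
  names(cols) <- vapply(config$gene_spec, `[[`, character(1L), "name")
  out <- tibble::tibble(line = line_ids(config), !!!cols)
  attr(out, "effects") <- lapply(config$gene_spec, function(g) g$effects)
  names(attr(out, "effects")) <- names(cols)
  out
}

#' Simulate true genetic and G-by-E effects
#'
#' Polygenic values are drawn matrix-normally with row covariance given by
#' the genomic kernel and column covariance `Sigma_t`; G-by-E effects with
#' row covariance `Sigma_E %x% G` and column covariance `Sigma_t`. Declared
#' target-gene additive effects (if any) are added on top of the polygenic
#' draw.
#'
#' @param config a [sim_config()].
#' @param kernel_G line-by-line relationship kernel (see [vanraden_g()]);
#'   identity if `NULL`.
#' @param genes optional target-gene table from [simulate_target_genes()]
#'   whose declared effects are injected additively.
#' @return object of class `true_effects` with elements `genetic_values`
#'   (lines x traits), `gxe_values` (lines x envs x traits) and
#'   `env_trait_means`.
#' @export
simulate_true_effects <- function(config, kernel_G = NULL, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_lines
  ids <- line_ids(config)
  if (is.null(kernel_G)) {
    G <- diag(n); dimnames(G) <- list(ids, ids)
  } else {
    G <- unclass(kernel_G)[ids, ids]
  }
  eg <- tryCatch(eigen_psd(G, floor = 0),
                 error = function(e) abort("kernel_G is not a valid covariance"))
  if (min(eigen(sym(config$Sigma_t), symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    abort("Sigma_t is not positive semidefinite")
  if (min(eigen(sym(config$Sigma_E), symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    abort("Sigma_E is not positive semidefinite")
  Lg <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
  et <- eigen_psd(config$Sigma_t, floor = 0)
  Lt <- et$vectors %*% diag(sqrt(pmax(et$values, 0)), config$n_traits)
  ee <- eigen_psd(config$Sigma_E, floor = 0)
  Le <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), config$n_envs)

  withr::with_seed(derive_seed(config$seed, 37L), {
    b1 <- rmatnorm_chol(matrix(0, n, config$n_traits), Lg, Lt)
    # b2: row covariance Sigma_E (x) G, column covariance Sigma_t.
    # Draw per trait-dimension in the (line, env) tensor layout.
    Z <- array(rnorm(n * config$n_envs * config$n_traits),
               dim = c(n, config$n_envs, config$n_traits))
    W <- array(0, dim = dim(Z))
    for (s in seq_len(config$n_traits)) W[, , s] <- Lg %*% Z[, , s] %*% t(Le)
    b2 <- array(0, dim = dim(Z))
    for (t in seq_len(config$n_traits)) {
      acc <- matrix(0, n, config$n_envs)
      for (s in seq_len(config$n_traits)) {
        if (Lt[t, s] != 0) acc <- acc + Lt[t, s] * W[, , s]
      }
      b2[, , t] <- acc
    }
  })
  dimnames(b1) <- list(ids, config$trait_names)
  dimnames(b2) <- list(ids, config$env_labels, config$trait_names)

  if (!is.null(genes)) {
    effects <- attr(genes, "effects")
    for (g in names(effects)) {
      eff <- effects[[g]]
      if (is.null(eff)) next
      eff <- as.matrix(eff)  # alleles x traits
      alle <- as.character(genes[[g]])
      rn <- rownames(eff) %||% unique(alle)
      add <- eff[match(alle, rn), config$trait_names, drop = FALSE]
      add[is.na(add)] <- 0
      b1 <- b1 + add[match(ids, as.character(genes$line)), , drop = FALSE]
    }
  }

  structure(list(genetic_values = b1, gxe_values = b2,
                 env_trait_means = config$env_means,
                 gbar = mean(diag(G))),
            class = "true_effects")
}

#' @export
print.true_effects <- function(x, ...) {
  d <- dim(x$gxe_values)
  cat(sprintf("<true_effects> %d lines, %d envs, %d traits\n", d[1L], d[2L], d[3L]))
  invisible(x)
}

#' @describeIn simulate_true_effects long tibble of the true effects.
#' @param x a `true_effects` object.
#' @param ... unused.
#' @method tidy true_effects
#' @export
tidy.true_effects <- function(x, ...) {
  g <- array_to_tibble(x$genetic_values, c("line", "trait"), "genetic")
  ge <- array_to_tibble(x$gxe_values, c("line", "env", "trait"), "gxe")
  dplyr::left_join(ge, g, by = c("line", "trait")) |>
    dplyr::select("line", "env", "trait", "genetic", "gxe")
}

#' Simulate replicated plot-level trials
#'
#' Plot values are the sum of the environment-trait mean, the line's genetic
#' value, its G-by-E deviation, a replication effect, a block-within-rep
#' effect, and residual noise. The residual variance for each environment and
#' trait is back-calculated from the entry-mean heritability target via
#' `sigma_eps^2 = r * sigma_g^2 * (1 - h2) / h2` with `r = n_reps`, where
#' `sigma_g^2` is the total per-environment genetic variance (main + G-by-E)
#' implied by the configuration.
#'
#' @param true_effects a [simulate_true_effects()] result.
#' @param config the matching [sim_config()].
#' @return tibble with columns `line, env, rep, block, trait, value`.
#' @export
simulate_trials <- function(true_effects, config) {
  stopifnot(inherits(true_effects, "true_effects"), inherits(config, "sim_config"))
  if (config$n_reps < 1L || config$n_blocks_per_rep < 1L)
    abort("design counts must be positive")
  n <- config$n_lines
  ids <- line_ids(config)
  gbar <- true_effects$gbar %||% 1
  # per (env, trait) variances implied by the generative covariances
  sig_g2 <- outer(1 + diag(config$Sigma_E), diag(config$Sigma_t) * gbar)
  h2 <- config$h2_target
  sig_e2 <- ifelse(h2 >= 1, 0, config$n_reps * sig_g2 * (1 - h2) / h2)
  sig_rep2 <- config$rep_var_frac * sig_g2
  sig_blk2 <- config$block_var_frac * sig_g2

  withr::with_seed(derive_seed(config$seed, 53L), {
    plots <- tidyr::expand_grid(env = config$env_labels,
                                rep = seq_len(config$n_reps),
                                line = ids)
    # random allocation of lines to incomplete blocks within each rep
    plots <- plots |>
      dplyr::group_by(.data$env, .data$rep) |>
      dplyr::mutate(block = sample(rep_len(seq_len(config$n_blocks_per_rep),
                                           dplyr::n()))) |>
      dplyr::ungroup()
    rep_eff <- tidyr::expand_grid(env = config$env_labels,
                                  rep = seq_len(config$n_reps),
                                  trait = config$trait_names) |>
      dplyr::mutate(rep_eff = rnorm(dplyr::n()) *
                      sqrt(sig_rep2[cbind(.data$env, .data$trait)]))
    blk_eff <- tidyr::expand_grid(env = config$env_labels,
                                  rep = seq_len(config$n_reps),
                                  block = seq_len(config$n_blocks_per_rep),
                                  trait = config$trait_names) |>
      dplyr::mutate(blk_eff = rnorm(dplyr::n()) *
                      sqrt(sig_blk2[cbind(.data$env, .data$trait)]))
    out <- tidyr::expand_grid(plots, trait = config$trait_names) |>
      dplyr::left_join(rep_eff, by = c("env", "rep", "trait")) |>
      dplyr::left_join(blk_eff, by = c("env", "rep", "block", "trait")) |>
      dplyr::mutate(
        mu = true_effects$env_trait_means[cbind(.data$env, .data$trait)],
        gen = true_effects$genetic_values[cbind(.data$line, .data$trait)],
        gxe = true_effects$gxe_values[cbind(.data$line, .data$env, .data$trait)],
        eps = rnorm(dplyr::n()) * sqrt(sig_e2[cbind(.data$env, .data$trait)]),
        value = .data$mu + .data$gen + .data$gxe + .data$rep_eff +
          .data$blk_eff + .data$eps
      ) |>
      dplyr::select("line", "env", "rep", "block", "trait", "value")
    if (config$missing_rate > 0) {
      keep <- runif(nrow(out)) >= config$missing_rate
      out <- out[keep, , drop = FALSE]
    }
    out
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper running genotypes, target genes, kernel, true effects
#' and plot trials in one call.
#'
#' @param config a [sim_config()].
#' @return list with elements `geno`, `genes`, `kernel`, `true`, `pheno`.
#' @export
simulate_study <- function(config) {
  geno <- simulate_genotypes(config)
  genes <- simulate_target_genes(config)
  kernel <- validate_kernel(vanraden_g(geno))
  true <- simulate_true_effects(config, kernel, genes)
  pheno <- simulate_trials(true, config)
  list(geno = geno, genes = genes, kernel = kernel, true = true, pheno = pheno)
}
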