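# Shared synthetic fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small two-trait, two-environment study with strongly correlated traits:
# cheap enough for sampler tests, big enough for signal.
small_study <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(
      n_lines = 120, n_markers = 500, trait_names = c("GN", "GW"),
      env_labels = c("1_A", "2_A", "3_A"),
      Sigma_t = matrix(c(1, 0.8, 0.8, 1), 2),
      Sigma_E = 0.3 * diag(3),
      env_means = matrix(0, 3, 2),
      h2_target = 0.5, gene_spec = default_gene_spec()[1:2],
      n_reps = 2, seed = 101)
    st <- simulate_study(cfg)
    st$config <- cfg
    st$blues <- adjust_phenotypes(st$pheno)
    .fixtures$small <- st
  }
  .fixtures$small
}

# A tiny deterministic BLUE set handy for bookkeeping tests.
toy_blues <- function(n_lines = 12, envs = c("E1", "E2"),
                      traits = c("T1", "T2"), seed = 42) {
  withr::with_seed(seed, {
    tidyr::expand_grid(line = sprintf("L%02d", seq_len(n_lines)),
                       env = envs, trait = traits) |>
      dplyr::mutate(blue = rnorm(dplyr::n()), se = 0.1)
  })
}

toy_kernel <- function(n_lines = 12, seed = 7) {
  withr::with_seed(seed, {
    M <- matrix(rbinom(n_lines * 60, 2, 0.4), n_lines,
                dimnames = list(sprintf("L%02d", seq_len(n_lines)),
                                sprintf("m%02d", 1:60)))
  })
  validate_kernel(vanraden_g(M, maf_min = 0))
}
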