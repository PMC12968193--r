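test_that("genotype simulation respects allele-frequency bounds and HWE", {
  cfg <- sim_config(n_lines = 500, n_markers = 1000, maf_range = c(0.5, 0.5),
                    trait_names = "GN", env_labels = "1_A",
                    Sigma_t = matrix(1), Sigma_E = matrix(0.5),
                    env_means = matrix(0), h2_target = 0.5,
                    gene_spec = default_gene_spec()[1], seed = 5)
  geno <- simulate_genotypes(cfg)
  M <- as.matrix(geno[-1])
  p_hat <- colMeans(M) / 2
  # binomial SE at n = 500 lines is ~0.016, so 0.05 is a ~3-sigma band:
  # essentially all markers inside, none far out
  expect_gt(mean(abs(p_hat - 0.5) < 0.05), 0.99)
  expect_lt(max(abs(p_hat - 0.5)), 0.08)
  expect_true(all(M %in% 0:2))
  # same seed twice -> identical
  expect_identical(geno, simulate_genotypes(cfg))
})

test_that("invalid configurations are rejected", {
  base <- list(trait_names = "GN", env_labels = "1_A",
               Sigma_t = matrix(1), Sigma_E = matrix(0.5),
               env_means = matrix(0), gene_spec = default_gene_spec()[1])
  expect_error(do.call(sim_config, c(base, list(maf_range = c(0.6, 0.7)))),
               "maf_range")
  expect_error(do.call(sim_config, c(base, list(h2_target = 0))), "h2_target")
  bad_gene <- list(list(name = "g", alleles = c("a", "b"), freq = c(0.5, 0.4)))
  expect_error(do.call(sim_config, c(base[-6], list(gene_spec = bad_gene,
                                                    h2_target = 0.5))),
               "sum to 1")
})

test_that("target-gene sampling matches declared frequencies", {
  spec1 <- list(list(name = "mono", alleles = "only", freq = 1))
  cfg1 <- sim_config(n_lines = 20, n_markers = 10, trait_names = "GN",
                     env_labels = "1_A", Sigma_t = matrix(1),
                     Sigma_E = matrix(0.5), env_means = matrix(0),
                     h2_target = 0.5, gene_spec = spec1, seed = 2)
  genes1 <- simulate_target_genes(cfg1)
  expect_true(all(genes1$mono == "only"))

  cfg2 <- sim_config(n_lines = 5000, n_markers = 10, trait_names = "GN",
                     env_labels = "1_A", Sigma_t = matrix(1),
                     Sigma_E = matrix(0.5), env_means = matrix(0),
                     h2_target = 0.5,
                     gene_spec = list(list(name = "g", alleles = c("a", "b"),
                                           freq = c(0.7, 0.3))), seed = 3)
  genes2 <- simulate_target_genes(cfg2)
  expect_lt(abs(mean(genes2$g == "a") - 0.7), 0.02)

  cfg3 <- sim_config(n_lines = 186, n_markers = 10, trait_names = "GN",
                     env_labels = "1_A", Sigma_t = matrix(1),
                     Sigma_E = matrix(0.5), env_means = matrix(0),
                     h2_target = 0.5, seed = 4)
  genes3 <- simulate_target_genes(cfg3)
  expect_equal(dim(genes3), c(186L, 5L))  # line + 4 genes
  for (g in cfg3$gene_spec) {
    expect_true(all(genes3[[g$name]] %in% g$alleles))
  }
})

test_that("true effects reproduce the generative covariances", {
  mk <- function(St, seed) {
    sim_config(n_lines = 1000, n_markers = 10, trait_names = c("A", "B"),
               env_labels = c("E1", "E2"), Sigma_t = St,
               Sigma_E = 0.5 * diag(2), env_means = matrix(0, 2, 2),
               h2_target = 0.5, gene_spec = default_gene_spec()[1],
               seed = seed)
  }
  # independent traits under identity covariances
  te0 <- simulate_true_effects(mk(diag(2), 11))
  expect_lt(abs(cor(te0$genetic_values)[1, 2]), 0.1)
  # correlation 0.7 recovered
  te7 <- simulate_true_effects(mk(matrix(c(1, 0.7, 0.7, 1), 2), 12))
  expect_lt(abs(cor(te7$genetic_values)[1, 2] - 0.7), 0.1)
  # zero Sigma_E kills the interaction exactly
  cfg0 <- sim_config(n_lines = 50, n_markers = 10, trait_names = "A",
                     env_labels = c("E1", "E2"), Sigma_t = matrix(1),
                     Sigma_E = matrix(0, 2, 2), env_means = matrix(0, 2, 1),
                     h2_target = 0.5, gene_spec = default_gene_spec()[1],
                     seed = 13)
  te <- simulate_true_effects(cfg0)
  expect_true(all(te$gxe_values == 0))
})

test_that("trial tables have the design arithmetic and no-noise limit", {
  cfg <- sim_config(n_lines = 186, n_markers = 10, trait_names = "GN",
                    env_labels = default_env_labels(),
                    Sigma_t = matrix(1), Sigma_E = 0.5 * diag(8),
                    env_means = matrix(0, 8, 1), h2_target = 1,
                    rep_var_frac = 0, block_var_frac = 0,
                    gene_spec = default_gene_spec()[1], n_reps = 2, seed = 21)
  te <- simulate_true_effects(cfg)
  pheno <- simulate_trials(te, cfg)
  expect_equal(nrow(pheno), 186 * 8 * 2)
  # h2 = 1 with zero rep/block variance: genotype means exact
  means <- pheno |>
    dplyr::group_by(line, env) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  truth <- te$env_trait_means[means$env, "GN"] +
    te$genetic_values[cbind(means$line, "GN")] +
    te$gxe_values[cbind(means$line, means$env, "GN")]
  expect_equal(means$m, unname(truth), tolerance = 1e-12)
  # labels survive
  expect_setequal(unique(pheno$env), default_env_labels())
  expect_setequal(unique(pheno$line), sprintf("L%03d", 1:186))
})

test_that("whole-study simulation is deterministic under the seed", {
  cfg <- sim_config(n_lines = 20, n_markers = 50, trait_names = c("GN", "GW"),
                    env_labels = c("E1", "E2"),
                    Sigma_t = diag(2), Sigma_E = 0.5 * diag(2),
                    env_means = matrix(0, 2, 2), h2_target = 0.5,
                    gene_spec = default_gene_spec()[1], seed = 31)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$genes, s2$genes)
  expect_equal(unclass(s1$kernel), unclass(s2$kernel))
})
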