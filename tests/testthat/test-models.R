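# Short chains are used throughout; the resulting low-ESS warnings are
# expected and suppressed.
quiet_fit <- function(...) suppressWarnings(fit_gp(...))

test_that("gp_spec validates its MCMC settings", {
  expect_error(gp_spec("SE", n_iter = 100, burn_in = 100), "burn_in")
  expect_error(gp_spec("SE", thin = 0), "thin")
  expect_error(gp_spec("XX"), "arg")
})

test_that("SE sampler: no signal gives near-zero effects, permutation equivariance", {
  K <- toy_kernel(20)
  blues <- tibble::tibble(line = sprintf("L%02d", 1:20), env = "E1",
                          trait = "T1", blue = 5, se = 0.1)
  f <- quiet_fit(blues, K, gp_spec("SE", n_iter = 600, burn_in = 200,
                                   thin = 2, seed = 4))
  expect_lt(max(abs(tidy(f)$effect)), 0.15)

  withr::with_seed(11, blues$blue <- rnorm(20))
  f1 <- quiet_fit(blues, K, gp_spec("SE", n_iter = 600, burn_in = 200,
                                    thin = 2, seed = 5))
  # shuffling input rows leaves per-line predictions unchanged
  f2 <- quiet_fit(blues[sample(20), ], K,
                  gp_spec("SE", n_iter = 600, burn_in = 200, thin = 2,
                          seed = 5))
  expect_equal(f1$predictions, f2$predictions)
  # seeded determinism
  f3 <- quiet_fit(blues, K, gp_spec("SE", n_iter = 600, burn_in = 200,
                                    thin = 2, seed = 5))
  expect_identical(f1$predictions$.pred, f3$predictions$.pred)
})

test_that("SE posterior means match the closed-form BLUP at fixed variances", {
  st <- small_study()
  f <- quiet_fit(st$blues, st$kernel,
                 gp_spec("SE", n_iter = 3000, burn_in = 1000, thin = 2,
                         seed = 6, fix = list(sigma_g2 = 1, sigma_e2 = 1)),
                 trait = "GN", env = "1_A")
  y <- st$blues |>
    dplyr::filter(trait == "GN", env == "1_A") |>
    dplyr::arrange(line)
  G <- as.matrix(st$kernel)[y$line, y$line]
  n <- nrow(G)
  ustar <- G %*% solve(G + diag(n), y$blue - mean(y$blue))
  expect_gt(cor(tidy(f)$effect, as.numeric(ustar)), 0.999)
})

test_that("MT borrows strength and reduces to SE for a single trait", {
  st <- small_study()
  sp <- function(m, seed) gp_spec(m, n_iter = 2000, burn_in = 700, thin = 2,
                                  seed = seed)
  f_se <- quiet_fit(st$blues, st$kernel, sp("SE", 7), trait = "GN", env = "1_A")
  f_mt1 <- quiet_fit(st$blues, st$kernel, sp("MT", 8), trait = "GN",
                     env = "1_A")
  expect_gt(cor(f_se$predictions$.pred, f_mt1$predictions$.pred), 0.99)
  # generative genetic correlation 0.8 is recovered by the full MT fit
  f_mt <- quiet_fit(st$blues, st$kernel,
                    gp_spec("MT", n_iter = 2500, burn_in = 800, thin = 2,
                            seed = 9), env = "1_A")
  expect_lt(abs(cov2cor(f_mt$posterior$Sigma_t)[1, 2] - 0.8), 0.15)
})

test_that("ME reduces to SE for one environment and finds null interaction", {
  st <- small_study()
  f_se <- quiet_fit(st$blues, st$kernel,
                    gp_spec("SE", n_iter = 2000, burn_in = 700, thin = 2,
                            seed = 10), trait = "GN", env = "1_A")
  f_me1 <- quiet_fit(st$blues, st$kernel,
                     gp_spec("ME", n_iter = 2000, burn_in = 700, thin = 2,
                             seed = 11), trait = "GN", env = "1_A")
  expect_gt(cor(f_se$predictions$.pred, f_me1$predictions$.pred), 0.98)

  # no G-by-E in the generative world at the study's own scale (186 lines,
  # 8 environments): sigma_Eg2 shrinks below 10% of sigma_g2
  cfg0 <- sim_config(n_lines = 186, n_markers = 150, trait_names = "GN",
                     env_labels = paste0("E", 1:8),
                     Sigma_t = matrix(1), Sigma_E = matrix(0, 8, 8),
                     env_means = matrix(0, 8, 1), h2_target = 0.6,
                     gene_spec = default_gene_spec()[1], n_reps = 2,
                     seed = 42)
  st0 <- simulate_study(cfg0)
  blues0 <- adjust_phenotypes(st0$pheno)
  f_me <- quiet_fit(blues0, st0$kernel,
                    gp_spec("ME", n_iter = 6000, burn_in = 2000, thin = 2,
                            seed = 12))
  expect_lt(f_me$posterior$sigma_Eg2, 0.1 * f_me$posterior$sigma_g2)
})

test_that("G-by-E prior has the Hadamard covariance structure", {
  K <- toy_kernel(6)
  G <- as.matrix(K)
  # Sigma_E = I * s2Eg reproduces the block covariance
  # (ZgGZg') # (ZE ZE') * s2Eg: zero across environments, G[j,j]*s2Eg within
  s2Eg <- 0.7
  draws <- sample_gxe_prior(30000, G, diag(s2Eg, 2), matrix(1), seed = 13)
  emp <- cov(draws)
  n <- nrow(G)
  same_line_same_env <- diag(emp)[1:n]
  expect_equal(unname(same_line_same_env), unname(diag(G) * s2Eg),
               tolerance = 0.05 * max(diag(G) * s2Eg) * 3)
  # same line, different environments: covariance ~ 0
  cross <- emp[cbind(1:n, n + 1:n)]
  expect_lt(max(abs(cross)), 4 * max(diag(G)) * s2Eg / sqrt(30000) * 3 + 0.02)
})

test_that("MTME reduces to SE and recovers the generative structure", {
  st <- small_study()
  f_se <- quiet_fit(st$blues, st$kernel,
                    gp_spec("SE", n_iter = 2000, burn_in = 700, thin = 2,
                            seed = 14), trait = "GN", env = "1_A")
  f_mm1 <- quiet_fit(st$blues, st$kernel,
                     gp_spec("MTME", n_iter = 2000, burn_in = 700, thin = 2,
                             seed = 15), trait = "GN", env = "1_A")
  expect_gt(cor(f_se$predictions$.pred, f_mm1$predictions$.pred), 0.98)

  f_mm <- quiet_fit(st$blues, st$kernel,
                    gp_spec("MTME", n_iter = 2500, burn_in = 800, thin = 2,
                            seed = 16))
  expect_lt(abs(cov2cor(f_mm$posterior$Sigma_t)[1, 2] - 0.8), 0.15)
  h2 <- genomic_h2(f_mm)
  expect_true(all(abs(h2$h2 - 0.5) < 0.15))
})

test_that("masked cells are augmented and returned by predict()", {
  st <- small_study()
  mask <- tibble::tibble(line = sprintf("L%03d", 1:25), env = "1_A",
                         trait = "GN")
  f <- quiet_fit(st$blues, st$kernel,
                 gp_spec("MT", n_iter = 1500, burn_in = 500, thin = 2,
                         seed = 17), env = "1_A", mask = mask)
  # masked cells are flagged unobserved and predicted from the posterior
  pm <- dplyr::filter(f$predictions, masked)
  expect_equal(nrow(pm), 25L)
  expect_true(all(!pm$observed))
  # predict() returns exactly the stored augmented means
  pr <- predict(f, dplyr::select(pm, line, env, trait))
  expect_equal(pr$.pred, pm$.pred)
  # masked predictions still track the hidden truth (information borrowed
  # from the correlated secondary trait)
  truth <- st$blues |>
    dplyr::filter(trait == "GN", env == "1_A",
                  line %in% mask$line) |>
    dplyr::arrange(line)
  expect_gt(cor(pr$.pred[order(pr$line)], truth$blue), 0.3)
})

test_that("predict() handles empty, duplicated and unknown targets", {
  K <- toy_kernel(12)
  blues <- toy_blues(12)
  f <- quiet_fit(blues, K, gp_spec("MT", n_iter = 400, burn_in = 100,
                                   thin = 1, seed = 18), env = "E1")
  empty <- predict(f, tibble::tibble(line = character(), env = character(),
                                     trait = character()))
  expect_equal(nrow(empty), 0L)
  dup <- tibble::tibble(line = c("L01", "L01"), env = "E1", trait = "T1")
  pd <- predict(f, dup)
  expect_equal(pd$.pred[1], pd$.pred[2])
  expect_error(predict(f, tibble::tibble(line = "ZZZ", env = "E1",
                                         trait = "T1")), "unknown line")
  expect_error(fit_gp(blues, toy_kernel(5),
                      gp_spec("MT", n_iter = 100, burn_in = 10, seed = 1),
                      env = "E1"),
               "absent from kernel")
})

test_that("model summaries expose ESS and variance components", {
  st <- small_study()
  f <- quiet_fit(st$blues, st$kernel,
                 gp_spec("SE", n_iter = 1000, burn_in = 300, thin = 2,
                         seed = 19), trait = "GN", env = "1_A")
  g <- glance(f)
  expect_equal(g$model, "SE")
  expect_true(all(c("sigma_g2", "sigma_e2", "h2", "min_ess") %in% names(g)))
  expect_true(g$sigma_g2 > 0 && g$sigma_e2 > 0)
  expect_equal(nrow(f$ess), 2L)
})
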