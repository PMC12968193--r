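# Balanced two-rep design with no rep/block variance injected.
balanced_pheno <- function(n_lines = 8, sd_eps = 0.5, seed = 3, shift = 0) {
  withr::with_seed(seed, {
    g <- rnorm(n_lines, 10, 2)
    tidyr::expand_grid(line = sprintf("L%02d", seq_len(n_lines)),
                       rep = 1:2, block = 1L) |>
      dplyr::mutate(env = "E1", trait = "T1",
                    value = g[match(line, sprintf("L%02d", seq_len(n_lines)))] +
                      rnorm(dplyr::n(), 0, sd_eps) + shift)
  })
}

test_that("BLUEs reduce to plot means on balanced data and shift with constants", {
  ph <- balanced_pheno()
  fit <- compute_blues(ph, "T1", "E1")
  means <- ph |>
    dplyr::group_by(line) |>
    dplyr::summarise(m = mean(value))
  expect_equal(fit$blues$blue, means$m, tolerance = 1e-6)
  # translation equivariance
  ph2 <- dplyr::mutate(ph, value = value + 11.5)
  fit2 <- compute_blues(ph2, "T1", "E1")
  expect_equal(fit2$blues$blue, fit$blues$blue + 11.5, tolerance = 1e-6)
  # h2 is invariant to rescaling all plots by a constant
  ph3 <- dplyr::mutate(ph, value = value * 3.7)
  fit3 <- compute_blues(ph3, "T1", "E1")
  expect_equal(fit3$h2, fit$h2, tolerance = 1e-4)
})

test_that("unbalanced BLUEs equal the direct GLS solution at REML components", {
  withr::with_seed(5, {
    n <- 6
    g <- rnorm(n, 20, 3)
    re <- rnorm(2, 0, 1)            # rep effects
    be <- rnorm(4, 0, 0.8)          # block-in-rep effects
    ph <- tidyr::expand_grid(line = sprintf("L%d", 1:n), rep = 1:2) |>
      dplyr::mutate(block = rep(c(1, 2), length.out = dplyr::n()),
                    env = "E1", trait = "T1",
                    value = g[match(line, sprintf("L%d", 1:n))] +
                      re[rep] + be[(rep - 1) * 2 + block] +
                      rnorm(dplyr::n(), 0, 0.6))
  })
  ph <- ph[-4L, ]  # delete one plot -> unbalanced
  fit <- compute_blues(ph, "T1", "E1")

  # independent GLS oracle with variance components at the REML estimates of
  # the same genotype-fixed model
  dat <- dplyr::mutate(ph, line = factor(line), rep_f = factor(rep),
                       blk_f = factor(paste(rep, block, sep = ":")))
  lf <- suppressWarnings(suppressMessages(lme4::lmer(
    value ~ 0 + line + (1 | rep_f) + (1 | blk_f), data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(lf))
  s2r <- vc$vcov[vc$grp == "rep_f"]
  s2b <- vc$vcov[vc$grp == "blk_f"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  X <- stats::model.matrix(~ 0 + line, dat)
  Zr <- stats::model.matrix(~ 0 + rep_f, dat)
  Zb <- stats::model.matrix(~ 0 + blk_f, dat)
  V <- s2r * tcrossprod(Zr) + s2b * tcrossprod(Zb) + s2e * diag(nrow(dat))
  beta <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, dat$value))
  expect_equal(fit$blues$blue, as.numeric(beta), tolerance = 1e-5)
})

test_that("heritability limits and the harmonic-mean basis behave", {
  mk_fit <- function(sg, se2, r = 2) {
    structure(list(varcomp = c(sigma_g2 = sg, sigma_rep2 = 0,
                               sigma_block2 = 0, sigma_eps2 = se2),
                   r_harmonic = r, blues = NULL, trait = "T", env = "E"),
              class = "blue_fit")
  }
  expect_equal(estimate_h2(mk_fit(2, 0)), 1)
  expect_equal(estimate_h2(mk_fit(0, 3)), 0)
  expect_equal(estimate_h2(mk_fit(1, 1, r = 2)), 1 / 1.5)
  expect_equal(estimate_h2(mk_fit(1, 1), basis = "plot"), 0.5)
  expect_warning(out <- estimate_h2(mk_fit(0, 0)), "undefined")
  expect_true(is.na(out))
})

test_that("singular designs fall back to plain means with a warning", {
  ph <- balanced_pheno() |> dplyr::filter(rep == 1)
  expect_warning(fit <- compute_blues(ph, "T1", "E1"), "plain line means")
  expect_true(fit$singular)
  means <- ph |> dplyr::group_by(line) |> dplyr::summarise(m = mean(value))
  expect_equal(fit$blues$blue, means$m)
  expect_error(compute_blues(ph, "T9", "E1"), "absent")
})

test_that("trait correlations match the textbook Pearson formula", {
  blues <- dplyr::bind_rows(
    tibble::tibble(line = sprintf("L%d", 1:5), env = "E1", trait = "A",
                   blue = c(1, 2, 3, 4, 5), se = 0),
    tibble::tibble(line = sprintf("L%d", 1:5), env = "E1", trait = "B",
                   blue = c(2, 1, 4, 3, 5), se = 0))
  tc <- trait_correlations(blues, "E1")
  # self-correlation
  expect_equal(tc$r[tc$trait1 == "A" & tc$trait2 == "A"], 1)
  # hand-evaluated Pearson: cov / (sd_x sd_y)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tc$r[tc$trait1 == "A" & tc$trait2 == "B"], r_hand,
               tolerance = 1e-12)
  # exact linearity
  blues2 <- dplyr::bind_rows(
    tibble::tibble(line = sprintf("L%d", 1:4), env = "E1", trait = "A",
                   blue = 1:4, se = 0),
    tibble::tibble(line = sprintf("L%d", 1:4), env = "E1", trait = "B",
                   blue = c(2, 4, 6, 8), se = 0))
  tc2 <- trait_correlations(blues2, "E1")
  expect_equal(tc2$r[tc2$trait1 == "A" & tc2$trait2 == "B"], 1)
  expect_identical(tc2$stars[tc2$trait1 == "A" & tc2$trait2 == "B"], "***")
})

test_that("environment correlations cluster duplicates together", {
  withr::with_seed(6, {
    base <- rnorm(30)
    blues <- dplyr::bind_rows(
      tibble::tibble(line = sprintf("L%02d", 1:30), env = "E1", trait = "T",
                     blue = base, se = 0),
      tibble::tibble(line = sprintf("L%02d", 1:30), env = "E2", trait = "T",
                     blue = base, se = 0),                     # duplicate
      tibble::tibble(line = sprintf("L%02d", 1:30), env = "E3", trait = "T",
                     blue = -base, se = 0),                    # anti
      tibble::tibble(line = sprintf("L%02d", 1:30), env = "E4", trait = "T",
                     blue = base + rnorm(30, 0, 2), se = 0))
  })
  ec <- env_correlations(blues, "T")
  get_r <- function(a, b) ec$r[ec$env1 == a & ec$env2 == b]
  expect_equal(get_r("E1", "E2"), 1, tolerance = 1e-12)
  expect_equal(get_r("E1", "E3"), -1, tolerance = 1e-12)
  ord <- attr(ec, "order")
  expect_setequal(ord, c("E1", "E2", "E3", "E4"))
  expect_equal(abs(match("E1", ord) - match("E2", ord)), 1)  # adjacent
})

test_that("adjust_phenotypes assembles a labelled BLUE set with variance table", {
  st <- small_study()
  blues <- st$blues
  expect_setequal(unique(blues$trait), c("GN", "GW"))
  expect_setequal(unique(blues$env), c("1_A", "2_A", "3_A"))
  vt <- varcomp_table(blues)
  expect_equal(nrow(vt), 6L)
  expect_true(all(vt$h2 > 0 & vt$h2 < 1))
  # entry-mean h2 targets 0.5 in the generative world
  expect_true(all(abs(vt$h2 - 0.5) < 0.2))
})
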