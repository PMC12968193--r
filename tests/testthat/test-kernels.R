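test_that("VanRaden kernel matches the hand-evaluated example", {
  M <- matrix(c(0, 2, 1, 1, 2, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("L1", "L2", "L3"), c("m1", "m2")))
  K <- vanraden_g(M, maf_min = 0)
  expect_equal(unname(as.matrix(K)),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3), tolerance = 1e-12)
  expect_identical(attr(K, "provenance"), "G")
})

test_that("duplicate genotypes give identical relationships", {
  M <- matrix(c(0, 2, 1, 0, 2, 1, 2, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("m1", "m2", "m3")))
  K <- as.matrix(vanraden_g(M, maf_min = 0))
  expect_equal(K["A", "A"], K["A", "B"])
  expect_equal(K["A", "A"], K["B", "B"])
})

test_that("kernel construction is marker-order invariant and line-order equivariant", {
  withr::with_seed(9, {
    M <- matrix(rbinom(20 * 40, 2, 0.3), 20,
                dimnames = list(sprintf("L%02d", 1:20), sprintf("m%02d", 1:40)))
  })
  K1 <- as.matrix(vanraden_g(M, maf_min = 0))
  K2 <- as.matrix(vanraden_g(M[, sample(40)], maf_min = 0))
  expect_equal(K1, K2, tolerance = 1e-12)
  perm <- sample(20)
  K3 <- as.matrix(vanraden_g(M[perm, ], maf_min = 0))
  expect_equal(K3, K1[perm, perm], tolerance = 1e-12)
})

test_that("missing dosages are mean-imputed and filters apply", {
  M <- matrix(c(0, 2, NA, 1, 2, 0, 2, 2, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("m1", "m2", "m3")))
  # column m2 = (2,2,2) is monomorphic; m3 has one missing call
  expect_message(K <- vanraden_g(M, maf_min = 0, max_missing = 0.5),
                 "monomorphic")
  expect_true(all(is.finite(unclass(K))))
  expect_error(vanraden_g(matrix(c(1, 1, 1, 1), 2,
                                 dimnames = list(c("A", "B"), c("m1", "m2"))),
                          maf_min = 0),
               "polymorphic")
  Mbad <- matrix(c(0, 3, 1, 1), 2,
                 dimnames = list(c("A", "B"), c("m1", "m2")))
  expect_error(vanraden_g(Mbad), "outside")
})

test_that("G2 equals VanRaden on the indicator matrix", {
  genes <- tibble::tibble(line = c("L1", "L2", "L3", "L4"),
                          g = c("a", "a", "b", "b"))
  fit <- target_gene_g2(genes)
  K <- as.matrix(fit)
  # hand evaluation: allele-count columns (2,0),(2,0),(0,2),(0,2), freqs
  # (.5,.5), centred Z rows (1,-1) / (-1,1), denominator 2*(0.25+0.25) = 1
  expect_equal(unname(K),
               matrix(c(2, 2, -2, -2,
                        2, 2, -2, -2,
                        -2, -2, 2, 2,
                        -2, -2, 2, 2), 4), tolerance = 1e-12)
  expect_identical(attr(fit, "provenance"), "G2")
})

test_that("biallelic G2 coincides with the 0/2 dosage recoding", {
  withr::with_seed(4, {
    alle <- sample(c("a", "b"), 30, replace = TRUE, prob = c(0.6, 0.4))
  })
  genes <- tibble::tibble(line = sprintf("L%02d", 1:30), g = alle)
  K2 <- as.matrix(target_gene_g2(genes))
  M <- matrix(2 * (alle == "b"), ncol = 1,
              dimnames = list(genes$line, "g"))
  KV <- as.matrix(vanraden_g(M, maf_min = 0))
  expect_equal(K2, KV, tolerance = 1e-10)
})

test_that("line permutation permutes the G2 kernel", {
  genes <- tibble::tibble(line = sprintf("L%02d", 1:10),
                          g1 = rep(c("a", "b"), 5),
                          g2 = rep(c("x", "y", "z"), length.out = 10))
  K <- as.matrix(target_gene_g2(genes))
  perm <- c(3, 1, 2, 7, 10, 4, 5, 9, 6, 8)
  Kp <- as.matrix(target_gene_g2(genes[perm, ]))
  expect_equal(Kp, K[perm, perm], tolerance = 1e-12)
})

test_that("validate_kernel handles PSD boundaries and jitter", {
  I5 <- diag(5); dimnames(I5) <- list(letters[1:5], letters[1:5])
  K <- validate_kernel(I5)
  expect_equal(attr(K, "jitter"), 0)
  # rank-deficient Gram matrix of duplicated rows: eigenvalue 0 is fine
  X <- matrix(c(1, 1, 2, 1, 1, 2), nrow = 3, byrow = TRUE)
  Gm <- tcrossprod(X); dimnames(Gm) <- list(1:3, 1:3)
  expect_equal(attr(validate_kernel(Gm), "jitter"), 0)
  # min eigenvalue -1e-5 needs the 1e-4 jitter
  withr::with_seed(8, {
    Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  })
  Bad <- Q %*% diag(c(1, 0.5, 0.2, -1e-5)) %*% t(Q)
  Bad <- (Bad + t(Bad)) / 2
  dimnames(Bad) <- list(1:4, 1:4)
  Kb <- validate_kernel(Bad)
  expect_equal(attr(Kb, "jitter"), 1e-4)
  expect_gt(min(eigen(as.matrix(Kb), symmetric = TRUE)$values), 0)
  # asymmetry and uncappable deficits are errors
  As <- diag(3); As[1, 2] <- 1e-6; dimnames(As) <- list(1:3, 1:3)
  expect_error(validate_kernel(As), "asymmetric")
  Neg <- diag(c(1, 1, -0.5)); dimnames(Neg) <- list(1:3, 1:3)
  expect_error(validate_kernel(Neg), "jitter cap")
})

test_that("centered kernels have (near) zero row sums on complete data", {
  withr::with_seed(10, {
    M <- matrix(rbinom(50 * 200, 2, runif(200, 0.1, 0.5)), 50, byrow = TRUE,
                dimnames = list(sprintf("L%02d", 1:50), sprintf("m%03d", 1:200)))
  })
  K <- as.matrix(vanraden_g(M, maf_min = 0))
  expect_lt(max(abs(rowSums(K))), 1e-8)
})
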