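#' Line-by-environment BLUE matrix for one trait
#'
#' @param blues BLUE set tibble (`line, env, trait, blue`).
#' @param trait trait to extract.
#' @return lines-by-environments numeric matrix (NA for missing cells).
#' @export
gxe_matrix <- function(blues, trait) {
  wide <- blues |>
    dplyr::filter(.data$trait == !!trait) |>
    tidyr::pivot_wider(id_cols = "line", names_from = "env",
                       values_from = "blue") |>
    dplyr::arrange(.data$line)
  M <- as.matrix(wide[-1L])
  rownames(M) <- wide$line
  if (ncol(M) < 2L) abort("need at least 2 environments")
  M
}

#' Low-rank imputation of missing cells
#'
#' Iterative low-rank completion: missing cells are initialised at their
#' column means, then the matrix is repeatedly approximated by its rank-r
#' truncated SVD and the missing cells refilled from the approximation,
#' until the largest absolute change is below `tol` or `max_iter` is
#' reached. Rank 2 is the default for coherence with the two-component
#' biplot.
#'
#' @param M lines-by-environments matrix with missing cells.
#' @param rank rank of the truncated reconstruction.
#' @param tol convergence tolerance on the imputed cells.
#' @param max_iter iteration cap.
#' @param method `"svd"` (iterative, default) or `"col_mean"` (single-shot
#'   column-mean fill).
#' @return completed matrix (unchanged when nothing is missing).
#' @export
impute_gxe <- function(M, rank = 2L, tol = 1e-6, max_iter = 200L,
                       method = c("svd", "col_mean")) {
  method <- match.arg(method)
  miss <- is.na(M)
  if (!any(miss)) return(M)
  if (any(colSums(!miss) == 0L)) {
    abort(sprintf("environment '%s' has no observed value",
                  colnames(M)[which(colSums(!miss) == 0L)[1L]]))
  }
  if (any(rowSums(!miss) == 0L)) {
    abort(sprintf("line '%s' has no observed value",
                  rownames(M)[which(rowSums(!miss) == 0L)[1L]]))
  }
  cm <- colMeans(M, na.rm = TRUE)
  X <- M
  X[miss] <- cm[col(M)[miss]]
  if (method == "col_mean") return(X)
  r <- min(rank, dim(M) - 0L)
  for (it in seq_len(max_iter)) {
    s <- svd(X, nu = r, nv = r)
    Xhat <- s$u %*% (s$d[seq_len(r)] * t(s$v))
    delta <- max(abs(Xhat[miss] - X[miss]))
    X[miss] <- Xhat[miss]
    if (delta < tol) break
  }
  X
}

#' Site-regression (SREG) decomposition for a GGE biplot
#'
#' Centres each environment column (removing the environment main effect and
#' leaving genotype plus genotype-by-environment variation, G+GE) and
#' decomposes the centred table by SVD. Genotype scores carry the singular
#' values under the default genotype-focused scaling
#' (`scores = U %*% diag(d)`, environment loadings `V`); `"symmetric"`
#' splits the singular values evenly between the two sets. The variance
#' fraction of the first two components is
#' `(d1^2 + d2^2) / sum(d^2)`. Sign convention: each component is flipped so
#' that its largest-magnitude environment loading is positive.
#'
#' @param M complete lines-by-environments matrix (run [impute_gxe()] first
#'   if cells are missing).
#' @param scaling `"genotype"` (default) or `"symmetric"`.
#' @param scale_env divide each centred column by its standard deviation
#'   before decomposition (off by default).
#' @return object of class `sreg_fit`: `genotype_scores` and `env_scores`
#'   tibbles (components PC1/PC2), `singular_values`, `var_fraction`
#'   (per-component fractions) and `var_explained_12`.
#' @export
sreg_decompose <- function(M, scaling = c("genotype", "symmetric"),
                           scale_env = FALSE) {
  scaling <- match.arg(scaling)
  if (anyNA(M)) abort("matrix has missing cells: run impute_gxe() first")
  Xc <- sweep(M, 2L, colMeans(M))
  if (scale_env) {
    s <- apply(Xc, 2L, stats::sd)
    if (any(s == 0)) abort("zero-variance environment column")
    Xc <- sweep(Xc, 2L, s, "/")
  }
  if (max(abs(Xc)) == 0) abort("zero-variance table: nothing to decompose")
  s <- svd(Xc)
  k <- length(s$d)
  # sign convention: largest-|loading| environment positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  frac <- s$d^2 / sum(s$d^2)
  gs <- switch(scaling,
               genotype = s$u %*% diag(s$d, k),
               symmetric = s$u %*% diag(sqrt(s$d), k))
  es <- switch(scaling,
               genotype = s$v,
               symmetric = s$v %*% diag(sqrt(s$d), k))
  n2 <- min(2L, k)
  structure(list(
    genotype_scores = tibble::tibble(line = rownames(M),
                                     PC1 = gs[, 1L],
                                     PC2 = if (k > 1L) gs[, 2L] else 0),
    env_scores = tibble::tibble(env = colnames(M),
                                PC1 = es[, 1L],
                                PC2 = if (k > 1L) es[, 2L] else 0),
    singular_values = s$d,
    var_fraction = frac,
    var_explained_12 = sum(frac[seq_len(n2)]),
    scaling = scaling,
    centered = Xc, u = s$u, v = s$v
  ), class = "sreg_fit")
}

#' @export
print.sreg_fit <- function(x, ...) {
  cat(sprintf("<sreg_fit> %d lines x %d environments; PC1+PC2 explain %.1f%% of G+GE\n",
              nrow(x$genotype_scores), nrow(x$env_scores),
              100 * x$var_explained_12))
  invisible(x)
}

#' SREG analysis of a BLUE set
#'
#' Convenience wrapper: extracts the line-by-environment table for one
#' trait, imputes missing cells at the biplot rank, and decomposes.
#'
#' @inheritParams sreg_decompose
#' @param blues BLUE set tibble.
#' @param trait trait to analyse.
#' @param rank imputation rank (default 2, matching the biplot).
#' @param ... passed to [impute_gxe()].
#' @return an `sreg_fit`.
#' @export
sreg <- function(blues, trait, rank = 2L, scaling = c("genotype", "symmetric"),
                 scale_env = FALSE, ...) {
  M <- gxe_matrix(blues, trait)
  M <- impute_gxe(M, rank = rank, ...)
  sreg_decompose(M, scaling = scaling, scale_env = scale_env)
}

#' @describeIn sreg genotype and environment scores as one long tibble.
#' @param x an `sreg_fit`.
#' @method tidy sreg_fit
#' @export
tidy.sreg_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$genotype_scores, id = "line"),
                  type = "genotype"),
    dplyr::mutate(dplyr::rename(x$env_scores, id = "env"),
                  type = "environment"))
}

#' @describeIn sreg one-row summary of the decomposition.
#' @method glance sreg_fit
#' @export
glance.sreg_fit <- function(x, ...) {
  tibble::tibble(n_lines = nrow(x$genotype_scores),
                 n_envs = nrow(x$env_scores),
                 var_pc1 = x$var_fraction[1L],
                 var_pc2 = if (length(x$var_fraction) > 1L) x$var_fraction[2L] else 0,
                 var_explained_12 = x$var_explained_12)
}
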