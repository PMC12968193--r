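#' Genomic relationship kernels
#'
#' A `gp_kernel` is a symmetric positive-semidefinite line-by-line
#' relationship matrix carrying its line IDs, a provenance tag (`"G"` for the
#' genome-wide VanRaden matrix, `"G2"` for the target-gene allelic matrix)
#' and the diagnostics recorded by [validate_kernel()].
#'
#' @name gp_kernel
NULL

new_gp_kernel <- function(K, provenance, jitter = 0, min_eig = NA_real_) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K), !is.null(rownames(K)))
  structure(K,
            provenance = provenance, jitter = jitter, min_eig = min_eig,
            class = c("gp_kernel", "matrix", "array"))
}

#' @export
print.gp_kernel <- function(x, ...) {
  cat(sprintf("<gp_kernel %s> %d lines, mean diagonal %.3f, min eigenvalue %.3g, jitter %g\n",
              attr(x, "provenance"), nrow(x), mean(diag(x)),
              attr(x, "min_eig"), attr(x, "jitter")))
  invisible(x)
}

#' @describeIn gp_kernel plain numeric matrix (diagnostic attributes
#'   dropped).
#' @export
as.matrix.gp_kernel <- function(x, ...) {
  y <- unclass(x)
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  y
}

#' @describeIn gp_kernel long tibble of pairwise relationships.
#' @param x a `gp_kernel`.
#' @param ... unused.
#' @method tidy gp_kernel
#' @export
tidy.gp_kernel <- function(x, ...) {
  array_to_tibble(unclass(x), c("line1", "line2"))
}

# Coerce a genotype tibble (first column = line ID) or matrix to a dosage
# matrix with line IDs as rownames.
as_dosage_matrix <- function(geno) {
  if (is.matrix(geno)) {
    if (is.null(rownames(geno))) abort("genotype matrix needs line IDs as rownames")
    return(geno)
  }
  geno <- tibble::as_tibble(geno)
  ids <- as.character(geno[[1L]])
  if (anyDuplicated(ids)) abort("duplicate line IDs in genotype table")
  M <- as.matrix(geno[-1L])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  M
}

#' VanRaden genomic relationship matrix
#'
#' Builds the genome-wide kernel G = ZZ' / (2 * sum(p_i (1 - p_i))) from SNP
#' dosages coded 0/1/2, where Z is the matrix of dosages centred at twice the
#' observed allele frequency p_i of each marker. Missing dosages are imputed
#' to the marker mean; markers that are monomorphic, below the MAF threshold
#' or with too many missing calls are dropped before construction.
#'
#' @param geno lines-by-markers dosage data: a data frame whose first column
#'   is the line ID (remaining columns markers), or a numeric matrix with
#'   line IDs as rownames. Values must be 0, 1, 2 or `NA`.
#' @param maf_min markers with minor-allele frequency below this are dropped.
#' @param max_missing markers with a larger missing fraction are dropped.
#' @return a [gp_kernel] with provenance `"G"`.
#' @examples
#' M <- matrix(c(0, 2, 1, 1, 2, 0), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("L1", "L2", "L3"), c("m1", "m2")))
#' vanraden_g(M, maf_min = 0)
#' @export
vanraden_g <- function(geno, maf_min = 0.01, max_missing = 0.2) {
  M <- as_dosage_matrix(geno)
  ok <- M %in% c(0, 1, 2) | is.na(M)
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow(M)), arr.ind = TRUE)[1L, ]
    abort(sprintf("dosage outside {0,1,2} at line '%s', marker '%s'",
                  rownames(M)[bad[1L]], colnames(M)[bad[2L]]))
  }
  if (nrow(M) < 2L) abort("need at least two lines")

  miss_frac <- colMeans(is.na(M))
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  mono <- apply(M, 2L, function(x) stats::var(x, na.rm = TRUE)) == 0
  mono[is.na(mono)] <- TRUE
  keep <- miss_frac <= max_missing & maf >= maf_min & !mono
  n_mono <- sum(mono)
  if (n_mono > 0L) inform(sprintf("dropped %d monomorphic marker(s)", n_mono))
  if (!any(keep)) abort("no polymorphic marker left after filtering")
  M <- M[, keep, drop = FALSE]
  p <- p[keep]

  # mean imputation of missing dosages
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- (2 * p)[idx[, 2L]]
  }
  Z <- sweep(M, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(Z) / denom
  e <- eigen(sym(K), symmetric = TRUE, only.values = TRUE)$values
  new_gp_kernel(sym(K), "G", jitter = 0, min_eig = min(e))
}

# One-hot indicator matrix for the allele classes of the target genes.
gene_indicators <- function(genes) {
  genes <- tibble::as_tibble(genes)
  ids <- as.character(genes[[1L]])
  if (anyDuplicated(ids)) abort("duplicate line IDs in target-gene table")
  cols <- lapply(names(genes)[-1L], function(g) {
    a <- factor(genes[[g]])
    if (nlevels(a) < 2L) return(NULL)  # monomorphic gene contributes nothing
    X <- stats::model.matrix(~ a - 1)
    colnames(X) <- paste(g, levels(a), sep = ":")
    X
  })
  cols <- cols[!vapply(cols, is.null, logical(1L))]
  if (!length(cols)) abort("all target genes are monomorphic")
  X <- do.call(cbind, cols)
  rownames(X) <- ids
  X
}

#' Target-gene relationship matrix (G2)
#'
#' Builds a relationship kernel from the allelic states of a small set of
#' characterised genes (e.g. vernalization, photoperiod and dwarfing loci).
#' Each gene's allele classes are one-hot encoded as homozygous diploid
#' allele counts (0/2, the lines being inbred), centred at twice the
#' observed class frequency, and run through the VanRaden scaling
#' `2 * sum(f_c * (1 - f_c))` over all indicator columns. For a biallelic
#' gene this coincides exactly with the genome-wide kernel formula applied
#' to the equivalent 0/2 dosage recoding. With `encoding = "combination"`
#' one indicator per observed joint multi-gene allele combination is used
#' instead of per-gene indicators.
#'
#' @param genes data frame, first column the line ID, remaining columns one
#'   categorical allele call per gene.
#' @param encoding `"per_gene"` (default) or `"combination"`.
#' @return a [gp_kernel] with provenance `"G2"`.
#' @export
target_gene_g2 <- function(genes, encoding = c("per_gene", "combination")) {
  encoding <- match.arg(encoding)
  genes <- tibble::as_tibble(genes)
  if (ncol(genes) < 2L) abort("need at least one gene column")
  if (encoding == "combination") {
    combo <- interaction(genes[-1L], drop = TRUE, sep = "|")
    genes <- tibble::tibble(line = genes[[1L]], combination = combo)
  }
  X <- 2 * gene_indicators(genes)  # homozygous allele counts
  f <- colMeans(X) / 2
  Z <- sweep(X, 2L, 2 * f)
  denom <- 2 * sum(f * (1 - f))
  if (denom <= 0) abort("all target genes are monomorphic")
  K <- tcrossprod(Z) / denom
  e <- eigen(sym(K), symmetric = TRUE, only.values = TRUE)$values
  new_gp_kernel(sym(K), "G2", jitter = 0, min_eig = min(e))
}

#' Validate a relationship kernel
#'
#' Checks symmetry (to 1e-10) and positive semidefiniteness. If the smallest
#' eigenvalue is below `-1e-8`, the smallest diagonal jitter from
#' `10^{-8}, 10^{-6}, 10^{-4}` (capped at `jitter_cap`) restoring
#' PSD is added and recorded in the result's attributes.
#'
#' @param kernel square symmetric matrix (or `gp_kernel`) with line IDs.
#' @param jitter_cap largest admissible diagonal jitter.
#' @return a [gp_kernel] whose `jitter` and `min_eig` attributes record what
#'   was done.
#' @export
validate_kernel <- function(kernel, jitter_cap = 1e-4) {
  K <- unclass(kernel)
  if (nrow(K) != ncol(K)) abort("kernel must be square")
  if (max(abs(K - t(K))) > 1e-10) abort("kernel asymmetric beyond 1e-10")
  provenance <- attr(kernel, "provenance") %||% "G"
  emin <- min(eigen(sym(K), symmetric = TRUE, only.values = TRUE)$values)
  jitter <- 0
  if (emin < -1e-8) {
    for (j in c(1e-8, 1e-6, 1e-4)) {
      if (j > jitter_cap) break
      if (emin + j > 0) { jitter <- j; break }
    }
    if (jitter == 0) {
      abort(sprintf("kernel not PSD (min eigenvalue %.3g) within jitter cap %g",
                    emin, jitter_cap))
    }
    K <- K + diag(jitter, nrow(K))
    emin <- emin + jitter
  }
  new_gp_kernel(sym(K), provenance, jitter = jitter, min_eig = emin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
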