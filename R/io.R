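#' Read a plot-level phenotype table
#'
#' Accepts either a long table with columns `line, env, rep, block, trait,
#' value` or a wide table with `line, env, rep, block` plus one numeric
#' column per trait (melted to long automatically). Duplicate
#' (line, env, rep, trait) records are an error.
#'
#' @param path CSV or TSV file (delimiter sniffed from the extension).
#' @return tibble `line, env, rep, block, trait, value`.
#' @export
read_phenotypes <- function(path) {
  dat <- read_delim_auto(path)
  need <- c("line", "env", "rep", "block")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols)) {
    abort(sprintf("missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (all(c("trait", "value") %in% names(dat))) {
    out <- dplyr::select(dat, "line", "env", "rep", "block", "trait", "value")
  } else {
    trait_cols <- setdiff(names(dat), need)
    if (!length(trait_cols)) abort("no trait column found")
    out <- tidyr::pivot_longer(dat, dplyr::all_of(trait_cols),
                               names_to = "trait", values_to = "value")
  }
  if (!is.numeric(out$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(out$value))) &
                   !is.na(out$value))
    if (length(bad)) {
      abort(sprintf("unparseable numeric value at row %d", bad[1L]))
    }
    out$value <- as.numeric(out$value)
  }
  dup <- out |>
    dplyr::count(.data$line, .data$env, .data$rep, .data$trait) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("duplicated plot record(s), first: line %s, env %s, rep %s, trait %s",
                  dup$line[1L], dup$env[1L], dup$rep[1L], dup$trait[1L]))
  }
  dplyr::mutate(out, line = as.character(.data$line),
                env = as.character(.data$env))
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read a genotype matrix
#'
#' CSV/TSV layout: first column the line ID, header the marker IDs, values
#' dosages 0/1/2 (empty/NA for missing). VCF input (diploid, biallelic
#' records) maps GT fields `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`,
#' `./. -> NA`; multi-allelic records are skipped with a logged count.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"vcf"`.
#' @return tibble, first column `line`, one column per marker.
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
    else if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  if (format == "vcf") return(read_genotypes_vcf(path))
  dat <- read_delim_auto(path)
  names(dat)[1L] <- "line"
  M <- as.matrix(dat[-1L])
  bad <- which(!(M %in% c(0, 1, 2) | is.na(M)), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("dosage outside {0,1,2} at line '%s', marker '%s'",
                  dat$line[bad[1L, 1L]], colnames(M)[bad[1L, 2L]]))
  }
  dplyr::mutate(dat, line = as.character(.data$line))
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("VCF input needs the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  nalt <- lengths(VariantAnnotation::alt(vcf))
  multi <- nalt > 1L
  if (any(multi)) {
    inform(sprintf("skipped %d multi-allelic VCF record(s)", sum(multi)))
    gt <- gt[!multi, , drop = FALSE]
  }
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  map <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
           "1/1" = 2, "1|1" = 2)
  dose[] <- map[gt]
  out <- t(dose)  # lines x markers
  tibble::as_tibble(out, rownames = "line")
}

#' Read a target-gene allele table
#'
#' @param path CSV/TSV, first column the line ID, one column per gene.
#' @return tibble of categorical allele calls.
#' @export
read_target_genes <- function(path) {
  dat <- read_delim_auto(path)
  names(dat)[1L] <- "line"
  dplyr::mutate(dat, line = as.character(.data$line),
                dplyr::across(-"line", as.character))
}

#' Write a kernel as a square CSV with line IDs
#'
#' @param kernel a [gp_kernel].
#' @param path output CSV path.
#' @export
write_kernel <- function(kernel, path) {
  df <- tibble::as_tibble(unclass(kernel), rownames = "line")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a kernel written by [write_kernel()]
#'
#' @param path CSV path.
#' @param provenance provenance tag to attach (`"G"` or `"G2"`).
#' @return a validated [gp_kernel].
#' @export
read_kernel <- function(path, provenance = "G") {
  dat <- read_delim_auto(path)
  M <- as.matrix(dat[-1L])
  rownames(M) <- as.character(dat[[1L]])
  validate_kernel(structure(M, provenance = provenance))
}
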