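#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: input files (or a simulation
#' request when no files are given), the model/scheme/kernel grid, CV and
#' MCMC settings, and the master seed. A configuration can also be stored
#' as a YAML mapping of the same names and read with
#' `run_pipeline("config.yml", ...)`.
#'
#' @param pheno,geno,genes optional input file paths (plot phenotypes,
#'   marker dosages, target-gene alleles); when `pheno` is `NULL` the
#'   pipeline simulates a study from `sim`.
#' @param sim named list of [sim_config()] arguments for the simulated case.
#' @param traits,envs optional analysis subsets.
#' @param models,schemes,kernels the cross-validation grid.
#' @param cv_k,cv_cycles fold count and number of CV cycles.
#' @param mcmc named list: `n_iter`, `burn_in`, `thin`.
#' @param sreg_traits traits for the SREG stage (default: all analysed).
#' @param top_n rows kept in the ranking table.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pheno = NULL, geno = NULL, genes = NULL,
                            sim = list(), traits = NULL, envs = NULL,
                            models = c("SE", "MT"),
                            schemes = c("CV1", "CV2"), kernels = "G",
                            cv_k = 5L, cv_cycles = 10L,
                            mcmc = list(n_iter = 2000L, burn_in = 500L,
                                        thin = 2L),
                            sreg_traits = NULL, top_n = 20L, seed = 1L) {
  for (p in c(pheno, geno, genes)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  if (!all(models %in% c("SE", "MT", "ME", "MTME"))) abort("unknown model name")
  if (!all(schemes %in% c("CV1", "CV2"))) abort("unknown CV scheme")
  if (!all(kernels %in% c("G", "G2"))) abort("unknown kernel name")
  if (!length(models)) abort("model grid is empty")
  structure(list(pheno = pheno, geno = geno, genes = genes, sim = sim,
                 traits = traits, envs = envs, models = models,
                 schemes = schemes, kernels = kernels,
                 cv_k = as.integer(cv_k), cv_cycles = as.integer(cv_cycles),
                 mcmc = mcmc, sreg_traits = sreg_traits,
                 top_n = as.integer(top_n), seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

file_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full genomic-prediction pipeline
#'
#' Executes the stages `blues` (plot-level adjustment, simulating the study
#' first when no phenotype file is configured), `kernels`, `cv` (the
#' model/scheme/kernel grid), `ranking` and `sreg`, writing tidy CSV outputs
#' to `out_dir` and a JSON run manifest recording the configuration
#' snapshot, package version, per-stage output checksums, wall-clock times
#' and warnings. Stages whose outputs already exist under an identical
#' configuration are skipped, so interrupted runs resume where they left
#' off; everything is deterministic under a fixed seed.
#'
#' @param config a [pipeline_config()] or the path of a YAML file with the
#'   same fields.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (a list; also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else NULL
  reusable <- !is.null(old_manifest) &&
    identical(old_manifest$config_hash, hash)

  manifest <- list(config = unclass(config), config_hash = hash,
                   package_version = as.character(packageVersion("mtmegp")),
                   stages = list(), warnings = character(0))
  warnings_seen <- character(0)
  out <- function(...) file.path(out_dir, ...)

  run_stage <- function(name, outputs, fun) {
    t0 <- Sys.time()
    skipped <- reusable && all(file.exists(out(outputs)))
    if (!skipped) {
      withCallingHandlers(fun(), warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    }
    manifest$stages[[name]] <<- list(
      outputs = as.list(outputs),
      checksums = file_checksums(out(outputs)),
      skipped = skipped,
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    inform(sprintf("stage %-8s %s", name,
                   if (skipped) "skipped (up to date)" else "done"))
  }

  # ---- stage: blues (simulate if needed, then adjust) ----------------
  sim_outputs <- if (is.null(config$pheno)) {
    c("pheno.csv", "geno.csv", "genes.csv")
  } else character(0)
  run_stage("blues", c(sim_outputs, "blues.csv", "varcomp.csv"), function() {
    if (is.null(config$pheno)) {
      cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
      study <- simulate_study(cfg)
      readr::write_csv(study$pheno, out("pheno.csv"))
      readr::write_csv(study$geno, out("geno.csv"))
      readr::write_csv(study$genes, out("genes.csv"))
      pheno <- study$pheno
    } else {
      pheno <- read_phenotypes(config$pheno)
    }
    blues <- adjust_phenotypes(pheno, traits = config$traits,
                               envs = config$envs)
    readr::write_csv(blues, out("blues.csv"))
    readr::write_csv(varcomp_table(blues), out("varcomp.csv"))
  })

  # ---- stage: kernels ------------------------------------------------
  kernel_files <- paste0("kernel_", config$kernels, ".csv")
  run_stage("kernels", kernel_files, function() {
    if ("G" %in% config$kernels) {
      geno <- if (!is.null(config$geno)) read_genotypes(config$geno)
      else read_genotypes(out("geno.csv"))
      write_kernel(validate_kernel(vanraden_g(geno)), out("kernel_G.csv"))
    }
    if ("G2" %in% config$kernels) {
      genes <- if (!is.null(config$genes)) read_target_genes(config$genes)
      else read_target_genes(out("genes.csv"))
      write_kernel(validate_kernel(target_gene_g2(genes)),
                   out("kernel_G2.csv"))
    }
  })

  # ---- stage: cv -----------------------------------------------------
  run_stage("cv", "cv_results.csv", function() {
    blues <- readr::read_csv(out("blues.csv"), show_col_types = FALSE)
    traits <- config$traits %||% unique(blues$trait)
    envs <- config$envs %||% unique(blues$env)
    folds <- make_folds(sort(unique(blues$line)), k = config$cv_k,
                        n_cycles = config$cv_cycles,
                        seed = derive_seed(config$seed, 71L))
    results <- list()
    for (kn in config$kernels) {
      kernel <- read_kernel(out(paste0("kernel_", kn, ".csv")),
                            provenance = kn)
      for (model in config$models) {
        schemes <- if (model == "SE") "CV1" else config$schemes
        for (scheme in schemes) {
          mask <- build_mask(folds, scheme, blues)
          spec <- gp_spec(model, n_iter = config$mcmc$n_iter,
                          burn_in = config$mcmc$burn_in,
                          thin = config$mcmc$thin,
                          seed = derive_seed(config$seed, 83L))
          res <- switch(model,
            SE = purrr::map_dfr(traits, function(tr) {
              purrr::map_dfr(envs, function(ev) {
                run_cv(blues, kernel, spec, mask, trait = tr, env = ev)
              })
            }),
            ME = purrr::map_dfr(traits, function(tr) {
              run_cv(blues, kernel, spec, mask, trait = tr)
            }),
            MT = purrr::map_dfr(envs, function(ev) {
              run_cv(blues, kernel, spec, mask, env = ev)
            }),
            MTME = run_cv(blues, kernel, spec, mask))
          results[[length(results) + 1L]] <- res
        }
      }
    }
    readr::write_csv(dplyr::bind_rows(results), out("cv_results.csv"))
  })

  # ---- stage: ranking ------------------------------------------------
  run_stage("ranking", "ranking.csv", function() {
    results <- readr::read_csv(out("cv_results.csv"), show_col_types = FALSE)
    readr::write_csv(rank_models(results, top_n = config$top_n),
                     out("ranking.csv"))
  })

  # ---- stage: sreg ---------------------------------------------------
  run_stage("sreg", c("sreg_scores.csv", "sreg_variance.csv"), function() {
    blues <- readr::read_csv(out("blues.csv"), show_col_types = FALSE)
    traits <- config$sreg_traits %||% config$traits %||% unique(blues$trait)
    scores <- purrr::map_dfr(traits, function(tr) {
      fit <- sreg(blues, tr)
      dplyr::mutate(tidy(fit), trait = tr)
    })
    variance <- purrr::map_dfr(traits, function(tr) {
      dplyr::mutate(glance(sreg(blues, tr)), trait = tr)
    })
    readr::write_csv(scores, out("sreg_scores.csv"))
    readr::write_csv(variance, out("sreg_variance.csv"))
  })

  manifest$warnings <- warnings_seen
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
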