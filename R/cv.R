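#' Random k-fold partitions of the line set
#'
#' Each cycle is an independent uniformly random partition of the lines into
#' `k` folds whose sizes differ by at most one (remainder lines spread one
#' per fold in random order).
#'
#' @param line_ids character vector of line IDs.
#' @param k number of folds (>= 2).
#' @param n_cycles number of independent partitions.
#' @param seed RNG seed.
#' @return tibble `cycle, fold, line`.
#' @export
make_folds <- function(line_ids, k = 5L, n_cycles = 10L, seed = 1L) {
  n <- length(line_ids)
  if (k < 2L) abort("need k >= 2")
  if (k > n) abort("k larger than the number of lines")
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_cycles), function(cy) {
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0L) {
        bump <- sample.int(k, extra)
        sizes[bump] <- sizes[bump] + 1L
      }
      fold <- sample(rep.int(seq_len(k), sizes))
      tibble::tibble(cycle = cy, fold = fold, line = line_ids)
    })
  })
}

#' Build a CV1 or CV2 masking plan
#'
#' CV1 (prediction of unseen genotypes) hides every cell of a test line
#' within the model's trait/environment scope. CV2 (prediction of tested
#' genotypes in new environments/traits) hides only the target-trait cells
#' of test lines in the target environments, keeping their secondary-trait
#' and other-environment records available to the sampler. Cells already
#' missing in the data simply stay missing.
#'
#' @param folds fold assignment from [make_folds()].
#' @param scheme `"CV1"` or `"CV2"`.
#' @param blues BLUE set tibble defining which cells exist.
#' @param target_envs,target_traits scope of the masking (default: all
#'   environments/traits present in `blues`).
#' @return tibble `cycle, fold, line, env, trait` of class `mask_plan`.
#' @export
build_mask <- function(folds, scheme = c("CV1", "CV2"), blues,
                       target_envs = NULL, target_traits = NULL) {
  scheme <- match.arg(scheme)
  blues <- tibble::as_tibble(blues)
  envs <- unique(blues$env)
  traits <- unique(blues$trait)
  target_envs <- target_envs %||% envs
  target_traits <- target_traits %||% traits
  if (!all(target_envs %in% envs) || !all(target_traits %in% traits))
    abort("masking targets not present in the BLUE set")
  cells <- dplyr::distinct(blues, .data$line, .data$env, .data$trait)
  masked_cells <- if (scheme == "CV1") cells else {
    dplyr::filter(cells, .data$env %in% target_envs,
                  .data$trait %in% target_traits)
  }
  out <- dplyr::inner_join(tibble::as_tibble(folds), masked_cells,
                           by = "line", relationship = "many-to-many")
  # a fold must leave at least two training lines per masked environment
  chk <- out |>
    dplyr::distinct(.data$cycle, .data$fold, .data$env, .data$trait,
                    .data$line) |>
    dplyr::count(.data$cycle, .data$fold, .data$env, .data$trait)
  totals <- cells |> dplyr::count(.data$env, .data$trait, name = "n_cells")
  chk <- dplyr::left_join(chk, totals, by = c("env", "trait"))
  if (any(chk$n_cells - chk$n < 2L))
    abort("masking would leave an environment with fewer than 2 training lines")
  structure(dplyr::select(out, "cycle", "fold", "line", "env", "trait"),
            scheme = scheme, target_envs = target_envs,
            target_traits = target_traits,
            class = c("mask_plan", class(out)))
}

#' Cross-validated prediction ability
#'
#' For each cycle and fold of the mask plan the model is refitted on the
#' masked data and the hidden cells predicted. Prediction ability is the
#' Pearson correlation between predicted and observed BLUEs of the masked
#' cells, computed per environment (and trait) per cycle pooling the folds
#' of that cycle, then summarised by mean and SD over cycles via
#' [summarize_cv()].
#'
#' A fold whose fit fails is recorded as missing for that cycle with a
#' warning rather than aborting the run. Cycles where the predictions are
#' constant yield a missing correlation with a warning.
#'
#' @param blues BLUE set tibble.
#' @param kernel a [gp_kernel].
#' @param spec a [gp_spec()]; its seed is offset per fold so refits are
#'   reproducible yet independent.
#' @param mask_plan a [build_mask()] plan.
#' @param trait,env scope passed to [fit_gp()] (SE/MT/ME restrictions).
#' @param progress print per-fold progress with timestamps.
#' @return tibble `model, scheme, kernel, env, trait, cycle, r` of class
#'   `cv_result`.
#' @export
run_cv <- function(blues, kernel, spec, mask_plan, trait = NULL, env = NULL,
                   progress = FALSE) {
  blues <- tibble::as_tibble(blues)
  scheme <- attr(mask_plan, "scheme")
  label <- model_label(spec$model, scheme, attr(kernel, "provenance") %||% "G")
  cycles <- sort(unique(mask_plan$cycle))
  out <- purrr::map_dfr(cycles, function(cy) {
    plan_cy <- dplyr::filter(mask_plan, .data$cycle == cy)
    folds <- sort(unique(plan_cy$fold))
    preds <- purrr::map(folds, function(fd) {
      cells <- dplyr::filter(plan_cy, .data$fold == fd)
      fit <- tryCatch({
        sp <- spec
        sp$seed <- derive_seed(spec$seed, 1000L * cy + fd)
        fit_gp(blues, kernel, sp, trait = trait, env = env, mask = cells)
      }, error = function(e) {
        warn(sprintf("fit failed for cycle %d fold %d: %s", cy, fd,
                     conditionMessage(e)))
        NULL
      })
      if (progress) {
        message(sprintf("[%s] %s cycle %d fold %d done",
                        format(Sys.time(), "%H:%M:%S"), label, cy, fd))
      }
      if (is.null(fit)) return(NULL)
      targets <- cells |>
        dplyr::filter(.data$env %in% fit$envs, .data$trait %in% fit$traits) |>
        dplyr::select("line", "env", "trait")
      predict(fit, targets)
    })
    preds <- dplyr::bind_rows(preds)
    if (!nrow(preds)) {
      return(tibble::tibble(model = label, scheme = scheme,
                            kernel = attr(kernel, "provenance") %||% "G",
                            env = NA_character_, trait = NA_character_,
                            cycle = cy, r = NA_real_))
    }
    obs <- dplyr::select(blues, "line", "env", "trait", "blue")
    scored <- dplyr::inner_join(preds, obs, by = c("line", "env", "trait"))
    scored |>
      dplyr::group_by(.data$env, .data$trait) |>
      dplyr::summarise(r = cor_or_na(.data$.pred, .data$blue),
                       .groups = "drop") |>
      dplyr::mutate(model = label, scheme = scheme,
                    kernel = attr(kernel, "provenance") %||% "G", cycle = cy,
                    .before = 1L)
  })
  structure(dplyr::select(out, "model", "scheme", "kernel", "env", "trait",
                          "cycle", "r"),
            class = c("cv_result", class(out)))
}

cor_or_na <- function(pred, obs) {
  ok <- stats::complete.cases(pred, obs)
  if (sum(ok) < 3L || stats::sd(pred[ok]) == 0 || stats::sd(obs[ok]) == 0) {
    warn("prediction ability undefined (constant or too few predictions)")
    return(NA_real_)
  }
  stats::cor(pred[ok], obs[ok])
}

model_label <- function(model, scheme, kernel) {
  parts <- model
  if (model != "SE" && !is.null(scheme)) parts <- paste(parts, scheme, sep = "_")
  if (identical(kernel, "G2")) parts <- paste(parts, "G2", sep = "_")
  parts
}

#' @describeIn run_cv aggregate prediction abilities: mean and SD over
#'   cycles per model-environment-trait, plus the overall per-model mean.
#' @param results a `cv_result` (or row-bound set of them).
#' @export
summarize_cv <- function(results) {
  per_env <- results |>
    dplyr::filter(!is.na(.data$env)) |>
    dplyr::group_by(.data$model, .data$scheme, .data$kernel, .data$env,
                    .data$trait) |>
    dplyr::summarise(mean_r = mean(.data$r, na.rm = TRUE),
                     sd_r = stats::sd(.data$r, na.rm = TRUE),
                     n_cycles = sum(!is.na(.data$r)), .groups = "drop")
  overall <- per_env |>
    dplyr::group_by(.data$model, .data$scheme, .data$kernel, .data$trait) |>
    dplyr::summarise(overall_r = mean(.data$mean_r), .groups = "drop")
  dplyr::left_join(per_env, overall,
                   by = c("model", "scheme", "kernel", "trait"))
}

#' Rank model-environment combinations by prediction ability
#'
#' Rows are sorted by mean prediction ability (descending); ties are broken
#' by smaller SD, then by label lexicographically. The top `top_n` rows are
#' returned, mirroring the "Top-20 models" presentation.
#'
#' @param results one `cv_result` or a list of them.
#' @param top_n number of rows to keep.
#' @return tibble `rank, model, scheme, kernel, env, trait, mean_r, sd_r`.
#' @export
rank_models <- function(results, top_n = 20L) {
  if (is.data.frame(results)) results <- list(results)
  if (!length(results)) abort("need at least one CV result")
  agg <- purrr::map_dfr(results, summarize_cv)
  agg |>
    dplyr::arrange(dplyr::desc(.data$mean_r), .data$sd_r, .data$model,
                   .data$env, .data$trait) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1L) |>
    head(top_n) |>
    dplyr::select("rank", "model", "scheme", "kernel", "env", "trait",
                  "mean_r", "sd_r")
}
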