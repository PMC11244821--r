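#' Validate a colony growth-rate table
#'
#' Checks the long-format colony table schema: required columns
#' (`strain_id`, `role`, `plate`, `well`, `field`, `colony_id`,
#' `growth_rate`), column types, and allowed `role` values
#' (`ma`, `reference`, `petite_control`). All violations are collected
#' and reported together. Negative growth rates are allowed (rates are
#' slopes of log-area fits) but flagged with a warning, as are assay
#' wells lacking reference colonies (such wells contribute no pairs).
#'
#' @param table a data frame or the path of a CSV file.
#' @param quiet suppress informational warnings (schema errors still
#'   raise).
#' @return The validated table (invisibly usable downstream).
#' @export
validate_colony_table <- function(table, quiet = FALSE) {
  if (is.character(table)) {
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  required <- c(strain_id = "character", role = "character",
                plate = "numeric", well = "character",
                field = "numeric", colony_id = "character",
                growth_rate = "numeric")
  problems <- character(0)
  for (col in names(required)) {
    if (!col %in% names(table)) {
      problems <- c(problems, paste0("missing column: ", col))
    }
  }
  if (!length(problems)) {
    for (col in c("plate", "field", "growth_rate")) {
      if (!is.numeric(table[[col]])) {
        problems <- c(problems, paste0("column ", col,
                                       " must be numeric"))
      }
    }
    for (col in c("strain_id", "role", "well", "colony_id")) {
      if (!is.character(table[[col]]) && !is.factor(table[[col]])) {
        problems <- c(problems,
                      paste0("column ", col, " must be character"))
      } else {
        table[[col]] <- as.character(table[[col]])
      }
    }
    bad_roles <- setdiff(unique(table$role),
                         c("ma", "reference", "petite_control"))
    if (length(bad_roles)) {
      problems <- c(problems, paste0("invalid role value(s): ",
                                     paste(bad_roles, collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop_domain("invalid colony table:\n  ",
                paste(problems, collapse = "\n  "))
  }
  if (!quiet) {
    if (any(table$growth_rate < 0)) {
      warning(sum(table$growth_rate < 0),
              " negative growth rate(s) present (allowed)",
              call. = FALSE)
    }
    assay <- table[table$role != "petite_control", ]
    has_ref <- tapply(assay$role == "reference", assay$well, any)
    if (any(!has_ref)) {
      warning("wells without reference colonies (excluded from ",
              "pairing): ",
              paste(names(has_ref)[!has_ref], collapse = ", "),
              call. = FALSE)
    }
  }
  table
}

#' Run a full simulate-fit-compare scenario
#'
#' Executes the whole pipeline on synthetic data: draw per-strain truths
#' from a DME model, simulate the colony table and petite controls, pair
#' colonies, fit the colony model, fit the requested DME model variants
#' to the per-strain summaries, and compare them. All randomness flows
#' from the named seeds in the configuration; rerunning with the same
#' configuration reproduces every number exactly.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{`design`}{an [experiment_design()].}
#'     \item{`truth_model`}{[dme_model()] generating the truths.}
#'     \item{`general`}{[general_params()] (means / `rho_ancestor`).}
#'     \item{`noise`}{[noise_model()].}
#'     \item{`seeds`}{list with `sim`, `pairing`, `fit` integer seeds.}
#'     \item{`models`}{character vector of DME kinds to fit
#'       (default `"snm_only"`).}
#'     \item{`rho`}{petite proportion(s) for simulated strains.}
#'     \item{`fdr`}{FDR level (default 0.05).}
#'     \item{`grid`}{list of [fit_dme()] grid controls (`n`, `s_max`).}
#'     \item{`n_starts`}{optimizer starts (default 1).}
#'   }
#' @param out_dir optional directory; when given, per-stage CSV/JSON
#'   artifacts and a reproducibility manifest are written there.
#' @return A list bundle with `truths`, `table`, `colony_fit`,
#'   `dme_fits`, `comparison` (when >= 2 models), and `manifest`.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  stopifnot(is.list(config), inherits(config$design, "ma_design"),
            inherits(config$truth_model, "dme_model"))
  seeds <- config$seeds %||% list(sim = 1L, pairing = 2L, fit = 3L)
  general <- config$general %||% general_params()
  noise <- config$noise %||% noise_model()
  models <- config$models %||% "snm_only"
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop_domain("scenario stage '", name, "' failed: ",
                  conditionMessage(e))
    })
    res
  }
  truths <- stage("simulate_truths", simulate_strain_effects(
    config$truth_model, length(config$design$strain_ids),
    seed = seeds$sim, rho = config$rho %||% 0.1))
  truths$strain_id <- config$design$strain_ids
  table <- stage("simulate_colonies", rbind(
    simulate_colony_table(config$design, truths, general, noise,
                          seed = seeds$sim + 1L),
    simulate_petite_controls(config$design, general, noise,
                             seed = seeds$sim + 2L)))
  cfit <- stage("fit_strains", fit_colony_model(
    table, baseline = config$design$baseline_strain_id,
    seed = seeds$pairing, fdr_level = config$fdr %||% 0.05,
    n_starts = config$n_starts %||% 1L))
  grid <- config$grid %||% list()
  summaries <- data.frame(strain_id = cfit$estimates$strain_id,
                          s_est = cfit$estimates$s,
                          se = cfit$estimates$se,
                          stringsAsFactors = FALSE)
  summaries <- summaries[is.finite(summaries$se) & summaries$se > 0, ]
  dme_fits <- lapply(models, function(kind) {
    stage(paste0("fit_dme_", kind), fit_dme(
      summaries, kind = kind, seed = seeds$fit,
      n = grid$n %||% 2^12, s_max = grid$s_max %||% 0.5,
      M_diploid = config$truth_model$M_diploid,
      n_starts = config$n_starts %||% 1L))
  })
  names(dme_fits) <- models
  comparison <- if (length(dme_fits) >= 2) {
    stage("compare", compare_models(dme_fits, baseline = 1L))
  } else NULL
  manifest <- list(
    seeds = seeds, models = models,
    n_strains = length(config$design$strain_ids),
    n_colonies = nrow(table), n_pairs = cfit$n_pairs,
    fdr = config$fdr %||% 0.05,
    timestamp = format(Sys.time(), tz = "UTC"))
  bundle <- list(truths = truths, table = table, colony_fit = cfit,
                 dme_fits = dme_fits, comparison = comparison,
                 manifest = manifest)
  if (!is.null(out_dir)) write_scenario(bundle, out_dir)
  bundle
}

write_scenario <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$table, file.path(out_dir, "colony_table.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$truths, file.path(out_dir, "truths.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$colony_fit$estimates,
                   file.path(out_dir, "strain_estimates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(bundle$colony_fit$general),
                       file.path(out_dir, "general_params.json"),
                       auto_unbox = TRUE, digits = NA)
  for (kind in names(bundle$dme_fits)) {
    jsonlite::write_json(
      fit_result_json(bundle$dme_fits[[kind]]),
      file.path(out_dir, paste0("dme_fit_", kind, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$comparison)) {
    utils::write.csv(bundle$comparison,
                     file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

fit_result_json <- function(fit) {
  list(kind = fit$model$kind, parameters = fit$par,
       logLik = fit$logLik, n_free_params = fit$n_free_params,
       AIC = fit$AIC, convergence = fit$convergence)
}
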