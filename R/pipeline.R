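#' Run the full trait-niche analysis pipeline
#'
#' Glues all stages together: input (a trait table file or a named preset
#' scenario), preprocessing, niche metrics, phenotypic integration, diversity
#' effects, niche-metric tests and predictor model comparison. All outputs
#' are written as CSV files to `out_dir` together with a JSON sidecar holding
#' the fully resolved configuration, so a run can be reproduced from its own
#' output. Given the same configuration and seed the outputs are
#' byte-identical.
#'
#' @param input Path to a delimited trait table, or `NULL` to simulate.
#' @param scenario Preset scenario name for simulation (see
#'   [preset_scenario()]); ignored when `input` is given.
#' @param seed Integer seed used for simulation and permutations.
#' @param out_dir Output directory (created if needed); `NULL` writes nothing.
#' @param trait_sets Named list of trait sets; default all single axes plus
#'   the multivariate set.
#' @param alpha Significance level for the integration counts.
#' @param permutations Permutation count for the niche-metric tests (0 =
#'   parametric only).
#' @param stages Character vector choosing which analysis stages to run;
#'   any of `"niche"`, `"integration"`, `"inference"`, `"predictors"`.
#' @return A list of class `niche_pipeline` with elements `table`, `std`,
#'   `niche`, `integration`, `diversity_effect`, `trait_tests`,
#'   `metric_tests`, `predictor_models`, `config`.
#' @export
run_pipeline <- function(input = NULL, scenario = "null", seed = 1L,
                         out_dir = NULL,
                         trait_sets = default_trait_sets(),
                         alpha = 0.05, permutations = 0L,
                         stages = c("niche", "integration", "inference",
                                    "predictors")) {
  config <- list(input = input, scenario = if (is.null(input)) scenario else NULL,
                 seed = seed, trait_sets = trait_sets, alpha = alpha,
                 permutations = permutations, stages = stages)
  table <- if (!is.null(input)) {
    read_trait_table(input)
  } else {
    generate_traits(preset_scenario(scenario, seed = seed))
  }
  std <- preprocess(table)
  bundle <- list(table = table, std = std, config = config)

  if ("niche" %in% stages) {
    bundle$niche <- niche_table(std, trait_sets)
  }
  if ("integration" %in% stages) {
    bundle$integration <- integration_summary(block_correct(log_transform(table)),
                                              alpha = alpha)
  }
  if ("inference" %in% stages) {
    bundle$diversity_effect <- tryCatch(diversity_effect(table),
                                        error = function(e) {
                                          warning(conditionMessage(e), call. = FALSE)
                                          NULL
                                        })
    bundle$trait_tests <- trait_response_models(table)
    if (!is.null(bundle$niche)) {
      bundle$metric_tests <- suppressWarnings(
        niche_metric_tests(std, trait_sets, permutations = permutations,
                           seed = seed))
    }
  }
  if ("predictors" %in% stages && !is.null(bundle$diversity_effect)) {
    bundle$predictor_models <- niche_predictor_models(table, std, trait_sets)
  }
  class(bundle) <- "niche_pipeline"
  if (!is.null(out_dir)) write_pipeline(bundle, out_dir)
  bundle
}

#' @keywords internal
write_pipeline <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  write_trait_table(bundle$table, file.path(out_dir, "trait_table.csv"))
  wcsv(as.data.frame(bundle$std), "standardized_table.csv")
  if (!is.null(bundle$niche)) {
    wcsv(bundle$niche$cells, "niche_cells.csv")
    wcsv(bundle$niche$separation, "niche_separation.csv")
    wcsv(bundle$niche$separation_pairs, "niche_separation_pairs.csv")
    wcsv(bundle$niche$shift, "niche_shift.csv")
    wcsv(bundle$niche$community, "niche_community.csv")
  }
  if (!is.null(bundle$integration)) {
    wcsv(bundle$integration$cells, "integration_cells.csv")
    wcsv(bundle$integration$pairs, "integration_pairs.csv")
  }
  if (!is.null(bundle$diversity_effect)) {
    wcsv(bundle$diversity_effect$shoots, "diversity_effect_shoots.csv")
    wcsv(bundle$diversity_effect$species, "diversity_effect_species.csv")
  }
  if (!is.null(bundle$trait_tests)) {
    wcsv(bundle$trait_tests$tests, "trait_lrt.csv")
    wcsv(bundle$trait_tests$contrasts, "trait_contrasts.csv")
  }
  if (!is.null(bundle$metric_tests)) {
    wcsv(bundle$metric_tests$width_paired_t, "metric_width_paired_t.csv")
    wcsv(bundle$metric_tests$anova, "metric_anova.csv")
  }
  wcsv(bundle$predictor_models, "predictor_models.csv")
  cfg <- bundle$config
  cfg$trait_sets <- lapply(cfg$trait_sets, as.character)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Human-readable summary of a pipeline run
#'
#' Prints per-species trait means by diversity level, the niche-metric
#' summaries (density, width, separation averaged across species), the
#' niche-shift log-response ratios, and the diversity-effect table.
#'
#' @param bundle A `niche_pipeline` from [run_pipeline()].
#' @param digits Rounding for display.
#' @return `bundle`, invisibly.
#' @export
report <- function(bundle, digits = 3L) {
  stopifnot(inherits(bundle, "niche_pipeline"))
  cfg <- trait_config_of(bundle$table)
  df <- as.data.frame(bundle$table)
  cat("== Trait means (+/- SE) per species x diversity ==\n")
  for (tr in niche_traits(cfg)) {
    agg <- stats::aggregate(df[[tr]],
                            by = list(species = df$species, diversity = df$diversity),
                            FUN = function(v) mean(v, na.rm = TRUE))
    wide <- stats::reshape(agg, idvar = "species", timevar = "diversity",
                           direction = "wide")
    names(wide) <- sub("^x\\.", "", names(wide))
    cat("--", tr, "(", cfg$unit[match(tr, cfg$trait)], ")\n")
    print(format(wide, digits = digits), row.names = FALSE)
  }
  if (!is.null(bundle$niche)) {
    cat("\n== Niche metrics, mean across species per diversity level ==\n")
    agg <- stats::aggregate(cbind(density, width) ~ trait_set + diversity,
                            data = bundle$niche$cells, FUN = mean)
    sep <- stats::aggregate(separation ~ trait_set + diversity,
                            data = bundle$niche$separation, FUN = mean,
                            na.action = stats::na.omit)
    print(format(merge(agg, sep, all.x = TRUE), digits = digits),
          row.names = FALSE)
    cat("\n== Niche shift (log-response ratio) per trait set ==\n")
    sh <- stats::aggregate(shift_lrr ~ trait_set, data = bundle$niche$shift,
                           FUN = mean)
    print(format(sh, digits = digits), row.names = FALSE)
  }
  if (!is.null(bundle$diversity_effect)) {
    cat("\n== Diversity effect D on shoot biomass per species ==\n")
    print(format(bundle$diversity_effect$species, digits = digits),
          row.names = FALSE)
  }
  invisible(bundle)
}

#' @export
print.niche_pipeline <- function(x, ...) {
  cat("niche_pipeline:", nrow(x$table), "shoots;",
      "stages run:", paste(x$config$stages, collapse = ", "), "\n")
  invisible(x)
}
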