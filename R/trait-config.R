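#' Default trait configuration
#'
#' Returns the canonical configuration of the 14 light-acquisition traits
#' (grouped into height growth, space filling and leaf morphology) plus shoot
#' biomass as the performance variable. For each trait the configuration
#' records its unit, the transform applied on the analysis scale (`"none"`,
#' `"log"` for strictly positive traits, `"log1p"` for count traits that may
#' legitimately be zero) and physical bounds used for validation.
#'
#' The log-transform set is exactly: shoot length, internode length, number of
#' secondary axes, leaf number, leaf length, leaf area, and maximum and
#' minimum specific leaf area. The two count traits (number of secondary
#' axes, leaf number) use `log(x + 1)` so that zero counts remain valid.
#'
#' @return A data frame of class `trait_config` with columns `trait`, `unit`,
#'   `transform`, `group`, `lower`, `upper` (physical bounds; `Inf` where
#'   unbounded above).
#' @export
#' @examples
#' cfg <- default_trait_config()
#' cfg$trait[cfg$transform == "log"]
default_trait_config <- function() {
  cfg <- data.frame(
    trait = c(
      "shoot_height", "shoot_length", "internode_length", "stem_mass_fraction",
      "stem_angle_basal", "stem_angle_canopy", "n_secondary_axes",
      "leaf_number", "leaf_angle_max", "leaf_angle_min",
      "leaf_length", "leaf_area", "sla_max", "sla_min",
      "shoot_biomass"
    ),
    unit = c(
      "cm", "cm", "cm", "mg mg-1",
      "deg", "deg", "count",
      "count", "deg", "deg",
      "mm", "cm2", "mm2 mg-1", "mm2 mg-1",
      "g"
    ),
    transform = c(
      "none", "log", "log", "none",
      "none", "none", "log1p",
      "log1p", "none", "none",
      "log", "log", "log", "log",
      "none"
    ),
    group = c(
      rep("height_growth", 4L),
      rep("space_filling", 6L),
      rep("leaf_morphology", 4L),
      "performance"
    ),
    lower = c(
      0, 0, 0, 0,
      0, 0, 0,
      0, 0, 0,
      0, 0, 0, 0,
      0
    ),
    upper = c(
      Inf, Inf, Inf, 1,
      180, 180, Inf,
      Inf, 180, 180,
      Inf, Inf, Inf, Inf,
      Inf
    ),
    stringsAsFactors = FALSE
  )
  class(cfg) <- c("trait_config", "data.frame")
  cfg
}

#' Names of the 14 niche trait axes
#'
#' Convenience accessor for the trait names of a configuration, excluding the
#' performance variable (shoot biomass), optionally restricted to one trait
#' group.
#'
#' @param config A `trait_config`, by default [default_trait_config()].
#' @param group Optional trait group: `"height_growth"`, `"space_filling"` or
#'   `"leaf_morphology"`.
#' @return Character vector of trait names.
#' @export
niche_traits <- function(config = default_trait_config(), group = NULL) {
  keep <- config$group != "performance"
  if (!is.null(group)) {
    group <- match.arg(group, c("height_growth", "space_filling", "leaf_morphology"))
    keep <- keep & config$group == group
  }
  config$trait[keep]
}

#' Read trait-configuration overrides from a YAML file
#'
#' The YAML file maps trait names to any subset of the fields `unit`,
#' `transform` (`none`, `log`, `log1p`), `group`, `lower`, `upper`; listed
#' traits override the defaults, all others keep their default
#' configuration. Traits absent from the default set, or unknown transforms,
#' are rejected.
#'
#' @param path Path to a YAML file.
#' @param base Configuration to override, default [default_trait_config()].
#' @return A `trait_config`.
#' @export
read_trait_config <- function(path, base = default_trait_config()) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML trait configurations",
         call. = FALSE)
  }
  overrides <- yaml::read_yaml(path)
  for (tr in names(overrides)) {
    i <- match(tr, base$trait)
    if (is.na(i)) stop("unknown trait in config: ", tr, call. = FALSE)
    ov <- overrides[[tr]]
    bad <- setdiff(names(ov), c("unit", "transform", "group", "lower", "upper"))
    if (length(bad) > 0L) {
      stop("unknown field(s) for trait '", tr, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!is.null(ov$transform) &&
        !ov$transform %in% c("none", "log", "log1p")) {
      stop("unknown transform for trait '", tr, "': ", ov$transform,
           call. = FALSE)
    }
    for (f in names(ov)) base[[f]][i] <- ov[[f]]
  }
  base
}

#' @keywords internal
id_columns <- function() c("species", "block", "plot", "diversity")

#' @keywords internal
diversity_levels <- function() c("monoculture", "mixture")
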