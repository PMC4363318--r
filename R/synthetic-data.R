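#' Default species-level monoculture trait means
#'
#' Mean trait values on the measurement scale for the seven simulated legume
#' species (labelled Lp, Lc, Mv, Ov, Th, Tp, Vc). Values are plausible for
#' temperate grassland legumes spanning short creeping to tall erect growth
#' forms; they define the default simulation conditions and are not fitted to
#' any dataset.
#'
#' @return Numeric matrix, species in rows, the 14 traits in columns.
#' @export
default_trait_means <- function() {
  traits <- niche_traits()
  m <- rbind(
    Lp = c(45, 60, 4.0, 0.45, 40, 35, 3, 12, 110, 40, 45, 6.0, 28, 18),
    Lc = c(25, 30, 2.0, 0.40, 50, 45, 5, 18, 100, 35, 12, 1.5, 22, 14),
    Mv = c(70, 85, 5.0, 0.50, 25, 20, 6, 25,  95, 30, 18, 2.5, 24, 16),
    Ov = c(80, 95, 6.0, 0.55, 20, 18, 4, 15,  90, 25, 35, 5.0, 20, 13),
    Th = c(30, 35, 2.5, 0.35, 45, 40, 4, 14, 105, 45, 20, 3.0, 30, 20),
    Tp = c(35, 40, 3.0, 0.38, 40, 35, 3, 13, 100, 40, 25, 4.0, 26, 17),
    Vc = c(50, 70, 4.5, 0.42, 55, 50, 5, 20, 115, 50, 30, 3.5, 32, 22)
  )
  colnames(m) <- traits
  m
}

#' @keywords internal
default_trait_sd <- function() {
  c(shoot_height = 6, shoot_length = 0.18, internode_length = 0.18,
    stem_mass_fraction = 0.05, stem_angle_basal = 12, stem_angle_canopy = 12,
    n_secondary_axes = 0.30, leaf_number = 0.25, leaf_angle_max = 12,
    leaf_angle_min = 10, leaf_length = 0.18, leaf_area = 0.22,
    sla_max = 0.12, sla_min = 0.12)
}

#' @keywords internal
default_biomass_model <- function(species) {
  mono_mean <- c(Lp = 1.2, Lc = 0.6, Mv = 2.5, Ov = 3.0, Th = 0.8,
                 Tp = 1.0, Vc = 1.5)[species]
  if (anyNA(mono_mean)) mono_mean <- stats::setNames(rep(1.0, length(species)), species)
  list(mono_mean = mono_mean,
       delta = stats::setNames(rep(0, length(species)), species),
       sdlog = 0.3)
}

#' Transform measurement-scale values to the analysis scale (and back)
#'
#' Log traits are natural-log transformed; count traits use `log(x + 1)`;
#' all other traits are unchanged.
#'
#' @param x Numeric vector of trait values (one trait).
#' @param transform One of `"none"`, `"log"`, `"log1p"`.
#' @return Transformed numeric vector.
#' @keywords internal
to_analysis_scale <- function(x, transform) {
  switch(transform, none = x, log = log(x), log1p = log1p(x),
         stop("unknown transform: ", transform))
}

#' @keywords internal
from_analysis_scale <- function(x, transform) {
  switch(transform, none = x, log = exp(x), log1p = expm1(x),
         stop("unknown transform: ", transform))
}

#' Specify a synthetic monoculture-mixture scenario
#'
#' Defines the full parameterization of the synthetic shoot-trait generator:
#' species, cell sizes, a blocked plot layout, species-specific trait means on
#' the measurement scale, diversity-induced mean shifts ("plasticity") on the
#' analysis scale, within-cell trait covariance on the analysis scale, block
#' effects, and a biomass model with per-species overyielding factors
#' (mixture mean biomass = `(1 + delta) *` monoculture mean, with lognormal
#' shoot-to-shoot noise).
#'
#' @param species Character vector of species labels (default seven legumes).
#' @param n_shoots_per_cell Shoots per species x diversity cell (default 10,
#'   must be >= 2).
#' @param n_blocks Number of experimental blocks (default 4).
#' @param trait_means Species x trait matrix of monoculture means on the
#'   measurement scale; defaults to [default_trait_means()].
#' @param plasticity Species x trait matrix of additive mixture-mean shifts
#'   on the analysis scale; default all zero.
#' @param covariance Trait covariance matrix on the analysis scale, shared by
#'   all cells (default diagonal with the package's per-trait SDs), or a named
#'   list with entry `default` plus optional `"<species>.<diversity>"`
#'   overrides.
#' @param block_effects Block x trait matrix of additive offsets on the
#'   analysis scale, identical across diversity levels; default all zero.
#' @param biomass_model List with `mono_mean` (named per species), `delta`
#'   (named per species, proportional overyielding) and `sdlog`.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(species = rownames(default_trait_means()),
                          n_shoots_per_cell = 10L,
                          n_blocks = 4L,
                          trait_means = default_trait_means()[species, , drop = FALSE],
                          plasticity = NULL,
                          covariance = NULL,
                          block_effects = NULL,
                          biomass_model = default_biomass_model(species),
                          seed = 1L) {
  traits <- niche_traits()
  stopifnot(n_shoots_per_cell >= 2L, n_blocks >= 1L)
  trait_means <- as.matrix(trait_means)
  if (is.null(rownames(trait_means))) rownames(trait_means) <- species
  stopifnot(all(species %in% rownames(trait_means)),
            all(traits %in% colnames(trait_means)))
  if (is.null(plasticity)) {
    plasticity <- matrix(0, length(species), length(traits),
                         dimnames = list(species, traits))
  }
  if (is.null(covariance)) covariance <- diag(default_trait_sd()[traits]^2)
  if (is.matrix(covariance)) {
    if (is.null(colnames(covariance))) dimnames(covariance) <- list(traits, traits)
    covariance <- list(default = covariance)
  }
  for (nm in names(covariance)) {
    sig <- covariance[[nm]]
    if (!isSymmetric(unname(sig), tol = 1e-8) ||
        min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("covariance '", nm, "' is not symmetric positive semi-definite",
           call. = FALSE)
    }
  }
  if (is.null(block_effects)) {
    block_effects <- matrix(0, n_blocks, length(traits),
                            dimnames = list(paste0("B", seq_len(n_blocks)), traits))
  }
  spec <- list(species = species, n_shoots_per_cell = as.integer(n_shoots_per_cell),
               n_blocks = as.integer(n_blocks), trait_means = trait_means,
               plasticity = plasticity, covariance = covariance,
               block_effects = block_effects, biomass_model = biomass_model,
               seed = as.integer(seed))
  class(spec) <- "scenario_spec"
  spec
}

#' Preset simulation scenarios
#'
#' Four named scenarios cover the qualitative regimes the niche metrics are
#' meant to detect:
#' \describe{
#'   \item{null}{No plasticity, no overyielding: monoculture and mixture
#'     populations are identically distributed; every downstream niche-shift
#'     and diversity-effect estimate is centred on zero.}
#'   \item{divergence}{Mixture means of the leaf-morphology traits are pushed
#'     away from the cross-species centre (0.6 analysis-scale units), so
#'     between-species separation on leaf traits increases in mixture.}
#'   \item{convergence}{Mixture means of the height-growth traits are pulled
#'     80% of the way towards the tallest species, so between-species
#'     separation on height traits shrinks in mixture.}
#'   \item{overyielding}{No trait plasticity, but proportional biomass
#'     overyielding delta = 0.5 for three species (Mv, Ov, Th), 0 elsewhere.}
#' }
#'
#' @param name One of `"null"`, `"divergence"`, `"convergence"`,
#'   `"overyielding"`.
#' @param seed Integer seed stored in the returned spec.
#' @param ... Further arguments passed to [scenario_spec()].
#' @return A `scenario_spec`.
#' @export
preset_scenario <- function(name = c("null", "divergence", "convergence", "overyielding"),
                            seed = 1L, ...) {
  name <- match.arg(name)
  spec <- scenario_spec(seed = seed, ...)
  cfg <- default_trait_config()
  analysis_means <- spec$trait_means
  for (tr in colnames(analysis_means)) {
    analysis_means[, tr] <- to_analysis_scale(
      spec$trait_means[, tr], cfg$transform[match(tr, cfg$trait)])
  }
  if (name == "divergence") {
    leaf <- niche_traits(group = "leaf_morphology")
    for (tr in leaf) {
      centre <- mean(analysis_means[, tr])
      push <- sign(analysis_means[, tr] - centre)
      push[push == 0] <- 1
      spec$plasticity[, tr] <- 0.6 * push
    }
  } else if (name == "convergence") {
    height <- niche_traits(group = "height_growth")
    tallest <- spec$species[which.max(spec$trait_means[spec$species, "shoot_height"])]
    for (tr in height) {
      spec$plasticity[, tr] <- 0.8 * (analysis_means[tallest, tr] - analysis_means[, tr])
    }
  } else if (name == "overyielding") {
    over <- intersect(c("Mv", "Ov", "Th"), spec$species)
    if (length(over) == 0L) over <- spec$species[1L]
    spec$biomass_model$delta[over] <- 0.5
  }
  spec$scenario <- name
  spec
}

#' Generate a synthetic shoot-level trait table
#'
#' Draws, for every species x diversity cell, exactly `n_shoots_per_cell`
#' shoots from a multivariate normal on the analysis scale with the cell's
#' mean (monoculture mean, plus the plasticity shift in mixture) and
#' covariance, adds the shoot's block effect, and back-transforms log-scale
#' traits to the measurement scale. Shoot biomass is drawn from a lognormal
#' whose arithmetic mean equals the species' monoculture mean times
#' `(1 + delta)` in mixture. Rows whose back-transformed values fall outside
#' the physical trait bounds are redrawn (up to 100 attempts, then an error):
#' resampling rather than clipping keeps cell means undistorted.
#'
#' The plot layout is balanced across blocks: each cell's shoots are assigned
#' round-robin to the blocks, monoculture shoots to a per-species subplot
#' within each block and mixture shoots to the block's mixture plot. This
#' keeps plot nested in block while leaving block effects estimable without
#' confounding with species identity, which is what the block-correction
#' step of the analysis chain assumes.
#'
#' @param spec A `scenario_spec`.
#' @return A validated `trait_table`; identical specs (including seed) yield
#'   identical tables.
#' @export
generate_traits <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  cfg <- default_trait_config()
  traits <- niche_traits(cfg)
  transforms <- stats::setNames(cfg$transform[match(traits, cfg$trait)], traits)
  lower <- stats::setNames(cfg$lower[match(traits, cfg$trait)], traits)
  upper <- stats::setNames(cfg$upper[match(traits, cfg$trait)], traits)
  n_blocks <- spec$n_blocks

  set.seed(spec$seed)
  rows <- list()
  for (si in seq_along(spec$species)) {
    sp <- spec$species[si]
    for (div in diversity_levels()) {
      n <- spec$n_shoots_per_cell
      mu <- vapply(traits, function(tr)
        to_analysis_scale(spec$trait_means[sp, tr], transforms[[tr]]), numeric(1L))
      if (div == "mixture") mu <- mu + spec$plasticity[sp, traits]
      key <- paste(sp, div, sep = ".")
      sigma <- if (key %in% names(spec$covariance)) spec$covariance[[key]] else
        spec$covariance$default
      blocks <- rep_len(seq_len(n_blocks), n)
      plots <- if (div == "monoculture") {
        paste0("mono_", sp, "_B", blocks)
      } else {
        paste0("mix_B", blocks)
      }
      vals <- matrix(NA_real_, n, length(traits), dimnames = list(NULL, traits))
      for (i in seq_len(n)) {
        ok <- FALSE
        for (attempt in seq_len(100L)) {
          y <- MASS::mvrnorm(1L, mu = mu, Sigma = sigma) +
            spec$block_effects[blocks[i], traits]
          x <- vapply(traits, function(tr)
            from_analysis_scale(y[[tr]], transforms[[tr]]), numeric(1L))
          if (all(x >= lower & x <= upper)) { ok <- TRUE; break }
        }
        if (!ok) stop("failed to draw an in-range shoot for ", sp, "/", div,
                      " after 100 attempts; check means and covariance",
                      call. = FALSE)
        vals[i, ] <- x
      }
      bm_mean <- spec$biomass_model$mono_mean[[sp]]
      if (div == "mixture") bm_mean <- bm_mean * (1 + spec$biomass_model$delta[[sp]])
      sdlog <- spec$biomass_model$sdlog
      biomass <- stats::rlnorm(n, meanlog = log(bm_mean) - sdlog^2 / 2, sdlog = sdlog)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, block = paste0("B", blocks), plot = plots, diversity = div,
        as.data.frame(vals), shoot_biomass = biomass,
        stringsAsFactors = FALSE)
    }
  }
  trait_table(do.call(rbind, rows), config = cfg)
}
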