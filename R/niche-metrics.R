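#' Euclidean distances between shoots in standardized trait space
#'
#' Computes all pairwise Euclidean distances over the given trait axes
#' between two sets of rows of a standardized table. Complete-case filtering
#' is applied per trait set: a shoot enters only if it has non-missing values
#' for every trait in `traits`. When `idx_b` is `NULL` the call is
#' within-set: pairs are unordered and self-pairs are excluded (n records
#' yield n(n-1)/2 distances). Otherwise every cross pair contributes one
#' distance. For a singleton trait set the distance is the absolute
#' difference.
#'
#' @param std A `standardized_table`.
#' @param traits Character vector of trait axes.
#' @param idx_a Integer row indices of the first set.
#' @param idx_b Optional integer row indices of the second set.
#' @return Numeric vector of distances; `numeric(0)` with attribute
#'   `insufficient = TRUE` when fewer than 2 usable records remain in a
#'   within-set call, or a set is empty in a cross-set call.
#' @export
pairwise_distances <- function(std, traits, idx_a, idx_b = NULL) {
  m <- as.matrix(as.data.frame(std)[, traits, drop = FALSE])
  usable <- function(idx) idx[stats::complete.cases(m[idx, , drop = FALSE])]
  a <- usable(idx_a)
  insufficient <- function() structure(numeric(0), insufficient = TRUE)
  if (is.null(idx_b)) {
    if (length(a) < 2L) return(insufficient())
    return(as.numeric(stats::dist(m[a, , drop = FALSE])))
  }
  b <- usable(idx_b)
  if (length(a) == 0L || length(b) == 0L) return(insufficient())
  cross <- sqrt(outer(rowSums(m[a, , drop = FALSE]^2),
                      rowSums(m[b, , drop = FALSE]^2), "+") -
                  2 * m[a, , drop = FALSE] %*% t(m[b, , drop = FALSE]))
  as.numeric(pmax(cross, 0))
}

#' @keywords internal
cell_rows <- function(std, species = NULL, diversity = NULL) {
  keep <- rep(TRUE, nrow(std))
  if (!is.null(species)) keep <- keep & std$species %in% species
  if (!is.null(diversity)) keep <- keep & std$diversity == diversity
  which(keep)
}

#' Niche density: mean within-species pairwise distance
#'
#' Mean of all n(n-1)/2 pairwise distances among conspecific shoots at one
#' diversity level. Note the inversion: a *small* mean distance means the
#' species' individuals are densely packed in trait space (high niche
#' density); the statistic reported is the mean distance itself.
#'
#' @param std A `standardized_table`.
#' @param traits Trait axes (singleton for a univariate axis).
#' @param species Focal species label.
#' @param diversity `"monoculture"` or `"mixture"`.
#' @return Mean distance, or `NA` (with a warning) when fewer than 2 usable
#'   shoots are available.
#' @export
niche_density <- function(std, traits, species, diversity) {
  d <- pairwise_distances(std, traits, cell_rows(std, species, diversity))
  if (length(d) == 0L) {
    warning("insufficient records for niche density of ", species, "/", diversity,
            call. = FALSE)
    return(NA_real_)
  }
  mean(d)
}

#' Niche width: maximum within-species pairwise distance
#'
#' The largest pairwise distance among conspecific shoots at one diversity
#' level: the total span the species occupies on the trait axis (or in the
#' multivariate trait space).
#'
#' @inheritParams niche_density
#' @return Maximum distance, or `NA` with a warning when insufficient.
#' @export
niche_width <- function(std, traits, species, diversity) {
  d <- pairwise_distances(std, traits, cell_rows(std, species, diversity))
  if (length(d) == 0L) {
    warning("insufficient records for niche width of ", species, "/", diversity,
            call. = FALSE)
    return(NA_real_)
  }
  max(d)
}

#' Niche separation: mean distance to heterospecific shoots
#'
#' Mean Euclidean distance from every shoot of the focal species to every
#' shoot of every other species at the same diversity level, all cross pairs
#' pooled. Symmetric per species pair; invariant to relabeling among the
#' non-focal species.
#'
#' @inheritParams niche_density
#' @return Pooled mean cross-species distance, or `NA` with a warning when no
#'   other species is usable.
#' @export
niche_separation <- function(std, traits, species, diversity) {
  focal <- cell_rows(std, species, diversity)
  others <- setdiff(cell_rows(std, diversity = diversity), cell_rows(std, species))
  d <- pairwise_distances(std, traits, focal, others)
  if (length(d) == 0L) {
    warning("no heterospecific records for niche separation of ", species, "/",
            diversity, call. = FALSE)
    return(NA_real_)
  }
  mean(d)
}

#' Niche shift from monoculture to mixture
#'
#' The mean distance of every monoculture shoot of a species to every mixture
#' shoot of the same species (`raw`), compared to the mean pairwise distance
#' among its monoculture shoots (`within_mono`), and summarized as the
#' log-response ratio `lrr = log(raw / within_mono)`. Positive values
#' indicate that the species occupies a shifted position in trait space in
#' mixture relative to the spread it shows within monoculture.
#'
#' @param std A `standardized_table`.
#' @param traits Trait axes.
#' @param species Focal species label.
#' @return List with `raw`, `within_mono` and `lrr`. If `within_mono` is 0
#'   with positive `raw`, `lrr` is `Inf`; if both are 0, `lrr` is 0; if
#'   either input set is insufficient, all are `NA`.
#' @export
niche_shift <- function(std, traits, species) {
  mono <- cell_rows(std, species, "monoculture")
  mix <- cell_rows(std, species, "mixture")
  cross <- pairwise_distances(std, traits, mono, mix)
  within <- pairwise_distances(std, traits, mono)
  if (length(cross) == 0L || length(within) == 0L) {
    warning("insufficient records for niche shift of ", species, call. = FALSE)
    return(list(raw = NA_real_, within_mono = NA_real_, lrr = NA_real_))
  }
  raw <- mean(cross)
  wm <- mean(within)
  lrr <- if (wm == 0 && raw == 0) 0 else if (wm == 0) Inf else log(raw / wm)
  list(raw = raw, within_mono = wm, lrr = lrr)
}

#' Community trait-space filling and range
#'
#' Pools all shoots of all species at one diversity level and returns the
#' mean (`filling`) and maximum (`range`) of all pairwise distances: how
#' evenly, and how widely, the whole species group occupies the trait space.
#'
#' @param std A `standardized_table`.
#' @param traits Trait axes.
#' @param diversity `"monoculture"` or `"mixture"`.
#' @return List with `filling` and `range` (both `NA` with a warning when
#'   fewer than 2 usable shoots exist at the level).
#' @export
community_trait_space <- function(std, traits, diversity) {
  d <- pairwise_distances(std, traits, cell_rows(std, diversity = diversity))
  if (length(d) == 0L) {
    warning("insufficient records for community trait space at ", diversity,
            call. = FALSE)
    return(list(filling = NA_real_, range = NA_real_))
  }
  list(filling = mean(d), range = max(d))
}

#' Default trait sets: each single axis plus the full multivariate set
#'
#' @param config A `trait_config`.
#' @return Named list of character vectors; the multivariate set is named
#'   `"multi"`.
#' @export
default_trait_sets <- function(config = default_trait_config()) {
  traits <- niche_traits(config)
  sets <- c(as.list(traits), list(traits))
  names(sets) <- c(traits, "multi")
  sets
}

#' Compute all niche statistics for a standardized table
#'
#' Evaluates niche density, width, separation (pooled, plus per species
#' pair), shift, and the community filling/range for every requested trait
#' set, every species, and both diversity levels. Cells failing a
#' precondition are carried as `NA` markers.
#'
#' @param std A `standardized_table`.
#' @param trait_sets Named list of trait sets; defaults to all 14 single axes
#'   plus the full multivariate set.
#' @return A list of class `niche_summary` with data frames `cells` (density,
#'   width per species x diversity x trait set), `separation`,
#'   `separation_pairs`, `shift` (raw, within-monoculture mean, log-response
#'   ratio) and `community` (filling, range per diversity level).
#' @export
niche_table <- function(std, trait_sets = default_trait_sets(trait_config_of(std))) {
  stopifnot(inherits(std, "standardized_table"))
  if (is.null(names(trait_sets))) {
    names(trait_sets) <- vapply(trait_sets, paste, character(1L), collapse = "+")
  }
  species <- unique(std$species)
  cells <- sep <- pairs <- shift <- comm <- list()
  for (set_name in names(trait_sets)) {
    traits <- trait_sets[[set_name]]
    for (div in diversity_levels()) {
      for (sp in species) {
        idx <- cell_rows(std, sp, div)
        d <- suppressWarnings(pairwise_distances(std, traits, idx))
        cells[[length(cells) + 1L]] <- data.frame(
          trait_set = set_name, species = sp, diversity = div,
          n_shoots = length(idx),
          density = if (length(d)) mean(d) else NA_real_,
          width = if (length(d)) max(d) else NA_real_,
          stringsAsFactors = FALSE)
        sep[[length(sep) + 1L]] <- data.frame(
          trait_set = set_name, species = sp, diversity = div,
          separation = suppressWarnings(niche_separation(std, traits, sp, div)),
          stringsAsFactors = FALSE)
      }
      if (length(species) > 1L) {
        cmb <- utils::combn(sort(species), 2L)
        for (k in seq_len(ncol(cmb))) {
          dd <- pairwise_distances(std, traits,
                                   cell_rows(std, cmb[1L, k], div),
                                   cell_rows(std, cmb[2L, k], div))
          pairs[[length(pairs) + 1L]] <- data.frame(
            trait_set = set_name, species_a = cmb[1L, k], species_b = cmb[2L, k],
            diversity = div,
            separation = if (length(dd)) mean(dd) else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
      cts <- suppressWarnings(community_trait_space(std, traits, div))
      comm[[length(comm) + 1L]] <- data.frame(
        trait_set = set_name, diversity = div,
        filling = cts$filling, range = cts$range, stringsAsFactors = FALSE)
    }
    for (sp in species) {
      sh <- suppressWarnings(niche_shift(std, traits, sp))
      shift[[length(shift) + 1L]] <- data.frame(
        trait_set = set_name, species = sp, shift_raw = sh$raw,
        within_mono = sh$within_mono, shift_lrr = sh$lrr,
        stringsAsFactors = FALSE)
    }
  }
  out <- list(cells = do.call(rbind, cells),
              separation = do.call(rbind, sep),
              separation_pairs = if (length(pairs)) do.call(rbind, pairs) else NULL,
              shift = do.call(rbind, shift),
              community = do.call(rbind, comm),
              trait_sets = trait_sets)
  class(out) <- "niche_summary"
  out
}

#' @export
print.niche_summary <- function(x, ...) {
  cat("Niche summary over", length(x$trait_sets), "trait set(s),",
      length(unique(x$cells$species)), "species\n")
  cat("Mean niche shift lrr per trait set:\n")
  agg <- stats::aggregate(shift_lrr ~ trait_set, data = x$shift, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
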