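#' Phenotypic integration: significant pairwise trait correlations per cell
#'
#' For every species x diversity cell, Pearson correlation coefficients are
#' computed for all unordered pairs of the 14 niche traits using individual
#' shoots as samples, with pairwise complete-case deletion. Two-sided
#' p-values come from the exact t transform of r at n - 2 degrees of freedom.
#' Phenotypic integration is summarized as the count of pairs with
#' `p <= alpha` (default 0.05, no multiple-testing correction, matching the
#' conventional raw count); a Holm-adjusted count is reported alongside.
#' Pairs with fewer than 3 complete cases, or involving a zero-variance
#' trait, are missing and excluded from that cell's `n_possible`.
#'
#' With the default 14 traits and all pairs estimable, `n_possible` is
#' 14 * 13 / 2 = 91 per cell.
#'
#' @param table A `trait_table`, normally after [log_transform()] and
#'   [block_correct()] (the z-step would not change Pearson r).
#' @param alpha Significance threshold for the raw count.
#' @return A list of class `integration_summary` with `cells` (one row per
#'   species x diversity: `n_significant`, `n_significant_holm`,
#'   `n_possible`, `n_unestimable`), and `pairs`, a long data frame with
#'   `species`, `diversity`, `trait_i`, `trait_j`, `r`, `p`, `n`.
#' @export
integration_summary <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "trait_table"))
  cfg <- trait_config_of(table)
  traits <- niche_traits(cfg)
  df <- as.data.frame(table)
  cells <- pairs_out <- list()
  cmb <- utils::combn(traits, 2L)
  for (sp in unique(df$species)) {
    for (div in intersect(diversity_levels(), df$diversity[df$species == sp])) {
      sub <- df[df$species == sp & df$diversity == div, traits, drop = FALSE]
      rr <- pp <- nn <- numeric(ncol(cmb))
      for (k in seq_len(ncol(cmb))) {
        x <- sub[[cmb[1L, k]]]
        y <- sub[[cmb[2L, k]]]
        ok <- !is.na(x) & !is.na(y)
        n <- sum(ok)
        nn[k] <- n
        if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
          rr[k] <- NA_real_
          pp[k] <- NA_real_
          next
        }
        r <- stats::cor(x[ok], y[ok])
        rr[k] <- r
        if (abs(r) >= 1) {
          pp[k] <- 0
        } else {
          tt <- r * sqrt((n - 2) / (1 - r^2))
          pp[k] <- 2 * stats::pt(-abs(tt), df = n - 2)
        }
      }
      estimable <- !is.na(pp)
      p_holm <- rep(NA_real_, length(pp))
      p_holm[estimable] <- stats::p.adjust(pp[estimable], method = "holm")
      cells[[length(cells) + 1L]] <- data.frame(
        species = sp, diversity = div,
        n_significant = sum(pp[estimable] <= alpha),
        n_significant_holm = sum(p_holm[estimable] <= alpha),
        n_possible = sum(estimable),
        n_unestimable = sum(!estimable),
        stringsAsFactors = FALSE)
      pairs_out[[length(pairs_out) + 1L]] <- data.frame(
        species = sp, diversity = div,
        trait_i = cmb[1L, ], trait_j = cmb[2L, ],
        r = rr, p = pp, n = nn, stringsAsFactors = FALSE)
    }
  }
  out <- list(cells = do.call(rbind, cells),
              pairs = do.call(rbind, pairs_out),
              alpha = alpha)
  class(out) <- "integration_summary"
  out
}

#' Correlation matrix of one species x diversity cell
#'
#' Reshapes the long pair table of an [integration_summary()] into a
#' symmetric correlation matrix with unit diagonal for one cell.
#'
#' @param summary An `integration_summary`.
#' @param species,diversity Cell selectors.
#' @return A symmetric numeric matrix of Pearson r with 1 on the diagonal.
#' @export
integration_matrix <- function(summary, species, diversity) {
  pr <- summary$pairs
  pr <- pr[pr$species == species & pr$diversity == diversity, , drop = FALSE]
  if (nrow(pr) == 0L) stop("no such cell: ", species, "/", diversity, call. = FALSE)
  traits <- unique(c(pr$trait_i, pr$trait_j))
  m <- matrix(NA_real_, length(traits), length(traits),
              dimnames = list(traits, traits))
  diag(m) <- 1
  for (k in seq_len(nrow(pr))) {
    m[pr$trait_i[k], pr$trait_j[k]] <- m[pr$trait_j[k], pr$trait_i[k]] <- pr$r[k]
  }
  m
}

#' Mixture-vs-monoculture contrast of integration counts
#'
#' Per species, the difference in the number of significant trait
#' correlations between mixture and monoculture. Species with only one
#' diversity level are skipped with a warning.
#'
#' @param summary An `integration_summary`.
#' @return Data frame with `species`, `n_mono`, `n_mix`, `difference`
#'   (mixture minus monoculture).
#' @export
integration_contrast <- function(summary) {
  cl <- summary$cells
  out <- list()
  for (sp in unique(cl$species)) {
    mono <- cl$n_significant[cl$species == sp & cl$diversity == "monoculture"]
    mix <- cl$n_significant[cl$species == sp & cl$diversity == "mixture"]
    if (length(mono) != 1L || length(mix) != 1L) {
      warning("species '", sp, "' lacks one diversity level; skipped", call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      species = sp, n_mono = mono, n_mix = mix, difference = mix - mono,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
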