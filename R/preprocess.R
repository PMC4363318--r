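#' Log-transform the configured traits
#'
#' Replaces each trait flagged `log` in the configuration by its natural
#' logarithm and each count trait flagged `log1p` by `log(x + 1)` (zero is a
#' legitimate count); all other columns are untouched. Strictly positive log
#' traits must be positive wherever non-missing.
#'
#' @param table A `trait_table`.
#' @return A `trait_table` on the analysis scale, with attribute
#'   `log_transformed = TRUE`.
#' @export
log_transform <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  if (isTRUE(attr(table, "log_transformed"))) return(table)
  cfg <- trait_config_of(table)
  out <- as.data.frame(table)
  for (i in seq_len(nrow(cfg))) {
    tr <- cfg$trait[i]
    x <- out[[tr]]
    if (cfg$transform[i] == "log") {
      bad <- which(!is.na(x) & x <= 0)
      if (length(bad) > 0L) {
        stop("non-positive value in log trait '", tr, "' at row ", bad[1L],
             call. = FALSE)
      }
      out[[tr]] <- log(x)
    } else if (cfg$transform[i] == "log1p") {
      out[[tr]] <- log1p(x)
    }
  }
  attr(out, "trait_config") <- cfg
  attr(out, "log_transformed") <- TRUE
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Correct trait values for block effects
#'
#' Additive mean-centering per block: each non-missing value of each niche
#' trait becomes `value - block mean + grand mean`, so block means are
#' equalized while the grand mean is preserved exactly. Applied after
#' [log_transform()] so the correction is additive on the analysis scale.
#' Shoot biomass (the performance variable) is left uncorrected so that the
#' diversity effect D stays on the raw biomass scale.
#'
#' A block with no non-missing entries for a trait contributes nothing and
#' its entries stay missing (with a warning).
#'
#' @param table A `trait_table` (analysis scale).
#' @return A `trait_table` with attribute `block_corrected = TRUE`.
#' @export
block_correct <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  cfg <- trait_config_of(table)
  out <- as.data.frame(table)
  blocks <- out$block
  for (tr in niche_traits(cfg)) {
    x <- out[[tr]]
    gm <- mean(x, na.rm = TRUE)
    for (b in unique(blocks)) {
      idx <- which(blocks == b & !is.na(x))
      if (length(idx) == 0L) {
        if (any(blocks == b)) {
          warning("block '", b, "' has no data for trait '", tr, "'",
                  call. = FALSE)
        }
        next
      }
      x[idx] <- x[idx] - mean(x[idx]) + gm
    }
    out[[tr]] <- x
  }
  for (a in c("trait_config", "log_transformed")) attr(out, a) <- attr(table, a)
  attr(out, "block_corrected") <- TRUE
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Z-standardize traits to mean 0, variance 1
#'
#' Each niche trait is centred and scaled by its pooled mean and sample
#' standard deviation (denominator n - 1) over all records of all species and
#' both diversity levels, so that monoculture and mixture positions live on a
#' common unitless axis. Shoot biomass is carried through unstandardized.
#'
#' @param table A `trait_table`, normally after [log_transform()] and
#'   [block_correct()].
#' @param scope `"pooled"` (default) or `"per_diversity"`, in which case each
#'   diversity level is standardized separately.
#' @return A data frame of class `standardized_table` holding the identifier
#'   columns, the z-scored traits, and `shoot_biomass`; attributes record the
#'   centring/scaling used and the transform provenance.
#' @export
standardize <- function(table, scope = c("pooled", "per_diversity")) {
  stopifnot(inherits(table, "trait_table"))
  scope <- match.arg(scope)
  cfg <- trait_config_of(table)
  out <- as.data.frame(table)
  centers <- scales <- stats::setNames(numeric(0), character(0))
  groups <- if (scope == "pooled") list(seq_len(nrow(out))) else
    split(seq_len(nrow(out)), out$diversity)
  for (tr in niche_traits(cfg)) {
    x <- out[[tr]]
    for (idx in groups) {
      v <- x[idx]
      nv <- v[!is.na(v)]
      if (length(unique(nv)) < 2L) {
        stop("trait '", tr, "' has fewer than 2 distinct values; cannot standardize",
             call. = FALSE)
      }
      x[idx] <- (v - mean(nv)) / stats::sd(nv)
    }
    if (scope == "pooled") {
      nv <- out[[tr]][!is.na(out[[tr]])]
      centers[tr] <- mean(nv)
      scales[tr] <- stats::sd(nv)
    }
    out[[tr]] <- x
  }
  attr(out, "trait_config") <- cfg
  attr(out, "centers") <- centers
  attr(out, "scales") <- scales
  attr(out, "scope") <- scope
  attr(out, "log_transformed") <- isTRUE(attr(table, "log_transformed"))
  attr(out, "block_corrected") <- isTRUE(attr(table, "block_corrected"))
  class(out) <- c("standardized_table", "data.frame")
  out
}

#' Full preprocessing chain
#'
#' Convenience composition of the fixed pipeline order:
#' [log_transform()], then [block_correct()], then [standardize()].
#'
#' @param table A raw `trait_table` on the measurement scale.
#' @param scope Standardization scope, see [standardize()].
#' @return A `standardized_table`.
#' @export
preprocess <- function(table, scope = "pooled") {
  standardize(block_correct(log_transform(table)), scope = scope)
}
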