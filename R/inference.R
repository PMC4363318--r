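#' @keywords internal
#' Fit a nested fixed-effect sequence by maximum likelihood
#'
#' Random intercepts are requested for block and plot; a grouping factor with
#' fewer than 2 levels, or a failed mixed fit, falls back to dropping that
#' term (flagged in `note`). Returns the fitted models and the note.
fit_nested_sequence <- function(df, fixed_terms, reml = FALSE) {
  note <- character(0)
  ran <- character(0)
  for (g in c("block", "plot")) {
    if (length(unique(df[[g]])) >= 2L) ran <- c(ran, sprintf("(1 | %s)", g))
    else note <- c(note, paste0("random term ", g, " dropped (<2 levels)"))
  }
  fits <- list()
  rhs <- "1"
  for (i in seq_along(fixed_terms)) {
    if (i > 1L) rhs <- paste(rhs, "+", fixed_terms[i])
    else if (fixed_terms[1L] != "1") rhs <- fixed_terms[1L]
    fit <- NULL
    if (length(ran) > 0L) {
      fml <- stats::as.formula(paste("value ~", rhs, "+", paste(ran, collapse = " + ")))
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(fml, data = df, REML = reml,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore")))),
        error = function(e) NULL)
    }
    if (is.null(fit)) {
      if (length(ran) > 0L && !any(grepl("mixed fit failed", note))) {
        note <- c(note, "mixed fit failed; random terms dropped")
      }
      fit <- stats::lm(stats::as.formula(paste("value ~", rhs)), data = df)
    }
    fits[[i]] <- fit
  }
  list(fits = fits, note = paste(note, collapse = "; "))
}

#' @keywords internal
lrt_between <- function(reduced, full) {
  ll0 <- stats::logLik(reduced)
  ll1 <- stats::logLik(full)
  chisq <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
  df <- abs(attr(ll1, "df") - attr(ll0, "df"))
  list(chisq = chisq, df = df,
       p = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_)
}

#' Mixed-model likelihood-ratio sequence for trait responses
#'
#' For each trait, models with random intercepts for block and plot are fitted
#' by maximum likelihood in a nested sequence of fixed effects: constant null,
#' + species identity, + plant diversity (monoculture vs mixture), + their
#' interaction. Likelihood-ratio (Chi-squared) tests assess each added term.
#' Optionally, the full model is refitted by REML and per-species
#' monoculture-vs-mixture contrasts are extracted with a family-wise
#' single-step multivariate-t adjustment (Holm on failure).
#'
#' Traits are put on the analysis scale (log transforms per the
#' configuration) before fitting; pass `table` raw.
#'
#' @param table A `trait_table` on the measurement scale.
#' @param traits Character vector of traits to analyse; default all 14 plus
#'   shoot biomass.
#' @param contrasts Logical: also compute per-species Tukey-style contrasts
#'   (default `TRUE`).
#' @return A list of class `trait_response_models`: `tests` (trait, term,
#'   chisq, df, p, note), `contrasts` (trait, species, estimate = mixture
#'   minus monoculture on the analysis scale, se, p_adj, direction), and
#'   `errors` naming traits whose fits were degenerate.
#' @export
trait_response_models <- function(table, traits = NULL, contrasts = TRUE) {
  stopifnot(inherits(table, "trait_table"))
  cfg <- trait_config_of(table)
  tl <- log_transform(table)
  if (is.null(traits)) traits <- cfg$trait
  df0 <- as.data.frame(tl)
  df0$species <- factor(df0$species)
  df0$diversity <- factor(df0$diversity, levels = diversity_levels())
  tests <- ctr_out <- list()
  errors <- character(0)
  for (tr in traits) {
    df <- df0[!is.na(df0[[tr]]), , drop = FALSE]
    df$value <- df[[tr]]
    if (nrow(df) == 0L || stats::sd(df$value) == 0) {
      errors[tr] <- "degenerate trait: zero variance or no data"
      next
    }
    seq_fit <- tryCatch(
      fit_nested_sequence(df, c("1", "species", "diversity", "species:diversity")),
      error = function(e) NULL)
    if (is.null(seq_fit)) {
      errors[tr] <- "model sequence failed"
      next
    }
    terms <- c("species", "diversity", "species_x_diversity")
    for (i in 1:3) {
      lt <- lrt_between(seq_fit$fits[[i]], seq_fit$fits[[i + 1L]])
      tests[[length(tests) + 1L]] <- data.frame(
        trait = tr, term = terms[i], chisq = lt$chisq, df = lt$df, p = lt$p,
        note = seq_fit$note, stringsAsFactors = FALSE)
    }
    if (contrasts && nlevels(df$diversity) == 2L) {
      full <- tryCatch(
        fit_nested_sequence(df, c("1", "species", "diversity", "species:diversity"),
                            reml = TRUE)$fits[[4L]],
        error = function(e) NULL)
      if (!is.null(full)) {
        cc <- tryCatch({
          emm <- emmeans::emmeans(full, ~ diversity | species)
          ct <- emmeans::contrast(emm, "revpairwise", by = "species")
          sm <- tryCatch(summary(ct, by = NULL, adjust = "mvt"),
                         error = function(e) summary(ct, by = NULL, adjust = "holm"))
          as.data.frame(sm)
        }, error = function(e) NULL)
        if (!is.null(cc)) {
          ctr_out[[length(ctr_out) + 1L]] <- data.frame(
            trait = tr, species = as.character(cc$species),
            estimate = cc$estimate, se = cc$SE, p_adj = cc$p.value,
            direction = ifelse(cc$estimate > 0, "+", "-"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- list(tests = if (length(tests)) do.call(rbind, tests) else NULL,
              contrasts = if (length(ctr_out)) do.call(rbind, ctr_out) else NULL,
              errors = errors)
  class(out) <- "trait_response_models"
  out
}

#' Reaction norms: standardized trait change from monoculture to mixture
#'
#' The slope of each z-standardized trait against the two-level diversity
#' coordinate (monoculture = 0, mixture = 1) per species, which equals the
#' difference of the species' standardized cell means (mixture minus
#' monoculture). Traits pass through the full preprocessing chain first.
#'
#' @param table A raw `trait_table` (or a `standardized_table`, used as-is).
#' @return Data frame with `species`, `trait`, `slope`; `NA` when a species
#'   lacks one diversity level.
#' @export
reaction_norms <- function(table) {
  std <- if (inherits(table, "standardized_table")) table else preprocess(table)
  cfg <- trait_config_of(std)
  out <- list()
  for (sp in unique(std$species)) {
    for (tr in niche_traits(cfg)) {
      mono <- std[[tr]][std$species == sp & std$diversity == "monoculture"]
      mix <- std[[tr]][std$species == sp & std$diversity == "mixture"]
      mono <- mono[!is.na(mono)]
      mix <- mix[!is.na(mix)]
      out[[length(out) + 1L]] <- data.frame(
        species = sp, trait = tr,
        slope = if (length(mono) && length(mix)) mean(mix) - mean(mono) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @keywords internal
#' Distance observations for the metric ANOVAs
#'
#' density: within-cell pairwise distances (factors species, diversity);
#' separation: focal-expanded cross distances (each unordered cross pair
#' contributes one observation per focal species); shift: within-monoculture
#' distances vs monoculture-to-mixture distances (factors species, set).
distance_observations <- function(std, traits, metric) {
  species <- unique(std$species)
  obs <- list()
  if (metric %in% c("density", "separation")) {
    for (sp in species) {
      for (div in diversity_levels()) {
        d <- if (metric == "density") {
          pairwise_distances(std, traits, cell_rows(std, sp, div))
        } else {
          pairwise_distances(std, traits, cell_rows(std, sp, div),
                             setdiff(cell_rows(std, diversity = div),
                                     cell_rows(std, sp)))
        }
        if (length(d)) {
          obs[[length(obs) + 1L]] <- data.frame(d = d, species = sp,
                                                diversity = div,
                                                stringsAsFactors = FALSE)
        }
      }
    }
  } else if (metric == "shift") {
    for (sp in species) {
      mono <- cell_rows(std, sp, "monoculture")
      mix <- cell_rows(std, sp, "mixture")
      dw <- pairwise_distances(std, traits, mono)
      dc <- pairwise_distances(std, traits, mono, mix)
      if (length(dw)) obs[[length(obs) + 1L]] <-
          data.frame(d = dw, species = sp, set = "within_mono",
                     stringsAsFactors = FALSE)
      if (length(dc)) obs[[length(obs) + 1L]] <-
          data.frame(d = dc, species = sp, set = "mono_to_mix",
                     stringsAsFactors = FALSE)
    }
  }
  if (length(obs) == 0L) return(NULL)
  do.call(rbind, obs)
}

#' Tests on the niche metrics
#'
#' Reproduces the testing scheme applied to the distance-based metrics: a
#' paired t-test across species for niche width (monoculture vs mixture, per
#' trait set); two-way ANOVAs with factors species and diversity (for niche
#' density and separation) or species and distance set (within-monoculture vs
#' monoculture-to-mixture, for niche shift) on the individual distance
#' observations, with interaction.
#'
#' Pairwise distances sharing individuals are not independent, so the ANOVA
#' p-values are anticonservative; when `permutations > 0` a permutation
#' p-value for the diversity (or distance-set) main effect is reported
#' alongside, obtained by permuting diversity labels of shoots within species
#' and recomputing the ANOVA F statistic.
#'
#' @param std A `standardized_table`.
#' @param trait_sets Named list of trait sets (default: all single axes plus
#'   the multivariate set).
#' @param permutations Number of label permutations for the permutation
#'   p-value (0 = skip).
#' @param seed Integer seed for the permutations.
#' @return A list of class `niche_metric_tests` with `width_paired_t` (trait
#'   set, t, df, p, mean_diff) and `anova` (trait_set, metric, term, df, F,
#'   p, p_perm).
#' @export
niche_metric_tests <- function(std, trait_sets = default_trait_sets(trait_config_of(std)),
                               permutations = 0L, seed = 1L) {
  stopifnot(inherits(std, "standardized_table"))
  summary_tab <- niche_table(std, trait_sets)
  wt <- av <- list()
  for (set_name in names(trait_sets)) {
    traits <- trait_sets[[set_name]]
    cells <- summary_tab$cells[summary_tab$cells$trait_set == set_name, ]
    wide <- merge(cells[cells$diversity == "monoculture", c("species", "width")],
                  cells[cells$diversity == "mixture", c("species", "width")],
                  by = "species", suffixes = c("_mono", "_mix"))
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    if (nrow(wide) >= 2L) {
      diffs <- wide$width_mix - wide$width_mono
      if (all(diffs == 0)) {
        wt[[length(wt) + 1L]] <- data.frame(trait_set = set_name, t = 0,
                                            df = nrow(wide) - 1L, p = 1,
                                            mean_diff = 0, stringsAsFactors = FALSE)
      } else {
        tt <- stats::t.test(wide$width_mix, wide$width_mono, paired = TRUE)
        wt[[length(wt) + 1L]] <- data.frame(
          trait_set = set_name, t = unname(tt$statistic),
          df = unname(tt$parameter), p = tt$p.value,
          mean_diff = unname(tt$estimate), stringsAsFactors = FALSE)
      }
    } else {
      warning("fewer than 2 species with both levels; paired t skipped for '",
              set_name, "'", call. = FALSE)
    }
    for (metric in c("density", "separation", "shift")) {
      obs <- distance_observations(std, traits, metric)
      factor2 <- if (metric == "shift") "set" else "diversity"
      if (is.null(obs) || length(unique(obs$species)) < 2L ||
          length(unique(obs[[factor2]])) < 2L) next
      obs$species <- factor(obs$species)
      obs[[factor2]] <- factor(obs[[factor2]])
      fit <- stats::aov(stats::as.formula(paste("d ~ species *", factor2)),
                        data = obs)
      at <- as.data.frame(summary(fit)[[1L]])
      terms_clean <- gsub(" ", "", rownames(at))
      keep <- terms_clean != "Residuals"
      res <- data.frame(trait_set = set_name, metric = metric,
                        term = terms_clean[keep], df = at$Df[keep],
                        F = at$`F value`[keep], p = at$`Pr(>F)`[keep],
                        p_perm = NA_real_, stringsAsFactors = FALSE)
      if (permutations > 0L) {
        f_obs <- res$F[res$term == factor2]
        set.seed(seed + match(set_name, names(trait_sets)) * 1000L +
                   match(metric, c("density", "separation", "shift")))
        f_perm <- numeric(permutations)
        for (b in seq_len(permutations)) {
          perm <- std
          for (sp in unique(std$species)) {
            idx <- which(std$species == sp)
            perm$diversity[idx] <- sample(std$diversity[idx])
          }
          pobs <- distance_observations(perm, traits, metric)
          if (is.null(pobs)) { f_perm[b] <- NA_real_; next }
          pobs$species <- factor(pobs$species)
          pobs[[factor2]] <- factor(pobs[[factor2]])
          pat <- tryCatch(
            as.data.frame(summary(stats::aov(
              stats::as.formula(paste("d ~ species *", factor2)),
              data = pobs))[[1L]]),
            error = function(e) NULL)
          f_perm[b] <- if (is.null(pat)) NA_real_ else {
            rn <- gsub(" ", "", rownames(pat))
            pat$`F value`[rn == factor2]
          }
        }
        f_perm <- f_perm[!is.na(f_perm)]
        res$p_perm[res$term == factor2] <-
          (1 + sum(f_perm >= f_obs)) / (1 + length(f_perm))
      }
      av[[length(av) + 1L]] <- res
    }
  }
  out <- list(width_paired_t = if (length(wt)) do.call(rbind, wt) else NULL,
              anova = if (length(av)) do.call(rbind, av) else NULL)
  class(out) <- "niche_metric_tests"
  out
}

#' Diversity effect on shoot biomass (proportional deviation)
#'
#' For every mixture shoot, D = (BM_mix - mean BM_mono) / mean BM_mono, the
#' proportional deviation of its biomass from the species' monoculture mean.
#' D = 0 when mixture biomass equals the monoculture mean; D > 0 indicates
#' overyielding. Per species, a one-sample t-test of the shoot-level D values
#' against 0 is reported.
#'
#' D is invariant to rescaling all biomass by a common positive factor.
#'
#' @param table A `trait_table` with `shoot_biomass`.
#' @return A list of class `diversity_effect` with `shoots` (species, plot,
#'   block, biomass, D) and `species` (species, mean_D, t, df, p, n).
#' @export
diversity_effect <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  df <- as.data.frame(table)
  shoots <- sp_out <- list()
  for (sp in unique(df$species)) {
    mono_bm <- df$shoot_biomass[df$species == sp & df$diversity == "monoculture"]
    mono_bm <- mono_bm[!is.na(mono_bm)]
    mix <- df[df$species == sp & df$diversity == "mixture" &
                !is.na(df$shoot_biomass), , drop = FALSE]
    if (length(mono_bm) == 0L || nrow(mix) == 0L) next
    mono_mean <- mean(mono_bm)
    if (mono_mean <= 0) {
      stop("monoculture mean biomass is not positive for species '", sp,
           "'; D undefined", call. = FALSE)
    }
    D <- (mix$shoot_biomass - mono_mean) / mono_mean
    shoots[[length(shoots) + 1L]] <- data.frame(
      species = sp, plot = mix$plot, block = mix$block,
      biomass = mix$shoot_biomass, D = D, stringsAsFactors = FALSE)
    if (length(D) >= 2L && stats::sd(D) > 0) {
      tt <- stats::t.test(D, mu = 0)
      sp_out[[length(sp_out) + 1L]] <- data.frame(
        species = sp, mean_D = mean(D), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value, n = length(D),
        stringsAsFactors = FALSE)
    } else {
      sp_out[[length(sp_out) + 1L]] <- data.frame(
        species = sp, mean_D = mean(D), t = if (all(D == 0)) 0 else NA_real_,
        df = length(D) - 1L, p = if (all(D == 0)) 1 else NA_real_,
        n = length(D), stringsAsFactors = FALSE)
    }
  }
  out <- list(shoots = do.call(rbind, shoots),
              species = do.call(rbind, sp_out))
  class(out) <- "diversity_effect"
  out
}

#' Per-shoot niche predictors for mixture shoots
#'
#' Shoot-resolution versions of the niche statistics, used as predictors of
#' the diversity effect: `identity` = the shoot's standardized trait value
#' (singleton trait sets only); `density` = the shoot's mean distance to the
#' other conspecific mixture shoots; `separation` = its mean distance to
#' heterospecific mixture shoots; `shift` = its mean distance to its species'
#' monoculture shoots.
#'
#' @param std A `standardized_table`.
#' @param traits Trait axes.
#' @param type One of `"identity"`, `"density"`, `"separation"`, `"shift"`.
#' @return Numeric vector aligned to the mixture rows of `std` (in row
#'   order); `NA` where not computable.
#' @export
shoot_predictors <- function(std, traits,
                             type = c("identity", "density", "separation", "shift")) {
  type <- match.arg(type)
  mix_idx <- which(std$diversity == "mixture")
  if (type == "identity") {
    if (length(traits) != 1L) {
      stop("niche identity is defined for a single trait axis", call. = FALSE)
    }
    return(as.numeric(as.data.frame(std)[mix_idx, traits]))
  }
  out <- rep(NA_real_, length(mix_idx))
  for (k in seq_along(mix_idx)) {
    i <- mix_idx[k]
    sp <- std$species[i]
    ref <- switch(type,
      density = setdiff(cell_rows(std, sp, "mixture"), i),
      separation = setdiff(cell_rows(std, diversity = "mixture"),
                           cell_rows(std, sp)),
      shift = cell_rows(std, sp, "monoculture"))
    d <- pairwise_distances(std, traits, i, ref)
    if (length(d)) out[k] <- mean(d)
  }
  out
}

#' Mixed-model comparison of niche predictors for the diversity effect
#'
#' Starting from a base mixed model of the shoot-level diversity effect D
#' with species identity as fixed effect and independent random intercepts
#' for plot and species, each candidate predictor (niche identity, density,
#' separation, shift, per trait set; plus any user-supplied columns) is added
#' separately. Models are fitted by maximum likelihood; the AIC of both fits,
#' the likelihood-ratio Chi-squared with its p-value, and the sign of the
#' fitted predictor effect are reported.
#'
#' @param table A raw `trait_table`.
#' @param std Optional precomputed `standardized_table` (defaults to
#'   `preprocess(table)`).
#' @param trait_sets Named list of trait sets.
#' @param predictors Subset of `c("identity", "density", "separation",
#'   "shift")`.
#' @param extra Optional named list of numeric vectors (aligned to the
#'   mixture rows of `std`) fitted as additional predictors.
#' @return Data frame of class `model_comparison`: `trait_set`, `predictor`,
#'   `aic_base`, `aic_aug`, `chisq`, `df`, `p`, `sign`, `note`.
#' @export
niche_predictor_models <- function(table, std = preprocess(table),
                                   trait_sets = default_trait_sets(trait_config_of(table)),
                                   predictors = c("identity", "density",
                                                  "separation", "shift"),
                                   extra = NULL) {
  mix_idx <- which(std$diversity == "mixture")
  dat <- data.frame(species = factor(std$species[mix_idx]),
                    plot = factor(std$plot[mix_idx]),
                    stringsAsFactors = FALSE)
  bm <- as.data.frame(std)$shoot_biomass[mix_idx]
  mono_means <- vapply(levels(dat$species), function(sp) {
    x <- as.data.frame(std)$shoot_biomass[std$species == sp &
                                            std$diversity == "monoculture"]
    mean(x[!is.na(x)])
  }, numeric(1L))
  dat$D <- (bm - mono_means[as.character(dat$species)]) /
    mono_means[as.character(dat$species)]

  fit_one <- function(d, with_pred) {
    rhs <- if (with_pred) "species + pred" else "species"
    ran <- character(0)
    if (nlevels(droplevels(d$plot)) >= 2L) ran <- c(ran, "(1 | plot)")
    if (nlevels(droplevels(d$species)) >= 2L) ran <- c(ran, "(1 | species)")
    if (length(ran) > 0L) {
      fml <- stats::as.formula(paste("D ~", rhs, "+", paste(ran, collapse = " + ")))
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(fml, data = d, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore")))),
        error = function(e) NULL)
      if (!is.null(fit)) return(fit)
    }
    stats::lm(stats::as.formula(paste("D ~", rhs)), data = d)
  }

  candidates <- list()
  for (set_name in names(trait_sets)) {
    traits <- trait_sets[[set_name]]
    for (pr in predictors) {
      if (pr == "identity" && length(traits) != 1L) next
      candidates[[paste(set_name, pr, sep = "|")]] <-
        list(trait_set = set_name, predictor = pr,
             values = shoot_predictors(std, traits, pr))
    }
  }
  for (nm in names(extra)) {
    candidates[[paste("extra", nm, sep = "|")]] <-
      list(trait_set = "extra", predictor = nm, values = extra[[nm]])
  }

  out <- list()
  for (cand in candidates) {
    d <- dat
    d$pred <- cand$values
    ok <- stats::complete.cases(d)
    d <- droplevels(d[ok, , drop = FALSE])
    note <- ""
    if (nrow(d) < 3L || stats::sd(d$pred) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        trait_set = cand$trait_set, predictor = cand$predictor,
        aic_base = NA_real_, aic_aug = NA_real_, chisq = NA_real_,
        df = NA_real_, p = NA_real_, sign = NA_character_,
        note = "constant or insufficient predictor; skipped",
        stringsAsFactors = FALSE)
      next
    }
    base <- fit_one(d, FALSE)
    aug <- fit_one(d, TRUE)
    if (inherits(base, "lm") != inherits(aug, "lm") &&
        !(inherits(base, "merMod") && inherits(aug, "merMod"))) {
      base <- stats::lm(D ~ species, data = d)
      aug <- stats::lm(D ~ species + pred, data = d)
      note <- "mixed fits inconsistent; plain ML comparison"
    }
    lt <- lrt_between(base, aug)
    coefs <- if (inherits(aug, "merMod")) lme4::fixef(aug) else stats::coef(aug)
    out[[length(out) + 1L]] <- data.frame(
      trait_set = cand$trait_set, predictor = cand$predictor,
      aic_base = stats::AIC(base), aic_aug = stats::AIC(aug),
      chisq = lt$chisq, df = lt$df, p = lt$p,
      sign = if (coefs[["pred"]] > 0) "+" else "-",
      note = note, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("model_comparison", "data.frame")
  res
}
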