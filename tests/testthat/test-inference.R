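test_that("the LRT chain reports chi-squared equal to twice the log-likelihood gain", {
  tab <- generate_traits(preset_scenario("convergence", seed = 2L))
  res <- trait_response_models(tab, traits = "shoot_height", contrasts = FALSE)
  tests <- res$tests
  expect_equal(tests$term, c("species", "diversity", "species_x_diversity"))
  expect_true(all(tests$chisq >= 0))
  # independent check of the species term: refit the two models directly
  tl <- as.data.frame(log_transform(tab))
  tl$value <- tl$shoot_height
  m0 <- lme4::lmer(value ~ 1 + (1 | block) + (1 | plot), data = tl, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
  m1 <- lme4::lmer(value ~ species + (1 | block) + (1 | plot), data = tl,
                   REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
  chisq <- 2 * (as.numeric(stats::logLik(m1)) - as.numeric(stats::logLik(m0)))
  expect_equal(tests$chisq[tests$term == "species"], chisq, tolerance = 1e-6)
  expect_equal(tests$df[tests$term == "species"], 6)  # 7 species - 1
})

test_that("a constant trait yields a per-trait degenerate-fit report, others unaffected", {
  tab <- as.data.frame(generate_traits(preset_scenario("null", seed = 5L)))
  tab$leaf_number <- 7
  res <- trait_response_models(trait_table(tab),
                               traits = c("leaf_number", "shoot_height"),
                               contrasts = FALSE)
  expect_true("leaf_number" %in% names(res$errors))
  expect_true("shoot_height" %in% res$tests$trait)
  expect_false("leaf_number" %in% res$tests$trait)
})

test_that("per-species contrasts carry direction and adjusted p-values", {
  spec <- preset_scenario("null", seed = 7L)
  spec$plasticity[, "shoot_height"] <- 3 * nichekit:::default_trait_sd()[["shoot_height"]]
  tab <- generate_traits(spec)
  res <- trait_response_models(tab, traits = "shoot_height", contrasts = TRUE)
  cc <- res$contrasts
  expect_equal(sort(unique(cc$species)), sort(unique(tab$species)))
  # a +3 SD shift in every species: all contrasts positive, most significant
  expect_true(all(cc$estimate > 0))
  expect_true(all(cc$direction == "+"))
  expect_gte(sum(cc$p_adj <= 0.05), 5L)
})

test_that("reaction norms equal differences of standardized cell means exactly", {
  tab <- generate_traits(preset_scenario("divergence", seed = 6L))
  std <- preprocess(tab)
  rn <- reaction_norms(std)
  for (k in sample(nrow(rn), 10L)) {
    sp <- rn$species[k]; tr <- rn$trait[k]
    mono <- std[[tr]][std$species == sp & std$diversity == "monoculture"]
    mix <- std[[tr]][std$species == sp & std$diversity == "mixture"]
    expect_equal(rn$slope[k], mean(mix) - mean(mono))
  }
  # equal cell means give slope 0
  df <- make_trait_df(n_per_cell = 3L, seed = 10L)
  df$shoot_height <- rep(c(10, 20, 30), length.out = nrow(df))
  ord <- order(df$species, df$diversity)
  df$shoot_height[ord] <- rep(c(10, 20, 30), times = nrow(df) / 3)
  rn0 <- reaction_norms(trait_table(df))
  expect_equal(rn0$slope[rn0$trait == "shoot_height"], rep(0, 2L),
               tolerance = 1e-12)
})

test_that("programmed plasticity sign is recovered by the reaction norm", {
  shift_sd <- nichekit:::default_trait_sd()[["leaf_area"]]
  hits <- 0L
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    spec <- preset_scenario("null", seed = s)
    spec$plasticity["Lp", "leaf_area"] <- 2 * shift_sd
    rn <- reaction_norms(generate_traits(spec))
    hits <- hits + (rn$slope[rn$species == "Lp" & rn$trait == "leaf_area"] > 0)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("diversity effect D follows its defining ratio and invariances", {
  df <- make_trait_df(n_per_cell = 2L, species = "A", seed = 3L)
  df$shoot_biomass <- c(2, 2, 3, 2)[order(order(df$diversity))]
  # force: monoculture biomasses {2, 2}, mixture {3, 2}
  df$shoot_biomass[df$diversity == "monoculture"] <- c(2, 2)
  df$shoot_biomass[df$diversity == "mixture"] <- c(3, 2)
  de <- diversity_effect(trait_table(df))
  expect_equal(sort(de$shoots$D), c(0, 0.5))
  # rescaling all biomass leaves D unchanged
  df2 <- df; df2$shoot_biomass <- df2$shoot_biomass * 37.5
  de2 <- diversity_effect(trait_table(df2))
  expect_equal(de2$shoots$D, de$shoots$D)
  # D >= -1 whenever biomass >= 0
  tab <- generate_traits(preset_scenario("overyielding", seed = 2L))
  expect_true(all(diversity_effect(tab)$shoots$D >= -1))
})

test_that("paired width t-test degenerates gracefully on identical levels", {
  tab <- generate_traits(preset_scenario("null", seed = 9L))
  mono <- as.data.frame(tab[tab$diversity == "monoculture", ])
  mix <- mono
  mix$diversity <- "mixture"
  mix$plot <- paste0(mix$plot, "_m")
  std <- preprocess(trait_table(rbind(mono, mix)))
  res <- niche_metric_tests(std, list(shoot_height = "shoot_height"))
  expect_equal(res$width_paired_t$t, 0)
  expect_equal(res$width_paired_t$p, 1)
})

test_that("metric ANOVAs report species, diversity and interaction terms", {
  tab <- generate_traits(preset_scenario("divergence", seed = 11L))
  std <- preprocess(tab)
  res <- niche_metric_tests(std, list(leaf_area = "leaf_area"),
                            permutations = 49L, seed = 1L)
  av <- res$anova
  expect_setequal(unique(av$metric), c("density", "separation", "shift"))
  expect_true(all(c("species", "diversity") %in%
                    av$term[av$metric == "density"]))
  expect_true(all(av$F[!is.na(av$F)] >= 0))
  # permutation p-value present for the diversity/set main effect
  expect_true(all(!is.na(av$p_perm[av$term %in% c("diversity", "set")])))
  # a strong programmed divergence on this axis is detected
  expect_lte(av$p_perm[av$metric == "separation" & av$term == "diversity"], 0.05)
})

test_that("noise predictors are not preferred and structure is recovered", {
  tab <- generate_traits(preset_scenario("null", seed = 14L))
  std <- preprocess(tab)
  set.seed(99)
  noise <- stats::rnorm(sum(std$diversity == "mixture"))
  res <- niche_predictor_models(tab, std,
                                trait_sets = list(shoot_height = "shoot_height"),
                                predictors = "identity",
                                extra = list(noise = noise))
  expect_true(all(res$chisq >= 0, na.rm = TRUE))
  # construct D linear in the shoot_height identity: that predictor must win
  tab2 <- as.data.frame(tab)
  mono_mean <- tapply(tab2$shoot_biomass[tab2$diversity == "monoculture"],
                      tab2$species[tab2$diversity == "monoculture"], mean)
  mix_rows <- tab2$diversity == "mixture"
  z <- std$shoot_height[mix_rows]
  tab2$shoot_biomass[mix_rows] <-
    mono_mean[tab2$species[mix_rows]] * (1 + 0.5 + 0.4 * z)
  res2 <- niche_predictor_models(trait_table(tab2), preprocess(trait_table(tab2)),
                                 trait_sets = list(shoot_height = "shoot_height"),
                                 predictors = c("identity", "density"))
  ident <- res2[res2$predictor == "identity", ]
  expect_lt(ident$aic_aug, ident$aic_base)
  expect_equal(ident$sign, "+")
  expect_lt(ident$p, 0.001)
})

test_that("constant predictors are skipped with a note", {
  tab <- generate_traits(preset_scenario("null", seed = 15L))
  std <- preprocess(tab)
  res <- niche_predictor_models(tab, std, trait_sets = list(),
                                predictors = character(0),
                                extra = list(flat = rep(1, sum(std$diversity == "mixture"))))
  expect_true(grepl("skipped", res$note[res$predictor == "flat"]))
  expect_true(is.na(res$chisq[res$predictor == "flat"]))
})
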