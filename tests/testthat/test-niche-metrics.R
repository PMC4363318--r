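# Hand-built univariate standardized table: species A = {-1, 0, 1} in
# monoculture; used for the closed-form examples below.
simple_std <- function(values, species, diversity) {
  df <- data.frame(species = rep_len(species, length(values)), block = "B1",
                   plot = "P1", diversity = rep_len(diversity, length(values)),
                   stringsAsFactors = FALSE)
  df$shoot_height <- values
  df$shoot_biomass <- 1
  attr(df, "trait_config") <- default_trait_config()
  class(df) <- c("standardized_table", "data.frame")
  df
}

test_that("pairwise distances match closed forms", {
  std <- simple_std(c(-1, 0, 1), "A", "monoculture")
  d <- pairwise_distances(std, "shoot_height", 1:3)
  expect_equal(sort(d), c(1, 1, 2))
  # bivariate 3-4-5
  std2 <- simple_std(c(0, 3), "A", "monoculture")
  std2$leaf_area <- c(0, 4)
  expect_equal(pairwise_distances(std2, c("shoot_height", "leaf_area"), 1L, 2L), 5)
  # insufficient records flagged, not an error
  out <- pairwise_distances(std, "shoot_height", 1L)
  expect_length(out, 0L)
  expect_true(attr(out, "insufficient"))
})

test_that("every metric equals the brute-force double-loop oracle", {
  max_err <- 0
  for (seed in 1:50) {
    std <- make_random_std(n = sample(6:30, 1L), n_species = sample(2:4, 1L),
                           seed = seed)
    traits <- niche_traits()
    sp <- unique(std$species)[1L]
    for (div in unique(std$diversity)) {
      within_idx <- which(std$species == sp & std$diversity == div)
      d <- pairwise_distances(std, traits, within_idx)
      b <- brute_distances(std, traits, within_idx)
      expect_equal(length(d), length(b))
      if (length(b) > 0L) {
        max_err <- max(max_err, abs(mean(d) - mean(b)), abs(max(d) - max(b)))
        expect_equal(niche_density(std, traits, sp, div), mean(b), tolerance = 1e-12)
        expect_equal(niche_width(std, traits, sp, div), max(b), tolerance = 1e-12)
      }
      other_idx <- which(std$species != sp & std$diversity == div)
      bx <- brute_distances(std, traits, within_idx, other_idx)
      if (length(bx) > 0L && length(within_idx) > 0L) {
        expect_equal(niche_separation(std, traits, sp, div), mean(bx),
                     tolerance = 1e-12)
      }
    }
    mono <- which(std$species == sp & std$diversity == "monoculture")
    mix <- which(std$species == sp & std$diversity == "mixture")
    bw <- brute_distances(std, traits, mono)
    bc <- brute_distances(std, traits, mono, mix)
    if (length(bw) > 0L && length(bc) > 0L) {
      sh <- niche_shift(std, traits, sp)
      expect_equal(sh$raw, mean(bc), tolerance = 1e-12)
      expect_equal(sh$lrr, log(mean(bc) / mean(bw)), tolerance = 1e-12)
    }
    for (div in unique(std$diversity)) {
      all_idx <- which(std$diversity == div)
      ba <- brute_distances(std, traits, all_idx)
      if (length(ba) > 0L) {
        cts <- community_trait_space(std, traits, div)
        expect_equal(cts$filling, mean(ba), tolerance = 1e-12)
        expect_equal(cts$range, max(ba), tolerance = 1e-12)
      }
    }
  }
  expect_lt(max_err, 1e-12)
})

test_that("univariate closed-form examples hold", {
  std <- simple_std(c(-1, 0, 1), "A", "monoculture")
  expect_equal(niche_density(std, "shoot_height", "A", "monoculture"), 4 / 3)
  expect_equal(niche_width(std, "shoot_height", "A", "monoculture"), 2)
  # coincident points give zero and width >= density always
  std0 <- simple_std(c(0.5, 0.5, 0.5), "A", "mixture")
  expect_equal(niche_density(std0, "shoot_height", "A", "mixture"), 0)
  expect_equal(niche_width(std0, "shoot_height", "A", "mixture"), 0)
})

test_that("doubling coordinates doubles the distance-based metrics", {
  std <- make_random_std(n = 15L, seed = 21L)
  std2 <- std
  for (tr in niche_traits()) std2[[tr]] <- 2 * std2[[tr]]
  sp <- unique(std$species)[1L]
  div <- std$diversity[std$species == sp][1L]
  expect_equal(niche_density(std2, niche_traits(), sp, div),
               2 * niche_density(std, niche_traits(), sp, div))
  expect_equal(niche_width(std2, niche_traits(), sp, div),
               2 * niche_width(std, niche_traits(), sp, div))
})

test_that("separation pools cross pairs and ignores non-focal labels", {
  std <- simple_std(c(0, 0, 1, 3), c("A", "A", "B", "B"), "mixture")
  expect_equal(niche_separation(std, "shoot_height", "A", "mixture"), 2)  # mean{1,3,1,3}
  # relabeling non-focal species leaves the focal separation unchanged
  std2 <- std
  std2$species[4L] <- "C"
  expect_equal(niche_separation(std2, "shoot_height", "A", "mixture"), 2)
  # symmetric in the species pair: swapping the roles changes nothing
  ab <- pairwise_distances(std, "shoot_height", which(std$species == "A"),
                           which(std$species == "B"))
  ba <- pairwise_distances(std, "shoot_height", which(std$species == "B"),
                           which(std$species == "A"))
  expect_equal(mean(ab), mean(ba))
  ns <- niche_table(std, list(shoot_height = "shoot_height"))
  pr <- ns$separation_pairs
  expect_equal(pr$separation[pr$diversity == "mixture"], 2)
})

test_that("niche shift matches direct enumeration and is monotone in displacement", {
  std <- simple_std(c(0, 2, 3, 5), "A",
                    c("monoculture", "monoculture", "mixture", "mixture"))
  sh <- niche_shift(std, "shoot_height", "A")
  expect_equal(sh$within_mono, 2)
  expect_equal(sh$raw, 3)           # mean{3,5,1,3}
  expect_equal(sh$lrr, log(1.5))
  # translate the mixture cloud farther away: raw strictly increases
  std2 <- std
  std2$shoot_height[3:4] <- std2$shoot_height[3:4] + 4
  expect_gt(niche_shift(std2, "shoot_height", "A")$raw, sh$raw)
})

test_that("relabeling halves of one cloud gives lrr centred on zero", {
  # permutation null for the shift statistic: split a single cloud into
  # pseudo-monoculture and pseudo-mixture at random; the average lrr over
  # shuffles must be near zero
  set.seed(31)
  vals <- stats::rnorm(20)
  lrrs <- replicate(200, {
    div <- sample(rep(c("monoculture", "mixture"), each = 10L))
    std <- simple_std(vals, "A", div)
    niche_shift(std, "shoot_height", "A")$lrr
  })
  expect_lt(abs(mean(lrrs)), 3 * stats::sd(lrrs) / sqrt(length(lrrs)))
})

test_that("metrics are invariant under record order permutation", {
  std <- make_random_std(n = 18L, seed = 41L)
  perm <- std[sample(nrow(std)), ]
  class(perm) <- class(std)
  attr(perm, "trait_config") <- attr(std, "trait_config")
  sp <- unique(std$species)[1L]
  for (div in unique(std$diversity)) {
    expect_equal(suppressWarnings(niche_density(perm, niche_traits(), sp, div)),
                 suppressWarnings(niche_density(std, niche_traits(), sp, div)))
    expect_equal(suppressWarnings(niche_separation(perm, niche_traits(), sp, div)),
                 suppressWarnings(niche_separation(std, niche_traits(), sp, div)))
  }
})

test_that("a single trait name and its singleton set agree; summary invariants hold", {
  tab <- generate_traits(preset_scenario("null", seed = 17L))
  std <- preprocess(tab)
  ns <- niche_table(std, list(shoot_height = "shoot_height",
                              also = c("shoot_height")))
  ce <- ns$cells
  expect_equal(ce$density[ce$trait_set == "shoot_height"],
               ce$density[ce$trait_set == "also"])
  # width >= density per cell; community range >= filling and >= any width
  expect_true(all(ce$width >= ce$density))
  cm <- ns$community
  expect_true(all(cm$range >= cm$filling))
  for (div in c("monoculture", "mixture")) {
    expect_gte(cm$range[cm$trait_set == "shoot_height" & cm$diversity == div],
               max(ce$width[ce$trait_set == "shoot_height" & ce$diversity == div]))
  }
  expect_true(all(ns$separation$separation >= 0))
})

test_that("missing traits trigger complete-case filtering per trait set", {
  std <- make_random_std(n = 12L, n_species = 2L, seed = 51L)
  std$shoot_height[1:3] <- NA
  sp <- std$species[1L]
  div <- std$diversity[1L]
  idx <- which(std$species == sp & std$diversity == div)
  d <- pairwise_distances(std, "shoot_height", idx)
  keep <- idx[!is.na(std$shoot_height[idx])]
  expect_length(d, choose(length(keep), 2L))
  # another axis is unaffected by those missing values
  d2 <- pairwise_distances(std, "leaf_area", idx)
  expect_length(d2, choose(length(idx), 2L))
})
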