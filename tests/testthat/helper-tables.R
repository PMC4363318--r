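# Small in-code fixtures shared across tests.

# A minimal valid trait data frame with n rows, all traits filled with
# in-range values; identifiers cycle over species/blocks.
make_trait_df <- function(n_per_cell = 2L, species = c("A", "B"), seed = 1L) {
  set.seed(seed)
  cfg <- default_trait_config()
  grid <- expand.grid(rep = seq_len(n_per_cell), species = species,
                      diversity = c("monoculture", "mixture"),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  df <- data.frame(
    species = grid$species,
    block = rep_len(c("B1", "B2"), n),
    diversity = grid$diversity,
    stringsAsFactors = FALSE
  )
  df$plot <- paste0(df$block, "_", df$diversity, "_", df$species)
  for (i in seq_len(nrow(cfg))) {
    tr <- cfg$trait[i]
    hi <- if (is.finite(cfg$upper[i])) cfg$upper[i] else 50
    df[[tr]] <- stats::runif(n, min = cfg$lower[i] + 0.05 * (hi - cfg$lower[i]),
                             max = cfg$lower[i] + 0.95 * (hi - cfg$lower[i]))
  }
  df
}

make_table <- function(n_per_cell = 2L, species = c("A", "B"), seed = 1L) {
  trait_table(make_trait_df(n_per_cell, species, seed))
}

# Random standardized table for oracle checks: species x diversity cells of
# random sizes, traits i.i.d. normal (standardization not required for the
# distance oracles).
make_random_std <- function(n = 20L, n_species = 3L, n_traits = 14L, seed = 1L) {
  set.seed(seed)
  traits <- niche_traits()[seq_len(n_traits)]
  df <- data.frame(
    species = sample(LETTERS[seq_len(n_species)], n, replace = TRUE),
    block = "B1", plot = "P1",
    diversity = sample(c("monoculture", "mixture"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  for (tr in traits) df[[tr]] <- stats::rnorm(n)
  df$shoot_biomass <- stats::rlnorm(n)
  attr(df, "trait_config") <- default_trait_config()
  class(df) <- c("standardized_table", "data.frame")
  df
}

# Independent brute-force double-loop Euclidean distance oracle.
brute_distances <- function(std, traits, idx_a, idx_b = NULL) {
  m <- as.data.frame(std)[, traits, drop = FALSE]
  keep <- function(idx) idx[apply(!is.na(m[idx, , drop = FALSE]), 1L, all)]
  a <- keep(idx_a)
  euclid <- function(i, j) {
    s <- 0
    for (tr in traits) s <- s + (m[i, tr] - m[j, tr])^2
    sqrt(s)
  }
  out <- numeric(0)
  if (is.null(idx_b)) {
    if (length(a) < 2L) return(out)
    for (i in seq_along(a)) {
      for (j in seq_along(a)) {
        if (j > i) out <- c(out, euclid(a[i], a[j]))
      }
    }
  } else {
    b <- keep(idx_b)
    for (i in a) for (j in b) out <- c(out, euclid(i, j))
  }
  out
}
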