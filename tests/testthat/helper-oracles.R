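# Independent oracles, deliberately written as plain loops over textbook
# formulas so they share no code path with the package implementation.

# Weighted kappa from the disagreement-weight definition:
# kappa = 1 - sum(w * O) / sum(w * E), E_ij = row_i * col_j / n.
oracle_weighted_kappa <- function(tab, scheme = "linear") {
  k <- nrow(tab)
  n <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  num <- 0
  den <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- if (scheme == "linear") abs(i - j) / (k - 1) else ((i - j) / (k - 1))^2
      num <- num + w * tab[i, j]
      den <- den + w * rs[i] * cs[j] / n
    }
  }
  unname(1 - num / den)
}

# Balanced one-way random-effects ANOVA estimator of the ICC.
oracle_anova_icc <- function(y, group) {
  groups <- unique(group)
  k <- length(groups)
  n <- length(y) / k
  means <- sapply(groups, function(g) mean(y[group == g]))
  msb <- n * sum((means - mean(y))^2) / (k - 1)
  ssw <- 0
  for (g in groups) ssw <- ssw + sum((y[group == g] - mean(y[group == g]))^2)
  msw <- ssw / (length(y) - k)
  s2b <- max(0, (msb - msw) / n)
  s2b / (s2b + msw)
}

# Loop-based population-weighted mean apportionment of one value column.
oracle_apportion <- function(values, crosswalk, col) {
  counties <- sort(unique(crosswalk$county_id))
  out <- data.frame(county_id = counties, value = NA_real_)
  for (ci in seq_along(counties)) {
    num <- 0
    den <- 0
    for (r in seq_len(nrow(crosswalk))) {
      if (crosswalk$county_id[r] != counties[ci]) next
      v <- values[[col]][match(crosswalk$zip_id[r], values$zip_id)]
      if (is.na(v)) next
      w <- crosswalk$allocation_population[r]
      num <- num + w * v
      den <- den + w
    }
    if (den > 0) out$value[ci] <- num / den
  }
  out[!is.na(out$value), ]
}

# Small, fast fixture configuration for structural tests.
small_config <- function(seed = 42, n_counties = 12,
                         insufficient_data_counties = 1L, ...) {
  synthetic_config(n_counties = n_counties, zips_per_county = c(4L, 7L),
                   insufficient_data_counties = insufficient_data_counties,
                   seed = seed, ...)
}

# Identity geography: one ZIP per county, no straddling, no exclusions.
identity_config <- function(seed = 7, n = 114) {
  synthetic_config(n_counties = n, zips_per_county = 1L,
                   multi_county_zip_fraction = 0,
                   insufficient_data_counties = 0L, seed = seed)
}

balanced_config <- function(seed, icc_hf = 0.44, icc_ho = 0.5,
                            n_counties = 114, zips = 9L) {
  synthetic_config(n_counties = n_counties, zips_per_county = zips,
                   multi_county_zip_fraction = 0,
                   insufficient_data_counties = 0L,
                   icc_hf = icc_hf, icc_ho = icc_ho, seed = seed)
}

# Latent ZIP domain scores as a (zip_id, county_id, score) tibble.
latent_scores_df <- function(cfg, domain = "ho") {
  geo <- generate_geography(cfg)
  tr <- generate_latent_scores(cfg, geo)
  df <- tr$zip_domain[c("zip_id", "county_id", domain)]
  names(df)[3] <- "score"
  df
}
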