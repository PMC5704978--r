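test_that("geography generation respects structure and determinism", {
  cfg <- small_config()
  geo1 <- generate_geography(cfg)
  geo2 <- generate_geography(cfg)
  expect_identical(geo1, geo2)

  expect_true(all(geo1$zips$population >= 1))
  expect_true(all(geo1$crosswalk_raw$allocation_population >= 0))
  # crosswalk allocation conserves each ZIP's total population
  totals <- tapply(geo1$crosswalk_raw$allocation_population,
                   geo1$crosswalk_raw$zip_id, sum)
  expect_equal(as.numeric(totals[geo1$zips$zip_id]), as.numeric(geo1$zips$population))
  # straddling ZIPs have two rows, others one
  n_rows <- table(geo1$crosswalk_raw$zip_id)
  expect_equal(unname(n_rows[geo1$zips$zip_id]),
               ifelse(geo1$zips$multi_county, 2L, 1L),
               ignore_attr = TRUE)
  expect_true(all(grepl("^[0-9]{5}$", geo1$zips$zip_id)))

  # degenerate split: fraction 0 puts every ZIP in exactly one county
  geo0 <- generate_geography(small_config(multi_county_zip_fraction = 0))
  expect_true(all(table(geo0$crosswalk_raw$zip_id) == 1L))

  expect_error(synthetic_config(n_counties = 1), class = "zipranks_error_config")
})

test_that("straddling fraction matches its binomial target over replicates", {
  fracs <- vapply(1:300, function(i) {
    geo <- generate_geography(synthetic_config(seed = 100 + i))
    mean(geo$zips$multi_county)
  }, numeric(1))
  # mean of per-replicate fractions within a 4-sigma binomial band around 0.1
  # (~900 ZIPs per replicate, 300 replicates)
  expect_lt(abs(mean(fracs) - 0.1), 4 * sqrt(0.1 * 0.9 / (300 * 900)))
})

test_that("latent scores carry the configured ICC structure", {
  expect_error(synthetic_config(icc_ho = 1.2), class = "zipranks_error_config")

  # icc = 1: all ZIPs in a county share the county latent
  cfg1 <- balanced_config(seed = 3, icc_ho = 1, n_counties = 20, zips = 5L)
  tr1 <- generate_latent_scores(cfg1, generate_geography(cfg1))
  spread <- tapply(tr1$zip_domain$ho, tr1$zip_domain$county_id,
                   function(x) diff(range(x)))
  expect_equal(max(spread), 0, tolerance = 1e-12)

  # icc = 0: between mean square about equal to within mean square
  cfg0 <- balanced_config(seed = 4, icc_ho = 0, n_counties = 60, zips = 9L)
  tr0 <- generate_latent_scores(cfg0, generate_geography(cfg0))
  fit <- stats::aov(ho ~ county_id, data = tr0$zip_domain)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  expect_lt(ms[1] / ms[2], 1.6)

  # icc = 0.5 recovered by the ANOVA estimator over replicates
  iccs <- vapply(1:60, function(i) {
    cfg <- balanced_config(seed = 200 + i, n_counties = 60, zips = 9L)
    tr <- generate_latent_scores(cfg, generate_geography(cfg))
    oracle_anova_icc(tr$zip_domain$ho, tr$zip_domain$county_id)
  }, numeric(1))
  expect_lt(abs(mean(iccs) - 0.5), 0.05)
})

test_that("generated measures match their marginal calibration targets", {
  cfg <- synthetic_config()
  fx <- simulate_zip_fixture(cfg)
  specs <- cfg$measure_specs
  n <- nrow(fx$measures_county)
  for (i in seq_len(nrow(specs))) {
    m <- specs$name[i]
    se <- specs$target_sd[i] / sqrt(n)
    expect_lt(abs(mean(fx$measures_county[[m]], na.rm = TRUE) - specs$target_mean[i]),
              3 * se, label = sprintf("county mean of %s", m))
  }
  # suppression: ZIPs below the floor have missing measures
  suppressed <- fx$measures_zip$population < cfg$min_zip_population
  expect_true(all(is.na(fx$measures_zip$premature_death[suppressed])))
  expect_true(!any(is.na(fx$measures_zip$premature_death[!suppressed])))

  # noiseless loading-1 measure is an affine map of its latent
  specs2 <- specs[specs$name == "premature_death", ]
  specs2$loading <- 1
  specs2$noise_sd <- 0
  cfg2 <- synthetic_config(measure_specs = specs2[rep(1, 6), ] |>
    dplyr::mutate(name = paste0("m", 1:6),
                  subdomain = names(zr_subdomains()),
                  domain = unname(zr_subdomains())), seed = 9)
  geo2 <- generate_geography(cfg2)
  tr2 <- generate_latent_scores(cfg2, geo2)
  mz2 <- generate_measures(tr2, geo2, cfg2)
  keep <- !is.na(mz2$m1)
  expect_equal(abs(cor(mz2$m1[keep], tr2$zip_subdomain$mortality[keep])), 1,
               tolerance = 1e-9)

  # unknown subdomain tag rejected
  bad <- specs
  bad$subdomain[1] <- "wellbeing"
  expect_error(synthetic_config(measure_specs = bad), class = "zipranks_error_config")
})

test_that("reference scores are fixed-weight combinations of subdomain references", {
  cfg <- small_config(chr_noise_sd = 0)
  fx <- simulate_zip_fixture(cfg)
  w <- cfg$domain_weights$health_factors
  combo <- as.matrix(fx$reference_county[names(w)]) %*% w
  expect_equal(fx$reference_county$health_factors, as.numeric(combo), tolerance = 1e-12)

  # the flagged county's ZIPs all fall below the suppression floor
  bad_county <- fx$counties$county_id[fx$counties$insufficient]
  bad_zips <- fx$zips[fx$zips$county_id %in% bad_county, ]
  expect_true(all(bad_zips$population < cfg$min_zip_population))

  # OLS on generated domain vs subdomain references recovers the weights
  cfgn <- synthetic_config(chr_noise_sd = 0.1, seed = 11)
  fxn <- simulate_zip_fixture(cfgn)
  wts <- cfgn$domain_weights$health_factors
  fit <- lm(stats::reformulate(names(wts), "health_factors"),
            data = fxn$reference_county)
  expect_lt(max(abs(coef(fit)[names(wts)] - wts)), 0.05)
})

test_that("encounters are Poisson with the designed rates", {
  cfg <- small_config(seed = 17)
  geo <- generate_geography(cfg)
  tr <- generate_latent_scores(cfg, geo)
  enc <- generate_encounters(cfg, geo, tr)
  lam <- attr(enc, "lambda")
  # totals per category within 4 SD of the configured Poisson intensity
  obs <- table(enc$category)
  for (cat in unique(lam$category)) {
    l <- sum(lam$lambda[lam$category == cat])
    expect_lt(abs(obs[[cat]] - l), 4 * sqrt(l), label = cat)
  }
  # multiplier 0 silences a category
  spec0 <- cfg$encounter_specs
  spec0$multiplier[spec0$category == "assault_diagnosis"] <- 0
  cfg0 <- small_config(seed = 17, encounter_specs = spec0)
  enc0 <- generate_encounters(cfg0, geo, tr)
  expect_false("assault_diagnosis" %in% enc0$category)
  # determinism
  expect_identical(enc, generate_encounters(cfg, geo, tr))
})

test_that("the full fixture is byte-deterministic under a fixed seed", {
  fx1 <- simulate_zip_fixture(small_config(seed = 99))
  fx2 <- simulate_zip_fixture(small_config(seed = 99))
  expect_identical(serialize(fx1, NULL), serialize(fx2, NULL))
  fx3 <- simulate_zip_fixture(small_config(seed = 100))
  expect_false(identical(fx1$measures_zip, fx3$measures_zip))
})
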