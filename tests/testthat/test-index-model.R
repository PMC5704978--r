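std_block <- function(n, k, seed = 1, rho = NULL) {
  withr::with_seed(seed, {
    if (is.null(rho)) {
      m <- matrix(rnorm(n * k), n, k)
    } else {
      f <- rnorm(n)
      m <- sqrt(rho) * f + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
    }
  })
  df <- tibble::as_tibble(as.data.frame(m))
  names(df) <- paste0("m", seq_len(k))
  dplyr::bind_cols(tibble::tibble(county_id = sprintf("29%03d", seq_len(n))), df)
}

test_that("subdomain PCA extracts the shared component with aligned sign", {
  # two identical standardized columns: eigenvalue 2, scores equal either column
  df <- std_block(50, 1, seed = 2)
  df$m2 <- df$m1
  fit <- fit_subdomain_pca(df, c("m1", "m2"), "behavior")
  expect_equal(fit$eigenvalue, 2, tolerance = 1e-9)
  z1 <- (df$m1 - mean(df$m1)) / sd(df$m1)
  expect_equal(fit$scores$score, z1, tolerance = 1e-9)
  expect_equal(mean(fit$scores$score), 0, tolerance = 1e-12)
  expect_equal(sd(fit$scores$score), 1, tolerance = 1e-12)

  # eigenvalues sum to the number of block measures (trace of correlation matrix)
  df4 <- std_block(80, 4, seed = 3, rho = 0.5)
  p <- prcomp(scale(as.matrix(df4[paste0("m", 1:4)])))
  expect_equal(sum(p$sdev^2), 4, tolerance = 1e-9)
  fit4 <- fit_subdomain_pca(df4, paste0("m", 1:4), "socioeconomic")
  expect_gt(fit4$eigenvalue, 1)
  # adverse alignment: positive correlation with the block mean
  expect_gt(cor(fit4$scores$score, rowMeans(scale(as.matrix(df4[paste0("m", 1:4)])))), 0)

  # single-measure subdomain passes through standardized, eigenvalue undefined
  fit1 <- fit_subdomain_pca(df, "m1", "environment")
  expect_true(is.na(fit1$eigenvalue))
  expect_equal(fit1$scores$score, z1, tolerance = 1e-12)
})

test_that("independent columns drive the first eigenvalue to 1; an exactly orthogonal block fails", {
  # independent data: eigenvalue just above 1, inside the Marchenko-Pastur edge
  df <- std_block(5000, 4, seed = 4)
  fit <- fit_subdomain_pca(df, paste0("m", 1:4), "quality_of_life")
  expect_gt(fit$eigenvalue, 1)
  expect_lt(fit$eigenvalue, (1 + sqrt(4 / 5000))^2 + 0.02)

  # exactly orthogonal columns: first eigenvalue 1 -> premise failure
  ortho <- tibble::tibble(county_id = sprintf("29%03d", 1:12),
                          m1 = rep(c(1, 1, -1, -1), 3),
                          m2 = rep(c(1, -1, 1, -1), 3))
  expect_equal(cor(ortho$m1, ortho$m2), 0)
  expect_error(fit_subdomain_pca(ortho, c("m1", "m2"), "behavior"),
               class = "zipranks_error_acceptance")
})

test_that("the domain regressions recover exact and noisy linear calibrations", {
  withr::with_seed(5, {
    n <- 114
    scores <- tibble::tibble(
      county_id = sprintf("29%03d", 1:n),
      behavior = rnorm(n), clinical_access = rnorm(n),
      environment = rnorm(n), socioeconomic = rnorm(n),
      mortality = rnorm(n), quality_of_life = rnorm(n))
    truth <- c(behavior = 0.3, clinical_access = 0.2,
               socioeconomic = 0.4, environment = 0.1)
    exact <- as.matrix(scores[names(truth)]) %*% truth
    noisy <- exact + rnorm(n, sd = 0.1)
  })
  ref0 <- tibble::tibble(county_id = scores$county_id, health_factors = as.numeric(exact))
  fit0 <- fit_domain_regression(scores, ref0, "health_factors")
  expect_equal(fit0$coefficients[names(truth)], truth, tolerance = 1e-9)
  expect_equal(fit0$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit0$intercept, 0, tolerance = 1e-9)

  refn <- tibble::tibble(county_id = scores$county_id, health_factors = as.numeric(noisy))
  fitn <- fit_domain_regression(scores, refn, "health_factors")
  expect_lt(max(abs(fitn$coefficients[names(truth)] - truth)), 0.05)
  expect_gt(fitn$r_squared, 0.95)

  # HO refuses to fit before HF exists
  refho <- dplyr::rename(refn, health_outcomes = "health_factors")
  expect_error(fit_domain_regression(scores, refho, "health_outcomes"),
               class = "zipranks_error_config")
  ho <- fit_domain_regression(scores, refho, "health_outcomes", hf_model = fit0)
  expect_setequal(names(ho$coefficients),
                  c("mortality", "quality_of_life", "predicted_hf"))

  # rank-deficient predictors are a fitting error
  degenerate <- dplyr::mutate(scores, clinical_access = behavior)
  expect_error(fit_domain_regression(degenerate, refn, "health_factors"),
               class = "zipranks_error_fit")
})

test_that("domain scoring is linear and reproduces stored fitted values", {
  cfg <- synthetic_config(seed = 23)
  fx <- simulate_zip_fixture(cfg)
  std <- standardize_measures(fx$measures_county, cfg$measure_specs)
  scr <- screen_measures(std, fx$reference_county, cfg$measure_specs,
                         overrides = "injury_mortality")
  sets <- fit_subdomain_scores(std, cfg$measure_specs, retained_measures(scr),
                               reference = fx$reference_county)
  tabs <- subdomain_scores_table(sets)
  hf <- fit_domain_regression(tabs, fx$reference_county, "health_factors")
  ho <- fit_domain_regression(tabs, fx$reference_county, "health_outcomes",
                              hf_model = hf)
  # scoring the calibration data reproduces lm fitted values
  hf_scores <- score_domains(tabs, hf)
  expect_equal(dplyr::inner_join(hf_scores, hf$fitted, by = "county_id",
                                 suffix = c("", "_fit"))$score,
               hf$fitted$score, tolerance = 1e-12)
  ho_scores <- score_domains(tabs, ho, hf_model = hf)
  expect_equal(dplyr::inner_join(ho_scores, ho$fitted, by = "county_id",
                                 suffix = c("", "_fit"))$score,
               ho$fitted$score, tolerance = 1e-12)

  # all-zero subdomains score the intercept; doubling one input moves the
  # output by coefficient x original value
  zero <- tabs[1, ]
  zero[setdiff(names(zero), "county_id")] <- 0
  expect_equal(score_domains(zero, hf)$score, hf$intercept)
  bumped <- tabs[1, ]
  bumped$behavior <- 2 * bumped$behavior
  delta <- score_domains(bumped, hf)$score - score_domains(tabs[1, ], hf)$score
  expect_equal(delta, hf$coefficients[["behavior"]] * tabs$behavior[1],
               tolerance = 1e-12)
})

test_that("ZIP scoring refits PCA and agrees with projection on the default fixture", {
  cfg <- synthetic_config(seed = 29)
  fx <- simulate_zip_fixture(cfg)
  cstd <- standardize_measures(fx$measures_county, cfg$measure_specs)
  scr <- screen_measures(cstd, fx$reference_county, cfg$measure_specs,
                         overrides = "injury_mortality")
  ret <- retained_measures(scr)
  csets <- fit_subdomain_scores(cstd, cfg$measure_specs, ret)
  zstd <- standardize_measures(fx$measures_zip[c("zip_id", ret)],
                               cfg$measure_specs, cols = ret)
  refit <- score_zip_subdomains(zstd, cfg$measure_specs, ret, method = "refit")
  proj <- score_zip_subdomains(zstd, cfg$measure_specs, ret, method = "project",
                               county_sets = csets)
  for (s in names(refit)) {
    expect_gt(fit <- cor(refit[[s]]$scores$score, proj[[s]]$scores$score), 0.95)
    if (length(refit[[s]]$measures) > 1L) expect_gt(refit[[s]]$eigenvalue, 1)
  }
})

test_that("fixed-weight combination matches a loop oracle and validates weights", {
  df <- std_block(40, 3, seed = 6, rho = 0.4)
  names(df)[2:4] <- c("behavior", "clinical_access", "socioeconomic")
  w <- c(behavior = 0.5, clinical_access = 0.3, socioeconomic = 0.2)
  got <- combine_fixed_weights(df, w)
  want <- vapply(seq_len(nrow(df)), function(i) {
    sum(vapply(names(w), function(s) w[[s]] * df[[s]][i], numeric(1)))
  }, numeric(1))
  expect_equal(got$score, want, tolerance = 1e-12)
  # concentrated weight reproduces that subdomain
  w1 <- c(behavior = 1, clinical_access = 0, socioeconomic = 0)
  expect_equal(combine_fixed_weights(df, w1)$score, df$behavior)
  expect_error(combine_fixed_weights(df, w * 2), class = "zipranks_error_config")
})

test_that("with identity geography the ZIP pipeline reproduces the county pipeline", {
  cfg <- identity_config(seed = 41)
  fx <- simulate_zip_fixture(cfg)
  defs <- cfg$measure_specs

  cstd <- standardize_measures(fx$measures_county, defs)
  scr <- screen_measures(cstd, fx$reference_county, defs,
                         overrides = "injury_mortality")
  ret <- retained_measures(scr)
  csets <- fit_subdomain_scores(cstd, defs, ret)
  ctab <- subdomain_scores_table(csets)
  hf <- fit_domain_regression(ctab, fx$reference_county, "health_factors")
  ho <- fit_domain_regression(ctab, fx$reference_county, "health_outcomes",
                              hf_model = hf)

  zstd <- standardize_measures(fx$measures_zip[c("zip_id", ret)], defs, cols = ret)
  zsets <- score_zip_subdomains(zstd, defs, ret)
  ztab <- subdomain_scores_table(zsets)
  zip_hf <- score_domains(ztab, hf)
  zip_ho <- score_domains(ztab, ho, hf_model = hf)

  # map zip ids back to their (single) county
  map <- fx$crosswalk[c("zip_id", "county_id")]
  zc_hf <- dplyr::inner_join(zip_hf, map, by = "zip_id")
  cmp_hf <- dplyr::inner_join(zc_hf, hf$fitted, by = "county_id",
                              suffix = c("_zip", "_county"))
  expect_equal(cmp_hf$score_zip, cmp_hf$score_county, tolerance = 1e-9)
  zc_ho <- dplyr::inner_join(zip_ho, map, by = "zip_id")
  cmp_ho <- dplyr::inner_join(zc_ho, ho$fitted, by = "county_id",
                              suffix = c("_zip", "_county"))
  expect_equal(cmp_ho$score_zip, cmp_ho$score_county, tolerance = 1e-9)
})

test_that("county analog domain scores track the generated references strongly", {
  cfg <- synthetic_config(seed = 47)
  fx <- simulate_zip_fixture(cfg)
  std <- standardize_measures(fx$measures_county, cfg$measure_specs)
  scr <- screen_measures(std, fx$reference_county, cfg$measure_specs,
                         overrides = "injury_mortality")
  sets <- fit_subdomain_scores(std, cfg$measure_specs, retained_measures(scr))
  tabs <- subdomain_scores_table(sets)
  hf <- fit_domain_regression(tabs, fx$reference_county, "health_factors")
  ho <- fit_domain_regression(tabs, fx$reference_county, "health_outcomes",
                              hf_model = hf)
  cr <- correlation_report(
    dplyr::full_join(dplyr::rename(hf$fitted, health_factors = "score"),
                     dplyr::rename(ho$fitted, health_outcomes = "score"),
                     by = "county_id"),
    fx$reference_county,
    vars_x = c("health_factors", "health_outcomes"),
    vars_y = c("health_factors", "health_outcomes"))
  same <- cr[cr$analog == cr$reference, ]
  expect_true(all(same$r > 0.8))
})
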