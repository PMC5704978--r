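#' CHR subdomain/domain vocabulary
#'
#' The County Health Rankings conceptual framework has a Health Factors
#' domain (health behaviors, clinical care, social & economic factors,
#' physical environment) and a Health Outcomes domain (length of life,
#' quality of life). These helpers expose the tags the package uses for
#' them throughout.
#'
#' @return `zr_subdomains()` returns a named character vector mapping each
#'   subdomain tag to its domain tag. `chr_domain_weights()` returns a list
#'   with one nonnegative, unit-sum weight vector per domain (the published
#'   CHR weighting: behaviors 30%, clinical care 20%, social & economic 40%,
#'   physical environment 10%; length of life 50%, quality of life 50%).
#' @export
zr_subdomains <- function() {
  c(mortality       = "health_outcomes",
    quality_of_life = "health_outcomes",
    behavior        = "health_factors",
    clinical_access = "health_factors",
    environment     = "health_factors",
    socioeconomic   = "health_factors")
}

#' @rdname zr_subdomains
#' @export
chr_domain_weights <- function() {
  list(
    health_factors  = c(behavior = 0.3, clinical_access = 0.2,
                        socioeconomic = 0.4, environment = 0.1),
    health_outcomes = c(mortality = 0.5, quality_of_life = 0.5)
  )
}

#' Default candidate-measure definitions
#'
#' One row per candidate measure, carrying both its metadata (domain,
#' subdomain, adverse/protective direction, source, transform) and the
#' generator's calibration targets: `target_mean`/`target_sd` are the
#' county-level marginals the synthetic fixture emulates, and `loading` is
#' the designed ZIP-level correlation with the measure's subdomain latent
#' (`noise_sd = sqrt(1 - loading^2 - cluster_loading^2)` keeps unit
#' variance). `cluster_loading` mixes in a per-subdomain shared component —
#' method variance that same-source measures share beyond the construct —
#' which keeps weak blocks (the two environment measures) positively
#' correlated so their principal component has a stable orientation. The set mirrors a
#' hospital + census measure panel: mortality and utilization rates,
#' birth/pregnancy outcomes, access and socioeconomic indicators, plus
#' `injury_mortality` designed to correlate weakly (~0.12 at county level)
#' with its subdomain — the conceptual-coverage override case — and
#' `random_noise_decoy`, a pure-noise measure the screening stage should
#' drop.
#'
#' @return A tibble of [MeasureDefinition][screen_measures] rows.
#' @export
default_measure_specs <- function() {
  tibble::tribble(
    ~name,                        ~domain,           ~subdomain,        ~direction,   ~source,    ~transform, ~target_mean, ~target_sd, ~loading, ~cluster_loading,
    "premature_death",            "health_outcomes", "mortality",       "adverse",    "hospital", "none",     5.7,          1.5,        0.66, 0,
    "years_productive_life_lost", "health_outcomes", "mortality",       "adverse",    "hospital", "none",     101.2,        30.2,       0.69, 0,
    "ed_visits",                  "health_outcomes", "quality_of_life", "adverse",    "hospital", "none",     1371,         356.7,      0.34, 0,
    "ip_visits",                  "health_outcomes", "quality_of_life", "adverse",    "hospital", "none",     416.4,        74.7,       0.42, 0,
    "low_birth_weight",           "health_outcomes", "quality_of_life", "adverse",    "hospital", "none",     55.1,         16.3,       0.30, 0,
    "psychiatric_diagnoses",      "health_outcomes", "quality_of_life", "adverse",    "hospital", "none",     30.6,         11.2,       0.45, 0,
    "teen_pregnancy",             "health_factors",  "behavior",        "adverse",    "hospital", "none",     35,           13.1,       0.63, 0,
    "sexually_transmitted_inf",   "health_factors",  "behavior",        "adverse",    "hospital", "none",     57.7,         24.5,       0.30, 0,
    "offhours_ed_visits",         "health_factors",  "clinical_access", "adverse",    "hospital", "none",     0.4,          0.1,        0.33, 0,
    "healthcare_worker_density",  "health_factors",  "clinical_access", "protective", "census",   "none",     23.7,         7.1,        0.51, 0,
    "ahrq_pqi_total",             "health_factors",  "clinical_access", "adverse",    "hospital", "none",     49.8,         15.6,       0.56, 0,
    "assault_diagnoses",          "health_factors",  "environment",     "adverse",    "hospital", "none",     12.0,         5.8,        0.39, 0.45,
    "injury_mortality",           "health_factors",  "environment",     "adverse",    "hospital", "none",     2.6,          0.7,        0.075, 0.45,
    "educ_less_than_hs",          "health_factors",  "socioeconomic",   "adverse",    "census",   "none",     0.16,         0.1,        0.68, 0,
    "unemployment",               "health_factors",  "socioeconomic",   "adverse",    "census",   "none",     0.09,         0.03,       0.62, 0,
    "childhood_poverty",          "health_factors",  "socioeconomic",   "adverse",    "census",   "none",     0.21,         0.07,       0.71, 0,
    "median_hh_income",           "health_factors",  "socioeconomic",   "protective", "census",   "none",     42667,        7995,       0.69, 0,
    "ses_deprivation",            "health_factors",  "socioeconomic",   "adverse",    "derived",  "none",     0,            1.1,        0.72, 0,
    "random_noise_decoy",         "health_factors",  "behavior",        "adverse",    "derived",  "none",     0,            1,          0,        0
  ) |>
    dplyr::mutate(noise_sd = sqrt(pmax(0, 1 - .data$loading^2 - .data$cluster_loading^2)))
}

#' Default encounter-category specifications
#'
#' Discharge-record categories emulating hospital inpatient, outpatient and
#' emergency-department databases. `base_per_1000` is the expected annual
#' encounter rate per 1,000 residents at an average ZIP; `loading` scales a
#' log-linear dependence of the Poisson rate on the ZIP's latent domain
#' score; `multiplier` is a convenience dial (0 silences a category).
#'
#' @return A tibble with columns `category`, `domain`, `base_per_1000`,
#'   `loading`, `multiplier`.
#' @export
default_encounter_specs <- function() {
  tibble::tribble(
    ~category,               ~domain,           ~base_per_1000, ~loading, ~multiplier,
    "ed_visit",              "health_outcomes", 60,             0.3,      1,
    "ip_visit",              "health_outcomes", 25,             0.3,      1,
    "offhours_ed_visit",     "health_factors",  18,             0.3,      1,
    "assault_diagnosis",     "health_factors",  1.5,            0.3,      1,
    "psychiatric_diagnosis", "health_outcomes", 6,              0.3,      1
  )
}

#' Configure the synthetic two-level fixture
#'
#' Parameters of the Missouri-like synthetic study population: a two-level
#' (county, ZIP) geography with a population crosswalk, latent Health
#' Factors / Health Outcomes scores with a configurable between-county
#' variance share (the intraclass correlation), measures calibrated to
#' county-level marginal targets, county reference scores in the CHR style,
#' and encounter-level discharge records.
#'
#' @param n_counties Number of counties (>= 2). Default 115, of which one is
#'   rendered data-insufficient so that 114 survive exclusion.
#' @param zips_per_county Single integer or length-2 integer range; each
#'   county draws its ZIP count from this range. Default 5–12.
#' @param multi_county_zip_fraction Proportion in \[0,1\] of ZIPs straddling
#'   two counties with a random population split.
#' @param icc_hf,icc_ho Between-county share of the latent Health Factors /
#'   Health Outcomes variance, in \[0,1\]. Defaults 0.44 and 0.5.
#' @param domain_cor Correlation between the HF and HO latents (county and
#'   ZIP components alike).
#' @param subdomain_noise_sd SD of the subdomain-specific component mixed
#'   into each subdomain latent (the domain latent carries the rest, so ZIP
#'   subdomain latents have unit variance).
#' @param subdomain_county_share Share of the subdomain-specific variance
#'   that is itself county-level, keeping county subdomain scores from being
#'   collinear artifacts of aggregation.
#' @param measure_specs Measure definition tibble; see
#'   [default_measure_specs()].
#' @param encounter_specs Encounter category tibble; see
#'   [default_encounter_specs()].
#' @param chr_noise_sd Nonnegative SD of the noise separating county
#'   reference subdomain scores from the aggregated subdomain latents.
#' @param domain_weights Fixed per-domain weight vectors combining subdomain
#'   reference scores into domain reference scores; see
#'   [chr_domain_weights()].
#' @param insufficient_data_counties Number of counties rendered
#'   data-insufficient (their ZIP populations fall below the suppression
#'   floor). Default 1.
#' @param min_zip_population Suppression floor: ZIPs below it report no
#'   measures.
#' @param seed Integer seed; a fixed seed makes every generated artifact
#'   byte-identical across runs.
#'
#' @return A `zr_config` list.
#' @export
synthetic_config <- function(n_counties = 115L,
                             zips_per_county = c(5L, 12L),
                             multi_county_zip_fraction = 0.1,
                             icc_hf = 0.44,
                             icc_ho = 0.5,
                             domain_cor = 0.8,
                             subdomain_noise_sd = 0.6,
                             subdomain_county_share = 0.4,
                             measure_specs = default_measure_specs(),
                             encounter_specs = default_encounter_specs(),
                             chr_noise_sd = 0.25,
                             domain_weights = chr_domain_weights(),
                             insufficient_data_counties = 1L,
                             min_zip_population = 200L,
                             seed = 20180301L) {
  if (!is.numeric(n_counties) || length(n_counties) != 1L || n_counties < 2) {
    zr_config_error("`n_counties` must be a single integer >= 2.")
  }
  if (!is.numeric(zips_per_county) || !length(zips_per_county) %in% 1:2 ||
      any(zips_per_county < 1)) {
    zr_config_error("`zips_per_county` must be a positive integer or length-2 range.")
  }
  stopifnot_scalar_number(multi_county_zip_fraction, "multi_county_zip_fraction", 0, 1)
  stopifnot_scalar_number(icc_hf, "icc_hf", 0, 1)
  stopifnot_scalar_number(icc_ho, "icc_ho", 0, 1)
  stopifnot_scalar_number(domain_cor, "domain_cor", -1, 1)
  stopifnot_scalar_number(subdomain_noise_sd, "subdomain_noise_sd", 0, 1)
  stopifnot_scalar_number(subdomain_county_share, "subdomain_county_share", 0, 1)
  stopifnot_scalar_number(chr_noise_sd, "chr_noise_sd", 0, Inf)
  stopifnot_scalar_number(min_zip_population, "min_zip_population", 1, Inf)
  stopifnot_scalar_number(insufficient_data_counties, "insufficient_data_counties",
                          0, n_counties - 1)
  if (insufficient_data_counties > 0 && min_zip_population < 11) {
    zr_config_error("`min_zip_population` must be >= 11 when counties are flagged data-insufficient.")
  }
  required_spec_cols <- c("name", "domain", "subdomain", "direction",
                          "target_mean", "target_sd", "loading", "noise_sd")
  if (!all(required_spec_cols %in% names(measure_specs))) {
    zr_config_error("`measure_specs` is missing required columns.")
  }
  unknown <- setdiff(unique(measure_specs$subdomain), names(zr_subdomains()))
  if (length(unknown) > 0L) {
    zr_config_error(sprintf("unknown subdomain tag(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  mismatch <- measure_specs$domain != zr_subdomains()[measure_specs$subdomain]
  if (any(mismatch)) {
    zr_config_error(sprintf(
      "measure(s) assigned to a subdomain outside their domain: %s",
      paste(measure_specs$name[mismatch], collapse = ", ")))
  }
  for (d in names(domain_weights)) {
    w <- domain_weights[[d]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      zr_config_error(sprintf("`domain_weights$%s` must be nonnegative and sum to 1.", d))
    }
  }
  structure(
    list(
      n_counties = as.integer(n_counties),
      zips_per_county = as.integer(zips_per_county),
      multi_county_zip_fraction = multi_county_zip_fraction,
      icc_hf = icc_hf,
      icc_ho = icc_ho,
      domain_cor = domain_cor,
      subdomain_noise_sd = subdomain_noise_sd,
      subdomain_county_share = subdomain_county_share,
      measure_specs = tibble::as_tibble(measure_specs),
      encounter_specs = tibble::as_tibble(encounter_specs),
      chr_noise_sd = chr_noise_sd,
      domain_weights = domain_weights,
      insufficient_data_counties = as.integer(insufficient_data_counties),
      min_zip_population = as.integer(min_zip_population),
      seed = as.integer(seed)
    ),
    class = "zr_config"
  )
}

#' @export
print.zr_config <- function(x, ...) {
  cat("<zr_config>\n")
  cat(sprintf("  counties: %d (%d data-insufficient), ZIPs/county: %s\n",
              x$n_counties, x$insufficient_data_counties,
              paste(x$zips_per_county, collapse = "-")))
  cat(sprintf("  icc_hf: %.2f  icc_ho: %.2f  domain_cor: %.2f\n",
              x$icc_hf, x$icc_ho, x$domain_cor))
  cat(sprintf("  measures: %d  seed: %d\n", nrow(x$measure_specs), x$seed))
  invisible(x)
}
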