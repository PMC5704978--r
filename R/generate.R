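#' Generate the synthetic two-level geography
#'
#' Draws a county roster, a ZIP roster with integer populations, and the raw
#' ZIP–county allocation rows that [normalize_allocation()] turns into a
#' crosswalk. A configured fraction of ZIPs straddles two counties with a
#' random population split (the primary county always keeps the larger
#' share); all other ZIPs sit wholly in one county. Counties flagged
#' data-insufficient have all their ZIP populations drawn below the
#' suppression floor, so their measures are suppressed downstream.
#'
#' @param config A [synthetic_config()].
#' @return A list with tibbles `counties` (`county_id`, `insufficient`),
#'   `zips` (`zip_id`, `county_id` of the primary county, `population`,
#'   `multi_county`) and `crosswalk_raw` (`zip_id`, `county_id`,
#'   `allocation_population`).
#' @export
generate_geography <- function(config) {
  stopifnot(inherits(config, "zr_config"))
  withr::with_seed(zr_seed(config$seed, "geography"), {
    n_c <- config$n_counties
    county_id <- sprintf("29%03d", seq(1L, by = 2L, length.out = n_c))
    insufficient_ids <- sample(county_id, config$insufficient_data_counties)
    counties <- tibble(county_id = county_id,
                       insufficient = county_id %in% insufficient_ids)

    rng <- config$zips_per_county
    m_c <- if (length(rng) == 1L) rep(rng, n_c) else sample(rng[1]:rng[2], n_c, replace = TRUE)
    n_z <- sum(m_c)
    zips <- tibble(
      zip_id = sprintf("%05d", 10000L + seq_len(n_z)),
      county_id = rep(county_id, m_c)
    )
    pop <- pmax(250, round(rlnorm(n_z, meanlog = log(2500), sdlog = 0.9)))
    suppressed <- zips$county_id %in% insufficient_ids
    if (any(suppressed)) {
      pop[suppressed] <- sample(seq(10L, config$min_zip_population - 1L),
                                sum(suppressed), replace = TRUE)
    }
    zips$population <- as.integer(pop)

    zips$multi_county <- runif(n_z) < config$multi_county_zip_fraction
    # Straddling ZIPs never allocate into data-insufficient counties, so the
    # insufficiency construction is not diluted by neighbours' data.
    eligible_second <- setdiff(county_id, insufficient_ids)
    second <- vapply(zips$county_id[zips$multi_county], function(cid) {
      sample(setdiff(eligible_second, cid), 1L)
    }, character(1), USE.NAMES = FALSE)
    share <- runif(sum(zips$multi_county), 0.55, 0.95)

    primary_rows <- zips |>
      dplyr::mutate(allocation_population = .data$population) |>
      dplyr::select("zip_id", "county_id", "allocation_population")
    if (any(zips$multi_county)) {
      alloc1 <- pmin(zips$population[zips$multi_county] - 1L,
                     as.integer(round(zips$population[zips$multi_county] * share)))
      primary_rows$allocation_population[zips$multi_county] <- alloc1
      secondary_rows <- tibble(
        zip_id = zips$zip_id[zips$multi_county],
        county_id = second,
        allocation_population = zips$population[zips$multi_county] - alloc1
      )
      crosswalk_raw <- dplyr::bind_rows(primary_rows, secondary_rows)
    } else {
      crosswalk_raw <- primary_rows
    }
    crosswalk_raw <- dplyr::arrange(crosswalk_raw, .data$zip_id, .data$county_id)
    list(counties = counties, zips = zips, crosswalk_raw = crosswalk_raw)
  })
}

#' Generate latent Health Factors / Health Outcomes scores
#'
#' County effects are drawn with variance equal to the configured intraclass
#' correlation and ZIP deviations with the complementary variance, so each
#' ZIP's latent domain score (county effect + ZIP deviation) has unit
#' variance and the configured between-county share. The HF and HO latents
#' are correlated (`domain_cor`) at both levels. Each of the six CHR
#' subdomains then receives its own latent: a blend of the domain latent
#' with subdomain-specific noise, part of which is county-level.
#'
#' @param config A [synthetic_config()].
#' @param geography Output of [generate_geography()].
#' @return A `zr_truth` list: `county_effects` (`county_id`, `hf`, `ho`),
#'   `zip_domain` (`zip_id`, `county_id`, `population`, `hf`, `ho`) and
#'   `zip_subdomain` (wide, one column per subdomain). Retained alongside
#'   generated outputs for parameter-recovery tests.
#' @export
generate_latent_scores <- function(config, geography) {
  stopifnot(inherits(config, "zr_config"))
  withr::with_seed(zr_seed(config$seed, "latents"), {
    counties <- geography$counties
    zips <- geography$zips
    rho <- config$domain_cor

    bivn <- function(n, v1, v2) {
      z1 <- rnorm(n); z2 <- rnorm(n)
      tibble(hf = sqrt(v1) * z1,
             ho = sqrt(v2) * (rho * z1 + sqrt(1 - rho^2) * z2))
    }
    county_effects <- dplyr::bind_cols(
      counties["county_id"],
      bivn(nrow(counties), config$icc_hf, config$icc_ho)
    )
    zip_dev <- bivn(nrow(zips), 1 - config$icc_hf, 1 - config$icc_ho)

    zip_domain <- zips |>
      dplyr::select("zip_id", "county_id", "population") |>
      dplyr::left_join(county_effects, by = "county_id") |>
      dplyr::mutate(hf = .data$hf + zip_dev$hf, ho = .data$ho + zip_dev$ho)

    tau <- config$subdomain_noise_sd
    phi <- config$subdomain_county_share
    a <- sqrt(1 - tau^2)
    subs <- names(zr_subdomains())
    zip_subdomain <- zip_domain[c("zip_id", "county_id")]
    for (s in subs) {
      d <- zr_subdomains()[[s]]
      nu_c <- setNames(rnorm(nrow(counties)), counties$county_id)
      eta_z <- rnorm(nrow(zips))
      L <- if (d == "health_factors") zip_domain$hf else zip_domain$ho
      zip_subdomain[[s]] <- a * L +
        tau * (sqrt(phi) * nu_c[zip_domain$county_id] + sqrt(1 - phi) * eta_z)
    }
    structure(list(county_effects = county_effects,
                   zip_domain = zip_domain,
                   zip_subdomain = tibble::as_tibble(zip_subdomain)),
              class = "zr_truth")
  })
}

#' Generate calibrated ZIP-level measures
#'
#' Each measure is `target_mean + target_sd * s * z`, where `z` is the
#' standardized combination `loading * subdomain latent + noise_sd * eps`
#' (standardized over non-suppressed ZIPs, so the generated marginals match
#' the targets up to sampling error at county level) and `s` is -1 for
#' protective measures (e.g. median household income loads negatively on
#' worse health) and +1 otherwise. Measures with a positive target mean are
#' truncated at 0, as rates are. ZIPs below the suppression floor are
#' emitted as missing.
#'
#' @param truth A `zr_truth` from [generate_latent_scores()].
#' @param geography Output of [generate_geography()].
#' @param config A [synthetic_config()].
#' @return A wide tibble: `zip_id`, `county_id`, `population`, then one
#'   column per measure.
#' @export
generate_measures <- function(truth, geography, config) {
  stopifnot(inherits(config, "zr_config"), inherits(truth, "zr_truth"))
  specs <- config$measure_specs
  missing_subs <- setdiff(names(zr_subdomains()), unique(specs$subdomain))
  if (length(missing_subs) > 0L) {
    zr_config_error(sprintf("measure_specs must cover all six subdomains; missing: %s",
                            paste(missing_subs, collapse = ", ")))
  }
  withr::with_seed(zr_seed(config$seed, "measures"), {
    zips <- geography$zips
    out <- truth$zip_subdomain |>
      dplyr::select("zip_id", "county_id") |>
      dplyr::left_join(zips[c("zip_id", "population")], by = "zip_id")
    keep <- out$population >= config$min_zip_population
    # per-subdomain shared measure component (source/method variance common
    # to same-subdomain measures, independent of the construct)
    has_cluster <- "cluster_loading" %in% names(specs)
    cluster <- purrr::map(setNames(nm = unique(specs$subdomain)),
                          ~ rnorm(nrow(out)))
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      S <- truth$zip_subdomain[[sp$subdomain]]
      cl <- if (has_cluster) sp$cluster_loading else 0
      z_raw <- sp$loading * S + cl * cluster[[sp$subdomain]] +
        sp$noise_sd * rnorm(length(S))
      z <- rep(NA_real_, length(S))
      z[keep] <- (z_raw[keep] - mean(z_raw[keep])) / sd(z_raw[keep])
      s_dir <- if (sp$direction == "protective") -1 else 1
      val <- sp$target_mean + sp$target_sd * s_dir * z
      if (sp$target_mean > 0) val <- pmax(0, val)
      out[[sp$name]] <- val
    }
    out
  })
}

#' Generate county CHR-style reference scores
#'
#' County subdomain reference scores are the population-weighted aggregate
#' of the member ZIPs' subdomain latents (via the allocation crosswalk),
#' standardized across counties and jittered with Gaussian noise
#' (`chr_noise_sd`). Domain reference scores are the configured fixed-weight
#' combinations of the subdomain references.
#'
#' @inheritParams generate_measures
#' @return A wide tibble: `county_id`, six subdomain columns, then
#'   `health_factors` and `health_outcomes`.
#' @export
generate_reference_scores <- function(truth, geography, config) {
  stopifnot(inherits(config, "zr_config"), inherits(truth, "zr_truth"))
  withr::with_seed(zr_seed(config$seed, "reference"), {
    cw <- geography$crosswalk_raw
    subs <- names(zr_subdomains())
    agg <- cw |>
      dplyr::left_join(truth$zip_subdomain, by = "zip_id",
                       suffix = c("", ".zip")) |>
      dplyr::group_by(county_id = .data$county_id) |>
      dplyr::summarise(dplyr::across(
        dplyr::all_of(subs),
        ~ sum(.x * .data$allocation_population) / sum(.data$allocation_population)
      ), .groups = "drop")
    ref <- agg["county_id"]
    for (s in subs) {
      x <- agg[[s]]
      ref[[s]] <- (x - mean(x)) / sd(x) + rnorm(length(x), sd = config$chr_noise_sd)
    }
    for (d in names(config$domain_weights)) {
      w <- config$domain_weights[[d]]
      ref[[d]] <- as.numeric(as.matrix(ref[names(w)]) %*% w)
    }
    dplyr::arrange(ref, .data$county_id)
  })
}

#' Generate synthetic encounter-level discharge records
#'
#' Per ZIP and encounter category, counts are Poisson with rate
#' `population * base_per_1000/1000 * multiplier * exp(loading * L - loading^2/2)`
#' where `L` is the ZIP's latent score for the category's domain (the
#' log-normal correction keeps the marginal expectation at the base rate).
#' Counts are expanded to one row per encounter, emulating the shape of an
#' inpatient/outpatient/ED discharge extract.
#'
#' @inheritParams generate_measures
#' @return A tibble (`encounter_id`, `zip_id`, `category`) with the exact
#'   per-ZIP Poisson rates attached as attribute `"lambda"` for
#'   calibration tests.
#' @export
generate_encounters <- function(config, geography, truth) {
  stopifnot(inherits(config, "zr_config"), inherits(truth, "zr_truth"))
  withr::with_seed(zr_seed(config$seed, "encounters"), {
    specs <- config$encounter_specs
    zd <- truth$zip_domain
    lam <- tidyr::crossing(zip_id = zd$zip_id, category = specs$category) |>
      dplyr::left_join(zd[c("zip_id", "population", "hf", "ho")], by = "zip_id") |>
      dplyr::left_join(specs, by = "category") |>
      dplyr::mutate(
        latent = ifelse(.data$domain == "health_factors", .data$hf, .data$ho),
        lambda = .data$population * .data$base_per_1000 / 1000 * .data$multiplier *
          exp(.data$loading * .data$latent - .data$loading^2 / 2)
      ) |>
      dplyr::select("zip_id", "category", "lambda")
    lam$count <- rpois(nrow(lam), lam$lambda)
    enc <- lam |>
      dplyr::filter(.data$count > 0) |>
      tidyr::uncount(weights = .data$count) |>
      dplyr::mutate(encounter_id = dplyr::row_number(), .before = 1) |>
      dplyr::select("encounter_id", "zip_id", "category")
    attr(enc, "lambda") <- dplyr::select(lam, "zip_id", "category", "lambda")
    enc
  })
}

#' Simulate the full synthetic fixture
#'
#' Runs every generator stage and bundles the results, including the ground
#' truth, the normalized crosswalk and the county-level measure table
#' obtained by population-weighted apportionment of the ZIP measures.
#'
#' @param config A [synthetic_config()].
#' @return A `zr_fixture` list: `config`, `counties`, `zips`, `crosswalk`
#'   (normalized), `crosswalk_raw`, `truth`, `measures_zip`,
#'   `measures_county`, `reference_county`, `encounters`.
#' @export
simulate_zip_fixture <- function(config = synthetic_config()) {
  geography <- generate_geography(config)
  truth <- generate_latent_scores(config, geography)
  measures_zip <- generate_measures(truth, geography, config)
  reference_county <- generate_reference_scores(truth, geography, config)
  encounters <- generate_encounters(config, geography, truth)
  crosswalk <- normalize_allocation(geography$crosswalk_raw)
  measure_cols <- config$measure_specs$name
  measures_county <- apportion_zip_to_county(
    measures_zip[c("zip_id", measure_cols)], crosswalk)
  structure(list(config = config,
                 counties = geography$counties,
                 zips = geography$zips,
                 crosswalk = crosswalk,
                 crosswalk_raw = geography$crosswalk_raw,
                 truth = truth,
                 measures_zip = measures_zip,
                 measures_county = measures_county,
                 reference_county = reference_county,
                 encounters = encounters),
            class = "zr_fixture")
}

#' @export
print.zr_fixture <- function(x, ...) {
  cat("<zr_fixture>\n")
  cat(sprintf("  %d counties, %d ZIPs (%d multi-county), %d measures, %d encounters\n",
              nrow(x$counties), nrow(x$zips), sum(x$zips$multi_county),
              nrow(x$config$measure_specs), nrow(x$encounters)))
  invisible(x)
}
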