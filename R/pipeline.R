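#' Configure an end-to-end pipeline run
#'
#' Exactly one input source is active: an embedded [synthetic_config()]
#' (the default) or a named list of CSV `input_paths` (`zips`, `counties`,
#' `crosswalk`, `measures_zip`, `reference_county`, `measure_definitions`,
#' optionally `encounters`).
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading files.
#' @param input_paths Named list of CSV paths, or `NULL` when simulating.
#' @param measure_definitions Measure definition tibble (defaults to the
#'   synthetic config's specs when simulating).
#' @param r_min,alpha Screening retention thresholds.
#' @param skew_threshold Absolute-skewness threshold for `log1p`.
#' @param overrides Measures force-retained by screening.
#' @param combiner `"regression"` (county-calibrated weights, default) or
#'   `"fixed_weights"`.
#' @param fixed_weights Per-domain weight vectors for the fixed combiner
#'   (default [chr_domain_weights()]).
#' @param k Tile count for agreement (default 5).
#' @param kappa_scheme `"linear"` or `"quadratic"`.
#' @param band Within-band agreement band.
#' @param variance_mode `"dominant"` or `"weighted"` county membership.
#' @param min_zip_population Suppression floor applied at ingest.
#' @param seed Run seed (defaults to the synthetic config's seed).
#' @param output_dir Directory for the report bundle (`NULL` = don't write).
#' @return A `zr_pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input_paths = NULL,
                            measure_definitions = NULL,
                            r_min = 0.20, alpha = 0.05,
                            skew_threshold = 2,
                            overrides = "injury_mortality",
                            combiner = c("regression", "fixed_weights"),
                            fixed_weights = chr_domain_weights(),
                            k = 5, kappa_scheme = "linear", band = 1,
                            variance_mode = "dominant",
                            min_zip_population = NULL,
                            seed = NULL,
                            output_dir = NULL) {
  combiner <- match.arg(combiner)
  if (is.null(synthetic) == is.null(input_paths)) {
    zr_config_error("exactly one of `synthetic` and `input_paths` must be supplied.")
  }
  stopifnot_scalar_number(r_min, "r_min", 0, 1)
  stopifnot_scalar_number(alpha, "alpha", 0, 1)
  stopifnot_scalar_number(k, "k", 2, Inf)
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "zr_config"))
    measure_definitions <- measure_definitions %||% synthetic$measure_specs
    min_zip_population <- min_zip_population %||% synthetic$min_zip_population
    seed <- seed %||% synthetic$seed
  } else {
    if (is.null(measure_definitions) && is.null(input_paths$measure_definitions)) {
      zr_config_error("file input requires `measure_definitions` (inline or as a path).")
    }
    min_zip_population <- min_zip_population %||% 0L
    seed <- seed %||% 1L
  }
  structure(list(synthetic = synthetic, input_paths = input_paths,
                 measure_definitions = measure_definitions,
                 r_min = r_min, alpha = alpha,
                 skew_threshold = skew_threshold, overrides = overrides,
                 combiner = combiner, fixed_weights = fixed_weights,
                 k = k, kappa_scheme = kappa_scheme, band = band,
                 variance_mode = variance_mode,
                 min_zip_population = min_zip_population,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "zr_pipeline_config")
}

read_input_bundle <- function(paths, measure_definitions = NULL) {
  rd <- function(nm, col_types = NULL) {
    if (is.null(paths[[nm]])) return(NULL)
    readr::read_csv(paths[[nm]], show_col_types = FALSE,
                    col_types = col_types, progress = FALSE)
  }
  defs <- measure_definitions %||% rd("measure_definitions")
  list(
    counties = rd("counties", readr::cols(county_id = "c", .default = "?")),
    zips = rd("zips", readr::cols(zip_id = "c", county_id = "c", .default = "?")),
    crosswalk_raw = rd("crosswalk", readr::cols(zip_id = "c", county_id = "c", .default = "?")),
    measures_zip = rd("measures_zip", readr::cols(zip_id = "c", county_id = "c", .default = "?")),
    reference_county = rd("reference_county", readr::cols(county_id = "c", .default = "?")),
    encounters = rd("encounters", readr::cols(zip_id = "c", .default = "?")),
    measure_definitions = defs
  )
}

#' Run the full pipeline
#'
#' Executes simulate/ingest, skew handling, screening, county model
#' calibration, ZIP scoring, ZIP-to-county apportionment, variance
#' decomposition, and agreement evaluation, returning (and optionally
#' writing) a reproducible report bundle with a run manifest. Any stage
#' failure aborts with the stage name; partial results produced so far are
#' still written when an `output_dir` is configured.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Overrides `config$output_dir`.
#' @return A `zr_pipeline_result` list; see the components it prints.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "zr_pipeline_config"))
  output_dir <- output_dir %||% config$output_dir
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(output_dir)) try(write_bundle(res, output_dir), silent = TRUE)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "zipranks_error_pipeline", parent = e, stage = name)
    })
  }
  defs <- config$measure_definitions

  # -- data -------------------------------------------------------------
  stage("data", {
    if (!is.null(config$synthetic)) {
      fx <- simulate_zip_fixture(config$synthetic)
      res$fixture <- fx
      res$zips <- fx$zips
      res$counties <- fx$counties
      res$crosswalk <- fx$crosswalk
      res$measures_zip_raw <- fx$measures_zip
      res$reference_county <- fx$reference_county
      res$encounters <- fx$encounters
    } else {
      inp <- read_input_bundle(config$input_paths, defs)
      defs <- inp$measure_definitions
      res$zips <- inp$zips
      res$counties <- inp$counties
      res$crosswalk <- normalize_allocation(inp$crosswalk_raw)
      res$measures_zip_raw <- inp$measures_zip
      res$reference_county <- inp$reference_county
      res$encounters <- inp$encounters
    }
    })
  measure_cols <- intersect(defs$name, names(res$measures_zip_raw))

  # -- ingest: encounter aggregation (rates artifact) -------------------
  stage("ingest", {
    if (!is.null(res$encounters) && nrow(res$encounters) > 0) {
      res$encounter_rates <- aggregate_encounters(
        res$encounters, res$zips, scale = 1000,
        min_zip_population = config$min_zip_population)
    }
  })

  # -- skew handling at ZIP level, applied before apportionment ---------
  stage("transform", {
    tr <- transform_if_skewed(res$measures_zip_raw,
                              skew_threshold = config$skew_threshold,
                              cols = measure_cols)
    res$measures_zip <- tr$data
    res$transform_report <- tr$report
  })

  # -- screening on apportioned county measures -------------------------
  stage("screen", {
    res$measures_county <- apportion_zip_to_county(
      res$measures_zip[c("zip_id", measure_cols)], res$crosswalk)
    county_std <- standardize_measures(res$measures_county, defs, cols = measure_cols)
    res$screening <- screen_measures(
      county_std, res$reference_county, defs,
      r_min = config$r_min, alpha = config$alpha,
      overrides = config$overrides,
      transform_report = res$transform_report)
    res$retained <- retained_measures(res$screening)
    res$measures_county_std <- county_std
  })

  # -- county-level calibration -----------------------------------------
  stage("county_fit", {
    sets <- fit_subdomain_scores(res$measures_county_std, defs, res$retained,
                                 reference = res$reference_county)
    res$county_subdomains <- sets
    res$county_subdomain_scores <- subdomain_scores_table(sets)
    hf <- fit_domain_regression(res$county_subdomain_scores, res$reference_county,
                                "health_factors")
    ho <- fit_domain_regression(res$county_subdomain_scores, res$reference_county,
                                "health_outcomes", hf_model = hf)
    res$hf_model <- hf
    res$ho_model <- ho
    res$county_domain_scores <- dplyr::full_join(
      dplyr::rename(hf$fitted, health_factors = "score"),
      dplyr::rename(ho$fitted, health_outcomes = "score"),
      by = "county_id")
    res$county_domain_fixed <- dplyr::full_join(
      dplyr::rename(combine_fixed_weights(res$county_subdomain_scores,
                                          config$fixed_weights$health_factors),
                    health_factors = "score"),
      dplyr::rename(combine_fixed_weights(res$county_subdomain_scores,
                                          config$fixed_weights$health_outcomes),
                    health_outcomes = "score"),
      by = "county_id")
  })

  # -- ZIP-level scoring with county-calibrated weights -----------------
  stage("zip_score", {
    zip_std <- standardize_measures(
      res$measures_zip[c("zip_id", res$retained)], defs, cols = res$retained)
    zsets <- score_zip_subdomains(zip_std, defs, res$retained, method = "refit")
    res$zip_subdomains <- zsets
    res$zip_subdomain_scores <- subdomain_scores_table(zsets)
    if (config$combiner == "regression") {
      hf_z <- score_domains(res$zip_subdomain_scores, res$hf_model)
      ho_z <- score_domains(res$zip_subdomain_scores, res$ho_model,
                            hf_model = res$hf_model)
    } else {
      hf_z <- combine_fixed_weights(res$zip_subdomain_scores,
                                    config$fixed_weights$health_factors)
      ho_z <- combine_fixed_weights(res$zip_subdomain_scores,
                                    config$fixed_weights$health_outcomes)
    }
    res$zip_domain_scores <- dplyr::full_join(
      dplyr::rename(hf_z, health_factors = "score"),
      dplyr::rename(ho_z, health_outcomes = "score"),
      by = "zip_id")
  })

  # -- reapportion ZIP scores to county ---------------------------------
  stage("apportion", {
    res$county_scores_from_zip <- apportion_zip_to_county(
      res$zip_domain_scores, res$crosswalk)
  })

  # -- variance decomposition -------------------------------------------
  stage("variance", {
    res$variance <- purrr::map(
      setNames(c("health_factors", "health_outcomes"),
               c("health_factors", "health_outcomes")),
      function(d) {
        df <- res$zip_domain_scores[c("zip_id", d)]
        names(df)[2] <- "score"
        fit_random_intercept(df, res$crosswalk, mode = config$variance_mode,
                             domain = d)
      })
  })

  # -- agreement evaluation ---------------------------------------------
  stage("agreement", {
    mk <- function(analog, ref_col) {
      agreement_report(
        dplyr::rename(analog[c("county_id", ref_col)], score = !!ref_col),
        dplyr::rename(res$reference_county[c("county_id", ref_col)], score = !!ref_col),
        k = config$k, scheme = config$kappa_scheme, band = config$band)
    }
    res$agreement <- list(
      county = list(health_factors = mk(res$county_domain_scores, "health_factors"),
                    health_outcomes = mk(res$county_domain_scores, "health_outcomes")),
      zip_derived = list(health_factors = mk(res$county_scores_from_zip, "health_factors"),
                         health_outcomes = mk(res$county_scores_from_zip, "health_outcomes"))
    )
    res$correlations <- correlation_report(
      res$county_domain_scores, res$reference_county,
      vars_x = c("health_factors", "health_outcomes"),
      vars_y = c("health_factors", "health_outcomes"))
    dom <- dominant_county(res$crosswalk)
    res$intracounty <- purrr::map(
      setNames(c("health_factors", "health_outcomes"),
               c("health_factors", "health_outcomes")),
      function(d) {
        zt <- assign_ktiles(
          dplyr::rename(res$zip_domain_scores[c("zip_id", d)], score = !!d),
          k = config$k)
        ct <- assign_ktiles(
          dplyr::rename(res$county_scores_from_zip[c("county_id", d)], score = !!d),
          k = config$k)
        intracounty_variation(zt, ct, dom, k = config$k)
      })
  })

  res$manifest <- build_manifest(res, config)
  res <- structure(res, class = "zr_pipeline_result")
  if (!is.null(output_dir)) {
    res$paths <- write_bundle(res, output_dir)
  }
  res
}

build_manifest <- function(res, config) {
  excluded <- setdiff(res$counties$county_id,
                      res$county_subdomain_scores$county_id %||% character(0))
  list(
    package_version = as.character(utils::packageVersion("zipranks")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    combiner = config$combiner,
    counts = list(
      counties = nrow(res$counties %||% tibble()),
      zips = nrow(res$zips %||% tibble()),
      zips_suppressed = if (!is.null(res$zips))
        sum(res$zips$population < config$min_zip_population) else 0L,
      measures_candidate = nrow(res$screening %||% tibble()),
      measures_retained = length(res$retained %||% character(0)),
      counties_evaluated = nrow(res$county_subdomain_scores %||% tibble()),
      counties_excluded = length(excluded)
    ),
    exclusions = list(counties = excluded,
                      reason = "insufficient data (all ZIP measures suppressed)"),
    screening_decisions = if (!is.null(res$screening))
      as.list(table(res$screening$decision)) else NULL
  )
}

#' @export
print.zr_pipeline_result <- function(x, ...) {
  cat("<zr_pipeline_result>\n")
  m <- x$manifest$counts
  cat(sprintf("  %d counties (%d evaluated, %d excluded), %d ZIPs (%d suppressed)\n",
              m$counties, m$counties_evaluated, m$counties_excluded,
              m$zips, m$zips_suppressed))
  cat(sprintf("  measures: %d candidates, %d retained\n",
              m$measures_candidate, m$measures_retained))
  if (!is.null(x$hf_model)) {
    cat(sprintf("  county R^2: HF %.3f, HO %.3f\n",
                x$hf_model$r_squared, x$ho_model$r_squared))
  }
  if (!is.null(x$variance)) {
    cat(sprintf("  ICC: HF %.3f, HO %.3f (%s membership)\n",
                x$variance$health_factors$icc, x$variance$health_outcomes$icc,
                x$variance$health_factors$mode))
  }
  invisible(x)
}

# Serialize the bundle as CSV + JSON only; content is a pure function of the
# config (no timestamps), so identical runs give byte-identical bundles.
write_bundle <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, nm) {
    if (is.null(df)) return()
    p <- file.path(output_dir, paste0(nm, ".csv"))
    readr::write_csv(df, p, progress = FALSE)
    paths[[nm]] <<- p
  }
  wjson <- function(x, nm) {
    if (is.null(x)) return()
    p <- file.path(output_dir, paste0(nm, ".json"))
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths[[nm]] <<- p
  }
  wcsv(res$counties, "counties")
  wcsv(res$zips, "zips")
  wcsv(res$crosswalk, "crosswalk")
  wcsv(res$measures_zip_raw, "measures_zip")
  wcsv(res$reference_county, "reference_scores_county")
  wcsv(res$encounters, "encounters")
  wcsv(res$encounter_rates, "encounter_rates_zip")
  wcsv(res$transform_report, "transform_report")
  wcsv(res$screening, "screening_report")
  wcsv(res$county_subdomain_scores, "subdomain_scores_county")
  wcsv(res$zip_subdomain_scores, "subdomain_scores_zip")
  wcsv(res$county_domain_scores, "domain_scores_county")
  wcsv(res$county_domain_fixed, "domain_scores_county_fixed_weights")
  wcsv(res$zip_domain_scores, "domain_scores_zip")
  wcsv(res$county_scores_from_zip, "domain_scores_county_from_zip")
  wcsv(res$correlations, "correlation_report")
  if (!is.null(res$hf_model)) {
    wjson(list(
      health_factors = domain_model_json(res$hf_model),
      health_outcomes = domain_model_json(res$ho_model),
      eigenvalues = purrr::map(res$county_subdomains, "eigenvalue")
    ), "domain_model")
  }
  if (!is.null(res$variance)) {
    wjson(purrr::map(res$variance, function(v) {
      list(domain = v$domain, sigma2_between = v$sigma2_between,
           sigma2_within = v$sigma2_within, icc = v$icc,
           grand_mean = v$grand_mean, n_zips_used = v$n_zips_used,
           n_counties = v$n_counties, mode = v$mode, engine = v$engine_used)
    }), "variance_decomposition")
    wcsv(dplyr::bind_rows(purrr::imap(res$variance, function(v, d) {
      dplyr::mutate(v$blups, domain = d, .before = 1)
    })), "county_blups")
  }
  if (!is.null(res$agreement)) {
    wjson(purrr::map(res$agreement, function(lvl) purrr::map(lvl, agreement_json)),
          "agreement_report")
    for (lvl in names(res$agreement)) {
      for (d in names(res$agreement[[lvl]])) {
        tab <- as.data.frame(res$agreement[[lvl]][[d]]$cross_table)
        wcsv(tibble::as_tibble(res$agreement[[lvl]][[d]]$cross_table, rownames = "tile_analog"),
             paste0("cross_table_", lvl, "_", d))
      }
    }
  }
  if (!is.null(res$intracounty)) {
    wjson(purrr::map(res$intracounty, function(ic) {
      ic_out <- unclass(ic)
      ic_out$per_county <- NULL
      ic_out
    }), "intracounty_report")
    wcsv(dplyr::bind_rows(purrr::imap(res$intracounty, function(ic, d) {
      dplyr::mutate(ic$per_county, domain = d, .before = 1)
    })), "intracounty_per_county")
  }
  if (!is.null(res$manifest)) wjson(res$manifest, "run_manifest")
  paths
}

domain_model_json <- function(m) {
  list(domain = m$domain, intercept = m$intercept,
       coefficients = as.list(m$coefficients),
       r_squared = m$r_squared, n_fit = m$n_fit)
}

agreement_json <- function(a) {
  list(k = a$k, n = a$n,
       exact_agreement = a$exact_agreement,
       within_band = a$within_band, band = a$band,
       weighted_kappa = a$weighted_kappa, kappa_p_value = a$kappa_p_value,
       kappa_scheme = a$kappa_scheme,
       pearson_r = a$pearson_r, pearson_p = a$pearson_p)
}

#' Validate a set of input CSVs
#'
#' Schema checks (required columns, ZIP id format), crosswalk weight-sum
#' and duplicate checks, and referential integrity (every measure ZIP in
#' the crosswalk). Failures are enumerated; non-fatal issues are reported
#' with severity `"warning"`.
#'
#' @param paths Named list of CSV paths (`zips`, `crosswalk`,
#'   `measures_zip`, `reference_county`, ...).
#' @return A tibble of violations (`file`, `check`, `severity`, `detail`);
#'   zero rows means the bundle is valid.
#' @export
validate_inputs <- function(paths) {
  v <- list()
  add <- function(file, check, detail, severity = "error") {
    v[[length(v) + 1L]] <<- tibble(file = file, check = check,
                                   severity = severity, detail = detail)
  }
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) add(nm, "exists", sprintf("file not found: %s", paths[[nm]]))
  }
  required <- list(zips = c("zip_id", "county_id", "population"),
                   crosswalk = c("zip_id", "county_id", "allocation_population"),
                   measures_zip = "zip_id",
                   reference_county = "county_id")
  tabs <- list()
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) next
    tab <- tryCatch(
      readr::read_csv(paths[[nm]], show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(zip_id = "c", county_id = "c",
                                              .default = "?")),
      error = function(e) {
        add(nm, "parse", conditionMessage(e)); NULL
      })
    if (is.null(tab)) next
    tabs[[nm]] <- tab
    need <- required[[nm]]
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) {
      add(nm, "columns", sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    }
    if ("zip_id" %in% names(tab)) {
      bad <- unique(tab$zip_id[!grepl("^[0-9]{5}$", tab$zip_id)])
      if (length(bad) > 0) {
        add(nm, "zip_format", sprintf("non-5-digit zip id(s): %s",
                                      paste(head(bad, 5), collapse = ", ")))
      }
    }
  }
  cw <- tabs$crosswalk
  if (!is.null(cw) && all(c("zip_id", "county_id") %in% names(cw))) {
    dup <- cw[duplicated(cw[c("zip_id", "county_id")]), ]
    if (nrow(dup) > 0) {
      add("crosswalk", "duplicates",
          sprintf("duplicated (zip, county) pair(s): %s",
                  paste(head(unique(dup$zip_id), 5), collapse = ", ")))
    }
    if ("weight" %in% names(cw)) {
      sums <- tapply(cw$weight, cw$zip_id, sum)
      bad <- names(sums)[abs(sums - 1) > 1e-6]
      if (length(bad) > 0) {
        add("crosswalk", "weight_sum",
            sprintf("weights do not sum to 1 for zip(s): %s",
                    paste(head(bad, 5), collapse = ", ")))
      }
    }
    if (!is.null(tabs$measures_zip) && "zip_id" %in% names(tabs$measures_zip)) {
      orphan <- setdiff(tabs$measures_zip$zip_id, cw$zip_id)
      if (length(orphan) > 0) {
        add("measures_zip", "referential_integrity",
            sprintf("zip(s) absent from crosswalk: %s",
                    paste(head(orphan, 5), collapse = ", ")))
      }
    }
  }
  if (!is.null(tabs$zips) && "population" %in% names(tabs$zips)) {
    if (any(tabs$zips$population <= 0, na.rm = TRUE)) {
      add("zips", "population", "non-positive population(s)", severity = "warning")
    }
  }
  if (length(v) == 0) {
    return(tibble(file = character(), check = character(),
                  severity = character(), detail = character()))
  }
  dplyr::bind_rows(v)
}
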