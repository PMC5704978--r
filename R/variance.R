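#' Variance decomposition of ZIP scores by county random intercepts
#'
#' Fits the one-way random-intercept model `score ~ 1 + (1 | county)` to
#' ZIP-level domain scores and reports the between/within variance
#' components, the intraclass correlation
#' `icc = sigma2_between / (sigma2_between + sigma2_within)` — the share of
#' ZIP-score variance explained by within-county clustering — and the BLUP
#' shrinkage predictions of county scores.
#'
#' County membership comes from the crosswalk: mode `"dominant"` (default)
#' counts each ZIP once in its largest-weight county; mode `"weighted"`
#' expands each ZIP over all its counties with the crosswalk weights used
#' as precision weights. Estimation is REML: for a balanced, unweighted
#' design the exact closed form (`sigma2_within = MSW`,
#' `sigma2_between = max(0, (MSB - MSW) / n)`), to which REML reduces, is
#' used; otherwise `lme4::lmer`. Negative between-county estimates are
#' truncated at 0 with a message.
#'
#' @param df A tibble of ZIP scores with `zip_id` and the score column (and
#'   optionally `county_id`, used directly when no crosswalk is given).
#' @param crosswalk Normalized crosswalk (needed unless `df` has
#'   `county_id`).
#' @param score_col Name of the score column (default `"score"`).
#' @param mode `"dominant"` or `"weighted"`.
#' @param engine `"auto"` (closed form when balanced/unweighted, else
#'   REML via lme4), `"anova"` (force closed form; errors on weighted
#'   mode), or `"reml"` (force lme4).
#' @param domain Optional domain tag carried into the result.
#' @return A `zr_variance_decomposition`: `domain`, `sigma2_between`,
#'   `sigma2_within`, `icc`, `grand_mean`, `blups` (per-county tibble),
#'   `n_zips_used`, `n_counties`, `mode`, `engine_used`.
#' @export
fit_random_intercept <- function(df, crosswalk = NULL, score_col = "score",
                                 mode = c("dominant", "weighted"),
                                 engine = c("auto", "anova", "reml"),
                                 domain = NA_character_) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  if (!score_col %in% names(df)) {
    zr_data_error(sprintf("score column '%s' not found.", score_col))
  }
  if (!is.null(crosswalk)) {
    membership <- if (mode == "dominant") {
      dominant_county(crosswalk) |> dplyr::mutate(weight = 1)
    } else {
      dplyr::select(crosswalk, "zip_id", "county_id", "weight") |>
        dplyr::filter(.data$weight > 0)
    }
    dat <- dplyr::inner_join(df[c("zip_id", score_col)], membership, by = "zip_id")
  } else {
    if (!"county_id" %in% names(df)) {
      zr_data_error("need either a crosswalk or a `county_id` column.")
    }
    dat <- df[c("zip_id", "county_id", score_col)]
    dat$weight <- 1
  }
  dat <- dat[!is.na(dat[[score_col]]), ]
  y <- dat[[score_col]]
  g <- dat$county_id
  w <- dat$weight
  n_counties <- dplyr::n_distinct(g)
  if (n_counties < 2L) {
    zr_data_error("variance decomposition needs at least 2 counties.")
  }
  sizes <- table(g)
  if (max(sizes) < 2L) {
    zr_data_error("all counties are singletons; within-county variance is unidentifiable.")
  }

  balanced <- length(unique(sizes)) == 1L && all(w == 1)
  use_anova <- switch(engine,
                      auto = balanced,
                      anova = TRUE,
                      reml = FALSE)
  if (engine == "anova" && any(w != 1)) {
    zr_config_error("closed-form estimator requires unweighted membership.")
  }

  if (use_anova && balanced) {
    n_per <- unname(sizes[1])
    gm <- tapply(y, g, mean)
    msb <- n_per * var(as.numeric(gm))
    msw <- sum((y - gm[g])^2) / (length(y) - n_counties)
    s2w <- msw
    s2b <- (msb - msw) / n_per
    grand_mean <- mean(y)
    engine_used <- "anova_closed_form"
  } else {
    fit <- lme4::lmer(y ~ 1 + (1 | g),
                      data = data.frame(y = y, g = g),
                      weights = w, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2b <- vc$vcov[vc$grp == "g"]
    s2w <- vc$vcov[vc$grp == "Residual"]
    grand_mean <- unname(lme4::fixef(fit)[1])
    engine_used <- "lme4_reml"
  }
  if (s2b < 0) {
    inform(sprintf("negative between-county variance estimate (%.4g) truncated at 0.", s2b))
    s2b <- 0
  }
  county_stats <- tibble(county_id = g, y = y, w = w) |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(n_eff = sum(.data$w),
                     county_mean = sum(.data$w * .data$y) / sum(.data$w),
                     .groups = "drop")
  res <- structure(list(
    domain = domain,
    sigma2_between = s2b,
    sigma2_within = s2w,
    icc = if (s2b + s2w > 0) s2b / (s2b + s2w) else 0,
    grand_mean = grand_mean,
    n_zips_used = length(y),
    n_counties = n_counties,
    mode = mode,
    engine_used = engine_used,
    county_stats = county_stats
  ), class = "zr_variance_decomposition")
  res$blups <- compute_blups(res)
  res
}

#' Best Linear Unbiased Predictors of county scores
#'
#' Shrinkage predictions from fitted variance components:
#' `BLUP_c = grand_mean + lambda_c * (county_mean_c - grand_mean)` with
#' `lambda_c = sigma2_b / (sigma2_b + sigma2_w / n_c)` and `n_c` the
#' effective (weight-summed) ZIP count of county `c`. Every BLUP lies
#' between the grand mean and the county mean; counties with fewer ZIPs are
#' shrunk harder.
#'
#' @param decomposition A `zr_variance_decomposition` from
#'   [fit_random_intercept()].
#' @return A tibble: `county_id`, `n_eff`, `county_mean`, `lambda`, `blup`.
#' @export
compute_blups <- function(decomposition) {
  stopifnot(inherits(decomposition, "zr_variance_decomposition"))
  s2b <- decomposition$sigma2_between
  s2w <- decomposition$sigma2_within
  gm <- decomposition$grand_mean
  decomposition$county_stats |>
    dplyr::mutate(
      lambda = if (s2b == 0) 0 else s2b / (s2b + s2w / .data$n_eff),
      blup = gm + .data$lambda * (.data$county_mean - gm)
    )
}

#' @export
print.zr_variance_decomposition <- function(x, ...) {
  cat(sprintf("<zr_variance_decomposition>%s mode = %s (%s)\n",
              ifelse(is.na(x$domain), "", paste0(" ", x$domain, ";")),
              x$mode, x$engine_used))
  cat(sprintf("  sigma2_between = %.4f, sigma2_within = %.4f, ICC = %.3f\n",
              x$sigma2_between, x$sigma2_within, x$icc))
  cat(sprintf("  %d ZIPs in %d counties; grand mean %.4f\n",
              x$n_zips_used, x$n_counties, x$grand_mean))
  invisible(x)
}
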