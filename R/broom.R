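# tidy()/glance() methods for the package's fitted objects.

#' Tidy a fitted domain regression
#'
#' @param x A `zr_domain_model`.
#' @param ... Unused.
#' @return One row per model term with estimate, standard error, statistic
#'   and p-value.
#' @export
tidy.zr_domain_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm),
         estimate = sm[, "Estimate"],
         std.error = sm[, "Std. Error"],
         statistic = sm[, "t value"],
         p.value = sm[, "Pr(>|t|)"])
}

#' @rdname tidy.zr_domain_model
#' @export
glance.zr_domain_model <- function(x, ...) {
  tibble(domain = x$domain, r.squared = x$r_squared,
         adj.r.squared = summary(x$fit)$adj.r.squared,
         nobs = x$n_fit)
}

#' Tidy a subdomain PCA score set
#'
#' @param x A `zr_subdomain_scores`.
#' @param ... Unused.
#' @return Loadings, one row per measure.
#' @export
tidy.zr_subdomain_scores <- function(x, ...) {
  tibble(subdomain = x$subdomain, measure = names(x$loadings),
         loading = unname(x$loadings))
}

#' @rdname tidy.zr_subdomain_scores
#' @export
glance.zr_subdomain_scores <- function(x, ...) {
  tibble(subdomain = x$subdomain, level = x$level,
         eigenvalue = x$eigenvalue, explained_share = x$explained_share,
         n_measures = length(x$measures), nobs = x$n_units,
         sign_aligned = x$sign_aligned)
}

#' Tidy a variance decomposition
#'
#' @param x A `zr_variance_decomposition`.
#' @param ... Unused.
#' @return One row per variance component.
#' @export
tidy.zr_variance_decomposition <- function(x, ...) {
  tibble(component = c("county", "residual"),
         variance = c(x$sigma2_between, x$sigma2_within),
         share = c(x$icc, 1 - x$icc))
}

#' @rdname tidy.zr_variance_decomposition
#' @export
glance.zr_variance_decomposition <- function(x, ...) {
  tibble(domain = x$domain, icc = x$icc,
         sigma2_between = x$sigma2_between, sigma2_within = x$sigma2_within,
         grand_mean = x$grand_mean, nobs = x$n_zips_used,
         n_counties = x$n_counties, mode = x$mode, engine = x$engine_used)
}

#' Tidy an agreement report
#'
#' @param x A `zr_agreement`.
#' @param ... Unused.
#' @return The cross-classification table in long form.
#' @export
tidy.zr_agreement <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$cross_table))) |>
    dplyr::rename(tile_analog = "a", tile_reference = "b", n = "Freq") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("tile_"),
                                ~ as.integer(as.character(.x))))
}

#' @rdname tidy.zr_agreement
#' @export
glance.zr_agreement <- function(x, ...) {
  tibble(k = x$k, nobs = x$n,
         exact_agreement = x$exact_agreement,
         within_band = x$within_band, band = x$band,
         weighted_kappa = x$weighted_kappa, kappa_p_value = x$kappa_p_value,
         kappa_scheme = x$kappa_scheme,
         pearson_r = x$pearson_r, pearson_p = x$pearson_p)
}

#' Tidy a screening report
#'
#' @param x A `zr_screening`.
#' @param ... Unused.
#' @return The underlying per-measure tibble.
#' @export
tidy.zr_screening <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.zr_screening
#' @export
glance.zr_screening <- function(x, ...) {
  tibble(n_candidates = nrow(x), n_retained = sum(x$retained),
         n_override = sum(x$decision == "retained_override"),
         n_dropped = sum(!x$retained))
}
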