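#' Aggregate encounter records into ZIP rates
#'
#' Counts encounters per ZIP and category and converts them to rates,
#' `scale * count / population`. ZIPs with no encounters in a category get
#' rate 0; ZIPs below the suppression floor are emitted as missing. A zero
#' population with a nonzero count is a data error.
#'
#' @param encounters A tibble with `zip_id` and `category` (one row per
#'   encounter record).
#' @param zip_population A tibble with `zip_id` and `population`.
#' @param scale Positive rate multiplier (default 1000, i.e. rate per 1,000
#'   residents).
#' @param min_zip_population Suppression floor (default 0 = no suppression).
#' @return A wide tibble: `zip_id`, `population`, one rate column per
#'   category.
#' @export
aggregate_encounters <- function(encounters, zip_population, scale = 1000,
                                 min_zip_population = 0) {
  stopifnot_scalar_number(scale, "scale", lower = 1e-12)
  unknown <- setdiff(unique(encounters$zip_id), zip_population$zip_id)
  if (length(unknown) > 0L) {
    zr_data_error(sprintf("encounter ZIP(s) absent from population table: %s",
                          paste(head(unknown, 10), collapse = ", ")))
  }
  counts <- encounters |>
    dplyr::count(.data$zip_id, .data$category, name = "n") |>
    tidyr::complete(zip_id = zip_population$zip_id,
                    category = unique(encounters$category),
                    fill = list(n = 0L))
  out <- counts |>
    dplyr::left_join(zip_population[c("zip_id", "population")], by = "zip_id")
  bad <- out$population == 0 & out$n > 0
  if (any(bad)) {
    zr_data_error(sprintf("nonzero encounter counts in zero-population ZIP(s): %s",
                          paste(unique(out$zip_id[bad]), collapse = ", ")))
  }
  out |>
    dplyr::mutate(rate = ifelse(.data$population < min_zip_population,
                                NA_real_, scale * .data$n / .data$population)) |>
    dplyr::select("zip_id", "population", "category", "rate") |>
    tidyr::pivot_wider(names_from = "category", values_from = "rate") |>
    dplyr::arrange(.data$zip_id)
}

#' Standardize measure columns to z-scores
#'
#' Centers and scales every measure column to mean 0 and sample SD 1
#' (denominator n-1) over its non-missing values, leaving missings in
#' place. Protective measures (per `definitions$direction`) are sign-flipped
#' first, so that larger always means worse health — the canonical adverse
#' orientation the PCA sign-alignment relies on. Standardization is
#' idempotent. A column with fewer than 3 non-missing values or zero
#' variance is a data error naming the column.
#'
#' @param df A wide measure table (`zip_id` or `county_id`, optional
#'   `population`, measure columns).
#' @param definitions Optional measure-definition tibble with `name` and
#'   `direction`; measures absent from it are treated as adverse.
#' @param cols Optional character vector of measure columns (default: all
#'   numeric non-id columns).
#' @return The table with measure columns replaced by z-scores.
#' @export
standardize_measures <- function(df, definitions = NULL, cols = NULL) {
  id_cols <- zr_id_cols(df)
  cols <- cols %||% setdiff(names(df)[vapply(df, is.numeric, logical(1))], id_cols)
  protective <- character(0)
  if (!is.null(definitions)) {
    protective <- definitions$name[definitions$direction == "protective"]
  }
  for (cl in cols) {
    x <- df[[cl]]
    if (cl %in% protective) x <- -x
    ok <- !is.na(x)
    if (sum(ok) < 3L) {
      zr_data_error(sprintf("column '%s' has fewer than 3 non-missing values.", cl))
    }
    s <- sd(x[ok])
    if (!is.finite(s) || s == 0) {
      zr_data_error(sprintf("column '%s' has zero variance.", cl))
    }
    df[[cl]] <- (x - mean(x[ok])) / s
  }
  df
}

#' Transform highly skewed measures
#'
#' Columns whose absolute sample skewness exceeds `skew_threshold` receive a
#' `log1p` transform. Columns selected for transformation that contain
#' negative values are flagged and left untransformed. The report records
#' skewness before and after for every column.
#'
#' @param df A wide measure table (raw scale).
#' @param skew_threshold Absolute skewness above which a column is
#'   transformed (default 2; `Inf` disables all transforms).
#' @param cols Optional measure columns (default: numeric non-id columns).
#' @return A list with `data` (transformed table) and `report` (tibble with
#'   `measure`, `skew_before`, `skew_after`, `transformed`,
#'   `flagged_negative`).
#' @export
transform_if_skewed <- function(df, skew_threshold = 2, cols = NULL) {
  stopifnot_scalar_number(skew_threshold, "skew_threshold", lower = 0)
  id_cols <- zr_id_cols(df)
  cols <- cols %||% setdiff(names(df)[vapply(df, is.numeric, logical(1))], id_cols)
  report <- purrr::map_dfr(cols, function(cl) {
    x <- df[[cl]]
    sk <- zr_skewness(x)
    row <- tibble(measure = cl, skew_before = sk, skew_after = sk,
                  transformed = FALSE, flagged_negative = FALSE)
    if (is.finite(sk) && abs(sk) > skew_threshold) {
      if (any(x < 0, na.rm = TRUE)) {
        warn(sprintf("column '%s' is skewed but has negative values; left untransformed.", cl),
             class = "zipranks_warning_negative_skew")
        row$flagged_negative <- TRUE
      } else {
        df[[cl]] <<- log1p(x)
        row$transformed <- TRUE
        row$skew_after <- zr_skewness(log1p(x))
      }
    }
    row
  })
  list(data = df, report = report)
}

#' Screen candidate measures against reference subdomain scores
#'
#' Computes each measure's Pearson correlation (two-sided t-test) with its
#' assigned county-level reference subdomain score and applies the retention
#' rule: keep a measure iff its correlation is positive, at least `r_min`,
#' and statistically significant at `alpha` — unless the measure is named in
#' `overrides`, in which case it is retained regardless (decision
#' `retained_override`), the mechanism that keeps a conceptually necessary
#' measure such as injury-related mortality in a thin subdomain.
#'
#' Decisions: `retained`, `retained_override`, `dropped_negative` (r <= 0),
#' `dropped_low_r` (0 < r < r_min), `dropped_nonsignificant` (r >= r_min but
#' p >= alpha).
#'
#' @param county_measures Standardized county-level measure table
#'   (`county_id` + measure columns), typically apportioned from ZIP level.
#' @param reference County reference scores (wide, `county_id` + subdomain
#'   columns), e.g. from [generate_reference_scores()].
#' @param definitions Measure definitions (`name`, `domain`, `subdomain`).
#' @param r_min Retention threshold on r (default 0.20).
#' @param alpha Significance level (default 0.05).
#' @param overrides Character vector of measure names to force-retain.
#' @param transform_report Optional report from [transform_if_skewed()] to
#'   carry skewness columns into the output.
#' @param min_counties Minimum complete pairs per measure (default 10).
#' @return A `zr_screening` tibble: `measure`, `domain`, `subdomain`, `n`,
#'   `r`, `p_value`, `decision`, `retained`.
#' @export
screen_measures <- function(county_measures, reference, definitions,
                            r_min = 0.20, alpha = 0.05,
                            overrides = character(0),
                            transform_report = NULL,
                            min_counties = 10L) {
  stopifnot_scalar_number(r_min, "r_min", 0, 1)
  stopifnot_scalar_number(alpha, "alpha", 0, 1)
  measures <- intersect(definitions$name, names(county_measures))
  if (length(measures) == 0L) zr_data_error("no definition-listed measures in table.")
  rows <- purrr::map_dfr(measures, function(m) {
    sub <- definitions$subdomain[definitions$name == m][1]
    if (is.na(sub) || !sub %in% names(reference)) {
      zr_config_error(sprintf("measure '%s' has no assigned subdomain reference.", m))
    }
    dat <- dplyr::inner_join(county_measures[c("county_id", m)],
                             reference[c("county_id", sub)], by = "county_id")
    dat <- dat[complete.cases(dat), ]
    if (nrow(dat) < min_counties) {
      zr_data_error(sprintf("measure '%s' has only %d complete counties (need >= %d).",
                            m, nrow(dat), min_counties))
    }
    ct <- cor.test(dat[[m]], dat[[sub]])
    r <- unname(ct$estimate); p <- ct$p.value
    decision <- if (m %in% overrides) "retained_override"
      else if (r <= 0) "dropped_negative"
      else if (r < r_min) "dropped_low_r"
      else if (p >= alpha) "dropped_nonsignificant"
      else "retained"
    tibble(measure = m,
           domain = definitions$domain[definitions$name == m][1],
           subdomain = sub, n = nrow(dat), r = r, p_value = p,
           decision = decision,
           retained = decision %in% c("retained", "retained_override"))
  })
  if (!is.null(transform_report)) {
    rows <- dplyr::left_join(rows, transform_report, by = "measure")
  }
  class(rows) <- c("zr_screening", class(rows))
  rows
}

#' Names of retained measures from a screening report
#' @param screening A `zr_screening` tibble.
#' @return Character vector of retained measure names.
#' @export
retained_measures <- function(screening) {
  screening$measure[screening$retained]
}
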