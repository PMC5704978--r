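#' Normalize raw ZIP–county population allocations into a crosswalk
#'
#' Converts MABLE/Geocorr-style rows of `(zip_id, county_id,
#' allocation_population)` into a source-to-target weighting file: each
#' ZIP's weights are its allocation populations divided by its total
#' population, renormalized to sum to exactly 1 and ordered by
#' `(zip_id, county_id)`. ZIPs with zero total population are excluded with
#' a warning; negative populations and duplicated `(zip, county)` pairs are
#' data errors. Normalization is idempotent.
#'
#' @param raw A data frame with columns `zip_id`, `county_id`,
#'   `allocation_population`.
#' @return A tibble with the input columns plus `weight`.
#' @export
normalize_allocation <- function(raw) {
  req <- c("zip_id", "county_id", "allocation_population")
  if (!all(req %in% names(raw))) {
    zr_data_error(sprintf("crosswalk rows need columns: %s", paste(req, collapse = ", ")))
  }
  if (any(raw$allocation_population < 0, na.rm = TRUE)) {
    zr_data_error("negative allocation populations in crosswalk.")
  }
  dup <- duplicated(raw[c("zip_id", "county_id")])
  if (any(dup)) {
    zr_data_error(sprintf("duplicate (zip, county) pairs in crosswalk: %s",
                          paste(unique(raw$zip_id[dup]), collapse = ", ")))
  }
  out <- raw |>
    dplyr::group_by(.data$zip_id) |>
    dplyr::mutate(.total = sum(.data$allocation_population)) |>
    dplyr::ungroup()
  zero <- unique(out$zip_id[out$.total == 0])
  if (length(zero) > 0L) {
    warn(sprintf("excluding %d ZIP(s) with zero total population: %s",
                 length(zero), paste(head(zero, 5), collapse = ", ")),
         class = "zipranks_warning_zero_population")
    out <- dplyr::filter(out, .data$.total > 0)
  }
  out |>
    dplyr::mutate(weight = .data$allocation_population / .data$.total) |>
    dplyr::group_by(.data$zip_id) |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup() |>
    dplyr::select("zip_id", "county_id", "allocation_population", "weight") |>
    dplyr::arrange(.data$zip_id, .data$county_id)
}

#' Apportion ZIP-level values to counties
#'
#' Population-weighted spatial interpolation from the ZIP ("source" zone) to
#' the county ("target" zone): for every value column, the county value is
#' `sum(weight * population * value) / sum(weight * population)` over
#' contributing ZIPs — i.e. a population-weighted mean, appropriate for the
#' intensive quantities (rates, standardized scores) this pipeline carries.
#' Missing ZIP values are dropped from both numerator and denominator column
#' by column; counties with no contributing population for any column are
#' absent from the output.
#'
#' @param values A data frame with `zip_id` and numeric value columns.
#' @param crosswalk A normalized crosswalk from [normalize_allocation()].
#' @param cols Optional character vector of value columns (default: all
#'   numeric non-id columns).
#' @return A tibble with `county_id` and one column per value column.
#' @export
apportion_zip_to_county <- function(values, crosswalk, cols = NULL) {
  if (!"zip_id" %in% names(values)) zr_data_error("`values` must contain `zip_id`.")
  missing_zips <- setdiff(values$zip_id, crosswalk$zip_id)
  if (length(missing_zips) > 0L) {
    zr_data_error(sprintf("ZIP(s) missing from crosswalk: %s",
                          paste(head(missing_zips, 10), collapse = ", ")),
                  missing_zips = missing_zips)
  }
  cols <- cols %||% setdiff(names(values)[vapply(values, is.numeric, logical(1))],
                            c("population"))
  joined <- crosswalk |>
    dplyr::inner_join(values, by = "zip_id") |>
    dplyr::mutate(.w = .data$allocation_population)
  joined |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), ~ {
      ok <- !is.na(.x)
      if (!any(ok) || sum(.data$.w[ok]) == 0) NA_real_
      else sum(.data$.w[ok] * .x[ok]) / sum(.data$.w[ok])
    }), .groups = "drop") |>
    dplyr::filter(dplyr::if_any(dplyr::all_of(cols), ~ !is.na(.x))) |>
    dplyr::arrange(.data$county_id)
}

#' Assign each ZIP to its dominant county
#'
#' The county receiving the largest crosswalk weight; exact ties break to
#' the lexicographically smaller `county_id`.
#'
#' @param crosswalk A normalized crosswalk from [normalize_allocation()].
#' @return A tibble (`zip_id`, `county_id`, `weight`).
#' @export
dominant_county <- function(crosswalk) {
  crosswalk |>
    dplyr::arrange(.data$zip_id, dplyr::desc(.data$weight), .data$county_id) |>
    dplyr::distinct(.data$zip_id, .keep_all = TRUE) |>
    dplyr::select("zip_id", "county_id", "weight")
}
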