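#' Assign rank tiles (quintiles by default)
#'
#' Units are ranked ascending on the score (with `best_is_low = TRUE`,
#' tile 1 holds the best health, i.e. the lowest adverse-oriented scores,
#' matching the rank-1-is-best CHR convention) and cut into `k` tiles whose
#' sizes differ by at most one; the larger tiles sit at the best-health end
#' (114 units in quintiles gives 23/23/23/23/22). Ties share their average
#' rank and therefore a tile — a tie block spanning a boundary lands in the
#' tile containing its average rank; output rows keep stable unit-id order.
#' If every unit lands in one tile the result is flagged degenerate
#' (attribute and warning).
#'
#' @param df A tibble with a unit id column and a score column.
#' @param score_col Name of the score column (default `"score"`).
#' @param k Number of tiles (default 5; must be >= 2).
#' @param best_is_low If `TRUE` (default) low scores are tile 1.
#' @return `df` (non-missing rows) with an integer `tile` column, ordered
#'   by unit id.
#' @export
assign_ktiles <- function(df, score_col = "score", k = 5, best_is_low = TRUE) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    zr_config_error("`k` must be a single integer >= 2.")
  }
  k <- as.integer(k)
  if (!score_col %in% names(df)) {
    zr_data_error(sprintf("score column '%s' not found.", score_col))
  }
  unit_col <- zr_unit_col(df)
  out <- df[!is.na(df[[score_col]]), ]
  n <- nrow(out)
  if (n < k) zr_data_error(sprintf("need at least k = %d non-missing scores, have %d.", k, n))
  s <- out[[score_col]]
  if (!best_is_low) s <- -s
  r <- rank(s, ties.method = "average")
  base <- n %/% k
  sizes <- base + as.integer(seq_len(k) <= (n %% k))
  tile <- .bincode(r, breaks = c(0, cumsum(sizes)), right = TRUE)
  out$tile <- as.integer(tile)
  out <- dplyr::arrange(out, .data[[unit_col]])
  if (length(unique(out$tile)) == 1L && n > k) {
    warn("all units share one tile (tied scores); ranking is degenerate.",
         class = "zipranks_warning_degenerate_tiles")
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Cross-classify two tile assignments
#'
#' @param tiles_a,tiles_b Tibbles from [assign_ktiles()] over the same unit
#'   set and the same `k`.
#' @param k Tile count; defaults to the largest tile seen.
#' @return A `k x k` integer matrix; cell `(i, j)` counts units in tile `i`
#'   of A and tile `j` of B.
#' @export
cross_classify <- function(tiles_a, tiles_b, k = NULL) {
  unit_col <- zr_unit_col(tiles_a)
  if (!setequal(tiles_a[[unit_col]], tiles_b[[unit_col]])) {
    zr_data_error("the two tile tables cover different unit sets.")
  }
  j <- dplyr::inner_join(tiles_a[c(unit_col, "tile")], tiles_b[c(unit_col, "tile")],
                         by = unit_col, suffix = c("_a", "_b"))
  k <- k %||% max(j$tile_a, j$tile_b)
  tab <- table(factor(j$tile_a, levels = seq_len(k)),
               factor(j$tile_b, levels = seq_len(k)))
  m <- matrix(as.integer(tab), nrow = k, dimnames = list(a = seq_len(k), b = seq_len(k)))
  m
}

#' Weighted kappa for an ordered cross-classification table
#'
#' Chance-corrected agreement `kappa = 1 - sum(w * O) / sum(w * E)` with
#' disagreement weights `w_ij = |i - j| / (k - 1)` (linear) or
#' `(i - j)^2 / (k - 1)^2` (quadratic) and expected counts `E` from the
#' marginal products. The p-value is the large-sample normal test of
#' `H0: kappa = 0` (Fleiss–Cohen–Everitt standard error under
#' independence).
#'
#' @param tab A nonnegative `k x k` count matrix.
#' @param scheme `"linear"` (default) or `"quadratic"`.
#' @return A list: `kappa`, `p_value`, `z`, `se0`, `scheme`, `n`, `k`.
#' @export
weighted_kappa <- function(tab, scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab) || any(tab < 0)) {
    zr_data_error("`tab` must be a square nonnegative count matrix.")
  }
  n <- sum(tab)
  if (n <= 0) zr_data_error("empty cross-classification table.")
  k <- nrow(tab)
  idx <- seq_len(k)
  dist <- abs(outer(idx, idx, "-"))
  w <- if (scheme == "linear") dist / (k - 1) else (dist / (k - 1))^2
  v <- 1 - w   # agreement weights
  O <- tab / n
  pr <- rowSums(O); pc <- colSums(O)
  E <- outer(pr, pc)
  po <- sum(v * O)
  pe <- sum(v * E)
  if (abs(1 - pe) < 1e-12) {
    return(list(kappa = NA_real_, p_value = NA_real_, z = NA_real_,
                se0 = NA_real_, scheme = scheme, n = n, k = k))
  }
  kap <- (po - pe) / (1 - pe)
  vbar_i <- as.numeric(v %*% pc)       # row-wise expected agreement weight
  vbar_j <- as.numeric(pr %*% v)       # column-wise
  term <- sum(E * (v - outer(vbar_i, rep(1, k)) - outer(rep(1, k), vbar_j))^2)
  se0 <- sqrt(max(0, term - pe^2)) / ((1 - pe) * sqrt(n))
  z <- if (se0 > 0) kap / se0 else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
  list(kappa = kap, p_value = p, z = z, se0 = se0, scheme = scheme, n = n, k = k)
}

#' Within-band agreement
#'
#' Proportion of units whose two tiles differ by at most `band` (band 0 is
#' exact agreement; band `k - 1` is always 1). Nondecreasing in `band`.
#'
#' @param tab A `k x k` count matrix.
#' @param band Nonnegative integer band (default 1).
#' @return A proportion in \[0, 1\].
#' @export
within_band_agreement <- function(tab, band = 1) {
  if (!is.numeric(band) || length(band) != 1L || band < 0) {
    zr_config_error("`band` must be a single nonnegative integer.")
  }
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n <= 0) zr_data_error("empty cross-classification table.")
  k <- nrow(tab)
  dist <- abs(outer(seq_len(k), seq_len(k), "-"))
  sum(tab[dist <= band]) / n
}

#' Pairwise Pearson correlation report between two score tables
#'
#' The Table-2-style correlation block: every analog score column crossed
#' with every reference score column, with two-sided p-values.
#'
#' @param x,y Tibbles sharing a unit id column, with numeric score columns.
#' @param vars_x,vars_y Optional column selections (default: all shared-unit
#'   numeric columns).
#' @return A tibble: `analog`, `reference`, `n`, `r`, `p_value`.
#' @export
correlation_report <- function(x, y, vars_x = NULL, vars_y = NULL) {
  unit_col <- zr_unit_col(x)
  vars_x <- vars_x %||% setdiff(names(x)[vapply(x, is.numeric, logical(1))], "population")
  vars_y <- vars_y %||% setdiff(names(y)[vapply(y, is.numeric, logical(1))], "population")
  j <- dplyr::inner_join(x[c(unit_col, vars_x)], y[c(unit_col, vars_y)],
                         by = unit_col, suffix = c("_analog", "_ref"))
  xn <- ifelse(vars_x %in% vars_y, paste0(vars_x, "_analog"), vars_x)
  yn <- ifelse(vars_y %in% vars_x, paste0(vars_y, "_ref"), vars_y)
  grid <- tidyr::crossing(analog = vars_x, reference = vars_y)
  purrr::pmap_dfr(grid, function(analog, reference) {
    a <- j[[xn[match(analog, vars_x)]]]
    b <- j[[yn[match(reference, vars_y)]]]
    ok <- complete.cases(a, b)
    if (sum(ok) < 3L) zr_data_error("fewer than 3 complete pairs.")
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      zr_data_error(sprintf("zero variance in '%s' or '%s'.", analog, reference))
    }
    ct <- cor.test(a[ok], b[ok])
    tibble(analog = analog, reference = reference, n = sum(ok),
           r = unname(ct$estimate), p_value = ct$p.value)
  })
}

#' Full agreement report between two score vectors
#'
#' Ranks both score tables into `k` tiles, cross-classifies them, and
#' summarizes agreement: exact and within-one-tile proportions, weighted
#' kappa with its p-value, and the Pearson correlation of the underlying
#' scores.
#'
#' @param scores_a,scores_b Tibbles with a shared unit id column and a score
#'   column each.
#' @param score_col_a,score_col_b Score column names (default `"score"`).
#' @param k Tile count (default 5).
#' @param scheme Kappa weighting scheme (default `"linear"`).
#' @param band Band for `within_band` (default 1).
#' @param best_is_low Tile direction convention (default `TRUE`).
#' @return A `zr_agreement` object: `k`, `n`, `cross_table`,
#'   `exact_agreement`, `within_band`, `band`, `weighted_kappa`,
#'   `kappa_p_value`, `kappa_scheme`, `pearson_r`, `pearson_p`.
#' @export
agreement_report <- function(scores_a, scores_b,
                             score_col_a = "score", score_col_b = "score",
                             k = 5, scheme = "linear", band = 1,
                             best_is_low = TRUE) {
  unit_col <- zr_unit_col(scores_a)
  j <- dplyr::inner_join(scores_a[c(unit_col, score_col_a)],
                         scores_b[c(unit_col, score_col_b)],
                         by = unit_col, suffix = c("_a", "_b"))
  ca <- if (score_col_a == score_col_b) paste0(score_col_a, "_a") else score_col_a
  cb <- if (score_col_a == score_col_b) paste0(score_col_b, "_b") else score_col_b
  j <- j[complete.cases(j), ]
  ta <- assign_ktiles(j[c(unit_col, ca)], score_col = ca, k = k, best_is_low = best_is_low)
  tb <- assign_ktiles(j[c(unit_col, cb)], score_col = cb, k = k, best_is_low = best_is_low)
  tab <- cross_classify(ta, tb, k = k)
  wk <- weighted_kappa(tab, scheme = scheme)
  ct <- cor.test(j[[ca]], j[[cb]])
  structure(list(
    k = as.integer(k), n = nrow(j), cross_table = tab,
    exact_agreement = within_band_agreement(tab, 0),
    within_band = within_band_agreement(tab, band),
    band = band,
    weighted_kappa = wk$kappa, kappa_p_value = wk$p_value,
    kappa_scheme = wk$scheme,
    pearson_r = unname(ct$estimate), pearson_p = ct$p.value
  ), class = "zr_agreement")
}

#' @export
print.zr_agreement <- function(x, ...) {
  cat(sprintf("<zr_agreement> n = %d, k = %d\n", x$n, x$k))
  cat(sprintf("  exact %.1f%%, within %d tile %.1f%%, weighted kappa (%s) = %.3f (p = %.3g), r = %.3f\n",
              100 * x$exact_agreement, x$band, 100 * x$within_band,
              x$kappa_scheme, x$weighted_kappa, x$kappa_p_value, x$pearson_r))
  invisible(x)
}

#' Intracounty quintile variation
#'
#' Quantifies subcounty spread of the rankings: how many counties have ZIP
#' codes in both the top and bottom tiles, and how many counties ranked in
#' the best two county tiles contain at least one ZIP in the worst two ZIP
#' tiles. Denominators (evaluated counties; counties in the top two tiles)
#' are reported explicitly.
#'
#' @param zip_tiles ZIP tile table from [assign_ktiles()].
#' @param county_tiles County tile table from [assign_ktiles()].
#' @param mapping ZIP-to-county mapping (`zip_id`, `county_id`), e.g. from
#'   [dominant_county()].
#' @param k Tile count (default: max tile observed).
#' @return A `zr_intracounty` list: `n_counties`, `spanning_count`,
#'   `spanning_prop`, `top2_n`, `top2_with_bottom2_count`,
#'   `top2_with_bottom2_prop`, and `per_county` (tibble with each county's
#'   tile and its ZIP-tile range).
#' @export
intracounty_variation <- function(zip_tiles, county_tiles, mapping, k = NULL) {
  unmapped <- setdiff(zip_tiles$zip_id, mapping$zip_id)
  if (length(unmapped) > 0L) {
    zr_data_error(sprintf("ZIP(s) without county mapping: %s",
                          paste(head(unmapped, 10), collapse = ", ")))
  }
  k <- k %||% max(county_tiles$tile, zip_tiles$tile)
  per_county <- zip_tiles[c("zip_id", "tile")] |>
    dplyr::inner_join(mapping[c("zip_id", "county_id")], by = "zip_id") |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(n_zips = dplyr::n(),
                     zip_tile_min = min(.data$tile),
                     zip_tile_max = max(.data$tile),
                     has_top = any(.data$tile == 1L),
                     has_bottom = any(.data$tile == k),
                     has_bottom2 = any(.data$tile >= k - 1L),
                     .groups = "drop") |>
    dplyr::inner_join(dplyr::rename(county_tiles[c("county_id", "tile")],
                                    county_tile = "tile"),
                      by = "county_id")
  n_counties <- nrow(per_county)
  spanning <- sum(per_county$has_top & per_county$has_bottom)
  top2 <- per_county[per_county$county_tile <= 2L, ]
  top2_bad <- sum(top2$has_bottom2)
  structure(list(
    n_counties = n_counties,
    spanning_count = spanning,
    spanning_prop = spanning / n_counties,
    top2_n = nrow(top2),
    top2_with_bottom2_count = top2_bad,
    top2_with_bottom2_prop = if (nrow(top2) > 0) top2_bad / nrow(top2) else NA_real_,
    k = k,
    per_county = per_county
  ), class = "zr_intracounty")
}

#' @export
print.zr_intracounty <- function(x, ...) {
  cat(sprintf("<zr_intracounty> %d counties evaluated (k = %d)\n", x$n_counties, x$k))
  cat(sprintf("  spanning both extremes: %d (%.1f%%)\n",
              x$spanning_count, 100 * x$spanning_prop))
  cat(sprintf("  top-2-tile counties with bottom-2 ZIPs: %d of %d (%.1f%%)\n",
              x$top2_with_bottom2_count, x$top2_n, 100 * x$top2_with_bottom2_prop))
  invisible(x)
}
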