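# Internal helpers: error classes, seed substreams, small assertions.

zr_config_error <- function(msg, ...) {
  abort(msg, class = "zipranks_error_config", ...)
}

zr_data_error <- function(msg, ...) {
  abort(msg, class = "zipranks_error_data", ...)
}

zr_fit_error <- function(msg, ...) {
  abort(msg, class = "zipranks_error_fit", ...)
}

# PCA premise failure: first eigenvalue not above the acceptance floor.
zr_acceptance_error <- function(msg, ...) {
  abort(msg, class = c("zipranks_error_acceptance", "zipranks_error_fit"), ...)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    zr_config_error(sprintf("`%s` must be a single number in [%s, %s].",
                            name, format(lower), format(upper)))
  }
  invisible(x)
}

# Named substream seeds so each generator stage is reproducible independently
# of call order; kept well below 2^31.
zr_seed <- function(seed, stage) {
  offsets <- c(geography = 11L, latents = 23L, measures = 37L,
               reference = 53L, encounters = 71L, pipeline = 97L)
  if (!stage %in% names(offsets)) {
    abort(sprintf("unknown seed stage '%s'", stage), .internal = TRUE)
  }
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

# Identify unit-id / bookkeeping columns in a wide measure or score table.
zr_id_cols <- function(df) {
  intersect(c("zip_id", "county_id", "population"), names(df))
}

zr_unit_col <- function(df) {
  unit <- intersect(c("zip_id", "county_id"), names(df))
  if (length(unit) == 0L) {
    zr_data_error("table must contain a `zip_id` or `county_id` column.")
  }
  unit[[1L]]
}

# Sample skewness (bias-corrected, as in SAS/e1071 type 2).
zr_skewness <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) return(NA_real_)
  e1071::skewness(x, type = 2)
}
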