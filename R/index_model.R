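#' Fit a one-component PCA analog score for one subdomain
#'
#' PCA on the correlation matrix of the subdomain's retained measures
#' (complete-case units), keeping the first component. Scores are the
#' standardized first-component scores (mean 0, sample SD 1). The
#' eigenvector's arbitrary sign is fixed by alignment with the adverse
#' orientation: the component is flipped so it correlates positively with
#' the mean of the (adverse-oriented, standardized) block measures. A first
#' eigenvalue at or below `eigenvalue_min` means no single component carries
#' the subdomain's common variance — the model premise fails — and raises a
#' `zipranks_error_acceptance` with the eigenvalue diagnostics.
#' Single-measure subdomains pass through as the standardized measure with
#' an undefined (NA) eigenvalue.
#'
#' @param df Standardized measure table (`zip_id` or `county_id` + measure
#'   columns).
#' @param measures Character vector of measure columns forming the block.
#' @param subdomain Subdomain tag (see [zr_subdomains()]).
#' @param reference Optional county reference table; when supplied, the
#'   positive-correlation check against the subdomain reference is recorded
#'   in `sign_aligned`.
#' @param min_units Minimum complete-case units (default 10).
#' @param eigenvalue_min Acceptance floor for the first eigenvalue
#'   (default 1).
#' @return A `zr_subdomain_scores` object: `subdomain`, `level`, `loadings`,
#'   `eigenvalue`, `explained_share`, `scores` (tibble of unit id + `score`),
#'   `sign_aligned`, `n_units`, `measures`.
#' @export
fit_subdomain_pca <- function(df, measures, subdomain,
                              reference = NULL,
                              min_units = 10L, eigenvalue_min = 1) {
  unit_col <- zr_unit_col(df)
  level <- if (unit_col == "county_id") "county" else "zip"
  missing_m <- setdiff(measures, names(df))
  if (length(missing_m) > 0L) {
    zr_data_error(sprintf("measure(s) absent from table: %s",
                          paste(missing_m, collapse = ", ")))
  }
  block <- df[c(unit_col, measures)]
  block <- block[complete.cases(block), ]
  n <- nrow(block)
  if (n < min_units) {
    zr_data_error(sprintf("subdomain '%s' has %d complete units (need >= %d).",
                          subdomain, n, min_units))
  }
  x <- as.matrix(block[measures])
  if (length(measures) == 1L) {
    z <- (x[, 1] - mean(x[, 1])) / sd(x[, 1])
    res <- list(subdomain = subdomain, level = level,
                loadings = setNames(1, measures),
                eigenvalue = NA_real_, explained_share = 1,
                scores = tibble(!!unit_col := block[[unit_col]], score = z),
                sign_aligned = TRUE, n_units = n, measures = measures)
  } else {
    pca <- prcomp(x, center = TRUE, scale. = TRUE)
    ev <- pca$sdev^2
    if (ev[1] <= eigenvalue_min) {
      zr_acceptance_error(
        sprintf("subdomain '%s': first eigenvalue %.4f <= %.2f; no dominant common component.",
                subdomain, ev[1], eigenvalue_min),
        eigenvalues = ev)
    }
    scores <- pca$x[, 1] / pca$sdev[1]
    loadings <- pca$rotation[, 1]
    # standardized block mean gives the adverse orientation of the block;
    # if the component is orthogonal to it (a contrast), fall back to making
    # the largest-magnitude loading positive so the sign stays deterministic
    zblock <- scale(x)
    r_mean <- cor(scores, rowMeans(zblock))
    flip <- if (abs(r_mean) > 1e-8) r_mean < 0 else {
      lead <- which.max(abs(loadings))
      loadings[lead] < 0
    }
    if (flip) {
      scores <- -scores
      loadings <- -loadings
    }
    res <- list(subdomain = subdomain, level = level,
                loadings = loadings,
                eigenvalue = ev[1], explained_share = ev[1] / sum(ev),
                scores = tibble(!!unit_col := block[[unit_col]], score = unname(scores)),
                sign_aligned = TRUE, n_units = n, measures = measures)
  }
  if (!is.null(reference) && subdomain %in% names(reference) && level == "county") {
    chk <- dplyr::inner_join(res$scores, reference[c("county_id", subdomain)],
                             by = "county_id")
    r_ref <- cor(chk$score, chk[[subdomain]], use = "complete.obs")
    res$sign_aligned <- isTRUE(r_ref > 0)
    if (!res$sign_aligned) {
      warn(sprintf("subdomain '%s': adverse-aligned scores correlate negatively (r = %.3f) with the county reference.",
                   subdomain, r_ref),
           class = "zipranks_warning_sign")
    }
  }
  structure(res, class = "zr_subdomain_scores")
}

#' @export
print.zr_subdomain_scores <- function(x, ...) {
  cat(sprintf("<zr_subdomain_scores> %s (%s level): %d units, eigenvalue %s, %d measures\n",
              x$subdomain, x$level, x$n_units,
              ifelse(is.na(x$eigenvalue), "NA (single measure)",
                     sprintf("%.3f", x$eigenvalue)),
              length(x$measures)))
  invisible(x)
}

#' Fit analog scores for every subdomain with retained measures
#'
#' @param df Standardized measure table.
#' @param definitions Measure definitions.
#' @param retained Character vector of retained measure names.
#' @param reference Optional county reference table for the sign check.
#' @inheritParams fit_subdomain_pca
#' @return A named list of `zr_subdomain_scores`, one per subdomain.
#' @export
fit_subdomain_scores <- function(df, definitions, retained,
                                 reference = NULL, min_units = 10L,
                                 eigenvalue_min = 1) {
  defs <- definitions[definitions$name %in% retained, ]
  subs <- intersect(names(zr_subdomains()), unique(defs$subdomain))
  sets <- purrr::map(subs, function(s) {
    fit_subdomain_pca(df, defs$name[defs$subdomain == s], s,
                      reference = reference, min_units = min_units,
                      eigenvalue_min = eigenvalue_min)
  })
  setNames(sets, subs)
}

#' Collect subdomain analog scores into a wide table
#'
#' @param sets A named list of `zr_subdomain_scores`.
#' @return A wide tibble: unit id column + one column per subdomain.
#' @export
subdomain_scores_table <- function(sets) {
  unit_col <- names(sets[[1]]$scores)[1]
  purrr::reduce(purrr::imap(sets, function(s, nm) {
    dplyr::rename(s$scores, !!nm := "score")
  }), dplyr::full_join, by = unit_col) |>
    dplyr::arrange(.data[[unit_col]])
}

#' Calibrate a domain regression at county level
#'
#' Ordinary least squares of the county reference domain score on the
#' derived subdomain analog scores. The Health Factors model uses the four
#' factor subdomains (behavior, clinical access, environment,
#' socioeconomic). The Health Outcomes model uses mortality, quality of
#' life, and `predicted_hf` — the fitted values of the already-calibrated
#' Health Factors model on the same counties — so it cannot be fitted
#' before the HF model exists. Fitted values are stored as the county
#' analog domain scores.
#'
#' @param scores A wide county subdomain score table
#'   ([subdomain_scores_table()]).
#' @param reference County reference table containing the domain column.
#' @param domain `"health_factors"` or `"health_outcomes"`.
#' @param hf_model The fitted HF `zr_domain_model` (required for HO).
#' @param min_units Minimum complete counties (default 20).
#' @return A `zr_domain_model`: `domain`, `intercept`, `coefficients`,
#'   `r_squared`, `n_fit`, `fitted` (tibble `county_id`, `score`), and the
#'   underlying `lm` fit.
#' @export
fit_domain_regression <- function(scores, reference, domain,
                                  hf_model = NULL, min_units = 20L) {
  domain <- match.arg(domain, c("health_factors", "health_outcomes"))
  if (domain == "health_factors") {
    predictors <- c("behavior", "clinical_access", "environment", "socioeconomic")
  } else {
    if (is.null(hf_model) || !inherits(hf_model, "zr_domain_model") ||
        hf_model$domain != "health_factors") {
      zr_config_error("the Health Outcomes model requires the fitted Health Factors model (`hf_model`).")
    }
    predictors <- c("mortality", "quality_of_life", "predicted_hf")
  }
  dat <- scores
  if (domain == "health_outcomes") {
    hf_pred <- score_domains(scores, hf_model)
    dat <- dplyr::left_join(dat, dplyr::rename(hf_pred, predicted_hf = "score"),
                            by = "county_id")
  }
  missing_p <- setdiff(predictors, names(dat))
  if (length(missing_p) > 0L) {
    zr_data_error(sprintf("missing predictor subdomain(s): %s",
                          paste(missing_p, collapse = ", ")))
  }
  dat <- dplyr::inner_join(dat[c("county_id", predictors)],
                           reference[c("county_id", domain)], by = "county_id")
  dat <- dat[complete.cases(dat), ]
  if (nrow(dat) < min_units) {
    zr_fit_error(sprintf("only %d complete counties for the %s regression (need >= %d).",
                         nrow(dat), domain, min_units))
  }
  X <- as.matrix(dat[predictors])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    zr_fit_error(sprintf("rank-deficient predictor block for %s (rank %d of %d); condition number %.3g.",
                         domain, qrX$rank, ncol(X) + 1L, kappa(cbind(1, X))))
  }
  fml <- as.formula(paste(domain, "~", paste(predictors, collapse = " + ")))
  fit <- lm(fml, data = dat)
  structure(list(
    domain = domain,
    intercept = unname(coef(fit)[1]),
    coefficients = coef(fit)[-1],
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_fit = nrow(dat),
    fitted = tibble(county_id = dat$county_id, score = unname(fitted(fit))),
    fit = fit
  ), class = "zr_domain_model")
}

#' @export
print.zr_domain_model <- function(x, ...) {
  cat(sprintf("<zr_domain_model> %s: n = %d, R^2 = %.3f\n",
              x$domain, x$n_fit, x$r_squared))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Score ZIP-level subdomains
#'
#' Refits the PCA independently at ZIP level on the retained measures
#' (`method = "refit"`, the default, matching a from-scratch ZIP analysis),
#' or projects the ZIP measures onto the county-level loadings
#' (`method = "project"`), then standardizes and sign-aligns either way.
#'
#' @param zip_measures Standardized ZIP measure table.
#' @param definitions Measure definitions.
#' @param retained Retained measure names from screening.
#' @param method `"refit"` or `"project"`.
#' @param county_sets County `zr_subdomain_scores` list (required for
#'   projection).
#' @param min_units Minimum complete ZIPs (default 30).
#' @inheritParams fit_subdomain_pca
#' @return A named list of ZIP-level `zr_subdomain_scores`.
#' @export
score_zip_subdomains <- function(zip_measures, definitions, retained,
                                 method = c("refit", "project"),
                                 county_sets = NULL, min_units = 30L,
                                 eigenvalue_min = 1) {
  method <- match.arg(method)
  if (method == "refit") {
    return(fit_subdomain_scores(zip_measures, definitions, retained,
                                min_units = min_units,
                                eigenvalue_min = eigenvalue_min))
  }
  if (is.null(county_sets)) {
    zr_config_error("projection mode requires `county_sets`.")
  }
  sets <- purrr::imap(county_sets, function(cs, s) {
    block <- zip_measures[c("zip_id", cs$measures)]
    block <- block[complete.cases(block), ]
    if (nrow(block) < min_units) {
      zr_data_error(sprintf("subdomain '%s' has %d complete ZIPs (need >= %d).",
                            s, nrow(block), min_units))
    }
    x <- scale(as.matrix(block[cs$measures]))
    raw <- as.numeric(x %*% cs$loadings)
    z <- (raw - mean(raw)) / sd(raw)
    if (length(cs$measures) > 1L && cor(z, rowMeans(x)) < 0) z <- -z
    structure(list(subdomain = s, level = "zip", loadings = cs$loadings,
                   eigenvalue = cs$eigenvalue,
                   explained_share = cs$explained_share,
                   scores = tibble(zip_id = block$zip_id, score = z),
                   sign_aligned = TRUE, n_units = nrow(block),
                   measures = cs$measures),
              class = "zr_subdomain_scores")
  })
  sets
}

#' Compute domain scores from subdomain scores and a calibrated model
#'
#' `score = intercept + sum(coefficient * subdomain score)`, linear in
#' every input. For the Health Outcomes model the `predicted_hf` predictor
#' is computed from `hf_model` on the same subdomain scores (at ZIP level
#' this is the ZIP-level HF score). Units missing any predictor are emitted
#' as missing with a message.
#'
#' @param scores Wide subdomain score table (county or ZIP level).
#' @param model A `zr_domain_model`.
#' @param hf_model The HF model, required when `model` is the HO model and
#'   `scores` lacks a `predicted_hf` column.
#' @return A tibble: unit id column + `score`.
#' @export
score_domains <- function(scores, model, hf_model = NULL) {
  stopifnot(inherits(model, "zr_domain_model"))
  unit_col <- zr_unit_col(scores)
  dat <- scores
  if (model$domain == "health_outcomes" && !"predicted_hf" %in% names(dat)) {
    if (is.null(hf_model)) {
      zr_config_error("scoring the Health Outcomes model requires `hf_model` (or a `predicted_hf` column).")
    }
    hf <- score_domains(dat, hf_model)
    dat <- dplyr::left_join(dat, dplyr::rename(hf, predicted_hf = "score"),
                            by = unit_col)
  }
  predictors <- names(model$coefficients)
  missing_p <- setdiff(predictors, names(dat))
  if (length(missing_p) > 0L) {
    zr_data_error(sprintf("missing predictor subdomain(s): %s",
                          paste(missing_p, collapse = ", ")))
  }
  X <- as.matrix(dat[predictors])
  score <- model$intercept + as.numeric(X %*% model$coefficients)
  n_missing <- sum(is.na(score))
  if (n_missing > 0) {
    inform(sprintf("%d unit(s) missing a predictor emitted as NA for %s.",
                   n_missing, model$domain))
  }
  tibble(!!unit_col := dat[[unit_col]], score = score)
}

#' Combine subdomain scores with fixed weights
#'
#' The alternative combiner: a fixed-weight sum of standardized subdomain
#' analog scores (standard CHR-style weighting), instead of the regression
#' calibration. Weights must be nonnegative and sum to 1.
#'
#' @param scores Wide subdomain score table.
#' @param weights Named nonnegative weights over subdomains, summing to 1.
#' @return A tibble: unit id column + `score`.
#' @export
combine_fixed_weights <- function(scores, weights) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    zr_config_error("`weights` must be nonnegative and sum to 1 (within 1e-9).")
  }
  unit_col <- zr_unit_col(scores)
  missing_s <- setdiff(names(weights), names(scores))
  if (length(missing_s) > 0L) {
    zr_data_error(sprintf("missing subdomain column(s): %s",
                          paste(missing_s, collapse = ", ")))
  }
  X <- as.matrix(scores[names(weights)])
  tibble(!!unit_col := scores[[unit_col]],
         score = as.numeric(X %*% weights))
}
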