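test_that("k-tile assignment follows the size and direction conventions", {
  df <- tibble::tibble(county_id = sprintf("29%03d", 1:10), score = c(10:1))
  t5 <- assign_ktiles(df, k = 5)
  expect_equal(unname(table(t5$tile)), rep(2L, 5), ignore_attr = TRUE)
  # best health (lowest score) is tile 1
  expect_equal(t5$tile[which.min(t5$score)], 1L)
  expect_equal(t5$tile[which.max(t5$score)], 5L)

  # 114 units: 23/23/23/23/22 with the larger tiles at the best-health end
  df114 <- tibble::tibble(county_id = sprintf("29%03d", 1:114), score = seq_len(114))
  t114 <- assign_ktiles(df114, k = 5)
  expect_equal(as.integer(table(t114$tile)), c(23L, 23L, 23L, 23L, 22L))

  # reversed direction flag
  trev <- assign_ktiles(df, k = 5, best_is_low = FALSE)
  expect_equal(trev$tile[which.max(trev$score)], 1L)

  # all-tied scores collapse to one tile and are flagged degenerate
  dft <- tibble::tibble(county_id = sprintf("29%03d", 1:10), score = rep(1, 10))
  expect_warning(tt <- assign_ktiles(dft, k = 5),
                 class = "zipranks_warning_degenerate_tiles")
  expect_equal(length(unique(tt$tile)), 1L)
  expect_true(isTRUE(attr(tt, "degenerate")))

  expect_error(assign_ktiles(df, k = 1), class = "zipranks_error_config")
  expect_error(assign_ktiles(df[1:3, ], k = 5), class = "zipranks_error_data")
})

test_that("cross-classification counts pairs exactly", {
  df <- tibble::tibble(county_id = sprintf("29%03d", 1:20), score = 1:20)
  ta <- assign_ktiles(df, k = 4)
  # identical assignments: diagonal table
  tab_same <- cross_classify(ta, ta)
  expect_equal(tab_same, diag(5, 4), ignore_attr = TRUE, tolerance = 1e-12)
  # reversed assignments: anti-diagonal table
  tb <- assign_ktiles(dplyr::mutate(df, score = -score), k = 4)
  tab_rev <- cross_classify(ta, tb)
  expect_equal(tab_rev[, 4:1], diag(5, 4), ignore_attr = TRUE, tolerance = 1e-12)
  # random assignments vs loop oracle
  withr::with_seed(3, {
    tr1 <- dplyr::mutate(ta, tile = sample(tile))
    tr2 <- dplyr::mutate(ta, tile = sample(tile))
  })
  tab <- cross_classify(tr1, tr2)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(tab[i, j],
                 sum(tr1$tile == i &
                       tr2$tile[match(tr1$county_id, tr2$county_id)] == j))
  }
  expect_equal(sum(tab), 20L)
  expect_error(cross_classify(ta, tb[1:10, ]), class = "zipranks_error_data")
})

test_that("weighted kappa matches its definition, boundaries, and an oracle", {
  # perfect agreement
  expect_equal(weighted_kappa(diag(4, 5))$kappa, 1)
  # chance agreement: table equal to the outer product of its marginals
  marg <- c(10, 20, 30, 25, 15)
  chance <- outer(marg, marg) / sum(marg)
  expect_equal(weighted_kappa(chance)$kappa, 0, tolerance = 1e-9)
  # symmetry in the two rank vectors
  withr::with_seed(5, tab <- matrix(rpois(25, 4), 5))
  expect_equal(weighted_kappa(tab)$kappa, weighted_kappa(t(tab))$kappa,
               tolerance = 1e-12)
  # linear-weighted kappa on a 2x2 table equals unweighted Cohen's kappa
  t22 <- matrix(c(20, 5, 8, 17), 2)
  po <- sum(diag(t22)) / sum(t22)
  pe <- sum(rowSums(t22) * colSums(t22)) / sum(t22)^2
  cohen <- (po - pe) / (1 - pe)
  expect_equal(weighted_kappa(t22, "linear")$kappa, cohen, tolerance = 1e-12)
  # 500 random tables vs the independent textbook oracle
  withr::with_seed(6, {
    for (i in 1:500) {
      tab <- matrix(rpois(25, sample(1:8, 1)), 5)
      if (sum(tab) == 0) tab[1, 1] <- 1
      scheme <- if (i %% 2 == 0) "linear" else "quadratic"
      expect_equal(weighted_kappa(tab, scheme)$kappa,
                   oracle_weighted_kappa(tab, scheme), tolerance = 1e-10)
    }
  })
  # significance behaves sensibly: strong diagonal -> small p
  strong <- diag(20, 5) + 1
  wk <- weighted_kappa(strong)
  expect_lt(wk$p_value, 1e-6)
  expect_error(weighted_kappa(matrix(0, 3, 3)), class = "zipranks_error_data")
})

test_that("within-band agreement counts the stated bands and is monotone", {
  expect_equal(within_band_agreement(diag(4, 5), 0), 1)
  expect_equal(within_band_agreement(diag(4, 5), 3), 1)
  # hand-built 3x3 table: diag 4s, one adjacent 2, one corner 1; n = 15
  tab <- matrix(0, 3, 3)
  diag(tab) <- 4
  tab[1, 2] <- 2
  tab[3, 1] <- 1
  expect_equal(within_band_agreement(tab, 1), (12 + 2) / 15)
  expect_equal(within_band_agreement(tab, 0), 12 / 15)
  expect_equal(within_band_agreement(tab, 2), 1)
  # monotone in band
  withr::with_seed(7, rtab <- matrix(rpois(25, 3), 5))
  bands <- vapply(0:4, function(b) within_band_agreement(rtab, b), numeric(1))
  expect_true(all(diff(bands) >= 0))
  expect_error(within_band_agreement(rtab, -1), class = "zipranks_error_config")
})

test_that("correlation reports reproduce the textbook Pearson formula", {
  withr::with_seed(9, {
    df <- tibble::tibble(county_id = sprintf("29%03d", 1:50),
                         health_factors = rnorm(50),
                         health_outcomes = rnorm(50))
  })
  same <- correlation_report(df, df)
  expect_equal(same$r[same$analog == same$reference], c(1, 1))
  neg <- correlation_report(df, dplyr::mutate(df, health_factors = -health_factors,
                                              health_outcomes = -health_outcomes))
  expect_equal(neg$r[neg$analog == neg$reference], c(-1, -1))
  # brute-force Pearson on random pairs
  other <- dplyr::mutate(df, health_factors = rnorm(50), health_outcomes = rnorm(50))
  rep <- correlation_report(df, other)
  for (row in seq_len(nrow(rep))) {
    a <- df[[rep$analog[row]]]
    b <- other[[rep$reference[row]]]
    r_hand <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(rep$r[row], r_hand, tolerance = 1e-12)
  }
  expect_error(correlation_report(df, dplyr::mutate(df, health_factors = 0)),
               class = "zipranks_error_data")
})

test_that("agreement_report combines tiles, kappa, and correlation coherently", {
  withr::with_seed(10, {
    n <- 114
    a <- tibble::tibble(county_id = sprintf("29%03d", 1:n), score = rnorm(n))
    b <- dplyr::mutate(a, score = score + rnorm(n, sd = 0.5))
  })
  rep <- agreement_report(a, b, k = 5)
  expect_equal(sum(rep$cross_table), n)
  expect_equal(rep$exact_agreement, sum(diag(rep$cross_table)) / n)
  expect_gte(rep$within_band, rep$exact_agreement)
  expect_gt(rep$weighted_kappa, 0)
  expect_equal(rep$weighted_kappa,
               oracle_weighted_kappa(rep$cross_table, "linear"), tolerance = 1e-10)
  # self-agreement is perfect
  self <- agreement_report(a, a)
  expect_equal(self$weighted_kappa, 1)
  expect_equal(self$exact_agreement, 1)
})

test_that("intracounty variation counts spanning and top-bottom counties", {
  # construction: 20 counties x 5 zips; counties 1-3 span both extremes
  k <- 5
  zips <- tibble::tibble(
    zip_id = sprintf("%05d", 1:100),
    county_id = rep(sprintf("29%03d", 1:20), each = 5))
  zip_tiles <- zips
  zip_tiles$tile <- rep(3L, 100)
  for (ci in 1:3) {
    rows <- which(zip_tiles$county_id == sprintf("29%03d", ci))
    zip_tiles$tile[rows[1]] <- 1L
    zip_tiles$tile[rows[2]] <- 5L
  }
  county_tiles <- tibble::tibble(county_id = sprintf("29%03d", 1:20),
                                 tile = rep(1:5, each = 4))
  mapping <- dplyr::distinct(zips[c("zip_id", "county_id")])
  iv <- intracounty_variation(zip_tiles, county_tiles, mapping, k = 5)
  expect_equal(iv$spanning_count, 3L)
  expect_equal(iv$spanning_prop, 0.15)
  # counties 1-3 are in the top 2 county tiles (tiles 1-2 cover counties 1-8)
  expect_equal(iv$top2_n, 8L)
  expect_equal(iv$top2_with_bottom2_count, 3L)
  expect_equal(iv$top2_with_bottom2_prop, 3 / 8)
  # no intracounty spread: both counts zero
  flat_tiles <- dplyr::mutate(
    dplyr::inner_join(zips, county_tiles, by = "county_id"), tile = tile)
  iv0 <- intracounty_variation(flat_tiles[c("zip_id", "tile")] |>
                                 dplyr::mutate(county_id = zips$county_id),
                               county_tiles, mapping, k = 5)
  expect_equal(iv0$spanning_count, 0L)
  expect_equal(iv0$top2_with_bottom2_count, 0L)
  # random fixture vs set-membership loop oracle
  withr::with_seed(11, {
    zr <- dplyr::mutate(zips, tile = sample(1:5, 100, replace = TRUE))
    cr <- dplyr::mutate(county_tiles, tile = sample(1:5, 20, replace = TRUE))
  })
  ivr <- intracounty_variation(zr, cr, mapping, k = 5)
  span <- 0
  for (ci in cr$county_id) {
    tl <- zr$tile[zr$county_id == ci]
    if (any(tl == 1) && any(tl == 5)) span <- span + 1
  }
  expect_equal(ivr$spanning_count, span)
  expect_error(intracounty_variation(zr, cr, mapping[1:50, ], k = 5),
               class = "zipranks_error_data")
})
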