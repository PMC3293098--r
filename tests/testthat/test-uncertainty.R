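test_that("draw summaries match hand arithmetic and closed-form quantiles", {
  d <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "x"))
  s <- summarize_draws(d)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)

  konst <- matrix(rep(7, 50), ncol = 1, dimnames = list(NULL, "x"))
  sk <- summarize_draws(konst)
  expect_equal(sk$sd, 0)
  expect_equal(c(sk$cr_low, sk$cr_high), c(7, 7))

  set.seed(99)
  z <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "z"))
  sz <- summarize_draws(z)
  expect_equal(sz$cr_low, -1.96, tolerance = 0.05)
  expect_equal(sz$cr_high, 1.96, tolerance = 0.05)

  expect_error(summarize_draws(d, percentiles = c(97.5, 2.5)), "percentiles")
  expect_error(summarize_draws(d[0, , drop = FALSE]), "at least one draw")
})

test_that("a degenerate PSA (all ranges collapsed) reproduces the base case exactly", {
  study <- toy_study(p_mean = 0.3, p_low = 0.3, p_high = 0.3,
                     cost = 100, cost_low = 100, cost_high = 100)
  psa <- run_psa(study, iterations = 25, seed = 3)
  rb <- rollback(study)
  s <- psa$summary
  expect_equal(s$mean, rb$cost)
  expect_true(all(s$sd == 0))
  expect_equal(s$cr_low, s$mean)
  expect_equal(s$cr_high, s$mean)
})

test_that("the PSA is seed-reproducible and keeps per-draw audit material", {
  study <- uganda_study()
  a <- run_psa(study, iterations = 150, seed = 42, keep_draws = TRUE)
  b <- run_psa(study, iterations = 150, seed = 42, keep_draws = TRUE)
  expect_identical(a$summary, b$summary)
  expect_identical(a$category_draws, b$category_draws)
  expect_identical(a$parameter_draws, b$parameter_draws)
  c2 <- run_psa(study, iterations = 150, seed = 43)
  expect_false(identical(a$summary, c2$summary))

  # draws respect domains: probabilities in [0,1], costs nonnegative
  kinds <- setNames(study$parameters$kind, study$parameters$id)
  pd <- a$parameter_draws
  pcols <- colnames(pd)[kinds[colnames(pd)] == "probability"]
  ccols <- colnames(pd)[kinds[colnames(pd)] == "cost"]
  expect_true(all(pd[, pcols] >= 0 & pd[, pcols] <= 1))
  expect_true(all(pd[, ccols] >= 0))
})

test_that("PSA means converge to the base case for the linear model", {
  study <- uganda_study()
  psa <- run_psa(study, iterations = 4000, seed = 7)
  rb <- rollback(study)
  s <- dplyr::left_join(psa$summary, rb, by = "category")
  # beta/normal draws are mean-preserving and the model is multilinear, so
  # category means sit within Monte Carlo error of the deterministic rollback
  bound <- pmax(4 * s$sd / sqrt(psa$iterations), 1e-9)
  expect_true(all(abs(s$mean - s$cost) <= bound))
})

test_that("tornado sweeps reproduce forced arithmetic and rank unused parameters last", {
  study <- toy_study(p_mean = 0.5, p_low = 0.1, p_high = 0.9, cost = 100)
  tor <- run_tornado(study, top_k = Inf)
  entry <- tor[tor$parameter == "p", ]
  expect_equal(entry$cost_low, 10)
  expect_equal(entry$cost_high, 90)
  expect_equal(entry$spread, 80)
  expect_equal(entry$rank, 1)

  # degenerate range: spread 0, ranked last
  study2 <- toy_study(p_mean = 0.5, p_low = 0.5, p_high = 0.5,
                      cost = 100, cost_low = 50, cost_high = 150)
  tor2 <- run_tornado(study2, top_k = Inf)
  expect_equal(tor2$spread[tor2$parameter == "p"], 0)
  expect_equal(tor2$rank[tor2$parameter == "p"], nrow(tor2))
})

test_that("parameters no path uses have spread exactly zero in the packaged study", {
  study <- uganda_study()
  tor <- run_tornado(study, top_k = Inf)
  unused <- c("p_untrained", "p_outpatient_care", "p_miscarriage_lt13")
  expect_true(all(tor$spread[tor$parameter %in% unused] == 0))
  used <- tor$spread[tor$parameter == "p_mort_hospital"]
  expect_gt(used, 0)
  # spreads are non-increasing down the ranking
  expect_true(all(diff(tor$spread) <= 1e-12))
})

test_that("the per-draw ledger identity holds for every iteration", {
  study <- uganda_study()
  psa <- run_psa(study, iterations = 500, seed = 5)
  cd <- psa$category_draws
  gap <- cd[, "direct_medical"] + cd[, "direct_non_medical"] + cd[, "indirect"] -
    cd[, "societal"]
  expect_lt(max(abs(gap)), 1e-9)
  payer_gap <- cd[, "patient"] + cd[, "government"] + cd[, "unallocated"] -
    (cd[, "direct_medical"] + cd[, "direct_non_medical"])
  expect_lt(max(abs(payer_gap)), 1e-9)
})

test_that("broom-style accessors and plots expose the PSA and tornado results", {
  study <- uganda_study()
  psa <- run_psa(study, iterations = 100, seed = 2)
  td <- tidy(psa)
  expect_equal(td$category, cost_categories())
  expect_true(all(c("mean", "sd", "cr_low", "cr_high", "min", "max") %in% names(td)))
  expect_true(all(td$min <= td$cr_low & td$cr_low <= td$mean &
                    td$mean <= td$cr_high & td$cr_high <= td$max))
  gl <- glance(psa)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$iterations, 100)

  tor <- run_tornado(study, top_k = 5)
  expect_equal(nrow(tor), 5)
  expect_s3_class(autoplot(psa), "ggplot")
  expect_s3_class(autoplot(tor), "ggplot")
})
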