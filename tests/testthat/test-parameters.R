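test_that("standard errors follow the range/4 rule and its algebra", {
  expect_equal(derive_se(0.14, 0.21), 0.0175)
  expect_equal(derive_se(5, 5), 0)
  expect_equal(derive_se(139.6, 223.3), 20.925)
  expect_error(derive_se(0.3, 0.1, id = "p_bad"), "p_bad")

  # translation invariance and linear scaling
  set.seed(11)
  for (i in 1:25) {
    l <- runif(1, -5, 5); h <- l + runif(1, 0, 3)
    c0 <- runif(1, -2, 2); k <- runif(1, 0.1, 4)
    expect_equal(derive_se(l + c0, h + c0), derive_se(l, h))
    expect_equal(derive_se(k * l, k * h), k * derive_se(l, h))
  }
})

test_that("fitted beta distributions reproduce the mean and standard error", {
  params <- tibble::tibble(
    id = c("p1", "p2", "c1"),
    label = id, kind = c("probability", "probability", "cost"),
    mean = c(0.44, 0.5, 65), low = c(0.21, 0.5, 65 - 4 * 9.4),
    high = c(0.52, 0.5, 65 + 0), source = "test"
  )
  params$high[3] <- 65 + 2 * 9.4 # asymmetric placement is irrelevant: se = width/4
  params$low[3] <- 65 - 2 * 9.4
  fit <- fit_distributions(params)

  b <- fit[fit$id == "p1", ]
  expect_equal(b$family, "beta")
  a <- b$shape1; bb <- b$shape2
  expect_equal(a / (a + bb), 0.44, tolerance = 1e-9)
  expect_equal(sqrt(a * bb / ((a + bb)^2 * (a + bb + 1))), b$se, tolerance = 1e-6)
  # method-of-moments shapes recomputed independently
  v <- ((0.52 - 0.21) / 4)^2
  k <- 0.44 * (1 - 0.44) / v - 1
  expect_equal(a, 0.44 * k)
  expect_equal(bb, (1 - 0.44) * k)

  expect_equal(fit$family[fit$id == "p2"], "point")
  n <- fit[fit$id == "c1", ]
  expect_equal(n$family, "normal")
  expect_equal(n$sd, 9.4)
})

test_that("beta moment-condition violations are clamped with a warning, preserving the mean", {
  params <- tibble::tibble(
    id = "p_wide", label = "wide", kind = "probability",
    mean = 0.03, low = 0, high = 1, source = "test"
  )
  expect_warning(fit <- fit_distributions(params), "p_wide")
  expect_equal(fit$shape1 / (fit$shape1 + fit$shape2), 0.03, tolerance = 1e-9)
  expect_lt(fit$sd, sqrt(0.03 * 0.97))
  expect_gt(fit$shape1, 0)
})

test_that("provider shares collapse to training probability and renormalized conditionals", {
  shares <- c(
    doctor = 0.20, clinical_officer = 0.17, nurse_midwife = 0.19,
    dispenser = 0.07, lay_practitioner = 0.22, self_induction = 0.15
  )
  d <- derive_provider_probabilities(shares)
  expect_equal(d$p_trained, 0.56)
  expect_equal(round(d$trained$share[d$trained$provider == "doctor"], 2), 0.36)
  expect_equal(sum(d$trained$share), 1, tolerance = 1e-12)
  expect_equal(sum(d$untrained$share), 1, tolerance = 1e-12)
  expect_false(d$degenerate)

  # conditionals sum to 1 for arbitrary valid share maps
  set.seed(7)
  for (i in 1:30) {
    s <- runif(6, 0.01, 1)
    s <- s / sum(s)
    names(s) <- names(shares)
    di <- derive_provider_probabilities(s)
    expect_equal(sum(di$trained$share), 1, tolerance = 1e-12)
    expect_equal(sum(di$untrained$share), 1, tolerance = 1e-12)
    expect_true(di$p_trained >= 0 && di$p_trained <= 1)
  }

  # all mass in one group is degenerate but not an error
  one <- c(doctor = 0.5, clinical_officer = 0.3, nurse_midwife = 0.2,
           dispenser = 0, lay_practitioner = 0, self_induction = 0)
  expect_true(derive_provider_probabilities(one)$degenerate)
  expect_equal(nrow(derive_provider_probabilities(one)$untrained), 0)
  expect_error(derive_provider_probabilities(shares[-1]), "doctor")
})

test_that("count-derived probabilities match the published fractions", {
  expect_equal(round(derive_failure_probability(8, 47), 2), 0.17)
  expect_equal(derive_failure_probability(0, 47), 0)
  expect_equal(derive_failure_probability(47, 47), 1)
  expect_error(derive_failure_probability(5, 0))
  expect_equal(round(derive_hospitalization_fraction(47828, 109926), 4), 0.4351)
  expect_equal(derive_hospitalization_fraction(0, 10), 0)
  expect_equal(derive_hospitalization_fraction(10, 10), 1)
})

test_that("the packaged study file loads, validates, and round-trips", {
  p <- uganda_parameters()
  expect_equal(sum(p$kind == "probability"), 27)
  expect_equal(sum(p$kind == "cost"), 24)
  expect_equal(p$se, (p$high - p$low) / 4)

  f <- tempfile(fileext = ".csv")
  write_parameters(p, f)
  p2 <- read_parameters(f)
  expect_tibble_equal(p[order(p$id), names(p2)], p2[order(p2$id), ], tol = 0)

  cs <- uganda_constants()
  expect_equal(cs$gdp_per_capita, 474.27)
  expect_equal(cs$annual_incidence, 362000)
})

test_that("validation aggregates all offending rows into one error", {
  p <- uganda_parameters()
  bad <- p
  bad$low[bad$id == "p_access"] <- 0.9 # low > high
  bad$kind[bad$id == "c_anc"] <- "fee" # unknown kind
  bad <- dplyr::bind_rows(bad, bad[bad$id == "p_trained", ]) # duplicate
  err <- tryCatch(validate_parameters(bad), error = conditionMessage)
  expect_match(err, "p_access")
  expect_match(err, "c_anc")
  expect_match(err, "p_trained")

  expect_error(validate_parameters(p[0, ]), "no parameters")
  neg <- p
  neg$low[neg$id == "c_anc"] <- -1
  neg$mean[neg$id == "c_anc"] <- -0.5
  expect_error(validate_parameters(neg), "c_anc")
})
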