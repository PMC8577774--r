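# Test densities, modality counting, MISE machinery, cross-validation.

test_that("every test density integrates to one", {
  for (id in 1:15) {
    td <- test_density(id)
    total <- integrate(td$pdf, td$support[1], td$support[2],
                       rel.tol = 1e-12, subdivisions = 2000)$value
    expect_equal(total, 1, tolerance = 1e-8, label = sprintf("case %d", id))
  }
  expect_error(test_density(16), "unknown")
})

test_that("closed-form values and truncation masses are right", {
  expect_equal(test_density(1)$pdf(0), 1 / sqrt(2 * pi))
  td13 <- test_density(13)
  expect_lt(td13$trunc_mass, 1)
  # case 13 is case 6 renormalised on [-2, 2]
  td6 <- test_density(6)
  expect_equal(td13$pdf(0.5), td6$pdf(0.5) / td13$trunc_mass)
  expect_equal(td13$pdf(2.5), 0)
  # case 15: gamma-normal mixture jointly renormalised on [0, Inf)
  td15 <- test_density(15)
  m15 <- 0.8 + 0.2 * pnorm(0, 2, 0.15, lower.tail = FALSE)
  expect_equal(td15$trunc_mass, m15)
  expect_equal(td15$pdf(1), (0.8 * dgamma(1, 2, 2) +
                             0.2 * dnorm(1, 2, 0.15)) / m15)
})

test_that("samplers reproduce the analytic mixture moments", {
  set.seed(50)
  N <- 1e5
  for (id in c(2, 7, 14)) {
    td <- test_density(id)
    x <- td$sampler(N)
    se_mean <- sqrt(td$var / N)
    expect_lt(abs(mean(x) - td$mean), 4 * se_mean)
    se_var <- td$var * sqrt(2 / N) * 3    # generous for non-normal kurtosis
    expect_lt(abs(var(x) - td$var), 4 * se_var)
  }
  # truncated case: moments from numerical integration of the exact pdf
  td <- test_density(15)
  x <- td$sampler(N)
  m1 <- integrate(function(t) t * td$pdf(t), 0, 20, rel.tol = 1e-12)$value
  m2 <- integrate(function(t) t^2 * td$pdf(t), 0, 20, rel.tol = 1e-12)$value
  expect_lt(abs(mean(x) - m1), 4 * sqrt((m2 - m1^2) / N))
  expect_true(all(x >= 0))
})

test_that("analytic pdf derivatives match finite differences", {
  h <- 1e-6
  for (id in c(2, 14, 15)) {
    td <- test_density(id)
    g <- seq(td$support[1] + 0.05, min(td$support[2], 6) - 0.05,
             length.out = 41)
    d <- td$deriv(g)
    fd1 <- (td$pdf(g + h) - td$pdf(g - h)) / (2 * h)
    expect_equal(d$f1, fd1, tolerance = 1e-6 * max(abs(fd1)))
    fd2 <- (td$pdf(g + h) - 2 * td$pdf(g) + td$pdf(g - h)) / h^2
    expect_equal(d$f2, fd2, tolerance = 1e-3 * max(abs(fd2)))
  }
})

test_that("mode and bump counting matches the known modality", {
  expect_equal(unname(count_modes_bumps(test_density(1), c(-3.5, 3.5))),
               c(1, 1))
  # unimodal density with two bumps
  expect_equal(unname(count_modes_bumps(test_density(5), c(-4, 6))), c(1, 2))
  expect_equal(unname(count_modes_bumps(test_density(7), c(-4, 4)))[1], 2)
  # bumps >= modes always; counts stable under grid refinement
  intervals <- list(`1` = c(-5.5, 5.5), `2` = c(-4, 4), `5` = c(-4, 6),
                    `6` = c(-5.5, 5.5), `7` = c(-4, 4), `8` = c(-0.5, 8),
                    `13` = c(-2, 2), `14` = c(0, 1), `15` = c(0, 4))
  for (id in 1:15) {
    td <- test_density(id)
    iv <- intervals[[as.character(id)]]
    if (is.null(iv)) iv <- td$support
    c1 <- count_modes_bumps(td, iv)
    expect_gte(c1["bumps"], c1["modes"])
    c2 <- count_modes_bumps(td, iv, n_grid = 4003)
    expect_equal(unname(c1), unname(c2), label = sprintf("case %d", id))
  }
})

test_that("the exact density scores a zero MISE and full detection", {
  s <- run_simulation_study(5, 200, 3, estimator = "TRUE",
                            interval = c(-4, 6), seed = 1)
  expect_equal(s$mise, 0)
  expect_equal(s$modes_correct, 3)
  expect_equal(s$bumps_correct, 3)
})

test_that("the squared-error integral is stable under grid refinement", {
  set.seed(51)
  td <- test_density(1)
  x <- td$sampler(500)
  est <- spde(x, td$domain, families = "POL")
  i1 <- spde:::integrated_squared_error(est, td, 4001)
  i2 <- spde:::integrated_squared_error(est, td, 8003)
  expect_lt(abs(i1 - i2) / i2, 0.01)
})

test_that("cross-validated log-likelihood has a brute-force fold oracle", {
  # fixed density: no refitting, plain sum of log densities
  set.seed(52)
  x <- rexp(30)
  expect_equal(loo_cv_loglik(function(t) dexp(t), x), sum(dexp(x, log = TRUE)))
  # one-parameter semi-infinite model: explicit loop over folds
  est <- spde(x, spde_domain("semi_infinite", a = 0), families = "POL",
              boundary_sets = list(character(0)),
              control = spde_control(Pm = 1))
  cv <- loo_cv_loglik(est)
  manual <- 0
  for (n in seq_along(x)) {
    fn <- spde:::refit_structure(est, x[-n])
    manual <- manual + log(density_estimate(fn, x[n]))
  }
  expect_equal(cv, manual, tolerance = 1e-12)
})

test_that("boundary bias vanishes for the exact density", {
  b <- boundary_bias(14, 100, 2, estimator = "TRUE", points = c(0, 1),
                     seed = 1)
  expect_equal(unname(b$bias), c(0, 0))
  # case 14/15 truths are zero at the relevant boundary points
  expect_equal(test_density(14)$pdf(c(0, 1)), c(0, 0))
  expect_equal(test_density(15)$pdf(0), 0)
})

test_that("sample files round-trip and bad input is rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("x", "0.5", "1.25", "-3e-1"), f)
  expect_equal(read_sample(f), c(0.5, 1.25, -0.3))
  writeLines(c("0.5", "", "1.0"), f)
  expect_error(read_sample(f), "blank")
  writeLines(c("0.5", "NaN"), f)
  expect_error(read_sample(f), "NaN|non-numeric")
  set.seed(53)
  est <- spde(rnorm(200), spde_domain("infinite"), families = "POL",
              control = spde_control(Pm = 3))
  out <- tempfile(fileext = ".tsv")
  d <- write_density_grid(est, out, n = 64)
  re <- read.delim(out)
  expect_equal(re$density, d$density)
  expect_equal(nrow(re), 64)
  unlink(c(f, out))
})
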