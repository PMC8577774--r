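# Domain declarations, rescaling, partition function and moments.

test_that("rescaling follows the domain-specific rules", {
  s <- rescale_sample(c(0.5, 1.5), spde_domain("bounded", a = 0, b = 2))
  expect_equal(s$y, c(-0.5, 0.5))
  expect_equal(s$c, 1); expect_equal(s$s, 1)

  s <- rescale_sample(c(-1, 1), spde_domain("infinite"))
  expect_equal(s$y, c(-1, 1))          # mu = 0, population sd = 1

  s <- rescale_sample(c(1, 3), spde_domain("semi_infinite", a = 0))
  expect_equal(s$y, c(0.5, 1.5))       # mu = 2
  expect_equal(mean(s$y), 1)

  x <- rlnorm(50)
  s <- rescale_sample(x, spde_domain("semi_infinite", a = 0))
  expect_equal(mean(s$y), 1)
  expect_true(all(s$y >= 0))
  s <- rescale_sample(x, spde_domain("infinite"))
  expect_equal(mean(s$y), 0)
  expect_equal(sqrt(mean(s$y^2)), 1)
})

test_that("domain violations and degenerate samples are rejected", {
  expect_error(spde_domain("bounded", a = 2, b = 1), "a < b")
  expect_error(spde_domain("bounded", a = 0, b = 1, symmetric = TRUE,
                           periodic = TRUE), "mutually exclusive")
  expect_error(spde_domain("infinite", periodic = TRUE), "bounded")
  expect_error(rescale_sample(c(0.5, 3), spde_domain("bounded", a = 0, b = 2)),
               "outside")
  expect_error(rescale_sample(c(-1, 2), spde_domain("semi_infinite", a = 0)),
               "outside")
  expect_error(rescale_sample(numeric(0), spde_domain("infinite")), "empty")
  expect_error(rescale_sample(rep(2, 5), spde_domain("infinite")),
               "degenerate")
})

test_that("upper-bounded semi-infinite domains are handled by negation", {
  set.seed(1)
  x <- 5 - rexp(2000)
  est_neg <- spde(x, spde_domain("semi_infinite", b = 5), families = "POL",
                  boundary_sets = list(character(0)),
                  control = spde_control(Pm = 3))
  g <- seq(1, 5, length.out = 101)
  expect_equal(density_estimate(est_neg, g),
               rev(density_estimate(est_neg, rev(g))))
  expect_lt(max(abs(density_estimate(est_neg, g) - dexp(5 - g))), 0.05)
})

test_that("trivial potentials give the closed-form partition function", {
  # uniform on [-1, 1]: Z = 2, l = -N log 2, density 1/(b-a) on the x-scale
  x <- c(0.25, 0.5, 1.6)
  m <- make_model(x, spde_domain("bounded", a = 0, b = 2),
                  list(type = "poly", J0 = 0))
  ev <- spde:::model_moments(m, numeric(0))
  expect_equal(ev$Z, 2)
  expect_equal(ev$A, log(2))
  fit <- fit_mle(m)
  expect_equal(fit$loglik, -3 * log(2))
  expect_equal(density_estimate(fit, c(0.1, 1.9)), rep(0.5, 2))

  # semi-infinite with fixed psi giving U(y) = 1 - y: Z0 = e(1 - e^-yb),
  # Z1 = e^(1-yb)/1, Z = e; the normalised density is the unit exponential
  psi <- list(f = function(y) -y, d1 = function(y) rep(-1, length(y)),
              d2 = function(y) rep(0, length(y)))
  sm <- rescale_sample(c(0.5, 1.0, 1.5, 3.0), spde_domain("semi_infinite", a = 0))
  bs <- spde:::assemble_basis(sm, list(type = "none"), psi = psi)
  m <- spde:::new_model(sm, bs)
  ev <- spde:::model_moments(m, numeric(0))
  yb <- sm$yb
  expect_equal(ev$Z0, exp(1) * (1 - exp(-yb)), tolerance = 1e-10)
  expect_equal(ev$Z1, exp(1 - yb), tolerance = 1e-12)
  expect_equal(ev$Z, exp(1), tolerance = 1e-10)
})

test_that("potential evaluation matches the expansion and its tail contract", {
  set.seed(2)
  x <- rnorm(200)
  m <- make_model(x, spde_domain("infinite"), list(type = "poly", J0 = 3))
  alpha <- fit_mle(m)$alpha
  yb <- m$sample$yb; ya <- m$sample$ya
  P <- evaluate_potential(m, c(ya - 0.7, yb + 0.7, yb), alpha)
  # linear continuation beyond the anchors, zero curvature
  expect_equal(P$U[2], P$U[3] + 0.7 * P$U1[3], tolerance = 1e-12)
  expect_equal(P$U2[1], 0)
  expect_equal(P$U2[2], 0)
  # psi contributes directly: U = psi + sum alpha_j phi_j
  psi <- list(f = function(y) log(y), d1 = function(y) 1 / y,
              d2 = function(y) -1 / y^2)
  sm <- rescale_sample(rexp(100) + 0.1, spde_domain("semi_infinite", a = 0))
  bs <- spde:::assemble_basis(sm, list(type = "none"), psi = psi)
  md <- spde:::new_model(sm, bs)
  P2 <- evaluate_potential(md, 2, numeric(0))
  expect_equal(P2$U, log(2) - mean(log(sm$y)))
  expect_equal(P2$U1, 1 / 2)
})

test_that("moments agree with a dense brute-force quadrature oracle", {
  set.seed(3)
  x <- runif(200, -0.9, 0.9)
  m <- make_model(x, spde_domain("bounded", a = -1, b = 1),
                  list(type = "poly", J0 = 4))
  alpha <- c(0.3, -0.5, 0.2, -0.4)
  ev <- spde:::model_moments(m, alpha)
  B <- function(y) spde:::basis_matrices(m$basis, y)
  h <- 2 / 1e6
  yg <- -1 + (seq_len(1e6) - 0.5) * h
  Bg <- B(yg)
  Ug <- drop(Bg$Phi %*% alpha)
  Zo <- sum(exp(Ug)) * h
  expect_equal(ev$Z, Zo, tolerance = 1e-8)
  po <- exp(Ug) / Zo * h
  mo <- drop(crossprod(Bg$Phi, po))
  Qo <- crossprod(Bg$Phi, Bg$Phi * po)
  expect_equal(ev$m, mo, tolerance = 1e-8)
  expect_equal(ev$Q, Qo, tolerance = 1e-8)
})

test_that("analytic tail integrals match adaptive numerical integration", {
  set.seed(4)
  x <- rnorm(500)
  m <- make_model(x, spde_domain("infinite"), list(type = "poly", J0 = 3))
  fit <- fit_mle(m)
  ev <- fit$evaluation
  Ufun <- function(y) exp(evaluate_potential(m, y, fit$alpha)$U - ev$log_offset)
  yb <- m$sample$yb; ya <- m$sample$ya
  s_hi <- abs(ev$slopes[["hi"]]); s_lo <- ev$slopes[["lo"]]
  Z1o <- integrate(Ufun, yb, yb + 40 / s_hi, rel.tol = 1e-12)$value
  Z2o <- integrate(Ufun, ya - 40 / s_lo, ya, rel.tol = 1e-12)$value
  expect_equal(ev$Z1 * exp(-ev$log_offset), Z1o, tolerance = 1e-8)
  expect_equal(ev$Z2 * exp(-ev$log_offset), Z2o, tolerance = 1e-8)
  # slope-condition violation raises a tail-divergence error
  bad <- fit$alpha; bad[1] <- bad[1] + 100
  if (!spde:::admissible(m, bad))
    expect_error(spde:::model_moments(m, bad), "divergence")
})

test_that("likelihood derivatives match finite differences", {
  set.seed(5)
  x <- runif(150, -1, 1)
  m <- make_model(x, spde_domain("bounded", a = -1, b = 1),
                  list(type = "poly", J0 = 3))
  alpha <- c(0.4, -0.3, 0.1)
  d <- log_likelihood_derivatives(m, alpha)
  lfun <- function(a) spde:::model_moments(m, a, "logZ")$l
  g_fd <- fd_gradient(lfun, alpha)
  expect_equal(d$g, g_fd, tolerance = 1e-5 * max(abs(g_fd)))
  H_fd <- fd_hessian(lfun, alpha)
  expect_equal(d$H, H_fd, tolerance = 1e-4 * max(abs(H_fd)))
  # Hessian negative definite at an interior point
  expect_true(all(eigen(d$H, symmetric = TRUE)$values < 0))
})

test_that("fitted densities are normalised and non-negative on all domains", {
  set.seed(6)
  cases <- list(
    list(x = rbeta(300, 2, 4), d = spde_domain("bounded", a = 0, b = 1),
         lim = c(0, 1)),
    list(x = rnorm(300), d = spde_domain("infinite"), lim = c(-Inf, Inf)),
    list(x = rgamma(300, 2, 1), d = spde_domain("semi_infinite", a = 0),
         lim = c(0, Inf)))
  for (cs in cases) {
    est <- spde(cs$x, cs$d, families = "POL",
                boundary_sets = list(character(0)),
                control = spde_control(Pm = 4))
    total <- integrate(function(t) density_estimate(est, t),
                       cs$lim[1], cs$lim[2], rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
    g <- seq(max(cs$lim[1], -10), min(cs$lim[2], 10), length.out = 200)
    expect_true(all(density_estimate(est, g) >= 0))
  }
})

test_that("the estimate is invariant under linear rescaling of the data", {
  set.seed(7)
  x <- rnorm(400)
  d <- spde_domain("infinite")
  f1 <- fit_mle(make_model(x, d, list(type = "poly", J0 = 3)))
  f2 <- fit_mle(make_model(3 * x + 5, d, list(type = "poly", J0 = 3)))
  g <- seq(-3, 3, length.out = 301)
  expect_lt(max(abs(density_estimate(f1, g) -
                    3 * density_estimate(f2, 3 * g + 5))), 1e-6)
})

test_that("the density matches the slope of its own accumulated CDF", {
  set.seed(8)
  x <- rnorm(400)
  fit <- fit_mle(make_model(x, spde_domain("infinite"),
                            list(type = "poly", J0 = 2)))
  g <- seq(-2, 2, by = 0.25)
  h <- 1e-4
  cdf <- vapply(g, function(t) integrate(function(u) density_estimate(fit, u),
                                         -Inf, t, rel.tol = 1e-10)$value, 0)
  cdf_hi <- vapply(g + h, function(t) integrate(function(u)
    density_estimate(fit, u), -Inf, t, rel.tol = 1e-10)$value, 0)
  expect_equal((cdf_hi - cdf) / h, density_estimate(fit, g + h / 2),
               tolerance = 1e-5)
})
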