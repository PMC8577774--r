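# Raw bases, constraints, splines, boundary terms, orthonormalisation.

test_that("polynomial raw bases span the requested monomials", {
  fs <- polynomial_raw(3)
  expect_length(fs, 3)
  y <- seq(-1, 1, by = 0.25)
  # degree-j Chebyshev representation spans {y, y^2, y^3}: fit exactly
  V <- vapply(fs, function(f) f$f(y), numeric(length(y)))
  M <- cbind(1, y, y^2, y^3)
  expect_lt(max(abs(V - M %*% qr.solve(M, V))), 1e-12)
  # symmetric: even functions only
  fs <- polynomial_raw(2, symmetric = TRUE)
  expect_equal(fs[[1]]$f(y), fs[[1]]$f(-y))
  expect_equal(fs[[2]]$f(y), fs[[2]]$f(-y))
  # explicit powers are monomials
  fs <- polynomial_raw(2, powers = c(1, 3))
  expect_equal(fs[[2]]$f(2), 8)
  expect_error(polynomial_raw(2, powers = c(2, 2)), "distinct")
  # derivatives are consistent with finite differences
  f <- polynomial_raw(5)[[5]]
  expect_equal(f$d1(0.3), (f$f(0.3 + 1e-6) - f$f(0.3 - 1e-6)) / 2e-6,
               tolerance = 1e-6)
  expect_equal(f$d2(0.3), (f$d1(0.3 + 1e-6) - f$d1(0.3 - 1e-6)) / 2e-6,
               tolerance = 1e-6)
})

test_that("trigonometric bases follow the cos/sin ordering", {
  fs <- trigonometric_raw(2)
  expect_equal(fs[[1]]$f(0.4), cos(pi / 2 * 0.4))
  expect_equal(fs[[2]]$f(0.4), sin(pi / 2 * 0.4))
  fs <- trigonometric_raw(3)
  expect_equal(fs[[3]]$f(0.4), cos(pi * 0.4))
  fs <- trigonometric_raw(2, symmetric = TRUE)
  expect_equal(fs[[2]]$f(0.4), cos(pi * 0.4))
  expect_length(trigonometric_raw(0), 0)
})

test_that("knot placement matches the two schemes", {
  expect_equal(place_knots(3, "equidistant", -1, 1), c(-0.5, 0, 0.5))
  ys <- sort(rnorm(10))
  expect_equal(place_knots(1, "quantile", min(ys) - 1, max(ys) + 1, ys),
               ys[5])                       # n_1 = floor(10/2) = 5
  ys8 <- sort(rnorm(8))
  expect_equal(place_knots(3, "quantile", -10, 10, ys8), ys8[c(2, 4, 6)])
  expect_error(place_knots(0, "equidistant", -1, 1), "at least 1")
  # ties collapse to fewer knots
  ytied <- sort(c(rep(0.5, 6), 1, 2))
  expect_lt(length(place_knots(3, "quantile", 0, 3, ytied)), 3)
})

test_that("spline spaces have dimension K + 3 and are C2 at the knots", {
  set.seed(10)
  y <- runif(120, -1, 1)
  for (K in c(1, 3)) {
    kn <- place_knots(K, "equidistant", -1, 1)
    fs <- spline_raw(kn, -1, 1, y)
    expect_length(fs, K + 3)
    h <- 1e-5
    for (f in fs) {
      expect_lt(max(abs(f$f(kn - h) + h * f$d1(kn - h) +
                        h^2 / 2 * f$d2(kn - h) -
                        (f$f(kn + h) - h * f$d1(kn + h) +
                         h^2 / 2 * f$d2(kn + h)))), 1e-9)
      expect_lt(abs(mean(f$f(y))), 1e-9)    # built-in mean-zero constraint
      # jumps of value/slope/curvature across each knot vanish
      expect_lt(max(abs(f$d2(kn - 1e-9) - f$d2(kn + 1e-9))), 1e-6)
    }
  }
})

test_that("symmetry and periodicity reduce the spline space via the SVD rank", {
  set.seed(11)
  y <- runif(200, -1, 1)
  kn <- c(-0.5, 0.5)
  fs <- spline_raw(kn, -1, 1, y, symmetric = TRUE)
  expect_lt(length(fs), 5)                  # fewer than K + 3 = 5
  for (f in fs) expect_equal(f$f(y), f$f(-y), tolerance = 1e-9)
  fp <- spline_raw(kn, -1, 1, y, periodic = TRUE)
  expect_length(fp, 4)                      # one extra constraint
  for (f in fp) expect_equal(f$f(-1), f$f(1), tolerance = 1e-9)
})

test_that("null-space construction handles periodicity and redundancy", {
  # gamma* = {y, y^2, y^3}: values at -1 minus values at 1 give [-2, 0, -2]
  C <- rbind(c(-2, 0, -2))
  ns <- constrained_null_space(C)
  expect_equal(ncol(ns), 2)
  # y^2 direction (0,1,0) and y - y^3 direction (1,0,-1) lie in the span
  proj <- ns %*% crossprod(ns, c(0, 1, 0))
  expect_equal(drop(proj), c(0, 1, 0), tolerance = 1e-12)
  proj <- ns %*% crossprod(ns, c(1, 0, -1) / sqrt(2))
  expect_equal(drop(proj), c(1, 0, -1) / sqrt(2), tolerance = 1e-12)
  # duplicated rows leave the null space unchanged
  ns2 <- constrained_null_space(rbind(C, C, C))
  expect_equal(ncol(ns2), 2)
  expect_equal(abs(det(crossprod(ns, ns2))), 1, tolerance = 1e-12)
  expect_error(constrained_null_space(diag(3)), "empty null space")
})

test_that("boundary term sets enforce the admissible subsets", {
  d <- spde_domain("bounded", a = 0, b = 1)
  fs <- boundary_term_set(d, "log_lower")
  expect_equal(fs[[1]]$f(0.5), log(1.5))
  expect_error(boundary_term_set(spde_domain("semi_infinite", a = 0), "log2"),
               "requires 'log'")
  expect_error(boundary_term_set(spde_domain("infinite"), "log"),
               "not supported")
  dsym <- spde_domain("bounded", a = -1, b = 1, symmetric = TRUE)
  fs <- boundary_term_set(dsym, "log_sym")
  expect_equal(fs[[1]]$f(0.3), log(1.3) + log(0.7))
  expect_error(boundary_term_set(dsym, "log_lower"), "symmetric")
  s2 <- boundary_term_set(spde_domain("semi_infinite", a = 0),
                          c("log", "log2"))
  expect_length(s2, 2)
})

test_that("modified Gram-Schmidt produces the statistically orthogonal basis", {
  # hand-computed example: sample {-1, 0, 1}, gamma = {y}:
  # centred column (-1, 0, 1), norm sqrt(2/3), phi_1 = y / sqrt(2/3)
  o <- orthonormalise(gamma = polynomial_raw(1, powers = 1),
                      sample = c(-1, 0, 1))
  expect_equal(o$W[1, 1], 1 / sqrt(2 / 3))
  # psi is the mean-centred base measure
  beta <- list(f = function(y) y^2, d1 = function(y) 2 * y,
               d2 = function(y) rep(2, length(y)))
  o2 <- orthonormalise(beta, polynomial_raw(1, powers = 1), c(-1, 0, 1))
  expect_equal(o2$psi_mean, 2 / 3)
  # orthonormality and zero means over the data, large J
  set.seed(12)
  x <- rgamma(400, 2, 1)
  sm <- rescale_sample(x, spde_domain("semi_infinite", a = 0))
  bs <- spde:::assemble_basis(sm, list(type = "poly", J0 = 15),
                              boundary = "log")
  B <- spde:::basis_matrices(bs, sm$y)
  G <- crossprod(B$Phi) / sm$N
  expect_lt(max(abs(G - diag(bs$J))), 1e-9)
  expect_lt(max(abs(colMeans(B$Phi))), 1e-9)
  # span preservation: each raw function is reproduced by its projection
  Graw <- spde:::raw_eval(bs$funs, sm$y, "f")$f
  Gc <- sweep(Graw, 2, colMeans(Graw))
  P <- B$Phi %*% (crossprod(B$Phi, Gc) / sm$N)
  expect_lt(max(abs(P - Gc)) / max(abs(Gc)), 1e-9)
  # collinear basis is rejected
  expect_error(
    orthonormalise(gamma = c(polynomial_raw(1, powers = 1),
                             polynomial_raw(1, powers = 1)),
                   sample = rnorm(50)),
    "collinear")
})

test_that("linear extrapolation continues value and slope past the anchors", {
  set.seed(13)
  x <- rnorm(150)
  sm <- rescale_sample(x, spde_domain("infinite"))
  bs <- spde:::assemble_basis(sm, list(type = "poly", J0 = 3))
  yb <- sm$yb
  B0 <- spde:::basis_matrices(bs, yb)
  B1 <- spde:::basis_matrices(bs, yb + 0.9)
  expect_equal(drop(B1$Phi), drop(B0$Phi) + 0.9 * drop(B0$dPhi),
               tolerance = 1e-12)
  expect_equal(drop(B1$dPhi), drop(B0$dPhi), tolerance = 1e-12)
  expect_equal(drop(B1$d2Phi), rep(0, 3))
})
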