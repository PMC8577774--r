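# Shared helpers: independent brute-force oracles and small fixtures.

# Dense midpoint-rule integral of g over [a, b].
midpoint_integral <- function(g, a, b, n = 1e6) {
  h <- (b - a) / n
  x <- a + (seq_len(n) - 0.5) * h
  sum(g(x)) * h
}

# Central finite-difference gradient of a scalar function.
fd_gradient <- function(fun, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (fun(x + e) - fun(x - e)) / (2 * h)
  }, 0)
}

# Central finite-difference Hessian.
fd_hessian <- function(fun, x, h = 1e-4) {
  J <- length(x)
  H <- matrix(0, J, J)
  for (j in seq_len(J)) for (k in j:J) {
    ej <- numeric(J); ej[j] <- h
    ek <- numeric(J); ek[k] <- h
    H[j, k] <- H[k, j] <-
      (fun(x + ej + ek) - fun(x + ej - ek) -
       fun(x - ej + ek) + fun(x - ej - ek)) / (4 * h^2)
  }
  H
}

# Rejection sampler for the density proportional to exp(-x^2) on [-1, 1].
r_trunc_sqexp <- function(n) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::runif(2 * n, -1, 1)
    u <- stats::runif(2 * n)
    out <- c(out, x[u < exp(-x^2)])
  }
  out[seq_len(n)]
}

# Build a ready-to-fit model in one call.
make_model <- function(x, domain, bulk, boundary = character(0),
                       psi = NULL, control = spde_control()) {
  sm <- rescale_sample(x, domain)
  bs <- spde:::assemble_basis(sm, bulk, boundary, psi, control)
  spde:::new_model(sm, bs, control)
}
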