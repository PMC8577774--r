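# Benchmark test densities: normal, beta and gamma mixtures on infinite,
# bounded and semi-infinite domains, with exact pdfs, analytic first and
# second derivatives, and samplers (rejection sampling for the truncated
# cases). Cases 1-12 are supported on the real line, case 13 on [-2, 2],
# case 14 on [0, 1] and case 15 on [0, Inf).

mix_components <- function(case_id) {
  n2 <- (2 / 3)^(0:7)
  switch(as.character(case_id),
    "1" = list(w = 1, family = "normal", p1 = 0, p2 = 1),
    "2" = list(w = rep(1/8, 8), family = rep("normal", 8),
               p1 = 3 * (n2 - 1), p2 = n2),
    "3" = list(w = c(2/3, 1/3), family = rep("normal", 2),
               p1 = c(0, 0), p2 = c(1, 1/10)),
    "4" = list(w = c(1/10, 9/10), family = rep("normal", 2),
               p1 = c(0, 0), p2 = c(1, 1/8)),
    "5" = list(w = c(13/20, 7/20), family = rep("normal", 2),
               p1 = c(0, 5/2), p2 = c(1, 1)),
    "6" = list(w = c(3/4, 1/4), family = rep("normal", 2),
               p1 = c(0, 3/2), p2 = c(1, 1/3)),
    "7" = list(w = c(1/2, 1/2), family = rep("normal", 2),
               p1 = c(-2, 2), p2 = c(1/2, 1/2)),
    "8" = list(w = c(1/2, 1/2), family = rep("normal", 2),
               p1 = c(0, 5), p2 = c(1/5, 1)),
    "9" = list(w = rep(1/3, 3), family = rep("normal", 3),
               p1 = 80 * (0:2), p2 = (1:3)^2),
    "10" = list(w = rep(1/5, 5), family = rep("normal", 5),
                p1 = 80 * (0:4), p2 = 1:5),
    "11" = list(w = c(1/2, rep(1/10, 5)), family = rep("normal", 6),
                p1 = c(0, (0:4)/2 - 1), p2 = c(1, rep(1/10, 5))),
    "12" = list(w = c(1/2, 2^(1 - (-2:2)) / 31), family = rep("normal", 6),
                p1 = c(0, (-2:2) + 1/2), p2 = c(1, 2^(-(-2:2)) / 10)),
    "13" = mix_components(6),
    "14" = list(w = c(1/2, 1/2), family = rep("beta", 2),
                p1 = c(2, 6), p2 = c(7, 4)),
    "15" = list(w = c(4/5, 1/5), family = c("gamma", "normal"),
                p1 = c(2, 2), p2 = c(2, 0.15)),
    stop("unknown test case"))
}

comp_d <- function(family, x, p1, p2) {
  switch(family,
    normal = stats::dnorm(x, p1, p2),
    beta = stats::dbeta(x, p1, p2),
    gamma = stats::dgamma(x, shape = p1, rate = p2))
}

comp_p <- function(family, x, p1, p2) {
  switch(family,
    normal = stats::pnorm(x, p1, p2),
    beta = stats::pbeta(x, p1, p2),
    gamma = stats::pgamma(x, shape = p1, rate = p2))
}

comp_r <- function(family, n, p1, p2) {
  switch(family,
    normal = stats::rnorm(n, p1, p2),
    beta = stats::rbeta(n, p1, p2),
    gamma = stats::rgamma(n, shape = p1, rate = p2))
}

# analytic first/second derivative of a component density
comp_d12 <- function(family, x, p1, p2) {
  if (family == "normal") {
    d <- stats::dnorm(x, p1, p2)
    z <- (x - p1) / p2
    list(f1 = -z / p2 * d, f2 = (z^2 - 1) / p2^2 * d)
  } else if (family == "gamma") {
    a <- p1; b <- p2
    cst <- b^a / gamma(a)
    e <- exp(-b * x)
    t1 <- if (a != 1) (a - 1) * x^(a - 2) else 0
    f1 <- cst * e * (t1 - b * x^(a - 1))
    t2 <- if (a != 1 && a != 2) (a - 1) * (a - 2) * x^(a - 3) else 0
    t3 <- if (a != 1) 2 * b * (a - 1) * x^(a - 2) else 0
    f2 <- cst * e * (t2 - t3 + b^2 * x^(a - 1))
    f1[x < 0] <- 0; f2[x < 0] <- 0
    list(f1 = f1, f2 = f2)
  } else {
    a <- p1; b <- p2
    cst <- 1 / beta(a, b)
    t10 <- if (a != 1) (a - 1) * x^(a - 2) * (1 - x)^(b - 1) else 0
    t11 <- if (b != 1) (b - 1) * x^(a - 1) * (1 - x)^(b - 2) else 0
    f1 <- cst * (t10 - t11)
    t20 <- if (a != 1 && a != 2)
      (a - 1) * (a - 2) * x^(a - 3) * (1 - x)^(b - 1) else 0
    t21 <- if (a != 1 && b != 1)
      2 * (a - 1) * (b - 1) * x^(a - 2) * (1 - x)^(b - 2) else 0
    t22 <- if (b != 1 && b != 2)
      (b - 1) * (b - 2) * x^(a - 1) * (1 - x)^(b - 3) else 0
    f2 <- cst * (t20 - t21 + t22)
    out <- x < 0 | x > 1
    f1[out] <- 0; f2[out] <- 0
    list(f1 = f1, f2 = f2)
  }
}

#' Benchmark test density
#'
#' The fifteen normal/beta/gamma mixture test densities used in the
#' simulation benchmark. Each object carries the exact pdf with analytic
#' first and second derivatives, a sampler (rejection sampling for the two
#' truncated cases, which are renormalised by the truncation mass), the
#' domain declaration and a numerical support interval.
#'
#' @param case_id Integer 1..15.
#' @return Object of class `"spde_testdens"` with elements `pdf(x)`,
#'   `deriv(x)` (list `f`, `f1`, `f2`), `sampler(n)`, `domain`, `support`,
#'   `trunc`, `trunc_mass` and the component table.
#' @examples
#' td <- test_density(1)
#' td$pdf(0)            # 1/sqrt(2*pi)
#' @export
test_density <- function(case_id) {
  case_id <- as.integer(case_id)
  if (is.na(case_id) || case_id < 1 || case_id > 15) stop("unknown test case")
  comp <- mix_components(case_id)
  K <- length(comp$w)
  domain <- switch(as.character(case_id),
    "13" = spde_domain("bounded", a = -2, b = 2),
    "14" = spde_domain("bounded", a = 0, b = 1),
    "15" = spde_domain("semi_infinite", a = 0),
    spde_domain("infinite"))
  trunc <- switch(as.character(case_id),
    "13" = c(-2, 2), "15" = c(0, Inf), NULL)
  trunc_mass <- if (is.null(trunc)) 1 else
    sum(vapply(seq_len(K), function(k)
      comp$w[k] * (comp_p(comp$family[k], trunc[2], comp$p1[k], comp$p2[k]) -
                   comp_p(comp$family[k], trunc[1], comp$p1[k], comp$p2[k])), 0))
  lo_dom <- switch(domain$kind, bounded = domain$a, semi_infinite = domain$a, -Inf)
  hi_dom <- switch(domain$kind, bounded = domain$b, Inf)
  mix_pdf <- function(x) {
    f <- rep(0, length(x))
    for (k in seq_len(K))
      f <- f + comp$w[k] * comp_d(comp$family[k], x, comp$p1[k], comp$p2[k])
    f <- f / trunc_mass
    f[x < lo_dom | x > hi_dom] <- 0
    f
  }
  mix_deriv <- function(x) {
    f <- rep(0, length(x)); f1 <- f; f2 <- f
    for (k in seq_len(K)) {
      f <- f + comp$w[k] * comp_d(comp$family[k], x, comp$p1[k], comp$p2[k])
      d <- comp_d12(comp$family[k], x, comp$p1[k], comp$p2[k])
      f1 <- f1 + comp$w[k] * d$f1
      f2 <- f2 + comp$w[k] * d$f2
    }
    out <- x < lo_dom | x > hi_dom
    f[out] <- 0; f1[out] <- 0; f2[out] <- 0
    list(f = f / trunc_mass, f1 = f1 / trunc_mass, f2 = f2 / trunc_mass)
  }
  sampler <- function(n) {
    draw <- function(m) {
      k <- sample.int(K, m, replace = TRUE, prob = comp$w)
      x <- numeric(m)
      for (j in unique(k)) {
        idx <- which(k == j)
        x[idx] <- comp_r(comp$family[j], length(idx), comp$p1[j], comp$p2[j])
      }
      x
    }
    x <- draw(n)
    if (!is.null(trunc)) {
      bad <- which(x < trunc[1] | x > trunc[2])
      while (length(bad)) {
        x[bad] <- draw(length(bad))
        bad <- bad[x[bad] < trunc[1] | x[bad] > trunc[2]]
      }
    }
    x
  }
  # numerical support: where the pdf exceeds ~1e-12
  lo_k <- hi_k <- numeric(K)
  for (k in seq_len(K)) {
    if (comp$family[k] == "normal") {
      lo_k[k] <- comp$p1[k] - 9 * comp$p2[k]; hi_k[k] <- comp$p1[k] + 9 * comp$p2[k]
    } else if (comp$family[k] == "gamma") {
      lo_k[k] <- 0
      hi_k[k] <- stats::qgamma(1e-13, shape = comp$p1[k], rate = comp$p2[k],
                               lower.tail = FALSE)
    } else { lo_k[k] <- 0; hi_k[k] <- 1 }
  }
  support <- c(max(lo_dom, min(lo_k)), min(hi_dom, max(hi_k)))
  # untruncated mixture moments (exact for the non-truncated cases)
  mk <- vapply(seq_len(K), function(k) switch(comp$family[k],
    normal = comp$p1[k], gamma = comp$p1[k] / comp$p2[k],
    beta = comp$p1[k] / (comp$p1[k] + comp$p2[k])), 0)
  vk <- vapply(seq_len(K), function(k) switch(comp$family[k],
    normal = comp$p2[k]^2, gamma = comp$p1[k] / comp$p2[k]^2,
    beta = {
      a <- comp$p1[k]; b <- comp$p2[k]
      a * b / ((a + b)^2 * (a + b + 1))
    }), 0)
  mean_mix <- sum(comp$w * mk)
  var_mix <- sum(comp$w * (vk + mk^2)) - mean_mix^2
  structure(list(case_id = case_id, components = comp, domain = domain,
                 trunc = trunc, trunc_mass = trunc_mass,
                 pdf = mix_pdf, deriv = mix_deriv, sampler = sampler,
                 support = support,
                 mean = mean_mix, var = var_mix),
            class = "spde_testdens")
}

#' @export
print.spde_testdens <- function(x, ...) {
  cat(sprintf("Test density %d: %d component(s)", x$case_id,
              length(x$components$w)))
  if (!is.null(x$trunc))
    cat(sprintf(", truncated to [%g, %g] (mass %.6f)", x$trunc[1],
                x$trunc[2], x$trunc_mass))
  cat("\n")
  print(x$domain)
  invisible(x)
}
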