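# Exponential-family model container: quadrature, partition function,
# population moments, likelihood derivatives and density evaluation.
#
# The density model is p(y|alpha) = exp[U(y|alpha) - A(alpha)] with potential
# U = psi + sum_j alpha_j phi_j over the orthonormalised basis. On unbounded
# domains the bulk integrals run over [y_a, y_b] (or [0, y_b]) by composite
# Gauss-Legendre quadrature while the exponential tails, where every basis
# function is linear, are integrated in closed form.

#' Tuning constants for fitting and model selection
#'
#' Defaults follow the method's standard constants: condition threshold
#' `kappa_th` = 1e5 for the regularised Newton direction, convergence
#' tolerance `epsilon` = 1e-5 on the Euclidean norm of the population mean
#' vector, at most 50 Newton iterations; search caps `Pm` (polynomial
#' order), `Km` (spline knots) and `Lm` (trigonometric wavenumber) chosen
#' generously and raised automatically (up to `expand_max` extra terms) when
#' a winner sits at a cap.
#'
#' @param Pm Maximum polynomial order searched.
#' @param Km Maximum number of spline knots searched.
#' @param Lm Maximum trigonometric wavenumber (2*Lm bulk functions).
#' @param kappa_th Condition-number threshold for Hessian regularisation.
#' @param epsilon Convergence tolerance on |m|.
#' @param max_iter Maximum Newton iterations per fit.
#' @param max_backtrack Maximum step halvings in the line search.
#' @param n_nodes Gauss--Legendre nodes per quadrature segment.
#' @param max_seg_len Longest quadrature segment on the rescaled scale;
#'   longer segments are subdivided so the rule resolves sharp density
#'   features (the data are standardised, so 1 is one standard deviation /
#'   mean unit).
#' @param sub_segments,sub_ratio Geometric subdivision next to a singular
#'   boundary term.
#' @param svd_rtol Relative zero threshold for constraint-matrix SVDs.
#' @param collinear_tol Norm-collapse tolerance in Gram--Schmidt.
#' @param warm_start Warm-start nested polynomial/trigonometric sweeps from
#'   the previous solution.
#' @param expand Raise a search cap when the winner sits on it.
#' @param expand_max Largest automatic cap increase.
#' @return A list of class `"spde_control"`.
#' @export
spde_control <- function(Pm = 12, Km = 10, Lm = 6,
                         kappa_th = 1e5, epsilon = 1e-5, max_iter = 50,
                         max_backtrack = 30, n_nodes = 50,
                         max_seg_len = 1, sub_segments = 10, sub_ratio = 0.2,
                         svd_rtol = 1e-10, collinear_tol = 1e-12,
                         warm_start = TRUE, expand = TRUE, expand_max = 8) {
  stopifnot(kappa_th > 1, epsilon > 0, max_iter >= 1)
  structure(as.list(environment()), class = "spde_control")
}

# Build a ready-to-fit model: basis + quadrature + cached node/anchor values.
new_model <- function(sample, basis, control = spde_control()) {
  breaks <- c(sample$bulk[1], basis$knots, sample$bulk[2])
  quad <- quadrature_scheme(breaks, n_nodes = control$n_nodes,
                            singular = basis$singular,
                            sub = control$sub_segments,
                            ratio = control$sub_ratio,
                            max_len = control$max_seg_len)
  Bn <- basis_matrices(basis, quad$nodes)
  anch <- NULL
  kind <- basis$kind
  if (kind != "bounded") {
    hi <- basis_matrices(basis, basis$anchors[2])
    anch <- list(hi = list(phi = drop(hi$Phi), dphi = drop(hi$dPhi),
                           psi = hi$psi, psi1 = hi$psi1))
    if (kind == "infinite") {
      lo <- basis_matrices(basis, basis$anchors[1])
      anch$lo <- list(phi = drop(lo$Phi), dphi = drop(lo$dPhi),
                      psi = lo$psi, psi1 = lo$psi1)
    }
  }
  structure(list(sample = sample, basis = basis, quad = quad,
                 Phi_n = Bn$Phi, psi_n = Bn$psi, anchors = anch,
                 kind = kind, J = basis$J, N = sample$N,
                 control = control),
            class = "spde_model")
}

# Tail slopes U'(anchor) for a parameter vector; NULL on bounded domains.
model_slopes <- function(model, alpha) {
  if (model$kind == "bounded") return(NULL)
  a <- model$anchors
  hi <- a$hi$psi1 + if (model$J) sum(a$hi$dphi * alpha) else 0
  if (model$kind == "infinite") {
    lo <- a$lo$psi1 + if (model$J) sum(a$lo$dphi * alpha) else 0
    c(lo = lo, hi = hi)
  } else c(hi = hi)
}

# Strict slope admissibility (hard constraints on unbounded domains).
admissible <- function(model, alpha) {
  s <- model_slopes(model, alpha)
  if (is.null(s)) return(TRUE)
  if (model$kind == "infinite") s[["lo"]] > 0 && s[["hi"]] < 0
  else s[["hi"]] < 0
}

# Partition function, population moments and likelihood derivatives.
# what = "logZ" computes only A (for the line search); "full" adds m and Q.
model_moments <- function(model, alpha, what = c("full", "logZ")) {
  what <- match.arg(what)
  J <- model$J
  U_n <- model$psi_n + if (J) drop(model$Phi_n %*% alpha) else 0
  slopes <- model_slopes(model, alpha)
  tail_hi <- tail_lo <- NULL
  Umax <- max(U_n)
  if (model$kind != "bounded") {
    if (model$kind == "infinite" && !(slopes[["lo"]] > 0))
      stop("tail divergence: U'(y_a) must be positive")
    if (!(slopes[["hi"]] < 0))
      stop("tail divergence: U'(y_b) must be negative")
    a <- model$anchors
    U_hi <- a$hi$psi + if (J) sum(a$hi$phi * alpha) else 0
    Umax <- max(Umax, U_hi)
    tail_hi <- list(U = U_hi, s = slopes[["hi"]], phi = a$hi$phi,
                    dphi = a$hi$dphi)
    if (model$kind == "infinite") {
      U_lo <- a$lo$psi + if (J) sum(a$lo$phi * alpha) else 0
      Umax <- max(Umax, U_lo)
      tail_lo <- list(U = U_lo, s = slopes[["lo"]], phi = a$lo$phi,
                      dphi = a$lo$dphi)
    }
  }
  e_n <- model$quad$weights * exp(U_n - Umax)
  Z0s <- sum(e_n)
  Z1s <- if (!is.null(tail_hi)) exp(tail_hi$U - Umax) * (-1 / tail_hi$s) else 0
  Z2s <- if (!is.null(tail_lo)) exp(tail_lo$U - Umax) * (1 / tail_lo$s) else 0
  Zs <- Z0s + Z1s + Z2s
  if (!is.finite(Zs) || Zs <= 0) stop("numerical overflow in partition function")
  A <- log(Zs) + Umax
  out <- list(A = A, l = -model$N * A, slopes = slopes,
              Z = exp(A), Z0 = Z0s * exp(Umax), Z1 = Z1s * exp(Umax),
              Z2 = Z2s * exp(Umax), log_offset = Umax)
  if (what == "logZ") return(out)
  if (J > 0) {
    p_n <- e_n / Zs
    m <- drop(crossprod(model$Phi_n, p_n))
    Q <- crossprod(model$Phi_n, model$Phi_n * p_n)
    if (!is.null(tail_hi)) {
      w1 <- Z1s / Zs
      c1 <- tail_hi$phi - tail_hi$dphi / tail_hi$s
      m <- m + w1 * c1
      Q <- Q + w1 * (outer(c1, c1) +
                     outer(tail_hi$dphi, tail_hi$dphi) / tail_hi$s^2)
    }
    if (!is.null(tail_lo)) {
      w2 <- Z2s / Zs
      c2 <- tail_lo$phi - tail_lo$dphi / tail_lo$s
      m <- m + w2 * c2
      Q <- Q + w2 * (outer(c2, c2) +
                     outer(tail_lo$dphi, tail_lo$dphi) / tail_lo$s^2)
    }
  } else {
    m <- numeric(0)
    Q <- matrix(0, 0, 0)
  }
  out$m <- m
  out$Q <- Q
  out$g <- -model$N * m
  out$H <- -model$N * (Q - outer(m, m))
  out
}

#' Evaluate the potential and its derivatives
#'
#' \eqn{U(y) = \psi(y) + \sum_j \alpha_j \phi_j(y)} with first and second
#' derivative, on the rescaled y-scale. Beyond the extrapolation anchors the
#' second derivative is exactly zero.
#'
#' @param model An `spde_model` (or `spde_fit`).
#' @param y Evaluation points (rescaled scale).
#' @param alpha Coefficient vector (defaults to the fitted one for a fit).
#' @return List with vectors `U`, `U1`, `U2`.
#' @export
evaluate_potential <- function(model, y, alpha = NULL) {
  if (inherits(model, "spde_fit")) {
    if (is.null(alpha)) alpha <- model$alpha
    model <- model$model
  }
  B <- basis_matrices(model$basis, y)
  J <- model$J
  list(U = B$psi + if (J) drop(B$Phi %*% alpha) else 0,
       U1 = B$psi1 + if (J) drop(B$dPhi %*% alpha) else 0,
       U2 = B$psi2 + if (J) drop(B$d2Phi %*% alpha) else 0)
}

#' Log-likelihood, score and Hessian on the orthogonalised basis
#'
#' With the statistically orthogonal basis all sample means of potential
#' terms vanish, so \eqn{l = -N \log Z}, \eqn{g = -N m} and
#' \eqn{H = -N (Q - m m^T)}.
#'
#' @param model An `spde_model`.
#' @param alpha Coefficient vector.
#' @return List with `l`, `g`, `H` (and the full evaluation in `eval`).
#' @export
log_likelihood_derivatives <- function(model, alpha) {
  ev <- model_moments(model, alpha, "full")
  list(l = ev$l, g = ev$g, H = ev$H, eval = ev)
}

#' Density estimate on the original scale
#'
#' \eqn{\hat f_X(x) = \exp[U((x - c)/s) - \log s - A]}. Points beyond the
#' extrapolation anchors use the linear tail continuation of the potential.
#'
#' @param fit A converged `spde_fit` (or an `spde` selection, whose chosen
#'   model is used).
#' @param x Evaluation points on the original scale.
#' @param deriv If `TRUE`, also return the first two derivatives of the
#'   density (needed e.g. for mode/bump counting).
#' @return Numeric vector of density values, or a list with `f`, `f1`, `f2`.
#' @export
density_estimate <- function(fit, x, deriv = FALSE) {
  if (inherits(fit, "spde")) fit <- fit$fit
  stopifnot(inherits(fit, "spde_fit"))
  model <- fit$model
  sample <- model$sample
  orient <- sample$domain$orient
  y <- x_to_y(sample, x)
  P <- evaluate_potential(model, y, fit$alpha)
  s <- sample$s
  f <- exp(P$U - fit$evaluation$A) / s
  # at a domain endpoint carrying a singular boundary term the potential is
  # an indeterminate form; take the density as its limit from the interior
  bad <- which(!is.finite(f) | is.na(P$U))
  if (length(bad)) {
    eps <- 1e-10 * max(1, abs(sample$bulk))
    yin <- pmin(pmax(y[bad], sample$bulk[1] + eps), sample$bulk[2] - eps)
    if (model$kind != "bounded") yin <- pmax(y[bad], sample$bulk[1] + eps)
    Pb <- evaluate_potential(model, yin, fit$alpha)
    fb <- exp(Pb$U - fit$evaluation$A) / s
    fb[fb < 1e-290] <- 0
    f[bad] <- fb
    P$U[bad] <- Pb$U
    P$U1[bad] <- Pb$U1
    P$U2[bad] <- Pb$U2
  }
  if (!deriv) return(f)
  f1 <- f * P$U1 / s * orient
  f2 <- f * (P$U2 + P$U1^2) / s^2
  f1[!is.finite(f1)] <- 0; f2[!is.finite(f2)] <- 0
  list(f = f, f1 = f1, f2 = f2)
}
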