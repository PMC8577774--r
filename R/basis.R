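# Raw basis functions, constraints, splines and the data-adaptive
# orthonormalisation.
#
# A raw basis function is a list(f, d1, d2, label, singular_at) carrying
# analytic value, first and second derivative. Analytic derivatives are
# needed throughout: for the slope constraints on unbounded domains, for the
# closed-form tail integrals, and for mode/bump counting of the fitted
# density.

raw_fun <- function(f, d1, d2, label, singular_at = NA_real_) {
  list(f = f, d1 = d1, d2 = d2, label = label, singular_at = singular_at)
}

# Evaluate a list of raw functions at y; returns N x J matrices.
raw_eval <- function(funs, y, what = c("f", "d1", "d2")) {
  n <- length(y)
  J <- length(funs)
  out <- lapply(what, function(w) {
    m <- matrix(0, n, J)
    for (j in seq_len(J)) m[, j] <- funs[[j]][[w]](y)
    m
  })
  names(out) <- what
  out
}

# Linear combinations of raw functions (used for null-space constructions).
combine_raw <- function(funs, coefs, labels = NULL) {
  lapply(seq_len(ncol(coefs)), function(q) {
    cf <- coefs[, q]
    keep <- which(abs(cf) > 0)
    raw_fun(
      f  = function(y) { v <- 0; for (j in keep) v <- v + cf[j] * funs[[j]]$f(y); v },
      d1 = function(y) { v <- 0; for (j in keep) v <- v + cf[j] * funs[[j]]$d1(y); v },
      d2 = function(y) { v <- 0; for (j in keep) v <- v + cf[j] * funs[[j]]$d2(y); v },
      label = if (is.null(labels)) sprintf("combo%d", q) else labels[q]
    )
  })
}

#' Polynomial raw basis
#'
#' Polynomials of degree \eqn{1, 2, \ldots, J_0} (even degrees only for a
#' symmetric density). The span is that of the monomials
#' \eqn{y, y^2, \ldots}, but the raw representation uses Chebyshev
#' polynomials of the variable mapped from `interval` onto \eqn{[-1, 1]}:
#' the statistically orthogonal functions are stored as linear combinations
#' of the raw ones, and a raw monomial representation of high degree would
#' lose the orthonormality to cancellation. With explicit `powers` (prior
#' knowledge of particular powers) plain monomials are used.
#'
#' @param J0 Number of basis functions.
#' @param powers Optional distinct positive integer powers (monomials).
#' @param symmetric Use even degrees only.
#' @param interval Bulk interval mapped onto \eqn{[-1, 1]} for the Chebyshev
#'   representation (default the already-standardised \eqn{[-1, 1]}).
#' @return A list of raw basis functions.
#' @export
polynomial_raw <- function(J0, powers = NULL, symmetric = FALSE,
                           interval = c(-1, 1)) {
  if (!is.null(powers)) {
    powers <- as.integer(powers)
    if (anyDuplicated(powers) || any(powers < 1))
      stop("'powers' must be distinct positive integers")
    return(lapply(powers, function(p) {
      force(p)
      raw_fun(
        f  = function(y) y^p,
        d1 = function(y) p * y^(p - 1),
        d2 = function(y) if (p >= 2) p * (p - 1) * y^(p - 2)
             else rep(0, length(y)),
        label = sprintf("y^%d", p)
      )
    }))
  }
  degrees <- if (symmetric) 2L * seq_len(J0) else seq_len(J0)
  mid <- mean(interval); half <- diff(interval) / 2
  lapply(degrees, function(p) {
    force(p)
    raw_fun(
      f  = function(y) cheb_eval(p, (y - mid) / half, 0),
      d1 = function(y) cheb_eval(p, (y - mid) / half, 1) / half,
      d2 = function(y) cheb_eval(p, (y - mid) / half, 2) / half^2,
      label = sprintf("T%d", p)
    )
  })
}

# Chebyshev polynomial T_p(t) and derivatives by the three-term recurrence
# (t is clamped-to-bulk, so |t| <= 1 up to rounding).
cheb_eval <- function(p, t, deriv) {
  T0 <- rep(1, length(t)); T1 <- t
  d0 <- rep(0, length(t)); d1 <- rep(1, length(t))
  e0 <- rep(0, length(t)); e1 <- rep(0, length(t))
  if (p == 0) return(switch(deriv + 1L, T0, d0, e0))
  if (p == 1) return(switch(deriv + 1L, T1, d1, e1))
  for (j in 2:p) {
    T2 <- 2 * t * T1 - T0
    d2 <- 2 * T1 + 2 * t * d1 - d0
    e2 <- 4 * d1 + 2 * t * e1 - e0
    T0 <- T1; T1 <- T2
    d0 <- d1; d1 <- d2
    e0 <- e1; e1 <- e2
  }
  switch(deriv + 1L, T1, d1, e1)
}

#' Trigonometric raw basis (bounded domain)
#'
#' Functions taken in the order cos(pi/2 y), sin(pi/2 y), cos(pi y),
#' sin(pi y), ... truncated at `J0`; for a symmetric density cosines only,
#' cos(j pi/2 y) for j = 1..J0.
#'
#' @inheritParams polynomial_raw
#' @export
trigonometric_raw <- function(J0, symmetric = FALSE) {
  if (J0 == 0) return(list())
  mk <- function(kind, k) {
    om <- k * pi / 2
    if (kind == "cos")
      raw_fun(function(y) cos(om * y), function(y) -om * sin(om * y),
              function(y) -om^2 * cos(om * y), sprintf("cos(%dpi/2 y)", k))
    else
      raw_fun(function(y) sin(om * y), function(y) om * cos(om * y),
              function(y) -om^2 * sin(om * y), sprintf("sin(%dpi/2 y)", k))
  }
  if (symmetric) return(lapply(seq_len(J0), function(j) mk("cos", j)))
  out <- vector("list", J0)
  for (j in seq_len(J0)) {
    k <- (j + 1) %/% 2
    out[[j]] <- mk(if (j %% 2 == 1) "cos" else "sin", k)
  }
  out
}

# ---------------------------------------------------------------------------
# Boundary terms

.boundary_bounded <- list(
  log_lower   = function() raw_fun(function(y) log1p(y), function(y) 1/(1+y),
                                   function(y) -1/(1+y)^2, "log(y+1)", -1),
  log_upper   = function() raw_fun(function(y) log1p(-y), function(y) -1/(1-y),
                                   function(y) -1/(1-y)^2, "log(1-y)", 1),
  recip_lower = function() raw_fun(function(y) 1/(1+y), function(y) -1/(1+y)^2,
                                   function(y) 2/(1+y)^3, "1/(y+1)", -1),
  recip_upper = function() raw_fun(function(y) 1/(1-y), function(y) 1/(1-y)^2,
                                   function(y) 2/(1-y)^3, "1/(1-y)", 1)
)

.boundary_semi <- list(
  log   = function() raw_fun(function(y) log(y), function(y) 1/y,
                             function(y) -1/y^2, "log(y)", 0),
  recip = function() raw_fun(function(y) 1/y, function(y) -1/y^2,
                             function(y) 2/y^3, "1/y", 0),
  log2  = function() raw_fun(function(y) log(y)^2, function(y) 2*log(y)/y,
                             function(y) (2 - 2*log(y))/y^2, "log(y)^2", 0)
)

#' Boundary basis terms
#'
#' Logarithmic and rational terms capturing power-law decay to zero or an
#' integrable singularity of the density at a domain endpoint. On a bounded
#' domain the available terms are `log_lower` = log(y+1), `log_upper` =
#' log(1-y), `recip_lower` = 1/(y+1), `recip_upper` = 1/(1-y) (for a
#' symmetric density the paired terms `log_sym`, `recip_sym`). On a
#' semi-infinite domain: `log` = log(y), `recip` = 1/y and `log2` = log(y)^2;
#' `log2` is only admitted together with `log`, which preserves the
#' invariance of the family under linear rescaling of the data.
#'
#' @param domain An [spde_domain()] (or its `kind` string).
#' @param subset Character vector of term names (possibly empty).
#' @return List of raw basis functions.
#' @export
boundary_term_set <- function(domain, subset = character(0)) {
  kind <- if (inherits(domain, "spde_domain")) domain$kind else domain
  symmetric <- inherits(domain, "spde_domain") && domain$symmetric
  subset <- as.character(subset)
  if (length(subset) == 0) return(list())
  if (kind == "infinite")
    stop("boundary terms are not supported on the infinite domain")
  if (kind == "bounded") {
    if (symmetric) {
      ok <- c("log_sym", "recip_sym")
      if (!all(subset %in% ok))
        stop("symmetric bounded boundary terms must be from: ",
             paste(ok, collapse = ", "))
      out <- lapply(subset, function(nm) {
        if (nm == "log_sym")
          raw_fun(function(y) log1p(y) + log1p(-y),
                  function(y) 1/(1+y) - 1/(1-y),
                  function(y) -1/(1+y)^2 - 1/(1-y)^2,
                  "log(y+1)+log(1-y)", NA)
        else
          raw_fun(function(y) 1/(1+y) + 1/(1-y),
                  function(y) -1/(1+y)^2 + 1/(1-y)^2,
                  function(y) 2/(1+y)^3 + 2/(1-y)^3,
                  "1/(y+1)+1/(1-y)", NA)
      })
      attr(out, "singular") <- c(TRUE, TRUE)
      return(out)
    }
    if (!all(subset %in% names(.boundary_bounded)))
      stop("bounded boundary terms must be from: ",
           paste(names(.boundary_bounded), collapse = ", "))
    out <- lapply(subset, function(nm) .boundary_bounded[[nm]]())
    attr(out, "singular") <- c(any(grepl("lower", subset)),
                               any(grepl("upper", subset)))
    return(out)
  }
  # semi-infinite
  if (!all(subset %in% names(.boundary_semi)))
    stop("semi-infinite boundary terms must be from: ",
         paste(names(.boundary_semi), collapse = ", "))
  if ("log2" %in% subset && !("log" %in% subset))
    stop("'log2' requires 'log' (rescaling invariance of the family)")
  out <- lapply(subset, function(nm) .boundary_semi[[nm]]())
  attr(out, "singular") <- c(TRUE, FALSE)
  out
}

# ---------------------------------------------------------------------------
# Spline knots and spline bases

#' Place spline knots
#'
#' Equidistant knots in y-space, or knots equally spaced with respect to the
#' empirical distribution function (order statistics
#' \eqn{\zeta_k = y^*_{n_k}}, \eqn{n_k = \lfloor kN/(K+1) \rfloor}).
#' Quantile knots that coincide (ties) or fall on the interval ends are
#' collapsed, reducing K.
#'
#' @param K Number of knots requested (K >= 1).
#' @param scheme `"equidistant"` or `"quantile"`.
#' @param y_l,y_u Interval endpoints.
#' @param sorted_sample Sorted rescaled sample (required for the quantile
#'   scheme).
#' @return Numeric vector of strictly increasing interior knots (possibly
#'   fewer than K).
#' @export
place_knots <- function(K, scheme = c("equidistant", "quantile"),
                        y_l, y_u, sorted_sample = NULL) {
  scheme <- match.arg(scheme)
  if (K < 1) stop("K must be at least 1")
  if (scheme == "equidistant") {
    return(y_l + seq_len(K) * (y_u - y_l) / (K + 1))
  }
  if (is.null(sorted_sample)) stop("quantile knots require the sorted sample")
  N <- length(sorted_sample)
  nk <- floor(seq_len(K) * N / (K + 1))
  nk <- nk[nk >= 1 & nk <= N]
  z <- unique(sorted_sample[nk])
  z[z > y_l & z < y_u]
}

#' Orthonormal null-space basis of a constraint matrix
#'
#' Singular value decomposition with relative threshold: singular values
#' below `rtol` times the largest are treated as zero; the null space is
#' spanned by the corresponding right singular vectors. Handles redundant
#' constraint rows (e.g. symmetry conditions already implied by the knot
#' conditions) through the rank.
#'
#' @param constraints Numeric constraint matrix (rows = constraints).
#' @param rtol Relative zero threshold for singular values.
#' @return Matrix whose columns span the null space, with attribute `rank`.
#' @export
constrained_null_space <- function(constraints, rtol = 1e-10) {
  p <- ncol(constraints)
  sv <- svd(constraints, nu = 0, nv = p)
  d <- sv$d
  rank <- sum(d > rtol * max(d, 0))
  if (rank >= p) stop("empty null space: constraints admit no basis function")
  ns <- sv$v[, (rank + 1):p, drop = FALSE]
  attr(ns, "rank") <- rank
  ns
}

# Shared piecewise-cubic evaluator: B is a 4 x (K+1) coefficient matrix over
# the sections defined by the interior knots; mids are section midpoints.
spline_piece_eval <- function(B, knots, mids) {
  force(B); force(knots); force(mids)
  ev <- function(y, deriv) {
    idx <- findInterval(y, knots) + 1L
    t <- y - mids[idx]
    if (deriv == 0) B[1, idx] + t * (B[2, idx] + t * (B[3, idx] + t * B[4, idx]))
    else if (deriv == 1) B[2, idx] + t * (2 * B[3, idx] + 3 * t * B[4, idx])
    else 2 * B[3, idx] + 6 * t * B[4, idx]
  }
  ev
}

#' Cubic spline raw basis
#'
#' Builds the space of twice continuously differentiable piecewise cubics on
#' the sections defined by the knots, represented in local monomials
#' \eqn{(y - \bar y_k)^i} per section. The C2 continuity conditions at the
#' knots and the sample mean-zero condition form a homogeneous
#' \eqn{(3K+1) \times (4K+4)} system whose null space (dimension K+3 in the
#' unconstrained case) is the basis. There are no end-point (natural spline)
#' conditions. Symmetry and periodicity add rows; the dimension then follows
#' from the SVD rank.
#'
#' @param knots Strictly increasing interior knots.
#' @param y_l,y_u Interval ends.
#' @param sample_y Rescaled sample (for the mean-zero constraint).
#' @param symmetric Impose \eqn{\gamma(y) = \gamma(-y)} (knots must be
#'   symmetric and the interval centred).
#' @param periodic Impose \eqn{\gamma(y_l) = \gamma(y_u)}.
#' @param rtol SVD zero threshold.
#' @return List of raw basis functions with attribute `knots`.
#' @export
spline_raw <- function(knots, y_l, y_u, sample_y, symmetric = FALSE,
                       periodic = FALSE, rtol = 1e-10) {
  K <- length(knots)
  if (K < 1) stop("spline basis requires at least one knot")
  if (any(diff(knots) <= 0) || knots[1] <= y_l || knots[K] >= y_u)
    stop("knots must be strictly increasing inside (y_l, y_u)")
  bounds <- c(y_l, knots, y_u)
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  nsec <- K + 1
  ncoef <- 4 * nsec
  col <- function(i, k) (k - 1) * 4 + i + 1   # i = 0..3
  rows <- list()
  for (k in seq_len(K)) {
    z <- knots[k]
    tl <- z - mids[k]; tr <- z - mids[k + 1]
    r0 <- r1 <- r2 <- numeric(ncoef)
    r0[col(0:3, k)] <- tl^(0:3); r0[col(0:3, k + 1)] <- -tr^(0:3)
    r1[col(1:3, k)] <- (1:3) * tl^(0:2); r1[col(1:3, k + 1)] <- -(1:3) * tr^(0:2)
    r2[col(2:3, k)] <- c(2, 6 * tl); r2[col(2:3, k + 1)] <- -c(2, 6 * tr)
    rows <- c(rows, list(r0, r1, r2))
  }
  # sample mean-zero constraint <gamma> = 0
  sec <- findInterval(sample_y, knots) + 1L
  N <- length(sample_y)
  rm0 <- numeric(ncoef)
  for (k in seq_len(nsec)) {
    in_k <- sample_y[sec == k]
    if (length(in_k)) {
      t <- in_k - mids[k]
      rm0[col(0:3, k)] <- vapply(0:3, function(i) sum(t^i), 0) / N
    }
  }
  rows <- c(rows, list(rm0))
  if (symmetric) {
    if (abs(y_l + y_u) > 1e-10 || max(abs(knots + rev(knots))) > 1e-8)
      stop("symmetric splines require a centred interval and symmetric knots")
    for (k in seq_len(nsec)) {
      km <- nsec + 1 - k
      for (i in 0:3) {
        r <- numeric(ncoef)
        r[col(i, k)] <- r[col(i, k)] + 1
        r[col(i, km)] <- r[col(i, km)] - (-1)^i
        rows <- c(rows, list(r))
      }
    }
  }
  if (periodic) {
    r <- numeric(ncoef)
    r[col(0:3, 1)] <- (y_l - mids[1])^(0:3)
    r[col(0:3, nsec)] <- r[col(0:3, nsec)] - (y_u - mids[nsec])^(0:3)
    rows <- c(rows, list(r))
  }
  C <- do.call(rbind, rows)
  ns <- constrained_null_space(C, rtol)
  if (!symmetric && !periodic && ncol(ns) != K + 3)
    stop(sprintf("spline construction: null space dimension %d, expected %d",
                 ncol(ns), K + 3))
  funs <- lapply(seq_len(ncol(ns)), function(q) {
    B <- matrix(ns[, q], nrow = 4)
    ev <- spline_piece_eval(B, knots, mids)
    raw_fun(f = function(y) ev(y, 0), d1 = function(y) ev(y, 1),
            d2 = function(y) ev(y, 2), label = sprintf("spl%d(K=%d)", q, K))
  })
  attr(funs, "knots") <- knots
  funs
}

# ---------------------------------------------------------------------------
# Orthonormalisation

#' Statistically orthogonal basis
#'
#' Removes the sample means of the base-measure term and of all raw basis
#' functions, then orthonormalises the latter with the modified Gram-Schmidt
#' algorithm under the empirical scalar product
#' \eqn{(e_1, e_2) = N^{-1} \sum_n e_1(y_n) e_2(y_n)}. The triangular
#' transform is recorded so that derivatives of the orthonormal functions are
#' the same linear combinations of the raw derivatives. With this basis the
#' likelihood machinery simplifies (sample means of all potential terms are
#' zero) and the Fisher information is close to N times the identity.
#'
#' @param beta Optional raw base-measure function (a `raw_fun` list); the
#'   centred version becomes the fixed potential term psi.
#' @param gamma List of raw basis functions.
#' @param sample An `spde_sample` (or numeric vector of rescaled data).
#' @param tol Collinearity tolerance: a vanishing norm during the sweep
#'   signals a (numerically) linearly dependent basis.
#' @return List with the transform `W` (J x J, phi = (gamma - mu) W),
#'   the raw means `mu`, and `psi_mean`.
#' @export
orthonormalise <- function(beta = NULL, gamma, sample, tol = 1e-12) {
  y <- if (inherits(sample, "spde_sample")) sample$y else as.numeric(sample)
  J <- length(gamma)
  psi_mean <- if (!is.null(beta)) mean(beta$f(y)) else 0
  if (J == 0)
    return(list(W = matrix(0, 0, 0), mu = numeric(0), psi_mean = psi_mean))
  G <- raw_eval(gamma, y, "f")$f
  if (!all(is.finite(G))) stop("basis function non-finite at a data point")
  mu <- colMeans(G)
  Phi <- sweep(G, 2, mu)
  W <- diag(J)
  # two sweeps: a single modified Gram-Schmidt pass loses orthogonality for
  # bases with extreme dynamic range (e.g. high monomial powers on a long
  # semi-infinite bulk); one re-orthogonalisation restores it to near
  # machine precision ("twice is enough")
  for (pass in 1:2) {
    for (j in seq_len(J)) {
      nrm <- sqrt(mean(Phi[, j]^2))
      if (!is.finite(nrm) || nrm < tol)
        stop("collinear basis: norm collapse during Gram-Schmidt sweep")
      Phi[, j] <- Phi[, j] / nrm
      W[, j] <- W[, j] / nrm
      if (j < J) {
        ks <- (j + 1):J
        r <- colMeans(Phi[, j] * Phi[, ks, drop = FALSE])
        Phi[, ks] <- Phi[, ks, drop = FALSE] - outer(Phi[, j], r)
        W[, ks] <- W[, ks, drop = FALSE] - outer(W[, j], r)
      }
    }
  }
  list(W = W, mu = mu, psi_mean = psi_mean)
}

# ---------------------------------------------------------------------------
# Assembled basis (boundary terms first, then bulk), with extrapolation
# anchors and the orthonormal transform.

assemble_basis <- function(sample, bulk, boundary = character(0),
                           psi = NULL, control = spde_control()) {
  domain <- sample$domain
  kind <- domain$kind
  bfuns <- boundary_term_set(domain, boundary)
  singular <- attr(bfuns, "singular")
  if (is.null(singular)) singular <- c(FALSE, FALSE)
  knots <- NULL
  bulk_funs <- switch(bulk$type,
    poly = {
      fs <- polynomial_raw(bulk$J0, bulk$powers, symmetric = domain$symmetric,
                           interval = sample$bulk)
      if (domain$periodic && length(fs) > 0) {
        ext <- polynomial_raw(bulk$J0 + 1, symmetric = domain$symmetric)
        vals <- vapply(ext, function(g) g$f(-1) - g$f(1), 0)
        ns <- constrained_null_space(rbind(vals), control$svd_rtol)
        combine_raw(ext, ns)[seq_len(min(bulk$J0, ncol(ns)))]
      } else fs
    },
    trig = {
      if (kind != "bounded") stop("trigonometric basis requires a bounded domain")
      fs <- trigonometric_raw(bulk$J0, symmetric = domain$symmetric)
      if (domain$periodic && length(fs) > 0) {
        ext <- trigonometric_raw(bulk$J0 + 1, symmetric = domain$symmetric)
        vals <- vapply(ext, function(g) g$f(-1) - g$f(1), 0)
        ns <- constrained_null_space(rbind(vals), control$svd_rtol)
        combine_raw(ext, ns)[seq_len(min(bulk$J0, ncol(ns)))]
      } else fs
    },
    spline = {
      knots <- bulk$knots
      spline_raw(knots, sample$bulk[1], sample$bulk[2], sample$y,
                 symmetric = domain$symmetric, periodic = domain$periodic,
                 rtol = control$svd_rtol)
    },
    none = list(),
    stop("unknown bulk basis type"))
  funs <- c(bfuns, bulk_funs)
  J_b <- length(bfuns); J_0 <- length(bulk_funs)
  ortho <- orthonormalise(psi, funs, sample, tol = control$collinear_tol)
  structure(list(
    funs = funs, W = ortho$W, mu = ortho$mu, J = J_b + J_0,
    J_b = J_b, J_0 = J_0,
    labels = vapply(funs, `[[`, "", "label"),
    psi = psi, psi_mean = ortho$psi_mean,
    anchors = sample$anchors, bulk = sample$bulk, knots = knots,
    singular = singular, kind = kind
  ), class = "spde_basis")
}

# Evaluate the orthonormal basis (and psi) with derivatives at y, applying
# the linear tail extrapolation beyond the anchors on unbounded domains.
basis_matrices <- function(basis, y) {
  kind <- basis$kind
  if (kind == "bounded") {
    if (any(y < -1 - 1e-9 | y > 1 + 1e-9)) stop("evaluation point outside the domain")
    yc <- pmin(pmax(y, -1), 1)
    ext <- rep(FALSE, length(y))
  } else if (kind == "semi_infinite") {
    if (any(y < 0)) stop("evaluation point outside the domain")
    yc <- pmin(y, basis$anchors[2])
    ext <- y > basis$anchors[2]
  } else {
    yc <- pmin(pmax(y, basis$anchors[1]), basis$anchors[2])
    ext <- y < basis$anchors[1] | y > basis$anchors[2]
  }
  E <- raw_eval(basis$funs, yc)
  F <- E$f; D1 <- E$d1; D2 <- E$d2
  if (any(ext)) {
    dy <- y - yc
    F[ext, ] <- F[ext, , drop = FALSE] + D1[ext, , drop = FALSE] * dy[ext]
    D2[ext, ] <- 0
  }
  J <- basis$J
  if (J > 0) {
    Fc <- sweep(F, 2, basis$mu)
    Phi <- Fc %*% basis$W; dPhi <- D1 %*% basis$W; d2Phi <- D2 %*% basis$W
  } else {
    Phi <- dPhi <- d2Phi <- matrix(0, length(y), 0)
  }
  if (!is.null(basis$psi)) {
    pv <- basis$psi$f(yc); p1 <- basis$psi$d1(yc); p2 <- basis$psi$d2(yc)
    if (any(ext)) {
      pv[ext] <- pv[ext] + p1[ext] * (y - yc)[ext]
      p2[ext] <- 0
    }
    psi_v <- pv - basis$psi_mean
  } else {
    psi_v <- p1 <- p2 <- rep(0, length(y))
  }
  list(Phi = Phi, dPhi = dPhi, d2Phi = d2Phi,
       psi = psi_v, psi1 = p1, psi2 = p2)
}
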