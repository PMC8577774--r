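#' Declare the support of a probability density
#'
#' A domain declaration describes the support of the density to be
#' estimated: a bounded interval \eqn{[a, b]}, the whole real line, or a
#' semi-infinite interval \eqn{[a, \infty)} (or \eqn{(-\infty, b]}, which is
#' handled internally by negating the data). Optional flags declare symmetry
#' of the density or, on bounded intervals, periodicity.
#'
#' @param kind One of `"bounded"`, `"infinite"`, `"semi_infinite"`.
#' @param a Lower endpoint (bounded and semi-infinite domains).
#' @param b Upper endpoint (bounded domains; for a semi-infinite domain,
#'   supplying `b` instead of `a` declares the upper-bounded interval
#'   \eqn{(-\infty, b]}).
#' @param symmetric Logical; is the density known to be symmetric? On the
#'   infinite domain the centre of symmetry `symmetry_point` must be given;
#'   on a bounded domain symmetry is about the interval midpoint.
#' @param symmetry_point Centre of symmetry \eqn{x_*} for the symmetric
#'   infinite domain.
#' @param periodic Logical; periodic density on a bounded interval (the two
#'   endpoints are identified). Mutually exclusive with `symmetric`.
#'
#' @return An object of class `"spde_domain"`.
#' @examples
#' spde_domain("bounded", a = 0, b = 1)
#' spde_domain("semi_infinite", a = 0)
#' spde_domain("infinite", symmetric = TRUE, symmetry_point = 0)
#' @export
spde_domain <- function(kind = c("bounded", "infinite", "semi_infinite"),
                        a = NULL, b = NULL, symmetric = FALSE,
                        symmetry_point = NULL, periodic = FALSE) {
  kind <- match.arg(kind)
  if (symmetric && periodic)
    stop("'symmetric' and 'periodic' are mutually exclusive")
  if (periodic && kind != "bounded")
    stop("'periodic' is only meaningful on a bounded domain")
  orient <- 1
  if (kind == "bounded") {
    if (is.null(a) || is.null(b)) stop("bounded domain requires both 'a' and 'b'")
    if (!is.finite(a) || !is.finite(b) || a >= b) stop("bounded domain requires a < b")
  } else if (kind == "semi_infinite") {
    if (is.null(a) && is.null(b))
      stop("semi-infinite domain requires a lower endpoint 'a' (or upper 'b')")
    if (!is.null(a) && !is.null(b))
      stop("semi-infinite domain takes exactly one of 'a' or 'b'")
    if (is.null(a)) {           # (-Inf, b]: work with -X on [-b, Inf)
      orient <- -1
      a <- -b
      b <- NULL
    }
    if (!is.finite(a)) stop("finite endpoint required")
    if (symmetric) stop("'symmetric' is not available on a semi-infinite domain")
  } else {
    a <- NULL; b <- NULL
    if (symmetric && is.null(symmetry_point))
      stop("symmetric infinite domain requires 'symmetry_point'")
  }
  structure(list(kind = kind, a = a, b = b, symmetric = isTRUE(symmetric),
                 symmetry_point = symmetry_point, periodic = isTRUE(periodic),
                 orient = orient),
            class = "spde_domain")
}

#' @export
print.spde_domain <- function(x, ...) {
  desc <- switch(x$kind,
    bounded = sprintf("[%g, %g]", x$a, x$b),
    infinite = "(-Inf, Inf)",
    semi_infinite = if (x$orient > 0) sprintf("[%g, Inf)", x$a)
                    else sprintf("(-Inf, %g]", -x$a))
  cat("Domain:", desc)
  if (x$symmetric) cat(" (symmetric)")
  if (x$periodic) cat(" (periodic)")
  cat("\n")
  invisible(x)
}

#' Rescale a data sample to the working coordinates
#'
#' Maps the sample onto the internal coordinate system in which all basis
#' construction and inference is done: a bounded interval \eqn{[a, b]} onto
#' \eqn{[-1, 1]} via \eqn{y = (2x - a - b)/(b - a)}; the infinite domain onto
#' itself via \eqn{y = (x - \mu)/\sigma} with the sample mean and (population)
#' standard deviation, or about the declared symmetry point; a semi-infinite
#' domain onto \eqn{[0, \infty)} via \eqn{y = (x - a)/\mu} with
#' \eqn{\mu = \mathrm{mean}(x - a)}, so that the rescaled sample has mean 1.
#'
#' @param x Numeric vector of observations.
#' @param domain An [spde_domain()] declaration.
#' @return An object of class `"spde_sample"` with elements `y` (rescaled
#'   data, original order), `ysort`, the rescaling constants `c` and `s`, the
#'   rescaled extremes `ya`, `yb`, the extrapolation `anchors`, the bulk
#'   interval `bulk`, and `N`.
#' @export
rescale_sample <- function(x, domain) {
  stopifnot(inherits(domain, "spde_domain"))
  if (length(x) == 0L) stop("empty sample")
  if (anyNA(x) || !all(is.finite(x))) stop("sample contains missing or non-finite values")
  x <- as.numeric(x) * domain$orient
  a <- if (!is.null(domain$a)) domain$a * ifelse(domain$orient < 0, 1, 1) else NULL
  kind <- domain$kind
  if (kind == "bounded") {
    if (any(x < domain$a | x > domain$b)) stop("data point outside the declared domain")
    cc <- (domain$a + domain$b) / 2
    ss <- (domain$b - domain$a) / 2
  } else if (kind == "infinite") {
    if (domain$symmetric) {
      cc <- domain$symmetry_point
      ss <- sqrt(mean((x - cc)^2))
    } else {
      cc <- mean(x)
      ss <- sqrt(mean((x - cc)^2))
    }
    if (ss <= 0) stop("degenerate sample: zero spread")
  } else {
    if (any(x < domain$a)) stop("data point outside the declared domain")
    cc <- domain$a
    ss <- mean(x - domain$a)
    if (ss <= 0) stop("degenerate sample: zero spread")
  }
  y <- (x - cc) / ss
  ya <- min(y); yb <- max(y)
  if (ya == yb) stop("degenerate sample: zero spread")
  anchors <- switch(kind,
    bounded = NULL,
    infinite = if (domain$symmetric) {
      M <- max(abs(ya), abs(yb)); c(-M, M)
    } else c(ya, yb),
    semi_infinite = c(NA_real_, yb))
  bulk <- switch(kind,
    bounded = c(-1, 1),
    infinite = anchors,
    semi_infinite = c(0, yb))
  structure(list(y = y, ysort = sort(y), c = cc, s = ss, ya = ya, yb = yb,
                 anchors = anchors, bulk = bulk, N = length(y),
                 domain = domain),
            class = "spde_sample")
}

#' @export
print.spde_sample <- function(x, ...) {
  cat(sprintf("Rescaled sample: N = %d, c = %g, s = %g, y in [%.4g, %.4g]\n",
              x$N, x$c, x$s, x$ya, x$yb))
  print(x$domain)
  invisible(x)
}

# Map x-scale points to y-scale, honouring domain orientation.
x_to_y <- function(sample, x) {
  (x * sample$domain$orient - sample$c) / sample$s
}
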