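# Composite Gauss-Legendre quadrature over the bulk interval.
#
# Segment breakpoints are placed at all spline knots plus the interval
# endpoints. A segment adjacent to an endpoint carrying a singular boundary
# term (log or reciprocal) is subdivided geometrically towards that endpoint;
# Gauss nodes are strictly interior, so integrable singularities of the
# potential are handled without special-casing.

.quad_cache <- new.env(parent = emptyenv())

gauss_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.quad_cache[[key]])) {
    .quad_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  .quad_cache[[key]]
}

# Geometric subdivision of [p, q] towards `end` ("lower"/"upper"):
# sub-segment widths shrink by `ratio` towards the singular endpoint.
geom_subdivide <- function(p, q, end, sub = 10, ratio = 0.2) {
  d <- (q - p) * ratio^(seq_len(sub - 1))
  if (end == "lower") sort(c(p, p + d, q)) else sort(c(p, q - d, q))
}

#' Build a composite Gauss--Legendre quadrature scheme
#'
#' @param breaks Ordered breakpoints covering the bulk interval (endpoints
#'   plus any interior spline knots).
#' @param n_nodes Gauss--Legendre nodes per segment.
#' @param singular Logical vector of length 2: does a singular boundary term
#'   sit at the lower / upper end of the interval?
#' @param sub,ratio Number of geometric sub-segments and shrink ratio used
#'   next to a singular endpoint.
#' @param max_len Longest allowed segment: longer segments are split
#'   uniformly so that the node spacing resolves density features on the
#'   scale of the standardised data (knot-free models would otherwise cover
#'   the whole bulk interval with a single rule).
#' @return A list with `nodes`, `weights` and the final `segments`.
#' @keywords internal
quadrature_scheme <- function(breaks, n_nodes = 50,
                              singular = c(FALSE, FALSE),
                              sub = 10, ratio = 0.2, max_len = 1) {
  breaks <- sort(unique(breaks))
  if (length(breaks) < 2) stop("need at least two breakpoints")
  if (any(singular)) {
    if (length(breaks) == 2 && all(singular)) {
      breaks <- c(breaks[1], mean(breaks), breaks[2])
    }
    if (singular[1]) {
      breaks <- sort(unique(c(geom_subdivide(breaks[1], breaks[2], "lower",
                                             sub, ratio), breaks)))
    }
    if (singular[2]) {
      nb <- length(breaks)
      breaks <- sort(unique(c(breaks,
                              geom_subdivide(breaks[nb - 1], breaks[nb],
                                             "upper", sub, ratio))))
    }
  }
  if (is.finite(max_len) && max_len > 0) {
    w <- diff(breaks)
    long <- which(w > max_len)
    if (length(long)) {
      extra <- unlist(lapply(long, function(i) {
        ns <- ceiling(w[i] / max_len)
        breaks[i] + w[i] * seq_len(ns - 1) / ns
      }))
      breaks <- sort(unique(c(breaks, extra)))
    }
  }
  base <- gauss_rule(n_nodes)
  nseg <- length(breaks) - 1
  half <- diff(breaks) / 2
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nodes <- as.vector(outer(base$x, half) + rep(mid, each = n_nodes))
  weights <- as.vector(outer(base$w, half))
  list(nodes = nodes, weights = weights, segments = breaks,
       n_nodes = n_nodes)
}

# Composite Simpson rule on n (odd) equispaced points.
simpson_weights <- function(n, a, b) {
  if (n %% 2 == 0) n <- n + 1
  h <- (b - a) / (n - 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  list(x = seq(a, b, length.out = n), w = w * h / 3)
}
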