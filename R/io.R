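# Plain-text input/output helpers.

#' Read a univariate sample from a plain-text or single-column CSV file
#'
#' One decimal number per row; an optional single header line is tolerated.
#' Blank rows and non-numeric values are rejected.
#'
#' @param path File path.
#' @return Numeric vector.
#' @export
read_sample <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (length(lines) == 0) stop("empty input file")
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(lines[1]))) && length(lines) > 1)
    start <- 2L
  lines <- lines[start:length(lines)]
  if (any(lines == "")) stop("blank row in input")
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x)) stop("non-numeric or NaN value in input")
  x
}

#' Write a density estimate on a grid to a TSV file
#'
#' @param object An `spde` or `spde_fit`.
#' @param path Output path.
#' @param from,to Grid range (defaults to the data range, extended on
#'   unbounded sides).
#' @param n Grid resolution.
#' @return Invisibly, the data frame written.
#' @export
write_density_grid <- function(object, path, from = NULL, to = NULL,
                               n = 512) {
  sm <- if (inherits(object, "spde")) object$sample else object$model$sample
  xr <- range(sm$y * sm$s + sm$c) * sm$domain$orient
  pad <- 0.1 * diff(xr)
  kind <- sm$domain$kind
  if (is.null(from))
    from <- switch(kind, bounded = sm$domain$a,
                   semi_infinite = if (sm$domain$orient > 0) sm$domain$a
                                   else min(xr) - pad,
                   min(xr) - pad)
  if (is.null(to))
    to <- switch(kind, bounded = sm$domain$b,
                 semi_infinite = if (sm$domain$orient > 0) max(xr) + pad
                                 else -sm$domain$a,
                 max(xr) + pad)
  x <- seq(from, to, length.out = n)
  d <- data.frame(x = x, density = density_estimate(
    if (inherits(object, "spde")) object$fit else object, x))
  utils::write.table(d, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(d)
}
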