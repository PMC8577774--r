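# Parameter uncertainty: Fisher information, error covariance with block
# inflation for dependent data, parameter ensembles under the slope
# constraints, and bootstrap refitting.

#' Fisher information matrix of a converged fit
#'
#' For an exponential family the expected and observed Fisher information
#' coincide: J = N (E[phi phi^T] - E[phi] E[phi]^T) = -H at the maximum
#' likelihood solution. On the statistically orthogonal basis J is close to
#' N times the identity.
#'
#' @param fit A converged `spde_fit`.
#' @return The J x J Fisher information matrix.
#' @export
fisher_information <- function(fit) {
  stopifnot(inherits(fit, "spde_fit"))
  if (!isTRUE(fit$converged)) stop("Fisher information requires a converged fit")
  -fit$evaluation$H
}

#' Error covariance with block inflation for dependent data
#'
#' The error covariance is C = J^{-1} V J^{-1} with V the covariance of the
#' score accumulated over blocks of `l_b` consecutive observations: block
#' sums of phi(y_n) - <phi> are formed over floor(N/l_b) disjoint blocks and
#' V = sum_i g_i g_i^T, multiplied by N/(floor(N/l_b) l_b) when N is not a
#' multiple of the block length. With l_b = 1 and independent data V = J and
#' C reduces to J^{-1}.
#'
#' @param fit A converged `spde_fit`.
#' @param l_b Block length (1 for independent data).
#' @return List of class `"spde_uncertainty"` with `fisher`, `V`, `C`, the
#'   Cholesky factor `L` (C = L L^T) and `l_b`.
#' @export
block_inflated_covariance <- function(fit, l_b = 1) {
  stopifnot(inherits(fit, "spde_fit"))
  J <- fisher_information(fit)
  y <- fit$model$sample$y            # original time order
  N <- length(y)
  l_b <- as.integer(l_b)
  if (l_b < 1) stop("l_b must be at least 1")
  nblock <- N %/% l_b
  if (nblock < 2) stop("fewer than 2 blocks: decrease the block length")
  B <- basis_matrices(fit$model$basis, y)
  Phi <- B$Phi                        # columns already have zero sample mean
  Phi <- sweep(Phi, 2, colMeans(Phi))
  idx <- rep(seq_len(nblock), each = l_b)
  used <- seq_len(nblock * l_b)
  G <- rowsum(Phi[used, , drop = FALSE], idx)
  V <- crossprod(G)
  if (N %% l_b != 0) V <- V * N / (nblock * l_b)
  Jinv <- solve(J)
  C <- Jinv %*% V %*% Jinv
  C <- (C + t(C)) / 2
  L <- t(chol(C))
  structure(list(fisher = J, V = V, C = C, L = L, l_b = l_b,
                 n_blocks = nblock),
            class = "spde_uncertainty")
}

#' Parameter ensemble under the slope constraints
#'
#' Draws proposals alpha-hat + L v with v standard normal and accepts only
#' those satisfying the tail slope inequality constraints, yielding an
#' ensemble of normalisable densities consistent with the parameter
#' uncertainty.
#'
#' @param fit A converged `spde_fit`.
#' @param C Error covariance (defaults to the independent-data
#'   `solve(fisher_information(fit))`).
#' @param M Ensemble size.
#' @param seed Optional RNG seed.
#' @param max_tries Cap on total proposals (guards against a solution close
#'   to the admissibility boundary).
#' @return M x J matrix of accepted parameter vectors with attribute
#'   `acceptance_rate`.
#' @export
parameter_ensemble <- function(fit, C = NULL, M = 1000, seed = NULL,
                               max_tries = 100 * M) {
  stopifnot(inherits(fit, "spde_fit"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(C)) C <- solve(fisher_information(fit))
  C <- (C + t(C)) / 2
  L <- t(chol(C))
  J <- fit$J
  out <- matrix(NA_real_, M, J)
  n_acc <- 0L; n_try <- 0L
  while (n_acc < M && n_try < max_tries) {
    take <- min(M - n_acc, 256L)
    prop <- matrix(fit$alpha, take, J, byrow = TRUE) +
      matrix(stats::rnorm(take * J), take, J) %*% t(L)
    n_try <- n_try + take
    for (i in seq_len(take)) {
      if (admissible(fit$model, prop[i, ])) {
        n_acc <- n_acc + 1L
        out[n_acc, ] <- prop[i, ]
      }
    }
  }
  out <- out[seq_len(n_acc), , drop = FALSE]
  rate <- if (n_try > 0) n_acc / n_try else NA_real_
  if (is.finite(rate) && rate < 0.01)
    warning("ensemble acceptance rate below 1%: solution near the admissibility boundary")
  attr(out, "acceptance_rate") <- rate
  out
}

#' Bootstrap refitting of the density model
#'
#' Resamples the data (with replacement; non-overlapping block resampling of
#' blocks of length `l_b` for dependent data, or moving blocks with
#' `moving = TRUE`) and re-runs the estimation on each resample. By default
#' the model structure (family, basis size, boundary terms, knot scheme) is
#' held fixed and only the parameters are re-estimated; with
#' `reselect = TRUE` the full BIC selection is repeated per resample.
#' Resamples on which no maximum likelihood estimate exists are recorded and
#' skipped.
#'
#' @param est An `spde` selection result (or `spde_fit` with its sample).
#' @param M Number of bootstrap resamples.
#' @param l_b Block length (1 = ordinary iid bootstrap).
#' @param seed Optional RNG seed.
#' @param moving Use moving (overlapping) blocks instead of the disjoint
#'   covariance blocks.
#' @param reselect Re-run the full model selection per resample.
#' @return List with `fits` (list of `spde_fit`s) and `failures` (count).
#' @export
bootstrap_models <- function(est, M = 100, l_b = 1, seed = NULL,
                             moving = FALSE, reselect = FALSE) {
  stopifnot(inherits(est, "spde"))
  if (!is.null(seed)) set.seed(seed)
  sample <- est$sample
  domain <- sample$domain
  x <- (sample$y * sample$s + sample$c) * domain$orient
  N <- length(x)
  fits <- vector("list", 0)
  failures <- 0L
  if (M < 1) return(list(fits = fits, failures = failures))
  for (b in seq_len(M)) {
    xb <- if (l_b <= 1) x[sample.int(N, N, replace = TRUE)] else {
      if (moving) {
        nb <- ceiling(N / l_b)
        starts <- sample.int(N - l_b + 1, nb, replace = TRUE)
        idx <- as.vector(outer(0:(l_b - 1), starts, `+`))[seq_len(N)]
        x[idx]
      } else {
        nblock <- N %/% l_b
        used <- seq_len(nblock * l_b)
        blocks <- split(used, rep(seq_len(nblock), each = l_b))
        idx <- unlist(blocks[sample.int(nblock, ceiling(N / l_b),
                                        replace = TRUE)])[seq_len(N)]
        x[idx]
      }
    }
    fb <- tryCatch({
      if (reselect)
        spde(xb, domain, families = est$families,
             boundary_sets = est$boundary_sets, control = est$control)$fit
      else
        refit_structure(est, xb)
    }, error = function(e) NULL)
    if (is.null(fb) || !isTRUE(fb$converged)) failures <- failures + 1L
    else fits[[length(fits) + 1L]] <- fb
  }
  list(fits = fits, failures = failures)
}

# Refit the chosen model structure (family, J0/knot scheme, boundary terms)
# on new data, re-estimating only the parameters.
refit_structure <- function(est, x) {
  stopifnot(inherits(est, "spde"))
  sample <- rescale_sample(x, est$sample$domain)
  bulk <- est$bulk
  if (bulk$type == "spline") {
    scheme <- if (est$family == "SPL1") "equidistant" else "quantile"
    K <- length(bulk$knots)
    kn <- place_knots(K, scheme, sample$bulk[1], sample$bulk[2],
                      sample$ysort)
    kn <- prune_knots_min_points(kn, sample)
    if (is.null(kn)) stop("refit: all knots pruned")
    bulk <- list(type = "spline", knots = kn)
  }
  basis <- assemble_basis(sample, bulk, est$boundary,
                          est$fit$model$basis$psi, est$control)
  model <- new_model(sample, basis, est$control)
  fit_mle(model, est$control)
}
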