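#' Fit ridge-regression BLUP of genome-wide marker effects
#'
#' Estimates additive marker effects from phenotypes by RR-BLUP: the model
#' `p = 1 mu + X a + e` with `a ~ N(0, sigma_a2 I)` and `e ~ N(0, sigma_e2 I)`
#' gives the shrinkage estimator `a_hat = (X'X + lambda I)^-1 X'(p - 1 mu_hat)`
#' with `lambda = sigma_e2 / sigma_a2` and `mu_hat` the generalised
#' least-squares intercept of the equivalent kernel model. Genotype columns
#' are used in their fixed -1/+1 coding without centring or standardisation;
#' the intercept absorbs the population mean (recoding rescales `a_hat`, not
#' the predictions).
#'
#' In `mode = "reml"` the variance ratio is estimated by restricted maximum
#' likelihood of the equivalent kernel model `p ~ N(1 mu, sigma_a2 K +
#' sigma_e2 I)`, `K = XX'`, via the spectral decomposition of the projected
#' kernel and a one-dimensional optimisation over `log10(lambda)`. In
#' `mode = "fixed_lambda"` the supplied ratio is used directly.
#'
#' The system is solved in the n-dimensional dual (kernel) space by default
#' whenever markers outnumber lines; the primal (marker-space) solver is
#' available for cross-checking and for wide-data-free problems. Both return
#' identical estimates up to numerical precision.
#'
#' @param genotypes A `dh_population` or a lines x markers matrix in -1/+1
#'   coding.
#' @param phenotypes A `phenotype_set` from [simulate_phenotypes()], or a
#'   numeric vector of phenotypic values (one per line).
#' @param mode `"reml"` (default) or `"fixed_lambda"`.
#' @param lambda Shrinkage ratio `sigma_e2 / sigma_a2`, required for
#'   `mode = "fixed_lambda"`.
#' @param solver `"auto"` (dual when markers > lines), `"dual"` or `"primal"`.
#'
#' @return An `rrblup` object: list with `mu` (intercept), `effects`
#'   (per-marker estimates), `lambda`, `sigma_a2`/`sigma_e2` (REML estimates;
#'   NA for fixed lambda), `mode`, `converged`, `marker_id`, and the training
#'   dimensions.
#' @examples
#' map <- build_map(n_markers = 70)
#' panel <- simulate_founders(map, seed = 1)
#' pop <- simulate_population(panel, cross_plan(panel, "factorial", 10), seed = 2)
#' eff <- calibrate_sigma_g(panel, cross_plan(panel, "factorial", 10),
#'                          draw_effects(map, seed = 3), 20, seed = 4)
#' ph <- simulate_phenotypes(genotypic_values(pop, eff), pop, trial_design())
#' fit <- fit_rrblup(pop, ph)
#' head(predict(fit, pop))
#' @export
fit_rrblup <- function(genotypes, phenotypes, mode = c("reml", "fixed_lambda"),
                       lambda = NULL, solver = c("auto", "dual", "primal")) {
  mode <- match.arg(mode)
  solver <- match.arg(solver)
  X <- if (inherits(genotypes, "dh_population")) genotypes$genotypes else as.matrix(genotypes)
  p <- if (is.data.frame(phenotypes)) phenotypes$p else as.numeric(phenotypes)
  n <- nrow(X); m <- ncol(X)
  if (length(p) != n) stop("phenotype length must equal line count", call. = FALSE)
  if (n < 2) stop("need at least two lines", call. = FALSE)
  if (any(!is.finite(X))) stop("genotype matrix must be finite", call. = FALSE)
  if (mode == "fixed_lambda") {
    if (is.null(lambda) || lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  }

  if (stats::var(p) < 1e-12) {
    return(new_rrblup(mu = mean(p), effects = numeric(m), lambda = Inf,
                      sigma_a2 = 0, sigma_e2 = NA_real_, mode = mode,
                      converged = FALSE, marker_id = colnames(X), n = n, m = m,
                      note = "zero phenotypic variance: all effects shrunk to 0"))
  }

  sigma_a2 <- NA_real_; sigma_e2 <- NA_real_; converged <- TRUE
  use_dual <- solver == "dual" || (solver == "auto" && m > n)
  K <- if (mode == "reml" || use_dual) tcrossprod(X) else NULL
  if (mode == "reml") {
    reml <- reml_lambda(K, p)
    lambda <- reml$lambda
    sigma_a2 <- reml$sigma_a2
    sigma_e2 <- reml$sigma_e2
    converged <- reml$converged
    if (!converged) {
      warning("REML hit the search boundary; using the clamped boundary lambda",
              call. = FALSE)
    }
  }

  if (use_dual) {
    H <- K
    diag(H) <- diag(H) + lambda
    Hi1 <- solve(H, rep(1, n))
    mu <- sum(Hi1 * p) / sum(Hi1)
    a <- drop(crossprod(X, solve(H, p - mu)))
  } else {
    # mixed-model equations in marker space, intercept included
    C <- crossprod(cbind(1, X))
    diag(C)[-1] <- diag(C)[-1] + lambda
    sol <- solve(C, crossprod(cbind(1, X), p))
    mu <- sol[1]
    a <- drop(sol[-1])
  }
  new_rrblup(mu = mu, effects = a, lambda = lambda, sigma_a2 = sigma_a2,
             sigma_e2 = sigma_e2, mode = mode, converged = converged,
             marker_id = colnames(X), n = n, m = m, note = NULL)
}

# Profile-REML estimate of lambda = sigma_e2/sigma_a2 for p ~ N(1 mu,
# sigma_a2 (K + lambda I)). The intercept is projected out; the restricted
# likelihood is profiled over sigma_a2 and optimised over log10(lambda) using
# the spectral decomposition of the projected kernel.
reml_lambda <- function(K, p, log10_bounds = c(-8, 8)) {
  n <- length(p)
  pc <- p - mean(p)
  Kc <- sweep(sweep(K, 1, colMeans(K)), 2, colMeans(K)) + mean(K)
  eig <- eigen(Kc, symmetric = TRUE)
  keep <- seq_len(n - 1) # the projected-out intercept direction has eigenvalue ~0
  xi <- pmax(eig$values[keep], 0)
  eta <- drop(crossprod(eig$vectors[, keep, drop = FALSE], pc))

  neg_restricted_ll <- function(log10_lambda) {
    d <- xi + 10^log10_lambda
    s2 <- sum(eta^2 / d) / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(d)))
  }
  opt <- stats::optimize(neg_restricted_ll, log10_bounds, tol = 1e-6)
  converged <- min(abs(opt$minimum - log10_bounds)) > 1e-3
  # a boundary solution is kept as the (clamped) REML estimate: the lower
  # bound is near-interpolation, the upper bound total shrinkage
  lam <- 10^opt$minimum
  sigma_a2 <- sum(eta^2 / (xi + lam)) / (n - 1)
  list(lambda = lam, sigma_a2 = sigma_a2, sigma_e2 = lam * sigma_a2,
       converged = converged)
}

new_rrblup <- function(mu, effects, lambda, sigma_a2, sigma_e2, mode,
                       converged, marker_id, n, m, note) {
  structure(list(mu = mu, effects = unname(effects), lambda = lambda,
                 sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, mode = mode,
                 converged = converged, marker_id = marker_id, n = n, m = m,
                 note = note),
            class = "rrblup")
}

#' @export
print.rrblup <- function(x, ...) {
  cat(sprintf("<rrblup> %d lines x %d markers, mode %s, lambda %.4g, mu %.4g\n",
              x$n, x$m, x$mode, x$lambda, x$mu))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Genomic predictions from a fitted RR-BLUP model
#'
#' `y = mu_hat + X a_hat` for the supplied genotypes — here typically the very
#' lines that were phenotyped, i.e. genomic prediction of tested material.
#'
#' @param object An `rrblup` fit.
#' @param genotypes A `dh_population` or -1/+1 matrix with the training marker
#'   set.
#' @param ... Unused.
#' @return A tibble (`line_id`, `y`); `line_id` is taken from the population
#'   (or row names, or an index when unnamed).
#' @export
predict.rrblup <- function(object, genotypes, ...) {
  X <- if (inherits(genotypes, "dh_population")) genotypes$genotypes else as.matrix(genotypes)
  if (ncol(X) != object$m) stop("marker set does not match the training set", call. = FALSE)
  if (!is.null(colnames(X)) && !is.null(object$marker_id) &&
      !identical(colnames(X), object$marker_id)) {
    stop("marker set does not match the training set", call. = FALSE)
  }
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  tibble::tibble(line_id = ids, y = object$mu + drop(X %*% object$effects))
}

#' @rdname fit_rrblup
#' @param x An `rrblup` fit.
#' @param ... Unused.
#' @return For `tidy()`: a tibble (`marker_id`, `estimate`) of estimated
#'   effects; for `glance()`: a one-row tibble of fit-level summaries.
#' @export
tidy.rrblup <- function(x, ...) {
  tibble::tibble(
    marker_id = x$marker_id %||% as.character(seq_len(x$m)),
    estimate = x$effects
  )
}

#' @rdname fit_rrblup
#' @export
glance.rrblup <- function(x, ...) {
  tibble::tibble(mu = x$mu, lambda = x$lambda, sigma_a2 = x$sigma_a2,
                 sigma_e2 = x$sigma_e2, mode = x$mode, converged = x$converged,
                 n_lines = x$n, n_markers = x$m)
}
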