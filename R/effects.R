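#' Draw raw additive marker effects
#'
#' Draws per-marker additive effects for the trait architecture. The default
#' is Gaussian effects at every marker — the infinitesimal-like regime in
#' which ridge-regression BLUP converges to GBLUP. `laplace` gives
#' heavier-tailed effects and `sparse` restricts the trait to `k` randomly
#' chosen markers (the remaining effects are exactly zero), for sensitivity
#' analyses of the genetic architecture.
#'
#' Raw effects are on an arbitrary scale; [calibrate_sigma_g()] rescales them
#' so the DH population genetic variance matches a target.
#'
#' @param map A `genetic_map`.
#' @param distribution `"gaussian"`, `"laplace"`, or `"sparse"`.
#' @param k Number of non-zero effects when `distribution = "sparse"`.
#' @param intercept Trait intercept in trait units (default 85, the centre of
#'   a typical barley yield range in dt/ha; correlations are
#'   location-invariant so this is cosmetic).
#' @param seed Optional integer seed.
#'
#' @return A `marker_effects` object: tibble (`marker_id`, `chrom`, `pos`,
#'   `effect`) with attributes `intercept` and `calibration` (NULL until
#'   calibrated).
#' @examples
#' eff <- draw_effects(build_map(n_markers = 70), seed = 1)
#' @export
draw_effects <- function(map, distribution = c("gaussian", "laplace", "sparse"),
                         k = NULL, intercept = 85, seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(inherits(map, "genetic_map"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- nrow(map)
  eff <- switch(distribution,
    gaussian = stats::rnorm(m),
    laplace = stats::rexp(m) * sample(c(-1, 1), m, replace = TRUE),
    sparse = {
      if (is.null(k)) stop("`k` is required for sparse effects", call. = FALSE)
      if (k > m) stop("`k` exceeds the marker count", call. = FALSE)
      a <- numeric(m)
      if (k > 0) a[sample.int(m, k)] <- stats::rnorm(k)
      a
    }
  )
  new_marker_effects(map, eff, intercept, calibration = NULL)
}

new_marker_effects <- function(map, effect, intercept, calibration) {
  stopifnot(length(effect) == nrow(map))
  out <- tibble::tibble(marker_id = map$marker_id, chrom = map$chrom,
                        pos = map$pos, effect = as.numeric(effect))
  structure(out, intercept = as.numeric(intercept), calibration = calibration,
            class = c("marker_effects", class(out)))
}

#' @export
print.marker_effects <- function(x, ...) {
  cal <- attr(x, "calibration")
  cat(sprintf("<marker_effects> %d markers, intercept %.3g%s\n",
              nrow(x), attr(x, "intercept"),
              if (is.null(cal)) " (uncalibrated)"
              else sprintf(", calibrated to sigma_g^2 = %.3g (%s)",
                           cal$target_sigma_g2, cal$scheme)))
  NextMethod()
}

#' True genotypic values of a DH population
#'
#' The genotypic value of each line is the linear genome-wide sum
#' `g = intercept + X a` with `X` the -1/+1 genotype matrix and `a` the
#' per-marker additive effects. DH material carries no dominance, so the
#' additive sum is the complete genetic model.
#'
#' @param pop A `dh_population`.
#' @param effects A `marker_effects` object on the same map.
#' @return A tibble (`line_id`, `cross_id`, `g`) of per-line genotypic values
#'   in trait units.
#' @export
genotypic_values <- function(pop, effects) {
  stopifnot(inherits(pop, "dh_population"), inherits(effects, "marker_effects"))
  if (ncol(pop$genotypes) != nrow(effects) ||
      !identical(colnames(pop$genotypes), effects$marker_id)) {
    stop("marker sets of population and effects do not match", call. = FALSE)
  }
  g <- attr(effects, "intercept") + unname(drop(pop$genotypes %*% effects$effect))
  tibble::tibble(line_id = pop$lines$line_id, cross_id = pop$lines$cross_id,
                 g = g)
}

#' Calibrate marker effects to a target population genetic variance
#'
#' Rescales raw marker effects so that the genetic variance of DH populations
#' produced under a given mating plan matches `target_sigma_g2`. A large
#' calibration population is simulated under the plan (the plan's crosses with
#' family sizes enlarged to roughly `n_calibration_lines` total), the variance
#' of the raw genotypic values is measured, and all effects are multiplied by
#' `sqrt(target / realized)`. On the calibration population itself the
#' rescaled genetic variance equals the target exactly; an independent fresh
#' draw is recorded in the calibration record as a Monte-Carlo check.
#'
#' Calibration is mating-scheme specific: the same raw effects calibrated
#' under a factorial plan (target e.g. 20) and under a diallel plan (target
#' e.g. 2) give different scaling factors, because the two schemes segregate
#' different subsets of markers.
#'
#' @param panel A `founder_panel`.
#' @param plan A `cross_plan` defining the mating scheme to calibrate for.
#' @param effects Raw `marker_effects` from [draw_effects()].
#' @param target_sigma_g2 Target genetic variance (trait units squared), > 0.
#' @param n_calibration_lines Approximate size of the calibration population
#'   (default 5000).
#' @param seed Optional integer seed for the calibration draws.
#'
#' @return A calibrated `marker_effects` object whose `calibration` attribute
#'   records the target, the raw (pre-scaling) variance, the scaling factor,
#'   the scheme, and the realized variance on a fresh draw.
#' @export
calibrate_sigma_g <- function(panel, plan, effects, target_sigma_g2,
                              n_calibration_lines = 5000, seed = NULL) {
  stopifnot(inherits(panel, "founder_panel"), inherits(plan, "cross_plan"),
            inherits(effects, "marker_effects"))
  if (target_sigma_g2 <= 0) stop("`target_sigma_g2` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_per <- max(2L, ceiling(n_calibration_lines / nrow(plan)))
  big_plan <- plan
  attr(big_plan, "n_lines_per_cross") <- n_per

  cal_pop <- simulate_population(panel, big_plan)
  g_raw <- drop(cal_pop$genotypes %*% effects$effect)
  raw_var <- stats::var(g_raw)
  if (raw_var < 1e-12) {
    stop("uncalibratable: raw genetic variance is (near) zero under this plan",
         call. = FALSE)
  }
  scale_factor <- sqrt(target_sigma_g2 / raw_var)
  scaled <- effects$effect * scale_factor

  check_pop <- simulate_population(panel, big_plan)
  check_var <- stats::var(drop(check_pop$genotypes %*% scaled))

  calibration <- list(
    target_sigma_g2 = target_sigma_g2,
    raw_sigma_g2 = raw_var,
    scale_factor = scale_factor,
    scheme = attr(plan, "scheme"),
    n_calibration_lines = nrow(cal_pop$genotypes),
    fresh_draw_sigma_g2 = check_var
  )
  new_marker_effects(panel$map, scaled, attr(effects, "intercept"), calibration)
}

#' @rdname calibrate_sigma_g
#' @param x A `marker_effects` object.
#' @param ... Unused.
#' @return For `glance()`: a one-row tibble with the calibration record
#'   (all-NA columns when uncalibrated).
#' @export
glance.marker_effects <- function(x, ...) {
  cal <- attr(x, "calibration")
  if (is.null(cal)) {
    return(tibble::tibble(target_sigma_g2 = NA_real_, raw_sigma_g2 = NA_real_,
                          scale_factor = NA_real_, scheme = NA_character_,
                          n_calibration_lines = NA_integer_,
                          fresh_draw_sigma_g2 = NA_real_))
  }
  tibble::as_tibble(cal)
}
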