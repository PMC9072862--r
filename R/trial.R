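#' Specify a virtual field-trial design
#'
#' A trial design is the number of environments `E`, the number of
#' replications per environment `R`, and the three masking variance
#' components on the single-trial scale: cross-by-environment `sigma_ce2`,
#' line-by-environment `sigma_le2` and plot residual `sigma_eps2` (all in
#' squared trait units). On the entry-mean scale the design masks genotypic
#' values with variance `sigma_ce2/E + sigma_le2/E + sigma_eps2/(E R)`.
#'
#' @param E Environments, >= 1.
#' @param R Replications per environment, >= 1.
#' @param sigma_ce2,sigma_le2,sigma_eps2 Non-negative variance components.
#' @return A `trial_design` (one-row tibble with the five fields).
#' @examples
#' trial_design(1, 1, 10, 10, 30)        # unreplicated single environment
#' trial_design(3, 2, 10, 10, 30)        # replicated multi-environment
#' @export
trial_design <- function(E = 1, R = 1, sigma_ce2 = 10, sigma_le2 = 10,
                         sigma_eps2 = 30) {
  if (E < 1 || R < 1) stop("E and R must be >= 1", call. = FALSE)
  if (sigma_ce2 < 0 || sigma_le2 < 0 || sigma_eps2 < 0) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  structure(
    tibble::tibble(E = as.integer(E), R = as.integer(R),
                   sigma_ce2 = sigma_ce2, sigma_le2 = sigma_le2,
                   sigma_eps2 = sigma_eps2),
    class = c("trial_design", "tbl_df", "tbl", "data.frame")
  )
}

#' Total masking variance of a trial design on the entry-mean scale
#'
#' @param design A `trial_design`.
#' @return `sigma_ce2/E + sigma_le2/E + sigma_eps2/(E R)`.
#' @export
masking_variance <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  design$sigma_ce2 / design$E + design$sigma_le2 / design$E +
    design$sigma_eps2 / (design$E * design$R)
}

#' Expected correlation between phenotype and genotypic value
#'
#' Closed-form expectation `sqrt(sigma_g2 / (sigma_g2 + sigma_m2))` where
#' `sigma_m2` is the entry-mean masking variance of the design — the analytic
#' oracle for the simulated r(p, g): it is the square root of the entry-mean
#' heritability.
#'
#' @param sigma_g2 Genetic variance of the population.
#' @param design A `trial_design`.
#' @return Expected Pearson correlation r(p, g).
#' @examples
#' expected_r_pg(20, trial_design(1, 1, 10, 10, 30)) # sqrt(20/70)
#' @export
expected_r_pg <- function(sigma_g2, design) {
  sqrt(sigma_g2 / (sigma_g2 + masking_variance(design)))
}

#' Simulate masking effects for a DH population in a trial design
#'
#' Draws the three independent masking components on the entry-mean scale:
#' one cross-by-environment deviation `u` per cross with variance
#' `sigma_ce2/E` (shared by all lines of the cross), one line-by-environment
#' deviation `v` per line with variance `sigma_le2/E`, and one residual `w`
#' per line with variance `sigma_eps2/(E R)`. The masking effect of a line is
#' `m = u + v + w`.
#'
#' @param pop A `dh_population` (supplies the cross-of-origin labels).
#' @param design A `trial_design`.
#' @return A tibble (`line_id`, `cross_id`, `u`, `v`, `w`, `m`).
#' @export
simulate_masking <- function(pop, design) {
  stopifnot(inherits(pop, "dh_population"), inherits(design, "trial_design"))
  lines <- pop$lines
  crosses <- unique(lines$cross_id)
  u_c <- stats::setNames(
    stats::rnorm(length(crosses), 0, sqrt(design$sigma_ce2 / design$E)), crosses)
  n <- nrow(lines)
  v <- stats::rnorm(n, 0, sqrt(design$sigma_le2 / design$E))
  w <- stats::rnorm(n, 0, sqrt(design$sigma_eps2 / (design$E * design$R)))
  tibble::tibble(
    line_id = lines$line_id, cross_id = lines$cross_id,
    u = unname(u_c[lines$cross_id]), v = v, w = w,
    m = .data$u + .data$v + .data$w
  )
}

#' Simulate phenotypes as genotypic value plus masking
#'
#' The phenotypic value of each line is `p = g + m`, where the masking effect
#' `m = u + v + w` is drawn by [simulate_masking()]. The three components are
#' retained in the result for diagnostics.
#'
#' @param g Tibble of genotypic values from [genotypic_values()] (columns
#'   `line_id`, `cross_id`, `g`).
#' @param pop The `dh_population` the values belong to.
#' @param design A `trial_design`.
#' @return A `phenotype_set` tibble (`line_id`, `cross_id`, `g`, `u`, `v`,
#'   `w`, `m`, `p`) with `p = g + m` exactly.
#' @export
simulate_phenotypes <- function(g, pop, design) {
  stopifnot(inherits(pop, "dh_population"))
  if (nrow(g) != nrow(pop$lines) || !identical(g$line_id, pop$lines$line_id)) {
    stop("genotypic values do not match the population lines", call. = FALSE)
  }
  mask <- simulate_masking(pop, design)
  out <- dplyr::mutate(
    dplyr::left_join(g, mask, by = c("line_id", "cross_id")),
    p = .data$g + .data$m
  )
  structure(out, design = design,
            class = c("phenotype_set", class(out)))
}
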