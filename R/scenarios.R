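#' Configure a replicated simulation scenario
#'
#' A scenario bundles everything one Monte-Carlo experiment needs: the genome
#' and founder-panel specification, the mating scheme and family size, the
#' trait architecture and its target genetic variance, the trial design, and
#' the replication settings. One scenario corresponds to one row of the
#' summary table produced by [run_table1()].
#'
#' The founder panel and the (calibrated) marker effects are built once per
#' scenario and held fixed across replicates — they play the role of the real
#' parental material and of effects treated as true values — while meiosis
#' and the trial noise are redrawn every replicate.
#'
#' @param scheme `"factorial"` (elite x donor) or `"diallel"` (within elite).
#' @param n_lines_per_cross DH family size (10 or 6 for the factorial, 25 for
#'   the diallel in the standard scenarios).
#' @param design A `trial_design`.
#' @param sigma_g2 Target genetic variance the effects are calibrated to
#'   (20 for the factorial scenarios, 2 for the diallel).
#' @param n_reps Number of simulation replicates (default 2000; the
#'   acceptance workflow uses 200 with standard-error-based tolerances).
#' @param seed Master seed; every random ingredient (founders, effects,
#'   calibration, each replicate) uses a substream derived from it.
#' @param genome List: `n_chrom`, `chrom_length_morgan`, `n_markers`,
#'   `spacing` passed to [build_map()].
#' @param founders List: `n_elite`, `n_donor`, `pool_divergence`, `min_maf`
#'   passed to [simulate_founders()].
#' @param effects List: `distribution`, `k` passed to [draw_effects()].
#' @param n_calibration_lines Calibration population size for
#'   [calibrate_sigma_g()].
#' @param predict Fit RR-BLUP and compute the prediction correlations? Set
#'   `FALSE` for r(p, g)-only studies (much faster).
#' @param rrblup_mode,rrblup_lambda Passed to [fit_rrblup()].
#'
#' @return A `scenario_config` list.
#' @examples
#' cfg <- scenario_config("factorial", 10, trial_design(1, 1, 10, 10, 30),
#'                        sigma_g2 = 20, n_reps = 5, seed = 1)
#' @export
scenario_config <- function(scheme = c("factorial", "diallel"),
                            n_lines_per_cross = 10,
                            design = trial_design(),
                            sigma_g2 = 20,
                            n_reps = 2000,
                            seed = 1,
                            genome = list(),
                            founders = list(),
                            effects = list(),
                            n_calibration_lines = 5000,
                            predict = TRUE,
                            rrblup_mode = "reml",
                            rrblup_lambda = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(design, "trial_design"))
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  if (sigma_g2 <= 0) stop("`sigma_g2` must be > 0", call. = FALSE)
  genome <- utils::modifyList(
    list(n_chrom = 7, chrom_length_morgan = 1.5, n_markers = 700,
         spacing = "uniform"), genome)
  founders <- utils::modifyList(
    list(n_elite = 5, n_donor = 5, pool_divergence = 0.3, min_maf = 0.1),
    founders)
  effects <- utils::modifyList(list(distribution = "gaussian", k = NULL),
                               effects)
  structure(
    list(scheme = scheme, n_lines_per_cross = as.integer(n_lines_per_cross),
         design = design, sigma_g2 = sigma_g2, n_reps = as.integer(n_reps),
         seed = as.integer(seed), genome = genome, founders = founders,
         effects = effects, n_calibration_lines = n_calibration_lines,
         predict = isTRUE(predict), rrblup_mode = rrblup_mode,
         rrblup_lambda = rrblup_lambda),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %s, n_l = %d, E = %d, R = %d, components (%g, %g, %g), sigma_g2 = %g, %d reps, seed %d\n",
    x$scheme, x$n_lines_per_cross, x$design$E, x$design$R,
    x$design$sigma_ce2, x$design$sigma_le2, x$design$sigma_eps2,
    x$sigma_g2, x$n_reps, x$seed))
  invisible(x)
}

# Counter-based derivation of replicate/ingredient sub-seeds from the master
# seed, so replicates are order-independent and parallelisable. Kept below
# 2^31 - 1.
derive_seed <- function(seed, k) {
  x <- (as.numeric(seed) %% 2147483647) + 1
  x <- (x * 69621 + as.numeric(k) * 1013904223) %% 2147483647
  as.integer((x * 630360016) %% 2147483647)
}

# Fixed per-scenario ingredients: map, founder panel, cross plan, calibrated
# effects. Built once; replicates reuse them.
scenario_setup <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  g <- config$genome
  map <- build_map(g$n_chrom, g$chrom_length_morgan, g$n_markers, g$spacing,
                   seed = derive_seed(config$seed, 1))
  f <- config$founders
  panel <- simulate_founders(map, f$n_elite, f$n_donor, f$pool_divergence,
                             f$min_maf, seed = derive_seed(config$seed, 2))
  plan <- cross_plan(panel, config$scheme, config$n_lines_per_cross)
  raw <- draw_effects(map, config$effects$distribution, k = config$effects$k,
                      seed = derive_seed(config$seed, 3))
  eff <- calibrate_sigma_g(panel, plan, raw, config$sigma_g2,
                           config$n_calibration_lines,
                           seed = derive_seed(config$seed, 4))
  list(config = config, map = map, panel = panel, plan = plan, effects = eff)
}

#' Run one simulation replicate of a scenario
#'
#' Executes the full pipeline once: DH population from the founder crosses,
#' true genotypic values `g` from the calibrated effects, phenotypes
#' `p = g + m` from the trial design, RR-BLUP fit on `p`, genomic predictions
#' `y` of the phenotyped lines, and the six correlations (Pearson and
#' Spearman for each of the pairs (p, g), (y, p), (y, g)).
#'
#' The replicate's random stream is derived from `(seed, rep_index)`, so any
#' replicate can be recomputed independently of the others.
#'
#' @param config A `scenario_config` (or the internal prebuilt setup).
#' @param rep_index Replicate counter, >= 1.
#' @param keep_data Attach the per-line tibble (g, p, y) as attribute `data`?
#' @return A one-row tibble: `rep`, Pearson `r_pg`, `r_yp`, `r_yg`, Spearman
#'   `rho_pg`, `rho_yp`, `rho_yg` (prediction columns `NA` when the scenario
#'   was configured with `predict = FALSE`) and `flagged` (degenerate
#'   zero-variance replicate).
#' @export
run_replicate <- function(config, rep_index = 1, keep_data = FALSE) {
  setup <- if (inherits(config, "scenario_config")) scenario_setup(config) else config
  config <- setup$config
  set.seed(derive_seed(config$seed, 1000L + as.integer(rep_index)))

  pop <- simulate_population(setup$panel, setup$plan)
  g <- genotypic_values(pop, setup$effects)
  ph <- simulate_phenotypes(g, pop, config$design)

  y <- rep(NA_real_, nrow(ph))
  if (config$predict) {
    fit <- fit_rrblup(pop, ph, mode = config$rrblup_mode,
                      lambda = config$rrblup_lambda)
    y <- predict(fit, pop)$y
  }

  flagged <- stats::var(ph$p) < 1e-12 || stats::var(ph$g) < 1e-12 ||
    (config$predict && stats::var(y) < 1e-12)
  cors <- function(a, b, method) {
    if (flagged || anyNA(a) || anyNA(b)) return(NA_real_)
    stats::cor(a, b, method = method)
  }
  out <- tibble::tibble(
    rep = as.integer(rep_index),
    r_pg = cors(ph$p, ph$g, "pearson"),
    r_yp = if (config$predict) cors(y, ph$p, "pearson") else NA_real_,
    r_yg = if (config$predict) cors(y, ph$g, "pearson") else NA_real_,
    rho_pg = cors(ph$p, ph$g, "spearman"),
    rho_yp = if (config$predict) cors(y, ph$p, "spearman") else NA_real_,
    rho_yg = if (config$predict) cors(y, ph$g, "spearman") else NA_real_,
    flagged = flagged
  )
  if (keep_data) {
    attr(out, "data") <- dplyr::mutate(tibble::as_tibble(ph), y = y)
    class(out) <- c("replicate_run", class(out))
  }
  out
}

#' Run a replicated simulation scenario
#'
#' Repeats [run_replicate()] `n_reps` times and summarises the correlations.
#' Degenerate replicates (zero variance anywhere) are excluded from the means
#' and reported; a scenario with more than 1% flagged replicates is marked
#' unreliable.
#'
#' @param config A `scenario_config`.
#' @param progress Print a progress line every 50 replicates?
#' @return A `scenario_result`: list with `replicates` (per-rep tibble),
#'   `summary` (one-row tibble of means and Monte-Carlo standard errors),
#'   `config`, `n_flagged`, `reliable`.
#' @examples
#' cfg <- scenario_config("factorial", 10, trial_design(1, 1, 10, 10, 30),
#'                        sigma_g2 = 20, n_reps = 3, seed = 1, predict = FALSE)
#' run_scenario(cfg)
#' @export
run_scenario <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  setup <- scenario_setup(config)
  reps <- vector("list", config$n_reps)
  for (i in seq_len(config$n_reps)) {
    reps[[i]] <- run_replicate(setup, i)
    if (progress && i %% 50 == 0) {
      message(sprintf("  replicate %d / %d", i, config$n_reps))
    }
  }
  replicates <- dplyr::bind_rows(reps)
  ok <- dplyr::filter(replicates, !.data$flagged)
  n_flagged <- sum(replicates$flagged)

  mean_se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(NA_real_, NA_real_))
    c(mean(v), stats::sd(v) / sqrt(length(v)))
  }
  stats_tbl <- vapply(ok[c("r_pg", "r_yp", "r_yg", "rho_pg", "rho_yp", "rho_yg")],
                      mean_se, numeric(2))
  summary <- tibble::as_tibble(as.list(stats_tbl[1, ]))
  names(summary) <- paste0("mean_", names(summary))
  se <- tibble::as_tibble(as.list(stats_tbl[2, ]))
  names(se) <- paste0("se_", sub("^mean_", "", names(summary)))
  summary <- dplyr::bind_cols(
    tibble::tibble(scheme = config$scheme, n_c = nrow(setup$plan),
                   n_l = config$n_lines_per_cross,
                   E = config$design$E, R = config$design$R,
                   sigma_ce2 = config$design$sigma_ce2,
                   sigma_le2 = config$design$sigma_le2,
                   sigma_eps2 = config$design$sigma_eps2,
                   sigma_g2 = config$sigma_g2,
                   n_reps = nrow(ok)),
    summary, se)

  structure(list(replicates = replicates, summary = summary, config = config,
                 n_flagged = n_flagged,
                 reliable = n_flagged <= 0.01 * config$n_reps),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<scenario_result> %s n_l=%d E=%d R=%d | r(p,g)=%.3f r(y,p)=%.3f r(y,g)=%.3f over %d reps%s\n",
    s$scheme, s$n_l, s$E, s$R, s$mean_r_pg, s$mean_r_yp, s$mean_r_yg,
    s$n_reps, if (x$reliable) "" else " [UNRELIABLE]"))
  invisible(x)
}

#' @rdname run_scenario
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return For `tidy()`: the per-replicate correlations in long form
#'   (`rep`, `pair`, `method`, `correlation`); for `glance()`: the one-row
#'   summary tibble.
#' @export
tidy.scenario_result <- function(x, ...) {
  long <- tidyr::pivot_longer(x$replicates,
                              cols = -c("rep", "flagged"),
                              names_to = "stat", values_to = "correlation")
  dplyr::mutate(long,
    method = ifelse(grepl("^rho", .data$stat), "spearman", "pearson"),
    pair = sub("^(r|rho)_", "", .data$stat),
    stat = NULL
  )[, c("rep", "pair", "method", "correlation", "flagged")]
}

#' @rdname run_scenario
#' @export
glance.scenario_result <- function(x, ...) x$summary

#' Standard scenario grid of the simulation study
#'
#' Builds the 30 standard scenario configurations: three mating schemes
#' (factorial 25 crosses x 10 lines, factorial 25 x 6, diallel 10 x 25), each
#' under an unreplicated (E = 1, R = 1) and a replicated (E = 3, R = 2)
#' trial, each with five masking-component sets (10,10,30), (2,18,30),
#' (18,2,30), (10,10,60), (20,20,120). Genetic variance targets are 20 for
#' the factorial schemes and 2 for the diallel.
#'
#' @param n_reps Replicates per scenario.
#' @param seed Master seed (each row derives its own substream).
#' @param predict Fit RR-BLUP in every replicate?
#' @param ... Further arguments passed to [scenario_config()] for every row.
#' @return A tibble with `row`, the defining columns, and a `config`
#'   list-column.
#' @export
table1_configs <- function(n_reps = 2000, seed = 1, predict = TRUE, ...) {
  schemes <- tibble::tibble(
    scheme = rep(c("factorial", "factorial", "diallel"), each = 10),
    n_l = rep(c(10L, 6L, 25L), each = 10),
    sigma_g2 = rep(c(20, 20, 2), each = 10)
  )
  designs <- tibble::tibble(
    E = rep(rep(c(1L, 3L), each = 5), 3),
    R = rep(rep(c(1L, 2L), each = 5), 3),
    sigma_ce2 = rep(c(10, 2, 18, 10, 20), 6),
    sigma_le2 = rep(c(10, 18, 2, 10, 20), 6),
    sigma_eps2 = rep(c(30, 30, 30, 60, 120), 6)
  )
  grid <- dplyr::bind_cols(schemes, designs)
  grid <- dplyr::mutate(grid, row = dplyr::row_number(), .before = 1)
  dots <- list(...)
  grid$config <- purrr::pmap(grid, function(row, scheme, n_l, sigma_g2, E, R,
                                            sigma_ce2, sigma_le2, sigma_eps2) {
    do.call(scenario_config, c(
      list(scheme, n_l, trial_design(E, R, sigma_ce2, sigma_le2, sigma_eps2),
           sigma_g2 = sigma_g2, n_reps = n_reps,
           seed = derive_seed(seed, 5000L + row), predict = predict),
      dots))
  })
  grid
}

#' Run the full standard scenario grid
#'
#' Iterates [run_scenario()] over (a subset of) the 30 standard scenarios and
#' binds the one-row summaries into a report table with the standard column
#' layout (`n_c`, `n_l`, `E`, `R`, the three masking components, `sigma_g2`,
#' and the mean correlations).
#'
#' @param n_reps Replicates per scenario (>= 1).
#' @param seed Master seed.
#' @param rows Which scenario rows to run (default all 30).
#' @param predict Fit RR-BLUP in every replicate? `FALSE` restricts the
#'   output to r(p, g) and is roughly an order of magnitude faster.
#' @param progress Print one line per completed scenario?
#' @param ... Passed on to [scenario_config()].
#' @return A tibble with one row per scenario: the defining columns plus mean
#'   correlations, their Monte-Carlo standard errors, and `reliable`.
#' @export
run_table1 <- function(n_reps = 2000, seed = 1, rows = 1:30, predict = TRUE,
                       progress = FALSE, ...) {
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  grid <- table1_configs(n_reps = n_reps, seed = seed, predict = predict, ...)
  grid <- grid[grid$row %in% rows, , drop = FALSE]
  res <- purrr::map(seq_len(nrow(grid)), function(i) {
    r <- run_scenario(grid$config[[i]])
    if (progress) {
      message(sprintf("row %2d: mean r(p,g) = %.3f", grid$row[i],
                      r$summary$mean_r_pg))
    }
    dplyr::bind_cols(tibble::tibble(row = grid$row[i]), r$summary,
                     tibble::tibble(reliable = r$reliable))
  })
  dplyr::bind_rows(res)
}

#' Compare two dependent overlapping correlations (Pearson-Filon z-test)
#'
#' Tests whether the genomic predictions `y` correlate more strongly with a
#' reference value `ghat` than the phenotypes `p` do, accounting for the fact
#' that both correlations share `ghat` and that `p` and `y` are themselves
#' correlated. The statistic is the Pearson-Filon (1898) z for two
#' overlapping dependent correlations
#' `r1 = r(p, ghat)`, `r2 = r(y, ghat)`, `r12 = r(p, y)`:
#' \deqn{z = \sqrt{n} (r_2 - r_1) / \sqrt{(1-r_1^2)^2 + (1-r_2^2)^2 - 2k}}
#' with
#' `k = r12 (1 - r1^2 - r2^2) - (r1 r2 / 2)(1 - r1^2 - r2^2 - r12^2)`.
#' The reported p-value is one-sided for the alternative
#' `H_A: r(y, ghat) > r(p, ghat)`.
#'
#' @param p,y,ghat Equal-length numeric vectors (n >= 4): phenotypes,
#'   genomic predictions, and the reference (estimated genotypic) values.
#' @return A `correlation_comparison` one-row tibble: `r_p_ghat`, `r_y_ghat`,
#'   `r_p_y`, `n`, `z`, `p_value`.
#' @examples
#' set.seed(1)
#' g <- rnorm(100); p <- g + rnorm(100, sd = 1.5); y <- g + rnorm(100, sd = 0.5)
#' compare_dependent_correlations(p, y, g)
#' @export
compare_dependent_correlations <- function(p, y, ghat) {
  n <- length(ghat)
  if (length(p) != n || length(y) != n) {
    stop("`p`, `y` and `ghat` must have equal length", call. = FALSE)
  }
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  r1 <- stats::cor(p, ghat)
  r2 <- stats::cor(y, ghat)
  r12 <- stats::cor(p, y)
  if (anyNA(c(r1, r2, r12))) stop("zero-variance input", call. = FALSE)
  if (any(abs(c(r1, r2)) >= 1 - 1e-12)) {
    stop("degenerate correlation (|r| = 1); the z statistic is undefined",
         call. = FALSE)
  }
  k <- r12 * (1 - r1^2 - r2^2) - 0.5 * r1 * r2 * (1 - r1^2 - r2^2 - r12^2)
  denom2 <- (1 - r1^2)^2 + (1 - r2^2)^2 - 2 * k
  if (denom2 <= 1e-14) {
    # the asymptotic variance vanishes only as p and y coincide; then the
    # difference of correlations is 0 by continuity
    if (abs(r2 - r1) < 1e-10) {
      z <- 0
    } else {
      stop("degenerate correlation (|r| = 1); the z statistic is undefined",
           call. = FALSE)
    }
  } else {
    z <- sqrt(n) * (r2 - r1) / sqrt(denom2)
  }
  structure(
    tibble::tibble(r_p_ghat = r1, r_y_ghat = r2, r_p_y = r12, n = n, z = z,
                   p_value = stats::pnorm(z, lower.tail = FALSE)),
    class = c("correlation_comparison", "tbl_df", "tbl", "data.frame")
  )
}
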