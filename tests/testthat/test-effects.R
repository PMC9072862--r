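test_that("effect drawing respects architecture and seed", {
  map <- tiny_map(2, 1, 100)
  e0 <- draw_effects(map, "sparse", k = 0, seed = 1)
  expect_true(all(e0$effect == 0))
  e50 <- draw_effects(map, "sparse", k = 50, seed = 1)
  expect_equal(sum(e50$effect != 0), 50)
  expect_error(draw_effects(map, "sparse", k = 101, seed = 1), "exceeds")
  expect_identical(draw_effects(map, seed = 7), draw_effects(map, seed = 7))
  expect_equal(nrow(draw_effects(map, "laplace", seed = 2)), 100)
})

test_that("genotypic values are the linear genome-wide sum", {
  map <- tiny_map(1, 1, 3)
  panel <- simulate_founders(map, n_elite = 1, n_donor = 1, seed = 1)
  pop <- simulate_population(panel, cross_plan(panel, "factorial", 4), seed = 2)

  # hand dot-product oracle on a crafted line
  pop$genotypes[1, ] <- c(1L, -1L, 1L)
  eff <- draw_effects(map, "sparse", k = 0, intercept = 0, seed = 1)
  eff$effect <- c(2, -1, 0.5)
  g <- genotypic_values(pop, eff)
  expect_equal(g$g[1], 2 - (-1) + 0.5) # 3.5

  # all-zero effects with intercept 85
  e85 <- draw_effects(map, "sparse", k = 0, intercept = 85, seed = 1)
  expect_true(all(genotypic_values(pop, e85)$g == 85))

  # linearity: doubling effects doubles g - intercept
  eff2 <- eff
  eff2$effect <- eff$effect * 2
  expect_equal(genotypic_values(pop, eff2)$g, 2 * g$g)

  bad <- draw_effects(tiny_map(1, 1, 4), seed = 1)
  expect_error(genotypic_values(pop, bad), "marker sets")
})

test_that("calibration anchors the population genetic variance to its target", {
  map <- build_map(7, 1.5, 210)
  panel <- simulate_founders(map, seed = 21)
  plan <- cross_plan(panel, "factorial", 10)
  raw <- draw_effects(map, seed = 22)

  cal <- calibrate_sigma_g(panel, plan, raw, target_sigma_g2 = 20,
                           n_calibration_lines = 5000, seed = 23)
  rec <- glance(cal)
  expect_equal(rec$target_sigma_g2, 20)
  expect_equal(rec$scheme, "factorial")

  # resimulation oracle: fresh 5000-line population variance within 3 SE of 20
  se_var <- 20 * sqrt(2 / (rec$n_calibration_lines - 1))
  expect_lt(abs(rec$fresh_draw_sigma_g2 - 20), 3 * se_var)
  pop <- simulate_population(panel, cross_plan(panel, "factorial", 200), seed = 24)
  v <- var(genotypic_values(pop, cal)$g)
  expect_lt(abs(v - 20), 3 * 20 * sqrt(2 / (nrow(pop$genotypes) - 1)))

  # recalibrating to the realized raw variance gives scaling factor 1
  cal1 <- calibrate_sigma_g(panel, plan, raw, rec$raw_sigma_g2,
                            n_calibration_lines = 5000, seed = 23)
  expect_equal(glance(cal1)$scale_factor, 1)

  # scaling effects by c multiplies the g-variance by c^2
  eff_c <- cal
  eff_c$effect <- cal$effect * 3
  expect_equal(var(genotypic_values(pop, eff_c)$g), 9 * v)
})

test_that("calibration is scheme-specific", {
  map <- build_map(7, 1.5, 210)
  panel <- simulate_founders(map, seed = 31)
  raw <- draw_effects(map, seed = 32)
  fac <- cross_plan(panel, "factorial", 10)
  dia <- cross_plan(panel, "diallel", 25)

  cal_f <- calibrate_sigma_g(panel, fac, raw, 20, 4000, seed = 33)
  cal_d <- calibrate_sigma_g(panel, dia, raw, 2, 4000, seed = 33)
  expect_false(isTRUE(all.equal(glance(cal_f)$scale_factor,
                                glance(cal_d)$scale_factor)))

  pop_f <- simulate_population(panel, cross_plan(panel, "factorial", 160), seed = 34)
  pop_d <- simulate_population(panel, cross_plan(panel, "diallel", 400), seed = 35)
  expect_lt(abs(var(genotypic_values(pop_f, cal_f)$g) - 20),
            3 * 20 * sqrt(2 / 3999))
  expect_lt(abs(var(genotypic_values(pop_d, cal_d)$g) - 2),
            3 * 2 * sqrt(2 / 3999))
})

test_that("a variance-free trait is uncalibratable", {
  map <- tiny_map(2, 1, 20)
  panel <- simulate_founders(map, seed = 41)
  plan <- cross_plan(panel, "factorial", 5)
  zero <- draw_effects(map, "sparse", k = 0, seed = 42)
  expect_error(calibrate_sigma_g(panel, plan, zero, 20, 500, seed = 43),
               "uncalibratable")
  expect_error(calibrate_sigma_g(panel, plan, zero, -1, 500), "target_sigma_g2")
})
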