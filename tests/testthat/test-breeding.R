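test_that("factorial and diallel plans enumerate the right crosses", {
  panel <- tiny_panel()
  fac <- cross_plan(panel, "factorial", 10)
  expect_equal(nrow(fac), 25)
  expect_true(all(fac$parent_a %in% names(panel$pool)[panel$pool == "elite"]))
  expect_true(all(fac$parent_b %in% names(panel$pool)[panel$pool == "donor"]))

  dia <- cross_plan(panel, "diallel", 25)
  expect_equal(nrow(dia), 10) # all unordered elite pairs, no selfs
  expect_true(all(dia$parent_a != dia$parent_b))
  pairs <- paste(pmin(dia$parent_a, dia$parent_b), pmax(dia$parent_a, dia$parent_b))
  expect_equal(anyDuplicated(pairs), 0L)
  elite <- names(panel$pool)[panel$pool == "elite"]
  expect_true(all(c(dia$parent_a, dia$parent_b) %in% elite))
})

test_that("population sizes follow the mating scheme and family size", {
  panel <- tiny_panel()
  expect_equal(nrow(simulate_population(panel, cross_plan(panel, "factorial", 10), seed = 1)$genotypes), 250)
  expect_equal(nrow(simulate_population(panel, cross_plan(panel, "factorial", 6), seed = 1)$genotypes), 150)
  pop <- simulate_population(panel, cross_plan(panel, "diallel", 25), seed = 1)
  expect_equal(nrow(pop$genotypes), 250)
  expect_equal(dplyr::n_distinct(pop$lines$cross_id), 10)
})

test_that("DH lines are homozygous and every allele traces to a cross parent", {
  panel <- tiny_panel(seed = 3)
  pop <- simulate_population(panel, cross_plan(panel, "factorial", 5), seed = 4)
  expect_true(all(pop$genotypes %in% c(-1L, 1L)))
  for (k in unique(pop$lines$cross_id)) {
    rows <- pop$lines$cross_id == k
    pa <- panel$haplotypes[pop$lines$parent_a[rows][1], ] * 2L - 1L
    pb <- panel$haplotypes[pop$lines$parent_b[rows][1], ] * 2L - 1L
    sub <- pop$genotypes[rows, , drop = FALSE]
    ok <- sweep(sub, 2, pa, "==") | sweep(sub, 2, pb, "==")
    expect_true(all(ok))
    # markers where the parents share an allele are fixed for it
    shared <- pa == pb
    expect_true(all(sweep(sub[, shared, drop = FALSE], 2, pa[shared], "==")))
  }
})

test_that("a gamete from identical haplotypes is that haplotype", {
  map <- tiny_map(1, 1, 10)
  hap <- rep(c(0, 1), 5)
  set.seed(1)
  for (i in 1:20) expect_equal(simulate_gamete(hap, hap, map), hap)
  expect_error(simulate_gamete(hap[1:5], hap, map), "length")
  expect_error(make_dh_line(c(0, 2, 1), c(0, 1, 1), tiny_map(1, 1, 3)), "homozygous")
})

test_that("recombinant fraction at 0.1 Morgan matches the Haldane map function", {
  # closed-form oracle: r = 0.5 (1 - exp(-2 d))
  r_expect <- 0.5 * (1 - exp(-2 * 0.1))
  map <- build_map(1, 0.1, 2) # two markers 0.1 M apart
  panel <- simulate_founders(map, n_elite = 1, n_donor = 1,
                             pool_divergence = 1, seed = 1)
  plan <- cross_plan(panel, "factorial", 100000)
  pop <- simulate_population(panel, plan, seed = 2)
  r_obs <- mean(pop$genotypes[, 1] != pop$genotypes[, 2])
  se <- sqrt(r_expect * (1 - r_expect) / 1e5)
  expect_lt(abs(r_obs - r_expect), 3 * se)

  # the single-gamete operation obeys the same law
  set.seed(3)
  gam <- replicate(4000, simulate_gamete(c(0, 0), c(1, 1), map))
  r_one <- mean(gam[1, ] != gam[2, ])
  expect_lt(abs(r_one - r_expect), 3 * sqrt(r_expect * (1 - r_expect) / 4000))
})

test_that("markers at identical positions never recombine", {
  map0 <- gpsim:::new_genetic_map(
    data.frame(marker_id = c("a", "b"), chrom = 1L, pos = c(0.5, 0.5)),
    chrom_len = 1)
  panel <- simulate_founders(map0, n_elite = 1, n_donor = 1,
                             pool_divergence = 1, seed = 1)
  pop <- simulate_population(panel, cross_plan(panel, "factorial", 1000), seed = 5)
  expect_equal(pop$genotypes[, 1], pop$genotypes[, 2])
})

test_that("within a cross, segregating markers split 1:1 and LD decays with distance", {
  map <- gpsim:::new_genetic_map(
    data.frame(marker_id = c("a", "b", "c"), chrom = 1L, pos = c(0, 0.01, 1.5)),
    chrom_len = 1.5)
  panel <- simulate_founders(map, n_elite = 1, n_donor = 1,
                             pool_divergence = 1, seed = 1)
  pop <- simulate_population(panel, cross_plan(panel, "factorial", 10000), seed = 6)
  freq <- colMeans(pop$genotypes == 1)
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 10000)))
  expect_gt(cor(pop$genotypes[, 1], pop$genotypes[, 2]),
            cor(pop$genotypes[, 1], pop$genotypes[, 3]))
})

test_that("population simulation is reproducible and validates parents", {
  panel <- tiny_panel()
  plan <- cross_plan(panel, "factorial", 4)
  p1 <- simulate_population(panel, plan, seed = 11)
  p2 <- simulate_population(panel, plan, seed = 11)
  expect_identical(p1$genotypes, p2$genotypes)
  bad <- plan
  bad$parent_a[1] <- "nope"
  expect_error(simulate_population(panel, bad, seed = 1), "unknown parent")
})
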