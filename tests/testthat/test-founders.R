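test_that("pool divergence controls the markers fixed between pools", {
  map <- tiny_map(2, 1, 700)

  full <- simulate_founders(map, pool_divergence = 1, seed = 1)
  d <- modified_rogers_distance(full)
  elite <- names(full$pool)[full$pool == "elite"]
  donor <- names(full$pool)[full$pool == "donor"]
  expect_true(all(d[elite, donor] == 1)) # opposite at every marker
  expect_true(all(d[elite, elite] == 0))

  none <- simulate_founders(map, pool_divergence = 0, min_maf = 0.1, seed = 2)
  freq <- colMeans(none$haplotypes)
  expect_true(all(pmin(freq, 1 - freq) >= 0.1))
  # no marker fixed between the pools
  e_fixed <- apply(none$haplotypes[none$pool == "elite", ], 2, function(a) length(unique(a)) == 1)
  d_fixed <- apply(none$haplotypes[none$pool == "donor", ], 2, function(a) length(unique(a)) == 1)
  e_val <- none$haplotypes[match("elite", none$pool), ]
  d_val <- none$haplotypes[match("donor", none$pool), ]
  expect_false(any(e_fixed & d_fixed & e_val != d_val))

  part <- simulate_founders(map, pool_divergence = 0.3, seed = 3)
  expect_equal(sum(part$pool_diff), round(0.3 * 700)) # 210, by rounding
  diff_cols <- part$haplotypes[, part$pool_diff]
  expect_true(all(diff_cols[part$pool == "elite", ] == 0))
  expect_true(all(diff_cols[part$pool == "donor", ] == 1))
})

test_that("founder simulation is bit-reproducible and validates inputs", {
  map <- tiny_map()
  expect_identical(simulate_founders(map, seed = 9), simulate_founders(map, seed = 9))
  expect_error(simulate_founders(map, n_elite = 1, n_donor = 0), "two founders")
  expect_error(simulate_founders(map, pool_divergence = 1.2), "pool_divergence")
  expect_error(simulate_founders(map, min_maf = 0.7), "min_maf")
})

test_that("marker QC applies the missingness and diversity rules, then the line rule", {
  # marker 2: 2/4 missing (50% > 10%); marker 3 monomorphic (diversity 0)
  geno <- rbind(
    l1 = c(0, NA, 2),
    l2 = c(2, NA, 2),
    l3 = c(0, 0, 2),
    l4 = c(2, 2, 2)
  )
  colnames(geno) <- c("m1", "m2", "m3")
  res <- filter_markers(geno)
  expect_equal(colnames(res$genotypes), "m1")
  expect_equal(res$report$n_markers_kept, 1)
  expect_equal(res$report$n_lines_kept, 4)

  # clean matrix at MAF 0.5: nothing removed, diversity 0.5 everywhere
  clean <- matrix(rep(c(0, 2), 10), nrow = 4, ncol = 5)
  res2 <- filter_markers(clean)
  expect_equal(dim(res2$genotypes), c(4, 5))
  expect_equal(unname(res2$report$markers$gene_diversity), rep(0.5, 5))

  expect_error(filter_markers(matrix(0, 4, 3)), "empty panel")
})

test_that("QC matches an independent brute-force oracle on a random fixture", {
  set.seed(77)
  geno <- matrix(sample(c(0, 2), 50 * 20, replace = TRUE), 50, 20)
  geno[, 3] <- 0                                   # monomorphic
  geno[sample(50, 10), 5] <- NA                    # 20% missing marker
  geno[, 8] <- c(rep(0, 48), 2, 2)                 # diversity 2*0.04*0.96 < 0.1
  geno[12, sample(20, 8)] <- NA                    # heavily missing line
  colnames(geno) <- sprintf("m%d", 1:20)
  rownames(geno) <- sprintf("l%d", 1:50)

  res <- filter_markers(geno)
  expect_identical(res$genotypes, brute_force_filter(geno))
  expect_true(res$report$n_markers_kept <= res$report$n_markers_in)
  expect_true(all(res$report$markers$missing_fraction >= 0 &
                  res$report$markers$missing_fraction <= 1))

  # idempotence: filtering the filtered matrix changes nothing
  res_again <- filter_markers(res$genotypes)
  expect_identical(res_again$genotypes, res$genotypes)
})

test_that("modified Rogers' distance follows its closed form and is a metric", {
  # identical, fully opposite, and half-opposite lines
  lines <- rbind(a = rep(0, 10), b = rep(0, 10), c = rep(1, 10),
                 d = c(rep(1, 5), rep(0, 5)))
  d <- modified_rogers_distance(lines)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
  expect_equal(d["a", "d"], sqrt(0.5))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))

  # triangle inequality on random homozygous fixtures
  set.seed(5)
  for (rep in 1:5) {
    g <- matrix(sample(c(0, 1), 8 * 30, replace = TRUE), 8, 30)
    dd <- modified_rogers_distance(g)
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
    }
  }

  expect_error(modified_rogers_distance(rbind(c(0, NA), c(1, 0))), "missing")
})
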