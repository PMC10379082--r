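test_that("the Balding-Nichols generator is deterministic under a fixed seed", {
  s1 <- simulate_balding_nichols(n_pops = 2, samples_per_pop = 5, n_chrom = 2,
                                 n_snps = 200, seed = 111)
  s2 <- simulate_balding_nichols(n_pops = 2, samples_per_pop = 5, n_chrom = 2,
                                 n_snps = 200, seed = 111)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_simulation(s1, d1); f2 <- write_simulation(s2, d2)
  expect_identical(readLines(f1[["vcf"]]), readLines(f2[["vcf"]]))
  s3 <- simulate_balding_nichols(n_pops = 2, samples_per_pop = 5, n_chrom = 2,
                                 n_snps = 200, seed = 112)
  expect_false(identical(s1$genotypes$dosages, s3$genotypes$dosages))
  expect_error(simulate_balding_nichols(n_snps = 10), "seed")
})

test_that("realized missingness tracks the configured rate", {
  sim <- simulate_balding_nichols(n_pops = 2, samples_per_pop = 25,
                                  n_chrom = 2, n_snps = 20000,
                                  missing_rate = 0.05, seed = 121)
  expect_equal(mean(is.na(sim$genotypes$dosages)), 0.05, tolerance = 0.01 / 0.05)
})

test_that("planted QD/FS violations are recorded in the truth table", {
  sim <- simulate_balding_nichols(n_pops = 1, samples_per_pop = 5,
                                  n_chrom = 1, n_snps = 500,
                                  n_qd_violations = 7, n_fs_violations = 4,
                                  seed = 131)
  expect_length(sim$truth$qd_violation_sites, 7L)
  expect_true(all(sim$variants$qd[sim$truth$qd_violation_sites] < 2))
  expect_true(all(sim$variants$fs[sim$truth$fs_violation_sites] > 30))
  mask <- filter_site_annotations(sim$variants)$mask
  expect_equal(sort(which(!mask)),
               sort(union(sim$truth$qd_violation_sites,
                          sim$truth$fs_violation_sites)))
})

test_that("planted sweeps depress focal diversity and are recorded in truth", {
  sim <- simulate_balding_nichols(n_pops = 2, samples_per_pop = 30,
                                  n_chrom = 2, chrom_length_bp = 1e6,
                                  n_snps = 6000, drift_f = 0.05, seed = 141)
  region <- data.frame(chrom = "chr1", start = 400001, end = 500000,
                       focal_pop = "POP2")
  swept <- plant_sweeps(sim, region, seed = 142)
  expect_length(swept$truth$sweep_regions, 1L)
  pops <- population_indices(swept$pmap, swept$genotypes, warn = FALSE)
  pw <- windowed_pi(swept$genotypes, swept$variants, pops$POP2,
                    window_bp = 100000, step_bp = 100000)
  in_region <- pw$chrom == "chr1" & pw$start == 400001
  expect_lt(pw$pi[in_region], 0.2 * median(pw$pi[!in_region]))
  # non-focal population untouched
  expect_equal(swept$genotypes$dosages[pops$POP1, ],
               sim$genotypes$dosages[pops$POP1, ])
})

test_that("plant_sweeps validates its regions", {
  sim <- simulate_balding_nichols(n_pops = 2, samples_per_pop = 5,
                                  n_chrom = 1, chrom_length_bp = 1e6,
                                  n_snps = 200, seed = 151)
  expect_identical(plant_sweeps(sim, data.frame()), sim)   # empty list: no-op
  expect_error(plant_sweeps(sim, data.frame(chrom = "chr9", start = 1,
                                            end = 10, focal_pop = "POP1")),
               "nonexistent chromosome")
  overlapping <- data.frame(chrom = "chr1", start = c(1, 50000),
                            end = c(100000, 150000), focal_pop = "POP1")
  expect_error(plant_sweeps(sim, overlapping), "disjoint")
})

test_that("Wright-Fisher segregating sites match the Watterson expectation", {
  sim <- wf_fixture()
  n_alleles <- 2 * sim$truth$sample_n
  expected_s <- 4 * sim$truth$census_n * sim$truth$mu * 1e6 *
    sum(1 / seq_len(n_alleles - 1))
  s_obs <- nrow(sim$variants)
  expect_gt(s_obs, 0.5 * expected_s)
  expect_lt(s_obs, 1.5 * expected_s)
  # dosages are a valid genotype matrix aligned to the variant table
  expect_equal(ncol(sim$genotypes$dosages), nrow(sim$variants))
  expect_true(all(diff(sim$variants$pos) > 0))
})

test_that("without recombination, MAF-matched pairs are in near-complete LD", {
  sim <- simulate_wright_fisher(census_n = 50, chrom_length_bp = 1e5,
                                mu = 4e-6, rec = 0, burn_in = 500,
                                sample_n = 25, seed = 161)
  d <- sim$genotypes$dosages
  ac <- colSums(d)
  mac <- pmin(ac, 2 * nrow(d) - ac)
  common <- which(mac >= 5)
  r2 <- c()
  for (count in unique(mac[common])) {
    grp <- common[mac[common] == count]
    if (length(grp) < 2) next
    cm <- suppressWarnings(cor(d[, grp]))^2
    r2 <- c(r2, cm[upper.tri(cm)])
  }
  expect_gt(median(r2, na.rm = TRUE), 0.8)
})

test_that("the Wright-Fisher generator is deterministic under a fixed seed", {
  a <- simulate_wright_fisher(census_n = 20, chrom_length_bp = 5e4,
                              mu = 5e-6, rec = 1e-7, burn_in = 100,
                              sample_n = 10, seed = 171)
  b <- simulate_wright_fisher(census_n = 20, chrom_length_bp = 5e4,
                              mu = 5e-6, rec = 1e-7, burn_in = 100,
                              sample_n = 10, seed = 171)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$variants$pos, b$variants$pos)
})
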