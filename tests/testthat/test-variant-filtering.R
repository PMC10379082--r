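vt_of <- function(pos, qd = 30, fs = 5, chrom = "chr1") {
  n <- length(pos)
  variant_table(rep(chrom, n), pos, rep("A", n), rep("G", n),
                qd = rep_len(qd, n), fs = rep_len(fs, n))
}

test_that("QD/FS thresholds are strict inequalities and NA annotations are kept", {
  vt <- vt_of(c(100, 200, 300, 400),
              qd = c(1.9, 5, 2.0, NA), fs = c(10, 31, 30.0, NA))
  res <- filter_site_annotations(vt)
  expect_equal(res$mask, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$report$n_removed, 2L)
  expect_equal(res$report$n_input, res$report$n_removed + res$report$n_retained)
})

test_that("SNP-cluster filter removes all members of windows with > max_snps sites", {
  # four SNPs within 31 bases: all removed
  res <- filter_snp_clusters(vt_of(c(100, 110, 120, 130)))
  expect_equal(res$mask, rep(FALSE, 4))
  # well-spaced sites survive
  expect_true(all(filter_snp_clusters(vt_of(c(100, 150, 200)))$mask))
  # exactly three in the window is tolerated ("more than 3")
  expect_true(all(filter_snp_clusters(vt_of(c(100, 110, 120)))$mask))
  # chromosomes are independent
  vt <- variant_table(c("chr1", "chr1", "chr2", "chr2"),
                      c(100L, 110L, 100L, 110L),
                      rep("A", 4), rep("G", 4))
  expect_true(all(filter_snp_clusters(vt)$mask))
})

test_that("depth masking keeps only the open interval (10, 60)", {
  gm <- genotype_matrix(matrix(1L, 1, 4), "S1",
                        depths = matrix(c(10, 59, 60, 11), 1, 4))
  out <- mask_genotypes_by_depth(gm)
  expect_equal(unname(out$dosages[1, ]), c(NA, 1L, NA, 1L))
  expect_equal(attr(out, "n_masked"), 2L)
  gm2 <- genotype_matrix(matrix(1L, 1, 2), "S1")
  expect_error(mask_genotypes_by_depth(gm2), "no depths")
})

test_that("missingness and MAF filtering follow VCFtools boundary semantics", {
  # 10 samples; site 1: 2 missing (20% > 10%); site 2: MAF exactly 0.05
  # (1 alt / 19 ref, boundary retained); site 3: monomorphic; site 4: clean
  d <- cbind(c(NA, NA, rep(0L, 8)),
             c(1L, rep(0L, 9)),
             rep(2L, 10),
             rep(c(0L, 1L), 5))
  gm <- genotype_matrix(d, paste0("S", 1:10))
  vt <- vt_of(c(1000, 2000, 3000, 4000))
  res <- filter_missing_maf(gm, vt)
  expect_equal(res$mask, c(FALSE, TRUE, FALSE, TRUE))
  expect_match(res$report$params, "uncalled_removed=0")
})

test_that("exact HWE test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(5, 0, 0), 1)          # monomorphic
  expect_equal(hwe_exact_test(1, 2, 1), hwe_oracle(1, 2, 1))
  # spot checks across the configuration space
  for (cfg in list(c(10, 1, 10), c(0, 10, 0), c(7, 2, 1), c(3, 3, 3),
                   c(25, 5, 20), c(0, 1, 12))) {
    expect_equal(hwe_exact_test(cfg[1], cfg[2], cfg[3]),
                 hwe_oracle(cfg[1], cfg[2], cfg[3]),
                 tolerance = 1e-10,
                 label = paste(cfg, collapse = ","))
  }
})

test_that("exact HWE test is conservative under the null", {
  set.seed(404)
  n <- 50
  reps <- 20000
  g <- matrix(rbinom(reps * n, 2, 0.5), reps, n)
  pvals <- vapply(seq_len(reps), function(i) {
    hwe_exact_test(sum(g[i, ] == 0), sum(g[i, ] == 1), sum(g[i, ] == 2))
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("HWE site filter removes only deviant sites and respects alpha", {
  # site 1 near expectation, site 2 all-het (extreme excess), n = 50
  d <- cbind(rep(c(0L, 1L, 1L, 2L), length.out = 50), rep(1L, 50))
  gm <- genotype_matrix(d, paste0("S", 1:50))
  vt <- vt_of(c(1000, 2000))
  res <- hwe_filter(gm, vt)
  expect_equal(res$mask, c(TRUE, FALSE))
  expect_lt(hwe_oracle(0, 50, 0), 1e-3)             # oracle agrees it deviates
  expect_true(all(hwe_filter(gm, vt, alpha = 0)$mask))
})

test_that("the filter cascade removes exactly the planted violations, in order", {
  fx <- planted_filter_fixture()
  res <- filter_pipeline(fx$gm, fx$vt)
  rep <- res$report
  expect_equal(rep$stage, c("site_annotations", "snp_clusters", "depth_mask",
                            "missing_maf", "hwe"))
  expect_equal(rep$n_removed[rep$stage == "site_annotations"],
               fx$planted$annotations)
  expect_equal(rep$n_removed[rep$stage == "snp_clusters"], fx$planted$clusters)
  expect_equal(rep$n_removed[rep$stage == "missing_maf"],
               fx$planted$missing_maf)
  expect_equal(rep$n_removed[rep$stage == "hwe"], fx$planted$hwe)
  expect_equal(nrow(res$variants), fx$planted$clean)
  # stages chain: each stage's input is the previous stage's retained count
  site_stages <- rep[rep$stage != "depth_mask", ]
  expect_equal(site_stages$n_input[-1],
               site_stages$n_retained[-nrow(site_stages)])
  expect_true(all(rep$n_input == rep$n_removed + rep$n_retained))
  # site_id stays aligned after renumbering
  expect_equal(res$variants$site_id, seq_len(nrow(res$variants)))
  expect_equal(ncol(res$genotypes$dosages), nrow(res$variants))
})
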