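# Independent oracles and shared fixtures.

## Brute-force exact HWE p-value: enumerate every genotype configuration
## consistent with the observed allele counts, weight by the multinomial
## count times 2^het, and sum the probabilities of configurations no more
## likely than the observed one. Direct factorial arithmetic, independent
## of the package's recurrence implementation.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2 * n_hom_alt + n_het
  hs <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logw <- vapply(hs, function(h) {
    hom_alt <- (n_a - h) / 2
    hom_ref <- n - h - hom_alt
    lfactorial(n) - lfactorial(hom_ref) - lfactorial(h) -
      lfactorial(hom_alt) + h * log(2)
  }, numeric(1))
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  p_obs <- w[match(n_het, hs)]
  min(1, sum(w[w <= p_obs * (1 + 1e-9)]))
}

## Brute-force nucleotide diversity: mean pairwise Hamming distance between
## explicit haplotypes, divided by the sequence length.
pi_pairwise_oracle <- function(haps, length_bp) {
  n <- nrow(haps)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + sum(haps[i, ] != haps[j, ])
    }
  }
  total / choose(n, 2) / length_bp
}

## Pair binary haplotype rows (1,2), (3,4), ... into diploid dosages.
haps_to_genotypes <- function(haps) {
  stopifnot(nrow(haps) %% 2 == 0)
  idx <- seq(1, nrow(haps), by = 2)
  dos <- haps[idx, , drop = FALSE] + haps[idx + 1, , drop = FALSE]
  genotype_matrix(dos, paste0("S", seq_along(idx)))
}

## Equilibrium forward Wright-Fisher fixture (N = 100, 1 Mb), computed once
## per test run and shared by the LD, Ne and generator tests.
.wf_cache <- new.env()
wf_fixture <- function() {
  if (is.null(.wf_cache$sim)) {
    .wf_cache$sim <- simulate_wright_fisher(
      census_n = 100, chrom_length_bp = 1e6, mu = 1e-6, rec = 1e-7,
      sample_n = 50, seed = 20240901)
  }
  .wf_cache$sim
}

wf_ld_bins <- function() {
  if (is.null(.wf_cache$bins)) {
    sim <- wf_fixture()
    pairs <- ld_pairs(sim$genotypes, sim$variants, max_dist = 1e6, seed = 1)
    .wf_cache$bins <- ld_decay_bins(pairs, bins = ld_bin_scheme(1e6, 12),
                                    n = 50)
  }
  .wf_cache$bins
}

## A hand-built 15-sample call set with one planted violation of each
## hard-filter rule; everything else passes every filter.
## Baseline genotype pattern: counts (4, 7, 4), allele frequency 0.5.
planted_filter_fixture <- function() {
  base_gt <- c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L, 0L, 1L, 2L)
  n_samp <- 15L
  site <- function(pos, gt = base_gt, qd = 30, fs = 5, dp = rep(30L, n_samp)) {
    list(pos = pos, gt = gt, qd = qd, fs = fs, dp = dp)
  }
  sites <- list(
    site(1000), site(3000), site(6000), site(9000),       # clean baseline
    site(12000, qd = 1.5),                                # fails QD < 2
    site(15000, fs = 40),                                 # fails FS > 30
    site(20000), site(20010), site(20020), site(20030),   # cluster of 4/35bp
    site(25000,                                           # depth-masked calls
         dp = c(5L, 70L, rep(30L, n_samp - 2L))),         #  -> >10% missing
    site(30000, gt = replace(base_gt, 1:2, NA_integer_)), # 2/15 missing calls
    site(35000, gt = rep(0L, n_samp)),                    # monomorphic, MAF 0
    site(40000, gt = rep(1L, n_samp)),                    # all het: HWE p<1e-3
    site(45000), site(50000)                              # clean baseline
  )
  pos <- vapply(sites, `[[`, numeric(1), "pos")
  vt <- variant_table(rep("chr1", length(sites)), pos,
                      rep("A", length(sites)), rep("G", length(sites)),
                      qd = vapply(sites, `[[`, numeric(1), "qd"),
                      fs = vapply(sites, `[[`, numeric(1), "fs"))
  gm <- genotype_matrix(do.call(cbind, lapply(sites, `[[`, "gt")),
                        sprintf("S%02d", seq_len(n_samp)),
                        do.call(cbind, lapply(sites, `[[`, "dp")))
  list(vt = vt, gm = gm,
       planted = list(annotations = 2L, clusters = 4L, depth_cells = 2L,
                      missing_maf = 3L, hwe = 1L, clean = 6L))
}
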