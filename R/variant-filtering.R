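## Hard-filter cascade between raw genotypes and analysis-ready SNPs:
## site-annotation thresholds, SNP-cluster removal, per-genotype depth
## masking, missingness/MAF, and an exact Hardy-Weinberg test.

filter_report <- function(stage, n_input, n_removed, params = "") {
  data.frame(stage = stage, n_input = n_input, n_removed = n_removed,
             n_retained = n_input - n_removed, params = params,
             stringsAsFactors = FALSE)
}

#' Filter sites on GATK annotations (QD, FS)
#'
#' A site is removed iff `qd < qd_min` or `fs > fs_max` (strict
#' inequalities, so boundary values are retained). Sites missing both
#' annotations are retained and counted in the report parameters.
#'
#' @param vt A [variant_table()].
#' @param qd_min Minimum quality-by-depth (default 2.0).
#' @param fs_max Maximum Fisher-strand phred score (default 30.0).
#' @return List with `mask` (logical keep vector over sites) and `report`
#'   (one-row filter report).
#' @export
filter_site_annotations <- function(vt, qd_min = 2.0, fs_max = 30.0) {
  stopifnot(is.finite(qd_min), is.finite(fs_max))
  bad_qd <- !is.na(vt$qd) & vt$qd < qd_min
  bad_fs <- !is.na(vt$fs) & vt$fs > fs_max
  keep <- !(bad_qd | bad_fs)
  n_unannotated <- sum(is.na(vt$qd) & is.na(vt$fs))
  list(mask = keep,
       report = filter_report(
         "site_annotations", nrow(vt), sum(!keep),
         sprintf("qd_min=%g,fs_max=%g,unannotated_retained=%d",
                 qd_min, fs_max, n_unannotated)))
}

#' Remove SNP clusters
#'
#' A site is removed iff it lies in any window of `window_bp` bases (on its
#' chromosome) containing more than `max_snps` SNPs; all members of a
#' violating window are removed. With the defaults this is the GATK
#' SnpCluster rule: more than 3 SNPs in a window of 35 bases.
#'
#' @param vt A [variant_table()] (sorted by chrom, pos).
#' @param window_bp Cluster window length in bases (default 35).
#' @param max_snps Maximum SNPs tolerated in any window (default 3).
#' @return List with `mask` and `report` as in [filter_site_annotations()].
#' @export
filter_snp_clusters <- function(vt, window_bp = 35, max_snps = 3) {
  keep <- rep(TRUE, nrow(vt))
  for (idx in split(seq_len(nrow(vt)), vt$chrom)) {
    pos <- vt$pos[idx]
    k <- max_snps            # runs of (max_snps + 1) sites spanning < window
    n <- length(pos)
    if (n <= k) next
    j <- seq_len(n - k)
    viol <- which(pos[j + k] - pos[j] <= window_bp - 1L)
    if (length(viol)) {
      drop <- unique(unlist(lapply(viol, function(v) v:(v + k))))
      keep[idx[drop]] <- FALSE
    }
  }
  list(mask = keep,
       report = filter_report("snp_clusters", nrow(vt), sum(!keep),
                              sprintf("window_bp=%d,max_snps=%d",
                                      as.integer(window_bp), as.integer(max_snps))))
}

#' Mask individual genotypes by read depth
#'
#' Genotype calls with depth `<= min_dp` or `>= max_dp` are set to missing;
#' only calls with depth strictly inside `(min_dp, max_dp)` are retained.
#' Calls without a recorded depth are left untouched.
#'
#' @param gm A [genotype_matrix()] with depths.
#' @param min_dp,max_dp Depth bounds (defaults 10 and 60, both exclusive).
#' @return A new `genotype_matrix` with masked cells set to `NA`, carrying an
#'   attribute `n_masked` with the number of newly masked calls.
#' @export
mask_genotypes_by_depth <- function(gm, min_dp = 10, max_dp = 60) {
  if (is.null(gm$depths)) {
    stop("mask_genotypes_by_depth: genotype matrix has no depths")
  }
  bad <- !is.na(gm$depths) & (gm$depths <= min_dp | gm$depths >= max_dp)
  n_masked <- sum(bad & !is.na(gm$dosages))
  d <- gm$dosages
  d[bad] <- NA_integer_
  out <- genotype_matrix(d, gm$samples, gm$depths)
  attr(out, "n_masked") <- n_masked
  out
}

#' Filter sites on missingness and minor-allele frequency
#'
#' A site is removed iff the fraction of missing genotype calls exceeds
#' `max_missing_frac`, or the minor-allele frequency among called alleles is
#' below `maf_min` (sites with MAF exactly `maf_min` are retained, matching
#' VCFtools `--maf` semantics). Sites with zero called genotypes are removed
#' and counted separately.
#'
#' @param gm A [genotype_matrix()].
#' @param vt The aligned [variant_table()].
#' @param max_missing_frac Maximum tolerated missing fraction (default 0.1,
#'   i.e. VCFtools `--max-missing 0.9`).
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @return List with `mask` and `report`.
#' @export
filter_missing_maf <- function(gm, vt, max_missing_frac = 0.1, maf_min = 0.05) {
  ac <- site_allele_counts(gm)
  n_samp <- nrow(gm$dosages)
  miss_frac <- 1 - ac$n_gt / n_samp
  p <- ifelse(ac$n > 0L, ac$ac / ac$n, NA_real_)
  maf <- pmin(p, 1 - p)
  uncalled <- ac$n == 0L
  keep <- !uncalled & miss_frac <= max_missing_frac & maf >= maf_min
  list(mask = keep,
       report = filter_report(
         "missing_maf", nrow(vt), sum(!keep),
         sprintf("max_missing_frac=%g,maf_min=%g,uncalled_removed=%d",
                 max_missing_frac, maf_min, sum(uncalled))))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test for one biallelic site: conditional on the observed
#' allele counts, enumerate every attainable heterozygote count, compute its
#' probability under random mating, and sum the probabilities of all
#' configurations no more likely than the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative, total
#'   >= 1).
#' @return The exact p-value, in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  stopifnot(n >= 1)
  n_a <- 2L * n_hom_alt + n_het          # alternate allele count
  ## attainable het counts share parity with the allele count
  h_min <- n_a %% 2L
  h_max <- min(n_a, 2L * n - n_a)
  hs <- seq.int(h_min, h_max, by = 2L)
  ## unnormalized probabilities by upward recurrence from h_min
  w <- numeric(length(hs))
  w[1L] <- 1
  if (length(hs) > 1L) {
    for (i in seq_len(length(hs) - 1L)) {
      h <- hs[i]
      hom_alt <- (n_a - h) / 2
      hom_ref <- n - h - hom_alt
      w[i + 1L] <- w[i] * 4 * hom_alt * hom_ref / ((h + 2) * (h + 1))
    }
  }
  w <- w / sum(w)
  p_obs <- w[match(n_het, hs)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(w[w <= p_obs * (1 + 1e-9)]))
}

#' Filter sites by exact Hardy-Weinberg test
#'
#' Pools called genotypes at each site (across all samples by default, or
#' within each population with `per_population = TRUE`, where a site is
#' removed if it deviates in any population) and removes sites with exact
#' p-value below `alpha`.
#'
#' @param gm A [genotype_matrix()].
#' @param vt The aligned [variant_table()].
#' @param pmap Optional [population_map()]; required for
#'   `per_population = TRUE`.
#' @param alpha Significance threshold (default 0.001); `alpha = 0` removes
#'   nothing.
#' @param per_population Test within populations instead of pooled.
#' @return List with `mask`, `report` and `p` (pooled p-values, or the
#'   per-site minimum across populations).
#' @export
hwe_filter <- function(gm, vt, pmap = NULL, alpha = 0.001,
                       per_population = FALSE) {
  groups <- if (per_population) {
    if (is.null(pmap)) stop("per_population HWE filtering needs a population map")
    population_indices(pmap, gm, warn = FALSE)
  } else {
    list(pooled = seq_len(nrow(gm$dosages)))
  }
  p <- rep(1, ncol(gm$dosages))
  for (rows in groups) {
    d <- gm$dosages[rows, , drop = FALSE]
    n0 <- colSums(d == 0L, na.rm = TRUE)
    n1 <- colSums(d == 1L, na.rm = TRUE)
    n2 <- colSums(d == 2L, na.rm = TRUE)
    pg <- vapply(seq_along(n0), function(j) {
      if (n0[j] + n1[j] + n2[j] == 0L) return(1)
      hwe_exact_test(n0[j], n1[j], n2[j])
    }, numeric(1))
    p <- pmin(p, pg)
  }
  keep <- !(p < alpha)
  list(mask = keep, p = p,
       report = filter_report("hwe", nrow(vt), sum(!keep),
                              sprintf("alpha=%g,per_population=%s",
                                      alpha, per_population)))
}

#' Run the full hard-filter cascade
#'
#' Applies, in order: site annotations (QD/FS), SNP-cluster removal,
#' per-genotype depth masking (skipped when no depths are present), the
#' missingness/MAF filter (so depth-masked cells count as missing), and the
#' exact HWE filter. Filter reports chain: each stage's input is the previous
#' stage's retained sites.
#'
#' @param gm A [genotype_matrix()].
#' @param vt The aligned [variant_table()].
#' @param pmap Optional [population_map()] for per-population HWE.
#' @param qd_min,fs_max See [filter_site_annotations()].
#' @param cluster_window,cluster_max See [filter_snp_clusters()].
#' @param min_dp,max_dp See [mask_genotypes_by_depth()]; set to `NULL` to
#'   skip depth masking.
#' @param max_missing_frac,maf_min See [filter_missing_maf()].
#' @param hwe_alpha,hwe_per_population See [hwe_filter()].
#' @return List with `genotypes`, `variants` (filtered, `site_id` renumbered),
#'   `report` (stacked per-stage reports) and `kept_site_id` (original site
#'   IDs retained).
#' @export
filter_pipeline <- function(gm, vt, pmap = NULL,
                            qd_min = 2.0, fs_max = 30.0,
                            cluster_window = 35, cluster_max = 3,
                            min_dp = 10, max_dp = 60,
                            max_missing_frac = 0.1, maf_min = 0.05,
                            hwe_alpha = 0.001, hwe_per_population = FALSE) {
  orig_id <- vt$site_id
  reports <- list()
  take <- function(mask) {
    vt <<- vt[mask, , drop = FALSE]
    orig_id <<- orig_id[mask]
    gm <<- subset_genotypes(gm, sites = which(mask))
  }

  st <- filter_site_annotations(vt, qd_min, fs_max)
  reports$annotations <- st$report; take(st$mask)

  st <- filter_snp_clusters(vt, cluster_window, cluster_max)
  reports$clusters <- st$report; take(st$mask)

  if (!is.null(min_dp) && !is.null(gm$depths)) {
    gm <- mask_genotypes_by_depth(gm, min_dp, max_dp)
    reports$depth <- filter_report(
      "depth_mask", nrow(vt), 0L,
      sprintf("min_dp=%g,max_dp=%g,cells_masked=%d",
              min_dp, max_dp, attr(gm, "n_masked")))
  }

  st <- filter_missing_maf(gm, vt, max_missing_frac, maf_min)
  reports$missing_maf <- st$report; take(st$mask)

  st <- hwe_filter(gm, vt, pmap, hwe_alpha, hwe_per_population)
  reports$hwe <- st$report; take(st$mask)

  vt2 <- vt
  vt2$site_id <- seq_len(nrow(vt2))
  report <- do.call(rbind, reports)
  rownames(report) <- NULL
  list(genotypes = gm, variants = vt2, report = report, kept_site_id = orig_id)
}
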