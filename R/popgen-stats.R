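## Per-population diversity: observed/expected heterozygosity, per-individual
## inbreeding coefficients, and sliding-window nucleotide diversity.

#' Observed heterozygosity per site and its mean
#'
#' Per-site HO is the fraction of called genotypes that are heterozygous;
#' missing calls are excluded from the denominator. The mean is over sites
#' with at least one called genotype.
#'
#' @param gm A [genotype_matrix()].
#' @param pop_samples Row indices (or sample names) of the population's
#'   samples; default all samples.
#' @return List with `per_site` (numeric vector, `NA` where no calls) and
#'   `mean`.
#' @export
observed_heterozygosity <- function(gm, pop_samples = NULL) {
  rows <- resolve_rows(gm, pop_samples)
  d <- gm$dosages[rows, , drop = FALSE]
  n_called <- colSums(!is.na(d))
  ho <- ifelse(n_called > 0L, colSums(d == 1L, na.rm = TRUE) / n_called,
               NA_real_)
  if (all(n_called == 0L)) warning("observed_heterozygosity: no callable sites")
  list(per_site = ho, mean = mean(ho, na.rm = TRUE))
}

#' Expected heterozygosity per site and its mean
#'
#' Per-site HE is `2p(1-p)` from called allele counts; the unbiased variant
#' multiplies by `n/(n-1)` with `n` the called allele count (Nei's unbiased
#' gene diversity).
#'
#' @inheritParams observed_heterozygosity
#' @param unbiased Apply the small-sample `n/(n-1)` correction.
#' @return List with `per_site` and `mean`.
#' @export
expected_heterozygosity <- function(gm, pop_samples = NULL, unbiased = FALSE) {
  rows <- resolve_rows(gm, pop_samples)
  ac <- site_allele_counts(gm, rows)
  p <- ifelse(ac$n > 0L, ac$ac / ac$n, NA_real_)
  he <- 2 * p * (1 - p)
  if (unbiased) {
    he <- ifelse(ac$n > 1L, he * ac$n / (ac$n - 1L), NA_real_)
  }
  list(per_site = he, mean = mean(he, na.rm = TRUE))
}

#' Per-individual inbreeding coefficients and population mean
#'
#' Method-of-moments F for each individual (the PLINK `--het` form): over the
#' individual's called sites, `F = (O_hom - E_hom) / (L - E_hom)`, where
#' `O_hom` is the observed count of homozygous genotypes, `L` the number of
#' called sites, and `E_hom = sum_site (1 - 2p(1-p) * n/(n-1))` the expected
#' homozygous count under Hardy-Weinberg at the population allele
#' frequencies (n = called allele count at the site). Individuals with
#' `L - E_hom` near zero are excluded with a warning. Alternatively,
#' `method = "ratio"` returns the population-level `1 - HO/HE`.
#'
#' @inheritParams observed_heterozygosity
#' @param method `"mom"` (per-individual method of moments, default) or
#'   `"ratio"` (`1 - HO/HE` over mean heterozygosities).
#' @return List with `per_individual` (named numeric, `NA` for excluded
#'   individuals; empty for `method = "ratio"`) and `mean`.
#' @export
inbreeding_fis <- function(gm, pop_samples = NULL, method = c("mom", "ratio")) {
  method <- match.arg(method)
  rows <- resolve_rows(gm, pop_samples)
  if (method == "ratio") {
    ho <- observed_heterozygosity(gm, rows)$mean
    he <- expected_heterozygosity(gm, rows, unbiased = TRUE)$mean
    return(list(per_individual = numeric(0), mean = 1 - ho / he))
  }
  ac <- site_allele_counts(gm, rows)
  p <- ifelse(ac$n > 0L, ac$ac / ac$n, NA_real_)
  ## expected homozygosity per site, unbiased (PLINK convention)
  e_hom_site <- ifelse(ac$n > 1L,
                       1 - 2 * p * (1 - p) * ac$n / (ac$n - 1L), NA_real_)
  usable <- !is.na(e_hom_site)
  d <- gm$dosages[rows, usable, drop = FALSE]
  e <- e_hom_site[usable]
  f <- vapply(seq_len(nrow(d)), function(i) {
    called <- !is.na(d[i, ])
    L <- sum(called)
    if (L == 0L) return(NA_real_)
    o_hom <- sum(d[i, called] != 1L)
    e_hom <- sum(e[called])
    denom <- L - e_hom
    if (abs(denom) < 1e-9) return(NA_real_)
    (o_hom - e_hom) / denom
  }, numeric(1))
  names(f) <- gm$samples[rows]
  if (anyNA(f)) {
    warning(sprintf("inbreeding_fis: %d individual(s) excluded (no usable sites)",
                    sum(is.na(f))))
  }
  list(per_individual = f, mean = mean(f, na.rm = TRUE))
}

## Per-site nucleotide diversity: average pairwise difference among called
## alleles, 2 * c_ref * c_alt / (n * (n - 1)).
per_site_pi <- function(gm, rows) {
  ac <- site_allele_counts(gm, rows)
  n <- ac$n
  ifelse(n > 1L, 2 * ac$ac * (n - ac$ac) / (n * (n - 1)), NA_real_)
}

#' Sliding-window nucleotide diversity
#'
#' Per-site pi is the mean pairwise difference among called alleles,
#' `2 * c_ref * c_alt / (n(n-1))`. Window pi sums per-site pi over the SNPs
#' in each half-open window `[start, start + window_bp)` and divides by the
#' window length in bp (VCFtools windowed-pi convention; set
#' `denominator = "snps"` to divide by the SNP count instead). Windows with
#' no SNPs report `pi = 0` and `n_snps = 0`.
#'
#' @inheritParams observed_heterozygosity
#' @param vt The aligned [variant_table()] (sorted by chrom, pos).
#' @param window_bp Window size in bp (default 100 kb).
#' @param step_bp Step between window starts in bp (default 10 kb).
#' @param denominator `"window"` (per-base over window length, default) or
#'   `"snps"`.
#' @return `data.frame`: `chrom`, `start`, `end` (1-based inclusive span),
#'   `n_snps`, `pi`.
#' @export
windowed_pi <- function(gm, vt, pop_samples = NULL, window_bp = 100000,
                        step_bp = 10000, denominator = c("window", "snps")) {
  denominator <- match.arg(denominator)
  rows <- resolve_rows(gm, pop_samples)
  pi_s <- per_site_pi(gm, rows)
  pi_s[is.na(pi_s)] <- 0      # sites with no calls in this population
  out <- lapply(split(seq_len(nrow(vt)), vt$chrom), function(idx) {
    ws <- window_sums(vt$pos[idx], list(pi_sum = pi_s[idx]),
                      window_bp, step_bp)
    ws$pi <- if (denominator == "window") {
      ws$pi_sum / window_bp
    } else {
      ifelse(ws$n_snps > 0L, ws$pi_sum / ws$n_snps, 0)
    }
    ws$pi_sum <- NULL
    ws
  })
  chroms <- unique(vt$chrom)
  out <- out[chroms]
  res <- data.frame(chrom = rep(chroms, vapply(out, nrow, integer(1))),
                    do.call(rbind, out), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Per-population diversity summary table
#'
#' One row per population: mean observed heterozygosity (HO), mean expected
#' heterozygosity (HE, unbiased), mean per-base nucleotide diversity over
#' non-overlapping windows, and the inbreeding coefficient F_IS.
#'
#' @param gm A [genotype_matrix()].
#' @param vt The aligned [variant_table()].
#' @param pmap A [population_map()].
#' @param window_bp Window for the pi column (non-overlapping; default 100 kb).
#' @param fis_method Passed to [inbreeding_fis()].
#' @return `data.frame`: `population`, `n`, `ho`, `he`, `pi`, `fis`.
#' @export
diversity_table <- function(gm, vt, pmap, window_bp = 100000,
                            fis_method = "mom") {
  pops <- population_indices(pmap, gm)
  rows <- lapply(names(pops), function(pop) {
    idx <- pops[[pop]]
    pw <- windowed_pi(gm, vt, idx, window_bp = window_bp, step_bp = window_bp)
    data.frame(population = pop, n = length(idx),
               ho = observed_heterozygosity(gm, idx)$mean,
               he = expected_heterozygosity(gm, idx, unbiased = TRUE)$mean,
               pi = mean(pw$pi),
               fis = inbreeding_fis(gm, idx, method = fis_method)$mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

resolve_rows <- function(gm, pop_samples) {
  if (is.null(pop_samples)) return(seq_len(nrow(gm$dosages)))
  if (is.character(pop_samples)) {
    rows <- match(pop_samples, gm$samples)
    if (anyNA(rows)) stop("unknown sample name(s) in pop_samples")
    return(rows)
  }
  pop_samples
}
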