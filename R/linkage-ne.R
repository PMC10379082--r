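## Pairwise linkage disequilibrium (composite genotype r^2), distance-binned
## decay curves, and Sved-type LD-based effective population size.

#' Genotypic r-squared between two sites
#'
#' Squared Pearson correlation of allele dosages over the individuals called
#' at both sites (composite genotypic LD; no phasing). Undefined (`NA`) when
#' fewer than two shared calls or either site has zero dosage variance among
#' them.
#'
#' @param g1,g2 Integer dosage vectors (`{0,1,2,NA}`) of equal length.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
genotype_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' All intra-chromosomal LD pairs within a distance limit
#'
#' Sites are first screened on minor-allele frequency and missingness; on
#' chromosomes with more than `max_snps_per_chrom` qualifying sites, sites
#' are thinned by uniform random subsampling (reproducible under the seed).
#' Every remaining intra-chromosomal pair with position difference
#' `<= max_dist` contributes one `(distance, r2)` record; pairs with
#' undefined r-squared are skipped.
#'
#' @param gm A [genotype_matrix()].
#' @param vt The aligned [variant_table()].
#' @param max_dist Maximum pair distance in bp (default 100 kb).
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param max_missing Maximum missing-call fraction per site (default 0.1).
#' @param max_snps_per_chrom Per-chromosome site cap before pairing
#'   (default 10000).
#' @param seed Seed for the thinning subsample (default 1).
#' @return `data.frame`: `chrom`, `dist`, `r2`.
#' @export
ld_pairs <- function(gm, vt, max_dist = 100000, maf_min = 0.05,
                     max_missing = 0.1, max_snps_per_chrom = 10000,
                     seed = 1) {
  ac <- site_allele_counts(gm)
  n_samp <- nrow(gm$dosages)
  p <- ifelse(ac$n > 0L, ac$ac / ac$n, NA_real_)
  maf <- pmin(p, 1 - p)
  pass <- !is.na(maf) & maf >= maf_min & (1 - ac$n_gt / n_samp) <= max_missing

  if (!is.null(seed)) set.seed(seed)
  chunks <- lapply(split(which(pass), vt$chrom[pass]), function(idx) {
    if (length(idx) > max_snps_per_chrom) {
      idx <- sort(sample(idx, max_snps_per_chrom))
    }
    if (length(idx) < 2L) return(NULL)
    pos <- vt$pos[idx]
    d <- gm$dosages[, idx, drop = FALSE]
    res_d <- vector("list", length(idx) - 1L)
    res_r <- vector("list", length(idx) - 1L)
    for (i in seq_len(length(idx) - 1L)) {
      j_hi <- findInterval(pos[i] + max_dist, pos)
      if (j_hi <= i) next
      js <- (i + 1L):j_hi
      r2 <- suppressWarnings(
        as.numeric(stats::cor(d[, i], d[, js, drop = FALSE],
                              use = "pairwise.complete.obs"))^2)
      keep <- !is.na(r2)
      res_d[[i]] <- pos[js][keep] - pos[i]
      res_r[[i]] <- r2[keep]
    }
    data.frame(dist = unlist(res_d), r2 = unlist(res_r))
  })
  chunks <- chunks[!vapply(chunks, is.null, logical(1))]
  if (!length(chunks)) {
    return(data.frame(chrom = character(0), dist = integer(0),
                      r2 = numeric(0)))
  }
  out <- data.frame(chrom = rep(names(chunks),
                                vapply(chunks, nrow, integer(1))),
                    do.call(rbind, chunks), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Default LD distance-bin scheme
#'
#' One linear bin for 0-1 kb, then logarithmically spaced bins up to
#' `max_dist`.
#'
#' @param max_dist Largest distance covered (default 100 kb).
#' @param n_log Number of logarithmic bins above 1 kb (default 15).
#' @return `data.frame` with `dist_lo`, `dist_hi` (half-open `(lo, hi]`
#'   except the first bin, which includes 0).
#' @export
ld_bin_scheme <- function(max_dist = 100000, n_log = 15) {
  edges <- if (max_dist <= 1000) {
    c(0, max_dist)
  } else {
    c(0, 1000, exp(seq(log(1000), log(max_dist),
                       length.out = n_log + 1L))[-1L])
  }
  edges <- unique(round(edges))
  data.frame(dist_lo = edges[-length(edges)], dist_hi = edges[-1L])
}

#' Distance-binned LD decay curve
#'
#' Mean r-squared per distance bin, plus the sample-size-adjusted mean
#' `mean_r2 - 1/(2n)` used for Ne estimation. Empty bins are dropped.
#'
#' @param pairs Output of [ld_pairs()].
#' @param bins Bin scheme as from [ld_bin_scheme()]; default spans the
#'   observed distances.
#' @param n Number of diploid individuals (for the adjusted column; default
#'   `NA` leaves it unset).
#' @return `data.frame`: `dist_lo`, `dist_hi`, `n_pairs`, `mean_r2`,
#'   `mean_r2_adj`.
#' @export
ld_decay_bins <- function(pairs, bins = NULL, n = NA) {
  stopifnot(nrow(pairs) >= 1L)
  if (is.null(bins)) bins <- ld_bin_scheme(max(pairs$dist))
  idx <- findInterval(pairs$dist, c(bins$dist_lo[1L], bins$dist_hi),
                      left.open = TRUE, rightmost.closed = FALSE)
  idx[pairs$dist <= bins$dist_hi[1L]] <- 1L     # first bin includes 0
  ok <- idx >= 1L & idx <= nrow(bins)
  mean_r2 <- tapply(pairs$r2[ok], idx[ok], mean)
  n_pairs <- tapply(pairs$r2[ok], idx[ok], length)
  bi <- as.integer(names(mean_r2))
  out <- data.frame(dist_lo = bins$dist_lo[bi], dist_hi = bins$dist_hi[bi],
                    n_pairs = as.integer(n_pairs),
                    mean_r2 = as.numeric(mean_r2))
  out$mean_r2_adj <- out$mean_r2 - 1 / (2 * n)
  rownames(out) <- NULL
  out
}

#' LD-based effective population size trajectory
#'
#' Applies the Sved-type relation per distance bin: with recombination
#' fraction `c` (Morgans) at the bin's midpoint distance under a constant
#' physical-to-genetic map, and the sample-size-adjusted
#' `r2_adj = mean_r2 - 1/(2n)`,
#' `Ne = (1/(4c)) * (1/r2_adj - alpha)`, dated to `t = 1/(2c)` generations
#' ago. Bins with non-positive `c` or non-positive adjusted r-squared give
#' no estimate.
#'
#' @param bins Output of [ld_decay_bins()] (needs `mean_r2`).
#' @param n Number of diploid individuals sampled.
#' @param bp_per_cM Physical distance per centimorgan (default 1e6, i.e.
#'   1 cM/Mb, the conventional assumption when no map exists).
#' @param alpha Mutation adjustment: 1 (no adjustment, default) or 2.2.
#' @return `data.frame`: `t` (generations ago), `ne`, `c`, `dist_mid`,
#'   `mean_r2_adj`; one row per estimable bin.
#' @export
ne_from_ld <- function(bins, n, bp_per_cM = 1e6, alpha = 1) {
  stopifnot(n >= 2, all(bins$n_pairs >= 1))
  mid <- (bins$dist_lo + bins$dist_hi) / 2
  cc <- mid / bp_per_cM / 100                       # Morgans
  r2_adj <- bins$mean_r2 - 1 / (2 * n)
  ne <- (1 / (4 * cc)) * (1 / r2_adj - alpha)
  t <- 1 / (2 * cc)
  ok <- cc > 0 & r2_adj > 0 & ne > 0
  out <- data.frame(t = t, ne = ne, c = cc, dist_mid = mid,
                    mean_r2_adj = r2_adj)[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}
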