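## Two-population selective-sweep scan: per-site Weir-Cockerham (1984)
## variance components, sliding-window FST, Z(FST), log2 pi-ratio, joint
## top-quantile outlier calling, region merging and gene annotation.

#' Per-site Weir-Cockerham variance components for two populations
#'
#' Computes the Weir & Cockerham (1984) among-population variance component
#' `a` and the total `a + b + c` for each biallelic site from the two
#' populations' genotype counts (homozygous reference, heterozygous,
#' homozygous alternate). The per-site estimator is `a / (a + b + c)`, which
#' may be negative; sites monomorphic across both populations, or with
#' fewer than two called alleles in either population, get components
#' `(0, 0)` and are excluded from ratios downstream.
#'
#' @param counts_a,counts_b Numeric matrices (`n_sites x 3`) or length-3
#'   vectors of genotype counts `(n_hom_ref, n_het, n_hom_alt)`.
#' @return `data.frame` with columns `a`, `abc` and `fst`
#'   (`NA` where undefined).
#' @export
site_fst_components <- function(counts_a, counts_b) {
  ca <- to_count_matrix(counts_a)
  cb <- to_count_matrix(counts_b)
  stopifnot(nrow(ca) == nrow(cb))
  n1 <- rowSums(ca); n2 <- rowSums(cb)             # called diploids
  p1 <- (ca[, 3L] + ca[, 2L] / 2) / n1             # alt allele frequency
  p2 <- (cb[, 3L] + cb[, 2L] / 2) / n2
  h1 <- ca[, 2L] / n1                              # observed het fraction
  h2 <- cb[, 2L] / n2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar   # r - 1 = 1
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  inner <- pbar * (1 - pbar) - s2 / 2 - hbar / 4
  a <- (nbar / nc) * (s2 - inner / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  usable <- n1 >= 1 & n2 >= 1 & nbar > 1 & nc > 0 &
    !(pbar %in% c(0, 1))                            # monomorphic overall
  a[!usable] <- 0
  abc <- a + b + cc
  abc[!usable] <- 0
  fst <- ifelse(usable & abc != 0, a / abc, NA_real_)
  data.frame(a = a, abc = abc, fst = fst)
}

to_count_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L)
  x
}

## Genotype count matrix (n_sites x 3) for one set of sample rows.
genotype_counts <- function(gm, rows) {
  d <- gm$dosages[rows, , drop = FALSE]
  cbind(colSums(d == 0L, na.rm = TRUE),
        colSums(d == 1L, na.rm = TRUE),
        colSums(d == 2L, na.rm = TRUE))
}

#' Sliding-window Weir-Cockerham FST
#'
#' Window FST is the ratio of sums `sum(a) / sum(a + b + c)` over the
#' informative sites in each half-open window `[start, start + window_bp)`
#' (the "weighted" VCFtools estimator). Windows with fewer than `min_snps`
#' informative sites, or a zero total component, report `NA`.
#'
#' @param comp Per-site components from [site_fst_components()].
#' @param vt The aligned [variant_table()].
#' @param window_bp,step_bp Window size and step (defaults 100 kb / 10 kb).
#' @param min_snps Minimum informative SNPs per window (default 1).
#' @return `data.frame`: `chrom`, `start`, `end`, `n_snps` (informative
#'   sites), `fst`.
#' @export
windowed_fst <- function(comp, vt, window_bp = 100000, step_bp = 10000,
                         min_snps = 1) {
  informative <- comp$abc != 0
  out <- lapply(split(seq_len(nrow(vt)), vt$chrom), function(idx) {
    ws <- window_sums(vt$pos[idx],
                      list(a = ifelse(informative[idx], comp$a[idx], 0),
                           abc = ifelse(informative[idx], comp$abc[idx], 0),
                           inf = as.numeric(informative[idx])),
                      window_bp, step_bp)
    ws$n_snps <- as.integer(ws$inf)
    ws$fst <- ifelse(ws$n_snps >= min_snps & ws$abc != 0, ws$a / ws$abc,
                     NA_real_)
    ws[c("start", "end", "n_snps", "fst")]
  })
  chroms <- unique(vt$chrom)
  out <- out[chroms]
  res <- data.frame(chrom = rep(chroms, vapply(out, nrow, integer(1))),
                    do.call(rbind, out), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Z-transform a vector of per-window statistics
#'
#' `z = (x - mean) / sd` over finite values, with the sample standard
#' deviation (denominator `n - 1`). Non-finite entries stay `NA`.
#'
#' @param values Numeric vector.
#' @return Numeric vector of z-scores.
#' @export
z_transform <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2L) stop("z_transform needs >= 2 finite values")
  s <- stats::sd(values[ok])
  if (s == 0) stop("z_transform: zero spread")
  out <- rep(NA_real_, length(values))
  out[ok] <- (values[ok] - mean(values[ok])) / s
  out
}

#' log2 ratio of window nucleotide diversities
#'
#' `log2(pi_a / pi_b)`, oriented reference over focal so that large positive
#' values indicate diversity loss in the focal population. Windows where
#' either diversity is zero (or missing) are undefined (`NA`) and are
#' excluded from quantile computation downstream.
#'
#' @param pi_a,pi_b Non-negative window diversities (reference, focal).
#' @return Numeric vector; `NA` where undefined.
#' @export
log2_pi_ratio <- function(pi_a, pi_b) {
  stopifnot(all(pi_a >= 0, na.rm = TRUE), all(pi_b >= 0, na.rm = TRUE))
  ifelse(!is.na(pi_a) & !is.na(pi_b) & pi_a > 0 & pi_b > 0,
         log2(pi_a / pi_b), NA_real_)
}

#' Joint top-quantile outlier windows
#'
#' Thresholds are the empirical `quantile` (default 95th percentile, type-7
#' linear interpolation) of `z_fst` and of `log2_pi_ratio`, each over the
#' windows where both statistics are defined. A window is an outlier iff it
#' meets or exceeds both thresholds simultaneously.
#'
#' @param z_fst,log2_ratio Per-window statistics (same length).
#' @param quantile Quantile for both thresholds (default 0.95).
#' @param min_windows Minimum number of jointly defined windows (default 20).
#' @return List with `outlier` (logical vector, `FALSE` where undefined),
#'   `z_threshold`, `ratio_threshold`, `n_defined`.
#' @export
joint_outliers <- function(z_fst, log2_ratio, quantile = 0.95,
                           min_windows = 20) {
  stopifnot(length(z_fst) == length(log2_ratio))
  defined <- is.finite(z_fst) & is.finite(log2_ratio)
  if (sum(defined) < min_windows) {
    stop(sprintf("joint_outliers: only %d window(s) with both statistics defined (need >= %d)",
                 sum(defined), min_windows))
  }
  t_z <- stats::quantile(z_fst[defined], quantile, names = FALSE, type = 7)
  t_r <- stats::quantile(log2_ratio[defined], quantile, names = FALSE, type = 7)
  out <- defined & z_fst >= t_z & log2_ratio >= t_r
  list(outlier = out, z_threshold = t_z, ratio_threshold = t_r,
       n_defined = sum(defined))
}

#' Merge outlier windows into sweep regions and attach genes
#'
#' Maximal runs of overlapping or adjacent outlier windows on a chromosome
#' are merged into regions; genes overlapping a region by at least 1 bp are
#' attached (deduplicated).
#'
#' @param windows `data.frame` with `chrom`, `start`, `end`, `z_fst`,
#'   `log2_pi_ratio` and logical `outlier` columns (e.g. from [sweep_scan()]).
#' @param genes Optional gene intervals as returned by [read_gff_genes()].
#' @return `data.frame`: `chrom`, `start`, `end`, `n_windows`, `peak_z_fst`,
#'   `peak_log2_pi_ratio`, `genes` (semicolon-joined IDs, `""` if none).
#' @export
merge_and_annotate <- function(windows, genes = NULL) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      peak_z_fst = numeric(0), peak_log2_pi_ratio = numeric(0),
                      genes = character(0), stringsAsFactors = FALSE)
  ow <- windows[which(windows$outlier), , drop = FALSE]
  if (nrow(ow) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(ow$chrom,
                               IRanges::IRanges(ow$start, ow$end))
  regions <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  hit <- GenomicRanges::findOverlaps(gr, regions)
  ri <- S4Vectors::subjectHits(hit)
  peak_z <- tapply(ow$z_fst[S4Vectors::queryHits(hit)], ri, max)
  peak_r <- tapply(ow$log2_pi_ratio[S4Vectors::queryHits(hit)], ri, max)
  n_win <- tabulate(ri, nbins = length(regions))
  gene_str <- rep("", length(regions))
  if (!is.null(genes) && nrow(genes) > 0L) {
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
    gh <- GenomicRanges::findOverlaps(gg, regions)
    if (length(gh)) {
      by_region <- split(genes$gene_id[S4Vectors::queryHits(gh)],
                         S4Vectors::subjectHits(gh))
      gene_str[as.integer(names(by_region))] <-
        vapply(by_region, function(g) paste(unique(g), collapse = ";"),
               character(1))
    }
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
             start = GenomicRanges::start(regions),
             end = GenomicRanges::end(regions),
             n_windows = n_win,
             peak_z_fst = as.numeric(peak_z),
             peak_log2_pi_ratio = as.numeric(peak_r),
             genes = gene_str, stringsAsFactors = FALSE)
}

#' Two-population selective-sweep scan
#'
#' Runs the full scan for one population pair: sliding-window nucleotide
#' diversity in each population, windowed Weir-Cockerham FST, Z(FST), the
#' log2 pi-ratio oriented `log2(pi[reference] / pi[focal])`, joint
#' top-quantile outlier calling, and region merging with optional gene
#' annotation.
#'
#' @param gm A [genotype_matrix()].
#' @param vt The aligned [variant_table()].
#' @param pmap A [population_map()].
#' @param pop_ref,pop_focal Population labels: the reference (e.g. wild)
#'   population and the focal (e.g. farmed) population whose diversity loss
#'   is scanned for.
#' @param window_bp,step_bp Window size and step (defaults 100 kb / 10 kb).
#' @param quantile Outlier quantile for both statistics (default 0.95).
#' @param genes Optional gene intervals ([read_gff_genes()]).
#' @param min_snps Minimum informative SNPs per window for FST (default 1).
#' @return List with `windows` (per-window statistics incl. `outlier`),
#'   `z_threshold`, `ratio_threshold`, and `regions`
#'   (see [merge_and_annotate()]).
#' @export
sweep_scan <- function(gm, vt, pmap, pop_ref, pop_focal,
                       window_bp = 100000, step_bp = 10000, quantile = 0.95,
                       genes = NULL, min_snps = 1) {
  pops <- population_indices(pmap, gm, warn = FALSE)
  for (p in c(pop_ref, pop_focal)) {
    if (!p %in% names(pops)) stop("unknown population label: ", p)
  }
  rows_a <- pops[[pop_ref]]
  rows_b <- pops[[pop_focal]]
  comp <- site_fst_components(genotype_counts(gm, rows_a),
                              genotype_counts(gm, rows_b))
  pi_a_site <- per_site_pi(gm, rows_a)
  pi_b_site <- per_site_pi(gm, rows_b)
  pi_a_site[is.na(pi_a_site)] <- 0
  pi_b_site[is.na(pi_b_site)] <- 0
  informative <- comp$abc != 0

  out <- lapply(split(seq_len(nrow(vt)), vt$chrom), function(idx) {
    ws <- window_sums(vt$pos[idx],
                      list(a = comp$a[idx], abc = comp$abc[idx],
                           pi_a = pi_a_site[idx], pi_b = pi_b_site[idx],
                           inf = as.numeric(informative[idx])),
                      window_bp, step_bp)
    ws$fst <- ifelse(ws$inf >= min_snps & ws$abc != 0, ws$a / ws$abc, NA_real_)
    ws$pi_a <- ws$pi_a / window_bp
    ws$pi_b <- ws$pi_b / window_bp
    ws
  })
  chroms <- unique(vt$chrom)
  out <- out[chroms]
  win <- data.frame(chrom = rep(chroms, vapply(out, nrow, integer(1))),
                    do.call(rbind, out), stringsAsFactors = FALSE)
  rownames(win) <- NULL
  win$z_fst <- z_transform(win$fst)
  win$log2_pi_ratio <- log2_pi_ratio(win$pi_a, win$pi_b)
  jo <- joint_outliers(win$z_fst, win$log2_pi_ratio, quantile = quantile)
  win$outlier <- jo$outlier
  win <- win[c("chrom", "start", "end", "n_snps", "pi_a", "pi_b", "fst",
               "z_fst", "log2_pi_ratio", "outlier")]
  list(windows = win,
       z_threshold = jo$z_threshold,
       ratio_threshold = jo$ratio_threshold,
       regions = merge_and_annotate(win, genes))
}
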