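#' radsweep: population-genomic diversity, differentiation and sweep scans
#'
#' Post-variant-calling population genomics for SNP genotype data: variant
#' filtering, per-population diversity, windowed Weir-Cockerham FST with a
#' joint Z(FST) / log2 pi-ratio selective-sweep scan, LD decay, LD-based
#' effective population size, PCA and maximum-likelihood admixture, plus
#' Balding-Nichols and forward Wright-Fisher simulators with known truth.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a genotype matrix
#'
#' The substrate of every statistic in the package: an integer dosage matrix
#' of samples by biallelic sites, with dosage codes 0 (homozygous reference),
#' 1 (heterozygous), 2 (homozygous alternate) and `NA` for missing calls, and
#' an optional aligned matrix of per-genotype read depths.
#'
#' @param dosages Integer matrix, `n_samples x n_sites`, entries in
#'   `{0, 1, 2, NA}`.
#' @param samples Character vector of sample IDs, one per row of `dosages`.
#' @param depths Optional numeric matrix of per-genotype read depths with the
#'   same dimensions as `dosages`; entries must be non-negative.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `samples` and (possibly `NULL`) `depths`.
#' @export
genotype_matrix <- function(dosages, samples, depths = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (length(samples) != nrow(dosages)) {
    stop("length(samples) must equal nrow(dosages)")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosage codes must be 0, 1, 2 or NA")
  }
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    if (!all(dim(depths) == dim(dosages))) {
      stop("depths must have the same dimensions as dosages")
    }
    if (any(depths < 0, na.rm = TRUE)) stop("depths must be non-negative")
  }
  rownames(dosages) <- samples
  structure(list(dosages = dosages, samples = as.character(samples),
                 depths = depths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("genotype_matrix: %d samples x %d sites (%.1f%% missing%s)\n",
              nrow(x$dosages), ncol(x$dosages), 100 * miss,
              if (is.null(x$depths)) ", no depths" else ", with depths"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param gm A [genotype_matrix()].
#' @param samples Row index (integer, logical, or sample names); default all.
#' @param sites Column index; default all.
#' @return A `genotype_matrix` restricted to the requested cells.
#' @export
subset_genotypes <- function(gm, samples = NULL, sites = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(samples)) samples <- seq_len(nrow(gm$dosages))
  if (is.character(samples)) samples <- match(samples, gm$samples)
  if (anyNA(samples)) stop("unknown sample in subset")
  if (is.null(sites)) sites <- seq_len(ncol(gm$dosages))
  genotype_matrix(gm$dosages[samples, sites, drop = FALSE],
                  gm$samples[samples],
                  if (!is.null(gm$depths)) {
                    gm$depths[samples, sites, drop = FALSE]
                  })
}

#' Construct a variant table
#'
#' Per-site metadata aligned to the columns of a [genotype_matrix()]:
#' chromosome, 1-based position, single-nucleotide REF/ALT alleles and the
#' GATK site annotations QD (quality by depth) and FS (Fisher-strand phred
#' score), which may be `NA` when absent from the source VCF.
#'
#' @param chrom Character chromosome names.
#' @param pos Integer 1-based positions, strictly increasing within chrom.
#' @param ref,alt Single-character alleles.
#' @param qd,fs Numeric site annotations (`NA` allowed).
#' @return A `data.frame` of class `variant_table` with a stable `site_id`
#'   column equal to the row (and genotype-matrix column) index.
#' @export
variant_table <- function(chrom, pos, ref, alt, qd = NA_real_, fs = NA_real_) {
  n <- length(pos)
  vt <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   qd = rep_len(as.numeric(qd), n),
                   fs = rep_len(as.numeric(fs), n),
                   site_id = seq_len(n), stringsAsFactors = FALSE)
  by_chrom <- split(vt$pos, vt$chrom)
  if (any(vapply(by_chrom, function(p) any(diff(p) <= 0), logical(1)))) {
    stop("positions must be strictly increasing within each chromosome")
  }
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Construct / validate a population map
#'
#' @param sample Character sample IDs (unique).
#' @param population Character population labels, one per sample.
#' @return A `data.frame` of class `population_map` with columns `sample`,
#'   `population`.
#' @export
population_map <- function(sample, population) {
  if (anyDuplicated(sample)) stop("duplicate sample rows in population map")
  if (length(sample) != length(population) || length(sample) == 0L) {
    stop("sample and population must be non-empty and of equal length")
  }
  pm <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   stringsAsFactors = FALSE)
  class(pm) <- c("population_map", "data.frame")
  pm
}

#' Row indices of each population's samples in a genotype matrix
#'
#' @param pmap A [population_map()].
#' @param gm A [genotype_matrix()] (or a character vector of sample IDs).
#' @param warn Warn about samples present in only one of the two inputs.
#' @return Named list of integer row indices, one element per population.
#' @export
population_indices <- function(pmap, gm, warn = TRUE) {
  samples <- if (inherits(gm, "genotype_matrix")) gm$samples else gm
  idx <- match(pmap$sample, samples)
  if (warn && anyNA(idx)) {
    warning(sprintf("%d mapped sample(s) absent from genotypes, excluded: %s",
                    sum(is.na(idx)),
                    paste(utils::head(pmap$sample[is.na(idx)], 5),
                          collapse = ", ")))
  }
  if (warn && length(setdiff(samples, pmap$sample))) {
    warning(sprintf("%d genotyped sample(s) missing from population map",
                    length(setdiff(samples, pmap$sample))))
  }
  keep <- !is.na(idx)
  out <- split(idx[keep], pmap$population[keep])
  if (!length(out)) stop("no mapped sample matches the genotype matrix")
  out
}

## Per-site called allele counts within a set of samples: returns a list with
## n (called allele count), ac (alternate allele count) and het (het calls).
site_allele_counts <- function(gm, rows = seq_len(nrow(gm$dosages))) {
  d <- gm$dosages[rows, , drop = FALSE]
  called <- !is.na(d)
  n_gt <- colSums(called)
  list(n = 2L * n_gt,
       ac = colSums(d, na.rm = TRUE),
       het = colSums(d == 1L, na.rm = TRUE),
       n_gt = n_gt)
}

## Half-open sliding windows [start, start + window) on 1-based starts
## 1, 1 + step, ...; generated while start <= max_pos.
sliding_window_starts <- function(max_pos, window_bp, step_bp) {
  if (max_pos < 1L) return(integer(0))
  seq.int(1L, max_pos, by = step_bp)
}

## Sum per-site values over sliding windows on one chromosome.
## pos must be sorted. Returns data.frame(start, end, n_snps, <sums>).
window_sums <- function(pos, values, window_bp, step_bp, max_pos = NULL) {
  if (is.null(max_pos)) max_pos <- if (length(pos)) max(pos) else 0L
  starts <- sliding_window_starts(max_pos, window_bp, step_bp)
  if (!length(starts)) {
    return(cbind(data.frame(start = integer(0), end = integer(0),
                            n_snps = integer(0)),
                 as.data.frame(lapply(values, function(v) numeric(0)))))
  }
  ends <- starts + window_bp - 1L          # inclusive end of [start, start+w)
  ## prefix sums over sorted positions
  lo <- findInterval(starts - 1L, pos) + 1L  # first site with pos >= start
  hi <- findInterval(ends, pos)              # last site with pos <= end
  n_snps <- pmax(hi - lo + 1L, 0L)
  sums <- lapply(values, function(v) {
    cs <- c(0, cumsum(as.numeric(v)))
    out <- cs[hi + 1L] - cs[lo]
    out[n_snps == 0L] <- 0
    out
  })
  cbind(data.frame(start = starts, end = ends, n_snps = n_snps),
        as.data.frame(sums))
}
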