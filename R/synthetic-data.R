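## Synthetic genotype data with known truth: a site-independent
## Balding-Nichols generator (drift-structured populations, planted sweeps)
## and a forward Wright-Fisher simulator (linked variants for LD/Ne).

#' Simulate drift-structured genotypes under the Balding-Nichols model
#'
#' Site-independent generator: ancestral allele frequencies are drawn
#' uniformly on `(maf_range)`, each population's frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with its drift parameter `F` (at `F = 0`
#' the population frequency equals the ancestral one, and the expected
#' Weir-Cockerham FST between two populations with drift `F` is
#' approximately `F`), and genotypes as `Binomial(2, q)`. Missing calls are
#' Bernoulli, per-genotype depths negative-binomial, and the QD/FS site
#' annotations come from a benign distribution with optional planted
#' violations.
#'
#' @param n_pops Number of populations (default 2).
#' @param samples_per_pop Diploid samples per population (default 50).
#' @param n_chrom Number of chromosomes (default 5).
#' @param chrom_length_bp Chromosome length in bp (default 2e6).
#' @param n_snps Total SNP count, spread evenly over chromosomes
#'   (default 20000).
#' @param drift_f Per-population drift F, recycled to `n_pops`
#'   (default 0.1).
#' @param missing_rate Per-genotype missing probability (default 0.02).
#' @param depth_mean,depth_size Negative-binomial depth model (defaults 30
#'   and 8; mean 30 sits inside the 10-60 retention band so depth masking is
#'   exercised without destroying most calls).
#' @param maf_range Ancestral frequency range (default `c(0.05, 0.95)`).
#' @param n_qd_violations,n_fs_violations Number of random sites given
#'   failing QD (< 2) / FS (> 30) annotations (default 0).
#' @param pop_labels Population labels (default `POP1`, `POP2`, ...).
#' @param seed Mandatory seed.
#' @return List of class `radsweep_sim`: `variants`, `genotypes`, `pmap`,
#'   `contigs` (named lengths) and `truth` (drift F per population,
#'   ancestral and per-population frequencies, planted annotation
#'   violations, empty `sweep_regions`).
#' @export
simulate_balding_nichols <- function(n_pops = 2, samples_per_pop = 50,
                                     n_chrom = 5, chrom_length_bp = 2e6,
                                     n_snps = 20000, drift_f = 0.1,
                                     missing_rate = 0.02,
                                     depth_mean = 30, depth_size = 8,
                                     maf_range = c(0.05, 0.95),
                                     n_qd_violations = 0, n_fs_violations = 0,
                                     pop_labels = NULL, seed) {
  if (missing(seed)) stop("simulate_balding_nichols: seed is mandatory")
  stopifnot(n_pops >= 1, samples_per_pop >= 1, n_snps >= 1,
            missing_rate >= 0, missing_rate < 1)
  drift_f <- rep_len(drift_f, n_pops)
  stopifnot(all(drift_f >= 0), all(drift_f < 1))
  if (is.null(pop_labels)) pop_labels <- paste0("POP", seq_len(n_pops))
  set.seed(seed)

  ## positions: even split over chromosomes, uniform within
  per_chrom <- diff(round(seq(0, n_snps, length.out = n_chrom + 1L)))
  chroms <- paste0("chr", seq_len(n_chrom))
  chrom <- rep(chroms, per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) {
    sort(sample.int(chrom_length_bp, k))
  }))

  m <- n_snps
  p_anc <- stats::runif(m, maf_range[1L], maf_range[2L])
  pop_freq <- vapply(seq_len(n_pops), function(i) {
    f <- drift_f[i]
    if (f == 0) p_anc
    else stats::rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }, numeric(m))                                  # m x n_pops
  colnames(pop_freq) <- pop_labels

  n_total <- n_pops * samples_per_pop
  dos <- matrix(NA_integer_, n_total, m)
  for (i in seq_len(n_pops)) {
    rows <- (i - 1L) * samples_per_pop + seq_len(samples_per_pop)
    dos[rows, ] <- matrix(
      stats::rbinom(samples_per_pop * m, 2L,
                    rep(pop_freq[, i], each = samples_per_pop)),
      samples_per_pop, m)
  }
  if (missing_rate > 0) {
    dos[stats::runif(length(dos)) < missing_rate] <- NA_integer_
  }
  depths <- matrix(stats::rnbinom(n_total * m, mu = depth_mean,
                                  size = depth_size), n_total, m)

  qd <- stats::runif(m, 20, 35)
  fs <- stats::runif(m, 0, 10)
  qd_bad <- fs_bad <- integer(0)
  if (n_qd_violations > 0) {
    qd_bad <- sample.int(m, n_qd_violations)
    qd[qd_bad] <- stats::runif(n_qd_violations, 0, 1.9)
  }
  if (n_fs_violations > 0) {
    fs_bad <- sample.int(m, n_fs_violations)
    fs[fs_bad] <- stats::runif(n_fs_violations, 31, 60)
  }

  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1))
  vt <- variant_table(chrom, pos, ref, alt, qd, fs)
  samples <- paste0(rep(pop_labels, each = samples_per_pop), "_",
                    sprintf("%02d", rep(seq_len(samples_per_pop), n_pops)))
  gm <- genotype_matrix(dos, samples, depths)
  pmap <- population_map(samples, rep(pop_labels, each = samples_per_pop))
  contigs <- stats::setNames(rep(chrom_length_bp, n_chrom), chroms)
  truth <- list(model = "balding_nichols", seed = seed,
                drift_f = stats::setNames(as.list(drift_f), pop_labels),
                samples_per_pop = samples_per_pop,
                ancestral_freq = p_anc, pop_freq = pop_freq,
                missing_rate = missing_rate,
                qd_violation_sites = sort(qd_bad),
                fs_violation_sites = sort(fs_bad),
                sweep_regions = list())
  structure(list(variants = vt, genotypes = gm, pmap = pmap,
                 contigs = contigs, truth = truth),
            class = "radsweep_sim")
}

#' Plant selective-sweep signals into a Balding-Nichols simulation
#'
#' Within each region the focal population's allele frequencies are pushed
#' toward fixation of the alternate allele
#' (`q' = 1 - (1 - freq_shift) * (1 - q)`), and heterozygosity is further
#' reduced by a factor of about `pi_reduction` by setting a fraction
#' `1 - 1/pi_reduction` of the region's sites exactly to fixation. The focal
#' population's genotypes at those sites are redrawn; other populations are
#' untouched. Truth gains the planted region coordinates.
#'
#' @param sim A `radsweep_sim` from [simulate_balding_nichols()].
#' @param regions `data.frame` with columns `chrom`, `start`, `end`,
#'   `focal_pop`; regions must be disjoint and lie on existing chromosomes.
#' @param freq_shift Fraction of the way to fixation (default 0.98).
#' @param pi_reduction Target diversity-reduction factor (default 10).
#' @param seed Seed for the genotype redraw.
#' @return The modified `radsweep_sim` with updated truth.
#' @export
plant_sweeps <- function(sim, regions, freq_shift = 0.98, pi_reduction = 10,
                         seed = 1) {
  stopifnot(inherits(sim, "radsweep_sim"))
  if (nrow(regions) == 0L) return(sim)
  bad_chrom <- setdiff(regions$chrom, names(sim$contigs))
  if (length(bad_chrom)) stop("sweep region on nonexistent chromosome: ",
                              paste(bad_chrom, collapse = ", "))
  if (any(regions$start < 1) ||
      any(regions$end > sim$contigs[regions$chrom])) {
    stop("sweep region outside chromosome bounds")
  }
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  if (length(GenomicRanges::reduce(gr)) < length(gr)) {
    stop("sweep regions must be disjoint")
  }
  set.seed(seed)
  vt <- sim$variants
  gm <- sim$genotypes
  pops <- population_indices(sim$pmap, gm, warn = FALSE)
  for (r in seq_len(nrow(regions))) {
    focal <- regions$focal_pop[r]
    if (!focal %in% names(pops)) stop("unknown focal population: ", focal)
    rows <- pops[[focal]]
    sites <- which(vt$chrom == regions$chrom[r] &
                     vt$pos >= regions$start[r] & vt$pos <= regions$end[r])
    if (!length(sites)) next
    pop_i <- match(focal, colnames(sim$truth$pop_freq))
    if (is.na(pop_i)) pop_i <- match(focal, names(sim$truth$drift_f))
    q <- sim$truth$pop_freq[sites, pop_i]
    q_new <- 1 - (1 - freq_shift) * (1 - q)
    fix <- stats::runif(length(sites)) < (1 - 1 / pi_reduction)
    q_new[fix] <- 1
    sim$truth$pop_freq[sites, pop_i] <- q_new
    redraw <- matrix(stats::rbinom(length(rows) * length(sites), 2L,
                                   rep(q_new, each = length(rows))),
                     length(rows), length(sites))
    old <- gm$dosages[rows, sites, drop = FALSE]
    redraw[is.na(old)] <- NA_integer_          # keep the missingness pattern
    gm$dosages[rows, sites] <- redraw
  }
  sim$genotypes <- gm
  sim$truth$sweep_regions <- c(sim$truth$sweep_regions,
                               lapply(seq_len(nrow(regions)), function(r) {
                                 list(chrom = regions$chrom[r],
                                      start = regions$start[r],
                                      end = regions$end[r],
                                      focal_pop = regions$focal_pop[r],
                                      freq_shift = freq_shift,
                                      pi_reduction = pi_reduction)
                               }))
  sim
}

#' Forward Wright-Fisher simulation with recombination and mutation
#'
#' Discrete-generation forward simulation of `2N` haplotypes per population:
#' each offspring is the random union of two recombinant gametes (crossover
#' count Poisson with rate `rec * L` per gamete, breakpoints uniform),
#' mutation is infinite-sites (Poisson `mu * L` new sites per gamete at
#' uniform positions), and fixed sites are purged. The population is burnt
#' in from an initially monomorphic state for `burn_in` generations
#' (default `10 N`), optionally split into `n_pops` replicate populations
#' that drift independently for `split_generations`, and `sample_n` diploids
#' are drawn from each population without replacement.
#'
#' The default recombination rate is 1e-7 per bp per generation (10 cM/Mb),
#' so the default 1 Mb chromosome spans about 0.1 Morgans and linkage
#' disequilibrium decays appreciably across it.
#'
#' @param census_n Diploid census size N per population (<= 500).
#' @param chrom_length_bp Chromosome length L in bp (default 1e6).
#' @param mu Mutation rate per bp per generation (default 1e-6, tuned for
#'   roughly 2000 segregating sites in a 50-diploid sample at N = 100).
#' @param rec Recombination rate per bp per generation (default 1e-7).
#' @param burn_in Burn-in generations (default `10 * census_n`).
#' @param n_pops Number of populations after the optional split (default 1).
#' @param split_generations Generations of independent drift after the split
#'   (default `census_n`, used only when `n_pops > 1`).
#' @param sample_n Diploids sampled per population (default 50).
#' @param max_sites Guard on the number of segregating sites (default 2e5).
#' @param chrom_name Chromosome name in the output (default `"chr1"`).
#' @param seed Mandatory seed.
#' @return A `radsweep_sim` list (`variants`, `genotypes`, `pmap`, `contigs`,
#'   `truth` with census size, rates and map).
#' @export
simulate_wright_fisher <- function(census_n = 100, chrom_length_bp = 1e6,
                                   mu = 1e-6, rec = 1e-7, burn_in = NULL,
                                   n_pops = 1, split_generations = NULL,
                                   sample_n = 50, max_sites = 2e5,
                                   chrom_name = "chr1", seed) {
  if (missing(seed)) stop("simulate_wright_fisher: seed is mandatory")
  stopifnot(census_n >= 2, census_n <= 500, sample_n <= census_n)
  if (is.null(burn_in)) burn_in <- 10L * census_n
  if (is.null(split_generations)) split_generations <- census_n
  set.seed(seed)
  L <- chrom_length_bp
  n_hap <- 2L * census_n

  evolve <- function(haps, generations) {
    for (gen in seq_len(generations)) {
      new_haps <- vector("list", n_hap)
      parents <- sample.int(census_n, n_hap, replace = TRUE)
      n_cross <- stats::rpois(n_hap, rec * L)
      n_mut <- stats::rpois(n_hap, mu * L)
      first_hap <- sample.int(2L, n_hap, replace = TRUE)
      for (i in seq_len(n_hap)) {
        pa <- haps[[2L * parents[i] - 1L]]
        pb <- haps[[2L * parents[i]]]
        if (first_hap[i] == 2L) { tmp <- pa; pa <- pb; pb <- tmp }
        g <- if (n_cross[i] == 0L) {
          pa
        } else {
          breaks <- sort(stats::runif(n_cross[i], 0, L))
          seg_a <- findInterval(pa, breaks) %% 2L == 0L
          seg_b <- findInterval(pb, breaks) %% 2L == 1L
          sort(c(pa[seg_a], pb[seg_b]))
        }
        if (n_mut[i] > 0L) {
          newpos <- sample.int(L, n_mut[i])
          newpos <- newpos[!(newpos %in% g)]
          if (length(newpos)) g <- sort(c(g, newpos))
        }
        new_haps[[i]] <- g
      }
      haps <- new_haps
      if (gen %% 25L == 0L) {
        cnt <- table(unlist(haps))
        if (length(cnt) > max_sites) {
          stop("simulate_wright_fisher: segregating sites exceed max_sites; ",
               "reduce mu or chrom_length_bp")
        }
        fixed <- as.integer(names(cnt)[cnt == n_hap])
        if (length(fixed)) {
          haps <- lapply(haps, function(x) x[!(x %in% fixed)])
        }
      }
    }
    haps
  }

  haps <- rep(list(integer(0)), n_hap)
  haps <- evolve(haps, burn_in)
  pools <- if (n_pops > 1L) {
    lapply(seq_len(n_pops), function(i) evolve(haps, split_generations))
  } else {
    list(haps)
  }

  pop_labels <- paste0("POP", seq_len(n_pops))
  dos_list <- list()
  samples <- character(0)
  all_pos <- sort(unique(unlist(pools)))
  for (ip in seq_len(n_pops)) {
    h <- pools[[ip]]
    ids <- sample.int(census_n, sample_n)
    dos <- matrix(0L, sample_n, length(all_pos))
    for (s in seq_len(sample_n)) {
      dos[s, ] <- (all_pos %in% h[[2L * ids[s] - 1L]]) +
        (all_pos %in% h[[2L * ids[s]]])
    }
    dos_list[[ip]] <- dos
    samples <- c(samples, paste0(pop_labels[ip], "_",
                                 sprintf("%02d", seq_len(sample_n))))
  }
  dos <- do.call(rbind, dos_list)
  ## keep sites segregating in the pooled sample
  ac <- colSums(dos)
  seg <- ac > 0L & ac < 2L * nrow(dos)
  dos <- dos[, seg, drop = FALSE]
  pos <- all_pos[seg]
  m <- length(pos)
  if (m == 0L) stop("simulate_wright_fisher: no segregating sites in sample")
  vt <- variant_table(rep(chrom_name, m), pos,
                      rep("A", m), rep("C", m),
                      qd = stats::runif(m, 20, 35),
                      fs = stats::runif(m, 0, 10))
  gm <- genotype_matrix(dos, samples)
  pmap <- population_map(samples, rep(pop_labels, each = sample_n))
  truth <- list(model = "wright_fisher", seed = seed, census_n = census_n,
                mu = mu, rec = rec, burn_in = burn_in,
                bp_per_cM = 0.01 / rec,
                n_pops = n_pops, sample_n = sample_n,
                theta_per_bp = 4 * census_n * mu)
  structure(list(variants = vt, genotypes = gm, pmap = pmap,
                 contigs = stats::setNames(L, chrom_name), truth = truth),
            class = "radsweep_sim")
}

#' @export
print.radsweep_sim <- function(x, ...) {
  cat(sprintf("radsweep_sim (%s): %d samples x %d sites, %d chromosome(s)\n",
              x$truth$model, nrow(x$genotypes$dosages),
              ncol(x$genotypes$dosages), length(x$contigs)))
  invisible(x)
}

#' Write a simulation to disk (VCF, population map, truth JSON, toy GFF3)
#'
#' @param sim A `radsweep_sim`.
#' @param dir Output directory (created if needed).
#' @param gff Also write a toy GFF3 with genes tiled every 50 kb
#'   (default FALSE).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir, gff = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "sim.vcf")
  write_vcf(sim$variants, sim$genotypes, vcf, contigs = sim$contigs,
            extra_header = sprintf("##radsweep_seed=%d",
                                   as.integer(sim$truth$seed)))
  pops <- file.path(dir, "pops.tsv")
  write_population_map(sim$pmap, pops)
  truth <- file.path(dir, "truth.json")
  tr <- sim$truth
  tr$pop_freq <- NULL                 # frequencies can be large; keep scalars
  tr$ancestral_freq <- NULL
  jsonlite::write_json(tr, truth, auto_unbox = TRUE, digits = NA)
  files <- c(vcf = vcf, pops = pops, truth = truth)
  if (gff) {
    files <- c(files, genes = write_toy_gff(sim$contigs,
                                            file.path(dir, "genes.gff3")))
  }
  invisible(files)
}

#' Write a toy GFF3 with one gene tiled every `spacing` bp per chromosome
#'
#' Synthetic annotation for gene-assignment tests: gene g<chrom>_<i> spans
#' `[(i-1) * spacing + 1, (i-1) * spacing + width]`.
#'
#' @param contigs Named integer vector of chromosome lengths.
#' @param path Output path.
#' @param spacing Gene spacing (default 50 kb).
#' @param width Gene width (default 20 kb).
#' @return `path`, invisibly.
#' @export
write_toy_gff <- function(contigs, path, spacing = 50000, width = 20000) {
  lines <- c("##gff-version 3")
  for (chrom in names(contigs)) {
    starts <- seq.int(1L, contigs[[chrom]] - width, by = spacing)
    lines <- c(lines, sprintf(
      "%s\tradsweep\tgene\t%d\t%d\t.\t+\t.\tID=gene:g_%s_%03d",
      chrom, starts, starts + width - 1L, chrom, seq_along(starts)))
  }
  writeLines(lines, path)
  invisible(path)
}
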