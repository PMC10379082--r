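toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##contig=<ID=chr2,length=100000>",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="qd">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="fs">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="dp">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\tG\t50\tPASS\tQD=25.0;FS=1.0\tGT:DP\t0/0:20\t0/1:30",
    "chr1\t200\t.\tC\tT\t50\tPASS\tQD=30.0;FS=2.0\tGT:DP\t./.:10\t1|1:25",
    "chr1\t300\t.\tG\tA,T\t50\tPASS\tQD=30.0;FS=2.0\tGT:DP\t0/1:20\t0/2:20",
    "chr2\t150\t.\tT\tC\t50\tPASS\tQD=28.0;FS=3.0\tGT:DP\t./1:15\t1/1:22"
  ), path)
  path
}

test_that("read_vcf parses genotypes, drops multiallelics, handles missing codes", {
  path <- toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  v <- read_vcf(path)
  expect_equal(v$n_dropped, 1L)                   # the A,G,T record
  expect_equal(dim(v$genotypes$dosages), c(2L, 3L))
  expect_equal(v$genotypes$samples, c("S1", "S2"))
  expect_equal(v$variants$pos, c(100L, 200L, 150L))
  # "./." and half-missing "./1" are missing; phased == unphased
  expect_equal(unname(v$genotypes$dosages["S1", ]), c(0L, NA, NA))
  expect_equal(unname(v$genotypes$dosages["S2", ]), c(1L, 2L, 2L))
  expect_equal(unname(v$genotypes$depths["S1", ]), c(20, 10, 15))
  expect_equal(v$variants$qd, c(25, 30, 28))
  expect_equal(v$contigs, c("chr1", "chr2"))      # header order
})

test_that("read_vcf fails on unreadable or empty inputs", {
  expect_error(read_vcf(tempfile()), "cannot read")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr1\t10\t.\tA\tAT\t.\t.\t.\tGT\t0/1"), path)
  expect_error(suppressMessages(read_vcf(path)), "no biallelic")
})

test_that("VCF write/read round trip preserves sites, alleles and genotypes", {
  sim <- simulate_balding_nichols(n_pops = 2, samples_per_pop = 5,
                                  n_chrom = 2, n_snps = 300, seed = 101)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$variants, sim$genotypes, path, contigs = sim$contigs)
  v <- read_vcf(path)
  expect_equal(v$variants$chrom, sim$variants$chrom)
  expect_equal(v$variants$pos, sim$variants$pos)
  expect_equal(v$variants$ref, sim$variants$ref)
  expect_equal(v$variants$alt, sim$variants$alt)
  expect_equal(unname(v$genotypes$dosages), unname(sim$genotypes$dosages))
  expect_equal(v$genotypes$samples, sim$genotypes$samples)
})

test_that("population map reading validates structure", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A1\tP1", "A2\tP1", "B1\tP2", "B2\tP2"), path)
  pm <- read_population_map(path)
  expect_equal(sort(unique(pm$population)), c("P1", "P2"))
  expect_equal(unname(table(pm$population)["P1"]), 2L)

  writeLines(c("A1\tP1", "A1\tP2"), path)
  expect_error(read_population_map(path), "duplicate")

  writeLines(character(0), path)
  expect_error(read_population_map(path))
})

test_that("samples present in only one of map and matrix are reported", {
  gm <- genotype_matrix(matrix(c(0L, 1L), 2, 3), c("A1", "A2"))
  pm <- population_map(c("A1", "A2", "GHOST"), c("P1", "P1", "P2"))
  expect_warning(idx <- population_indices(pm, gm), "absent from genotypes")
  expect_equal(idx, list(P1 = c(1L, 2L)))
})

test_that("read_gff_genes keeps gene features only and skips bad records", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=gene:g1;Name=alpha",
    "chr1\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\tgene\t900\t700\t.\t+\t.\tID=g_bad",
    "malformed line without tabs",
    "chr2\tsrc\tgene\t1\t250\t.\t-\t.\tID=g2"
  ), path)
  expect_warning(expect_warning(genes <- read_gff_genes(path),
                                "malformed"), "invalid coordinates")
  expect_equal(genes$gene_id, c("g1", "g2"))
  expect_equal(genes$start, c(100L, 1L))
  expect_equal(genes$end, c(500L, 250L))
})

test_that("read_gff_genes returns nothing for mRNA-only annotations", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines("chr1\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=t1", path)
  expect_equal(nrow(read_gff_genes(path)), 0L)
})

test_that("snp_density uses non-overlapping 100 kb windows and conserves counts", {
  vt <- variant_table(rep("chr1", 10), seq(5000, 95000, by = 10000),
                      rep("A", 10), rep("C", 10))
  d <- snp_density(vt)
  expect_equal(nrow(d), 1L)
  expect_equal(d$count, 10L)

  vt2 <- variant_table(c("chr1", "chr1"), c(50000L, 150000L),
                       c("A", "A"), c("C", "C"))
  d2 <- snp_density(vt2)
  expect_equal(d2$start0, c(0, 100000))
  expect_equal(d2$end, c(100000, 200000))
  expect_equal(d2$count, c(1L, 1L))

  empty <- variant_table(character(0), integer(0), character(0), character(0))
  expect_equal(nrow(snp_density(empty)), 0L)

  # counts sum to the per-chromosome totals
  sim <- simulate_balding_nichols(n_pops = 1, samples_per_pop = 2,
                                  n_chrom = 3, n_snps = 1500, seed = 7)
  dens <- snp_density(sim$variants)
  expect_equal(tapply(dens$count, dens$chrom, sum)[unique(sim$variants$chrom)],
               table(sim$variants$chrom)[unique(sim$variants$chrom)],
               ignore_attr = TRUE)
})
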