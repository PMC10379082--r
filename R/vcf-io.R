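#' Read a multi-sample VCF into the package data model
#'
#' Parses a VCF 4.x file (plain or gzipped) and returns the per-site metadata
#' and the sample-by-site dosage matrix. Only biallelic single-nucleotide
#' records are retained when `require_biallelic = TRUE` (the default);
#' multiallelic and indel records are dropped and counted. Missing (`./.`)
#' and half-missing (`./1`) genotype calls become `NA`; phased (`|`) and
#' unphased (`/`) separators are treated identically. Per-genotype depths are
#' taken from FORMAT/DP when present, and the GATK site annotations QD and FS
#' from INFO.
#'
#' @param path Path to a VCF file with GT in FORMAT.
#' @param require_biallelic Drop multiallelic / non-SNP records (default TRUE).
#' @return A list with components `variants` (a [variant_table()]), `genotypes`
#'   (a [genotype_matrix()]), `n_dropped` (records removed as multiallelic or
#'   non-SNP) and `contigs` (chromosome order from the header, else
#'   first-appearance order).
#' @export
read_vcf <- function(path, require_biallelic = TRUE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@gt) == 0L) stop("VCF contains no records: ", path)
  if (ncol(vcf@gt) < 2L) stop("VCF contains no samples: ", path)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)

  is_snp <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  n_dropped <- 0L
  keep <- rep(TRUE, nrow(fix))
  if (require_biallelic) {
    keep <- is_snp
    n_dropped <- sum(!keep)
    if (n_dropped > 0L) {
      message(sprintf("read_vcf: dropped %d multiallelic/non-SNP record(s)",
                      n_dropped))
    }
  }
  if (!any(keep)) stop("no biallelic SNP records retained from ", path)

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt)
  ## dosage: count of "1" alleles; any missing allele -> NA
  allele1 <- substr(gt, 1L, 1L)
  allele2 <- substr(gt, 3L, 3L)
  haploid <- !is.na(gt) & nchar(gt) == 1L       # tolerate haploid GT as 0/2
  allele2[haploid] <- allele1[haploid]
  to_num <- function(a) {
    out <- rep(NA_integer_, length(a))
    out[a == "0"] <- 0L
    out[a == "1"] <- 1L
    out
  }
  dos <- to_num(allele1) + to_num(allele2)
  dos <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt))

  depths <- NULL
  if (any(grepl("DP", vcf@gt[keep, 1L]))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    )[keep, , drop = FALSE]
    depths <- t(dp)
  }

  qd <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "QD")))[keep]
  fs <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "FS")))[keep]

  vt <- variant_table(chrom = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      qd = qd, fs = fs)
  contigs <- vcf_header_contigs(vcf@meta)
  if (!length(contigs)) contigs <- unique(vt$chrom)
  list(variants = vt,
       genotypes = genotype_matrix(t(dos), samples, depths),
       n_dropped = n_dropped,
       contigs = contigs)
}

vcf_header_contigs <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  sub('^##contig=<ID=([^,>]+).*$', "\\1", ln)
}

#' Write the data model back out as a plain-text VCF 4.2 file
#'
#' Emits QD/FS in INFO when present and GT (plus DP when depths exist) in
#' FORMAT. Output is deterministic: identical inputs give byte-identical
#' files.
#'
#' @param vt A [variant_table()].
#' @param gm The aligned [genotype_matrix()].
#' @param path Output path.
#' @param contigs Optional contig name vector for `##contig` header lines;
#'   lengths may be supplied as a named integer vector.
#' @param extra_header Optional character vector of extra `##` header lines
#'   (e.g. a simulation seed comment).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, gm, path, contigs = NULL, extra_header = NULL) {
  stopifnot(nrow(vt) == ncol(gm$dosages))
  has_dp <- !is.null(gm$depths)
  header <- c("##fileformat=VCFv4.2",
              extra_header,
              '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
              '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias (phred)">',
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (has_dp) {
    header <- c(header,
                '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  }
  if (!is.null(contigs)) {
    if (!is.null(names(contigs))) {
      header <- c(header, sprintf("##contig=<ID=%s,length=%s>",
                                  names(contigs), format(contigs, scientific = FALSE, trim = TRUE)))
    } else {
      header <- c(header, sprintf("##contig=<ID=%s>", contigs))
    }
  }
  gt_code <- c("0/0", "0/1", "1/1")
  gts <- matrix("./.", nrow = nrow(gm$dosages), ncol = ncol(gm$dosages))
  ok <- !is.na(gm$dosages)
  gts[ok] <- gt_code[gm$dosages[ok] + 1L]
  if (has_dp) {
    dp <- gm$depths
    dp_chr <- matrix(".", nrow = nrow(dp), ncol = ncol(dp))
    dp_chr[!is.na(dp)] <- format(dp[!is.na(dp)], scientific = FALSE, trim = TRUE)
    gts <- matrix(paste(gts, dp_chr, sep = ":"), nrow = nrow(gts))
  }
  info <- paste0(ifelse(is.na(vt$qd), "", sprintf("QD=%.2f", vt$qd)),
                 ifelse(is.na(vt$qd) | is.na(vt$fs), "", ";"),
                 ifelse(is.na(vt$fs), "", sprintf("FS=%.3f", vt$fs)))
  info[info == ""] <- "."
  body <- paste(vt$chrom, vt$pos, ".", vt$ref, vt$alt, ".", "PASS", info,
                if (has_dp) "GT:DP" else "GT", sep = "\t")
  gt_lines <- apply(gts, 2, paste, collapse = "\t")
  writeLines(c(header,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t"),
               paste(body, gt_lines, sep = "\t")),
             path)
  invisible(path)
}

#' Read a two-column sample-to-population map (TSV)
#'
#' @param path TSV with columns sample and population (header optional; if the
#'   first line looks like a header naming those columns it is used).
#' @return A [population_map()].
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("cannot read population map: ", path)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    grepl("sample", tolower(first)) && grepl("pop", tolower(first))
  df <- if (has_header) {
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("population map must have >= 1 row and 2 columns: ", path)
  }
  names(df)[1:2] <- c("sample", "population")
  population_map(df$sample, df$population)
}

#' Write a population map to TSV
#' @param pmap A [population_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(pmap, path) {
  utils::write.table(pmap, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a GFF3 file
#'
#' Keeps only features whose type column is `gene`, as 1-based inclusive
#' intervals. The gene identifier is taken from the `ID=` attribute (with any
#' `gene:` prefix stripped), falling back to `gene_id=` or `Name=`. Malformed
#' lines (fewer than 9 columns, non-numeric or inverted coordinates) are
#' skipped with a warning.
#'
#' @param path GFF3 file path.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("cannot read GFF3: ", path)
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  if (!length(ln)) return(empty)
  fields <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    warning(sprintf("read_gff_genes: skipped %d malformed line(s)", sum(nf < 9L)))
    fields <- fields[nf >= 9L]
  }
  if (!length(fields)) return(empty)
  m <- do.call(rbind, fields)
  gene <- m[, 3L] == "gene"
  m <- m[gene, , drop = FALSE]
  if (!nrow(m)) return(empty)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  bad <- is.na(start) | is.na(end) | start > end
  if (any(bad)) {
    warning(sprintf("read_gff_genes: rejected %d gene record(s) with invalid coordinates",
                    sum(bad)))
  }
  attr <- m[, 9L]
  id <- sub("^.*?ID=([^;]+).*$", "\\1", attr)
  no_id <- !grepl("ID=", attr)
  id[no_id] <- sub("^.*?(?:gene_id|Name)=([^;]+).*$", "\\1", attr[no_id])
  id[!grepl("(ID|gene_id|Name)=", attr)] <- NA_character_
  id <- sub("^gene:", "", id)
  out <- data.frame(chrom = m[, 1L], start = start, end = end, gene_id = id,
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window SNP density
#'
#' Counts SNPs in non-overlapping, consecutive windows of `window_bp` along
#' each chromosome (windows `[1, w]`, `[w+1, 2w]`, ...). Counts sum to the
#' total number of SNPs per chromosome.
#'
#' @param vt A [variant_table()].
#' @param window_bp Window length in bp (default 100 kb).
#' @return BED-like `data.frame`: `chrom`, `start0` (0-based), `end`, `count`.
#' @export
snp_density <- function(vt, window_bp = 100000) {
  stopifnot(window_bp > 0)
  if (nrow(vt) == 0L) {
    return(data.frame(chrom = character(0), start0 = integer(0),
                      end = integer(0), count = integer(0)))
  }
  out <- lapply(split(vt$pos, vt$chrom), function(pos) {
    win <- (pos - 1L) %/% window_bp         # 0-based window index
    tab <- table(win)
    idx <- as.integer(names(tab))
    data.frame(start0 = idx * window_bp,
               end = (idx + 1L) * window_bp,
               count = as.integer(tab))
  })
  chroms <- unique(vt$chrom)
  out <- out[chroms]
  res <- do.call(rbind, out)
  res <- data.frame(chrom = rep(chroms, vapply(out, nrow, integer(1))), res,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
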