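# Shared I/O for the pipeline's plain-text formats. All genomic intervals
# are 1-based inclusive in memory; the only 0-based half-open conversion
# happens at the junction-BED boundary.

.rpe_version <- function() {
  as.character(utils::packageVersion("rpeqtl"))
}

# md5 of a parameter list, for output provenance headers
.param_hash <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(params), collapse = ""), f)
  unname(tools::md5sum(f))
}

.provenance_header <- function(seed = NA, params = list()) {
  sprintf("# rpeqtl v%s seed=%s params=%s", .rpe_version(),
          as.character(seed), .param_hash(params))
}

# fread tolerating leading '#' comment lines
.fread_commented <- function(path, ...) {
  head <- readLines(path, n = 50L)
  k <- 0L
  while (k < length(head) && startsWith(head[k + 1L], "#")) k <- k + 1L
  data.table::fread(path, skip = k, ...)
}

#' Write a cohort's phased genotypes as VCF v4.2
#'
#' Phased GT fields ("0|1"), imputation quality in INFO key AR2.
#'
#' @param geno An \code{rpe_geno} with phased haplotypes (h1/h2), or an
#'   \code{rpe_cohort}.
#' @param path Output path (plain text .vcf).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(geno, path) {
  if (inherits(geno, "rpe_cohort")) geno <- as_geno(geno)
  stopifnot(inherits(geno, "rpe_geno"))
  if (is.null(geno$h1) || is.null(geno$h2))
    stop("phased haplotypes required to write VCF", call. = FALSE)
  vm <- geno$variant_meta
  samples <- rownames(geno$dosage)
  gt <- matrix(paste0(t(geno$h1), "|", t(geno$h2)),
               nrow = ncol(geno$dosage))  # variants x samples
  gt[is.na(t(geno$dosage))] <- ".|."
  info <- if (!is.null(vm$imputation_quality))
    sprintf("AR2=%.3f", vm$imputation_quality) else "."
  body <- paste(vm$chrom, vm$pos,
                if (!is.null(vm$variant)) vm$variant else ".",
                vm$ref, vm$alt, ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=rpeqtl_v%s", .rpe_version()),
    "##INFO=<ID=AR2,Number=1,Type=Float,Description=\"Imputation allelic r-squared\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a (phased) VCF into a genotype table
#'
#' Minimal VCF v4.2 reader for the dialect this package writes: biallelic
#' or multi-allelic sites, GT first in FORMAT, optional AR2 INFO key.
#' Unphased separators ("/") are accepted; missing genotypes become NA
#' dosage.
#'
#' @param path VCF path (uncompressed).
#' @return An \code{rpe_geno}.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("malformed VCF: no #CHROM header line", call. = FALSE)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  dt <- data.table::fread(text = lines[(hdr + 1):length(lines)],
                          header = FALSE, sep = "\t")
  if (ncol(dt) != length(cols))
    stop("malformed VCF line: expected ", length(cols), " fields", call. = FALSE)
  data.table::setnames(dt, cols)
  m <- nrow(dt)
  ar2 <- suppressWarnings(as.numeric(sub(".*AR2=([0-9.eE+-]+).*", "\\1",
                                         dt$INFO)))
  ar2[!grepl("AR2=", dt$INFO)] <- NA_real_
  vm <- data.frame(variant = ifelse(dt$ID == ".", paste0("site_", seq_len(m)),
                                    dt$ID),
                   chrom = dt$`#CHROM`, pos = as.integer(dt$POS),
                   ref = dt$REF, alt = dt$ALT,
                   imputation_quality = ar2,
                   n_alleles = 1L + lengths(strsplit(dt$ALT, ",")),
                   stringsAsFactors = FALSE)
  h1 <- h2 <- matrix(NA_integer_, length(samples), m,
                     dimnames = list(samples, vm$variant))
  for (j in seq_along(samples)) {
    gt <- sub(":.*", "", dt[[samples[j]]])
    a <- sub("[|/].*", "", gt)
    b <- sub(".*[|/]", "", gt)
    h1[j, ] <- suppressWarnings(as.integer(a))
    h2[j, ] <- suppressWarnings(as.integer(b))
  }
  dos <- h1 + h2
  geno_table(dos, vm, h1 = h1, h2 = h2)
}

#' Write / read a gene x sample count matrix as TSV
#'
#' First column "gene"; missing cells are written as the literal "NA",
#' never as zero.
#'
#' @param counts Gene x sample matrix.
#' @param path File path.
#' @param seed,params Provenance recorded in the header comment.
#' @return \code{path} invisibly (write); matrix (read).
#' @export
write_counts_tsv <- function(counts, path, seed = NA, params = list()) {
  writeLines(.provenance_header(seed, params), path)
  dt <- data.table::data.table(gene = rownames(counts))
  for (s in colnames(counts)) dt[[s]] <- counts[, s]
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  dt <- .fread_commented(path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Write / read an allelic count table as TSV
#'
#' Columns: gene, sample, variant, hap_ref_count, hap_alt_count.
#'
#' @param ase data.table of allelic counts.
#' @param path File path.
#' @param seed,params Provenance for the header comment.
#' @export
write_ase_tsv <- function(ase, path, seed = NA, params = list()) {
  writeLines(.provenance_header(seed, params), path)
  data.table::fwrite(ase, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_ase_tsv
#' @export
read_ase_tsv <- function(path) .fread_commented(path)

#' Write / read per-sample junction counts as BED-like TSV
#'
#' On disk: 6 columns (chrom, intron_start, intron_end, cluster_hint,
#' count, strand) in 0-based half-open coordinates, one file per sample.
#' In memory: a single long table in 1-based inclusive coordinates.
#'
#' @param junctions Long junction table (chrom, intron_start, intron_end,
#'   strand, sample, count, optional cluster_hint), 1-based inclusive.
#' @param dir Output directory; files are named <sample>.junc.tsv.
#' @return Written paths invisibly (write); long table (read).
#' @export
write_junctions_bed <- function(junctions, dir) {
  j <- data.table::as.data.table(junctions)
  if (is.null(j$cluster_hint)) j$cluster_hint <- "."
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in unique(j$sample)) {
    js <- j[j$sample == s, ]
    bed <- data.table::data.table(
      chrom = js$chrom, start = js$intron_start - 1L, end = js$intron_end,
      name = js$cluster_hint, score = js$count, strand = js$strand)
    p <- file.path(dir, paste0(s, ".junc.tsv"))
    data.table::fwrite(bed, p, sep = "\t", col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_junctions_bed
#' @param files Paths of per-sample junction files (sample name taken
#'   from the file name).
#' @export
read_junctions_bed <- function(files) {
  out <- lapply(files, function(p) {
    bed <- data.table::fread(p, header = FALSE,
                             col.names = c("chrom", "start", "end", "name",
                                           "score", "strand"))
    data.table::data.table(
      chrom = bed$chrom, intron_start = bed$start + 1L,
      intron_end = bed$end, strand = bed$strand,
      sample = sub("\\.junc\\.tsv$", "", basename(p)),
      count = bed$score, cluster_hint = bed$name)
  })
  data.table::rbindlist(out)
}

#' Write / read GWAS summary statistics as TSV
#'
#' Columns: variant, chrom, pos, ref, alt, beta, se, z, p, n.
#'
#' @param stats Summary-statistics table.
#' @param path File path.
#' @param seed,params Provenance for the header comment.
#' @export
write_gwas_tsv <- function(stats, path, seed = NA, params = list()) {
  writeLines(.provenance_header(seed, params), path)
  data.table::fwrite(stats, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) .fread_commented(path)
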