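#' SNP table: per-scaffold sorted heterozygous site positions
#'
#' Holds, for each scaffold of a genome, the strictly increasing 1-based
#' positions at which the diploid individual is heterozygous.  Only
#' heterozygous calls belong in a `snp_table`; homozygous-alternate
#' records are dropped at the VCF boundary because the downstream
#' statistic counts heterozygous positions against the assembly.
#'
#' @param positions named list, one sorted numeric vector of 1-based
#'   positions per scaffold.  Scaffolds absent from the list get an
#'   empty vector.
#' @param g the [genome()] the positions refer to.
#' @return An object of class `snp_table`: a named list of position
#'   vectors (one per genome scaffold, in genome order) with the genome
#'   attached as attribute `genome`.
#' @export
snp_table <- function(positions, g) {
  stopifnot(inherits(g, "genome"))
  out <- vector("list", nrow(g))
  names(out) <- g$name
  extra <- setdiff(names(positions), g$name)
  if (length(extra)) stop("positions on unknown scaffold(s): ",
                          paste(extra, collapse = ", "))
  for (nm in names(out)) {
    p <- positions[[nm]]
    if (is.null(p)) p <- numeric()
    p <- as.numeric(p)
    if (is.unsorted(p, strictly = TRUE)) {
      p <- sort(unique(p))
    }
    L <- g$length[match(nm, g$name)]
    if (length(p) && (p[1L] < 1 || p[length(p)] > L)) {
      stop("SNP position outside scaffold ", nm)
    }
    out[[nm]] <- p
  }
  structure(out, genome = g, class = "snp_table")
}

#' Number of heterozygous sites in a SNP table
#' @param snps a [snp_table()].
#' @return Integer-like scalar.
#' @export
n_snps <- function(snps) {
  stopifnot(inherits(snps, "snp_table"))
  sum(vapply(snps, length, 1L))
}

#' @export
print.snp_table <- function(x, ...) {
  g <- attr(x, "genome")
  cat(sprintf("<snp_table> %s heterozygous sites on %d scaffold(s)\n",
              format(n_snps(x), big.mark = ","), nrow(g)))
  invisible(x)
}

#' Read heterozygous SNPs from a VCF file
#'
#' Keeps only records whose genotype for the selected sample is
#' heterozygous (`0/1`, `0|1`, `1|0`, or any two distinct alleles, e.g.
#' het multi-allelic `1/2`).  Positions are stored 1-based as in the
#' VCF.  By default only single-nucleotide variants count; indel and
#' multi-nucleotide records are excluded unless `include_indels = TRUE`.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @param g the [genome()] the calls refer to; scaffolds in the VCF must
#'   be a subset of the genome's scaffolds.
#' @param sample sample name to use.  Required when the VCF carries more
#'   than one sample; defaults to the single sample present.
#' @param include_indels logical; if `TRUE`, heterozygous indel /
#'   multi-nucleotide records also count as heterozygous positions.
#' @return A [snp_table()].  Records with missing genotypes are skipped;
#'   their count is reported in a warning.
#' @export
read_het_snps <- function(path, g, sample = NULL, include_indels = FALSE) {
  stopifnot(inherits(g, "genome"))
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-record VCFs come back as a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0L) {
    return(snp_table(list(), g))
  }
  samples <- colnames(v@gt)[-1L]
  if (length(samples) == 0L) stop("VCF has no sample genotype column")
  if (is.null(sample)) {
    if (length(samples) > 1L) {
      stop("VCF contains ", length(samples),
           " samples; pass `sample =` to select one")
    }
    sample <- samples[1L]
  } else if (!sample %in% samples) {
    stop("sample not found in VCF: ", sample)
  }
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  # VCFs must be position-sorted within each scaffold
  for (nm in unique(chrom)) {
    if (is.unsorted(pos[chrom == nm])) {
      stop("VCF is not position-sorted on scaffold ", nm)
    }
  }
  gt_raw <- v@gt[, sample]
  fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  gt_idx <- vapply(fmt, function(f) match("GT", f), 1L)
  fields <- strsplit(gt_raw, ":", fixed = TRUE)
  gt <- rep(NA_character_, length(gt_raw))
  ok <- !is.na(gt_idx) & lengths(fields) >= ifelse(is.na(gt_idx), 1L, gt_idx)
  gt[ok] <- mapply(function(f, i) f[i], fields[ok], gt_idx[ok])
  missing_gt <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  if (any(missing_gt)) {
    warning(sum(missing_gt), " record(s) without a usable GT were skipped")
  }
  alleles <- strsplit(gt, "[/|]")
  het <- !missing_gt &
    lengths(alleles) == 2L &
    vapply(alleles, function(a) a[1L] != a[2L] && !any(a == "."), TRUE)
  if (!include_indels) {
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    snv <- nchar(ref) == 1L &
      vapply(strsplit(alt, ",", fixed = TRUE),
             function(a) all(nchar(a) == 1L & a != "*"), TRUE)
    het <- het & snv
  }
  chrom <- chrom[het]
  pos <- pos[het]
  bad <- setdiff(unique(chrom), g$name)
  if (length(bad)) stop("VCF scaffold(s) not in genome: ",
                        paste(bad, collapse = ", "))
  snp_table(split(pos, factor(chrom, levels = g$name)), g)
}

#' Write a SNP table as a minimal single-sample VCF
#'
#' Emits the dialect [read_het_snps()] reads back: one `0/1` SNV record
#' per heterozygous position (placeholder `A`/`T` alleles, since only
#' positions carry information here).
#'
#' @param snps a [snp_table()].
#' @param path output path (`.vcf`, plain text).
#' @param sample sample name written in the header.
#' @return `path`, invisibly.
#' @export
write_het_vcf <- function(snps, path, sample = "SYNTH") {
  stopifnot(inherits(snps, "snp_table"))
  g <- attr(snps, "genome")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%s>", g$name,
                       format(g$length, scientific = FALSE, trim = TRUE)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample, sep = "\t")), con)
  for (nm in g$name) {
    p <- snps[[nm]]
    if (!length(p)) next
    writeLines(paste(nm, format(p, scientific = FALSE, trim = TRUE), ".",
                     "A", "T", ".", "PASS", ".", "GT", "0/1", sep = "\t"),
               con)
  }
  invisible(path)
}

# All het sites of one scaffold that fall inside half-open [start, end):
# a 1-based site p lies inside iff start <= p - 1 < end.
snps_in_interval <- function(p, start, end) {
  p[p > start & p <= end]
}
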