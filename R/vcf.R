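#' Pool allele frequencies from a VCF with allelic depths
#'
#' Derives a pool frequency matrix from the per-sample `AD` (allelic
#' depth) FORMAT field of a VCF: for each biallelic site and sample the
#' frequency is `alt / (ref + alt)` and the recorded depth is
#' `ref + alt`; zero total depth yields a missing cell. Multiallelic
#' records are skipped with a message.
#'
#' @param vcf_path path to an (uncompressed or gzipped) VCF file.
#' @return A [pool_freq()] object with SNP ids `CHROM_POS` and the VCF
#'   sample names as family ids.
#' @export
frequencies_from_vcf <- function(vcf_path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the 'vcfR' package is required to read VCF files")
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (nrow(vcf@gt) == 0L) stop("VCF contains no records: ", vcf_path)
  fmt <- vcf@gt[, 1L]
  if (!all(grepl("AD", fmt)))
    stop("VCF FORMAT lacks the AD (allelic depth) field")
  bi <- vcfR::is.biallelic(vcf)
  n_multi <- sum(!bi)
  if (n_multi > 0L) {
    message("skipping ", n_multi, " multiallelic record(s)")
    vcf <- vcf[bi, ]
  }
  if (nrow(vcf@fix) == 0L) stop("no biallelic records left in ", vcf_path)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  split2 <- function(i) as.numeric(vapply(strsplit(ad, ",", fixed = TRUE),
                                          function(x) x[i], character(1L)))
  ref <- matrix(split2(1L), nrow(ad), ncol(ad))
  alt <- matrix(split2(2L), nrow(ad), ncol(ad))
  ref[is.na(ref)] <- 0
  alt[is.na(alt)] <- 0
  depth <- ref + alt
  freq <- ifelse(depth > 0, alt / depth, NA_real_)
  snp_ids <- paste(vcf@fix[, "CHROM"], vcf@fix[, "POS"], sep = "_")
  pool_freq(freq, depths = depth, snp_ids = snp_ids,
            family_ids = colnames(ad))
}
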