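#' Read genotypes from a VCF file
#'
#' Loads biallelic SNP records from a VCF (v4.x) via \pkg{vcfR} and converts
#' GT calls to alternate-allele dosages: \code{0/0 -> 0}, \code{0/1} or
#' \code{1/0 -> 1}, \code{1/1 -> 2}, \code{./. -> NA}. Phased separators
#' (\code{|}) are accepted.
#'
#' @param vcf_path path to an uncompressed or bgzipped VCF.
#' @param population_map named character vector mapping \code{sample_id} to
#'   population label; every VCF sample must be present.
#' @param multiallelic \code{"error"} (default) or \code{"skip"}: what to do
#'   with records whose ALT lists more than one allele.
#' @return A \code{genotype_table}.
#' @export
read_vcf <- function(vcf_path, population_map,
                     multiallelic = c("error", "skip")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2 ||
      !all(vapply(strsplit(vcf@gt[, "FORMAT"], ":"),
                  function(f) "GT" %in% f, logical(1))))
    stop("VCF has no GT field")

  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multiallelic record(s) at: ",
           paste(utils::head(fix[multi, "ID"], 5), collapse = ", "))
    vcf <- vcf[!multi, ]
    fix <- vcf@fix
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  sample_ids <- colnames(gt)
  missing_map <- setdiff(sample_ids, names(population_map))
  if (length(missing_map))
    stop("samples absent from population_map: ",
         paste(missing_map, collapse = ", "))

  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  dosages <- t(apply(gt, 1, code))   # loci x samples -> transpose below
  if (nrow(gt) == 1L) dosages <- matrix(dosages, nrow = 1L)
  dosages <- t(dosages)

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]

  genotype_table(
    dosages,
    data.frame(sample_id = sample_ids,
               population = unname(population_map[sample_ids]),
               stringsAsFactors = FALSE),
    data.frame(locus_id = ids, chromosome = fix[, "CHROM"],
               position = as.integer(fix[, "POS"]),
               allele_ref = fix[, "REF"], allele_alt = fix[, "ALT"],
               stringsAsFactors = FALSE)
  )
}

#' Write a genotype table as VCF v4.2
#'
#' Emits a minimal plain-text VCF (GT-only FORMAT). Population labels are
#' not representable in VCF; keep the sample-to-population map alongside.
#'
#' @param table a \code{genotype_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(table, path) {
  loci <- table$loci
  gt_codes <- c("0/0", "0/1", "1/1")
  d <- table$dosages
  body <- vapply(seq_len(ncol(d)), function(l) {
    g <- d[, l]
    gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    paste(c(loci$chromosome[l], loci$position[l], loci$locus_id[l],
            loci$allele_ref[l],
            ifelse(loci$allele_alt[l] %in% c("N", ""), ".",
                   loci$allele_alt[l]),
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples$sample_id), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
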