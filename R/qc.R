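#' Quality-control configuration
#'
#' Thresholds for the genotype QC pass. Defaults mirror standard SNP-chip
#' practice: SNP and sample call rates of at least 99%, a pooled minor
#' allele frequency floor of 0.05, and pruning of near-duplicate samples by
#' identity-by-state above 0.95.
#'
#' @param min_snp_callrate minimum per-locus call rate, in \code{[0,1]}.
#' @param min_maf minimum pooled minor-allele frequency, in \code{[0,1]}.
#' @param min_sample_callrate minimum per-sample call rate, in \code{[0,1]}.
#' @param max_ibs IBS threshold above which one member of a pair is removed.
#' @param filter_snp_callrate,filter_maf,filter_sample_callrate,filter_ibs
#'   enable/disable flags per filter.
#' @return A list of class \code{qc_config}.
#' @export
qc_config <- function(min_snp_callrate = 0.99, min_maf = 0.05,
                      min_sample_callrate = 0.99, max_ibs = 0.95,
                      filter_snp_callrate = TRUE, filter_maf = TRUE,
                      filter_sample_callrate = TRUE, filter_ibs = TRUE) {
  fr <- c(min_snp_callrate, min_maf, min_sample_callrate, max_ibs)
  if (any(fr < 0 | fr > 1)) stop("all qc fractions must lie in [0,1]")
  structure(list(
    min_snp_callrate = min_snp_callrate, min_maf = min_maf,
    min_sample_callrate = min_sample_callrate, max_ibs = max_ibs,
    filter_snp_callrate = filter_snp_callrate, filter_maf = filter_maf,
    filter_sample_callrate = filter_sample_callrate, filter_ibs = filter_ibs
  ), class = "qc_config")
}

#' Pairwise identity-by-state matrix
#'
#' IBS between two individuals is the mean, over loci typed in both, of the
#' proportion of shared alleles: \code{(2 - |d_i - d_j|) / 2} under dosage
#' coding. The matrix is symmetric with unit diagonal and is invariant to
#' which allele is labelled alternate. A pair with no shared typed locus
#' gets \code{NA} and a warning.
#'
#' @param table a \code{genotype_table} with at least 2 samples.
#' @return An n x n numeric matrix in \code{[0,1]}.
#' @export
ibs_matrix <- function(table) {
  d <- table$dosages
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 samples for IBS")
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- !is.na(d[i, ]) & !is.na(d[j, ])
      if (!any(shared)) {
        m[i, j] <- m[j, i] <- NA_real_
        next
      }
      m[i, j] <- m[j, i] <- mean((2 - abs(d[i, shared] - d[j, shared])) / 2)
    }
  }
  if (anyNA(m)) warning("sample pair(s) with no shared typed loci: IBS undefined")
  dimnames(m) <- list(table$samples$sample_id, table$samples$sample_id)
  m
}

#' Apply genotype quality control
#'
#' Single-pass filtering in a fixed order: (1) loci below the SNP call-rate
#' floor, (2) loci below the pooled-MAF floor (missing genotypes excluded
#' from the frequency), (3) samples below the sample call-rate floor, (4)
#' IBS pruning — for each pair exceeding \code{max_ibs} the member with the
#' lower call rate is removed (tie: the later sample index).
#'
#' @param table a \code{genotype_table}.
#' @param config a \code{\link{qc_config}}.
#' @return A list with the filtered \code{table} and a \code{report} of
#'   class \code{qc_report} recording counts and removed ids per stage.
#' @export
apply_qc <- function(table, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  d0 <- dim(table$dosages)
  rm_snp_cr <- rm_snp_maf <- character(0)
  rm_smp_cr <- rm_smp_ibs <- character(0)

  if (config$filter_snp_callrate) {
    cr <- colMeans(!is.na(table$dosages))
    drop <- cr < config$min_snp_callrate
    rm_snp_cr <- table$loci$locus_id[drop]
    if (any(drop)) table <- drop_loci(table, drop)
  }
  if (config$filter_maf && ncol(table$dosages) > 0) {
    p <- colSums(table$dosages, na.rm = TRUE) /
      (2 * colSums(!is.na(table$dosages)))
    maf <- pmin(p, 1 - p)
    drop <- is.na(maf) | maf < config$min_maf
    rm_snp_maf <- table$loci$locus_id[drop]
    if (any(drop)) table <- drop_loci(table, drop)
  }
  if (ncol(table$dosages) == 0)
    stop("all SNPs removed by QC; review thresholds")

  if (config$filter_sample_callrate) {
    cr <- rowMeans(!is.na(table$dosages))
    drop <- cr < config$min_sample_callrate
    rm_smp_cr <- table$samples$sample_id[drop]
    if (any(drop)) table <- drop_samples(table, drop)
  }
  if (nrow(table$dosages) == 0)
    stop("all samples removed by QC; review thresholds")

  if (config$filter_ibs && nrow(table$dosages) >= 2) {
    ibs <- suppressWarnings(ibs_matrix(table))
    cr <- rowMeans(!is.na(table$dosages))
    removed <- logical(nrow(ibs))
    pairs <- which(upper.tri(ibs) & !is.na(ibs) & ibs > config$max_ibs,
                   arr.ind = TRUE)
    if (nrow(pairs)) {
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        if (removed[i] || removed[j]) next
        # drop lower call rate; tie -> later sample index
        removed[if (cr[i] < cr[j]) i else j] <- TRUE
      }
    }
    rm_smp_ibs <- table$samples$sample_id[removed]
    if (any(removed)) table <- drop_samples(table, removed)
  }
  if (nrow(table$dosages) == 0)
    stop("all samples removed by QC; review thresholds")

  report <- structure(list(
    input_dim = d0,
    output_dim = dim(table$dosages),
    filter_order = c("snp_callrate", "maf", "sample_callrate", "ibs"),
    snps_removed_callrate = length(rm_snp_cr),
    snps_removed_maf = length(rm_snp_maf),
    samples_removed_callrate = length(rm_smp_cr),
    samples_removed_ibs = length(rm_smp_ibs),
    removed_snp_ids_callrate = rm_snp_cr,
    removed_snp_ids_maf = rm_snp_maf,
    removed_sample_ids_callrate = rm_smp_cr,
    removed_sample_ids_ibs = rm_smp_ibs,
    config = unclass(config)
  ), class = "qc_report")
  list(table = table, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    paste0("qc_report: %d x %d -> %d x %d\n",
           "  SNPs removed: %d (call rate), %d (MAF)\n",
           "  samples removed: %d (call rate), %d (IBS)\n"),
    x$input_dim[1], x$input_dim[2], x$output_dim[1], x$output_dim[2],
    x$snps_removed_callrate, x$snps_removed_maf,
    x$samples_removed_callrate, x$samples_removed_ibs))
  invisible(x)
}

drop_loci <- function(table, drop) {
  genotype_table(table$dosages[, !drop, drop = FALSE], table$samples,
                 table$loci[!drop, , drop = FALSE])
}

drop_samples <- function(table, drop) {
  genotype_table(table$dosages[!drop, , drop = FALSE],
                 table$samples[!drop, , drop = FALSE], table$loci)
}
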