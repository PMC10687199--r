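#' Construct a genotype table
#'
#' The central container of the package: a samples x loci matrix of
#' alternate-allele dosages (0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, \code{NA} = missing) together with sample and
#' locus metadata. Every statistic in the package consumes this object.
#'
#' @param dosages integer matrix, samples in rows, loci in columns; entries
#'   in \code{{0, 1, 2, NA}}.
#' @param samples data.frame with columns \code{sample_id} and
#'   \code{population}; one row per dosage row.
#' @param loci data.frame with columns \code{locus_id}, \code{chromosome},
#'   \code{position}, \code{allele_ref}, \code{allele_alt}; one row per
#'   dosage column.
#'
#' @return An object of class \code{genotype_table}.
#' @export
genotype_table <- function(dosages, samples, loci) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  obj <- structure(
    list(dosages = dosages, samples = samples, loci = loci),
    class = "genotype_table"
  )
  validate_genotype_table(obj)
  rownames(obj$dosages) <- obj$samples$sample_id
  colnames(obj$dosages) <- obj$loci$locus_id
  obj
}

#' Validate a genotype table
#'
#' Checks the structural invariants: dosage entries in \code{{0,1,2,NA}},
#' dimensions matching metadata, unique sample and locus ids, and non-empty
#' population labels.
#'
#' @param x a \code{genotype_table}.
#' @return \code{x}, invisibly; stops on violation.
#' @export
validate_genotype_table <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  d <- x$dosages
  if (!all(d %in% c(0L, 1L, 2L) | is.na(d)))
    stop("dosage entries must be 0, 1, 2 or NA")
  req_s <- c("sample_id", "population")
  if (!all(req_s %in% names(x$samples)))
    stop("samples metadata needs columns: ", paste(req_s, collapse = ", "))
  req_l <- c("locus_id", "chromosome", "position", "allele_ref", "allele_alt")
  if (!all(req_l %in% names(x$loci)))
    stop("loci metadata needs columns: ", paste(req_l, collapse = ", "))
  if (nrow(x$samples) != nrow(d))
    stop("samples metadata does not match dosage rows")
  if (nrow(x$loci) != ncol(d))
    stop("loci metadata does not match dosage columns")
  if (anyDuplicated(x$samples$sample_id))
    stop("sample_ids must be unique")
  if (anyDuplicated(x$loci$locus_id))
    stop("locus_ids must be unique")
  pops <- x$samples$population
  if (any(is.na(pops)) || any(!nzchar(pops)))
    stop("every sample needs a non-empty population label")
  invisible(x)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "genotype_table: %d samples x %d loci, %d population(s) [%s], %.2f%% missing\n",
    nrow(x$dosages), ncol(x$dosages),
    length(unique(x$samples$population)),
    paste(sort(unique(x$samples$population)), collapse = ", "),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosages)

#' Subset a genotype table
#'
#' @param x a \code{genotype_table}.
#' @param i sample index (logical, integer or sample_id character).
#' @param j locus index (logical, integer or locus_id character).
#' @param ... unused.
#' @return A \code{genotype_table} restricted to the selected samples/loci.
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$loci$locus_id)
  if (anyNA(i) || anyNA(j)) stop("unknown sample or locus id in subset")
  genotype_table(
    x$dosages[i, j, drop = FALSE],
    x$samples[i, , drop = FALSE],
    x$loci[j, , drop = FALSE]
  )
}

#' Combine two genotype tables locus-wise
#'
#' Binds the loci of two tables over the same samples (ids and order must
#' match). Used e.g. to append loci simulated under a different
#' differentiation level to a neutral background.
#'
#' @param x,y \code{genotype_table}s with identical samples.
#' @return A \code{genotype_table} with the loci of both inputs.
#' @export
bind_loci <- function(x, y) {
  if (!identical(x$samples$sample_id, y$samples$sample_id))
    stop("tables must share identical samples to bind loci")
  genotype_table(cbind(x$dosages, y$dosages), x$samples, rbind(x$loci, y$loci))
}

# population factor in stable (first-appearance) order
pop_factor <- function(table) {
  factor(table$samples$population, levels = unique(table$samples$population))
}
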