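#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses whitespace-delimited PLINK text files into a
#' \code{\link{genotype_table}}. The family ID (first .ped column) is taken
#' as the population label. The alternate allele at each locus is the pooled
#' minor allele computed over all samples (tie broken towards the
#' lexicographically later allele), so dosages count copies of the minor
#' allele; this orientation is recorded in the locus metadata. A genotype
#' pair containing the missing code \code{0} becomes \code{NA}.
#'
#' @param ped_path path to the .ped file (>= 7 columns: FID, IID, PAT, MAT,
#'   SEX, PHENO, then two allele columns per locus, alleles in
#'   \code{A,C,G,T,0}).
#' @param map_path path to the .map file (4 columns: chromosome, locus id,
#'   genetic distance, bp position).
#' @return A \code{genotype_table}.
#' @export
read_plink <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  if (any(lengths(map_fields) != 4L))
    stop(".map must have 4 columns; offending line ",
         which(lengths(map_fields) != 4L)[1])
  map <- do.call(rbind, map_fields)
  n_loci <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6L + 2L * n_loci
  bad <- which(lengths(ped_fields) != expected)
  if (length(bad))
    stop(sprintf(".ped line %d has %d fields, expected %d (6 + 2 x %d loci)",
                 bad[1], lengths(ped_fields)[bad[1]], expected, n_loci))
  ped <- do.call(rbind, ped_fields)
  n <- nrow(ped)

  a1 <- ped[, 6L + 2L * seq_len(n_loci) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(n_loci), drop = FALSE]
  ok <- c("A", "C", "G", "T", "0")
  if (!all(a1 %in% ok) || !all(a2 %in% ok))
    stop("alleles must be one of A,C,G,T or 0 (missing)")

  dosages <- matrix(NA_integer_, n, n_loci)
  allele_ref <- allele_alt <- character(n_loci)
  for (l in seq_len(n_loci)) {
    pair <- cbind(a1[, l], a2[, l])
    miss <- pair[, 1] == "0" | pair[, 2] == "0"
    obs <- pair[!miss, , drop = FALSE]
    alleles <- sort(unique(as.vector(obs)))
    if (length(alleles) > 2L)
      stop(sprintf("locus %s has >2 alleles: %s", map[l, 2],
                   paste(alleles, collapse = "/")))
    if (length(alleles) == 0L) {            # fully missing locus
      allele_ref[l] <- "N"; allele_alt[l] <- "N"
      next
    }
    if (length(alleles) == 1L) {
      allele_ref[l] <- alleles; allele_alt[l] <- "N"
      dosages[!miss, l] <- 0L
      next
    }
    cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    # minor allele is alt; tie -> lexicographically later allele
    alt <- if (cnt[1] < cnt[2]) alleles[1] else alleles[2]
    ref <- setdiff(alleles, alt)
    allele_ref[l] <- ref; allele_alt[l] <- alt
    dosages[!miss, l] <- (obs[, 1] == alt) + (obs[, 2] == alt)
  }

  genotype_table(
    dosages,
    data.frame(sample_id = ped[, 2], population = ped[, 1],
               stringsAsFactors = FALSE),
    data.frame(locus_id = map[, 2], chromosome = map[, 1],
               position = as.integer(map[, 4]),
               allele_ref = allele_ref, allele_alt = allele_alt,
               stringsAsFactors = FALSE)
  )
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' @param table a \code{genotype_table}.
#' @param prefix output path prefix; writes \code{<prefix>.ped} and
#'   \code{<prefix>.map}.
#' @return The two paths, invisibly.
#' @export
write_plink <- function(table, prefix) {
  loci <- table$loci
  map <- paste(loci$chromosome, loci$locus_id, 0L, loci$position)
  writeLines(map, paste0(prefix, ".map"))

  d <- table$dosages
  n <- nrow(d); L <- ncol(d)
  geno <- matrix("0", n, 2L * L)
  for (l in seq_len(L)) {
    ref <- loci$allele_ref[l]; alt <- loci$allele_alt[l]
    g <- d[, l]
    c1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, alt, ref))
    c2 <- ifelse(is.na(g), "0", ifelse(g == 2L, alt, ref))
    geno[, 2L * l - 1L] <- c1
    geno[, 2L * l] <- c2
  }
  lines <- vapply(seq_len(n), function(i) {
    paste(c(table$samples$population[i], table$samples$sample_id[i],
            "0", "0", "0", "-9", geno[i, ]), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}
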