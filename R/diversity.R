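#' Per-locus allele frequencies
#'
#' Alternate-allele frequency per locus, pooled over all samples or within
#' each population: p_alt = sum(dosage) / (2 * n_typed), missing genotypes
#' excluded. A locus with no typed sample in a group gets \code{NA}
#' frequencies and a warning.
#'
#' @param table a \code{genotype_table}.
#' @param by_population if \code{TRUE}, one row per locus per population;
#'   otherwise one pooled row per locus (population \code{"pooled"}).
#' @return data.frame with columns \code{locus_id}, \code{population},
#'   \code{n_typed}, \code{p_ref}, \code{p_alt}.
#' @export
allele_frequencies <- function(table, by_population = FALSE) {
  groups <- freq_groups(table, by_population)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    d <- table$dosages[groups[[g]], , drop = FALSE]
    n_typed <- colSums(!is.na(d))
    p_alt <- ifelse(n_typed > 0, colSums(d, na.rm = TRUE) / (2 * n_typed), NA_real_)
    data.frame(locus_id = table$loci$locus_id, population = g,
               n_typed = n_typed, p_ref = 1 - p_alt, p_alt = p_alt,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (anyNA(out$p_alt))
    warning("locus/group combination(s) with zero typed samples: frequency undefined")
  out
}

#' Observed and expected heterozygosity per locus
#'
#' H_O is the observed heterozygote proportion among typed genotypes; H_E is
#' Nei's gene diversity 2p(1-p) at a biallelic locus, optionally with the
#' small-sample factor 2n/(2n-1). The per-locus fixation index
#' F_IS = 1 - H_O/H_E is included (NA where H_E = 0).
#'
#' @inheritParams allele_frequencies
#' @param unbiased apply the 2n/(2n-1) correction to H_E (default off).
#' @return data.frame with columns \code{locus_id}, \code{population},
#'   \code{n_typed}, \code{p_alt}, \code{H_O}, \code{H_E}, \code{F_IS}.
#' @export
heterozygosity <- function(table, by_population = FALSE, unbiased = FALSE) {
  groups <- freq_groups(table, by_population)
  do.call(rbind, lapply(names(groups), function(g) {
    d <- table$dosages[groups[[g]], , drop = FALSE]
    n_typed <- colSums(!is.na(d))
    p <- ifelse(n_typed > 0, colSums(d, na.rm = TRUE) / (2 * n_typed), NA_real_)
    H_O <- ifelse(n_typed > 0, colSums(d == 1L, na.rm = TRUE) / n_typed, NA_real_)
    H_E <- 2 * p * (1 - p)
    if (unbiased) H_E <- H_E * ifelse(n_typed > 0, 2 * n_typed / (2 * n_typed - 1), NA_real_)
    data.frame(locus_id = table$loci$locus_id, population = g,
               n_typed = n_typed, p_alt = p, H_O = H_O, H_E = H_E,
               F_IS = ifelse(!is.na(H_E) & H_E > 0, 1 - H_O / H_E, NA_real_),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Fixation index F_IS
#'
#' Per-locus F_IS = 1 - H_O/H_E and a multilocus overall value. The overall
#' estimator is the ratio of sums 1 - sum(H_O) / sum(H_E) by default
#' (stable when low-diversity loci are present); \code{"mean-of-ratios"}
#' averages the per-locus values instead. Negative values indicate
#' heterozygote excess. With \code{by_population = TRUE} the overall table
#' has one row per population plus a \code{"within_overall"} row combining
#' all within-population sums — the multilocus, multi-population F_IS.
#'
#' @inheritParams heterozygosity
#' @param method \code{"ratio-of-sums"} (default) or \code{"mean-of-ratios"}.
#' @return list with \code{per_locus} (as \code{\link{heterozygosity}}) and
#'   \code{overall} (data.frame of population and \code{F_IS}).
#' @export
fis <- function(table, by_population = FALSE, unbiased = FALSE,
                method = c("ratio-of-sums", "mean-of-ratios")) {
  method <- match.arg(method)
  het <- heterozygosity(table, by_population = by_population, unbiased = unbiased)
  comb <- function(rows) {
    keep <- !is.na(rows$H_E) & rows$H_E > 0
    if (!any(keep)) return(NA_real_)
    if (method == "ratio-of-sums")
      1 - sum(rows$H_O[keep]) / sum(rows$H_E[keep])
    else mean(1 - rows$H_O[keep] / rows$H_E[keep])
  }
  overall <- do.call(rbind, lapply(split(het, het$population), function(rows)
    data.frame(population = rows$population[1], F_IS = comb(rows),
               stringsAsFactors = FALSE)))
  rownames(overall) <- NULL
  if (by_population)
    overall <- rbind(overall,
                     data.frame(population = "within_overall",
                                F_IS = comb(het), stringsAsFactors = FALSE))
  list(per_locus = het, overall = overall)
}

#' Hill-number diversity profile
#'
#' Effective number of alleles of order q at each locus,
#' qD = (sum_i p_i^q)^(1/(1-q)) over alleles with p_i > 0; q = 1 is the
#' limit exp(-sum p_i log p_i) (exponentiated Shannon information) and
#' q = 0 counts the alleles present (allelic richness). For a biallelic
#' locus 1 <= qD <= 2 and qD is non-increasing in q. Profile means are
#' arithmetic means of per-locus qD.
#'
#' @inheritParams allele_frequencies
#' @param q numeric vector of orders (non-negative), default \code{c(0,1,2)}.
#' @return list with \code{per_locus} (long data.frame: locus, population,
#'   q, qD) and \code{summary} (population, q, mean_qD over loci).
#' @export
hill_profile <- function(table, q = c(0, 1, 2), by_population = FALSE) {
  if (length(q) == 0) stop("q must contain at least one order")
  if (any(q < 0)) stop("Hill orders must be non-negative")
  fr <- allele_frequencies(table, by_population = by_population)
  per <- do.call(rbind, lapply(q, function(qq) {
    qD <- vapply(fr$p_alt, function(p) hill_number(c(p, 1 - p), qq), numeric(1))
    data.frame(locus_id = fr$locus_id, population = fr$population,
               q = qq, qD = qD, stringsAsFactors = FALSE)
  }))
  summ <- stats::aggregate(qD ~ population + q, data = per,
                           FUN = mean, na.action = stats::na.omit)
  names(summ)[names(summ) == "qD"] <- "mean_qD"
  summ <- summ[order(summ$population, summ$q), ]
  rownames(summ) <- NULL
  list(per_locus = per, summary = summ)
}

#' Hill number of a frequency vector
#'
#' @param p allele frequency vector (sums to 1).
#' @param q order, q >= 0.
#' @return qD; \code{NA} if frequencies are missing.
#' @export
hill_number <- function(p, q) {
  if (anyNA(p)) return(NA_real_)
  p <- p[p > 0]
  if (q == 0) return(length(p))
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

freq_groups <- function(table, by_population) {
  if (by_population) {
    f <- pop_factor(table)
    stats::setNames(lapply(levels(f), function(l) which(f == l)), levels(f))
  } else {
    list(pooled = seq_len(nrow(table$dosages)))
  }
}
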