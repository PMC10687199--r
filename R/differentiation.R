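#' Weir-Cockerham variance components at one locus
#'
#' Moment estimator of F_ST from genotype counts in r populations. With
#' per-population sizes n_i, alternate-allele frequencies p_i and observed
#' heterozygote proportions h_i, the among-population (a), among-individual
#' (b) and within-individual (c) variance components are computed from
#' nbar, n_c, pbar, the weighted frequency variance s2 and hbar, and
#' theta = a / (a + b + c). \code{theta_nocorr} is the analogue with the
#' finite-sample correction terms dropped (used by the outlier scan).
#'
#' @param counts K x 3 matrix of genotype counts per population; columns are
#'   (hom ref, het, hom alt) under dosage coding.
#' @return list with \code{a}, \code{b}, \code{c}, \code{theta},
#'   \code{theta_nocorr}; theta is \code{NA} (flagged monomorphic) when all
#'   components vanish.
#' @export
wc_components <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 3) stop("counts must be K x 3 (hom ref, het, hom alt)")
  ni <- rowSums(counts)
  keep <- ni > 0
  counts <- counts[keep, , drop = FALSE]
  ni <- ni[keep]
  r <- nrow(counts)
  if (r < 2) stop("need >= 2 populations with typed individuals")

  pi <- (2 * counts[, 3] + counts[, 2]) / (2 * ni)
  hi <- counts[, 2] / ni
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  a_nc <- (nbar / nc) * s2
  b_nc <- pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar)

  tot <- a + b + cc
  tot_nc <- a_nc + b_nc + cc
  list(
    a = a, b = b, c = cc,
    theta = if (abs(tot) < 1e-300) NA_real_ else a / tot,
    theta_nocorr = if (abs(tot_nc) < 1e-300) NA_real_ else a_nc / tot_nc,
    abc = tot, abc_nocorr = tot_nc
  )
}

# per-locus genotype counts for the populations in `pops` (indices into
# levels of the population factor); returns list of K x 3 matrices
locus_counts <- function(table, pop_idx = NULL) {
  f <- pop_factor(table)
  lev <- levels(f)
  if (is.null(pop_idx)) pop_idx <- seq_along(lev)
  d <- table$dosages
  lapply(seq_len(ncol(d)), function(l) {
    t(vapply(pop_idx, function(k) {
      g <- d[f == lev[k], l]
      c(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
        sum(g == 2L, na.rm = TRUE))
    }, numeric(3)))
  })
}

#' Per-locus Weir-Cockerham components across all populations
#'
#' @param table a \code{genotype_table} with >= 2 populations.
#' @return data.frame with per-locus \code{a}, \code{b}, \code{c},
#'   \code{theta}, \code{theta_nocorr}.
#' @export
wc_components_table <- function(table) {
  cl <- locus_counts(table)
  rows <- lapply(cl, function(cnt) {
    w <- wc_components(cnt)
    data.frame(a = w$a, b = w$b, c = w$c, theta = w$theta,
               theta_nocorr = w$theta_nocorr, abc = w$abc,
               abc_nocorr = w$abc_nocorr)
  })
  out <- do.call(rbind, rows)
  out <- cbind(locus_id = table$loci$locus_id, out)
  rownames(out) <- NULL
  out
}

#' Pairwise Weir-Cockerham F_ST matrix
#'
#' For each population pair, the multilocus estimate is the ratio of sums
#' over loci, sum(a_l) / sum(a_l + b_l + c_l).
#'
#' @param table a \code{genotype_table} with >= 2 populations.
#' @param method \code{"ratio-of-sums"} (default) or \code{"mean-of-ratios"}.
#' @return symmetric K x K matrix with zero diagonal.
#' @export
pairwise_fst <- function(table, method = c("ratio-of-sums", "mean-of-ratios")) {
  method <- match.arg(method)
  lev <- levels(pop_factor(table))
  K <- length(lev)
  if (K < 2) stop("need >= 2 populations")
  if (any(table(pop_factor(table)) == 0)) stop("population with zero samples")
  m <- matrix(0, K, K, dimnames = list(lev, lev))
  for (j in seq_len(K - 1)) {
    for (k in seq(j + 1, K)) {
      cl <- locus_counts(table, c(j, k))
      comps <- lapply(cl, wc_components)
      a <- vapply(comps, `[[`, numeric(1), "a")
      tot <- vapply(comps, `[[`, numeric(1), "abc")
      est <- if (method == "ratio-of-sums") {
        sum(a) / sum(tot)
      } else {
        th <- a / tot
        mean(th[is.finite(th)])
      }
      m[j, k] <- m[k, j] <- est
    }
  }
  m
}

#' Pairwise Nei G_ST matrix
#'
#' Per locus, H_S is the unweighted mean of the two within-population gene
#' diversities 2 p_k (1 - p_k) and H_T = 2 pbar (1 - pbar) with pbar the
#' unweighted mean frequency; the multilocus estimate is
#' sum(H_T - H_S) / sum(H_T) over loci.
#'
#' @inheritParams pairwise_fst
#' @return symmetric K x K matrix with zero diagonal; attribute
#'   \code{"components"} holds per-pair per-locus H_S and H_T.
#' @export
nei_gst_pairwise <- function(table) {
  fr <- allele_frequencies(table, by_population = TRUE)
  lev <- levels(pop_factor(table))
  K <- length(lev)
  if (K < 2) stop("need >= 2 populations")
  pm <- matrix(fr$p_alt[order(match(fr$population, lev))],
               ncol = K, dimnames = list(NULL, lev))
  m <- matrix(0, K, K, dimnames = list(lev, lev))
  comp <- list()
  for (j in seq_len(K - 1)) {
    for (k in seq(j + 1, K)) {
      pj <- pm[, j]; pk <- pm[, k]
      ok <- !is.na(pj) & !is.na(pk)
      hs <- (2 * pj[ok] * (1 - pj[ok]) + 2 * pk[ok] * (1 - pk[ok])) / 2
      pb <- (pj[ok] + pk[ok]) / 2
      ht <- 2 * pb * (1 - pb)
      if (sum(ht) == 0) stop("total gene diversity is zero for pair ",
                             lev[j], "-", lev[k])
      m[j, k] <- m[k, j] <- sum(ht - hs) / sum(ht)
      comp[[paste(lev[j], lev[k], sep = "-")]] <-
        data.frame(locus_id = table$loci$locus_id[ok], H_S = hs, H_T = ht)
    }
  }
  attr(m, "components") <- comp
  m
}

#' Pairwise Euclidean distance between population frequency vectors
#'
#' d(j,k) = sqrt(sum_l (p_j,l - p_k,l)^2) on alternate-allele frequencies in
#' [0,1], one coordinate per locus; loci with an undefined frequency in
#' either population are excluded pairwise.
#'
#' @inheritParams pairwise_fst
#' @return symmetric K x K matrix with zero diagonal.
#' @export
euclidean_pairwise <- function(table) {
  fr <- allele_frequencies(table, by_population = TRUE)
  lev <- levels(pop_factor(table))
  K <- length(lev)
  if (K < 2) stop("need >= 2 populations")
  pm <- matrix(fr$p_alt[order(match(fr$population, lev))],
               ncol = K, dimnames = list(NULL, lev))
  m <- matrix(0, K, K, dimnames = list(lev, lev))
  for (j in seq_len(K - 1)) {
    for (k in seq(j + 1, K)) {
      ok <- !is.na(pm[, j]) & !is.na(pm[, k])
      if (!any(ok)) stop("no shared typed loci for pair ", lev[j], "-", lev[k])
      m[j, k] <- m[k, j] <- sqrt(sum((pm[ok, j] - pm[ok, k])^2))
    }
  }
  m
}

#' All three pairwise distance matrices
#'
#' Convenience wrapper returning Weir-Cockerham F_ST, Nei G_ST and Euclidean
#' distances in one object.
#'
#' @inheritParams pairwise_fst
#' @return list of class \code{distance_set} with elements \code{fst},
#'   \code{gst}, \code{euclidean}.
#' @export
distance_set <- function(table) {
  structure(list(fst = pairwise_fst(table),
                 gst = nei_gst_pairwise(table),
                 euclidean = euclidean_pairwise(table)),
            class = "distance_set")
}
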