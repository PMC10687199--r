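#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test on the observed genotype counts at a biallelic
#' locus. Given the allele counts, every heterozygote count h of the same
#' parity as the rarer-allele count is enumerated; its conditional
#' probability is proportional to 2^h / (n_AA(h)! h! n_BB(h)!), evaluated
#' by a log-space recurrence to stay stable at large n. The p-value is the
#' total probability of all outcomes no more probable than the observed
#' one; the mid-p variant subtracts half the observed outcome's probability.
#'
#' @param n_AA,n_AB,n_BB genotype counts (non-negative, n >= 1).
#' @param midp return the mid-p variant.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact <- function(n_AA, n_AB, n_BB, midp = FALSE) {
  counts <- c(n_AA, n_AB, n_BB)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop("need at least one genotype")
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  n_rare <- min(nA, nB)
  if (n_rare == 0)                           # monomorphic: single outcome
    return(if (midp) 0.5 else 1)             # mid-p subtracts half its mass

  hs <- seq(n_rare %% 2, n_rare, by = 2)
  # log P(h+2) - log P(h) = log(4 hom_rare(h) hom_common(h)) - log((h+1)(h+2))
  lp <- numeric(length(hs))
  for (i in seq_along(hs)[-1]) {
    h <- hs[i - 1]
    hom_rare <- (n_rare - h) / 2
    hom_common <- (2 * n - n_rare - h) / 2
    lp[i] <- lp[i - 1] + log(4 * hom_rare * hom_common) -
      log((h + 1) * (h + 2))
  }
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))

  obs <- which(hs == n_AB)
  p_obs <- pr[obs]
  p <- sum(pr[pr <= p_obs * (1 + 1e-12)])
  if (midp) p <- p - 0.5 * p_obs
  min(p, 1)
}

#' Genome-wide exact HWE scan
#'
#' Runs \code{\link{hwe_exact}} at every locus, within each population by
#' default (the test is only meaningful inside a panmictic unit) or pooled.
#' A locus is counted as deviating when it is significant at \code{alpha}
#' in at least one population. Raw exact p-values are used by default;
#' Bonferroni or Benjamini-Hochberg correction is available.
#'
#' @param table a \code{genotype_table}.
#' @param per_population test within populations (default) or pooled.
#' @param alpha significance level for the deviation flag.
#' @param midp use the mid-p variant.
#' @param adjust multiple-testing correction applied within each population:
#'   \code{"none"} (default), \code{"bonferroni"} or \code{"BH"}.
#' @return list with \code{results} (data.frame: locus, population, genotype
#'   counts, p_exact, p_mid, p_adj, significant, ternary x/y) and
#'   \code{n_deviating} (loci significant in >= 1 population).
#' @export
hwe_scan <- function(table, per_population = TRUE, alpha = 0.05,
                     midp = FALSE, adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  groups <- freq_groups(table, per_population)
  res <- do.call(rbind, lapply(names(groups), function(g) {
    d <- table$dosages[groups[[g]], , drop = FALSE]
    n0 <- colSums(d == 0L, na.rm = TRUE)
    n1 <- colSums(d == 1L, na.rm = TRUE)
    n2 <- colSums(d == 2L, na.rm = TRUE)
    p_exact <- p_mid <- rep(NA_real_, ncol(d))
    xy <- matrix(NA_real_, ncol(d), 2)
    for (l in seq_len(ncol(d))) {
      if (n0[l] + n1[l] + n2[l] == 0) next
      p_exact[l] <- hwe_exact(n0[l], n1[l], n2[l], midp = FALSE)
      p_mid[l] <- hwe_exact(n0[l], n1[l], n2[l], midp = TRUE)
      xy[l, ] <- ternary_coordinates(n0[l], n1[l], n2[l])
    }
    data.frame(locus_id = table$loci$locus_id, population = g,
               n_AA = n0, n_AB = n1, n_BB = n2,
               p_exact = p_exact, p_mid = p_mid,
               ternary_x = xy[, 1], ternary_y = xy[, 2],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  p_used <- if (midp) res$p_mid else res$p_exact
  res$p_adj <- stats::ave(p_used, res$population,
                          FUN = function(p) stats::p.adjust(p, method = if (adjust == "none") "none" else adjust))
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  deviating <- unique(res$locus_id[res$significant])
  list(results = res, n_deviating = length(deviating),
       deviating_loci = deviating)
}

#' Ternary (de Finetti) coordinates of genotype frequencies
#'
#' Maps the genotype frequency triple (f_AA, f_AB, f_BB) into the unit
#' triangle: x = f_BB + f_AB/2, y = f_AB * sqrt(3)/2. The AA vertex is
#' (0,0), BB is (1,0) and AB the apex (0.5, sqrt(3)/2).
#'
#' @param n_AA,n_AB,n_BB genotype counts, n >= 1.
#' @return numeric vector \code{c(x, y)}.
#' @export
ternary_coordinates <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  if (n < 1) stop("need at least one genotype")
  f_AB <- n_AB / n
  f_BB <- n_BB / n
  c(x = f_BB + f_AB / 2, y = f_AB * sqrt(3) / 2)
}

#' Hardy-Weinberg parabola in ternary coordinates
#'
#' The locus of genotype points expected under Hardy-Weinberg proportions,
#' (f_AA, f_AB, f_BB) = ((1-p)^2, 2p(1-p), p^2), traced over p in [0, 1].
#'
#' @param n_points number of points along the curve.
#' @return data.frame with columns \code{p}, \code{x}, \code{y}.
#' @export
hwe_parabola <- function(n_points = 101) {
  p <- seq(0, 1, length.out = n_points)
  f_AB <- 2 * p * (1 - p)
  f_BB <- p^2
  data.frame(p = p, x = f_BB + f_AB / 2, y = f_AB * sqrt(3) / 2)
}
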