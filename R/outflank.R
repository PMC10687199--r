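#' F_ST outlier scan by trimmed chi-square fitting
#'
#' Infers the neutral F_ST distribution directly from the data and flags
#' loci in its right tail as selection candidates. Per-locus
#' uncorrected Weir-Cockerham estimates (theta without the finite-sample
#' correction terms) are computed across all populations; loci with pooled
#' expected heterozygosity below \code{h_min} are excluded; the lowest and
#' highest \code{trim} quantiles are discarded; and a scaled chi-square
#' model F_ST * df / fst_bar ~ chi-square(df), truncated to the kept range,
#' is fitted by maximum likelihood over (df, fst_bar). Right-tail p-values
#' from the fitted distribution are assigned to every included locus and
#' those below \code{alpha} are flagged.
#'
#' @param table a \code{genotype_table} with >= 2 populations.
#' @param trim length-2 vector: fractions trimmed from the low and high end
#'   of the empirical F_ST distribution before fitting (default 5% each).
#' @param h_min minimum pooled expected heterozygosity for a locus to enter
#'   the scan (default 0.1).
#' @param alpha right-tail significance level for the outlier flag.
#' @return list of class \code{outlier_scan}: \code{df_inferred},
#'   \code{fst_bar}, trim settings, and a per-locus data.frame with
#'   \code{theta_nocorr}, \code{H_E_pooled}, \code{included},
#'   \code{p_right} and \code{outlier}.
#' @export
outflank_scan <- function(table, trim = c(0.05, 0.05), h_min = 0.1,
                          alpha = 0.05) {
  if (length(trim) != 2 || any(trim < 0) || sum(trim) >= 1)
    stop("trim must be two fractions with sum < 1")
  wc <- wc_components_table(table)
  fr <- allele_frequencies(table, by_population = FALSE)
  he <- 2 * fr$p_alt * (1 - fr$p_alt)

  included <- !is.na(wc$theta_nocorr) & !is.na(he) & he >= h_min
  x_all <- wc$theta_nocorr
  x <- x_all[included]
  if (length(x) < 20) stop("too few loci to fit the neutral distribution (need >= 20 passing h_min)")
  if (stats::sd(x) < 1e-12)
    stop("degenerate input: all per-locus F_ST identical; cannot fit a neutral distribution")

  xs <- sort(x)
  L <- length(xs)
  lo_n <- floor(L * trim[1])
  hi_n <- floor(L * trim[2])
  kept <- xs[(lo_n + 1):(L - hi_n)]
  xlow <- kept[1]; xhigh <- kept[length(kept)]
  kept <- kept[kept > 0]           # chi-square support is positive
  if (length(kept) < 10) stop("too few positive F_ST values after trimming")
  xlow <- max(xlow, 0)

  nll <- function(par) {
    df <- exp(par[1]); fb <- exp(par[2])
    if (!is.finite(df) || !is.finite(fb) || df > 1e5) return(1e10)
    s <- df / fb
    z <- stats::pchisq(xhigh * s, df) - stats::pchisq(xlow * s, df)
    if (z <= 0) return(1e10)
    -sum(stats::dchisq(kept * s, df, log = TRUE) + log(s)) +
      length(kept) * log(z)
  }
  # coarse grid on df, fst_bar at the trimmed mean, then joint refinement
  fb0 <- mean(kept)
  grid <- exp(seq(log(0.5), log(200), length.out = 40))
  g_nll <- vapply(grid, function(df) nll(c(log(df), log(fb0))), numeric(1))
  start <- c(log(grid[which.min(g_nll)]), log(fb0))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 2000))
  if (opt$convergence != 0)
    stop("neutral-distribution fit did not converge (code ",
         opt$convergence, ", nll ", signif(opt$value, 6), ")")
  df_hat <- exp(opt$par[1]); fb_hat <- exp(opt$par[2])
  if (df_hat > 5e4)
    stop("degenerate fit: inferred df diverged (near-constant F_ST values)")

  p_right <- rep(NA_real_, length(x_all))
  p_right[included] <-
    stats::pchisq(x_all[included] * df_hat / fb_hat, df_hat,
                  lower.tail = FALSE)
  outlier <- !is.na(p_right) & p_right < alpha

  structure(list(
    df_inferred = df_hat, fst_bar = fb_hat,
    trim = trim, h_min = h_min, alpha = alpha,
    n_included = sum(included), n_outliers = sum(outlier),
    loci = data.frame(locus_id = wc$locus_id,
                      theta_nocorr = x_all, H_E_pooled = he,
                      included = included, p_right = p_right,
                      outlier = outlier, stringsAsFactors = FALSE)
  ), class = "outlier_scan")
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf(
    "outlier_scan: %d loci included (H_E >= %.2f), df = %.2f, mean F_ST = %.4f, %d outlier(s) at alpha = %.2f\n",
    x$n_included, x$h_min, x$df_inferred, x$fst_bar, x$n_outliers, x$alpha))
  invisible(x)
}
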