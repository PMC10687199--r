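#' Simulation configuration for multi-breed genotypes
#'
#' Parameters of the Balding-Nichols genotype simulator. Defaults emulate a
#' three-breed SNP-panel design: 3 populations x 100 individuals x 300
#' biallelic loci, between-population differentiation F_ST = 0.04 and a
#' mild within-population heterozygote excess (F_IS = -0.03).
#'
#' @param n_pops number of populations (K >= 1).
#' @param n_per_pop individuals per population; scalar or length-K vector.
#' @param n_loci number of biallelic loci (L).
#' @param fst_target Balding-Nichols drift parameter F, in (0,1); scalar or
#'   per-locus vector of length L (e.g. to spike a few loci to high
#'   differentiation on a neutral background).
#' @param fis_target within-population fixation index in (-1,1); negative
#'   values produce heterozygote excess.
#' @param anc_maf_range range (low, high] in (0, 0.5] for the uniform
#'   ancestral minor-allele frequency.
#' @param missing_rate i.i.d. genotype missingness rate in [0,1).
#' @param seed integer RNG seed; the simulation is fully reproducible.
#' @param clamp_fis with a negative \code{fis_target}, drifted frequencies
#'   near fixation can make the requested heterozygote excess infeasible
#'   (homozygote probability would go negative). When \code{TRUE} (default)
#'   F_IS is clamped at such locus-population cells to the maximal feasible
#'   excess \code{-min(p,1-p)/max(p,1-p)}; when \code{FALSE} the simulation
#'   errors naming the locus. Clamped cells have near-zero gene diversity,
#'   so the realized multilocus F_IS is essentially unaffected.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_pops = 3, n_per_pop = 100, n_loci = 300,
                       fst_target = 0.04, fis_target = -0.03,
                       anc_maf_range = c(0.05, 0.5),
                       missing_rate = 0, seed = 1L, clamp_fis = TRUE) {
  if (n_pops < 1) stop("n_pops must be >= 1")
  if (length(n_per_pop) == 1L) n_per_pop <- rep(n_per_pop, n_pops)
  if (length(n_per_pop) != n_pops) stop("n_per_pop must be scalar or length K")
  if (any(fst_target <= 0) || any(fst_target >= 1))
    stop("fst_target must lie in (0,1)")
  if (!length(fst_target) %in% c(1L, n_loci))
    stop("fst_target must be scalar or length n_loci")
  if (fis_target <= -1 || fis_target >= 1) stop("fis_target must lie in (-1,1)")
  if (anc_maf_range[1] <= 0 || anc_maf_range[2] > 0.5 ||
      anc_maf_range[1] > anc_maf_range[2])
    stop("anc_maf_range must satisfy 0 < low <= high <= 0.5")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)")
  structure(list(
    n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
    n_loci = as.integer(n_loci), fst_target = fst_target,
    fis_target = fis_target, anc_maf_range = anc_maf_range,
    missing_rate = missing_rate, seed = as.integer(seed),
    clamp_fis = isTRUE(clamp_fis)
  ), class = "sim_config")
}

#' Simulate multi-breed SNP genotypes
#'
#' Balding-Nichols model: each locus draws an ancestral frequency p from
#' Uniform(anc_maf_range); each population draws its frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so E[p_k] = p and Var[p_k] = F p(1-p).
#' Individual genotypes are drawn with the inbreeding-adjusted frequencies
#' P(het) = 2 p_k (1-p_k) (1 - F_IS) and homozygote probabilities
#' p_k^2 + p_k (1-p_k) F_IS (and symmetrically), which gives an expected
#' within-population fixation index of F_IS (negative = heterozygote
#' excess). Missing genotypes are set i.i.d. at \code{missing_rate}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with the \code{table} (a \code{genotype_table}) and
#'   \code{truth} (ancestral and realized per-population frequencies plus a
#'   config echo) for parameter-recovery checks.
#' @export
simulate_genotypes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_pops; L <- config$n_loci
  ns <- config$n_per_pop; n <- sum(ns)
  F <- rep(config$fst_target, length.out = L)
  Fis <- config$fis_target

  p_anc <- stats::runif(L, config$anc_maf_range[1], config$anc_maf_range[2])
  p_pop <- matrix(0, L, K)
  for (k in seq_len(K))
    p_pop[, k] <- stats::rbeta(L, p_anc * (1 - F) / F,
                               (1 - p_anc) * (1 - F) / F)
  # Beta can return exact 0/1 for tiny shapes; keep loci segregating overall
  p_pop <- pmin(pmax(p_pop, 1e-9), 1 - 1e-9)

  # validity of inbreeding-adjusted genotype probabilities
  Fmat <- matrix(Fis, L, K)
  if (Fis < 0) {
    bound <- -pmin(p_pop, 1 - p_pop) / pmax(p_pop, 1 - p_pop)
    bad <- which(Fis < bound, arr.ind = TRUE)
    if (nrow(bad)) {
      if (!isTRUE(config$clamp_fis))
        stop(sprintf("fis_target = %.3f yields negative homozygote probability at locus %d (pop %d, p = %.4f)",
                     Fis, bad[1, 1], bad[1, 2], p_pop[bad[1, 1], bad[1, 2]]))
      Fmat <- pmax(Fmat, bound)
    }
  }

  dos <- matrix(NA_integer_, n, L)
  row0 <- 0L
  for (k in seq_len(K)) {
    pk <- p_pop[, k]
    Fk <- Fmat[, k]
    g2 <- pk^2 + pk * (1 - pk) * Fk
    g1 <- 2 * pk * (1 - pk) * (1 - Fk)
    g0 <- (1 - pk)^2 + pk * (1 - pk) * Fk
    u <- matrix(stats::runif(ns[k] * L), ns[k], L)
    gmat <- matrix(0L, ns[k], L)
    gmat[u > matrix(g0, ns[k], L, byrow = TRUE)] <- 1L
    gmat[u > matrix(g0 + g1, ns[k], L, byrow = TRUE)] <- 2L
    dos[row0 + seq_len(ns[k]), ] <- gmat
    row0 <- row0 + ns[k]
  }
  if (config$missing_rate > 0)
    dos[matrix(stats::runif(n * L) < config$missing_rate, n, L)] <- NA_integer_

  pops <- rep(paste0("pop", seq_len(K)), ns)
  sample_id <- sprintf("%s_%03d", pops, unlist(lapply(ns, seq_len)))
  bases <- c("A", "C", "G", "T")
  ref_idx <- sample.int(4L, L, replace = TRUE)
  alt_off <- sample.int(3L, L, replace = TRUE)
  alt_idx <- ((ref_idx - 1L + alt_off) %% 4L) + 1L

  table <- genotype_table(
    dos,
    data.frame(sample_id = sample_id, population = pops,
               stringsAsFactors = FALSE),
    data.frame(locus_id = sprintf("snp%04d", seq_len(L)),
               chromosome = "1", position = 1000L * seq_len(L),
               allele_ref = bases[ref_idx], allele_alt = bases[alt_idx],
               stringsAsFactors = FALSE)
  )
  truth <- list(p_anc = p_anc, p_pop = p_pop, config = config)
  list(table = table, truth = truth)
}
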