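# Small in-code fixtures and independent oracles shared across test files.

# hand-built 4-sample, 3-locus table (alt is the minor allele everywhere)
toy_table <- function() {
  genotype_table(
    rbind(c(0L, 1L, 0L),
          c(1L, 0L, 0L),
          c(0L, 1L, 1L),
          c(2L, 0L, NA)),
    data.frame(sample_id = paste0("s", 1:4),
               population = c("A", "A", "B", "B")),
    data.frame(locus_id = paste0("L", 1:3), chromosome = "1",
               position = c(100L, 200L, 300L),
               allele_ref = c("A", "C", "G"), allele_alt = c("G", "T", "A"))
  )
}

# table built from explicit genotype counts per population at each locus;
# counts is a list (one element per locus) of K x 3 matrices
table_from_counts <- function(counts, pops = NULL) {
  K <- nrow(counts[[1]])
  if (is.null(pops)) pops <- paste0("pop", seq_len(K))
  n_per <- rowSums(counts[[1]])
  rows <- lapply(seq_len(K), function(k) {
    sapply(counts, function(cnt) {
      rep(c(0L, 1L, 2L), times = cnt[k, ])
    })
  })
  dos <- do.call(rbind, rows)
  genotype_table(
    dos,
    data.frame(sample_id = sprintf("%s_%02d", rep(pops, n_per),
                                   unlist(lapply(n_per, seq_len))),
               population = rep(pops, n_per)),
    data.frame(locus_id = sprintf("L%03d", seq_along(counts)),
               chromosome = "1", position = 100L * seq_along(counts),
               allele_ref = "A", allele_alt = "C")
  )
}

# Independent transcription of the Weir & Cockerham (1984) two-level
# diploid estimator, written directly from the published formulas and kept
# separate from the package implementation. counts: K x 3 genotype counts.
wc_oracle <- function(counts) {
  n_i <- rowSums(counts)
  r <- nrow(counts)
  p_i <- (counts[, 2] + 2 * counts[, 3]) / (2 * n_i)
  h_i <- counts[, 2] / n_i
  nbar <- sum(n_i) / r
  CV2_term <- sum(n_i^2) / (r * nbar)
  nc <- (r * nbar - CV2_term) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cv <- hbar / 2
  c(a = a, b = b, c = cv, theta = a / (a + b + cv))
}

# direct (non-recurrence) enumeration of the exact HWE test: every term
# evaluated straight from log-factorials, no shared code with hwe_exact
hwe_enum_oracle <- function(nAA, nAB, nBB, midp = FALSE) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  nr <- min(nA, nB)
  if (nr == 0) return(1)
  hs <- seq(nr %% 2, nr, by = 2)
  lp <- sapply(hs, function(h) {
    homr <- (nr - h) / 2
    homc <- (2 * n - nr - h) / 2
    h * log(2) + lgamma(n + 1) - lgamma(homr + 1) - lgamma(h + 1) -
      lgamma(homc + 1) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  })
  pr <- exp(lp)
  pr <- pr / sum(pr)
  pobs <- pr[hs == nAB]
  p <- sum(pr[pr <= pobs * (1 + 1e-12)])
  if (midp) p <- p - pobs / 2
  min(p, 1)
}

# random genotype-count configuration for K populations
random_counts <- function(K = 3, n_max = 120) {
  t(sapply(seq_len(K), function(k) {
    n <- sample(5:n_max, 1)
    p <- runif(1, 0.05, 0.95)
    g <- sample(0:2, n, replace = TRUE,
                prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
    c(sum(g == 0), sum(g == 1), sum(g == 2))
  }))
}
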