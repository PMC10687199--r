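counts_table <- function() {
  # one population: AA=60, AB=30, BB=10 (alt = B)
  table_from_counts(list(matrix(c(60, 30, 10), 1)), pops = "P")
}

test_that("allele frequencies from dosages, pooled and per population", {
  tab <- toy_table()
  fr <- allele_frequencies(tab)
  # L1 dosages 0,1,0,2 -> p_alt = 3/8
  expect_equal(fr$p_alt[fr$locus_id == "L1"], 3 / 8)
  expect_equal(fr$p_ref + fr$p_alt, rep(1, 3))
  # missing excluded: L3 has dosages 0,0,1,NA -> p = 1/6
  expect_equal(fr$p_alt[fr$locus_id == "L3"], 1 / 6)
  expect_equal(fr$n_typed[fr$locus_id == "L3"], 3)

  cnt <- counts_table()
  expect_equal(allele_frequencies(cnt)$p_alt, 0.25)  # (2*10+30)/200

  fixed <- genotype_table(
    matrix(2L, 4, 1),
    data.frame(sample_id = paste0("s", 1:4), population = "P"),
    data.frame(locus_id = "L1", chromosome = "1", position = 1L,
               allele_ref = "A", allele_alt = "C"))
  expect_equal(allele_frequencies(fixed)$p_alt, 1)

  byp <- allele_frequencies(tab, by_population = TRUE)
  expect_setequal(unique(byp$population), c("A", "B"))
  expect_equal(byp$p_alt[byp$locus_id == "L1" & byp$population == "A"], 1 / 4)
})

test_that("heterozygosity and per-locus F_IS match hand computation", {
  h <- heterozygosity(counts_table())
  expect_equal(h$H_O, 0.30)
  expect_equal(h$H_E, 2 * 0.25 * 0.75)
  expect_equal(h$F_IS, 1 - 0.30 / 0.375)

  mono <- genotype_table(
    matrix(0L, 5, 1),
    data.frame(sample_id = paste0("s", 1:5), population = "P"),
    data.frame(locus_id = "L1", chromosome = "1", position = 1L,
               allele_ref = "A", allele_alt = "C"))
  hm <- heterozygosity(mono)
  expect_equal(hm$H_O, 0)
  expect_equal(hm$H_E, 0)
  expect_true(is.na(hm$F_IS))

  allhet <- genotype_table(
    matrix(1L, 10, 1),
    data.frame(sample_id = paste0("s", 1:10), population = "P"),
    data.frame(locus_id = "L1", chromosome = "1", position = 1L,
               allele_ref = "A", allele_alt = "C"))
  ha <- heterozygosity(allhet)
  expect_equal(ha$H_O, 1)
  expect_equal(ha$H_E, 0.5)
  expect_equal(fis(allhet)$overall$F_IS, -1)   # maximal heterozygote excess

  hu <- heterozygosity(allhet, unbiased = TRUE)
  expect_equal(hu$H_E, 0.5 * 20 / 19)
})

test_that("overall F_IS combines loci as a ratio of sums, excluding H_E = 0", {
  tab <- bind_loci(
    counts_table(),
    {
      t2 <- genotype_table(
        matrix(0L, 100, 1),
        data.frame(sample_id = sprintf("P_%02d", 1:100), population = "P"),
        data.frame(locus_id = "M1", chromosome = "1", position = 5L,
                   allele_ref = "A", allele_alt = "C"))
      t2
    })
  f <- fis(tab)
  # monomorphic locus contributes nothing: overall = 1 - 0.3/0.375
  expect_equal(f$overall$F_IS, 0.2)
  fm <- fis(tab, method = "mean-of-ratios")
  expect_equal(fm$overall$F_IS, 0.2)
})

test_that("Hill numbers match closed forms and are monotone in q", {
  expect_equal(hill_number(c(0.5, 0.5), 0), 2)
  expect_equal(hill_number(c(0.5, 0.5), 1), 2)
  expect_equal(hill_number(c(0.5, 0.5), 2), 2)
  expect_equal(hill_number(c(1, 0), 0), 1)
  expect_equal(hill_number(c(1, 0), 2), 1)
  p <- c(0.75, 0.25)
  expect_equal(hill_number(p, 0), 2)
  expect_equal(hill_number(p, 1), exp(-sum(p * log(p))), tolerance = 1e-12)
  expect_equal(hill_number(p, 1), 1.7548, tolerance = 1e-4)
  expect_equal(hill_number(p, 2), 1.6)

  for (pp in seq(0.05, 0.5, by = 0.05)) {
    qs <- c(0, 0.5, 1, 1.5, 2, 3)
    vals <- sapply(qs, function(q) hill_number(c(pp, 1 - pp), q))
    expect_true(all(diff(vals) <= 1e-12),
                label = sprintf("qD non-increasing at p = %.2f", pp))
  }
})

test_that("hill_profile links q = 2 to expected heterozygosity per locus", {
  sim <- simulate_genotypes(sim_config(n_per_pop = 25, n_loci = 40, seed = 6))
  hp <- hill_profile(sim$table, q = c(0, 1, 2))
  het <- heterozygosity(sim$table)
  d2 <- hp$per_locus$qD[hp$per_locus$q == 2]
  expect_equal(d2, 1 / (1 - het$H_E), tolerance = 1e-12)
  expect_error(hill_profile(sim$table, q = numeric(0)), "at least one")
})
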