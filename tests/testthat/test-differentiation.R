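test_that("variance components reproduce the worked two-population example", {
  w <- wc_components(rbind(c(60, 30, 10), c(10, 30, 60)))
  expect_equal(w$a, 0.1238636, tolerance = 1e-6)
  expect_equal(w$b, 0.0386364, tolerance = 1e-6)
  expect_equal(w$c, 0.15, tolerance = 1e-12)
  expect_equal(w$theta, 0.3963636, tolerance = 1e-6)
})

test_that("fixed difference gives theta = 1; identical counts give theta <= 0", {
  fixed <- wc_components(rbind(c(100, 0, 0), c(0, 0, 100)))
  expect_equal(fixed$theta, 1)
  same <- wc_components(rbind(c(40, 40, 20), c(40, 40, 20)))
  expect_lte(same$theta, 0)   # unbiased estimator dips below zero at s2 = 0
})

test_that("components match the independently coded estimator on random configurations", {
  set.seed(99)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    cnt <- random_counts(K)
    if (any(rowSums(cnt) == 0)) next
    got <- wc_components(cnt)
    ref <- wc_oracle(cnt)
    expect_equal(got$a, unname(ref["a"]), tolerance = 1e-12)
    expect_equal(got$b, unname(ref["b"]), tolerance = 1e-12)
    expect_equal(got$c, unname(ref["c"]), tolerance = 1e-12)
    if (!is.na(got$theta))
      expect_equal(got$theta, unname(ref["theta"]), tolerance = 1e-12)
  }
})

test_that("monomorphic locus across all populations is flagged", {
  w <- wc_components(rbind(c(50, 0, 0), c(50, 0, 0)))
  expect_true(is.na(w$theta))
  expect_error(wc_components(rbind(c(10, 5, 5))), ">= 2 populations")
})

test_that("single-locus pairwise fst equals that locus's theta; multilocus is bounded by per-locus values", {
  cnts <- list(rbind(c(60, 30, 10), c(10, 30, 60)),
               rbind(c(50, 40, 10), c(45, 40, 15)),
               rbind(c(20, 50, 30), c(35, 45, 20)))
  tab <- table_from_counts(cnts)
  one <- tab[, "L001"]
  m1 <- pairwise_fst(one)
  expect_equal(m1[1, 2], 0.3963636, tolerance = 1e-6)

  m <- pairwise_fst(tab)
  per <- sapply(cnts, function(cnt) wc_components(cnt)$theta)
  expect_gte(m[1, 2], min(per) - 1e-12)
  expect_lte(m[1, 2], max(per) + 1e-12)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 2))
  mr <- pairwise_fst(tab, method = "mean-of-ratios")
  expect_equal(mr[1, 2], mean(per), tolerance = 1e-12)
})

test_that("Nei G_ST matches closed forms", {
  # fixed difference: p = 1 vs 0 -> G_ST = 1
  fixed <- table_from_counts(list(rbind(c(0, 0, 50), c(50, 0, 0))))
  expect_equal(nei_gst_pairwise(fixed)[1, 2], 1)
  # p = 0.75 vs 0.25: H_S = 0.375, H_T = 0.5 -> 0.25
  cnt <- list(rbind(c(0, 40, 40), c(40, 40, 0))) # exact freqs 0.75 / 0.25
  tab <- table_from_counts(cnt)
  expect_equal(nei_gst_pairwise(tab)[1, 2], 0.25, tolerance = 1e-12)
  # identical frequencies -> 0
  same <- table_from_counts(list(rbind(c(30, 40, 30), c(30, 40, 30))))
  expect_equal(nei_gst_pairwise(same)[1, 2], 0)
})

test_that("Euclidean distance on frequency vectors matches closed forms", {
  same <- table_from_counts(list(rbind(c(30, 40, 30), c(30, 40, 30))))
  expect_equal(euclidean_pairwise(same)[1, 2], 0)
  # single locus, p 0.2 vs 0.6 -> 0.4
  one <- table_from_counts(list(rbind(c(30, 20, 0), c(10, 20, 20))))
  expect_equal(euclidean_pairwise(one)[1, 2], 0.4, tolerance = 1e-12)
  # delta p = 0.1 at each of 300 loci -> sqrt(3)
  cnts <- rep(list(rbind(c(25, 50, 25), c(15, 50, 35))), 300) # p 0.5 vs 0.6
  tab <- table_from_counts(cnts)
  expect_equal(euclidean_pairwise(tab)[1, 2], sqrt(3), tolerance = 1e-12)
})

test_that("the three distance matrices rank population pairs consistently", {
  # pop2 sits between pop1 and pop3 in frequency space
  set.seed(2)
  L <- 120
  p1 <- runif(L, 0.25, 0.7)
  cnts <- lapply(seq_len(L), function(l) {
    ps <- c(p1[l], min(p1[l] + 0.06, 0.95), min(p1[l] + 0.25, 0.98))
    t(sapply(ps, function(p) {
      n <- 100
      nAB <- round(2 * p * (1 - p) * n)
      nBB <- round(p * n - nAB / 2)
      c(n - nAB - nBB, nAB, nBB)
    }))
  })
  tab <- table_from_counts(cnts)
  ds <- distance_set(tab)
  for (nm in c("fst", "gst", "euclidean")) {
    m <- ds[[nm]]
    expect_lt(m["pop1", "pop2"], m["pop1", "pop3"])
    expect_lt(m["pop2", "pop3"], m["pop1", "pop3"])
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 3))
  }
})

test_that("pairwise fst recovers the simulated differentiation", {
  sim <- simulate_genotypes(sim_config(n_pops = 2, n_per_pop = 100,
                                       n_loci = 1000, fst_target = 0.05,
                                       fis_target = 0, seed = 31))
  expect_lt(abs(pairwise_fst(sim$table)[1, 2] - 0.05), 0.01)
  # duplicated population: near-zero differentiation
  base <- simulate_genotypes(sim_config(n_pops = 1, n_per_pop = 200,
                                        n_loci = 300, fst_target = 0.04,
                                        seed = 32))$table
  base$samples$population <- rep(c("X", "Y"), each = 100)
  expect_lt(abs(pairwise_fst(base)[1, 2]), 0.005)
})
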