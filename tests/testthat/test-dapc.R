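two_pop_sim <- function(F = 0.15, n = 20, L = 40, seed = 3, K = 3)
  simulate_genotypes(sim_config(n_pops = K, n_per_pop = n, n_loci = L,
                                fst_target = F, seed = seed))$table

test_that("pca handles trivial and degenerate cases", {
  tab <- genotype_table(
    matrix(c(0L, 2L), 2, 1),
    data.frame(sample_id = c("a", "b"), population = c("P", "P")),
    data.frame(locus_id = "L1", chromosome = "1", position = 1L,
               allele_ref = "A", allele_alt = "C"))
  pca <- fit_pca(tab)
  expect_equal(ncol(pca$scores), 1L)
  expect_equal(sort(pca$scores[, 1]), c(-1, 1))
  expect_equal(pca$var_explained, 1)

  const <- tab
  const$dosages[] <- 1L
  expect_error(fit_pca(const), "zero-variance")
})

test_that("duplicating a locus doubles the leading variance share", {
  x <- c(0L, 2L, 0L, 2L)
  y <- c(0L, 0L, 2L, 2L)   # orthogonal to x, equal variance
  meta <- function(ids) data.frame(locus_id = ids, chromosome = "1",
                                   position = seq_along(ids),
                                   allele_ref = "A", allele_alt = "C")
  smp <- data.frame(sample_id = paste0("s", 1:4), population = "P")
  indep <- fit_pca(genotype_table(cbind(x, y), smp, meta(c("L1", "L2"))))
  dup <- fit_pca(genotype_table(cbind(x, x, y), smp, meta(c("L1", "L1b", "L2"))))
  expect_equal(indep$eigenvalues[1], indep$eigenvalues[2])   # shares 1/2, 1/2
  expect_equal(dup$eigenvalues[1] / indep$eigenvalues[1], 2) # duplicated axis
  expect_equal(dup$var_explained[1], 2 / 3)
})

test_that("all retained components reconstruct the centered imputed matrix", {
  tab <- two_pop_sim(L = 25, n = 10, seed = 12)
  tab$dosages[1, 3] <- NA
  pca <- fit_pca(tab)
  X <- pca$scores %*% t(pca$rotation)
  imputed <- tab$dosages
  imputed[1, 3] <- mean(tab$dosages[-1, 3])
  centered <- sweep(imputed, 2, pca$center)
  expect_equal(X, unname(centered), tolerance = 1e-10)
})

test_that("full-rank DAPC reproduces direct linear discriminant analysis", {
  skip_if_not_installed("MASS")
  tab <- two_pop_sim(F = 0.15, n = 20, L = 30, seed = 3)
  pca <- fit_pca(tab)
  model <- fit_dapc(tab, ncol(pca$scores), pca = pca)
  rep <- assign_populations(model, tab)
  X <- tab$dosages
  lda_fit <- MASS::lda(X, grouping = factor(tab$samples$population))
  pred <- predict(lda_fit)
  expect_equal(mean(as.character(pred$class) == rep$assigned), 1)
  expect_equal(unname(rep$posterior), unname(pred$posterior),
               tolerance = 1e-8)
})

test_that("contribution columns are normalized and equivariant to locus order", {
  tab <- two_pop_sim(F = 0.1, n = 25, L = 40, seed = 17)
  model <- fit_dapc(tab, 10)
  expect_equal(unname(colSums(model$contrib)), rep(1, 2), tolerance = 1e-12)
  expect_true(all(model$contrib >= 0))

  set.seed(1)
  perm <- sample(ncol(tab$dosages))
  model_p <- fit_dapc(tab[, perm], 10)
  expect_equal(model_p$contrib[tab$loci$locus_id, , drop = FALSE],
               model$contrib, tolerance = 1e-8)
})

test_that("assignment is invariant to allele relabeling and posteriors sum to one", {
  tab <- two_pop_sim(F = 0.08, n = 30, L = 50, seed = 19)
  model <- fit_dapc(tab, 15)
  rep1 <- assign_populations(model, tab)
  expect_equal(unname(rowSums(rep1$posterior)), rep(1, nrow(tab$dosages)),
               tolerance = 1e-12)

  flipped <- tab
  flipped$dosages[, 1:20] <- 2L - flipped$dosages[, 1:20]
  model2 <- fit_dapc(flipped, 15)
  rep2 <- assign_populations(model2, flipped)
  expect_equal(rep2$assigned, rep1$assigned)
  expect_equal(rep2$posterior, rep1$posterior, tolerance = 1e-8)

  expect_error(assign_populations(model, tab[, 1:10]), "lacks model loci")
})

test_that("a-score is near zero for labels unrelated to genotype", {
  # chance reassignment approaches 1/K once n is large relative to the
  # retained dimensions (training-set optimism scales like n_pca / n)
  set.seed(23)
  tab <- two_pop_sim(F = 0.05, n = 250, L = 60, seed = 23)
  tab$samples$population <- sample(tab$samples$population)  # break structure
  asc <- a_score_optimize(tab, grid = c(2, 5), n_sim = 20, seed = 23)
  expect_lt(max(abs(asc$scores$a_score)), 0.15)
  expect_lt(max(abs(asc$scores$P_r - 1 / 3)), 0.05)
})

test_that("strong structure yields perfect reassignment and a deterministic choice", {
  tab <- two_pop_sim(F = 0.3, n = 30, L = 80, seed = 29)
  asc1 <- a_score_optimize(tab, grid = 1:10, n_sim = 5, seed = 7)
  asc2 <- a_score_optimize(tab, grid = 1:10, n_sim = 5, seed = 7)
  expect_identical(asc1$chosen, asc2$chosen)
  model <- fit_dapc(tab, asc1$chosen)
  expect_equal(assign_populations(model, tab)$overall_correct, 1)
  expect_equal(asc1$scores$P_t[asc1$scores$n_pca == asc1$chosen], 1)
  expect_error(a_score_optimize(tab, grid = 1000), "grid")
})

test_that("panel selection respects threshold boundaries and policies", {
  tab <- two_pop_sim(F = 0.1, n = 25, L = 40, seed = 31)
  model <- fit_dapc(tab, 10)
  expect_equal(select_informative(model, threshold = 0)$n_selected, 40L)
  expect_lte(select_informative(model, threshold = 1)$n_selected, 2L)
  expect_error(select_informative(model, threshold = 1.5), "threshold")
  p_max <- select_informative(model, 0.01, axis_policy = "max")
  p_ax1 <- select_informative(model, 0.01, axis_policy = "axis1")
  expect_true(all(p_ax1$panel$locus_id %in% p_max$panel$locus_id))
})

test_that("high-differentiation loci are enriched in the selected panel", {
  cfg <- sim_config(n_per_pop = 60, n_loci = 300,
                    fst_target = c(rep(0.03, 290), rep(0.4, 10)),
                    seed = 37)
  tab <- simulate_genotypes(cfg)$table
  model <- fit_dapc(tab, 20)
  panel <- select_informative(model, threshold = 0.01)
  spiked <- sprintf("snp%04d", 291:300)
  in_panel <- sum(spiked %in% panel$panel$locus_id)
  frac_spiked_selected <- in_panel / 10
  frac_neutral_selected <-
    sum(!panel$panel$locus_id %in% spiked) / 290
  expect_gt(frac_spiked_selected, frac_neutral_selected)
})

test_that("compare_panels with threshold zero reduces to the identity comparison", {
  tab <- two_pop_sim(F = 0.1, n = 20, L = 40, seed = 41)
  cp <- compare_panels(tab, threshold = 0, seed = 5, grid = c(2, 5, 8),
                       n_sim = 3)
  expect_equal(cp$panel$n_selected, 40L)
  expect_equal(cp$reduced$assigned, cp$full$assigned)
  expect_equal(cp$reduced$posterior, cp$full$posterior, tolerance = 1e-10)
  # deterministic under a fixed seed
  cp2 <- compare_panels(tab, threshold = 0, seed = 5, grid = c(2, 5, 8),
                        n_sim = 3)
  expect_identical(cp$n_pca, cp2$n_pca)
  expect_equal(cp$full$posterior, cp2$full$posterior)
})
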