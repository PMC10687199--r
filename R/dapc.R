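#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are imputed with the locus mean, columns are centered
#' (and optionally scaled to unit variance), and the decomposition is taken
#' by SVD. Eigenvalues are squared singular values / (n - 1); components
#' with numerically zero variance are dropped.
#'
#' @param table a \code{genotype_table} (>= 2 samples, >= 1 locus).
#' @param scale scale columns to unit variance (default off; centering only).
#' @return object of class \code{pca_model}: \code{center}, \code{scale},
#'   \code{rotation} (L x r loadings), \code{eigenvalues},
#'   \code{var_explained}, \code{cum_var}, \code{scores} (n x r),
#'   \code{locus_ids}.
#' @export
fit_pca <- function(table, scale = FALSE) {
  d <- table$dosages
  if (nrow(d) < 2) stop("need >= 2 samples for PCA")
  X <- impute_center(d, scale = scale)
  sv <- svd(X$mat)
  tol <- max(dim(X$mat)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > max(tol, 1e-12))
  if (r == 0) stop("zero-variance genotype matrix: PCA undefined")
  ev <- sv$d[seq_len(r)]^2 / (nrow(X$mat) - 1)
  structure(list(
    center = X$center, scale = X$scale,
    rotation = sv$v[, seq_len(r), drop = FALSE],
    eigenvalues = ev,
    var_explained = ev / sum(sv$d^2 / (nrow(X$mat) - 1)),
    cum_var = cumsum(ev) / sum(sv$d^2 / (nrow(X$mat) - 1)),
    scores = sv$u[, seq_len(r), drop = FALSE] %*% diag(ev * 0 + sv$d[seq_len(r)], r),
    locus_ids = table$loci$locus_id
  ), class = "pca_model")
}

impute_center <- function(d, scale = FALSE) {
  mu <- colMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  X <- d
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  X <- sweep(X, 2, mu)
  sc <- rep(1, ncol(X))
  if (scale) {
    sc <- apply(X, 2, stats::sd)
    sc[sc < 1e-12] <- 1
    X <- sweep(X, 2, sc, "/")
  }
  list(mat = X, center = mu, scale = sc)
}

#' Discriminant analysis of principal components
#'
#' Fits a linear discriminant analysis on the sample scores of the first
#' \code{n_pca} principal components of the genotype matrix: the
#' generalized eigenproblem of between-group versus pooled within-group
#' covariance is solved, K - 1 discriminant axes are kept, and each axis is
#' normalized to unit pooled within-group variance. Group membership is the
#' population label of the table. Per-SNP contributions to axis j are the
#' squared composite loadings (PCA loadings times discriminant
#' coefficients), normalized so each axis's contributions sum to 1.
#'
#' @param table a \code{genotype_table} with K >= 2 populations.
#' @param n_pca number of principal components to retain
#'   (<= n - K and <= PCA rank).
#' @param pca optional precomputed \code{pca_model} for \code{table}.
#' @return object of class \code{dapc_model}.
#' @export
fit_dapc <- function(table, n_pca, pca = NULL) {
  labels <- pop_factor(table)
  if (nlevels(labels) < 2) stop("need >= 2 populations for DAPC")
  if (is.null(pca)) pca <- fit_pca(table)
  core <- dapc_core(pca$scores, labels, n_pca)
  P <- pca$rotation[, seq_len(core$n_pca), drop = FALSE] %*% core$da_coef
  contrib <- P^2
  contrib <- sweep(contrib, 2, colSums(contrib), "/")
  rownames(contrib) <- pca$locus_ids
  structure(c(core, list(
    pca = pca, contrib = contrib,
    locus_ids = pca$locus_ids,
    training_labels = labels
  )), class = "dapc_model")
}

# LDA in PC-score space; returns coefficients, centroids, axis variances
dapc_core <- function(scores, labels, n_pca) {
  n <- nrow(scores)
  K <- nlevels(labels)
  n_pca <- as.integer(n_pca)
  if (n_pca < 1 || n_pca > ncol(scores) || n_pca > n - K)
    stop(sprintf("n_pca must lie in [1, min(rank = %d, n - K = %d)]",
                 ncol(scores), n - K))
  S <- scores[, seq_len(n_pca), drop = FALSE]
  m_all <- colMeans(S)
  W <- matrix(0, n_pca, n_pca)
  B <- matrix(0, n_pca, n_pca)
  centroids_pc <- matrix(0, K, n_pca)
  for (k in seq_len(K)) {
    Sk <- S[labels == levels(labels)[k], , drop = FALSE]
    mk <- colMeans(Sk)
    centroids_pc[k, ] <- mk
    W <- W + crossprod(sweep(Sk, 2, mk))
    B <- B + nrow(Sk) * tcrossprod(mk - m_all)
  }
  W <- W / (n - K)
  M <- tryCatch(solve(W, B), error = function(e) NULL)
  if (is.null(M)) {
    warning("singular within-group covariance; ridge 1e-8 added")
    W <- W + diag(1e-8 * mean(diag(W)) + 1e-12, n_pca)
    M <- solve(W, B)
  }
  eig <- eigen(M)
  ord <- order(Re(eig$values), decreasing = TRUE)
  n_da <- min(K - 1L, n_pca)   # fewer PCs than groups-1: fewer axes exist
  V <- Re(eig$vectors[, ord[seq_len(n_da)], drop = FALSE])
  # unit pooled within-group variance per axis
  for (j in seq_len(n_da)) {
    s <- sqrt(drop(t(V[, j]) %*% W %*% V[, j]))
    V[, j] <- V[, j] / s
  }
  Y <- S %*% V
  centroids <- centroids_pc %*% V
  rownames(centroids) <- levels(labels)
  within_var <- rep(0, n_da)
  for (k in seq_len(K)) {
    Yk <- Y[labels == levels(labels)[k], , drop = FALSE]
    within_var <- within_var +
      colSums(sweep(Yk, 2, colMeans(Yk))^2)
  }
  within_var <- within_var / (n - K)
  list(n_pca = n_pca, groups = levels(labels), da_coef = V,
       da_eigenvalues = Re(eig$values[ord[seq_len(n_da)]]),
       centroids = centroids, within_var = within_var,
       disc_scores = Y)
}

#' Assign individuals to populations with a fitted DAPC model
#'
#' Projects genotypes through the stored centering/imputation into PC space
#' and then onto the discriminant axes; the posterior probability of group
#' k is a Gaussian membership weight,
#' proportional to exp(-1/2 * sum_j (y_j - centroid_kj)^2 / var_j) with the
#' pooled within-group variance per axis, normalized over groups (equal
#' priors).
#'
#' @param model a \code{dapc_model}.
#' @param table a \code{genotype_table} whose loci match the model's.
#' @return object of class \code{assignment_report}: per-individual
#'   assignments and posterior matrix, K x K confusion matrix (rows = true
#'   population where available), per-population and overall
#'   correct-assignment proportions, and mean posterior of the true group.
#' @export
assign_populations <- function(model, table) {
  miss <- setdiff(model$locus_ids, table$loci$locus_id)
  if (length(miss))
    stop("table lacks model loci: ", paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  table <- table[, model$locus_ids]
  d <- table$dosages
  X <- d
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- model$pca$center[idx[, 2]]
  X <- sweep(X, 2, model$pca$center)
  X <- sweep(X, 2, model$pca$scale, "/")
  S <- X %*% model$pca$rotation[, seq_len(model$n_pca), drop = FALSE]
  Y <- S %*% model$da_coef

  K <- length(model$groups)
  v <- pmax(model$within_var, 1e-12)
  ll <- matrix(0, nrow(Y), K)
  for (k in seq_len(K))
    ll[, k] <- -0.5 * colSums((t(Y) - model$centroids[k, ])^2 / v)
  ll <- ll - apply(ll, 1, max)
  post <- exp(ll) / rowSums(exp(ll))
  colnames(post) <- model$groups
  assigned <- model$groups[max.col(post, ties.method = "first")]

  truth <- table$samples$population
  known <- truth %in% model$groups
  confusion <- matrix(0L, K, K, dimnames = list(true = model$groups,
                                                assigned = model$groups))
  for (i in which(known))
    confusion[truth[i], assigned[i]] <- confusion[truth[i], assigned[i]] + 1L
  per_pop <- diag(confusion) / pmax(rowSums(confusion), 1L)
  overall <- if (any(known)) mean(assigned[known] == truth[known]) else NA_real_
  mean_post_true <- if (any(known))
    mean(post[cbind(which(known), match(truth[known], model$groups))])
  else NA_real_

  structure(list(
    sample_id = table$samples$sample_id,
    true_population = truth, assigned = assigned, posterior = post,
    confusion = confusion, per_population_correct = per_pop,
    overall_correct = overall, mean_posterior_true = mean_post_true
  ), class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  cat(sprintf("assignment_report: overall correct %.1f%% (mean true-group posterior %.3f)\n",
              100 * x$overall_correct, x$mean_posterior_true))
  print(round(100 * x$per_population_correct, 1))
  invisible(x)
}

#' Choose the number of retained PCs by a-score
#'
#' For each candidate number of PCs the a-score is the observed training
#' reassignment proportion minus its expectation under chance, estimated by
#' refitting with randomly permuted group labels \code{n_sim} times. The
#' candidate with the highest a-score wins (tie: fewer PCs). All
#' permutations are driven by \code{seed}.
#'
#' @param table a \code{genotype_table}.
#' @param grid candidate numbers of PCs; default \code{1:min(100, n - K, rank)}.
#' @param n_sim permutations per candidate (default 10).
#' @param seed integer seed for the permutations.
#' @param pca optional precomputed \code{pca_model}.
#' @return list with \code{chosen} (n_pca) and \code{scores} (data.frame of
#'   candidate, observed P_t, permuted mean P_r, a_score).
#' @export
a_score_optimize <- function(table, grid = NULL, n_sim = 10, seed = 1L,
                             pca = NULL) {
  labels <- pop_factor(table)
  K <- nlevels(labels)
  n <- length(labels)
  if (is.null(pca)) pca <- fit_pca(table)
  max_pc <- min(100L, n - K, ncol(pca$scores))
  if (is.null(grid)) grid <- seq_len(max_pc)
  if (length(grid) == 0 || any(grid < 1) || any(grid > min(n - K, ncol(pca$scores))))
    stop("candidate grid must lie within [1, min(n - K, rank)]")

  set.seed(seed)
  perms <- replicate(n_sim, sample.int(n), simplify = FALSE)
  score_one <- function(np) {
    fit <- dapc_core(pca$scores, labels, np)
    P_t <- mean(reassign_core(fit, labels))
    P_r <- vapply(perms, function(pm) {
      lp <- labels[pm]
      f <- dapc_core(pca$scores, lp, np)
      mean(reassign_core(f, lp))
    }, numeric(1))
    c(P_t = P_t, P_r = mean(P_r), a_score = P_t - mean(P_r))
  }
  res <- t(vapply(grid, score_one, numeric(3)))
  scores <- data.frame(n_pca = grid, P_t = res[, 1], P_r = res[, 2],
                       a_score = res[, 3])
  best <- max(scores$a_score)
  chosen <- min(scores$n_pca[scores$a_score >= best - 1e-12])
  list(chosen = chosen, scores = scores)
}

# training reassignment correctness from a dapc_core fit
reassign_core <- function(fit, labels) {
  v <- pmax(fit$within_var, 1e-12)
  Y <- fit$disc_scores
  K <- length(fit$groups)
  ll <- matrix(0, nrow(Y), K)
  for (k in seq_len(K))
    ll[, k] <- -0.5 * colSums((t(Y) - fit$centroids[k, ])^2 / v)
  fit$groups[max.col(ll, ties.method = "first")] == as.character(labels)
}

#' Select breed-informative SNPs by contribution threshold
#'
#' A SNP enters the panel when its contribution exceeds the threshold under
#' the chosen axis policy: the maximum over discriminant axes (default),
#' axis 1 only, or the eigenvalue-weighted mean over axes.
#'
#' @param model a \code{dapc_model}.
#' @param threshold contribution cut-off in [0, 1].
#' @param axis_policy \code{"max"}, \code{"axis1"} or \code{"eigen-weighted"}.
#' @return object of class \code{snp_panel}: data.frame of selected loci
#'   with their score and best axis, plus the policy and threshold.
#' @export
select_informative <- function(model, threshold = 0.01,
                               axis_policy = c("max", "axis1", "eigen-weighted")) {
  axis_policy <- match.arg(axis_policy)
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  contrib <- model$contrib
  score <- switch(axis_policy,
    max = apply(contrib, 1, max),
    axis1 = contrib[, 1],
    `eigen-weighted` = {
      w <- model$da_eigenvalues / sum(model$da_eigenvalues)
      drop(contrib %*% w)
    })
  axis <- apply(contrib, 1, which.max)
  sel <- score >= threshold
  structure(list(
    threshold = threshold, axis_policy = axis_policy,
    panel = data.frame(locus_id = model$locus_ids[sel],
                       contribution = score[sel], axis = axis[sel],
                       row.names = NULL, stringsAsFactors = FALSE),
    n_selected = sum(sel)
  ), class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel: %d loci at threshold %.3g (policy: %s)\n",
              x$n_selected, x$threshold, x$axis_policy))
  invisible(x)
}

#' Compare full-panel and reduced-panel breed assignment
#'
#' Runs the full chain: a-score selection of the number of PCs, DAPC on all
#' loci, contribution-threshold panel selection, a refit of the DAPC on the
#' reduced panel, and training-set assignment under both models. With
#' \code{threshold = 0} the reduced panel equals the full panel and the two
#' reports are identical.
#'
#' @param table a \code{genotype_table}.
#' @param threshold contribution threshold for the panel (default 0.01).
#' @param seed seed for the a-score permutations.
#' @param grid optional candidate grid of PC numbers (see
#'   \code{\link{a_score_optimize}}).
#' @param n_sim permutations per a-score candidate.
#' @param axis_policy see \code{\link{select_informative}}.
#' @return list of class \code{panel_comparison}: \code{full} and
#'   \code{reduced} assignment reports, the \code{panel}, chosen
#'   \code{n_pca}, and both fitted models.
#' @export
compare_panels <- function(table, threshold = 0.01, seed = 1L, grid = NULL,
                           n_sim = 10, axis_policy = "max") {
  pca <- fit_pca(table)
  asc <- a_score_optimize(table, grid = grid, n_sim = n_sim, seed = seed,
                          pca = pca)
  full_model <- fit_dapc(table, asc$chosen, pca = pca)
  full_report <- assign_populations(full_model, table)
  panel <- select_informative(full_model, threshold = threshold,
                              axis_policy = axis_policy)
  reduced_table <- table[, panel$panel$locus_id]
  red_pca <- fit_pca(reduced_table)
  K <- nlevels(pop_factor(table))
  red_npca <- min(asc$chosen, ncol(red_pca$scores),
                  nrow(reduced_table$dosages) - K)
  reduced_model <- fit_dapc(reduced_table, red_npca, pca = red_pca)
  reduced_report <- assign_populations(reduced_model, reduced_table)
  structure(list(
    full = full_report, reduced = reduced_report, panel = panel,
    n_pca = asc$chosen, n_pca_reduced = red_npca,
    a_scores = asc$scores,
    full_model = full_model, reduced_model = reduced_model
  ), class = "panel_comparison")
}

#' @export
print.panel_comparison <- function(x, ...) {
  cat(sprintf(
    "panel_comparison: %d PCs retained; full %.1f%% vs reduced (%d SNPs) %.1f%% correct\n",
    x$n_pca, 100 * x$full$overall_correct, x$panel$n_selected,
    100 * x$reduced$overall_correct))
  invisible(x)
}
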