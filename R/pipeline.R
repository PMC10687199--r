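#' Pipeline run configuration
#'
#' Describes one reproducible end-to-end run: input (a genotype table, a
#' .ped/.map pair, or a VCF plus population map), QC thresholds, test
#' levels, DAPC settings, and which stages to execute.
#'
#' @param table optional in-memory \code{genotype_table} (takes precedence).
#' @param ped_path,map_path PLINK text input.
#' @param vcf_path,population_map VCF input.
#' @param qc a \code{\link{qc_config}}.
#' @param hwe_alpha significance level of the HWE scan.
#' @param outlier_alpha significance level of the F_ST outlier scan.
#' @param dapc_threshold contribution threshold for the informative panel.
#' @param dapc_grid optional a-score candidate grid.
#' @param dapc_n_sim permutations per a-score candidate.
#' @param seed integer seed recorded in every output.
#' @param outdir output directory (created if absent).
#' @param stages subset of
#'   \code{c("qc","diversity","hwe","distances","outliers","dapc")}.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(table = NULL, ped_path = NULL, map_path = NULL,
                       vcf_path = NULL, population_map = NULL,
                       qc = qc_config(), hwe_alpha = 0.05,
                       outlier_alpha = 0.05, dapc_threshold = 0.01,
                       dapc_grid = NULL, dapc_n_sim = 10,
                       seed = 1L, outdir = "breedpanel_run",
                       stages = c("qc", "diversity", "hwe", "distances",
                                  "outliers", "dapc")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(table) && is.null(ped_path) && is.null(vcf_path))
    stop("provide a genotype table, a .ped/.map pair, or a VCF")
  for (p in c(ped_path, map_path, vcf_path))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  structure(list(
    table = table, ped_path = ped_path, map_path = map_path,
    vcf_path = vcf_path, population_map = population_map,
    qc = qc, hwe_alpha = hwe_alpha, outlier_alpha = outlier_alpha,
    dapc_threshold = dapc_threshold, dapc_grid = dapc_grid,
    dapc_n_sim = dapc_n_sim, seed = as.integer(seed),
    outdir = outdir, stages = stages
  ), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order on the QC-passed table: within-population diversity
#' (frequencies, heterozygosity, F_IS, Hill profiles), the exact HWE scan,
#' the three pairwise distance matrices, the F_ST outlier scan, and the
#' DAPC panel-selection/assignment comparison. Writes machine-readable
#' outputs (TSV/JSON) into the output directory and returns a run report.
#' Identical config and seed give identical outputs. A stage failure aborts
#' with the stage name; outputs written so far are kept next to a FAILED
#' marker file.
#'
#' @param config a \code{\link{run_config}}.
#' @return list of class \code{run_report} with per-stage summaries,
#'   timings, the package version and a config echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  report <- list(version = as.character(utils::packageVersion("breedpanel")),
                 seed = config$seed, stages = list())
  tsv <- function(x, f) utils::write.table(x, out(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  jsn <- function(x, f) jsonlite::write_json(x, out(f), auto_unbox = TRUE,
                                             digits = NA, pretty = TRUE)
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                 out("FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    list(value = val, seconds = proc.time()[["elapsed"]] - t0)
  }

  table <- config$table
  if (is.null(table)) {
    table <- if (!is.null(config$ped_path))
      read_plink(config$ped_path, config$map_path)
    else read_vcf(config$vcf_path, config$population_map)
  }

  if ("qc" %in% config$stages) {
    st <- timed("qc", apply_qc(table, config$qc))
    table <- st$value$table
    qcr <- st$value$report
    jsn(qcr[setdiff(names(qcr), "config")], "qc_report.json")
    report$stages$qc <- list(seconds = st$seconds,
                             output_dim = qcr$output_dim,
                             snps_removed = qcr$snps_removed_callrate +
                               qcr$snps_removed_maf,
                             samples_removed = qcr$samples_removed_callrate +
                               qcr$samples_removed_ibs)
  }

  if ("diversity" %in% config$stages) {
    st <- timed("diversity", {
      het <- heterozygosity(table, by_population = TRUE)
      f <- fis(table, by_population = TRUE)
      hp <- hill_profile(table, q = c(0, 1, 2), by_population = TRUE)
      hp_pool <- hill_profile(table, q = c(0, 1, 2), by_population = FALSE)
      list(het = het, fis = f, hill = hp, hill_pooled = hp_pool)
    })
    tsv(st$value$het, "diversity.tsv")
    jsn(list(fis_overall = st$value$fis$overall,
             hill_by_population = st$value$hill$summary,
             hill_pooled = st$value$hill_pooled$summary,
             seed = config$seed), "diversity_summary.json")
    ov <- st$value$fis$overall
    report$stages$diversity <- list(
      seconds = st$seconds,
      fis_within_overall = ov$F_IS[ov$population == "within_overall"],
      hill_pooled_means = stats::setNames(
        st$value$hill_pooled$summary$mean_qD,
        paste0("q", st$value$hill_pooled$summary$q)))
  }

  if ("hwe" %in% config$stages) {
    st <- timed("hwe", hwe_scan(table, per_population = TRUE,
                                alpha = config$hwe_alpha))
    tsv(st$value$results, "hwe.tsv")
    report$stages$hwe <- list(seconds = st$seconds,
                              n_deviating = st$value$n_deviating,
                              alpha = config$hwe_alpha)
  }

  if ("distances" %in% config$stages) {
    st <- timed("distances", distance_set(table))
    for (nm in c("fst", "gst", "euclidean")) {
      m <- st$value[[nm]]
      tsv(data.frame(population = rownames(m), as.data.frame(m),
                     check.names = FALSE),
          sprintf("distances_%s.tsv", nm))
    }
    report$stages$distances <- list(
      seconds = st$seconds,
      fst = st$value$fst, gst = st$value$gst,
      euclidean = st$value$euclidean)
  }

  if ("outliers" %in% config$stages) {
    st <- timed("outliers", outflank_scan(table, alpha = config$outlier_alpha))
    tsv(st$value$loci, "outliers.tsv")
    report$stages$outliers <- list(seconds = st$seconds,
                                   df_inferred = st$value$df_inferred,
                                   fst_bar = st$value$fst_bar,
                                   n_outliers = st$value$n_outliers)
  }

  if ("dapc" %in% config$stages) {
    st <- timed("dapc", compare_panels(table,
                                       threshold = config$dapc_threshold,
                                       seed = config$seed,
                                       grid = config$dapc_grid,
                                       n_sim = config$dapc_n_sim))
    cp <- st$value
    tsv(cp$panel$panel, "panel.tsv")
    m <- cp$full_model
    jsn(list(n_pca = cp$n_pca, groups = m$groups,
             center = m$pca$center,
             loadings = m$pca$rotation[, seq_len(cp$n_pca), drop = FALSE],
             da_coef = m$da_coef, centroids = m$centroids,
             within_var = m$within_var, seed = config$seed),
        "dapc_model.json")
    jsn(list(
      seed = config$seed,
      full = list(overall = cp$full$overall_correct,
                  per_population = as.list(cp$full$per_population_correct),
                  mean_posterior_true = cp$full$mean_posterior_true),
      reduced = list(overall = cp$reduced$overall_correct,
                     per_population = as.list(cp$reduced$per_population_correct),
                     mean_posterior_true = cp$reduced$mean_posterior_true,
                     n_snps = cp$panel$n_selected)), "assignment.json")
    tsv(data.frame(sample_id = cp$full$sample_id,
                   population = cp$full$true_population,
                   LD1 = cp$full_model$disc_scores[, 1],
                   LD2 = if (ncol(cp$full_model$disc_scores) > 1)
                     cp$full_model$disc_scores[, 2] else NA_real_),
        "dapc_scatter.tsv")
    report$stages$dapc <- list(seconds = st$seconds, n_pca = cp$n_pca,
                               n_panel = cp$panel$n_selected,
                               full_overall = cp$full$overall_correct,
                               reduced_overall = cp$reduced$overall_correct)
  }

  report$config <- config[setdiff(names(config), "table")]
  class(report) <- "run_report"
  jsonlite::write_json(
    report[setdiff(names(report), "config")], out("run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$seed, "): stages",
      paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}
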