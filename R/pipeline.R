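#' Configuration of a full analysis run
#'
#' Bundles every tunable of the pipeline: the input source (a trials CSV
#' path, or a [synth_config()] to simulate), the time normalization, the
#' standardization mode, the clustering scan, the classifier penalty, the
#' significance level and the symmetry options. Serializes losslessly to
#' YAML via [save_config()] / [load_config()].
#'
#' @param input Path to a trials CSV, or `NULL` to simulate from `synth`.
#' @param synth A [synth_config()] used when `input` is `NULL`.
#' @param n_time Samples per normalized cycle (default 201).
#' @param sd_mode Standardization scale mode, `"block"` or `"column"`.
#' @param k_candidates Candidate cluster counts; `NULL` means
#'   `2:min(40, n - 1)` at run time.
#' @param restarts K-means restarts (default 25).
#' @param seed Seed for the clustering stage.
#' @param cost Linear-separator margin penalty (default 1).
#' @param alpha Significance level (default 0.05).
#' @param reference Reference condition label (default `"Neutral"`).
#' @param sum_mode Symmetry summation mode, `"signed"` or `"absolute"`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, synth = synth_config(),
                            n_time = 201L, sd_mode = "block",
                            k_candidates = NULL, restarts = 25L, seed = 1L,
                            cost = 1, alpha = 0.05, reference = "Neutral",
                            sum_mode = "signed") {
  structure(list(input = input, synth = synth, n_time = as.integer(n_time),
                 sd_mode = sd_mode,
                 k_candidates = if (is.null(k_candidates)) NULL
                                else as.integer(k_candidates),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 cost = as.numeric(cost), alpha = as.numeric(alpha),
                 reference = reference, sum_mode = sum_mode),
            class = "analysis_config")
}

#' Save an analysis configuration as YAML
#'
#' @param config An [analysis_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  x <- unclass(config)
  x$synth <- unclass(x$synth)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Load an analysis configuration from YAML
#'
#' @param path YAML file written by [save_config()].
#' @return An [analysis_config()]; `load_config(save_config(x))` equals `x`.
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  synth <- do.call(synth_config, x$synth)
  analysis_config(input = x$input, synth = synth, n_time = x$n_time,
                  sd_mode = x$sd_mode, k_candidates = x$k_candidates,
                  restarts = x$restarts, seed = x$seed, cost = x$cost,
                  alpha = x$alpha, reference = x$reference,
                  sum_mode = x$sum_mode)
}

write_stage_csv <- function(df, out_dir, name) {
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

#' Run the full movement-pattern analysis
#'
#' Orchestrates every stage: ingest (or simulate) the trials, assemble and
#' standardize the feature matrix, scan cluster counts and compute loading
#' rates, run the three classification schemes (pairwise subjects,
#' conditions across subjects, conditions within subjects), compute the
#' symmetry table with its Kruskal-Wallis, gender-subgroup and
#' running-speed statistics, and write every stage output as CSV plus a
#' plain-text report. Reruns with the same configuration are bit-identical.
#'
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @return An `analysis_report` list with the matrix shape, cluster summary,
#'   classification tables, symmetry results and provenance, invisibly
#'   written to `report.txt`.
#' @export
run_full_analysis <- function(config, out_dir) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trials <- if (is.null(config$input)) {
    generate_cohort(config$synth)$trials
  } else {
    read_trials(config$input)
  }
  write_trials(trials, file.path(out_dir, "trials.csv"))
  fm <- build_feature_matrix(trials, n_time = config$n_time)
  std <- standardize(fm, sd_mode = config$sd_mode)
  x <- std$matrix
  rl <- row_labels(fm)

  k_candidates <- config$k_candidates %||% (2:min(40L, nrow(x) - 1L))
  ks <- suppressMessages(select_k(x, k_candidates, seed = config$seed,
                                  restarts = config$restarts))
  write_stage_csv(ks$silhouette_by_k, out_dir, "silhouette_by_k.csv")
  cr <- ks$best
  write_stage_csv(cbind(rl, cluster = cr$assignments,
                        silhouette = cr$silhouette),
                  out_dir, "cluster_assignments.csv")
  lr <- lapply(c("subject", "condition", "subject_condition_side"),
               function(g) loading_rates(cr$assignments, rl, g))
  names(lr) <- c("subject", "condition", "subject_condition_side")
  for (g in names(lr)) {
    write_stage_csv(data.frame(group = rownames(lr[[g]]$rates),
                               lr[[g]]$rates, check.names = FALSE,
                               max_rate = lr[[g]]$max_rate),
                    out_dir, paste0("loading_rates_", g, ".csv"))
  }
  as_newick(merge_tree(x), file.path(out_dir, "dendrogram.nwk"))

  pw <- pairwise_subject_comparisons(x, cost = config$cost,
                                     alpha = config$alpha)
  write_stage_csv(pw, out_dir, "pairwise_subjects.csv")
  across <- condition_comparisons_across(x, reference = config$reference,
                                         cost = config$cost,
                                         alpha = config$alpha)
  write_stage_csv(across, out_dir, "condition_across.csv")
  within <- condition_comparisons_within(x, reference = config$reference,
                                         cost = config$cost,
                                         alpha = config$alpha)
  write_stage_csv(within, out_dir, "condition_within.csv")
  write_stage_csv(within_subject_table(within), out_dir,
                  "condition_within_table.csv")

  st <- symmetry_table(trials, n_time = config$n_time,
                       sum_mode = config$sum_mode)
  write_stage_csv(as.data.frame(st), out_dir, "symmetry_table.csv")
  meds <- condition_medians(st)
  kw <- kruskal_wallis(split(st$symmetry[!is.na(st$symmetry)],
                             st$condition[!is.na(st$symmetry)]))
  gender <- if (!is.null(st$sex)) gender_subgroup_analysis(st) else NULL
  speed <- if (!is.null(trials$meta$speed)) {
    compare_running_speed(trials$meta$speed)
  } else {
    NULL
  }

  report <- structure(list(
    matrix_shape = dim(fm),
    best_k = ks$best_k,
    mean_silhouette = cr$mean_silhouette,
    loading = lapply(lr, function(t) list(n_groups = t$n_groups,
                                          n_full = t$n_full,
                                          median_max = t$median_max)),
    pairwise_subjects = list(n = attr(pw, "n_comparisons"),
                             n_significant = attr(pw, "n_significant")),
    condition_across = across,
    condition_within_means = attr(within, "mean_rates"),
    symmetry_medians = meds,
    kruskal_wallis = kw,
    gender = gender,
    speed = speed,
    config = config,
    package_version = as.character(utils::packageVersion("gaitpattern"))),
    class = "analysis_report")
  writeLines(format_report(report), file.path(out_dir, "report.txt"))
  save_config(config, file.path(out_dir, "config.yaml"))
  report
}

format_report <- function(r) {
  lines <- c(
    "gaitpattern analysis report",
    sprintf("feature matrix: %d rows x %d columns", r$matrix_shape[1L],
            r$matrix_shape[2L]),
    sprintf("best k: %d (mean silhouette %.4f)", r$best_k,
            r$mean_silhouette),
    sprintf("loading rates [%s]: %d/%d groups at rate 1, median max %.3f",
            names(r$loading),
            vapply(r$loading, function(x) x$n_full, numeric(1L)),
            vapply(r$loading, function(x) x$n_groups, numeric(1L)),
            vapply(r$loading, function(x) x$median_max, numeric(1L))),
    sprintf("pairwise subjects: %d of %d significant",
            r$pairwise_subjects$n_significant, r$pairwise_subjects$n),
    sprintf("across-subject condition rates: %s",
            paste(sprintf("%s=%.3f", r$condition_across$group_b,
                          r$condition_across$r_class), collapse = ", ")),
    sprintf("within-subject mean rates: %s",
            paste(sprintf("%s=%.3f", names(r$condition_within_means),
                          r$condition_within_means), collapse = ", ")),
    sprintf("symmetry medians: %s",
            paste(sprintf("%s=%.3f", names(r$symmetry_medians),
                          r$symmetry_medians), collapse = ", ")),
    sprintf("Kruskal-Wallis: H=%.4f, df=%d, n=%d, p=%.4f",
            r$kruskal_wallis$statistic, r$kruskal_wallis$df,
            r$kruskal_wallis$n, r$kruskal_wallis$p),
    sprintf("seed: %d; package version: %s", r$config$seed,
            r$package_version))
  if (!is.null(r$speed)) {
    lines <- c(lines, sprintf("running speed ANOVA: p=%.4f", r$speed$anova$p))
  }
  lines
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Write small deterministic fixture files
#'
#' Generates a 4-subject x 4-condition x 3-trial x 2-side cohort (96 trials)
#' from a packaged fixed seed and writes it as `trials.csv` together with
#' its expected symmetry table (`symmetry_expected.csv`). The files
#' regenerate identically on every call.
#'
#' @param outdir Writable output directory.
#' @return Character vector of the file paths written.
#' @export
make_fixtures <- function(outdir) {
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  }
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  cfg <- synth_config(n_subjects = 4L, n_trials = 3L, seed = 20150813L)
  trials <- generate_cohort(cfg)$trials
  p1 <- file.path(outdir, "trials.csv")
  write_trials(trials, p1)
  st <- symmetry_table(trials)
  p2 <- file.path(outdir, "symmetry_expected.csv")
  utils::write.csv(as.data.frame(st), p2, row.names = FALSE)
  c(p1, p2)
}
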