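## End-to-end workflows: clonal reconstruction, survival summary and synergy
## scoring, with configuration objects, run logs and hash-stamped outputs.

#' Build and validate a run configuration
#'
#' Collects input paths, analysis thresholds and the seed for one pipeline
#' run. Thresholds are range-checked; the configuration round-trips through
#' YAML unchanged.
#'
#' @param scenario Name of a packaged scenario or path of a scenario YAML;
#'   when set, inputs are simulated instead of read from files.
#' @param mutations,segments,purity_table,survival_table,plates Input paths
#'   (mutation TSV/VCFs, SEG TSV, purity TSV with columns \code{sample_id}
#'   and \code{purity}, survival TSV, plate CSVs).
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed for all stochastic stages.
#' @param min_depth,min_cluster_size,merge_tol,clonal_threshold,
#'   absent_threshold,sum_rule_tol Analysis thresholds (see the stage
#'   functions for semantics and defaults).
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(scenario = NULL, mutations = NULL, segments = NULL,
                       purity_table = NULL, survival_table = NULL,
                       plates = NULL, out_dir = tempfile("clonevolve_run_"),
                       seed = 1L, min_depth = 20, min_cluster_size = 5,
                       merge_tol = 0.10, clonal_threshold = 0.85,
                       absent_threshold = 0.10, sum_rule_tol = 0.10) {
  cfg <- list(scenario = scenario, mutations = mutations,
              segments = segments, purity_table = purity_table,
              survival_table = survival_table, plates = plates,
              out_dir = out_dir, seed = as.integer(seed),
              min_depth = min_depth, min_cluster_size = min_cluster_size,
              merge_tol = merge_tol, clonal_threshold = clonal_threshold,
              absent_threshold = absent_threshold,
              sum_rule_tol = sum_rule_tol)
  in_range <- function(x, lo, hi) is.numeric(x) && x >= lo && x <= hi
  if (!in_range(cfg$min_depth, 1, 10000)) stop("min_depth out of range")
  if (!in_range(cfg$min_cluster_size, 1, 1000))
    stop("min_cluster_size out of range")
  if (!in_range(cfg$merge_tol, 0, 0.5)) stop("merge_tol out of range")
  if (!in_range(cfg$clonal_threshold, 0.5, 1))
    stop("clonal_threshold out of range")
  if (!in_range(cfg$absent_threshold, 0, 0.5))
    stop("absent_threshold out of range")
  if (!in_range(cfg$sum_rule_tol, 0, 0.5)) stop("sum_rule_tol out of range")
  class(cfg) <- "run_config"
  cfg
}

## Hash of the analytic configuration (inputs, thresholds, seed); the output
## location is excluded so reruns into different directories hash alike.
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  keep <- unclass(cfg)
  keep$out_dir <- NULL
  yaml::write_yaml(keep, tf)
  unname(tools::md5sum(tf))
}

write_stamped_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the clonal-evolution pipeline end to end
#'
#' Executes CCF computation, subclone deconvolution, clone-tree
#' reconstruction, per-biopsy composition and inter-lesion distances, and
#' writes all artifacts (CCF table, cluster and assignment tables,
#' composition table, distance matrix, Newick tree, JSON run log) to the
#' configured output directory. Errors carry a stage tag.
#'
#' @param config A \code{\link{run_config}}. Either \code{scenario} (inputs
#'   are simulated) or \code{mutations} + \code{purity_table} (and optionally
#'   \code{segments}) must be set.
#' @return Invisibly, the result bundle: \code{ccf} (ccf_matrix),
#'   \code{clusters}, \code{tree}, \code{compositions} (list per sample),
#'   \code{distances}, \code{newick}, \code{out_dir}.
#' @examples
#' \donttest{
#' cfg <- run_config(scenario = "p04_like", seed = 7)
#' bundle <- run_clonal(cfg)
#' bundle$compositions$peritoneal
#' }
#' @export
run_clonal <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$scenario)) {
    sc <- stage("simulate", {
      s <- build_scenario(config$scenario, seed = config$seed)
      s$seed <- config$seed
      s
    })
    calls <- stage("simulate", do.call(rbind, lapply(
      sc$samples$sample_id, function(s) simulate_biopsy(sc, s))))
    purities <- stats::setNames(sc$samples$purity, sc$samples$sample_id)
    segments <- NULL
  } else {
    if (is.null(config$mutations) || is.null(config$purity_table))
      stop("[input] mutation table and purity table required")
    calls <- stage("parse-mutations", {
      paths <- config$mutations
      do.call(rbind, lapply(paths, function(p)
        if (grepl("\\.vcf$", p)) read_mutation_vcf(p)
        else read_mutation_tsv(p)))
    })
    purities <- stage("parse-purity", {
      pt <- utils::read.delim(config$purity_table, stringsAsFactors = FALSE)
      stats::setNames(pt$purity, pt$sample_id)
    })
    segments <- if (!is.null(config$segments))
      stage("parse-segments", read_seg(config$segments)) else NULL
  }

  cm <- stage("ccf", ccf_matrix(calls, purities, segments,
                                min_depth = config$min_depth))
  cl <- stage("deconvolute", deconvolute(
    cm, min_cluster_size = config$min_cluster_size,
    merge_tol = config$merge_tol,
    clonal_threshold = config$clonal_threshold,
    absent_threshold = config$absent_threshold))
  tree <- stage("tree", build_tree(cl, tol = config$sum_rule_tol,
                                   clonal_threshold = config$clonal_threshold))
  comps <- stage("composition", {
    out <- lapply(cl$samples, function(s)
      composition(tree, s, absent_threshold = config$absent_threshold))
    names(out) <- cl$samples
    out
  })
  dmat <- stage("distance", distance_matrix(cm))
  nwk <- to_newick(tree)

  ccf_df <- data.frame(cm$info, cm$ccf, check.names = FALSE)
  write_stamped_tsv(ccf_df, file.path(config$out_dir, "ccf.tsv"), hash)
  write_stamped_tsv(cl$clusters, file.path(config$out_dir, "clusters.tsv"),
                    hash)
  write_stamped_tsv(
    data.frame(key = names(cl$assignment), cluster = cl$assignment,
               row.names = NULL),
    file.path(config$out_dir, "assignments.tsv"), hash)
  comp_df <- do.call(rbind, lapply(names(comps), function(s)
    if (length(comps[[s]]))
      data.frame(sample_id = s, clone = names(comps[[s]]),
                 fraction = unname(comps[[s]])) else NULL))
  write_stamped_tsv(comp_df, file.path(config$out_dir, "composition.tsv"),
                    hash)
  write_stamped_tsv(data.frame(sample_id = rownames(dmat), dmat,
                               check.names = FALSE),
                    file.path(config$out_dir, "distances.tsv"), hash)
  writeLines(nwk, file.path(config$out_dir, "tree.nwk"))
  write_run_log(config, hash, "clonal")

  invisible(list(ccf = cm, clusters = cl, tree = tree,
                 compositions = comps, distances = dmat, newick = nwk,
                 out_dir = config$out_dir))
}

#' Run the survival stage: Kaplan-Meier curve, median and summary
#'
#' @param config A \code{\link{run_config}} with \code{survival_table} set,
#'   or \code{records} passed directly.
#' @param records Optional survival record data frame (overrides the file);
#'   defaults to \code{\link{packaged_survival_table}} when no file is
#'   configured.
#' @return Invisibly: \code{curve} (km_curve), \code{median_days},
#'   \code{median_months}, \code{out_dir}.
#' @export
run_survival <- function(config, records = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(records)) {
    records <- if (!is.null(config$survival_table))
      stage("parse-survival", read_survival_tsv(config$survival_table))
    else packaged_survival_table()
  }
  if (!nrow(records)) stop("[survival] empty survival table")
  km <- stage("survival", km_estimate(records))
  med <- km_median(km)
  write_stamped_tsv(km$table, file.path(config$out_dir, "km_curve.tsv"),
                    hash)
  summary <- list(
    n = nrow(records), events = sum(records$event),
    median_days = if (is.na(med)) "undefined" else med,
    median_months = if (is.na(med)) "undefined"
                    else round(days_to_months(med), 2),
    config_hash = hash)
  jsonlite::write_json(summary, file.path(config$out_dir, "km_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_log(config, hash, "survival")
  invisible(list(curve = km, median_days = med,
                 median_months = days_to_months(med),
                 out_dir = config$out_dir))
}

#' Run the synergy stage over replicate plates (or a layered stack)
#'
#' Normalizes each plate, scores ZIP synergy per plate and reports the mean
#' and SD of the top-9 summary across replicates. When \code{layered = TRUE}
#' the plates are treated as a third-drug dose stack and scored per layer.
#'
#' @param config A \code{\link{run_config}} with \code{plates} set, or
#'   \code{matrices} supplied directly.
#' @param matrices Optional list of \code{dose_matrix} objects (overrides the
#'   plate files).
#' @param layered Score the plates as a 3-D stack (default FALSE).
#' @param conc_c Third-drug doses for a layered stack.
#' @return Invisibly: per-plate \code{results}, \code{summaries},
#'   \code{mean}, \code{sd}, \code{out_dir}.
#' @export
run_synergy <- function(config, matrices = NULL, layered = FALSE,
                        conc_c = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(matrices)) {
    if (is.null(config$plates)) stop("[input] no plates configured")
    matrices <- stage("parse-plates",
                      lapply(config$plates, read_plate_csv))
  }
  if (layered) {
    res <- stage("synergy", zip_delta_3d(
      matrices, conc_c = conc_c %||% (seq_along(matrices) - 1)))
    report <- list(layer_summaries = res$summaries,
                   y_c = res$y_c, config_hash = hash)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "synergy_3d.json"),
                         auto_unbox = TRUE, digits = NA)
    write_run_log(config, hash, "synergy3d")
    return(invisible(c(res, list(out_dir = config$out_dir))))
  }
  results <- stage("synergy", lapply(matrices, zip_delta))
  summaries <- vapply(results, `[[`, 0, "summary")
  for (i in seq_along(results))
    write_stamped_tsv(as.data.frame(results[[i]]$delta),
                      file.path(config$out_dir,
                                sprintf("zip_delta_%02d.tsv", i)), hash)
  report <- list(summaries = summaries, mean = mean(summaries),
                 sd = if (length(summaries) > 1) stats::sd(summaries)
                      else NA, config_hash = hash)
  jsonlite::write_json(report, file.path(config$out_dir, "synergy.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_log(config, hash, "synergy")
  invisible(list(results = results, summaries = summaries,
                 mean = mean(summaries),
                 sd = if (length(summaries) > 1) stats::sd(summaries)
                      else NA_real_,
                 out_dir = config$out_dir))
}

write_run_log <- function(config, hash, stage_name) {
  log <- list(stage = stage_name,
              package_version =
                as.character(utils::packageVersion("clonevolve")),
              r_version = as.character(getRversion()),
              seed = config$seed,
              thresholds = unclass(config)[c(
                "min_depth", "min_cluster_size", "merge_tol",
                "clonal_threshold", "absent_threshold", "sum_rule_tol")],
              config_hash = hash)
  jsonlite::write_json(log,
                       file.path(config$out_dir,
                                 paste0("run_log_", stage_name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
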