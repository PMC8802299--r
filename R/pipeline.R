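#' Default pipeline configuration
#'
#' Bundles every tunable of the full analysis into one object: the
#' synthetic-data generator settings (used when no input files are given),
#' the quality threshold, calibrator and reference genes of the expression
#' stage, the clustering settings, and the correlation window. Every
#' parameter is echoed into the run manifest written by [run_all()].
#'
#' @param seed integer master seed for the run.
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1) {
  sim <- default_sim_config(seed)
  structure(list(
    sim = sim,
    qc_threshold = 0.65,
    reference_genes = c("REF1", "REF2", "REF3"),
    calibrator = paste0("101_", sim$sampling$cultivars[1]),
    season_start = sim$sampling$first_date,
    ch_band = c(low = 0, high = 7.2),
    gdh = gdh_params(),
    k = 6L,
    n_starts = 25L,
    wss_k_range = c(2L, 9L),
    window_days = 14L,
    seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the complete dormancy analysis pipeline
#'
#' Executes the stages chill accumulation, phenology, expression
#' quantification, clustering and correlation in order, on either supplied
#' input data or (by default) a dataset from the built-in generator, and
#' writes every result plus a run manifest to `out_dir`. The whole run is
#' reproducible from the configuration alone: identical config and seed
#' give byte-identical output files.
#'
#' @param config a [default_config()] list.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param data optional list with elements `series`, `forcing`, `budbreak`,
#'   `ct` to analyse measured data instead of simulating; any missing
#'   element falls back to the generator.
#' @return Invisible list with elements `data`, `accumulations`,
#'   `phenology`, `qc`, `rel_expr`, `profiles`, `clustering`, `wss`,
#'   `covariates`, `correlations`, `manifest`.
#' @export
run_all <- function(config = default_config(), out_dir = NULL, data = NULL) {
  stage <- "simulate"
  result <- tryCatch({
    sim <- NULL
    need_sim <- is.null(data) ||
      !all(c("series", "forcing", "budbreak", "ct") %in% names(data))
    if (need_sim) sim <- simulate_dataset(config$sim)
    series <- if (!is.null(data$series)) data$series else sim$series
    forcing <- if (!is.null(data$forcing)) data$forcing else sim$forcing
    budbreak <- if (!is.null(data$budbreak)) data$budbreak else
      data.frame(cultivar = sim$events$cultivar,
                 budbreak_start = sim$events$budbreak_date,
                 budbreak_end = pmin(sim$events$budbreak_date + 7,
                                     as.Date(max(sim$series$timestamp),
                                             tz = "UTC")))
    ct <- if (!is.null(data$ct)) data$ct else sim$ct

    stage <- "chill"
    acc <- list(CH = chilling_hours(series, low = config$ch_band[["low"]],
                                    high = config$ch_band[["high"]]),
                CP = chill_portions(series),
                GDH = growing_degree_hours(series, config$gdh))

    stage <- "phenology"
    phen <- phenology_events(series, forcing, budbreak,
                             season_start = config$season_start,
                             gdh = config$gdh)

    stage <- "expression"
    if (is.null(config$calibrator) || !nzchar(config$calibrator))
      stop("no calibrator sample configured", call. = FALSE)
    qc <- qc_filter(ct, threshold = config$qc_threshold)
    refs <- intersect(config$reference_genes, qc$kept$gene)
    if (length(refs) == 0L)
      stop("no configured reference gene survived quality filtering",
           call. = FALSE)
    stability <- reference_stability(qc$kept, refs)
    rel <- delta_delta_ct(qc$kept, refs, config$calibrator)
    profiles <- summarize_profiles(rel)

    stage <- "cluster"
    features <- build_feature_matrix(profiles)
    clustering <- kmeans_best_of_n(features, k = config$k,
                                   n_starts = config$n_starts,
                                   seed = config$seed)
    wss <- wss_curve(features, k_min = config$wss_k_range[1],
                     k_max = config$wss_k_range[2],
                     n_starts = config$n_starts, seed = config$seed)

    stage <- "correlate"
    covariates <- build_covariates(series, unique(profiles$date),
                                   window_days = config$window_days,
                                   ch_low = config$ch_band[["low"]],
                                   ch_high = config$ch_band[["high"]])
    correlations <- correlate(profiles, covariates, grouping = "both")

    list(data = list(series = series, forcing = forcing,
                     budbreak = budbreak, ct = ct,
                     truth = sim$truth, events = sim$events),
         accumulations = acc, phenology = phen, qc = qc,
         stability = stability, rel_expr = rel, profiles = profiles,
         clustering = clustering, wss = wss, covariates = covariates,
         correlations = correlations)
  }, error = function(e) {
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  result$manifest <- build_manifest(config, result)
  if (!is.null(out_dir)) write_bundle(result, out_dir)
  invisible(result)
}

build_manifest <- function(config, result) {
  list(
    package = "buddorm",
    version = as.character(utils::packageVersion("buddorm")),
    seed = config$seed,
    parameters = list(
      qc_threshold = config$qc_threshold,
      reference_genes = config$reference_genes,
      calibrator = config$calibrator,
      season_start = format(as.Date(config$season_start)),
      ch_band = as.list(config$ch_band),
      gdh = unclass(config$gdh),
      dynamic_model = unclass(dynamic_model_params()),
      k = config$k, n_starts = config$n_starts,
      window_days = config$window_days),
    exclusions = result$qc$exclusions,
    n_genes_clustered = length(result$clustering$assignments),
    wss_elbow = attr(result$wss, "elbow"))
}

write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_temperature_csv(result$data$series, p("temperature.csv"))
  write_ct_csv(result$data$ct, p("ct.csv"))
  utils::write.csv(result$data$forcing, p("forcing.csv"),
                   row.names = FALSE, quote = FALSE)
  for (m in names(result$accumulations))
    write_accumulation_csv(result$accumulations[[m]],
                           p(sprintf("accumulation_%s.csv", tolower(m))))
  utils::write.csv(result$phenology, p("phenology.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$stability, p("reference_stability.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$rel_expr, p("relative_expression.csv"),
                   row.names = FALSE, quote = FALSE, na = "NA")
  write_profile_csv(result$profiles, p("profiles.csv"))
  utils::write.csv(
    data.frame(gene = names(result$clustering$assignments),
               cluster = as.integer(result$clustering$assignments)),
    p("cluster_assignments.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(cluster = seq_len(result$clustering$k),
               result$clustering$centroids, check.names = FALSE),
    p("cluster_centroids.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(result$wss, p("wss_curve.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$covariates, p("covariates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$correlations, p("correlations.csv"),
                   row.names = FALSE, quote = FALSE, na = "NA")
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
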