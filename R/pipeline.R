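#' Run configuration
#'
#' Validates and normalizes the settings for [run_pipeline()]. Any
#' setting may come from a YAML config file (see the CLI in
#' `inst/cli/mutprop.R`) or be passed directly.
#'
#' @param property_table path to the property TSV (default: the packaged
#'   synthetic 49-property table).
#' @param mutations path to the mutant CSV (required for `correlate`,
#'   `search`, `classify`).
#' @param fasta optional receptor FASTA path.
#' @param pdb optional PDB path; `chain`, `offset` select/align the chain.
#' @param chain,offset PDB chain id and resno-to-position offset.
#' @param encodings feature encodings for correlate/search.
#' @param k half-window size; `radius` contact radius in Angstrom.
#' @param scale `"normalized"` or `"raw"`.
#' @param sizes subset sizes for `search`.
#' @param top_m ranked combinations to report.
#' @param allow_saturated permit N < s + 2 fits.
#' @param max_fits search-space refusal ceiling.
#' @param methods classifier methods for `classify`.
#' @param knn_k k-nearest-neighbor size.
#' @param seed integer seed for all stochastic steps.
#' @param n_mutants,n_properties,class_margin,noise_sd simulate settings
#'   (see [simulation_config()]).
#' @param outdir output directory (created if absent).
#' @return list of class `run_config`.
#' @export
run_config <- function(property_table = NULL, mutations = NULL, fasta = NULL,
                       pdb = NULL, chain = NULL, offset = 0L,
                       encodings = "delta", k = 1L, radius = 8.0,
                       scale = "normalized",
                       sizes = 1:3, top_m = 10, allow_saturated = FALSE,
                       max_fits = 5e6,
                       methods = CLASSIFIER_METHODS, knn_k = 3L,
                       seed = 1L,
                       n_mutants = 28L, n_properties = 49L,
                       class_margin = 0.5, noise_sd = 0.05,
                       outdir = ".") {
  if (is.null(property_table)) {
    property_table <- system.file("extdata", "aa_properties_synthetic49.tsv",
                                  package = "mutprop")
  }
  cfg <- list(property_table = property_table, mutations = mutations,
              fasta = fasta, pdb = pdb, chain = chain,
              offset = as.integer(offset),
              encodings = encodings, k = as.integer(k), radius = radius,
              scale = scale, sizes = as.integer(sizes), top_m = top_m,
              allow_saturated = isTRUE(allow_saturated), max_fits = max_fits,
              methods = methods, knn_k = as.integer(knn_k),
              seed = as.integer(seed),
              n_mutants = as.integer(n_mutants),
              n_properties = as.integer(n_properties),
              class_margin = class_margin, noise_sd = noise_sd,
              outdir = outdir)
  for (p in c("property_table", "mutations", "fasta", "pdb")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop(errorCondition(sprintf("config_error: %s path does not exist: %s",
                                  p, cfg[[p]]),
                          class = c("mutprop_config_error", "error")))
    }
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("config_error: config file not found: ", path),
                        class = c("mutprop_config_error", "error")))
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop(errorCondition(paste0("config_error: unknown config key(s): ",
                               paste(unknown, collapse = ", ")),
                        class = c("mutprop_config_error", "error")))
  }
  do.call(run_config, vals)
}

load_pipeline_inputs <- function(config) {
  table <- load_property_table(config$property_table)
  sequence <- if (!is.null(config$fasta)) read_receptor_sequence(config$fasta)
  struct <- if (!is.null(config$pdb))
    read_structure_pdb(config$pdb, chain = config$chain, offset = config$offset)
  dataset <- read_mutation_table(config$mutations, sequence = sequence,
                                 structure = struct)
  list(table = table, dataset = dataset)
}

#' Run one pipeline stage end to end
#'
#' Chains the package stages into four commands and writes their result
#' files (plus a YAML run log capturing every setting, N, p and the
#' search-space size) to `config$outdir`:
#' \describe{
#'   \item{`correlate`}{single-property correlations of every requested
#'     encoding column with the response -> `correlations.tsv`}
#'   \item{`search`}{exhaustive best-subset regression ->
#'     `search_report.tsv`/`.json` and `predictions.tsv`
#'     (observed vs predicted under the best model)}
#'   \item{`classify`}{increase/decrease discrimination, self-consistency
#'     and jack-knife for every bundled method ->
#'     `evaluation_report.tsv`/`.json`}
#'   \item{`simulate`}{synthetic property table, mutant CSV, FASTA and
#'     labelled set written to `outdir` for use by the other commands}
#' }
#' All outputs are deterministic given the seed.
#'
#' @param config a [run_config] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @param command one of `"correlate"`, `"search"`, `"classify"`,
#'   `"simulate"`.
#' @return invisibly, the command's main result object.
#' @export
run_pipeline <- function(config, command = c("correlate", "search",
                                             "classify", "simulate")) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (command != "simulate" && is.null(config$mutations)) {
    stop(errorCondition("config_error: 'mutations' CSV is required",
                        class = c("mutprop_config_error", "error")))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  log <- list(command = command,
              settings = unclass(config),
              warnings = character(0))
  result <- withCallingHandlers(
    switch(
      command,
      correlate = {
        inp <- load_pipeline_inputs(config)
        fm <- build_feature_matrix(inp$dataset, inp$table,
                                   encodings = config$encodings,
                                   k = config$k, radius = config$radius,
                                   scale = config$scale)
        rep <- correlate_all(fm, inp$dataset$records$response)
        utils::write.table(rep$results, out("correlations.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        log$N <- nrow(fm); log$p <- ncol(fm)
        log$skipped_columns <- rep$skipped
        rep
      },
      search = {
        inp <- load_pipeline_inputs(config)
        fm <- build_feature_matrix(inp$dataset, inp$table,
                                   encodings = config$encodings,
                                   k = config$k, radius = config$radius,
                                   scale = config$scale)
        y <- inp$dataset$records$response
        rep <- exhaustive_subset_search(fm, y, sizes = config$sizes,
                                        top_m = config$top_m,
                                        allow_saturated = config$allow_saturated,
                                        max_fits = config$max_fits)
        write_search_report(rep, out("search_report.tsv"),
                            out("search_report.json"))
        pred <- predict(rep$best, fm)
        utils::write.table(
          data.frame(mutant = rownames(fm), observed = y, predicted = pred),
          out("predictions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        log$N <- rep$N; log$p <- rep$p
        log$search_space <- rep$search_space
        rep
      },
      classify = {
        inp <- load_pipeline_inputs(config)
        labeled <- encode_for_classification(inp$dataset, inp$table,
                                             inp$table$property_ids[
                                               seq_len(min(3, length(inp$table$property_ids)))],
                                             k = config$k, scale = config$scale)
        rep <- evaluate_classifiers(labeled, methods = config$methods,
                                    seed = config$seed, knn_k = config$knn_k)
        write_evaluation_report(rep, out("evaluation_report.tsv"),
                                out("evaluation_report.json"))
        log$N <- length(labeled$labels); log$p <- ncol(labeled$features)
        rep
      },
      simulate = {
        table <- simulate_property_table(config$n_properties, seed = config$seed)
        cfg <- simulation_config(seed = config$seed,
                                 n_mutants = config$n_mutants,
                                 n_properties = config$n_properties,
                                 noise_sd = config$noise_sd,
                                 class_margin = config$class_margin,
                                 k = config$k, radius = config$radius)
        ds <- simulate_mutation_dataset(table, cfg)
        write_property_table(table, out("properties.tsv"))
        write_mutation_table(ds, out("mutations.csv"))
        write_sequence_fasta(ds$sequence, out("receptor.fasta"))
        gt <- attr(ds, "ground_truth")
        yaml::write_yaml(list(true_subset = gt$true_subset,
                              beta0 = gt$beta0, beta = gt$beta,
                              noise_sd = gt$noise_sd, encoding = gt$encoding,
                              k = gt$k, seed = gt$seed),
                         out("ground_truth.yaml"))
        log$N <- config$n_mutants; log$p <- config$n_properties
        ds
      }
    ),
    warning = function(w) {
      log$warnings <<- c(log$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  yaml::write_yaml(log, out("run_log.yaml"))
  invisible(result)
}
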