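# Orchestration: stage runners behind a single validated run configuration,
# with TSV report tables mirroring the analysis layouts (per-gene coefficient
# and inference tables, per-fold CV coefficients, method comparison) and JSON
# run manifests for reproducibility.

#' Build and validate a run configuration
#'
#' A configuration either names input files (`annotation`, `tracks`,
#' `expression`) or contains a `simulate` block (arguments to
#' [generative_config()]); exactly one of the two. All other fields have
#' defaults. Can be given as a list or a path to a YAML file.
#'
#' @param x A list or a YAML file path.
#' @return A validated list of class `pc_run_config`.
#' @export
run_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(paste0("config file does not exist: ", x))
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) abort("config must be a list or a YAML file path")
  has_inputs <- !is.null(x$inputs)
  has_sim <- !is.null(x$simulate)
  if (has_inputs == has_sim) {
    abort("config must contain exactly one of 'inputs' or 'simulate'")
  }
  defaults <- list(
    promoter = list(upstream = 1500, downstream = 500),
    min_height = 1,
    annotation_format = "bed6",
    models = c(1, 2, 3, 4),
    stepwise = NULL,
    fraction = 0.3,
    cv = list(k = 10, seed = 1),
    threshold_rule = "global",
    evaluate = "all",
    out_dir = "peakcourse_run",
    seed = 1
  )
  config <- utils::modifyList(defaults, x)
  if (has_sim) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    config$simulate <- do.call(generative_config, sim_args)
  } else {
    needed <- c("annotation", "tracks", "expression")
    missing <- setdiff(needed, names(config$inputs))
    if (length(missing) > 0) {
      abort(paste0("inputs block missing: ", paste(missing, collapse = ", ")))
    }
  }
  structure(config, class = "pc_run_config")
}

#' Write a commented YAML configuration template
#'
#' @param path Destination file.
#' @return The path, invisibly.
#' @export
write_config_template <- function(path) {
  writeLines(c(
    "# peakcourse run configuration",
    "# Exactly one of 'inputs' or 'simulate' must be present.",
    "#",
    "# inputs:",
    "#   annotation: genes.bed        # BED6 or GTF (set annotation_format: gtf)",
    "#   expression: expression.tsv   # TSV: gene_id, day, expression",
    "#   tracks:                      # one bedGraph per day, keyed by day",
    "#     0: day00.bedGraph",
    "#     1: day01.bedGraph",
    "simulate:",
    "  n_genes: 30",
    "  noise_sd: 0.01",
    "promoter:",
    "  upstream: 1500                 # bp upstream of the TSS",
    "  downstream: 500                # bp downstream of the TSS",
    "min_height: 1                    # signal threshold for peak derivation",
    "models: [1, 2, 3, 4]             # model ids to fit",
    "# stepwise:                      # enable stepwise term selection",
    "#   criterion: aic               # aic or pvalue",
    "fraction: 0.3                    # high/low group fraction",
    "cv:",
    "  k: 10",
    "  seed: 1",
    "threshold_rule: global           # global or training",
    "evaluate: all                    # all or extremes",
    "out_dir: peakcourse_run",
    "seed: 1"
  ), path)
  invisible(path)
}

# Internal: write a stage manifest (config + outputs + hashes).
write_stage_manifest <- function(config, stage, outputs, dir) {
  manifest <- file.path(dir, paste0(stage, "_manifest.json"))
  cfg <- unclass(config)
  if (inherits(cfg$simulate, "pc_config")) cfg$simulate <- unclass(cfg$simulate)
  jsonlite::write_json(
    list(
      stage = stage,
      package_version = as.character(utils::packageVersion("peakcourse")),
      config = cfg,
      outputs = as.list(setNames(
        unname(tools::md5sum(outputs)), basename(outputs)
      ))
    ),
    manifest,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest
}

#' Run the extraction stage
#'
#' With a `simulate` block: generates the synthetic dataset, writes its
#' genomic artifacts under `out_dir/simulated`, and reads them back through
#' the I/O pipeline (so the extraction path is genuinely exercised). With an
#' `inputs` block: reads the named annotation, per-day tracks and expression
#' table. Writes `features.tsv`, the joined `records.tsv` and a stage
#' manifest into `out_dir`.
#'
#' @param config A [run_config()] (or something coercible by it).
#' @return The joined records tibble, invisibly.
#' @export
run_extract <- function(config) {
  config <- if (inherits(config, "pc_run_config")) config else run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$simulate)) {
    sim <- generate_timecourse(config$simulate)
    paths <- write_genomic_artifacts(sim, file.path(config$out_dir, "simulated"))
    genes <- read_gene_annotation(paths$annotation, "bed6")
    tracks <- paths$tracks
    expression <- read_expression(paths$expression)
    # Synthetic tracks have no background signal; any positive threshold
    # recovers the written peaks.
    min_height <- min(config$min_height, min(sim$records$height) / 2)
  } else {
    genes <- read_gene_annotation(config$inputs$annotation, config$annotation_format)
    tracks <- unlist(config$inputs$tracks)
    expression <- read_expression(config$inputs$expression)
    min_height <- config$min_height
  }
  features <- purrr::map_dfr(names(tracks), function(d) {
    extract_features(
      read_bedgraph(tracks[[d]]), genes,
      day = as.integer(d),
      upstream = config$promoter$upstream,
      downstream = config$promoter$downstream,
      min_height = min_height
    )
  })
  records <- join_expression(features, expression)
  features_path <- file.path(config$out_dir, "features.tsv")
  records_path <- file.path(config$out_dir, "records.tsv")
  readr::write_tsv(features, features_path, progress = FALSE)
  readr::write_tsv(records, records_path, progress = FALSE)
  write_stage_manifest(config, "extract", c(features_path, records_path), config$out_dir)
  invisible(records)
}

#' Run the model-fitting stage
#'
#' Reads `records.tsv` from `out_dir`, fits every requested model per gene
#' and pooled across genes, and writes the coefficient table (`fits.tsv`),
#' the inference table (`inference.tsv`: adjusted R-squared, F-test p-value
#' and per-coefficient p-values), a per-model goodness-of-fit comparison
#' (`model_comparison.tsv`), and, when a `stepwise` block is configured, the
#' selected term list (`selected_terms.txt`).
#'
#' @param config A [run_config()].
#' @return A list of the written tibbles, invisibly.
#' @export
run_fit <- function(config) {
  config <- if (inherits(config, "pc_run_config")) config else run_config(config)
  records_path <- file.path(config$out_dir, "records.tsv")
  if (!file.exists(records_path)) {
    abort(paste0("records.tsv not found in ", config$out_dir, "; run run_extract() first"))
  }
  records <- readr::read_tsv(records_path, show_col_types = FALSE, progress = FALSE)

  per_model <- purrr::map(config$models, function(m) {
    per_gene <- fit_per_gene(records, model = m)
    pooled <- fit_expression_model(records, model = m)
    pooled_row <- tibble(
      gene_id = "(pooled)", model = as.character(m),
      beta1 = pooled$beta[[1]], beta2 = pooled$beta[[2]], beta3 = pooled$beta[[3]],
      intercept = pooled$intercept,
      adj_r_squared = pooled$adj_r_squared,
      f_stat = pooled$f_stat, f_pvalue = pooled$f_pvalue,
      p1 = pooled$t_pvalues[1], p2 = pooled$t_pvalues[2], p3 = pooled$t_pvalues[3]
    )
    dplyr::bind_rows(per_gene, pooled_row)
  })
  all_fits <- dplyr::bind_rows(per_model)

  fits <- all_fits[c("gene_id", "model", "beta1", "beta2", "beta3", "intercept")]
  inference <- all_fits[c("gene_id", "model", "adj_r_squared", "f_stat", "f_pvalue", "p1", "p2", "p3")]
  comparison <- all_fits |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      mean_adj_r_squared = mean(.data$adj_r_squared[.data$gene_id != "(pooled)"]),
      pooled_adj_r_squared = .data$adj_r_squared[.data$gene_id == "(pooled)"],
      .groups = "drop"
    )

  fits_path <- file.path(config$out_dir, "fits.tsv")
  inference_path <- file.path(config$out_dir, "inference.tsv")
  comparison_path <- file.path(config$out_dir, "model_comparison.tsv")
  readr::write_tsv(fits, fits_path, progress = FALSE)
  readr::write_tsv(inference, inference_path, progress = FALSE)
  readr::write_tsv(comparison, comparison_path, progress = FALSE)
  outputs <- c(fits_path, inference_path, comparison_path)

  selected <- NULL
  if (!is.null(config$stepwise)) {
    criterion <- config$stepwise$criterion %||% "aic"
    selected <- stepwise_select(records, criterion = criterion)
    selected_path <- file.path(config$out_dir, "selected_terms.txt")
    writeLines(selected, selected_path)
    outputs <- c(outputs, selected_path)
  }
  write_stage_manifest(config, "fit", outputs, config$out_dir)
  invisible(list(
    fits = fits, inference = inference, comparison = comparison,
    selected_terms = selected
  ))
}

#' Run the classification stage
#'
#' Reads `records.tsv`, min-max normalizes height, distance, width and
#' expression, and evaluates the Model-4 threshold classifier and the
#' back-propagation baseline under identical seeded folds. Writes `cv.tsv`
#' (per-fold regression coefficients and fitted disturbance) and
#' `metrics.tsv` (one row per method: Acc, Sn, Sp, Mcc).
#'
#' @param config A [run_config()].
#' @return A list with the CV object and the metrics tibble, invisibly.
#' @export
run_classify <- function(config) {
  config <- if (inherits(config, "pc_run_config")) config else run_config(config)
  records_path <- file.path(config$out_dir, "records.tsv")
  if (!file.exists(records_path)) {
    abort(paste0("records.tsv not found in ", config$out_dir, "; run run_extract() first"))
  }
  records <- readr::read_tsv(records_path, show_col_types = FALSE, progress = FALSE)
  if (config$cv$k > nrow(records)) {
    abort(paste0("cv k = ", config$cv$k, " exceeds the ", nrow(records), " available samples"))
  }
  normalized <- min_max_normalize(records)
  cv <- kfold_cv(normalized,
    k = config$cv$k, seed = config$cv$seed, model = 4,
    fraction = config$fraction, threshold_rule = config$threshold_rule,
    evaluate = config$evaluate
  )
  metrics <- compare_classifiers(normalized,
    k = config$cv$k, seed = config$cv$seed, model = 4,
    fraction = config$fraction, threshold_rule = config$threshold_rule,
    evaluate = config$evaluate
  )
  cv_path <- file.path(config$out_dir, "cv.tsv")
  metrics_path <- file.path(config$out_dir, "metrics.tsv")
  readr::write_tsv(tidy(cv), cv_path, progress = FALSE)
  readr::write_tsv(metrics, metrics_path, progress = FALSE)
  write_stage_manifest(config, "classify", c(cv_path, metrics_path), config$out_dir)
  invisible(list(cv = cv, metrics = metrics))
}

#' Run every stage
#'
#' [run_extract()], then [run_fit()], then [run_classify()].
#'
#' @param config A [run_config()].
#' @return The [run_classify()] result, invisibly.
#' @export
run_all <- function(config) {
  config <- if (inherits(config, "pc_run_config")) config else run_config(config)
  run_extract(config)
  run_fit(config)
  invisible(run_classify(config))
}
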