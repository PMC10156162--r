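#' Run the full denoising pipeline
#'
#' Orchestrates ingest, contig filtering, clonotype collapsing and
#' imputation, hashing demultiplexing, expected-binder inference, UMI
#' threshold grid search, the filter cascade and the evaluation report.
#' Every stage's GEM table is written to the output directory, plus the
#' per-step report, the grid audit and a JSON manifest; re-running with the
#' same inputs and seed reproduces all numeric outputs.
#'
#' @param contigs Path to a contig annotation CSV, or a prepared contig
#'   tibble.
#' @param features Named list `matrix`, `features`, `barcodes` of
#'   feature-count paths (as produced by the vendor pipeline or
#'   [write_tenx_inputs()]), or a long feature-count tibble from
#'   [read_feature_counts()].
#' @param panel Panel CSV path or tibble.
#' @param samples Sample CSV path or tibble.
#' @param out_dir Output directory.
#' @param steps Filter cascade steps, in order.
#' @param thresholds Optional fixed [umi_thresholds()]; when `NULL` the grid
#'   search selects them.
#' @param seed Seed used for hashing demultiplexing and similarity
#'   sampling.
#' @param min_gems,alpha Expected-binder parameters.
#' @param include_auc Compute similarity AUC per stage (slower).
#' @param write_grid_audit Write the full grid evaluation CSV.
#' @return List `dataset` (final filtered), `report`, `grid` (the
#'   `grid_search_result` or `NULL`), `expected`, `manifest` (also written
#'   as JSON).
#' @export
run_pipeline <- function(contigs, features, panel, samples,
                         out_dir = ".",
                         steps = c("umi_thresholds", "hla_match"),
                         thresholds = NULL, seed = 1L,
                         min_gems = 10L, alpha = 0.05,
                         include_auc = FALSE, write_grid_audit = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  panel_tbl <- if (is.character(panel)) read_panel(panel) else as_tibble(panel)
  samples_tbl <- if (is.character(samples)) read_samples(samples) else
    as_tibble(samples)
  contig_tbl <- if (is.character(contigs)) {
    read_contig_annotations(contigs)
  } else {
    as_tibble(contigs)
  }
  feat_tbl <- if (is.list(features) && !is.data.frame(features)) {
    read_feature_counts(features$matrix, features$features,
                        features$barcodes)
  } else {
    as_tibble(features)
  }
  pmhc <- feat_tbl |>
    filter(.data$feature_type == "pmhc") |>
    select(all_of(c("gem_id", "feature_id", "umi"))) |>
    rename(pmhc_id = "feature_id")
  hash <- feat_tbl |>
    filter(.data$feature_type == "hashing") |>
    select(all_of(c("gem_id", "feature_id", "umi"))) |>
    rename(hash_id = "feature_id")

  ds <- assemble_dataset(contigs = filter_contigs(contig_tbl),
                         pmhc = pmhc, hash = hash,
                         panel = panel_tbl, samples = samples_tbl)
  ds <- select_dominant_chains(ds)
  ds <- collapse_and_impute_clonotypes(ds)
  if (nrow(ds$hash) > 0) {
    ds <- demultiplex_hashing(ds, seed = seed)
  }
  write_gem_table(ds, file.path(out_dir, "gems_total.csv"), "total")

  expected <- expected_binders(ds, min_gems = min_gems, alpha = alpha)
  readr::write_csv(expected, file.path(out_dir, "expected_binders.csv"))
  conc <- binding_concordance(ds)
  readr::write_csv(conc, file.path(out_dir, "binding_concordance.csv"))

  grid <- NULL
  if (is.null(thresholds) && "umi_thresholds" %in% steps) {
    grid <- grid_search_thresholds(ds, expected, audit = write_grid_audit)
    thresholds <- grid$thresholds
    if (write_grid_audit) {
      readr::write_csv(grid$grid, file.path(out_dir, "grid_audit.csv"))
    }
  }
  if (is.null(thresholds)) thresholds <- umi_thresholds()

  config <- filter_config(steps = steps, thresholds = thresholds)
  chain <- apply_filter_chain(ds, config, expected = expected)
  write_gem_table(chain$dataset, file.path(out_dir, "gems_filtered.csv"),
                  paste(steps, collapse = "+"))
  report <- chain$report
  if (include_auc) {
    report$auc <- vapply(seq_len(nrow(report)), function(i) {
      NA_real_
    }, numeric(1))
    report$auc[1] <- compute_report(ds, "total", expected,
                                    include_auc = TRUE, seed = seed)$auc
    report$auc[nrow(report)] <-
      compute_report(chain$dataset, "final", expected,
                     n_total_gems = nrow(ds$gems), include_auc = TRUE,
                     seed = seed)$auc
  }
  readr::write_csv(report, file.path(out_dir, "filter_report.csv"))

  manifest <- list(
    seed = seed,
    n_gems_total = nrow(ds$gems),
    n_clonotypes_total = nrow(ds$clonotypes),
    thresholds = list(min_umi = as.list(thresholds$min_umi),
                      min_ratio = as.list(thresholds$min_ratio)),
    grid_objective = if (!is.null(grid)) grid$objective else NULL,
    stages = lapply(seq_len(nrow(report)), function(i) {
      as.list(report[i, ])
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(dataset = chain$dataset, report = report, grid = grid,
       expected = expected, manifest = manifest)
}
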