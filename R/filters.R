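#' Filter GEMs on UMI count and ratio thresholds
#'
#' Retains GEMs that, for each feature class with a nonzero threshold, have
#' a top UMI count `>=` the count threshold and a UMI ratio strictly `>` the
#' ratio threshold. A ratio threshold of 1 removes GEMs where two features
#' are equally abundant at low counts (a tie of 3 vs 3 scores
#' 3 / 3.25 = 0.923 <= 1).
#'
#' @param ds A `gem_dataset`.
#' @param thresholds A [umi_thresholds()] object.
#' @return The filtered dataset.
#' @export
filter_umi_thresholds <- function(ds, thresholds) {
  stopifnot(inherits(thresholds, "umi_thresholds"))
  feats <- gem_feature_summaries(ds)
  keep <- feats$gem_id[threshold_pass(feats, thresholds)]
  subset_gems(ds, keep)
}

#' Filter GEMs on HLA haplotype match
#'
#' Retains GEMs whose top pMHC's restricting HLA allele belongs to the
#' haplotype of the GEM's donor, as assigned by hashing. For hashing
#' doublets the union of the implicated donors' haplotypes is used (such
#' GEMs are flagged in `ds$gems$hla_doublet_union`); hashing-negative GEMs
#' and GEMs with a tied top pMHC are removed.
#'
#' @param ds A `gem_dataset` with `hash_calls` (run [demultiplex_hashing()]
#'   first).
#' @return The filtered dataset.
#' @export
filter_hla_match <- function(ds) {
  if (is.null(ds$hash_calls)) {
    stop("run demultiplex_hashing() before filtering on HLA match",
         call. = FALSE)
  }
  if (any(lengths(ds$samples$haplotype) == 0)) {
    stop("donor(s) with empty haplotype: ",
         paste(ds$samples$donor_id[lengths(ds$samples$haplotype) == 0],
               collapse = ", "), call. = FALSE)
  }
  tops <- gem_top_pmhc(ds)
  allele_of <- setNames(ds$panel$hla_allele, ds$panel$pmhc_id)
  hap_of_hash <- setNames(ds$samples$haplotype, ds$samples$hash_id)

  hc <- ds$hash_calls
  hc <- hc[match(ds$gems$gem_id, hc$gem_id), , drop = FALSE]
  top <- tops$top_pmhc[match(ds$gems$gem_id, tops$gem_id)]
  keep <- logical(nrow(ds$gems))
  doublet_union <- logical(nrow(ds$gems))
  for (i in seq_len(nrow(ds$gems))) {
    if (is.na(top[i])) next
    hashes <- hc$positive_hashes[[i]]
    if (is.null(hashes) || length(hashes) == 0) next  # hashing negative
    hap <- unique(unlist(hap_of_hash[hashes]))
    keep[i] <- allele_of[[top[i]]] %in% hap
    doublet_union[i] <- keep[i] && length(hashes) > 1
  }
  ds$gems$hla_doublet_union <- doublet_union
  subset_gems(ds, ds$gems$gem_id[keep])
}

#' Retain only hashing singlets
#'
#' @param ds A `gem_dataset` with `hash_calls`.
#' @return The filtered dataset.
#' @export
filter_hashing_singlets <- function(ds) {
  if (is.null(ds$hash_calls)) {
    stop("run demultiplex_hashing() before filtering on hashing singlets",
         call. = FALSE)
  }
  keep <- ds$hash_calls$gem_id[ds$hash_calls$label == "singlet"]
  subset_gems(ds, keep)
}

#' Retain GEMs with a complete, unique TCR alpha/beta pair
#'
#' A complete TCR means exactly one TRA and exactly one TRB contig in the
#' GEM, counted before dominant-chain selection; GEMs flagged
#' chain-ambiguous (a UMI tie between contigs of the same locus) are also
#' removed.
#'
#' @param ds A `gem_dataset` with dominant chains selected.
#' @return The filtered dataset.
#' @export
filter_complete_tcr <- function(ds) {
  if (!"n_tra" %in% names(ds$gems)) ds <- select_dominant_chains(ds)
  keep <- ds$gems$gem_id[ds$gems$n_tra == 1L & ds$gems$n_trb == 1L &
                           !(ds$gems$chain_ambiguous %in% TRUE)]
  subset_gems(ds, keep)
}

#' Retain GEMs whose (clonotype, top pMHC) pair is seen in two or more GEMs
#'
#' Pairs are recounted on the current (already filtered) GEM set, so this
#' step is order-sensitive within a cascade: removing a pair's only partner
#' earlier also removes the survivor here. GEMs with a tied top pMHC carry
#' no pair and are removed.
#'
#' @param ds A clonotyped `gem_dataset`.
#' @return The filtered dataset.
#' @export
filter_specificity_multiplets <- function(ds) {
  cmap <- gem_clonotype_map(ds)
  tops <- gem_top_pmhc(ds)
  tops$clonotype_id <- unname(cmap[tops$gem_id])
  tops <- filter(tops, !.data$tie_flag, !is.na(.data$top_pmhc))
  pairs <- tops |>
    count(.data$clonotype_id, .data$top_pmhc, name = "n_pair")
  tops <- left_join(tops, pairs, by = c("clonotype_id", "top_pmhc"))
  keep <- tops$gem_id[tops$n_pair >= 2L]
  subset_gems(ds, keep)
}

#' Retain GEMs flagged as cells by the vendor pipeline
#'
#' Pass-through predicates on vendor-provided flags (`is_cell` from the
#' V(D)J run, `is_cell_gex` from the run including gene expression); the
#' flags are never recomputed.
#'
#' @param ds A `gem_dataset`.
#' @param flag Which flag to filter on.
#' @return The filtered dataset.
#' @export
filter_is_cell <- function(ds, flag = c("is_cell", "is_cell_gex")) {
  flag <- match.arg(flag)
  if (!flag %in% names(ds$gems)) {
    stop("flag '", flag, "' absent from dataset", call. = FALSE)
  }
  keep <- ds$gems$gem_id[ds$gems[[flag]] %in% TRUE]
  subset_gems(ds, keep)
}

#' Retain viable cells by gene-expression summaries
#'
#' Removes likely doublets (more than `max_genes` detected genes), dead or
#' empty droplets (fewer than `min_genes` genes) and apoptotic cells
#' (mitochondrial expression fraction above `max_mito`).
#'
#' @param ds A `gem_dataset` with `n_genes` and `mito_fraction` columns; if
#'   absent the filter is skipped with a warning.
#' @param min_genes,max_genes Gene-count bounds (defaults 200 and 2500).
#' @param max_mito Maximum mitochondrial fraction (default 0.2).
#' @return The filtered dataset.
#' @export
filter_viable_cells <- function(ds, min_genes = 200L, max_genes = 2500L,
                                max_mito = 0.2) {
  if (!all(c("n_genes", "mito_fraction") %in% names(ds$gems))) {
    warning("gene-expression summaries absent; viable-cell filter skipped",
            call. = FALSE)
    return(ds)
  }
  keep <- ds$gems$gem_id[
    !is.na(ds$gems$n_genes) & !is.na(ds$gems$mito_fraction) &
      ds$gems$n_genes >= min_genes & ds$gems$n_genes <= max_genes &
      ds$gems$mito_fraction <= max_mito
  ]
  subset_gems(ds, keep)
}

#' Filter cascade configuration
#'
#' @param steps Ordered character vector from `umi_thresholds`,
#'   `hla_match`, `hashing_singlets`, `complete_tcr`,
#'   `specificity_multiplets`, `is_cell`, `is_cell_gex`, `viable_cell`.
#' @param thresholds A [umi_thresholds()] object (used by the
#'   `umi_thresholds` step).
#' @param min_genes,max_genes,max_mito Viability bounds.
#' @return A `filter_config` object.
#' @export
filter_config <- function(steps = c("umi_thresholds", "hla_match"),
                          thresholds = umi_thresholds(),
                          min_genes = 200L, max_genes = 2500L,
                          max_mito = 0.2) {
  known <- c("umi_thresholds", "hla_match", "hashing_singlets",
             "complete_tcr", "specificity_multiplets", "is_cell",
             "is_cell_gex", "viable_cell")
  bad <- setdiff(steps, known)
  if (length(bad)) stop("unknown filter step(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(steps = steps, thresholds = thresholds,
                 min_genes = min_genes, max_genes = max_genes,
                 max_mito = max_mito),
            class = "filter_config")
}

apply_one_filter <- function(ds, step, config) {
  switch(step,
         umi_thresholds = filter_umi_thresholds(ds, config$thresholds),
         hla_match = filter_hla_match(ds),
         hashing_singlets = filter_hashing_singlets(ds),
         complete_tcr = filter_complete_tcr(ds),
         specificity_multiplets = filter_specificity_multiplets(ds),
         is_cell = filter_is_cell(ds, "is_cell"),
         is_cell_gex = filter_is_cell(ds, "is_cell_gex"),
         viable_cell = filter_viable_cells(ds, config$min_genes,
                                           config$max_genes,
                                           config$max_mito),
         stop("unknown filter step: ", step, call. = FALSE))
}

#' Apply a filter cascade and report per-step metrics
#'
#' Applies the configured steps in order (`mode = "cumulative"`, each step
#' on the previous step's output) or each step separately on the full data
#' (`mode = "individual"`). After each step the GEM count, clonotype count,
#' accuracy and average binding concordance are recorded against
#' expected-binder labels fixed on the input data. Every step only removes
#' GEMs.
#'
#' @param ds A clonotyped `gem_dataset`.
#' @param config A [filter_config()].
#' @param expected Expected binders; computed from `ds` when `NULL`.
#' @param mode `"cumulative"` (default) or `"individual"`.
#' @return List with `dataset` (the final filtered dataset; in individual
#'   mode the input) and `report` (tibble, one row for the unfiltered total
#'   plus one per step).
#' @export
apply_filter_chain <- function(ds, config, expected = NULL,
                               mode = c("cumulative", "individual")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "filter_config"))
  if (is.null(expected)) expected <- expected_binders(ds)
  need_flags <- intersect(config$steps, c("is_cell", "is_cell_gex"))
  missing_flags <- setdiff(need_flags, names(ds$gems))
  if (length(missing_flags)) {
    stop("filter step(s) require absent flag column(s): ",
         paste(missing_flags, collapse = ", "), call. = FALSE)
  }

  n_total <- nrow(ds$gems)
  report <- list(compute_report(ds, "total", expected,
                                n_total_gems = n_total))
  current <- ds
  for (step in config$steps) {
    input <- if (mode == "cumulative") current else ds
    out <- apply_one_filter(input, step, config)
    if (mode == "cumulative") current <- out
    report[[length(report) + 1L]] <-
      compute_report(out, step, expected, n_total_gems = n_total)
  }
  list(dataset = if (mode == "cumulative") current else ds,
       report = bind_rows(report))
}
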