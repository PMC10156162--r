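#' Aggregate metrics for one filtering stage
#'
#' One report row per stage: GEM and clonotype counts, retained fraction
#' (relative to `n_total_gems`), GEM-level accuracy against the fixed
#' expected-binder labels, average binding concordance, and optionally the
#' intra/inter similarity ROC-AUC.
#'
#' @param ds The (possibly filtered) clonotyped `gem_dataset`.
#' @param stage_label Label recorded in the row.
#' @param expected Expected binders fixed on the unfiltered data.
#' @param n_total_gems GEM count of the unfiltered stage (defaults to
#'   `nrow(ds$gems)`).
#' @param include_auc Also compute the similarity AUC (slower).
#' @param seed Seed for the AUC's inter-set sampling.
#' @return One-row tibble `stage`, `n_gems`, `n_clonotypes`,
#'   `retained_fraction`, `accuracy`, `avg_concordance`, `auc`.
#' @export
compute_report <- function(ds, stage_label, expected,
                           n_total_gems = NULL, include_auc = FALSE,
                           seed = 1L) {
  if (is.null(n_total_gems)) n_total_gems <- nrow(ds$gems)
  n_ct <- if (is.null(ds$clonotypes)) NA_integer_ else {
    sum(ds$clonotypes$n_gems > 0)
  }
  acc <- if (nrow(ds$gems)) {
    suppressWarnings(annotation_accuracy(ds, expected))
  } else {
    NA_real_
  }
  conc <- if (nrow(ds$gems)) {
    suppressWarnings(average_concordance(ds))
  } else {
    NA_real_
  }
  auc <- NA_real_
  if (include_auc && nrow(ds$gems)) {
    labels <- clonotype_specificity_labels(ds, expected)
    recs <- suppressWarnings(intra_inter_scores(labels, seed = seed))
    if (nrow(recs)) auc <- suppressWarnings(similarity_auc(recs))
  }
  tibble(
    stage = stage_label,
    n_gems = nrow(ds$gems),
    n_clonotypes = n_ct,
    retained_fraction = nrow(ds$gems) / n_total_gems,
    accuracy = acc,
    avg_concordance = conc,
    auc = auc
  )
}

#' Adjusted antigen-specific cell counts from multimer response frequencies
#'
#' Converts per-donor fluorescent multimer response frequencies into
#' adjusted counts of sorted cells: with `normalization = "donor_share"`
#' (default) the `n_sorted` multimer-positive cells sorted per donor are
#' allocated proportionally to each detected response's share of the donor's
#' summed detected frequencies; `"capacity"` instead multiplies each
#' frequency (in percent) by `n_sorted / 100`. A response is detected
#' (`above_threshold`) when it has at least 10 events and frequency >=
#' 0.002% of CD8 T cells, or at most 10 events but frequency >= 0.01%.
#'
#' @param responses Tibble `donor_id`, `pmhc_id`, `frequency` (percent of
#'   CD8 T cells), `n_events`.
#' @param n_sorted Cells sorted per donor (default 1800).
#' @param normalization `"donor_share"` or `"capacity"`.
#' @return `responses` with `above_threshold` and `adjusted_cells` added.
#' @export
adjusted_cell_counts <- function(responses, n_sorted = 1800,
                                 normalization = c("donor_share",
                                                   "capacity")) {
  normalization <- match.arg(normalization)
  r <- as_tibble(responses)
  r$above_threshold <- (r$n_events >= 10 & r$frequency >= 0.002) |
    (r$n_events <= 10 & r$frequency >= 0.01)
  if (normalization == "capacity") {
    r$adjusted_cells <- ifelse(r$above_threshold,
                               r$frequency * n_sorted / 100, 0)
    return(r)
  }
  r <- r |>
    group_by(.data$donor_id) |>
    mutate(
      .sumfreq = sum(.data$frequency[.data$above_threshold]),
      adjusted_cells = dplyr::case_when(
        !.data$above_threshold ~ 0,
        .data$.sumfreq > 0 ~ n_sorted * .data$frequency / .data$.sumfreq,
        TRUE ~ NA_real_
      )
    ) |>
    ungroup()
  if (any(is.na(r$adjusted_cells) & r$above_threshold)) {
    warning("donor(s) with zero summed detected frequency; adjusted counts ",
            "undefined there", call. = FALSE)
  }
  select(r, -all_of(".sumfreq"))
}

#' Compare single-cell pMHC assignments with multimer staining responses
#'
#' Multimer responses above their detection threshold are the binary truth;
#' (donor, pMHC) populations with at least one GEM after filtering are the
#' query. Returns Matthews correlation coefficient, recall and precision
#' from the 2x2 agreement table, the Pearson correlation between adjusted
#' cell counts and GEM counts, and an ordinary least-squares regression in
#' log10-log10 space. Correlation and regression are restricted to
#' populations with at least one adjusted cell or at least one GEM; the
#' log-log fit additionally requires both counts positive (no pseudocount
#' is added).
#'
#' @param responses Output of [adjusted_cell_counts()].
#' @param gem_counts Tibble `donor_id`, `pmhc_id`, `n_gems` (populations
#'   absent from the table count 0 GEMs).
#' @return List `mcc`, `recall`, `precision`, `pearson_r`, `regression`
#'   (list `slope`, `intercept`, `r2`), `table` (the 2x2 counts).
#' @export
compare_with_multimer <- function(responses, gem_counts) {
  r <- as_tibble(responses)
  g <- as_tibble(gem_counts)
  merged <- left_join(r, g, by = c("donor_id", "pmhc_id"))
  merged$n_gems[is.na(merged$n_gems)] <- 0L

  truth <- merged$above_threshold
  query <- merged$n_gems >= 1L
  tp <- sum(truth & query); fp <- sum(!truth & query)
  fn <- sum(truth & !query); tn <- sum(!truth & !query)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) {
    warning("degenerate 2x2 table; MCC undefined", call. = FALSE)
    NA_real_
  } else {
    (tp * tn - fp * fn) / denom
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_

  inc <- merged$adjusted_cells >= 1 | merged$n_gems >= 1
  inc[is.na(inc)] <- FALSE
  pearson_r <- if (sum(inc) >= 3) {
    cor(merged$adjusted_cells[inc], merged$n_gems[inc])
  } else {
    NA_real_
  }
  fit_ok <- inc & merged$adjusted_cells > 0 & merged$n_gems > 0
  regression <- if (sum(fit_ok) >= 3) {
    fit <- lm(log10(n_gems) ~ log10(adjusted_cells),
              data = merged[fit_ok, ])
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = summary(fit)$r.squared)
  } else {
    list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_)
  }
  list(mcc = mcc, recall = recall, precision = precision,
       pearson_r = pearson_r, regression = regression,
       table = c(tp = tp, fp = fp, fn = fn, tn = tn))
}
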