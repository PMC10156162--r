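#' Most abundant pMHC per GEM
#'
#' For each GEM, the pMHC barcode with the highest UMI count defines the
#' GEM-level specificity annotation. When two or more pMHCs share the
#' maximum the GEM carries no unique top feature and is flagged tied; tied
#' GEMs are excluded from concordance and counted as mismatches in
#' accuracy.
#'
#' @param ds A `gem_dataset` (uses its `pmhc` slice), or a long tibble
#'   `gem_id`, `pmhc_id`, `umi`.
#' @return Tibble `gem_id`, `top_pmhc` (`NA` when tied), `umi_max`,
#'   `umi_sec` (0 when only one pMHC is detected), `tie_flag`.
#' @export
gem_top_pmhc <- function(ds) {
  pmhc <- if (inherits(ds, "gem_dataset")) ds$pmhc else as_tibble(ds)
  pmhc |>
    arrange(.data$gem_id, dplyr::desc(.data$umi), .data$pmhc_id) |>
    group_by(.data$gem_id) |>
    summarise(
      top_pmhc = if (n() > 1 && .data$umi[1] == .data$umi[2]) {
        NA_character_
      } else {
        .data$pmhc_id[1]
      },
      umi_max = .data$umi[1],
      umi_sec = if (n() > 1) .data$umi[2] else 0L,
      tie_flag = n() > 1 && .data$umi[1] == .data$umi[2],
      .groups = "drop"
    )
}

# gem_id -> clonotype_id lookup, erroring when clonotyping hasn't run.
gem_clonotype_map <- function(ds) {
  if (is.null(ds$clonotypes) || !"clonotype_id" %in% names(ds$gems)) {
    stop("dataset has no clonotype assignment; run ",
         "collapse_and_impute_clonotypes() first", call. = FALSE)
  }
  setNames(ds$gems$clonotype_id, ds$gems$gem_id)
}

#' Infer the expected pMHC binder of each clonotype
#'
#' Pools each clonotype's member GEMs and compares the UMI count
#' distributions of the detected pMHCs, assigning 0 UMIs when a pMHC is not
#' detected in a GEM. The two pMHCs with the highest mean UMI count are
#' compared with a one-sided Wilcoxon test of the hypothesis that the top
#' pMHC's counts exceed the runner-up's; at `p < alpha` the top pMHC becomes
#' the clonotype's expected target. Clonotypes with fewer than `min_gems`
#' GEMs are not tested. A clonotype observing a single pMHC across all its
#' GEMs (with enough GEMs) is assigned that pMHC degenerately, with an
#' undefined p-value.
#'
#' Both pMHCs are measured within the same GEMs, so the default test is the
#' paired signed-rank over per-GEM differences (exact and tie-aware for
#' small clonotypes, see [signed_rank_test()]); `method = "ranksum"`
#' switches to the unpaired rank-sum test.
#'
#' @param ds A clonotyped `gem_dataset`.
#' @param min_gems Minimum clonotype size to test (default 10).
#' @param alpha Significance level (default 0.05).
#' @param method `"paired"` (default) or `"ranksum"`.
#' @param exact_max Passed to [signed_rank_test()].
#' @return Tibble `clonotype_id`, `pmhc_id` (`NA` when no expected target),
#'   `p_value`, `n_gems`, `tested`, `degenerate`.
#' @export
expected_binders <- function(ds, min_gems = 10L, alpha = 0.05,
                             method = c("paired", "ranksum"),
                             exact_max = 25L) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "gem_dataset"))
  if (is.null(ds$clonotypes)) {
    stop("run collapse_and_impute_clonotypes() first", call. = FALSE)
  }
  cmap <- gem_clonotype_map(ds)
  pm <- ds$pmhc
  pm$clonotype_id <- unname(cmap[pm$gem_id])

  res <- lapply(seq_len(nrow(ds$clonotypes)), function(i) {
    ct <- ds$clonotypes$clonotype_id[i]
    members <- ds$clonotypes$member_gems[[i]]
    ng <- length(members)
    sub <- pm[pm$clonotype_id %in% ct, , drop = FALSE]
    pmhcs <- unique(sub$pmhc_id)
    out <- tibble(clonotype_id = ct, pmhc_id = NA_character_,
                  p_value = NA_real_, n_gems = ng, tested = FALSE,
                  degenerate = FALSE)
    if (ng < min_gems || length(pmhcs) == 0L) return(out)
    if (length(pmhcs) == 1L) {
      out$pmhc_id <- pmhcs
      out$degenerate <- TRUE
      return(out)
    }
    # per-pMHC counts across member GEMs, 0 when not detected
    mat <- matrix(0, nrow = ng, ncol = length(pmhcs),
                  dimnames = list(members, pmhcs))
    mat[cbind(match(sub$gem_id, members), match(sub$pmhc_id, pmhcs))] <-
      sub$umi
    mu <- colMeans(mat)
    n_obs <- colSums(mat > 0)
    ord <- order(-mu, -n_obs, colnames(mat))
    top <- colnames(mat)[ord[1]]
    sec <- colnames(mat)[ord[2]]
    p <- if (method == "paired") {
      signed_rank_test(mat[, top], mat[, sec], alternative = "greater",
                       exact_max = exact_max)$p_value
    } else {
      suppressWarnings(
        stats::wilcox.test(mat[, top], mat[, sec], alternative = "greater",
                           exact = FALSE)$p.value
      )
    }
    out$tested <- TRUE
    out$p_value <- p
    if (!is.na(p) && p < alpha) out$pmhc_id <- top
    out
  })
  bind_rows(res)
}

#' Binding concordance per (clonotype, pMHC)
#'
#' The fraction of a clonotype's GEMs whose most abundant pMHC is a given
#' specificity, computed over GEMs with an unambiguous top pMHC (tied GEMs
#' are excluded from numerator and denominator and reported in the
#' `n_tied` attribute). A clonotype detected with only one pMHC has
#' concordance 1 for it.
#'
#' @param ds A clonotyped `gem_dataset`.
#' @return Tibble `clonotype_id`, `pmhc_id`, `fraction`, `n_support`, with
#'   attribute `n_tied` (tied GEMs per clonotype).
#' @export
binding_concordance <- function(ds) {
  cmap <- gem_clonotype_map(ds)
  tops <- gem_top_pmhc(ds)
  tops$clonotype_id <- unname(cmap[tops$gem_id])
  tops <- filter(tops, !is.na(.data$clonotype_id))

  tied <- tops |>
    group_by(.data$clonotype_id) |>
    summarise(n_tied = sum(.data$tie_flag), .groups = "drop")
  unamb <- filter(tops, !.data$tie_flag)
  if (!nrow(unamb)) {
    warning("all GEMs have tied top pMHCs; concordance undefined",
            call. = FALSE)
    out <- tibble(clonotype_id = character(), pmhc_id = character(),
                  fraction = numeric(), n_support = integer())
    attr(out, "n_tied") <- tied
    return(out)
  }
  out <- unamb |>
    count(.data$clonotype_id, .data$top_pmhc, name = "n_support") |>
    group_by(.data$clonotype_id) |>
    mutate(fraction = .data$n_support / sum(.data$n_support)) |>
    ungroup() |>
    rename(pmhc_id = "top_pmhc") |>
    select(all_of(c("clonotype_id", "pmhc_id", "fraction", "n_support")))
  attr(out, "n_tied") <- tied
  out
}

#' GEM-level annotation accuracy against expected binders
#'
#' The proportion of GEMs -- among GEMs belonging to clonotypes with an
#' assigned expected target -- whose unambiguous most abundant pMHC equals
#' that target. GEMs of clonotypes without an expected target are left out;
#' tied GEMs count as mismatches.
#'
#' @param ds A clonotyped `gem_dataset`.
#' @param expected Expected-binder table from [expected_binders()].
#' @return A single number in `[0, 1]`, or `NA` when no clonotype has an
#'   expected target.
#' @export
annotation_accuracy <- function(ds, expected) {
  lab <- expected$pmhc_id[match(ds$gems$clonotype_id,
                                expected$clonotype_id)]
  eligible <- !is.na(lab)
  if (!any(eligible)) {
    warning("no clonotype has an expected target; accuracy undefined",
            call. = FALSE)
    return(NA_real_)
  }
  tops <- gem_top_pmhc(ds)
  top <- tops$top_pmhc[match(ds$gems$gem_id, tops$gem_id)]
  match_flag <- !is.na(top) & top == lab
  sum(match_flag[eligible]) / sum(eligible)
}

#' Average binding concordance of a dataset
#'
#' GEM-weighted by default: every GEM with an unambiguous top pMHC
#' contributes its clonotype's concordance fraction for that pMHC, and the
#' contributions are averaged over GEMs (paralleling the GEM-wise accuracy).
#' `weighting = "clonotype"` instead averages each clonotype's highest
#' concordance fraction once per clonotype.
#'
#' @param ds A clonotyped `gem_dataset`.
#' @param weighting `"gem"` (default) or `"clonotype"`.
#' @return A single number in `[0, 1]` (`NA` on an empty dataset).
#' @export
average_concordance <- function(ds, weighting = c("gem", "clonotype")) {
  weighting <- match.arg(weighting)
  conc <- binding_concordance(ds)
  if (!nrow(conc)) return(NA_real_)
  if (weighting == "clonotype") {
    return(conc |>
             group_by(.data$clonotype_id) |>
             summarise(best = max(.data$fraction), .groups = "drop") |>
             pull(.data$best) |>
             mean())
  }
  cmap <- gem_clonotype_map(ds)
  tops <- gem_top_pmhc(ds)
  tops$clonotype_id <- unname(cmap[tops$gem_id])
  tops <- filter(tops, !.data$tie_flag, !is.na(.data$clonotype_id))
  joined <- left_join(tops, conc,
                      by = c("clonotype_id", top_pmhc = "pmhc_id"))
  mean(joined$fraction, na.rm = TRUE)
}
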