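#' UMI ratio between the two most abundant features
#'
#' The ratio between the highest and second-highest UMI count of a feature
#' class within a GEM, with 0.25 added to the denominator to avoid division
#' by zero: `umi_max / (umi_sec + 0.25)`. The ratio measures multiplets: a
#' clean single-specificity GEM has a high ratio, equally abundant features
#' give a ratio below 1.
#'
#' @param umi_max,umi_sec Non-negative counts with `umi_max >= umi_sec`
#'   (vectorized).
#' @return Numeric vector of ratios.
#' @examples
#' umi_ratio(2, 0)   # 8
#' umi_ratio(3, 3)   # 0.923 -- a tie scores below 1
#' @export
umi_ratio <- function(umi_max, umi_sec) {
  if (any(umi_max < 0 | umi_sec < 0, na.rm = TRUE)) {
    stop("UMI counts must be non-negative", call. = FALSE)
  }
  if (any(umi_max < umi_sec, na.rm = TRUE)) {
    stop("umi_max must be >= umi_sec", call. = FALSE)
  }
  umi_max / (umi_sec + 0.25)
}

#' Weighted accuracy/retention objective
#'
#' The grid-search objective `o = (2 * acc + f) / 3`: a weighted average of
#' annotation accuracy and the fraction of retained GEMs, favoring accuracy
#' gains over data loss.
#'
#' @param acc Accuracy in `[0, 1]`.
#' @param retained_fraction Fraction of GEMs retained, in `[0, 1]`.
#' @return The objective value in `[0, 1]`.
#' @export
objective_score <- function(acc, retained_fraction) {
  if (any(acc < 0 | acc > 1 | retained_fraction < 0 | retained_fraction > 1,
          na.rm = TRUE)) {
    stop("acc and retained_fraction must lie in [0, 1]", call. = FALSE)
  }
  (2 * acc + retained_fraction) / 3
}

#' Construct a UMI threshold set
#'
#' Six thresholds drive the UMI filter: a minimum count and a minimum ratio
#' for each of the pMHC, TRA and TRB feature classes. A threshold of 0
#' disables that criterion. Counts are compared with `>=` (a GEM with
#' exactly 2 pMHC UMIs passes `min_umi = 2`), ratios strictly with `>`.
#'
#' @param pmhc_count,tra_count,trb_count Minimum top-feature UMI counts.
#' @param pmhc_ratio,tra_ratio,trb_ratio Minimum UMI ratios.
#' @return A `umi_thresholds` object.
#' @export
umi_thresholds <- function(pmhc_count = 0, pmhc_ratio = 0,
                           tra_count = 0, tra_ratio = 0,
                           trb_count = 0, trb_ratio = 0) {
  th <- list(
    min_umi = c(pmhc = pmhc_count, tra = tra_count, trb = trb_count),
    min_ratio = c(pmhc = pmhc_ratio, tra = tra_ratio, trb = trb_ratio)
  )
  if (any(unlist(th) < 0)) stop("thresholds must be non-negative",
                                call. = FALSE)
  structure(th, class = "umi_thresholds")
}

#' @export
print.umi_thresholds <- function(x, ...) {
  cat("<umi_thresholds> min count:",
      paste0(names(x$min_umi), "=", x$min_umi, collapse = " "),
      "| min ratio:",
      paste0(names(x$min_ratio), "=", x$min_ratio, collapse = " "), "\n")
  invisible(x)
}

#' Per-GEM UMI feature summaries for the three feature classes
#'
#' For each GEM: the top and second UMI count and the UMI ratio of the pMHC
#' barcodes, the TRA contigs and the TRB contigs. A missing chain yields a
#' top count of 0 (so any nonzero TCR threshold removes chain-less GEMs,
#' while zero thresholds keep them).
#'
#' @param ds A `gem_dataset` with dominant chains selected.
#' @return Tibble `gem_id`, then `<class>_max`, `<class>_sec`,
#'   `<class>_ratio` for `pmhc`, `tra`, `trb`.
#' @export
gem_feature_summaries <- function(ds) {
  if (!"va" %in% names(ds$gems)) ds <- select_dominant_chains(ds)
  tops <- gem_top_pmhc(ds)
  g <- ds$gems
  idx <- match(g$gem_id, tops$gem_id)
  z <- function(x) ifelse(is.na(x), 0L, x)
  out <- tibble(
    gem_id = g$gem_id,
    pmhc_max = z(tops$umi_max[idx]),
    pmhc_sec = z(tops$umi_sec[idx]),
    tra_max = z(g$umi_a), tra_sec = z(g$umi_a_sec),
    trb_max = z(g$umi_b), trb_sec = z(g$umi_b_sec)
  )
  out$pmhc_ratio <- umi_ratio(out$pmhc_max, out$pmhc_sec)
  out$tra_ratio <- umi_ratio(out$tra_max, out$tra_sec)
  out$trb_ratio <- umi_ratio(out$trb_max, out$trb_sec)
  out
}

#' Evaluate one threshold set against fixed expected-binder labels
#'
#' @param ds A clonotyped `gem_dataset`.
#' @param thresholds A [umi_thresholds()] object.
#' @param expected Expected binders computed on the unfiltered data.
#' @return List `acc`, `retained_fraction`, `objective`, `n_gems_retained`,
#'   `acc_defined` (FALSE when no eligible GEM survives; `acc` is then 0).
#' @export
evaluate_thresholds <- function(ds, thresholds, expected) {
  feats <- gem_feature_summaries(ds)
  pass <- threshold_pass(feats, thresholds)
  lab <- expected$pmhc_id[match(ds$gems$clonotype_id,
                                expected$clonotype_id)]
  tops <- gem_top_pmhc(ds)
  top <- tops$top_pmhc[match(ds$gems$gem_id, tops$gem_id)]
  eligible <- !is.na(lab)
  match_flag <- eligible & !is.na(top) & top == lab
  n_ret <- sum(pass)
  n_eli <- sum(pass & eligible)
  acc <- if (n_eli > 0) sum(pass & match_flag) / n_eli else 0
  f <- n_ret / nrow(ds$gems)
  list(acc = acc, retained_fraction = f,
       objective = objective_score(acc, f),
       n_gems_retained = n_ret, acc_defined = n_eli > 0)
}

threshold_pass <- function(feats, th) {
  (th$min_umi[["pmhc"]] == 0 | feats$pmhc_max >= th$min_umi[["pmhc"]]) &
    (th$min_ratio[["pmhc"]] == 0 | feats$pmhc_ratio > th$min_ratio[["pmhc"]]) &
    (th$min_umi[["tra"]] == 0 | feats$tra_max >= th$min_umi[["tra"]]) &
    (th$min_ratio[["tra"]] == 0 | feats$tra_ratio > th$min_ratio[["tra"]]) &
    (th$min_umi[["trb"]] == 0 | feats$trb_max >= th$min_umi[["trb"]]) &
    (th$min_ratio[["trb"]] == 0 | feats$trb_ratio > th$min_ratio[["trb"]])
}

#' Exhaustive grid search over UMI count and ratio thresholds
#'
#' Evaluates every combination of the six thresholds (count and ratio for
#' pMHC, TRA, TRB) and returns the combination maximizing the objective
#' `o = (2 * acc + f) / 3`, where accuracy is computed over the surviving
#' GEMs against expected-binder labels fixed on the unfiltered data (the
#' training set is defined once, before thresholding) and `f` is the
#' retained fraction of all GEMs.
#'
#' Default grids follow the rule "0 up to the median": integer count
#' thresholds from 0 to the per-class median of the per-GEM top UMI count,
#' and a ratio ladder `0, 1, 1.5, 2, 3, 4, 5` continued with ~1.5x
#' geometric steps, capped at the per-class median per-GEM UMI ratio. Ties
#' in the objective prefer the higher retained fraction, then lower
#' thresholds component-wise in the order pMHC count, pMHC ratio, TRA
#' count, TRA ratio, TRB count, TRB ratio.
#'
#' @param ds A clonotyped `gem_dataset`.
#' @param expected Expected binders from [expected_binders()] on `ds`.
#' @param grids Optional named list overriding the default grids; names
#'   among `pmhc_count`, `pmhc_ratio`, `tra_count`, `tra_ratio`,
#'   `trb_count`, `trb_ratio`.
#' @param audit Also return the full grid evaluation (`$grid`, one row per
#'   grid point). Off by default; the grid can be large.
#' @return A `grid_search_result`: list with `thresholds`
#'   ([umi_thresholds()]), `acc`, `retained_fraction`, `objective`,
#'   `n_gems_retained`, `grids`, and optionally `grid`.
#' @export
grid_search_thresholds <- function(ds, expected, grids = NULL,
                                   audit = FALSE) {
  feats <- gem_feature_summaries(ds)
  n_total <- nrow(feats)
  g <- default_grids(feats)
  if (!is.null(grids)) {
    bad <- setdiff(names(grids), names(g))
    if (length(bad)) stop("unknown grid name(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    g[names(grids)] <- lapply(grids, function(x) sort(unique(x)))
  }

  lab <- expected$pmhc_id[match(ds$gems$clonotype_id,
                                expected$clonotype_id)]
  tops <- gem_top_pmhc(ds)
  top <- tops$top_pmhc[match(ds$gems$gem_id, tops$gem_id)]
  idx <- match(feats$gem_id, ds$gems$gem_id)
  eligible <- as.numeric(!is.na(lab))[idx]
  match_w <- as.numeric(!is.na(lab) & !is.na(top) & top == lab)[idx]

  # Per class: pass matrix over (count, ratio) combinations; the overall
  # pass indicator factorizes over the three classes, so retained / eligible
  # / matching counts are three weighted tensor contractions.
  class_combos <- function(cls) {
    cnt <- g[[paste0(cls, "_count")]]
    rat <- g[[paste0(cls, "_ratio")]]
    combos <- expand.grid(count = cnt, ratio = rat,
                          KEEP.OUT.ATTRS = FALSE)
    combos <- combos[order(combos$count, combos$ratio), , drop = FALSE]
    mx <- feats[[paste0(cls, "_max")]]
    rt <- feats[[paste0(cls, "_ratio")]]
    pass <- matrix(0, nrow = n_total, ncol = nrow(combos))
    for (ci in seq_len(nrow(combos))) {
      pass[, ci] <- as.numeric(
        (combos$count[ci] == 0 | mx >= combos$count[ci]) &
          (combos$ratio[ci] == 0 | rt > combos$ratio[ci])
      )
    }
    list(combos = combos, pass = pass)
  }
  c1 <- class_combos("pmhc")
  c2 <- class_combos("tra")
  c3 <- class_combos("trb")

  tol <- 1e-12
  best <- list(o = -Inf, f = -Inf)
  audit_rows <- if (audit) vector("list", nrow(c1$combos)) else NULL

  for (i in seq_len(nrow(c1$combos))) {
    w1 <- c1$pass[, i]
    n_ret <- crossprod(c2$pass * w1, c3$pass)
    n_eli <- crossprod(c2$pass * (w1 * eligible), c3$pass)
    n_mat <- crossprod(c2$pass * (w1 * match_w), c3$pass)
    acc <- ifelse(n_eli > 0, n_mat / n_eli, 0)
    f <- n_ret / n_total
    o <- (2 * acc + f) / 3

    mo <- max(o)
    cand <- which(o >= mo - tol)
    cand <- cand[order(-f[cand], cand)]
    j <- (cand[1] - 1) %% nrow(o) + 1
    k <- (cand[1] - 1) %/% nrow(o) + 1
    better <- mo > best$o + tol ||
      (abs(mo - best$o) <= tol && f[cand[1]] > best$f + tol)
    if (better) {
      best <- list(
        o = o[cand[1]], f = f[cand[1]], acc = acc[cand[1]],
        n_ret = n_ret[cand[1]],
        i = i, j = j, k = k,
        acc_defined = n_eli[cand[1]] > 0
      )
    }
    if (audit) {
      audit_rows[[i]] <- tibble(
        pmhc_count = c1$combos$count[i], pmhc_ratio = c1$combos$ratio[i],
        tra_count = rep(c2$combos$count, times = ncol(o)),
        tra_ratio = rep(c2$combos$ratio, times = ncol(o)),
        trb_count = rep(c3$combos$count, each = nrow(o)),
        trb_ratio = rep(c3$combos$ratio, each = nrow(o)),
        acc = as.vector(acc), retained_fraction = as.vector(f),
        objective = as.vector(o),
        n_gems_retained = as.vector(n_ret),
        acc_defined = as.vector(n_eli > 0)
      )
    }
  }

  th <- umi_thresholds(
    pmhc_count = c1$combos$count[best$i], pmhc_ratio = c1$combos$ratio[best$i],
    tra_count = c2$combos$count[best$j], tra_ratio = c2$combos$ratio[best$j],
    trb_count = c3$combos$count[best$k], trb_ratio = c3$combos$ratio[best$k]
  )
  res <- list(
    thresholds = th, acc = best$acc, retained_fraction = best$f,
    objective = best$o, n_gems_retained = as.integer(best$n_ret),
    acc_defined = best$acc_defined, grids = g
  )
  if (audit) res$grid <- bind_rows(audit_rows)
  structure(res, class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("<grid_search_result>\n")
  print(x$thresholds)
  cat(sprintf("  acc = %.4f  f = %.4f  o = %.4f  (%d GEMs retained)\n",
              x$acc, x$retained_fraction, x$objective, x$n_gems_retained))
  invisible(x)
}

default_grids <- function(feats) {
  count_grid <- function(mx) 0:max(1, floor(median(mx)))
  ratio_grid <- function(rt) {
    cap <- median(rt)
    ladder <- c(0, 1, 1.5, 2, 3, 4, 5)
    v <- 5
    repeat {
      v <- ceiling(v * 1.5)
      if (v > cap) break
      ladder <- c(ladder, v)
    }
    ladder[ladder <= max(cap, 1)]
  }
  list(
    pmhc_count = count_grid(feats$pmhc_max),
    pmhc_ratio = ratio_grid(feats$pmhc_ratio),
    tra_count = count_grid(feats$tra_max),
    tra_ratio = ratio_grid(feats$tra_ratio),
    trb_count = count_grid(feats$trb_max),
    trb_ratio = ratio_grid(feats$trb_ratio)
  )
}
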