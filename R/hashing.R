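#' Demultiplex hashed samples from hashing-barcode UMI counts
#'
#' Implements cell-hashing demultiplexing in the HTO-demux style: the
#' count matrix is normalized by a centered log-ratio across barcodes within
#' each GEM and clustered by k-medoids into `k = n_samples + 1` clusters.
#' For each hashing barcode, a negative binomial is fitted by maximum
#' likelihood to the raw counts of all GEMs outside the cluster with the
#' highest average expression of that barcode (the background pool); a GEM
#' is positive for the barcode when its raw count strictly exceeds the
#' fitted distribution's `quantile` quantile. GEMs positive for exactly one
#' barcode are singlets, for several are doublets, for none are negatives.
#'
#' When the maximum-likelihood fit fails or the pool is under-dispersed
#' (variance at or below the mean), a Poisson quantile is used instead.
#'
#' @param ds A `gem_dataset` (uses its `hash` slice), or a long tibble
#'   `gem_id`, `hash_id`, `umi`.
#' @param n_samples Number of hashed samples pooled in the run; defaults to
#'   the dataset's sample table.
#' @param quantile Background quantile a count must exceed to call a barcode
#'   positive (default 0.99).
#' @param seed Seed for any stochastic refinement of the clustering (the
#'   k-medoid build step itself is deterministic).
#' @return If `ds` is a `gem_dataset`, `ds` with `ds$hash_calls` set;
#'   otherwise the calls tibble itself: `gem_id`, `label`
#'   (`singlet`/`doublet`/`negative`), `positive_hashes` (list-column),
#'   plus the per-barcode thresholds in `attr(, "thresholds")`.
#' @export
demultiplex_hashing <- function(ds, n_samples = NULL, quantile = 0.99,
                                seed = 1L) {
  is_ds <- inherits(ds, "gem_dataset")
  hash <- if (is_ds) ds$hash else as_tibble(ds)
  if (is.null(n_samples)) {
    if (is_ds && nrow(ds$samples)) {
      n_samples <- nrow(ds$samples)
    } else {
      n_samples <- dplyr::n_distinct(hash$hash_id)
    }
  }
  gem_ids <- if (is_ds) ds$gems$gem_id else unique(hash$gem_id)
  hash_ids <- if (is_ds && nrow(ds$samples)) {
    ds$samples$hash_id
  } else {
    sort(unique(hash$hash_id))
  }
  k <- n_samples + 1L
  if (length(gem_ids) < k) {
    stop("need at least n_samples + 1 = ", k, " GEMs for hashing demux",
         call. = FALSE)
  }

  counts <- matrix(0, nrow = length(gem_ids), ncol = length(hash_ids),
                   dimnames = list(gem_ids, hash_ids))
  counts[cbind(match(hash$gem_id, gem_ids),
               match(hash$hash_id, hash_ids))] <- hash$umi

  # CLR across barcodes within each GEM; cluster on normalized values,
  # threshold on raw counts.
  lc <- log1p(counts)
  clr <- lc - rowMeans(lc)
  set.seed(seed)
  cl <- cluster::pam(clr, k = k, pamonce = 5, cluster.only = TRUE)

  thresholds <- setNames(numeric(length(hash_ids)), hash_ids)
  positive <- matrix(FALSE, nrow = length(gem_ids), ncol = length(hash_ids),
                     dimnames = dimnames(counts))
  for (h in seq_along(hash_ids)) {
    x <- counts[, h]
    if (all(x == 0)) {
      warning("hash barcode '", hash_ids[h],
              "' has no counts; no positives called", call. = FALSE)
      thresholds[h] <- Inf
      next
    }
    cluster_means <- tapply(x, cl, mean)
    # The positive population can split across clusters (k exceeds the
    # number of natural groups when few droplets are negative), so every
    # cluster with above-average mean expression of this barcode is
    # excluded from the background pool -- at minimum the highest one.
    high <- cluster_means > mean(cluster_means)
    high[which.max(cluster_means)] <- TRUE
    pool <- x[!(as.character(cl) %in% names(cluster_means)[high])]
    if (!length(pool)) pool <- x
    thresholds[h] <- nb_background_quantile(pool, quantile)
    positive[, h] <- x > thresholds[h]
  }

  n_pos <- unname(rowSums(positive))
  label <- ifelse(n_pos == 0, "negative",
                  ifelse(n_pos == 1, "singlet", "doublet"))
  pos_list <- lapply(seq_along(gem_ids),
                     function(i) hash_ids[positive[i, ]])
  calls <- tibble(
    gem_id = gem_ids,
    label = label,
    positive_hashes = pos_list
  )
  if (is_ds && nrow(ds$samples)) {
    donor_of <- setNames(ds$samples$donor_id, ds$samples$hash_id)
    calls$donor_id <- vapply(pos_list, function(p) {
      if (length(p) == 1) unname(donor_of[p]) else NA_character_
    }, character(1))
  }
  attr(calls, "thresholds") <- thresholds
  if (is_ds) {
    ds$hash_calls <- calls
    ds
  } else {
    calls
  }
}

# Quantile of the fitted background distribution: NB by ML, Poisson when the
# pool is under-dispersed or the fit fails.
nb_background_quantile <- function(pool, q) {
  m <- mean(pool)
  v <- stats::var(pool)
  if (is.na(v) || v <= m || m == 0) {
    return(qpois(q, lambda = max(m, .Machine$double.eps)))
  }
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(pool, "negative binomial")),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # method-of-moments fallback
    size <- m^2 / (v - m)
    return(qnbinom(q, size = size, mu = m))
  }
  qnbinom(q, size = fit$estimate[["size"]], mu = fit$estimate[["mu"]])
}
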