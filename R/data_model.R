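#' Assemble a GEM dataset from its component tables
#'
#' The central container of the package is a `gem_dataset`: one record per
#' droplet (GEM, gel-bead in emulsion) carrying its TCR contig observations,
#' its pMHC dextramer-barcode UMI counts, its cell-hashing UMI counts, and
#' optional gene-expression summaries. Only GEMs observed with at least one
#' TCR contig *and* at least one pMHC barcode enter the dataset; the pairing
#' problem is defined on those droplets.
#'
#' Zero counts are never materialized in `pmhc` or `hash`: absence of a
#' (gem, feature) row means 0 UMIs, matching the sparse count-matrix source.
#'
#' @param contigs Tibble of TCR contigs as returned by
#'   [read_contig_annotations()] (columns `gem_id`, `locus`, `v_gene`,
#'   `j_gene`, `c_gene`, `cdr3_aa`, `cdr3_nt`, `umi_count`, `full_length`,
#'   `productive`, optionally `is_cell`, `raw_clonotype_id`).
#' @param pmhc Long tibble `gem_id`, `pmhc_id`, `umi` (positive integers).
#' @param hash Long tibble `gem_id`, `hash_id`, `umi`.
#' @param panel Tibble of pMHC panel entries from [read_panel()].
#' @param samples Tibble of hashed samples from [read_samples()].
#' @param gex Optional tibble `gem_id`, `n_genes`, `mito_fraction`,
#'   `is_cell_gex` with per-GEM gene-expression summaries.
#' @param validate Check referential integrity (default `TRUE`).
#' @return A `gem_dataset` object (a list of tibbles).
#' @export
assemble_dataset <- function(contigs, pmhc, hash = NULL, panel, samples = NULL,
                             gex = NULL, validate = TRUE) {
  contigs <- as_tibble(contigs)
  pmhc <- as_tibble(pmhc)
  tcr_gems <- unique(contigs$gem_id)
  pmhc_gems <- unique(pmhc$gem_id)
  keep <- intersect(tcr_gems, pmhc_gems)
  n_drop <- length(union(tcr_gems, pmhc_gems)) - length(keep)
  if (n_drop > 0) {
    tp_message(n_drop, " GEMs lacked either a TCR contig or a pMHC barcode and were dropped")
  }

  gems <- tibble(gem_id = keep)
  if ("is_cell" %in% names(contigs)) {
    flags <- contigs |>
      group_by(.data$gem_id) |>
      summarise(is_cell = any(.data$is_cell %in% TRUE), .groups = "drop")
    gems <- left_join(gems, flags, by = "gem_id")
  }
  if (!is.null(gex)) {
    gems <- left_join(gems, as_tibble(gex), by = "gem_id")
  }

  hash <- if (is.null(hash)) {
    tibble(gem_id = character(), hash_id = character(), umi = integer())
  } else {
    filter(as_tibble(hash), .data$gem_id %in% keep)
  }

  ds <- structure(
    list(
      gems = gems,
      contigs = filter(contigs, .data$gem_id %in% keep),
      pmhc = filter(pmhc, .data$gem_id %in% keep),
      hash = hash,
      panel = as_tibble(panel),
      samples = if (is.null(samples)) {
        tibble(hash_id = character(), donor_id = character(),
               haplotype = list())
      } else {
        as_tibble(samples)
      },
      clonotypes = NULL,
      hash_calls = NULL
    ),
    class = "gem_dataset"
  )
  if (validate) validate_dataset(ds)
  ds
}

#' Validate a gem_dataset's referential integrity
#'
#' @param ds A `gem_dataset`.
#' @return `ds`, invisibly; errors on violation.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "gem_dataset"))
  if (anyDuplicated(ds$gems$gem_id)) {
    stop("duplicated gem_id in dataset", call. = FALSE)
  }
  if (anyDuplicated(ds$panel$pmhc_id)) {
    stop("duplicated pmhc_id in panel", call. = FALSE)
  }
  bad <- setdiff(unique(ds$pmhc$pmhc_id), ds$panel$pmhc_id)
  if (length(bad)) {
    stop("pMHC ids absent from panel: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ds$hash) && nrow(ds$samples)) {
    bad <- setdiff(unique(ds$hash$hash_id), ds$samples$hash_id)
    if (length(bad)) {
      stop("hash ids absent from sample table: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(ds$pmhc$umi <= 0)) {
    stop("pmhc UMI counts must be positive (absence encodes zero)",
         call. = FALSE)
  }
  if (!is.null(ds$clonotypes)) {
    bad <- setdiff(unlist(ds$clonotypes$member_gems), ds$gems$gem_id)
    if (length(bad)) {
      stop("clonotype member GEMs absent from dataset", call. = FALSE)
    }
  }
  invisible(ds)
}

#' Restrict a dataset to a set of GEMs
#'
#' Used by every filter step: subsets all per-GEM tables and recounts
#' clonotype membership. Filters only ever remove GEMs.
#'
#' @param ds A `gem_dataset`.
#' @param keep_ids Character vector of GEM ids to retain.
#' @return The restricted `gem_dataset`.
#' @export
subset_gems <- function(ds, keep_ids) {
  stopifnot(inherits(ds, "gem_dataset"))
  ds$gems <- filter(ds$gems, .data$gem_id %in% keep_ids)
  ds$contigs <- filter(ds$contigs, .data$gem_id %in% keep_ids)
  ds$pmhc <- filter(ds$pmhc, .data$gem_id %in% keep_ids)
  ds$hash <- filter(ds$hash, .data$gem_id %in% keep_ids)
  if (!is.null(ds$hash_calls)) {
    ds$hash_calls <- filter(ds$hash_calls, .data$gem_id %in% keep_ids)
  }
  if (!is.null(ds$clonotypes)) {
    ds$clonotypes$member_gems <- lapply(ds$clonotypes$member_gems,
                                        intersect, x = keep_ids)
    ds$clonotypes$member_gems <- lapply(ds$clonotypes$member_gems, identity)
    keep_ct <- lengths(ds$clonotypes$member_gems) > 0
    ds$clonotypes <- ds$clonotypes[keep_ct, , drop = FALSE]
    ds$clonotypes$n_gems <- lengths(ds$clonotypes$member_gems)
  }
  ds
}

#' @export
print.gem_dataset <- function(x, ...) {
  cat("<gem_dataset>\n")
  cat("  GEMs:      ", nrow(x$gems), "\n")
  cat("  contigs:   ", nrow(x$contigs), "\n")
  cat("  pMHC panel:", nrow(x$panel), "barcodes;",
      nrow(x$pmhc), "nonzero (gem, pMHC) counts\n")
  cat("  samples:   ", nrow(x$samples), "hashed;",
      nrow(x$hash), "nonzero (gem, hash) counts\n")
  if (!is.null(x$clonotypes)) {
    cat("  clonotypes:", nrow(x$clonotypes), "\n")
  }
  if (!is.null(x$hash_calls)) {
    cat("  hashing:   ",
        sum(x$hash_calls$label == "singlet"), "singlets /",
        sum(x$hash_calls$label == "doublet"), "doublets /",
        sum(x$hash_calls$label == "negative"), "negatives\n")
  }
  invisible(x)
}

# Number of GEMs in a dataset.
n_gems <- function(ds) nrow(ds$gems)
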