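#' Read a 10x-style contig annotation table
#'
#' Parses the `all_contig_annotations.csv` dialect produced by the vendor
#' V(D)J pipeline. Only TRA/TRB contigs are kept (other loci -- IGH, IGK,
#' IGL, Multi -- are dropped with a reported count). Boolean columns accept
#' `"True"/"False"` as well as `"true"/"false"` spellings.
#'
#' @param path Path to a delimited contig annotation file.
#' @param dialect Input dialect; `"10x"` expects the vendor column names
#'   (`barcode`, `chain`, `v_gene`, `j_gene`, `c_gene`, `cdr3`, `cdr3_nt`,
#'   `umis`, `full_length`, `productive`, optionally `is_cell`,
#'   `raw_clonotype_id`).
#' @return Tibble with one row per TRA/TRB contig: `gem_id`, `locus`,
#'   `v_gene`, `j_gene`, `c_gene`, `cdr3_aa`, `cdr3_nt`, `umi_count`,
#'   `full_length`, `productive` (+ `is_cell`, `raw_clonotype_id` when
#'   present).
#' @export
read_contig_annotations <- function(path, dialect = c("10x")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "cdr3_nt",
                "umis", "full_length", "productive")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("contig table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  umis <- suppressWarnings(as.integer(raw$umis))
  if (anyNA(umis) && !all(is.na(raw$umis[is.na(umis)]))) {
    bad <- which(is.na(umis) & !is.na(raw$umis))
    stop("unparseable UMI count at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out <- tibble(
    gem_id = as.character(raw$barcode),
    locus = as.character(raw$chain),
    v_gene = as.character(raw$v_gene),
    j_gene = as.character(raw$j_gene),
    c_gene = if ("c_gene" %in% names(raw)) as.character(raw$c_gene) else "",
    cdr3_aa = as.character(raw$cdr3),
    cdr3_nt = as.character(raw$cdr3_nt),
    umi_count = umis,
    full_length = parse_flexible_logical(raw$full_length),
    productive = parse_flexible_logical(raw$productive)
  )
  if ("is_cell" %in% names(raw)) {
    out$is_cell <- parse_flexible_logical(raw$is_cell)
  }
  if ("raw_clonotype_id" %in% names(raw)) {
    rcid <- as.character(raw$raw_clonotype_id)
    rcid[rcid %in% c("", "None", "NA")] <- NA_character_
    out$raw_clonotype_id <- rcid
  }
  keep <- out$locus %in% c("TRA", "TRB")
  if (any(!keep)) {
    tp_message(sum(!keep), " non-TRA/TRB contigs dropped")
  }
  out[keep, , drop = FALSE]
}

#' Read a feature-barcode count matrix (Matrix Market triplets)
#'
#' Reads an unfiltered feature x barcode UMI matrix together with its
#' feature and barcode lists, returning long-format counts with features
#' classified into pMHC / hashing / gene-expression slices. Zero entries are
#' never materialized. Duplicate triplets for the same (feature, barcode)
#' cell are summed with a warning (the Matrix Market convention).
#'
#' @param matrix_path `.mtx` triplet file.
#' @param features_path TSV of features; column 1 = feature id, optional
#'   column 3 = feature type (the vendor convention, e.g. `Antibody Capture`).
#' @param barcodes_path One barcode per line.
#' @param prefix_rules Named list with regexes classifying feature ids when
#'   no feature-type column is present, e.g.
#'   `list(pmhc = "^pMHC", hashing = "^HTO")`; unmatched ids are `gene`.
#' @return Tibble `gem_id`, `feature_id`, `feature_type`
#'   (`"pmhc"`, `"hashing"` or `"gene"`), `umi`.
#' @export
read_feature_counts <- function(matrix_path, features_path, barcodes_path,
                                prefix_rules = list(pmhc = "^pMHC",
                                                    hashing = "^(HTO|Hash)")) {
  m <- Matrix::readMM(matrix_path)
  features <- readr::read_tsv(features_path, col_names = FALSE,
                              show_col_types = FALSE, progress = FALSE)
  barcodes <- readr::read_lines(barcodes_path)
  if (nrow(m) != nrow(features)) {
    stop("matrix has ", nrow(m), " rows but features file lists ",
         nrow(features), call. = FALSE)
  }
  if (ncol(m) != length(barcodes)) {
    stop("matrix has ", ncol(m), " columns but barcodes file lists ",
         length(barcodes), call. = FALSE)
  }
  tm <- methods::as(m, "TsparseMatrix")
  key <- paste(tm@i, tm@j)
  if (anyDuplicated(key)) {
    warning("duplicate (feature, barcode) triplets summed", call. = FALSE)
  }
  # dgTMatrix -> dgCMatrix sums duplicates; go through summary of CsparseMatrix
  cm <- methods::as(tm, "CsparseMatrix")
  s <- Matrix::summary(cm)
  feature_id <- as.character(features[[1]])[s$i]
  if (ncol(features) >= 3) {
    ftype_raw <- tolower(as.character(features[[3]]))[s$i]
    feature_type <- dplyr::case_when(
      grepl("antibody|pmhc|multimer|dextramer", ftype_raw) &
        grepl("hash", tolower(feature_id)) ~ "hashing",
      grepl("hash", ftype_raw) ~ "hashing",
      grepl("antibody|pmhc|multimer|dextramer|custom", ftype_raw) ~ "pmhc",
      TRUE ~ "gene"
    )
  } else {
    feature_type <- rep("gene", length(feature_id))
    for (cls in names(prefix_rules)) {
      feature_type[grepl(prefix_rules[[cls]], feature_id)] <- cls
    }
  }
  out <- tibble(
    gem_id = barcodes[s$j],
    feature_id = feature_id,
    feature_type = feature_type,
    umi = as.integer(s$x)
  )
  filter(out, .data$umi > 0)
}

#' Read the pMHC panel configuration
#'
#' Delimited text (comma or tab, auto-detected) with columns
#' `pmhc_id`, `peptide`, `hla`, `barcode`, `selection`. HLA alleles are
#' canonicalized on read; duplicate panel ids are rejected.
#'
#' @param path Path to the panel file.
#' @return Tibble `pmhc_id`, `peptide`, `hla_allele`, `barcode_seq`,
#'   `selection_label`.
#' @export
read_panel <- function(path) {
  raw <- read_delim_auto(path)
  required <- c("pmhc_id", "peptide", "hla")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("panel table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$pmhc_id)) {
    stop("duplicate pmhc_id in panel: ",
         paste(unique(raw$pmhc_id[duplicated(raw$pmhc_id)]), collapse = ", "),
         call. = FALSE)
  }
  tibble(
    pmhc_id = as.character(raw$pmhc_id),
    peptide = as.character(raw$peptide),
    hla_allele = canonicalize_hla(as.character(raw$hla)),
    barcode_seq = if ("barcode" %in% names(raw)) as.character(raw$barcode) else NA_character_,
    selection_label = if ("selection" %in% names(raw)) {
      as.character(raw$selection)
    } else {
      "sorted"
    }
  )
}

#' Read the hashed-sample configuration
#'
#' Columns `hash_id`, `donor`, `haplotype`; the haplotype cell holds
#' `;`-separated alleles (any notation; canonicalized on read).
#'
#' @param path Path to the sample file.
#' @return Tibble `hash_id`, `donor_id`, `haplotype` (list-column of
#'   canonical allele sets).
#' @export
read_samples <- function(path) {
  raw <- read_delim_auto(path)
  required <- c("hash_id", "donor", "haplotype")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("sample table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$hash_id)) {
    stop("duplicate hash_id in sample table", call. = FALSE)
  }
  tibble(
    hash_id = as.character(raw$hash_id),
    donor_id = as.character(raw$donor),
    haplotype = parse_haplotype(as.character(raw$haplotype))
  )
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, comment = "#")
}

#' Write the flat per-GEM table
#'
#' One row per GEM with its clonotype, dominant VJ-CDR3 alpha/beta chains and
#' UMIs, the most abundant pMHC, the serialized pMHC UMI vector, the hashing
#' call and donor, HLA-match flag and viability summaries. The stage label is
#' recorded in a `#` header comment and survives the round trip through
#' [read_gem_table()].
#'
#' @param ds A `gem_dataset` (any annotation stage; absent annotations yield
#'   empty columns, never an error).
#' @param path Output CSV path.
#' @param stage_label Label for the filtering stage being written.
#' @return `path`, invisibly.
#' @export
write_gem_table <- function(ds, path, stage_label = "total") {
  tab <- flatten_gem_table(ds)
  writeLines(paste0("# stage: ", stage_label), path)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

flatten_gem_table <- function(ds) {
  chains <- gem_chain_table(ds)
  tops <- gem_top_pmhc(ds)
  pvec <- ds$pmhc |>
    arrange(.data$gem_id, .data$pmhc_id) |>
    group_by(.data$gem_id) |>
    summarise(pmhc_vector = paste0(.data$pmhc_id, ":", .data$umi,
                                   collapse = ";"),
              .groups = "drop")
  tab <- ds$gems |>
    select(all_of("gem_id"),
           any_of(c("clonotype_id", "n_genes", "mito_fraction", "is_cell",
                    "is_cell_gex"))) |>
    left_join(chains, by = "gem_id") |>
    left_join(tops, by = "gem_id") |>
    left_join(pvec, by = "gem_id")
  if (!is.null(ds$hash_calls)) {
    hc <- ds$hash_calls |>
      mutate(positive_hashes = vapply(.data$positive_hashes, paste,
                                      character(1), collapse = ";")) |>
      select(all_of(c("gem_id", "label", "positive_hashes")), any_of("donor_id")) |>
      rename(hash_label = "label")
    tab <- left_join(tab, hc, by = "gem_id")
  } else {
    tab$hash_label <- NA_character_
    tab$positive_hashes <- NA_character_
  }
  arrange(tab, .data$gem_id)
}

#' Read back a flat GEM table written by [write_gem_table()]
#'
#' @param path CSV path.
#' @return List with elements `table` (tibble) and `stage` (the recorded
#'   stage label).
#' @export
read_gem_table <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  stage <- if (startsWith(first, "# stage: ")) {
    sub("^# stage: ", "", first)
  } else {
    NA_character_
  }
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  list(table = as_tibble(tab), stage = stage)
}

#' @importFrom dplyr any_of
NULL
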