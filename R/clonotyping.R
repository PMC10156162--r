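#' Filter contigs on completeness and productivity
#'
#' Retains only receptor contigs that are full length (spanning the V-gene
#' start codon to the J-gene stop codon) and productive (no frameshift
#' inducing an early stop or removing it). Removal counts are reported per
#' reason.
#'
#' @param contigs Contig tibble from [read_contig_annotations()].
#' @return The retained contigs (possibly zero rows).
#' @export
filter_contigs <- function(contigs) {
  incomplete <- !(contigs$full_length %in% TRUE)
  unproductive <- !(contigs$productive %in% TRUE)
  if (any(incomplete) || any(unproductive)) {
    tp_message(sum(incomplete), " incomplete and ",
               sum(unproductive & !incomplete),
               " unproductive contigs removed")
  }
  contigs[!(incomplete | unproductive), , drop = FALSE]
}

#' Select the dominant chain per locus in each GEM
#'
#' A GEM can carry several TRA and/or TRB contigs (true dual-TCR cells,
#' doublets, or ambient transcripts). Per locus the contig with the highest
#' UMI count is selected to represent the TCR. UMI ties are broken toward
#' the lexicographically smallest CDR3 nucleotide sequence for determinism,
#' and the GEM is flagged `chain_ambiguous` so the complete-TCR filter can
#' exclude it. The original per-locus contig multiplicity (`n_tra`,
#' `n_trb`) is retained for the same filter. Applied after clonotype
#' definition in the pipeline.
#'
#' @param ds A `gem_dataset`.
#' @return `ds` with dominant-chain columns added to `ds$gems`: `va`, `ja`,
#'   `cdr3a`, `cdr3a_nt`, `umi_a`, `umi_a_sec`, `n_tra` (and the `b`
#'   equivalents), plus `chain_ambiguous`.
#' @export
select_dominant_chains <- function(ds) {
  stopifnot(inherits(ds, "gem_dataset"))
  chains <- dominant_chain_table(ds$contigs)
  drop_cols <- setdiff(names(chains), "gem_id")
  ds$gems <- ds$gems[, setdiff(names(ds$gems), drop_cols), drop = FALSE]
  ds$gems <- left_join(ds$gems, chains, by = "gem_id")
  ds$gems$n_tra[is.na(ds$gems$n_tra)] <- 0L
  ds$gems$n_trb[is.na(ds$gems$n_trb)] <- 0L
  ds$gems$chain_ambiguous[is.na(ds$gems$chain_ambiguous)] <- FALSE
  ds
}

dominant_chain_table <- function(contigs) {
  per_locus <- function(loc, suffix) {
    cc <- filter(contigs, .data$locus == loc) |>
      arrange(.data$gem_id, dplyr::desc(.data$umi_count), .data$cdr3_nt) |>
      group_by(.data$gem_id) |>
      summarise(
        v = first(.data$v_gene),
        j = first(.data$j_gene),
        cdr3 = first(.data$cdr3_aa),
        cdr3_nt = first(.data$cdr3_nt),
        umi = first(.data$umi_count),
        umi_sec = if (n() > 1) .data$umi_count[2] else 0L,
        n_chain = n(),
        tie = n() > 1 && .data$umi_count[1] == .data$umi_count[2],
        .groups = "drop"
      )
    names(cc) <- c("gem_id",
                   paste0(c("v", "j", "cdr3"), suffix),
                   paste0("cdr3", suffix, "_nt"),
                   paste0("umi_", suffix),
                   paste0("umi_", suffix, "_sec"),
                   paste0("n_tr", suffix),
                   paste0("tie_", suffix))
    cc
  }
  a <- per_locus("TRA", "a")
  b <- per_locus("TRB", "b")
  out <- dplyr::full_join(a, b, by = "gem_id")
  out$n_tra <- ifelse(is.na(out$n_tra), 0L, out$n_tra)
  out$n_trb <- ifelse(is.na(out$n_trb), 0L, out$n_trb)
  out$chain_ambiguous <- (out$tie_a %in% TRUE) | (out$tie_b %in% TRUE)
  out$tie_a <- NULL
  out$tie_b <- NULL
  out
}

gem_chain_table <- function(ds) {
  if (!"va" %in% names(ds$gems)) {
    ds <- select_dominant_chains(ds)
  }
  select(ds$gems, all_of(c("gem_id")),
         any_of(c("va", "ja", "cdr3a", "cdr3a_nt", "umi_a", "umi_a_sec",
                  "n_tra", "vb", "jb", "cdr3b", "cdr3b_nt", "umi_b",
                  "umi_b_sec", "n_trb", "chain_ambiguous")))
}

#' Collapse clonotypes on identical VJ-CDR3 alpha/beta and impute unassigned GEMs
#'
#' Vendor clonotypes consisting of identical V gene, J gene and CDR3 on both
#' the alpha and beta chain are merged under one id (reducing functional
#' duplicates). GEMs without a vendor clonotype annotation (the vendor flags
#' rare transcripts as unlikely cells and leaves them unassigned) are imputed
#' by searching the duplicate-reduced clonotype set: a full VJ-CDR3
#' alpha/beta match joins the matching clonotype; a GEM carrying only one
#' chain joins a clonotype only when exactly one clonotype matches that
#' chain's VJ-CDR3 (several matches are left unresolved and the GEM founds
#' its own single-chain clonotype); novel combinations found new clonotypes.
#' Every TCR-bearing GEM ends with exactly one clonotype id.
#'
#' Members whose defined chains contradict their vendor clonotype's
#' consensus definition are reassigned by the same matching rule, with a
#' warning. The merge key uses amino-acid CDR3 by default (`use_nt = TRUE`
#' switches to nucleotide CDR3), plus V and J gene names; the C gene is
#' ignored.
#'
#' @param ds A `gem_dataset` (dominant chains are selected first if absent).
#' @param use_nt Match CDR3 at nucleotide rather than amino-acid level.
#' @return `ds` with `ds$gems$clonotype_id` set and `ds$clonotypes` a tibble
#'   `clonotype_id`, `va`, `ja`, `cdr3a`, `vb`, `jb`, `cdr3b`,
#'   `member_gems` (list-column), `n_gems`.
#' @export
collapse_and_impute_clonotypes <- function(ds, use_nt = FALSE) {
  stopifnot(inherits(ds, "gem_dataset"))
  if (!"va" %in% names(ds$gems)) ds <- select_dominant_chains(ds)
  g <- ds$gems
  cdr3a <- if (use_nt) g$cdr3a_nt else g$cdr3a
  cdr3b <- if (use_nt) g$cdr3b_nt else g$cdr3b

  # Per-GEM chain triples (NA = chain absent)
  key <- tibble(
    gem_id = g$gem_id,
    a = ifelse(is.na(g$va), NA_character_,
               paste(g$va, g$ja, cdr3a, sep = "|")),
    b = ifelse(is.na(g$vb), NA_character_,
               paste(g$vb, g$jb, cdr3b, sep = "|"))
  )
  has_tcr <- !(is.na(key$a) & is.na(key$b))

  vendor <- vendor_clonotype_ids(ds)
  key$vendor <- vendor[match(key$gem_id, names(vendor))]

  # Consensus triple per vendor clonotype and chain; contradictory members
  # are released for re-imputation.
  assigned <- filter(key, !is.na(.data$vendor) & has_tcr)
  unassigned <- filter(key, is.na(.data$vendor) & has_tcr)

  consensus <- assigned |>
    group_by(.data$vendor) |>
    summarise(a = mode_or_na(.data$a), b = mode_or_na(.data$b),
              .groups = "drop")
  assigned <- left_join(assigned, consensus, by = "vendor",
                        suffix = c("", "_def"))
  contra <- (!is.na(assigned$a) & !is.na(assigned$a_def) &
               assigned$a != assigned$a_def) |
    (!is.na(assigned$b) & !is.na(assigned$b_def) &
       assigned$b != assigned$b_def)
  if (any(contra)) {
    warning(sum(contra), " GEM(s) contradicted their vendor clonotype ",
            "definition and were reassigned", call. = FALSE)
    unassigned <- bind_rows(unassigned,
                            select(assigned[contra, ], all_of(c("gem_id", "a", "b", "vendor"))))
    assigned <- assigned[!contra, , drop = FALSE]
  }

  # Merge vendor clonotypes with identical defined tuples
  consensus <- filter(consensus, .data$vendor %in% assigned$vendor)
  consensus$tuple <- paste(ifelse(is.na(consensus$a), "", consensus$a),
                           ifelse(is.na(consensus$b), "", consensus$b),
                           sep = "||")
  tuples <- unique(consensus$tuple)
  consensus$ct <- match(consensus$tuple, tuples)
  assigned$ct <- consensus$ct[match(assigned$vendor, consensus$vendor)]

  ct_def <- consensus |>
    distinct(.data$ct, .data$a, .data$b) |>
    arrange(.data$ct)

  # Imputation against the duplicate-reduced clonotype set
  new_rows <- list()
  if (nrow(unassigned)) {
    imp <- impute_gems(unassigned, ct_def)
    assigned <- bind_rows(select(assigned, all_of(c("gem_id", "ct"))),
                          imp$assigned)
    new_rows <- imp$new_defs
    ct_def <- bind_rows(ct_def, imp$new_defs)
  } else {
    assigned <- select(assigned, all_of(c("gem_id", "ct")))
  }

  # Materialize
  ct_def <- arrange(ct_def, .data$ct)
  ids <- sprintf("ct%04d", seq_len(nrow(ct_def)))
  split_triple <- function(x, i) {
    ifelse(is.na(x), NA_character_,
           vapply(strsplit(x, "|", fixed = TRUE), `[`, character(1), i))
  }
  members <- split(assigned$gem_id, assigned$ct)
  members <- unname(lapply(members[as.character(ct_def$ct)], unique))
  clonotypes <- tibble(
    clonotype_id = ids,
    va = split_triple(ct_def$a, 1), ja = split_triple(ct_def$a, 2),
    cdr3a = split_triple(ct_def$a, 3),
    vb = split_triple(ct_def$b, 1), jb = split_triple(ct_def$b, 2),
    cdr3b = split_triple(ct_def$b, 3),
    member_gems = members,
    n_gems = lengths(members)
  )
  keep <- clonotypes$n_gems > 0
  clonotypes <- clonotypes[keep, , drop = FALSE]

  assign_map <- setNames(ids[match(assigned$ct, ct_def$ct)], assigned$gem_id)
  ds$gems$clonotype_id <- unname(assign_map[ds$gems$gem_id])
  ds$clonotypes <- clonotypes
  validate_dataset(ds)
  ds
}

# Vendor clonotype annotation per GEM: previous in-package assignment wins
# (making the operation idempotent), else the vendor's raw id.
vendor_clonotype_ids <- function(ds) {
  if ("clonotype_id" %in% names(ds$gems) &&
      any(!is.na(ds$gems$clonotype_id))) {
    ids <- ds$gems$clonotype_id
    return(setNames(ids, ds$gems$gem_id))
  }
  if ("raw_clonotype_id" %in% names(ds$contigs)) {
    per_gem <- ds$contigs |>
      filter(!is.na(.data$raw_clonotype_id)) |>
      distinct(.data$gem_id, .data$raw_clonotype_id) |>
      group_by(.data$gem_id) |>
      summarise(id = first(.data$raw_clonotype_id), .groups = "drop")
    return(setNames(per_gem$id, per_gem$gem_id))
  }
  setNames(character(0), character(0))
}

mode_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  tt <- sort(table(x), decreasing = TRUE)
  names(tt)[1]
}

impute_gems <- function(unassigned, ct_def) {
  # Group unassigned GEMs by their own key first: identical novel keys found
  # one clonotype together.
  res_ct <- integer(nrow(unassigned))
  next_ct <- max(c(ct_def$ct, 0L))
  new_defs <- list()
  new_key_ct <- character(0)

  for (i in seq_len(nrow(unassigned))) {
    a <- unassigned$a[i]; b <- unassigned$b[i]
    if (!is.na(a) && !is.na(b)) {
      hit <- which(!is.na(ct_def$a) & !is.na(ct_def$b) &
                     ct_def$a == a & ct_def$b == b)
      matched <- length(hit) >= 1L
      if (matched) res_ct[i] <- ct_def$ct[hit[1]]
    } else if (!is.na(a)) {
      hit <- which(!is.na(ct_def$a) & ct_def$a == a)
      matched <- length(hit) == 1L
      if (matched) res_ct[i] <- ct_def$ct[hit]
    } else {
      hit <- which(!is.na(ct_def$b) & ct_def$b == b)
      matched <- length(hit) == 1L
      if (matched) res_ct[i] <- ct_def$ct[hit]
    }
    if (!matched) {
      k <- paste(ifelse(is.na(a), "", a), ifelse(is.na(b), "", b), sep = "||")
      j <- match(k, names(new_key_ct))
      if (is.na(j)) {
        next_ct <- next_ct + 1L
        new_key_ct[k] <- next_ct
        new_defs[[length(new_defs) + 1L]] <- tibble(ct = next_ct, a = a, b = b)
        res_ct[i] <- next_ct
      } else {
        res_ct[i] <- as.integer(new_key_ct[j])
      }
    }
  }
  list(
    assigned = tibble(gem_id = unassigned$gem_id, ct = res_ct),
    new_defs = if (length(new_defs)) bind_rows(new_defs) else
      tibble(ct = integer(), a = character(), b = character())
  )
}
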