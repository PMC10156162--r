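#' Parameters for the synthetic GEM-level data generator
#'
#' The generator emulates the noise processes of droplet-based barcoded
#' immune profiling: ambient pMHC contamination (free-floating reagents
#' partitioned into droplets), chain dropout, droplet doublets, and hashing
#' background. Defaults describe a mid-sized screen: 300 clonotypes with
#' power-law clone sizes, 10 pMHC barcodes over 5 HLA alleles, negative
#' binomial signal UMIs (mean 8, dispersion 5), Poisson(0.5) ambient
#' contamination per non-target pMHC, chain dropout 0.1 (alpha) / 0.05
#' (beta), 5% droplet doublets, and hashing counts of NB(mean 80, size 10)
#' on the true sample versus NB(mean 2, size 5) background.
#'
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @param n_clonotypes Number of distinct TCR clonotypes.
#' @param clone_size_exponent,clone_size_max Power-law exponent and cap of
#'   the clone-size distribution (`P(s) ~ s^-exponent`, `s = 1..max`).
#' @param n_pmhc Number of pMHC barcodes in the panel (>= 2).
#' @param n_samples Number of hashed donors.
#' @param signal_mean,signal_size Negative binomial UMI model for the
#'   planted target pMHC and the TCR chains.
#' @param hash_signal_mean,hash_signal_size,hash_bg_mean,hash_bg_size
#'   Hashing UMI models (true sample vs background).
#' @param ambient_rate Poisson mean of ambient UMIs per non-target pMHC per
#'   GEM (zeros are not materialized).
#' @param dropout_alpha,dropout_beta Per-GEM chain dropout probabilities.
#' @param doublet_rate Fraction of GEMs formed by merging two droplets.
#' @param multi_chain_rate Probability of a spurious extra low-UMI chain.
#' @param junk_contig_rate Probability of an additional incomplete or
#'   unproductive contig copy (removed by the contig filter).
#' @param unassigned_rate Fraction of GEMs the simulated vendor pipeline
#'   leaves without a clonotype annotation (exercises imputation).
#' @param hla_mismatch_rate Fraction of clonotypes planted with a target
#'   outside their donor's haplotype (exercises the HLA filter).
#' @param cross_reactive_rate Fraction of clonotypes with two planted
#'   targets (off by default; exercises the concordance machinery).
#' @return A validated `simulation_params` object.
#' @export
simulation_params <- function(seed = 42L,
                              n_clonotypes = 300L,
                              clone_size_exponent = 1.5,
                              clone_size_max = 50L,
                              n_pmhc = 10L,
                              n_samples = 4L,
                              signal_mean = 8, signal_size = 5,
                              hash_signal_mean = 80, hash_signal_size = 10,
                              hash_bg_mean = 2, hash_bg_size = 5,
                              ambient_rate = 0.5,
                              dropout_alpha = 0.1, dropout_beta = 0.05,
                              doublet_rate = 0.05,
                              multi_chain_rate = 0.05,
                              junk_contig_rate = 0.03,
                              unassigned_rate = 0.1,
                              hla_mismatch_rate = 0,
                              cross_reactive_rate = 0) {
  p <- as.list(environment())
  rates <- c(p$ambient_rate, p$signal_mean, p$hash_signal_mean, p$hash_bg_mean)
  probs <- c(p$dropout_alpha, p$dropout_beta, p$doublet_rate,
             p$multi_chain_rate, p$junk_contig_rate, p$unassigned_rate,
             p$hla_mismatch_rate, p$cross_reactive_rate)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]",
                                       call. = FALSE)
  if (p$n_pmhc < 2) stop("need at least 2 pMHC barcodes", call. = FALSE)
  structure(p, class = "simulation_params")
}

sim_alleles <- c("A*01:01", "A*02:01", "A*03:01", "B*07:02", "B*08:01")
aa_letters <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_cdr3 <- function(n, prefix, suffix = "F") {
  len <- sample(10:18, n, replace = TRUE)
  mid <- len - nchar(prefix) - nchar(suffix)
  vapply(seq_len(n), function(i) {
    paste0(prefix,
           paste(sample(aa_letters, mid[i], replace = TRUE), collapse = ""),
           suffix)
  }, character(1))
}

random_nt <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a GEM-level dataset with planted ground truth
#'
#' Each clonotype receives a unique VJ-CDR3 alpha/beta identity, a donor,
#' and one planted target pMHC consistent with the donor's haplotype (unless
#' planted mismatching via `hla_mismatch_rate`). Per GEM, target pMHC UMIs
#' follow the signal model, every non-target pMHC receives Poisson ambient
#' UMIs (zeros dropped), chains drop out independently, hashing counts are
#' drawn signal-vs-background, and a configured fraction of droplets are
#' doublets merging two GEMs' contents. The ground-truth table lists each
#' GEM's true clonotype, target and donor.
#'
#' @param params A [simulation_params()] object.
#' @return List with `dataset` (an assembled `gem_dataset`), `truth`
#'   (tibble `gem_id`, `true_clonotype`, `true_target`, `true_donor`,
#'   `true_hash`, `is_doublet`), and `clonotype_truth` (per-clonotype
#'   identities and planted targets).
#' @export
simulate_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  set.seed(p$seed)

  # Panel and donors
  alleles <- rep_len(sim_alleles, p$n_pmhc)
  panel <- tibble(
    pmhc_id = sprintf("pMHC%02d", seq_len(p$n_pmhc)),
    peptide = random_cdr3(p$n_pmhc, prefix = "", suffix = ""),
    hla_allele = alleles,
    barcode_seq = random_nt(p$n_pmhc, 15),
    selection_label = "sorted"
  )
  samples <- tibble(
    hash_id = sprintf("Hash%02d", seq_len(p$n_samples)),
    donor_id = sprintf("donor%02d", seq_len(p$n_samples)),
    haplotype = lapply(seq_len(p$n_samples), function(i) {
      sort(sample(unique(alleles), min(3, length(unique(alleles)))))
    })
  )
  if (!all(vapply(samples$haplotype,
                  function(h) any(panel$hla_allele %in% h), logical(1)))) {
    stop("simulated haplotypes incompatible with panel", call. = FALSE)
  }

  # Clonotype identities (unique VJ-CDR3 pairs)
  nct <- p$n_clonotypes
  repeat {
    cdr3a <- random_cdr3(nct, "CA")
    cdr3b <- random_cdr3(nct, "CASS")
    if (!anyDuplicated(paste(cdr3a, cdr3b))) break
  }
  donor_idx <- sample(p$n_samples, nct, replace = TRUE)
  target <- character(nct)
  for (i in seq_len(nct)) {
    hap <- samples$haplotype[[donor_idx[i]]]
    matching <- panel$pmhc_id[panel$hla_allele %in% hap]
    nonmatching <- setdiff(panel$pmhc_id, matching)
    mismatch <- length(nonmatching) > 0 && runif(1) < p$hla_mismatch_rate
    pool <- if (mismatch) nonmatching else matching
    target[i] <- sample(pool, 1)
  }
  second_target <- rep(NA_character_, nct)
  xr <- runif(nct) < p$cross_reactive_rate
  for (i in which(xr)) {
    hap <- samples$haplotype[[donor_idx[i]]]
    pool <- setdiff(panel$pmhc_id[panel$hla_allele %in% hap], target[i])
    if (length(pool)) second_target[i] <- sample(pool, 1)
  }
  sizes <- sample(seq_len(p$clone_size_max), nct, replace = TRUE,
                  prob = seq_len(p$clone_size_max)^(-p$clone_size_exponent))
  clonotype_truth <- tibble(
    true_clonotype = sprintf("simct%03d", seq_len(nct)),
    va = sprintf("TRAV%d", sample(1:40, nct, replace = TRUE)),
    ja = sprintf("TRAJ%d", sample(1:50, nct, replace = TRUE)),
    cdr3a = cdr3a,
    cdr3a_nt = random_nt(nct, 36),
    vb = sprintf("TRBV%d", sample(1:30, nct, replace = TRUE)),
    jb = sprintf("TRBJ%d-%d", sample(1:2, nct, replace = TRUE),
                 sample(1:6, nct, replace = TRUE)),
    cdr3b = cdr3b,
    cdr3b_nt = random_nt(nct, 42),
    donor_idx = donor_idx,
    true_donor = samples$donor_id[donor_idx],
    true_hash = samples$hash_id[donor_idx],
    true_target = target,
    second_target = second_target,
    n_gems = sizes
  )

  # Per-GEM draws
  ct_of_gem <- rep(seq_len(nct), sizes)
  n <- length(ct_of_gem)
  gem_id <- sprintf("%s-1", random_nt(n, 16))
  while (anyDuplicated(gem_id)) {
    dup <- duplicated(gem_id)
    gem_id[dup] <- sprintf("%s-1", random_nt(sum(dup), 16))
  }

  contigs <- vector("list", n)
  pmhc_rows <- vector("list", n)
  hash_rows <- vector("list", n)
  for (g in seq_len(n)) {
    i <- ct_of_gem[g]
    rows <- list()
    if (runif(1) >= p$dropout_alpha) {
      rows[[length(rows) + 1L]] <- tibble(
        gem_id = gem_id[g], locus = "TRA",
        v_gene = clonotype_truth$va[i], j_gene = clonotype_truth$ja[i],
        c_gene = "TRAC", cdr3_aa = clonotype_truth$cdr3a[i],
        cdr3_nt = clonotype_truth$cdr3a_nt[i],
        umi_count = pmax(1L, rnbinom(1, mu = p$signal_mean,
                                     size = p$signal_size)),
        full_length = TRUE, productive = TRUE
      )
    }
    if (runif(1) >= p$dropout_beta) {
      rows[[length(rows) + 1L]] <- tibble(
        gem_id = gem_id[g], locus = "TRB",
        v_gene = clonotype_truth$vb[i], j_gene = clonotype_truth$jb[i],
        c_gene = "TRBC1", cdr3_aa = clonotype_truth$cdr3b[i],
        cdr3_nt = clonotype_truth$cdr3b_nt[i],
        umi_count = pmax(1L, rnbinom(1, mu = p$signal_mean,
                                     size = p$signal_size)),
        full_length = TRUE, productive = TRUE
      )
    }
    if (length(rows) && runif(1) < p$multi_chain_rate) {
      other <- sample(setdiff(seq_len(nct), i), 1)
      rows[[length(rows) + 1L]] <- tibble(
        gem_id = gem_id[g], locus = "TRA",
        v_gene = clonotype_truth$va[other], j_gene = clonotype_truth$ja[other],
        c_gene = "TRAC", cdr3_aa = clonotype_truth$cdr3a[other],
        cdr3_nt = clonotype_truth$cdr3a_nt[other],
        umi_count = 1L + rpois(1, 0.5),
        full_length = TRUE, productive = TRUE
      )
    }
    if (length(rows) && runif(1) < p$junk_contig_rate) {
      junk <- rows[[1]]
      junk$umi_count <- 1L
      junk$cdr3_aa <- paste0(substr(junk$cdr3_aa, 1, 4), "*")
      if (runif(1) < 0.5) junk$full_length <- FALSE else junk$productive <- FALSE
      rows[[length(rows) + 1L]] <- junk
    }
    contigs[[g]] <- bind_rows(rows)

    targets <- c(clonotype_truth$true_target[i],
                 clonotype_truth$second_target[i])
    targets <- targets[!is.na(targets)]
    tgt_umi <- rnbinom(length(targets), mu = p$signal_mean,
                       size = p$signal_size)
    ambient <- rpois(p$n_pmhc, p$ambient_rate)
    names(ambient) <- panel$pmhc_id
    ambient[targets] <- ambient[targets] + tgt_umi
    pos <- ambient[ambient > 0]
    if (length(pos)) {
      pmhc_rows[[g]] <- tibble(gem_id = gem_id[g], pmhc_id = names(pos),
                               umi = as.integer(pos))
    }
    hcounts <- rnbinom(p$n_samples, mu = p$hash_bg_mean, size = p$hash_bg_size)
    hcounts[clonotype_truth$donor_idx[i]] <-
      rnbinom(1, mu = p$hash_signal_mean, size = p$hash_signal_size)
    hpos <- which(hcounts > 0)
    if (length(hpos)) {
      hash_rows[[g]] <- tibble(gem_id = gem_id[g],
                               hash_id = samples$hash_id[hpos],
                               umi = as.integer(hcounts[hpos]))
    }
  }
  contigs <- bind_rows(contigs)
  pmhc <- bind_rows(pmhc_rows)
  hash <- bind_rows(hash_rows)

  truth <- tibble(
    gem_id = gem_id,
    true_clonotype = clonotype_truth$true_clonotype[ct_of_gem],
    true_target = clonotype_truth$true_target[ct_of_gem],
    true_donor = clonotype_truth$true_donor[ct_of_gem],
    true_hash = clonotype_truth$true_hash[ct_of_gem],
    is_doublet = FALSE,
    second_clonotype = NA_character_
  )

  # Droplet doublets: merge pairs of GEMs' full contents
  n_doublet <- floor(p$doublet_rate * n / 2)
  if (n_doublet > 0) {
    picked <- sample(n, 2 * n_doublet)
    keepers <- picked[seq_len(n_doublet)]
    absorbed <- picked[n_doublet + seq_len(n_doublet)]
    for (d in seq_len(n_doublet)) {
      a <- gem_id[keepers[d]]
      b <- gem_id[absorbed[d]]
      contigs$gem_id[contigs$gem_id == b] <- a
      pmhc$gem_id[pmhc$gem_id == b] <- a
      hash$gem_id[hash$gem_id == b] <- a
      truth$is_doublet[truth$gem_id == a] <- TRUE
      truth$second_clonotype[truth$gem_id == a] <-
        truth$true_clonotype[truth$gem_id == b]
    }
    truth <- filter(truth, !.data$gem_id %in% gem_id[absorbed])
    pmhc <- pmhc |>
      group_by(.data$gem_id, .data$pmhc_id) |>
      summarise(umi = sum(.data$umi), .groups = "drop")
    hash <- hash |>
      group_by(.data$gem_id, .data$hash_id) |>
      summarise(umi = sum(.data$umi), .groups = "drop")
  }

  # Vendor clonotype annotation (left blank for a fraction of GEMs) and
  # gene-expression summaries
  all_gems <- unique(contigs$gem_id)
  vendor_of_ct <- sprintf("clonotype%d", seq_len(nct))
  vend <- vendor_of_ct[ct_of_gem[match(all_gems, gem_id)]]
  vend[runif(length(vend)) < p$unassigned_rate] <- NA_character_
  contigs$raw_clonotype_id <- vend[match(contigs$gem_id, all_gems)]
  contigs$is_cell <- runif(nrow(contigs)) > 0.02

  gex <- tibble(
    gem_id = all_gems,
    n_genes = as.integer(rnbinom(length(all_gems), mu = 1200, size = 6)),
    mito_fraction = stats::rbeta(length(all_gems), 2, 18),
    is_cell_gex = runif(length(all_gems)) > 0.03
  )

  ds <- suppressMessages(assemble_dataset(
    contigs = filter_contigs(contigs),
    pmhc = pmhc, hash = hash, panel = panel, samples = samples, gex = gex
  ))
  list(dataset = ds, truth = truth, clonotype_truth = clonotype_truth)
}

#' Write a simulated dataset in the raw input formats
#'
#' Emits the same files the readers consume: a contig annotation CSV, a
#' Matrix Market feature-barcode matrix with feature and barcode lists, and
#' panel / sample config CSVs, so simulated fixtures exercise the I/O layer
#' end to end.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_tenx_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  contig_path <- file.path(dir, "all_contig_annotations.csv")
  contigs <- ds$contigs
  readr::write_csv(tibble(
    barcode = contigs$gem_id, is_cell = contigs$is_cell %||% TRUE,
    chain = contigs$locus, v_gene = contigs$v_gene, j_gene = contigs$j_gene,
    c_gene = contigs$c_gene, cdr3 = contigs$cdr3_aa,
    cdr3_nt = contigs$cdr3_nt, umis = contigs$umi_count,
    full_length = contigs$full_length, productive = contigs$productive,
    raw_clonotype_id = contigs$raw_clonotype_id %||% NA_character_
  ), contig_path)

  feats <- c(ds$panel$pmhc_id, ds$samples$hash_id)
  barcodes <- ds$gems$gem_id
  long <- bind_rows(
    tibble(f = ds$pmhc$pmhc_id, b = ds$pmhc$gem_id, x = ds$pmhc$umi),
    tibble(f = ds$hash$hash_id, b = ds$hash$gem_id, x = ds$hash$umi)
  )
  m <- Matrix::sparseMatrix(
    i = match(long$f, feats), j = match(long$b, barcodes), x = long$x,
    dims = c(length(feats), length(barcodes))
  )
  mtx_path <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(m, mtx_path)
  features_path <- file.path(dir, "features.tsv")
  readr::write_tsv(tibble(id = feats, name = feats,
                          type = "Antibody Capture"),
                   features_path, col_names = FALSE)
  barcodes_path <- file.path(dir, "barcodes.tsv")
  readr::write_lines(barcodes, barcodes_path)

  panel_path <- file.path(dir, "panel.csv")
  readr::write_csv(tibble(
    pmhc_id = ds$panel$pmhc_id, peptide = ds$panel$peptide,
    hla = ds$panel$hla_allele, barcode = ds$panel$barcode_seq,
    selection = ds$panel$selection_label
  ), panel_path)
  samples_path <- file.path(dir, "samples.csv")
  readr::write_csv(tibble(
    hash_id = ds$samples$hash_id, donor = ds$samples$donor_id,
    haplotype = vapply(ds$samples$haplotype, paste, character(1),
                       collapse = ";")
  ), samples_path)

  invisible(list(contigs = contig_path, matrix = mtx_path,
                 features = features_path, barcodes = barcodes_path,
                 panel = panel_path, samples = samples_path))
}

#' Score pipeline outputs against the simulation's planted truth
#'
#' @param ds The clonotyped, hash-demultiplexed `gem_dataset` built from a
#'   simulation (raw or filtered).
#' @param truth The simulation's ground-truth table.
#' @param expected Expected binders on `ds` (computed when `NULL`).
#' @param min_gems Clonotype size floor for the recovery metric.
#' @return List `target_recovery` (fraction of >= `min_gems`-GEM true
#'   clonotypes whose expected binder equals the planted target),
#'   `gem_precision`, `gem_recall` (retained-GEM annotation vs truth),
#'   `hashing_accuracy` (singlet call with the true hash among non-doublet
#'   GEMs), `n_clonotypes_scored`.
#' @export
score_against_truth <- function(ds, truth, expected = NULL,
                                min_gems = 10L) {
  if (!all(ds$gems$gem_id %in% truth$gem_id)) {
    stop("dataset contains GEMs absent from the ground-truth table",
         call. = FALSE)
  }
  if (is.null(expected)) expected <- expected_binders(ds, min_gems = min_gems)
  tr <- filter(truth, .data$gem_id %in% ds$gems$gem_id)

  # Map true clonotypes (>= min_gems GEMs present) to inferred clonotypes by
  # majority membership, then compare expected binders to planted targets.
  cmap <- gem_clonotype_map(ds)
  tr$inferred <- unname(cmap[tr$gem_id])
  by_ct <- tr |>
    filter(!.data$is_doublet) |>
    group_by(.data$true_clonotype) |>
    summarise(
      n = n(),
      inferred = mode_or_na(.data$inferred),
      true_target = first(.data$true_target),
      .groups = "drop"
    ) |>
    filter(.data$n >= min_gems)
  called <- expected$pmhc_id[match(by_ct$inferred, expected$clonotype_id)]
  target_recovery <- if (nrow(by_ct)) {
    mean(!is.na(called) & called == by_ct$true_target)
  } else {
    NA_real_
  }

  tops <- gem_top_pmhc(ds)
  top <- tops$top_pmhc[match(tr$gem_id, tops$gem_id)]
  correct <- !is.na(top) & top == tr$true_target
  gem_precision <- mean(correct)
  gem_recall <- sum(correct) / nrow(truth)

  hashing_accuracy <- NA_real_
  if (!is.null(ds$hash_calls)) {
    hc <- ds$hash_calls[match(tr$gem_id, ds$hash_calls$gem_id), ]
    nd <- !tr$is_doublet
    ok <- hc$label == "singlet" &
      vapply(hc$positive_hashes, function(p) length(p) == 1,
             logical(1)) &
      vapply(seq_len(nrow(tr)), function(i) {
        length(hc$positive_hashes[[i]]) == 1 &&
          hc$positive_hashes[[i]] == tr$true_hash[i]
      }, logical(1))
    hashing_accuracy <- mean(ok[nd])
  }
  list(target_recovery = target_recovery,
       gem_precision = gem_precision,
       gem_recall = gem_recall,
       hashing_accuracy = hashing_accuracy,
       n_clonotypes_scored = nrow(by_ct))
}
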