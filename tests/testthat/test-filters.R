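# A hand-built multi-donor dataset exercising every filter predicate.
filter_fixture <- function() {
  contigs <- dplyr::bind_rows(
    # G1: complete clean TCR, donor01, top pA (A*03:01, matches donor01)
    tiny_contig("G1-1", "TRA", "TRAV1", "TRAJ1", "CAVAAF", "TGTA", 5L),
    tiny_contig("G1-1", "TRB", "TRBV1", "TRBJ1-1", "CASSAAF", "TGTB", 6L),
    # G2: alpha only
    tiny_contig("G2-1", "TRA", "TRAV2", "TRAJ2", "CAVBBF", "TGTC", 4L),
    # G3: two alphas + one beta
    tiny_contig("G3-1", "TRA", "TRAV3", "TRAJ3", "CAVCCF", "TGTD", 7L),
    tiny_contig("G3-1", "TRA", "TRAV4", "TRAJ4", "CAVDDF", "TGTE", 2L),
    tiny_contig("G3-1", "TRB", "TRBV3", "TRBJ1-2", "CASSCCF", "TGTF", 5L),
    # G4: complete TCR, donor02, top pB (B*07:02, NOT in donor02 haplotype)
    tiny_contig("G4-1", "TRA", "TRAV5", "TRAJ5", "CAVEEF", "TGTG", 5L),
    tiny_contig("G4-1", "TRB", "TRBV5", "TRBJ2-1", "CASSEEF", "TGTH", 6L),
    # G5: same clonotype as G1 (specificity multiplet partner)
    tiny_contig("G5-1", "TRA", "TRAV1", "TRAJ1", "CAVAAF", "TGTA", 3L),
    tiny_contig("G5-1", "TRB", "TRBV1", "TRBJ1-1", "CASSAAF", "TGTB", 4L),
    # G6: complete TCR, hashing negative, pA
    tiny_contig("G6-1", "TRA", "TRAV6", "TRAJ6", "CAVFFF", "TGTI", 5L),
    tiny_contig("G6-1", "TRB", "TRBV6", "TRBJ2-2", "CASSFFF", "TGTJ", 6L)
  )
  pmhc <- dplyr::bind_rows(
    tibble::tibble(gem_id = "G1-1", pmhc_id = c("pA", "pB"),
                   umi = c(10L, 2L)),
    tibble::tibble(gem_id = "G2-1", pmhc_id = "pA", umi = 1L),
    tibble::tibble(gem_id = "G3-1", pmhc_id = c("pA", "pB"),
                   umi = c(3L, 3L)),
    tibble::tibble(gem_id = "G4-1", pmhc_id = "pB", umi = 8L),
    tibble::tibble(gem_id = "G5-1", pmhc_id = "pA", umi = 6L),
    tibble::tibble(gem_id = "G6-1", pmhc_id = "pA", umi = 7L)
  )
  hash <- dplyr::bind_rows(
    tibble::tibble(gem_id = c("G1-1", "G2-1", "G3-1"), hash_id = "Hash01",
                   umi = 80L),
    tibble::tibble(gem_id = "G4-1", hash_id = "Hash02", umi = 90L),
    # G5: doublet across both donors
    tibble::tibble(gem_id = "G5-1", hash_id = c("Hash01", "Hash02"),
                   umi = c(70L, 75L)),
    tibble::tibble(gem_id = "G6-1", hash_id = "Hash01", umi = 1L)
  )
  gex <- tibble::tibble(
    gem_id = sprintf("G%d-1", 1:6),
    n_genes = c(1000L, 150L, 2600L, 1200L, 900L, 1000L),
    mito_fraction = c(0.05, 0.1, 0.1, 0.25, 0.08, 0.12),
    is_cell_gex = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  ds <- assemble_dataset(contigs = contigs, pmhc = pmhc, hash = hash,
                         panel = tiny_panel(), samples = tiny_samples(),
                         gex = gex)
  ds <- collapse_and_impute_clonotypes(select_dominant_chains(ds))
  # deterministic hash calls matching the planted counts (the statistical
  # demultiplexer is exercised in test-hashing.R)
  ds$hash_calls <- tibble::tibble(
    gem_id = sprintf("G%d-1", 1:6),
    label = c("singlet", "singlet", "singlet", "singlet", "doublet",
              "negative"),
    positive_hashes = list("Hash01", "Hash01", "Hash01", "Hash02",
                           c("Hash01", "Hash02"), character(0)),
    donor_id = c("donor01", "donor01", "donor01", "donor02", NA, NA)
  )
  ds
}

test_that("UMI thresholds remove low-count and tied-top GEMs", {
  ds <- filter_fixture()
  th <- umi_thresholds(pmhc_count = 2, pmhc_ratio = 1)
  out <- filter_umi_thresholds(ds, th)
  expect_false("G2-1" %in% out$gems$gem_id)  # top UMI 1 < 2
  expect_false("G3-1" %in% out$gems$gem_id)  # 3 vs 3: ratio 0.923 <= 1
  expect_true("G1-1" %in% out$gems$gem_id)   # 10 vs 2: ratio 4.44 > 1
  expect_true(all(out$gems$gem_id %in% ds$gems$gem_id))
})

test_that("HLA matching keeps haplotype-consistent GEMs, unions doublets, drops negatives", {
  ds <- filter_fixture()
  out <- filter_hla_match(ds)
  expect_true("G1-1" %in% out$gems$gem_id)   # A*03:01 in donor01 haplotype
  expect_false("G4-1" %in% out$gems$gem_id)  # B*07:02 not in donor02
  expect_true("G5-1" %in% out$gems$gem_id)   # doublet union covers A*03:01
  expect_false("G6-1" %in% out$gems$gem_id)  # hashing negative
  expect_false("G3-1" %in% out$gems$gem_id)  # tied top pMHC: no allele

  # empty haplotype is a configuration error
  ds_bad <- ds
  ds_bad$samples$haplotype[[1]] <- character(0)
  expect_error(filter_hla_match(ds_bad), "haplotype")
})

test_that("hashing-singlet filter keeps exactly the singlets", {
  ds <- filter_fixture()
  out <- filter_hashing_singlets(ds)
  expect_setequal(out$gems$gem_id, sprintf("G%d-1", 1:4))
})

test_that("complete-TCR filter requires exactly one alpha and one beta", {
  ds <- filter_fixture()
  out <- filter_complete_tcr(ds)
  expect_true(all(c("G1-1", "G4-1", "G5-1", "G6-1") %in% out$gems$gem_id))
  expect_false("G2-1" %in% out$gems$gem_id)  # alpha only
  expect_false("G3-1" %in% out$gems$gem_id)  # two alphas
})

test_that("specificity multiplets require pair support of two GEMs, recounted", {
  ds <- filter_fixture()
  out <- filter_specificity_multiplets(ds)
  # G1+G5 share (clonotype, pA); every other pair is a singleton
  expect_setequal(out$gems$gem_id, c("G1-1", "G5-1"))

  # removing one partner first removes the survivor too
  ds_minus <- subset_gems(ds, setdiff(ds$gems$gem_id, "G5-1"))
  out2 <- filter_specificity_multiplets(ds_minus)
  expect_false("G1-1" %in% out2$gems$gem_id)
})

test_that("viability and vendor-flag filters apply their bounds", {
  ds <- filter_fixture()
  out <- filter_viable_cells(ds)
  expect_false("G2-1" %in% out$gems$gem_id)  # 150 genes
  expect_false("G3-1" %in% out$gems$gem_id)  # 2600 genes
  expect_false("G4-1" %in% out$gems$gem_id)  # mito 0.25
  expect_true("G1-1" %in% out$gems$gem_id)

  out_gex <- filter_is_cell(ds, "is_cell_gex")
  expect_false("G5-1" %in% out_gex$gems$gem_id)

  ds$gems$is_cell <- NULL
  expect_error(filter_is_cell(ds, "is_cell"), "absent")
})

test_that("an empty filter chain is the identity with a single total row", {
  ds <- filter_fixture()
  eb <- tibble::tibble(clonotype_id = ds$clonotypes$clonotype_id,
                       pmhc_id = NA_character_)
  eb$pmhc_id[1] <- "pA"
  res <- apply_filter_chain(ds, filter_config(steps = character(0)),
                            expected = eb)
  expect_equal(nrow(res$report), 1L)
  expect_equal(res$report$stage, "total")
  expect_equal(res$dataset$gems$gem_id, ds$gems$gem_id)
})

test_that("a cumulative cascade only removes GEMs and keeps counts non-increasing", {
  run <- default_sim_run()
  ds <- run$ds
  config <- filter_config(
    steps = c("umi_thresholds", "hla_match", "hashing_singlets",
              "complete_tcr", "specificity_multiplets", "is_cell",
              "is_cell_gex", "viable_cell"),
    thresholds = run$grid$thresholds
  )
  res <- apply_filter_chain(ds, config, expected = run$expected)
  expect_true(all(diff(res$report$n_gems) <= 0))
  expect_true(all(diff(res$report$n_clonotypes) <= 0))
  expect_true(all(res$dataset$gems$gem_id %in% ds$gems$gem_id))
})

test_that("filters other than specificity multiplets commute pairwise", {
  ds <- filter_fixture()
  config <- filter_config(thresholds = umi_thresholds(pmhc_count = 2,
                                                      pmhc_ratio = 1))
  steps <- c("umi_thresholds", "hla_match", "hashing_singlets",
             "complete_tcr", "viable_cell")
  for (i in seq_along(steps)) {
    for (j in seq_along(steps)) {
      if (i >= j) next
      ab <- tcrpair:::apply_one_filter(
        tcrpair:::apply_one_filter(ds, steps[i], config), steps[j], config)
      ba <- tcrpair:::apply_one_filter(
        tcrpair:::apply_one_filter(ds, steps[j], config), steps[i], config)
      expect_setequal(ab$gems$gem_id, ba$gems$gem_id)
    }
  }
})

test_that("individual mode evaluates each filter on the full data", {
  ds <- filter_fixture()
  eb <- tibble::tibble(clonotype_id = ds$clonotypes$clonotype_id,
                       pmhc_id = NA_character_)
  config <- filter_config(steps = c("complete_tcr", "hashing_singlets"))
  res <- suppressWarnings(
    apply_filter_chain(ds, config, expected = eb, mode = "individual")
  )
  # each row counts GEMs surviving that filter alone
  expect_equal(res$report$n_gems[res$report$stage == "complete_tcr"], 4L)
  expect_equal(res$report$n_gems[res$report$stage == "hashing_singlets"], 4L)
  expect_equal(nrow(res$dataset$gems), nrow(ds$gems))
})
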