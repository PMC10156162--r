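test_that("contig filter removes incomplete and unproductive transcripts", {
  contigs <- dplyr::bind_rows(
    tiny_contig("G1-1", "TRA", "TRAV1", "TRAJ2", "CAVRDF", "TGTGCT", 5L),
    tiny_contig("G1-1", "TRA", "TRAV1", "TRAJ2", "CAVRDF", "TGTGCT", 5L,
                full = FALSE),
    tiny_contig("G1-1", "TRB", "TRBV2", "TRBJ1-1", "CASS*", "TGTGCC", 3L,
                prod = FALSE)
  )
  out <- suppressMessages(filter_contigs(contigs))
  expect_equal(nrow(out), 1L)
  expect_true(out$full_length && out$productive)
})

test_that("vendor clonotypes with identical VJ-CDR3ab merge; novel GEMs found new ones", {
  # vendor clonotype1 (3 GEMs) and clonotype2 (2 GEMs) share VJ-CDR3ab
  mk <- function(gem, vendor) {
    dplyr::bind_rows(
      tiny_contig(gem, "TRA", "TRAV1", "TRAJ2", "CAVRDF", "TGTGCT", 5L,
                  vendor = vendor),
      tiny_contig(gem, "TRB", "TRBV2", "TRBJ1-1", "CASSLGF", "TGTGCC", 7L,
                  vendor = vendor)
    )
  }
  contigs <- dplyr::bind_rows(
    mk("G1-1", "clonotype1"), mk("G2-1", "clonotype1"),
    mk("G3-1", "clonotype1"),
    mk("G4-1", "clonotype2"), mk("G5-1", "clonotype2"),
    # unassigned GEM matching the merged clonotype
    mk("G6-1", NA_character_),
    # unassigned GEM with a novel pair
    dplyr::bind_rows(
      tiny_contig("G7-1", "TRA", "TRAV9", "TRAJ9", "CAVXYZF", "TGTAAA", 4L),
      tiny_contig("G7-1", "TRB", "TRBV9", "TRBJ2-1", "CASSXYZF", "TGTCCC", 6L)
    )
  )
  pmhc <- tibble::tibble(gem_id = sprintf("G%d-1", 1:7), pmhc_id = "pA",
                         umi = 5L)
  ds <- assemble_dataset(contigs = contigs, pmhc = pmhc,
                         panel = tiny_panel(), samples = tiny_samples())
  ds <- collapse_and_impute_clonotypes(select_dominant_chains(ds))
  expect_equal(nrow(ds$clonotypes), 2L)
  sizes <- sort(ds$clonotypes$n_gems)
  expect_equal(sizes, c(1L, 6L))
  big <- ds$clonotypes[ds$clonotypes$n_gems == 6L, ]
  expect_setequal(big$member_gems[[1]], sprintf("G%d-1", 1:6))
  expect_equal(big$cdr3a, "CAVRDF")
})

test_that("single-chain GEM joins a unique match but founds its own on ambiguity", {
  mk <- function(gem, vendor, cdr3b, vb = "TRBV2") {
    dplyr::bind_rows(
      tiny_contig(gem, "TRA", "TRAV1", "TRAJ2", "CAVRDF", "TGTGCT", 5L,
                  vendor = vendor),
      tiny_contig(gem, "TRB", vb, "TRBJ1-1", cdr3b, "TGTGCC", 7L,
                  vendor = vendor)
    )
  }
  contigs <- dplyr::bind_rows(
    mk("G1-1", "clonotype1", "CASSLGF"),
    mk("G2-1", "clonotype2", "CASSOTHERF"),
    # alpha-only GEM: its alpha matches BOTH clonotypes -> own clonotype
    tiny_contig("G3-1", "TRA", "TRAV1", "TRAJ2", "CAVRDF", "TGTGCT", 3L),
    # beta-only GEM: unique match to clonotype2
    tiny_contig("G4-1", "TRB", "TRBV2", "TRBJ1-1", "CASSOTHERF", "TGTGCC", 2L)
  )
  pmhc <- tibble::tibble(gem_id = sprintf("G%d-1", 1:4), pmhc_id = "pA",
                         umi = 5L)
  ds <- assemble_dataset(contigs = contigs, pmhc = pmhc,
                         panel = tiny_panel(), samples = tiny_samples())
  ds <- collapse_and_impute_clonotypes(select_dominant_chains(ds))
  expect_equal(nrow(ds$clonotypes), 3L)
  ct_of <- setNames(ds$gems$clonotype_id, ds$gems$gem_id)
  expect_equal(ct_of[["G4-1"]], ct_of[["G2-1"]])   # unique beta match joins
  expect_false(ct_of[["G3-1"]] %in% ct_of[c("G1-1", "G2-1")])  # ambiguous
})

test_that("dominant chain selection keeps the highest-UMI chain and flags ties", {
  contigs <- dplyr::bind_rows(
    tiny_contig("G1-1", "TRA", "TRAV1", "TRAJ2", "CAVRDF", "TGTGCT", 7L),
    tiny_contig("G1-1", "TRA", "TRAV5", "TRAJ5", "CAVZZF", "TGTAAA", 2L),
    tiny_contig("G1-1", "TRB", "TRBV2", "TRBJ1-1", "CASSLGF", "TGTGCC", 4L),
    # G2: TRB tie at 4 UMIs; lexicographically smallest cdr3_nt wins
    tiny_contig("G2-1", "TRB", "TRBV2", "TRBJ1-1", "CASSLGF", "TGTGCC", 4L),
    tiny_contig("G2-1", "TRB", "TRBV7", "TRBJ2-2", "CASSAAF", "AAAAAA", 4L),
    # G3: one of each, untouched
    tiny_contig("G3-1", "TRA", "TRAV1", "TRAJ2", "CAVRDF", "TGTGCT", 3L),
    tiny_contig("G3-1", "TRB", "TRBV2", "TRBJ1-1", "CASSLGF", "TGTGCC", 2L)
  )
  pmhc <- tibble::tibble(gem_id = sprintf("G%d-1", 1:3), pmhc_id = "pA",
                         umi = 5L)
  ds <- assemble_dataset(contigs = contigs, pmhc = pmhc,
                         panel = tiny_panel(), samples = tiny_samples())
  ds <- select_dominant_chains(ds)
  g <- ds$gems[match(sprintf("G%d-1", 1:3), ds$gems$gem_id), ]
  expect_equal(g$umi_a[1], 7L)
  expect_equal(g$va[1], "TRAV1")
  expect_equal(g$n_tra[1], 2L)
  expect_false(g$chain_ambiguous[1])
  # tie: deterministic winner by cdr3_nt, flagged ambiguous
  expect_equal(g$cdr3b_nt[2], "AAAAAA")
  expect_true(g$chain_ambiguous[2])
  expect_equal(g$umi_b[3], 2L)
  expect_false(g$chain_ambiguous[3])

  # order independence: shuffling contig rows gives the same selection
  set.seed(1)
  ds2 <- assemble_dataset(contigs = contigs[sample(nrow(contigs)), ],
                          pmhc = pmhc, panel = tiny_panel(),
                          samples = tiny_samples())
  ds2 <- select_dominant_chains(ds2)
  g2 <- ds2$gems[match(g$gem_id, ds2$gems$gem_id), ]
  expect_equal(g2$cdr3b_nt, g$cdr3b_nt)
  expect_equal(g2$umi_a, g$umi_a)
})

test_that("collapse is idempotent and clonotypes partition TCR-bearing GEMs", {
  sim <- simulate_dataset(simulation_params(seed = 21, n_clonotypes = 40,
                                            n_samples = 2))
  ds <- suppressWarnings(
    collapse_and_impute_clonotypes(select_dominant_chains(sim$dataset))
  )
  # partition: every GEM in exactly one member list
  members <- unlist(ds$clonotypes$member_gems)
  expect_equal(anyDuplicated(members), 0L)
  expect_setequal(members, ds$gems$gem_id)
  expect_equal(sum(ds$clonotypes$n_gems), nrow(ds$gems))

  ds2 <- suppressWarnings(collapse_and_impute_clonotypes(ds))
  expect_equal(ds2$gems$clonotype_id, ds$gems$clonotype_id)
  expect_equal(nrow(ds2$clonotypes), nrow(ds$clonotypes))
})

test_that("clonotype assignment matches brute-force key grouping on small data", {
  sim <- simulate_dataset(simulation_params(seed = 33, n_clonotypes = 12,
                                            n_samples = 2, doublet_rate = 0,
                                            multi_chain_rate = 0))
  ds <- suppressWarnings(
    collapse_and_impute_clonotypes(select_dominant_chains(sim$dataset))
  )
  g <- ds$gems
  both <- !is.na(g$va) & !is.na(g$vb)
  key <- paste(g$va, g$ja, g$cdr3a, g$vb, g$jb, g$cdr3b)
  # GEMs with identical full keys always share a clonotype
  for (k in unique(key[both])) {
    expect_equal(length(unique(g$clonotype_id[both & key == k])), 1L)
  }
  # GEMs in one clonotype never have contradicting defined chains
  for (i in seq_len(nrow(ds$clonotypes))) {
    m <- g[g$clonotype_id %in% ds$clonotypes$clonotype_id[i], ]
    a_def <- unique(stats::na.omit(paste(m$va, m$ja, m$cdr3a)[!is.na(m$va)]))
    b_def <- unique(stats::na.omit(paste(m$vb, m$jb, m$cdr3b)[!is.na(m$vb)]))
    expect_lte(length(a_def), 1L)
    expect_lte(length(b_def), 1L)
  }
})

test_that("GEMs contradicting their vendor definition are reassigned with a warning", {
  contigs <- dplyr::bind_rows(
    tiny_contig("G1-1", "TRA", "TRAV1", "TRAJ2", "CAVRDF", "TGTGCT", 5L,
                vendor = "clonotype1"),
    tiny_contig("G2-1", "TRA", "TRAV1", "TRAJ2", "CAVRDF", "TGTGCT", 5L,
                vendor = "clonotype1"),
    # same vendor id, different alpha -> contradiction
    tiny_contig("G3-1", "TRA", "TRAV8", "TRAJ8", "CAVWWF", "TGTTTT", 5L,
                vendor = "clonotype1")
  )
  pmhc <- tibble::tibble(gem_id = sprintf("G%d-1", 1:3), pmhc_id = "pA",
                         umi = 5L)
  ds <- assemble_dataset(contigs = contigs, pmhc = pmhc,
                         panel = tiny_panel(), samples = tiny_samples())
  expect_warning(
    ds <- collapse_and_impute_clonotypes(select_dominant_chains(ds)),
    "reassigned"
  )
  expect_equal(nrow(ds$clonotypes), 2L)
  ct_of <- setNames(ds$gems$clonotype_id, ds$gems$gem_id)
  expect_equal(ct_of[["G1-1"]], ct_of[["G2-1"]])
  expect_false(ct_of[["G3-1"]] == ct_of[["G1-1"]])
})
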