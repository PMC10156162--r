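test_that("the most abundant pMHC per GEM is found, ties flagged", {
  pm <- tibble::tibble(
    gem_id = c("G1", "G1", "G2", "G2", "G3"),
    pmhc_id = c("pA", "pB", "pA", "pB", "pA"),
    umi = c(5L, 2L, 3L, 3L, 4L)
  )
  tops <- gem_top_pmhc(pm)
  expect_equal(tops$top_pmhc[tops$gem_id == "G1"], "pA")
  expect_equal(tops$umi_max[tops$gem_id == "G1"], 5L)
  expect_equal(tops$umi_sec[tops$gem_id == "G1"], 2L)
  expect_true(tops$tie_flag[tops$gem_id == "G2"])
  expect_true(is.na(tops$top_pmhc[tops$gem_id == "G2"]))
  expect_equal(tops$umi_sec[tops$gem_id == "G3"], 0L)
})

test_that("clonotypes under the size floor are not tested", {
  counts <- replicate(9, c(pA = 8L, pB = 1L), simplify = FALSE)
  ds <- clonotype_dataset(counts)
  eb <- expected_binders(ds)
  expect_false(eb$tested)
  expect_true(is.na(eb$pmhc_id))
})

test_that("a clearly dominant pMHC is assigned with the exact signed-rank p-value", {
  x <- c(5L, 6L, 7L, 5L, 6L, 7L, 5L, 6L, 7L, 6L)
  y <- c(0L, 1L, 0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L)
  counts <- lapply(seq_along(x), function(i) c(pA = x[i], pB = y[i]))
  ds <- clonotype_dataset(counts)
  eb <- expected_binders(ds)
  expect_true(eb$tested)
  expect_equal(eb$pmhc_id, "pA")
  # all 10 differences positive: exact one-sided p = 1 / 2^10
  expect_equal(eb$p_value, 1 / 1024, tolerance = 1e-12)
  # and the absent pMHC counts as 0: oracle over the same vectors agrees
  expect_equal(eb$p_value, signed_rank_enumeration_oracle(x, y),
               tolerance = 1e-12)
})

test_that("expected-binder p-values equal exhaustive enumeration for small clonotypes", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(10:12, 1)
    x <- rpois(n, 6) + 1L
    y <- rpois(n, 2)
    counts <- lapply(seq_len(n), function(i) c(pA = x[i], pB = y[i]))
    ds <- clonotype_dataset(counts)
    eb <- expected_binders(ds)
    if (!eb$tested) next
    expect_equal(eb$p_value, signed_rank_enumeration_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("a single observed pMHC in a large clonotype is assigned degenerately", {
  counts <- replicate(10, c(pA = 6L), simplify = FALSE)
  ds <- clonotype_dataset(counts)
  eb <- expected_binders(ds)
  expect_equal(eb$pmhc_id, "pA")
  expect_true(eb$degenerate)
  expect_true(is.na(eb$p_value))
})

test_that("binding concordance counts unambiguous GEMs and excludes ties", {
  counts <- list(c(pA = 5L), c(pA = 4L), c(pA = 6L), c(pB = 3L))
  ds <- clonotype_dataset(counts)
  conc <- binding_concordance(ds)
  expect_equal(conc$fraction[conc$pmhc_id == "pA"], 0.75)
  expect_equal(conc$fraction[conc$pmhc_id == "pB"], 0.25)
  expect_equal(sum(conc$fraction), 1, tolerance = 1e-12)

  # single-GEM clonotype has concordance 1
  ds1 <- clonotype_dataset(list(c(pA = 2L)))
  expect_equal(binding_concordance(ds1)$fraction, 1)

  # ties excluded from numerator and denominator, reported separately
  counts <- list(c(pA = 5L), c(pA = 4L), c(pA = 3L, pB = 3L))
  ds2 <- clonotype_dataset(counts)
  conc2 <- binding_concordance(ds2)
  expect_equal(conc2$fraction, 1)
  expect_equal(conc2$n_support, 2L)
  expect_equal(attr(conc2, "n_tied")$n_tied, 1L)
})

test_that("concordance fractions sum to one per clonotype on simulated data", {
  sim <- simulate_dataset(simulation_params(seed = 13, n_clonotypes = 50,
                                            n_samples = 2))
  ds <- suppressWarnings(
    collapse_and_impute_clonotypes(select_dominant_chains(sim$dataset))
  )
  conc <- binding_concordance(ds)
  sums <- tapply(conc$fraction, conc$clonotype_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("annotation accuracy is the eligible-GEM match fraction", {
  # 10 GEMs, 7 with top pA (the expected target), 3 with top pB
  counts <- c(replicate(7, c(pA = 8L, pB = 1L), simplify = FALSE),
              replicate(3, c(pA = 1L, pB = 8L), simplify = FALSE))
  ds <- clonotype_dataset(counts)
  eb <- tibble::tibble(clonotype_id = ds$clonotypes$clonotype_id,
                       pmhc_id = "pA")
  expect_equal(annotation_accuracy(ds, eb), 0.7)
  eb$pmhc_id <- NA_character_
  expect_warning(acc <- annotation_accuracy(ds, eb), "undefined")
  expect_true(is.na(acc))

  # all matching -> 1.0
  ds_all <- clonotype_dataset(replicate(10, c(pA = 8L, pB = 1L),
                                        simplify = FALSE))
  eb_all <- tibble::tibble(clonotype_id = ds_all$clonotypes$clonotype_id,
                           pmhc_id = "pA")
  expect_equal(annotation_accuracy(ds_all, eb_all), 1.0)
})

test_that("adding a matching GEM never decreases accuracy", {
  base <- replicate(6, c(pA = 8L, pB = 1L), simplify = FALSE)
  noisy <- c(base, list(c(pA = 1L, pB = 9L)))
  ds_noisy <- clonotype_dataset(noisy)
  eb <- tibble::tibble(clonotype_id = ds_noisy$clonotypes$clonotype_id,
                       pmhc_id = "pA")
  acc_before <- annotation_accuracy(ds_noisy, eb)
  ds_more <- clonotype_dataset(c(noisy, list(c(pA = 7L))))
  eb_more <- tibble::tibble(clonotype_id = ds_more$clonotypes$clonotype_id,
                            pmhc_id = "pA")
  expect_gte(annotation_accuracy(ds_more, eb_more), acc_before)
})

test_that("noise-free simulation gives perfect target recovery and accuracy", {
  sim <- simulate_dataset(simulation_params(
    seed = 3, n_clonotypes = 40, n_samples = 2,
    ambient_rate = 0, dropout_alpha = 0, dropout_beta = 0,
    doublet_rate = 0, multi_chain_rate = 0, junk_contig_rate = 0
  ))
  ds <- collapse_and_impute_clonotypes(select_dominant_chains(sim$dataset))
  eb <- expected_binders(ds)
  sc <- score_against_truth(ds, sim$truth, eb)
  expect_equal(sc$target_recovery, 1)
  expect_equal(annotation_accuracy(ds, eb), 1)
  expect_equal(average_concordance(ds), 1)
})
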