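test_that("configuration validates frequencies and parameters", {
  expect_error(simulation_config(kir_complete_haplotype_freqs =
                                   c("cA01/tA01" = 0.5)), "sum to 1")
  expect_error(simulation_config(transmission_tau = 1.5))
  expect_error(simulation_config(case_enrichment_or = 0))
  cfg <- simulation_config()
  expect_equal(sum(cfg$hap_freqs), 1)
  expect_equal(sum(cfg$c_freqs), 1)
  expect_equal(sum(cfg$b_freqs), 1)
})

test_that("cohorts are reproducible from the seed", {
  t1 <- simulate_trios(simulation_config(n_families = 20, seed = 123))
  t2 <- simulate_trios(simulation_config(n_families = 20, seed = 123))
  expect_identical(t1, t2)
  p1 <- simulate_control_pool(simulation_config(seed = 5), 1000)
  p2 <- simulate_control_pool(simulation_config(seed = 5), 1000)
  expect_identical(p1, p2)
})

test_that("children inherit one haplotype and one allele per parent", {
  trios <- simulate_trios(simulation_config(n_families = 100, seed = 11))
  expect_true(all(trios$ch_hap1 == trios$fa_hap1 |
                    trios$ch_hap1 == trios$fa_hap2))
  expect_true(all(trios$ch_hap2 == trios$mo_hap1 |
                    trios$ch_hap2 == trios$mo_hap2))
  expect_true(all(trios$ch_c1 == trios$fa_c1 | trios$ch_c1 == trios$fa_c2))
  expect_true(all(trios$ch_c2 == trios$mo_c1 | trios$ch_c2 == trios$mo_c2))
  expect_true(all(trios$ch_b1 == trios$fa_b1 | trios$ch_b1 == trios$fa_b2))
  expect_true(all(trios$ch_b2 == trios$mo_b1 | trios$ch_b2 == trios$mo_b2))
})

test_that("null transmission is balanced and tau = 1 is degenerate", {
  trios <- simulate_trios(simulation_config(n_families = 500, seed = 21))
  t <- tdt_from_trios(trios, "cB01/tA01")
  n <- t$b_transmitted + t$c_untransmitted
  # transmitted fraction within 3 binomial SE of 1/2
  expect_lt(abs(t$b_transmitted / n - 0.5), 3 * sqrt(0.25 / n))

  det <- simulate_trios(simulation_config(n_families = 300,
                                          transmission_tau = 1,
                                          seed = 22))
  for (m in c("fa", "mo")) {
    h1 <- det[[paste0(m, "_hap1")]]
    h2 <- det[[paste0(m, "_hap2")]]
    het <- xor(h1 == "cB01/tA01", h2 == "cB01/tA01")
    ch <- det[[if (m == "fa") "ch_hap1" else "ch_hap2"]]
    expect_true(all(ch[het] == "cB01/tA01"))
  }
})

test_that("degenerate frequencies force a constant GCN profile", {
  cfg <- simulation_config(
    n_families = 10,
    kir_complete_haplotype_freqs = c("cA01/tA01" = 1),
    duplication_rate = 0, seed = 31)
  trios <- simulate_trios(cfg)
  tabs <- cohort_tables(trios)
  target <- gcn_from_haplotypes(c("cA01/tA01", "cA01/tA01"), ref)
  genes <- setdiff(colnames(tabs$gcn), "subject_id")
  for (g in genes) {
    expect_true(all(tabs$gcn[[g]] == target[[g]]))
  }
})

test_that("control pool tallies follow multinomial moments", {
  pool <- simulate_control_pool(simulation_config(seed = 41), 9024)
  expect_equal(sum(pool), 9024)
  p <- default_haplotype_freqs()["cB01/tA01"]
  expected <- 9024 * p
  expect_lt(abs(pool["cB01/tA01"] - expected),
            3 * sqrt(expected * (1 - p)))
  one <- simulate_control_pool(
    simulation_config(kir_complete_haplotype_freqs = c("cA01/tA01" = 1),
                      seed = 42), 1)
  expect_equal(unname(one["cA01/tA01"]), 1L)
  expect_error(simulate_control_pool(simulation_config(), 0), "positive")
})

test_that("deconvolution recovers the simulated haplotypes", {
  cfg <- simulation_config(n_families = 60, seed = 51)
  trios <- simulate_trios(cfg)
  tabs <- cohort_tables(trios)
  cohort <- haplotype_cohort(tabs$gcn, ref)
  calls <- complete_calls(cohort, tabs$ped)
  truth <- tabs$truth
  det <- calls[calls$determined, ]
  expect_gt(nrow(det), 0)
  for (i in seq_len(nrow(det))) {
    tr <- truth[truth$subject_id == det$subject_id[i], ]
    if (tr$duplication == 1) next
    expect_equal(sort(c(det$call1[i], det$call2[i])),
                 sort(c(tr$hap1, tr$hap2)),
                 label = det$subject_id[i])
  }
  # undetermined children are the doubly-heterozygous ones without
  # resolving parents, a small minority
  expect_gt(mean(calls$determined), 0.8)
})

test_that("case enrichment raises the risk-haplotype frequency in probands", {
  cfg <- simulation_config(n_families = 400, case_enrichment_or = 3,
                           seed = 61)
  trios <- simulate_trios(cfg)
  freq_case <- mean(c(trios$ch_hap1, trios$ch_hap2) == "cB01/tA01")
  p0 <- default_haplotype_freqs()["cB01/tA01"]
  expect_gt(freq_case, p0 + 3 * sqrt(p0 * (1 - p0) / 800))
})

test_that("transmission counting handles the classic informative cases", {
  # trio 1: het father, mother cannot have given the copy -> transmitted
  # trio 2: het father, mother must have given it -> not transmitted
  # trio 3: everyone heterozygous -> uninformative for both parents
  tc <- transmission_counts(fa_k = c(1, 1, 1), mo_k = c(0, 2, 1),
                            ch_k = c(1, 1, 1))
  expect_equal(tc$b, 1)
  expect_equal(tc$c, 1)
  expect_equal(tc$informative, 2)
  expect_equal(tc$total_het, 4)
})

test_that("allele-level tallies resolve trios dosage counting cannot", {
  # father C*07/C*04, mother C*03/C*04, child C*07/C*04: every member is
  # C1-group heterozygous, so group dosages (1,1,1) are uninformative --
  # yet at allele level the only consistent assignment is father->C*07,
  # mother->C*04
  fa <- matrix(c("C*07", "C*04"), 1)
  mo <- matrix(c("C*03", "C*04"), 1)
  ch <- matrix(c("C*07", "C*04"), 1)
  c1k <- c("C*01", "C*03", "C*07", "C*08", "C*12", "C*14", "C*16")
  tal <- transmission_tally(fa, mo, ch, function(x) x %in% c1k)
  expect_equal(tal$informative, 2)
  expect_equal(tal$b, 1)  # father transmitted C1; mother transmitted C2
  expect_equal(tal$c, 1)
  tc <- transmission_counts(1, 1, 1)
  expect_equal(tc$informative, 0)
  # a shared-genotype trio stays ambiguous even at allele level
  tal2 <- transmission_tally(fa, fa, fa, function(x) x %in% c1k)
  expect_equal(tal2$informative, 0)
})
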