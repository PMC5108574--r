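test_that("profile validation enforces copy range and framework genes", {
  expect_error(gcn_profile("s", c(`2DL3` = 4)), "\\[0, 3\\]")
  expect_error(gcn_profile("s", c(`2DL3` = -1)), "\\[0, 3\\]")
  expect_error(gcn_profile("s", c(`3DP1` = 0)), "framework")
  expect_error(gcn_profile("s", c(`9XY9` = 1)), "unknown")
  expect_warning(gcn_profile("s", c(`2DL5c` = 1, `2DS35c` = 2)),
                 "unequal copy counts")
  p <- gcn_profile("s", c(`2DL3` = 2, `3DP1` = 3))
  expect_s3_class(p, "gcn_profile")
})

test_that("presence projection is present iff copies >= 1, and monotone", {
  p <- gcn_profile("s", c(`2DS2` = 0, `2DL3` = 2, `3DP1` = 3))
  g <- presence_from_gcn(p)
  expect_equal(unname(g["2DS2"]), "absent")
  expect_equal(unname(g["2DL3"]), "present")
  expect_equal(unname(g["3DP1"]), "present")
  # monotone: raising any count never flips present -> absent
  set.seed(1)
  for (i in 1:25) {
    copies <- c(`2DS2` = sample(0:3, 1), `2DL3` = sample(0:3, 1),
                `3DP1` = sample(1:3, 1))
    g0 <- presence_from_gcn(gcn_profile("s", copies))
    j <- sample(names(copies), 1)
    copies[j] <- min(copies[j] + 1L, 3L)
    g1 <- presence_from_gcn(gcn_profile("s", copies))
    expect_true(all(!(g0 == "present" & g1 == "absent")))
  }
})

test_that("GCN/genotype ratio summary reproduces known distributions", {
  # 89 subjects, 2DL3 distribution 12/45/32 and 3DP1 distribution 0/4/78/7
  cohort <- data.frame(
    subject_id = sprintf("S%02d", 1:89),
    `2DL3` = rep(0:2, times = c(12, 45, 32)),
    `3DP1` = rep(1:3, times = c(4, 78, 7)),
    check.names = FALSE
  )
  tab <- gcn_ratio_table(cohort)
  r2dl3 <- tab[tab$gene == "2DL3", ]
  expect_equal(r2dl3$present, 77)
  expect_equal(r2dl3$total_copies, 109)
  expect_equal(r2dl3$ratio, 1.42)
  r3dp1 <- tab[tab$gene == "3DP1", ]
  expect_equal(r3dp1$present, 89)
  expect_equal(r3dp1$total_copies, 181)
  expect_equal(r3dp1$ratio, 2.03)
  expect_equal(r3dp1$gcn3, 7)
  # distribution columns account for the whole cohort
  expect_true(all(tab$gcn0 + tab$gcn1 + tab$gcn2 + tab$gcn3 == 89))

  one <- gcn_ratio_table(data.frame(subject_id = "a", `2DL3` = 1,
                                    check.names = FALSE))
  expect_equal(one$ratio, 1.00)

  none <- gcn_ratio_table(data.frame(subject_id = c("a", "b"),
                                     `2DS2` = c(0, 0), check.names = FALSE))
  expect_true(is.na(none$ratio))
})

test_that("ratio lies in [1, max copies] whenever a carrier exists", {
  set.seed(2)
  for (i in 1:20) {
    x <- sample(0:3, 30, replace = TRUE)
    cohort <- data.frame(subject_id = sprintf("s%d", 1:30), `2DS2` = x,
                         check.names = FALSE)
    tab <- gcn_ratio_table(cohort)
    if (tab$present > 0) {
      expect_gte(tab$ratio, 1)
      expect_lte(tab$ratio, max(x))
    }
  }
})

test_that("region deconvolution recovers known diplotypes uniquely", {
  p <- profile_from_pair(c("cA01", "cA01"), c("tA01", "tA01"))
  cent <- deconvolve_region(p, "centromeric", ref)
  expect_equal(cent$status, "unique")
  expect_equal(sort(cent$pairs[[1]]), c("cA01", "cA01"))

  p2 <- profile_from_pair(c("cA01", "cA01"), c("tA01", "tB01"))
  tel <- deconvolve_region(p2, "telomeric", ref)
  expect_equal(tel$status, "unique")
  expect_equal(sort(tel$pairs[[1]]), c("tA01", "tB01"))
})

test_that("copy numbers matching no motif pair come back unresolved", {
  copies <- gcn_from_haplotypes(c("cA01/tA01", "cA01/tA01"), ref)
  copies[c("2DL3", "2DP1", "2DL1")] <- 0L  # bare 3DL3/3DP1 skeleton
  p <- gcn_profile("odd", copies)
  res <- deconvolve_region(p, "centromeric", ref)
  expect_equal(res$status, "unresolved")
  expect_length(res$pairs, 0)
})

test_that("sum-then-deconvolve round-trips every reference pair", {
  for (pr in cent_pairs_all()) {
    p <- profile_from_pair(pr, c("tA01", "tA01"))
    res <- deconvolve_region(p, "centromeric", ref)
    expect_true(res$status %in% c("unique", "ambiguous"))
    hit <- any(vapply(res$pairs, function(x) setequal(x, pr) &&
                        identical(sort(x), sort(pr)), logical(1)))
    expect_true(hit, label = paste("pair", paste(pr, collapse = "+")))
  }
  for (pr in tel_pairs_all()) {
    p <- profile_from_pair(c("cA01", "cA01"), pr)
    res <- deconvolve_region(p, "telomeric", ref)
    expect_true(res$status %in% c("unique", "ambiguous"))
    hit <- any(vapply(res$pairs, function(x) identical(sort(x), sort(pr)),
                      logical(1)))
    expect_true(hit, label = paste("pair", paste(pr, collapse = "+")))
  }
})

test_that("a third copy is explained as a flagged single-gene duplication", {
  p <- profile_from_pair(c("cA01", "cB01"), c("tA01", "tB01"),
                         duplication = TRUE)
  cent <- deconvolve_region(p, "centromeric", ref)
  tel <- deconvolve_region(p, "telomeric", ref)
  expect_equal(cent$status, "unique")
  expect_equal(tel$status, "unique")
  expect_true("duplication" %in% cent$flags)
  expect_true("duplication" %in% tel$flags)
  expect_equal(sort(cent$pairs[[1]]), c("cA01", "cB01"))
  expect_equal(sort(tel$pairs[[1]]), c("tA01", "tB01"))
})

test_that("complete-haplotype assembly phases via homozygosity or family", {
  mk <- function(cpair, tpair) {
    p <- profile_from_pair(cpair, tpair)
    list(cent = deconvolve_region(p, "centromeric", ref),
         tel = deconvolve_region(p, "telomeric", ref))
  }
  hom <- mk(c("cA01", "cA01"), c("tA01", "tB01"))
  call <- assemble_complete(hom$cent, hom$tel)
  expect_true(call$determined)
  expect_setequal(call$calls, c("cA01/tA01", "cA01/tB01"))

  both_hom <- mk(c("cB01", "cB01"), c("tA01", "tA01"))
  call2 <- assemble_complete(both_hom$cent, both_hom$tel)
  expect_true(call2$determined)
  expect_equal(call2$calls, c("cB01/tA01", "cB01/tA01"))

  het <- mk(c("cA01", "cB01"), c("tA01", "tB01"))
  call3 <- assemble_complete(het$cent, het$tel)
  expect_false(call3$determined)
  expect_length(call3$calls, 0)

  # parents force one phasing: father can only give cA01/tA01, mother only
  # cB01/tB01
  call4 <- assemble_complete(het$cent, het$tel, family_phase = list(
    father = "cA01/tA01", mother = "cB01/tB01"))
  expect_true(call4$determined)
  expect_setequal(call4$calls, c("cA01/tA01", "cB01/tB01"))

  # parents compatible with both phasings leave it undetermined
  call5 <- assemble_complete(het$cent, het$tel, family_phase = list(
    father = c("cA01/tA01", "cA01/tB01", "cB01/tA01", "cB01/tB01"),
    mother = c("cA01/tA01", "cA01/tB01", "cB01/tA01", "cB01/tB01")))
  expect_false(call5$determined)

  unres <- mk(c("cA01", "cA01"), c("tA01", "tA01"))
  unres$cent$status <- "ambiguous"
  expect_error(assemble_complete(unres$cent, unres$tel), "unique")
})

test_that("cohort deconvolution conserves haplotype tallies", {
  set.seed(3)
  cfg <- simulation_config(n_families = 40, seed = 9)
  trios <- simulate_trios(cfg)
  tabs <- cohort_tables(trios)
  cohort <- haplotype_cohort(tabs$gcn, ref)
  calls <- complete_calls(cohort, tabs$ped)
  det <- calls[calls$determined, ]
  tal <- table(c(det$call1, det$call2))
  expect_equal(sum(tal), 2 * nrow(det))
})
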