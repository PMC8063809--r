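test_that("merge_mate_calls matches the 4x4 enumeration oracle", {
  lv <- c("REF", "ALT", "NONE", "AMBIGUOUS")
  for (c1 in lv) for (c2 in lv)
    expect_identical(merge_mate_calls(c1, c2), oracle_merge(c1, c2),
                     info = paste(c1, c2))
  # vectorized form agrees
  grid <- expand.grid(c1 = lv, c2 = lv, stringsAsFactors = FALSE)
  expect_identical(merge_mate_calls(grid$c1, grid$c2),
                   mapply(oracle_merge, grid$c1, grid$c2, USE.NAMES = FALSE))
})

test_that("tabulate_pairs classifies and conserves counts", {
  t0 <- tabulate_pairs(character(0), character(0))
  expect_true(all(unlist(t0[c("n_rr", "n_ra", "n_ar", "n_aa")]) == 0L))

  ca <- c(rep("ALT", 3), rep("REF", 2), "NONE", "AMBIGUOUS", "REF")
  cb <- c(rep("REF", 3), rep("ALT", 2), "NONE", "ALT", "NONE")
  tt <- tabulate_pairs(ca, cb)
  expect_identical(tt$n_ar, 3L)
  expect_identical(tt$n_ra, 2L)
  expect_identical(tt$n_uninformative, 1L)
  expect_identical(tt$n_conflict, 1L)
  expect_identical(tt$n_site_a_only, 1L)
  total <- tt$n_informative + tt$n_site_a_only + tt$n_site_b_only +
    tt$n_uninformative + tt$n_conflict
  expect_identical(total, length(ca))
})

test_that("count conservation over random call vectors", {
  set.seed(21)
  lv <- c("REF", "ALT", "NONE", "AMBIGUOUS")
  for (i in 1:20) {
    n <- sample(0:200, 1)
    ca <- sample(lv, n, TRUE); cb <- sample(lv, n, TRUE)
    tt <- tabulate_pairs(ca, cb)
    expect_identical(tt$n_informative + tt$n_site_a_only +
                       tt$n_site_b_only + tt$n_uninformative +
                       tt$n_conflict, n)
  }
})

test_that("call_phase thresholds and p-value", {
  pure_cis <- haplotype_table(list(n_rr = 50, n_aa = 50))
  pc <- call_phase(pure_cis)
  expect_identical(pc$configuration, "CIS")
  expect_identical(pc$support_fraction, 1)

  trans <- haplotype_table(list(n_ra = 48, n_ar = 47, n_rr = 2, n_aa = 1))
  pt <- call_phase(trans)
  expect_identical(pt$configuration, "TRANS")
  expect_equal(pt$p_value, binom.test(3, 98, 0.5)$p.value)

  expect_identical(call_phase(haplotype_table(list(n_rr = 4)))$configuration,
                   "INSUFFICIENT_DATA")
  mixed <- haplotype_table(list(n_rr = 30, n_ra = 25, n_ar = 25, n_aa = 20))
  expect_identical(call_phase(mixed)$configuration, "AMBIGUOUS")
  expect_error(haplotype_table(list(n_rr = -1)), "negative")
})

test_that("label symmetry: double swap preserves, single swap flips", {
  set.seed(33)
  for (i in 1:40) {
    cells <- as.list(rpois(4, 20))
    names(cells) <- c("n_rr", "n_ra", "n_ar", "n_aa")
    tt <- haplotype_table(cells)
    both <- haplotype_table(list(n_rr = cells$n_aa, n_aa = cells$n_rr,
                                 n_ra = cells$n_ar, n_ar = cells$n_ra))
    one <- haplotype_table(list(n_rr = cells$n_ar, n_ar = cells$n_rr,
                                n_ra = cells$n_aa, n_aa = cells$n_ra))
    c0 <- call_phase(tt)$configuration
    expect_identical(call_phase(both)$configuration, c0)
    c1 <- call_phase(one)$configuration
    if (c0 == "CIS") expect_identical(c1, "TRANS")
    if (c0 == "TRANS") expect_identical(c1, "CIS")
    if (c0 %in% c("AMBIGUOUS", "INSUFFICIENT_DATA"))
      expect_identical(c1, c0)
  }
})

test_that("raising min_support_fraction only demotes calls", {
  set.seed(44)
  for (i in 1:30) {
    tt <- haplotype_table(stats::setNames(as.list(rpois(4, 15)),
                                          c("n_rr", "n_ra", "n_ar", "n_aa")))
    prev <- call_phase(tt, min_support_fraction = 0.5)$configuration
    for (f in c(0.7, 0.9, 0.99)) {
      cur <- call_phase(tt, min_support_fraction = f)$configuration
      if (prev %in% c("CIS", "TRANS"))
        expect_true(cur %in% c(prev, "AMBIGUOUS"))
      prev <- cur
    }
  }
})

test_that("simulated trans data with 1% error is called TRANS", {
  cfg <- sim_config(configuration = "TRANS", n_pairs = 1000,
                    sub_error_rate = 0.01, pcr_duplication_mean = 1,
                    seed = 99)
  sim <- simulate_pairs(cfg)
  res <- run_phase_analysis(sim$reads, cfg$ref_amplicon, cfg$variant_a,
                            cfg$variant_b)
  expect_identical(res$phase$configuration, "TRANS")
  expect_gte(res$phase$support_fraction, 0.95)
})

test_that("error-free tabulation equals truth-table spanning counts", {
  cfg <- sim_config(n_pairs = 200, sub_error_rate = 0,
                    pcr_duplication_mean = 1, seed = 12,
                    library_mode = "fragmentation")
  sim <- simulate_pairs(cfg)
  res <- run_phase_analysis(sim$reads, cfg$ref_amplicon, cfg$variant_a,
                            cfg$variant_b, umi_scheme = "none",
                            dedup_method = "none")
  expect_identical(res$n_informative_both,
                   sum(sim$truth$spans_a & sim$truth$spans_b))
  expect_identical(res$n_informative_a, sum(sim$truth$spans_a))
  expect_identical(res$n_informative_b, sum(sim$truth$spans_b))
})

test_that("summarize_run both-site fraction behaves at the extremes", {
  tt <- tabulate_pairs(rep("NONE", 5), rep("NONE", 5))
  s <- summarize_run(5, NULL, tt,
                     list(site_allele_counts("a", 0, 0),
                          site_allele_counts("b", 0, 0)),
                     call_phase(tt))
  expect_identical(s$both_site_fraction, 0)

  cfg <- sim_config(n_pairs = 60, sub_error_rate = 0,
                    pcr_duplication_mean = 1, seed = 2)
  sim <- simulate_pairs(cfg)
  res <- run_phase_analysis(sim$reads, cfg$ref_amplicon, cfg$variant_a,
                            cfg$variant_b, umi_scheme = "none")
  expect_identical(res$both_site_fraction, 1)
})
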