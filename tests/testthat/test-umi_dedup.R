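test_that("extract_umi handles both placement schemes", {
  p <- data.frame(name = "M00001:7:000:1:1:1:1_ACGTACGT",
                  seq1 = "ACGTACGTTTTTTTTT", qual1 = strrep("F", 16),
                  seq2 = "GGGG", qual2 = "FFFF",
                  stringsAsFactors = FALSE)
  out <- extract_umi(p, "name_suffix", 8)
  expect_identical(out$umi, "ACGTACGT")
  expect_identical(out$seq1, p$seq1)  # untouched

  out2 <- extract_umi(p, "inline_prefix", 8)
  expect_identical(out2$umi, "ACGTACGT")
  expect_true(startsWith(out2$seq1, "TTTT"))
  expect_identical(nchar(out2$qual1), nchar(out2$seq1))

  expect_error(extract_umi(data.frame(name = "noumi", seq1 = "A",
                                      qual1 = "F", seq2 = "A", qual2 = "F"),
                           "name_suffix", 8), "noumi")
  short <- p; short$seq1 <- "ACGT"; short$qual1 <- "FFFF"
  expect_error(extract_umi(short, "inline_prefix", 8), "shorter")
})

test_that("simulator UMIs round-trip through extract_umi", {
  for (scheme in c("name_suffix", "inline_prefix")) {
    sim <- simulate_pairs(sim_config(n_pairs = 80, seed = 3,
                                     umi_scheme = scheme))
    got <- extract_umi(sim$reads, scheme, 8)
    expect_identical(got$umi, sim$truth$umi)
  }
})

test_that("dedup hand-evaluated directional cases", {
  # all distinct UMIs: nothing collapses
  d <- dedup_pairs(pairs_df(c("AAAA", "CCCC", "GGGG", "TTTT", "ACGT")),
                   "exact")
  expect_identical(d$stats$n_kept, 5L)
  expect_identical(d$stats$n_removed, 0L)

  # 10x AAAA absorbs 1x AAAT (10 >= 2*1-1)
  d2 <- dedup_pairs(pairs_df(c(rep("AAAA", 10), "AAAT")), "directional")
  expect_identical(d2$stats$n_kept, 1L)
  expect_identical(d2$kept$umi, "AAAA")
  expect_identical(d2$kept$dup_count, 10L)

  # Hamming 4: no edge, two molecules
  d3 <- dedup_pairs(pairs_df(c(rep("AAAA", 10), rep("TTTT", 10))),
                    "directional")
  expect_identical(d3$stats$n_kept, 2L)

  # counts 2 vs 2 at Hamming 1: 2 < 2*2-1, no merge
  d4 <- dedup_pairs(pairs_df(c("AAAA", "AAAA", "AAAT", "AAAT")),
                    "directional")
  expect_identical(d4$stats$n_kept, 2L)
})

test_that("anchors partition the dedup groups", {
  d <- dedup_pairs(pairs_df(rep("AAAA", 6),
                            anchor = rep(c("x", "y", "z"), 2)),
                   "directional")
  expect_identical(d$stats$n_kept, 3L)
})

test_that("representative selection prefers quality then name", {
  p <- pairs_df(rep("AAAA", 3), qual = NULL,
                names = c("bb", "aa", "cc"))
  p$qual1 <- c(strrep("F", 10), strrep("A", 10), strrep("F", 10))
  d <- dedup_pairs(p, "exact")
  expect_identical(d$kept$name, "bb")  # highest quality, then smallest name
})

test_that("directional clustering equals the brute-force graph oracle", {
  set.seed(101)
  for (rep_i in 1:60) {
    n_unique <- sample(2:25, 1)
    umis <- unique(random_umis(n_unique, len = 4))
    counts <- stats::setNames(sample(1:20, length(umis), TRUE), umis)
    impl <- ampliphase:::.cluster_directional(counts)
    orac <- oracle_directional(counts)
    # same partition (cluster ids may differ)
    expect_identical(unname(tapply(names(impl), impl,
                                   function(x) paste(sort(x), collapse = ","))
                            [order(tapply(names(impl), impl, min))]),
                     unname(tapply(names(orac), orac,
                                   function(x) paste(sort(x), collapse = ","))
                            [order(tapply(names(orac), orac, min))]))
  }
})

test_that("dedup invariants: idempotence, kept <= input, method ordering", {
  set.seed(55)
  for (rep_i in 1:25) {
    umis <- sample(random_umis(sample(3:12, 1), 4),
                   sample(10:60, 1), replace = TRUE)
    p <- pairs_df(umis, names = sprintf("r%04d", seq_along(umis)))
    for (method in c("exact", "directional")) {
      d1 <- dedup_pairs(p, method)
      expect_lte(d1$stats$n_kept, nrow(p))
      d2 <- dedup_pairs(d1$kept, method)
      expect_identical(d2$kept, d1$kept)  # idempotent
    }
    expect_lte(dedup_pairs(p, "directional")$stats$n_kept,
               dedup_pairs(p, "exact")$stats$n_kept)
  }
  # all-distinct UMIs: kept == input
  pu <- pairs_df(c("AAAA", "CCGG", "GTCA"))
  expect_identical(dedup_pairs(pu, "directional")$stats$n_kept, 3L)
})

test_that("mixed UMI lengths are rejected", {
  expect_error(dedup_pairs(pairs_df(c("AAAA", "AAAAA")), "exact"), "mixed")
})

test_that("dedup moves allele frequency toward truth under biased PCR", {
  # hap1 (alt at site A) amplified 5x, hap2 2x: raw read counts are
  # biased toward alt; UMI collapse must undo most of it
  cfg <- sim_config(n_pairs = 600, hap1_fraction = 0.5,
                    sub_error_rate = 0, seed = 19,
                    pcr_duplication_mean = c(5, 2))
  sim <- simulate_pairs(cfg)
  cp <- sim$contexts$A
  raw_calls <- merge_mate_calls(
    match_allele(sim$reads$seq1, cp, both_strands = TRUE),
    match_allele(sim$reads$seq2, cp, both_strands = TRUE))
  raw_freq <- mean(raw_calls[raw_calls %in% c("REF", "ALT")] == "ALT")

  res <- run_phase_analysis(sim$reads, cfg$ref_amplicon, cfg$variant_a,
                            cfg$variant_b, dedup_method = "directional")
  sa <- res$site_counts[[1]]
  dedup_freq <- sa$n_alt / sa$depth
  expect_gt(abs(raw_freq - 0.5), abs(dedup_freq - 0.5))
  expect_lt(abs(dedup_freq - 0.5), 0.05)
})
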