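test_that("sim_config validates and fills defaults", {
  cfg <- sim_config(seed = 1)
  expect_identical(nchar(cfg$ref_amplicon), 621L)
  expect_identical(cfg$read_len, 250L)
  expect_identical(cdna_span(cfg$variant_a$gpos, cfg$variant_b$gpos), 464L)
  expect_error(sim_config(hap1_fraction = 0), "hap1_fraction")
  expect_error(sim_config(sub_error_rate = 0.5), "sub_error_rate")
  expect_error(sim_config(ref_amplicon = "ACGT"), "together")
  # overlapping variants rejected
  expect_error(
    sim_config(ref_amplicon = strrep("ACGT", 100),
               variant_a = variant("amp", 10, "G", "GG"),
               variant_b = variant("amp", 10, "T", "C"), read_len = 50),
    "left of|overlap")
})

test_that("build_haplotypes applies edits with correct bookkeeping", {
  amp <- "AACCGGTTACGTACGTACGT"
  va <- variant("amp", 3, "C", "A")
  vb <- variant("amp", 10, "C", "G")
  cis <- build_haplotypes(amp, va, vb, "CIS")
  expect_identical(substr(cis[1], 3, 3), "A")
  expect_identical(substr(cis[1], 10, 10), "G")
  expect_identical(cis[2], amp)

  vins <- variant("amp", 5, "G", "GG")
  tr <- build_haplotypes(amp, vins, vb, "TRANS")
  expect_identical(nchar(tr[1]), nchar(amp) + 1L)
  expect_identical(nchar(tr[2]), nchar(amp))

  expect_error(build_haplotypes(amp, variant("amp", 9, "AC", "A"),
                                variant("amp", 10, "C", "G"), "CIS"),
               "overlap")
})

test_that("each haplotype presents exactly one context per site", {
  cfg <- sim_config(seed = 23)
  haps <- build_haplotypes(cfg$ref_amplicon, cfg$variant_a, cfg$variant_b,
                           "TRANS")
  for (h in 1:2) for (site in c("A", "B")) {
    sim <- simulate_pairs(cfg)  # for contexts only
    cp <- sim$contexts[[site]]
    ref_in <- grepl(cp$ref_context, haps[h], fixed = TRUE)
    alt_in <- grepl(cp$alt_context, haps[h], fixed = TRUE)
    expect_true(xor(ref_in, alt_in),
                info = sprintf("hap %d site %s", h, site))
  }
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_pairs = 100, seed = 1)
  s1 <- simulate_pairs(cfg)
  s2 <- simulate_pairs(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  # byte-identical FASTQ
  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_fastq_pairs(s1$reads, f1, f2)
  write_fastq_pairs(s2$reads, g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
  s3 <- simulate_pairs(sim_config(n_pairs = 100, seed = 2))
  expect_false(identical(s1$reads$seq1, s3$reads$seq1))
})

test_that("every truth record corresponds to one emitted pair", {
  sim <- simulate_pairs(sim_config(n_pairs = 120, seed = 8))
  expect_identical(nrow(sim$reads), nrow(sim$truth))
  expect_identical(sim$reads$name, sim$truth$name)
  expect_false(anyDuplicated(sim$reads$name) > 0)
  # duplicate_of refers to an existing original
  expect_true(all(sim$truth$duplicate_of %in% sim$truth$name))
})

test_that("amplicon mode with zero error is fully double-informative", {
  cfg <- sim_config(n_pairs = 150, sub_error_rate = 0,
                    pcr_duplication_mean = 1, seed = 4)
  sim <- simulate_pairs(cfg)
  expect_true(all(sim$truth$spans_a & sim$truth$spans_b))
  res <- run_phase_analysis(sim$reads, cfg$ref_amplicon, cfg$variant_a,
                            cfg$variant_b, umi_scheme = "none")
  expect_identical(res$both_site_fraction, 1)
})

test_that("observed haplotype fraction is within 3 binomial SE", {
  for (f in c(0.3, 0.5, 0.65)) {
    cfg <- sim_config(n_pairs = 2000, hap1_fraction = f,
                      pcr_duplication_mean = 1, seed = 17)
    sim <- simulate_pairs(cfg)
    mol <- !duplicated(sim$truth$duplicate_of)
    obs <- mean(sim$truth$haplotype[mol] == 1L)
    se <- sqrt(f * (1 - f) / sum(mol))
    expect_lt(abs(obs - f), 3 * se)
  }
})

test_that("fragmentation mode lowers the both-site informative fraction", {
  base <- list(n_pairs = 400, sub_error_rate = 0,
               pcr_duplication_mean = 1, seed = 31)
  amp <- do.call(sim_config, c(base, library_mode = "amplicon"))
  fr <- do.call(sim_config, c(base, library_mode = "fragmentation"))
  run <- function(cfg) {
    sim <- simulate_pairs(cfg)
    run_phase_analysis(sim$reads, cfg$ref_amplicon, cfg$variant_a,
                       cfg$variant_b, umi_scheme = "none")
  }
  expect_lt(run(fr)$both_site_fraction, run(amp)$both_site_fraction)
})

test_that("per-haplotype PCR duplication bias shows up in raw reads", {
  cfg <- sim_config(n_pairs = 400, pcr_duplication_mean = c(4, 1),
                    sub_error_rate = 0, seed = 41)
  sim <- simulate_pairs(cfg)
  t1 <- table(sim$truth$haplotype)
  mol <- !duplicated(sim$truth$duplicate_of)
  t0 <- table(sim$truth$haplotype[mol])
  expect_gt(t1[["1"]] / sum(t1), t0[["1"]] / sum(t0))
})
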