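## Paired-end targeted cDNA amplicon read simulator.
##
## Emulates sequencing of a two-variant amplicon RT-PCR product
## (default geometry: a 621 bp amplicon read as 2 x 250 bp) under two
## library models:
##   amplicon      - direct adapter ligation: every fragment is the
##                   full-length molecule, so the two mates read inward
##                   from the amplicon ends and can jointly span both
##                   variant sites;
##   fragmentation - tagmentation-style: fragment length drawn from a
##                   truncated normal, so most pairs cover only one
##                   site.
## Every emitted pair carries a per-molecule UMI and a ground-truth
## record, making the simulator the oracle for the rest of the package.

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Default 621 bp amplicon: random background with two embedded variant
## neighbourhoods 464 bases apart (inclusive) -- an SNV site (C>T) at
## position 80 and a single-G insertion site inside a 6-G run at
## position 543.
.default_amplicon_len <- 621L
.site_a_window <- "CCCGTGGACC"   # SNV C at window offset 8 -> pos 80
.site_a_pos <- 80L
.site_b_window <- "ATGGGGGGCG"   # last run G at window offset 7 -> pos 543
.site_b_pos <- 543L

.default_amplicon <- function() {
  s <- .random_dna(.default_amplicon_len)
  substr(s, .site_a_pos - 8L, .site_a_pos + 1L) <- .site_a_window
  substr(s, .site_b_pos - 7L, .site_b_pos + 2L) <- .site_b_window
  s
}

#' Simulator configuration
#'
#' Defaults describe the targeted cDNA use case: a 621 bp amplicon
#' sequenced 2 x 250 bp, one SNV site and one homopolymer single-base
#' insertion site 464 bases apart (inclusive), heterozygous haplotypes
#' mixed 50:50, direct-adapter-ligation (amplicon) library, 8 bp UMIs.
#' When `ref_amplicon`/`variant_a`/`variant_b` are omitted, a random
#' amplicon with those two embedded sites is generated from `seed`.
#'
#' @param configuration `"TRANS"` (hap1 = alt_A+ref_B) or `"CIS"`
#'   (hap1 = alt_A+alt_B).
#' @param n_pairs Number of distinct molecules to simulate.
#' @param hap1_fraction Expression fraction of haplotype 1, in (0, 1).
#' @param ref_amplicon Reference amplicon sequence (ACGT).
#' @param variant_a,variant_b [variant()] objects whose `gpos` is the
#'   1-based position within `ref_amplicon`; `variant_a` must lie left
#'   of `variant_b`.
#' @param read_len Read length (default 250).
#' @param library_mode `"amplicon"` or `"fragmentation"`.
#' @param fragment_len_mean,fragment_len_sd Fragment length model for
#'   fragmentation mode (default 350 +/- 80, a typical tagmentation
#'   insert distribution).
#' @param sub_error_rate Per-base substitution error rate in \[0, 0.2\]
#'   (default 0.001, Illumina-like).
#' @param umi_len UMI length (default 8).
#' @param umi_scheme `"name_suffix"` or `"inline_prefix"`.
#' @param pcr_duplication_mean Mean emitted copies per molecule
#'   (>= 1); scalar, or length 2 for per-haplotype (allele-biased)
#'   duplication.  Default 2.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `"ap_sim_config"`.
#' @export
sim_config <- function(configuration = c("TRANS", "CIS"),
                       n_pairs = 2000L,
                       hap1_fraction = 0.5,
                       ref_amplicon = NULL,
                       variant_a = NULL, variant_b = NULL,
                       read_len = 250L,
                       library_mode = c("amplicon", "fragmentation"),
                       fragment_len_mean = 350, fragment_len_sd = 80,
                       sub_error_rate = 0.001,
                       umi_len = 8L,
                       umi_scheme = c("name_suffix", "inline_prefix"),
                       pcr_duplication_mean = 2,
                       seed = 1L) {
  configuration <- match.arg(configuration)
  library_mode <- match.arg(library_mode)
  umi_scheme <- match.arg(umi_scheme)
  seed <- as.integer(seed)
  if (is.null(ref_amplicon) || is.null(variant_a) || is.null(variant_b)) {
    if (!(is.null(ref_amplicon) && is.null(variant_a) && is.null(variant_b)))
      stop("supply ref_amplicon, variant_a and variant_b together, or none")
    withr_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    ref_amplicon <- .default_amplicon()
    if (!is.null(withr_seed)) assign(".Random.seed", withr_seed,
                                     envir = globalenv())
    variant_a <- variant("amplicon", .site_a_pos, "C", "T",
                         cdna_pos = .site_a_pos, label = "siteA_SNV")
    variant_b <- variant("amplicon", .site_b_pos, "G", "GG",
                         cdna_pos = .site_b_pos, label = "siteB_dupG")
  }
  ref_amplicon <- toupper(ref_amplicon)
  stopifnot(grepl("^[ACGT]+$", ref_amplicon),
            inherits(variant_a, "ap_variant"),
            inherits(variant_b, "ap_variant"))
  if (variant_a$gpos >= variant_b$gpos)
    stop("variant_a must lie left of variant_b within the amplicon")
  if (variant_a$gpos + nchar(variant_a$ref) - 1L >= variant_b$gpos)
    stop("variants overlap")
  n_pairs <- as.integer(n_pairs); read_len <- as.integer(read_len)
  umi_len <- as.integer(umi_len)
  stopifnot(n_pairs >= 1L, read_len >= 20L, umi_len >= 4L,
            read_len <= nchar(ref_amplicon),
            hap1_fraction > 0, hap1_fraction < 1,
            sub_error_rate >= 0, sub_error_rate <= 0.2,
            all(pcr_duplication_mean >= 1),
            length(pcr_duplication_mean) %in% c(1L, 2L))
  for (v in list(variant_a, variant_b))
    if (substr(ref_amplicon, v$gpos, v$gpos + nchar(v$ref) - 1L) != v$ref)
      stop("amplicon disagrees with ", v$label, " reference allele")
  structure(list(configuration = configuration, n_pairs = n_pairs,
                 hap1_fraction = hap1_fraction,
                 ref_amplicon = ref_amplicon,
                 variant_a = variant_a, variant_b = variant_b,
                 read_len = read_len, library_mode = library_mode,
                 fragment_len_mean = fragment_len_mean,
                 fragment_len_sd = fragment_len_sd,
                 sub_error_rate = sub_error_rate,
                 umi_len = umi_len, umi_scheme = umi_scheme,
                 pcr_duplication_mean = pcr_duplication_mean,
                 seed = seed),
            class = "ap_sim_config")
}

.apply_edits <- function(seq, edits) {
  # edits: list of ap_variant sorted by gpos; returns edited sequence
  out <- character(0)
  cur <- 1L
  for (v in edits) {
    out <- c(out, substr(seq, cur, v$gpos - 1L), v$alt)
    cur <- v$gpos + nchar(v$ref)
  }
  paste(c(out, substr(seq, cur, nchar(seq))), collapse = "")
}

#' Build the two haplotype sequences of an amplicon
#'
#' @param ref_amplicon Reference amplicon sequence.
#' @param variant_a,variant_b Non-overlapping [variant()] objects with
#'   amplicon-local `gpos`, `variant_a` left of `variant_b`.
#' @param configuration `"TRANS"`: hap1 = alt_A + ref_B, hap2 =
#'   ref_A + alt_B; `"CIS"`: hap1 = alt_A + alt_B, hap2 = reference.
#' @return Character vector `c(hap1, hap2)`.
#' @export
build_haplotypes <- function(ref_amplicon, variant_a, variant_b,
                             configuration = c("TRANS", "CIS")) {
  configuration <- match.arg(configuration)
  if (variant_a$gpos + nchar(variant_a$ref) - 1L >= variant_b$gpos)
    stop("overlapping edits")
  if (configuration == "TRANS")
    c(.apply_edits(ref_amplicon, list(variant_a)),
      .apply_edits(ref_amplicon, list(variant_b)))
  else
    c(.apply_edits(ref_amplicon, list(variant_a, variant_b)),
      ref_amplicon)
}

.add_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  flat <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    subs <- matrix(c("C", "G", "T",   # A ->
                     "A", "G", "T",   # C ->
                     "A", "C", "T",   # G ->
                     "A", "C", "G"),  # T ->
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
    flat[hit] <- subs[cbind(match(flat[hit], rownames(subs)),
                            sample.int(3L, length(hit), replace = TRUE))]
  }
  ends <- cumsum(lens)
  substring(paste(flat, collapse = ""), ends - lens + 1L, ends)
}

## Position of an amplicon-local site within a haplotype sequence,
## given the edits that haplotype carries.
.hap_pos <- function(pos, edits_present) {
  shift <- 0L
  for (v in edits_present)
    if (v$gpos < pos) shift <- shift + nchar(v$alt) - nchar(v$ref)
  pos + shift
}

#' Simulate paired-end amplicon reads with ground truth
#'
#' One molecule is drawn per `n_pairs` from haplotype 1 with
#' probability `hap1_fraction`; a fragment is taken (whole molecule in
#' amplicon mode, truncated-normal length at uniform start in
#' fragmentation mode); the two mates read `read_len` bases inward from
#' the fragment ends (mate 2 reverse-complemented); i.i.d. substitution
#' errors are applied; each molecule is emitted `1 + Poisson(mean - 1)`
#' times with a shared per-molecule UMI.  Deterministic given
#' `cfg$seed`.
#'
#' @param cfg An [sim_config()].
#' @return List with `reads` (data.frame `name`, `seq1`, `qual1`,
#'   `seq2`, `qual2`), `truth` (one row per emitted pair: `name`,
#'   `haplotype`, `umi`, `frag_start`, `frag_end`, `allele_a`,
#'   `allele_b`, `spans_a`, `spans_b`, `duplicate_of`), `contexts`
#'   (site A/B [build_contexts()] pairs), and `config`.
#' @export
simulate_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "ap_sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  haps <- build_haplotypes(cfg$ref_amplicon, cfg$variant_a, cfg$variant_b,
                           cfg$configuration)
  hlen <- nchar(haps)
  # per-haplotype allele truth
  if (cfg$configuration == "TRANS") {
    allele_a <- c("ALT", "REF"); allele_b <- c("REF", "ALT")
  } else {
    allele_a <- c("ALT", "REF"); allele_b <- c("ALT", "REF")
  }
  edits <- list(
    if (allele_a[1] == "ALT") list(cfg$variant_a) else list(),
    if (allele_a[2] == "ALT") list(cfg$variant_a) else list())
  edits[[1]] <- c(edits[[1]], if (allele_b[1] == "ALT") list(cfg$variant_b))
  edits[[2]] <- c(edits[[2]], if (allele_b[2] == "ALT") list(cfg$variant_b))

  cpa <- contexts_from_reference(cfg$ref_amplicon, cfg$variant_a$gpos,
                                 cfg$variant_a)
  cpb <- contexts_from_reference(cfg$ref_amplicon, cfg$variant_b$gpos,
                                 cfg$variant_b)
  # context interval of each site within each haplotype
  ctx_iv <- function(v, cp, hap_allele, hap_edits) {
    p <- .hap_pos(v$gpos, hap_edits)
    alen <- if (hap_allele == "ALT") nchar(v$alt) else nchar(v$ref)
    c(p - cp$flank_left, p + alen - 1L + cp$flank_right)
  }
  iva <- list(ctx_iv(cfg$variant_a, cpa, allele_a[1], edits[[1]]),
              ctx_iv(cfg$variant_a, cpa, allele_a[2], edits[[2]]))
  ivb <- list(ctx_iv(cfg$variant_b, cpb, allele_b[1], edits[[1]]),
              ctx_iv(cfg$variant_b, cpb, allele_b[2], edits[[2]]))

  n <- cfg$n_pairs
  hap <- ifelse(stats::runif(n) < cfg$hap1_fraction, 1L, 2L)
  mlen <- hlen[hap]

  if (cfg$library_mode == "amplicon") {
    fstart <- rep(1L, n)
    flen <- mlen
  } else {
    flen <- as.integer(round(stats::rnorm(n, cfg$fragment_len_mean,
                                          cfg$fragment_len_sd)))
    flen <- pmin(pmax(flen, 50L), mlen)
    fstart <- 1L + as.integer(floor(stats::runif(n) * (mlen - flen + 1L)))
  }
  fend <- fstart + flen - 1L

  umi <- do.call(paste0, as.data.frame(
    matrix(sample(c("A", "C", "G", "T"), n * cfg$umi_len, replace = TRUE),
           nrow = n), stringsAsFactors = FALSE))

  lambda <- cfg$pcr_duplication_mean
  if (length(lambda) == 1L) lambda <- rep(lambda, 2L)
  k <- 1L + stats::rpois(n, lambda[hap] - 1)

  # expand molecules to emitted pairs
  mol <- rep.int(seq_len(n), k)
  dupi <- sequence(k)
  frag <- substr(haps[hap], fstart, fend)[mol]
  r1 <- substr(frag, 1L, cfg$read_len)
  r2 <- .revcomp(substr(frag, pmax(1L, nchar(frag) - cfg$read_len + 1L),
                        nchar(frag)))
  r1 <- .add_errors(r1, cfg$sub_error_rate)
  r2 <- .add_errors(r2, cfg$sub_error_rate)

  base <- sprintf("SIM%06d.%d", mol, dupi)
  name <- base
  if (cfg$umi_scheme == "name_suffix") {
    name <- paste0(base, "_", umi[mol])
  } else {
    r1 <- paste0(umi[mol], r1)
  }
  q1 <- strrep("F", nchar(r1))
  q2 <- strrep("F", nchar(r2))

  # truth: does the mate union cover each site's context interval?
  r1s <- fstart[mol]; r1e <- pmin(fend[mol], fstart[mol] + cfg$read_len - 1L)
  r2e <- fend[mol];   r2s <- pmax(fstart[mol], fend[mol] - cfg$read_len + 1L)
  covered <- function(iv_by_hap) {
    lo <- vapply(iv_by_hap, `[`, integer(1), 1L)[hap[mol]]
    hi <- vapply(iv_by_hap, `[`, integer(1), 2L)[hap[mol]]
    (r1s <= lo & r1e >= hi) | (r2s <= lo & r2e >= hi)
  }
  spans_a <- covered(iva)
  spans_b <- covered(ivb)

  truth <- data.frame(
    name = name,
    haplotype = hap[mol],
    umi = umi[mol],
    frag_start = fstart[mol],
    frag_end = fend[mol],
    allele_a = allele_a[hap[mol]],
    allele_b = allele_b[hap[mol]],
    spans_a = spans_a,
    spans_b = spans_b,
    duplicate_of = if (cfg$umi_scheme == "name_suffix")
      paste0(sprintf("SIM%06d.1", mol), "_", umi[mol])
    else sprintf("SIM%06d.1", mol),
    stringsAsFactors = FALSE)

  list(reads = data.frame(name = name, seq1 = r1, qual1 = q1,
                          seq2 = r2, qual2 = q2,
                          stringsAsFactors = FALSE),
       truth = truth,
       contexts = list(A = cpa, B = cpb),
       config = cfg)
}
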